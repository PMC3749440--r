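test_that("deflection histograms are normalized on uniform bins", {
  set.seed(61)
  x <- c(rnorm(3e4, 0, 0.6), rnorm(3e4, 3, 0.6))
  h <- deflection_histogram(x, 0.25)
  expect_equal(sum(h$density) * attr(h, "bin_width"), 1, tolerance = 1e-12)
  expect_equal(diff(h$bin_center), rep(0.25, nrow(h) - 1), tolerance = 1e-9)
  # two modes at the component means within a bin width
  m <- mode_positions(h)
  expect_length(m, 2)
  expect_lt(abs(m[1] - 0), 0.25)
  expect_lt(abs(m[2] - 3), 0.25)
  # degenerate data: one occupied bin
  h1 <- deflection_histogram(rep(2.2, 1500), 0.25)
  expect_identical(sum(h1$count > 0), 1L)
  expect_error(deflection_histogram(c(rnorm(999)), 0.25), "1000")
  expect_error(deflection_histogram(c(rnorm(2000), NA)), "finite")
})

test_that("the PSF is the centered control density", {
  set.seed(62)
  x <- rnorm(5e4, mean = 412, sd = 1.2)
  psf <- estimate_psf(x, 0.25)
  expect_equal(attr(psf, "sd"), 1.2, tolerance = 0.02)
  expect_equal(sum(psf$density) * 0.25, 1, tolerance = 1e-12)
  expect_equal(sum(psf$offset_nm * psf$density) * 0.25, 0, tolerance = 0.02)
  # constant control: delta-like, single occupied bin
  psf0 <- estimate_psf(rep(7, 2000), 0.25)
  expect_identical(sum(psf0$density > 0), 1L)
  # a contaminated (bimodal) control is rejected
  bim <- c(rnorm(2e4, 0, 0.5), rnorm(2e4, 4, 0.5))
  expect_error(estimate_psf(bim, 0.25), "bimodal")
})

test_that("deconvolution inverts the forward blur", {
  h <- mixture_histogram(sep = 3, mode_sd = 0.6)
  psf <- gaussian_psf(1.0, 0.25)
  m <- convolve_histogram(h, psf)
  dec <- deconvolve(m, psf)
  modes <- mode_positions(dec)
  expect_length(modes, 2)
  expect_lt(abs(modes[1] - 0), 0.25 + 1e-9)       # positions within 1 bin
  expect_lt(abs(modes[2] - 3), 0.25 + 1e-9)
  expect_lt(abs(diff(modes) - 3) / 3, 0.10)       # separation within 10%
  # reconvolution residual not worse than that of the blurred input
  rn <- function(p) sqrt(sum((rigidlink:::convolve_density(p, psf) -
                                m$density)^2))
  expect_lte(rn(dec$density), rn(m$density))
  expect_true(all(dec$density >= 0))
  expect_equal(sum(dec$density) * 0.25, 1, tolerance = 1e-9)
})

test_that("a delta PSF leaves the histogram unchanged", {
  h <- mixture_histogram(sep = 2, mode_sd = 0.5)
  delta <- structure(data.frame(offset_nm = 0, density = 4),
                     sd = 0, force = NA_real_, bin_width = 0.25,
                     zero_index = 1L, class = c("psf", "data.frame"))
  expect_equal(convolve_histogram(h, delta)$density, h$density,
               tolerance = 1e-12)
  dec <- deconvolve(h, delta, max_iter = 200)
  expect_equal(density_on(dec, h$bin_center), h$density, tolerance = 1e-9)
})

test_that("deconvolution round trip is accurate for resolvable modes", {
  psf <- gaussian_psf(1.0, 0.25)
  for (sep in c(2, 2.5, 3)) {  # separations >= 2 psf SDs
    h <- mixture_histogram(sep = sep, mode_sd = 0.8)
    dec <- deconvolve(convolve_histogram(h, psf), psf)
    expect_lt(l2_error(dec, h), 0.05)
  }
})

test_that("Boltzmann inversion turns densities into free energies", {
  # uniform density: flat landscape at zero
  hu <- structure(data.frame(bin_center = seq(0, 5, 0.25),
                             count = NA_integer_,
                             density = rep(1 / 5.25, 21)),
                  bin_width = 0.25, class = c("defl_histogram", "data.frame"))
  Lu <- boltzmann_invert(hu)
  expect_true(all(abs(Lu$G_pNnm) < 1e-12))
  # density ratio e gives exactly kT
  h2 <- hu
  h2$density <- c(rep(exp(1), 10), rep(1, 11))
  h2$density <- h2$density / (sum(h2$density) * 0.25)
  L2 <- boltzmann_invert(h2)
  expect_equal(max(L2$G_pNnm) - min(L2$G_pNnm), 4.18, tolerance = 1e-9)
  # two-Gaussian fixture: double well with a barrier between the minima
  h3 <- mixture_histogram(sep = 3, mode_sd = 0.6)
  L3 <- boltzmann_invert(h3)
  expect_identical(min(L3$G_pNnm, na.rm = TRUE), 0)
  wells <- mode_positions(h3)
  iw <- vapply(wells, function(w) which.min(abs(L3$coordinate_nm - w)),
               integer(1))
  ib <- which.min(abs(L3$coordinate_nm - 1.5))
  expect_gt(L3$G_pNnm[ib], max(L3$G_pNnm[iw]))
  # bins below the density floor are NA, not infinite
  expect_true(anyNA(L3$G_pNnm))
  expect_false(any(is.infinite(L3$G_pNnm), na.rm = TRUE))
})

test_that("landscapes tolerate sub-bin shifts of the histogram origin", {
  set.seed(63)
  x <- c(rnorm(4e4, 0, 0.6), rnorm(4e4, 3, 0.6))
  h1 <- deflection_histogram(x, 0.25)
  h2 <- deflection_histogram(x + 0.1, 0.25)  # origin shift < bin/2
  L1 <- boltzmann_invert(h1)
  L2 <- boltzmann_invert(h2)
  m1 <- mode_positions(h1)
  m2 <- mode_positions(h2) - 0.1
  expect_equal(m1, m2, tolerance = 0.25 + 1e-9)
})

test_that("the contour-length transform is a bounded monotone rescaling", {
  h <- mixture_histogram(sep = 3, mode_sd = 0.6)
  L <- boltzmann_invert(h)
  ss <- polymer_model("wlc", L = 15, p = 1)
  suppressWarnings(Lc <- to_contour_length(L, ss, force = 6.25, offset = 0))
  ok <- Lc$coordinate_nm >= 0
  expect_true(all(diff(Lc$coordinate_nm) > 0))  # strictly monotone
  # zero extension maps to zero contour at zero offset
  i0 <- which.min(abs(Lc$coordinate_nm))
  expect_lt(Lc$coordinate_nm[i0], 0.25 / rigidlink:::ms_rel_extension(
    6.25 * 1 / 4.18))
  # the offset magnitude is bounded by 5 nm
  expect_error(to_contour_length(L, ss, force = 6.25, offset = 7), "5 nm")
  suppressWarnings(La <- to_contour_length(L, ss, force = 6.25))
  expect_lte(abs(attr(La, "offset")), 5)
  # auto offset puts the small-contour minimum at zero
  imin <- which.min(La$G_pNnm[La$coordinate_nm < median(La$coordinate_nm)])
  expect_lt(abs(La$coordinate_nm[imin]), 0.5)
})

test_that("a landscape blurred with a broad PSF matches its broad-PSF view", {
  # sample from the narrow-PSF and broad-PSF measurements of the same
  # two-state density, deconvolve the sharp one, reconvolve with the
  # broad kernel, and compare with the broad measurement by chi-square
  set.seed(64)
  n <- 4e4
  states <- sample(c(0, 3), n, replace = TRUE)
  sharp <- states + rnorm(n, 0, 0.7)
  broad <- states + rnorm(n, 0, 1.4)
  h_sharp <- deflection_histogram(sharp, 0.25)
  dec <- deconvolve(h_sharp, gaussian_psf(0.7, 0.25))
  pred <- convolve_histogram(dec, gaussian_psf(1.4, 0.25))
  predf <- splinefun(pred$bin_center, pred$density, method = "monoH.FC")
  h_broad <- deflection_histogram(broad, 0.25)
  E <- pmax(predf(h_broad$bin_center), 0) * n * 0.25
  keep <- E >= 5
  chi2 <- sum((h_broad$count[keep] - E[keep])^2 / E[keep])
  df <- sum(keep) - 1
  expect_gt(pchisq(chi2, df, lower.tail = FALSE), 0.01)
})
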