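test_that("WLC force law matches the interpolation formula and its domain", {
  w <- ssdna_model()  # p = 1 nm, L = 15 nm
  expect_identical(wlc_force(0, w), 0)
  # independent evaluation of (kT/p)[1/(4(1-z)^2) - 1/4 + z] at z = 1/2
  expect_equal(wlc_force(7.5, w), 4.18 * (1 / (4 * 0.25) - 0.25 + 0.5),
               tolerance = 1e-12)
  expect_equal(wlc_force(7.5, w), 5.225, tolerance = 1e-6)
  # monotone divergence towards the contour length
  f <- wlc_force(c(0.5, 0.9, 0.99) * 15, w)
  expect_true(all(diff(f) > 0))
  expect_error(wlc_force(15, w), "contour")
  expect_error(wlc_force(-1, w), ">= 0")
})

test_that("eWLC extension inverts the extensible Marko-Siggia relation", {
  e <- dsdna_model()  # p = 50, L = 530, K = 1000
  expect_identical(ewlc_extension(0, e), 0)
  x <- ewlc_extension(10, e)
  expect_equal(x, 511, tolerance = 1e-3)
  # the solution satisfies the defining relation to high accuracy
  l <- x / e$L - 10 / e$K
  expect_equal((4.18 / 50) * (1 / (4 * (1 - l)^2) - 0.25 + l), 10,
               tolerance = 1e-9)
  # K -> Inf reduces to the inextensible WLC inverse
  e_inf <- polymer_model("ewlc", L = 530, p = 50, K = Inf)
  F <- c(0.5, 2, 10, 30)
  expect_equal(ewlc_extension(F, e_inf),
               vapply(F, function(f) {
                 uniroot(function(x) wlc_force(x, polymer_model("wlc",
                   L = 530, p = 50)) - f, c(0, 529.999), tol = 1e-12)$root
               }, numeric(1)),
               tolerance = 1e-7)
  # strictly increasing in force
  expect_true(all(diff(ewlc_extension(seq(0.1, 40, by = 0.1), e)) > 0))
})

test_that("eFJC extension is the Langevin chain with enthalpic stretch", {
  f <- bundle_model()  # L = 485, K = 10000, 2 segments
  expect_identical(efjc_extension(0, f), 0)
  # hand evaluation: b = 242.5, u = 2*242.5/4.18
  b <- 242.5; u <- 2 * b / 4.18
  expect_equal(efjc_extension(2, f),
               485 * (1 / tanh(u) - 1 / u) * (1 + 2 / 10000),
               tolerance = 1e-12)
  expect_equal(efjc_extension(2, f), 480.9, tolerance = 1e-4)
  # high-force asymptote L (1 + F/K)
  expect_equal(efjc_extension(100, f), 485 * (1 + 100 / 10000),
               tolerance = 2e-3)
  expect_error(polymer_model("efjc", L = 485, K = 1e4, n_segments = 0),
               "n_segments")
})

test_that("series composition adds extensions at common tension", {
  f <- bundle_model(); w <- ssdna_model()
  expect_equal(series_extension(3, list(f)), efjc_extension(3, f))
  expect_equal(series_extension(2, list(f, f)), 2 * efjc_extension(2, f))
  # at the force that stretches the ssDNA handle to 7.5 nm, the chain
  # extension is the bundle extension plus 7.5 nm
  F <- wlc_force(7.5, w)
  expect_equal(series_extension(F, list(f, w)),
               efjc_extension(F, f) + 7.5, tolerance = 1e-9)
})

test_that("stretch energy integrates the force law", {
  hk <- polymer_model("hooke", k = 0.4)
  expect_identical(stretch_energy(0, hk), 0)
  expect_equal(stretch_energy(3, hk), 0.5 * 0.4 * 9, tolerance = 1e-12)
  # WLC closed form against a trapezoid-rule oracle at 1e4 points
  w <- ssdna_model()
  xg <- seq(0, 7.5, length.out = 1e4)
  oracle <- sum(diff(xg) * (wlc_force(xg[-1], w) +
                            wlc_force(xg[-length(xg)], w)) / 2)
  expect_equal(stretch_energy(7.5, w), oracle, tolerance = 1e-4)
  # quadrature path (eWLC) against a parametric trapezoid oracle:
  # E = integral F dx along the explicit x(F) curve up to F = 10 pN
  e <- dsdna_model()
  Fg <- seq(0, 10, length.out = 1e4)
  xg2 <- ewlc_extension(Fg, e)
  oracle_e <- sum(0.5 * (Fg[-1] + Fg[-length(Fg)]) * diff(xg2))
  expect_equal(stretch_energy(max(xg2), e), oracle_e, tolerance = 1e-4)
  # convexity of the WLC energy
  Ew <- stretch_energy(seq(0, 13.5, by = 0.5), w)
  expect_true(all(diff(diff(Ew)) > 0))
})

test_that("force-extension round trips are accurate to 1e-6 relative", {
  th <- thermal()
  models <- list(wlc = ssdna_model(), ewlc = dsdna_model(),
                 efjc = bundle_model())
  for (m in models) {
    z <- seq(0.01, 0.95, by = 0.05)
    x <- z * m$L
    F <- model_force(x, m, th)
    expect_equal(model_extension(F, m, th), x, tolerance = 1e-6)
  }
})

test_that("the two-segment eFJC bundle is stiffer than the eWLC dsDNA", {
  # local stiffness dF/dx compared across the working force range; this is
  # the design premise of the rigid-linker system
  f <- bundle_model(); e <- dsdna_model()
  h <- 1e-3
  for (F in seq(1, 10, by = 1)) {
    k_efjc <- h / (efjc_extension(F + h, f) - efjc_extension(F, f))
    k_ewlc <- h / (ewlc_extension(F + h, e) - ewlc_extension(F, e))
    expect_gt(k_efjc, k_ewlc)
  }
})

test_that("expected bundle stiffness is N K / L", {
  expect_equal(expected_stiffness(10, 1000, 250), 40)
  expect_equal(expected_stiffness(1, 1200, 300), 4)
  expect_equal(expected_stiffness(8, 1000, 321), 2 * expected_stiffness(4, 1000, 321))
})

test_that("model constructors validate their parameters", {
  expect_error(polymer_model("wlc", L = 15), "p")
  expect_error(polymer_model("wlc", L = -1, p = 1))
  expect_error(polymer_model("ewlc", L = 530, p = 50), "K")
  expect_s3_class(polymer_model("wlc", L = 15, p = 1), "polymer_model")
})
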