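#' Deflection histogram
#'
#' Normalized density of the deflection (or extension) states visited by a
#' constant-trap-distance trace, on uniform bins spanning the data. The
#' default bin width of 0.25 nm is about a quarter of the typical
#' point-spread-function SD.
#'
#' @param signal Numeric signal, nm; at least 1000 samples.
#' @param bin_width Bin width, nm.
#' @return A `defl_histogram`: data frame with `bin_center`, `count`,
#'   `density`; `bin_width` is carried as an attribute.
#' @export
deflection_histogram <- function(signal, bin_width = 0.25) {
  if (any(!is.finite(signal)))
    stop("signal contains non-finite values", call. = FALSE)
  if (length(signal) < 1000)
    stop("need at least 1000 samples for a meaningful histogram",
         call. = FALSE)
  stopifnot(bin_width > 0)
  lo <- floor(min(signal) / bin_width) * bin_width - bin_width / 2
  hi <- ceiling(max(signal) / bin_width) * bin_width + bin_width / 2
  breaks <- seq(lo, hi, by = bin_width)
  counts <- as.integer(table(cut(signal, breaks = breaks,
                                 include.lowest = TRUE)))
  out <- data.frame(bin_center = (head(breaks, -1) + tail(breaks, -1)) / 2,
                    count = counts,
                    density = counts / (length(signal) * bin_width))
  attr(out, "bin_width") <- bin_width
  class(out) <- c("defl_histogram", "data.frame")
  out
}

# Local maxima of a density vector above a fraction of its peak.
density_modes <- function(d, frac = 0.1) {
  n <- length(d)
  if (n < 3) return(which.max(d))
  cand <- which(d[2:(n - 1)] >= d[1:(n - 2)] & d[2:(n - 1)] > d[3:n]) + 1L
  cand <- cand[d[cand] >= frac * max(d)]
  if (d[1] >= frac * max(d) && d[1] > d[2]) cand <- c(1L, cand)
  if (d[n] >= frac * max(d) && d[n] > d[n - 1]) cand <- c(cand, n)
  sort(unique(cand))
}

#' Empirical point-spread function from a hairpin-free control
#'
#' The measurement blur of the assay is estimated from a control construct
#' with no conformational transitions: the centered empirical density of
#' its extension signal. A control with two modes (above 10% of the peak,
#' more than 3 bins apart) is rejected as contaminated.
#'
#' @param control A `tweezer_trace` (its `extension_nm` is used and the
#'   mean of `force_pN` recorded) or a numeric signal.
#' @param bin_width Bin width, nm.
#' @param force Mean force to record when `control` is a bare vector, pN.
#' @return A `psf` object: data frame with `offset_nm` (bin centers,
#'   0-centered) and `density`; attributes `sd`, `force`, `bin_width`.
#' @export
estimate_psf <- function(control, bin_width = 0.25, force = NA_real_) {
  if (is.data.frame(control)) {
    force <- mean(control$force_pN)
    signal <- control$extension_nm
  } else signal <- control
  if (any(!is.finite(signal)))
    stop("control signal contains non-finite values", call. = FALSE)
  x <- signal - mean(signal)
  m <- max(1L, ceiling(max(abs(x)) / bin_width - 0.5) + 1L)
  breaks <- (seq(-m, m + 1L) - 0.5) * bin_width
  counts <- as.integer(table(cut(x, breaks = breaks, include.lowest = TRUE)))
  dens <- counts / (length(x) * bin_width)
  modes <- density_modes(dens, 0.1)
  if (length(modes) > 1 && max(diff(sort(modes))) > 3)
    stop("control appears bimodal (contaminated): modes at offsets ",
         paste(sprintf("%.2f", (modes - m - 1L) * bin_width), collapse = ", "),
         " nm", call. = FALSE)
  out <- data.frame(offset_nm = seq(-m, m) * bin_width, density = dens)
  attr(out, "sd") <- sd(x)
  attr(out, "force") <- force
  attr(out, "bin_width") <- bin_width
  attr(out, "zero_index") <- m + 1L
  class(out) <- c("psf", "data.frame")
  out
}

#' Gaussian point-spread function
#'
#' Analytic Gaussian fallback PSF for synthetic work, on the same grid
#' convention as [estimate_psf()].
#'
#' @param sd Gaussian SD, nm.
#' @param bin_width Bin width, nm.
#' @param half_width Grid half-extent in SDs.
#' @param force Force label, pN.
#' @return A `psf` object.
#' @export
gaussian_psf <- function(sd, bin_width = 0.25, half_width = 6,
                         force = NA_real_) {
  stopifnot(sd > 0)
  m <- ceiling(half_width * sd / bin_width)
  off <- seq(-m, m) * bin_width
  dens <- dnorm(off, 0, sd)
  dens <- dens / (sum(dens) * bin_width)
  out <- data.frame(offset_nm = off, density = dens)
  attr(out, "sd") <- sd
  attr(out, "force") <- force
  attr(out, "bin_width") <- bin_width
  attr(out, "zero_index") <- m + 1L
  class(out) <- c("psf", "data.frame")
  out
}

# Convolve a density (on the bins of `template`) with a psf sharing the
# same bin width. FFT-based full convolution, cut back to the input grid.
convolve_density <- function(density, psf) {
  bw <- attr(psf, "bin_width")
  k0 <- attr(psf, "zero_index")
  z <- convolve(density, rev(psf$density), type = "open")
  n <- length(density)
  bw * z[seq_len(n) + k0 - 1L]
}

#' Convolve a histogram with a point-spread function
#'
#' Forward model of the measurement: the true state density blurred by the
#' PSF. Grids must share the bin width. The result lives on the extended
#' support (input support widened by the PSF support), so no blurred mass
#' is clipped.
#'
#' @param hist A `defl_histogram`.
#' @param psf A `psf` object.
#' @return A `defl_histogram` on the extended bin grid.
#' @export
convolve_histogram <- function(hist, psf) {
  bw <- attr(hist, "bin_width")
  if (abs(bw - attr(psf, "bin_width")) > 1e-12)
    stop("histogram and psf bin widths differ", call. = FALSE)
  z <- convolve(hist$density, rev(psf$density), type = "open") * bw
  centers <- hist$bin_center[1] + min(psf$offset_nm) +
    bw * (seq_along(z) - 1)
  out <- data.frame(bin_center = centers, count = NA_integer_,
                    density = pmax(z, 0))
  attr(out, "bin_width") <- bw
  class(out) <- c("defl_histogram", "data.frame")
  out
}

#' Constrained iterative deconvolution of a deflection histogram
#'
#' Removes the measurement blur from a measured deflection histogram by
#' damped iterative refinement (Jansson-type additive updates): at each
#' step the current estimate is corrected by `damping` times the
#' reconvolution residual, clamped to non-negative values and
#' renormalized. Iteration stops when the best L2 reconvolution error has
#' not improved by more than `tol` (relative), or at `max_iter`; the
#' iterate with the smallest reconvolution error is returned.
#'
#' @param measured A `defl_histogram`.
#' @param psf A `psf` on the same bin width.
#' @param damping Fractional update step (default 0.5).
#' @param max_iter Iteration cap.
#' @param tol Relative improvement of the reconvolution error declaring
#'   convergence.
#' @return A `defl_histogram` with the deconvolved density; attributes
#'   `converged`, `iterations`, `reconvolution_error` (L2, density units).
#'   Non-convergence returns the best iterate with a warning.
#' @export
deconvolve <- function(measured, psf, damping = 0.5, max_iter = 1e4,
                       tol = 1e-8) {
  if (abs(attr(measured, "bin_width") - attr(psf, "bin_width")) > 1e-12)
    stop("measured histogram and psf bin widths differ", call. = FALSE)
  stopifnot(damping > 0, damping <= 1)
  bw <- attr(measured, "bin_width")
  m <- measured$density
  p <- m  # start from the measured density
  resid_norm <- function(p) sqrt(sum((convolve_density(p, psf) - m)^2))
  m_norm <- sqrt(sum(m^2))
  best <- p
  best_err <- resid_norm(p)
  window_err <- best_err
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    p <- p + damping * (m - convolve_density(p, psf))
    p[p < 0] <- 0
    s <- sum(p) * bw
    if (s <= 0) break
    p <- p / s
    err <- resid_norm(p)
    if (err < best_err) {
      best <- p
      best_err <- err
    }
    # windowed stopping: improvement of the best reconvolution error over
    # the last 100 iterations below tol (relative to the data norm)
    if (it %% 100L == 0L) {
      if (window_err - best_err < tol * m_norm) { converged <- TRUE; break }
      window_err <- best_err
    }
  }
  if (!converged && it >= max_iter)
    warning("deconvolution did not converge; returning best iterate")
  out <- measured
  out$density <- best
  out$count <- NA_integer_
  attr(out, "converged") <- converged
  attr(out, "iterations") <- it
  attr(out, "reconvolution_error") <- best_err
  out
}

#' Boltzmann inversion of a state density
#'
#' `G(x) = -kT log p(x)`, shifted so the minimum is zero. Bins whose
#' density falls below `floor` times the peak are undefined (`NA`), not
#' infinite.
#'
#' @param hist A `defl_histogram` (normalized density).
#' @param thermal A [thermal()] object.
#' @param floor Density floor as a fraction of the peak (default 1e-4).
#' @return An `energy_landscape`: data frame with `coordinate_nm` and
#'   `G_pNnm`; attribute `coordinate_kind = "extension"`.
#' @export
boltzmann_invert <- function(hist, thermal = rigidlink::thermal(),
                             floor = 1e-4) {
  d <- hist$density
  keep <- d > floor * max(d)
  G <- rep(NA_real_, length(d))
  G[keep] <- -thermal$kT * log(d[keep])
  G <- G - min(G, na.rm = TRUE)
  out <- data.frame(coordinate_nm = hist$bin_center, G_pNnm = G)
  attr(out, "coordinate_kind") <- "extension"
  attr(out, "kT") <- thermal$kT
  class(out) <- c("energy_landscape", "data.frame")
  out
}

#' Transform a landscape from extension to released contour length
#'
#' At fixed force the released ssDNA extends by the same relative fraction
#' `z(F)` per contour length (worm-like chain), so extension maps linearly
#' to contour length: `Lc = x / z(F)`, plus a small alignment offset that
#' puts the folded-state minimum at zero. The offset magnitude is bounded
#' by 5 nm.
#'
#' @param landscape An `energy_landscape` in extension coordinates.
#' @param elastic A `polymer_model` of kind `"wlc"` for the released ssDNA.
#' @param force Force at which the transform is evaluated, pN.
#' @param offset Contour-length shift, nm (`|offset| <= 5`); `NULL`
#'   auto-aligns the lowest-coordinate minimum to zero (clamped to 5 nm
#'   with a warning if a larger shift would be needed).
#' @param thermal A [thermal()] object.
#' @return An `energy_landscape` with `coordinate_kind = "contour"`.
#' @export
to_contour_length <- function(landscape, elastic, force, offset = NULL,
                              thermal = rigidlink::thermal()) {
  stopifnot(inherits(landscape, "energy_landscape"),
            attr(landscape, "coordinate_kind") == "extension",
            inherits(elastic, "polymer_model"), elastic$kind == "wlc",
            force > 0)
  if (!is.null(offset) && abs(offset) > 5)
    stop("offset magnitude must be at most 5 nm", call. = FALSE)
  z <- ms_rel_extension(force * elastic$p / thermal$kT)
  x <- landscape$coordinate_nm
  drop <- x < 0
  if (any(drop)) {
    warning(sprintf("dropping %d bins with negative extension", sum(drop)))
    landscape <- landscape[!drop, , drop = FALSE]
    x <- x[!drop]
  }
  Lc <- x / z
  if (is.null(offset)) {
    ok <- !is.na(landscape$G_pNnm)
    # folded (small-contour) minimum: lowest-G bin in the lower half
    lower <- ok & Lc <= median(Lc[ok])
    tgt <- if (any(lower)) Lc[lower][which.min(landscape$G_pNnm[lower])]
           else Lc[ok][which.min(landscape$G_pNnm[ok])]
    offset <- -tgt
    if (abs(offset) > 5) {
      warning("auto offset exceeds 5 nm; clamped")
      offset <- sign(offset) * 5
    }
  }
  if (abs(offset) > 5)
    stop("offset magnitude must be at most 5 nm", call. = FALSE)
  out <- data.frame(coordinate_nm = Lc + offset,
                    G_pNnm = landscape$G_pNnm)
  attr(out, "coordinate_kind") <- "contour"
  attr(out, "kT") <- attr(landscape, "kT")
  attr(out, "force") <- force
  attr(out, "offset") <- offset
  class(out) <- c("energy_landscape", "data.frame")
  out
}
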