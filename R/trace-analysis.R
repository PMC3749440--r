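#' Moving-window noise profile of a trace
#'
#' Standard deviation of the extension signal and mean force load in a
#' moving window (stride 1 sample), the standard way of quantifying the
#' force-dependent noise amplitude of a force-extension trace. The default
#' window is 200 samples.
#'
#' @param trace A `tweezer_trace`, or any data frame with `extension_nm`
#'   and `force_pN` columns.
#' @param window Window width in samples (>= 2).
#' @return A data frame of class `noise_profile` with columns
#'   `mean_force_pN` and `extension_sd_nm`, one row per complete window
#'   (right-aligned); `window` is carried as an attribute.
#' @export
noise_profile <- function(trace, window = 200) {
  stopifnot(window >= 2)
  x <- trace$extension_nm
  f <- trace$force_pN
  n <- length(x)
  if (n < window)
    stop(sprintf("trace length %d is shorter than window %d", n, window),
         call. = FALSE)
  sx <- data.table::frollsum(x, window)
  sxx <- data.table::frollsum(x * x, window)
  mu <- sx / window
  v <- pmax(0, (sxx - window * mu^2) / (window - 1))
  keep <- window:n
  out <- data.frame(mean_force_pN = data.table::frollmean(f, window)[keep],
                    extension_sd_nm = sqrt(v[keep]))
  attr(out, "window") <- window
  class(out) <- c("noise_profile", "data.frame")
  out
}

# Bin a noise profile onto a force grid (used to compare linker systems).
bin_noise_profile <- function(profile, breaks) {
  idx <- cut(profile$mean_force_pN, breaks = breaks)
  data.frame(force_mid = (head(breaks, -1) + tail(breaks, -1)) / 2,
             sd_nm = as.numeric(tapply(profile$extension_sd_nm, idx, mean)))
}

#' Apparent stiffness from a force-extension trace
#'
#' Least-squares slope of force versus extension over a force range,
#' the apparent linear extensibility `k_app` of a stretched construct.
#' For linkers much stiffer than the traps, `k_app` is limited by the
#' trap stiffness (via calibration-error propagation), not by the linker.
#'
#' @param trace A `tweezer_trace` or data frame with `force_pN` and
#'   `extension_nm`.
#' @param force_range `c(lower, upper)` in pN.
#' @param min_points Minimum number of samples required in the range.
#' @return `list(k_app, force_range, r_squared, n)` of class
#'   `stiffness_fit`.
#' @export
fit_apparent_stiffness <- function(trace, force_range, min_points = 50) {
  stopifnot(length(force_range) == 2L, force_range[2] > force_range[1])
  sel <- trace$force_pN >= force_range[1] & trace$force_pN <= force_range[2]
  if (sum(sel) < min_points)
    stop(sprintf("only %d samples in force range [%g, %g]", sum(sel),
                 force_range[1], force_range[2]), call. = FALSE)
  fit <- lm(force_pN ~ extension_nm, data = trace[sel, ])
  k <- unname(coef(fit)[2])
  if (!is.finite(k) || k <= 0)
    stop("apparent stiffness fit did not yield a positive slope",
         call. = FALSE)
  structure(list(k_app = k, force_range = force_range,
                 r_squared = summary(fit)$r.squared, n = sum(sel)),
            class = "stiffness_fit")
}

#' @export
print.stiffness_fit <- function(x, ...) {
  cat(sprintf("<stiffness_fit k_app = %.3g pN/nm over [%g, %g] pN, R2 = %.3f, n = %d>\n",
              x$k_app, x$force_range[1], x$force_range[2], x$r_squared, x$n))
  invisible(x)
}

#' Bead-contact detection from deflection correlation
#'
#' When two trapped beads are pushed into contact their deflection signals
#' become anti-correlated: the windowed Pearson r drops from about 0 to
#' about -0.5. The first sample at which the windowed correlation falls
#' below `threshold_r` marks the contact point, used as the zero-deflection
#' reference.
#'
#' @param defl1,defl2 Equal-length deflection series, nm.
#' @param window Correlation window in samples.
#' @param threshold_r Detection threshold (default -0.25, midway between 0
#'   and the contact value of about -0.5).
#' @return Index of the first sample whose trailing window has
#'   `r < threshold_r`, or `NA_integer_` if never.
#' @export
detect_contact <- function(defl1, defl2, window = 200, threshold_r = -0.25) {
  stopifnot(length(defl1) == length(defl2))
  n <- length(defl1)
  if (window > n)
    stop("window longer than the series", call. = FALSE)
  s1 <- data.table::frollsum(defl1, window)
  s2 <- data.table::frollsum(defl2, window)
  s11 <- data.table::frollsum(defl1 * defl1, window)
  s22 <- data.table::frollsum(defl2 * defl2, window)
  s12 <- data.table::frollsum(defl1 * defl2, window)
  num <- s12 - s1 * s2 / window
  den <- sqrt(pmax(0, s11 - s1^2 / window) * pmax(0, s22 - s2^2 / window))
  r <- ifelse(den > 0, num / den, 0)
  hit <- which(!is.na(r) & r < threshold_r)
  if (length(hit) == 0) NA_integer_ else hit[1]
}
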