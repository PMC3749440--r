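#' Mean squared end-to-end distance of a 2D-equilibrated semiflexible beam
#'
#' For a worm-like chain of persistence length `p` (3D convention) and
#' contour length `L` equilibrated in a plane, the tangent correlation is
#' `exp(-s/2p)` and
#' \deqn{\langle R^2\rangle = 4pL\left[1 - \frac{2p}{L}
#'   \left(1 - e^{-L/2p}\right)\right].}
#' Evaluated in a cancellation-safe form, so the rigid-rod limit
#' (`p >> L`, result `-> L^2`) is accurate.
#'
#' @param p Persistence length, nm (vectorised).
#' @param L Contour length, nm.
#' @return Mean squared end-to-end distance, nm^2.
#' @export
msd_end_to_end_2d <- function(p, L) {
  stopifnot(all(p > 0), all(L > 0))
  u <- L / (2 * p)
  # 4pL * (u - 1 + e^-u) / u  ==  closed form above, stable for small u
  4 * p * L * (u + expm1(-u)) / u
}

# Moving average with shrinking symmetric windows at the ends, so the
# endpoints stay (nearly) in place and no contour is clipped.
smooth_polyline <- function(xy, k) {
  if (k <= 1) return(xy)
  n <- nrow(xy)
  h <- (k - 1L) %/% 2L
  out <- xy
  for (i in seq_len(n)) {
    w <- min(h, i - 1L, n - i)
    idx <- (i - w):(i + w)
    out[i, ] <- colMeans(xy[idx, , drop = FALSE])
  }
  out
}

#' Backbone metrics of a traced polyline
#'
#' Contour length (arc length of the optionally smoothed polyline) and
#' end-to-end distance of one traced filament backbone. Smoothing is a
#' moving average of the vertex coordinates (odd window recommended) with
#' shrinking windows at the ends; it suppresses the contour-length
#' overestimate caused by tracing jitter.
#'
#' @param polyline An `n x 2` matrix of vertex coordinates, nm (`n >= 3`).
#' @param smoothing Moving-average window in points (1 = none).
#' @return A one-row data frame (`shape_sample`) with `contour_length` and
#'   `end_to_end` in nm.
#' @export
trace_backbone <- function(polyline, smoothing = 1) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 3 || ncol(polyline) != 2)
    stop("polyline must be an n x 2 matrix with n >= 3", call. = FALSE)
  xy <- smooth_polyline(polyline, smoothing)
  seg <- sqrt(rowSums(diff(xy)^2))
  data.frame(contour_length = sum(seg),
             end_to_end = sqrt(sum((xy[nrow(xy), ] - xy[1, ])^2)))
}

#' Backbone metrics for a whole ensemble
#'
#' @param chains List of polylines (as from [chain_ensemble_2d()]'s `true`
#'   or `noisy` element).
#' @param smoothing Moving-average window, points.
#' @return Data frame with one `shape_sample` row per chain.
#' @export
trace_backbones <- function(chains, smoothing = 1) {
  do.call(rbind, lapply(chains, trace_backbone, smoothing = smoothing))
}

#' Persistence length from end-to-end statistics
#'
#' Solves `msd_end_to_end_2d(p, mean contour) = mean(end_to_end^2)` for
#' `p` by root bracketing, with a bootstrap percentile confidence
#' interval. When the measured mean squared end-to-end distance is within
#' one standard error of the squared contour length the chains are
#' straight at the resolution of the tracing and only a lower bound on `p`
#' is meaningful (`lower_bound_only = TRUE`).
#'
#' @param samples Data frame with `contour_length` and `end_to_end`
#'   columns (>= 20 rows).
#' @param n_boot Bootstrap resamples for the CI.
#' @param conf Confidence level.
#' @param p_cap Upper search bound for `p`, nm.
#' @return `list(p_hat, ci_low, ci_high, lower_bound_only, n)` of class
#'   `persistence_fit`.
#' @export
fit_persistence_length <- function(samples, n_boot = 1000, conf = 0.95,
                                   p_cap = 1e7) {
  if (nrow(samples) < 20)
    stop("need at least 20 shape samples", call. = FALSE)
  Lbar <- mean(samples$contour_length)
  r2 <- samples$end_to_end^2
  mr2 <- mean(r2)
  se <- sd(r2) / sqrt(length(r2))
  if (mr2 > Lbar^2 + max(3 * se, 0.02 * Lbar^2))
    stop("mean squared end-to-end exceeds squared contour length beyond ",
         "noise tolerance; inputs inconsistent", call. = FALSE)
  solve_p <- function(target, L) {
    target <- min(target, msd_end_to_end_2d(p_cap, L))
    if (target <= msd_end_to_end_2d(1e-3, L)) return(1e-3)
    uniroot(function(pp) msd_end_to_end_2d(pp, L) - target,
            lower = 1e-3, upper = p_cap, tol = 1e-6)$root
  }
  p_hat <- solve_p(mr2, Lbar)
  lower_bound_only <- mr2 >= Lbar^2 - se
  boot <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(nrow(samples), replace = TRUE)
    solve_p(mean(samples$end_to_end[idx]^2),
            mean(samples$contour_length[idx]))
  }, numeric(1))
  a <- (1 - conf) / 2
  ci <- unname(quantile(boot, c(a, 1 - a)))
  structure(list(p_hat = p_hat, ci_low = ci[1], ci_high = ci[2],
                 lower_bound_only = lower_bound_only, n = nrow(samples),
                 mean_contour = Lbar),
            class = "persistence_fit")
}

#' @export
print.persistence_fit <- function(x, ...) {
  cat(sprintf("<persistence_fit p_hat = %.3g nm [%.3g, %.3g], n = %d%s>\n",
              x$p_hat, x$ci_low, x$ci_high, x$n,
              if (x$lower_bound_only) ", lower bound only" else ""))
  invisible(x)
}
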