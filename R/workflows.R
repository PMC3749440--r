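#' State-resolved force partition at constant trap distance
#'
#' Tunes the trap separation so that the folded-state mean force of a
#' hairpin construct matches `folded_force`, then measures the mean force
#' the system exerts in each hairpin state. The separation is first set by
#' the deterministic force balance and then corrected once from a
#' simulated estimate (secant step with the measured system stiffness), so
#' the reported folded-state mean matches the target within Monte-Carlo
#' error.
#'
#' @param config An [assay_config()] with a hairpin.
#' @param folded_force Target folded-state mean force, pN.
#' @param duration Simulated time per run, s.
#' @param rates `c(k_fold, k_unfold)` telegraph rates, 1/s.
#' @param tol Folded-state force tolerance that stops the correction, pN.
#' @param max_refine Maximum correction iterations.
#' @return `list(force_folded, force_unfolded, separation, extension_gap,
#'   trace)`.
#' @export
constant_distance_force_partition <- function(config, folded_force,
                                              duration = 2, rates = c(50, 50),
                                              tol = 0.03, max_refine = 2) {
  stopifnot(!is.null(config$hairpin))
  d <- separation_for_force(folded_force, config, "folded")
  # local stiffness of the folded branch: dF/dd
  h <- 0.5
  k_dd <- (equilibrium_force(d + h, config, "folded") -
           equilibrium_force(d - h, config, "folded")) / (2 * h)
  run <- function(d) {
    tr <- simulate_constant_distance(config, duration = duration,
                                     rates = rates, trap_separation = d)
    f <- tr$state == "folded"
    list(ff = mean(tr$force_pN[f]), fu = mean(tr$force_pN[!f]),
         gap = mean(tr$extension_nm[!f]) - mean(tr$extension_nm[f]),
         trace = tr)
  }
  res <- run(d)
  for (i in seq_len(max_refine)) {
    if (abs(res$ff - folded_force) <= tol) break
    d <- d + (folded_force - res$ff) / k_dd
    res <- run(d)
  }
  list(force_folded = res$ff, force_unfolded = res$fu, separation = d,
       extension_gap = res$gap, trace = res$trace)
}

#' Ensemble moving-window noise amplitude versus force
#'
#' Simulates `n_traces` force ramps and averages the moving-window
#' extension SD in force bins, the standard summary of linker-dependent
#' measurement noise.
#'
#' @param config An [assay_config()] (its seed, if any, is offset per
#'   trace).
#' @param n_traces Number of pulls.
#' @param max_force Per-pull force cap, pN.
#' @param breaks Force bin edges, pN.
#' @param window Moving-window width, samples.
#' @param seed Base seed; trace `i` uses `seed + i`.
#' @return Data frame with `force_mid` and the ensemble-mean `sd_nm`.
#' @export
ensemble_noise_sd <- function(config, n_traces = 20, max_force = 12,
                              breaks = 1:10, window = 200, seed = 1) {
  sds <- vapply(seq_len(n_traces), function(i) {
    cfg <- config
    cfg$seed <- seed + i
    tr <- simulate_pull(cfg, max_force = max_force)
    bin_noise_profile(noise_profile(tr, window), breaks)$sd_nm
  }, numeric(length(breaks) - 1))
  data.frame(force_mid = (head(breaks, -1) + tail(breaks, -1)) / 2,
             sd_nm = rowMeans(sds))
}
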