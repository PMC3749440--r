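#' Threshold (Schmitt-trigger) state assignment
#'
#' Assigns each sample to the folded (low) or unfolded (high) state. The
#' state flips only when the signal crosses `midpoint + hysteresis/2`
#' upward or `midpoint - hysteresis/2` downward, which suppresses spurious
#' flips from noise within the dead band.
#'
#' @param signal Numeric signal (extension or deflection), nm.
#' @param midpoint Threshold between the two levels, nm.
#' @param hysteresis Width of the dead band, nm.
#' @param sample_rate Sampling rate carried on the result, Hz.
#' @return Integer vector of class `state_sequence` with values 1 (low /
#'   folded) and 2 (high / unfolded), same length as `signal`.
#' @export
assign_states_threshold <- function(signal, midpoint, hysteresis = 0,
                                    sample_rate = NULL) {
  stopifnot(all(is.finite(signal)), hysteresis >= 0)
  hi <- midpoint + hysteresis / 2
  lo <- midpoint - hysteresis / 2
  s <- rep(NA_integer_, length(signal))
  s[signal > hi] <- 2L
  s[signal < lo] <- 1L
  s <- data.table::nafill(s, type = "locf")
  # leading dead-band samples: take the first decided state
  if (anyNA(s)) {
    first <- s[which(!is.na(s))[1]]
    if (is.na(first)) first <- if (mean(signal) > midpoint) 2L else 1L
    s[is.na(s)] <- first
  }
  structure(s, sample_rate = sample_rate, class = "state_sequence")
}

# Complete (uncensored) dwell times per state, in samples. The first and
# last runs touch the trace boundary and are censored, so they are dropped.
complete_dwells <- function(states) {
  r <- rle(as.integer(states))
  if (length(r$lengths) < 3L)
    return(list(s1 = integer(0), s2 = integer(0),
                n_transitions = length(r$lengths) - 1L))
  len <- r$lengths[-c(1L, length(r$lengths))]
  val <- r$values[-c(1L, length(r$values))]
  list(s1 = len[val == 1L], s2 = len[val == 2L],
       n_transitions = length(r$lengths) - 1L)
}

#' Rate constants from dwell-time analysis
#'
#' Maximum-likelihood exponential rates from the distribution of complete
#' dwell times: `k = 1 / mean(dwell)` per state, with standard error
#' `k / sqrt(n_dwells)`. Censored boundary dwells (first and last) are
#' excluded. State 1 is folded, state 2 unfolded, so the folded-state
#' dwells determine `k_unfold` and vice versa.
#'
#' @param states A `state_sequence` from [assign_states_threshold()] or an
#'   integer vector in `{1, 2}`.
#' @param sample_rate Sampling rate, Hz; taken from `states` if carried.
#' @param force Optional per-sample force, pN, to report state-conditional
#'   mean loads.
#' @return `list(k_unfold, k_fold, se_unfold, se_fold, n_dwells,
#'   mean_force_folded, mean_force_unfolded)` of class `rate_estimate`.
#' @export
dwell_rates <- function(states, sample_rate = attr(states, "sample_rate"),
                        force = NULL) {
  if (is.null(sample_rate))
    stop("sample_rate is required", call. = FALSE)
  dw <- complete_dwells(states)
  if (dw$n_transitions < 2L)
    stop("rate undefined: fewer than 2 transitions in the state sequence",
         call. = FALSE)
  if (length(dw$s1) == 0L || length(dw$s2) == 0L)
    stop("rate undefined: no complete dwell in one of the states",
         call. = FALSE)
  k_unfold <- sample_rate / mean(dw$s1)  # escape rate from folded
  k_fold <- sample_rate / mean(dw$s2)
  out <- list(k_unfold = k_unfold, k_fold = k_fold,
              se_unfold = k_unfold / sqrt(length(dw$s1)),
              se_fold = k_fold / sqrt(length(dw$s2)),
              n_dwells = c(folded = length(dw$s1),
                           unfolded = length(dw$s2)),
              mean_force_folded = if (is.null(force)) NA_real_ else
                mean(force[as.integer(states) == 1L]),
              mean_force_unfolded = if (is.null(force)) NA_real_ else
                mean(force[as.integer(states) == 2L]))
  class(out) <- "rate_estimate"
  out
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate k_unfold = %.3g +/- %.2g /s, k_fold = %.3g +/- %.2g /s (n = %d + %d dwells)>\n",
              x$k_unfold, x$se_unfold, x$k_fold, x$se_fold,
              x$n_dwells[1], x$n_dwells[2]))
  invisible(x)
}

#' Two-state Gaussian hidden-Markov fit
#'
#' Fits a two-state HMM with Gaussian emissions by expectation-maximization
#' (Baum-Welch), initialised from a median split of the signal. Transition
#' rates are derived from the per-sample transition probabilities as
#' `k_ij = a_ij * sample_rate` (exact in the small-probability limit; the
#' difference from `-fs log(1 - a)` is below 1% for `a < 0.02`, which holds
#' throughout the regimes here). The most probable state path is decoded by
#' Viterbi dynamic programming. The fit reports `converged = FALSE` when
#' the log-likelihood has not stabilised within `max_iter`, or when the
#' fitted means are closer than the pooled emission SD - the failure mode
#' of noise-dominated signals where the two populations are unresolvable.
#'
#' @param signal Numeric signal, length >= 1000.
#' @param sample_rate Sampling rate, Hz.
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood change declaring convergence.
#' @return `list(means, sds, transition, loglik, path, rates, converged)`
#'   of class `hmm_fit`; `path` is a `state_sequence` (1 = lower mean,
#'   2 = higher mean) and `rates` has `k_unfold`/`k_fold` (NULL when not
#'   converged).
#' @export
fit_hmm_two_state <- function(signal, sample_rate, max_iter = 500,
                              tol = 1e-6) {
  stopifnot(all(is.finite(signal)), length(signal) >= 1000, sample_rate > 0)
  med <- median(signal)
  lowv <- signal[signal <= med]; highv <- signal[signal > med]
  mu <- c(mean(lowv), mean(highv))
  sg <- rep(max(sd(signal) / 2, 1e-8), 2)
  A <- matrix(c(0.99, 0.01, 0.01, 0.99), 2, 2, byrow = TRUE)
  pi0 <- c(0.5, 0.5)
  ll_old <- -Inf
  converged_em <- FALSE
  for (it in seq_len(max_iter)) {
    es <- hmm_estep_cpp(signal, mu, sg, A, pi0)
    mu <- es$sum_x / es$N
    sg <- sqrt(pmax(es$sum_xx / es$N - mu^2, 1e-12))
    A <- es$xi / rowSums(es$xi)
    pi0 <- es$gamma1 / sum(es$gamma1)
    if (is.finite(ll_old) &&
        abs(es$loglik - ll_old) <= tol * abs(ll_old)) {
      converged_em <- TRUE
      ll_old <- es$loglik
      break
    }
    ll_old <- es$loglik
  }
  # order states by mean: 1 = low (folded), 2 = high (unfolded)
  ord <- order(mu)
  mu <- mu[ord]; sg <- sg[ord]; A <- A[ord, ord]; pi0 <- pi0[ord]
  pooled_sd <- sqrt(mean(sg^2))
  separated <- (mu[2] - mu[1]) > pooled_sd
  converged <- converged_em && separated
  path <- structure(hmm_viterbi_cpp(signal, mu, sg, A, pi0),
                    sample_rate = sample_rate, class = "state_sequence")
  rates <- if (converged)
    list(k_unfold = A[1, 2] * sample_rate,
         k_fold = A[2, 1] * sample_rate) else NULL
  structure(list(means = mu, sds = sg, transition = A, loglik = ll_old,
                 path = path, rates = rates, converged = converged,
                 sample_rate = sample_rate),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("<hmm_fit means = %.3g/%.3g nm, sds = %.3g/%.3g nm, converged = %s>\n",
              x$means[1], x$means[2], x$sds[1], x$sds[2], x$converged))
  if (!is.null(x$rates))
    cat(sprintf("  rates: k_unfold = %.3g /s, k_fold = %.3g /s\n",
                x$rates$k_unfold, x$rates$k_fold))
  invisible(x)
}

#' Force-dependent rate table from constant-distance traces
#'
#' Applies [dwell_rates()] to each (trace, state-sequence) pair and
#' aggregates the state-conditional mean forces and rate constants into a
#' table sorted by force, the ingredients of a rate-versus-load plot.
#' Traces whose rates are undefined (fewer than 2 transitions) are skipped
#' with a warning.
#'
#' @param traces List of `list(trace =, states =)` pairs; `trace` must have
#'   `force_pN` and `states` must match its length.
#' @return Data frame with columns `mean_force_folded`,
#'   `mean_force_unfolded`, `k_unfold`, `k_fold`, `se_unfold`, `se_fold`,
#'   `n_dwells`, sorted by `mean_force_folded`.
#' @export
force_dependent_rates <- function(traces) {
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]$trace
    st <- traces[[i]]$states
    fs <- attr(st, "sample_rate")
    if (is.null(fs)) fs <- attr(tr, "sample_rate")
    est <- tryCatch(dwell_rates(st, sample_rate = fs, force = tr$force_pN),
                    error = function(e) {
                      warning(sprintf("trace %d skipped: %s", i,
                                      conditionMessage(e)), call. = FALSE)
                      NULL
                    })
    if (is.null(est)) return(NULL)
    data.frame(mean_force_folded = est$mean_force_folded,
               mean_force_unfolded = est$mean_force_unfolded,
               k_unfold = est$k_unfold, k_fold = est$k_fold,
               se_unfold = est$se_unfold, se_fold = est$se_fold,
               n_dwells = sum(est$n_dwells))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(mean_force_folded = numeric(0),
                      mean_force_unfolded = numeric(0),
                      k_unfold = numeric(0), k_fold = numeric(0),
                      se_unfold = numeric(0), se_fold = numeric(0),
                      n_dwells = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(out$mean_force_folded), , drop = FALSE]
}
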