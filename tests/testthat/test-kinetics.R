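test_that("Schmitt-trigger assignment recovers telegraph states", {
  ts0 <- telegraph_signal(100, 100, 0, 3, noise_sd = 0, duration = 5,
                          seed = 31)
  st0 <- assign_states_threshold(ts0$signal, 1.5, hysteresis = 1,
                                 sample_rate = 2e4)
  expect_identical(as.integer(st0), ts0$state)  # noiseless: exact
  # noise at separation/6 with hysteresis separation/2: >= 99% agreement
  ts <- telegraph_signal(100, 100, 0, 3, noise_sd = 0.5, duration = 10,
                         seed = 32)
  st <- assign_states_threshold(ts$signal, 1.5, hysteresis = 1.5,
                                sample_rate = 2e4)
  expect_gt(mean(as.integer(st) == ts$state), 0.99)
  # constant signal: one state throughout
  stc <- assign_states_threshold(rep(0.2, 100), 1.5, 1, sample_rate = 2e4)
  expect_identical(unique(as.integer(stc)), 1L)
})

test_that("dwell-time rates are exponential MLEs with censoring removed", {
  # exact 10 ms dwells at 20 kHz: both rates 100/s
  st <- structure(rep(rep(1:2, 25), each = 200), sample_rate = 2e4,
                  class = "state_sequence")
  est <- dwell_rates(st)
  expect_equal(est$k_unfold, 100)
  expect_equal(est$k_fold, 100)
  expect_equal(est$se_unfold, 100 / sqrt(24))  # censored dwells dropped
  # generator ground truth recovered within 2 standard errors
  ts <- telegraph_signal(80, 120, 0, 3, noise_sd = 0, duration = 30,
                         seed = 33)
  est2 <- dwell_rates(structure(ts$state, sample_rate = 2e4,
                                class = "state_sequence"))
  expect_lt(abs(est2$k_unfold - 80), 2 * est2$se_unfold)
  expect_lt(abs(est2$k_fold - 120), 2 * est2$se_fold)
  # single dwell: rate undefined
  expect_error(dwell_rates(structure(rep(1L, 100), sample_rate = 2e4,
                                     class = "state_sequence")),
               "rate undefined")
})

test_that("two-state HMM recovers rates, levels, and the hidden path", {
  ts <- telegraph_signal(100, 100, 0, 3, noise_sd = 0.5, duration = 30,
                         seed = 34)
  fit <- fit_hmm_two_state(ts$signal, 2e4)
  expect_true(fit$converged)
  expect_equal(fit$means, c(0, 3), tolerance = 0.02)
  expect_equal(fit$sds, c(0.5, 0.5), tolerance = 0.05)
  expect_equal(fit$rates$k_unfold, 100, tolerance = 0.1)
  expect_equal(fit$rates$k_fold, 100, tolerance = 0.1)
  expect_gt(mean(as.integer(fit$path) == ts$state), 0.999)
  # near-noiseless: Viterbi path identical to the generator states
  ts0 <- telegraph_signal(100, 100, 0, 3, noise_sd = 0.02, duration = 2,
                          seed = 35)
  fit0 <- fit_hmm_two_state(ts0$signal, 2e4)
  expect_identical(as.integer(fit0$path), ts0$state)
})

test_that("HMM declares failure when noise swamps the level separation", {
  # noise well above the separation: the fitted populations are closer
  # than the pooled emission SD, mirroring the floppy-linker failure
  ts <- telegraph_signal(100, 100, 0, 3, noise_sd = 4.5, duration = 10,
                         seed = 36)
  fit <- fit_hmm_two_state(ts$signal, 2e4)
  expect_false(fit$converged)
  expect_null(fit$rates)
})

test_that("HMM and dwell estimates agree across rate regimes", {
  for (k in c(10, 100, 1000)) {
    dur <- max(5, 3000 / k)
    ts <- telegraph_signal(k, k, 0, 3, noise_sd = 0.5, duration = dur,
                           seed = 37 + k)
    fit <- fit_hmm_two_state(ts$signal, 2e4)
    st <- assign_states_threshold(ts$signal, 1.5, hysteresis = 1.5,
                                  sample_rate = 2e4)
    dw <- dwell_rates(st)
    expect_true(fit$converged)
    comb <- 2 * sqrt(dw$se_unfold^2 + (fit$rates$k_unfold /
                                         sqrt(sum(dw$n_dwells)))^2)
    expect_lt(abs(fit$rates$k_unfold - dw$k_unfold), comb + 0.05 * k)
    expect_equal(fit$rates$k_unfold, k, tolerance = 0.12)
  }
})

test_that("rate estimates are invariant to signal offsets", {
  ts <- telegraph_signal(100, 100, 0, 3, noise_sd = 0.5, duration = 10,
                         seed = 38)
  st1 <- assign_states_threshold(ts$signal, 1.5, 1.5, sample_rate = 2e4)
  st2 <- assign_states_threshold(ts$signal + 50, 51.5, 1.5,
                                 sample_rate = 2e4)
  expect_identical(as.integer(st1), as.integer(st2))
  f1 <- fit_hmm_two_state(ts$signal, 2e4)
  f2 <- fit_hmm_two_state(ts$signal + 50, 2e4)
  expect_equal(f2$rates$k_unfold, f1$rates$k_unfold, tolerance = 1e-6)
  expect_equal(f2$means - 50, f1$means, tolerance = 1e-6)
})

test_that("dwell-rate parameter recovery is accurate at large n", {
  # median relative error of the 1 -> 2 rate below 5% once several
  # hundred dwells are observed
  errs <- vapply(1:50, function(i) {
    ts <- telegraph_signal(100, 100, 0, 3, noise_sd = 0, duration = 8,
                           seed = 400 + i)
    est <- dwell_rates(structure(ts$state, sample_rate = 2e4,
                                 class = "state_sequence"))
    expect_gte(sum(est$n_dwells), 300)
    abs(est$k_unfold - 100) / 100
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("force-dependent rate tables aggregate per-trace estimates", {
  # Bell-type force dependence imposed on the generator
  mk <- function(F, seed) {
    ku <- 20 * exp(F / 2)
    kf <- 2000 * exp(-F / 2)
    ts <- telegraph_signal(ku, kf, 0, 3, noise_sd = 0, duration = 15,
                           seed = seed)
    tr <- data.frame(force_pN = F + 0.2 * (ts$state - 1.5))
    list(trace = tr, states = structure(ts$state, sample_rate = 2e4,
                                        class = "state_sequence"))
  }
  forces <- c(4, 5, 6, 7)
  tab <- force_dependent_rates(Map(mk, forces, 50 + seq_along(forces)))
  expect_identical(nrow(tab), 4L)
  expect_true(all(diff(tab$k_unfold) > 0))  # unfolding accelerates
  expect_true(all(diff(tab$k_fold) < 0))    # refolding slows
  expect_true(!is.unsorted(tab$mean_force_folded))
  # single trace -> one row; empty input -> empty table
  expect_identical(nrow(force_dependent_rates(list(mk(5, 99)))), 1L)
  expect_identical(nrow(force_dependent_rates(list())), 0L)
  # a one-state trace is skipped with a warning
  bad <- list(trace = data.frame(force_pN = rep(5, 1000)),
              states = structure(rep(1L, 1000), sample_rate = 2e4,
                                 class = "state_sequence"))
  expect_warning(out <- force_dependent_rates(list(bad, mk(5, 98))),
                 "skipped")
  expect_identical(nrow(out), 1L)
})
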