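#' Noisy two-state telegraph signal
#'
#' Generates a continuous-time two-state Markov (telegraph) process sampled
#' at `sample_rate`, with exponential dwell times and iid Gaussian
#' observation noise around the two state levels. This is the ground-truth
#' fixture for the kinetics estimators.
#'
#' @param k12 Rate from state 1 to state 2, 1/s.
#' @param k21 Rate from state 2 to state 1, 1/s.
#' @param level1,level2 Observation levels of the two states, nm.
#' @param noise_sd Gaussian observation noise SD, nm.
#' @param sample_rate Sampling rate, Hz.
#' @param duration Signal duration, s.
#' @param seed Optional integer seed.
#' @return `list(time_s, signal, state)` with `state` in `{1, 2}`;
#'   `sample_rate` is carried as an attribute.
#' @export
telegraph_signal <- function(k12, k21, level1 = 0, level2 = 3,
                             noise_sd = 0.5, sample_rate = 2e4,
                             duration = 10, seed = NULL) {
  stopifnot(k12 >= 0, k21 >= 0, sample_rate > 0, duration > 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * sample_rate)
  s01 <- telegraph_states(rate01 = k12, rate10 = k21, n, sample_rate)
  state <- s01 + 1L
  signal <- ifelse(state == 1L, level1, level2) +
    if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
  out <- list(time_s = seq_len(n) / sample_rate, signal = signal,
              state = state)
  attr(out, "sample_rate") <- sample_rate
  out
}

#' 2D semiflexible chain ensemble with tracing noise
#'
#' Simulates worm-like chains equilibrated in the plane (the convention for
#' filaments adsorbed on an EM grid), discretised into `n_segments` equal
#' segments whose tangent angle performs a Gaussian walk with variance
#' `ds / p` per segment, so that the tangent correlation is
#' `<t(0) . t(s)> = exp(-s / 2p)` with `p` the 3D persistence length. A
#' noisy copy of each backbone adds iid Gaussian jitter of
#' `tracing_jitter_sd * pixel_size` to every vertex, emulating manual
#' backbone tracing on pixelated micrographs.
#'
#' @param p Persistence length, nm.
#' @param L Contour length, nm.
#' @param n_chains Number of chains.
#' @param n_segments Segments per chain (>= 10).
#' @param pixel_size Pixel size of the emulated micrograph, nm (default 2).
#' @param tracing_jitter_sd Vertex jitter SD in pixels (default 1).
#' @param seed Optional integer seed.
#' @return `list(true = <list of (n_segments+1) x 2 matrices>,
#'   noisy = <same shape>, p = p, L = L)`.
#' @export
chain_ensemble_2d <- function(p, L, n_chains, n_segments = 100,
                              pixel_size = 2, tracing_jitter_sd = 1,
                              seed = NULL) {
  stopifnot(p > 0, L > 0, n_chains >= 1, n_segments >= 10)
  if (!is.null(seed)) set.seed(seed)
  ds <- L / n_segments
  sd_theta <- sqrt(ds / p)
  jit <- tracing_jitter_sd * pixel_size
  true <- vector("list", n_chains)
  noisy <- vector("list", n_chains)
  for (i in seq_len(n_chains)) {
    theta <- cumsum(c(runif(1, 0, 2 * pi),
                      rnorm(n_segments - 1, 0, sd_theta)))
    xy <- cbind(c(0, cumsum(ds * cos(theta))),
                c(0, cumsum(ds * sin(theta))))
    true[[i]] <- xy
    noisy[[i]] <- xy + matrix(rnorm(length(xy), 0, jit), ncol = 2)
  }
  list(true = true, noisy = noisy, p = p, L = L)
}

# Bundle geometry: an N-helix bundle folds from a 7560-base scaffold, so
# its contour is (7560 / N) * 0.34 nm.
NM_PER_BP <- 0.34
SCAFFOLD_BASES <- 7560

#' Expected contour length of an N-helix bundle
#'
#' @param N Number of helices in the bundle.
#' @param bases Scaffold length in bases (default 7560).
#' @return Contour length in nm.
#' @export
expected_bundle_contour <- function(N, bases = SCAFFOLD_BASES) {
  stopifnot(N >= 1)
  bases / N * NM_PER_BP
}

# Assumed bundle persistence lengths for backbone-tracing fixtures, nm.
# Six- and eight-helix values are the fitted ones (2 and 3.5 um); the ten-
# and twelve-helix bundles only have lower bounds from shape analysis, so
# nominal stiff values following the cross-section scaling are assumed.
bundle_persistence <- function(N) {
  switch(as.character(N),
         "6" = 2e3, "8" = 3.5e3, "10" = 6e3, "12" = 9e3,
         stop("no persistence value for N = ", N, call. = FALSE))
}

#' Preset dual-trap assay configurations
#'
#' Named parameterizations of the simulated constructs:
#' \describe{
#'   \item{dsDNA_linker}{Conventional linker: one eWLC dsDNA, p = 50 nm,
#'     L = 530 nm, K = 1000 pN.}
#'   \item{tenhelix_linker}{One rigid ten-helix bundle modelled as a
#'     two-segment eFJC (L = 485 nm, K = 10000 pN) plus a 15 nm ssDNA WLC
#'     attachment strand (p = 1 nm).}
#'   \item{tenhelix_hairpin6 / tenhelix_hairpin20}{Two ten-helix bundles in
#'     series flanking a 6 bp (16 released nt) or 20 bp (44 released nt)
#'     hairpin, each bundle bead-attached through a 15 nm ssDNA strand.}
#'   \item{dsDNA_hairpin6 / dsDNA_hairpin20}{The ~530 nm dsDNA construct
#'     with the hairpin inserted.}
#'   \item{control_no_hairpin}{The double ten-helix-bundle linker connected
#'     directly, used to measure the point-spread function.}
#' }
#' Hairpins release 2 x stem + 4 loop nucleotides at 0.59 nm/nt and have a
#' 2 nm folded width.
#'
#' @param name Preset name.
#' @param seed Optional seed stored in the config.
#' @return An [assay_config()].
#' @export
preset_config <- function(name = c("dsDNA_linker", "tenhelix_linker",
                                   "tenhelix_hairpin6", "tenhelix_hairpin20",
                                   "dsDNA_hairpin6", "dsDNA_hairpin20",
                                   "control_no_hairpin"),
                          seed = NULL) {
  if (is.character(name) && length(name) == 1L &&
      !name %in% eval(formals(preset_config)$name))
    stop("unknown preset '", name, "'; valid: ",
         paste(eval(formals(preset_config)$name), collapse = ", "),
         call. = FALSE)
  name <- match.arg(name)
  dsdna <- polymer_model("ewlc", L = 530, p = 50, K = 1000)
  bundle <- polymer_model("efjc", L = 485, K = 10000, n_segments = 2)
  ss <- polymer_model("wlc", L = 15, p = 1)
  hp6 <- hairpin_model(released_nt = 2 * 6 + 4)
  hp20 <- hairpin_model(released_nt = 2 * 20 + 4)
  cfg <- switch(name,
    dsDNA_linker = assay_config(list(dsdna), seed = seed),
    tenhelix_linker = assay_config(list(bundle, ss), seed = seed),
    tenhelix_hairpin6 = assay_config(list(ss, bundle, bundle, ss),
                                     hairpin = hp6, seed = seed),
    tenhelix_hairpin20 = assay_config(list(ss, bundle, bundle, ss),
                                      hairpin = hp20, seed = seed),
    dsDNA_hairpin6 = assay_config(list(dsdna), hairpin = hp6, seed = seed),
    dsDNA_hairpin20 = assay_config(list(dsdna), hairpin = hp20, seed = seed),
    control_no_hairpin = assay_config(list(ss, bundle, bundle, ss),
                                      seed = seed))
  cfg
}
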