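#' Optical trap model
#'
#' A 3D anisotropic harmonic trap. The two directions perpendicular to the
#' laser beam (one of which is the pulling axis) share one stiffness; the
#' direction along the beam is much softer.
#'
#' @param k_perp Stiffness perpendicular to the beam, pN/nm (default 0.4).
#' @param k_beam Stiffness along the beam axis, pN/nm (default 0.04).
#' @return An object of class `trap_model`.
#' @export
trap_model <- function(k_perp = 0.4, k_beam = 0.04) {
  stopifnot(k_perp > 0, k_beam > 0)
  structure(list(k_perp = k_perp, k_beam = k_beam), class = "trap_model")
}

#' Two-state DNA hairpin model
#'
#' Geometric and energetic parameters of a hairpin inserted in the tether.
#' Folded, the hairpin contributes a short inelastic width; unfolded, it
#' releases `released_nt` nucleotides of single-stranded DNA that are added
#' to the tether as a WLC element.
#'
#' @param released_nt Nucleotides released on unfolding (2 x stem + loop).
#' @param nm_per_nt Contour length per released nucleotide, nm (default 0.59).
#' @param folded_width Inelastic width of the folded hairpin, nm (default 2).
#' @param ssdna_p Persistence length of the released ssDNA, nm (default 1).
#' @param dG0 Unfolding free energy at zero force, pN nm, added to the
#'   unfolded state's energy. Use [calibrate_dg0()] to set it from a target
#'   mid-transition force.
#' @return An object of class `hairpin_model`.
#' @export
hairpin_model <- function(released_nt, nm_per_nt = 0.59, folded_width = 2.0,
                          ssdna_p = 1.0, dG0 = 0) {
  stopifnot(released_nt >= 0, nm_per_nt > 0, folded_width > 0, ssdna_p > 0)
  structure(list(released_nt = released_nt, nm_per_nt = nm_per_nt,
                 folded_width = folded_width, ssdna_p = ssdna_p, dG0 = dG0),
            class = "hairpin_model")
}

#' Dual-trap assay configuration
#'
#' @param tether List of [polymer_model()] elements in mechanical series
#'   between the two beads (hairpin excluded; see `hairpin`).
#' @param trap1,trap2 [trap_model()] objects.
#' @param hairpin Optional [hairpin_model()].
#' @param thermal A [thermal()] object.
#' @param pulling_speed Trap retraction speed for force ramps, nm/s.
#' @param mc_rate Monte-Carlo step rate, Hz; one step advances 1/mc_rate s.
#' @param output_rate Output sampling rate, Hz; traces are block-mean
#'   downsampled from `mc_rate` to `output_rate`. Must divide `mc_rate`.
#' @param step_size Metropolis proposal half-width n, nm: all six bead
#'   coordinates are perturbed simultaneously, uniformly within +/- n.
#' @param calibration_error Relative error of the deflection sensitivity
#'   calibration (default 0 = perfect calibration). Recorded deflections
#'   are scaled by `1 + calibration_error`, which propagates into force
#'   and extension the way real miscalibrated bead displacements do; for
#'   linkers much stiffer than the traps this produces the trap-limited
#'   apparent extensibility seen when stretching rigid bundles past their
#'   contour length.
#' @param seed Integer seed recorded and used by the simulators.
#' @return An object of class `assay_config`.
#' @export
assay_config <- function(tether, trap1 = trap_model(), trap2 = trap_model(),
                         hairpin = NULL, thermal = rigidlink::thermal(),
                         pulling_speed = 500, mc_rate = 1e5,
                         output_rate = 2e4, step_size = 0.25,
                         calibration_error = 0, seed = NULL) {
  if (inherits(tether, "polymer_model")) tether <- list(tether)
  stopifnot(all(vapply(tether, inherits, logical(1), "polymer_model")),
            inherits(trap1, "trap_model"), inherits(trap2, "trap_model"),
            pulling_speed >= 0, mc_rate > 0, output_rate > 0, step_size > 0)
  if (mc_rate %% output_rate != 0)
    stop("mc_rate must be an integer multiple of output_rate", call. = FALSE)
  if (!is.null(hairpin)) stopifnot(inherits(hairpin, "hairpin_model"))
  structure(list(tether = tether, trap1 = trap1, trap2 = trap2,
                 hairpin = hairpin, thermal = thermal,
                 pulling_speed = pulling_speed, mc_rate = mc_rate,
                 output_rate = output_rate, step_size = step_size,
                 calibration_error = calibration_error, seed = seed),
            class = "assay_config")
}

# Effective elastic chain and inelastic (rigid) length for a hairpin state.
# state: "folded" keeps the hairpin as a short rigid width; "unfolded"
# appends the released ssDNA as a WLC element; "none" ignores the hairpin.
tether_chain <- function(config, state = c("folded", "unfolded", "none")) {
  state <- match.arg(state)
  hp <- config$hairpin
  if (is.null(hp) || state == "none")
    return(list(chain = config$tether, rigid = 0, dG = 0))
  if (state == "folded")
    return(list(chain = config$tether, rigid = hp$folded_width, dG = 0))
  ss <- polymer_model("wlc", L = hp$released_nt * hp$nm_per_nt, p = hp$ssdna_p)
  list(chain = c(config$tether, list(ss)), rigid = 0, dG = hp$dG0)
}

# Stretch energy of a series chain at total extension x (exact, by solving
# for the common tension). Inf when overstretched. Used by the R-level
# total_energy; the MC engine uses an interpolation table instead.
series_stretch_energy <- function(x, chain, thermal, f_cap = 1e4) {
  vapply(x, function(xi) {
    if (xi <= 0) return(0)
    if (xi >= series_extension(f_cap, chain, thermal)) return(Inf)
    F <- series_force(xi, chain, thermal, f_max = f_cap)
    sum(vapply(chain, function(m)
      stretch_energy(model_extension(F, m, thermal), m, thermal), numeric(1)))
  }, numeric(1))
}

#' System state of the dual-trap assay
#'
#' @param bead1,bead2 3D bead positions, nm. Trap 1 sits at the origin,
#'   trap 2 at `(trap_separation, 0, 0)`; the x axis is the pulling axis.
#' @param trap_separation Distance between trap centers, nm.
#' @param hairpin_folded Logical; ignored when the config has no hairpin.
#' @return An object of class `system_state`.
#' @export
system_state <- function(bead1 = c(0, 0, 0), bead2 = c(0, 0, 0),
                         trap_separation = 0, hairpin_folded = TRUE) {
  stopifnot(length(bead1) == 3L, length(bead2) == 3L,
            all(is.finite(bead1)), all(is.finite(bead2)),
            is.finite(trap_separation))
  structure(list(bead1 = as.numeric(bead1), bead2 = as.numeric(bead2),
                 trap_separation = trap_separation,
                 hairpin_folded = isTRUE(hairpin_folded)),
            class = "system_state")
}

#' Total free energy of the two-bead system
#'
#' Sum of the two anisotropic harmonic trap energies and the stretch energy
#' of the series tether at the bead-bead distance. With a hairpin, the
#' folded state carries the inelastic folded width, the unfolded state the
#' released ssDNA plus the unfolding free energy `dG0`. An overstretched
#' tether yields `Inf` (the Metropolis move is rejected), not an error.
#'
#' @param state A [system_state()].
#' @param config An [assay_config()].
#' @return Energy in pN nm.
#' @export
total_energy <- function(state, config) {
  tc <- tether_chain(config, if (is.null(config$hairpin)) "none"
                     else if (state$hairpin_folded) "folded" else "unfolded")
  k1 <- config$trap1; k2 <- config$trap2
  c2 <- c(state$trap_separation, 0, 0)
  kvec1 <- c(k1$k_perp, k1$k_perp, k1$k_beam)
  kvec2 <- c(k2$k_perp, k2$k_perp, k2$k_beam)
  e_trap <- 0.5 * sum(kvec1 * state$bead1^2) +
            0.5 * sum(kvec2 * (state$bead2 - c2)^2)
  r <- sqrt(sum((state$bead2 - state$bead1)^2))
  xe <- r - tc$rigid
  e_tether <- if (length(tc$chain) == 0 || xe <= 0) 0 else
    series_stretch_energy(xe, tc$chain, config$thermal)
  e_trap + e_tether + tc$dG
}

#' One Metropolis Monte-Carlo step
#'
#' Proposes a simultaneous uniform perturbation of all six bead coordinates
#' within +/- `step_size` and accepts with probability
#' `min(1, exp(-dE/kT))`. This is the reference R implementation of the move
#' used by the compiled simulation engine; rejected proposals leave the
#' state unchanged.
#'
#' @param state A [system_state()].
#' @param config An [assay_config()].
#' @return `list(state = <new state>, accepted = <logical>, dE = <pN nm>)`.
#' @export
mc_step <- function(state, config) {
  n <- config$step_size
  prop <- state
  prop$bead1 <- state$bead1 + runif(3, -n, n)
  prop$bead2 <- state$bead2 + runif(3, -n, n)
  e0 <- total_energy(state, config)
  e1 <- total_energy(prop, config)
  dE <- e1 - e0
  accepted <- if (dE <= 0) TRUE else
    is.finite(dE) && runif(1) < exp(-dE / config$thermal$kT)
  list(state = if (accepted) prop else state, accepted = accepted,
       dE = if (accepted) dE else 0)
}

#' Deterministic force balance at a given trap separation
#'
#' Solves for the tension `F` at which tether extension plus both axial
#' bead deflections (`F/k` each) plus any inelastic length equals the trap
#' separation. This is the mechanical equilibrium about which the
#' Monte-Carlo trace fluctuates.
#'
#' @param separation Trap separation, nm (vectorised).
#' @param config An [assay_config()].
#' @param state Hairpin state: `"folded"`, `"unfolded"`, or `"none"`.
#' @return Equilibrium force, pN.
#' @export
equilibrium_force <- function(separation, config,
                              state = c("folded", "unfolded", "none")) {
  state <- match.arg(state)
  tc <- tether_chain(config, state)
  compl <- 1 / config$trap1$k_perp + 1 / config$trap2$k_perp
  vapply(separation, function(d) {
    if (d <= tc$rigid) return(0)
    uniroot(function(F)
      series_extension(F, tc$chain, config$thermal) + F * compl + tc$rigid - d,
      lower = 0, upper = 100, tol = 1e-10, extendInt = "upX")$root
  }, numeric(1))
}

#' Trap separation that equilibrates at a target force
#'
#' Inverse of [equilibrium_force()]: closed form, since the extension law
#' is explicit in force.
#'
#' @param force Target equilibrium tension, pN (vectorised).
#' @inheritParams equilibrium_force
#' @return Trap separation, nm.
#' @export
separation_for_force <- function(force, config,
                                 state = c("folded", "unfolded", "none")) {
  state <- match.arg(state)
  tc <- tether_chain(config, state)
  compl <- 1 / config$trap1$k_perp + 1 / config$trap2$k_perp
  series_extension(force, tc$chain, config$thermal) + force * compl + tc$rigid
}

# Beads at their deterministic equilibrium positions for separation d.
equilibrium_beads <- function(d, config, state) {
  F <- equilibrium_force(d, config, state)
  list(b1 = c(F / config$trap1$k_perp, 0, 0),
       b2 = c(d - F / config$trap2$k_perp, 0, 0), force = F)
}

mc_table <- function(config, state) {
  tc <- tether_chain(config, state)
  if (length(tc$chain) == 0) return(list())
  tab <- build_energy_table(tc$chain, config$thermal)
  tab$rigid <- tc$rigid
  tab
}

# Emulate deflection-sensitivity miscalibration on the recorded columns.
apply_calibration <- function(df, config) {
  b <- config$calibration_error
  if (is.null(b) || b == 0) return(df)
  df$defl1_nm <- (1 + b) * df$defl1_nm
  df$defl2_nm <- (1 + b) * df$defl2_nm
  df$force_pN <- 0.5 * (config$trap1$k_perp * df$defl1_nm -
                        config$trap2$k_perp * df$defl2_nm)
  df$extension_nm <- df$trap_sep_nm - df$defl1_nm + df$defl2_nm
  df
}

new_trace <- function(df, config, protocol, acceptance = NA_real_) {
  attr(df, "sample_rate") <- config$output_rate
  attr(df, "seed") <- config$seed
  attr(df, "protocol") <- protocol
  attr(df, "acceptance") <- acceptance
  class(df) <- c("tweezer_trace", "data.frame")
  df
}

#' Simulate a force-ramp (pulling) experiment
#'
#' Metropolis dynamics of the two trapped beads while one trap retreats by
#' `pulling_speed / mc_rate` nm after every accepted step. Observables are
#' recorded every step and block-mean downsampled to `output_rate`. The
#' recorded force is the mean of the two axial trap forces; the extension
#' is the trap separation minus both axial deflections.
#'
#' @param config An [assay_config()]. With a hairpin present the pull is
#'   run in the given fixed `hairpin_state`.
#' @param max_force Stop once the block-mean force reaches this, pN.
#' @param start_force Equilibrium pre-tension at the starting separation,
#'   pN; sets the starting separation unless `start_separation` is given.
#' @param start_separation Optional explicit starting trap separation, nm.
#' @param max_duration Hard cap on simulated time, s.
#' @param hairpin_state `"folded"` or `"unfolded"` during the pull.
#' @param burn_in Unrecorded equilibration steps before the ramp.
#' @return A `tweezer_trace` data frame with columns `time_s`,
#'   `trap_sep_nm`, `defl1_nm`, `defl2_nm`, `force_pN`, `extension_nm`,
#'   `state`.
#' @export
simulate_pull <- function(config, max_force = 30, start_force = 0.2,
                          start_separation = NULL, max_duration = 20,
                          hairpin_state = c("folded", "unfolded"),
                          burn_in = 5000) {
  hairpin_state <- match.arg(hairpin_state)
  st <- if (is.null(config$hairpin)) "none" else hairpin_state
  stopifnot(max_force > 0)
  d0 <- if (is.null(start_separation))
    separation_for_force(start_force, config, st) else start_separation
  eq <- equilibrium_beads(d0, config, st)
  tab <- mc_table(config, st)
  kvec <- c(config$trap1$k_perp, config$trap1$k_perp, config$trap1$k_beam,
            config$trap2$k_perp, config$trap2$k_perp, config$trap2$k_beam)
  factor <- as.integer(config$mc_rate / config$output_rate)
  if (!is.null(config$seed)) set.seed(config$seed)
  res <- mc_pull_cpp(eq$b1, eq$b2, d0, kvec, config$step_size,
                     config$thermal$kT, tab,
                     config$pulling_speed / config$mc_rate, max_force,
                     as.integer(max_duration * config$mc_rate), factor,
                     as.integer(burn_in))
  n <- length(res$force_pN)
  df <- data.frame(time_s = seq_len(n) / config$output_rate,
                   trap_sep_nm = res$trap_sep_nm,
                   defl1_nm = res$defl1_nm, defl2_nm = res$defl2_nm,
                   force_pN = res$force_pN, extension_nm = res$extension_nm,
                   state = NA_character_)
  df <- apply_calibration(df, config)
  new_trace(df, config, "pull", res$acceptance)
}

# Exact-exponential-dwell telegraph state sequence at sampling rate fs.
# Returns integers in {0, 1}; rate01 = 0 -> 1, rate10 = 1 -> 0.
telegraph_states <- function(rate01, rate10, n, fs, init = NULL) {
  stopifnot(rate01 >= 0, rate10 >= 0, n >= 1)
  if (rate01 == 0 && rate10 == 0)
    return(rep(if (is.null(init)) 0L else as.integer(init), n))
  p1 <- if (rate01 + rate10 > 0) rate01 / (rate01 + rate10) else 0
  s <- if (is.null(init)) as.integer(runif(1) < p1) else as.integer(init)
  out <- integer(n)
  i <- 1L
  while (i <= n) {
    rate <- if (s == 0L) rate01 else rate10
    len <- if (rate == 0) n - i + 1L else max(1L, round(rexp(1, rate) * fs))
    j <- min(n, i + len - 1L)
    out[i:j] <- s
    i <- j + 1L
    s <- 1L - s
  }
  out
}

#' Simulate a constant-trap-distance experiment
#'
#' The traps are held fixed while the bead coordinates are sampled by
#' Metropolis sweeps. With a hairpin and kinetic `rates`, a hidden two-state
#' telegraph sequence with exponential dwell times switches the tether
#' composition between the folded and unfolded states; on each switch the
#' beads are re-equilibrated with unrecorded sweeps, so every output sample
#' is drawn from the equilibrium ensemble of its state. Metropolis time is
#' not physical time, which is why the hairpin kinetics are imposed rather
#' than emergent; equilibrium occupancies remain Boltzmann-consistent via
#' [boltzmann_rates()].
#'
#' @param config An [assay_config()] (hairpin required when `rates` given).
#' @param duration Simulated time, s.
#' @param rates Optional `c(k_fold, k_unfold)` in 1/s: `k_fold` is the
#'   unfolded-to-folded rate, `k_unfold` the folded-to-unfolded rate.
#' @param trap_separation Trap separation, nm; alternatively give
#'   `target_force`.
#' @param target_force Sets the separation so the folded-state (or bare
#'   tether) equilibrium force equals this, pN.
#' @param initial_state Optional `"folded"` or `"unfolded"` start state.
#' @param max_samples Size cap on `duration * output_rate`.
#' @param burn_in,burn_switch Unrecorded equilibration sweeps at the start
#'   and after each state switch.
#' @return A `tweezer_trace` with the hidden state in column `state`
#'   (`"folded"`/`"unfolded"`, `NA` without a hairpin).
#' @export
simulate_constant_distance <- function(config, duration, rates = NULL,
                                       trap_separation = NULL,
                                       target_force = NULL,
                                       initial_state = NULL,
                                       max_samples = 2e6,
                                       burn_in = 5000, burn_switch = 500) {
  stopifnot(duration > 0)
  if (!is.null(rates) && is.null(config$hairpin))
    stop("rates given but config has no hairpin", call. = FALSE)
  n_out <- round(duration * config$output_rate)
  if (n_out > max_samples)
    stop(sprintf("requested %d samples exceeds max_samples = %g",
                 n_out, max_samples), call. = FALSE)
  base_state <- if (is.null(config$hairpin)) "none" else "folded"
  if (is.null(trap_separation)) {
    if (is.null(target_force))
      stop("give trap_separation or target_force", call. = FALSE)
    trap_separation <- separation_for_force(target_force, config, base_state)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  states <- if (is.null(rates)) rep(0L, n_out) else
    telegraph_states(rate01 = rates[2], rate10 = rates[1], n_out,
                     config$output_rate,
                     init = if (is.null(initial_state)) NULL
                            else as.integer(initial_state == "unfolded"))
  tab0 <- mc_table(config, base_state)
  tab1 <- if (is.null(config$hairpin)) list() else mc_table(config, "unfolded")
  eq <- equilibrium_beads(trap_separation, config,
                          if (states[1] == 0L) base_state else "unfolded")
  kvec <- c(config$trap1$k_perp, config$trap1$k_perp, config$trap1$k_beam,
            config$trap2$k_perp, config$trap2$k_perp, config$trap2$k_beam)
  factor <- as.integer(config$mc_rate / config$output_rate)
  res <- mc_cd_cpp(eq$b1, eq$b2, trap_separation, kvec, config$step_size,
                   config$thermal$kT, tab0, tab1, states, factor,
                   as.integer(burn_in), as.integer(burn_switch))
  state_col <- if (is.null(config$hairpin)) NA_character_ else
    c("folded", "unfolded")[states + 1L]
  df <- data.frame(time_s = seq_len(n_out) / config$output_rate,
                   trap_sep_nm = trap_separation,
                   defl1_nm = res$defl1_nm, defl2_nm = res$defl2_nm,
                   force_pN = res$force_pN, extension_nm = res$extension_nm,
                   state = state_col)
  df <- apply_calibration(df, config)
  new_trace(df, config, "constant_distance", res$acceptance)
}

#' Block-mean downsampling
#'
#' Non-overlapping block means by an integer factor, the reduction applied
#' to traces before analysis (matching 100 kHz acquisition downsampled to
#' 20 kHz). A trailing partial block is dropped with a warning.
#'
#' @param series Numeric vector, or a `tweezer_trace` (numeric columns are
#'   block-averaged; the `state` column takes the block's last value).
#' @param factor Integer >= 1.
#' @return Same type as the input.
#' @export
downsample <- function(series, factor) {
  stopifnot(factor >= 1, factor == round(factor))
  factor <- as.integer(factor)
  if (factor == 1L) return(series)
  if (is.data.frame(series)) {
    n <- nrow(series)
    nb <- n %/% factor
    if (nb * factor < n)
      warning(sprintf("dropping %d trailing samples", n - nb * factor))
    idx <- rep(seq_len(nb), each = factor)
    out <- series[seq_len(nb) * factor, , drop = FALSE]
    num <- vapply(series, is.numeric, logical(1))
    for (cn in names(series)[num])
      out[[cn]] <- as.numeric(tapply(series[[cn]][seq_len(nb * factor)],
                                     idx, mean))
    if ("sample_rate" %in% names(attributes(series)))
      attr(out, "sample_rate") <- attr(series, "sample_rate") / factor
    rownames(out) <- NULL
    return(out)
  }
  n <- length(series)
  nb <- n %/% factor
  if (nb * factor < n)
    warning(sprintf("dropping %d trailing samples", n - nb * factor))
  colMeans(matrix(series[seq_len(nb * factor)], nrow = factor))
}

#' Auto-tune the Metropolis step size
#'
#' Bisects the proposal half-width so that the acceptance frequency of
#' short constant-distance runs falls in `[target[1], target[2]]`
#' (default 40-60%), the usual efficiency window for random-walk
#' Metropolis. Large steps decorrelate the soft bead modes faster, which
#' matters for moving-window noise statistics.
#'
#' @param config An [assay_config()].
#' @param trap_separation Separation at which to tune, nm; defaults to the
#'   separation giving 5 pN equilibrium force.
#' @param target Acceptance window.
#' @param probe_duration Duration of each probe run, s.
#' @return A copy of `config` with the tuned `step_size`.
#' @export
tune_step_size <- function(config, trap_separation = NULL,
                           target = c(0.4, 0.6), probe_duration = 0.05) {
  st <- if (is.null(config$hairpin)) "none" else "folded"
  if (is.null(trap_separation))
    trap_separation <- separation_for_force(5, config, st)
  probe <- function(step) {
    cfg <- config
    cfg$step_size <- step
    cfg$seed <- if (is.null(config$seed)) 1L else config$seed
    tr <- simulate_constant_distance(cfg, probe_duration,
                                     trap_separation = trap_separation,
                                     burn_in = 1000)
    attr(tr, "acceptance")
  }
  lo <- config$step_size / 8
  hi <- config$step_size * 64
  for (i in 1:20) {
    mid <- sqrt(lo * hi)
    a <- probe(mid)
    if (a > target[2]) lo <- mid
    else if (a < target[1]) hi <- mid
    else { config$step_size <- mid; return(config) }
  }
  config$step_size <- mid
  config
}

# Log partition function of one hairpin state over the two axial bead
# coordinates (transverse coordinates are state-independent Gaussians and
# cancel in free-energy differences). 2D trapezoid on a grid around the
# mechanical equilibrium.
state_log_z <- function(config, d, state, half_width = 25, n_grid = 201) {
  tc <- tether_chain(config, state)
  tab <- build_energy_table(tc$chain, config$thermal)
  eq <- equilibrium_beads(d, config, if (is.null(config$hairpin)) "none"
                          else state)
  kT <- config$thermal$kT
  k1 <- config$trap1$k_perp; k2 <- config$trap2$k_perp
  x1 <- seq(eq$b1[1] - half_width, eq$b1[1] + half_width, length.out = n_grid)
  x2 <- seq(eq$b2[1] - half_width, eq$b2[1] + half_width, length.out = n_grid)
  g <- expand.grid(b1 = x1, b2 = x2)
  r <- g$b2 - g$b1 - tc$rigid
  Et <- rep(Inf, nrow(g))
  inside <- r < tab$x_max
  low <- r <= 0
  Et[low] <- 0
  mid <- inside & !low
  Et[mid] <- approx(seq(0, by = tab$dx, length.out = length(tab$E)), tab$E,
                    xout = r[mid], rule = 2)$y
  E <- 0.5 * k1 * g$b1^2 + 0.5 * k2 * (g$b2 - d)^2 + Et + tc$dG
  w <- exp(-(E - min(E[is.finite(E)])) / kT)
  h1 <- diff(x1)[1]; h2 <- diff(x2)[1]
  log(sum(w) * h1 * h2) - min(E[is.finite(E)]) / kT
}

#' Effective free-energy difference between hairpin states
#'
#' `G(unfolded) - G(folded)` of the whole bead-tether system at a fixed
#' trap separation, by numerical integration over the axial bead
#' coordinates. Includes the hairpin `dG0`.
#'
#' @param config An [assay_config()] with a hairpin.
#' @param trap_separation Trap separation, nm.
#' @return Free-energy difference in pN nm (positive: folded favoured).
#' @export
state_free_energy_difference <- function(config, trap_separation) {
  stopifnot(!is.null(config$hairpin))
  kT <- config$thermal$kT
  -kT * (state_log_z(config, trap_separation, "unfolded") -
         state_log_z(config, trap_separation, "folded"))
}

#' Calibrate the hairpin dG0 to a target mid-transition force
#'
#' Root-finds `dG0` so that the folded and unfolded states of the combined
#' system are equally occupied when the trap separation puts the
#' folded-state equilibrium force at `target_force`.
#'
#' @param config An [assay_config()] with a hairpin.
#' @param target_force Mid-transition force, pN.
#' @return A copy of `config` with the calibrated `hairpin$dG0`.
#' @export
calibrate_dg0 <- function(config, target_force) {
  stopifnot(!is.null(config$hairpin))
  d <- separation_for_force(target_force, config, "folded")
  cfg0 <- config
  cfg0$hairpin$dG0 <- 0
  dg_mech <- state_free_energy_difference(cfg0, d)
  config$hairpin$dG0 <- -dg_mech  # cancels: equal occupancy at d
  config
}

#' Boltzmann-consistent telegraph rates at a trap separation
#'
#' Splits a total rate `k_sum = k_fold + k_unfold` so that
#' `k_unfold / k_fold = exp(-dG_eff / kT)` with `dG_eff` from
#' [state_free_energy_difference()]; imposing these rates on the telegraph
#' process makes the simulated occupancies match the Boltzmann weights of
#' the two states.
#'
#' @inheritParams state_free_energy_difference
#' @param k_sum Total rate `k_fold + k_unfold`, 1/s.
#' @return `c(k_fold =, k_unfold =)` in 1/s.
#' @export
boltzmann_rates <- function(config, trap_separation, k_sum = 100) {
  dg <- state_free_energy_difference(config, trap_separation)
  p_unf <- 1 / (1 + exp(dg / config$thermal$kT))
  c(k_fold = k_sum * (1 - p_unf), k_unfold = k_sum * p_unf)
}
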