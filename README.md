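# rigidlink

Simulation and analysis toolkit for dual-trap optical tweezer assays
with rigid DNA helix-bundle linkers.

## The problem

Single-molecule force spectroscopy resolves conformational transitions
by watching two optically trapped beads connected through a molecule of
interest. The molecule is attached through linkers — classically soft
double-stranded DNA — and every degree of freedom of the bead–linker
system carries kT/2 of thermal energy, so soft linkers let the beads
wander and bury sub-nanometre transitions in noise, precisely in the
sub-10 pN regime where functionally relevant protein dynamics live.
Rigid beams self-assembled from N parallel cross-linked DNA helices
clamp the beads instead. This package provides the computational side of
that design, end to end, on synthetic data:

* **Polymer elasticity** — worm-like chain (Marko–Siggia interpolation),
  extensible WLC (substitution *l = x/L − F/K*), and the two-segment
  extensible freely-jointed chain
  *x(F) = L\[coth(Fb/kT) − kT/(Fb)\](1 + F/K)* that models a rigid
  bundle; series composition, inversion, stretch energies, and the
  parallel-bundle stiffness *k = N·K/L*.
* **Monte-Carlo assay simulation** (compiled core) — two beads in 3D
  anisotropic harmonic traps (0.4 / 0.04 pN/nm) joined by a series
  tether, Metropolis dynamics with simultaneous ±n coordinate moves,
  force-ramp and constant-trap-distance protocols, optional two-state
  DNA hairpin switched by an exponential-dwell telegraph process,
  100 kHz → 20 kHz block-mean downsampling.
* **Trace analysis** — moving-window noise profiles (SD of extension vs
  mean force, 200-sample window), apparent stiffness fits,
  bead-contact detection from deflection anti-correlation.
* **Kinetics** — Schmitt-trigger state assignment, maximum-likelihood
  dwell-time rates with censoring, two-state Gaussian hidden-Markov
  fitting (Baum–Welch + Viterbi, *k = a·f_s*), force-dependent rate
  tables.
* **Energy landscapes** — deflection histograms, empirical point-spread
  functions from hairpin-free controls, damped iterative constrained
  deconvolution, Boltzmann inversion *G = −kT ln p*, extension →
  released-contour-length mapping.
* **Beam shape statistics** — 2D-equilibrated worm-like chain ensembles
  with tracing jitter, backbone contour/end-to-end measurement, and
  persistence-length fitting from
  ⟨R²⟩ = 4pL\[1 − (2p/L)(1 − e^(−L/2p))\] with bootstrap CIs.

The methods vignette (`vignettes/rigid-linker-methods.Rmd`) documents the
models, conventions and numerical choices in detail.

## Worked example

A 6 bp DNA hairpin flanked by two ten-helix bundles, held at constant
trap distance tuned so the folded state carries 6.5 pN:

```r
library(rigidlink)

cfg <- preset_config("tenhelix_hairpin6", seed = 42)
cfg$step_size <- 3      # ~50% Metropolis acceptance
cfg$mc_rate <- 1e6      # 50 MC steps averaged per 20 kHz sample

part <- constant_distance_force_partition(cfg, folded_force = 6.5,
                                          duration = 2)
sprintf("folded state: %.2f pN   unfolded state: %.2f pN",
        part$force_folded, part$force_unfolded)
#> "folded state: 6.50 pN   unfolded state: 6.04 pN"
sprintf("extension separation between states: %.2f nm", part$extension_gap)
#> "extension separation between states: 2.31 nm"

tr <- part$trace
fit <- fit_hmm_two_state(tr$extension_nm, attr(tr, "sample_rate"))
fit
#> <hmm_fit means = 986/989 nm, sds = 0.898/1.05 nm, converged = TRUE>
#>   rates: k_unfold = 47 /s, k_fold = 48 /s
dwell_rates(fit$path, attr(tr, "sample_rate"), force = tr$force_pN)
#> <rate_estimate k_unfold = 43.3 +/- 6.5 /s, k_fold = 45.2 +/- 6.8 /s (n = 44 + 44 dwells)>
```

Unfolding releases 16 nt of ssDNA; at fixed trap distance the released
length relaxes the whole system, so the unfolded state carries ~0.46 pN
less force and the extension histogram splits by ~2.3 nm. The blind HMM
recovers the imposed 50/50 s⁻¹ switching rates from the extension signal
alone. The telegraph rates are inputs (Metropolis time is not physical
time); what the simulation predicts is the mechanics — forces,
separations, noise.

The numbered scripts under `analysis/` run the full studies and write
tables under `results/`: `01_noise_suppression.R` (floppy vs rigid
linker noise over 1–10 pN), `02_bundle_shapes.R` (traced-backbone shape
statistics and persistence-length fits), `03_apparent_stiffness.R`
(trap-limited apparent extensibility), `04_hairpin_kinetics.R`
(HMM/dwell rate recovery vs load), `05_energy_landscape.R` (PSF
estimation, deconvolution, Boltzmann inversion, reconvolution
consistency).

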