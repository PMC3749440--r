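---
title: "Simulating and analysing dual-trap assays with rigid DNA beam linkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing dual-trap assays with rigid DNA beam linkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rigidlink)
```

## The problem

In a dual-trap optical tweezer assay, the molecule of interest is held
between two micron-sized beads through molecular linkers, classically
double-stranded DNA. Every degree of freedom of the bead-linker system
carries $k_BT/2$ of thermal energy, so soft linkers let the beads wander
and bury sub-nanometre conformational signals in noise, precisely in the
low-force regime (below 10 pN) where protein and nucleic-acid
conformational dynamics live. Rigid DNA-origami helix bundles — N double
helices cross-linked in parallel — clamp the beads instead. This package
implements the computational machinery needed to study that design
quantitatively: polymer elasticity models and their series composition, a
Metropolis Monte-Carlo simulator of the two-bead assay, trace
post-processing, two-state kinetics estimators, free-energy-landscape
reconstruction by histogram deconvolution, and semiflexible-beam shape
statistics for bundle micrograph analysis. Everything runs on synthetic
data generated by the package itself.

Units throughout: nm, pN, pN·nm, s, Hz. The default thermal energy is
$k_BT = 4.18$ pN·nm (30 °C, the assay temperature).

## Elasticity models

Three closed-form force–extension laws cover the tether elements:

* **WLC** (`wlc_force`): the Marko–Siggia interpolation
  $F(x) = \frac{k_BT}{p}\left[\frac{1}{4(1-x/L)^2}-\frac14+\frac{x}{L}\right]$,
  used for short single-stranded DNA segments ($p = 1$ nm, $L = 15$ nm for
  the bead-attachment strands; released hairpin ssDNA at 0.59 nm/nt).
* **eWLC** (`ewlc_extension`): the same entropic law with an enthalpic
  term, written with the substitution $l = x/L - F/K$, so
  $x(F) = L\,(l(F) + F/K)$. The conventional dsDNA linker is
  $p = 50$ nm, $L = 530$ nm, $K = 1$ nN.
* **eFJC** (`efjc_extension`): the Langevin freely-jointed chain with
  Kuhn length $b = L/n$ and stretch factor $(1+F/K)$,
  $x(F) = L\left[\coth\frac{Fb}{k_BT}-\frac{k_BT}{Fb}\right](1+F/K)$.
  With $n = 2$ segments, $L = 485$ nm and $K = 10$ nN this is the
  ten-helix bundle: two essentially straight arms meeting at a flexible
  vertex, plus axial enthalpic stretching.

Elements combine in mechanical series (`series_extension`): common
tension, additive extensions. Stretch energies are exact closed forms
where available (WLC, Hookean) and adaptive quadrature via the Legendre
identity $E(x) = Fx - \int_0^F x(F')\,dF'$ otherwise. The helper
`expected_stiffness(N, K, L)` returns the ideal parallel-bundle stiffness
$NK/L$ (40 pN/nm for the ten-helix bundle at $L = 250$ nm).

## The Monte-Carlo engine

The system energy is two anisotropic 3D harmonic traps (0.4 pN/nm in the
two directions perpendicular to the laser beam, one of which is the
pulling axis; 0.04 pN/nm along the beam) plus the tether stretch energy
at the bead–bead distance. Beads are treated as points at the tether
ends; the energy function has no bead-surface term. A Metropolis step
perturbs all six bead coordinates simultaneously, uniformly within
$\pm n$, and accepts with probability $\min(1, e^{-\Delta E/k_BT})$.

Two protocols are provided. `simulate_pull` moves one trap away by
(pulling speed)/(MC rate) after every accepted step — 0.005 nm per
accepted step at the default 500 nm/s and 100 kHz — and records trap
separation, both deflections, force (mean of the two axial trap forces)
and extension (trap separation minus both axial deflections), block-mean
downsampled to the 20 kHz output rate. `simulate_constant_distance`
holds the traps fixed; with a hairpin present, a hidden telegraph
process with exponential dwell times switches the tether composition,
and the bead coordinates are re-equilibrated by unrecorded sweeps after
each switch, so every output sample is drawn from the equilibrium
ensemble of its current state.

Numerical choices worth knowing:

* **Tabulated tether energy.** The series-chain stretch energy is
  precomputed once per hairpin state on a 0.02 nm extension grid
  (cumulative trapezoid of $F\,dx$ along the explicit $x(F)$ curve) and
  linearly interpolated inside the compiled MC loop. The interpolation
  error is far below $k_BT$ everywhere. Extensions beyond the tabulated
  range (200 pN) give infinite energy, so the move is rejected rather
  than erroring.
* **Step size.** The default $n = 0.25$ nm is conservative;
  `tune_step_size` bisects to 40–60% acceptance (about 3 nm for these
  constructs), which decorrelates the soft bead modes orders of
  magnitude faster. Equilibrium *distributions* are exact for any step
  size; only mixing speed changes.
* **Measurement bandwidth.** Metropolis time is not physical time. The
  package's convention for constant-distance kinetics work is to run the
  MC clock fast relative to the output clock (e.g. `mc_rate = 1e6` Hz
  against 20 kHz output, i.e. 50 steps averaged per sample). The block
  averaging plays the role of the instrument's finite bandwidth: fast
  stiff-linker fluctuations average away while slow floppy-linker
  fluctuations survive, which is exactly the mechanism that makes rigid
  linkers resolve small transitions. Conditional means (e.g. the
  state-resolved forces) are unbiased under any of these settings.
* **Hairpin kinetics are imposed, not emergent.** Folding/unfolding is a
  telegraph process with user-specified rates, because Metropolis
  dynamics carries no physical timescale. Occupancies can be made
  Boltzmann-consistent with `boltzmann_rates`, which splits a total rate
  according to the effective free-energy difference of the two states
  (computed by numerical integration of the partition function over the
  axial bead coordinates — the transverse coordinates are
  state-independent Gaussians and cancel). `calibrate_dg0` root-finds
  the hairpin's zero-force unfolding free energy so both states are
  equally occupied at a target load.
* **Calibration error.** Real assays infer bead displacement from a
  calibrated detector; a relative sensitivity error propagates into
  force and extension. `assay_config(calibration_error = )` (default 0)
  reproduces this: with linkers much stiffer than the traps it yields
  the apparent extensibility $k_{app}$ far below $NK/L$ that *rises*
  with trap stiffness — the tell-tale that apparent bundle stretching
  is a displacement-calibration artefact.

## Trace analysis

`noise_profile` computes the SD of the extension signal and the mean
force in a moving window of 200 samples (stride 1). `ensemble_noise_sd`
averages profiles over an ensemble of simulated pulls in force bins; 20
pulls per arm is enough to order the linker systems cleanly over
1–10 pN, and 200 reproduces the reference ensemble.
`fit_apparent_stiffness` is a least-squares slope of force versus
extension in a force window; `detect_contact` finds the first sample
where the windowed Pearson correlation of the two deflection signals
drops below −0.25 (the beads-touching signature is a drop from 0 to about
−0.5).

## Two-state kinetics

`assign_states_threshold` is a Schmitt trigger (state flips only outside
a hysteresis dead band). `dwell_rates` uses the maximum-likelihood
exponential estimator $k = 1/\overline{\tau}$ on complete dwells —
censored boundary dwells are dropped — with $se = k/\sqrt{n}$.
`fit_hmm_two_state` is Gaussian-emission Baum–Welch (compiled
forward–backward, median-split initialisation, relative log-likelihood
tolerance $10^{-6}$, 500 iterations max) with Viterbi decoding. Rates
derive from the transition matrix as $k_{ij} = a_{ij} f_s$; the
alternative $-f_s\log(1-a)$ differs by under 1% for $a < 0.02$, which
covers every regime here. The fit reports `converged = FALSE` when EM
stalls or when the fitted means are closer than the pooled emission SD —
the regime where the two populations are not meaningfully resolvable, as
happens to noise-dominated floppy-linker recordings. Dwell and HMM
estimates agree within combined errors across $k$ from 10 to 1000 s$^{-1}$
at 20 kHz sampling.

## Landscape reconstruction

The deflection histogram of a constant-distance trace is the true state
density blurred by the measurement point-spread function. The PSF is
estimated empirically (`estimate_psf`) as the centered density of a
control construct without a hairpin, recorded together with its mean
force; a bimodal control is rejected as contaminated. `gaussian_psf`
provides an analytic fallback for synthetic work. When control
measurements exist at several loads, use the one nearest the working
force; no interpolation between PSFs is attempted.

`deconvolve` inverts the blur by damped additive (Jansson-type)
iteration: $p \leftarrow p + \lambda\,(m - \mathrm{psf}\otimes p)$ with
$\lambda = 0.5$, clamped to non-negative values and renormalized each
step, returning the iterate with the smallest reconvolution error.
Iteration stops when that error stops improving (windowed check,
relative tolerance $10^{-8}$) or at $10^4$ iterations. Round trips
recover two-Gaussian fixtures to well under 5% L2 error when the mode
separation is at least twice the PSF SD. `boltzmann_invert` then gives
$G(x) = -k_BT\ln p(x)$, with bins below $10^{-4}$ of the peak density
left undefined rather than infinite. `to_contour_length` maps the
extension axis to released ssDNA contour length — at fixed force the WLC
extends by a force-dependent fraction $z(F)$ per unit contour, so the map
is the linear rescaling $L_c = x/z(F)$ — followed by an alignment offset
of at most 5 nm that puts the folded-state minimum at zero. The default
bin width, 0.25 nm, is about a quarter of the typical PSF SD.

The reconvolution-consistency check closes the loop: blurring the
sharp-linker-derived density with the broad floppy-linker PSF must
reproduce the floppy-linker histogram (χ² at α = 0.01, on samples thinned
past the noise correlation time so that counts are effectively
independent). One caveat applies to fully simulated comparisons: a
stationary control trace contains slow fluctuations that 20 ms dwells
undersample, so the empirical PSF is slightly broader than the
within-dwell noise of the hairpin construct, and at large sample sizes
the χ² resolves that systematic even when the shape agreement is at the
few-percent level. The landscape analysis script reports both the χ²
and the L2 mismatch for this reason.

## Bundle shape statistics

Bundles adsorbed on an EM grid equilibrate in the plane, so the package
uses the 2D-equilibrated convention consistently: tangent correlation
$\langle t(0)\cdot t(s)\rangle = e^{-s/2p}$ with $p$ the 3D persistence
length, and
$\langle R^2\rangle = 4pL\left[1-\frac{2p}{L}(1-e^{-L/2p})\right]$
(`msd_end_to_end_2d`, evaluated in a cancellation-safe form; it matches
the numerical double integral of the tangent correlation to $10^{-6}$).
Whether the upstream beam theory intended the 2D or projected-3D
convention is not decidable from the available text; the 2D pair is
self-consistent, and the generator (`chain_ensemble_2d`) uses the same
convention, so fits are internally coherent. A sensitivity note: the
projected-3D convention would halve the decay length, i.e. rescale
fitted $p$ by a factor 2.

`chain_ensemble_2d` discretises chains into equal segments whose tangent
angle performs a Gaussian walk (variance $ds/p$ per segment), giving
exact arc length $L$; traced copies add iid Gaussian vertex jitter of one
2 nm pixel. `trace_backbone` measures arc length and end-to-end distance
after a moving-average smoothing (window 5 by default in the analyses,
with shrinking windows at the ends so no contour is clipped).
Backbone fixtures use a vertex every ~20 nm (about 10 pixels), the
spacing at which manual tracing of stiff filaments operates; at that
spacing the jitter-induced contour bias after smoothing is below 0.1%,
comfortably inside the 2% accuracy the analysis reports.
`fit_persistence_length` solves
$\langle R^2 \rangle_{\mathrm{model}}(p, \bar L) = \overline{R^2}$ by
root bracketing — deliberately using only the quantities the micrograph
analysis yields (contours and end-to-end distances), not
tangent-correlation decay — with a bootstrap percentile CI (1000
resamples). When $\overline{R^2}$ is within one standard error of
$\bar L^2$ the chains are straight at tracing resolution and the fit is
flagged `lower_bound_only`, as happens for the ten- and twelve-helix
ensembles.

Assumed stiffnesses for the tracing fixtures: 2 μm (six-helix) and
3.5 μm (eight-helix) are the fitted values; 6 μm and 9 μm for the ten-
and twelve-helix bundles are nominal extrapolations of the
cross-section scaling, used only where any sufficiently stiff value
behaves identically (contour accuracy, lower-bound behaviour).

## What the generators do and do not emulate

The synthetic data reproduce: thermal bead motion at the correct
Boltzmann statistics (equipartition is exact), entropic and enthalpic
tether elasticity, two-state hopping with exponential dwells,
force-dependent state separations, bandwidth-limited recording, tracing
jitter on backbones, and (optionally) deflection-calibration error.

They deliberately omit: hydrodynamic drag and real relaxation times
(Metropolis time is unphysical — kinetic quantities are inputs, not
predictions), bead-attachment compliance, beam crosstalk, hardware
anti-alias filters, instrument drift, and sequence-dependent hairpin
thermodynamics. Two consequences matter when comparing with real data.
First, recovered rate constants validate the *estimators*, not any
physical rate prediction. Second, the simulated floppy-linker hairpin
recordings at ~6 pN are cleaner than real ones (real dsDNA tethers carry
extra attachment noise), so the well-known failure of HMM analysis on
floppy-linker data is exercised on telegraph fixtures with realistic
noise rather than emerging from the tether model itself; what does
emerge from the MC is the ordering of the noise amplitudes, the
state-separation dilution, and the trap-limited apparent stiffness.

## Problem sizes

The shipped analyses and tests run at desk scale: 20–50 pulls per noise
ensemble (200 reproduces the reference curves), 500 chains per
persistence fit, 1.5–6 s of constant-distance trace at 20 kHz output,
and bootstrap sizes of 500–1000. These sizes put every sampling error
comfortably below the effect being measured while keeping each analysis
interactive; all are parameters, not constants.

## Reproducing the headline numbers

`scripts/acceptance.R` regenerates every input and recomputes, from the
installed package alone: the six- and eight-helix persistence-length
recoveries (≈2 μm and ≈3.5 μm), the worst-case traced-contour error
(≤2%), the folded/unfolded extension separation of the 6 bp hairpin at
its mid-transition load (≈3 nm), and the unfolded-state force when the
folded state is tuned to 6.5 pN (≈6.0 pN). See the README for how to run
it.
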