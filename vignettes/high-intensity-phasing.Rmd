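---
title: "Modelling heavy-atom ionization contrast for high-intensity phasing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling heavy-atom ionization contrast for high-intensity phasing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipxfel)
```

## The problem

Serial femtosecond crystallography collects one still diffraction snapshot
per microcrystal per XFEL pulse. At the peak fluences of an unattenuated,
sub-micrometre focus (~10^13 photons/um^2), a heavy atom such as Gd — whose
photoabsorption cross section at 8.48 keV is ~140 times that of carbon —
absorbs tens of photons during a 40 fs pulse. Each inner-shell absorption
triggers an Auger cascade that ejects several more electrons, so the atom's
scattering power collapses while the pulse is still on. Two data sets
recorded at different fluences therefore differ systematically at the
heavy-atom sites: an exploitable phasing signal ("high-intensity phasing"),
but also a complication for any analysis that assumes static form factors.

This package provides the pieces needed to quantify that effect for given
beam parameters, entirely on synthetic inputs: beam/focus arithmetic,
charge-state dynamics, pulse-weighted effective scattering strengths and
their fluctuations, fluence-proxy sorting of pattern metadata, and
electron counting on omit maps.

## Beam and focus model

The photon count per pulse is `E_pulse * attenuation * T_optics / E_photon`;
for the reference conditions (1.6 mJ, 30% optics transmission, 8.48 keV)
this is 3.53e11 photons. A 2-D Gaussian focus of FWHM 0.2 um then has peak
fluence `N / (2 pi sigma^2)` = 7.79e12 photons/um^2; attenuation to 1.73%
gives 1.35e11. The saturation fluence of Gd — one absorbed photon per atom
on average — is `1 / sigma_total` = 9.6e10 photons/um^2, so the attenuated
beam sits right at saturation while the full beam exceeds it ~81-fold.

A key closed form used throughout: for a 2-D Gaussian focus the fluence
*seen by the photons* (equivalently, weighted by scattered signal at
constant crystal thickness) is exactly uniform on `(0, F_peak]`. The
spatial average in the effective scattering strength therefore reduces to a
one-dimensional midpoint quadrature per focus component, verified in the
tests against brute-force 2-D integration. The crystal (>= 1 um across) is
assumed wider than the hot spot, so the integration domain is the infinite
focal plane and crystal-boundary clipping is not modelled.

Doses are estimates. The default convention multiplies the absorption
product `F * E_photon * mu_en/rho` by the mean-over-FWHM-disc factor 0.3385
when handed a peak fluence, because a peak-fluence ("point") convention
with any physically sensible protein absorption coefficient (~5 cm^2/g at
8.48 keV) overstates the conventionally quoted "average dose" several-fold.
Only dose *ratios* between conditions are convention-free. The conventions
`"point"` and `"photon_mean"` remain available.

## The reduced charge ladder

Full configuration-resolved ionization dynamics (Hartree–Fock–Slater rate
equations over millions of configurations) is out of scope for a desk
model. Instead, a single charge coordinate `q = 0..Z` carries the dynamics:

* cross section `sigma(q) = sigma_0 (1 - q/q_floor)_+`, linear to zero at
  the floor `q_floor` where remaining binding energies exceed the photon
  energy (for Gd at 8.48 keV the calibrated floor is 33; the L-III edge of
  Gd lies at 7.24 keV, so L-shell ionization shuts down once the ion is
  deep into its L shell);
* each absorption instantaneously ejects `1 + A` electrons, `A` uniform on
  {4..12} (Auger lifetimes of a few fs are folded into the instantaneous
  burst; the 4–12 range reflects the multi-step cascades of a heavy atom);
* cascade sizes are **truncated at the floor**: `A` is redrawn
  (renormalized) among sizes with `q + 1 + A <= q_floor`, and an event with
  no admissible size lands exactly at `q_floor`.

The truncation rule was a genuinely open design point. The alternative —
capping overshoot at `q_floor + max(A)` = 45 — was implemented and
measured: it drives the high-fluence atom ~10 charges past the floor and
yields a point-mode contrast of 29.1 e-, inconsistent with the 25 e-
reference value that the calibration is meant to reproduce, while the
floor-truncated ladder gives 58.4 / 32.8 / 25.6 e- (LF / HF / contrast).
Physically, the floor is the terminal charge of the *reduced* ladder; deep
cascade overshoot beyond it has no counterpart in the calibration data, so
the stricter truncation is kept and frozen.

For a flat-top pulse the generator matrix is time-independent, so the
one-step propagator `expm(A dt)` (via `Matrix::expm`) is exact at the grid
points. The requested step (default 0.05 fs, auto-halved until the per-step
absorption probability is < 0.1) only sets the resolution of the stored
trajectory and of the trapezoid time quadrature. Explicit Euler stepping
was rejected because it cannot reach the 1e-6 total-variation agreement
with the Poisson closed form (constant-sigma, no-cascade limit) that serves
as the analytic oracle; the exact propagator reaches machine precision.
Probability conservation is asserted to 1e-9 at every step.

A seeded event-driven Monte Carlo implements the identical jump process;
rate-equation and Monte Carlo mean charges agree within Monte Carlo
standard error across fluences 1e9–1e13 photons/um^2 (a property test).

## Effective scattering strength, gating, contrast

`effective_scattering_strength()` averages `Re f~(t)` over the flat-top
pulse and, in `"spatial"` mode, over the photon-weighted fluence
distribution. Two interpretation choices are frozen:

* the single-Gaussian reference numbers are **point mode** (hot-spot peak
  fluence, temporal weighting only); spatial averaging is used for the
  double-Gaussian focus. Only this reading reproduces ~57 e- at low
  fluence — a fully spatial single-Gaussian average gives 61.1 e-.
* the average is of `Re f~` (amplitude level), not `|f~|^2`: the
  intensity-level formulation is deliberately out of scope.

Bragg termination enters as a gate: both the numerator and the temporal
normalization are restricted to `[0, gate]`, i.e. the measurement only
integrates signal while lattice coherence persists. Gating the high-fluence
arm at 20 fs (low fluence ungated — at ~1 saturation fluence the lattice
survives the pulse) raises `f_eff(HF)` and lowers the contrast:

| quantity | point mode | double-Gaussian spatial |
|---|---|---|
| f_eff(LF) | 58.4 | 63.2 |
| f_eff(HF) | 32.8 | 48.3 |
| contrast | 25.6 | 14.9 |
| contrast, HF gated 20 fs | 23.9 | 10.9 |

(The double-Gaussian default is 50% of photons in the 0.2 um hot spot and
50% in a concentric 0.6 um pedestal.) These are the numbers the acceptance
tests pin, at ±3–4 e-.

## Fluctuations

`scattering_strength_std()` is defined as the standard deviation, over
Monte Carlo realizations (and photon-weighted fluence nodes in spatial
mode), of the per-realization time-averaged forward scattering strength —
the per-atom, per-pulse spread that static-form-factor software silently
averages over. At low fluence (point mode, n = 1e4) this gives ~5.3 e-,
consistent with the ~5.9 e- reference value.

## Sorting by fluence proxies

The on-crystal fluence of a snapshot is unobserved, but three recorded
quantities rise with it: the number of Bragg peaks, their average
integrated intensity, and the upstream pulse-energy monitor. The score is
the mean of the three empirical percentile ranks (midranks for ties) — a
scale-free statistic invariant under monotone recalibration of any single
proxy — and `select_best()` keeps the top fraction (default 0.33, the
ratio of the published "best" subset to its parent set). On the default
synthetic stream the top third has ~1.8x the mean true fluence of the full
stream and the score–fluence rank correlation is ~0.87. The exact
selection recipe used in practice varies by experiment; the midrank score
is this package's documented, reproducible stand-in.

## Electron counting on omit maps

Atoms are rendered as isotropic 3-D Gaussians with integral
`occupancy * n_electrons` and variance `B / (8 pi^2)` — single Gaussians,
not form-factor sums, which suffices because the counting procedure is a
*ratio*: positive density integrated over a sphere (default radius 2.0 A)
around the heavy site, divided by the same integral over a union of
spheres covering an eight-atom, 48-electron carbon-like reference group,
times 48, times the occupancy correction `occ_ref / occ_target`. The
estimate is invariant under global map scaling, so the missing
structure-factor machinery (space groups, FFT map synthesis, refinement)
cannot affect it. Repeating the calibration against alternative reference
groups yields the relative uncertainty, mirroring the ~20% error bar this
procedure carries on real data.

On planted ground truth (two Gd sites at occupancies 1.0 and 0.7 whose
electron counts differ by 25 between conditions), the recovered contrast is
within 0.1% on a fine noiseless grid and within ~3% at the default map
noise of 0.05 e-/A^3 — comfortably inside the 5% / 20% acceptance bands.

## What the synthetic world does and does not establish

The generators emulate: pulse-energy jitter (gamma, ~10% relative),
pointing/crystal-position coupling (lognormal, sdlog 0.8 — the dominant
fluence spread), fluence-linked peak counts (Poisson with saturating
mean), intensity and resolution laws with multiplicative noise, and
omit-map noise as white Gaussian density error. They do not emulate:
detector physics, indexing failures, non-isomorphism, scaling artifacts,
Bragg-termination physics (the gate time is an input, not predicted), or
secondary/collisional ionization of the lattice. A green sorting or
densitometry test therefore establishes that the *procedures* recover
planted truth under realistic noise — not that the experimental values
(8.8–12 e- observed contrast, 9.0/6.2 sigma peaks) are reproduced; those
depend on unavailable raw data and on physics (plasma environment, charge
transfer) explicitly outside the reduced model.

## Numerical choices

* Master equation: exact per-step propagator, default grid 0.05 fs,
  conservation asserted to 1e-9; trapezoid time quadrature with a node
  inserted exactly at the gate.
* Spatial quadrature: 32 midpoint nodes per focus component; doubling the
  node count moves f_eff by < 0.1 e- (tested).
* Degenerate inputs: zero fluence short-circuits to the neutral atom;
  gates beyond the pulse duration are clipped with a recorded warning;
  ties in sorting share midranks and selection breaks residual ties by id.
* All stochastic entry points take an explicit seed, restore the caller's
  RNG state, and record the seed in their result.

## Known limitations

* **High-fluence fluctuation (red acceptance expectation).** In point mode
  the reduced ladder drives every realization to the floor within ~4 fs at
  7.8e12 photons/um^2, so the realization-to-realization spread of the
  time-averaged scattering strength collapses to ~0.9 e-, far below the
  ~10.6 e- reference value (the corresponding low-fluence number, ~5.3 vs
  5.9 e-, is fine). Measured alternatives: single-Gaussian spatial mode
  gives LF 4.3 / HF 6.7 e-; double-Gaussian spatial mode gives LF 2.5 /
  HF 10.8 e- (the HF value matching the reference almost exactly). No
  single mode reproduces both reference numbers, which suggests the
  reference fluctuation mixes sources (configuration-level stochasticity,
  spatial heterogeneity) that the one-coordinate ladder separates. The
  acceptance test keeps the point-mode definition used for the headline
  contrast numbers and is intentionally left failing rather than
  redefined per number.
* The ladder has no configuration structure: anomalous corrections are
  zero by default, Q-dependence only enters through user tables, and
  recombination/electron transfer from neighbours is absent.
* The double-Gaussian low-fluence value (63.2 e-) overshoots its ~59 e-
  reference; the contrast (the quantity the analysis uses) is within 0.2
  e- of its reference.
* Dose absolute scales are convention-bound estimates (see above).
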