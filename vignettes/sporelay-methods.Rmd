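---
title: "Modelling sporulation initiation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sporulation initiation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sporelay)
```

## The model

`sporelay` implements a deterministic kinetic model of the decision network
that commits *Bacillus subtilis* to sporulation. Thirteen species — the lac
repressor and its IPTG-bound inactive form, the histidine kinase KinA (free,
dimeric and phospho-dimeric), the phosphorelay proteins Spo0F, Spo0B and
Spo0A with their phospho-forms, the eight transcripts, and the six *spoII*
effector proteins AA/AB/AC, IIE and GA/GB — give rise to 27 molecular forms.
Two of them, IPTG and the abstract sporulation signal SS, are clamped
boundary inputs. The network comprises 55 unidirectional reactions: 29
synthesis/translation/binding/phosphotransfer reactions with published rate
laws, one first-order Spo0B~P dephosphorylation, and one first-order
degradation per non-clamped form.

Rate laws are mass action, constant synthesis, or Hill-type transcription:

* *kinA* transcription: `(k1 + k2·KL²/(KL² + [LacI]²)) · (1 + k3·[Spo0A~P]²/(KS² + [Spo0A~P]²))`
  — cooperative LacI repression (released by IPTG sequestering LacI into
  LacI_d) times a Spo0A~P fold-activation;
* *spo0F* transcription: basal plus second-order Spo0A~P activation;
* *spo0A* transcription: a decreasing first term (`k1·Kk1/(Kk1+[Spo0A~P])`)
  plus second-order activation;
* *spoII* promoters: basal plus fourth-order Spo0A~P activation.

Translation is first-order in the cognate transcript throughout. (The
published table prints three translation laws as first-order in the protein
itself; these are treated as typographical slips for the transcript, which
is the stated modelling rule and the only reading that yields finite
steady states.) Dimerization consumes two KinA per dimer; only the
unphosphorylated dimer dissociates. Phosphotransfer follows
KinA₂~P → Spo0F → Spo0B → Spo0A, with first-order Spo0F~P and Spo0A~P
drains standing in for the Rap/Spo0E phosphatases. The all-zero state is a
legal initial condition: every Hill denominator carries a positive constant.

## Units and input scales

All concentrations are expressed in a single internal unit, the nM of the
kinetic-constant table, with time in seconds. The published outputs label
concentration axes in μM while printing values that are numerically
consistent only with the nM constants; the package therefore compares
kinase-side quantities (e.g. the total-KinA dose-response endpoints 200 and
2800) as raw model numbers, and converts the Spo0A accumulation benchmarks
(4.5 and 37.5 μM), which are genuine μM quantities, by nM/1000 in
`wildtype_discrepancy_report()`. On this reading a phospho-Spo0A level of a
few model units at full induction reads "of the order of μM" on the printed
axes, exactly as the source describes.

The IPTG dosing axis (levels 0–20) is mapped to an intracellular
concentration by the constant `IPTG.scale`: at the printed sequestration
constants (k1 = 1.75e-4 nM⁻¹s⁻¹ against a reactivation rate of 0.016 s⁻¹) a
level of 0–20 taken literally as nM would divert at most ~18% of LacI and
produce essentially no induction, so the axis cannot be the intracellular
concentration itself. The sporulation-signal axis (0–2) is used unscaled: at
`k5 = 0.001 nM⁻¹s⁻¹` this keeps the autophosphorylation drive below the
Spo0F-mediated drain, giving the linear (unsaturated) signal response the
published scans show; scaling it like IPTG would saturate the kinase
immediately.

## Implicit constants and their one-time calibration

The published tables omit every degradation constant, the Spo0B~P free
dephosphorylation rate, the nominal SS level, and the IPTG axis scale. The
package fixes them once, ships them frozen in `spore_parameters()`, and
never adjusts them per analysis:

* `d_mRNA = 0.01 s⁻¹` — a typical bacterial transcript half-life (~70 s),
  shared by all eight transcripts.
* `d_prot = 9.102e-4 s⁻¹` — shared by all seventeen protein forms, solved by
  root finding so that the basal steady-state total KinA (zero induction,
  nominal SS) equals the published endpoint of 200. This endpoint pins the
  product `d_mRNA·d_prot` and is independent of the IPTG scale.
* `IPTG.scale = 679.1` — solved so that total KinA doubles ("about 100%
  increase") between induction levels 4 and 10, the published mid-range
  anchor.
* `kBdeph = 1e-4 s⁻¹` — a small first-order Spo0B~P drain. The source is
  contradictory about this reaction (it is excluded in the design section
  and invoked in the sensitivity results); it is included, kept small, and
  toggleable via `kBdeph.k = 0`.
* `SS_in = 0.5` — the nominal sporulation signal. The natural design rule
  (smallest round value with basal phospho-Spo0A below 5% of its
  full-induction value, while nonzero) turns out to be unsatisfiable: both
  quantities are linear in SS, so their ratio (~6.8%) is SS-independent.
  0.5 is a small round value inside the scanned signal range that yields the
  intended weakly-activated basal state.

Degradation constants are materialized per form (`deg_<form>.k`) when the
network is built, so sensitivity analyses can perturb a single turnover
reaction the way a per-reaction simulator does; assigning `d_mRNA`/`d_prot`
through `set_parameters()` re-propagates the shared values.

## What the calibrated model can and cannot reproduce

With the basal endpoint pinned at 200, steady-state LacI sits near 2200 nM
and the repression law caps induction at `(k1+k2)/k1 ≈ 9.7`-fold; the same
shared turnover fixes the phosphorelay pools (total Spo0F ≈ 158, total
Spo0B ≈ 2811, total Spo0A ≈ 326). Phosphotransfer through
`k8 = 1e-5 nM⁻¹s⁻¹` against the 0.05 s⁻¹ Spo0A~P drain then keeps
phospho-Spo0A at the few-nM scale at any reachable stimulus — three orders
of magnitude below the 2100 nM half-saturation of its transcriptional
feedback on *kinA*. Consequences, all computed by the shipped tests and
acceptance analyses:

* the upper dose-response endpoint reaches ≈1784 rather than the published
  2800 (the published 14-fold span needs the feedback to contribute);
* the feedback knockout changes the phospho-KinA dose-response only at the
  1e-6 relative level, so refitting the two repression constants trivially
  meets the published ≤1.72% compensation distance;
* phospho-Spo0B rises monotonically along the induction scan instead of
  showing the published non-monotonicity, and the *spoII* effectors respond
  only marginally (their fourth-order activation thresholds of 140–1700 nM
  are never approached);
* in the Spo0B-translation scan, phospho-Spo0B and phospho-Spo0A track the
  Spo0B pool with elasticity ≈0.65 instead of being insulated from it.

The last point reflects a genuine tension in the published sensitivity
claims: insulation of phospho-Spo0B from the Spo0B pool requires
`k8·[Spo0B] ≫ k7` (phosphotransfer-dominated Spo0F~P turnover), while a
unit sensitivity of phospho-Spo0B to the phosphotransfer rate itself
requires `k8·[Spo0B] ≪ k7`. No parameterization satisfies both; the shipped
model sits in between (`k8·[Spo0B] ≈ 0.028` against `k7 = 0.05`), which is
why the per-rate sensitivity bound reports ≈0.645 for the phosphotransfer
rate while the five synthesis/turnover rates reach ≈1.0. These findings are
reported as-is rather than being tuned away; the corresponding acceptance
checks are intentionally left failing at the published values.

## Numerics

*Integration.* `simulate()` uses the stiff-capable `deSolve::lsoda` with
relative tolerance 1e-8 (absolute 1e-10); reported states clip round-off
undershoot at −1e-9. Trajectories are invariant to ~1e-6 under tolerance
halving (tested).

*Steady states.* `steady_state()` runs a damped Newton iteration on the 25
free forms (finite-difference Jacobian, step halving on the residual
max-norm, projection onto the nonnegative orthant) to a derivative max-norm
of 1e-9 nM/s; on failure it falls back to integration in growing chunks with
Newton re-polish and reports which route converged. Cold starts integrate
from the all-zero state first. Scans warm-start each point from the previous
solution; `dose_response()` re-solves its last point cold and reports the
relative deviation (`hysteresis`, ~1e-15 here — the model is monostable on
the scanned envelope, so warm starting is purely an efficiency device).

*Sensitivities.* Relative coefficients S = (p/c)·(∂c/∂p) are computed by
central differences with relative step 1e-3, re-solving the steady state at
each perturbed value; if the two one-sided secants disagree by more than 10%
the step is halved (up to three times). Entries are reproducible to three
significant figures under step halving. A target sitting at exactly zero
concentration with zero response is assigned S = 0 by continuity; a failed
perturbed solve flags the entry as NA rather than zeroing it. Zero-valued
nominal parameters have no relative coefficient and report 0.

*Compensation refit.* `compensate_repression_params()` minimizes the mean
relative distance between phospho-KinA-dimer curves over (`tr2.k2`,
`tr2.KL`) only, on log scale, with Nelder–Mead followed by an L-BFGS-B
polish, bounded to [0, 10×] and [1, 20×] the nominal values. The objective
is the package's own `goodness_of_agreement()` metric, the published
curve-comparison measure.

## Synthetic data

The generators exist so every pipeline stage is testable without external
data. Dose-response observations take the deterministic steady-state curve
and apply multiplicative Gaussian noise (coefficient of variation `cv`,
truncated at −90%) — appropriate because the concentrations span orders of
magnitude and the comparison metric is relative. Wild-type time courses are
straight lines per species plus additive Gaussian noise of constant scatter,
the statistical structure of the single-cell accumulation measurements the
wild-type comparison refers to; the default slopes bring total Spo0A to the
37.5 μM benchmark over 150 min. Both are pure functions of their explicit
seed and leave the caller's RNG state untouched. They emulate noise
structure only — not digitization error, not cell-to-cell heterogeneity, and
not the true (unknown) error model of the published experiments — so passing
recovery tests demonstrates that the fitting machinery is sound, not that
the model fits real measurements.

`parameter_recovery_study()` closes the loop: simulate noisy observations,
perturb chosen constants, refit by minimizing the distance metric, report
relative errors. A structurally non-identifiable pair (e.g. Spo0B
transcription × translation, which enter the steady state only through
their product with turnover) is recovered as a product while the individual
factors stay at their starting offsets — a useful diagnostic mirror of the
steady-state algebra.

## Problem sizes

The shipped test-suite analyses use 21-point dose-response grids (induction
0–20, signal 0–2), an 11×11 (tests) or 21×21 (acceptance script) stimulus
envelope with an additional 10×-widened coarse envelope for the Spo0A
ceiling, six perturbed rates × 25 forms for the sensitivity matrix, and 20
replicates for the recovery study — sizes at which every analysis is exact
to solver tolerance and the full suite runs in minutes on one CPU.

## Limitations

Stochastic simulation is out of scope (deliberately, as in the source
study), as are the kinases KinB–KinE, SinI/SinR, AbrB, explicit Rap/Spo0E
phosphatases, cell-cycle modulation and the downstream sigma-factor
cascade. The SBML importer targets the dialect the exporter writes (rate
laws are recognized by reaction id); it is not a general SBML reader. The
degradation constants, the signal level and the induction-axis scale are
calibrated quantities, not measurements, and analyses that depend on the
absolute phosphorelay pool sizes inherit that uncertainty.
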