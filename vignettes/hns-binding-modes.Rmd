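---
title: "Models and methods behind hnsmodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hnsmodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hnsmodes)
```

H-NS is a bacterial nucleoid-associated protein with two mutually exclusive
DNA binding modes: lateral polymerisation along one duplex (stiffening) and
bridging of two duplexes. This vignette documents the models implemented in
`hnsmodes`, the assumptions behind them, the tunable parameters, the
numerical choices, and what the synthetic-data generators do and do not
emulate.

## Cooperative lattice binding

### The isotherm

A protein covering `n` contiguous base pairs on a long DNA lattice, with
intrinsic association constant `K` (per unit free protein concentration)
and a multiplicative cooperativity `omega` for each pair of protomers in
direct contact, follows the McGhee–von Hippel isotherm. With `theta` the
bound-protein density per base pair and `d = n * theta` the fractional
saturation,

$$
\frac{\vartheta}{c} = K(1-n\vartheta)
 \left[\frac{(2\omega-1)(1-n\vartheta)+\vartheta-R}{2(\omega-1)(1-n\vartheta)}\right]^{n-1}
 \left[\frac{1-(n+1)\vartheta+R}{2(1-n\vartheta)}\right]^{2},
\qquad
R = \sqrt{(1-(n+1)\vartheta)^2 + 4\omega\vartheta(1-n\vartheta)} .
$$

Assumptions worth stating: the lattice is effectively infinite and
homogeneous (no sequence dependence), binding is at equilibrium, and the
titrated protein concentration is treated as the *free* concentration —
appropriate when protein is in large excess over lattice sites, which is
the regime of a TPM flow cell. At `omega = 1` the cooperative bracket is a
0/0 form, so for `|omega - 1| < 1e-8` the code switches to the algebraic
non-cooperative limit
$\vartheta/c = K(1-n\vartheta)[(1-n\vartheta)/(1-(n-1)\vartheta)]^{n-1}$;
continuity across the switch is tested to 1e-6.

### Inversion

`c(theta)` is strictly increasing on `[0, 1/n)`, so `mvh_coverage` inverts
it by bisection. The iteration stops when the implied concentration matches
the target to better than 1e-13 relative (or the bracket is exhausted at
machine precision). A fixed tolerance on `theta` alone would not do: near
saturation `d ln c / d theta` grows like `n/(1-d)`, and the package
guarantees the round trip `mvh_concentration(mvh_coverage(c)) = c` to 1e-9
relative across eight decades of concentration, which requires terminating
on the concentration residual.

### The finite-lattice oracle

Because the isotherm is itself an approximation (an infinite-lattice
limit), the package carries an independent exact reference:
`finite_lattice_coverage` computes the grand-canonical partition function
of a *linear* lattice of `M` sites by a transfer-matrix recursion over the
position of the last covered site, with per-step rescaling so neither `M`
nor `K*c` can overflow. The mean occupancy comes from the simultaneous
recursion for the derivative with respect to `log(K*c)` — no numerical
differentiation. A linear (non-periodic) lattice was chosen over a ring;
the two differ only by edge terms of order `n/M`, irrelevant at the
`M = 3000` used for validation (worst observed deviation from the isotherm
is about 3e-3 in `d` for `n <= 3`, `omega <= 100`). The tests also verify
the recursion against exhaustive enumeration at `M = 4, n = 2`, where the
five configurations can be written down by hand.

### Weighted orthogonal distance regression

`fit_binding` estimates `(K, omega)` at fixed `n` (30 bp for H-NS, the
established footprint) from points `(c_i, d_i)` with inverse-variance
weights. No ODRPACK-style solver ships with R, so the estimator is written
out directly. Positivity is enforced by optimising `(log K, log omega)`;
a Nelder–Mead sweep is followed by a tight quasi-Newton refinement
(`nlminb`, relative tolerance 1e-14). When only coverage-axis weights are
given — the default, since TPM concentration is set by pipetting and its
error is not quantified — the orthogonal distance collapses to weighted
vertical residuals. When `weight_c` is supplied, each point's latent
concentration is profiled out by an inner one-dimensional minimisation,
recovering classical ODR behaviour. Standard errors come from the
Gauss–Newton covariance `(J'WJ)^{-1}` scaled by the reduced chi-square and
mapped from log space by the delta method. Starting values are
`K0 = 1/c_half` (reciprocal concentration at half saturation) and
`omega0 = 1`; over the tested grid `K` in {0.01, 0.1, 1}/µM × `omega` in
{1, 10, 100} the noiseless fit recovers the truth to well below 0.1%
relative, so the optimiser's basin is comfortably wide at these scales.

Non-convergence is reported through the `converged` flag, never silently;
fewer than three points, or fewer than two with `0 < d < 1`, raise a
degenerate-data error.

## The TPM chain

TPM reports the root-mean-square excursion of a bead tethered by one DNA
molecule; protein binding stiffens the tether and raises the RMS. The
calibration for a 685-bp tether is

$$\mathrm{RMS} = a - b\,(1+\alpha L_p)^{-\beta}$$

with `a = 233` nm, `b = 156` nm, `alpha = 0.08`/nm, `beta = 0.45`. The
negative exponent is the only monotone-increasing reading consistent with
stiffening raising the RMS, and it pins the admissible RMS window to
(77, 233) nm; measurements outside it cannot be inverted and are reported
as rejects rather than fitted. Coverage follows by reciprocal
interpolation between the naked and saturated persistence lengths,

$$ d = \frac{1/L_{p,\mathrm{meas}} - 1/L_{p,\mathrm{naked}}}
           {1/L_{p,\mathrm{sat}} - 1/L_{p,\mathrm{naked}}} , $$

i.e. the complex's flexibility (inverse persistence length) is taken as
linear in coverage. Reference values default to the mean of the rows
flagged `naked`/`saturated`; those rows pin the coverage scale and are
excluded from the regression itself — a saturated reference sits at
`d = 1` by construction, which the isotherm only reaches asymptotically.
Noise-driven excursions of `d` outside [0, 1] are clipped for fitting, with
raw values retained and a warning past 0.05.

Weights propagate the standard error of the per-condition mean RMS
(`sd/sqrt(n_beads)`) through both transforms by the delta method using the
exact derivatives; the variance floor of 1e-12 only guards the noiseless
limit against division by zero.

## MD trajectory statistics

All trajectory analyses share three conventions: the first 10 ns of each
replica are excluded as equilibration (configurable `burn_in`; a frame at
time `t` is retained iff `t > burn_in`, and results are tested to be
identical whether burn-in frames are skipped internally or deleted
beforehand); retained frames are pooled across replicas with equal weight,
so replicas of unequal length contribute proportionally to their retained
frames; and per-residue profiles are averaged over the two monomers, with
residues aligned by their 1-based index within each chain.

Distances use heavy atoms only. The 0.6 nm contact cutoff is a heavy-atom
scale, and the synthetic fixtures carry no hydrogens; whether the original
GROMACS-based maps included hydrogens is not documented, so the convention
is fixed here explicitly. Minimum-image distances are applied when a box is
present; the geometric fixtures are non-periodic.

* `contact_map`: P[i,j] is the fraction of retained frames in which the
  minimum heavy-atom distance between residues i and j is at most the
  cutoff; symmetric, unit diagonal.
* `ion_contact_profile`: per residue, the fraction of retained frames with
  *at least one* ion of the species within the cutoff — a probability, not
  an expected ion count.
* `domain_contact_summary`: both directions (each dimerization-domain
  residue against any DNA-binding-domain residue of either monomer, and
  vice versa) are reported explicitly, since the P_1-40 / P_96-137 naming
  convention is used inconsistently in the literature.

### Helix buckles

Helical integrity along the long central helix (alpha3, residues 22–67) is
monitored through the backbone O(i)···N(i+4) distance, the heavy-atom
proxy for the helical hydrogen bond, with a 0.35 nm formation threshold.
`detect_buckle_events` finds maximal runs above threshold, merges
sub-threshold gaps up to `gap_tolerance = 0.05` ns, and discards events
shorter than `min_duration = 0.1` ns. The two constants are this package's
own anti-flicker defaults for a 10 ps frame cadence — ten frames minimum,
five frames of tolerated gap — and are configurable; no published value
exists for either. An event is `irreversible` when it extends to the final
frame (the helix never reforms within the trajectory), `reversible`
otherwise: classification is conditional on the observation window by
construction. Event duration is counted as frames × cadence, including
merged gaps.

## Bridging quantification

Recovery normalises background-corrected counts to a reference sample
carrying the full labelled-DNA input:
`100 * (sample - background) / (reference - background)`. The reference is
assumed to share the background subtraction — the natural reading when the
background is a no-protein sample counted identically. Negative corrected
counts are floored at 0 for reporting, with raw values kept for statistics;
replicate aggregation uses mean counts, making the mean of recoveries equal
the recovery of means. The four-parameter logistic
`y = A + (B - A)/(1 + exp(-k(x - m)))` (fit with `k > 0` via `log k`;
direction is the sign of `B - A`; 10–90% width `log(81)/k`) is a
characterisation layer this package adds on top of the raw recoveries —
transitions in the literature are usually described qualitatively — and is
reported separately so nothing downstream depends on it. Curves with
amplitude under 5 percentage points return a no-transition result rather
than an ill-posed fit.

## What the generators emulate — and what they do not

`gen_tpm_dataset` runs the *forward* analysis chain (isotherm → reciprocal
interpolation → calibration) plus Gaussian noise on the per-condition mean
RMS. Defaults are the study conditions of a typical H-NS titration:
`K = 0.1`/µM, `omega = 10`, `n = 30` bp, `Lp` 50→300 nm, per-bead sd 4 nm,
70 beads per condition, and a 14-point log-spaced grid from 3.2 nM to
31.6 µM chosen so saturation spans <0.1 to >0.9 (a spec the constructor
enforces). Because generator and analysis share the same forward model,
noiseless recovery tests are *self-consistency* checks; the simulation
studies with noise probe estimator robustness, not model misspecification.
Real titrations can violate the model (ligand depletion, heterogeneous
sites, drift), and passing tests say nothing about that.

`gen_trajectory` writes geometric fixtures, not physics: ideal alpha-helical
backbones (canonical dihedrals, giving O(i)···N(i+4) ≈ 0.30 nm), with
events that *directly encode the observables the analyses measure* — an
exact O···N distance during a buckle window, an exact minimum-distance
contact, an ion parked at an exact distance. Frame cadence defaults to
10 ps and duration to 50 ns, matching the analysis regime the package
targets; tests and the acceptance script use shorter fixtures (tens of
residues, 0.05–2 ns) because event recovery is exact by construction and
longer fixtures only add identical frames. Coordinates are written in
Ångström (PDB convention) and converted to nm on read; PDB's three decimal
places bound the read-back error at 5e-5 nm. What these fixtures do not
contain: force-field realism, side chains, solvent, correlated motion, or
any thermodynamics — conclusions about real simulations rest on the
correctness of the measurement code, which is what the fixtures test.

`gen_bridging_counts` draws Poisson counts around
`background + recovery/100 * (total - background)` at the ~8000 cpm scale
of a radiolabelled assay, in triplicate, with background and reference rows
included so the analysis path is identical to real data.

All generators are bit-reproducible functions of (spec, seed).

## Problem sizes and runtime choices

Validation sizes were chosen as the smallest that make the checks sharp:
`M = 3000` lattice sites (edge effects ~`n/M` are then well below the 1e-2
comparison band), 20-seed simulation studies for standard-error coverage,
100 seeds for the bridging mean (Poisson error of the mean ≈ 0.16
percentage points), and 40–51-frame trajectory fixtures whose scripted
occupancies are exact rational fractions (30/40 = 0.75). The full test
suite runs in well under a minute on one core.

## Known limitations

* Free-concentration treatment ignores ligand depletion; do not use the
  fit for stoichiometric-regime titrations.
* The site size `n` is fixed, not estimated; the profile likelihood in `n`
  is flat over wide ranges for this class of data.
* Contact analyses are O(frames × residue-pairs) in plain R; ensembles of
  hundreds of thousands of frames at full protein size will be slow —
  subsample frames first.
* `irreversible` is relative to the trajectory end; longer simulations can
  reclassify events.
* The ODR covariance is the usual asymptotic Gauss–Newton approximation;
  with very few points or near-flat directions (`omega` at low saturation)
  the 2-sigma intervals are approximate, which the 20-seed coverage check
  quantifies.
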