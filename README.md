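# hnsmodes

Analysis toolkit for experiments on the bacterial nucleoid-associated
protein **H-NS**, which switches between two DNA binding modes: lateral
filament formation that *stiffens* a single DNA duplex, and *bridging* of
two duplexes. The package implements the quantitative analyses such studies
rely on, for anyone running tethered particle motion (TPM) titrations,
molecular dynamics (MD) ensembles of the H-NS dimer, or pull-down
DNA-bridging assays:

* **Cooperative lattice binding.** The McGhee–von Hippel isotherm for a
  large ligand covering *n* lattice sites (bp) with intrinsic association
  constant *K* and nearest-neighbour cooperativity *ω*:

  ```
  ϑ/c = K(1 − nϑ) · [((2ω−1)(1−nϑ) + ϑ − R) / (2(ω−1)(1−nϑ))]^(n−1)
                  · [(1 − (n+1)ϑ + R) / (2(1−nϑ))]²
  R   = sqrt((1 − (n+1)ϑ)² + 4ωϑ(1−nϑ))
  ```

  with ϑ the bound-ligand density per site and *d* = *n*ϑ the fractional
  saturation. Forward evaluation (`mvh_concentration`), numerical inversion
  (`mvh_coverage`), an **exact finite-lattice transfer-matrix reference**
  (`finite_lattice_coverage`) for validating the infinite-lattice limit,
  and estimation of (*K*, *ω*) at fixed *n* by **weighted orthogonal
  distance regression** (`fit_binding`, returning a classed model object
  with `print`/`summary`/`coef`/`vcov`/`predict`/`plot`/`residuals`/
  `simulate` methods).

* **TPM pipeline.** RMS bead excursion → apparent persistence length via
  the empirical calibration `RMS = 233 − 156(1 + 0.08·Lp)^(−0.45)` (nm),
  persistence length → fractional coverage by reciprocal interpolation
  between naked and saturated references, delta-method propagation of the
  per-condition standard error into fit weights, and the end-to-end
  inference `fit_tpm` (site size fixed at 30 bp for H-NS).

* **MD conformational statistics.** Residue–residue contact-probability
  maps (0.6 nm minimum heavy-atom distance cutoff), per-residue ion contact
  profiles (P_Mg²⁺, P_K⁺, P_Cl⁻), inter-domain contact probabilities
  (dimerization domain 1–40 vs DNA-binding domain 96–137), and helix-buckle
  analysis from backbone O(i)···N(i+4) hydrogen-bond distances
  (0.35 nm threshold; events classified reversible/irreversible), all with
  burn-in exclusion and replica/monomer averaging. Trajectories are read
  from multi-model PDB.

* **DNA-bridging quantification.** Background-corrected,
  reference-normalised recovery of prey DNA from scintillation counts, and
  four-parameter-logistic characterisation of titration transitions
  (midpoint, 10–90 % width, direction).

* **Seeded synthetic-data generators** (`gen_tpm_dataset`,
  `gen_trajectory`, `gen_bridging_counts`) produce every input the analyses
  consume with exactly known ground truth, so the whole chain is testable
  without instrument data.

## Worked example

A synthetic TPM titration with realistic measurement noise (per-bead RMS
sd 4 nm, 70 beads per condition), generated with true *K* = 0.1 /µM,
*ω* = 10, *n* = 30 bp, and re-analysed end to end:

```r
library(hnsmodes)
ds  <- gen_tpm_dataset(tpm_gen_spec(noise_sd = 4, seed = 2))
fit <- fit_tpm(ds)
summary(fit)
#> McGhee-von Hippel cooperative binding fit
#>   site size n = 30 bp (fixed), 14 points, converged
#>       Estimate Std. Error  CI95 lo CI95 hi
#> K     0.114005   0.007812 0.099678    0.13
#> omega 8.850927   0.719003 7.548146   10.38
#>   weighted residual norm: 17.29
```

Both true parameters sit inside their 95 % intervals: the titration
recovers an association constant of ≈0.11 /µM and cooperativity ≈9 from
noisy bead excursions alone. A bridging titration programmed to switch at
5 mM Mg²⁺ (Poisson counting noise at the ~8000 cpm scale of a
³²P-labelled-DNA assay):

```r
x <- seq(0, 12, 2)
counts <- gen_bridging_counts(axis = x, recovery = 60 / (1 + exp(-2.2 * (x - 5))),
                              seed = 2)
titration_transition(recovery_curve(counts))
#> Titration transition: midpoint 5.047, 10-90% width 2.068, direction +1
#>   plateaus: -0.0447% -> 60% recovery
```

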