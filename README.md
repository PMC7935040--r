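# connectrl

Network controllability of structural connectomes and its gray-matter
correlates.

## What this package is for

In network control theory the brain is modeled as a noise-free linear
discrete-time system over its white-matter scaffold,

    x(t+1) = A x(t) + B u(t),

where `A` is a region-by-region structural connectivity matrix (streamline
counts from tractography) and `B` selects the regions receiving a control
input. Two nodal statistics summarize how well a single region can steer
this system:

* **Average controllability (AC)** — the trace of the controllability
  Gramian `W_k = Σ_{i≥0} A^i B Bᵀ (Aᵀ)^i` with `B = e_k`: a proxy for the
  average ease (inverse energy) of driving the network to arbitrary states
  from region *k*.
* **Modal controllability (MC)** — `ϕ_k = Σ_j (1 − ξ_j²) v_kj²` over the
  eigenvalues `ξ_j` and orthonormal eigenvectors `v_j` of `A`: region *k*'s
  scaled ability to excite all dynamical modes, dominated by fast-decaying,
  hard-to-reach ones.

The scientific question the pipeline addresses: does regional gray-matter
volume (rGM) explain controllability *beyond* what nodal degree (the
weighted row sum of `A`) already explains? The package provides, as tested
and reusable components:

1. connectome ingestion, validation, proportional thresholding (keep the
   strongest 10% of possible connections by default) and node strength;
2. AC, MC, Gramian and Kalman-rank computations on the normalized system;
3. assembly of the long-format subject-by-region study table with
   within-subject centering and z-scaling, plus TIV as a covariate;
4. the two linear mixed-effects models
   `AC/MC ~ TIV + Regions + Degree × rGM + (1|participants)` and
   `AC/MC ~ TIV + Regions × Degree + Regions × rGM + (1|participants)`
   (fitted with lme4), stepwise likelihood-ratio selection, and
   Bonferroni-corrected per-region effects;
5. degree-preserving Maslov–Sneppen null networks and an empirical test of
   the rGM coefficient against them;
6. a fully seeded synthetic cohort generator with known ground truth, so
   every stage is testable without any imaging data.

Intended users: researchers working with derived structural connectomes
(e.g. AAL2-parcellated streamline-count matrices) and regional volumetric
tables who want a reproducible controllability–morphometry analysis.

## Worked example

```r
library(connectrl)

cfg    <- cohort_config(n_subjects = 12, n_regions = 30,
                        rgm_topology_coupling = 0.5, seed = 42)
cohort <- generate_cohort(cfg)

profiles <- lapply(cohort$connectomes, control_profile, proportion = 0.10)
head(profiles[["sub-001"]], 3)
#>   subject_id region_name       ac        mc strength
#> 1    sub-001  region_001 7.626956 0.9534326 578.1109
#> 2    sub-001  region_002 1.107284 0.9940856 119.2225
#> 3    sub-001  region_003 7.127183 0.9739663 250.1330

tab <- center_and_scale(assemble(profiles, cohort$volumetrics, cohort$atlas))
fit <- fit_lme(tab, model_spec_one("ac"), method = "REML")
print(fit)
#> <model_result> model1: ac ~ tiv + region + degree x rgm [REML], n = 360 obs / 12 participants, logLik = 110.5497
#>              term      beta      se  ci_low ci_high    p_raw   p_bonf
#>       (Intercept) -0.218491 0.06331 -0.3426 -0.0944 5.58e-04 5.58e-04
#>             tiv_z  0.000248 0.00832 -0.0161  0.0166 9.76e-01 9.76e-01
#>        strength_z  0.757537 0.05748  0.6449  0.8702 1.17e-39 1.17e-39
#>             rgm_z  0.228493 0.08567  0.0606  0.3964 7.65e-03 7.65e-03
#>  strength_z:rgm_z  0.375373 0.04896  0.2794  0.4713 1.76e-14 1.76e-14
```

Reading the output: `strength_z` (nodal degree) is strongly positively
associated with AC; `rgm_z` carries additional positive signal beyond
degree — here genuinely planted by the generator's coupling dial — and the
`strength_z:rgm_z` interaction indicates the highest AC occurs where both
degree and gray matter are high. `tiv_z` is the across-subject
intracranial-volume covariate, null in this synthetic world.

Per-region effects come from model 2, and the null-network test asks
whether the rGM coefficient survives degree-preserving randomization:

```r
m2 <- fit_lme(tab, model_spec_two("ac"), method = "REML")
head(regional_effects(m2, family = "rgm"))

nd <- null_beta_test(cohort$connectomes, cohort$volumetrics,
                     n_replicates = 200, seed = 1)
print(nd)
```

The whole pipeline, with artifacts and a provenance record, is one call
(or the CLI script in `inst/cli/connectrl.R` with subcommands `generate`,
`metrics`, `analyze`, `nulltest`, `run-all`):

```r
run_pipeline(pipeline_config(synthetic = cohort_config(), seed = 1),
             out_dir = "results/run1")
```

## Documentation

The methods vignette (`vignettes/controllability-pipeline.Rmd`) describes
the model and its assumptions, every tunable parameter with its default
and rationale, what the synthetic generator does and does not emulate, and
the numerical design choices (normalization schemes, tie-breaking,
tolerances, ML/REML policy).
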