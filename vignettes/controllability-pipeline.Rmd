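---
title: "Methods: linear controllability of structural connectomes and its gray-matter correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linear controllability of structural connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the model and
its assumptions, the parameters that matter, what the synthetic world does
and does not emulate, and the numerical and design decisions taken where
the problem was genuinely open. It states no empirical result that the test
suite does not itself compute.

## 1. The model

A subject's structural connectome is an undirected, weighted graph: an
`n × n` symmetric matrix `A` of streamline counts between atlas regions
(the packaged default atlas has 120 regions following the AAL2 naming
convention). Regional brain activity `x` is modeled by noise-free linear
discrete-time time-invariant dynamics

```
x(t+1) = A x(t) + B u(t)
```

with `B = e_k` when region `k` is the single control input. Three nodal
statistics are computed:

* **Average controllability**, `AC_k = tr(W_k)`, with
  `W_k = Σ_{i≥0} A^i B Bᵀ (Aᵀ)^i` the infinite-horizon controllability
  Gramian. The sum converges iff the spectral radius of `A` is below 1.
* **Modal controllability**, `ϕ_k = Σ_j (1 − ξ_j²) v_kj²`, from the
  eigenvalues `ξ_j` and orthonormal eigenvectors `v_j` of `A`. Because only
  `v_kj²` enters, eigenvector sign indeterminacy is irrelevant.
* **Node strength** (the field's "nodal degree" for weighted graphs): the
  row sum of `A`.

Assumptions worth stating plainly: linearity (no saturation, no
neuromodulatory state dependence), time invariance, an undirected `A`
(complex eigenmodes are unsupported and non-symmetric matrices are
rejected for MC), and full observability (no output equation is used —
output matrices play no role in any metric here).

## 2. Processing parameters

| parameter | default | units | rationale |
|---|---|---|---|
| threshold proportion | 0.10 | fraction of possible edges | standard robustness step: keep the strongest 10% of the `n(n−1)/2` undirected connections |
| normalization scheme | `singular_value` | — | divide `A` by `1 + σ_max(A)` so the Gramian converges; the convention of the controllability literature |
| swaps per edge (null model) | 10 | attempts/edge | standard Maslov–Sneppen mixing heuristic |
| null replicates `R` | 1000 | — | reference analysis used 1,000; tests reduce it for runtime |
| stepwise α | 0.05 | — | likelihood-ratio retention threshold |
| Bonferroni family | per regional family (n regions) | — | matches per-region reporting of interaction effects |

Decisions on points the underlying procedure leaves open, each exposed as
configuration:

* **Edge-counting basis.** "10% of connections" is read as 10% of
  *possible* upper-triangle edges (`k = round_half_up(p · n(n−1)/2)`), the
  proportional-threshold convention of the standard connectivity toolbox.
* **Tie handling.** Ties at the cutoff are broken by ascending (row,
  column) index instead of keeping all tied edges: the surviving edge count
  is then exact and the output reproducible.
* **Per-subject thresholding.** Thresholding is applied to each subject's
  matrix (each subject's `A` enters the dynamics separately), not to a
  group-average matrix.
* **Normalization.** How the original analysis stabilized `A` is not
  recoverable; `singular_value` is the default, with `spectral_radius` and
  `none` as alternatives, and every result records the scheme used. AC and
  MC are computed on the same thresholded, normalized matrix; strength on
  the thresholded, unnormalized one.

## 3. Study table and scaling

Controllability profiles and volumetrics are inner-joined into one row per
(subject, region): `ac`, `mc`, `strength`, `rgm`, `tiv`. The variables
`ac`, `mc`, `strength`, `rgm` are centered to mean zero *within each
subject* and then z-scaled. The z denominator is genuinely ambiguous
(within-subject vs pooled); the default is the **pooled SD of the
within-subject-centered column**, which preserves between-subject
differences in within-subject dispersion and keeps interaction
coefficients on one common scale; `scale_within = TRUE` selects the
per-subject alternative, and the parameter-recovery tests run under both
conventions. TIV is constant within subject — within-subject centering
would annihilate it — so it is centered and scaled across subjects and
enters as a covariate.

## 4. Mixed models

Two fixed-effects structures, always with a single random intercept by
participant and fixed slopes:

```
model 1:  ac/mc ~ tiv + region + degree × rgm        + (1 | participant)
model 2:  ac/mc ~ tiv + region × degree + region × rgm + (1 | participant)
```

Fitting is via lme4. Policy decisions:

* **ML vs REML.** Any fit entering a likelihood-ratio comparison is ML
  (REML likelihoods are not comparable across fixed-effects structures);
  final reported models are refit by REML.
* **Inference.** Wald: `z = β/se`, two-sided normal p-values, symmetric
  95% intervals. Asymptotic rather than Satterthwaite degrees of freedom —
  documented, and adequate at thousands of rows per fit.
* **Region encoding.** Treatment contrasts with the alphabetically first
  region as reference (deterministic; regional betas depend on it, so it
  is stated). Per-region slopes from model 2 are reported as the linear
  combination *main effect + that region's interaction contrast*, with the
  covariance-propagated standard error, so every region (including the
  reference) gets one row; Bonferroni correction uses the family size = the
  number of regions.
* **Rank checking.** The fixed-effects design is QR-rank-checked before
  fitting and aliased columns are named in the error, rather than letting
  the backend silently drop columns.
* **Stepwise selection.** Forward, in the caller's stated candidate order,
  χ² likelihood-ratio tests with df = added parameters, retention at
  p < α; the full trace (term, LR, df, p, kept) is returned so any chosen
  order is auditable.

## 5. Null networks

The null asks: would the gray-matter coefficient arise for *any* network
with this degree distribution? Each replicate rewires every subject's
thresholded matrix by Maslov–Sneppen double-edge swaps — weights travel
with their edges, so the *binary* degree sequence, edge count and weight
multiset are conserved exactly; node strength is deliberately **not**
conserved (destroying weight placement is the point). The mixed model is
refit per replicate and the rGM coefficient recorded; the empirical
p-value is one-sided, `p = (1 + #{β_null ≥ β_orig}) / (R + 1)`, matching
the reported direction (the original coefficient exceeds the randomized
ones); a two-sided variant is available. Per-(replicate, subject) seeds
are derived from the master seed by a stable hash, so the distribution is
a pure function of (inputs, seed, R) regardless of execution order.
Replicates whose fit errors are excluded and counted; more than 10%
failures aborts the test.

## 6. The synthetic world

The generator emulates the *derived* tables of a connectome–morphometry
study — streamline-count matrices, regional gray-matter volumes, TIV —
never raw imaging. Defaults mirror the reference dimensions: 65 subjects,
120 regions.

**Connectomes.** One group template is built by a weighted
configuration-style construction: target strengths follow a truncated
Pareto (exponent 2.5, capped at 6 in units of the Pareto minimum), edge
weights are `s_i s_j / Σs` with lognormal
edge-level dispersion of one log-unit, scaled to streamline-count
magnitudes. Two constants deserve justification:

* *Hub cap 6.* Uncapped Pareto draws occasionally make one region so
  strong that the 10%-thresholded graph degenerates into a star — a region
  adjacent to everything — which empirical thresholded connectomes do not
  show and which leaves no legal degree-preserving swap. With the cap, a
  120-node graph at 10% density has maximum binary degree near 50,
  matching the empirical range.
* *Edge dispersion 1.0.* Streamline counts between fixed region pairs span
  orders of magnitude; with too little dispersion the top-decile edges
  collapse onto a frozen hub clique that double-edge swaps cannot mix.

Each subject is the template under multiplicative lognormal edge noise
(SD 0.3), symmetrized, zero diagonal.

**Volumetrics.** TIV is normal (mean 1.5·10⁶ mm³, SD 1.2·10⁵), truncated
positive, and rGM is rescaled if its sum would exceed TIV. Regional gray
matter has scale 8000 ± 1500 mm³ and is coupled to topology by one dial,
`rgm_topology_coupling`, through two channels:

1. *Between regions*: the mean rGM profile mixes the rank-Gaussianized
   template strength with an orthogonalized noise vector. The sample
   correlation is exact **on the Gaussianized-rank scale**; the raw-scale
   Spearman correlation tracks it with ~`1/√n` sampling noise (~0.09 at
   n = 120), which no mixing construction can avoid.
2. *Within regions, between subjects*: a small jitter (SD 0.1 relative to
   the rGM SD) couples to the subject's own nodal AC deviation
   orthogonalized to their strength and binary-degree deviations, computed
   under the default pipeline. This channel exists because of two exact
   absorption results: region fixed effects absorb any region-constant
   gray-matter profile, and degree-preserving rewiring conserves exactly
   the strength/degree information. A gray-matter signal that a
   region-controlled mixed model can detect *and* that rewiring can
   destroy must therefore live in the placement-specific, within-region
   component — which is also precisely the scientific claim being
   emulated: gray matter carries controllability information beyond
   degree.

**What the generator does not emulate** — and hence what a green test does
not establish: spatial embedding and distance-dependent connectivity,
hemispheric symmetry of real connectomes, tractography biases (gyral crown
effects, SIFT residuals), measurement error in segmentation-derived
volumes, age/sex structure, and site effects. Green acceptance tests
establish that the *computational machinery* is correct and calibrated on
a world with known truth, not that the scientific claim holds in any
empirical population.

**LME fixtures.** For model-recovery tests a second generator builds the
study table directly: standardized predictors, response
`Xβ + participant intercept + noise` with stated coefficients — the
reference study's whole-brain values (β_degree = 0.36, β_rGM = 0.44,
interaction 0.04) serve as simulation ground truth. Coverage of the Wald
intervals and the type-I rate of stepwise retention are then directly
checkable.

## 7. Numerical choices

* **Gramian.** Solved exactly from the stationary equation
  `W = A W Aᵀ + B Bᵀ` in the eigenbasis of the symmetric `A`
  (`W̃_ij = (VᵀBBᵀV)_ij / (1 − λ_i λ_j)`); a dense Kronecker solve covers
  small non-symmetric systems. The truncated infinite sum (increment
  Frobenius norm < 1e−14) is retained in the tests as an independent
  oracle, never as the implementation.
* **Kalman rank.** SVD-based with tolerance `max(dim) · eps · σ_max`:
  Kalman matrices are notoriously ill-conditioned and a documented
  tolerance makes the controllability flag reproducible.
* **Ingestion tolerances.** Asymmetry up to `1e−9 · max(w)` is repaired as
  `(W + Wᵀ)/2`; larger asymmetry is an error. Nonzero diagonals are zeroed
  with a warning.
* **Degenerate inputs.** Zero-variance columns, single-region subjects,
  single participants, empty candidate lists, unstable systems under
  scheme `none`, and graphs with no legal swap all produce named errors or
  warnings rather than silent results.
* **Determinism.** All randomness flows from one master seed through named
  substream hashes (template, subjects, volumetrics, replicate × subject);
  the pipeline's JSON artifacts are byte-identical across reruns with the
  same config and seed.

## 8. Known limitations

* Linear, trajectory-unspecific controllability only; no target control,
  control energy along specified trajectories, or nonlinear dynamics.
* Undirected connectomes only.
* Asymptotic Wald inference; profile or bootstrap intervals are out of
  scope.
* The null model conserves binary degree, not strength; a
  strength-preserving null would test a different (stricter) hypothesis
  and is intentionally not provided.
* The empirical p-value resolution is bounded by `1/(R+1)`; small test
  runs with `R = 49` cannot report below 0.02.
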