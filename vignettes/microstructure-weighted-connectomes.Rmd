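---
title: "Microstructure-weighted connectomes: models, pipeline and reliability statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstructure-weighted connectomes: models, pipeline and reliability statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwconn)
```

# What this package computes

`mwconn` is a desk-scale emulation of a test-retest study of
*microstructure-weighted structural connectomes*: brain networks whose edges
carry not streamline counts but diffusion-model parameters sampled along the
streamlines. The package covers the full chain —

1. multi-shell diffusion-weighted signal synthesis from compartment models,
2. voxel-wise fitting of the diffusion tensor and of the Bingham-NODDI
   multi-compartment model,
3. tractometry-based connectome construction with SIFT2 streamline weights,
4. weighted graph metrics, and
5. the reliability battery (CV, Bland-Altman, ICC(2,1)) applied to two-site
   per-subject network metrics

— together with synthetic generators for every input, so the whole pipeline
is testable without scanner data.

# The signal models

## Compartments

All signals are unitless attenuations `S/S0` as functions of the b-value
(s/mm²) and gradient direction `g`. Diffusivities are quoted in m²/s, the
scale on which the fixed constants are usually printed.

* **Ball** — free water (CSF): `exp(-b λ_iso)`, isotropic, with
  `λ_iso = 3.0e-9 m²/s` (`LAMBDA_CSF`).
* **Stick** — intra-neurite water in a zero-radius axon along `μ`:
  `exp(-b λ∥ (g·μ)²)`, with `λ∥ = 1.7e-9 m²/s` (`LAMBDA_PAR`).
* **Zeppelin** — extra-neurite water, axially symmetric:
  `exp(-b [λ⊥ + (λ∥-λ⊥)(g·μ)²])`. The perpendicular diffusivity is tied to
  the neurite density by the standard tortuosity constraint
  `λ⊥ = λ∥ (1 - ν)` (`tortuosity_perp()`), the convention of the NODDI
  model family this package builds on.

## Orientation dispersion: the Bingham distribution

Neurites are not perfectly parallel. The dispersed signal convolves the
stick/zeppelin kernel over a **Bingham** orientation distribution,
`B(n) ∝ exp(-κ₁ (n·e₁)² - κ₂ (n·e₂)²)`, an antipodally symmetric density
whose concentrations `κ₁ ≥ κ₂ ≥ 0` allow *anisotropic* dispersion (fanning)
about the main axis `μ`; `κ₁ = κ₂` recovers the rotationally symmetric
Watson distribution and `κ₁ = κ₂ = 0` the uniform density. Two scalar
summaries are exposed:

* **ODI** `= (2/π) atan(1/κ₁)` in [0, 1] (0 = perfectly coherent fibres;
  defined as 1 at κ₁ = 0), and
* **β-fraction** `= κ₂/κ₁` in [0, 1], the dispersion anisotropy.

The composite model is

```
S(g, b) = f_CSF · Ball(λ_CSF)
        + (1 - f_CSF) · ∫ B(n) [ ν Stick(n; λ∥) + (1-ν) Zeppelin(n; λ⊥^tort, λ∥) ] dn
```

with `f_intra = (1-f_CSF)·ν` and `f_extra = (1-f_CSF)·(1-ν)`, so the three
global fractions sum to one by construction. Unweighted (b = 0) volumes
return exactly 1.

## Numerical convolution

The spherical convolution has no convenient closed form for the Bingham
kernel pair, so it is evaluated by quadrature. A fixed uniform spherical
point set cannot work across the full concentration range: at `κ₁ ~ 10⁴`
the density occupies ~10⁻⁴ of the sphere and a uniform 768-point set sees
essentially one point of it. The rule used here is a product rule **in the
dispersion frame** with `sinh`-stretched Gauss–Legendre nodes in both
angles:

* polar angle θ (from `μ`): nodes log-spread from the peak width
  `1/√κ₁` out to the equator, shared by all azimuths;
* azimuth φ: nodes on a quarter period clustered at φ = π/2 — where the
  density concentrates when `κ₁ ≫ κ₂`, with width `~1/√(κ₁-κ₂)` — mirrored
  to the four quadrants.

The default order is 28 × 32 = 896 nodes. Against adaptive 2-D integration
the worst relative signal error is ~10⁻⁵ at moderate concentrations,
≤ ~8·10⁻⁴ for `κ₁ ≤ 64`, and the delta-ODF limit (`κ = 10⁴`) matches the
closed-form stick to better than 10⁻³ — the regime the tests exercise by
doubling the order and comparing. The Bingham normalization constant itself
is *not* taken from this rule: the azimuthal integral reduces exactly to a
modified Bessel function `I₀`, leaving a smooth 1-D integral evaluated
adaptively to ~10⁻¹⁰, which is what lets `bingham_odf()` match an
independent Watson oracle to machine precision at `κ₁ = κ₂`.

# Fitting

## Diffusion tensor

`fit_dti()` is the classical log-linear least-squares estimator: S0 is the
mean of the b = 0 volumes, and `ln(S/S0)` of the weighted volumes is
regressed on the six b-matrix components (ordinary LS by default, matching
the reference tool's default; one WLS pass is available via
`weighted = TRUE`). Eigenvalues are sorted descending, negatives clamped to
zero with a per-voxel flag, and FA/MD follow the standard closed forms with
`FA(0) := 0`. Signals ≤ 0 are floored at 10⁻¹⁰ before the log, with a
warning.

## Bingham-NODDI

`fit_bingham_noddi()` minimizes the sum of squared residuals on normalized
attenuations over `(f_CSF, ν, θ, φ, ψ, ODI, β-fraction)` with the two
diffusivities held fixed, using box-constrained Levenberg–Marquardt
(`minpack.lm`). Design choices that matter:

* **Multi-start.** The objective is genuinely multimodal in the
  `(ψ, ODI, β-fraction)` subspace: with the constraint `κ₁ ≥ κ₂`, a start
  whose dispersion plane is ~90° off can converge to a local optimum with a
  biased ODI (observed at residual MSE ~10⁻⁵ on noise-free data). The
  default start set is therefore *structured*: eight starts share the fibre
  axis of the tensor fit's principal eigenvector and scan ψ over
  {0, π/4, π/2, 3π/4} × β-fraction over {0.3, 0.8}; further starts (if
  requested) are seeded uniform draws. With this grid, 100/100 random
  noise-free draws recover all parameters to machine precision.
* **Early exit.** Once any start reaches MSE < 10⁻¹⁰ the remaining starts
  are skipped — noise-free fits typically cost 1–3 starts, noisy fits run
  all of them. Ties between starts are broken by lowest objective, then
  start index, so fits are deterministic given the seed.
* **Boundary polish.** A fraction parameter that converges onto a box face
  (e.g. ν = 1 when the true ν is 0.95 under strong dispersion) can shadow a
  nearby interior optimum; after the multi-start phase each active bound
  among (f_CSF, ν, β-fraction) is pulled 0.1 inward once and the fit
  re-polished, keeping the better solution.
* **Bounds and wrapping.** Fractions and β-fraction live in [0, 1], ODI in
  [10⁻³, 1]; angles get generous bounds and are wrapped afterwards into
  canonical ranges with `μ` in the upper hemisphere (the model is antipodal,
  so `-μ` fits score identically).
* **Degeneracy.** A fitted `f_CSF ≥ 0.98` leaves no tissue signal to
  constrain the remaining parameters; such voxels are flagged `degenerate`
  rather than treated as errors. Crossing-fibre voxels are likewise fitted
  as-is with the single-population model — the degraded fit there is the
  expected behaviour the phantom analysis demonstrates, not an error.

The ICVF ("intra-cellular volume fraction") reported by `derive_noddi_maps()`
defaults to the tissue fraction `1 - f_CSF`, which makes `ICVF ≈ 1` in
fluid-free fibre phantoms and keeps `ECVF = 1 - ICVF` the extra-cellular
complement; the classic NODDI reading `ICVF = ν` is selectable
(`icvf = "nu"`). INVF is always `(1-f_CSF)·ν`.

# Synthetic data

`generate_phantom()` emulates a two-strand crossing-fibre diffusion phantom
at the signal level: two fibre bands crossing at 60° (configurable) in a
fluid bath, strand voxels carrying one coherent dispersed population,
crossing voxels an equal 50/50 mixture of the two (the physical mixing
fraction of a wound phantom is unknown), fluid voxels the free-water ball.
Noise is Rician — `sqrt((S+ε₁)² + ε₂²)` with Gaussian ε of sd `1/SNR` —
the magnitude-MRI convention; the generator is a pure function of
(spec, seed). What it does *not* emulate: relaxation contrast (T2/TE
dependence), susceptibility or eddy distortions, the spindle's winding
geometry, or realistic whole-brain anatomy. Passing tests on this phantom
therefore validate the *model and pipeline arithmetic*, not robustness to
scanner artefacts.

`generate_tractogram_fixture()` builds a block parcellation, mildly curved
streamlines between parcel pairs, positive SIFT2 weights, and a
piecewise-constant scalar map — and computes the exact edge weights the
tractometry rule must produce, analytically from the block geometry. Because
the map is piecewise constant and vertices are kept off voxel boundaries,
nearest-neighbour sampling reproduces the analytic values exactly, giving a
10⁻¹⁰-level oracle for the whole connectome construction path.

`generate_two_site_dataset()` draws subject × site matrices from the two-way
random-effects model `X_ij = base + subject_i + site_j + error_ij`, whose
population ICC(2,1) is the closed-form variance ratio — the oracle for the
ICC implementation.

# Connectome construction

The tractometry rule: sample the parameter map at every streamline vertex
(trilinear by default, as in the reference sampler; nearest available for
exact tests), summarize each streamline by the **median** of its vertex
values (robust to outlying end-of-bundle vertices, no distributional
assumption along the bundle), assign each streamline to the parcel pair of
its endpoints (nearest nonzero label within 2 mm, the assignment tool's
convention; neither the radius nor the interpolation is standardized across
studies, so both are configurable), and set

```
edge(a, b) = Σ_s w_s m_s / Σ_s w_s
```

over assigned streamlines, with `m_s` the streamline median and `w_s` its
SIFT2 weight — so streamlines representing more fibre density contribute
proportionally more. Self-loops are zeroed on the diagonal, the matrix is
symmetric by construction, and *no thresholding or pruning* is applied.
`build_nos_connectome()` provides the SIFT2-weighted streamline-count
reference. For weightings where large values mean weak coupling (MD in
mm²/s, ECVF), `neg_log_transform()` maps nonzero entries `w → -ln(w)`
(positive because those entries lie in (0,1)); entries ≥ 1 are clamped out
with a warning, and zero entries remain absent edges.

ODI- and β-fraction-weighted connectomes are refused by the pipeline
configuration by default: those parameters' test-retest variability exceeds
the 5% CV threshold, and propagating an unstable weighting would contaminate
the network metrics. An explicit override exists for exploration.

# Graph metrics

Following the weighted conventions of the standard brain-connectivity
toolbox: density (edge count fraction — weight-independent, hence identical
across weightings of one tractogram); mean nodal strength; global efficiency
with lengths `1/w` and disconnected pairs contributing 0; Onnela clustering
(triangle weights normalized by the global maximum, geometric mean, nodes of
degree < 2 contributing 0); and Louvain modularity at resolution γ = 1
(the community-detection algorithm and γ are this package's own choice, as
studies rarely state them). Because greedy Louvain can stall in local optima
even on 8-node graphs, each run is polished by a deterministic refinement
sweep (best single-node moves, including to fresh singleton communities,
plus community merges, until no move improves Q), and each of the `n_runs`
seeded restarts also tries a random initial partition. The per-run Q values
are returned (`q_runs`) rather than hidden, so the known run-to-run
instability of modularity can be inspected. On 120 random ≤ 8-node weighted
graphs the result matched exhaustive partition search exactly.

# Reliability statistics

* **CV** `= 100·sd/mean` with the *population* (divisor-n) standard
  deviation — for a site pair this is `100·|x₁-x₂|/(x₁+x₂)`. This divisor
  choice is verified against the published per-subject CVs (e.g. a 0.748 /
  0.784 density pair gives 2.35% against a printed 2.36%; the sample-sd
  variant gives 3.32% and is clearly not what was reported). The 5%
  acceptability threshold is exported as `CV_THRESHOLD_PERCENT`.
* **Bland-Altman**: bias `= mean(x₁-x₂)`; limits of agreement
  `bias ± 1.96·sd` with the *sample* (divisor n-1) sd of the differences —
  again the only divisor that reproduces the published limits.
* **ICC(2,1)**: two-way random effects, single measure, absolute agreement,
  computed directly from the ANOVA mean squares
  `(MS_S - MS_E) / (MS_S + (k-1)MS_E + (k/n)(MS_R - MS_E))` rather than
  delegated to a package, so the formula itself is under test (the mean
  squares are cross-checked against `aov()` in the suite). Interpretation
  bands: < 0.5 poor, 0.5–0.75 moderate, 0.75–0.9 good, > 0.9 excellent.

`reliability_table()` applies the battery per (weighting, metric) to paired
two-site values and regenerates the statistical rows of the packaged
per-subject tables. Recomputed ICCs agree with the published ones within
0.02, biases within 0.001 and limits of agreement within 0.005 — the
precision supported by 3-decimal published inputs. One documented exception:
the published *modularity* CV column cannot be reproduced to 0.15 percentage
points from rounded inputs, because modularity values of 0.03–0.13 make the
CV sensitive to ±0.0005 input rounding at the level of up to ~1.7 points;
those CVs were evidently computed on unrounded values.

A caution on simulation tests of the ICC: the ICC(2,1) *estimator* is biased
low in small samples (measured ≈ −0.07 at n = 4 subjects for a true value of
0.9), so parameter-recovery simulations compare the estimator mean to the
closed form at n = 30 subjects, where the measured bias is within ±0.02; at
n = 4 the suite asserts only the direction of the bias. Study-sized (n = 4)
ICCs should be read with that in mind.

# Problem sizes and runtime choices

The test-suite sizes are chosen to exercise every code path at full default
settings while staying desk-scale: phantoms of 11 × 11 × 3 voxels on the
full 150-volume four-shell scheme; 100 noise-free plus 25 Rician-noise
(SNR 30) parameter-recovery fits; 1000-replicate ICC simulations at n = 30;
brute-force graph oracles on ≤ 8 nodes (exhaustive partition search grows as
the Bell numbers, 4140 partitions at n = 8); and 50-streamline tractogram
fixtures. The acceptance script uses 30 recovery draws.

# Known limitations

* Single fibre population per voxel in both models; crossing regions are
  deliberately mis-modelled (that is the phenomenon under study), so FA and
  ODI there are biased by design.
* The quadrature is tuned for `κ₁ ≤ ~10³` plus the delta limit; the
  pathological corner `κ₁ large, κ₂ = 0` is accurate to ~1% at default
  order (double the order if that corner matters).
* No distortion correction, registration, tracking or SIFT2 estimation —
  those stages are upstream of this package and their outputs are consumed
  as inputs.
* Built-in gradient tables are electrostatic-repulsion layouts, not the
  (unpublished) vendor tables of any particular scanner.
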