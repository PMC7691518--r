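---
title: "Methods: hormone-linked network coherence in dense-sampling designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hormone-linked network coherence in dense-sampling designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclecoh)
```

## The design and the model

`cyclecoh` analyses dense-sampling studies in which one participant is
scanned and phlebotomized every day for about a month, producing per day:
a node × time signal matrix (here 99 cerebellar parcels, ~833 samples at
0.72 s), serum concentrations of estradiol (pg/mL), progesterone (ng/mL),
LH and FSH (mIU/mL), and a head-motion summary (mean framewise
displacement, mm). The scientific question is whether day-to-day
fluctuations of the sex hormones covary with (a) edgewise functional
connectivity and (b) network-level topology.

The pipeline treats the day as the unit of observation. Each stage is an
exported function; `run_pipeline()` wires them together.

### Connectivity estimation

Node series are band-limited by a maximal overlap discrete wavelet
transform (MODWT) with the length-8 Daubechies extremal-phase filter and
periodic boundary handling, retaining detail levels 3–6. Level *j* spans
`[fs/2^(j+1), fs/2^j]` cycles/s, so at `dt = 0.72` s levels 3–6 cover
~0.011–0.174 Hz, the conventional low-frequency window for resting-state
connectivity. The MODWT is implemented directly in the package (no
installed R package provides it); its multiresolution components satisfy
exact additivity (details + smooth reconstruct the input to < 1e−8),
which the test suite asserts, together with an independent FFT-cascade
oracle for each detail component.

Pairwise association is Welch magnitude-squared coherence averaged over
the band: segments of 128 samples (50% overlap, Hann taper, per-segment
mean removal), `C(f) = |Sxy(f)|²/(Sxx(f)Syy(f))`, averaged over the
frequency bins inside 0.01–0.17 Hz. For sessions shorter than 512
samples the segment length shrinks (powers of two) so at least four
non-overlapping segments always remain; at the design's 833 samples it is
exactly 128. MSC is invariant to per-node affine rescaling, bounded in
[0, 1], and positively biased under independence with null mean `1/d`
for `d` independent segments — all asserted by tests.

**Per-edge null and daily thresholding.** The matrices are sparsified by
BH-FDR at `q < .05` using an analytic independence null. For a single
frequency bin estimated from `d` independent segments the null MSC is
Beta(1, d−1), with tail `(1−C)^(d−1)`. Our statistic is the *band
average* over `B` bins, which preserves the null mean `1/d` but shrinks
the variance; we therefore moment-match the null as
Beta(B, B(d−1)), which reduces exactly to the single-bin form at `B = 1`.
Using the non-overlapping equivalent segment count `d = floor(N/L)`
(rather than the larger overlapped count) keeps the p-value conservative,
which the null-calibration test verifies (the fraction of surviving edges
in an independent-noise session stays at or below `q`). The single-bin
form applied to the band average is far too conservative in practice — at
`d = 6` it zeroes essentially every edge of every session at realistic
coherence levels, leaving the downstream stages with empty graphs — which
is why the band-aware null is the package default.

### Edgewise hormone regression

Each edge's day series (zeros included where the daily threshold removed
it) is Z-scored and regressed on the standardized hormone by OLS; the
test statistic is `β/SE`. Hormones are modelled in separate
single-regressor fits, matching how per-hormone maps are reported.
Significance is empirical: the day labels of the hormone vector are
permuted uniformly (one shared permutation per iteration across all
edges, preserving cross-edge dependence of the null), all edges are
refit, and the two-tailed p-value is `(1 + #{|T_perm| ≥ |T_obs|})/(n_perm
+ 1)` — so `p_threshold` must satisfy `n_perm ≥ 1/p_threshold − 1`, and
the default 10,000 permutations support the conservative `p < .001`
threshold. Edges whose series are constant (e.g. always sub-threshold)
cannot be standardized and are excluded rather than imputed. Nodal
association strengths sum the suprathreshold positive and |negative|
statistics per node; network summaries report means with 95% t-intervals
across member nodes (singletons report an undefined interval).

### Topology

From each day's thresholded matrix we compute the weighted participation
coefficient `P_i = 1 − Σ_m (κ_im/κ_i)²` on the full graph — the
between-network notion requires cross-network edges, so subdividing first
would make it identically zero; a `participation_graph = "block"` switch
exists for the subdivided reading, which is degenerate by construction —
and weighted global efficiency on each within-network submatrix, with
connection lengths `1/w`, Dijkstra shortest paths (via igraph), ordered-
pair averaging `n(n−1)`, zero contribution for disconnected pairs, and
efficiency 0 for singleton networks. Efficiency is linear under uniform
weight scaling and never decreases when an edge is added; participation
is scale-invariant. For 0/1 weights efficiency equals the classic
unweighted definition. All of these are tested against brute-force
oracles.

### Network hormone models

Per network × metric × hormone the pipeline is fixed as: initial fit →
MAD outlier screen → removal → Z-score → residualize the metric on motion
→ simple OLS on the hormone. The MAD rule flags days with
`|r − median(r)|/(1.4826·MAD) > 3` (the 1.4826 factor makes the scale
SD-consistent under normality; raw-MAD multiples are available via
`normalized = FALSE`), and flags nothing when the MAD is zero. Motion is
removed from the metric only — the plainest reading of residualizing
network metrics on motion — and the reported statistics obey `F = t²`,
`df2 = n_obs − 2`, and adjusted `R² = 1 − (1 − R²)(n − 1)/(n − 2)`.
Reported degrees of freedom always reflect the days actually used: if the
screen removes one of 30 days, `df2 = 27`. (Printed tables elsewhere
sometimes keep `F(1, 28)` alongside day removal; `adj_r2_from_f()` lets
either convention be checked.) BH-FDR is applied across the whole model
family. Under a null study the pipeline's type-I rate at `α = .05` sits
inside the binomial 95% interval (tested over 400 model fits); the
residualization step costs one unmodelled degree of freedom, a
second-order effect at n = 30 that the calibration test bounds.

## The synthetic-study generator

`simulate_study()` emulates the study conditions so that the pipeline's
operating characteristics can be measured:

* **Hormones** are sums of Gaussian bumps on the day axis with period 27
  days (the observed cycle length): estradiol has a tall follicular bump
  at day 12 (amplitude 210 pg/mL over a 30 pg/mL baseline) plus a smaller
  luteal bump, progesterone a single luteal bump at day 22 (8.7 ng/mL
  over 0.11), LH/FSH sharp midcycle surges; multiplicative log-normal
  noise (SD 5%, an assay-scale perturbation) is applied. These values
  reproduce the reported morphology: estradiol peaking in days 10–14 with
  ~8-fold dynamic range, progesterone peaking in days 19–27 with ~80-fold
  range and a luteal maximum above 5 ng/mL.
* **Motion** is a log-normal series whose latent Gaussian is a noisy copy
  of progesterone's normal scores (Gaussian copula,
  `ρ_pearson = 2·sin(π·ρ_s/6)`), giving a target Spearman correlation of
  .42 with progesterone and mean ~0.115 mm — the confound structure the
  residualization step must remove.
* **Coupling.** Baseline inter-node coupling is block-structured on the
  6-network partition — 0.75 within, 0.50 between — and planted effects
  move designated edges linearly with the standardized hormone
  (`base + β_P z(P_d) + β_E z(E_d)`), with designated baselines recentred
  to 0.55 (or 0.65 for the within-network efficiency experiments) so the
  coupling stays in [0, 1) across the hormone range. The default planted
  magnitude, 0.12 coupling units per SD of hormone, realizes standardized
  edge effects of roughly 0.7–0.9 after estimation noise.
* **Signals.** Per day, Gaussian innovations with the day's coupling
  matrix as correlation are passed through a common AR(1) filter
  (φ = 0.92), concentrating power in the retained band, plus white
  measurement noise (SD 0.15). Band coherence then increases
  monotonically with coupling (approximately its square, attenuated by
  noise), landing within-network coherence near 0.5–0.7 and
  between-network near 0.25–0.35 — the dense-connectivity regime the
  analysis assumes. The coupling → coherence mapping is validated
  empirically (Monte-Carlo sign checks), not analytically. On extreme
  hormone days the target pattern can leave the positive-definite cone;
  the generator then projects to the nearest feasible correlation matrix
  by eigenvalue clipping, a small documented distortion of the mapping.
* **Seeding.** All randomness flows from one integer seed through a
  fixed LCG splitting scheme, so studies are bit-reproducible.

What the generator does *not* emulate: volumetric images, haemodynamics,
scanner artifacts beyond white noise, physiological noise spectra, or
empirical inter-network coupling topographies. Passing tests therefore
demonstrate the statistical machinery — estimator calibration, error
control, sign recovery under the assumed linear coupling model — not
fidelity to any particular brain.

## Numerical choices and degenerate inputs

* MODWT depth requires `N ≥ 2^J` (periodic transform); coherence requires
  ≥ 64 samples and non-constant series; zero-variance inputs raise typed
  data errors rather than NaNs.
* Coherence values are clipped into [0, 1] at 1e−12 tolerance; the
  diagonal is stored as 1 and excluded from every statistic.
* Winner-take-all parcel assignment breaks ties by the fixed atlas order
  (Visual, SMN, DAN, VAN, Limbic, FCN, DMN), earliest first, making the
  assignment deterministic; it is invariant to uniform voxel-count
  scaling.
* Edges constant across days are excluded from regression (NA) and never
  masked; empty networks are skipped with a warning; constant-motion
  residualization warns and centers.
* In batch model fitting, a degenerate (zero-variance) metric yields an
  NA-filled model row with a warning instead of an error, so one dead
  network cannot sink a whole study.

## Problem sizes used in the shipped checks

The test-suite Monte-Carlos use: 20 full-scale studies (30 days × 99
nodes × 833 samples) for designated-edge sign recovery; 50 full-scale
studies for the within-VAN efficiency experiment; 5 × 210 null edges ×
1,000 permutations for type-I calibration; 500 white-noise pairs for the
MSC bias check; and reduced fixtures (6–12 nodes, 128–400 samples)
elsewhere. These sizes give stable Monte-Carlo estimates while keeping a
complete run of the suite in the minutes range.

## Known limitations

* The analytic coherence null treats band bins as independent; with 50%
  segment overlap this is conservative rather than exact, and the daily
  FDR is correspondingly slightly strict.
* Separate per-hormone regressions do not model the (real) correlation
  between estradiol and progesterone; joint or lagged models are out of
  scope.
* Participation on heavily thresholded graphs can be degenerate for tiny
  networks (no surviving cross edges); the batch fitter reports NA for
  those combinations.
* The coupling → coherence mapping is monotone but compressive; planted
  effect sizes are calibrated empirically, and recovered slopes should be
  read as standardized associations, not as the planted coupling units.
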