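---
title: "Autocorrelation-decay complexity mapping: model, pipeline and phantom design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autocorrelation-decay complexity mapping: model, pipeline and phantom design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Resting-state BOLD dynamics can be summarised, voxel by voxel, through the
decay of the temporal autocorrelation function (ACF). `acfmap` models each
voxel's sample ACF over lags $k = 0, \dots, 8$ (lag unit: one TR) as an
exponential decay

$$\mathrm{ACF}(k) = a\,e^{-bk}, \qquad b > 0,$$

and reports the decay rate $b$ (per TR) and the mean lifetime
$\tau = \mathrm{TR}/b$ in seconds. Low $b$ (long $\tau$) means persistent,
constrained, less chaotic dynamics; white noise has $\tau$ of essentially
zero. The frequency-domain analogue is the power-law exponent $\beta$ of
$P(f) \sim 1/f^{\beta}$ (`pssi_beta()`), connected to the ACF by the
Wiener–Khinchin theorem; `wiener_khinchin_gap()` verifies the discrete
identity numerically, and the package's biased ACF estimator (denominator
$n$, pooled-variance normalisation) is chosen precisely because it keeps
$|r_k| \le 1$ and makes that identity exact.

The clinical use case driving the design is focal epilepsy: a region
generating interictal epileptic activity is expected to show slower ACF
decay (lower $b$) than the same region in healthy controls, so a voxel-wise
group comparison of $b$ maps, followed by subject-level classification,
is a candidate non-invasive localiser of the epileptogenic zone.

## The analysis chain and its assumptions

1. **Conditioning** (`detrend()`, `regress_nuisance()`, `bandpass()`):
   linear detrending, OLS residualisation against an intercept, the six
   realignment parameters and mean white-matter/CSF signals, then a
   band-pass to 0.01–0.1 Hz. The stage order is fixed; despiking
   (`despike_tanh()`) belongs only to the connectivity pathway, never
   before ACF fitting, because the squashing nonlinearity would distort
   the ACF shape.
2. **Complexity mapping** (`b_map()`): per-voxel ACF estimation and
   bounded nonlinear least squares on the 9 ACF points. The amplitude is
   profiled out analytically; the 1-D problem in $b$ is solved by a dense
   log-grid seeded with a log-linear initialisation, golden-section
   refinement and a damped Gauss–Newton polish. Bounds $a \in (0, 2]$,
   $b \in (10^{-6}, 20]$ keep white-noise fits well-posed ($\tau$ floor
   0.1 s at TR = 2 s). Voxels with zero variance or degenerate fits are
   dropped from the map's mask, never imputed.
3. **Group inference** (`two_sample_tmap()`, `cluster_threshold()`):
   pooled-variance two-sample t per voxel, cluster extraction at
   uncorrected $p < 0.005$ with extent $\ge 27$ voxels under
   18-connectivity. No FWE/FDR correction is applied — height plus extent
   is the inference rule, a deliberate and documented limitation.
   `lilliefors_map()` screens voxel-wise normality against Monte-Carlo
   critical values (exact for small $n$); `loso_stability()` and
   `subject_deviation_map()` probe robustness and single-subject use.
4. **Classification** (`loso_gpc()`, `permutation_test()`): binary
   Gaussian-process classification with a linear kernel on the voxels of
   the group-difference ("second-level") mask, probit likelihood, Laplace
   posterior, leave-one-subject-out cross-validation. Feature centring
   and kernel scaling are recomputed inside each training fold, so no
   information from the held-out subject reaches training. Note one
   deliberate asymmetry: the second-level mask itself is fitted on the
   full sample, mirroring common practice in the field; this is
   optimistically biased, and the honest alternative is to recompute the
   mask per fold (the package exposes the mask as an explicit argument so
   either protocol can be run). Permutation p-values use the
   $(r+1)/(n_{\mathrm{perm}}+1)$ smoothing convention.
5. **Connectivity** (`extract_seed_series()`, `seed_to_voxel()`,
   `conn_group_ttest()`, `clinical_correlation()`): seed-to-voxel Pearson
   correlations of conditioned series (this pathway adds tanh despiking
   and motion first derivatives), Fisher-z transformed with $|r|$ clipped
   at $1 - 10^{-7}$, one-sided group contrasts at $p < 0.005$,
   $k \ge 10$, and cluster-mean z correlated with clinical covariates.
   Seed voxels stay in the target mask by default (they appear as
   trivially high z near the seed).
6. **Graph metrics** (`build_network()`, `threshold_by_cost()`,
   `graph_metrics()`, `compare_groups_metric()`): node series are
   conditioned cluster means; the correlation network is binarised at a
   connection cost (the kept fraction of the $n(n-1)/2$ possible edges,
   ranking by signed correlation with deterministic lexicographic
   tie-breaks), and six unweighted metrics are compared one-sidedly
   across the cost grid 0.10–0.30. Disconnected-graph conventions:
   efficiency uses $1/\infty = 0$; average path length is over connected
   pairs only; betweenness is normalised by $(n-1)(n-2)/2$; nodes with
   fewer than two neighbours contribute zero clustering and local
   efficiency.

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `filter.low_hz` / `high_hz` | 0.01 / 0.1 | Hz | standard resting-state band; power-law behaviour holds here |
| `filter.order` | 10 | — | order of the band-pass itself (5 analogue poles per edge) |
| `max_lag` | 8 | TR | 9 fitted points; longer lags dilute the early decay the model targets |
| `despike.c_mult` | 3 | SD | squashing width; near-identity inside ±1 SD |
| `group.p_thresh` / `k_min` | 0.005 / 27 | — / voxels | height-plus-extent rule ("greater than 26 voxels") |
| `conn k_min` | 10 | voxels | extent rule for connectivity contrasts |
| `classifier.n_perm` | 2000 | — | permutation resolution ~5e-4 |
| `graph costs` | 0.10–0.30 step 0.05 | — | cost grid; the step is the package's choice |

Two filtering decisions deserve note. "10th-order Butterworth" is read as
the order of the band-pass filter itself (`signal::butter(5, band)`); a
MATLAB-style `butter(10, band)` would produce a 20th-order band-pass.
Filtering is zero-phase (forward–backward, with odd-reflection padding
and transient-minimising initial conditions, numerically equivalent to
scipy's `filtfilt`), because phase distortion would corrupt the ACF shape
fitted downstream; a causal single pass is available via
`bandpass(..., zero_phase = FALSE)`. Edges are retained, not trimmed.

## What the phantom generator emulates

`phantom_spec()` / `make_cohort()` build a 19-versus-19 cohort of
200-volume, TR = 2 s images on a 24×24×16 grid (3×3×4 mm voxels): an
ellipsoidal brain, six spherical grey-matter regions (region 1, ~150
voxels, is the focal region), WM/CSF blocks as nuisance sources,
random-walk head motion, and confound signals leaked into brain voxels.
Regional dynamics are AR(1) processes — with $\varphi = e^{-b}$ the
theoretical ACF is exactly $e^{-bk}$, so the fitted model is
well-specified on unfiltered phantoms.

**The observed scale.** The conditioning pipeline imprints its own
autocorrelation on every series: at $n = 200$ it compresses generative
AR(1) rate differences roughly four-fold, bounds the observable fitted
rate to about $[0.38, 0.79]$, and leaves a per-series estimation noise
floor of about 0.095 (all three facts were cross-checked against an
independent scipy implementation). Reference cluster statistics live on
this *observed* scale. The generator therefore specifies regional decay
rates on the observed scale by default and maps them to generative AR(1)
rates through a frozen monotone calibration table
(`b_observed_to_generative()`, computed once from the conditioning
pipeline at the default acquisition and stored as package constants;
targets outside the attainable band are censored at its edges). For
recovery and monotonicity studies, `b_scale = "generative"` uses the
rates directly.

**The voxel model.** A voxel in region $r$ is
$\sqrt{w}\,S_r + \sqrt{1-w}\,V_i + \sigma\varepsilon$: one region-wide
AR(1) realisation $S_r$ (variance share $w = 0.3$) carrying the planted
inter-regional correlations, an independent per-voxel realisation $V_i$
at the same subject-level rate, and measurement noise
($\sigma = 0.2$). Background voxels are fully voxel-independent. A single
shared realisation per region would look simpler, but its estimation
noise (~0.095 in fitted $b$) would then be perfectly correlated across
the region and irreducible at the cluster level, making the focal effect
undetectable at the study's sample size; the mixture emulates the
spatially extended, smoothed signal of real data while keeping region
voxels correlated for the connectivity stages.

**Defaults as study conditions.** Focal decay rate (observed scale):
controls $0.71 \pm 0.09$, patients $0.57 \pm 0.05$ across subjects;
non-focal regions $0.66 \pm 0.05$ and background $0.70 \pm 0.05$, shared
between groups. Planted edges: region 1–2 (local) $r = 0.25$ in controls
vs $0.55$ in patients; region 1–5 (long-range) $0.45$ vs $0.15$;
subject-level SD 0.12 in Fisher z. Clinical covariates are drawn by a
Gaussian copula against each patient's *realized* edge Fisher z
(duration: $\rho = 0.6$ with the long-range edge, gamma marginal in
years; verbal-memory score: $\rho = -0.5$ with the local edge, rounded
normal marginal), so the planted correlation is unbiased for the
estimable quantity. Subject seeds derive deterministically from the
master seed (`derive_seed()`), making cohorts bit-reproducible.

**What the phantom does not emulate** — and hence what passing tests do
not show about real data: anatomy and tissue contrast, hemodynamic
response shapes, scanner noise spectra and drifts beyond a linear trend,
spatially varying smoothness, true motion artefacts (motion only enters
as a trace plus an additive confound), and any nonstationarity. Passing
the cohort-level checks demonstrates that the pipeline recovers planted
dynamics, localises a focal effect of the reference magnitude, and keeps
its false-positive behaviour — not that it would perform identically on
clinical data.

## Numerical choices and degenerate inputs

- The exponential fit computes profile SSE from explicit residuals (the
  expanded quadratic form cancels catastrophically near exact fits) and
  accepts Gauss–Newton steps only when the objective decreases, so the
  converged objective can never exceed the initialisation's.
- Curves whose positive-lag values are all non-positive collapse the
  amplitude to its lower bound and are flagged unconverged, then dropped
  from maps.
- Lilliefors critical values are Monte-Carlo (10,000 null samples per
  $n$, fixed private seed, memoised) rather than an approximation
  formula: exact for the small group sizes used here.
- Cluster connectivity defaults to 18 (faces + edges); 6 and 26 are
  selectable. Ties in cost thresholding break lexicographically.
- Zero-variance voxels, empty masks, rank-deficient nuisance designs and
  constant covariates all have explicit, tested behaviours (drop, error,
  or warn-and-project) rather than silent propagation.
- Problem sizes in the test suite: recovery studies use $n = 10{,}000$
  series; cohort-level checks use 20 phantom cohorts per arm at the
  default 19 + 19 geometry; graph oracles exhaust all labeled graphs to
  5 nodes and all 6-node isomorphism classes.

## Known limitations

- Uncorrected height-plus-extent inference; no random-field or
  permutation correction at the voxel level.
- The observed-scale calibration is computed at the default acquisition
  (200 volumes, TR = 2 s, 0.01–0.1 Hz); phantoms generated at other
  settings fall back to the same table and will be approximate.
- The full-sample second-level mask in the classification stage is
  optimistically biased (see above).
- Graph analysis binarises networks; weighted-graph variants are out of
  scope.
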