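# acfmap

Voxel-wise complexity mapping of resting-state fMRI through the decay of
the temporal autocorrelation function, with the full analysis chain
needed to turn that statistic into a candidate localiser of epileptogenic
brain tissue: group inference with cluster-extent thresholding,
leave-one-subject-out Gaussian-process classification, seed-to-voxel
functional connectivity with clinical correlations, cost-thresholded
graph metrics, and a synthetic phantom-cohort generator with known ground
truth for end-to-end validation.

## The statistic

Each voxel's BOLD time series (after detrending, nuisance regression
against motion and mean WM/CSF signals, and a zero-phase 10th-order
Butterworth band-pass to 0.01–0.1 Hz) is summarised by fitting

    ACF(k) = a · exp(−b k),   k = 0 … 8 lags (lag unit: one TR)

to its sample autocorrelation function by bounded nonlinear least
squares. The decay rate `b` (per TR) and the mean lifetime
`τ = TR / b` (seconds) index how chaotic or persistent the local dynamics
are: white noise has τ ≈ 0; a region generating epileptic activity is
expected to show *slower* decay (lower b) than the same region in
controls. The frequency-domain analogue `β` of the power-law spectrum
P(f) ~ 1/f^β is available as a cross-check (`pssi_beta()`), linked to the
ACF by the Wiener–Khinchin theorem.

## Worked example

A phantom cohort (19 patients vs 19 controls, 200 volumes at TR = 2 s) in
which the focal region's observed decay rate is lowered in patients
(0.71 ± 0.09 vs 0.57 ± 0.05), analysed end to end:

```r
library(acfmap)

spec <- phantom_spec(master_seed = 42)
cohort <- make_cohort(spec)

maps <- lapply(cohort$subjects, function(s)
  b_map(s$bold, cohort$masks$analysis, motion = s$motion,
        wm_mask = cohort$masks$wm, csf_mask = cohort$masks$csf)$b)

patient <- cohort$table$group == "patient"
stat <- two_sample_tmap(maps[patient], maps[!patient], "two_sided")
clusters <- cluster_threshold(stat, p_thresh = 0.005, k_min = 27)
clusters
#> <cluster_set> 1 cluster(s) at p < 0.005, k >= 27
#>   label size peak_x peak_y peak_z    peak_t       peak_p
#> 1     1   91  -16.5   -4.5     -6 -6.398948 2.042915e-07
```

One cluster of 91 voxels survives, its peak t(36) = −6.40 (patients
lower), and it sits inside the phantom's focal region — the ground-truth
ledger (`cohort$ledger`) confirms the localisation. The per-subject
cluster-mean decay rates reproduce the planted group statistics
(controls 0.747 ± 0.076, patients 0.627 ± 0.060 here), and voxel-wise
normality screening retains ~94 % of voxels:

```r
lilliefors_map(maps[!patient])$pass_fraction
#> [1] 0.9444444
```

Classification restricted to that single cluster then separates most
subjects individually (a mask of one region carries less information
than a multi-region difference mask, so accuracy in the mid-80s is the
expected regime here):

```r
fm <- extract_features(maps, cluster_mask(clusters), cohort$table$group,
                       cohort$table$subject_id)
loso_gpc(fm)
#> <classification_result> accuracy 0.816 (sensitivity 0.842, specificity 0.789) over 38 folds
```

Downstream stages follow the same pattern: `extract_seed_series()` /
`seed_to_voxel()` / `conn_group_ttest()` / `clinical_correlation()` for
connectivity, and `build_network()` / `threshold_by_cost()` /
`graph_metrics()` / `compare_groups_metric()` for network topology.

## Command line

Every stage is also a subcommand over a YAML config (see
`inst/cli/acfmap`):

```sh
acfmap simulate --config run.yaml
acfmap bmap     --config run.yaml
acfmap group    --config run.yaml
acfmap classify --config run.yaml --seed 7
acfmap conn     --config run.yaml
acfmap graph    --config run.yaml
```

Each command validates its inputs, writes fixed-name artifacts (NIfTI
maps, CSV/JSON tables) plus a JSON provenance record into its output
directory, and is byte-reproducible from config + seed.

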