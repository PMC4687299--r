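# Seed-to-voxel functional connectivity of the complexity-identified
# cluster. The connectivity pathway conditions series more aggressively
# than the ACF pathway: hyperbolic-tangent despiking, detrending,
# confound regression including motion first derivatives, then the same
# zero-phase band-pass. Correlations are Fisher-z transformed; perfect
# correlations are clipped at |r| = 1 - 1e-7 before atanh so infinities
# never propagate.

#' Fisher z transform of a correlation
#'
#' `z = atanh(r)` with `|r|` clipped to `1 - 1e-7` first.
#' @param r correlation value(s)
#' @return Fisher z value(s)
#' @export
fisher_z <- function(r) {
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' Conditioned mean seed time series
#'
#' Conditions every seed voxel through the connectivity pathway
#' (despike -> detrend -> confound regression with motion derivatives ->
#' band-pass) and averages over the seed.
#'
#' @param bold a [bold_image()]
#' @param seed_mask nonempty mask on the image grid
#' @param motion optional T x 6 motion matrix
#' @param wm_mask,csf_mask optional tissue masks
#' @param spec a [filter_spec()] (defaults to 0.01-0.1 Hz at the image TR)
#' @param c_mult despiking width multiplier
#' @param condition set `FALSE` to average raw series
#' @return numeric vector of length `n_volumes`
#' @export
extract_seed_series <- function(bold, seed_mask, motion = NULL,
                                wm_mask = NULL, csf_mask = NULL, spec = NULL,
                                c_mult = 3, condition = TRUE) {
  m <- as_mask(seed_mask)
  idx <- which(m)
  if (!length(idx)) stop_acf("extract_seed_series: empty seed mask")
  X <- bold_matrix(bold, idx)
  if (condition) {
    spec <- spec %||% filter_spec(sampling_hz = 1 / bold$tr)
    wm <- if (!is.null(wm_mask)) extract_tissue_mean(bold, wm_mask)
    csf <- if (!is.null(csf_mask)) extract_tissue_mean(bold, csf_mask)
    X <- .condition_conn_matrix(X, motion = motion, wm = wm, csf = csf,
                                spec = spec, c_mult = c_mult)
  }
  rowMeans(X)
}

#' Seed-to-voxel connectivity map
#'
#' Pearson correlation of every in-mask voxel's conditioned series with
#' the seed series, Fisher-z transformed. Zero-variance voxels are dropped
#' from the mask. Seed voxels remain in the target mask by default (they
#' appear as trivially high z near the seed); set `exclude_seed = TRUE`
#' with a seed mask to remove them.
#'
#' @param bold a [bold_image()]
#' @param seed_series conditioned seed time series
#'   (see [extract_seed_series()])
#' @param brain_mask analysis mask
#' @param motion,wm_mask,csf_mask,spec,c_mult conditioning controls, as in
#'   [extract_seed_series()]
#' @param condition set `FALSE` to correlate raw series
#' @param exclude_seed optional seed mask whose voxels are removed from
#'   the output
#' @return object of class `conn_map`: `z` ([volume_map()]) of Fisher-z
#'   correlations
#' @export
seed_to_voxel <- function(bold, seed_series, brain_mask, motion = NULL,
                          wm_mask = NULL, csf_mask = NULL, spec = NULL,
                          c_mult = 3, condition = TRUE, exclude_seed = NULL) {
  if (length(seed_series) != bold$n_volumes)
    stop_acf("seed_to_voxel: seed series length does not match the image")
  mask <- as_mask(brain_mask)
  if (!is.null(exclude_seed)) mask <- mask & !as_mask(exclude_seed)
  idx <- which(mask)
  X <- bold_matrix(bold, idx)
  if (condition) {
    spec <- spec %||% filter_spec(sampling_hz = 1 / bold$tr)
    wm <- if (!is.null(wm_mask)) extract_tissue_mean(bold, wm_mask)
    csf <- if (!is.null(csf_mask)) extract_tissue_mean(bold, csf_mask)
    keep0 <- .col_vars(X) > 0
    X[, keep0] <- .condition_conn_matrix(X[, keep0, drop = FALSE],
                                         motion = motion, wm = wm, csf = csf,
                                         spec = spec, c_mult = c_mult)
  }
  sv <- .col_vars(X)
  keep <- sv > 0 & sd(seed_series) > 0
  sc <- seed_series - mean(seed_series)
  Xc <- sweep(X, 2, colMeans(X))
  r <- as.numeric(crossprod(Xc, sc)) /
    (sqrt(colSums(Xc^2)) * sqrt(sum(sc^2)))
  z <- fisher_z(r)
  dm <- dim(mask)
  arr <- array(NaN, dm)
  m <- array(FALSE, dm)
  arr[idx[keep]] <- z[keep]
  m[idx[keep]] <- TRUE
  structure(list(z = volume_map(arr, bold$affine, m)),
            class = "conn_map")
}

#' Group contrast of seed-to-voxel connectivity maps
#'
#' One-sided two-sample t-tests on Fisher-z maps with cluster-extent
#' thresholding (`k_min = 10` by convention for connectivity contrasts).
#' `direction = "both"` runs the increase (patients > controls) and the
#' decrease contrast side by side.
#'
#' @param zmaps_patients,zmaps_controls lists of Fisher-z [volume_map()]s
#'   (or `conn_map`s)
#' @param direction `"both"`, `"increase"` (patients > controls) or
#'   `"decrease"`
#' @param p_thresh,k_min,connectivity cluster rule
#' @return a `cluster_set`, or a list with elements `increases` and
#'   `decreases` when `direction = "both"`
#' @export
conn_group_ttest <- function(zmaps_patients, zmaps_controls,
                             direction = c("both", "increase", "decrease"),
                             p_thresh = 0.005, k_min = 10,
                             connectivity = 18) {
  direction <- match.arg(direction)
  unwrap <- function(m) if (inherits(m, "conn_map")) m$z else m
  zp <- lapply(zmaps_patients, unwrap)
  zc <- lapply(zmaps_controls, unwrap)
  one <- function(dir) {
    stat <- two_sample_tmap(zp, zc, dir)
    cluster_threshold(stat, p_thresh, k_min, connectivity)
  }
  switch(direction,
         increase = one("g1_gt_g2"),
         decrease = one("g1_lt_g2"),
         both = list(increases = one("g1_gt_g2"),
                     decreases = one("g1_lt_g2")))
}

#' Correlation of cluster connectivity with a clinical covariate
#'
#' Per subject, the cluster-mean Fisher z over `cluster_mask`; Pearson
#' correlation of that summary against the covariate with the two-sided p
#' from the t transform on n - 2 degrees of freedom.
#'
#' @param zmaps list of Fisher-z [volume_map()]s (or `conn_map`s), one per
#'   subject
#' @param cluster_mask mask of the cluster whose mean connectivity is
#'   summarised
#' @param covariate per-subject values (n >= 3, non-constant); subjects
#'   with missing covariate are dropped
#' @param covariate_name label carried into the result
#' @return object of class `clinical_correlation`: `r`, `p`, `n`,
#'   `covariate`, `cluster_mean_z`
#' @export
clinical_correlation <- function(zmaps, cluster_mask, covariate,
                                 covariate_name = "covariate") {
  unwrap <- function(m) if (inherits(m, "conn_map")) m$z else m
  zmaps <- lapply(zmaps, unwrap)
  if (length(zmaps) != length(covariate))
    stop_acf("clinical_correlation: covariate length does not match maps")
  cmask <- as_mask(cluster_mask)
  mean_z <- vapply(zmaps, function(m) {
    sel <- cmask & m$mask
    if (!any(sel)) return(NA_real_)
    mean(m$values[sel])
  }, numeric(1))
  ok <- is.finite(mean_z) & is.finite(covariate)
  if (sum(ok) < 3) stop_acf("clinical_correlation: need n >= 3 complete subjects")
  if (sd(covariate[ok]) == 0) stop_acf("clinical_correlation: constant covariate")
  if (sd(mean_z[ok]) == 0) stop_acf("clinical_correlation: constant connectivity summary")
  ct <- cor.test(mean_z[ok], covariate[ok], method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
                 covariate = covariate_name, cluster_mean_z = mean_z),
            class = "clinical_correlation")
}

#' @export
print.clinical_correlation <- function(x, ...) {
  cat(sprintf("<clinical_correlation> %s: r = %.3f, p = %.4g, n = %d\n",
              x$covariate, x$r, x$p, x$n))
  invisible(x)
}
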