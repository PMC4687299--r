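# Voxel-wise group inference on decay-rate maps: pooled-variance
# two-sample t maps, cluster-extent thresholding on the uncorrected p map
# (no FWE/FDR correction is applied - extent plus an uncorrected height
# threshold is the inference rule, a documented limitation), Monte-Carlo
# Lilliefors normality screening, leave-one-subject-out stability of the
# cluster finding, and single-subject deviation maps against a control
# reference.

# Stack the in-mask values of a list of volume_maps into subjects x voxels;
# the common mask is the intersection of the subject masks.
.stack_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  mask <- Reduce(`&`, lapply(maps, function(m) as_mask(m)))
  idx <- which(mask)
  X <- do.call(rbind, lapply(maps, function(m) m$values[idx]))
  list(X = X, mask = mask, idx = idx, affine = maps[[1]]$affine,
       dim = dim(mask))
}

#' Voxel-wise two-sample t map
#'
#' Pooled-variance two-sample t statistic per voxel over the intersection
#' of the subject masks, with `df = n1 + n2 - 2`. Direction `two_sided`
#' gives the two-sided p; `g1_gt_g2` / `g1_lt_g2` give one-sided p values
#' for the corresponding alternative. Voxels with zero pooled variance are
#' dropped from the mask.
#'
#' @param maps_g1,maps_g2 lists of [volume_map()] (>= 2 per group)
#' @param direction `"two_sided"`, `"g1_gt_g2"` or `"g1_lt_g2"`
#' @return object of class `stat_map`: arrays `t` and `p`, `df`,
#'   `direction`, `mask`, `affine`
#' @export
two_sample_tmap <- function(maps_g1, maps_g2,
                            direction = c("two_sided", "g1_gt_g2", "g1_lt_g2")) {
  direction <- match.arg(direction)
  if (length(maps_g1) < 2 || length(maps_g2) < 2)
    stop_acf("two_sample_tmap: need at least 2 maps per group")
  st <- .stack_maps(c(maps_g1, maps_g2))
  n1 <- length(maps_g1)
  n2 <- length(maps_g2)
  X1 <- st$X[seq_len(n1), , drop = FALSE]
  X2 <- st$X[n1 + seq_len(n2), , drop = FALSE]
  m1 <- colMeans(X1)
  m2 <- colMeans(X2)
  ss1 <- colSums(sweep(X1, 2, m1)^2)
  ss2 <- colSums(sweep(X2, 2, m2)^2)
  df <- n1 + n2 - 2L
  sp2 <- (ss1 + ss2) / df
  ok <- sp2 > 0
  tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- switch(direction,
              two_sided = 2 * pt(abs(tval), df, lower.tail = FALSE),
              g1_gt_g2 = pt(tval, df, lower.tail = FALSE),
              g1_lt_g2 = pt(tval, df, lower.tail = TRUE))
  dmv <- st$dim
  tarr <- array(NaN, dmv)
  parr <- array(NaN, dmv)
  mask <- array(FALSE, dmv)
  keep <- st$idx[ok]
  tarr[keep] <- tval[ok]
  parr[keep] <- p[ok]
  mask[keep] <- TRUE
  structure(list(t = tarr, p = parr, df = df, direction = direction,
                 mask = mask, affine = st$affine, n1 = n1, n2 = n2),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> df = %d, %s, %d in-mask voxels, max |t| = %.2f\n",
              x$df, x$direction, sum(x$mask), max(abs(x$t[x$mask]))))
  invisible(x)
}

# Neighbourhood offsets for 6 / 18 / 26 connectivity.
.conn_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  lim <- switch(as.character(connectivity), "6" = 1, "18" = 2, "26" = 3,
                stop_acf("connectivity must be 6, 18 or 26"))
  g[rowSums(abs(g)) <= lim, , drop = FALSE]
}

#' Label connected components of a 3D logical array
#'
#' Breadth-first flood fill under face (6), face+edge (18, the default
#' convention of SPM-style cluster reporting) or face+edge+corner (26)
#' connectivity.
#'
#' @param mask logical 3D array
#' @param connectivity 6, 18 or 26
#' @return integer array of component labels (0 = background)
#' @export
label_components <- function(mask, connectivity = 18) {
  dm <- dim(mask)
  off <- .conn_offsets(connectivity)
  lab <- array(0L, dm)
  todo <- which(mask)
  if (!length(todo)) return(lab)
  visited <- array(FALSE, dm)
  cur <- 0L
  for (seed in todo) {
    if (visited[seed]) next
    cur <- cur + 1L
    frontier <- seed
    visited[seed] <- TRUE
    lab[seed] <- cur
    while (length(frontier)) {
      ijk <- lin_to_ijk(frontier, dm)
      nb <- do.call(rbind, lapply(seq_len(nrow(off)), function(o)
        sweep(ijk, 2, -off[o, ])))
      inb <- nb[, 1] >= 1 & nb[, 1] <= dm[1] &
        nb[, 2] >= 1 & nb[, 2] <= dm[2] &
        nb[, 3] >= 1 & nb[, 3] <= dm[3]
      nb <- nb[inb, , drop = FALSE]
      lin <- unique(ijk_to_lin(nb, dm))
      lin <- lin[mask[lin] & !visited[lin]]
      visited[lin] <- TRUE
      lab[lin] <- cur
      frontier <- lin
    }
  }
  lab
}

#' Extract suprathreshold clusters from a statistic map
#'
#' Thresholds the uncorrected p map at `p_thresh`, labels connected
#' components, and keeps components of at least `k_min` voxels (the
#' extent rule "greater than 26 voxels" is `k_min = 27`). Clusters are
#' returned sorted by descending peak |t|, with peak world coordinates
#' (mm, rounded to one decimal).
#'
#' @param stat a [two_sample_tmap()] result
#' @param p_thresh height threshold on the uncorrected p
#' @param k_min minimum cluster extent in voxels
#' @param connectivity 6, 18 (default) or 26
#' @return object of class `cluster_set`: data.frame `clusters` (label,
#'   size, peak coordinates, peak t/p) plus the integer `label_volume`
#' @export
cluster_threshold <- function(stat, p_thresh = 0.005, k_min = 27,
                              connectivity = 18) {
  supra <- stat$mask & is.finite(stat$p) & stat$p < p_thresh
  lab <- label_components(supra, connectivity)
  keep_tab <- table(lab[lab > 0])
  keep <- as.integer(names(keep_tab))[keep_tab >= k_min]
  out_lab <- array(0L, dim(lab))
  rows <- list()
  for (l in keep) {
    vox <- which(lab == l)
    tv <- stat$t[vox]
    pk <- vox[which.max(abs(tv))]
    ijk <- lin_to_ijk(pk, dim(lab))
    wc <- round(voxel_to_world(stat$affine, ijk), 1)
    rows[[length(rows) + 1]] <- data.frame(
      size = length(vox), peak_x = wc[1], peak_y = wc[2], peak_z = wc[3],
      peak_t = stat$t[pk], peak_p = stat$p[pk], old_label = l)
  }
  if (length(rows)) {
    df <- do.call(rbind, rows)
    ord <- order(-abs(df$peak_t))
    df <- df[ord, , drop = FALSE]
    df$label <- seq_len(nrow(df))
    for (i in seq_len(nrow(df)))
      out_lab[lab == df$old_label[i]] <- df$label[i]
    df$old_label <- NULL
    rownames(df) <- NULL
    df <- df[, c("label", "size", "peak_x", "peak_y", "peak_z",
                 "peak_t", "peak_p")]
  } else {
    df <- data.frame(label = integer(0), size = integer(0),
                     peak_x = numeric(0), peak_y = numeric(0),
                     peak_z = numeric(0), peak_t = numeric(0),
                     peak_p = numeric(0))
  }
  structure(list(clusters = df, label_volume = out_lab,
                 affine = stat$affine, p_thresh = p_thresh, k_min = k_min,
                 connectivity = connectivity),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s) at p < %g, k >= %d\n",
              nrow(x$clusters), x$p_thresh, x$k_min))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Binary mask of one cluster (or of all clusters)
#'
#' @param cs a [cluster_threshold()] result
#' @param label cluster label, or `NULL` for the union of all clusters
#'   (the "2nd-level mask" used to restrict classification features)
#' @return logical 3D array
#' @export
cluster_mask <- function(cs, label = NULL) {
  if (is.null(label)) cs$label_volume > 0L else cs$label_volume == label
}

# Lilliefors sup-distance statistic for each column of an n x V matrix.
.lilliefors_stat_cols <- function(X) {
  n <- nrow(X)
  Xs <- apply(X, 2, sort)
  if (is.null(dim(Xs))) Xs <- matrix(Xs, nrow = n)
  mu <- colMeans(Xs)
  s <- sqrt(.col_vars(Xs))
  Z <- sweep(sweep(Xs, 2, mu), 2, s, "/")
  Phi <- pnorm(Z)
  i <- seq_len(n)
  Dplus <- apply(i / n - Phi, 2, max)
  Dminus <- apply(Phi - (i - 1) / n, 2, max)
  pmax(Dplus, Dminus)
}

#' Lilliefors goodness-of-fit statistic
#'
#' Sup distance between the empirical CDF of a sample and the normal CDF
#' with the sample's estimated mean and SD.
#'
#' @param x numeric sample (n >= 5, non-constant)
#' @return the statistic
#' @export
lilliefors_stat <- function(x) {
  if (length(x) < 5) stop_acf("lilliefors_stat: need n >= 5")
  if (sd(x) == 0) stop_acf("lilliefors_stat: constant sample")
  as.numeric(.lilliefors_stat_cols(matrix(x, ncol = 1)))
}

.lillie_env <- new.env(parent = emptyenv())

#' Monte-Carlo critical value for the Lilliefors test
#'
#' Exact-by-simulation critical value for sample size `n`: the
#' `1 - alpha` quantile of the statistic over `nsim` standard-normal
#' samples, computed once per `(n, alpha, nsim)` under a fixed private
#' seed (the caller's RNG stream is untouched) and memoised.
#'
#' @param n sample size
#' @param alpha test level
#' @param nsim number of null simulations (>= 10000 recommended)
#' @return the critical value
#' @export
lilliefors_critical <- function(n, alpha = 0.05, nsim = 10000) {
  key <- paste(n, alpha, nsim, sep = "_")
  if (!is.null(.lillie_env[[key]])) return(.lillie_env[[key]])
  crit <- with_private_seed(7231 + n, {
    X <- matrix(rnorm(n * nsim), n, nsim)
    D <- .lilliefors_stat_cols(X)
    as.numeric(quantile(D, 1 - alpha, type = 7))
  })
  .lillie_env[[key]] <- crit
  crit
}

#' Voxel-wise Lilliefors normality screening
#'
#' Tests, at each in-mask voxel, whether one group's decay-rate values are
#' consistent with a normal distribution, against Monte-Carlo critical
#' values for the group's n. Voxels constant across subjects are dropped.
#'
#' @param maps list of [volume_map()] for one group (>= 5 subjects)
#' @param alpha test level
#' @param nsim null simulations for the critical value
#' @return object of class `normality_map`: `pass_fraction` (share of
#'   in-mask voxels where normality is not rejected) and the per-voxel
#'   `decisions` [volume_map()] (1 = normality retained)
#' @export
lilliefors_map <- function(maps, alpha = 0.05, nsim = 10000) {
  if (length(maps) < 5) stop_acf("lilliefors_map: need at least 5 subjects")
  st <- .stack_maps(maps)
  v <- .col_vars(st$X)
  ok <- v > 0
  D <- rep(NA_real_, ncol(st$X))
  D[ok] <- .lilliefors_stat_cols(st$X[, ok, drop = FALSE])
  crit <- lilliefors_critical(nrow(st$X), alpha, nsim)
  pass <- D <= crit
  arr <- array(NaN, st$dim)
  mask <- array(FALSE, st$dim)
  arr[st$idx[ok]] <- as.numeric(pass[ok])
  mask[st$idx[ok]] <- TRUE
  structure(list(pass_fraction = mean(pass[ok]),
                 decisions = volume_map(arr, st$affine, mask),
                 critical = crit, alpha = alpha, n = nrow(st$X)),
            class = "normality_map")
}

#' Leave-one-subject-out stability of a cluster finding
#'
#' Repeats the two-sample t-test `n1 + n2` times, each time leaving one
#' subject out, and reports the fraction of repetitions in which a
#' surviving cluster contains the target world coordinate.
#'
#' @param maps_g1,maps_g2 lists of [volume_map()]
#' @param target_world mm coordinate (length-3)
#' @param p_thresh,k_min,connectivity cluster rule (see
#'   [cluster_threshold()])
#' @param direction t-test sidedness passed to [two_sample_tmap()]
#' @return fraction in `[0, 1]`
#' @export
loso_stability <- function(maps_g1, maps_g2, target_world,
                           p_thresh = 0.005, k_min = 27, connectivity = 18,
                           direction = "two_sided") {
  if (length(maps_g1) < 2 || length(maps_g2) < 2)
    stop_acf("loso_stability: need at least 2 subjects per group")
  aff <- maps_g1[[1]]$affine
  ijk <- world_to_voxel(aff, target_world)
  dm <- dim(maps_g1[[1]]$mask)
  if (any(ijk < 1) || any(ijk > dm))
    stop_acf("loso_stability: target coordinate outside the image grid")
  tgt <- ijk_to_lin(matrix(ijk, nrow = 1), dm)
  common <- Reduce(`&`, lapply(c(maps_g1, maps_g2), as_mask))
  if (!common[tgt]) stop_acf("loso_stability: target coordinate outside the mask")
  n1 <- length(maps_g1)
  n2 <- length(maps_g2)
  hit <- logical(n1 + n2)
  for (i in seq_len(n1 + n2)) {
    g1 <- if (i <= n1) maps_g1[-i] else maps_g1
    g2 <- if (i > n1) maps_g2[-(i - n1)] else maps_g2
    stat <- two_sample_tmap(g1, g2, direction)
    cs <- cluster_threshold(stat, p_thresh, k_min, connectivity)
    hit[i] <- cs$label_volume[tgt] > 0L
  }
  mean(hit)
}

#' Single-subject deviation mapping against a control reference
#'
#' Flags voxels where a patient's map deviates from the control mean by
#' more than `z_thresh` control SDs (below, by default: the direction of a
#' pathologically slowed decay), then clusters the flagged voxels and
#' keeps clusters of at least `k_min` voxels. Voxels with zero control SD
#' are dropped.
#'
#' @param patient_map a [volume_map()]
#' @param control_maps list of >= 5 control [volume_map()]s
#' @param z_thresh deviation threshold in control SD units
#' @param k_min minimum cluster extent (default 7, i.e. "> 6 voxels")
#' @param sign `"below"` or `"above"`
#' @param connectivity cluster connectivity
#' @return a `cluster_set` (peak fields hold the deviation z value)
#' @export
subject_deviation_map <- function(patient_map, control_maps, z_thresh = 2,
                                  k_min = 7, sign = c("below", "above"),
                                  connectivity = 18) {
  sign <- match.arg(sign)
  if (length(control_maps) < 5)
    stop_acf("subject_deviation_map: need at least 5 control maps")
  st <- .stack_maps(c(list(patient_map), control_maps))
  pat <- st$X[1, ]
  ctl <- st$X[-1, , drop = FALSE]
  mu <- colMeans(ctl)
  s <- sqrt(.col_vars(ctl))
  ok <- s > 0
  z <- (pat - mu) / ifelse(s > 0, s, NA_real_)
  dev <- if (sign == "below") z < -z_thresh else z > z_thresh
  dev[!ok] <- FALSE
  mask <- array(FALSE, st$dim)
  mask[st$idx] <- dev
  lab <- label_components(mask, connectivity)
  zarr <- array(NaN, st$dim)
  zarr[st$idx] <- z
  keep_tab <- table(lab[lab > 0])
  keep <- as.integer(names(keep_tab))[keep_tab >= k_min]
  out_lab <- array(0L, st$dim)
  rows <- list()
  for (l in keep) {
    vox <- which(lab == l)
    pk <- vox[which.max(abs(zarr[vox]))]
    ijk <- lin_to_ijk(pk, st$dim)
    wc <- round(voxel_to_world(st$affine, ijk), 1)
    rows[[length(rows) + 1]] <- data.frame(
      size = length(vox), peak_x = wc[1], peak_y = wc[2], peak_z = wc[3],
      peak_t = zarr[pk], peak_p = NA_real_, old_label = l)
  }
  if (length(rows)) {
    df <- do.call(rbind, rows)
    df <- df[order(-abs(df$peak_t)), , drop = FALSE]
    df$label <- seq_len(nrow(df))
    for (i in seq_len(nrow(df)))
      out_lab[lab == df$old_label[i]] <- df$label[i]
    df$old_label <- NULL
    rownames(df) <- NULL
    df <- df[, c("label", "size", "peak_x", "peak_y", "peak_z",
                 "peak_t", "peak_p")]
  } else {
    df <- data.frame(label = integer(0), size = integer(0),
                     peak_x = numeric(0), peak_y = numeric(0),
                     peak_z = numeric(0), peak_t = numeric(0),
                     peak_p = numeric(0))
  }
  structure(list(clusters = df, label_volume = out_lab, affine = st$affine,
                 p_thresh = NA_real_, k_min = k_min,
                 connectivity = connectivity, z_thresh = z_thresh),
            class = "cluster_set")
}
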