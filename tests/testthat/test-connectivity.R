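# Seed-to-voxel connectivity, Fisher z, group contrasts and clinical
# correlations.

test_that("Fisher z is the closed form, odd, monotone, and clipped at |r| = 1", {
  expect_equal(fisher_z(0.5), log((1 + 0.5) / (1 - 0.5)) / 2, tolerance = 1e-12)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-r), -fisher_z(r), tolerance = 1e-12)
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_true(is.finite(fisher_z(1)))
  expect_gt(fisher_z(1), 8)
})

test_that("seed series is the conditioned mean and matches a loop oracle", {
  bold <- tiny_bold(dm = c(5, 5, 4), nt = 120, seed = 50)
  seed_mask <- array(FALSE, c(5, 5, 4))
  seed_mask[2:3, 2:3, 2] <- TRUE
  # raw path: equals the loop-based mean
  got <- extract_seed_series(bold, seed_mask, condition = FALSE)
  oracle <- rep(0, 120)
  for (i in 1:5) for (j in 1:5) for (k in 1:4)
    if (seed_mask[i, j, k]) oracle <- oracle + bold$data[i, j, k, ]
  oracle <- oracle / sum(seed_mask)
  expect_equal(got, oracle, tolerance = 1e-12)

  # single-voxel seed, conditioned: equals conditioning that voxel
  m1 <- array(FALSE, c(5, 5, 4)); m1[3, 3, 2] <- TRUE
  fs <- filter_spec(sampling_hz = 0.5)
  got1 <- extract_seed_series(bold, m1, spec = fs)
  ref <- acfmap:::.condition_conn_matrix(matrix(bold$data[3, 3, 2, ], ncol = 1),
                                         spec = fs)
  expect_equal(got1, drop(ref), tolerance = 1e-10)

  # antisymmetric pair of voxels averages to (numerically) zero
  b2 <- bold
  b2$data[2, 1, 1, ] <- -b2$data[1, 1, 1, ]
  m2 <- array(FALSE, c(5, 5, 4)); m2[1:2, 1, 1] <- TRUE
  expect_lt(max(abs(extract_seed_series(b2, m2, spec = fs))), 1e-8)

  expect_error(extract_seed_series(bold, array(FALSE, c(5, 5, 4))), "empty")
})

test_that("seed-to-voxel maps hit the clip ceiling at r = 1 and stay small for noise", {
  set.seed(51)
  dm <- c(5, 5, 4)
  nt <- 200
  arr <- array(rnorm(prod(dm) * nt), c(dm, nt))
  seed_series <- rnorm(nt)
  arr[2, 2, 2, ] <- seed_series            # identical to the seed
  bold <- bold_image(arr, diag(4), 2)
  cm <- seed_to_voxel(bold, seed_series, array(TRUE, dm), condition = FALSE)
  expect_gt(cm$z$values[2, 2, 2], 8)       # atanh at the clip ceiling
  others <- cm$z$values[cm$z$mask]
  others <- others[abs(others) < 8]
  expect_true(all(abs(others) < 0.3))      # ~2 x 2/sqrt(n) bound

  # zero-variance voxel is dropped
  arr2 <- arr
  arr2[1, 1, 1, ] <- 3
  bold2 <- bold_image(arr2, diag(4), 2)
  cm2 <- seed_to_voxel(bold2, seed_series, array(TRUE, dm), condition = FALSE)
  expect_false(cm2$z$mask[1, 1, 1])
})

test_that("group contrasts recover planted increases and decreases", {
  dm <- c(10, 10, 6)
  local_roi <- array(FALSE, dm); local_roi[2:5, 2:5, 2:3] <- TRUE
  distant_roi <- array(FALSE, dm); distant_roi[7:9, 7:9, 4:5] <- TRUE
  mkz <- function(z_local, z_distant, seed) {
    set.seed(seed)
    vals <- array(rnorm(prod(dm), 0, 0.1), dm)
    vals[local_roi] <- vals[local_roi] + z_local
    vals[distant_roi] <- vals[distant_roi] + z_distant
    volume_map(vals, diag(4))
  }
  zp <- lapply(1:10, function(i) mkz(0.6, 0.1, 900 + i))   # patients: local up, distant down
  zc <- lapply(1:10, function(i) mkz(0.2, 0.5, 950 + i))
  res <- conn_group_ttest(zp, zc, "both")
  expect_gt(nrow(res$increases$clusters), 0)
  expect_gt(nrow(res$decreases$clusters), 0)
  inc_mask <- cluster_mask(res$increases, 1)
  dec_mask <- cluster_mask(res$decreases, 1)
  expect_gt(sum(inc_mask & local_roi) / sum(inc_mask), 0.9)
  expect_gt(sum(dec_mask & distant_roi) / sum(dec_mask), 0.9)

  # identical groups: both directions empty
  res0 <- conn_group_ttest(zp, zp, "both")
  expect_equal(nrow(res0$increases$clusters), 0L)
  expect_equal(nrow(res0$decreases$clusters), 0L)

  # subject ordering cannot matter
  res_perm <- conn_group_ttest(zp[c(3, 1, 2, 4:10)], zc, "increase")
  expect_equal(res_perm$clusters, res$increases$clusters)

  # a 9-voxel effect dies at k_min = 10
  tiny_roi <- array(FALSE, dm); tiny_roi[1:3, 1:3, 1] <- TRUE
  mkt <- function(shift, seed) {
    set.seed(seed)
    vals <- array(rnorm(prod(dm), 0, 0.1), dm)
    vals[tiny_roi] <- vals[tiny_roi] + shift
    volume_map(vals, diag(4))
  }
  zp2 <- lapply(1:10, function(i) mkt(1, 970 + i))
  zc2 <- lapply(1:10, function(i) mkt(0, 980 + i))
  res2 <- conn_group_ttest(zp2, zc2, "increase", k_min = 10)
  expect_equal(nrow(res2$clusters), 0L)
})

test_that("clinical correlations match the covariance-formula oracle", {
  dm <- c(6, 6, 4)
  cmask <- array(FALSE, dm); cmask[2:4, 2:4, 2] <- TRUE
  set.seed(52)
  zmaps <- lapply(1:19, function(i) tiny_map(dm = dm, seed = 1000 + i))
  mean_z <- vapply(zmaps, function(m) mean(m$values[cmask]), numeric(1))

  # exact linear covariate: r = 1 with tiny p
  cl <- clinical_correlation(zmaps, cmask, 3 * mean_z - 1)
  expect_equal(cl$r, 1, tolerance = 1e-12)
  expect_lt(cl$p, 1e-12)

  # perfect negative example
  mk3 <- function(v) volume_map(array(v, dm), diag(4))
  expect_equal(clinical_correlation(list(mk3(1), mk3(2), mk3(3)),
                                    array(TRUE, dm), c(6, 4, 2))$r,
               -1, tolerance = 1e-12)

  # random covariate vs direct formula
  covar <- rnorm(19)
  cl2 <- clinical_correlation(zmaps, cmask, covar)
  r_oracle <- sum((mean_z - mean(mean_z)) * (covar - mean(covar))) /
    sqrt(sum((mean_z - mean(mean_z))^2) * sum((covar - mean(covar))^2))
  t_oracle <- r_oracle * sqrt(17 / (1 - r_oracle^2))
  p_oracle <- 2 * pt(abs(t_oracle), 17, lower.tail = FALSE)
  expect_equal(cl2$r, r_oracle, tolerance = 1e-10)
  expect_equal(cl2$p, p_oracle, tolerance = 1e-10)
  expect_equal(cl2$n, 19L)

  expect_error(clinical_correlation(zmaps, cmask, rep(1, 19)), "constant")
})

test_that("planted covariate links are estimable without bias at the generator level", {
  # Gaussian-copula covariate against realized edge Fisher z, as
  # make_cohort draws it: across replicate cohorts of n = 19 the
  # estimated correlation centres on the planted rho.
  rho <- 0.6
  set.seed(53)
  est <- replicate(400, {
    z_hat <- vapply(1:19, function(i) {
      r_i <- tanh(rnorm(1, atanh(0.45), 0.12))
      pair <- make_connected_pair(r_i, 200)
      fisher_z(cor(pair$a, pair$b))
    }, numeric(1))
    u <- as.numeric(scale(z_hat))
    covar <- rho * u + sqrt(1 - rho^2) * rnorm(19)
    cor(covar, z_hat)
  })
  expect_lt(abs(mean(est) - rho), 0.05)
  expect_gt(mean(est > 0.2 & est < 0.9), 0.95)
})
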