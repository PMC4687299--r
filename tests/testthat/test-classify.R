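# Gaussian-process classification: feature extraction, the Laplace
# classifier, leave-one-subject-out accuracy, permutation significance.

make_fm <- function(X, y) {
  structure(list(X = X, y = y, ids = sprintf("s%02d", seq_len(nrow(X))),
                 voxel_index = NULL, dim = NULL, affine = diag(4)),
            class = "feature_matrix")
}

test_that("feature extraction is deterministic and respects masks", {
  dm <- c(6, 6, 4)
  mask <- array(FALSE, dm)
  mask[2:5, 2:5, 2:3] <- TRUE
  maps <- lapply(1:8, function(i) tiny_map(dm = dm, seed = 800 + i))
  labels <- rep(c("patient", "control"), 4)
  fm <- extract_features(maps, mask, labels)
  expect_equal(dim(fm$X), c(8L, sum(mask)))
  expect_equal(fm$y, ifelse(labels == "patient", 1, -1))
  # permuting subjects permutes rows identically
  ord <- c(3, 1, 2, 8, 7, 4, 5, 6)
  fm2 <- extract_features(maps[ord], mask, labels[ord])
  expect_equal(fm2$X, fm$X[ord, ])

  # subject mask excluding a voxel shrinks the feature set with a warning
  m2 <- maps
  mm <- mask
  mm[2, 2, 2] <- FALSE
  v <- m2[[1]]$values
  v[2, 2, 2] <- NaN
  m2[[1]] <- volume_map(v, diag(4), is.finite(v))
  expect_warning(fm3 <- extract_features(m2, mask, labels), "excluded")
  expect_equal(ncol(fm3$X), sum(mask) - 1L)

  # disjoint mask is an error
  far <- array(FALSE, dm)
  far[1, 1, 1] <- TRUE
  m4 <- lapply(maps, function(m) {
    v <- m$values
    v[1, 1, 1] <- NaN
    volume_map(v, diag(4), is.finite(v))
  })
  expect_error(extract_features(m4, far, labels), "disjoint")
})

test_that("the GP classifier separates distant clusters and is calibrated on noise", {
  set.seed(40)
  X <- matrix(c(rnorm(10, -10), rnorm(10, 10)), ncol = 1)
  y <- rep(c(-1, 1), each = 10)
  model <- gpc_fit(X, y)
  p_new <- gpc_predict(model, matrix(c(-10, 10), ncol = 1))
  expect_lt(p_new[1], 0.1)
  expect_gt(p_new[2], 0.9)

  # pure-noise features: held-out probabilities hover near 1/2
  set.seed(41)
  Xn <- matrix(rnorm(30 * 10), 30, 10)
  yn <- rep(c(-1, 1), 15)
  probs <- acfmap:::.loso_gpc_gram(tcrossprod(Xn), yn)
  expect_lt(abs(mean(probs) - 0.5), 0.1)

  # duplicating a feature column leaves predictions essentially unchanged
  set.seed(42)
  Xd <- matrix(rnorm(20 * 5), 20, 5)
  yd <- rep(c(-1, 1), 10)
  m1 <- gpc_fit(Xd, yd)
  m2 <- gpc_fit(cbind(Xd, Xd[, 3]), yd)
  xnew <- matrix(rnorm(10 * 5), 10, 5)
  p1 <- gpc_predict(m1, xnew)
  p2 <- gpc_predict(m2, cbind(xnew, xnew[, 3]))
  expect_lt(max(abs(p1 - p2)), 0.05)
})

test_that("predictions are invariant to global affine rescaling of features", {
  set.seed(43)
  X <- matrix(rnorm(24 * 6), 24, 6)
  y <- rep(c(-1, 1), 12)
  fm1 <- make_fm(X, y)
  fm2 <- make_fm(X * 250 + 3, y)
  r1 <- loso_gpc(fm1)
  r2 <- loso_gpc(fm2)
  expect_lt(max(abs(r1$folds$probability - r2$folds$probability)), 1e-6)
})

test_that("kernel-space LOSO agrees with explicit per-fold feature-space fits", {
  set.seed(44)
  X <- matrix(rnorm(14 * 4), 14, 4)
  X[8:14, ] <- X[8:14, ] + 1.5
  y <- rep(c(-1, 1), c(7, 7))
  probs_gram <- acfmap:::.loso_gpc_gram(tcrossprod(X), y)
  probs_feat <- vapply(1:14, function(i) {
    m <- gpc_fit(X[-i, , drop = FALSE], y[-i])
    gpc_predict(m, X[i, , drop = FALSE])
  }, numeric(1))
  expect_equal(probs_gram, probs_feat, tolerance = 1e-8)
})

test_that("GP probabilities broadly agree with kernlab on a shared problem", {
  skip_if_not_installed("kernlab")
  set.seed(45)
  X <- matrix(rnorm(30 * 3), 30, 3)
  X[16:30, 1] <- X[16:30, 1] + 2
  y <- rep(c(-1, 1), each = 15)
  model <- gpc_fit(X, y, kernel = "rbf")
  p_ours <- gpc_predict(model, X)
  kl <- kernlab::gausspr(X, factor(y))
  p_kl <- kernlab::predict(kl, X, type = "probabilities")[, "1"]
  # same ranking and same decisions on clearly separated points
  expect_gt(cor(p_ours, p_kl), 0.8)
  clear <- abs(p_kl - 0.5) > 0.25
  expect_true(all((p_ours[clear] > 0.5) == (p_kl[clear] > 0.5)))
})

test_that("LOSO is perfect on separable cohorts and chance-level on shuffled labels", {
  set.seed(46)
  n <- 19
  X <- rbind(matrix(rnorm(n * 20, 0), n, 20),
             matrix(rnorm(n * 20, 3), n, 20))
  y <- rep(c(-1, 1), each = n)
  fm <- make_fm(X, y)
  res <- loso_gpc(fm)
  expect_equal(res$accuracy, 1.0)
  expect_equal(res$sensitivity, 1.0)
  expect_equal(res$specificity, 1.0)
  expect_true(all(res$folds$probability > 0 & res$folds$probability < 1))

  # label shuffling: accuracy near 1/2 across repetitions
  set.seed(47)
  accs <- replicate(10, {
    loso_gpc(make_fm(X, sample(y)))$accuracy
  })
  expect_lt(abs(mean(accs) - 0.5), 0.12)
})

test_that("weight maps concentrate on the informative region", {
  set.seed(48)
  dm <- c(8, 8, 4)
  mask <- array(TRUE, dm)
  informative <- array(FALSE, dm)
  informative[2:4, 2:4, 2] <- TRUE      # 9 voxels carry the effect
  maps <- list()
  labels <- rep(c("patient", "control"), each = 10)
  for (i in seq_along(labels)) {
    vals <- array(rnorm(prod(dm), 0, 0.3), dm)
    if (labels[i] == "patient") vals[informative] <- vals[informative] - 1
    maps[[i]] <- volume_map(vals, diag(4))
  }
  fm <- extract_features(maps, mask, labels)
  res <- loso_gpc(fm)
  w <- abs(res$weights$values)
  top <- order(w[mask], decreasing = TRUE)[1:ceiling(0.1 * sum(mask))]
  top_voxels <- which(mask)[top]
  overlap <- mean(which(informative) %in% top_voxels)
  expect_gt(overlap, 0.8)
})

test_that("permutation p-values follow the +1 smoothing formula", {
  set.seed(49)
  n <- 8
  X <- rbind(matrix(rnorm(n * 5, 0), n, 5), matrix(rnorm(n * 5, 4), n, 5))
  y <- rep(c(-1, 1), each = n)
  fm <- make_fm(X, y)
  perm <- permutation_test(fm, n_perm = 100, seed = 5)
  # observed accuracy 1.0 beats every null permutation
  expect_equal(perm$observed[["accuracy"]], 1.0)
  expect_equal(perm$p_overall, 1 / 101)
  expect_gte(perm$p_overall, 1 / (perm$n_perm + 1))
  expect_error(permutation_test(fm, n_perm = 0), "n_perm")
})

test_that("a fold that loses one class entirely is an error", {
  X <- matrix(rnorm(10), 5, 2)
  y <- c(1, -1, -1, -1, -1)
  expect_error(loso_gpc(make_fm(X, y)), "lost one class")
})
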