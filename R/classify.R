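# Subject-level diagnosis from decay-rate maps: binary Gaussian-process
# classification over the voxels of a second-level mask (the
# group-difference clusters), leave-one-subject-out cross-validation, and
# label-permutation significance. The classifier is a linear-kernel GP
# with probit likelihood and Laplace-approximate posterior - deterministic
# and standard for whole-map neuroimaging classification, and the linear
# kernel makes the voxel weight map exact: w = X' alpha.

#' Build the subjects x features matrix from decay-rate maps
#'
#' One row per subject, one column per in-mask voxel, in deterministic
#' (linear voxel index, i.e. lexicographic) order. If a subject's own mask
#' excludes some mask voxels, the feature mask is intersected with a
#' warning.
#'
#' @param maps list of [volume_map()], one per subject
#' @param second_level_mask logical array or [volume_map()]: the voxels
#'   used as features
#' @param labels vector of group labels (`"patient"`/`"control"`, logical,
#'   or +1/-1); patients are coded +1
#' @param ids optional subject identifiers
#' @return object of class `feature_matrix`: `X`, `y` (+1/-1), `ids`,
#'   `voxel_index`, `dim`, `affine`
#' @export
extract_features <- function(maps, second_level_mask, labels, ids = NULL) {
  mask <- as_mask(second_level_mask)
  common <- Reduce(`&`, lapply(maps, as_mask))
  feat <- mask & common
  n_lost <- sum(mask) - sum(feat)
  if (!sum(feat))
    stop_acf("extract_features: the second-level mask is disjoint from the data masks")
  if (n_lost > 0)
    warning(sprintf("extract_features: %d mask voxel(s) excluded by subject masks",
                    n_lost), call. = FALSE)
  idx <- which(feat)
  X <- do.call(rbind, lapply(maps, function(m) m$values[idx]))
  y <- .coerce_labels(labels, length(maps))
  ids <- ids %||% sprintf("sub%02d", seq_along(maps))
  structure(list(X = X, y = y, ids = ids, voxel_index = idx,
                 dim = dim(mask), affine = maps[[1]]$affine),
            class = "feature_matrix")
}

.coerce_labels <- function(labels, n) {
  if (length(labels) != n) stop_acf("labels length does not match subjects")
  y <- if (is.character(labels)) ifelse(labels == "patient", 1, -1)
  else if (is.logical(labels)) ifelse(labels, 1, -1)
  else as.numeric(labels)
  if (!all(y %in% c(-1, 1))) stop_acf("labels must code two classes as +1/-1")
  if (length(unique(y)) < 2) stop_acf("both classes must be present")
  y
}

# Laplace approximation for binary GP classification with probit
# likelihood (Newton iteration on the latent posterior mode). K must be
# symmetric PSD. Returns the quantities needed for prediction.
.gpc_laplace <- function(K, y, max_iter = 100, tol = 1e-10) {
  n <- length(y)
  f <- numeric(n)
  obj_old <- -Inf
  for (it in seq_len(max_iter)) {
    z <- y * f
    lr <- exp(dnorm(z, log = TRUE) - pnorm(z, log.p = TRUE))  # phi/Phi at z
    grad <- y * lr
    W <- lr^2 + z * lr
    W <- pmax(W, 1e-12)
    sw <- sqrt(W)
    B <- diag(n) + (sw %o% sw) * K
    L <- chol(B)
    bvec <- W * f + grad
    v <- backsolve(L, forwardsolve(t(L), sw * (K %*% bvec)))
    avec <- bvec - sw * v
    f_new <- as.numeric(K %*% avec)
    obj <- -0.5 * sum(avec * f_new) + sum(pnorm(y * f_new, log.p = TRUE))
    if (is.finite(obj) && abs(obj - obj_old) < tol) {
      f <- f_new
      break
    }
    f <- f_new
    obj_old <- obj
  }
  z <- y * f
  lr <- exp(dnorm(z, log = TRUE) - pnorm(z, log.p = TRUE))
  grad <- y * lr
  W <- pmax(lr^2 + z * lr, 1e-12)
  sw <- sqrt(W)
  L <- chol(diag(n) + (sw %o% sw) * K)
  list(f = f, grad = grad, sqrtW = sw, L = L,
       converged = it < max_iter)
}

# Averaged probit predictive probability for latent mean/variance.
.gpc_prob <- function(fstar, vstar) {
  pnorm(fstar / sqrt(1 + pmax(vstar, 0)))
}

#' Fit a Gaussian-process classifier
#'
#' Linear kernel `K = Xc Xc' / s` on training-centred features (`s` is the
#' mean kernel diagonal, making predictions invariant to global affine
#' rescaling of the features), probit likelihood, Laplace-approximate
#' posterior. An RBF kernel is available for comparison.
#'
#' @param X subjects x features matrix
#' @param y labels in +1/-1 (or `"patient"`/`"control"`)
#' @param kernel `"linear"` (default) or `"rbf"`
#' @param jitter diagonal jitter added to the kernel
#' @param rbf_scale bandwidth multiplier for the RBF kernel (median
#'   heuristic times this factor)
#' @return object of class `gpc_model`
#' @export
gpc_fit <- function(X, y, kernel = c("linear", "rbf"), jitter = 1e-8,
                    rbf_scale = 1) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  y <- .coerce_labels(y, nrow(X))
  if (min(table(y)) < 2) stop_acf("gpc_fit: need >= 2 subjects per class")
  centre <- colMeans(X)
  Xc <- sweep(X, 2, centre)
  if (kernel == "linear") {
    G <- tcrossprod(Xc)
    s <- mean(diag(G))
    if (s <= 0) stop_acf("gpc_fit: degenerate (constant) features")
    K <- G / s
    rbf_gamma <- NA_real_
  } else {
    D2 <- as.matrix(stats::dist(Xc))^2
    med <- median(D2[upper.tri(D2)])
    if (med <= 0) stop_acf("gpc_fit: degenerate features for RBF kernel")
    rbf_gamma <- 1 / (rbf_scale * med)
    K <- exp(-rbf_gamma * D2)
    s <- 1
  }
  if (any(!is.finite(K))) stop_acf("gpc_fit: non-finite kernel")
  K <- K + diag(jitter, nrow(K))
  fit <- .gpc_laplace(K, y)
  if (!fit$converged)
    warning("gpc_fit: Laplace Newton iteration did not converge", call. = FALSE)
  structure(list(kernel = kernel, centre = centre, scale = s,
                 rbf_gamma = rbf_gamma, Xc = Xc, y = y, K = K,
                 grad = fit$grad, sqrtW = fit$sqrtW, L = fit$L,
                 f = fit$f, converged = fit$converged),
            class = "gpc_model")
}

#' Predict class probabilities from a fitted GP classifier
#'
#' @param model a [gpc_fit()] model
#' @param x_new matrix (or vector) of new feature rows
#' @return predictive probability of class +1 for each row
#' @export
gpc_predict <- function(model, x_new) {
  if (is.null(dim(x_new))) x_new <- matrix(x_new, nrow = 1)
  Xn <- sweep(as.matrix(x_new), 2, model$centre)
  if (model$kernel == "linear") {
    kstar <- tcrossprod(Xn, model$Xc) / model$scale
    kss <- rowSums(Xn^2) / model$scale
  } else {
    D2 <- outer(rowSums(Xn^2), rowSums(model$Xc^2), "+") -
      2 * tcrossprod(Xn, model$Xc)
    kstar <- exp(-model$rbf_gamma * pmax(D2, 0))
    kss <- rep(1, nrow(Xn))
  }
  fstar <- as.numeric(kstar %*% model$grad)
  Vm <- forwardsolve(t(model$L), t(kstar) * model$sqrtW)
  vstar <- kss - colSums(Vm^2)
  .gpc_prob(fstar, vstar)
}

# Kernel-space LOSO over a precomputed Gram matrix G = X X' (uncentred):
# per-fold centring of the kernel is done algebraically from G, so label
# permutations re-use the same Gram matrix. Returns per-fold predictive
# probabilities of class +1.
.loso_gpc_gram <- function(G, y, jitter = 1e-8) {
  n <- length(y)
  probs <- numeric(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    ytr <- y[tr]
    if (length(unique(ytr)) < 2)
      stop_acf("loso_gpc: a fold lost one class entirely")
    Gtt <- G[tr, tr]
    rm_ <- rowMeans(Gtt)
    mm <- mean(Gtt)
    Kc <- sweep(sweep(Gtt, 1, rm_), 2, rm_) + mm
    s <- mean(diag(Kc))
    K <- Kc / s + diag(jitter, n - 1)
    fit <- .gpc_laplace(K, ytr)
    # centred cross-kernel of the held-out subject with training rows
    gi <- G[i, tr]
    kstar <- (gi - mean(gi) - rm_ + mm) / s
    kss <- (G[i, i] - 2 * mean(gi) + mm) / s
    fstar <- sum(kstar * fit$grad)
    v <- forwardsolve(t(fit$L), kstar * fit$sqrtW)
    probs[i] <- .gpc_prob(fstar, kss - sum(v^2))
  }
  probs
}

#' Leave-one-subject-out Gaussian-process classification
#'
#' For each subject: train on the remaining subjects (feature centring and
#' kernel scaling recomputed per fold from the training rows only - no
#' leakage from the held-out subject), predict the held-out subject's
#' class probability, threshold at 0.5. The voxel weight map comes from
#' the full-data model (`w = X' alpha` for the linear kernel).
#'
#' @param fm a [extract_features()] feature matrix (n >= 4, both classes)
#' @param jitter kernel jitter
#' @return object of class `classification_result`: `folds` data.frame
#'   (subject, truth, probability, prediction), `accuracy`, `sensitivity`
#'   (class +1), `specificity` (class -1), and `weights` [volume_map()]
#' @export
loso_gpc <- function(fm, jitter = 1e-8) {
  X <- fm$X
  y <- fm$y
  if (nrow(X) < 4) stop_acf("loso_gpc: need at least 4 subjects")
  G <- tcrossprod(X)
  probs <- .loso_gpc_gram(G, y, jitter)
  pred <- ifelse(probs > 0.5, 1, -1)
  correct <- pred == y
  folds <- data.frame(subject = fm$ids, truth = y, probability = probs,
                      prediction = pred, stringsAsFactors = FALSE)
  full <- gpc_fit(X, y, kernel = "linear", jitter = jitter)
  w <- as.numeric(crossprod(full$Xc, full$grad) / full$scale)
  weights <- NULL
  if (!is.null(fm$voxel_index)) {
    arr <- array(NaN, fm$dim)
    arr[fm$voxel_index] <- w
    m <- array(FALSE, fm$dim)
    m[fm$voxel_index] <- TRUE
    weights <- volume_map(arr, fm$affine, m)
  }
  structure(list(folds = folds,
                 accuracy = mean(correct),
                 sensitivity = mean(correct[y == 1]),
                 specificity = mean(correct[y == -1]),
                 weights = weights, weight_vector = w),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> accuracy %.3f (sensitivity %.3f, specificity %.3f) over %d folds\n",
              x$accuracy, x$sensitivity, x$specificity, nrow(x$folds)))
  invisible(x)
}

#' Permutation test of classification accuracy
#'
#' Repeats the full leave-one-subject-out classification under uniformly
#' random label permutations and reports smoothed permutation p-values
#' `p = (#(null >= observed) + 1) / (n_perm + 1)` (never exactly zero) for
#' the overall and the two class accuracies.
#'
#' @param fm a [extract_features()] feature matrix
#' @param n_perm number of permutations (>= 1)
#' @param seed RNG seed for the permutation stream
#' @return object of class `permutation_result`: observed accuracies,
#'   null accuracy vectors, and `p_overall`, `p_sensitivity`,
#'   `p_specificity`
#' @export
permutation_test <- function(fm, n_perm = 2000, seed = 1) {
  if (n_perm < 1) stop_acf("permutation_test: n_perm must be >= 1")
  obs <- loso_gpc(fm)
  G <- tcrossprod(fm$X)
  set.seed(seed)
  null_acc <- matrix(NA_real_, n_perm, 3)
  for (r in seq_len(n_perm)) {
    yp <- sample(fm$y)
    probs <- .loso_gpc_gram(G, yp)
    pred <- ifelse(probs > 0.5, 1, -1)
    ok <- pred == yp
    null_acc[r, ] <- c(mean(ok), mean(ok[yp == 1]), mean(ok[yp == -1]))
  }
  pval <- function(null, observed) (sum(null >= observed) + 1) / (n_perm + 1)
  structure(list(n_perm = n_perm, seed = seed,
                 observed = c(accuracy = obs$accuracy,
                              sensitivity = obs$sensitivity,
                              specificity = obs$specificity),
                 null_accuracy = null_acc[, 1],
                 null_sensitivity = null_acc[, 2],
                 null_specificity = null_acc[, 3],
                 p_overall = pval(null_acc[, 1], obs$accuracy),
                 p_sensitivity = pval(null_acc[, 2], obs$sensitivity),
                 p_specificity = pval(null_acc[, 3], obs$specificity)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %d permutations: p_overall = %.4g (observed accuracy %.3f)\n",
              x$n_perm, x$p_overall, x$observed["accuracy"]))
  invisible(x)
}
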