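# Shared fixtures, built in code. The tiny phantom keeps module tests in
# the seconds range; cohort-scale simulations live in test-acceptance.R.

# Small grid, few subjects, and a focal contrast strong enough to be
# detectable at this reduced scale (the default-scale contrast is tested
# at full size in test-acceptance.R).
tiny_spec <- function(n_per_group = 6, n_volumes = 80, master_seed = 11) {
  phantom_spec(grid_shape = c(14, 14, 10), n_per_group = n_per_group,
               n_volumes = n_volumes, master_seed = master_seed,
               focal_b = list(control = c(0.71, 0.04),
                              patient = c(0.45, 0.03)))
}

# One small bold_image with a known affine, deterministic content.
tiny_bold <- function(dm = c(5, 5, 4), nt = 40, tr = 2, seed = 99) {
  set.seed(seed)
  aff <- rbind(c(3, 0, 0, -21), c(0, 3, 0, -21), c(0, 0, 4, -14),
               c(0, 0, 0, 1))
  bold_image(array(rnorm(prod(dm) * nt), dim = c(dm, nt)), aff, tr)
}

# A volume_map on a small grid with values drawn by `fn(n)`.
tiny_map <- function(fn = rnorm, dm = c(8, 8, 6), seed = NULL,
                     mask = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(mask)) mask <- array(TRUE, dm)
  vals <- array(NaN, dm)
  vals[mask] <- fn(sum(mask))
  volume_map(vals, diag(4), mask)
}

# Cache expensive fixtures across test files within one run.
.fixture_env <- new.env()

cached_fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# Brute-force graph-metric oracle: Floyd-Warshall distances plus explicit
# shortest-path enumeration for betweenness. Independent of igraph and of
# the package implementation.
oracle_graph_metrics <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A > 0] <- 1
  NP <- matrix(0, n, n)          # number of shortest paths
  NP[A > 0] <- 1
  diag(NP) <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || i == k || j == k) next
    alt <- D[i, k] + D[k, j]
    if (alt < D[i, j]) {
      D[i, j] <- alt
      NP[i, j] <- NP[i, k] * NP[k, j]
    } else if (is.finite(alt) && alt == D[i, j]) {
      NP[i, j] <- NP[i, j] + NP[i, k] * NP[k, j]
    }
  }
  off <- upper.tri(D)
  inv <- ifelse(is.finite(D[off]), 1 / D[off], 0)
  global_eff <- mean(inv)
  path_length <- if (any(is.finite(D[off]))) mean(D[off][is.finite(D[off])]) else NA_real_
  # betweenness by path counting: fraction of s-t shortest paths through v
  betw <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s >= t || s == v || t == v) next
      if (!is.finite(D[s, t])) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t]) {
        tot <- tot + (NP[s, v] * NP[v, t]) / NP[s, t]
      }
    }
    betw[v] <- tot / ((n - 1) * (n - 2) / 2)
  }
  clust <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    sub <- A[nb, nb, drop = FALSE]
    sum(sub) / (length(nb) * (length(nb) - 1))
  }, numeric(1))
  local_eff <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_graph_metrics(A[nb, nb, drop = FALSE])$global_efficiency
  }, numeric(1))
  list(global_efficiency = global_eff, local_efficiency = mean(local_eff),
       betweenness = mean(betw), path_length = path_length,
       clustering = mean(clust), degree = mean(rowSums(A)))
}
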