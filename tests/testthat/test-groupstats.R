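# Voxel-wise group inference: t maps, cluster extraction, Lilliefors
# screening, leave-one-out stability, single-subject deviation maps.

test_that("two-sample t map matches hand computation and the direct formula", {
  dm <- c(4, 4, 3)
  # one voxel carries the worked example g1 = {0,1,2}, g2 = {3,4,5}
  mk <- function(v) {
    vals <- array(0, dm)
    vals[2, 2, 2] <- v
    vals[1, 1, 1] <- rnorm(1)
    volume_map(vals, diag(4))
  }
  set.seed(20)
  g1 <- lapply(0:2, mk)
  g2 <- lapply(3:5, mk)
  stat <- two_sample_tmap(g1, g2, "two_sided")
  expect_equal(stat$df, 4L)
  expect_equal(stat$t[2, 2, 2], -3.674, tolerance = 1e-3)  # pooled var 1, se 0.8165

  # df notation: 19 vs 19 subjects gives df = 36
  maps1 <- lapply(1:19, function(i) tiny_map(seed = 100 + i))
  maps2 <- lapply(1:19, function(i) tiny_map(seed = 200 + i))
  stat36 <- two_sample_tmap(maps1, maps2)
  expect_equal(stat36$df, 36L)

  # direct-formula oracle on random inputs
  X1 <- sapply(maps1, function(m) m$values[m$mask])
  X2 <- sapply(maps2, function(m) m$values[m$mask])
  i <- 37
  m1 <- mean(X1[i, ]); m2 <- mean(X2[i, ])
  sp <- sqrt((sum((X1[i, ] - m1)^2) + sum((X2[i, ] - m2)^2)) / 36)
  t_oracle <- (m1 - m2) / (sp * sqrt(2 / 19))
  expect_equal(stat36$t[stat36$mask][i], t_oracle, tolerance = 1e-10)
  expect_equal(stat36$p[stat36$mask][i],
               2 * pt(abs(t_oracle), 36, lower.tail = FALSE),
               tolerance = 1e-12)

  # identical groups: t = 0, p = 1
  same <- lapply(1:3, function(i) tiny_map(seed = 300 + i))
  stat0 <- two_sample_tmap(same, same)
  expect_true(all(abs(stat0$t[stat0$mask]) < 1e-12))
  expect_true(all(stat0$p[stat0$mask] > 1 - 1e-12))
})

test_that("cluster extraction honours extent, connectivity and ordering", {
  dm <- c(12, 12, 8)
  tarr <- array(0, dm)
  mask <- array(TRUE, dm)
  tarr[2:6, 2:7, 2:2] <- 5        # 30-voxel slab
  tarr[9:10, 9:10, 5:6] <- -6     # 8-voxel blob (below k_min)
  df <- 36
  parr <- 2 * pt(abs(tarr), df, lower.tail = FALSE)
  stat <- structure(list(t = tarr, p = parr, df = df,
                         direction = "two_sided", mask = mask,
                         affine = diag(4)),
                    class = "stat_map")
  cs <- cluster_threshold(stat, k_min = 27)
  expect_equal(nrow(cs$clusters), 1L)
  expect_equal(cs$clusters$size, 30L)
  cs2 <- cluster_threshold(stat, k_min = 8)
  expect_equal(nrow(cs2$clusters), 2L)
  expect_equal(cs2$clusters$label, 1:2)            # sorted by |peak t|
  expect_equal(cs2$clusters$peak_t[1], -6)
  # total labelled voxels = suprathreshold count
  expect_equal(sum(cs2$label_volume > 0), sum(parr < 0.005))

  # 20-voxel blob dies at k_min = 27
  tarr2 <- array(0, dm)
  tarr2[2:5, 2:6, 2] <- 5
  stat$t <- tarr2
  stat$p <- 2 * pt(abs(tarr2), df, lower.tail = FALSE)
  expect_equal(nrow(cluster_threshold(stat, k_min = 27)$clusters), 0L)
})

test_that("connectivity schemes split corner-touching blobs as igraph does", {
  dm <- c(6, 6, 6)
  m <- array(FALSE, dm)
  m[2:3, 2:3, 2:3] <- TRUE               # cube A
  m[4:5, 4:5, 4:4] <- TRUE               # plate B touching A at a corner
  for (conn in c(6, 18, 26)) {
    lab <- label_components(m, conn)
    # igraph flood-fill oracle
    idx <- which(m)
    coords <- which(m, arr.ind = TRUE)
    off <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
    off <- off[rowSums(abs(off)) > 0 &
                 rowSums(abs(off)) <= c("6" = 1, "18" = 2, "26" = 3)[as.character(conn)], ]
    edges <- c()
    key <- function(ijk) paste(ijk[, 1], ijk[, 2], ijk[, 3])
    pos <- setNames(seq_along(idx), key(coords))
    for (v in seq_along(idx)) {
      nb <- sweep(as.matrix(off), 2, -as.numeric(coords[v, ]))
      nb <- nb[nb[, 1] >= 1 & nb[, 1] <= 6 & nb[, 2] >= 1 & nb[, 2] <= 6 &
                 nb[, 3] >= 1 & nb[, 3] <= 6, , drop = FALSE]
      hit <- pos[key(nb)]
      hit <- hit[!is.na(hit)]
      edges <- c(edges, rbind(v, hit))
    }
    g <- igraph::make_empty_graph(length(idx), directed = FALSE)
    if (length(edges)) g <- igraph::add_edges(g, edges)
    comp <- igraph::components(g)$no
    expect_equal(max(lab), comp)
  }
  # corner contact: joined under 26-connectivity, split under 18
  expect_equal(max(label_components(m, 26)), 1L)
  expect_equal(max(label_components(m, 18)), 2L)
})

test_that("Lilliefors screening holds its size and flags skewed data", {
  n <- 19
  nv <- 1500
  mk_group <- function(fn, seed) {
    set.seed(seed)
    vals <- matrix(fn(n * nv), n, nv)
    lapply(1:n, function(i) {
      arr <- array(vals[i, ], dim = c(15, 10, 10))
      volume_map(arr, diag(4))
    })
  }
  normal <- mk_group(rnorm, 30)
  res <- lilliefors_map(normal, nsim = 5000)
  expect_gt(res$pass_fraction, 0.93)
  expect_lt(res$pass_fraction, 0.97)

  skewed <- mk_group(rexp, 31)
  res_skew <- lilliefors_map(skewed, nsim = 5000)
  expect_lt(res_skew$pass_fraction, res$pass_fraction)
  expect_lt(res_skew$pass_fraction, 0.9)

  # the statistic itself agrees with the nortest implementation
  set.seed(32)
  x <- rnorm(19)
  expect_equal(lilliefors_stat(x),
               unname(nortest::lillie.test(x)$statistic),
               tolerance = 1e-10)

  expect_error(lilliefors_map(normal[1:3]), "at least 5")
})

test_that("leave-one-subject-out stability is 1 for strong effects, 0 for null", {
  dm <- c(10, 10, 6)
  blob <- array(FALSE, dm)
  blob[3:8, 3:8, 2:4] <- TRUE
  mk <- function(shift, seed) {
    set.seed(seed)
    vals <- array(rnorm(prod(dm), 1, 0.05), dm)
    vals[blob] <- vals[blob] + shift
    volume_map(vals, diag(4))
  }
  g1 <- lapply(1:8, function(i) mk(-0.5, 400 + i))  # strong focal decrease
  g2 <- lapply(1:8, function(i) mk(0, 500 + i))
  target <- voxel_to_world(diag(4), c(5L, 5L, 3L))
  expect_equal(loso_stability(g1, g2, target), 1.0)

  g_null <- lapply(1:8, function(i) mk(0, 600 + i))
  expect_lt(loso_stability(g_null, g2, target), 0.1)

  expect_error(loso_stability(g1[1], g2[1], target), "at least 2")
  expect_error(loso_stability(g1, g2, c(500, 500, 500)), "outside")
})

test_that("subject deviation maps flag planted drops and respect the threshold", {
  dm <- c(10, 10, 6)
  controls <- lapply(1:8, function(i) tiny_map(dm = dm, seed = 700 + i))
  st <- acfmap:::.stack_maps(controls)
  mu <- colMeans(st$X)
  sdv <- apply(st$X, 2, sd)
  # patient identical to the control mean: empty
  mean_map <- volume_map(array(mu, dm), diag(4))
  expect_equal(nrow(subject_deviation_map(mean_map, controls)$clusters), 0L)

  # planted 3-SD drop in a 10-voxel ball
  ball <- array(FALSE, dm)
  ball[4:5, 4:5, 2:3] <- TRUE           # 8 voxels
  ball[6, 4, 2:3] <- TRUE               # + 2 = 10 voxels
  vals <- array(mu, dm)
  vals[ball] <- vals[ball] - 3 * array(sdv, dm)[ball]
  pat <- volume_map(vals, diag(4))
  dev <- subject_deviation_map(pat, controls, z_thresh = 2, k_min = 7)
  expect_equal(nrow(dev$clusters), 1L)
  expect_equal(dev$clusters$size, 10L)
  # raising the threshold can only shrink the finding (monotone)
  expect_equal(nrow(subject_deviation_map(pat, controls, z_thresh = 4,
                                          k_min = 7)$clusters), 0L)

  expect_error(subject_deviation_map(pat, controls[1:3]), "at least 5")
})
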