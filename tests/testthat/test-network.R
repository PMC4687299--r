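# Correlation networks, cost thresholding and graph metrics.

test_that("node networks have the right shape and detect shared series", {
  set.seed(60)
  dm <- c(8, 8, 4)
  nt <- 200
  arr <- array(rnorm(prod(dm) * nt), c(dm, nt))
  shared <- rnorm(nt)
  arr[1, 1, 1, ] <- shared
  arr[8, 8, 4, ] <- shared
  bold <- bold_image(arr, diag(4), 2)
  mk <- function(i, j, k) {
    m <- array(FALSE, dm); m[i, j, k] <- TRUE; m
  }
  nodes <- list(mk(1, 1, 1), mk(8, 8, 4), mk(4, 4, 2), mk(5, 5, 3))
  net <- build_network(bold, nodes, condition = FALSE)
  expect_equal(dim(net$C), c(4L, 4L))
  expect_equal(diag(net$C), rep(1, 4))
  expect_equal(net$C, t(net$C), tolerance = 1e-12)
  expect_equal(net$C[1, 2], 1, tolerance = 1e-12)   # identical series
  expect_lt(abs(net$C[3, 4]), 0.3)                  # independent nodes

  # constant node series is an error naming the node
  arr2 <- arr
  arr2[4, 4, 2, ] <- 1
  expect_error(build_network(bold_image(arr2, diag(4), 2), nodes,
                             condition = FALSE), "node 3")
  expect_error(build_network(bold, nodes[1:2], condition = FALSE),
               "at least 3")
})

test_that("cost thresholding fixes the edge count with deterministic ties", {
  set.seed(61)
  n <- 16
  M <- matrix(rnorm(n * n), n, n)
  C <- cov2cor(crossprod(M))
  net <- structure(list(C = C, n_nodes = n, subject_id = "x"),
                   class = "corr_network")
  g <- threshold_by_cost(net, 0.2)
  expect_equal(g$edge_count, 24L)                  # round(0.2 * 120)
  expect_equal(sum(g$adjacency) / 2, 24)
  expect_equal(g$adjacency, t(g$adjacency))
  expect_true(all(diag(g$adjacency) == 0))

  # kept edges are exactly the 24 largest correlations
  ut <- C[upper.tri(C)]
  kept <- C[upper.tri(C) & (g$adjacency == 1)]
  expect_equal(sort(kept), sort(ut)[(120 - 23):120])

  # all-equal correlations: deterministic, reproducible edge set
  Ceq <- matrix(0.5, 6, 6); diag(Ceq) <- 1
  g1 <- threshold_by_cost(Ceq, 0.3)
  g2 <- threshold_by_cost(Ceq, 0.3)
  expect_equal(g1$adjacency, g2$adjacency)
  expect_equal(g1$edge_count, round(0.3 * 15))

  # cost = 1 gives the complete graph; cost too small errors
  expect_equal(sum(threshold_by_cost(Ceq, 1)$adjacency), 6 * 5)
  expect_error(threshold_by_cost(Ceq, 0.01), "no edges")
})

test_that("metrics match closed forms on canonical graphs", {
  K5 <- matrix(1, 5, 5) - diag(5)
  m <- graph_metrics(K5)
  expect_equal(m$global_efficiency, 1)
  expect_equal(m$clustering, 1)
  expect_equal(m$path_length, 1)
  expect_equal(m$degree, 4)

  # path graph on 3 nodes: ge = mean(1/1, 1/2, 1/1) = 5/6; centre
  # betweenness = 1 after (n-1)(n-2)/2 normalisation
  P3 <- matrix(0, 3, 3)
  P3[1, 2] <- P3[2, 1] <- P3[2, 3] <- P3[3, 2] <- 1
  mp <- graph_metrics(P3)
  expect_equal(mp$global_efficiency, 5 / 6)
  expect_equal(igraph::betweenness(
    igraph::graph_from_adjacency_matrix(P3, mode = "undirected"),
    normalized = TRUE)[2], c("2" = 1), ignore_attr = TRUE)

  # star graph S5 against the brute-force oracle, exactly
  S5 <- matrix(0, 5, 5)
  S5[1, 2:5] <- S5[2:5, 1] <- 1
  ms <- graph_metrics(S5)
  os <- oracle_graph_metrics(S5)
  for (f in names(os)) expect_equal(ms[[f]], os[[f]], tolerance = 1e-12)
})

test_that("metrics agree exactly with the brute-force oracle on random small graphs", {
  set.seed(62)
  for (rep in 1:40) {
    n <- sample(3:6, 1)
    A <- matrix(0L, n, n)
    up <- which(upper.tri(A))
    on <- up[runif(length(up)) < 0.5]
    A[on] <- 1L
    A <- A + t(A)
    m <- graph_metrics(A)
    o <- oracle_graph_metrics(A)
    for (f in names(o)) {
      if (is.na(o[[f]])) expect_true(is.na(m[[f]]))
      else expect_equal(m[[f]], o[[f]], tolerance = 1e-12)
    }
  }
})

test_that("global efficiency is monotone in cost and under edge additions", {
  set.seed(63)
  M <- matrix(rnorm(256), 16, 16)
  C <- cov2cor(crossprod(M))
  ge <- vapply(c(0.1, 0.15, 0.2, 0.25, 0.3), function(cst)
    graph_metrics(threshold_by_cost(C, cst))$global_efficiency, numeric(1))
  expect_true(all(diff(ge) >= 0))

  # adding one edge never decreases global efficiency
  A <- threshold_by_cost(C, 0.15)$adjacency
  off <- which(A == 0 & upper.tri(A))
  pick <- off[5]
  A2 <- A
  A2[pick] <- 1L
  A2[cbind(col(A)[pick], row(A)[pick])] <- 1L
  expect_gte(graph_metrics(A2)$global_efficiency,
             graph_metrics(A)$global_efficiency)
})

test_that("group comparison flags planted efficiency deficits across costs", {
  set.seed(64)
  # 16-node block networks; the cost threshold fixes the edge count, so
  # the groups differ only in where the supra-threshold long-range
  # correlations sit: spread across all block pairs (efficient,
  # control-like) or concentrated between two blocks (locally dense /
  # long-range sparse, patient-like), which lengthens paths to the
  # remaining blocks.
  blocks <- list(1:4, 5:8, 9:12, 13:16)
  sim_rows <- function(spread, n_sub, seed_off) {
    do.call(rbind, lapply(1:n_sub, function(s) {
      set.seed(seed_off + s)
      base <- matrix(0, 16, 16)
      for (blk in blocks) base[blk, blk] <- 0.7
      if (spread) {
        for (i in 1:3) for (j in (i + 1):4)
          base[blocks[[i]], blocks[[j]]] <- base[blocks[[j]], blocks[[i]]] <- 0.35
      } else {
        base[blocks[[1]], blocks[[2]]] <- base[blocks[[2]], blocks[[1]]] <- 0.45
      }
      noise <- matrix(rnorm(256, 0, 0.1), 16, 16)
      C <- base + (noise + t(noise)) / 2
      diag(C) <- 1
      C <- pmin(pmax(C, -0.99), 0.99)
      net <- structure(list(C = C, n_nodes = 16,
                            subject_id = sprintf("s%d", s)),
                       class = "corr_network")
      metrics_across_costs(net)
    }))
  }
  rows_p <- sim_rows(FALSE, 14, 100)    # concentrated long-range coupling
  rows_c <- sim_rows(TRUE, 14, 200)
  cmp <- compare_groups_metric(rows_p, rows_c, "global_efficiency")
  expect_equal(cmp$cost, c(0.10, 0.15, 0.20, 0.25, 0.30))
  expect_gte(sum(cmp$p[cmp$cost >= 0.2] < 0.05), 2)

  # identical groups: no significance expected at alpha well below 0.5
  rows_c2 <- sim_rows(TRUE, 14, 300)
  cmp0 <- compare_groups_metric(rows_c2, rows_c, "global_efficiency")
  expect_true(all(cmp0$p > 0.001))

  expect_error(compare_groups_metric(rows_p, rows_c, "global_efficiency",
                                     costs = c(0.2, 0.4)), "missing")
  expect_error(compare_groups_metric(rows_p, rows_c, "no_such_metric"),
               "unknown metric")
})
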