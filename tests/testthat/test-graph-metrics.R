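# Analytic fixtures, tie-break determinism, null-model invariants and
# AUC behavior for the sparsity-grid graph metrics.

star4 <- local({
  m <- matrix(0, 5, 5)
  m[1, 2:5] <- m[2:5, 1] <- 1
  m
})
path3 <- local({
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- m[2, 3] <- m[3, 2] <- 1
  m
})
k5 <- local({
  m <- matrix(1, 5, 5); diag(m) <- 0; m
})
dyads <- local({
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- m[3, 4] <- m[4, 3] <- 1
  m
})

test_that("sparsity grid matches the 25-point analysis range", {
  g <- sparsity_grid()
  expect_length(g, 25)
  expect_equal(min(g), 0.10)
  expect_equal(max(g), 0.34)
  expect_error(sparsity_grid(0.1, 0.34, 0.07), "divide")
  expect_error(sparsity_grid(0.5, 0.4), "s_min")
})

test_that("thresholding keeps exactly round(S*N*(N-1)/2) strongest edges", {
  set.seed(11)
  n <- 90
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- runif(n * (n - 1) / 2)
  w <- w + t(w)
  a <- threshold_by_sparsity(w, 0.10)
  expect_equal(a$n_edges, 400)  # round(0.10 * 4005)
  expect_equal(sum(a$matrix[upper.tri(a$matrix)]), 400)
  expect_true(all(a$matrix %in% c(0, 1)))
  # the kept edges are the 400 largest weights
  kept <- w[a$matrix > 0]
  expect_true(min(kept) >= max(w[a$matrix == 0 & upper.tri(w)]))
  # weighted mode at the matrix's own density is the identity
  w_sparse <- w * (w > 0.4)   # density ~0.6
  dens <- sum(w_sparse[upper.tri(w_sparse)] > 0) / (n * (n - 1) / 2)
  aw <- threshold_by_sparsity(w_sparse, dens, mode = "weighted")
  expect_equal(aw$matrix, w_sparse, ignore_attr = TRUE)
  # insufficient edges -> informative error
  expect_error(threshold_by_sparsity(dyads, 0.9), "density")
})

test_that("tied weights are cut deterministically and reproducibly", {
  m <- matrix(1, 5, 5); diag(m) <- 0
  a1 <- threshold_by_sparsity(m, 0.5)
  a2 <- threshold_by_sparsity(m, 0.5)
  expect_equal(sum(a1$matrix) / 2, 5)  # round(0.5 * 10)
  expect_identical(a1$matrix, a2$matrix)
  # ascending (i, j) order among ties: first rows of the upper triangle win
  expect_equal(a1$matrix[1, 2:5], c(1, 1, 1, 1))
})

test_that("clustering coefficient matches analytic and enumerated values", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(clustering_coefficient(tri)$Cp, 1)
  expect_equal(clustering_coefficient(star4)$Cp, 0)
  g <- random_binary_graph(12, 0.4, seed = 21)
  expect_equal(clustering_coefficient(g)$Ci, oracle_clustering(g)$Ci, tolerance = 1e-12)
})

test_that("shortest paths, Lp and efficiencies match hand enumeration", {
  expect_equal(shortest_paths_matrix(path3)[1, 3], 2)
  expect_equal(characteristic_path_length(k5, warn_disconnected = FALSE)$Lp, 1)
  expect_equal(global_efficiency(k5), 1)
  expect_equal(characteristic_path_length(path3, warn_disconnected = FALSE)$Lp, 4 / 3)
  expect_equal(global_efficiency(path3), 5 / 6)
  # two disconnected dyads: 4 reachable ordered pairs at distance 1 out of
  # 12, unreachable pairs count 0, so Eglob = 4/12
  expect_equal(global_efficiency(dyads), 1 / 3)
  expect_equal(global_efficiency(dyads), oracle_efficiency_global(dyads))
  expect_warning(characteristic_path_length(dyads), "disconnected")
  d <- shortest_paths_matrix(dyads)
  expect_true(all(is.infinite(d[1:2, 3:4])))
  # weighted triangle: direct 1/0.2 = 5 vs detour 1/0.5 + 1/0.5 = 4
  wt <- matrix(0, 3, 3)
  wt[1, 2] <- wt[2, 1] <- 0.5; wt[2, 3] <- wt[3, 2] <- 0.5
  wt[1, 3] <- wt[3, 1] <- 0.2
  expect_equal(shortest_paths_matrix(wt)[1, 3], 4)
})

test_that("local efficiency matches analytic and brute-force values", {
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  expect_equal(local_efficiency(k4)$Eloc, 1)
  expect_equal(local_efficiency(star4)$Eloc, 0)
  g <- random_binary_graph(10, 0.5, seed = 33)
  expect_equal(local_efficiency(g)$Ei, oracle_local_efficiency(g)$Ei, tolerance = 1e-12)
})

test_that("nodal metrics match the analytic star and brute-force enumeration", {
  nm <- nodal_metrics(star4)
  expect_equal(unname(nm$degree[1]), 4)
  expect_equal(unname(nm$efficiency[1]), 1)
  expect_equal(unname(nm$betweenness[1]), 6)       # C(4,2) leaf pairs
  expect_equal(unname(nm$efficiency[2]), (1 + 3 * 0.5) / 4)  # 0.625
  expect_equal(unname(nm$betweenness[2]), 0)
  g <- random_binary_graph(12, 0.4, seed = 55)
  expect_equal(nodal_metrics(g)$betweenness, oracle_betweenness_binary(g),
               tolerance = 1e-9)
})

test_that("weighted nodal metrics match exhaustive path enumeration", {
  for (seed in 1:5) {
    g <- random_weighted_graph(7, 0.5, seed = seed)
    expect_equal(nodal_metrics(g)$betweenness, oracle_betweenness_weighted(g),
                 tolerance = 1e-9, label = sprintf("weighted betweenness seed %d", seed))
    expect_equal(nodal_metrics(g)$efficiency, oracle_nodal_efficiency(g, weighted = TRUE),
                 tolerance = 1e-9)
    expect_equal(unname(nodal_metrics(g)$degree), unname(rowSums(g)))
  }
})

test_that("betweenness total equals the pairwise mean intermediate count", {
  # sum_i B_i = sum over reachable unordered pairs of the mean number of
  # intermediate vertices on their shortest paths
  for (seed in 1:10) {
    g <- random_binary_graph(9, 0.35, seed = 100 + seed)
    d <- oracle_distances(g)
    fin <- d[upper.tri(d)]
    expected <- sum(fin[is.finite(fin)] - 1)  # hop count d has d-1 intermediates
    expect_equal(sum(nodal_metrics(g)$betweenness), expected, tolerance = 1e-9)
  }
})

test_that("degree-preserving rewiring preserves degrees and destroys lattice triangles", {
  ring <- matrix(0, 24, 24)
  for (i in 1:24) for (off in 1:2) {
    j <- ((i + off - 1) %% 24) + 1
    ring[i, j] <- ring[j, i] <- 1
  }
  r <- random_rewire(ring, seed = 5)
  expect_equal(rowSums(r$matrix), rowSums(ring), ignore_attr = TRUE)
  expect_equal(sum(r$matrix), sum(ring))
  expect_true(all(diag(r$matrix) == 0))
  expect_lt(clustering_coefficient(r)$Cp, clustering_coefficient(ring)$Cp)
  # zero swaps: identity
  expect_equal(random_rewire(ring, n_swaps = 0)$matrix, ring)
  # star admits no swap: returned unchanged with warning
  expect_warning(rs <- random_rewire(star4, seed = 2), "unchanged")
  expect_equal(rs$matrix, star4, ignore_attr = TRUE)
  # weighted rewiring preserves the weight multiset and the degree sequence
  gw <- random_weighted_graph(12, 0.5, seed = 9)
  rw <- random_rewire(gw, seed = 7)
  expect_equal(sort(rw$matrix[upper.tri(rw$matrix) & rw$matrix > 0]),
               sort(gw[upper.tri(gw) & gw > 0]))
  expect_equal(rowSums(rw$matrix > 0), rowSums(gw > 0), ignore_attr = TRUE)
})

test_that("small-world normalization is self-consistent and sigma = gamma/lambda", {
  set.seed(71)
  g <- igraph::sample_smallworld(1, 90, 5, 0.1)
  m <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  sw <- small_world(m, n_rand = 30, seed = 3)
  expect_equal(sw$sigma, sw$gamma / sw$lambda)
  expect_gt(sw$sigma, 1)  # canonical Watts-Strogatz small world
  expect_gt(sw$gamma, 1)
  # a rewired random graph is its own null: gamma ~ 1, lambda ~ 1
  er <- random_binary_graph(60, 0.2, seed = 8)
  er <- random_rewire(er, seed = 12)
  swr <- small_world(er, n_rand = 30, seed = 4)
  expect_equal(swr$gamma, 1, tolerance = 0.1)
  expect_equal(swr$lambda, 1, tolerance = 0.05)
  # determinism under the same master seed
  sw2 <- small_world(m, n_rand = 30, seed = 3)
  expect_identical(sw, sw2)
})

test_that("global metrics are node-permutation invariant, nodal metrics equivariant", {
  g <- random_binary_graph(12, 0.4, seed = 77)
  perm <- sample(12)
  gp <- g[perm, perm]
  expect_equal(clustering_coefficient(gp)$Cp, clustering_coefficient(g)$Cp)
  expect_equal(global_efficiency(gp), global_efficiency(g))
  nm <- nodal_metrics(g)
  nmp <- nodal_metrics(gp)
  expect_equal(unname(nmp$betweenness), unname(nm$betweenness[perm]), tolerance = 1e-9)
  expect_equal(unname(nmp$efficiency), unname(nm$efficiency[perm]), tolerance = 1e-9)
})

test_that("binary global efficiency is non-decreasing in sparsity", {
  set.seed(91)
  n <- 40
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- runif(n * (n - 1) / 2)
  w <- w + t(w)
  eg <- sapply(seq(0.1, 0.5, by = 0.05), function(S)
    global_efficiency(threshold_by_sparsity(w, S)))
  expect_true(all(diff(eg) >= 0))
})

test_that("AUC follows the trapezoid rule on the sparsity grid", {
  s <- sparsity_grid()
  expect_equal(auc_trapezoid(s, rep(3, 25)), 0.24 * 3)
  lin <- (s - 0.10) / 0.24
  expect_equal(auc_trapezoid(s, lin), 0.12)
  expect_equal(unname(auc_trapezoid(s, cbind(rep(3, 25), lin))), c(0.72, 0.12))
})

test_that("metric curves carry 25 values per metric and consistent AUCs", {
  set.seed(5)
  n <- 40
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- runif(n * (n - 1) / 2)
  w <- w + t(w)
  mc <- metric_curves(w, n_rand = 5, seed = 2)
  expect_equal(nrow(mc$global), 25)
  expect_equal(dim(mc$nodal$degree), c(25, n))
  expect_equal(mc$auc$global[["Cp"]], auc_trapezoid(mc$global$S, mc$global$Cp))
  expect_equal(unname(mc$auc$nodal$degree),
               unname(auc_trapezoid(mc$global$S, mc$nodal$degree)))
  expect_equal(mc$global$sigma, mc$global$gamma / mc$global$lambda)
  # nodal_only skips the global-only quantities but keeps nodal AUCs identical
  mc2 <- metric_curves(w, n_rand = 0, nodal_only = TRUE)
  expect_true(all(is.na(mc2$global$Cp)))
  expect_equal(mc2$auc$nodal$betweenness, mc$auc$nodal$betweenness)
})
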