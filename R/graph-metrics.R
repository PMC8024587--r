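# Sparsity thresholding, global and nodal graph metrics, degree-preserving
# null normalization, and AUC summaries over the sparsity grid.
#
# Conventions (binary default, weighted mode available throughout):
#   * distances use hop counts (binary) or edge lengths 1/w (weighted);
#   * unreachable pairs contribute 0 to efficiencies and are dropped from Lp;
#   * nodes with degree < 2 contribute 0 to clustering and local efficiency;
#   * betweenness is the unnormalized Freeman count over unordered pairs.

#' Sparsity grid for repeated thresholding
#'
#' The connectivity matrix is thresholded repeatedly over a range of
#' connection sparsities (fraction of realized edges among all possible node
#' pairs) so that group comparisons do not hinge on a single arbitrary
#' threshold. The default grid spans 0.10 to 0.34 in steps of 0.01
#' (25 points).
#'
#' @param s_min,s_max Range of sparsity values, `0 < s_min < s_max < 1`.
#' @param step Grid step; must divide the range.
#' @return Numeric vector of sparsity values with class `wm_sparsity_grid`.
#' @export
sparsity_grid <- function(s_min = 0.10, s_max = 0.34, step = 0.01) {
  if (!(is_scalar_number(s_min) && is_scalar_number(s_max) && is_scalar_number(step))) {
    stopf("s_min, s_max and step must be finite scalars")
  }
  if (!(s_min > 0 && s_min < s_max && s_max < 1)) {
    stopf("require 0 < s_min < s_max < 1")
  }
  n_steps <- (s_max - s_min) / step
  if (abs(n_steps - round(n_steps)) > 1e-8) {
    stopf("step %g does not divide the range [%g, %g]", step, s_min, s_max)
  }
  grid <- s_min + step * seq(0L, round(n_steps))
  structure(grid, class = "wm_sparsity_grid")
}

# Number of edges a sparsity S implies on n nodes.
edges_at_sparsity <- function(S, n) as.integer(round(S * n * (n - 1) / 2))

#' Threshold a connectivity matrix at a fixed sparsity
#'
#' Keeps exactly the `round(S * N * (N - 1) / 2)` largest-weight edges,
#' equating edge counts across subjects. Ties at the cut are broken by
#' descending weight then ascending `(i, j)` lexicographic order, so
#' thresholding is deterministic.
#'
#' @param w Symmetric nonnegative connectivity matrix (or
#'   [connectivity_matrix()] object) with zero diagonal.
#' @param S Target sparsity in (0, 1).
#' @param mode `"binary"` sets kept entries to 1 (the default analysis mode);
#'   `"weighted"` retains the original weights.
#' @return A `wm_adjacency` object: list with elements `matrix`, `mode`,
#'   `sparsity` (achieved value) and `n_edges`.
#' @export
threshold_by_sparsity <- function(w, S, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  w <- weights_of(w)
  check_symmetric_matrix(w, what = "connectivity matrix")
  n <- nrow(w)
  if (!is_scalar_number(S) || S <= 0 || S >= 1) stopf("S must be in (0, 1)")
  k <- edges_at_sparsity(S, n)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  vals <- w[ut]
  nz <- vals > 0
  if (sum(nz) < k) {
    stopf("cannot threshold at sparsity %.3f: need %d edges but only %d nonzero (density %.3f)",
          S, k, sum(nz), sum(nz) / nrow(ut))
  }
  ord <- order(-vals, ut[, 1L], ut[, 2L])
  keep <- ord[seq_len(k)]
  a <- matrix(0, n, n, dimnames = dimnames(w))
  sel <- ut[keep, , drop = FALSE]
  a[sel] <- if (mode == "binary") 1 else vals[keep]
  a[sel[, c(2L, 1L), drop = FALSE]] <- a[sel]
  structure(
    list(matrix = a, mode = mode, sparsity = k / (n * (n - 1) / 2), n_edges = k),
    class = "wm_adjacency"
  )
}

# Coerce metric input to a wm_adjacency, inferring mode for bare matrices.
as_adjacency <- function(a, mode = NULL) {
  if (inherits(a, "wm_adjacency")) return(a)
  m <- weights_of(a)
  check_symmetric_matrix(m, what = "adjacency matrix")
  diag(m) <- 0
  if (is.null(mode)) {
    mode <- if (all(m %in% c(0, 1))) "binary" else "weighted"
  }
  k <- sum(m[upper.tri(m)] > 0)
  structure(
    list(matrix = m, mode = mode, sparsity = k / (nrow(m) * (nrow(m) - 1) / 2),
         n_edges = as.integer(k)),
    class = "wm_adjacency"
  )
}

# igraph view of an adjacency; weighted graphs carry a length attribute 1/w
# so shortest paths minimize summed inverse weight.
as_igraph <- function(a) {
  a <- as_adjacency(a)
  if (a$mode == "binary") {
    igraph::graph_from_adjacency_matrix(a$matrix, mode = "undirected", diag = FALSE)
  } else {
    g <- igraph::graph_from_adjacency_matrix(a$matrix, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    igraph::E(g)$length <- 1 / igraph::E(g)$weight
    g
  }
}

#' Clustering coefficient
#'
#' Watts-Strogatz clustering: for each node, the fraction of realized links
#' among its neighbors, `C_i = 2 t_i / (k_i (k_i - 1))`; nodes with fewer
#' than two neighbors contribute 0. The network-level `Cp` is the unweighted
#' mean over all nodes. In weighted mode the Onnela geometric-mean triangle
#' intensity is used, with weights scaled by the maximum weight.
#'
#' @param a Adjacency from [threshold_by_sparsity()], or a bare symmetric
#'   matrix.
#' @return List with `Cp` (scalar mean) and `Ci` (per-node vector).
#' @export
clustering_coefficient <- function(a) {
  a <- as_adjacency(a)
  m <- a$matrix
  bin <- (m > 0) * 1
  k <- rowSums(bin)
  if (a$mode == "binary") {
    t_i <- rowSums((bin %*% bin) * bin) / 2
  } else {
    wmax <- max(m)
    wn <- if (wmax > 0) (m / wmax)^(1 / 3) else m
    t_i <- rowSums((wn %*% wn) * wn) / 2
  }
  ci <- ifelse(k < 2, 0, 2 * t_i / (k * (k - 1)))
  list(Cp = mean(ci), Ci = ci)
}

#' All-pairs shortest-path distances
#'
#' Binary graphs use hop counts; weighted graphs use Dijkstra on edge
#' lengths `1 / w`, so strong connections are short. Unreachable pairs are
#' `Inf`.
#'
#' @inheritParams clustering_coefficient
#' @return An N x N distance matrix with zero diagonal.
#' @export
shortest_paths_matrix <- function(a) {
  a <- as_adjacency(a)
  g <- as_igraph(a)
  if (a$mode == "binary") {
    igraph::distances(g, weights = NA)
  } else {
    igraph::distances(g, weights = igraph::E(g)$length)
  }
}

#' Characteristic path length
#'
#' Mean shortest-path distance over all reachable (finite) off-diagonal
#' pairs. A disconnected graph triggers a warning and is flagged, because
#' averaging only finite distances understates the true path length.
#'
#' @inheritParams clustering_coefficient
#' @param warn_disconnected Emit a warning when the graph is disconnected.
#' @return List with `Lp` and logical `connected`.
#' @export
characteristic_path_length <- function(a, warn_disconnected = TRUE) {
  d <- shortest_paths_matrix(a)
  off <- d[upper.tri(d)]
  connected <- all(is.finite(off))
  if (!connected && warn_disconnected) {
    warnf("graph is disconnected; Lp averages finite distances only")
  }
  fin <- off[is.finite(off)]
  list(Lp = if (length(fin)) mean(fin) else NA_real_, connected = connected)
}

#' Global efficiency
#'
#' Mean of inverse shortest-path distances over all ordered node pairs;
#' unreachable pairs contribute 0, so `Eglob` is well defined on
#' disconnected graphs.
#'
#' @inheritParams clustering_coefficient
#' @return Scalar efficiency (in `[0, 1]` for binary graphs).
#' @export
global_efficiency <- function(a) {
  d <- shortest_paths_matrix(a)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  n <- nrow(d)
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' Latora-Marchiori local efficiency: for each node, the global efficiency
#' of the subgraph induced by its neighbors; nodes with fewer than two
#' neighbors contribute 0. `Eloc` is the mean over all nodes.
#'
#' @inheritParams clustering_coefficient
#' @return List with `Eloc` (scalar) and `Ei` (per-node vector).
#' @export
local_efficiency <- function(a) {
  a <- as_adjacency(a)
  g <- as_igraph(a)
  list_ei <- local_efficiency_on_graph(a, g)
  list(Eloc = mean(list_ei), Ei = list_ei)
}

# Per-node efficiency of the neighbor-induced subgraph, given a prebuilt
# igraph view of the adjacency. Binary subgraphs use breadth-first search
# by boolean matrix powers, which is much faster than building an igraph
# object per neighborhood.
local_efficiency_on_graph <- function(a, g) {
  m <- a$matrix
  n <- nrow(m)
  ei <- numeric(n)
  binary <- a$mode == "binary"
  for (i in seq_len(n)) {
    nb <- which(m[i, ] > 0)
    kn <- length(nb)
    if (kn < 2L) next
    if (binary) {
      B <- m[nb, nb, drop = FALSE]
      inv_sum <- sum(B)                      # distance-1 pairs
      reached <- (B > 0) | diag(kn) > 0
      R_cur <- B
      dist <- 1L
      while (any(!reached) && dist < kn) {
        R_cur <- (R_cur %*% B) > 0
        fresh <- R_cur & !reached
        if (!any(fresh)) break                # remainder unreachable
        dist <- dist + 1L
        inv_sum <- inv_sum + sum(fresh) / dist
        reached <- reached | fresh
      }
      ei[i] <- inv_sum / (kn * (kn - 1))
    } else {
      sg <- igraph::induced_subgraph(g, nb)
      d <- igraph::distances(sg, weights = igraph::E(sg)$length)
      inv <- 1 / d
      diag(inv) <- 0
      inv[!is.finite(inv)] <- 0
      ei[i] <- sum(inv) / (kn * (kn - 1))
    }
  }
  ei
}

# All global and nodal metrics of one thresholded network, sharing a single
# igraph build and one all-pairs distance computation. include_global = FALSE
# skips the clustering and local-efficiency work when only nodal metrics are
# needed.
metrics_at_threshold <- function(a, include_global = TRUE) {
  a <- as_adjacency(a)
  m <- a$matrix
  n <- nrow(m)
  g <- as_igraph(a)
  wts <- if (a$mode == "binary") NA else igraph::E(g)$length
  d <- igraph::distances(g, weights = wts)
  off <- d[upper.tri(d)]
  connected <- all(is.finite(off))
  fin <- off[is.finite(off)]
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  list(Cp = if (include_global) clustering_coefficient(a)$Cp else NA_real_,
       Lp = if (length(fin)) mean(fin) else NA_real_,
       Eglob = sum(inv) / (n * (n - 1)),
       Eloc = if (include_global) mean(local_efficiency_on_graph(a, g)) else NA_real_,
       connected = connected,
       degree = rowSums(m),
       efficiency = rowSums(inv) / (n - 1),
       betweenness = as.numeric(igraph::betweenness(g, directed = FALSE,
                                                    normalized = FALSE,
                                                    weights = wts)))
}

#' Nodal degree, efficiency and betweenness
#'
#' * degree: number of incident edges (binary) or nodal strength, the sum of
#'   incident edge weights (weighted);
#' * nodal efficiency: mean inverse distance from the node to every other
#'   node (unreachable pairs contribute 0), the node's information
#'   propagation ability;
#' * betweenness: unnormalized Freeman betweenness, the number of shortest
#'   paths between other node pairs passing through the node, with
#'   equal-length multiplicity shared proportionally (Brandes accumulation).
#'
#' @inheritParams clustering_coefficient
#' @return List of length-N vectors `degree`, `efficiency`, `betweenness`.
#' @export
nodal_metrics <- function(a) {
  a <- as_adjacency(a)
  m <- a$matrix
  n <- nrow(m)
  deg <- rowSums(m)
  d <- shortest_paths_matrix(a)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  eff <- rowSums(inv) / (n - 1)
  g <- as_igraph(a)
  btw <- as.numeric(igraph::betweenness(
    g, directed = FALSE, normalized = FALSE,
    weights = if (a$mode == "binary") NA else igraph::E(g)$length
  ))
  nm <- rownames(m)
  if (!is.null(nm)) names(deg) <- names(eff) <- names(btw) <- nm
  list(degree = deg, efficiency = eff, betweenness = btw)
}

#' Degree-preserving random rewiring
#'
#' Maslov-Sneppen double-edge swaps producing a matched random network with
#' exactly the same number of nodes, edges and per-node degrees as the
#' input, and no self-loops or multi-edges. These matched nulls normalize
#' Cp and Lp into gamma and lambda. In weighted mode the topology is rewired
#' and the original multiset of weights is reassigned to the new edges in
#' seeded random order.
#'
#' @inheritParams clustering_coefficient
#' @param n_swaps Number of attempted swaps; default 10x the edge count.
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return A `wm_adjacency` with identical degree sequence.
#' @export
random_rewire <- function(a, n_swaps = NULL, seed = NULL) {
  a <- as_adjacency(a)
  if (is.null(n_swaps)) n_swaps <- 10L * a$n_edges
  if (n_swaps == 0L) return(a)
  bin <- (a$matrix > 0) * 1
  g <- igraph::graph_from_adjacency_matrix(bin, mode = "undirected", diag = FALSE)
  res <- with_seed(seed, {
    g2 <- igraph::rewire(g, igraph::keeping_degseq(niter = n_swaps))
    m2 <- as.matrix(igraph::as_adjacency_matrix(g2, sparse = FALSE))
    if (a$mode == "weighted") {
      wvals <- a$matrix[upper.tri(a$matrix)]
      wvals <- wvals[wvals > 0]
      ut <- which(upper.tri(m2) & m2 > 0, arr.ind = TRUE)
      perm <- sample.int(length(wvals))
      m2[ut] <- wvals[perm]
      m2[ut[, c(2L, 1L), drop = FALSE]] <- m2[ut]
    }
    m2
  })
  dimnames(res) <- dimnames(a$matrix)
  if (a$n_edges > 1L && identical((res > 0) * 1, bin)) {
    warnf("rewiring left the graph unchanged (no admissible swap found)")
  }
  structure(
    list(matrix = res, mode = a$mode, sparsity = a$sparsity, n_edges = a$n_edges),
    class = "wm_adjacency"
  )
}

#' Small-world parameters with matched random-network normalization
#'
#' Computes Cp, Lp, Eglob and Eloc of the network together with the
#' normalized quantities `gamma = Cp / C_random`, `lambda = Lp / L_random`
#' and the small-worldness `sigma = gamma / lambda`, where `C_random` and
#' `L_random` are the means over `n_rand` degree-preserving matched random
#' networks. A small-world network satisfies `gamma > 1`, `lambda ~ 1`,
#' hence `sigma > 1`.
#'
#' @inheritParams clustering_coefficient
#' @param n_rand Number of matched null networks (default 100).
#' @param seed Master seed; each null uses a seed derived from it by a
#'   counter, so runs are reproducible.
#' @return List with `Cp`, `Lp`, `Eglob`, `Eloc`, `gamma`, `lambda`,
#'   `sigma`, `C_random`, `L_random`, and logical `connected`.
#' @export
small_world <- function(a, n_rand = 100L, seed = NULL) {
  a <- as_adjacency(a)
  mt <- metrics_at_threshold(a)
  if (!mt$connected) warnf("network is disconnected; small-world indices use finite distances")
  nm <- null_means(a, n_rand, seed)
  gamma <- if (isTRUE(nm$C_random > 0)) mt$Cp / nm$C_random else {
    warnf("mean null clustering is 0; gamma undefined")
    NA_real_
  }
  lambda <- mt$Lp / nm$L_random
  list(Cp = mt$Cp, Lp = mt$Lp, Eglob = mt$Eglob, Eloc = mt$Eloc,
       gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       C_random = nm$C_random, L_random = nm$L_random, connected = mt$connected)
}

# Mean Cp and Lp over n_rand degree-preserving rewired null networks.
null_means <- function(a, n_rand, seed = NULL) {
  c_rand <- l_rand <- rep(NA_real_, n_rand)
  if (a$mode == "binary") {
    # fast path: stay on igraph objects; same swaps and same RNG stream as
    # random_rewire(), so results are identical to the generic path
    g <- igraph::graph_from_adjacency_matrix((a$matrix > 0) * 1,
                                             mode = "undirected", diag = FALSE)
    n_swaps <- 10L * a$n_edges
    for (b in seq_len(n_rand)) {
      gb <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, b),
                      igraph::rewire(g, igraph::keeping_degseq(niter = n_swaps)))
      ci <- igraph::transitivity(gb, type = "local", isolates = "nan")
      ci[is.na(ci)] <- 0
      c_rand[b] <- mean(ci)
      l_rand[b] <- igraph::mean_distance(gb, directed = FALSE, unconnected = TRUE)
    }
  } else {
    for (b in seq_len(n_rand)) {
      null_b <- random_rewire(a, seed = if (is.null(seed)) NULL else derive_seed(seed, b))
      c_rand[b] <- clustering_coefficient(null_b)$Cp
      l_rand[b] <- characteristic_path_length(null_b, warn_disconnected = FALSE)$Lp
    }
  }
  list(C_random = mean(c_rand), L_random = mean(l_rand))
}

#' Metric curves and AUCs over the sparsity grid
#'
#' Thresholds a connectivity matrix at every grid sparsity, computes all
#' global metrics (Cp, Lp, Eglob, Eloc, gamma, lambda, sigma) and nodal
#' metrics (degree, efficiency, betweenness) at each threshold, and
#' summarizes each curve by its trapezoidal area under the curve (AUC).
#'
#' @param w Connectivity matrix (or [connectivity_matrix()]).
#' @param grid Sparsity grid from [sparsity_grid()].
#' @param mode `"binary"` (default) or `"weighted"`.
#' @param n_rand Matched nulls per threshold for gamma/lambda/sigma; set to
#'   0 to skip normalization (those columns become `NA`).
#' @param seed Master seed for the null networks.
#' @param nodal_only Compute only the nodal metrics (plus Lp and Eglob,
#'   which come free from the distance matrix); Cp, Eloc and the normalized
#'   indices become `NA`. Useful when only nodal AUCs are analyzed.
#' @return A `wm_metric_curves` list: `grid`; `global` (data frame, one row
#'   per threshold); `nodal` (list of grid x N matrices per metric);
#'   `auc$global` (named vector); `auc$nodal` (list of length-N vectors).
#' @export
metric_curves <- function(w, grid = sparsity_grid(), mode = c("binary", "weighted"),
                          n_rand = 100L, seed = NULL, nodal_only = FALSE) {
  mode <- match.arg(mode)
  w <- weights_of(w)
  n <- nrow(w)
  ns <- length(grid)
  glob <- data.frame(S = as.numeric(grid), Cp = NA_real_, Lp = NA_real_,
                     Eglob = NA_real_, Eloc = NA_real_, gamma = NA_real_,
                     lambda = NA_real_, sigma = NA_real_, connected = NA)
  nodal <- list(degree = matrix(NA_real_, ns, n),
                efficiency = matrix(NA_real_, ns, n),
                betweenness = matrix(NA_real_, ns, n))
  for (s_i in seq_len(ns)) {
    a <- threshold_by_sparsity(w, grid[s_i], mode = mode)
    mt <- metrics_at_threshold(a, include_global = !nodal_only)
    gamma <- lambda <- NA_real_
    if (n_rand > 0L && !nodal_only) {
      nulls <- null_means(a, n_rand,
                          seed = if (is.null(seed)) NULL else derive_seed(seed, s_i * 1000L))
      if (isTRUE(nulls$C_random > 0)) gamma <- mt$Cp / nulls$C_random
      lambda <- mt$Lp / nulls$L_random
    }
    glob[s_i, c("Cp", "Lp", "Eglob", "Eloc", "gamma", "lambda", "sigma")] <-
      c(mt$Cp, mt$Lp, mt$Eglob, mt$Eloc, gamma, lambda, gamma / lambda)
    glob$connected[s_i] <- mt$connected
    nodal$degree[s_i, ] <- mt$degree
    nodal$efficiency[s_i, ] <- mt$efficiency
    nodal$betweenness[s_i, ] <- mt$betweenness
  }
  gm <- c("Cp", "Lp", "Eglob", "Eloc", "gamma", "lambda", "sigma")
  auc_global <- vapply(gm, function(mname) {
    v <- glob[[mname]]
    if (anyNA(v)) NA_real_ else auc_trapezoid(glob$S, v)
  }, numeric(1))
  auc_nodal <- lapply(nodal, function(mat) auc_trapezoid(glob$S, mat))
  node_names <- rownames(w)
  if (!is.null(node_names)) {
    auc_nodal <- lapply(auc_nodal, function(v) stats::setNames(v, node_names))
  }
  structure(
    list(grid = as.numeric(grid), global = glob, nodal = nodal,
         auc = list(global = auc_global, nodal = auc_nodal),
         mode = mode, n_rand = n_rand, seed = seed),
    class = "wm_metric_curves"
  )
}
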