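# Independent brute-force oracles used to validate the graph metrics.
# These deliberately avoid igraph and the package's own code paths:
# distances by Floyd-Warshall, clustering by triple enumeration,
# betweenness by path counting with adjacency-matrix powers (a minimal-
# length walk cannot repeat vertices, so walk counts at the shortest
# distance equal path counts), and weighted variants by exhaustive simple-
# path enumeration on tiny graphs.

oracle_distances <- function(m, weighted = FALSE) {
  n <- nrow(m)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && m[i, j] > 0) d[i, j] <- if (weighted) 1 / m[i, j] else 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

oracle_clustering <- function(m) {
  bin <- (m > 0) * 1
  n <- nrow(bin)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(bin[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (a < b && bin[nb[a], nb[b]] > 0) links <- links + 1
    }
    ci[i] <- 2 * links / (k * (k - 1))
  }
  list(Cp = mean(ci), Ci = ci)
}

oracle_efficiency_global <- function(m, weighted = FALSE) {
  d <- oracle_distances(m, weighted)
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(d[i, j])) tot <- tot + 1 / d[i, j]
  }
  tot / (n * (n - 1))
}

oracle_local_efficiency <- function(m, weighted = FALSE) {
  n <- nrow(m)
  ei <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(m[i, ] > 0)
    if (length(nb) < 2) next
    ei[i] <- oracle_efficiency_global(m[nb, nb, drop = FALSE], weighted)
  }
  list(Eloc = mean(ei), Ei = ei)
}

oracle_lp <- function(m, weighted = FALSE) {
  d <- oracle_distances(m, weighted)
  off <- d[upper.tri(d)]
  mean(off[is.finite(off)])
}

oracle_nodal_efficiency <- function(m, weighted = FALSE) {
  d <- oracle_distances(m, weighted)
  n <- nrow(m)
  sapply(seq_len(n), function(i) {
    v <- 1 / d[i, -i]
    sum(v[is.finite(v)]) / (n - 1)
  })
}

# Binary betweenness: sigma_st = (A^d(s,t))[s,t]; a node i lies on a
# shortest s-t path iff d(s,i) + d(i,t) = d(s,t), contributing
# sigma_si * sigma_it paths.
oracle_betweenness_binary <- function(m) {
  bin <- (m > 0) * 1
  n <- nrow(bin)
  d <- oracle_distances(bin)
  maxd <- max(d[is.finite(d)])
  pows <- vector("list", max(maxd, 1))
  pows[[1]] <- bin
  if (maxd >= 2) for (k in 2:maxd) pows[[k]] <- pows[[k - 1]] %*% bin
  sigma <- function(i, j) {
    if (i == j) return(1)
    if (!is.finite(d[i, j])) return(0)
    pows[[d[i, j]]][i, j]
  }
  btw <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t || !is.finite(d[s, t])) next
    tot <- sigma(s, t)
    for (i in seq_len(n)) {
      if (i == s || i == t) next
      if (is.finite(d[s, i]) && is.finite(d[i, t]) && d[s, i] + d[i, t] == d[s, t]) {
        btw[i] <- btw[i] + sigma(s, i) * sigma(i, t) / tot
      }
    }
  }
  btw
}

# Weighted betweenness by exhaustive simple-path enumeration (tiny n only).
oracle_betweenness_weighted <- function(m, tol = 1e-9) {
  n <- nrow(m)
  btw <- numeric(n)
  all_paths <- function(s, t) {
    paths <- list()
    walk <- function(v, visited, len) {
      if (v == t) {
        paths[[length(paths) + 1]] <<- list(nodes = visited, len = len)
        return(invisible())
      }
      for (u in which(m[v, ] > 0)) {
        if (!(u %in% visited)) walk(u, c(visited, u), len + 1 / m[v, u])
      }
    }
    walk(s, s, 0)
    paths
  }
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t) next
    paths <- all_paths(s, t)
    if (!length(paths)) next
    lens <- vapply(paths, `[[`, numeric(1), "len")
    short <- paths[lens <= min(lens) + tol]
    for (i in seq_len(n)) {
      if (i == s || i == t) next
      through <- sum(vapply(short, function(p) i %in% p$nodes, logical(1)))
      btw[i] <- btw[i] + through / length(short)
    }
  }
  btw
}

# Brute-force Benjamini-Hochberg step-up: reject the k smallest p-values
# where k = max { k : p_(k) <= k q / m }.
oracle_bh_mask <- function(p, q = 0.05) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(m) * q / m)
  mask <- rep(FALSE, m)
  if (length(k)) mask[ord[seq_len(max(k))]] <- TRUE
  mask
}

# Random symmetric test graphs.
random_binary_graph <- function(n, p, seed) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- rbinom(n * (n - 1) / 2, 1, p)
  m + t(m)
}

random_weighted_graph <- function(n, p, seed) {
  set.seed(seed)
  m <- matrix(0, n, n)
  e <- rbinom(n * (n - 1) / 2, 1, p) * runif(n * (n - 1) / 2, 0.1, 1)
  m[upper.tri(m)] <- e
  m + t(m)
}
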