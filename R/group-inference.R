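# Covariate-adjusted permutation group inference on metric AUCs, FDR
# control, overlap-node identification, partial correlation with clinical
# variables, and the demographics comparison table.

#' Residualize outcomes on covariates
#'
#' Ordinary-least-squares residuals of `y` on an intercept plus the
#' covariate columns, fitted on the pooled cohort. This is the adjustment
#' step of the Freedman-Lane permutation scheme.
#'
#' @param y Numeric vector, or matrix with one column per outcome.
#' @param covariates Numeric matrix / data frame of covariates, or `NULL`
#'   (intercept only, i.e. centering).
#' @return Residuals with the same shape as `y`.
#' @export
residualize <- function(y, covariates = NULL) {
  y_mat <- as.matrix(y)
  n <- nrow(y_mat)
  x <- if (is.null(covariates)) matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  else {
    cm <- as.matrix(covariates)
    if (nrow(cm) != n) stopf("covariates have %d rows but y has %d", nrow(cm), n)
    cbind("(Intercept)" = 1, cm)
  }
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    dropped <- colnames(x)[qr_x$pivot[seq.int(qr_x$rank + 1L, ncol(x))]]
    stopf("design matrix is rank deficient; collinear columns: %s",
          paste(dropped, collapse = ", "))
  }
  res <- qr.resid(qr_x, y_mat)
  if (is.matrix(y)) res else drop(res)
}

# Pooled-variance two-sample t statistics for each column of Y, group A
# minus group B, for one or many group-indicator columns at once.
pooled_t <- function(Y, ind_a) {
  n <- nrow(Y)
  n1 <- colSums(ind_a)
  n2 <- n - n1
  s <- crossprod(Y, ind_a)            # m x P sums in group A
  ss <- crossprod(Y^2, ind_a)         # m x P sums of squares in group A
  tot <- colSums(Y)
  tot2 <- colSums(Y^2)
  m1 <- sweep(s, 2L, n1, "/")
  m2 <- sweep(-s, 1L, tot, "+")
  m2 <- sweep(m2, 2L, n2, "/")
  ss2 <- sweep(-ss, 1L, tot2, "+")
  var1 <- sweep(ss - sweep(m1^2, 2L, n1, "*"), 2L, n1 - 1, "/")
  var2 <- sweep(ss2 - sweep(m2^2, 2L, n2, "*"), 2L, n2 - 1, "/")
  sp2 <- sweep(sweep(var1, 2L, n1 - 1, "*") + sweep(var2, 2L, n2 - 1, "*"), 2L, n - 2, "/")
  se <- sqrt(sweep(sp2, 2L, 1 / n1 + 1 / n2, "*"))
  (m1 - m2) / se
}

#' Covariate-adjusted two-sample permutation test
#'
#' Freedman-Lane style test of a group difference: `y` is residualized on
#' the covariates once, the pooled-variance two-sample t statistic of the
#' residuals is computed, and the group labels are permuted `n_perm` times.
#' The two-tailed p-value is `(b + 1) / (n_perm + 1)` where `b` counts
#' permutations with `|t| >= |t_obs|`, so p can never be exactly 0.
#'
#' @param y Outcome vector (e.g. a metric AUC per subject), or a matrix
#'   with one column per outcome (all columns share the same permutations).
#' @param group Two-level factor/character vector; the first level (sorted)
#'   is group A and differences are reported as A minus B.
#' @param covariates Optional covariate matrix / data frame.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed for the permutations.
#' @return For vector `y`, list with `p`, `observed_stat`, `n_perm`; for
#'   matrix `y`, list with vectors `p` and `observed_stat`.
#' @export
permutation_test <- function(y, group, covariates = NULL, n_perm = 10000L, seed = 1L) {
  y_mat <- as.matrix(y)
  group <- as.character(group)
  lev <- sort(unique(group))
  if (length(lev) != 2L) stopf("group must have exactly two levels")
  if (min(table(group)) < 2L) stopf("each group needs at least 2 subjects")
  n <- nrow(y_mat)
  res <- residualize(y_mat, covariates)
  const <- apply(y_mat, 2L, function(v) stats::sd(v) == 0)
  ind_obs <- matrix(as.numeric(group == lev[1L]), n, 1L)
  t_obs <- drop(pooled_t(res, ind_obs))
  perm_ind <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) as.numeric(sample(group) == lev[1L]), numeric(n))
  })
  t_perm <- pooled_t(res, perm_ind)   # m x n_perm
  exceed <- rowSums(abs(t_perm) >= abs(t_obs) - 1e-12)
  p <- (exceed + 1) / (n_perm + 1)
  if (any(const)) {
    warnf("%d outcome(s) are constant; their p-values set to 1", sum(const))
    p[const] <- 1
    t_obs[const] <- 0
  }
  if (!is.matrix(y)) list(p = p[1L], observed_stat = t_obs[1L], n_perm = n_perm)
  else list(p = p, observed_stat = t_obs, n_perm = n_perm)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR adjustment; a test is declared significant when its adjusted
#' q-value is at most `q`.
#'
#' @param pvals Vector of p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return List with `q_values` (monotone BH-adjusted values) and logical
#'   `significant`.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvals, method = "BH")
  list(q_values = adj, significant = !is.na(adj) & adj <= q)
}

#' Overlap nodes across the three nodal metrics
#'
#' A node is an overlap node when it is significant in nodal betweenness,
#' nodal degree AND nodal efficiency, with a consistent direction of group
#' difference. Nodes significant everywhere but with conflicting directions
#' are excluded with a warning.
#'
#' @param masks List of three equal-length logical significance vectors
#'   (one per metric).
#' @param directions List of three matching sign vectors (+1 for A > B,
#'   -1 for A < B).
#' @return List with integer `nodes` and their common `direction`.
#' @export
overlap_nodes <- function(masks, directions) {
  if (length(masks) != 3L || length(directions) != 3L) {
    stopf("expected three masks and three direction vectors (one per nodal metric)")
  }
  len <- unique(vapply(masks, length, integer(1)))
  if (length(len) != 1L) stopf("masks must have equal length")
  all_sig <- Reduce(`&`, masks)
  dir_mat <- do.call(cbind, lapply(directions, sign))
  consistent <- apply(dir_mat, 1L, function(r) length(unique(r)) == 1L)
  conflicted <- which(all_sig & !consistent)
  if (length(conflicted)) {
    warnf("node(s) %s significant in all metrics but with conflicting directions; excluded",
          paste(conflicted, collapse = ", "))
  }
  nodes <- which(all_sig & consistent)
  list(nodes = nodes, direction = dir_mat[nodes, 1L])
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the two covariate-residualized vectors, with
#' `t = r * sqrt((n - 2 - k) / (1 - r^2))` on `n - 2 - k` degrees of
#' freedom (`k` covariates). With no covariates this reduces to the plain
#' Pearson correlation test.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional covariate matrix / data frame.
#' @return List with `r`, `p`, `df` and `n`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stopf("x and y must have equal length")
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n <= k + 2L) stopf("need n > k + 2 observations (n = %d, k = %d)", n, k)
  rx <- residualize(x, covariates)
  ry <- residualize(y, covariates)
  if (stats::sd(rx) <= 1e-10 * (stats::sd(x) + 1) ||
      stats::sd(ry) <= 1e-10 * (stats::sd(y) + 1)) {
    stopf("zero residual variance; partial correlation undefined")
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  t_stat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(r = r, p = p, df = df, n = n)
}

#' Demographics and clinical comparison table
#'
#' Group means +/- SD with two-tailed independent-sample t-tests (pooled
#' variance) for the continuous variables, and a chi-squared test without
#' continuity correction for gender counts, mirroring the conventional
#' Table-1 comparison of a two-group imaging study.
#'
#' @param cohort Cohort data frame with columns `group`, `age`, `gender`,
#'   `SAS`, `SDS` (plus any patient-only variables, summarized without a
#'   test).
#' @param correct Apply Yates continuity correction to the chi-squared test
#'   (default `FALSE`).
#' @return Data frame with one row per variable: group summaries, test
#'   statistic and p-value.
#' @export
compare_demographics <- function(cohort, correct = FALSE) {
  groups <- sort(unique(as.character(cohort$group)))
  if (length(groups) != 2L) stopf("cohort must contain exactly two groups")
  ga <- cohort[cohort$group == groups[1L], ]
  gb <- cohort[cohort$group == groups[2L], ]
  if (nrow(ga) < 2L || nrow(gb) < 2L) stopf("each group needs n >= 2 subjects")
  cont_vars <- intersect(c("age", "SAS", "SDS", "duration", "CCS", "PACQOL"),
                         names(cohort))
  rows <- lapply(cont_vars, function(v) {
    xa <- ga[[v]][!is.na(ga[[v]])]
    xb <- gb[[v]][!is.na(gb[[v]])]
    both <- length(xa) >= 2L && length(xb) >= 2L
    pv <- st <- NA_real_
    if (both) {
      if (stats::sd(c(xa, xb)) == 0) {
        st <- 0; pv <- 1
      } else {
        tt <- stats::t.test(xa, xb, var.equal = TRUE)
        st <- unname(tt$statistic); pv <- tt$p.value
      }
    }
    data.frame(variable = v, test = if (both) "t" else "none",
               group_a = sprintf("%.2f ± %.2f", mean(xa), stats::sd(xa)),
               group_b = if (length(xb)) sprintf("%.2f ± %.2f", mean(xb), stats::sd(xb)) else "/",
               statistic = st, p = pv)
  })
  tab <- NULL
  if ("gender" %in% names(cohort)) {
    counts <- rbind(table(factor(ga$gender, levels = c(1, 0))),
                    table(factor(gb$gender, levels = c(1, 0))))
    suppressWarnings(cs <- stats::chisq.test(counts, correct = correct))
    tab <- data.frame(variable = "gender", test = "chisq",
                      group_a = sprintf("%d/%d", counts[1L, 1L], counts[1L, 2L]),
                      group_b = sprintf("%d/%d", counts[2L, 1L], counts[2L, 2L]),
                      statistic = unname(cs$statistic), p = cs$p.value)
  }
  out <- do.call(rbind, c(rows[1L], list(tab), rows[-1L]))
  rownames(out) <- NULL
  out
}

#' Full group inference on metric AUCs
#'
#' Runs the covariate-adjusted permutation test on every global-metric AUC
#' and every (nodal metric, node) AUC, applies Benjamini-Hochberg FDR
#' within each nodal metric family (90 nodes; configurable to pool all
#' nodal tests), identifies overlap nodes across degree, efficiency and
#' betweenness, and computes partial correlations between the overlap
#' nodes' betweenness AUC and the clinical variables (duration, CCS) within
#' group A, FDR-corrected across the tested pairs.
#'
#' @param aucs Result of [cohort_aucs()]: list with `global` (subjects x
#'   metrics matrix) and `nodal` (list of subjects x nodes matrices named
#'   degree, efficiency, betweenness).
#' @param cohort Cohort data frame (columns group, age, gender, SAS, SDS,
#'   and for group A duration, CCS).
#' @param covariate_names Covariates regressed out (default age, gender,
#'   SAS, SDS).
#' @param n_perm Permutations (default 10000).
#' @param seed Integer seed.
#' @param alpha FDR level (default 0.05).
#' @param fdr_family `"per_metric"` (default) corrects each nodal metric's
#'   90 tests separately; `"pooled"` corrects all nodal tests together.
#' @return A `wm_inference` list: `global` and `nodal` result tables,
#'   `overlap` (nodes, names, directions), `correlations`, `demographics`,
#'   and the run parameters.
#' @export
analyze_cohort <- function(aucs, cohort, covariate_names = c("age", "gender", "SAS", "SDS"),
                           n_perm = 10000L, seed = 1L, alpha = 0.05,
                           fdr_family = c("per_metric", "pooled")) {
  fdr_family <- match.arg(fdr_family)
  missing_cov <- setdiff(covariate_names, names(cohort))
  if (length(missing_cov)) stopf("cohort lacks covariates: %s", paste(missing_cov, collapse = ", "))
  covs <- as.matrix(cohort[, covariate_names, drop = FALSE])
  if (anyNA(covs)) stopf("missing values among covariates %s", paste(covariate_names, collapse = ", "))
  sds <- apply(covs, 2L, stats::sd)
  if (any(sds == 0)) {
    warnf("dropping constant covariate column(s): %s",
          paste(colnames(covs)[sds == 0], collapse = ", "))
    covs <- covs[, sds > 0, drop = FALSE]
  }
  if (ncol(covs) == 0L) covs <- NULL
  group <- as.character(cohort$group)

  glob_mat <- as.matrix(aucs$global)
  glob_mat <- glob_mat[, colSums(is.na(glob_mat)) == 0, drop = FALSE]  # e.g. sigma when n_rand = 0
  if (ncol(glob_mat)) {
    glob <- permutation_test(glob_mat, group, covariates = covs,
                             n_perm = n_perm, seed = derive_seed(seed, 11L))
    global_tab <- data.frame(metric = colnames(glob_mat),
                             statistic = glob$observed_stat, p = glob$p,
                             q = fdr_bh(glob$p, alpha)$q_values)
    global_tab$significant <- global_tab$q <= alpha
    global_tab$direction <- ifelse(global_tab$statistic >= 0, "A>B", "A<B")
  } else {
    global_tab <- data.frame(metric = character(), statistic = numeric(),
                             p = numeric(), q = numeric(),
                             significant = logical(), direction = character())
  }

  nodal_metrics_names <- names(aucs$nodal)
  nodal_tabs <- list()
  for (mi in seq_along(nodal_metrics_names)) {
    mname <- nodal_metrics_names[mi]
    pt <- permutation_test(aucs$nodal[[mname]], group, covariates = covs,
                           n_perm = n_perm, seed = derive_seed(seed, 20L + mi))
    node_names <- colnames(aucs$nodal[[mname]])
    if (is.null(node_names)) node_names <- sprintf("node_%03d", seq_along(pt$p))
    nodal_tabs[[mname]] <- data.frame(metric = mname, node = seq_along(pt$p),
                                      node_name = node_names,
                                      statistic = pt$observed_stat, p = pt$p)
  }
  if (fdr_family == "per_metric") {
    for (mname in nodal_metrics_names) {
      fb <- fdr_bh(nodal_tabs[[mname]]$p, alpha)
      nodal_tabs[[mname]]$q <- fb$q_values
      nodal_tabs[[mname]]$significant <- fb$significant
    }
  } else {
    all_p <- unlist(lapply(nodal_tabs, `[[`, "p"))
    fb <- fdr_bh(all_p, alpha)
    off <- 0L
    for (mname in nodal_metrics_names) {
      nn <- nrow(nodal_tabs[[mname]])
      nodal_tabs[[mname]]$q <- fb$q_values[off + seq_len(nn)]
      nodal_tabs[[mname]]$significant <- fb$significant[off + seq_len(nn)]
      off <- off + nn
    }
  }
  nodal_tab <- do.call(rbind, nodal_tabs)
  rownames(nodal_tab) <- NULL
  nodal_tab$direction <- ifelse(nodal_tab$statistic >= 0, "A>B", "A<B")

  triad <- c("betweenness", "degree", "efficiency")
  ov <- if (all(triad %in% nodal_metrics_names)) {
    overlap_nodes(lapply(triad, function(m) nodal_tabs[[m]]$significant),
                  lapply(triad, function(m) sign(nodal_tabs[[m]]$statistic)))
  } else {
    list(nodes = integer(0), direction = integer(0))
  }
  node_names_all <- nodal_tabs[[1L]]$node_name
  overlap <- list(nodes = ov$nodes, node_names = node_names_all[ov$nodes],
                  direction = ifelse(ov$direction >= 0, "A>B", "A<B"))

  correlations <- NULL
  clin_vars <- intersect(c("duration", "CCS"), names(cohort))
  n_cov <- if (is.null(covs)) 0L else ncol(covs)
  in_a <- group == sort(unique(group))[1L]
  if (length(ov$nodes) && length(clin_vars) && "betweenness" %in% nodal_metrics_names &&
      sum(in_a) <= n_cov + 2L) {
    warnf("too few group-A subjects (%d) for partial correlation with %d covariates; skipped",
          sum(in_a), n_cov)
  } else if (length(ov$nodes) && length(clin_vars) && "betweenness" %in% nodal_metrics_names) {
    cov_a <- if (is.null(covs)) NULL else covs[in_a, , drop = FALSE]
    rows <- list()
    for (node in ov$nodes) {
      x <- aucs$nodal$betweenness[in_a, node]
      for (cv in clin_vars) {
        yv <- cohort[[cv]][in_a]
        ok <- !is.na(yv)
        if (sum(ok) <= n_cov + 2L) next
        pc <- partial_correlation(x[ok], yv[ok],
                                  if (is.null(cov_a)) NULL else cov_a[ok, , drop = FALSE])
        rows[[length(rows) + 1L]] <- data.frame(
          node = node, node_name = node_names_all[node], clinical = cv,
          r = pc$r, p = pc$p, n = pc$n)
      }
    }
    if (length(rows)) {
      correlations <- do.call(rbind, rows)
      fb <- fdr_bh(correlations$p, alpha)
      correlations$q <- fb$q_values
      correlations$significant <- fb$significant
    }
  }

  structure(list(global = global_tab, nodal = nodal_tab, overlap = overlap,
                 correlations = correlations,
                 demographics = compare_demographics(cohort),
                 params = list(covariates = covariate_names, n_perm = n_perm,
                               seed = seed, alpha = alpha, fdr_family = fdr_family)),
            class = "wm_inference")
}

#' @export
print.wm_inference <- function(x, ...) {
  cat(sprintf("wm_inference: %d global metrics, %d nodal tests, %d permutations\n",
              nrow(x$global), nrow(x$nodal), x$params$n_perm))
  cat(sprintf("overlap nodes (significant in all three nodal metrics): %s\n",
              if (length(x$overlap$nodes))
                paste(sprintf("%s[%s]", x$overlap$node_names, x$overlap$direction),
                      collapse = ", ")
              else "none"))
  invisible(x)
}
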