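# End-to-end orchestration: cohort-level metric AUCs, YAML run
# configuration, and the full simulate -> metrics -> analyze pipeline with
# a reproducibility manifest.

#' Metric AUCs for every subject in a cohort
#'
#' Runs [metric_curves()] on each subject's connectivity matrix and
#' collects the AUC summaries into subjects x metrics matrices ready for
#' group inference.
#'
#' @param matrices List of connectivity matrices (one per subject).
#' @param grid Sparsity grid (default [sparsity_grid()]).
#' @param mode `"binary"` (default) or `"weighted"`.
#' @param n_rand Matched nulls per threshold for gamma/lambda/sigma; 0
#'   skips normalization (their AUC columns become `NA`).
#' @param seed Master seed; each subject derives its own null seeds.
#' @param nodal_only Compute only the nodal metrics (see [metric_curves()]).
#' @param verbose Print per-subject progress.
#' @return List with `global` (subjects x 7 matrix: Cp, Lp, Eglob, Eloc,
#'   gamma, lambda, sigma), `nodal` (list of subjects x N matrices:
#'   degree, efficiency, betweenness), and `curves` (per-subject
#'   [metric_curves()] results).
#' @export
cohort_aucs <- function(matrices, grid = sparsity_grid(), mode = "binary",
                        n_rand = 100L, seed = 1L, nodal_only = FALSE,
                        verbose = FALSE) {
  n_sub <- length(matrices)
  if (!n_sub) stopf("no matrices supplied")
  curves <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    if (verbose) message(sprintf("subject %d / %d", s, n_sub))
    curves[[s]] <- metric_curves(matrices[[s]], grid = grid, mode = mode,
                                 n_rand = n_rand, nodal_only = nodal_only,
                                 seed = derive_seed(seed, 7000L + s))
  }
  global <- do.call(rbind, lapply(curves, function(cv) cv$auc$global))
  rownames(global) <- names(matrices)
  nodal <- lapply(c(degree = "degree", efficiency = "efficiency",
                    betweenness = "betweenness"), function(mname) {
    m <- do.call(rbind, lapply(curves, function(cv) cv$auc$nodal[[mname]]))
    rownames(m) <- names(matrices)
    m
  })
  list(global = global, nodal = nodal, curves = curves)
}

#' Write cohort metrics as a long-format TSV
#'
#' One row per (subject, metric, scope, grid point or AUC): columns
#' `subject`, `metric`, `node` (`global` for network-level metrics, the
#' node name otherwise), `S` (the sparsity, or `"AUC"` for the summary row)
#' and `value`.
#'
#' @param aucs Result of [cohort_aucs()].
#' @param path Output TSV path.
#' @param curves Also write the full per-threshold curves (default: AUC
#'   rows only, which is what group inference consumes).
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(aucs, path, curves = FALSE) {
  subjects <- rownames(aucs$global)
  if (is.null(subjects)) subjects <- sprintf("S%03d", seq_len(nrow(aucs$global)))
  rows <- list()
  add <- function(df) rows[[length(rows) + 1L]] <<- df
  for (s in seq_along(subjects)) {
    g <- aucs$global[s, ]
    add(data.frame(subject = subjects[s], metric = names(g), node = "global",
                   S = "AUC", value = unname(g)))
    for (mname in names(aucs$nodal)) {
      v <- aucs$nodal[[mname]][s, ]
      nn <- colnames(aucs$nodal[[mname]])
      if (is.null(nn)) nn <- sprintf("node_%03d", seq_along(v))
      add(data.frame(subject = subjects[s], metric = mname, node = nn,
                     S = "AUC", value = unname(v)))
    }
    if (curves && !is.null(aucs$curves)) {
      cv <- aucs$curves[[s]]
      for (mname in c("Cp", "Lp", "Eglob", "Eloc", "gamma", "lambda", "sigma")) {
        add(data.frame(subject = subjects[s], metric = mname, node = "global",
                       S = format(cv$global$S), value = cv$global[[mname]]))
      }
    }
  }
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write inference results to disk
#'
#' Results TSVs (global, nodal, correlations, demographics), an overlap
#' JSON, and a run-manifest JSON recording all parameters and seeds.
#'
#' @param inference A `wm_inference` from [analyze_cohort()].
#' @param dir Output directory.
#' @param extra_manifest Named list merged into the manifest.
#' @return The output directory, invisibly.
#' @export
write_inference_results <- function(inference, dir, extra_manifest = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    if (!is.null(df)) utils::write.table(df, file.path(dir, name), sep = "\t",
                                         row.names = FALSE, quote = FALSE)
  }
  wt(inference$global, "global_metrics.tsv")
  wt(inference$nodal, "nodal_metrics.tsv")
  wt(inference$correlations, "correlations.tsv")
  wt(inference$demographics, "demographics.tsv")
  jsonlite::write_json(
    list(nodes = inference$overlap$nodes, node_names = inference$overlap$node_names,
         direction = inference$overlap$direction),
    file.path(dir, "overlap_nodes.json"), auto_unbox = FALSE, digits = NA, pretty = TRUE)
  manifest <- c(list(package = "wmnet",
                     version = as.character(utils::packageVersion("wmnet")),
                     params = inference$params), extra_manifest)
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run configuration
#'
#' Builds and validates the configuration of a full pipeline run. Every
#' random stage must carry an explicit seed so that a configuration fully
#' determines its outputs.
#'
#' @param cohort Arguments for [cohort_spec()] (list).
#' @param grid Arguments for [sparsity_grid()] (list).
#' @param mode Analysis mode, `"binary"` or `"weighted"`.
#' @param n_rand Matched nulls per threshold.
#' @param n_perm Permutations for group inference.
#' @param seed Master seed (integer, required).
#' @param out_dir Output directory (required for [full_run()]).
#' @return A validated `wm_run_config` list.
#' @export
run_config <- function(cohort = list(), grid = list(), mode = "binary",
                       n_rand = 100L, n_perm = 10000L, seed = NULL,
                       out_dir = NULL) {
  if (is.null(seed) || !is_scalar_number(seed)) {
    stopf("config must set an explicit integer seed")
  }
  mode <- match.arg(mode, c("binary", "weighted"))
  spec <- do.call(cohort_spec, c(cohort, list(seed = as.integer(seed))))
  g <- do.call(sparsity_grid, grid)
  structure(list(cohort = spec, grid = g, mode = mode,
                 n_rand = as.integer(n_rand), n_perm = as.integer(n_perm),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "wm_run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with keys matching [run_config()] arguments.
#' @return A validated `wm_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- c("cohort", "grid", "mode", "n_rand", "n_perm", "seed", "out_dir")
  unknown <- setdiff(names(y), allowed)
  if (length(unknown)) stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  do.call(run_config, y)
}

#' Full pipeline run
#'
#' Simulate a cohort, compute per-subject metric curves and AUCs over the
#' sparsity grid, run the covariate-adjusted permutation group analysis,
#' and write all results plus a manifest that suffices to reproduce the
#' run. Identical configurations (including seeds) produce identical
#' outputs.
#'
#' @param config A `wm_run_config` from [run_config()] or
#'   [read_run_config()].
#' @param verbose Print stage progress.
#' @return Invisibly, a list with `cohort_data`, `aucs`, `inference`, and
#'   `out_dir`.
#' @export
full_run <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "wm_run_config"))
  if (is.null(config$out_dir)) stopf("config must set out_dir")
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s (partial outputs kept in %s)",
            name, conditionMessage(e), config$out_dir)
    })
  }
  say("stage simulate: %d + %d subjects, %d nodes",
      config$cohort$n_group_a, config$cohort$n_group_b, config$cohort$n_nodes)
  cohort_data <- stage("simulate", gen_cohort(config$cohort))
  stage("simulate", write_cohort(cohort_data, file.path(config$out_dir, "cohort")))
  say("stage metrics: %d thresholds, mode %s, %d nulls",
      length(config$grid), config$mode, config$n_rand)
  aucs <- stage("metrics", cohort_aucs(cohort_data$matrices, grid = config$grid,
                                       mode = config$mode, n_rand = config$n_rand,
                                       seed = derive_seed(config$seed, 5L),
                                       verbose = verbose))
  stage("metrics", write_metrics_tsv(aucs, file.path(config$out_dir, "metrics.tsv")))
  say("stage analyze: %d permutations", config$n_perm)
  inference <- stage("analyze", analyze_cohort(aucs, cohort_data$cohort,
                                               n_perm = config$n_perm,
                                               seed = derive_seed(config$seed, 6L)))
  stage("analyze", write_inference_results(
    inference, file.path(config$out_dir, "results"),
    extra_manifest = list(
      seed = config$seed, mode = config$mode, n_rand = config$n_rand,
      grid = list(s_min = min(config$grid), s_max = max(config$grid),
                  n_points = length(config$grid)),
      cohort = config$cohort[setdiff(names(config$cohort), "covariate_model")])))
  say("done: results in %s", file.path(config$out_dir, "results"))
  invisible(list(cohort_data = cohort_data, aucs = aucs, inference = inference,
                 out_dir = config$out_dir))
}
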