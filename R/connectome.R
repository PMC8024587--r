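# Connectivity-matrix container, streamline-to-parcellation mapping, and
# TSV matrix I/O.

#' FA-weighted structural connectivity matrix
#'
#' A weighted, undirected, symmetric N x N anatomical network: one node per
#' parcellation region, edge weight = mean fractional anisotropy (FA) of the
#' streamlines connecting the two regions, in [0, 1].
#'
#' @param weights N x N symmetric nonnegative matrix with zero diagonal.
#' @param node_names Region labels (default taken from `dimnames`, else
#'   `node_01`, ...).
#' @param counts Optional N x N streamline-count matrix.
#' @return A `connectivity_matrix` object.
#' @export
connectivity_matrix <- function(weights, node_names = NULL, counts = NULL) {
  check_symmetric_matrix(weights, what = "connectivity matrix")
  if (any(diag(weights) != 0)) stopf("connectivity matrix must have a zero diagonal")
  n <- nrow(weights)
  if (is.null(node_names)) node_names <- rownames(weights)
  if (is.null(node_names)) node_names <- sprintf("node_%02d", seq_len(n))
  if (length(node_names) != n || anyDuplicated(node_names)) {
    stopf("node_names must be %d unique labels", n)
  }
  dimnames(weights) <- list(node_names, node_names)
  if (!is.null(counts)) {
    if (!is.matrix(counts) || !all(dim(counts) == n)) stopf("counts must be %d x %d", n, n)
    dimnames(counts) <- dimnames(weights)
  }
  structure(list(weights = weights, counts = counts, node_names = node_names),
            class = "connectivity_matrix")
}

# Extract the weight matrix from either representation.
weights_of <- function(x) {
  if (inherits(x, "connectivity_matrix")) x$weights
  else if (inherits(x, "wm_adjacency")) x$matrix
  else as.matrix(x)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  nz <- sum(x$weights[upper.tri(x$weights)] > 0)
  n <- nrow(x$weights)
  cat(sprintf("connectivity_matrix: %d nodes, %d edges (density %.3f), weights [%.3f, %.3f]\n",
              n, nz, nz / (n * (n - 1) / 2),
              min(x$weights[x$weights > 0]), max(x$weights)))
  invisible(x)
}

#' Assign a streamline to a region pair
#'
#' A streamline connects regions `i` and `j` when its two terminal points
#' fall inside voxels labeled `i` and `j > 0` with `i != j`; pass-through
#' regions are ignored. Streamlines ending in unlabeled tissue or with both
#' ends in the same region are unassigned.
#'
#' @param streamline One element of a [fact_track()] streamline set (uses
#'   its visited-voxel list).
#' @param labels A label volume (see [gen_tensor_phantom()]): integer array
#'   with 0 for unlabeled voxels.
#' @return Sorted integer pair `c(i, j)`, or `NULL` when unassigned.
#' @export
assign_endpoints <- function(streamline, labels) {
  vox <- streamline$voxels
  if (is.null(vox) || nrow(vox) == 0L) stopf("streamline has no visited voxels")
  lab <- label_data(labels)
  l1 <- lab[vox[1L, 1L], vox[1L, 2L], vox[1L, 3L]]
  l2 <- lab[vox[nrow(vox), 1L], vox[nrow(vox), 2L], vox[nrow(vox), 3L]]
  if (l1 == 0L || l2 == 0L || l1 == l2) return(NULL)
  sort(c(l1, l2))
}

label_data <- function(labels) {
  if (is.list(labels) && !is.null(labels$data)) labels$data else labels
}

label_names <- function(labels, n) {
  nm <- if (is.list(labels)) labels$region_names else NULL
  if (is.null(nm)) nm <- sprintf("region_%02d", seq_len(n))
  nm
}

#' Build an FA-weighted connectome from streamlines
#'
#' Maps every streamline onto the parcellation with [assign_endpoints()] and
#' accumulates, per region pair, the streamline count and the mean of the
#' per-streamline mean FA (FA sampled at each visited voxel). Pairs with
#' fewer than `min_count` streamlines get weight 0.
#'
#' @param tracks A `wm_streamlines` object from [fact_track()].
#' @param labels Label volume; regions named in its `region_names` become
#'   node names.
#' @param fa Scalar FA volume on the same grid (see [compute_fa()]); used
#'   only if streamlines carry no FA samples.
#' @param min_count Minimum streamline count for an edge (default 1; the
#'   pipeline applies no count filter unless asked).
#' @return A [connectivity_matrix()] with both weights and counts.
#' @export
build_connectome <- function(tracks, labels, fa = NULL, min_count = 1L) {
  lab <- label_data(labels)
  n_regions <- if (is.list(labels) && !is.null(labels$region_names)) {
    length(labels$region_names)
  } else {
    max(lab)
  }
  if (n_regions < 2L) stopf("label volume defines fewer than two regions")
  if (max(lab) > n_regions) stopf("label volume contains label %d beyond the %d named regions",
                                  max(lab), n_regions)
  node_names <- label_names(labels, n_regions)
  present <- sort(unique(as.integer(lab[lab > 0])))
  missing <- setdiff(seq_len(n_regions), present)
  if (length(missing)) {
    warnf("regions absent from label volume (isolated nodes): %s",
          paste(node_names[missing], collapse = ", "))
  }
  counts <- matrix(0L, n_regions, n_regions)
  fa_sum <- matrix(0, n_regions, n_regions)
  for (sl in tracks$streamlines) {
    pair <- assign_endpoints(sl, labels)
    if (is.null(pair)) next
    mfa <- if (!is.null(sl$fa)) mean(sl$fa) else {
      vol <- if (is.list(fa)) fa$data else fa
      mean(vol[sl$voxels])
    }
    counts[pair[1L], pair[2L]] <- counts[pair[1L], pair[2L]] + 1L
    fa_sum[pair[1L], pair[2L]] <- fa_sum[pair[1L], pair[2L]] + mfa
  }
  weights <- ifelse(counts >= min_count & counts > 0, fa_sum / pmax(counts, 1L), 0)
  weights <- weights + t(weights)
  counts <- counts + t(counts)
  connectivity_matrix(weights, node_names = node_names, counts = counts)
}

#' Read / write a connectivity matrix as TSV
#'
#' The on-disk format is a tab-separated N x N matrix with a single header
#' row of node names. `read_matrix()` validates squareness, finiteness,
#' nonnegativity and symmetry (tolerance 1e-9), naming the offending cell
#' on failure; write-then-read round-trips to 12 significant digits.
#'
#' @param path File path.
#' @param m A [connectivity_matrix()] or bare symmetric matrix.
#' @return `read_matrix()` returns a [connectivity_matrix()];
#'   `write_matrix()` returns `path` invisibly.
#' @export
read_matrix <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  raw <- utils::read.table(path, sep = "\t", skip = 1L, header = FALSE,
                           colClasses = "numeric", col.names = header,
                           check.names = FALSE)
  if (ncol(raw) != length(header)) {
    stopf("matrix in %s is not square: %d columns for %d header names",
          path, ncol(raw), length(header))
  }
  if (nrow(raw) != length(header)) {
    stopf("matrix in %s is not square: %d rows for %d columns", path, nrow(raw), ncol(raw))
  }
  m <- as.matrix(raw)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stopf("matrix in %s has a missing/NaN value at (%d, %d)", path, bad[1L], bad[2L])
  }
  dimnames(m) <- list(header, header)
  check_symmetric_matrix(m, tol = 1e-9, what = sprintf("matrix in %s", path))
  connectivity_matrix(m, node_names = header)
}

#' @rdname read_matrix
#' @export
write_matrix <- function(m, path) {
  w <- weights_of(m)
  check_symmetric_matrix(w, what = "connectivity matrix")
  nm <- rownames(w)
  if (is.null(nm)) nm <- sprintf("node_%02d", seq_len(nrow(w)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nm, collapse = "\t"), con)
  body <- apply(w, 1L, function(row) paste(sprintf("%.12g", row), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}
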