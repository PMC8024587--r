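# Synthetic data: tensor phantoms with labeled end-caps for tractography,
# and two-group connectome cohorts with planted nodal effects plus clinical
# covariate tables matching the statistical structure of a functional
# constipation (group A) vs healthy subjects (group B) study.

#' Tensor-phantom specification
#'
#' Describes a digital phantom: fiber bundles (tubes around polyline paths)
#' embedded in a low-anisotropy background. Bundles must have
#' `fa_target > 0.2` so FACT tracking can traverse them, and the background
#' must stay below the 0.2 FA termination threshold so tracking never leaves
#' a bundle.
#'
#' @param grid_shape Three positive voxel counts.
#' @param voxel_size Voxel edge lengths in mm.
#' @param bundles List of bundles: each a list with `path` (k x 3 matrix of
#'   control points, 1-based voxel coordinates), `radius` (voxels, >= 1) and
#'   `fa_target` (in (0.2, 1]).
#' @param background_fa Background anisotropy, in [0, 0.2).
#' @param noise_sd SD of Gaussian perturbation added to the tensor
#'   components, relative to the mean diffusivity.
#' @param seed Integer seed for the noise.
#' @return A validated `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape, voxel_size = c(2, 2, 2), bundles,
                         background_fa = 0.1, noise_sd = 0, seed = 1L) {
  if (length(grid_shape) != 3L || any(grid_shape < 1)) stopf("grid_shape must be 3 positive integers")
  if (!(background_fa >= 0 && background_fa < 0.2)) stopf("background_fa must lie in [0, 0.2)")
  if (noise_sd < 0) stopf("noise_sd must be nonnegative")
  if (!length(bundles)) stopf("at least one bundle is required")
  for (b in seq_along(bundles)) {
    bd <- bundles[[b]]
    if (is.null(bd$path) || !is.matrix(bd$path) || ncol(bd$path) != 3L || nrow(bd$path) < 2L) {
      stopf("bundle %d: path must be a k x 3 matrix with k >= 2", b)
    }
    if (is.null(bd$radius) || bd$radius < 1) stopf("bundle %d: radius must be >= 1 voxel", b)
    if (is.null(bd$fa_target) || bd$fa_target <= 0.2 || bd$fa_target > 1) {
      stopf("bundle %d: fa_target must lie in (0.2, 1] to be trackable", b)
    }
  }
  structure(list(grid_shape = as.integer(grid_shape), voxel_size = as.numeric(voxel_size),
                 bundles = bundles, background_fa = background_fa,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Axially symmetric tensor with prescribed FA and principal direction.
# For lambda = (1, r, r), FA = (1 - r) / sqrt(1 + 2 r^2); solve for r and
# scale so the mean diffusivity equals md.
tensor_from_fa <- function(fa, direction, md = 7e-4) {
  if (fa < 0 || fa > 1) stopf("FA must lie in [0, 1]")
  if (fa == 0) {
    r <- 1
  } else {
    denom <- 1 - 2 * fa^2
    r <- if (abs(denom) < 1e-12) (1 - fa^2) / 2 else
      (1 - fa * sqrt(3 - 2 * fa^2)) / denom
    r <- min(max(r, 0), 1)
  }
  l1 <- 3 * md / (1 + 2 * r)
  l2 <- r * l1
  v <- direction / sqrt(sum(direction^2))
  m <- l2 * diag(3) + (l1 - l2) * tcrossprod(v)
  c(m[1, 1], m[1, 2], m[2, 2], m[1, 3], m[2, 3], m[3, 3])
}

# Resample a polyline at ~step spacing; returns points and unit tangents.
resample_polyline <- function(path, step = 0.25) {
  seg <- diff(path)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  s <- seq(0, total, by = step)
  if (s[length(s)] < total) s <- c(s, total)
  pts <- matrix(NA_real_, length(s), 3L)
  tan <- matrix(NA_real_, length(s), 3L)
  for (i in seq_along(s)) {
    j <- max(which(cum <= s[i] + 1e-12))
    j <- min(j, nrow(seg))
    f <- if (seg_len[j] > 0) (s[i] - cum[j]) / seg_len[j] else 0
    pts[i, ] <- path[j, ] + f * seg[j, ]
    tan[i, ] <- seg[j, ] / seg_len[j]
  }
  # smooth tangents at control-point joints by central difference
  if (nrow(pts) > 2L) {
    tan[c(-1L, -nrow(tan)), ] <- (pts[-(1:2), , drop = FALSE] -
                                    pts[1:(nrow(pts) - 2L), , drop = FALSE])
    tan <- tan / sqrt(rowSums(tan^2))
  }
  list(points = pts, tangents = tan)
}

#' Generate a tensor phantom with labeled end-caps
#'
#' Voxels inside a bundle tube carry an axially symmetric tensor whose
#' principal eigenvector is tangent to the bundle path and whose FA equals
#' `fa_target` (plus tensor-component noise when `noise_sd > 0`); background
#' voxels are near-isotropic at `background_fa`. The label volume assigns a
#' distinct region to each bundle end-cap (in-bundle voxels within one
#' radius of the path end points), 0 elsewhere, giving 2 regions per bundle.
#'
#' @param spec A [phantom_spec()].
#' @return List with `tensors` ([tensor_volume()]), `labels` (list: integer
#'   array `data`, `region_names`), and `fa` (the noiseless design FA array).
#' @export
gen_tensor_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$grid_shape
  n_vox <- prod(dm)
  data <- array(0, c(dm, 6L))
  bg <- tensor_from_fa(spec$background_fa, c(1, 0, 0))
  for (c6 in 1:6) data[, , , c6] <- bg[c6]
  design_fa <- array(spec$background_fa, dm)
  labels <- array(0L, dm)
  region_names <- character(0)

  grid_idx <- as.matrix(expand.grid(i = seq_len(dm[1L]), j = seq_len(dm[2L]),
                                    k = seq_len(dm[3L])))
  for (b in seq_along(spec$bundles)) {
    bd <- spec$bundles[[b]]
    rs <- resample_polyline(bd$path, step = 0.25)
    # nearest path sample per voxel (voxels within radius of any sample)
    in_bundle <- rep(FALSE, n_vox)
    best_d2 <- rep(Inf, n_vox)
    best_s <- rep(NA_integer_, n_vox)
    r2 <- bd$radius^2
    for (s_i in seq_len(nrow(rs$points))) {
      p <- rs$points[s_i, ]
      lo <- pmax(ceiling(p - bd$radius), 1L)
      hi <- pmin(floor(p + bd$radius), dm)
      if (any(lo > hi)) next
      for (i in lo[1L]:hi[1L]) for (j in lo[2L]:hi[2L]) for (k in lo[3L]:hi[3L]) {
        d2 <- (i - p[1L])^2 + (j - p[2L])^2 + (k - p[3L])^2
        if (d2 <= r2) {
          flat <- i + (j - 1L) * dm[1L] + (k - 1L) * dm[1L] * dm[2L]
          in_bundle[flat] <- TRUE
          if (d2 < best_d2[flat]) {
            best_d2[flat] <- d2
            best_s[flat] <- s_i
          }
        }
      }
    }
    vox <- which(in_bundle)
    for (flat in vox) {
      ijk <- grid_idx[flat, ]
      tang <- rs$tangents[best_s[flat], ]
      comp <- tensor_from_fa(bd$fa_target, tang)
      data[ijk[1L], ijk[2L], ijk[3L], ] <- comp
      design_fa[ijk[1L], ijk[2L], ijk[3L]] <- bd$fa_target
    }
    # end-caps: in-bundle voxels within one radius of the path end points
    ends <- rbind(rs$points[1L, ], rs$points[nrow(rs$points), ])
    for (e in 1:2) {
      lab_id <- 2L * (b - 1L) + e
      region_names[lab_id] <- sprintf("bundle%d_end%d", b, e)
      d2e <- (grid_idx[, 1L] - ends[e, 1L])^2 + (grid_idx[, 2L] - ends[e, 2L])^2 +
        (grid_idx[, 3L] - ends[e, 3L])^2
      cap <- which(in_bundle & d2e <= r2)
      clash <- cap[labels[cap] != 0L & labels[cap] != lab_id]
      if (length(clash)) {
        stopf("end-cap collision: region %s overlaps region %s",
              region_names[lab_id], region_names[labels[clash[1L]]])
      }
      labels[cap] <- lab_id
    }
  }
  if (spec$noise_sd > 0) {
    data <- with_seed(spec$seed, {
      data + array(stats::rnorm(length(data), 0, spec$noise_sd * 7e-4), dim(data))
    })
  }
  list(tensors = tensor_volume(data, voxel_size = spec$voxel_size),
       labels = list(data = labels, region_names = region_names),
       fa = design_fa)
}

#' AAL-90 parcellation region table
#'
#' The 90 cortical and subcortical regions of the Automated Anatomical
#' Labeling atlas used as network nodes, in the standard order (45
#' structures, left/right interleaved), with conventional abbreviations
#' (e.g. `ORBsup.L`, `CAU.L`, `THA.L`).
#'
#' @return Data frame with columns `index`, `abbrev`, `name`, `hemisphere`.
#' @export
aal90_regions <- function() {
  path <- system.file("extdata", "aal90_regions.tsv", package = "wmnet", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Default clinical covariate model
#'
#' Group-wise means, SDs and truncation bounds for the simulated clinical
#' table: age (years, inclusion range 20-40), gender (Bernoulli on the male
#' proportion, coded 1 = male), anxiety (SAS) and depression (SDS) scale
#' scores for both groups, plus symptom duration (months), constipation
#' severity (CCS) and quality-of-life (PAC-QoL) scores for the patient
#' group only. Defaults reproduce the reference cohort of 70 patients and
#' 45 controls.
#'
#' @return Nested list `list(a = ..., b = ...)` of per-variable parameters.
#' @export
default_covariate_model <- function() {
  list(
    a = list(
      age = list(mean = 20.66, sd = 1.99, lower = 20, upper = 40),
      gender_male_prob = 8 / 70,
      SAS = list(mean = 40.23, sd = 8.24, lower = 20, upper = 80),
      SDS = list(mean = 43.91, sd = 9.90, lower = 20, upper = 80),
      duration = list(mean = 61.04, sd = 29.44, lower = 6, upper = 180),
      CCS = list(mean = 12.31, sd = 2.00, lower = 5, upper = 30),
      PACQOL = list(mean = 36.06, sd = 12.67, lower = 0, upper = 110)
    ),
    b = list(
      age = list(mean = 21.38, sd = 1.86, lower = 20, upper = 40),
      gender_male_prob = 10 / 45,
      SAS = list(mean = 33.75, sd = 5.95, lower = 20, upper = 80),
      SDS = list(mean = 35.17, sd = 7.84, lower = 20, upper = 80)
    )
  )
}

# Mean and SD of a normal(mu, sigma) truncated to [a, b].
trunc_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  z <- stats::pnorm(be) - stats::pnorm(al)
  dal <- stats::dnorm(al)
  dbe <- stats::dnorm(be)
  m <- mu + sigma * (dal - dbe) / z
  v <- sigma^2 * (1 + (al * dal - be * dbe) / z - ((dal - dbe) / z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Truncated-normal draws via inverse-CDF sampling. The underlying normal
# parameters are adjusted so the *truncated* distribution has the requested
# mean and SD (the published summary statistics describe the bounded data,
# so naive truncation would shrink the SD below its target). Some published
# moment pairs are infeasible for a truncated normal (e.g. an SD larger
# than the distance of the mean from a hard bound); the optimizer then
# returns the closest achievable compromise. The search is penalized away
# from parameter regions where the truncation mass underflows.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  obj <- function(par) {
    mu <- par[1L]
    sigma <- exp(par[2L])
    z <- stats::pnorm(upper, mu, sigma) - stats::pnorm(lower, mu, sigma)
    if (!is.finite(z) || z < 1e-10) return(1e6 + (mu - mean)^2)
    mm <- trunc_moments(mu, sigma, lower, upper)
    if (!all(is.finite(mm))) return(1e6)
    (mm[["mean"]] - mean)^2 + (mm[["sd"]] - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  mu <- fit$par[1L]
  sigma <- exp(fit$par[2L])
  p_lo <- stats::pnorm(lower, mu, sigma)
  p_hi <- stats::pnorm(upper, mu, sigma)
  u <- stats::runif(n, p_lo, p_hi)
  pmin(pmax(stats::qnorm(u, mu, sigma), lower), upper)
}

#' Simulate a clinical covariate table for one group
#'
#' Continuous scores are truncated-normal draws; gender is Bernoulli
#' (coded 0/1, 1 = male). Patient-only variables (duration, CCS, PAC-QoL)
#' appear when the model supplies them, `NA` otherwise.
#'
#' @param n Number of subjects (>= 1).
#' @param model One group's sublist of [default_covariate_model()].
#' @param seed Integer seed.
#' @return Data frame with columns age, gender, SAS, SDS, duration, CCS,
#'   PACQOL.
#' @export
gen_covariates <- function(n, model = default_covariate_model()$a, seed = 1L) {
  if (n < 1) stopf("n must be >= 1")
  draw <- function(par) {
    if (is.null(par)) rep(NA_real_, n)
    else rtruncnorm(n, par$mean, par$sd, par$lower, par$upper)
  }
  with_seed(seed, {
    data.frame(
      age = draw(model$age),
      gender = stats::rbinom(n, 1L, model$gender_male_prob),
      SAS = draw(model$SAS),
      SDS = draw(model$SDS),
      duration = draw(model$duration),
      CCS = draw(model$CCS),
      PACQOL = draw(model$PACQOL)
    )
  })
}

#' Two-group connectome cohort specification
#'
#' All subjects share a spatially structured backbone: nodes placed
#' uniformly at random in a unit cube, with edge weights decaying as
#' `exp(-distance / tau)` plus per-subject Gaussian noise; the backbone
#' carries exactly `round(base_density * n (n - 1) / 2)` edges so that the
#' whole sparsity grid (up to 0.34) can be thresholded. Group-A effects are
#' multiplicative rescalings of all edge weights incident to the designated
#' nodes, so rank-based thresholding feels them.
#'
#' @param n_group_a,n_group_b Subject counts (defaults 70 and 45).
#' @param n_nodes Node count (default 90).
#' @param base_density Fraction of possible edges on the backbone; must
#'   exceed 0.34, the top of the sparsity grid (default 0.5).
#' @param effect_nodes_up,effect_nodes_down Disjoint node index sets whose
#'   incident weights are scaled up / down in group A.
#' @param effect_size Standardized effect: each incident edge weight shifts
#'   by `effect_size` between-subject SDs (applied multiplicatively as
#'   `1 +/- effect_size * subject_noise_sd / weight_mean`).
#' @param weight_mean,weight_sd Mean and spatial SD of backbone FA weights.
#' @param subject_noise_sd SD of the per-subject edge-weight noise.
#' @param tau Spatial decay length of the backbone in unit-cube distance.
#' @param covariate_model See [default_covariate_model()].
#' @param seed Master integer seed.
#' @return A validated `cohort_spec` object.
#' @export
cohort_spec <- function(n_group_a = 70L, n_group_b = 45L, n_nodes = 90L,
                        base_density = 0.5, effect_nodes_up = integer(0),
                        effect_nodes_down = integer(0), effect_size = 0,
                        weight_mean = 0.5, weight_sd = 0.1,
                        subject_noise_sd = 0.02, tau = 0.2,
                        covariate_model = default_covariate_model(), seed = 1L) {
  if (n_group_a < 2 || n_group_b < 2) stopf("each group needs at least 2 subjects")
  if (base_density <= 0.34) stopf("base_density %.3f <= 0.34: sparsity grid would exhaust edges", base_density)
  if (base_density > 1) stopf("base_density must be <= 1")
  if (length(intersect(effect_nodes_up, effect_nodes_down))) {
    stopf("effect_nodes_up and effect_nodes_down must be disjoint")
  }
  eff <- c(effect_nodes_up, effect_nodes_down)
  if (length(eff) && (any(eff < 1) || any(eff > n_nodes))) {
    stopf("effect node indices must lie in 1..%d", n_nodes)
  }
  if (effect_size < 0) stopf("effect_size must be nonnegative")
  structure(list(n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
                 n_nodes = as.integer(n_nodes), base_density = base_density,
                 effect_nodes_up = as.integer(effect_nodes_up),
                 effect_nodes_down = as.integer(effect_nodes_down),
                 effect_size = effect_size, weight_mean = weight_mean,
                 weight_sd = weight_sd, subject_noise_sd = subject_noise_sd,
                 tau = tau, covariate_model = covariate_model, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a two-group connectome cohort with planted effects
#'
#' Produces one symmetric, zero-diagonal FA-weighted matrix per subject
#' (weights clipped to (0, 1], exactly the backbone edge count nonzero) and
#' a clinical covariate table. Group A carries the planted nodal effects;
#' group B is the reference. Fully deterministic given the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return List with `matrices` (list of [connectivity_matrix()], one per
#'   subject), `cohort` (data frame: subject_id, group, covariates) and
#'   `backbone` (node coordinates and mean weights, for diagnostics).
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_nodes
  node_names <- if (n == 90L) {
    reg <- aal90_regions()
    reg$abbrev
  } else {
    sprintf("node_%03d", seq_len(n))
  }
  k <- edges_at_sparsity(spec$base_density, n)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)

  backbone <- with_seed(derive_seed(spec$seed, 1L), {
    xyz <- matrix(stats::runif(3L * n), n, 3L)
    d <- as.matrix(stats::dist(xyz))
    score <- exp(-d[ut] / spec$tau)
    keep <- order(-score, ut[, 1L], ut[, 2L])[seq_len(k)]
    z <- scale(score[keep])[, 1L]
    list(xyz = xyz, edges = ut[keep, , drop = FALSE],
         mu = pmin(1, pmax(1e-3, spec$weight_mean + spec$weight_sd * z)))
  })

  delta <- spec$effect_size * spec$subject_noise_sd / spec$weight_mean
  up_factor <- 1 + delta
  down_factor <- max(0, 1 - delta)
  e_i <- backbone$edges[, 1L]
  e_j <- backbone$edges[, 2L]
  eff_mult <- rep(1, k)
  for (v in spec$effect_nodes_up) eff_mult[e_i == v | e_j == v] <-
    eff_mult[e_i == v | e_j == v] * up_factor
  for (v in spec$effect_nodes_down) eff_mult[e_i == v | e_j == v] <-
    eff_mult[e_i == v | e_j == v] * down_factor

  n_total <- spec$n_group_a + spec$n_group_b
  group <- rep(c("A", "B"), c(spec$n_group_a, spec$n_group_b))
  matrices <- vector("list", n_total)
  for (s in seq_len(n_total)) {
    wv <- with_seed(derive_seed(spec$seed, 100L + s), {
      backbone$mu + stats::rnorm(k, 0, spec$subject_noise_sd)
    })
    if (group[s] == "A") wv <- wv * eff_mult
    wv <- pmin(1, pmax(1e-6, wv))
    m <- matrix(0, n, n, dimnames = list(node_names, node_names))
    m[backbone$edges] <- wv
    m[backbone$edges[, c(2L, 1L), drop = FALSE]] <- wv
    matrices[[s]] <- connectivity_matrix(m, node_names = node_names)
  }

  cov_a <- gen_covariates(spec$n_group_a, spec$covariate_model$a,
                          seed = derive_seed(spec$seed, 2L))
  cov_b <- gen_covariates(spec$n_group_b, spec$covariate_model$b,
                          seed = derive_seed(spec$seed, 3L))
  cohort <- cbind(
    data.frame(subject_id = sprintf("S%03d", seq_len(n_total)), group = group),
    rbind(cov_a, cov_b)
  )
  list(matrices = matrices, cohort = cohort,
       backbone = list(xyz = backbone$xyz, edges = backbone$edges, mu = backbone$mu))
}

#' Write a cohort to disk
#'
#' One TSV matrix per subject (see [write_matrix()]), the cohort table as
#' TSV, and a JSON manifest listing subjects, groups and file paths.
#'
#' @param cohort_data Result of [gen_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort_data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(cohort_data$matrices))
  for (s in seq_along(cohort_data$matrices)) {
    paths[s] <- file.path(dir, sprintf("%s_connectome.tsv", cohort_data$cohort$subject_id[s]))
    write_matrix(cohort_data$matrices[[s]], paths[s])
  }
  cohort_path <- file.path(dir, "cohort.tsv")
  utils::write.table(cohort_data$cohort, cohort_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest <- list(
    n_subjects = nrow(cohort_data$cohort),
    subjects = data.frame(subject_id = cohort_data$cohort$subject_id,
                          group = cohort_data$cohort$group,
                          matrix_path = basename(paths)),
    cohort_table = basename(cohort_path)
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest_path)
}

#' Write phantom volumes as NIfTI
#'
#' The tensor volume is written as a 4-D NIfTI with 6 components per voxel
#' in lower-triangular order; the label volume as an integer NIfTI.
#'
#' @param phantom Result of [gen_tensor_phantom()].
#' @param tensors_path,labels_path Output `.nii.gz` paths.
#' @return Invisibly, the two paths.
#' @export
write_phantom_nifti <- function(phantom, tensors_path, labels_path) {
  vs <- phantom$tensors$voxel_size
  dm <- dim(phantom$tensors$data)
  t_hdr <- RNifti::niftiHeader(list(dim = c(4L, dm, 1L, 1L, 1L),
                                    pixdim = c(1, vs, 1, 1, 1, 1)))
  RNifti::writeNifti(RNifti::asNifti(phantom$tensors$data, reference = t_hdr),
                     tensors_path)
  ldm <- dim(phantom$labels$data)
  l_hdr <- RNifti::niftiHeader(list(dim = c(3L, ldm, 1L, 1L, 1L, 1L),
                                    pixdim = c(1, vs, 1, 1, 1, 1)))
  RNifti::writeNifti(RNifti::asNifti(phantom$labels$data * 1L, reference = l_hdr),
                     labels_path)
  invisible(c(tensors = tensors_path, labels = labels_path))
}

#' Read a phantom tensor volume from NIfTI
#'
#' @param tensors_path 4-D tensor NIfTI (6 components, lower-triangular
#'   order).
#' @param labels_path Optional integer label NIfTI on the same grid.
#' @return List with `tensors` ([tensor_volume()]) and `labels` (or `NULL`).
#' @export
read_phantom_nifti <- function(tensors_path, labels_path = NULL) {
  img <- RNifti::readNifti(tensors_path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L || dim(arr)[4L] != 6L) {
    stopf("%s is not a 6-component tensor volume", tensors_path)
  }
  vs <- RNifti::pixdim(img)[1:3]
  tens <- tensor_volume(arr, voxel_size = vs)
  labels <- NULL
  if (!is.null(labels_path)) {
    larr <- as.array(RNifti::readNifti(labels_path))
    storage.mode(larr) <- "integer"
    labels <- list(data = larr,
                   region_names = sprintf("region_%02d", seq_len(max(larr))))
  }
  list(tensors = tens, labels = labels)
}
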