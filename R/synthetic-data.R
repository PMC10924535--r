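# Synthetic lesion cohorts: template, Voronoi parcel atlas, spherical
# Gaussian-smoothed lesions with a planted effect region, and lesion-coupled
# neuropsychological test scores. The generator gives every pipeline stage a
# fully specified, seed-reproducible input with known ground truth.

#' Neurocognitive domains
#'
#' The five domains assessed by the battery: attention and executive
#' function, language, memory, visuospatial/constructive abilities and
#' visuomotor speed.
#'
#' @return Character vector of domain identifiers.
#' @export
vlsm_domains <- function() {
  c("attention_executive", "language", "memory", "visuospatial",
    "visuomotor_speed")
}

#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. Defaults emulate the data
#' contract of a registered glioma cohort: ~100 subjects with one fuzzy
#' (smoothed, \[0,1\]-valued) lesion each on a shared isotropic grid, an
#' "eloquent" spherical effect region whose involvement drives severe
#' deficit, and a parcellated atlas.
#'
#' @param grid_shape Integer triple, >= 16 per axis. Default `c(32,32,32)`.
#' @param n_subjects Number of subjects (default 100).
#' @param n_affected Number of subjects whose lesion placement is biased
#'   toward the effect region (default 40).
#' @param lesion_radius_range Min/max lesion ball radius in voxels. The
#'   default (`NULL`) is 3–7 voxels at the reference 32-voxel grid, scaled
#'   by `min(grid_shape)/32` on other grids so that lesions occupy the same
#'   realistic fraction (roughly 1–10%) of brain volume at any resolution.
#' @param smoothing_sigma Gaussian smoothing sigma in voxels (default 1.5),
#'   producing fuzzy registered-mask-like values.
#' @param effect_center,effect_radius Sphere defining the ground-truth
#'   effect region; `NULL` places it at 0.18·grid off-centre along x with
#'   radius `round(min(grid_shape)/5)`.
#' @param effect_strength Probability in \[0,1\] that an affected subject's
#'   lesion centre is drawn inside the effect region (0 = global null;
#'   default 0.9).
#' @param score_noise_sd SD of the Gaussian noise on simulated z-scores
#'   (default 0.5).
#' @param severe_overlap Fraction of effect-region involvement above which
#'   the deterministic score component falls below z = -2 (default 0.25).
#' @param deficit_shift Slope of the score deficit per unit overlap;
#'   `NULL` derives it as `2.5/severe_overlap`.
#' @param n_parcels Number of atlas parcels (default 24).
#' @param seed Integer master seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(grid_shape = c(32, 32, 32),
                       n_subjects = 100,
                       n_affected = 40,
                       lesion_radius_range = NULL,
                       smoothing_sigma = 1.5,
                       effect_center = NULL,
                       effect_radius = NULL,
                       effect_strength = 0.9,
                       score_noise_sd = 0.5,
                       severe_overlap = 0.25,
                       deficit_shift = NULL,
                       n_parcels = 24,
                       seed = 1) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    .stop_validation("`grid_shape` must be a triple with every axis >= 16")
  .check_number(n_subjects, "n_subjects", lower = 2, integer = TRUE)
  .check_number(n_affected, "n_affected", lower = 0, upper = n_subjects,
                integer = TRUE)
  if (is.null(lesion_radius_range))
    lesion_radius_range <- c(3, 7) * min(grid_shape) / 32
  if (length(lesion_radius_range) != 2L ||
      any(lesion_radius_range <= 0) ||
      lesion_radius_range[1] > lesion_radius_range[2])
    .stop_validation("`lesion_radius_range` must be an increasing positive pair")
  .check_number(smoothing_sigma, "smoothing_sigma", lower = 0)
  .check_number(effect_strength, "effect_strength", lower = 0, upper = 1)
  .check_number(score_noise_sd, "score_noise_sd", lower = 0)
  .check_number(severe_overlap, "severe_overlap", lower = 0, upper = 1,
                open_lower = TRUE)
  if (is.null(deficit_shift)) deficit_shift <- 2.5 / severe_overlap
  .check_number(deficit_shift, "deficit_shift", lower = 0)
  .check_number(n_parcels, "n_parcels", lower = 2, integer = TRUE)
  .check_number(seed, "seed", integer = TRUE)
  if (is.null(effect_center)) effect_center <-
      round((grid_shape + 1) / 2) + c(round(0.18 * grid_shape[1]), 0, 0)
  if (is.null(effect_radius)) effect_radius <- round(min(grid_shape) / 5)
  .check_number(effect_radius, "effect_radius", lower = 1)
  structure(list(
    grid_shape = grid_shape, n_subjects = as.integer(n_subjects),
    n_affected = as.integer(n_affected),
    lesion_radius_range = as.numeric(lesion_radius_range),
    smoothing_sigma = smoothing_sigma,
    effect_center = as.numeric(effect_center),
    effect_radius = as.numeric(effect_radius),
    effect_strength = effect_strength, score_noise_sd = score_noise_sd,
    severe_overlap = severe_overlap, deficit_shift = deficit_shift,
    n_parcels = as.integer(n_parcels), seed = as.integer(seed)
  ), class = "sim_config")
}

# Logical sphere on a grid.
.sphere_mask <- function(grid_shape, center, radius) {
  g <- .voxel_grid(grid_shape)
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  array(d2 <= radius^2, grid_shape)
}

#' Build the synthetic template space
#'
#' The brain mask is an axis-aligned ellipsoid with semi-axes 0.45 times the
#' grid shape, centred on the grid — a deterministic stand-in for a
#' template brain at 1 mm isotropic resolution.
#'
#' @param config A [sim_config()].
#' @return A [template_space()].
#' @export
make_template <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  d <- config$grid_shape
  ctr <- (d + 1) / 2
  semi <- 0.45 * d
  g <- .voxel_grid(d)
  inside <- ((g$x - ctr[1]) / semi[1])^2 + ((g$y - ctr[2]) / semi[2])^2 +
    ((g$z - ctr[3]) / semi[3])^2 <= 1
  template_space(array(inside, d))
}

#' Build a synthetic Voronoi parcel atlas
#'
#' Parcel seeds are drawn uniformly (without replacement) from brain-mask
#' voxels and every mask voxel is assigned to its nearest seed, yielding a
#' partition of the mask into `n_parcels` non-empty parcels. Parcels whose
#' seed lies within 60% of the mask's radial extent are tagged
#' "subcortical", the rest "cortical", mimicking a dual cortical /
#' subcortical atlas.
#'
#' @param space A [template_space()].
#' @param n_parcels Number of parcels (>= 2).
#' @param seed Integer seed.
#' @return A [parcel_atlas()].
#' @export
make_atlas <- function(space, n_parcels = 24, seed = 1) {
  .check_space(space)
  .check_number(n_parcels, "n_parcels", lower = 2, integer = TRUE)
  idx <- which(space$brain_mask)
  if (n_parcels > length(idx))
    .stop_validation("n_parcels (%d) exceeds mask voxel count (%d)",
                     n_parcels, length(idx))
  d <- space$grid_shape
  g <- .voxel_grid(d)
  seeds <- .with_seed(seed, sample(idx, n_parcels))
  # nearest-seed assignment; ties resolved to the lowest parcel label
  sx <- g$x[seeds]; sy <- g$y[seeds]; sz <- g$z[seeds]
  mx <- g$x[idx]; my <- g$y[idx]; mz <- g$z[idx]
  d2 <- outer(mx, sx, function(a, b) (a - b)^2) +
    outer(my, sy, function(a, b) (a - b)^2) +
    outer(mz, sz, function(a, b) (a - b)^2)
  lab <- max.col(-d2, ties.method = "first")
  labels <- array(0L, d)
  labels[idx] <- lab
  ctr <- (d + 1) / 2
  seed_rad <- sqrt(((sx - ctr[1]) / (0.45 * d[1]))^2 +
                   ((sy - ctr[2]) / (0.45 * d[2]))^2 +
                   ((sz - ctr[3]) / (0.45 * d[3]))^2)
  tab <- data.frame(
    label = seq_len(n_parcels),
    name = sprintf("parcel_%02d", seq_len(n_parcels)),
    hemisphere = ifelse(sx <= ctr[1], "L", "R"),
    class = ifelse(seed_rad <= 0.6, "subcortical", "cortical"),
    stringsAsFactors = FALSE
  )
  parcel_atlas(labels, tab, space)
}

# Separable 3D Gaussian smoothing, zero padding at the edges.
.gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

.conv_matrix <- function(n, k) {
  r <- (length(k) - 1L) / 2L
  K <- matrix(0, n, n)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    K[cbind(which(ok), src[ok])] <- K[cbind(which(ok), src[ok])] + k[j]
  }
  K
}

.gauss_smooth3d <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  k <- .gauss_kernel(sigma)
  d <- dim(vol)
  Ks <- lapply(d, .conv_matrix, k = k)
  for (ax in 1:3) {
    dd <- dim(vol)
    vol <- array(Ks[[ax]] %*% matrix(vol, dd[1]), dd)
    vol <- aperm(vol, c(2, 3, 1))
  }
  vol
}

#' Simulate a lesion cohort with a planted effect
#'
#' Each subject receives one spherical lesion (radius drawn uniformly from
#' `lesion_radius_range`), Gaussian-smoothed to fuzzy \[0,1\] values,
#' rescaled to peak 1 and clipped to the brain mask. Affected subjects'
#' lesion centres fall inside the effect region with probability
#' `effect_strength`, otherwise uniformly in the mask; control centres are
#' always uniform in the mask. With `effect_strength = 0` the two groups'
#' lesion processes are identical (the global null), making group labels
#' exchangeable.
#'
#' @param config A [sim_config()].
#' @param space Optional [template_space()]; defaults to
#'   `make_template(config)`.
#' @return List with elements `cohort` (a [lesion_cohort()]) and `truth`
#'   (class `ground_truth`: `effect_mask`, logical `affected` per subject,
#'   per-subject `centers` and `radii`).
#' @export
simulate_cohort <- function(config, space = NULL) {
  stopifnot(inherits(config, "sim_config"))
  space <- space %||% make_template(config)
  d <- space$grid_shape
  effect_mask <- .sphere_mask(d, config$effect_center, config$effect_radius)
  if (any(effect_mask & !space$brain_mask))
    .stop_validation("effect region is not fully inside the brain mask")
  mask_idx <- which(space$brain_mask)
  region_idx <- which(effect_mask)
  n <- config$n_subjects
  affected <- seq_len(n) <= config$n_affected
  g <- .voxel_grid(d)
  res <- .with_seed(.derive_seed(config$seed, "cohort"), {
    centers <- matrix(0, n, 3)
    radii <- numeric(n)
    arr <- array(0, c(d, n))
    for (i in seq_len(n)) {
      in_region <- affected[i] && runif(1) < config$effect_strength
      pick <- if (in_region) region_idx[sample.int(length(region_idx), 1)]
              else mask_idx[sample.int(length(mask_idx), 1)]
      ctr <- c(g$x[pick], g$y[pick], g$z[pick])
      r <- runif(1, config$lesion_radius_range[1], config$lesion_radius_range[2])
      vol <- .sphere_mask(d, ctr, r) + 0
      vol <- .gauss_smooth3d(vol, config$smoothing_sigma)
      mx <- max(vol)
      if (mx > 0) vol <- vol / mx
      vol[!space$brain_mask] <- 0
      vol[vol < 0] <- 0; vol[vol > 1] <- 1
      arr[, , , i] <- vol
      centers[i, ] <- ctr
      radii[i] <- r
    }
    list(arr = arr, centers = centers, radii = radii)
  })
  ids <- sprintf("S%03d", seq_len(n))
  cohort <- lesion_cohort(res$arr, ids, space)
  truth <- structure(list(
    effect_mask = effect_mask,
    affected = setNames(affected, ids),
    centers = res$centers, radii = res$radii,
    config = config
  ), class = "ground_truth")
  list(cohort = cohort, truth = truth)
}

#' Read a simulation configuration from a YAML file
#'
#' Fields mirror the arguments of [sim_config()]; omitted fields take the
#' defaults. Unknown fields are an error, to catch typos.
#'
#' @param path YAML file path.
#' @return A [sim_config()].
#' @export
sim_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    .stop_validation("unknown simulation config field(s): %s",
                     paste(unknown, collapse = ", "))
  do.call(sim_config, raw)
}

#' Calibrate the score deficit slope to a target recruitment rate
#'
#' Chooses `deficit_shift` (and the implied severe-overlap threshold) so
#' that a target fraction of the affected subjects is expected to be graded
#' severe (z < -2) and thus recruited into the affected analysis group.
#' The overlap distribution of region-centred lesions is estimated by
#' Monte-Carlo from the generator's own geometry (lesion radii, smoothing,
#' effect region); the threshold is placed at the overlap quantile
#' corresponding to `target_frac` of affected subjects given
#' `effect_strength`, with the deterministic score component set to -2.5
#' there (half a default noise SD beyond the severe cutoff).
#'
#' @param config A [sim_config()].
#' @param target_frac Desired recruited fraction of affected subjects
#'   (default 0.6).
#' @param n_draws Monte-Carlo draws for the overlap distribution.
#' @return The calibrated `deficit_shift` (scalar).
#' @export
calibrate_deficit_shift <- function(config, target_frac = 0.6,
                                    n_draws = 200) {
  stopifnot(inherits(config, "sim_config"))
  if (config$effect_strength <= 0)
    .stop_validation("calibration needs a planted effect (effect_strength > 0)")
  space <- make_template(config)
  d <- space$grid_shape
  region <- .sphere_mask(d, config$effect_center, config$effect_radius)
  region_idx <- which(region)
  g <- .voxel_grid(d)
  overlaps <- .with_seed(.derive_seed(config$seed, "scores"), {
    vapply(seq_len(n_draws), function(i) {
      pick <- region_idx[sample.int(length(region_idx), 1)]
      r <- runif(1, config$lesion_radius_range[1],
                 config$lesion_radius_range[2])
      vol <- .sphere_mask(d, c(g$x[pick], g$y[pick], g$z[pick]), r) + 0
      vol <- .gauss_smooth3d(vol, config$smoothing_sigma)
      mx <- max(vol)
      if (mx > 0) vol <- vol / mx
      vol[!space$brain_mask] <- 0
      mean(vol[region])
    }, numeric(1))
  })
  # fraction of in-region lesions that must clear the threshold so that
  # target_frac of all affected subjects does
  frac_needed <- min(1, target_frac / config$effect_strength)
  thr <- unname(quantile(overlaps, probs = 1 - frac_needed, type = 7))
  if (thr <= 0) .stop_validation("degenerate overlap distribution")
  2.5 / thr
}

#' Simulate neuropsychological test z-scores
#'
#' For each of the five domains and two tests per domain, a subject's score
#' is `z = noise - deficit_shift * overlap`, where `overlap` is the mean
#' lesion probability inside that domain's effect region and noise is
#' Gaussian with SD `score_noise_sd`. With the default `deficit_shift`,
#' involvement above `severe_overlap` pushes the deterministic component
#' below the severe cutoff z = -2.
#'
#' @param cohort A [lesion_cohort()].
#' @param truth The `ground_truth` from [simulate_cohort()].
#' @param config The same [sim_config()].
#' @param domain_regions Optional named list of logical effect-region masks
#'   per domain; defaults to the planted effect region for every domain
#'   (emulating multidomain involvement of one eloquent region).
#' @return Long data.frame: `subject_id`, `domain`, `test_name`, `z_score`,
#'   `subjective_grade` (NA; all synthetic scores are standardized).
#' @export
simulate_scores <- function(cohort, truth, config, domain_regions = NULL) {
  stopifnot(inherits(cohort, "lesion_cohort"),
            inherits(truth, "ground_truth"),
            inherits(config, "sim_config"))
  domains <- vlsm_domains()
  if (is.null(domain_regions))
    domain_regions <- setNames(rep(list(truth$effect_mask), length(domains)),
                               domains)
  n <- .n_subjects(cohort)
  flat <- matrix(cohort$data, ncol = n)
  rows <- .with_seed(.derive_seed(config$seed, "scores"), {
    out <- vector("list", length(domains))
    for (di in seq_along(domains)) {
      reg <- domain_regions[[domains[di]]]
      overlap <- colMeans(flat[as.vector(reg), , drop = FALSE])
      for (ti in 1:2) {
        z <- rnorm(n, 0, config$score_noise_sd) -
          config$deficit_shift * overlap
        out[[di]][[ti]] <- data.frame(
          subject_id = cohort$subject_ids,
          domain = domains[di],
          test_name = sprintf("%s_test%d", domains[di], ti),
          z_score = z,
          subjective_grade = NA_character_,
          stringsAsFactors = FALSE
        )
      }
    }
    out
  })
  do.call(rbind, unlist(rows, recursive = FALSE))
}
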