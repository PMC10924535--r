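# The modelling surface: vlsm() fits a voxelwise lesion-symptom map for one
# domain grouping and wraps observed statistic, permutation null, p/q maps
# and significance masks in a single classed object.

#' Fit a voxel-based lesion-symptom map
#'
#' Compares, at every brain voxel, the distribution of fuzzy tumor
#' probabilities between subjects with a severe deficit in one
#' neurocognitive domain ("affected") and all remaining subjects
#' ("control"), and attaches permutation inference:
#'
#' * `inference = "perm95"` — the extreme-percentile family-wise null: per
#'   permutation, record the `percentile_q`-th percentile (default 5th) of
#'   the whole-brain one-sided t values; powerful at moderate sample sizes
#'   while still curbing family-wise error.
#' * `inference = "min_stat"` — the classical minimum-statistic (maxT-type)
#'   null giving strict family-wise error control.
#' * `inference = "per_voxel"` — uncorrected per-voxel permutation test
#'   (the usual choice with `statistic = "rr"`), with Benjamini-Hochberg
#'   q-values attached.
#' * `inference = "parametric"` — Student-t left-tail p-values (t only).
#'
#' @param cohort A [lesion_cohort()].
#' @param groups A `vlsm_groups` object (see [build_groups()]), or a
#'   character vector of affected subject ids (the rest become controls).
#' @param statistic `"t"` (pooled two-sample t on fuzzy probabilities) or
#'   `"rr"` (relative risk on masks binarized at `rr_threshold`).
#' @param inference Inference mode, see above.
#' @param n_permutations,percentile_q,seed,exhaustive_limit See
#'   [perm_config()].
#' @param alpha Significance cutoffs for the returned masks
#'   (default `c(0.05, 0.2)`).
#' @param rr_threshold Binarization threshold for the RR pathway
#'   (default 0.03).
#' @param var_equal `FALSE` switches the t statistic to Welch.
#' @return Object of class `vlsm`: `observed` (`stat_map`), `null`
#'   (`null_distribution` or NULL), `p` (`pvalue_map`), `q` (`pvalue_map`
#'   or NULL), `masks` (named list of `sig_mask` per alpha), `groups`,
#'   `settings`, `call`.
#' @examples
#' cfg <- sim_config(grid_shape = c(16, 16, 16), n_subjects = 20,
#'                   n_affected = 8, seed = 42)
#' sim <- simulate_cohort(cfg)
#' grp <- vlsm_groups(affected = sim$cohort$subject_ids[sim$truth$affected],
#'                    control = sim$cohort$subject_ids[!sim$truth$affected])
#' fit <- vlsm(sim$cohort, grp, n_permutations = 99, seed = 7)
#' fit
#' @export
vlsm <- function(cohort, groups, statistic = c("t", "rr"),
                 inference = c("perm95", "min_stat", "per_voxel",
                               "parametric"),
                 n_permutations = 1000, percentile_q = 5,
                 alpha = c(0.05, 0.2), rr_threshold = 0.03, seed = 1,
                 var_equal = TRUE, exhaustive_limit = 20000) {
  statistic <- match.arg(statistic)
  inference <- match.arg(inference)
  if (is.character(groups))
    groups <- vlsm_groups(affected = groups,
                          control = setdiff(cohort$subject_ids, groups))
  if (statistic == "rr" && inference %in% c("perm95", "min_stat",
                                            "parametric"))
    .stop_validation(
      "family-wise and parametric modes are defined for statistic = \"t\"")
  cfg <- perm_config(
    n_permutations = n_permutations, percentile_q = percentile_q,
    mode = switch(inference, perm95 = "perm_percentile",
                  min_stat = "min_stat", "per_voxel"),
    alpha_levels = alpha, seed = seed, exhaustive_limit = exhaustive_limit)
  observed <- if (statistic == "t") t_map(cohort, groups, var_equal)
              else rr_map(cohort, groups, threshold = rr_threshold)
  null <- NULL; qmap <- NULL
  if (inference %in% c("perm95", "min_stat")) {
    null <- build_null(cohort, groups, cfg, statistic = "t",
                       var_equal = var_equal)
    pmap <- p_map_fwe(observed, null)
  } else if (inference == "per_voxel") {
    pmap <- p_map_pervoxel(cohort, groups, cfg, statistic = statistic,
                           rr_threshold = rr_threshold,
                           var_equal = var_equal)
    qmap <- q_values(pmap)
  } else {
    pmap <- p_map_parametric(observed)
  }
  masks <- lapply(alpha, function(a) threshold_map(pmap, a))
  names(masks) <- sprintf("alpha_%g", alpha)
  structure(list(
    observed = observed, null = null, p = pmap, q = qmap, masks = masks,
    groups = groups, statistic = statistic, inference = inference,
    settings = cfg, rr_threshold = if (statistic == "rr") rr_threshold,
    call = match.call()
  ), class = "vlsm")
}

#' @export
print.vlsm <- function(x, ...) {
  cat("Voxel-based lesion-symptom map\n")
  cat(sprintf("  statistic: %s   inference: %s%s\n", x$statistic,
              x$inference,
              if (!is.null(x$null) && x$null$exhaustive)
                " (exhaustive enumeration)" else ""))
  cat(sprintf("  groups: %d affected vs %d control%s\n",
              length(x$groups$affected), length(x$groups$control),
              if (is.na(x$groups$domain)) "" else
                sprintf(" [%s]", x$groups$domain)))
  cat(sprintf("  valid voxels: %d of %d in brain mask\n",
              sum(x$observed$valid), sum(x$observed$space$brain_mask)))
  for (m in x$masks)
    cat(sprintf("  significant voxels at alpha=%g: %d\n", m$alpha,
                sum(m$mask)))
  invisible(x)
}

#' @export
summary.vlsm <- function(object, ...) {
  v <- object$observed$values[object$observed$valid]
  p <- object$p$values[object$p$valid]
  out <- list(
    statistic = object$statistic, inference = object$inference,
    domain = object$groups$domain,
    group_sizes = c(affected = length(object$groups$affected),
                    control = length(object$groups$control)),
    n_valid = sum(object$observed$valid),
    stat_quantiles = quantile(v[is.finite(v)],
                              c(0, .05, .25, .5, .75, .95, 1)),
    p_min = suppressWarnings(min(p)),
    n_significant = vapply(object$masks, function(m) sum(m$mask),
                           numeric(1)),
    null_summary = if (!is.null(object$null))
      quantile(object$null$summary_values, c(0, .05, .5, .95, 1)),
    n_permutations = if (!is.null(object$null))
      object$null$n_permutations else object$p$n_permutations
  )
  class(out) <- "summary.vlsm"
  out
}

#' @export
print.summary.vlsm <- function(x, ...) {
  cat(sprintf("VLSM fit (%s statistic, %s inference)\n", x$statistic,
              x$inference))
  if (!is.na(x$domain)) cat(sprintf("  domain: %s\n", x$domain))
  cat(sprintf("  groups: %d affected vs %d control; %d valid voxels\n",
              x$group_sizes[1], x$group_sizes[2], x$n_valid))
  cat("  observed statistic quantiles:\n")
  print(round(x$stat_quantiles, 3))
  if (!is.null(x$null_summary)) {
    cat("  permutation null summary quantiles:\n")
    print(round(x$null_summary, 3))
  }
  cat(sprintf("  minimum p: %.4g\n", x$p_min))
  for (i in seq_along(x$n_significant))
    cat(sprintf("  %s: %d significant voxels\n",
                names(x$n_significant)[i], x$n_significant[i]))
  invisible(x)
}

#' Plot a fitted lesion-symptom map
#'
#' Axial-slice montage of the p-value map (as -log10 p) with the
#' significance outline at the chosen alpha.
#'
#' @param x A `vlsm` fit.
#' @param slices Integer vector of axial (z) slice indices; default 6
#'   evenly spaced brain-covering slices.
#' @param alpha Mask level to outline (must be one of the fitted levels).
#' @param ... Unused.
#' @export
plot.vlsm <- function(x, slices = NULL, alpha = NULL, ...) {
  space <- x$observed$space
  zs <- which(apply(space$brain_mask, 3, any))
  if (is.null(slices))
    slices <- unique(round(seq(min(zs), max(zs), length.out = 6)))
  if (is.null(alpha)) alpha <- x$masks[[length(x$masks)]]$alpha
  key <- sprintf("alpha_%g", alpha)
  mask <- if (key %in% names(x$masks)) x$masks[[key]]$mask
          else threshold_map(x$p, alpha)$mask
  lp <- -log10(pmax(x$p$values, 1e-16))
  lp[!x$p$valid] <- NA
  op <- par(mfrow = c(2, ceiling(length(slices) / 2)), mar = c(1, 1, 2, 1))
  on.exit(par(op))
  for (z in slices) {
    bg <- space$brain_mask[, , z] + 0
    image(bg, col = gray.colors(2, start = 0.15, end = 0.55), axes = FALSE,
          main = sprintf("z = %d", z), cex.main = 0.9)
    sl <- lp[, , z]
    if (any(is.finite(sl)))
      image(sl, col = hcl.colors(32, "YlOrRd", rev = TRUE),
            zlim = c(0, max(lp, na.rm = TRUE)), add = TRUE)
    sm <- mask[, , z]
    if (any(sm)) {
      pts <- which(sm, arr.ind = TRUE)
      d <- dim(sm)
      text((pts[, 1] - 1) / (d[1] - 1), (pts[, 2] - 1) / (d[2] - 1), ".",
           col = "cyan", cex = 0.6)
    }
  }
  mtext(sprintf("-log10 p (%s), dots: significant at alpha=%g",
                x$p$method, alpha),
        side = 3, outer = TRUE, line = -1.2, cex = 0.8)
  invisible(x)
}
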