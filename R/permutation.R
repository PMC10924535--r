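# Permutation inference. Group labels are exchangeable under the voxelwise
# null, so relabeling the subjects and recomputing the whole-brain statistic
# map builds an empirical null. Two family-wise summaries are supported:
# the classical minimum statistic (strict FWE control, maxT-style) and the
# Perm95 variant, which records the 5th percentile of the voxelwise t values
# per permutation — trading some strictness of FWE control for power at
# moderate sample sizes. Per-voxel (uncorrected) permutation p-values with
# Benjamini-Hochberg q-values serve the relative-risk pathway.

#' Permutation settings
#'
#' @param n_permutations Monte-Carlo permutations (default 1000).
#' @param percentile_q Percentile (on the t scale, in (0, 50\]) of the
#'   valid-voxel statistic recorded per permutation in `perm_percentile`
#'   mode. The default 5 is the "Perm95" setting: the 5th percentile of a
#'   left-tailed statistic is the 95th percentile of extremeness.
#' @param mode One of `"perm_percentile"` (Perm95), `"min_stat"` (strict
#'   FWE via the per-permutation minimum), `"per_voxel"` (uncorrected
#'   per-voxel permutation test).
#' @param alpha_levels Significance cutoffs, default `c(0.05, 0.2)` — the
#'   statistical and "clinically significant" thresholds.
#' @param seed Integer seed for the permutation stream.
#' @param exhaustive_limit If the number of distinct group assignments
#'   `choose(N, n_affected)` is at most this, all assignments are
#'   enumerated instead of sampled (default 20000; set 0 to force
#'   Monte-Carlo).
#' @param interpolate Percentile computed with linear interpolation between
#'   order statistics (default); `FALSE` uses nearest-rank.
#' @return Object of class `perm_config`.
#' @export
perm_config <- function(n_permutations = 1000, percentile_q = 5,
                        mode = c("perm_percentile", "min_stat", "per_voxel"),
                        alpha_levels = c(0.05, 0.2), seed = 1,
                        exhaustive_limit = 20000, interpolate = TRUE) {
  mode <- match.arg(mode)
  .check_number(n_permutations, "n_permutations", lower = 1, integer = TRUE)
  .check_number(percentile_q, "percentile_q", lower = 0, upper = 50,
                open_lower = TRUE)
  if (length(alpha_levels) < 1 || any(alpha_levels <= 0 | alpha_levels >= 1))
    .stop_validation("`alpha_levels` must lie in (0, 1)")
  .check_number(seed, "seed", integer = TRUE)
  .check_number(exhaustive_limit, "exhaustive_limit", lower = 0,
                integer = TRUE)
  structure(list(n_permutations = as.integer(n_permutations),
                 percentile_q = percentile_q, mode = mode,
                 alpha_levels = as.numeric(alpha_levels),
                 seed = as.integer(seed),
                 exhaustive_limit = as.integer(exhaustive_limit),
                 interpolate = isTRUE(interpolate)),
            class = "perm_config")
}

#' Generate group-label permutations
#'
#' Produces size-preserving reassignments of the affected/control labels.
#' When the number of distinct assignments `choose(N, n_affected)` does not
#' exceed `exhaustive_limit`, the full enumeration is returned (including
#' the identity assignment); otherwise `k` independent uniform draws.
#'
#' @param n_total Number of subjects.
#' @param n_affected Affected-group size.
#' @param k Monte-Carlo permutation count.
#' @param seed Integer seed.
#' @param exhaustive_limit Enumeration cutoff (see [perm_config()]).
#' @return List: `Z` (0/1 matrix, subjects x assignments, 1 = affected),
#'   `exhaustive` flag, `n_assignments`.
#' @export
permute_labels <- function(n_total, n_affected, k, seed = 1,
                           exhaustive_limit = 20000) {
  .check_number(n_total, "n_total", lower = 2, integer = TRUE)
  .check_number(n_affected, "n_affected", lower = 1, upper = n_total - 1,
                integer = TRUE)
  n_distinct <- choose(n_total, n_affected)
  if (n_distinct <= exhaustive_limit) {
    sets <- combn(n_total, n_affected)
    Z <- matrix(0, n_total, ncol(sets))
    Z[cbind(as.vector(sets), rep(seq_len(ncol(sets)), each = n_affected))] <- 1
    return(list(Z = Z, exhaustive = TRUE, n_assignments = ncol(sets)))
  }
  Z <- .with_seed(seed, {
    m <- matrix(0, n_total, k)
    for (j in seq_len(k)) m[sample.int(n_total, n_affected), j] <- 1
    m
  })
  list(Z = Z, exhaustive = FALSE, n_assignments = as.integer(k))
}

# Per-permutation whole-brain summaries (minimum and q-th percentile of the
# valid-voxel statistic), chunked to bound memory.
.null_summaries <- function(Y, affected_obs, Z, statistic, percentile_q,
                            interpolate, var_equal = TRUE) {
  n_a <- sum(affected_obs); n_c <- length(affected_obs) - n_a
  Y2 <- if (statistic == "t") Y^2 else NULL
  k <- ncol(Z)
  mins <- numeric(k); pcts <- numeric(k)
  type <- if (interpolate) 7 else 1
  chunk <- max(1L, min(k, floor(2e7 / max(1, nrow(Y)))))
  for (s in seq(1, k, by = chunk)) {
    j <- s:min(k, s + chunk - 1)
    S <- if (statistic == "t")
      .t_engine(Y, Y2, Z[, j, drop = FALSE], n_a, n_c, var_equal)
    else
      .rr_engine(Y, Z[, j, drop = FALSE], n_a, n_c)
    fin <- is.finite(S)
    for (jj in seq_along(j)) {
      v <- S[fin[, jj], jj]
      if (length(v) == 0L)
        .stop_validation("permutation %d: no valid voxel", j[jj])
      mins[j[jj]] <- min(v)
      pcts[j[jj]] <- quantile(v, percentile_q / 100, type = type,
                              names = FALSE)
    }
  }
  list(min = mins, pct = pcts)
}

#' Build the permutation null distribution of a whole-brain summary
#'
#' For each permuted labeling, recomputes the voxelwise statistic map and
#' records a whole-brain summary of its valid voxels: the minimum
#' (`min_stat` mode — strict FWE control) or the `percentile_q`-th
#' percentile (`perm_percentile` mode — the Perm95 null). The histogram of
#' these summaries is the empirical null against which observed voxel
#' values are compared by [p_map_fwe()].
#'
#' @param cohort A [lesion_cohort()].
#' @param groups A `vlsm_groups` grouping.
#' @param config A [perm_config()]; its `mode` must be a family-wise mode.
#' @param statistic `"t"`: the whole-brain summaries (minimum, low
#'   percentile) encode the left-tailed t alternative, so the family-wise
#'   pathway is defined on the t map; use [p_map_pervoxel()] for the
#'   relative risk.
#' @param perms Optional precomputed [permute_labels()] result, allowing
#'   several null modes to share one permutation stream.
#' @param var_equal Passed to the t engine.
#' @param rr_threshold Binarization threshold for `statistic = "rr"`.
#' @return Object of class `null_distribution`: `summary_values`, `mode`,
#'   `percentile_q`, `n_permutations`, `exhaustive`, `statistic`,
#'   `group_sizes`, `seed`.
#' @export
build_null <- function(cohort, groups, config, statistic = "t",
                       perms = NULL, var_equal = TRUE, rr_threshold = 0.03) {
  statistic <- match.arg(statistic, "t")
  stopifnot(inherits(config, "perm_config"))
  if (config$mode == "per_voxel")
    .stop_validation("build_null is for family-wise modes; use p_map_pervoxel")
  inp <- .stat_input(cohort, groups, statistic, rr_threshold)
  if (sum(rowSums(inp$Y != 0) > 0) < 2L)
    .stop_validation("need >= 2 voxels with signal to build a null")
  if (is.null(perms))
    perms <- permute_labels(ncol(inp$Y), inp$n_a, config$n_permutations,
                            seed = .derive_seed(config$seed, "perm"),
                            exhaustive_limit = config$exhaustive_limit)
  sm <- .null_summaries(inp$Y, inp$affected, perms$Z, statistic,
                        config$percentile_q, config$interpolate, var_equal)
  vals <- if (config$mode == "min_stat") sm$min else sm$pct
  structure(list(summary_values = vals, mode = config$mode,
                 percentile_q = config$percentile_q,
                 n_permutations = perms$n_assignments,
                 exhaustive = perms$exhaustive, statistic = statistic,
                 group_sizes = c(inp$n_a, inp$n_c), seed = config$seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "Permutation null (%s%s, %s): %d %s, summary range %.3g .. %.3g\n",
    x$mode,
    if (x$mode == "perm_percentile") sprintf(" q=%g", x$percentile_q) else "",
    x$statistic, x$n_permutations,
    if (x$exhaustive) "exhaustive assignments" else "Monte-Carlo permutations",
    min(x$summary_values), max(x$summary_values)))
  invisible(x)
}

.new_pvalue_map <- function(p_vec_on_valid, template_map, method,
                            null = NULL) {
  vals <- array(NaN, template_map$space$grid_shape)
  vals[template_map$valid] <- p_vec_on_valid
  structure(list(values = vals, valid = template_map$valid, method = method,
                 statistic = template_map$statistic,
                 group_sizes = template_map$group_sizes,
                 null = null, space = template_map$space),
            class = "pvalue_map")
}

#' @export
print.pvalue_map <- function(x, ...) {
  v <- x$values[x$valid]
  cat(sprintf("p/q map (%s): %d valid voxels, min %.4g, %d below 0.05\n",
              x$method, length(v), suppressWarnings(min(v)), sum(v < 0.05)))
  invisible(x)
}

#' Family-wise p-value map from a whole-brain null
#'
#' Compares each observed valid-voxel statistic with the null histogram of
#' whole-brain summaries. The test is left-tailed in t (more negative =
#' more extreme). In Monte-Carlo mode `p = (1 + #{summary <= t_obs}) /
#' (n_perm + 1)`, never zero; in exhaustive mode `p = #{summary <= t_obs} /
#' n_assignments` with the identity assignment among them. Ties count as
#' extreme.
#'
#' @param observed The observed `stat_map` (same cohort/groups/statistic as
#'   the null).
#' @param null A `null_distribution` from [build_null()].
#' @return A `pvalue_map`.
#' @export
p_map_fwe <- function(observed, null) {
  stopifnot(inherits(observed, "stat_map"),
            inherits(null, "null_distribution"))
  if (observed$statistic == "t" && null$statistic != "t" ||
      observed$statistic == "relative_risk" && null$statistic != "rr")
    .stop_validation("null was built for statistic `%s`, map is `%s`",
                     null$statistic, observed$statistic)
  if (!identical(unname(observed$group_sizes), unname(null$group_sizes)))
    .stop_validation("group sizes of map (%s) and null (%s) differ",
                     paste(observed$group_sizes, collapse = "v"),
                     paste(null$group_sizes, collapse = "v"))
  s <- sort(null$summary_values)
  tv <- observed$values[observed$valid]
  cnt <- findInterval(tv, s)   # #{summary <= t_obs}, ties included
  p <- if (null$exhaustive) cnt / null$n_permutations
       else (1 + cnt) / (null$n_permutations + 1)
  method <- if (null$mode == "min_stat") "min_stat_fwe" else
    sprintf("perm%g_fwe", 100 - null$percentile_q)
  .new_pvalue_map(p, observed, method, null = null)
}

#' Per-voxel (uncorrected) permutation p-value map
#'
#' Permutes group labels and compares each voxel's statistic only with its
#' own permutation distribution. For the relative risk the alternative is a
#' larger RR in the affected group (right tail); for t it is a more
#' negative t (left tail). Ties count toward the tail and `+Inf` compares
#' as extreme as `+Inf`. Monte-Carlo p-values use the (+1)/(+1) correction;
#' exhaustive enumeration divides by the assignment count (identity
#' included).
#'
#' @param cohort A [lesion_cohort()].
#' @param groups A `vlsm_groups` grouping.
#' @param config A [perm_config()].
#' @param statistic `"rr"` (default, the classical per-voxel pathway) or
#'   `"t"`.
#' @param rr_threshold Binarization threshold for the RR statistic.
#' @param var_equal Passed to the t engine.
#' @return A `pvalue_map` (method `"per_voxel_perm"`); its `observed` field
#'   carries the observed `stat_map`.
#' @export
p_map_pervoxel <- function(cohort, groups, config, statistic = c("rr", "t"),
                           rr_threshold = 0.03, var_equal = TRUE) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(config, "perm_config"))
  inp <- .stat_input(cohort, groups, statistic, rr_threshold)
  obs_map <- if (statistic == "rr")
    rr_map(cohort, groups, threshold = rr_threshold)
  else t_map(cohort, groups, var_equal = var_equal)
  perms <- permute_labels(ncol(inp$Y), inp$n_a, config$n_permutations,
                          seed = .derive_seed(config$seed, "perm"),
                          exhaustive_limit = config$exhaustive_limit)
  keep <- obs_map$valid[cohort$space$brain_mask]
  Y <- inp$Y[keep, , drop = FALSE]
  Y2 <- if (statistic == "t") Y^2 else NULL
  obs <- obs_map$values[obs_map$valid]
  k <- ncol(perms$Z)
  cnt <- numeric(length(obs))
  chunk <- max(1L, min(k, floor(2e7 / max(1, nrow(Y)))))
  for (s in seq(1, k, by = chunk)) {
    j <- s:min(k, s + chunk - 1)
    S <- if (statistic == "t")
      .t_engine(Y, Y2, perms$Z[, j, drop = FALSE], inp$n_a, inp$n_c,
                var_equal)
    else
      .rr_engine(Y, perms$Z[, j, drop = FALSE], inp$n_a, inp$n_c)
    ex <- if (statistic == "rr") S >= obs else S <= obs
    ex[is.na(ex)] <- FALSE   # degenerate permutation statistic: not counted
    cnt <- cnt + rowSums(ex)
  }
  p <- if (perms$exhaustive) cnt / perms$n_assignments
       else (1 + cnt) / (perms$n_assignments + 1)
  out <- .new_pvalue_map(p, obs_map, "per_voxel_perm")
  out$observed <- obs_map
  out$exhaustive <- perms$exhaustive
  out$n_permutations <- perms$n_assignments
  out
}

#' Parametric one-sided t p-value map
#'
#' Student-t left-tail p-values for an observed t map, with
#' `n_a + n_c - 2` degrees of freedom — the parametric comparison surface
#' for the permutation maps.
#'
#' @param observed A `stat_map` with `statistic = "t"`.
#' @return A `pvalue_map` (method `"parametric_t"`).
#' @export
p_map_parametric <- function(observed) {
  stopifnot(inherits(observed, "stat_map"))
  if (observed$statistic != "t")
    .stop_validation("parametric p-values are defined for t maps only")
  df <- sum(observed$group_sizes) - 2
  p <- pt(observed$values[observed$valid], df = df)
  .new_pvalue_map(p, observed, "parametric_t")
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR-adjusted values over the valid voxels of a p-value map:
#' after sorting, `q(i) = min_{j >= i} p(j) * m / j`, clipped at 1.
#'
#' @param pmap A `pvalue_map`.
#' @return A `pvalue_map` with method `"bh_fdr"`.
#' @export
q_values <- function(pmap) {
  stopifnot(inherits(pmap, "pvalue_map"))
  p <- pmap$values[pmap$valid]
  if (length(p) == 0L) .stop_validation("no valid voxels")
  q <- p.adjust(p, method = "BH")
  out <- .new_pvalue_map(q, pmap, "bh_fdr")
  out$source_method <- pmap$method
  out
}

#' Threshold a p/q map into a significance mask
#'
#' A voxel is significant where its value is strictly below `alpha` and the
#' voxel is valid.
#'
#' @param pmap A `pvalue_map`.
#' @param alpha Cutoff in (0, 1).
#' @return Object of class `sig_mask`: logical `mask`, `alpha`, `method`,
#'   `space`.
#' @export
threshold_map <- function(pmap, alpha) {
  stopifnot(inherits(pmap, "pvalue_map"))
  .check_number(alpha, "alpha", lower = 0, upper = 1, open_lower = TRUE,
                open_upper = TRUE)
  m <- pmap$valid & !is.na(pmap$values) & pmap$values < alpha
  m[is.na(m)] <- FALSE
  structure(list(mask = m, alpha = alpha, method = pmap$method,
                 space = pmap$space),
            class = "sig_mask")
}

#' @export
print.sig_mask <- function(x, ...) {
  cat(sprintf("Significance mask (%s, alpha=%g): %d voxels\n",
              x$method, x$alpha, sum(x$mask)))
  invisible(x)
}
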