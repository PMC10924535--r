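# Observed voxelwise statistics: pooled-variance two-sample t maps on fuzzy
# tumor probabilities, and relative-risk maps on thresholded masks. The
# shared matrix engine also serves the permutation machinery, evaluating
# many relabelings at once as dense matrix products.

.VAR_TOL <- 1e-10  # below this SE a voxel has (numerically) zero variance

# t statistics for each column of the 0/1 affected-indicator matrix Z.
# Y: voxels x subjects (restricted to in-group subjects), Y2 = Y^2.
# Sign convention: t = (mean_control - mean_affected)/SE, so excess tumor
# probability in the affected group gives negative t.
.t_engine <- function(Y, Y2, Z, n_a, n_c, var_equal = TRUE) {
  SA <- Y %*% Z
  QA <- Y2 %*% Z
  SC <- rowSums(Y) - SA
  QC <- rowSums(Y2) - QA
  ma <- SA / n_a
  mc <- SC / n_c
  ssa <- pmax(QA - SA^2 / n_a, 0)
  ssc <- pmax(QC - SC^2 / n_c, 0)
  se <- if (var_equal) {
    sqrt((ssa + ssc) / (n_a + n_c - 2) * (1 / n_a + 1 / n_c))
  } else {
    sqrt(ssa / (n_a - 1) / n_a + ssc / (n_c - 1) / n_c)
  }
  t <- (mc - ma) / se
  t[se < .VAR_TOL] <- NaN
  t
}

# Relative risk for each relabeling column: ratio of tumor-positive
# proportions, affected over control. B: voxels x subjects 0/1.
.rr_engine <- function(B, Z, n_a, n_c) {
  A <- B %*% Z
  C <- rowSums(B) - A
  rr <- (A * n_c) / (C * n_a)       # C=0, A>0 -> Inf (kept); 0/0 -> NaN
  rr[rowSums(B) == 0, ] <- NaN      # no tumor in anyone: undefined
  rr
}

# Shared preparation: in-group subject matrix on brain-mask voxels.
.stat_input <- function(cohort, groups, statistic, rr_threshold = 0.03,
                        min_per_group = 2L) {
  stopifnot(inherits(cohort, "lesion_cohort"))
  if (!inherits(groups, "vlsm_groups"))
    .stop_validation("`groups` must be a `vlsm_groups` object")
  if (length(groups$affected) == 0L || length(groups$control) == 0L)
    .stop_validation("both groups must be non-empty")
  if (length(groups$affected) < min_per_group ||
      length(groups$control) < min_per_group)
    .stop_validation(
      "insufficient data: each group needs >= %d subjects (got %d vs %d)",
      min_per_group, length(groups$affected), length(groups$control))
  ind <- .group_indicator(cohort, groups)
  Y <- .cohort_matrix(cohort)[, ind$in_groups, drop = FALSE]
  aff <- ind$affected[ind$in_groups]
  if (statistic == "rr") {
    .check_number(rr_threshold, "rr_threshold", lower = 0, upper = 1,
                  open_lower = TRUE, open_upper = TRUE)
    Y <- (Y >= rr_threshold) + 0  # closed lower bound: prob == threshold counts
  }
  list(Y = Y, affected = aff, n_a = sum(aff), n_c = sum(!aff))
}

.new_stat_map <- function(values_vec, space, statistic, group_sizes,
                          rr_threshold = NULL) {
  vals <- array(NaN, space$grid_shape)
  vals[space$brain_mask] <- values_vec
  # +Inf (relative risk with zero control count) is a defined, valid value;
  # only NaN marks an undefined statistic
  valid <- !is.nan(vals) & space$brain_mask
  vals[!valid] <- NaN
  structure(list(values = vals, valid = valid, statistic = statistic,
                 group_sizes = group_sizes, rr_threshold = rr_threshold,
                 space = space),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  v <- x$values[x$valid]
  cat(sprintf(
    "%s map: %d valid voxels (of %d in mask), range %.3g .. %.3g\n",
    x$statistic, sum(x$valid), sum(x$space$brain_mask),
    suppressWarnings(min(v)), suppressWarnings(max(v))))
  cat(sprintf("  groups: %d affected vs %d control\n",
              x$group_sizes[1], x$group_sizes[2]))
  invisible(x)
}

#' Voxelwise two-sample t map
#'
#' At every brain-mask voxel, compares the distribution of fuzzy tumor
#' probabilities between the affected and control groups with a
#' pooled-variance two-sample t statistic, signed so that greater tumor
#' probability in the affected group yields negative t (the one-sided
#' alternative of interest). Voxels with zero pooled variance (e.g. no
#' lesion in any subject) are marked invalid.
#'
#' @param cohort A [lesion_cohort()].
#' @param groups A `vlsm_groups` grouping; both groups need >= 2 subjects.
#' @param var_equal If `FALSE`, use the Welch (unpooled) statistic.
#' @return A `stat_map` (fields `values`, `valid`, `statistic`,
#'   `group_sizes`, `space`).
#' @export
t_map <- function(cohort, groups, var_equal = TRUE) {
  inp <- .stat_input(cohort, groups, "t")
  Z <- matrix(inp$affected + 0, ncol = 1)
  t <- .t_engine(inp$Y, inp$Y^2, Z, inp$n_a, inp$n_c, var_equal)
  .new_stat_map(t[, 1], cohort$space, "t", c(inp$n_a, inp$n_c))
}

#' Voxelwise relative-risk map
#'
#' Binarizes each subject's fuzzy lesion map at `threshold` (probability >=
#' threshold counts as tumor-positive) and computes, per voxel, the ratio of
#' tumor-positive proportions, affected over control. A voxel with positive
#' affected count but zero control count is recorded as `+Inf` and stays
#' valid; a voxel with no tumor-positive subject at all is invalid.
#'
#' @param cohort A [lesion_cohort()].
#' @param groups A `vlsm_groups` grouping.
#' @param threshold Binarization threshold in (0, 1); default 0.03.
#' @return A `stat_map` with `statistic = "relative_risk"`.
#' @export
rr_map <- function(cohort, groups, threshold = 0.03) {
  inp <- .stat_input(cohort, groups, "rr", rr_threshold = threshold)
  Z <- matrix(inp$affected + 0, ncol = 1)
  rr <- .rr_engine(inp$Y, Z, inp$n_a, inp$n_c)
  .new_stat_map(rr[, 1], cohort$space, "relative_risk",
                c(inp$n_a, inp$n_c), rr_threshold = threshold)
}
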