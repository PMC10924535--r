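# Shared fixtures and independent oracles, built in code at test time.

# Template space with an all-brain mask (simplest valid space).
full_space <- function(d = c(5, 5, 5)) {
  template_space(array(TRUE, d))
}

# Cohort whose brain-voxel x subject matrix equals `m` (values in [0,1]).
cohort_from_matrix <- function(m, d = c(5, 5, 5), space = NULL,
                               ids = sprintf("S%02d", seq_len(ncol(m)))) {
  space <- if (is.null(space)) full_space(d) else space
  vols <- lapply(seq_len(ncol(m)), function(i) {
    v <- array(0, space$grid_shape)
    v[space$brain_mask] <- m[, i]
    v
  })
  lesion_cohort(vols, ids, space)
}

# Random fuzzy lesion-like cohort: smoothed random blobs, values in [0,1].
random_cohort <- function(n_subjects, d = c(8, 8, 8), seed = 1,
                          space = NULL) {
  space <- if (is.null(space)) full_space(d) else space
  withr::with_seed(seed, {
    vols <- lapply(seq_len(n_subjects), function(i) {
      v <- array(0, space$grid_shape)
      ctr <- sapply(space$grid_shape, function(k) sample.int(k, 1))
      g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                       z = seq_len(d[3]))
      dist2 <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2
      v[] <- exp(-dist2 / (2 * runif(1, 1.5, 3)^2))
      v[!space$brain_mask] <- 0
      v
    })
    lesion_cohort(vols, sprintf("S%02d", seq_len(n_subjects)), space)
  })
}

# Oracle: per-voxel pooled/Welch two-sample t via stats::t.test, with the
# package's sign convention t = (mean_control - mean_affected)/SE.
oracle_t <- function(values_affected, values_control, var_equal = TRUE) {
  if (stats::sd(c(values_affected, values_control)) == 0) return(NaN)
  out <- tryCatch(
    stats::t.test(values_control, values_affected,
                  var.equal = var_equal)$statistic,
    error = function(e) NaN)
  unname(out)
}

# Oracle: relative risk by direct counting.
oracle_rr <- function(values_affected, values_control, threshold) {
  a <- sum(values_affected >= threshold)
  c <- sum(values_control >= threshold)
  if (a == 0 && c == 0) return(NaN)
  (a / length(values_affected)) / (c / length(values_control))
}

# Oracle: full enumeration of group assignments with per-assignment
# whole-brain summary (min or percentile of valid-voxel oracle t values).
# Returns the summary vector, one entry per assignment (identity included).
oracle_null_summaries <- function(m, n_affected, mode = "min",
                                  percentile_q = 5) {
  n <- ncol(m)
  sets <- utils::combn(n, n_affected)
  apply(sets, 2, function(aff_idx) {
    aff <- seq_len(n) %in% aff_idx
    tv <- apply(m, 1, function(row) oracle_t(row[aff], row[!aff]))
    tv <- tv[is.finite(tv)]
    if (mode == "min") min(tv)
    else unname(stats::quantile(tv, percentile_q / 100, type = 7))
  })
}

# Oracle: exhaustive per-voxel permutation p-values (right tail, RR).
oracle_pervoxel_rr_p <- function(m, n_affected, threshold) {
  n <- ncol(m)
  sets <- utils::combn(n, n_affected)
  aff_obs <- seq_len(n) <= n_affected
  apply(m, 1, function(row) {
    obs <- oracle_rr(row[aff_obs], row[!aff_obs], threshold)
    if (is.nan(obs)) return(NA_real_)
    stat <- apply(sets, 2, function(aff_idx) {
      aff <- seq_len(n) %in% aff_idx
      oracle_rr(row[aff], row[!aff], threshold)
    })
    sum(stat >= obs) / ncol(sets)
  })
}

# Oracle: Benjamini-Hochberg step-up by the textbook recipe.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}
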