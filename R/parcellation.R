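# Atlas parcels: mapping significant voxels onto named cortical/subcortical
# regions, percentage-involvement tables, top-N ranking and heatmap
# matrices.

#' Parcel atlas
#'
#' An integer-labelled volume (0 = background) on the template grid plus a
#' parcel table naming each label.
#'
#' @param labels Integer 3D array; labels confined to the brain mask.
#' @param parcel_table data.frame with columns `label`, `name`,
#'   `hemisphere`, `class` (`"cortical"`/`"subcortical"`); every nonzero
#'   label in `labels` must appear.
#' @param space A [template_space()].
#' @return Object of class `parcel_atlas`.
#' @export
parcel_atlas <- function(labels, parcel_table, space) {
  .check_space(space)
  .check_grid(labels, space, "atlas")
  labels <- array(as.integer(labels), dim(labels))
  if (any(labels[!space$brain_mask] != 0))
    .stop_validation("atlas labels extend outside the brain mask")
  used <- sort(unique(labels[labels > 0]))
  need <- c("label", "name", "class")
  if (!all(need %in% names(parcel_table)))
    .stop_validation("parcel table needs columns %s",
                     paste(need, collapse = ", "))
  miss <- setdiff(used, parcel_table$label)
  if (length(miss))
    .stop_validation("labels missing from parcel table: %s",
                     paste(miss, collapse = ", "))
  if (anyDuplicated(parcel_table$label))
    .stop_validation("duplicated labels in parcel table")
  structure(list(labels = labels,
                 parcel_table = parcel_table[order(parcel_table$label), ,
                                             drop = FALSE],
                 space = space),
            class = "parcel_atlas")
}

#' @export
print.parcel_atlas <- function(x, ...) {
  cat(sprintf("Parcel atlas: %d parcels (%d cortical, %d subcortical), %s grid\n",
              nrow(x$parcel_table), sum(x$parcel_table$class == "cortical"),
              sum(x$parcel_table$class == "subcortical"),
              paste(x$space$grid_shape, collapse = "x")))
  invisible(x)
}

#' Save / load a parcel atlas (integer NIfTI + CSV parcel table)
#'
#' @param atlas A [parcel_atlas()].
#' @param nifti_path,csv_path Output paths.
#' @export
save_atlas <- function(atlas, nifti_path, csv_path) {
  stopifnot(inherits(atlas, "parcel_atlas"))
  RNifti::writeNifti(.nifti_from(atlas$labels, atlas$space), nifti_path,
                     datatype = "int16")
  write.csv(atlas$parcel_table, csv_path, row.names = FALSE)
  invisible(nifti_path)
}

#' @rdname save_atlas
#' @param space Template space the atlas must match.
#' @export
load_atlas <- function(nifti_path, csv_path, space) {
  lab <- .read_volume(nifti_path)$data
  tab <- read.csv(csv_path, stringsAsFactors = FALSE)
  parcel_atlas(lab, tab, space)
}

#' Per-parcel coverage by significant voxels
#'
#' For every parcel, the percentage of its voxels that are significant:
#' `100 * |sig intersect parcel| / |parcel|`. Parcels with no significant
#' voxel are retained at 0%. Mask voxels carrying no parcel label are
#' reported in a residual `<unparcellated>` row so that voxel conservation
#' is auditable.
#'
#' @param sig A `sig_mask` (from [threshold_map()]) or logical 3D array.
#' @param atlas A [parcel_atlas()].
#' @param domain Domain tag recorded in the table.
#' @param alpha Alpha tag recorded in the table (taken from `sig` if it is
#'   a `sig_mask`).
#' @return data.frame of class `parcel_coverage`: `domain`, `label`,
#'   `parcel`, `hemisphere`, `class`, `parcel_voxels`,
#'   `significant_voxels`, `coverage_percent`, `alpha_used`.
#' @export
parcel_coverage <- function(sig, atlas, domain = NA_character_,
                            alpha = NA_real_) {
  stopifnot(inherits(atlas, "parcel_atlas"))
  if (inherits(sig, "sig_mask")) {
    if (is.na(alpha)) alpha <- sig$alpha
    sig <- sig$mask
  }
  .check_grid(sig, atlas$space, "significance mask")
  lab <- atlas$labels
  tab <- atlas$parcel_table
  nlev <- max(tab$label)
  par_n <- tabulate(lab[lab > 0], nbins = nlev)[tab$label]
  sig_n <- tabulate(lab[sig & lab > 0], nbins = nlev)[tab$label]
  res_par <- sum(atlas$space$brain_mask & lab == 0)
  res_sig <- sum(sig & atlas$space$brain_mask & lab == 0)
  out <- data.frame(
    domain = domain,
    label = c(tab$label, 0L),
    parcel = c(tab$name, "<unparcellated>"),
    hemisphere = c(if (!is.null(tab$hemisphere)) tab$hemisphere else
      rep(NA_character_, nrow(tab)), NA_character_),
    class = c(tab$class, "residual"),
    parcel_voxels = c(par_n, res_par),
    significant_voxels = c(sig_n, res_sig),
    alpha_used = alpha,
    stringsAsFactors = FALSE
  )
  out$coverage_percent <- ifelse(out$parcel_voxels > 0,
                                 100 * out$significant_voxels /
                                   out$parcel_voxels, 0)
  class(out) <- c("parcel_coverage", "data.frame")
  out
}

#' Top-N parcels by coverage
#'
#' Ranks parcels by `coverage_percent` descending, breaking ties by parcel
#' size (descending) then label (ascending), and returns the first `n`.
#' The residual `<unparcellated>` row is excluded from ranking.
#'
#' @param coverage A `parcel_coverage` table.
#' @param n Number of parcels to report (default 15).
#' @return The ranked head of the table.
#' @export
top_parcels <- function(coverage, n = 15) {
  .check_number(n, "n", lower = 1, integer = TRUE)
  cov <- coverage[coverage$label != 0L, , drop = FALSE]
  ord <- order(-cov$coverage_percent, -cov$parcel_voxels, cov$label)
  head(cov[ord, , drop = FALSE], n)
}

#' Parcel x domain coverage heatmap matrix
#'
#' Combines one coverage table per domain into a matrix whose rows are the
#' union of each domain's top-`top_n` parcels of the requested atlas class
#' (for cortical atlases the field convention shows the top 40; subcortical
#' parcels are all shown), ordered by each parcel's maximum coverage across
#' domains; cells hold `coverage_percent` (missing parcels 0).
#'
#' @param tables Named list of `parcel_coverage` tables, one per domain.
#' @param class_filter `"cortical"`, `"subcortical"` or `"all"`.
#' @param top_n Per-domain parcel cutoff; default 40 for cortical, `Inf`
#'   for subcortical.
#' @return Numeric matrix (parcels x domains) with parcel names as
#'   rownames; attribute `"labels"` holds the parcel labels.
#' @export
heatmap_matrix <- function(tables, class_filter = c("cortical",
                                                    "subcortical", "all"),
                           top_n = NULL) {
  class_filter <- match.arg(class_filter)
  if (is.null(top_n)) top_n <- if (class_filter == "cortical") 40 else Inf
  stopifnot(length(tables) >= 1)
  if (is.null(names(tables)))
    names(tables) <- vapply(tables, function(t) as.character(t$domain[1]),
                            character(1))
  ref <- tables[[1]][tables[[1]]$label != 0L,
                     c("label", "parcel", "class")]
  keep_rows <- integer(0)
  for (tab in tables) {
    t0 <- tab[tab$label != 0L, , drop = FALSE]
    if (!identical(sort(t0$label), sort(ref$label)))
      .stop_validation("coverage tables use inconsistent atlases")
    if (class_filter != "all")
      t0 <- t0[t0$class == class_filter, , drop = FALSE]
    tp <- top_parcels(t0, n = min(top_n, nrow(t0)))
    keep_rows <- union(keep_rows, tp$label)
  }
  mat <- sapply(tables, function(tab) {
    t0 <- tab[tab$label != 0L, , drop = FALSE]
    setNames(t0$coverage_percent, t0$label)[as.character(keep_rows)]
  })
  mat <- matrix(mat, nrow = length(keep_rows),
                dimnames = list(ref$parcel[match(keep_rows, ref$label)],
                                names(tables)))
  mat[is.na(mat)] <- 0
  ord <- order(-apply(mat, 1, max))
  mat <- mat[ord, , drop = FALSE]
  attr(mat, "labels") <- keep_rows[ord]
  mat
}

#' Plot a parcel coverage heatmap
#'
#' Base-graphics rendering of a [heatmap_matrix()]: parcels on the y axis,
#' domains on the x axis, cell colour = percentage coverage.
#'
#' @param mat Matrix from [heatmap_matrix()].
#' @param main Plot title.
#' @export
plot_parcel_heatmap <- function(mat, main = "Parcel coverage (%)") {
  m <- mat[rev(seq_len(nrow(mat))), , drop = FALSE]
  op <- par(mar = c(6, 10, 3, 2))
  on.exit(par(op))
  image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m),
        col = hcl.colors(64, "YlOrRd", rev = TRUE),
        zlim = c(0, max(mat, 1)), axes = FALSE, xlab = "", ylab = "")
  axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
       cex.axis = 0.8)
  axis(2, at = seq_len(nrow(m)), labels = rownames(m), las = 2,
       cex.axis = 0.7)
  title(main)
  box()
  invisible(mat)
}
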