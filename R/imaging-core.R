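# Imaging core: the template-space data contract and NIfTI/CSV plumbing.
# All statistics are computed in voxel (array) space; geometric orientation
# travels with the NIfTI affine but never influences results.

#' Template space
#'
#' Defines the common grid every analyzed volume must share: grid shape,
#' voxel size (mm, default 1 mm isotropic as for template-registered data)
#' and a brain mask restricting all voxelwise statistics.
#'
#' @param brain_mask Logical 3D array; `TRUE` inside the brain.
#' @param voxel_size Positive numeric triple, mm per voxel.
#' @return An object of class `template_space` with elements `grid_shape`,
#'   `voxel_size` and `brain_mask`.
#' @export
template_space <- function(brain_mask, voxel_size = c(1, 1, 1)) {
  if (!is.array(brain_mask) || length(dim(brain_mask)) != 3L)
    .stop_validation("`brain_mask` must be a 3D array")
  mask <- array(as.logical(brain_mask), dim(brain_mask))
  if (anyNA(mask)) .stop_validation("`brain_mask` contains NA")
  if (!any(mask)) .stop_validation("`brain_mask` has no TRUE voxel")
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    .stop_validation("`voxel_size` must be a positive triple")
  structure(
    list(grid_shape = as.integer(dim(mask)),
         voxel_size = as.numeric(voxel_size),
         brain_mask = mask),
    class = "template_space"
  )
}

#' @export
print.template_space <- function(x, ...) {
  cat(sprintf("Template space: %s grid, %s mm voxels, %d brain voxels\n",
              paste(x$grid_shape, collapse = "x"),
              paste(format(x$voxel_size), collapse = "x"),
              sum(x$brain_mask)))
  invisible(x)
}

.check_space <- function(space) {
  if (!inherits(space, "template_space"))
    .stop_validation("expected a `template_space` object")
  space
}

.check_grid <- function(x, space, what = "volume") {
  if (!.same_grid(dim(x), space$grid_shape))
    .stop_validation("%s grid (%s) does not match template grid (%s)", what,
                     paste(dim(x), collapse = "x"),
                     paste(space$grid_shape, collapse = "x"))
  invisible(x)
}

.check_probability_volume <- function(vol, space, label, tol = 1e-6) {
  .check_grid(vol, space, label)
  inside <- vol[space$brain_mask]
  if (any(!is.finite(inside)))
    .stop_validation("%s has non-finite values inside the brain mask", label)
  rng <- range(vol, na.rm = TRUE)
  if (rng[1] < -tol || rng[2] > 1 + tol)
    .stop_validation(
      "%s has values outside [0,1] beyond tolerance (range %.6g..%.6g)",
      label, rng[1], rng[2])
  # clip roundoff-level excursions only
  vol[vol < 0] <- 0
  vol[vol > 1] <- 1
  vol
}

#' Lesion cohort
#'
#' A stack of per-subject fuzzy lesion volumes on one template grid: the
#' per-voxel "distribution of tumor probabilities across patients" that all
#' voxelwise statistics operate on.
#'
#' @param volumes Either a list of 3D arrays (one per subject) or a 4D array
#'   with subjects along the fourth dimension. Values must lie in
#'   \[0, 1\] (tolerance 1e-6 for roundoff, which is clipped).
#' @param subject_ids Character vector of unique subject identifiers.
#' @param space A [template_space()].
#' @return Object of class `lesion_cohort`: elements `data` (4D array
#'   x,y,z,subject), `subject_ids`, `space`.
#' @export
lesion_cohort <- function(volumes, subject_ids, space) {
  .check_space(space)
  if (is.list(volumes)) {
    if (length(volumes) == 0L) .stop_validation("empty cohort")
    arr <- array(0, c(space$grid_shape, length(volumes)))
    for (i in seq_along(volumes)) arr[, , , i] <- .check_probability_volume(
      volumes[[i]], space, sprintf("volume %d", i))
  } else if (is.array(volumes) && length(dim(volumes)) == 4L) {
    arr <- volumes
    for (i in seq_len(dim(arr)[4])) arr[, , , i] <- .check_probability_volume(
      arr[, , , i], space, sprintf("volume %d", i))
  } else .stop_validation("`volumes` must be a list of 3D arrays or a 4D array")
  n <- dim(arr)[4]
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != n)
    .stop_validation("%d subject ids for %d volumes", length(subject_ids), n)
  if (anyDuplicated(subject_ids))
    .stop_validation("duplicated subject ids: %s",
                     paste(unique(subject_ids[duplicated(subject_ids)]),
                           collapse = ", "))
  structure(list(data = arr, subject_ids = subject_ids, space = space),
            class = "lesion_cohort")
}

#' @export
print.lesion_cohort <- function(x, ...) {
  cat(sprintf("Lesion cohort: %d subjects on a %s grid (%d brain voxels)\n",
              length(x$subject_ids),
              paste(x$space$grid_shape, collapse = "x"),
              sum(x$space$brain_mask)))
  invisible(x)
}

.n_subjects <- function(cohort) length(cohort$subject_ids)

# Brain-mask voxel x subject matrix view of a cohort.
.cohort_matrix <- function(cohort) {
  n <- .n_subjects(cohort)
  m <- matrix(cohort$data, ncol = n)
  m[as.vector(cohort$space$brain_mask), , drop = FALSE]
}

.read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  list(data = arr, pixdim = RNifti::pixdim(img))
}

#' Load a lesion cohort from NIfTI files
#'
#' Reads per-subject fuzzy lesion volumes plus a template brain mask, checks
#' that every volume sits on the mask grid and carries probabilities in
#' \[0, 1\] (values within 1e-6 of the bounds are clipped; anything farther
#' out is an error), and assembles a [lesion_cohort()]. Subject ids default
#' to the file base names.
#'
#' @param volume_paths Character vector of NIfTI file paths (one per subject).
#' @param mask_path NIfTI brain mask path (nonzero = brain).
#' @param subject_ids Optional character vector overriding the default ids.
#' @return A `lesion_cohort`.
#' @export
load_cohort <- function(volume_paths, mask_path, subject_ids = NULL) {
  if (length(volume_paths) == 0L) .stop_validation("no volumes given")
  mk <- .read_volume(mask_path)
  if (length(dim(mk$data)) != 3L)
    .stop_validation("mask `%s` is not a 3D volume", mask_path)
  space <- template_space(mk$data != 0, voxel_size = mk$pixdim[1:3])
  if (is.null(subject_ids))
    subject_ids <- sub("\\.nii(\\.gz)?$", "", basename(volume_paths))
  vols <- vector("list", length(volume_paths))
  for (i in seq_along(volume_paths)) {
    v <- .read_volume(volume_paths[i])$data
    if (!.same_grid(dim(v), space$grid_shape))
      .stop_validation("grid of `%s` (%s) does not match mask grid (%s)",
                       volume_paths[i], paste(dim(v), collapse = "x"),
                       paste(space$grid_shape, collapse = "x"))
    vols[[i]] <- .check_probability_volume(v, space, basename(volume_paths[i]))
  }
  lesion_cohort(vols, subject_ids, space)
}

.nifti_from <- function(values, space) {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- space$voxel_size
  img
}

.sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Save a statistic / p / q map as NIfTI with a JSON sidecar
#'
#' Values are stored as 64-bit floats so finite voxels round-trip
#' bit-identically; invalid voxels are stored as the sentinel `NaN`, which
#' the sidecar documents along with the map's provenance (statistic kind,
#' group sizes, valid-voxel count).
#'
#' @param map A `stat_map`, `pvalue_map` or significance mask (see
#'   [t_map()], [p_map_fwe()], [threshold_map()]).
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
save_map <- function(map, path) {
  if (!inherits(map, c("stat_map", "pvalue_map", "sig_mask")))
    .stop_validation("`map` must be a stat_map, pvalue_map or sig_mask")
  values <- if (inherits(map, "sig_mask")) map$mask + 0 else {
    v <- map$values
    v[!map$valid] <- NaN
    v
  }
  .check_grid(values, map$space, "map")
  if (!dir.exists(dirname(path)))
    stop(sprintf("cannot write map to `%s`: directory does not exist", path),
         call. = FALSE)
  img <- .nifti_from(values, map$space)
  ok <- tryCatch({
    RNifti::writeNifti(img, path, datatype = "double")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop(sprintf("cannot write map to `%s`: %s", path,
                 conditionMessage(ok)), call. = FALSE)
  meta <- list(
    kind = class(map)[1],
    statistic = map$statistic %||% NULL,
    method = map$method %||% NULL,
    group_sizes = map$group_sizes %||% NULL,
    rr_threshold = map$rr_threshold %||% NULL,
    alpha = map$alpha %||% NULL,
    n_valid = if (inherits(map, "sig_mask")) sum(map$mask) else sum(map$valid),
    invalid_sentinel = "NaN"
  )
  .write_json(meta[!vapply(meta, is.null, logical(1))], .sidecar_path(path))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a map written by [save_map()]
#'
#' @param path NIfTI path.
#' @param space Optional [template_space()] the map must match.
#' @return A list with `values` (NaN at invalid voxels), `valid`, `space`
#'   and the sidecar `meta`data (if present).
#' @export
load_map <- function(path, space = NULL) {
  v <- .read_volume(path)
  sp <- space %||% template_space(array(TRUE, dim(v$data)),
                                  voxel_size = v$pixdim[1:3])
  .check_grid(v$data, sp, basename(path))
  sidecar <- .sidecar_path(path)
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL
  list(values = v$data, valid = !is.nan(v$data), space = sp, meta = meta)
}

#' Save a probability volume (or the brain mask) as NIfTI
#'
#' @param values 3D numeric array on the template grid.
#' @param space A [template_space()].
#' @param path Output NIfTI path.
#' @return `path`, invisibly.
#' @export
save_volume <- function(values, space, path) {
  .check_space(space)
  .check_grid(values, space, "volume")
  RNifti::writeNifti(.nifti_from(values, space), path, datatype = "double")
  invisible(path)
}
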