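#' Spatial data model
#'
#' All scalar volumes in the pipeline (frequency shift in Hz, local field,
#' susceptibility in ppb, SUVR, ...) travel as `vol_grid` objects: a 3D numeric
#' array plus voxel spacing in mm. Coordinates are voxel-indexed and 0-based;
#' physical units only enter through `voxel_size_mm`. Masks are plain logical
#' arrays on the same grid; label maps carry an integer array plus a
#' label-to-structure lookup table.
#'
#' @name volume-model
NULL

#' Construct a volume grid
#'
#' @param data 3D numeric array.
#' @param voxel_size_mm Numeric length-3, voxel edge lengths in mm, all > 0.
#' @return A `vol_grid` object.
#' @export
vol_grid <- function(data, voxel_size_mm = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0)) {
    stop("`voxel_size_mm` must be three positive numbers", call. = FALSE)
  }
  structure(
    list(data = data, voxel_size_mm = voxel_size_mm),
    class = "vol_grid"
  )
}

#' @export
print.vol_grid <- function(x, ...) {
  cat(sprintf(
    "<vol_grid> %s voxels @ %s mm, range [%.4g, %.4g]\n",
    paste(dim(x$data), collapse = "x"),
    paste(signif(x$voxel_size_mm, 4), collapse = "x"),
    suppressWarnings(min(x$data, na.rm = TRUE)),
    suppressWarnings(max(x$data, na.rm = TRUE))
  ))
  invisible(x)
}

#' @export
dim.vol_grid <- function(x) dim(x$data)

is_vol_grid <- function(x) inherits(x, "vol_grid")

#' Voxel volume in millilitres
#'
#' @param vol A `vol_grid` or numeric length-3 voxel size in mm.
#' @return Volume of a single voxel in ml.
#' @export
voxel_volume_ml <- function(vol) {
  vs <- if (is_vol_grid(vol)) vol$voxel_size_mm else as.numeric(vol)
  prod(vs) / 1000
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  da <- if (is_vol_grid(a)) dim(a$data) else dim(a)
  db <- if (is_vol_grid(b)) dim(b$data) else dim(b)
  if (!identical(da, db)) {
    stop(sprintf(
      "%s are on different grids: %s vs %s", what,
      paste(da, collapse = "x"), paste(db, collapse = "x")
    ), call. = FALSE)
  }
  if (is_vol_grid(a) && is_vol_grid(b) &&
      any(abs(a$voxel_size_mm - b$voxel_size_mm) > 1e-6)) {
    stop(sprintf("%s have different voxel sizes", what), call. = FALSE)
  }
  invisible(TRUE)
}

#' Canonical brain structure table
#'
#' The fixed label dictionary used by the phantom generator and all ROI
#' operations: subcortical nuclei, four cortical lobes, entorhinal cortex,
#' cerebellar gray, ventricular CSF, white matter and the MPFC seed patch.
#'
#' @return A tibble with columns `label` (integer) and `structure` (character).
#' @export
structure_table <- function() {
  tibble::tibble(
    label = 1:16,
    structure = c(
      "amygdala", "hippocampus", "thalamus", "caudate_nucleus", "putamen",
      "globus_pallidus", "nucleus_accumbens", "entorhinal_cortex",
      "frontal_cortex", "temporal_cortex", "parietal_cortex",
      "occipital_cortex", "cerebellar_gray", "csf_ventricles",
      "white_matter", "mpfc_seed"
    )
  )
}

#' Construct a label map
#'
#' @param data 3D integer array; 0 is background.
#' @param table Data frame with columns `label`, `structure`. Every label in
#'   the table must occur in `data`.
#' @param voxel_size_mm Voxel size in mm.
#' @return A `label_map` object.
#' @export
label_map <- function(data, table = structure_table(), voxel_size_mm = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("label data must be a 3D array", call. = FALSE)
  }
  if (any(data < 0)) stop("labels must be non-negative (0 = background)", call. = FALSE)
  table <- tibble::as_tibble(table)
  present <- sort(unique(as.integer(data[data > 0])))
  missing <- setdiff(table$label, present)
  if (length(missing)) {
    stop(sprintf(
      "labels in table absent from the field: %s",
      paste(table$structure[table$label %in% missing], collapse = ", ")
    ), call. = FALSE)
  }
  structure(
    list(data = data, table = table, voxel_size_mm = as.numeric(voxel_size_mm)),
    class = "label_map"
  )
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf(
    "<label_map> %s voxels, %d structures\n",
    paste(dim(x$data), collapse = "x"), nrow(x$table)
  ))
  invisible(x)
}

#' Logical mask of one named structure
#'
#' @param labels A `label_map`.
#' @param structure Structure name as in `labels$table`.
#' @return Logical array.
#' @export
structure_mask <- function(labels, structure) {
  row <- labels$table[labels$table$structure == structure, ]
  if (nrow(row) == 0L) {
    stop(sprintf("structure '%s' not in label table", structure), call. = FALSE)
  }
  labels$data == row$label[1]
}

#' Read a 3D NIfTI volume
#'
#' @param path Path to a `.nii`/`.nii.gz` file containing a 3D scalar volume.
#' @return A `vol_grid` with voxel sizes taken from the header.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(as.numeric(img), d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L) {
    stop(sprintf(
      "expected a 3D volume, got %dD (%s): %s",
      length(d), paste(d, collapse = "x"), path
    ), call. = FALSE)
  }
  vs <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(vs)) || any(vs <= 0)) {
    stop(sprintf("non-positive voxel size in header of %s", path), call. = FALSE)
  }
  vol_grid(array(as.numeric(img), d), vs)
}

#' Write a volume to NIfTI-1
#'
#' @param vol A `vol_grid`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param datatype Storage type; `"double"` round-trips bit-exactly.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "double") {
  stopifnot(is_vol_grid(vol))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$voxel_size_mm
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a 4D BOLD series
#'
#' @param path NIfTI file with a 4D array (x, y, z, time).
#' @return List with `data` (4D array), `voxel_size_mm`, `tr_s` (repetition
#'   time from the header's 4th pixdim).
#' @export
read_bold <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) {
    stop(sprintf("expected a 4D series, got %dD: %s", length(d), path), call. = FALSE)
  }
  pd <- RNifti::pixdim(img)
  list(
    data = array(as.numeric(img), d),
    voxel_size_mm = pd[1:3],
    tr_s = if (length(pd) >= 4 && is.finite(pd[4]) && pd[4] > 0) pd[4] else NA_real_
  )
}

#' Write a 4D BOLD series
#'
#' @param data 4D array (x, y, z, time).
#' @param path Output path.
#' @param voxel_size_mm Spatial voxel size, mm.
#' @param tr_s Repetition time in seconds, stored in the 4th pixdim.
#' @return `path`, invisibly.
#' @export
write_bold <- function(data, path, voxel_size_mm = c(1, 1, 1), tr_s = 2) {
  stopifnot(length(dim(data)) == 4L)
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- c(voxel_size_mm, tr_s)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a label map from NIfTI plus the canonical structure table
#'
#' @param path NIfTI file of integer labels.
#' @param table Label lookup table (default the canonical one).
#' @return A `label_map`.
#' @export
read_label_map <- function(path, table = structure_table()) {
  vol <- read_volume(path)
  label_map(array(as.integer(round(vol$data)), dim(vol$data)),
            table = table, voxel_size_mm = vol$voxel_size_mm)
}

#' Nearest-neighbour mask resampling between co-registered grids
#'
#' Used to carry a group mask defined on the (coarser) BOLD grid onto the QSM
#' grid. This is a pure resolution change: both grids are assumed to cover the
#' same field of view with aligned axes (synthetic data is generated
#' co-registered; registration is out of scope).
#'
#' @param mask Logical 3D array.
#' @param target_shape Integer length-3 target dimensions.
#' @return Logical array of dimension `target_shape`.
#' @export
resample_mask_nearest <- function(mask, target_shape) {
  stopifnot(length(dim(mask)) == 3L, length(target_shape) == 3L)
  src <- dim(mask)
  idx <- lapply(1:3, function(k) {
    pmin(src[k], pmax(1L, as.integer(ceiling((seq_len(target_shape[k]) - 0.5) *
                                               src[k] / target_shape[k]))))
  })
  mask[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}
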