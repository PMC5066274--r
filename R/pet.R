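#' Compute an SUVR map from late-frame PET activity
#'
#' Voxelwise mean of the late frames, standardized by the cerebellar-gray
#' mean of that average. SUVR is therefore invariant to any global rescaling
#' of activity, and the anchor region has mean exactly 1. A single
#' pre-normalized SUVR volume may be passed as the only frame: normalization
#' is then a validated no-op.
#'
#' @param late_frames A `vol_grid` or list of `vol_grid`s (activity frames).
#' @param labels A `label_map` containing `cerebellar_gray`.
#' @return A `suvr_map`: list with `suvr` (`vol_grid`) and
#'   `normalization_region`.
#' @export
compute_suvr <- function(late_frames, labels) {
  if (is_vol_grid(late_frames)) late_frames <- list(late_frames)
  if (length(late_frames) < 1L) stop("need at least one frame", call. = FALSE)
  for (f in late_frames) stop_if_grid_mismatch(f, late_frames[[1]], "PET frames")
  avg <- Reduce(`+`, lapply(late_frames, function(f) f$data)) / length(late_frames)
  cb <- structure_mask(labels, "cerebellar_gray")
  if (!any(cb)) stop("cerebellar gray label empty", call. = FALSE)
  anchor <- mean(avg[cb])
  if (!is.finite(anchor) || abs(anchor) < 1e-12) {
    stop("cerebellar gray mean activity is zero", call. = FALSE)
  }
  structure(
    list(suvr = vol_grid(avg / anchor, late_frames[[1]]$voxel_size_mm),
         normalization_region = "cerebellar_gray"),
    class = "suvr_map"
  )
}

#' @export
print.suvr_map <- function(x, ...) {
  cat(sprintf("<suvr_map> %s voxels, normalized to %s\n",
              paste(dim(x$suvr$data), collapse = "x"), x$normalization_region))
  invisible(x)
}

#' Cortical composite SUVR score
#'
#' A single measure of cortical amyloid load: the voxel-weighted mean SUVR
#' over the merged (union of) cortical-lobe voxels.
#'
#' @param suvr A `suvr_map` or `vol_grid` of SUVR.
#' @param labels A `label_map`.
#' @param cortical Structure names to merge (default the four lobes).
#' @return Scalar composite SUVR.
#' @export
cortical_composite <- function(suvr, labels,
                               cortical = c("frontal_cortex", "temporal_cortex",
                                            "parietal_cortex", "occipital_cortex")) {
  vol <- if (inherits(suvr, "suvr_map")) suvr$suvr else suvr
  stopifnot(is_vol_grid(vol))
  miss <- setdiff(cortical, labels$table$structure)
  if (length(miss)) {
    stop(sprintf("cortical structures missing from label table: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  ids <- labels$table$label[labels$table$structure %in% cortical]
  m <- array(labels$data %in% ids, dim(labels$data))
  if (!any(m)) stop("cortical union is empty", call. = FALSE)
  mean(vol$data[m])
}
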