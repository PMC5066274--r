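#' Geometric brain phantom label map
#'
#' Places every structure of [structure_table()] as a simple geometric body
#' inside an ellipsoidal intracranial mask: paired ellipsoidal nuclei
#' (amygdala, hippocampus, thalamus, caudate, putamen, globus pallidus,
#' accumbens, entorhinal cortex), a cortical shell split into four lobes,
#' central ventricular CSF, a cerebellar patch, an anterior-medial MPFC seed
#' patch, and white matter filling the remainder. Geometry is defined in
#' normalized coordinates so it scales with the grid; structures are painted
#' in a fixed order into unassigned voxels, which makes labels mutually
#' exclusive by construction. The map is a pure deterministic function of the
#' grid (the `seed` argument is accepted for interface uniformity; anatomy is
#' identical across subjects, mirroring data generated co-registered).
#'
#' For grids of at least 48 voxels per axis every structure occupies at least
#' 50 voxels; smaller grids (>= 12 per axis) are supported for smoke-scale
#' fixtures with proportionally smaller structures.
#'
#' @param shape Integer length-3 grid dimensions (>= 12 per axis).
#' @param voxel_size_mm Voxel size in mm.
#' @param seed Unused; kept so all generators share a signature.
#' @return A `label_map` containing all 16 structures.
#' @export
make_phantom_labels <- function(shape = c(64, 64, 64), voxel_size_mm = c(1, 1, 1),
                                seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 12L)) {
    stop("grid too small to place all structures (need >= 12 voxels per axis)",
         call. = FALSE)
  }
  cx <- (seq_len(shape[1]) - 0.5) / shape[1]
  cy <- (seq_len(shape[2]) - 0.5) / shape[2]
  cz <- (seq_len(shape[3]) - 0.5) / shape[3]
  X <- array(rep(cx, times = shape[2] * shape[3]), shape)
  Y <- array(rep(rep(cy, each = shape[1]), times = shape[3]), shape)
  Z <- array(rep(cz, each = shape[1] * shape[2]), shape)

  ell <- function(center, semi) {
    ((X - center[1]) / semi[1])^2 + ((Y - center[2]) / semi[2])^2 +
      ((Z - center[3]) / semi[3])^2 <= 1
  }
  pair <- function(xoff, center_yz, semi) {
    ell(c(0.5 - xoff, center_yz), semi) | ell(c(0.5 + xoff, center_yz), semi)
  }

  head_semi <- c(0.44, 0.46, 0.40)
  head <- ell(c(0.5, 0.5, 0.5), head_semi)
  inner_factor <- if (min(shape) < 32L) 0.72 else 0.82
  inner <- ell(c(0.5, 0.5, 0.5), head_semi * inner_factor)
  shell <- head & !inner

  lab <- array(0L, shape)
  tab <- structure_table()
  lid <- function(name) tab$label[tab$structure == name]
  paint <- function(name, mask) {
    sel <- mask & head & lab == 0L
    lab[sel] <<- lid(name)
  }

  # deep / discrete structures first (paint order fixes exclusivity)
  paint("csf_ventricles", ell(c(0.5, 0.52, 0.55), c(0.11, 0.14, 0.065)))
  paint("thalamus", pair(0.07, c(0.46, 0.46), c(0.065, 0.075, 0.06)))
  paint("caudate_nucleus", pair(0.13, c(0.60, 0.58), c(0.05, 0.07, 0.05)))
  paint("putamen", pair(0.20, c(0.54, 0.48), c(0.05, 0.08, 0.06)))
  paint("globus_pallidus", pair(0.12, c(0.48, 0.42), c(0.045, 0.055, 0.045)))
  paint("nucleus_accumbens", pair(0.08, c(0.66, 0.40), c(0.045, 0.045, 0.045)))
  paint("amygdala", pair(0.22, c(0.62, 0.33), c(0.05, 0.05, 0.045)))
  paint("hippocampus", pair(0.20, c(0.42, 0.35), c(0.05, 0.09, 0.045)))
  paint("entorhinal_cortex", pair(0.24, c(0.56, 0.26), c(0.05, 0.06, 0.04)))
  paint("cerebellar_gray", ell(c(0.5, 0.26, 0.28), c(0.16, 0.12, 0.10)))
  paint("mpfc_seed", ell(c(0.5, 0.80, 0.56), c(0.09, 0.075, 0.075)))

  # cortical shell, split into lobes by height and anterior-posterior position
  paint("parietal_cortex", shell & Z > 0.62)
  paint("frontal_cortex", shell & Y > 0.58)
  paint("occipital_cortex", shell & Y < 0.42)
  paint("temporal_cortex", shell)

  paint("white_matter", head)

  counts <- tabulate(lab[lab > 0L], nbins = max(tab$label))
  if (any(counts[tab$label] == 0L)) {
    stop(sprintf(
      "grid too small to place all structures (empty: %s)",
      paste(tab$structure[counts[tab$label] == 0L], collapse = ", ")
    ), call. = FALSE)
  }
  label_map(lab, table = tab, voxel_size_mm = voxel_size_mm)
}
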