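#' Cell-level susceptibility and SUVR parameters
#'
#' Per-structure means and standard errors of susceptibility (ppb, referenced
#' to CSF) and PiB-PET SUVR for each (group x APOE-e4) cell, as estimated in
#' the 7T MCI cohort the generator emulates, plus fixed parameters for the
#' reference/auxiliary structures (cerebellar gray, ventricular CSF, white
#' matter; the MPFC patch shares the frontal-cortex cell values). `n_cell`
#' is the number of subjects behind each cell (controls 15/7, MCI 9/6),
#' used to convert standard errors to between-subject standard deviations.
#'
#' @return Tibble with columns `structure`, `group`, `apoe_e4`, `chi_mean`,
#'   `chi_ste`, `suvr_mean`, `suvr_ste`, `n_cell`.
#' @export
cell_parameters <- function() {
  structures <- c("amygdala", "nucleus_accumbens", "hippocampus",
                  "entorhinal_cortex", "thalamus", "caudate_nucleus",
                  "putamen", "globus_pallidus", "frontal_cortex",
                  "temporal_cortex", "parietal_cortex", "occipital_cortex")
  # columns: chi-/chi_ste-/chi+/chi_ste+  then suvr-/ste-/suvr+/ste+
  ctrl <- matrix(c(
    -17.2, 2.5, -15.3, 2.2,  1.19, 0.02, 1.19, 0.02,
     12.1, 4.1,  11.2, 3.2,  1.17, 0.02, 1.23, 0.03,
     -1.4, 1.7,  -1.2, 2.1,  1.25, 0.02, 1.31, 0.02,
     22.6, 5.1,  25.0, 2.6,  1.08, 0.02, 1.14, 0.01,
     -6.5, 1.9, -10.5, 1.4,  1.48, 0.04, 1.48, 0.04,
     46.0, 3.7,  31.5, 5.5,  1.26, 0.03, 1.28, 0.03,
     67.2, 4.3,  55.9, 5.3,  1.33, 0.02, 1.36, 0.01,
    106.4, 5.0, 100.4, 5.7,  1.45, 0.02, 1.50, 0.04,
      2.6, 1.9,   1.1, 2.0,  1.02, 0.03, 1.13, 0.04,
      0.7, 1.6,  -0.6, 2.0,  1.04, 0.02, 1.10, 0.04,
      4.1, 1.6,   2.7, 1.8,  0.99, 0.02, 1.15, 0.05,
      4.0, 1.9,   2.9, 1.8,  1.14, 0.03, 1.19, 0.04
  ), ncol = 8, byrow = TRUE)
  mci <- matrix(c(
    -17.5, 1.8, -17.2, 2.6,  1.07, 0.02, 1.54, 0.03,
      8.2, 4.9,  17.3, 4.7,  1.16, 0.02, 2.41, 0.07,
     -2.0, 2.0,   1.5, 3.5,  1.14, 0.03, 1.42, 0.03,
     23.1, 3.4,  30.0, 2.5,  1.02, 0.03, 1.31, 0.03,
     -9.1, 1.4,  -8.5, 2.1,  1.46, 0.02, 1.80, 0.06,
     32.7, 2.0,  46.3, 4.5,  1.24, 0.04, 2.13, 0.09,
     58.6, 3.7,  65.2, 4.0,  1.29, 0.01, 2.23, 0.05,
     96.4, 3.3, 103.5, 6.3,  1.41, 0.03, 1.92, 0.06,
      0.1, 1.6,   6.3, 2.2,  0.98, 0.05, 1.95, 0.10,
      0.0, 1.8,   5.2, 1.8,  1.03, 0.02, 1.73, 0.07,
      1.3, 1.2,   8.1, 1.8,  1.00, 0.03, 1.87, 0.09,
      1.5, 1.4,   7.2, 2.4,  1.13, 0.02, 1.59, 0.08
  ), ncol = 8, byrow = TRUE)

  cell_n <- c(control.FALSE = 15, control.TRUE = 7, MCI.FALSE = 9, MCI.TRUE = 6)
  one_block <- function(m, group) {
    dplyr::bind_rows(
      tibble::tibble(structure = structures, group = group, apoe_e4 = FALSE,
                     chi_mean = m[, 1], chi_ste = m[, 2],
                     suvr_mean = m[, 5], suvr_ste = m[, 6]),
      tibble::tibble(structure = structures, group = group, apoe_e4 = TRUE,
                     chi_mean = m[, 3], chi_ste = m[, 4],
                     suvr_mean = m[, 7], suvr_ste = m[, 8])
    )
  }
  tab <- dplyr::bind_rows(one_block(ctrl, "control"), one_block(mci, "MCI"))

  # auxiliary structures, identical across cells: CSF is constructed with the
  # lowest between-subject variability so the reference-selection rule picks
  # it; white matter carries a small negative susceptibility (myelin), the
  # cerebellar patch anchors SUVR at 1.
  aux <- tidyr::expand_grid(
    tibble::tibble(
      structure = c("cerebellar_gray", "csf_ventricles", "white_matter"),
      chi_mean = c(0, 0, -20), chi_ste = c(0.5, 0.1, 0.8),
      suvr_mean = c(1.0, 0.6, 1.2), suvr_ste = c(0, 0.02, 0.03)
    ),
    tibble::tibble(group = rep(c("control", "MCI"), each = 2),
                   apoe_e4 = rep(c(FALSE, TRUE), 2))
  )
  mpfc <- dplyr::mutate(tab[tab$structure == "frontal_cortex", ],
                        structure = "mpfc_seed")
  tab <- dplyr::bind_rows(tab, aux, mpfc)
  tab$n_cell <- cell_n[paste(tab$group, tab$apoe_e4, sep = ".")]
  tab$group <- factor(tab$group, levels = c("control", "MCI"))
  tibble::as_tibble(tab)
}

#' Synthetic cohort specification
#'
#' Defaults reproduce the study conditions the generator emulates: 22
#' controls / 15 MCI with 7 and 6 APOE-e4 carriers, 8F/14M and 5F/10M, ages
#' ~N(72, 5) and N(75, 8) truncated to [62, 89]; per-cell susceptibility and
#' SUVR distributions from [cell_parameters()] with SD = STE * sqrt(n_cell);
#' chi-SUVR rank coupling 0.86 in MCI (0.3 in controls) inside the
#' frontomedial colocalization region; 3-echo GRE at TE 6/12/18 ms, 7 T,
#' phase SNR 50; BOLD at TR 2 s, 210 frames, seed-target correlation 0.6 in
#' the MCI & high-iron cell and ~0.1-0.15 elsewhere.
#'
#' @param n_control,n_mci Group sizes.
#' @param apoe_pos_control,apoe_pos_mci Exact APOE-e4 carrier counts.
#' @param coupling Named rank-coupling strengths in `[0, 1]` for
#'   `control` and `MCI`.
#' @param shape,voxel_size_mm Phantom grid.
#' @param phase_snr Complex-signal SNR of the simulated GRE echoes.
#' @param chi_texture_sd,pet_texture_sd Within-structure voxel noise.
#' @param echo_times_s,field_strength_t GRE timing and field.
#' @param bold_r Named target seed-target correlations per
#'   (group x iron-class) cell.
#' @param bold_tr_s,bold_frames,bold_downsample BOLD sampling: TR, number of
#'   frames, and spatial downsampling factor relative to the phantom grid.
#' @param seed Base seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_control = 22L, n_mci = 15L,
                        apoe_pos_control = 7L, apoe_pos_mci = 6L,
                        coupling = c(control = 0.3, MCI = 0.86),
                        shape = c(64L, 64L, 64L), voxel_size_mm = c(1, 1, 1),
                        phase_snr = 50,
                        chi_texture_sd = 1, pet_texture_sd = 0.03,
                        echo_times_s = c(0.006, 0.012, 0.018),
                        field_strength_t = 7,
                        bold_r = c(control.low = 0.10, control.high = 0.15,
                                   MCI.low = 0.15, MCI.high = 0.60),
                        bold_tr_s = 2, bold_frames = 210L, bold_downsample = 4L,
                        seed = 1L) {
  stopifnot(n_control > 0, n_mci > 0,
            apoe_pos_control >= 0, apoe_pos_control <= n_control,
            apoe_pos_mci >= 0, apoe_pos_mci <= n_mci,
            all(coupling >= 0), all(coupling <= 1),
            phase_snr > 0, bold_frames > 0)
  spec <- list(
    n_control = as.integer(n_control), n_mci = as.integer(n_mci),
    apoe_pos_control = as.integer(apoe_pos_control),
    apoe_pos_mci = as.integer(apoe_pos_mci),
    cells = cell_parameters(),
    coupling = coupling,
    coloc_structures = c("frontal_cortex", "mpfc_seed"),
    shape = as.integer(shape), voxel_size_mm = as.numeric(voxel_size_mm),
    phase_snr = phase_snr,
    chi_texture_sd = chi_texture_sd, pet_texture_sd = pet_texture_sd,
    echo_times_s = echo_times_s, field_strength_t = field_strength_t,
    bold_r = bold_r, bold_tr_s = bold_tr_s,
    bold_frames = as.integer(bold_frames),
    bold_downsample = as.integer(bold_downsample),
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  spec
}

#' Generate the subject metadata table
#'
#' APOE-e4 carrier flags and gender are assigned at the exact specified
#' counts (which subject gets which is permuted by the seed); ages are drawn
#' from the group-specific truncated normals.
#'
#' @param spec A `cohort_spec`.
#' @param seed Integer seed.
#' @return A subject tibble (see [read_subject_table()]).
#' @export
make_participants <- function(spec, seed = spec$seed) {
  n <- spec$n_control + spec$n_mci
  grp <- c(rep("control", spec$n_control), rep("mci", spec$n_mci))
  with_local_seed(seed, {
    apoe <- c(
      sample(rep(c(TRUE, FALSE),
                 c(spec$apoe_pos_control, spec$n_control - spec$apoe_pos_control))),
      sample(rep(c(TRUE, FALSE),
                 c(spec$apoe_pos_mci, spec$n_mci - spec$apoe_pos_mci)))
    )
    n_f_ctrl <- round(spec$n_control * 8 / 22)
    n_f_mci <- round(spec$n_mci * 5 / 15)
    gender <- c(
      sample(rep(c("F", "M"), c(n_f_ctrl, spec$n_control - n_f_ctrl))),
      sample(rep(c("F", "M"), c(n_f_mci, spec$n_mci - n_f_mci)))
    )
    rtnorm <- function(k, mean, sd, lo = 62, hi = 89) {
      out <- numeric(k)
      for (i in seq_len(k)) {
        repeat {
          v <- stats::rnorm(1, mean, sd)
          if (v >= lo && v <= hi) break
        }
        out[i] <- v
      }
      round(out, 1)
    }
    age <- c(rtnorm(spec$n_control, 72, 5), rtnorm(spec$n_mci, 75, 8))
    as_subject_table(data.frame(
      subject_id = sprintf("sub-%03d", seq_len(n)),
      group = grp, apoe_e4 = apoe, age = age, gender = gender
    ))
  })
}

#' Draw per-subject latent regional means
#'
#' For every subject and structure, the subject-level regional mean of chi
#' and SUVR is `cell_mean + cell_sd * z` with `cell_sd = STE * sqrt(n_cell)`.
#' Within the colocalization region all structures share a single latent pair
#' `(z_chi, z_suvr)` coupled through a Gaussian copula: the Pearson
#' correlation of the pair is `2 * sin(pi * rho_s / 6)` so that the population
#' Spearman correlation of the regional means equals the requested rank
#' coupling `rho_s`. All other structures get independent draws.
#'
#' @param spec A `cohort_spec`.
#' @param subjects Subject tibble.
#' @param seed Integer seed.
#' @return Tibble `subject_id` x `structure` with `chi_true`, `suvr_true`.
#' @export
draw_subject_latents <- function(spec, subjects, seed = spec$seed) {
  cells <- spec$cells
  with_local_seed(seed, {
    rows <- purrr::map(seq_len(nrow(subjects)), function(i) {
      s <- subjects[i, ]
      par <- cells[cells$group == as.character(s$group) &
                     cells$apoe_e4 == s$apoe_e4, ]
      if (nrow(par) == 0L) {
        stop(sprintf("no cell parameters for group=%s apoe=%s",
                     s$group, s$apoe_e4), call. = FALSE)
      }
      rho_s <- unname(spec$coupling[[as.character(s$group)]])
      rho_p <- 2 * sin(pi * rho_s / 6)
      z_chi_c <- stats::rnorm(1)
      z_suvr_c <- rho_p * z_chi_c + sqrt(1 - rho_p^2) * stats::rnorm(1)
      in_coloc <- par$structure %in% spec$coloc_structures
      z_chi <- ifelse(in_coloc, z_chi_c, stats::rnorm(nrow(par)))
      z_suvr <- ifelse(in_coloc, z_suvr_c, stats::rnorm(nrow(par)))
      sdc <- par$chi_ste * sqrt(par$n_cell)
      sds <- par$suvr_ste * sqrt(par$n_cell)
      tibble::tibble(
        subject_id = s$subject_id, structure = par$structure,
        chi_true = par$chi_mean + sdc * z_chi,
        suvr_true = pmax(0, par$suvr_mean + sds * z_suvr)
      )
    })
    dplyr::bind_rows(rows)
  })
}

latents_for <- function(latents, subject_id) {
  l <- latents[latents$subject_id == subject_id, ]
  if (nrow(l) == 0L) stop(sprintf("no latents for %s", subject_id), call. = FALSE)
  l
}

#' Paint a susceptibility volume for one subject
#'
#' Each structure is filled with the subject's latent regional mean plus
#' within-structure Gaussian texture; voxels outside the head are 0. The CSF
#' reference region is generated centred near 0 with the lowest
#' between-subject variability among candidate reference regions.
#'
#' @param labels A `label_map`.
#' @param subject One-row subject tibble.
#' @param spec A `cohort_spec`.
#' @param latents Output of [draw_subject_latents()]; drawn internally when
#'   `NULL`.
#' @param seed Integer seed for the texture draw.
#' @return List with `chi` (`vol_grid`, ppb) and `truth` (the subject's
#'   latent tibble).
#' @export
assign_susceptibility <- function(labels, subject, spec, latents = NULL,
                                  seed = spec$seed) {
  if (is.null(latents)) latents <- draw_subject_latents(spec, subject, seed = seed)
  l <- latents_for(latents, subject$subject_id)
  chi <- array(0, dim(labels$data))
  with_local_seed(derive_seed(seed, 101L), {
    for (j in seq_len(nrow(l))) {
      m <- labels$data == labels$table$label[labels$table$structure == l$structure[j]]
      nv <- sum(m)
      if (nv > 0) {
        chi[m] <- l$chi_true[j] +
          if (spec$chi_texture_sd > 0) stats::rnorm(nv, 0, spec$chi_texture_sd) else 0
      }
    }
  })
  list(chi = vol_grid(chi, labels$voxel_size_mm), truth = l)
}

#' Simulate a PiB-PET SUVR volume for one subject
#'
#' Regional activity is the subject's latent SUVR mean plus voxel texture;
#' the volume is then normalized by its cerebellar-gray mean, so the anchor
#' region has mean exactly 1. Within the colocalization region the latent
#' SUVR deviation is rank-coupled to the subject's chi deviation (see
#' [draw_subject_latents()]).
#'
#' @inheritParams assign_susceptibility
#' @return A `vol_grid` of SUVR.
#' @export
simulate_pet <- function(labels, subject, spec, latents = NULL,
                         seed = spec$seed) {
  if (!any(labels$data == labels$table$label[labels$table$structure == "cerebellar_gray"])) {
    stop("cerebellar gray label missing: SUVR anchor undefined", call. = FALSE)
  }
  if (is.null(latents)) latents <- draw_subject_latents(spec, subject, seed = seed)
  l <- latents_for(latents, subject$subject_id)
  act <- array(0, dim(labels$data))
  with_local_seed(derive_seed(seed, 202L), {
    for (j in seq_len(nrow(l))) {
      m <- labels$data == labels$table$label[labels$table$structure == l$structure[j]]
      nv <- sum(m)
      if (nv > 0) {
        act[m] <- pmax(0, l$suvr_true[j] +
          if (spec$pet_texture_sd > 0) stats::rnorm(nv, 0, spec$pet_texture_sd) else 0)
      }
    }
  })
  cb <- structure_mask(labels, "cerebellar_gray")
  anchor <- mean(act[cb])
  if (!is.finite(anchor) || anchor <= 0) {
    stop("cerebellar gray activity is zero: cannot normalize", call. = FALSE)
  }
  vol_grid(act / anchor, labels$voxel_size_mm)
}

# Band-limited unit-variance latent time course
band_limited_latent <- function(n_frames, tr_s, low = 0.01, high = 0.1) {
  x <- stats::rnorm(n_frames)
  xf <- bandpass_filter(matrix(x, ncol = 1), tr_s, low, high)
  v <- as.numeric(xf)
  v / stats::sd(v)
}

#' Simulate a seed-coupled BOLD series for one subject
#'
#' The series lives on a grid downsampled by `spec$bold_downsample` from the
#' phantom grid (mirroring the coarser fMRI resolution). The MPFC seed region
#' carries a band-limited (0.01-0.1 Hz) latent signal; voxels of the
#' frontomedial target region carry `alpha * latent + noise`, where `alpha`
#' is calibrated so the true seed-target correlation equals the subject's
#' (group x iron-class) cell value in `spec$bold_r`; all other in-head voxels
#' are noise. Six synthetic motion regressors plus the CSF and WM mean series
#' form the confound table; a scaled copy of the first motion regressor
#' contaminates every voxel so confound regression has real work to do.
#'
#' @param labels A `label_map` (phantom resolution).
#' @param subject One-row subject tibble.
#' @param iron_class `"high"` or `"low"`.
#' @param spec A `cohort_spec`.
#' @param seed Integer seed.
#' @return List with `data` (4D array), `voxel_size_mm`, `tr_s`, `confounds`
#'   (tibble with motion_1..6, csf, white_matter), `labels_small`
#'   (downsampled `label_map`).
#' @export
simulate_bold <- function(labels, subject, iron_class, spec, seed = spec$seed) {
  if (spec$bold_frames <= 0) stop("series length must be positive", call. = FALSE)
  iron_class <- match.arg(iron_class, c("high", "low"))
  labs <- downsample_labels(labels, spec$bold_downsample)
  d <- dim(labs$data)
  n_t <- spec$bold_frames
  seedmask <- structure_mask(labs, "mpfc_seed")
  if (!any(seedmask)) stop("MPFC seed label missing at BOLD resolution", call. = FALSE)
  target <- structure_mask(labs, "frontal_cortex")
  head <- labs$data > 0
  r <- unname(spec$bold_r[[paste(as.character(subject$group), iron_class, sep = ".")]])
  # calibrate alpha for the requested correlation AFTER band-pass filtering:
  # the latent is unit-sd and band-limited, while white voxel noise keeps
  # only the in-band fraction of its variance
  f <- abs(fft_freq(n_t, spec$bold_tr_s))
  band_frac <- mean(f >= 0.01 & f <= 0.1)
  alpha <- r * sqrt(band_frac) / sqrt(1 - r^2)
  with_local_seed(seed, {
    latent <- band_limited_latent(n_t, spec$bold_tr_s)
    motion <- vapply(1:6, function(i) {
      cumsum(stats::rnorm(n_t, 0, 0.05))
    }, numeric(n_t))
    colnames(motion) <- paste0("motion_", 1:6)
    nvox <- prod(d)
    mat <- matrix(stats::rnorm(nvox * n_t), nrow = n_t)   # time x voxel noise
    mat[, !head] <- mat[, !head] * 0.05
    idx_seed <- which(seedmask); idx_tgt <- which(target & !seedmask)
    mat[, idx_seed] <- 0.2 * mat[, idx_seed] + latent
    mat[, idx_tgt] <- mat[, idx_tgt] + alpha * latent
    mat[, head] <- mat[, head] + 0.3 * motion[, 1]
  })
  csf <- structure_mask(labs, "csf_ventricles")
  wm <- structure_mask(labs, "white_matter")
  confounds <- tibble::as_tibble(as.data.frame(motion))
  confounds$csf <- rowMeans(mat[, which(csf), drop = FALSE])
  confounds$white_matter <- rowMeans(mat[, which(wm), drop = FALSE])
  data4d <- array(t(mat), c(d, n_t))
  list(data = data4d,
       voxel_size_mm = labs$voxel_size_mm, tr_s = spec$bold_tr_s,
       confounds = confounds, labels_small = labs)
}

#' Downsample a label map by integer stride
#'
#' Nearest-voxel decimation: pure resolution change on co-registered grids.
#'
#' @param labels A `label_map`.
#' @param factor Integer downsampling factor (1 keeps the map).
#' @return A `label_map` on the coarse grid.
#' @export
downsample_labels <- function(labels, factor = 4L) {
  if (factor <= 1L) return(labels)
  d <- dim(labels$data)
  idx <- lapply(1:3, function(k) seq.int(as.integer(ceiling(factor / 2)), d[k], by = factor))
  small <- labels$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  # drop table rows for structures that vanished at the coarse resolution
  present <- unique(as.integer(small[small > 0]))
  label_map(small, table = labels$table[labels$table$label %in% present, ],
            voxel_size_mm = labels$voxel_size_mm * factor)
}

#' Generate a complete synthetic cohort
#'
#' Builds the phantom, subject metadata, latent regional means, and per
#' subject the requested modalities: multi-echo wrapped phase + magnitude
#' (forward dipole field of the subject's chi volume, complex noise at the
#' spec SNR), PET SUVR, and seed-coupled BOLD with confounds. Iron classes
#' are assigned by a median split of the true cortical gray susceptibility
#' (voxel-count-weighted mean over the four lobes). When `out_dir` is given
#' the cohort tree is written through the package I/O layer
#' (`cohort/sub-XXX/...`, `participants.tsv`, `ground_truth/`).
#'
#' @param spec A `cohort_spec`.
#' @param seed Integer base seed (defaults to the spec's).
#' @param modalities Subset of `c("qsm", "pet", "bold")`.
#' @param out_dir Optional directory to write the cohort tree to.
#' @return A `cohort` list: `spec`, `subjects` (with `iron_class` column),
#'   `labels`, `latents`, `coloc_mask` (ground-truth coupled-region mask),
#'   and `data` (per-subject list with elements among `phase`, `pet`, `bold`,
#'   `chi_true`).
#' @export
make_cohort <- function(spec = cohort_spec(), seed = spec$seed,
                        modalities = c("qsm", "pet", "bold"), out_dir = NULL) {
  labels <- make_phantom_labels(spec$shape, spec$voxel_size_mm)
  subjects <- make_participants(spec, seed = seed)
  latents <- draw_subject_latents(spec, subjects, seed = derive_seed(seed, 1L))

  lobes <- c("frontal_cortex", "temporal_cortex", "parietal_cortex", "occipital_cortex")
  w <- vapply(lobes, function(s) sum(structure_mask(labels, s)), numeric(1))
  cort <- latents[latents$structure %in% lobes, ]
  cort <- dplyr::summarise(
    dplyr::group_by(cort, .data$subject_id),
    chi_cortical = sum(.data$chi_true * w[.data$structure]) / sum(w)
  )
  split <- median_split(cort, value = "chi_cortical", measure = "chi_cortical")
  subjects$iron_class <- split$classes$class[match(subjects$subject_id,
                                                   split$classes$subject_id)]

  coloc_ids <- labels$table$label[labels$table$structure %in% spec$coloc_structures]
  coloc_mask <- array(labels$data %in% coloc_ids, dim(labels$data))

  data <- vector("list", nrow(subjects))
  names(data) <- subjects$subject_id
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, ]
    sub_seed <- derive_seed(seed, 1000L + i)
    entry <- list()
    if (any(c("qsm", "pet") %in% modalities)) {
      asg <- assign_susceptibility(labels, s, spec, latents = latents,
                                   seed = sub_seed)
      entry$chi_true <- asg$chi
    }
    if ("qsm" %in% modalities) {
      df <- forward_dipole_field(entry$chi_true, spec$field_strength_t)
      entry$phase <- simulate_multiecho_phase(
        df, spec$echo_times_s, snr = spec$phase_snr,
        mask = labels$data > 0, field_strength_t = spec$field_strength_t,
        seed = derive_seed(sub_seed, 7L)
      )
    }
    if ("pet" %in% modalities) {
      entry$pet <- simulate_pet(labels, s, spec, latents = latents,
                                seed = sub_seed)
    }
    if ("bold" %in% modalities) {
      entry$bold <- simulate_bold(labels, s, s$iron_class, spec,
                                  seed = derive_seed(sub_seed, 9L))
    }
    data[[i]] <- entry
  }
  cohort <- structure(
    list(spec = spec, subjects = subjects, labels = labels, latents = latents,
         coloc_mask = coloc_mask, data = data),
    class = "cohort"
  )
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' Write a cohort tree to disk
#'
#' @param cohort A `cohort` from [make_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_subject_table(cohort$subjects[, c("subject_id", "group", "apoe_e4",
                                          "age", "gender")],
                      file.path(out_dir, "participants.tsv"))
  utils::write.table(cohort$subjects[, c("subject_id", "iron_class")],
                     file.path(out_dir, "iron_class.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  labvol <- vol_grid(cohort$labels$data + 0, cohort$labels$voxel_size_mm)
  gt_dir <- file.path(out_dir, "ground_truth")
  dir.create(gt_dir, showWarnings = FALSE)
  write_volume(vol_grid(cohort$coloc_mask * 1, cohort$labels$voxel_size_mm),
               file.path(gt_dir, "coloc_region_mask.nii.gz"))
  utils::write.table(as.data.frame(cohort$latents),
                     file.path(gt_dir, "latent_regional_means.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (id in names(cohort$data)) {
    d <- file.path(out_dir, id)
    dir.create(d, showWarnings = FALSE)
    entry <- cohort$data[[id]]
    write_volume(labvol, file.path(d, "labels.nii.gz"), datatype = "int16")
    if (!is.null(entry$phase)) {
      for (e in seq_along(entry$phase$echo_times_s)) {
        write_volume(entry$phase$phase[[e]], file.path(d, sprintf("phase_e%d.nii.gz", e)))
        write_volume(entry$phase$magnitude[[e]], file.path(d, sprintf("mag_e%d.nii.gz", e)))
      }
    }
    if (!is.null(entry$pet)) {
      write_volume(entry$pet, file.path(d, "pet_suvr.nii.gz"))
    }
    if (!is.null(entry$bold)) {
      write_bold(entry$bold$data, file.path(d, "bold.nii.gz"),
                 entry$bold$voxel_size_mm, entry$bold$tr_s)
      utils::write.table(as.data.frame(entry$bold$confounds),
                         file.path(d, "confounds.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(entry$chi_true)) {
      write_volume(entry$chi_true, file.path(gt_dir, paste0(id, "_chi_true.nii.gz")))
    }
  }
  invisible(out_dir)
}
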