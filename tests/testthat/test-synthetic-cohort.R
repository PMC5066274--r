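test_that("phantom labels contain every structure and are deterministic", {
  lm1 <- make_phantom_labels(c(64, 64, 64))
  counts <- table(factor(lm1$data[lm1$data > 0], levels = structure_table()$label))
  expect_equal(length(counts), 16L)
  expect_true(all(counts >= 50))
  lm2 <- make_phantom_labels(c(64, 64, 64))
  expect_identical(lm1$data, lm2$data)
  expect_error(make_phantom_labels(c(8, 8, 8)), "too small")
})

test_that("labels are mutually exclusive and 48^3 still gives >= 50 voxels each", {
  lm_ <- make_phantom_labels(c(48, 48, 48))
  counts <- table(factor(lm_$data[lm_$data > 0], levels = structure_table()$label))
  expect_true(all(counts >= 50))
  # exclusivity is structural (one integer per voxel); check background reserved
  expect_true(all(lm_$data >= 0 & lm_$data <= 16))
})

test_that("susceptibility assignment reproduces cell means", {
  labels <- make_phantom_labels(c(48, 48, 48))
  spec0 <- cohort_spec()
  # degenerate noise: zero STEs and zero texture give exactly the cell means
  spec0$cells$chi_ste <- 0
  spec0$chi_texture_sd <- 0
  s <- one_subject("MCI", TRUE)
  asg <- assign_susceptibility(labels, s, spec0, seed = 5)
  frontal <- structure_mask(labels, "frontal_cortex")
  cell <- cell_parameters()
  want <- cell$chi_mean[cell$structure == "frontal_cortex" &
                          cell$group == "MCI" & cell$apoe_e4]
  expect_equal(unique(asg$chi$data[frontal]), want)
  expect_equal(want, 6.3)  # the MCI/APOE+ frontal cell
})

test_that("subject-level draws have the advertised first two moments", {
  spec <- cohort_spec()
  subs <- as_subject_table(data.frame(
    subject_id = sprintf("s%03d", 1:200), group = "control", apoe_e4 = FALSE,
    age = 72, gender = "F"
  ))
  lat1 <- draw_subject_latents(spec, subs, seed = 21)
  lat2 <- draw_subject_latents(spec, subs, seed = 22)
  gp1 <- lat1$chi_true[lat1$structure == "globus_pallidus"]
  gp2 <- lat2$chi_true[lat2$structure == "globus_pallidus"]
  expect_false(identical(gp1, gp2))  # different seeds, different draws
  cell <- cell_parameters()
  row <- cell[cell$structure == "globus_pallidus" &
                cell$group == "control" & !cell$apoe_e4, ]
  sd_true <- row$chi_ste * sqrt(row$n_cell)
  for (g in list(gp1, gp2)) {
    expect_lt(abs(mean(g) - row$chi_mean), 3 * sd_true / sqrt(200))
    expect_lt(abs(sd(g) - sd_true), 0.25 * sd_true)
  }
})

test_that("control grand means recover the pooled group values", {
  # pooled over APOE cells with Table-composition weights, globus pallidus
  cell <- cell_parameters()
  gp <- cell[cell$structure == "globus_pallidus" & cell$group == "control", ]
  pooled <- sum(gp$chi_mean * gp$n_cell) / sum(gp$n_cell)
  expect_equal(pooled, 104.5, tolerance = 0.01)

  spec <- cohort_spec(n_control = 200L, n_mci = 2L, apoe_pos_control = 64L,
                      apoe_pos_mci = 1L)
  subs <- make_participants(spec, seed = 31)
  lat <- draw_subject_latents(spec, subs, seed = 31)
  g <- dplyr::left_join(lat, subs, by = "subject_id")
  g <- g[g$structure == "globus_pallidus" & g$group == "control", ]
  se <- sd(g$chi_true) / sqrt(nrow(g))
  expect_lt(abs(mean(g$chi_true) - pooled), 3 * se)
})

test_that("forward dipole field: uniform chi gives zero shift, sphere matches theory", {
  n <- 48
  u <- vol_grid(array(7.5, rep(n, 3)))
  fu <- forward_dipole_field(u, 7)
  expect_lt(max(abs(fu$data)), 1e-10)

  sp <- sphere_chi(n, radius = 6, value = 100)
  f <- forward_dipole_field(sp$chi, 7)
  fl <- larmor_hz(7)
  costh2 <- (sp$g$z / pmax(sp$r, 1e-9))^2
  pred <- fl * (100e-9 / 3) * (6 / sp$r)^3 * (3 * costh2 - 1)
  # upper radius keeps periodic image sources of the FFT forward model
  # below ~4% of the local field scale
  sel <- sp$r >= 9 & sp$r <= 12
  scale_ref <- fl * (100e-9 / 3) * (6 / sp$r[sel])^3 * 2
  expect_lt(max(abs(f$data[sel] - pred[sel]) / scale_ref), 0.05)
  # Lorentz-sphere result: mean internal shift vanishes (global mean is 0)
  expect_lt(abs(mean(f$data[sp$r <= 4.5])), 1e-10 * fl * 100e-9)
  expect_error(forward_dipole_field(vol_grid(array(NaN, rep(16, 3)))), "finite")
})

test_that("multi-echo phase simulation wraps correctly and scales with TE", {
  n <- 16
  df10 <- vol_grid(array(10, rep(n, 3)))
  me <- simulate_multiecho_phase(df10, c(0.006, 0.012), snr = Inf, seed = 1)
  expect_equal(unique(round(as.numeric(me$phase[[2]]$data), 6)),
               round(0.24 * pi, 6))
  expect_equal(me$phase[[2]]$data[1, 1, 1], 0.7540, tolerance = 1e-4)

  df50 <- vol_grid(array(50, rep(n, 3)))
  me50 <- simulate_multiecho_phase(df50, c(0.006, 0.018), snr = Inf, seed = 1)
  # 2*pi*50*0.018 = 5.655 rad wraps to -0.628
  expect_equal(unique(round(as.numeric(me50$phase[[2]]$data), 4)), -0.6283,
               tolerance = 1e-3)

  me3 <- simulate_multiecho_phase(df10, c(0.006, 0.012, 0.018), snr = Inf, seed = 1)
  p1 <- me3$phase[[1]]$data[1, 1, 1]
  expect_equal(me3$phase[[2]]$data[1, 1, 1], wrap_phase(2 * p1), tolerance = 1e-10)
  expect_equal(me3$phase[[3]]$data[1, 1, 1], wrap_phase(3 * p1), tolerance = 1e-10)

  a <- simulate_multiecho_phase(df10, snr = 20, seed = 9)
  b <- simulate_multiecho_phase(df10, snr = 20, seed = 9)
  expect_identical(a$phase[[1]]$data, b$phase[[1]]$data)
  expect_error(simulate_multiecho_phase(df10, snr = 0), "positive")
  # all wrapped output in (-pi, pi]
  expect_true(all(a$phase[[1]]$data > -pi & a$phase[[1]]$data <= pi))
})

test_that("PET simulation anchors cerebellum at 1 and honors the copula limit", {
  labels <- make_phantom_labels(c(48, 48, 48))
  spec <- cohort_spec()
  pet <- simulate_pet(labels, one_subject("MCI", TRUE), spec, seed = 3)
  cb <- structure_mask(labels, "cerebellar_gray")
  expect_equal(mean(pet$data[cb]), 1.0, tolerance = 1e-12)

  # coupling = 1: chi and SUVR deviations share the latent exactly -> rho = 1
  spec1 <- cohort_spec(coupling = c(control = 1, MCI = 1))
  subs <- as_subject_table(data.frame(
    subject_id = sprintf("s%03d", 1:30), group = "MCI", apoe_e4 = TRUE,
    age = 75, gender = "M"
  ))
  lat <- draw_subject_latents(spec1, subs, seed = 4)
  fr <- lat[lat$structure == "frontal_cortex", ]
  expect_equal(cor(rank(fr$chi_true), rank(fr$suvr_true)), 1.0)

  labs_nocb <- labels
  labs_nocb$data[cb] <- 0L
  labs_nocb$table <- labs_nocb$table[labs_nocb$table$structure != "cerebellar_gray", ]
  expect_error(simulate_pet(labs_nocb, one_subject(), spec, seed = 1),
               "cerebellar")
})

test_that("copula calibration hits requested rank couplings", {
  subs <- as_subject_table(data.frame(
    subject_id = sprintf("s%05d", 1:4000), group = "MCI", apoe_e4 = TRUE,
    age = 75, gender = "M"
  ))
  for (target in c(0.3, 0.6, 0.86)) {
    spec <- cohort_spec(coupling = c(control = target, MCI = target))
    lat <- draw_subject_latents(spec, subs, seed = 17)
    fr <- lat[lat$structure == "frontal_cortex", ]
    rho <- cor(rank(fr$chi_true), rank(fr$suvr_true))
    expect_lt(abs(rho - target), 0.03)
  }
})

test_that("BOLD simulation couples seed and target at the requested level", {
  labels <- make_phantom_labels(c(32, 32, 32))
  spec <- cohort_spec(shape = c(32L, 32L, 32L), bold_downsample = 2L)
  s <- as_subject_table(data.frame(subject_id = "m1", group = "MCI",
                                   apoe_e4 = TRUE, age = 75, gender = "M"))
  b1 <- simulate_bold(labels, s, "high", spec, seed = 8)
  b2 <- simulate_bold(labels, s, "high", spec, seed = 8)
  expect_identical(b1$data, b2$data)
  expect_equal(dim(b1$data)[4], spec$bold_frames)
  expect_equal(names(b1$confounds),
               c(paste0("motion_", 1:6), "csf", "white_matter"))

  # target r = 0.6 for MCI & high iron: mean z over coupled voxels within the
  # Fisher-z 95% band of atanh(0.6)
  pre <- preprocess_bold(b1)
  cm <- seed_to_voxel(pre, structure_mask(b1$labels_small, "mpfc_seed"),
                      b1$labels_small$data > 0)
  tgt <- structure_mask(b1$labels_small, "frontal_cortex") &
    !structure_mask(b1$labels_small, "mpfc_seed")
  zbar <- mean(cm$z[tgt])
  expect_lt(abs(zbar - atanh(0.6)), 1.96 / sqrt(spec$bold_frames - 3))
})

test_that("uncoupled BOLD shows near-zero seed-target correlation over seeds", {
  labels <- make_phantom_labels(c(32, 32, 32))
  spec <- cohort_spec(shape = c(32L, 32L, 32L), bold_downsample = 2L,
                      bold_r = c(control.low = 0, control.high = 0,
                                 MCI.low = 0, MCI.high = 0))
  s <- one_subject("control", FALSE)
  for (sd_ in 1:5) {
    b <- simulate_bold(labels, s, "low", spec, seed = sd_)
    pre <- preprocess_bold(b)
    cm <- seed_to_voxel(pre, structure_mask(b$labels_small, "mpfc_seed"),
                        b$labels_small$data > 0)
    tgt <- structure_mask(b$labels_small, "frontal_cortex") &
      !structure_mask(b$labels_small, "mpfc_seed")
    expect_lt(abs(tanh(mean(cm$z[tgt]))), 0.15)
  }
  expect_error(simulate_bold(labels, s, "low",
                             cohort_spec(shape = c(32L, 32L, 32L),
                                         bold_frames = 1L)),
               "positive|too short|length")
})

test_that("cohort generation has the study composition and is reproducible", {
  spec <- cohort_spec()
  p <- make_participants(spec, seed = 1)
  expect_equal(nrow(p), 37L)
  expect_equal(sum(p$group == "control"), 22L)
  expect_equal(sum(p$group == "MCI"), 15L)
  expect_equal(sum(p$apoe_e4[p$group == "control"]), 7L)
  expect_equal(sum(p$apoe_e4[p$group == "MCI"]), 6L)
  expect_equal(sum(p$gender == "F" & p$group == "control"), 8L)
  expect_equal(sum(p$gender == "F" & p$group == "MCI"), 5L)
  expect_true(all(p$age >= 62 & p$age <= 89))

  # smoke cohort: all modalities, byte-identical on regeneration
  coh1 <- make_cohort(test_smoke_spec(), seed = 2)
  coh2 <- make_cohort(test_smoke_spec(), seed = 2)
  expect_identical(coh1$data[["sub-001"]]$phase$phase[[1]]$data,
                   coh2$data[["sub-001"]]$phase$phase[[1]]$data)
  expect_identical(coh1$data[["sub-003"]]$bold$data, coh2$data[["sub-003"]]$bold$data)
  expect_identical(coh1$latents, coh2$latents)
  expect_setequal(names(coh1$data[["sub-001"]]),
                  c("chi_true", "phase", "pet", "bold"))

  dir <- withr::local_tempdir()
  write_cohort(coh1, dir)
  expect_true(file.exists(file.path(dir, "participants.tsv")))
  expect_true(file.exists(file.path(dir, "sub-001", "phase_e3.nii.gz")))
  expect_true(file.exists(file.path(dir, "sub-004", "confounds.tsv")))
  expect_true(file.exists(file.path(dir, "ground_truth", "coloc_region_mask.nii.gz")))
})
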