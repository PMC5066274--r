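test_that("6-connected erosion shrinks cubes as hand-computed", {
  m <- array(FALSE, c(11, 11, 11))
  m[3:9, 3:9, 3:9] <- TRUE  # solid 7^3
  e2 <- erode_mask(m, 2)
  expect_equal(sum(e2), 27)
  expect_true(all(which(e2, arr.ind = TRUE) >= 5) &&
                all(which(e2, arr.ind = TRUE) <= 7))
  expect_identical(erode_mask(m, 0), m)
  s <- array(FALSE, c(7, 7, 7)); s[3:5, 3:5, 3:5] <- TRUE  # 3^3
  expect_equal(sum(erode_mask(s, 2)), 0)
})

test_that("roi_means extracts eroded chi means, SUVR means and volumes", {
  labels <- make_phantom_labels(c(48, 48, 48), voxel_size_mm = c(0.5, 0.5, 0.5))
  d <- dim(labels$data)
  chi <- array(0, d)
  cn <- structure_mask(labels, "caudate_nucleus")
  chi[cn] <- 41.4
  suvr <- array(1.3, d)
  rows <- suppressWarnings(
    roi_means(vol_grid(chi, c(0.5, 0.5, 0.5)), vol_grid(suvr, c(0.5, 0.5, 0.5)),
              labels, erosion_voxels = 1, subject_id = "s1")
  )
  crow <- rows[rows$structure == "caudate_nucleus", ]
  expect_equal(crow$mean_chi, 41.4)
  expect_equal(crow$mean_suvr, 1.3)
  expect_equal(crow$volume_ml, sum(cn) * 0.125 / 1000)

  # 1000 voxels at 0.5 mm isotropic = 0.125 ml
  expect_equal(1000 * voxel_volume_ml(c(0.5, 0.5, 0.5)), 0.125)

  # a structure that vanishes under heavy erosion is dropped with a warning
  expect_warning(
    few <- roi_means(vol_grid(chi, c(0.5, 0.5, 0.5)), NULL, labels,
                     erosion_voxels = 4, subject_id = "s1",
                     structures = "nucleus_accumbens"),
    "dropped"
  )
  expect_equal(nrow(few), 0L)
})

test_that("ICV volume correction follows the exact formula", {
  expect_equal(correct_volume(10, 1500, 1400), 10 * 1400 / 1500)
  expect_equal(correct_volume(10, 1500, 1400), 9.3333, tolerance = 1e-4)
  expect_equal(correct_volume(7.3, 1450, 1450), 7.3)
  expect_equal(correct_volume(10, 3000, 1500), correct_volume(10, 1500, 1500) / 2)
  expect_error(correct_volume(-1, 1500, 1400), "positive")
})

test_that("ANCOVA adjusts for confounded covariates and detects separation", {
  # age fully explains the apparent group difference
  set.seed(14)
  n <- 40
  age <- c(runif(n / 2, 64, 72), runif(n / 2, 78, 88))
  d <- data.frame(
    value = 0.5 * age + rnorm(n, sd = 0.01),
    group = rep(c("control", "MCI"), each = n / 2),
    age = age, gender = sample(c("F", "M"), n, TRUE)
  )
  expect_gt(ancova_group_test(d)$p, 0.5)

  # perfect separation with zero noise
  d2 <- data.frame(
    value = rep(c(0, 10), each = 10) + rep(seq(0, 0.09, 0.01), 2),
    group = rep(c("control", "MCI"), each = 10),
    age = rep(seq(65, 83, 2), 2), gender = rep(c("F", "M"), 10)
  )
  expect_lt(suppressWarnings(ancova_group_test(d2)$p), 1e-10)

  expect_error(ancova_group_test(d[1:4, ]), ">= 3")
})

test_that("ANCOVA holds its nominal type-I error under a permutation null", {
  set.seed(77)
  reps <- 1000; n <- 30
  rej <- 0
  for (i in seq_len(reps)) {
    d <- data.frame(
      value = rnorm(n),
      group = sample(rep(c("control", "MCI"), c(15, 15))),
      age = runif(n, 62, 89),
      gender = sample(c("F", "M"), n, TRUE)
    )
    rej <- rej + (ancova_group_test(d)$p < 0.05)
  }
  expect_gte(rej / reps, 0.03)
  expect_lte(rej / reps, 0.07)
})

test_that("fdr_bh reproduces hand results and the reference implementation", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.37), 0.37)
  expect_equal(fdr_bh(rep(1, 5)), rep(1, 5))
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")

  set.seed(19)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    expect_identical(round(fdr_bh(p), 12), round(p.adjust(p, "BH"), 12))
  }
})

test_that("Cohen's d matches hand calculations", {
  expect_equal(cohens_d(c(1, 2, 3), c(4, 5, 6)), 3.0)
  x <- rnorm(20)
  expect_equal(cohens_d(x, x), 0)
  set.seed(30)
  a <- rnorm(5000, 0, 1); b <- rnorm(5000, 1, 1)
  expect_equal(cohens_d(a, b), 1, tolerance = 0.06)
  expect_error(cohens_d(1, c(2, 3)), ">= 2")
  expect_error(cohens_d(c(2, 2), c(2, 2)), "variance")
})

test_that("median split: mid-value threshold, strict-greater highs, ties low", {
  d <- tibble::tibble(subject_id = c("a", "b", "c", "d"), value = c(1, 2, 3, 4))
  ms <- median_split(d)
  expect_equal(ms$threshold, 2.5)
  expect_setequal(ms$classes$subject_id[ms$classes$class == "high"], c("c", "d"))

  set.seed(41)
  d37 <- tibble::tibble(subject_id = as.character(1:37), value = sample(rnorm(37)))
  g <- glance(median_split(d37))
  expect_equal(g$n_high, 18L)
  expect_equal(g$n_low, 19L)

  ties <- tibble::tibble(subject_id = as.character(1:5), value = c(1, 2, 2, 2, 3))
  mt <- median_split(ties)
  expect_equal(mt$threshold, 2)
  expect_equal(sum(mt$classes$class == "high"), 1L)  # ties at the median go low
})

test_that("odds ratios use Haldane correction and Wald intervals", {
  expect_equal(odds_ratio(matrix(c(10, 10, 10, 10), 2))$or, 1.0)

  o <- odds_ratio(matrix(c(6, 0, 5, 4), 2, byrow = TRUE))
  expect_true(o$corrected)
  expect_equal(o$or, (6.5 * 4.5) / (0.5 * 5.5), tolerance = 1e-12)
  expect_equal(o$or, 10.636, tolerance = 1e-3)

  t2 <- matrix(c(2, 8, 8, 2), 2, byrow = TRUE)
  o2 <- odds_ratio(t2)
  expect_false(o2$corrected)
  expect_equal(o2$or, 0.0625)
  se <- sqrt(sum(1 / t2))
  expect_equal(o2$ci_low, exp(log(0.0625) - qnorm(0.975) * se))
  expect_equal(o2$ci_high, exp(log(0.0625) + qnorm(0.975) * se))
  expect_equal(o2$p, fisher.test(t2)$p.value)

  expect_error(odds_ratio(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "zero")
})

test_that("odds-ratio Wald CI is consistent with a bootstrap oracle", {
  tab <- matrix(c(2, 8, 8, 2), 2, byrow = TRUE)
  o <- odds_ratio(tab)
  set.seed(55)
  n1 <- sum(tab[1, ]); n2 <- sum(tab[2, ])
  boot <- replicate(4000, {
    a <- rbinom(1, n1, tab[1, 1] / n1); c_ <- rbinom(1, n2, tab[2, 1] / n2)
    ct <- matrix(c(a, n1 - a, c_, n2 - c_), 2, byrow = TRUE) + 0.5
    log((ct[1, 1] * ct[2, 2]) / (ct[1, 2] * ct[2, 1]))
  })
  bq <- exp(quantile(boot, c(0.025, 0.975)))
  # Wald and bootstrap intervals agree within a factor ~2 on the log scale
  expect_lt(abs(log(o$ci_low) - log(bq[1])), 1.2)
  expect_lt(abs(log(o$ci_high) - log(bq[2])), 1.2)
})

test_that("Spearman colocalization statistic matches rank oracles", {
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  sp <- spearman_coloc(x, y)
  expect_equal(sp$rho, 0.6)
  expect_equal(sp$rho, unname(cor.test(x, y, method = "spearman")$estimate))

  mono <- spearman_coloc(1:8, (1:8)^3 + 2)
  expect_equal(mono$rho, 1)
  rev_ <- spearman_coloc(x, -y)
  expect_equal(rev_$rho, -0.6)

  # adjusted R^2 equals the closed form from the OLS R^2
  set.seed(61)
  xx <- rnorm(12); yy <- 2 * xx + rnorm(12)
  s2 <- spearman_coloc(xx, yy)
  r2 <- summary(lm(yy ~ xx))$r.squared
  expect_equal(s2$r2_adjusted, 1 - (1 - r2) * (12 - 1) / (12 - 2))

  expect_error(spearman_coloc(1:3, 1:3), "n >= 4")
  expect_error(spearman_coloc(rep(1, 5), 1:5), "constant")
})

test_that("group statistics tables combine ANCOVA, FDR and effect sizes", {
  set.seed(71)
  subs <- make_participants(cohort_spec(), seed = 71)
  lat <- draw_subject_latents(cohort_spec(), subs, seed = 71)
  roi <- dplyr::rename(lat[, c("subject_id", "structure", "chi_true")],
                       mean_chi = "chi_true")
  tab <- group_stats_table(roi, subs, "mean_chi", fdr_level = 0.05)
  expect_equal(nrow(tab), length(unique(roi$structure)))
  ok <- is.finite(tab$p)
  expect_true(all(tab$q[ok] >= tab$p[ok]))
  amg <- roi$mean_chi[roi$structure == "amygdala"]
  grp <- subs$group[match(roi$subject_id[roi$structure == "amygdala"],
                          subs$subject_id)]
  expect_equal(tab$cohens_d[tab$structure == "amygdala"],
               cohens_d(amg[grp == "control"], amg[grp == "MCI"]))
  expect_equal(tab$mean_control[tab$structure == "amygdala"],
               mean(amg[grp == "control"]))
})
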