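#' Per-subject ROI means and volumes
#'
#' For each structure: mean susceptibility over the 2-voxel-eroded label
#' intersected with the chi validity mask (erosion counters partial-volume
#' and edge effects), mean SUVR over the uneroded label, and structure volume
#' in ml (voxel count times voxel volume). Structures whose eroded mask is
#' empty (or falls entirely outside the validity mask) are dropped with a
#' warning.
#'
#' @param chi_map A `susceptibility_map` (or `vol_grid`, in which case the
#'   validity mask defaults to everywhere).
#' @param suvr_map A `suvr_map`, `vol_grid`, or `NULL` to skip SUVR.
#' @param labels A `label_map`.
#' @param erosion_voxels Erosion iterations for the chi means (default 2).
#' @param subject_id Identifier for the output rows.
#' @param structures Structure names to quantify (default: all in the table).
#' @return Tibble: `subject_id`, `structure`, `mean_chi`, `volume_ml`,
#'   `mean_suvr`.
#' @export
roi_means <- function(chi_map, suvr_map = NULL, labels, erosion_voxels = 2L,
                      subject_id = NA_character_,
                      structures = labels$table$structure) {
  chi <- if (inherits(chi_map, "susceptibility_map")) chi_map$chi else chi_map
  validity <- if (inherits(chi_map, "susceptibility_map")) chi_map$validity
              else array(TRUE, dim(chi$data))
  stop_if_grid_mismatch(chi$data, labels$data, "chi and labels")
  suvr <- if (inherits(suvr_map, "suvr_map")) suvr_map$suvr else suvr_map
  vv <- voxel_volume_ml(labels$voxel_size_mm)
  rows <- purrr::map(structures, function(s) {
    m <- structure_mask(labels, s)
    me <- erode_mask(m, erosion_voxels) & validity
    if (!any(me)) {
      warning(sprintf("structure '%s' empty after erosion/validity; dropped", s),
              call. = FALSE)
      return(NULL)
    }
    tibble::tibble(
      subject_id = subject_id, structure = s,
      mean_chi = mean(chi$data[me]),
      volume_ml = sum(m) * vv,
      mean_suvr = if (is.null(suvr)) NA_real_ else mean(suvr$data[m])
    )
  })
  dplyr::bind_rows(rows)
}

#' Intracranial-volume-corrected structure volume
#'
#' `corrected = volume * (group mean ICV / subject ICV)`.
#'
#' @param volume_ml Structure volume, ml.
#' @param subject_icv_ml Subject intracranial volume, ml.
#' @param group_mean_icv_ml Group mean intracranial volume, ml.
#' @return Corrected volume in ml.
#' @export
correct_volume <- function(volume_ml, subject_icv_ml, group_mean_icv_ml) {
  if (any(volume_ml <= 0) || any(subject_icv_ml <= 0) || any(group_mean_icv_ml <= 0)) {
    stop("all volumes must be positive", call. = FALSE)
  }
  volume_ml * (group_mean_icv_ml / subject_icv_ml)
}

#' Covariate-adjusted group comparison (ANCOVA)
#'
#' Linear model `value ~ group + age + gender`; returns the group
#' coefficient (MCI minus control, adjusted for age and gender) and its
#' two-sided p-value.
#'
#' @param data Data frame with columns `value`, `group` (2 levels), `age`,
#'   `gender`.
#' @return Tibble with `effect`, `p`, `df`.
#' @export
ancova_group_test <- function(data) {
  stopifnot(all(c("value", "group", "age", "gender") %in% names(data)))
  data$group <- droplevels(factor(data$group))
  if (nlevels(data$group) != 2L || any(table(data$group) < 3L)) {
    stop("need two groups with >= 3 subjects each", call. = FALSE)
  }
  fit <- stats::lm(value ~ group + age + gender, data = data)
  sm <- summary(fit)$coefficients
  gr <- grep("^group", rownames(sm))
  if (length(gr) != 1L || any(is.na(stats::coef(fit)))) {
    stop("singular design in ANCOVA", call. = FALSE)
  }
  tibble::tibble(effect = sm[gr, 1], p = sm[gr, 4],
                 df = stats::df.residual(fit))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR correction: `q_(i) = min_{j >= i} p_(j) * m / j`, restored to
#' the input order and capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
fdr_bh <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

#' Cohen's d effect size
#'
#' `d = (mean_b - mean_a) / s_pooled` with the pooled standard deviation
#' weighted by degrees of freedom.
#'
#' @param a,b Numeric vectors (>= 2 values each).
#' @return Scalar d.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("need >= 2 values per group", call. = FALSE)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0) stop("zero pooled variance", call. = FALSE)
  (mean(b) - mean(a)) / sqrt(sp2)
}

#' Median-split classification
#'
#' Threshold at the sample median (mid-value convention for even n);
#' subjects strictly above the threshold are "high", ties at the threshold go
#' "low". For an odd number of distinct values this puts (n-1)/2 subjects in
#' the high class.
#'
#' @param data Data frame with `subject_id` and the value column.
#' @param value Name of the value column.
#' @param measure Label for the classified measure.
#' @return A `classification_result`: list with `measure`, `threshold`,
#'   `classes` (tibble `subject_id`, `value`, `class`).
#' @export
median_split <- function(data, value = "value", measure = value) {
  v <- data[[value]]
  if (length(v) < 2L) stop("need >= 2 subjects", call. = FALSE)
  thr <- stats::median(v)
  structure(
    list(measure = measure, threshold = thr,
         classes = tibble::tibble(
           subject_id = data$subject_id, value = v,
           class = ifelse(v > thr, "high", "low")
         )),
    class = "classification_result"
  )
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %s: threshold %.4g (%d high / %d low)\n",
              x$measure, x$threshold,
              sum(x$classes$class == "high"), sum(x$classes$class == "low")))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.classification_result <- function(x, ...) x$classes

#' @export
glance.classification_result <- function(x, ...) {
  tibble::tibble(measure = x$measure, threshold = x$threshold,
                 n_high = sum(x$classes$class == "high"),
                 n_low = sum(x$classes$class == "low"))
}

#' Odds ratio of a 2x2 table
#'
#' `OR = (a d)/(b c)` with the Haldane-Anscombe +0.5 correction applied to
#' all cells when any cell is zero; Wald 95% CI on the log scale; Fisher
#' exact p from the uncorrected table.
#'
#' @param tab 2x2 matrix of counts: rows = exposure (e.g. APOE-e4 +/-),
#'   columns = outcome (high/low).
#' @return Tibble with `or`, `ci_low`, `ci_high`, `p`, `corrected`.
#' @export
odds_ratio <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("a row or column of the 2x2 table is entirely zero; OR undefined",
         call. = FALSE)
  }
  corrected <- any(tab == 0)
  ct <- if (corrected) tab + 0.5 else tab
  or <- (ct[1, 1] * ct[2, 2]) / (ct[1, 2] * ct[2, 1])
  se <- sqrt(sum(1 / ct))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  p <- stats::fisher.test(round(tab))$p.value
  tibble::tibble(or = or, ci_low = ci[1], ci_high = ci[2], p = p,
                 corrected = corrected)
}

#' Spearman correlation with regression-based adjusted R-squared
#'
#' rho is the Pearson correlation of mid-ranks; the p-value uses the exact
#' permutation distribution for n <= 10 without ties and the t-approximation
#' otherwise; adjusted R-squared comes from the OLS fit of y on x:
#' `1 - (1 - R^2)(n - 1)/(n - 2)`.
#'
#' @param x,y Numeric vectors, paired, n >= 4, no missing values.
#' @return Tibble with `rho`, `p`, `r2_adjusted`, `n`.
#' @export
spearman_coloc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing pairs not allowed", call. = FALSE)
  n <- length(x)
  if (n < 4L) stop("need n >= 4", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant x or y: correlation undefined", call. = FALSE)
  }
  rho <- stats::cor(rank(x), rank(y))
  has_ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  p <- suppressWarnings(stats::cor.test(
    x, y, method = "spearman", exact = (n <= 10 && !has_ties)
  ))$p.value
  fit <- stats::lm(y ~ x)
  tibble::tibble(rho = rho, p = p,
                 r2_adjusted = summary(fit)$adj.r.squared, n = n)
}

#' Group statistics table across structures
#'
#' Per structure: covariate-adjusted (age, gender) group comparison of the
#' outcome via [ancova_group_test()], BH correction across structures,
#' Cohen's d on the raw values, and group means with standard errors -- the
#' tabular group analysis of the pipeline.
#'
#' @param roi_table Long tibble: `subject_id`, `structure`, and the outcome
#'   column.
#' @param subjects Subject tibble (`subject_id`, `group`, `age`, `gender`).
#' @param outcome Name of the outcome column in `roi_table`.
#' @param fdr_level FDR level used for the significance flag (default 0.05).
#' @return Tibble per structure: `structure`, `mean_control`, `ste_control`,
#'   `mean_mci`, `ste_mci`, `effect`, `p`, `q`, `cohens_d`, `significant`.
#' @export
group_stats_table <- function(roi_table, subjects, outcome = "mean_chi",
                              fdr_level = 0.05) {
  df <- dplyr::left_join(roi_table, subjects, by = "subject_id")
  ste <- function(v) stats::sd(v) / sqrt(length(v))
  rows <- purrr::map(unique(df$structure), function(s) {
    d <- df[df$structure == s & is.finite(df[[outcome]]), ]
    a <- d[[outcome]][d$group == "control"]
    b <- d[[outcome]][d$group == "MCI"]
    test <- tryCatch(
      ancova_group_test(data.frame(value = d[[outcome]], group = d$group,
                                   age = d$age, gender = d$gender)),
      error = function(e) tibble::tibble(effect = NA_real_, p = NA_real_,
                                         df = NA_real_)
    )
    dd <- tryCatch(cohens_d(a, b), error = function(e) NA_real_)
    tibble::tibble(
      structure = s,
      mean_control = mean(a), ste_control = ste(a),
      mean_mci = mean(b), ste_mci = ste(b),
      effect = test$effect, p = test$p, cohens_d = dd
    )
  })
  out <- dplyr::bind_rows(rows)
  out$q <- NA_real_
  ok <- is.finite(out$p)
  if (any(ok)) out$q[ok] <- fdr_bh(out$p[ok])
  out$significant <- !is.na(out$q) & out$q < fdr_level
  out
}
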