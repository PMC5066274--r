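#' Per-subject mask means of susceptibility and SUVR
#'
#' Averages each subject's susceptibility and SUVR over the intersection of
#' the group connectivity mask, the gray-matter labels, and the subject's
#' chi validity mask. Subjects with an empty intersection are excluded and
#' reported via message.
#'
#' @param mask A `group_mask` or logical 3D array (resampled to the chi grid
#'   with [resample_mask_nearest()] if shapes differ).
#' @param chi_maps Named list (by subject id) of `susceptibility_map`s.
#' @param suvr_maps Named list (by subject id) of `suvr_map`s.
#' @param labels `label_map` on the chi grid.
#' @param gray_structures Structures counting as gray matter (default: the
#'   four lobes, entorhinal cortex, the subcortical nuclei and the MPFC
#'   patch).
#' @return Tibble: `subject_id`, `chi_mask_mean` (ppb), `suvr_mask_mean`,
#'   `n_voxels`.
#' @export
extract_mask_means <- function(mask, chi_maps, suvr_maps, labels,
                               gray_structures = c(
                                 "amygdala", "hippocampus", "thalamus",
                                 "caudate_nucleus", "putamen", "globus_pallidus",
                                 "nucleus_accumbens", "entorhinal_cortex",
                                 "frontal_cortex", "temporal_cortex",
                                 "parietal_cortex", "occipital_cortex",
                                 "mpfc_seed")) {
  m <- if (inherits(mask, "group_mask")) mask$mask else mask
  if (!identical(dim(m), dim(labels$data))) {
    m <- resample_mask_nearest(m, dim(labels$data))
  }
  ids <- labels$table$label[labels$table$structure %in% gray_structures]
  gray <- array(labels$data %in% ids, dim(labels$data))
  base <- m & gray
  rows <- purrr::map(names(chi_maps), function(id) {
    cm <- chi_maps[[id]]
    sel <- base & cm$validity
    if (!any(sel)) {
      message(sprintf("subject %s: empty mask/gray/validity intersection; excluded", id))
      return(NULL)
    }
    tibble::tibble(
      subject_id = id,
      chi_mask_mean = mean(cm$chi$data[sel]),
      suvr_mask_mean = mean(suvr_maps[[id]]$suvr$data[sel]),
      n_voxels = sum(sel)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    stop("empty mask intersection for all subjects", call. = FALSE)
  }
  out
}

apoe_stratified_tests <- function(pairs, subjects) {
  df <- dplyr::left_join(pairs, subjects, by = "subject_id")
  ste <- function(v) stats::sd(v) / sqrt(length(v))
  rows <- list()
  for (g in c("control", "MCI")) {
    for (meas in c("chi_mask_mean", "suvr_mask_mean")) {
      d <- df[df$group == g, ]
      neg <- d[[meas]][!d$apoe_e4]; pos <- d[[meas]][d$apoe_e4]
      if (length(neg) < 2L || length(pos) < 2L) {
        message(sprintf("stratum %s/%s skipped: fewer than 2 subjects", g, meas))
        next
      }
      p <- stats::t.test(pos, neg)$p.value
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group = g, measure = meas,
        mean_apoe_neg = mean(neg), ste_apoe_neg = ste(neg),
        mean_apoe_pos = mean(pos), ste_apoe_pos = ste(pos),
        p = p, cohens_d = tryCatch(cohens_d(neg, pos), error = function(e) NA_real_)
      )
    }
  }
  dplyr::bind_rows(rows)
}

apoe_odds_ratios <- function(pairs, subjects, classifications) {
  df <- dplyr::left_join(pairs, subjects, by = "subject_id")
  mci <- df[df$group == "MCI", ]
  rows <- list()
  for (nm in names(classifications)) {
    cls <- tidy(classifications[[nm]])
    cl <- cls$class[match(mci$subject_id, cls$subject_id)]
    if (anyNA(cl)) next
    tab <- matrix(c(
      sum(mci$apoe_e4 & cl == "high"), sum(mci$apoe_e4 & cl == "low"),
      sum(!mci$apoe_e4 & cl == "high"), sum(!mci$apoe_e4 & cl == "low")
    ), nrow = 2, byrow = TRUE,
    dimnames = list(c("apoe_pos", "apoe_neg"), c("high", "low")))
    orr <- tryCatch(odds_ratio(tab), error = function(e) {
      message(sprintf("odds ratio for %s undefined: %s", nm, conditionMessage(e)))
      NULL
    })
    if (!is.null(orr)) {
      orr$measure <- nm
      rows[[length(rows) + 1L]] <- orr[, c("measure", "or", "ci_low", "ci_high",
                                           "p", "corrected")]
    }
  }
  dplyr::bind_rows(rows)
}

#' Colocalization analysis inside the connectivity mask
#'
#' The headline analysis: Spearman correlation (with adjusted R-squared)
#' between mask-mean susceptibility and mask-mean SUVR over the MCI
#' subjects; APOE-e4-stratified comparisons of both measures within MCI and
#' within controls; and odds ratios for an MCI APOE-e4 carrier to be "high"
#' on each supplied median-split classification.
#'
#' @param pairs Output of [extract_mask_means()].
#' @param subjects Subject tibble.
#' @param classifications Named list of `classification_result`s (e.g.
#'   cohort-wide median splits of cortical SUVR and cortical chi).
#' @return A `coloc_report`: list with `pairs` (per-subject rows joined with
#'   group/APOE), `spearman` (MCI correlation tibble), `apoe_tests`,
#'   `odds_ratios`.
#' @export
colocalization_analysis <- function(pairs, subjects, classifications = list()) {
  df <- dplyr::left_join(pairs, subjects, by = "subject_id")
  mci <- df[df$group == "MCI", ]
  if (nrow(mci) < 4L) stop("need >= 4 MCI subjects with pairs", call. = FALSE)
  sp <- spearman_coloc(mci$chi_mask_mean, mci$suvr_mask_mean)
  structure(
    list(
      pairs = df[, c("subject_id", "group", "apoe_e4",
                     "chi_mask_mean", "suvr_mask_mean", "n_voxels")],
      spearman = sp,
      apoe_tests = apoe_stratified_tests(pairs, subjects),
      odds_ratios = apoe_odds_ratios(pairs, subjects, classifications)
    ),
    class = "coloc_report"
  )
}

#' @export
print.coloc_report <- function(x, ...) {
  cat(sprintf(
    "<coloc_report> %d subjects; MCI Spearman rho = %.3f (p = %.3g, adj R2 = %.3f)\n",
    nrow(x$pairs), x$spearman$rho, x$spearman$p, x$spearman$r2_adjusted
  ))
  if (nrow(x$odds_ratios)) {
    for (i in seq_len(nrow(x$odds_ratios))) {
      cat(sprintf("  OR[APOE-e4 -> high %s] = %.2f (95%% CI %.2f-%.2f, p = %.3g)\n",
                  x$odds_ratios$measure[i], x$odds_ratios$or[i],
                  x$odds_ratios$ci_low[i], x$odds_ratios$ci_high[i],
                  x$odds_ratios$p[i]))
    }
  }
  invisible(x)
}

#' @export
tidy.coloc_report <- function(x, ...) x$pairs

#' @export
glance.coloc_report <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$pairs),
    n_mci = sum(x$pairs$group == "MCI"),
    rho_mci = x$spearman$rho,
    p_rho = x$spearman$p,
    r2_adjusted = x$spearman$r2_adjusted
  )
}

#' Scatter plot of the colocalization report
#'
#' Mask-mean SUVR against mask-mean susceptibility for the MCI subjects,
#' colored by APOE-e4 carrier status, with the OLS trend line.
#'
#' @param object A `coloc_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coloc_report <- function(object, ...) {
  d <- object$pairs[object$pairs$group == "MCI", ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$chi_mask_mean,
                                  y = .data$suvr_mask_mean)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "grey60", linewidth = 0.6) +
    ggplot2::geom_point(ggplot2::aes(color = .data$apoe_e4), size = 2.5) +
    ggplot2::labs(
      x = "Mask-mean susceptibility (ppb)",
      y = "Mask-mean PiB-PET retention (SUVR)",
      color = "APOE-e4",
      title = sprintf("MCI colocalization: rho = %.2f, adj R2 = %.2f",
                      object$spearman$rho, object$spearman$r2_adjusted)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
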