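#' Zero-phase band-pass filter for BOLD series
#'
#' Frequency-domain brick-wall filter: Fourier coefficients with
#' `low <= |f| <= high` are kept, everything else (including DC) is zeroed,
#' so the output has mean 0 and the filter applies no phase shift.
#'
#' @param series Numeric vector (one series), matrix (time x voxels) or 4D
#'   array (x, y, z, time).
#' @param tr_s Sampling interval (repetition time) in seconds.
#' @param low,high Band edges in Hz; `0 < low < high < 1/(2 tr_s)`.
#' @return Filtered data in the same shape as the input.
#' @export
bandpass_filter <- function(series, tr_s, low = 0.01, high = 0.1) {
  if (!(low > 0 && low < high && high < 1 / (2 * tr_s))) {
    stop("band edges must satisfy 0 < low < high < Nyquist", call. = FALSE)
  }
  if (is.array(series) && length(dim(series)) == 4L) {
    d <- dim(series)
    mat <- t(matrix(series, nrow = prod(d[1:3]), ncol = d[4]))
    out <- bandpass_filter(mat, tr_s, low, high)
    return(array(t(out), d))
  }
  vec_in <- is.null(dim(series))
  mat <- if (vec_in) matrix(series, ncol = 1) else series
  n <- nrow(mat)
  if (n < 32L) stop("series too short (need >= 32 frames)", call. = FALSE)
  f <- abs(fft_freq(n, tr_s))
  keep <- f >= low & f <= high
  co <- stats::mvfft(mat)
  co[!keep, ] <- 0
  out <- Re(stats::mvfft(co, inverse = TRUE)) / n
  if (vec_in) as.numeric(out) else out
}

#' Regress nuisance confounds out of voxel series
#'
#' Ordinary-least-squares residualization of every voxel series against
#' `[intercept, confounds]`. Residuals are numerically orthogonal to all
#' confound columns. The confound matrix must have full column rank after
#' demeaning.
#'
#' @param series Matrix (time x voxels) or 4D array.
#' @param confounds Data frame or matrix of confound series (time x k), e.g.
#'   6 motion parameters plus CSF and white-matter means.
#' @return Residual series, same shape as the input.
#' @export
regress_confounds <- function(series, confounds) {
  if (is.array(series) && length(dim(series)) == 4L) {
    d <- dim(series)
    mat <- t(matrix(series, nrow = prod(d[1:3]), ncol = d[4]))
    out <- regress_confounds(mat, confounds)
    return(array(t(out), d))
  }
  vec_in <- is.null(dim(series))
  mat <- if (vec_in) matrix(series, ncol = 1) else series
  X <- cbind(intercept = 1, as.matrix(confounds))
  if (nrow(X) != nrow(mat)) stop("confound length does not match series", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("confound matrix is rank deficient after adding intercept", call. = FALSE)
  }
  out <- mat - X %*% qr.coef(qrX, mat)
  if (vec_in) as.numeric(out) else out
}

#' Seed-to-voxel connectivity map
#'
#' The seed signal is the unweighted mean series over the seed mask; each
#' in-brain voxel's Pearson correlation with it is Fisher-z transformed
#' (`z = atanh(r)`, with |r| clamped at `1 - 1e-7` so self-correlated voxels
#' stay finite). Preprocessing (confound regression, band-pass) must already
#' have been applied. Seed voxels are flagged for exclusion from group tests.
#'
#' @param series 4D array (x, y, z, time), preprocessed.
#' @param seed_mask Logical 3D array, nonempty.
#' @param brain_mask Logical 3D array of analysis voxels.
#' @param subject_id Identifier carried into the result.
#' @return A `connectivity_map`: list with `z` (3D array, NA outside brain),
#'   `seed_mask`, `brain_mask`, `subject_id`.
#' @export
seed_to_voxel <- function(series, seed_mask, brain_mask, subject_id = NA_character_) {
  d <- dim(series)
  stopifnot(length(d) == 4L)
  stop_if_grid_mismatch(seed_mask, brain_mask, "seed and brain masks")
  if (!any(seed_mask)) stop("seed mask is empty", call. = FALSE)
  mat <- t(matrix(series, nrow = prod(d[1:3]), ncol = d[4]))  # time x voxel
  seed_sig <- rowMeans(mat[, which(seed_mask), drop = FALSE])
  if (stats::sd(seed_sig) < 1e-12) stop("seed signal has zero variance", call. = FALSE)
  idx <- which(brain_mask)
  vox <- mat[, idx, drop = FALSE]
  sds <- apply(vox, 2, stats::sd)
  r <- rep(NA_real_, length(idx))
  ok <- sds > 1e-12
  r[ok] <- as.numeric(stats::cor(seed_sig, vox[, ok, drop = FALSE]))
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- array(NA_real_, d[1:3])
  z[idx] <- atanh(r)
  structure(
    list(z = z, seed_mask = seed_mask, brain_mask = brain_mask,
         subject_id = subject_id),
    class = "connectivity_map"
  )
}

# Vectorized OLS over voxels: returns the one-sided p-field and t-field for
# contrast %*% beta > 0.
fit_voxelwise_contrast <- function(Z, X, contrast) {
  n <- nrow(X); k <- ncol(X)
  XtXinv <- solve(crossprod(X))
  B <- XtXinv %*% crossprod(X, Z)
  resid <- Z - X %*% B
  df <- n - k
  s2 <- colSums(resid^2) / df
  cb <- as.numeric(contrast %*% B)
  se <- sqrt(as.numeric(t(contrast) %*% XtXinv %*% contrast) * s2)
  tval <- cb / se
  list(t = tval, p = stats::pt(tval, df, lower.tail = FALSE), df = df)
}

#' Group-level FDR-thresholded connectivity mask
#'
#' Voxelwise linear model of the Fisher-z maps on the 2x2 (MCI x iron-class)
#' design in cell-means form, testing the one-sided contrast "coupling in the
#' MCI & high-iron cell exceeds the average of the other cells" - the
#' combined MCI-and-high-iron effect. Benjamini-Hochberg correction runs
#' across all analysis voxels and the mask keeps voxels with q below the
#' threshold. If any design cell has fewer than 2 subjects, the model falls
#' back to the two-group contrast (MCI & high-iron) vs rest, and the result
#' records which design was used. Seed voxels are excluded from the analysis.
#'
#' @param maps List of `connectivity_map`s, one per subject.
#' @param subjects Subject tibble (with `subject_id`, `group`).
#' @param iron_class Character vector ("high"/"low") aligned with `maps`, or
#'   a tibble with `subject_id`, `iron_class`.
#' @param fdr_threshold FDR level for the mask (default 0.001).
#' @param labels Optional `label_map` on the map grid for the region summary.
#' @return A `group_mask`: list with `mask` (logical), `stat` (t field),
#'   `q` (q-value field), `fdr_threshold`, `design`, `n_mask_voxels`,
#'   `region_summary` (tibble region / voxels / pct_of_region, mask voxel
#'   counts summing to the mask size).
#' @export
group_mask <- function(maps, subjects, iron_class, fdr_threshold = 0.001,
                       labels = NULL) {
  ids <- vapply(maps, function(m) m$subject_id, character(1))
  if (is.data.frame(iron_class)) {
    iron_class <- iron_class$iron_class[match(ids, iron_class$subject_id)]
  }
  stopifnot(length(iron_class) == length(maps))
  grp <- as.character(subjects$group[match(ids, subjects$subject_id)])
  mci <- grp == "MCI"
  high <- iron_class == "high"
  analysis <- maps[[1]]$brain_mask & !maps[[1]]$seed_mask
  idx <- which(analysis)
  Z <- vapply(maps, function(m) m$z[idx], numeric(length(idx)))
  Z <- t(Z)  # subjects x voxels
  ok <- colSums(!is.finite(Z)) == 0
  cells <- interaction(factor(mci, c(FALSE, TRUE)), factor(high, c(FALSE, TRUE)))
  tab <- table(cells)
  if (all(tab >= 2L)) {
    X <- stats::model.matrix(~ 0 + cells)
    # columns: ctrl.low, mci.low, ctrl.high, mci.high
    contrast <- c(-1 / 3, -1 / 3, -1 / 3, 1)
    design <- "cell_means"
  } else {
    g <- mci & high
    if (sum(g) < 2L || sum(!g) < 2L) {
      stop("empty design cell: fewer than 2 subjects in (MCI & high-iron) or rest",
           call. = FALSE)
    }
    X <- cbind(rest = 1 * !g, target = 1 * g)
    contrast <- c(-1, 1)
    design <- "combined"
  }
  fit <- fit_voxelwise_contrast(Z[, ok, drop = FALSE], X, contrast)
  p <- rep(NA_real_, length(idx)); tval <- rep(NA_real_, length(idx))
  p[ok] <- fit$p; tval[ok] <- fit$t
  q <- rep(NA_real_, length(idx))
  q[ok] <- fdr_bh(p[ok])
  sig <- !is.na(q) & q < fdr_threshold
  mask <- array(FALSE, dim(analysis)); mask[idx[sig]] <- TRUE
  stat <- array(NA_real_, dim(analysis)); stat[idx] <- tval
  qf <- array(NA_real_, dim(analysis)); qf[idx] <- q
  region_summary <- NULL
  if (!is.null(labels)) {
    region_summary <- summarize_mask_regions(mask, labels)
  }
  structure(
    list(mask = mask, stat = stat, q = qf, fdr_threshold = fdr_threshold,
         design = design, n_mask_voxels = sum(mask),
         region_summary = region_summary),
    class = "group_mask"
  )
}

#' @export
print.group_mask <- function(x, ...) {
  cat(sprintf("<group_mask> %d voxels at q < %g (%s design)\n",
              x$n_mask_voxels, x$fdr_threshold, x$design))
  invisible(x)
}

#' Per-region voxel counts of a mask
#'
#' @param mask Logical 3D array.
#' @param labels `label_map` on the same grid.
#' @return Tibble with `region`, `voxels` (counts sum to the mask size,
#'   voxels outside any label reported as `unlabeled`), `pct_of_region`.
#' @export
summarize_mask_regions <- function(mask, labels) {
  stop_if_grid_mismatch(mask, labels$data, "mask and labels")
  rows <- purrr::map(seq_len(nrow(labels$table)), function(i) {
    lm_ <- labels$data == labels$table$label[i]
    tibble::tibble(
      region = labels$table$structure[i],
      voxels = sum(mask & lm_),
      pct_of_region = 100 * sum(mask & lm_) / max(1L, sum(lm_))
    )
  })
  out <- dplyr::bind_rows(rows)
  unlab <- sum(mask & labels$data == 0L)
  if (unlab > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      region = "unlabeled", voxels = unlab, pct_of_region = NA_real_
    ))
  }
  dplyr::arrange(out, dplyr::desc(.data$voxels))
}

#' Preprocess one subject's BOLD run
#'
#' Fixed pipeline order: confound regression first, then band-pass filtering.
#'
#' @param bold List with `data` (4D), `tr_s`, `confounds` (as produced by
#'   [simulate_bold()] or read from disk).
#' @param low,high Band edges in Hz.
#' @return 4D array of preprocessed series.
#' @export
preprocess_bold <- function(bold, low = 0.01, high = 0.1) {
  res <- regress_confounds(bold$data, bold$confounds)
  bandpass_filter(res, bold$tr_s, low, high)
}
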