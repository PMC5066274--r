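#' Laplacian phase unwrapping
#'
#' Solves the Poisson problem
#' `Lap(phi_u) = cos(phi_w) * Lap(sin(phi_w)) - sin(phi_w) * Lap(cos(phi_w))`
#' spectrally. The right-hand side equals the Laplacian of the true phase
#' wherever the true phase is smooth, so inversion recovers it up to an
#' additive constant (the zero-frequency component is set to 0) and a
#' harmonic residual. Operators act on the even-symmetric (mirror) extension
#' of the volume, which avoids wrap-around bias for non-periodic fields.
#'
#' With `congruence = TRUE` the smooth Poisson estimate is snapped back to
#' the measured phase modulo 2 pi (`phi_w + 2 pi * round((phi_u - phi_w) /
#' (2 pi))`), which removes the harmonic residual wherever it is below pi and
#' preserves the measured voxel noise; the reconstruction chain uses this
#' refinement.
#'
#' @param wrapped `vol_grid` of wrapped phase, values in (-pi, pi].
#' @param congruence Snap the estimate back to the measured phase modulo
#'   2 pi (default `FALSE`: return the raw zero-mean Poisson solution).
#' @return `vol_grid` of unwrapped phase.
#' @export
unwrap_phase_laplacian <- function(wrapped, congruence = FALSE) {
  stopifnot(is_vol_grid(wrapped))
  if (any(dim(wrapped$data) < 16L)) stop("grid must be >= 16 voxels per axis", call. = FALSE)
  if (any(wrapped$data <= -pi - 1e-9) || any(wrapped$data > pi + 1e-9)) {
    stop("wrapped phase must lie in (-pi, pi]", call. = FALSE)
  }
  vs <- wrapped$voxel_size_mm
  s <- sin(wrapped$data); co <- cos(wrapped$data)
  rhs <- co * laplacian_mirror(s, vs) - s * laplacian_mirror(co, vs)
  phi_u <- poisson_solve_mirror(rhs, vs)
  if (congruence) {
    # anchor the arbitrary additive constant at the circular mean of the
    # offset first, so the per-voxel cycle counts are not near half-integers
    delta <- phi_u - wrapped$data
    anchor <- atan2(mean(sin(delta)), mean(cos(delta)))
    phi_u <- wrapped$data + 2 * pi * round((delta - anchor) / (2 * pi))
  }
  vol_grid(phi_u, vs)
}

#' Brain mask from a GRE magnitude image
#'
#' A self-contained stand-in for FSL BET: voxels at or above
#' `fractional_threshold` times the robust maximum (98th percentile of
#' nonzero intensities) are kept, reduced to the largest 6-connected
#' component, and interior holes are filled. Deterministic.
#'
#' @param magnitude `vol_grid`, non-negative intensities.
#' @param fractional_threshold Fraction of the robust maximum (default 0.3).
#' @return Logical mask array.
#' @export
compute_brain_mask <- function(magnitude, fractional_threshold = 0.3) {
  stopifnot(is_vol_grid(magnitude))
  nz <- magnitude$data[magnitude$data > 0]
  if (length(nz) == 0L) stop("all-zero magnitude image", call. = FALSE)
  thr <- fractional_threshold * stats::quantile(nz, 0.98, names = FALSE)
  fill_holes(largest_component(magnitude$data >= thr))
}

#' Convert unwrapped phase to frequency shift
#'
#' @param unwrapped `vol_grid` of phase in radians.
#' @param echo_time_s Echo time in seconds (> 0).
#' @return `vol_grid` of frequency shift in Hz (`phi / (2*pi*TE)`).
#' @export
phase_to_frequency <- function(unwrapped, echo_time_s) {
  stopifnot(is_vol_grid(unwrapped))
  if (!(echo_time_s > 0)) stop("echo time must be positive", call. = FALSE)
  vol_grid(unwrapped$data / (2 * pi * echo_time_s), unwrapped$voxel_size_mm)
}

#' V-SHARP background-field removal
#'
#' Variable-kernel spherical-mean-value filtering: for integer kernel radii
#' from the maximum down to 1 voxel, the field is filtered with
#' `(delta - rho_r)` wherever the sphere of radius r fits entirely inside the
#' brain mask; each voxel keeps the estimate from the largest radius that
#' fits. Background (external-source) fields are harmonic inside the mask and
#' satisfy the spherical mean value property, so the filter annihilates them
#' while local fields pass. The SMV filtering is finally undone by k-space
#' deconvolution with `(delta - rho_max)`, with the inverse-filter gain
#' capped at `1/regularization` where `|1 - FT(rho_max)|` falls below the
#' regularization parameter (truncation of the ill-conditioned band). The
#' validity mask is the set of voxels where at least the 1-voxel sphere fits.
#'
#' @param freq `vol_grid` of frequency shift in Hz.
#' @param mask Logical brain mask.
#' @param max_radius_mm Maximum kernel radius in mm (default 4).
#' @param regularization Truncation threshold of the deconvolution filter, in
#'   (0, 1) (default 0.05).
#' @return List with `local` (`vol_grid`, Hz) and `validity` (logical mask).
#' @export
sharp_remove_background <- function(freq, mask, max_radius_mm = 4,
                                    regularization = 0.05) {
  stopifnot(is_vol_grid(freq))
  stop_if_grid_mismatch(freq$data, mask, "field and mask")
  if (!any(mask)) stop("brain mask is empty", call. = FALSE)
  vs <- freq$voxel_size_mm
  d <- dim(freq$data)
  r_max_vox <- max(1L, floor(max_radius_mm / min(vs)))
  f <- freq$data * mask
  m <- mask * 1
  combined <- array(0, d)
  assigned <- array(FALSE, d)
  ker_hat_max <- NULL
  for (r in seq.int(r_max_vox, 1L)) {
    ker <- sphere_kernel(d, vs, r * min(vs))
    ker_hat <- fft3(ker)
    if (is.null(ker_hat_max)) ker_hat_max <- ker_hat
    fits <- conv_fft(m, ker_hat) >= 1 - 1e-6
    filtered <- f - conv_fft(f, ker_hat)
    sel <- fits & !assigned
    combined[sel] <- filtered[sel]
    assigned <- assigned | fits
  }
  if (!any(assigned)) {
    stop("mask smaller than the smallest spherical kernel", call. = FALSE)
  }
  C <- 1 - Re(ker_hat_max)
  gain <- ifelse(abs(C) >= regularization, 1 / ifelse(C == 0, 1, C),
                 sign(C) / regularization)
  gain[C == 0] <- 1 / regularization
  local <- ifft3_real(fft3(combined * assigned) * gain) * assigned
  list(local = vol_grid(local, vs), validity = assigned)
}

#' Average per-echo local-field maps
#'
#' @param fields List of `vol_grid`s on a common grid.
#' @return `vol_grid`, the voxelwise arithmetic mean.
#' @export
average_echo_fields <- function(fields) {
  if (length(fields) < 1L) stop("need at least one field", call. = FALSE)
  for (f in fields) stop_if_grid_mismatch(f, fields[[1]], "echo fields")
  acc <- Reduce(`+`, lapply(fields, function(f) f$data))
  vol_grid(acc / length(fields), fields[[1]]$voxel_size_mm)
}

# Paige-Saunders LSQR for min ||A x - b|| with matrix-free operators.
lsqr_solve <- function(Afun, Atfun, b, tol = 1e-6, maxit = 300L) {
  beta0 <- sqrt(sum(b^2))
  x <- array(0, dim(b))
  if (beta0 == 0) return(list(x = x, iterations = 0L, converged = TRUE, relres = 0))
  u <- b / beta0
  v <- Atfun(u)
  alpha <- sqrt(sum(v^2))
  v <- v / alpha
  w <- v
  phibar <- beta0; rhobar <- alpha
  anorm2 <- alpha^2
  converged <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    u <- Afun(v) - alpha * u
    beta <- sqrt(sum(u^2))
    if (beta > 0) u <- u / beta
    v <- Atfun(u) - beta * v
    alpha <- sqrt(sum(v^2))
    if (alpha > 0) v <- v / alpha
    anorm2 <- anorm2 + alpha^2 + beta^2
    rho <- sqrt(rhobar^2 + beta^2)
    c_ <- rhobar / rho; s_ <- beta / rho
    theta <- s_ * alpha
    rhobar <- -c_ * alpha
    phi <- c_ * phibar; phibar <- s_ * phibar
    x <- x + (phi / rho) * w
    w <- v - (theta / rho) * w
    # S1: residual small; S2: least-squares optimality ||A'r|| small
    arnorm <- phibar * alpha * abs(c_)
    if (phibar / beta0 <= tol ||
        arnorm <= tol * sqrt(anorm2) * phibar) {
      converged <- TRUE
      break
    }
  }
  list(x = x, iterations = it, converged = converged, relres = phibar / beta0)
}

#' Dipole inversion by masked LSQR
#'
#' Solves `argmin_chi || M (F^-1 D F S chi - b) ||` with the k-space dipole
#' kernel D, the field-validity mask M and the source-support mask S, by the
#' iterative LSQR algorithm with zero initialization and no additional
#' regularization. Restricting the susceptibility sources to the head
#' support removes the ghost-source freedom of the unconstrained
#' minimum-norm solution (which systematically underestimates contrast when
#' the field is only observed inside the head). The field is scaled to ppm
#' before inversion (`b = local_Hz / f_Larmor * 1e6`) and the result
#' returned in ppb. Since D(0) = 0, any spatially constant offset is in the
#' null space; it is removed later by referencing.
#'
#' @param local_field `vol_grid` of background-free field in Hz.
#' @param validity Logical mask of valid field voxels.
#' @param field_strength_t Tesla.
#' @param support Logical mask of allowed susceptibility sources (default:
#'   the validity mask; the reconstruction chain passes the brain mask).
#' @param tol LSQR relative-residual tolerance (default 1e-6).
#' @param maxit Maximum iterations (default 300).
#' @return List: `chi` (`vol_grid`, ppb, unreferenced), `converged`,
#'   `iterations`, `relres`. Non-convergence is reported with a warning and
#'   the partial result flagged.
#' @export
invert_dipole_lsqr <- function(local_field, validity, field_strength_t = 7,
                               support = validity, tol = 1e-6, maxit = 300L) {
  stopifnot(is_vol_grid(local_field))
  stop_if_grid_mismatch(local_field$data, validity, "field and validity mask")
  if (!any(validity)) stop("validity mask is empty", call. = FALSE)
  d <- dim(local_field$data)
  D <- dipole_kernel(d, local_field$voxel_size_mm)
  M <- validity * 1
  S <- support * 1
  b <- (local_field$data / larmor_hz(field_strength_t)) * 1e6 * M
  Afun <- function(x) M * ifft3_real(D * fft3(S * x))
  Atfun <- function(y) S * ifft3_real(D * fft3(M * y))
  sol <- lsqr_solve(Afun, Atfun, b, tol = tol, maxit = maxit)
  if (!sol$converged) {
    warning(sprintf(
      "LSQR did not reach tol %.1e in %d iterations (relres %.3e); partial result",
      tol, sol$iterations, sol$relres
    ), call. = FALSE)
  }
  list(chi = vol_grid(sol$x * 1000, local_field$voxel_size_mm),
       converged = sol$converged, iterations = sol$iterations,
       relres = sol$relres)
}

#' Select the susceptibility reference region
#'
#' Among candidate regions (white-matter tracts, central CSF), returns the
#' one whose across-subject standard deviation of region-mean susceptibility
#' is lowest. Ties break deterministically to the first candidate in sorted
#' order (logged via message).
#'
#' @param roi_means Tibble with columns `subject_id`, `region`, `mean_chi`;
#'   one row per subject x candidate, no missing cells.
#' @param candidates Character vector of candidate region names (>= 2).
#' @return The selected region name.
#' @export
select_reference_region <- function(roi_means,
                                    candidates = c("white_matter", "csf_ventricles")) {
  stopifnot(length(candidates) >= 2L)
  sub <- roi_means[roi_means$region %in% candidates, ]
  wide <- tidyr::pivot_wider(sub[, c("subject_id", "region", "mean_chi")],
                             names_from = "region", values_from = "mean_chi")
  if (nrow(wide) < 2L) stop("need >= 2 subjects", call. = FALSE)
  miss <- setdiff(candidates, names(wide))
  if (length(miss) || anyNA(wide[candidates])) {
    stop("missing cells in candidate region means", call. = FALSE)
  }
  sds <- vapply(candidates, function(r) stats::sd(wide[[r]]), numeric(1))
  ord <- sort(candidates)
  sds <- sds[ord]
  best <- ord[which.min(sds)]
  if (sum(abs(sds - min(sds)) < 1e-12) > 1L) {
    message(sprintf("reference-region tie; taking first in sorted order: %s", best))
  }
  best
}

#' Reference a susceptibility map to a region
#'
#' Subtracts the mean susceptibility over the reference region (within the
#' validity mask) everywhere, and records the removed offset. Idempotent.
#'
#' @param chi `vol_grid` of susceptibility in ppb.
#' @param labels A `label_map`.
#' @param reference Structure name of the reference region.
#' @param validity Logical validity mask (default: everywhere).
#' @return A `susceptibility_map`: list with `chi` (`vol_grid`), `validity`,
#'   `reference_region`, `reference_mean_removed` (ppb).
#' @export
reference_susceptibility <- function(chi, labels, reference = "csf_ventricles",
                                     validity = NULL) {
  stopifnot(is_vol_grid(chi))
  if (is.null(validity)) validity <- array(TRUE, dim(chi$data))
  ref_mask <- structure_mask(labels, reference) & validity
  if (!any(ref_mask)) stop("reference region empty within validity mask", call. = FALSE)
  offset <- mean(chi$data[ref_mask])
  structure(
    list(chi = vol_grid(chi$data - offset, chi$voxel_size_mm),
         validity = validity,
         reference_region = reference,
         reference_mean_removed = offset),
    class = "susceptibility_map"
  )
}

#' @export
print.susceptibility_map <- function(x, ...) {
  cat(sprintf(
    "<susceptibility_map> %s voxels, referenced to %s (offset %.3f ppb removed)\n",
    paste(dim(x$chi$data), collapse = "x"), x$reference_region,
    x$reference_mean_removed
  ))
  invisible(x)
}

#' Full single-subject QSM reconstruction (unreferenced)
#'
#' Chains the per-subject stages in protocol order: Laplacian unwrapping of
#' each selected echo, brain masking from the first selected echo's
#' magnitude, phase-to-frequency conversion, V-SHARP background removal per
#' echo, echo averaging, and LSQR dipole inversion. Referencing is a cohort
#' level step (see [select_reference_region()]).
#'
#' @param me_phase A `multi_echo_phase`.
#' @param config A `pipeline_config` (QSM section used).
#' @return List: `chi` (`vol_grid`, ppb, unreferenced), `validity`,
#'   `brain_mask`, `lsqr` (convergence info).
#' @export
qsm_reconstruct <- function(me_phase, config = default_config()) {
  q <- config$qsm
  echoes <- q$echoes_used
  echoes <- echoes[echoes <= length(me_phase$echo_times_s)]
  if (length(echoes) < 1L) stop("no usable echoes selected", call. = FALSE)
  mask <- compute_brain_mask(me_phase$magnitude[[echoes[1]]],
                             q$bet_fractional_threshold)
  locals <- vector("list", length(echoes))
  validity <- NULL
  for (i in seq_along(echoes)) {
    e <- echoes[i]
    uw <- unwrap_phase_laplacian(me_phase$phase[[e]], congruence = TRUE)
    fr <- phase_to_frequency(uw, me_phase$echo_times_s[e])
    sh <- sharp_remove_background(fr, mask, q$sharp_max_radius_mm,
                                  q$sharp_regularization)
    locals[[i]] <- sh$local
    validity <- if (is.null(validity)) sh$validity else validity & sh$validity
  }
  avg <- average_echo_fields(locals)
  inv <- invert_dipole_lsqr(avg, validity, me_phase$field_strength_t,
                            support = mask, tol = q$lsqr_tol,
                            maxit = q$lsqr_maxit)
  list(chi = inv$chi, validity = validity, brain_mask = mask,
       lsqr = inv[c("converged", "iterations", "relres")])
}
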