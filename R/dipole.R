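GYROMAGNETIC_MHZ_PER_T <- 42.577

#' Larmor frequency in Hz
#'
#' @param field_strength_t Main field strength in Tesla.
#' @return Proton Larmor frequency in Hz (42.577 MHz/T x B0).
#' @export
larmor_hz <- function(field_strength_t) GYROMAGNETIC_MHZ_PER_T * 1e6 * field_strength_t

#' Forward dipole field: susceptibility to frequency shift
#'
#' Computes the magnetic-field perturbation induced by a susceptibility
#' distribution via k-space multiplication with the unit dipole kernel:
#' `df = f_Larmor * IFFT[ D(k) * FFT(chi * 1e-9) ]` with chi in ppb. The
#' convention D(0) = 0 means a uniform susceptibility produces no shift.
#'
#' @param chi A `vol_grid` of susceptibility in ppb.
#' @param field_strength_t Field strength in Tesla (default 7).
#' @return A `vol_grid` of frequency shift in Hz.
#' @export
forward_dipole_field <- function(chi, field_strength_t = 7) {
  stopifnot(is_vol_grid(chi))
  if (any(!is.finite(chi$data))) stop("chi contains non-finite values", call. = FALSE)
  if (any(dim(chi$data) < 16L)) stop("grid must be at least 16 voxels per axis", call. = FALSE)
  D <- dipole_kernel(dim(chi$data), chi$voxel_size_mm)
  df <- larmor_hz(field_strength_t) * ifft3_real(D * fft3(chi$data * 1e-9))
  vol_grid(df, chi$voxel_size_mm)
}

#' Multi-echo phase container
#'
#' @param phase List of `vol_grid`s, wrapped phase in radians, one per echo,
#'   values strictly in (-pi, pi].
#' @param magnitude List of `vol_grid`s, one per echo, arbitrary units.
#' @param echo_times_s Strictly increasing echo times in seconds (>= 2).
#' @param field_strength_t Field strength in Tesla.
#' @return A `multi_echo_phase` object.
#' @export
multi_echo_phase <- function(phase, magnitude, echo_times_s, field_strength_t = 7) {
  if (length(echo_times_s) < 2L) stop("need at least 2 echoes", call. = FALSE)
  if (any(diff(echo_times_s) <= 0)) stop("echo times must be strictly increasing", call. = FALSE)
  if (length(phase) != length(echo_times_s) || length(magnitude) != length(echo_times_s)) {
    stop("one phase and magnitude volume per echo required", call. = FALSE)
  }
  for (p in phase) {
    if (any(p$data <= -pi - 1e-12) || any(p$data > pi + 1e-12)) {
      stop("wrapped phase must lie in (-pi, pi]", call. = FALSE)
    }
    stop_if_grid_mismatch(p, phase[[1]], "echo volumes")
  }
  structure(
    list(phase = phase, magnitude = magnitude,
         echo_times_s = as.numeric(echo_times_s),
         field_strength_t = field_strength_t),
    class = "multi_echo_phase"
  )
}

#' Wrap phase into (-pi, pi]
#'
#' @param phi Numeric array or vector of phase in radians.
#' @return Values wrapped to the principal interval.
#' @export
wrap_phase <- function(phi) {
  out <- (phi + pi) %% (2 * pi) - pi
  # put the branch point at +pi, not -pi
  out[out <= -pi + 1e-15 & !is.na(out)] <- pi
  out
}

#' Simulate wrapped multi-echo GRE phase from a frequency-shift map
#'
#' The complex signal per echo is `m * exp(i * 2*pi*df*TE)` with unit
#' magnitude inside the head (where `mask` is TRUE) and zero outside, plus
#' circular complex Gaussian noise of sd `1/snr` per channel. Returned phase
#' is the principal argument, strictly in (-pi, pi].
#'
#' @param delta_f `vol_grid` of frequency shift in Hz.
#' @param echo_times_s Echo times in seconds (default 6/12/18 ms).
#' @param snr Signal-to-noise ratio of the complex signal; `Inf` for
#'   noiseless.
#' @param mask Logical array, the head support (default all TRUE).
#' @param field_strength_t Tesla.
#' @param seed Integer seed for the noise draw.
#' @return A `multi_echo_phase`.
#' @export
simulate_multiecho_phase <- function(delta_f, echo_times_s = c(0.006, 0.012, 0.018),
                                     snr = 50, mask = NULL, field_strength_t = 7,
                                     seed = 1L) {
  stopifnot(is_vol_grid(delta_f))
  if (!(snr > 0)) stop("snr must be positive", call. = FALSE)
  d <- dim(delta_f$data)
  if (is.null(mask)) mask <- array(TRUE, d)
  stop_if_grid_mismatch(delta_f$data, mask, "field and mask")
  phase <- vector("list", length(echo_times_s))
  magnitude <- vector("list", length(echo_times_s))
  with_local_seed(seed, {
    for (e in seq_along(echo_times_s)) {
      phi <- 2 * pi * delta_f$data * echo_times_s[e]
      sig <- (mask * 1) * exp(1i * phi)
      if (is.finite(snr)) {
        sig <- sig + (stats::rnorm(length(sig)) + 1i * stats::rnorm(length(sig))) / snr
      }
      phase[[e]] <- vol_grid(array(wrap_phase(Arg(sig)), d), delta_f$voxel_size_mm)
      magnitude[[e]] <- vol_grid(array(Mod(sig), d), delta_f$voxel_size_mm)
    }
  })
  multi_echo_phase(phase, magnitude, echo_times_s, field_strength_t)
}
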