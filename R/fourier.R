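# Spectral helpers shared by the forward model, unwrapping and SHARP.
# All operators act on plain 3D arrays; callers own the vol_grid wrapping.

fft_freq <- function(n, d = 1) {
  # DFT sample frequencies in cycles per unit, numpy layout
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  k / (n * d)
}

fft3 <- function(x) stats::fft(x)

ifft3_real <- function(X) Re(stats::fft(X, inverse = TRUE)) / length(X)

# Frequency-squared arrays |k|^2 and k_z^2 broadcast to the grid shape
k_arrays <- function(shape, voxel_size_mm) {
  kx <- fft_freq(shape[1], voxel_size_mm[1])
  ky <- fft_freq(shape[2], voxel_size_mm[2])
  kz <- fft_freq(shape[3], voxel_size_mm[3])
  kx2 <- array(rep(kx^2, times = shape[2] * shape[3]), shape)
  ky2 <- array(rep(rep(ky^2, each = shape[1]), times = shape[3]), shape)
  kz2 <- array(rep(kz^2, each = shape[1] * shape[2]), shape)
  list(k2 = kx2 + ky2 + kz2, kz2 = kz2)
}

#' Unit dipole kernel in k-space
#'
#' The Lorentz-corrected point-dipole response `D(k) = 1/3 - kz^2/|k|^2`
#' relating susceptibility to the induced fractional field shift along B0
#' (z axis). The value at k = 0 is set to 0, which makes spatially constant
#' susceptibility unobservable (the solver's null space; removed later by
#' referencing).
#'
#' @param shape Integer length-3 grid dimensions.
#' @param voxel_size_mm Voxel size in mm.
#' @return 3D numeric array of kernel values in DFT layout.
#' @export
dipole_kernel <- function(shape, voxel_size_mm = c(1, 1, 1)) {
  ka <- k_arrays(shape, voxel_size_mm)
  D <- 1 / 3 - ka$kz2 / ka$k2
  D[ka$k2 == 0] <- 0
  D
}

# Eigenvalues of the 6-neighbour discrete Laplacian under periodic boundary,
# in units of 1/mm^2; the zero mode is returned as 0.
laplacian_eigenvalues <- function(shape, voxel_size_mm) {
  ev_axis <- function(n, d) (2 * cos(2 * pi * seq(0L, n - 1L) / n) - 2) / d^2
  ex <- ev_axis(shape[1], voxel_size_mm[1])
  ey <- ev_axis(shape[2], voxel_size_mm[2])
  ez <- ev_axis(shape[3], voxel_size_mm[3])
  array(rep(ex, times = shape[2] * shape[3]), shape) +
    array(rep(rep(ey, each = shape[1]), times = shape[3]), shape) +
    array(rep(ez, each = shape[1] * shape[2]), shape)
}

# Even-symmetric (mirror) extension to double size along every axis. The
# extension makes any field periodic and continuous, so spectral Laplacian /
# Poisson operators apply without wrap-around bias; equivalent to working in
# a DCT basis.
mirror_extend <- function(x) {
  d <- dim(x)
  x <- x[c(seq_len(d[1]), rev(seq_len(d[1]))), , , drop = FALSE]
  x <- x[, c(seq_len(d[2]), rev(seq_len(d[2]))), , drop = FALSE]
  x[, , c(seq_len(d[3]), rev(seq_len(d[3]))), drop = FALSE]
}

mirror_crop <- function(x, shape) {
  x[seq_len(shape[1]), seq_len(shape[2]), seq_len(shape[3]), drop = FALSE]
}

# Apply the discrete Laplacian spectrally on the mirror-extended grid
laplacian_mirror <- function(x, voxel_size_mm) {
  d <- dim(x)
  xe <- mirror_extend(x)
  L <- laplacian_eigenvalues(dim(xe), voxel_size_mm)
  mirror_crop(ifft3_real(L * fft3(xe)), d)
}

# Solve the Poisson equation Laplacian(phi) = rhs on the mirror-extended
# grid; the zero-frequency component of phi is set to 0 (solution defined
# up to an additive constant).
poisson_solve_mirror <- function(rhs, voxel_size_mm) {
  d <- dim(rhs)
  re <- mirror_extend(rhs)
  L <- laplacian_eigenvalues(dim(re), voxel_size_mm)
  R <- fft3(re)
  L[abs(L) < .Machine$double.eps] <- Inf
  mirror_crop(ifft3_real(R / L), d)
}

# Normalized spherical averaging kernel of radius r_mm, centred at the DFT
# origin with circular coordinates (ready for periodic convolution).
sphere_kernel <- function(shape, voxel_size_mm, r_mm) {
  ax <- function(n, d) {
    j <- seq_len(n) - 1L
    (pmin(j, n - j) * d)^2
  }
  dx2 <- ax(shape[1], voxel_size_mm[1])
  dy2 <- ax(shape[2], voxel_size_mm[2])
  dz2 <- ax(shape[3], voxel_size_mm[3])
  r2 <- array(rep(dx2, times = shape[2] * shape[3]), shape) +
    array(rep(rep(dy2, each = shape[1]), times = shape[3]), shape) +
    array(rep(dz2, each = shape[1] * shape[2]), shape)
  ker <- (r2 <= r_mm^2 + 1e-9) * 1
  ker / sum(ker)
}

# Periodic convolution with a pre-transformed kernel
conv_fft <- function(x, ker_hat) ifft3_real(fft3(x) * ker_hat)
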