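test_that("Laplacian unwrapping recovers smooth, wrapped and constant phase", {
  n <- 48
  vs <- c(1, 1, 1)
  # smooth small phase, no wraps: output equals input up to a constant
  g <- grid_coords(n)
  sm <- (pi / 5) * sin(2 * pi * g$x / n) * cos(2 * pi * g$z / n)
  uw <- unwrap_phase_laplacian(vol_grid(sm, vs))
  d <- uw$data - sm
  expect_lt(max(abs(d - mean(d))), 0.05)

  # constant phase: constant output (zero-mean convention)
  uc <- unwrap_phase_laplacian(vol_grid(array(pi / 2, rep(n, 3)), vs))
  expect_lt(diff(range(uc$data)), 1e-8)

  expect_error(unwrap_phase_laplacian(vol_grid(array(4, rep(16, 3)))), "pi")
})

test_that("a 6*pi linear ramp unwraps in the volume interior", {
  n <- 64
  ramp <- array(rep(seq(0, 6 * pi, length.out = n), times = n * n), rep(n, 3))
  w <- vol_grid(array(wrap_phase(ramp), rep(n, 3)))
  uw <- unwrap_phase_laplacian(w)
  d <- uw$data - ramp
  d <- d - mean(d)
  int <- 13:(n - 12)
  expect_lt(max(abs(d[int, int, int])), 0.1)
  # congruence restoration removes the harmonic boundary residual entirely
  uwc <- unwrap_phase_laplacian(w, congruence = TRUE)
  dc <- uwc$data - ramp
  expect_lt(max(abs(dc - mean(dc))), 1e-9)
})

test_that("brain masking finds the head and survives background speckle", {
  n <- 48
  g <- grid_coords(n)
  ell <- (g$x / 18)^2 + (g$y / 20)^2 + (g$z / 16)^2 <= 1
  mag <- array(0, rep(n, 3)); mag[ell] <- 1
  m <- compute_brain_mask(vol_grid(mag), 0.3)
  expect_identical(m, ell)

  # 5% speckle outside: below threshold and disconnected, mask unchanged
  set.seed(7)
  spk <- mag
  out <- which(!ell)
  spk[sample(out, 200)] <- 0.05
  m2 <- compute_brain_mask(vol_grid(spk), 0.3)
  expect_identical(m2, ell)

  expect_error(compute_brain_mask(vol_grid(array(0, rep(16, 3)))), "zero")
})

test_that("phase converts to frequency by 1/(2 pi TE)", {
  v <- vol_grid(array(2 * pi, rep(16, 3)))
  expect_equal(unique(as.numeric(phase_to_frequency(v, 1)$data)), 1)
  v2 <- vol_grid(array(0.7540, rep(16, 3)))
  expect_equal(unique(as.numeric(phase_to_frequency(v2, 0.012)$data)), 10.0,
               tolerance = 1e-3)
  expect_equal(unique(as.numeric(phase_to_frequency(vol_grid(array(0, rep(16, 3))),
                                                    0.01)$data)), 0)
  expect_error(phase_to_frequency(v, 0), "positive")
})

test_that("V-SHARP suppresses external-source fields and passes internal ones", {
  n <- 64
  g <- grid_coords(n)
  r0 <- sqrt(g$x^2 + g$y^2 + g$z^2)
  mask <- r0 <= 24
  chie <- array(0, rep(n, 3)); chie[sqrt(g$x^2 + g$y^2 + (g$z - 29)^2) <= 4] <- 500
  fe <- forward_dipole_field(vol_grid(chie), 7)
  chii <- array(0, rep(n, 3)); chii[r0 <= 6] <- 100
  fi <- forward_dipole_field(vol_grid(chii), 7)

  se <- sharp_remove_background(fe, mask, 4, 0.05)
  si <- sharp_remove_background(fi, mask, 4, 0.05)
  v <- se$validity
  expect_gte(1 - rms(se$local$data[v]) / rms(fe$data[v]), 0.90)
  fint <- fi$data[v] - mean(fi$data[v])
  expect_lte(rms(si$local$data[v] - fint) / rms(fint), 0.15)

  # zero field -> zero field (linearity), validity inside the mask
  s0 <- sharp_remove_background(vol_grid(array(0, rep(n, 3))), mask, 4, 0.05)
  expect_equal(max(abs(s0$local$data)), 0)
  expect_true(all(mask[s0$validity]))
  expect_error(sharp_remove_background(fe, array(FALSE, rep(n, 3))), "empty")
})

test_that("echo-field averaging is exact and reduces noise like 1/sqrt(2)", {
  f <- vol_grid(array(rnorm(16^3), rep(16, 3)))
  expect_identical(average_echo_fields(list(f, f))$data, f$data)
  neg <- vol_grid(-f$data)
  expect_equal(max(abs(average_echo_fields(list(f, neg))$data)), 0)

  set.seed(5)
  base <- array(rnorm(24^3, sd = 2), rep(24, 3))
  n1 <- vol_grid(base + array(rnorm(24^3), rep(24, 3)))
  n2 <- vol_grid(base + array(rnorm(24^3), rep(24, 3)))
  resid <- average_echo_fields(list(n1, n2))$data - base
  expect_equal(sd(resid), 1 / sqrt(2), tolerance = 0.05)
  bad <- vol_grid(array(0, rep(8, 3)))
  expect_error(average_echo_fields(list(f, bad)), "grids")
})

test_that("LSQR dipole inversion is consistent with the forward model", {
  n <- 48
  sp <- sphere_chi(n, radius = 7, value = 50)
  f <- forward_dipole_field(sp$chi, 7)
  mask <- array(TRUE, rep(n, 3))
  inv <- suppressWarnings(invert_dipole_lsqr(f, mask, 7, tol = 1e-6, maxit = 150))
  rec <- inv$chi$data - mean(inv$chi$data[sp$r > 18])
  expect_lt(abs(mean(rec[sp$r <= 6]) - 50) / 50, 0.10)

  # b = 0 -> chi = 0
  z <- invert_dipole_lsqr(vol_grid(array(0, rep(16, 3))), array(TRUE, rep(16, 3)))
  expect_equal(max(abs(z$chi$data)), 0)
  expect_true(z$converged)

  # constant chi offset is invisible: same field, removed at referencing
  f2 <- forward_dipole_field(vol_grid(sp$chi$data + 20), 7)
  expect_equal(f2$data, f$data, tolerance = 1e-10)
  expect_error(invert_dipole_lsqr(f, array(FALSE, rep(n, 3))), "empty")
})

test_that("reconstruction is linear in the field for pre-unwrapped input", {
  n <- 32
  set.seed(11)
  sp <- sphere_chi(n, radius = 5, value = 30)
  f <- forward_dipole_field(sp$chi, 7)
  g <- grid_coords(n)
  mask <- sqrt(g$x^2 + g$y^2 + g$z^2) <= 13
  r1 <- sharp_remove_background(f, mask, 3, 0.05)
  i1 <- suppressWarnings(invert_dipole_lsqr(r1$local, r1$validity, 7,
                                            support = mask, maxit = 60))
  f3 <- vol_grid(3 * f$data)
  r3 <- sharp_remove_background(f3, mask, 3, 0.05)
  i3 <- suppressWarnings(invert_dipole_lsqr(r3$local, r3$validity, 7,
                                            support = mask, maxit = 60))
  expect_equal(i3$chi$data, 3 * i1$chi$data, tolerance = 1e-6)
})

test_that("reference region selection minimizes across-subject SD with sorted ties", {
  tab <- tibble::tibble(
    subject_id = rep(sprintf("s%d", 1:4), each = 2),
    region = rep(c("white_matter", "csf_ventricles"), 4),
    mean_chi = c(1, 10, 2, 10.1, 1.5, 9.9, 0.5, 10.05)
  )
  expect_equal(select_reference_region(tab), "csf_ventricles")

  tie <- tibble::tibble(
    subject_id = rep(c("a", "b"), each = 2),
    region = rep(c("zeta", "alpha"), 2),
    mean_chi = c(1, 3, 2, 4)  # both sd = sqrt(0.5)
  )
  expect_message(
    got <- select_reference_region(tie, candidates = c("zeta", "alpha")),
    "tie"
  )
  expect_equal(got, "alpha")

  miss <- tab[-1, ]
  expect_error(select_reference_region(miss), "missing")
})

test_that("referencing zeroes the reference mean, records the offset, idempotent", {
  labels <- make_phantom_labels(c(32, 32, 32))
  chi <- array(0, c(32, 32, 32))
  csf <- structure_mask(labels, "csf_ventricles")
  chi[csf] <- 5.8
  chi[!csf] <- 12
  sm <- reference_susceptibility(vol_grid(chi), labels, "csf_ventricles")
  expect_equal(sm$reference_mean_removed, 5.8)
  expect_lt(abs(mean(sm$chi$data[csf])), 1e-6)
  sm2 <- reference_susceptibility(sm$chi, labels, "csf_ventricles", sm$validity)
  expect_equal(sm2$reference_mean_removed, 0, tolerance = 1e-12)
  expect_equal(sm2$chi$data, sm$chi$data)
  expect_error(reference_susceptibility(vol_grid(chi), labels, "csf_ventricles",
                                        array(FALSE, c(32, 32, 32))),
               "empty")
})

test_that("referenced output is invariant to constant offsets in true chi", {
  labels <- make_phantom_labels(c(32, 32, 32))
  spec <- cohort_spec(shape = c(32L, 32L, 32L))
  s <- one_subject()
  asg <- assign_susceptibility(labels, s, spec, seed = 6)
  head <- labels$data > 0
  for (off in c(0, 50)) {
    f <- forward_dipole_field(vol_grid(asg$chi$data + off), 7)
    sh <- sharp_remove_background(f, head, 3, 0.05)
    inv <- suppressWarnings(invert_dipole_lsqr(sh$local, sh$validity, 7,
                                               support = head, maxit = 60))
    sm <- reference_susceptibility(inv$chi, labels, "csf_ventricles", sh$validity)
    if (off == 0) base <- sm$chi$data else {
      expect_equal(sm$chi$data, base, tolerance = 1e-6)
    }
  }
})
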