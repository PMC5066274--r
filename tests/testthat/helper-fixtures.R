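# Shared small fixtures, built in code at load time.

# Coordinate arrays centred on the grid, in voxel units
grid_coords <- function(n) {
  cx <- (seq_len(n) - 0.5) - n / 2
  list(
    x = array(rep(cx, times = n * n), rep(n, 3)),
    y = array(rep(rep(cx, each = n), times = n), rep(n, 3)),
    z = array(rep(cx, each = n * n), rep(n, 3))
  )
}

sphere_chi <- function(n, radius, value = 100, center = c(0, 0, 0)) {
  g <- grid_coords(n)
  r <- sqrt((g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2)
  chi <- array(0, rep(n, 3))
  chi[r <= radius] <- value
  list(chi = vol_grid(chi, c(1, 1, 1)), r = r, g = g)
}

rms <- function(x) sqrt(mean(x^2))

# One-row subject tibble for generator tests
one_subject <- function(group = "control", apoe = FALSE) {
  as_subject_table(data.frame(
    subject_id = "sub-001", group = group, apoe_e4 = apoe,
    age = 72, gender = "M"
  ))
}

# Small cohort spec used across tests (fast, all modalities)
test_smoke_spec <- function(...) smoke_cohort_spec(...)
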