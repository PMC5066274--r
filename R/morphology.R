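# 3D binary morphology on logical arrays, 6-connected, implemented with
# vectorized axis shifts (no external image library needed at these sizes).

shift_array <- function(x, axis, by, fill = FALSE) {
  d <- dim(x)
  n <- d[axis]
  if (abs(by) >= n) return(array(fill, d))
  idx <- lapply(d, seq_len)
  src <- seq_len(n) - by
  valid <- src >= 1 & src <= n
  out <- array(fill, d)
  idx_dst <- idx; idx_dst[[axis]] <- which(valid)
  idx_src <- idx; idx_src[[axis]] <- src[valid]
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    x[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

neighbor_reduce <- function(x, op, fill) {
  out <- x
  for (axis in 1:3) {
    for (by in c(-1L, 1L)) {
      out <- op(out, shift_array(x, axis, by, fill = fill))
    }
  }
  out
}

#' Morphological erosion of a binary mask
#'
#' `n_voxels` iterations of 6-connected erosion; voxels outside the array
#' border count as background. An empty result is legal and produces a
#' warning at the call sites that drop structures.
#'
#' @param mask Logical 3D array.
#' @param n_voxels Number of erosion iterations (>= 0).
#' @return Logical array of the same shape.
#' @export
erode_mask <- function(mask, n_voxels = 2L) {
  stopifnot(length(dim(mask)) == 3L)
  if (n_voxels < 0) stop("n_voxels must be >= 0", call. = FALSE)
  out <- mask
  n <- as.integer(n_voxels)
  while (n > 0L && any(out)) {
    out <- neighbor_reduce(out, `&`, fill = FALSE)
    n <- n - 1L
  }
  if (n > 0L) out[] <- FALSE
  out
}

dilate_mask <- function(mask, n_voxels = 1L) {
  out <- mask
  for (i in seq_len(n_voxels)) out <- neighbor_reduce(out, `|`, fill = FALSE)
  out
}

# Largest 6-connected component, by iterative minimum-label propagation.
largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  d <- dim(mask)
  lab <- array(Inf, d)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    nxt <- neighbor_reduce(lab, pmin, fill = Inf)
    nxt[!mask] <- Inf
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  ids <- lab[mask]
  counts <- table(ids)
  keep <- as.numeric(names(counts)[which.max(counts)])
  out <- array(FALSE, d)
  out[mask] <- ids == keep
  out
}

# Fill interior cavities: background voxels not 6-connected to the array
# border become foreground.
fill_holes <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  reach <- array(FALSE, d)
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  reach[bg & border] <- TRUE
  repeat {
    nxt <- (reach | neighbor_reduce(reach, `|`, fill = FALSE)) & bg
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  mask | (bg & !reach)
}
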