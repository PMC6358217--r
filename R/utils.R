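# Internal numeric helpers shared across modules.

# Round half away from the lower index. Unlike base round(), which rounds
# half to even, this is exactly equivariant under the 90-degree grid
# rotations used in the invariance checks.
round_half_up <- function(x) floor(x + 0.5)

# Rotate a matrix 90 degrees clockwise: (r, c) -> (c, nrow + 1 - r).
rot90_cw <- function(m) {
  t(m[nrow(m):1, , drop = FALSE])
}

# Rotate (row, col) pixel coordinates to match rot90_cw(image).
rot90_points_cw <- function(points, nrow_img) {
  cbind(row = points[, 2], col = nrow_img + 1 - points[, 1])
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort(sprintf("`%s` must be a numeric matrix (single-channel 2D image).", arg))
  }
  invisible(image)
}

in_bounds <- function(points, dim) {
  points[, 1] >= 1 & points[, 1] <= dim[1] & points[, 2] >= 1 & points[, 2] <= dim[2]
}

# Circular moving average over the rows of an n x 2 coordinate matrix.
smooth_closed_polyline <- function(points, window = 5) {
  n <- nrow(points)
  if (window <= 1 || n <= window) return(points)
  half <- (window - 1L) %/% 2L
  out <- points * 0
  for (k in -half:half) {
    out <- out + points[(((seq_len(n) - 1L) + k) %% n) + 1L, , drop = FALSE]
  }
  out / window
}

# Length of each step of a closed polyline (step i joins row i to row i+1,
# the last step closing back to row 1). Returns a vector of length nrow(p).
closed_step_lengths <- function(p) {
  nxt <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  sqrt(rowSums((nxt - p)^2))
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}
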