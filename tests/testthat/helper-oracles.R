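# Independent oracles and shared fixtures for the test suite. These
# re-derive expected values from first principles (closed forms or brute
# force), never by calling the code under test.

# Ramanujan's second approximation to the ellipse perimeter; accurate to
# far better than 0.1% for the aspect ratios used here.
ramanujan_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# Brute-force two-sided Mann-Whitney p value by enumerating every
# assignment of the pooled observations to the two groups. Returns U for
# `x` and the two-sided p (total null probability of all assignments with
# a U at least as far from n1*n2/2 as the observed one).
mw_enumeration_oracle <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  mid <- n1 * n2 / 2
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, u_of)
  p <- mean(abs(us - mid) >= abs(u_obs - mid) - 1e-12)
  list(u = u_obs, p = p)
}

# Exhaustive search for the brightest pixel within a Euclidean radius,
# ties broken by lowest row then lowest column (mirrors the documented
# snapping contract, implemented independently with explicit loops).
snap_oracle <- function(image, at, radius) {
  best <- NULL
  best_val <- -Inf
  for (r in seq_len(nrow(image))) {
    for (c in seq_len(ncol(image))) {
      if ((r - at[1])^2 + (c - at[2])^2 <= radius^2) {
        v <- image[r, c]
        if (v > best_val) {
          best_val <- v
          best <- c(r, c)
        }
      }
    }
  }
  best
}

# 90-degree clockwise rotation of an image and of (row, col) points, kept
# local to the tests so invariance checks do not reuse package internals.
rot_image_cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
rot_point_cw <- function(pt, nrow_img) c(pt[2], nrow_img + 1 - pt[1])
rot_anchors_cw <- function(anchors, nrow_img) {
  anchor_points(
    rot_point_cw(anchors$a1, nrow_img),
    rot_point_cw(anchors$a2, nrow_img),
    rot_point_cw(anchors$p, nrow_img)
  )
}

# Closed polygon approximating a circle: `n` vertices of radius `r` around
# `center` (row, col). Non-integer coordinates, so membrane_trace() treats
# it as a polygon (exact arc lengths, no smoothing). theta = 0 is the top
# of the circle (lowest row); theta increases towards larger columns.
circle_polygon <- function(center = c(100, 100), r = 360 / (2 * pi),
                           n = 360, theta0 = 0) {
  th <- (theta0 + seq(0, 360 - 360 / n, by = 360 / n)) * pi / 180
  cbind(center[1] - r * cos(th), center[2] + r * sin(th))
}

# Minimal hand-built domain measurement, for unit-testing compute_metrics()
# arithmetic in isolation from the imaging pipeline.
fake_measurement <- function(label, mean_intensity, length) {
  structure(
    list(label = label, mean_intensity = mean_intensity, length = length,
         length_um = length, quantity = mean_intensity * length),
    class = "domain_measurement"
  )
}

fake_cytoplasm <- function(mean_intensity, area) {
  structure(
    list(mean_intensity = mean_intensity, area = area,
         quantity = mean_intensity * area),
    class = "cytoplasm_measurement"
  )
}

# A noiseless nurse-free oocyte spec used by several geometry tests.
plain_spec <- function(...) {
  oocyte_spec(
    nurse = list(present = FALSE),
    noise = list(gaussian_sd = 0, poisson = FALSE),
    ...
  )
}

# Run the full quantification on a generated oocyte, measuring the nurse
# membranes from the generator's masks (as a user would from the image).
quantify_generated <- function(oo, config = oopolar_config()) {
  if (any(oo$truth$simple_mask)) {
    quantify_oocyte(
      oo$image, oo$truth$anchors, config,
      simple_mean = measure_mask_mean(oo$image, oo$truth$simple_mask),
      double_mean = measure_mask_mean(oo$image, oo$truth$double_mask)
    )
  } else {
    quantify_oocyte(oo$image, oo$truth$anchors, config)
  }
}
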