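#' Masked two-channel image pair for colocalization
#'
#' Bundles two aligned single-plane channels, a region-of-interest mask
#' (typically the cytoplasm), and per-channel thresholds for the Manders
#' coefficients. Thresholds default to the masked Otsu value
#' ([auto_threshold()]).
#'
#' @param ch1,ch2 Numeric matrices of identical dimensions (e.g. the
#'   GFP-tagged protein and a compartment marker).
#' @param mask Logical matrix; defaults to all pixels.
#' @param thresholds Numeric length-2 vector of per-channel thresholds, or
#'   `NULL` to auto-threshold.
#' @return A `coloc_pair` object.
#' @export
coloc_pair <- function(ch1, ch2, mask = NULL, thresholds = NULL) {
  check_image(ch1, "ch1")
  check_image(ch2, "ch2")
  if (!identical(dim(ch1), dim(ch2))) abort("Channels must have identical shapes.")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(ch1), ncol(ch1))
  if (!identical(dim(mask), dim(ch1))) abort("Mask must match the channel shape.")
  if (!any(mask)) abort("Mask is empty.")
  if (is.null(thresholds)) {
    thresholds <- c(auto_threshold(ch1, mask), auto_threshold(ch2, mask))
  }
  if (length(thresholds) != 2 || any(thresholds < 0)) {
    abort("`thresholds` must be two non-negative numbers.")
  }
  structure(list(ch1 = ch1, ch2 = ch2, mask = mask, thresholds = thresholds),
            class = "coloc_pair")
}

#' Deterministic intensity threshold within a mask
#'
#' Otsu's method on a 256-bin histogram of the masked pixel values:
#' maximises the between-class variance, breaking ties at the lowest
#' threshold.
#'
#' @param channel Numeric matrix.
#' @param mask Logical matrix (default: all pixels).
#' @param n_bins Histogram bins.
#' @return The threshold grey level.
#' @export
auto_threshold <- function(channel, mask = NULL, n_bins = 256) {
  check_image(channel, "channel")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(channel), ncol(channel))
  v <- channel[mask]
  rng <- range(v)
  if (diff(rng) == 0) abort("Threshold error: channel is constant within the mask.")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE), nbins = n_bins)
  w <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  valid <- omega > 0 & omega < 1
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[valid] <- (mu_t * omega[valid] - mu[valid])^2 /
    (omega[valid] * (1 - omega[valid]))
  k <- which.max(sigma_b)
  breaks[k + 1]
}

masked_values <- function(pair) {
  list(v1 = pair$ch1[pair$mask], v2 = pair$ch2[pair$mask])
}

#' Pearson correlation within the mask
#'
#' Sample Pearson correlation of the two channels over masked pixels only.
#' Errors when either channel has zero variance in the mask (undefined
#' correlation).
#'
#' @param pair A [coloc_pair()].
#' @return Correlation in `[-1, 1]`.
#' @export
coloc_pearson <- function(pair) {
  stopifnot(inherits(pair, "coloc_pair"))
  mv <- masked_values(pair)
  if (length(mv$v1) < 2) abort("Need at least 2 masked pixels.")
  if (sd(mv$v1) == 0 || sd(mv$v2) == 0) {
    abort("Undefined correlation: zero variance within the mask.")
  }
  cor(mv$v1, mv$v2)
}

#' Thresholded Manders fractions
#'
#' `m1` is the fraction of channel-1 signal (above its threshold, within the
#' mask) that lies on channel-2 support (above the channel-2 threshold);
#' `m2` is the symmetric quantity. A channel with no above-threshold signal
#' yields `NA` for its coefficient (undefined, not 0).
#'
#' @param pair A [coloc_pair()].
#' @return Named numeric `c(m1, m2)`, each in `[0, 1]` or `NA`.
#' @export
coloc_manders <- function(pair) {
  stopifnot(inherits(pair, "coloc_pair"))
  t1 <- pair$thresholds[1]; t2 <- pair$thresholds[2]
  m <- pair$mask
  sup1 <- m & pair$ch1 > t1
  sup2 <- m & pair$ch2 > t2
  den1 <- sum(pair$ch1[sup1])
  den2 <- sum(pair$ch2[sup2])
  m1 <- if (den1 > 0) sum(pair$ch1[sup1 & sup2]) / den1 else NA_real_
  m2 <- if (den2 > 0) sum(pair$ch2[sup1 & sup2]) / den2 else NA_real_
  c(m1 = m1, m2 = m2)
}

#' Classic overlap coefficient
#'
#' The Manders overlap coefficient
#' `sum(ch1 * ch2) / sqrt(sum(ch1^2) * sum(ch2^2))` over masked pixels,
#' provided as an alternative reading of "overlap coefficient".
#'
#' @param pair A [coloc_pair()].
#' @return Overlap coefficient in `[0, 1]`.
#' @export
overlap_coefficient <- function(pair) {
  stopifnot(inherits(pair, "coloc_pair"))
  mv <- masked_values(pair)
  den <- sqrt(sum(mv$v1^2) * sum(mv$v2^2))
  if (den == 0) abort("Overlap coefficient undefined: a channel is all zero.")
  sum(mv$v1 * mv$v2) / den
}

# Rotate a frame 90 degrees clockwise and re-embed it centre-aligned onto
# the original grid (non-square frames transpose their shape; the centred
# overlap is used). Pixels with no rotated counterpart are NA / FALSE.
rotate_embed <- function(m, fill = NA) {
  r <- rot90_cw(m)
  out <- matrix(fill, nrow(m), ncol(m))
  nr <- min(nrow(m), nrow(r)); nc <- min(ncol(m), ncol(r))
  o_r0 <- (nrow(m) - nr) %/% 2L
  o_c0 <- (ncol(m) - nc) %/% 2L
  i_r0 <- (nrow(r) - nr) %/% 2L
  i_c0 <- (ncol(r) - nc) %/% 2L
  out[o_r0 + seq_len(nr), o_c0 + seq_len(nc)] <-
    r[i_r0 + seq_len(nr), i_c0 + seq_len(nc)]
  out
}

#' Rotation null for colocalization
#'
#' The negative control of the Pearson analysis: channel 2 (and the mask)
#' are rotated by 90 degrees, after which only chance colocalization
#' remains; the correlation is computed on the intersection of the mask and
#' its rotated copy. Note the control is blind to patterns that are
#' themselves 90-degree rotation symmetric.
#'
#' @param pair A [coloc_pair()].
#' @param min_overlap Minimum pixels in the mask intersection.
#' @return The null Pearson correlation.
#' @export
rotation_null <- function(pair, min_overlap = 100) {
  stopifnot(inherits(pair, "coloc_pair"))
  ch2r <- rotate_embed(pair$ch2, fill = NA)
  maskr <- rotate_embed(pair$mask, fill = FALSE)
  maskr[is.na(maskr)] <- FALSE
  both <- pair$mask & maskr & !is.na(ch2r)
  if (sum(both) < min_overlap) {
    abort(sprintf("Insufficient overlap: mask and rotated mask share %d pixels (< %d).",
                  sum(both), min_overlap))
  }
  v1 <- pair$ch1[both]
  v2 <- ch2r[both]
  if (sd(v1) == 0 || sd(v2) == 0) {
    abort("Undefined null correlation: zero variance within the rotated overlap.")
  }
  cor(v1, v2)
}

#' Full colocalization analysis of a channel pair
#'
#' Auto-thresholds both channels within the mask, then computes the masked
#' Pearson correlation, thresholded Manders fractions and the 90-degree
#' rotation null.
#'
#' @param ch1,ch2 Numeric matrices.
#' @param mask Logical matrix ROI (e.g. the cytoplasm); default all pixels.
#' @param thresholds Optional fixed thresholds (length 2).
#' @return One-row tibble: `pearson_r`, `m1`, `m2`, `null_r`, `threshold1`,
#'   `threshold2`, `n_pixels`.
#' @export
coloc_analyze <- function(ch1, ch2, mask = NULL, thresholds = NULL) {
  pair <- coloc_pair(ch1, ch2, mask, thresholds)
  m <- coloc_manders(pair)
  tibble(
    pearson_r = coloc_pearson(pair),
    m1 = m[["m1"]],
    m2 = m[["m2"]],
    null_r = rotation_null(pair),
    threshold1 = pair$thresholds[1],
    threshold2 = pair$thresholds[2],
    n_pixels = sum(pair$mask)
  )
}
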