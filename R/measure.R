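#' Measure one membrane domain
#'
#' Samples a band of `band_width` pixels normal to the trace at every vertex
#' of the domain segment. The per-vertex band mean is the along-membrane
#' intensity profile; the domain mean is the average of the profile, and the
#' raw quantity is the mean intensity multiplied by the domain arc length
#' (so quantities are additive across domains).
#'
#' @param image Numeric matrix.
#' @param partition A `domain_partition` from [partition_domains()].
#' @param domain One of `"anterior"`, `"lateral1"`, `"lateral2"`,
#'   `"posterior"`.
#' @param band_width Odd band width in pixels (default 3).
#' @return A `domain_measurement`: label, mean intensity, length (px), raw
#'   quantity, and the profile tibble (`index`, `arc_position`, `domain`,
#'   `intensity`).
#' @export
measure_domain <- function(image, partition, domain, band_width = 3) {
  check_image(image)
  stopifnot(inherits(partition, "domain_partition"))
  if (!is_scalar_number(band_width) || band_width < 1 || band_width %% 2 != 1) {
    abort("`band_width` must be an odd positive integer.")
  }
  idx <- segment_indices(partition, domain)
  if (length(idx) == 0) abort("Invalid input: empty domain segment.")
  tr <- partition$trace
  v <- trace_vertices(tr)
  sm <- tr$smoothed
  n <- tr$n
  half <- (band_width - 1) / 2
  clipped <- FALSE
  profile <- vapply(idx, function(i) {
    ip <- (i %% n) + 1L
    im <- ((i - 2L) %% n) + 1L
    tg <- sm[ip, ] - sm[im, ]
    len <- sqrt(sum(tg^2))
    if (len == 0) return(image[v[i, 1], v[i, 2]])
    nrm <- c(-tg[2], tg[1]) / len
    vals <- numeric(0)
    for (k in (-half):half) {
      pp <- round_half_up(v[i, ] + k * nrm)
      if (pp[1] < 1 || pp[1] > nrow(image) || pp[2] < 1 || pp[2] > ncol(image)) {
        clipped <<- TRUE
        next
      }
      vals <- c(vals, image[pp[1], pp[2]])
    }
    if (length(vals) == 0) {
      clipped <<- TRUE
      return(NA_real_)
    }
    mean(vals)
  }, numeric(1))
  if (clipped) {
    warn(sprintf("Band extends outside the image for domain `%s`; clipped.", domain))
  }
  seg <- partition$segments[partition$segments$domain == domain, ]
  mean_int <- mean(profile, na.rm = TRUE)
  structure(
    list(
      label = domain,
      mean_intensity = mean_int,
      length = seg$length_px,
      length_um = seg$length_um,
      quantity = mean_int * seg$length_px,
      profile = tibble(
        index = idx,
        arc_position = tr$arc_pos[idx],
        domain = domain,
        intensity = profile
      )
    ),
    class = "domain_measurement"
  )
}

#' @export
print.domain_measurement <- function(x, ...) {
  cat(sprintf("<domain_measurement> %s: mean %.3f over %.1f px (quantity %.1f)\n",
              x$label, x$mean_intensity, x$length, x$quantity))
  invisible(x)
}

# Even-odd scanline fill of the region enclosed by a closed polyline,
# including the polyline's own integer pixels. Robust for 8-connected pixel
# traces, which a hole-filling morphology would leak through diagonally.
fill_trace_mask <- function(trace, dim) {
  v <- trace_vertices(trace)
  n <- nrow(v)
  nxt <- c(2:n, 1L)
  y1 <- v[, 1]; x1 <- v[, 2]
  y2 <- v[nxt, 1]; x2 <- v[nxt, 2]
  keep <- y1 != y2
  y1 <- y1[keep]; x1 <- x1[keep]; y2 <- y2[keep]; x2 <- x2[keep]
  mask <- matrix(FALSE, dim[1], dim[2])
  for (r in max(1, floor(min(v[, 1]))):min(dim[1], ceiling(max(v[, 1])))) {
    crosses <- (y1 <= r & y2 > r) | (y2 <= r & y1 > r)
    if (!any(crosses)) next
    xs <- sort(x1[crosses] + (r - y1[crosses]) * (x2[crosses] - x1[crosses]) /
                 (y2[crosses] - y1[crosses]))
    for (j in seq(1, length(xs) - 1, by = 2)) {
      c0 <- max(1L, ceiling(xs[j] + 1e-9))
      c1 <- min(dim[2], floor(xs[j + 1] - 1e-9))
      if (c1 >= c0) mask[r, c0:c1] <- TRUE
    }
  }
  vi <- round_half_up(v)
  ok <- in_bounds(vi, dim)
  mask[vi[ok, , drop = FALSE]] <- TRUE
  mask
}

#' Measure the cytoplasmic signal
#'
#' Mean intensity over the region enclosed by the trace, eroded by `margin`
#' pixels so the membrane band (and its bleed) is excluded. `margin` should
#' be at least half the measurement band width. An optional nucleus mask is
#' excluded from the region.
#'
#' @param image Numeric matrix.
#' @param trace A [membrane_trace()] or `domain_partition`.
#' @param margin Erosion margin in pixels.
#' @param nucleus_mask Optional logical matrix of pixels to exclude.
#' @return A `cytoplasm_measurement`: mean intensity, area (px^2), quantity.
#' @export
measure_cytoplasm <- function(image, trace, margin = 3, nucleus_mask = NULL) {
  check_image(image)
  if (inherits(trace, "domain_partition")) trace <- trace$trace
  stopifnot(inherits(trace, "membrane_trace"))
  mask <- fill_trace_mask(trace, dim(image))
  if (margin > 0) {
    mask <- EBImage::erode(mask * 1, EBImage::makeBrush(2 * round(margin) + 1, "disc")) > 0
  }
  if (!is.null(nucleus_mask)) mask <- mask & !nucleus_mask
  area <- sum(mask)
  if (area == 0) {
    abort("Degenerate geometry: erosion margin emptied the cytoplasm region.")
  }
  mean_int <- mean(image[mask])
  structure(
    list(mean_intensity = mean_int, area = area, quantity = mean_int * area,
         mask = mask),
    class = "cytoplasm_measurement"
  )
}

#' @export
print.cytoplasm_measurement <- function(x, ...) {
  cat(sprintf("<cytoplasm_measurement> mean %.3f over %d px^2 (quantity %.1f)\n",
              x$mean_intensity, x$area, x$quantity))
  invisible(x)
}

#' Mean intensity within a pixel mask
#'
#' Convenience for region measurements such as the simple and double
#' nurse-cell membranes used by [estimate_nurse_background()].
#'
#' @param image Numeric matrix.
#' @param mask Logical matrix of the same dimensions.
#' @return Mean of `image` over `mask`.
#' @export
measure_mask_mean <- function(image, mask) {
  check_image(image)
  if (!identical(dim(image), dim(mask))) abort("`mask` must match `image` dimensions.")
  if (!any(mask)) abort("Mask is empty.")
  mean(image[mask])
}
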