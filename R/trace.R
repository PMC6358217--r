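#' Closed membrane trace
#'
#' An ordered closed path of pixel coordinates along the oocyte plasma
#' membrane. Two kinds are supported: a `"pixel"` trace (integer
#' coordinates, consecutive points 8-connected — the output of
#' [trace_perimeter()]) and a `"polygon"` trace (arbitrary real vertices,
#' e.g. a manually drawn outline). Arc length along a pixel trace is
#' measured on a circular moving-average smoothing of the vertex polyline
#' (window `smoothing_window`), which removes the staircase bias of raw
#' chain-code lengths; polygon traces are measured as-is.
#'
#' @param points An `n x 2` matrix of `(row, col)` coordinates. The path is
#'   closed: either the last row repeats the first, or the closing edge is
#'   implicit.
#' @param pixel_size Physical length per pixel (micrometres per pixel),
#'   default 1.
#' @param smoothing_window Odd window (in vertices) of the circular moving
#'   average used for arc-length measurement of pixel traces. 1 disables
#'   smoothing.
#' @return A `membrane_trace` object.
#' @export
membrane_trace <- function(points, pixel_size = 1, smoothing_window = 5) {
  points <- as.matrix(points)
  if (ncol(points) != 2 || !is.numeric(points)) {
    abort("`points` must be an n x 2 numeric matrix of (row, col) coordinates.")
  }
  colnames(points) <- c("row", "col")
  n <- nrow(points)
  if (n >= 2 && all(points[n, ] == points[1, ])) {
    points <- points[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 3) abort("A closed trace needs at least 3 distinct points.")
  if (anyDuplicated(points)) {
    abort("Trace is self-intersecting: duplicated vertices found.")
  }
  is_pixel <- all(points == round(points))
  if (is_pixel) {
    d <- abs(rbind(points[-1, , drop = FALSE], points[1, , drop = FALSE]) - points)
    if (any(pmax(d[, 1], d[, 2]) > 1)) {
      abort("Consecutive points of a pixel trace must be 8-connected neighbours.")
    }
  }
  # shoelace with x = col, y = row; zero area means a degenerate path
  x <- points[, 2]; y <- points[, 1]
  area2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (abs(area2) < .Machine$double.eps) abort("Trace encloses no area.")
  win <- if (is_pixel) smoothing_window else 1L
  sm <- smooth_closed_polyline(points, win)
  steps <- closed_step_lengths(sm)
  structure(
    list(
      points = rbind(points, points[1, , drop = FALSE]),
      n = n,
      kind = if (is_pixel) "pixel" else "polygon",
      pixel_size = pixel_size,
      smoothing_window = win,
      smoothed = sm,
      arc_pos = c(0, cumsum(steps)),   # length n + 1; last entry = perimeter
      signed_area = area2 / 2
    ),
    class = "membrane_trace"
  )
}

#' @export
print.membrane_trace <- function(x, ...) {
  cat(sprintf(
    "<membrane_trace> %d vertices (%s), perimeter %.2f px%s\n",
    x$n, x$kind, perimeter(x),
    if (x$pixel_size != 1) sprintf(" (%.2f um)", perimeter(x) * x$pixel_size) else ""
  ))
  invisible(x)
}

#' Perimeter of a membrane trace
#'
#' @param trace A [membrane_trace()].
#' @param units `"px"` or `"um"` (pixels times `pixel_size`).
#' @return Total closed arc length.
#' @export
perimeter <- function(trace, units = c("px", "um")) {
  units <- match.arg(units)
  p <- trace$arc_pos[trace$n + 1L]
  if (units == "um") p * trace$pixel_size else p
}

trace_vertices <- function(trace) trace$points[seq_len(trace$n), , drop = FALSE]

#' @rdname membrane_trace
#' @param x A `membrane_trace`.
#' @param ... Unused.
#' @export
tidy.membrane_trace <- function(x, ...) {
  v <- trace_vertices(x)
  tibble(
    index = seq_len(x$n),
    row = v[, 1],
    col = v[, 2],
    arc_position = x$arc_pos[seq_len(x$n)]
  )
}

#' Read or write a membrane trace as CSV
#'
#' On-disk traces are ordered `row,col` pixel coordinates, 0-based; the
#' closing edge back to the first point is implicit.
#'
#' @param path CSV path.
#' @param trace A [membrane_trace()].
#' @param ... Passed to [membrane_trace()] when reading.
#' @export
read_trace <- function(path, ...) {
  df <- read.csv(path)
  membrane_trace(cbind(df$row, df$col) + 1, ...)
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  v <- trace_vertices(trace)
  write.csv(data.frame(row = v[, 1] - 1, col = v[, 2] - 1), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Densify a polygon outline into an 8-connected pixel trace
#'
#' Fallback for manually outlined membranes: takes a coarse vertex list and
#' rasterises each edge (Bresenham) so the result satisfies the pixel-trace
#' invariants.
#'
#' @param vertices `n x 2` matrix of `(row, col)` polygon vertices.
#' @param ... Passed to [membrane_trace()].
#' @return A pixel-kind [membrane_trace()].
#' @export
densify_polygon <- function(vertices, ...) {
  vertices <- round_half_up(as.matrix(vertices))
  n <- nrow(vertices)
  pts <- list()
  for (i in seq_len(n)) {
    a <- vertices[i, ]
    b <- vertices[if (i == n) 1L else i + 1L, ]
    seg <- bresenham(a, b)
    pts[[i]] <- seg[-nrow(seg), , drop = FALSE]
  }
  pts <- do.call(rbind, pts)
  pts <- pts[!duplicated(pts), , drop = FALSE]
  membrane_trace(pts, ...)
}

bresenham <- function(a, b) {
  d <- b - a
  steps <- max(abs(d))
  if (steps == 0) return(rbind(a))
  t <- seq(0, 1, length.out = steps + 1)
  round_half_up(cbind(a[1] + t * d[1], a[2] + t * d[2]))
}

# ---- automatic perimeter tracing -------------------------------------------

# Moore-neighbour boundary tracing of a binary mask: returns the ordered
# outer boundary as an n x 2 integer matrix. Start pixel is the
# lexicographically smallest (row, col) foreground pixel.
moore_trace <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  idx <- which(pad)
  if (length(idx) == 0) abort("Tracing error: empty mask.")
  prow <- ((idx - 1L) %% (nr + 2L)) + 1L
  pcol <- ((idx - 1L) %/% (nr + 2L)) + 1L
  o <- order(prow, pcol)
  start <- c(prow[o[1]], pcol[o[1]])
  # Moore neighbourhood, clockwise starting from West
  nb <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
              c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  pts <- matrix(0L, length(idx) * 4L, 2L)
  pts[1, ] <- start
  npts <- 1L
  cur <- start
  backtrack <- 1L  # we notionally came from the West
  limit <- length(idx) * 4L
  repeat {
    found <- FALSE
    for (j in 0:7) {
      k <- ((backtrack + j - 1L) %% 8L) + 1L
      cand <- cur + nb[k, ]
      if (pad[cand[1], cand[2]]) {
        backtrack <- ((k - 2L + 7L) %% 8L) + 1L
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    if (cur[1] == start[1] && cur[2] == start[2]) break
    npts <- npts + 1L
    if (npts > limit) abort("Tracing error: boundary walk failed to close.")
    pts[npts, ] <- cur
  }
  pts[seq_len(npts), , drop = FALSE] - 1L
}

largest_component <- function(bw) {
  lab <- EBImage::bwlabel(bw * 1)
  tab <- tabulate(lab[lab > 0])
  if (length(tab) == 0) abort("Tracing error: no foreground component.")
  lab == which.max(tab)
}

# Boundary of a mask as a simple closed path. One-pixel-wide spurs and necks
# make the Moore walk visit a pixel twice; those pinch pixels are removed
# from the mask and the (largest remaining component's) boundary retraced.
simple_boundary <- function(mask) {
  for (i in 1:8) {
    mask <- largest_component(mask)
    contour <- moore_trace(mask)
    dup <- duplicated(contour) | duplicated(contour, fromLast = TRUE)
    if (!any(dup)) return(contour)
    pinch <- unique(contour[dup, , drop = FALSE])
    mask[pinch] <- FALSE
    if (sum(mask) < 8) break
  }
  abort("Tracing error: contour is pinched and could not be simplified.")
}

# Median offset from the outer contour to the membrane intensity ridge,
# measured along inward normals. Used to centre the trace on the band.
ridge_offset <- function(image, contour, threshold, max_depth = 8) {
  n <- nrow(contour)
  cen <- colMeans(contour)
  samp <- seq(1L, n, by = max(1L, n %/% 200L))
  offs <- vapply(samp, function(i) {
    ip <- (i %% n) + 1L
    im <- ((i - 2L) %% n) + 1L
    tg <- contour[ip, ] - contour[im, ]
    len <- sqrt(sum(tg^2))
    if (len == 0) return(NA_real_)
    nrm <- c(-tg[2], tg[1]) / len
    if (sum((cen - contour[i, ]) * nrm) < 0) nrm <- -nrm
    v <- vapply(0:max_depth, function(k) {
      pp <- round_half_up(contour[i, ] + k * nrm)
      if (pp[1] < 1 || pp[1] > nrow(image) || pp[2] < 1 || pp[2] > ncol(image)) {
        return(-Inf)
      }
      image[pp[1], pp[2]]
    }, numeric(1))
    hi <- which(v > threshold & v >= 0.8 * max(v))
    if (length(hi) == 0) return(0)
    # contiguous above-threshold run starting at the contour
    run <- hi[cumsum(c(1, diff(hi)) != 1) == 0]
    mean(run) - 1
  }, numeric(1))
  stats::median(offs, na.rm = TRUE)
}

#' Trace the oocyte perimeter from an image and anchor points
#'
#' Automates the manual membrane delineation step: the image is thresholded
#' at a percentile of its intensities, morphologically closed, and the
#' largest connected component is filled; its outer boundary is then eroded
#' onto the membrane intensity ridge and walked into an ordered,
#' counter-clockwise, 8-connected closed pixel path starting at the vertex
#' nearest `a1`.
#'
#' @param image Numeric matrix (single-channel image).
#' @param anchors Snapped [anchor_points()]; the trace must pass within
#'   `snap_radius` of all three, otherwise a tracing error is raised.
#' @param threshold_percentile Percentile of in-image intensity used for the
#'   foreground threshold (strict `>`), default 0.75. If the contour fails
#'   validation at this percentile — it misses an anchor, or the anterior
#'   arc wraps an adjacent structure such as an apposed nurse-cell
#'   compartment — progressively higher percentiles (steps of 0.05 up to
#'   0.95) are tried before giving up with the original error.
#' @param closing_size Diameter (px) of the disc used for morphological
#'   closing of the thresholded mask.
#' @param snap_radius Maximum allowed distance (px) between each anchor and
#'   the trace.
#' @param smoothing_window Arc-length smoothing window, see
#'   [membrane_trace()].
#' @param pixel_size Micrometres per pixel.
#' @return A [membrane_trace()].
#' @export
trace_perimeter <- function(image, anchors, threshold_percentile = 0.75,
                            closing_size = 5, snap_radius = 5,
                            smoothing_window = 5, pixel_size = 1) {
  check_image(image)
  stopifnot(inherits(anchors, "anchor_points"))
  if (diff(range(image)) == 0) {
    abort("Tracing error: image has constant intensity, no contour exists.")
  }
  # threshold escalation ladder: when the object is small relative to the
  # field, a fixed percentile can fall below an adjacent dim structure
  # (e.g. nurse-cell cytoplasm) and merge it into the mask
  pcts <- threshold_percentile
  if (threshold_percentile < 0.95) {
    pcts <- unique(c(pcts, seq(min(threshold_percentile + 0.05, 0.95), 0.95,
                               by = 0.05)))
  }
  first_err <- NULL
  for (pct in pcts) {
    res <- tryCatch(
      trace_once(image, anchors, pct, closing_size, snap_radius,
                 smoothing_window, pixel_size),
      error = function(e) e
    )
    if (!inherits(res, "error")) return(res)
    if (is.null(first_err)) first_err <- res
  }
  stop(first_err)
}

trace_once <- function(image, anchors, threshold_percentile,
                       closing_size, snap_radius, smoothing_window,
                       pixel_size) {
  thr <- quantile(image, threshold_percentile, names = FALSE)
  bw <- image > thr
  if (!any(bw) || all(bw)) {
    abort("Tracing error: threshold produced an empty or full mask.")
  }
  bw <- EBImage::closing(bw * 1, EBImage::makeBrush(closing_size, "disc")) > 0
  comp <- largest_component(bw)
  filled <- EBImage::fillHull(comp * 1) > 0
  contour <- simple_boundary(filled)
  if (nrow(contour) < 8) abort("Tracing error: contour is degenerate.")
  k <- round(ridge_offset(image, contour, thr))
  k_used <- 0
  if (is.finite(k) && k > 0) {
    eroded <- EBImage::erode(filled * 1, EBImage::makeBrush(2 * k + 1, "disc")) > 0
    if (sum(eroded) > 8) {
      contour <- simple_boundary(eroded)
      k_used <- k
    }
  }
  # orient counter-clockwise (positive shoelace area in (x = col, y = row))
  x <- contour[, 2]; y <- contour[, 1]
  area2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (area2 < 0) {
    contour <- contour[c(1L, nrow(contour):2L), , drop = FALSE]
  }
  # start at the vertex nearest a1
  d2 <- (contour[, 1] - anchors$a1[1])^2 + (contour[, 2] - anchors$a1[2])^2
  i0 <- which(d2 == min(d2))
  if (length(i0) > 1) i0 <- i0[order(contour[i0, 1], contour[i0, 2])][1]
  contour <- contour[c(i0:nrow(contour), seq_len(i0 - 1L)), , drop = FALSE]
  # the trace was pulled inward by k_used px, so a ridge anchor may
  # legitimately sit that far outside the traced line
  limit <- snap_radius + k_used
  for (nm in c("a1", "a2", "p")) {
    a <- anchors[[nm]]
    dmin <- sqrt(min((contour[, 1] - a[1])^2 + (contour[, 2] - a[2])^2))
    if (dmin > limit) {
      abort(sprintf(
        "Tracing error: contour passes %.1f px from anchor `%s` (limit %g). The membrane may be open or the anchors on different structures.",
        dmin, nm, limit
      ))
    }
  }
  # wrap check: the anterior arc (a1 -> a2 not through p) of a sane oocyte
  # outline stays below ~1.5x the a1-a2 chord for any plausible aspect
  # ratio; a contour that wraps an apposed structure far exceeds that
  idx_near <- function(a) {
    which.min((contour[, 1] - a[1])^2 + (contour[, 2] - a[2])^2)
  }
  i1 <- idx_near(anchors$a1)
  i2 <- idx_near(anchors$a2)
  ip <- idx_near(anchors$p)
  step <- sqrt(rowSums((contour[c(2:nrow(contour), 1L), , drop = FALSE] -
                          contour)^2))
  lo <- min(i1, i2); hi <- max(i1, i2)
  arc_inside <- if (hi > lo) sum(step[lo:(hi - 1L)]) else 0
  anterior_arc <- if (ip >= lo && ip <= hi) sum(step) - arc_inside else arc_inside
  chord <- sqrt(sum((anchors$a1 - anchors$a2)^2))
  if (anterior_arc > 2 * chord) {
    abort(sprintf(
      "Tracing error: anterior arc is %.0f px for a %.0f px anchor chord; the trace may wrap an adjacent structure.",
      anterior_arc, chord
    ))
  }
  membrane_trace(contour, pixel_size = pixel_size,
                 smoothing_window = smoothing_window)
}
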