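#' Anchor points delimiting the oocyte membrane domains
#'
#' Three pixel positions seed the membrane quantification: `a1` and `a2`
#' flank the anterior membrane (the oocyte/nurse-cell interface) and `p`
#' marks the midpoint of the posterior membrane. Coordinates are 1-based
#' `(row, col)` pixel positions; the CSV interchange format
#' ([read_anchors()], [write_anchors()]) is 0-based.
#'
#' @param a1,a2 Numeric length-2 `(row, col)` positions flanking the anterior
#'   membrane.
#' @param p Numeric length-2 `(row, col)` position at the posterior membrane
#'   midpoint.
#' @return An `anchor_points` object (named list of the three positions).
#' @export
anchor_points <- function(a1, a2, p) {
  pts <- list(a1 = a1, a2 = a2, p = p)
  for (nm in names(pts)) {
    v <- pts[[nm]]
    if (!is.numeric(v) || length(v) != 2L || any(!is.finite(v))) {
      abort(sprintf("Anchor `%s` must be a finite numeric (row, col) pair.", nm))
    }
    pts[[nm]] <- as.numeric(v)
  }
  if (identical(pts$a1, pts$a2) || identical(pts$a1, pts$p) || identical(pts$a2, pts$p)) {
    abort("Anchor points must be pairwise distinct.")
  }
  structure(pts, class = "anchor_points")
}

#' @export
print.anchor_points <- function(x, ...) {
  cat("<anchor_points>\n")
  for (nm in c("a1", "a2", "p")) {
    cat(sprintf("  %s: (%g, %g)\n", nm, x[[nm]][1], x[[nm]][2]))
  }
  invisible(x)
}

#' @rdname anchor_points
#' @param x An `anchor_points` object.
#' @param ... Unused.
#' @export
tidy.anchor_points <- function(x, ...) {
  tibble(
    label = c("a1", "a2", "p"),
    row = c(x$a1[1], x$a2[1], x$p[1]),
    col = c(x$a1[2], x$a2[2], x$p[2])
  )
}

anchor_matrix <- function(anchors) {
  rbind(a1 = anchors$a1, a2 = anchors$a2, p = anchors$p)
}

#' Read or write anchor points as CSV
#'
#' The on-disk format has a header `label,row,col` and one row for each of
#' `a1`, `a2`, `p`, with 0-based pixel coordinates (row 0 is the top image
#' row). In-memory anchor points are 1-based.
#'
#' @param path Path to a CSV file.
#' @return `read_anchors()` returns an [anchor_points()] object.
#' @export
read_anchors <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "row", "col")
  if (!all(need %in% names(df))) {
    abort("Anchor CSV must have columns `label,row,col`.")
  }
  get <- function(lab) {
    i <- match(lab, df$label)
    if (is.na(i)) abort(sprintf("Anchor CSV is missing row `%s`.", lab))
    c(df$row[i], df$col[i]) + 1
  }
  anchor_points(get("a1"), get("a2"), get("p"))
}

#' @rdname read_anchors
#' @param anchors An [anchor_points()] object.
#' @export
write_anchors <- function(anchors, path) {
  df <- as.data.frame(tidy(anchors))
  df$row <- df$row - 1
  df$col <- df$col - 1
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Snap anchor points onto the membrane intensity ridge
#'
#' Manual clicks rarely land exactly on the membrane. Each anchor is moved to
#' the brightest pixel within `snap_radius` (Euclidean) of its position,
#' which on a membrane image is the ridge of the band. Ties break
#' deterministically to the lowest row, then lowest column. With
#' `snap_radius = 0` the anchors are returned unchanged.
#'
#' @param image Numeric matrix, single-channel image.
#' @param anchors [anchor_points()].
#' @param snap_radius Search radius in pixels (>= 0).
#' @param background_percentile Snapping fails (with an error naming the
#'   anchor) when no pixel in the search window exceeds this percentile of
#'   the whole image, i.e. the anchor sits in featureless background.
#' @return Snapped [anchor_points()].
#' @export
snap_anchors <- function(image, anchors, snap_radius = 5,
                         background_percentile = 0.5) {
  check_image(image)
  stopifnot(inherits(anchors, "anchor_points"))
  if (!is_scalar_number(snap_radius) || snap_radius < 0) {
    abort("`snap_radius` must be a single non-negative number.")
  }
  m <- anchor_matrix(anchors)
  if (!all(in_bounds(m, dim(image)))) {
    abort("All anchor points must lie inside the image bounds.")
  }
  if (snap_radius == 0) return(anchors)
  bg <- quantile(image, background_percentile, names = FALSE)
  r <- ceiling(snap_radius)
  snapped <- lapply(c("a1", "a2", "p"), function(nm) {
    a <- round_half_up(anchors[[nm]])
    rows <- max(1, a[1] - r):min(nrow(image), a[1] + r)
    cols <- max(1, a[2] - r):min(ncol(image), a[2] + r)
    grid <- expand.grid(row = rows, col = cols)
    d2 <- (grid$row - anchors[[nm]][1])^2 + (grid$col - anchors[[nm]][2])^2
    keep <- d2 <= snap_radius^2
    grid <- grid[keep, , drop = FALSE]
    vals <- image[cbind(grid$row, grid$col)]
    if (!any(vals > bg)) {
      abort(sprintf(
        "Snap failure for anchor `%s`: no pixel above the background percentile within radius %g.",
        nm, snap_radius
      ))
    }
    best <- which(vals == max(vals))
    best <- best[order(grid$row[best], grid$col[best])][1]
    c(grid$row[best], grid$col[best])
  })
  anchor_points(snapped[[1]], snapped[[2]], snapped[[3]])
}
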