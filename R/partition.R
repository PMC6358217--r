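#' Partition a membrane trace into the four cortical domains
#'
#' Splits the closed trace into the anterior, lateral 1, lateral 2 and
#' posterior plasma-membrane domains. The anterior domain is the arc from
#' `a1` to `a2` that does not contain `p`; the posterior domain is an arc of
#' length `posterior_fraction * (perimeter - anterior length)` centred (by
#' arc length) on `p`; the two remaining arcs are the lateral domains,
#' `lateral1` being the one adjacent to `a1`. Segments are contiguous,
#' disjoint vertex-index ranges that jointly cover the trace, and their
#' lengths sum exactly to the perimeter.
#'
#' @param trace A [membrane_trace()].
#' @param anchors Snapped [anchor_points()] lying on (or within a couple of
#'   pixels of) the trace.
#' @param posterior_fraction Fraction of the non-anterior perimeter assigned
#'   to the posterior domain; default 0.20.
#' @return A `domain_partition` object: the (possibly re-oriented) trace, a
#'   `segments` tibble with columns `domain`, `start_index`, `end_index`,
#'   `length_px`, `length_um`, and the anchor vertex indices.
#' @export
partition_domains <- function(trace, anchors, posterior_fraction = 0.2) {
  stopifnot(inherits(trace, "membrane_trace"), inherits(anchors, "anchor_points"))
  if (!is_scalar_number(posterior_fraction) ||
      posterior_fraction <= 0 || posterior_fraction >= 1) {
    abort("`posterior_fraction` must lie strictly between 0 and 1.")
  }
  v <- trace_vertices(trace)
  n <- trace$n
  # Nearest vertex to `a`; ties (exact integer-distance ties do occur) are
  # broken by distance to the other anchors, which is invariant under
  # rotation/reflection of the image, so the chosen vertex is a physical
  # point rather than an artefact of traversal order.
  d2_to <- function(a) (v[, 1] - a[1])^2 + (v[, 2] - a[2])^2
  nearest <- function(a) {
    d2 <- d2_to(a)
    i <- which(d2 == min(d2))
    if (length(i) > 1) {
      i <- i[order(d2_to(anchors$a1)[i], d2_to(anchors$a2)[i],
                   d2_to(anchors$p)[i])][1]
    }
    i
  }
  i_a1 <- nearest(anchors$a1)
  # rotate vertex order so the trace starts at a1
  if (i_a1 != 1L) {
    v <- v[c(i_a1:n, seq_len(i_a1 - 1L)), , drop = FALSE]
  }
  i_a2 <- nearest(anchors$a2)
  i_p <- nearest(anchors$p)
  if (i_a2 == 1L || i_p == 1L || i_a2 == i_p) {
    abort("Invalid anchors: the three anchor points map to coincident trace vertices.")
  }
  # anterior must be the a1 -> a2 arc not containing p
  if (i_p < i_a2) {
    v <- v[c(1L, n:2L), , drop = FALSE]
    i_a2 <- n + 2L - i_a2
    i_p <- n + 2L - i_p
  }
  tr <- membrane_trace(v, pixel_size = trace$pixel_size,
                       smoothing_window = trace$smoothing_window)
  s <- tr$arc_pos
  P <- s[n + 1L]
  ant_len <- s[i_a2]
  rem <- P - ant_len
  post_len <- posterior_fraction * rem
  s_p <- s[i_p]
  lo <- s_p - post_len / 2
  hi <- s_p + post_len / 2
  if (lo <= ant_len || hi >= P) {
    abort("Configuration error: the posterior arc would overlap the anterior arc.")
  }
  cand <- (i_a2 + 1L):n
  j1 <- cand[which.min(abs(s[cand] - lo))]
  j2 <- cand[which.min(abs(s[cand] - hi))]
  if (j2 <= j1 || j1 <= i_a2 || j2 > n) {
    abort("Configuration error: posterior arc is degenerate for this trace.")
  }
  b <- c(1L, i_a2, j1, j2)
  lengths_px <- c(s[i_a2] - s[1L], s[j1] - s[i_a2], s[j2] - s[j1], P - s[j2])
  segments <- tibble(
    domain = c("anterior", "lateral2", "posterior", "lateral1"),
    start_index = b,
    end_index = c(i_a2 - 1L, j1 - 1L, j2 - 1L, n),
    length_px = lengths_px,
    length_um = lengths_px * tr$pixel_size
  )
  if (any(segments$length_px <= 0)) {
    abort("Configuration error: a domain received zero length.")
  }
  structure(
    list(
      trace = tr,
      segments = segments,
      anchor_index = c(a1 = 1L, a2 = i_a2, p = i_p),
      posterior_fraction = posterior_fraction
    ),
    class = "domain_partition"
  )
}

#' @export
print.domain_partition <- function(x, ...) {
  cat("<domain_partition>\n")
  print(x$segments)
  invisible(x)
}

#' @rdname partition_domains
#' @param x A `domain_partition`.
#' @param ... Unused.
#' @export
tidy.domain_partition <- function(x, ...) x$segments

#' Write a domain partition as CSV
#'
#' Columns `domain,start_index,end_index,length_px,length_um`; indices are
#' 0-based on the trace written by [write_trace()].
#'
#' @param partition A `domain_partition`.
#' @param path CSV path.
#' @export
write_partition <- function(partition, path) {
  df <- as.data.frame(partition$segments)
  df$start_index <- df$start_index - 1L
  df$end_index <- df$end_index - 1L
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# vertex indices belonging to one domain segment
segment_indices <- function(partition, domain) {
  seg <- partition$segments[partition$segments$domain == domain, ]
  if (nrow(seg) == 0) abort(sprintf("Unknown domain `%s`.", domain))
  seq.int(seg$start_index, seg$end_index)
}
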