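#' Per-domain FRAP quantity series
#'
#' Raw anterior and posterior membrane-domain quantities over a time-lapse
#' acquisition with `n_prebleach` frames taken before the photobleach.
#' Frames are 1-based; `bleach_index`, where used, is the index of the first
#' post-bleach frame (so with the usual six pre-bleach frames the bleach
#' index is 7).
#'
#' @param times Frame acquisition times in seconds, strictly increasing.
#' @param anterior,posterior Non-negative per-frame domain quantities.
#' @param n_prebleach Number of pre-bleach frames (>= 1).
#' @return A `frap_series` object.
#' @export
frap_series <- function(times, anterior, posterior, n_prebleach = 6) {
  n <- length(times)
  if (n < 3) abort("A FRAP series needs at least 3 frames.")
  if (length(anterior) != n || length(posterior) != n) {
    abort("`anterior` and `posterior` must have one value per frame.")
  }
  if (any(diff(times) <= 0)) abort("`times` must be strictly increasing.")
  if (any(anterior < 0) || any(posterior < 0)) {
    abort("Quantities must be non-negative.")
  }
  if (!is_scalar_number(n_prebleach) || n_prebleach < 1 || n_prebleach >= n) {
    abort("`n_prebleach` must be >= 1 and smaller than the number of frames.")
  }
  structure(
    list(
      data = tibble(frame = seq_len(n), time_s = as.numeric(times),
                    anterior = as.numeric(anterior),
                    posterior = as.numeric(posterior)),
      n_prebleach = as.integer(n_prebleach)
    ),
    class = "frap_series"
  )
}

#' @export
print.frap_series <- function(x, ...) {
  cat(sprintf("<frap_series> %d frames (%d pre-bleach)\n",
              nrow(x$data), x$n_prebleach))
  invisible(x)
}

#' Measure a FRAP stack into a quantity series
#'
#' Traces and partitions the membrane on the first frame (the geometry is
#' reused for all frames, no drift correction) and measures the anterior and
#' posterior raw quantities on every frame.
#'
#' @param stack 3D numeric array `(row, col, frame)` or list of matrices.
#' @param anchors [anchor_points()].
#' @param config [oopolar_config()].
#' @param frame_interval_s Seconds between frames (used when `times` is
#'   `NULL`).
#' @param times Optional explicit frame times (seconds).
#' @param n_prebleach Pre-bleach frame count.
#' @return A [frap_series()].
#' @export
measure_frap_stack <- function(stack, anchors, config = oopolar_config(),
                               frame_interval_s = 1, times = NULL,
                               n_prebleach = 6) {
  frames <- if (is.list(stack)) stack else
    lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  first <- frames[[1]]
  snapped <- snap_anchors(first, anchors, snap_radius = config$snap_radius)
  trace <- trace_perimeter(
    first, snapped,
    threshold_percentile = config$threshold_percentile,
    closing_size = config$closing_size,
    snap_radius = config$snap_radius,
    smoothing_window = config$smoothing_window,
    pixel_size = config$pixel_size
  )
  partition <- partition_domains(trace, snapped,
                                 posterior_fraction = config$posterior_fraction)
  q <- purrr::map(frames, function(f) {
    c(
      anterior = measure_domain(f, partition, "anterior",
                                band_width = config$band_width)$quantity,
      posterior = measure_domain(f, partition, "posterior",
                                 band_width = config$band_width)$quantity
    )
  })
  if (is.null(times)) times <- (seq_along(frames) - 1) * frame_interval_s
  frap_series(times,
              anterior = purrr::map_dbl(q, "anterior"),
              posterior = purrr::map_dbl(q, "posterior"),
              n_prebleach = n_prebleach)
}

#' Locate the first post-bleach frame
#'
#' The bleach event is normally known from the acquisition; when declared it
#' is passed through. Otherwise the frame with the largest single-step
#' fractional drop in the anterior quantity is returned, requiring a drop of
#' at least `min_drop`.
#'
#' @param series A [frap_series()].
#' @param declared_index Known 1-based index of the first post-bleach frame.
#' @param min_drop Minimum fractional drop for automatic detection.
#' @return Integer bleach index.
#' @export
detect_bleach_frame <- function(series, declared_index = NULL, min_drop = 0.2) {
  stopifnot(inherits(series, "frap_series"))
  n <- nrow(series$data)
  if (!is.null(declared_index)) {
    if (!is_scalar_number(declared_index) || declared_index < 2 ||
        declared_index > n) {
      abort("`declared_index` must be a frame index past the first frame.")
    }
    return(as.integer(declared_index))
  }
  a <- series$data$anterior
  prev <- a[-n]
  drops <- ifelse(prev > 0, (prev - a[-1]) / prev, 0)
  if (max(drops) <= min_drop) {
    abort(sprintf("Detection error: no anterior drop exceeding %.0f%% found and no declared index.",
                  100 * min_drop))
  }
  which.max(drops) + 1L
}

frap_long <- function(series) {
  tidyr::pivot_longer(series$data, c("anterior", "posterior"),
                      names_to = "domain", values_to = "quantity")
}

#' Rebase a FRAP series to zero at the bleach frame
#'
#' For each domain, the quantity at the bleach frame is subtracted from all
#' post-bleach frames, so the curve starts at exactly 0; pre-bleach frames
#' are dropped from this representation.
#'
#' @param series A [frap_series()].
#' @param bleach_index First post-bleach frame (see [detect_bleach_frame()]).
#' @return Tibble `frame`, `time_s`, `domain`, `rebased`.
#' @export
rebase_to_zero <- function(series, bleach_index) {
  stopifnot(inherits(series, "frap_series"))
  d <- series$data
  if (bleach_index < 1 || bleach_index > nrow(d)) abort("Invalid `bleach_index`.")
  post <- d[d$frame >= bleach_index, ]
  tibble(
    frame = rep(post$frame, 2),
    time_s = rep(post$time_s, 2),
    domain = rep(c("anterior", "posterior"), each = nrow(post)),
    rebased = c(post$anterior - post$anterior[1],
                post$posterior - post$posterior[1])
  )
}

#' Normalise a FRAP series to its pre-bleach mean
#'
#' Every frame of each domain is divided by that domain's mean over the
#' pre-bleach frames, so the pre-bleach level is 1.
#'
#' @param series A [frap_series()].
#' @param bleach_index First post-bleach frame.
#' @param n_prebleach Number of pre-bleach frames averaged (defaults to the
#'   series value).
#' @return Tibble `frame`, `time_s`, `domain`, `normalized`.
#' @export
normalize_prebleach <- function(series, bleach_index,
                                n_prebleach = series$n_prebleach) {
  stopifnot(inherits(series, "frap_series"))
  d <- series$data
  if (n_prebleach < 1 || n_prebleach >= bleach_index) {
    abort("`n_prebleach` must be >= 1 and precede the bleach frame.")
  }
  out <- purrr::map(c("anterior", "posterior"), function(dom) {
    q <- d[[dom]]
    pre <- mean(q[seq_len(n_prebleach)])
    if (pre <= 0) {
      abort(sprintf("Invalid input: zero pre-bleach mean for the %s domain.", dom))
    }
    tibble(frame = d$frame, time_s = d$time_s, domain = dom,
           normalized = q / pre)
  })
  dplyr::bind_rows(out)
}

#' Analyse a FRAP series under both normalisations
#'
#' Runs [detect_bleach_frame()] (unless an index is given),
#' [rebase_to_zero()] and [normalize_prebleach()], and summarises recovery
#' per domain by the mean over the last `end_window` frames and the sign of
#' the least-squares trend of the rebased post-bleach curve.
#'
#' @param series A [frap_series()].
#' @param bleach_index Optional declared first post-bleach frame.
#' @param end_window Frames averaged for the recovery plateau summary.
#' @return A `frap_result`; [tidy()] gives the long per-frame table and
#'   [glance()] the one-row recovery summary.
#' @export
frap_analyze <- function(series, bleach_index = NULL, end_window = 3) {
  stopifnot(inherits(series, "frap_series"))
  bi <- detect_bleach_frame(series, declared_index = bleach_index)
  rebased <- rebase_to_zero(series, bi)
  normalized <- normalize_prebleach(series, bi)
  summary <- rebased |>
    dplyr::group_by(.data$domain) |>
    dplyr::summarise(
      end_rebased = mean(tail(.data$rebased, end_window)),
      trend_sign = sign(sum((.data$time_s - mean(.data$time_s)) *
                              (.data$rebased - mean(.data$rebased)))),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      normalized |>
        dplyr::group_by(.data$domain) |>
        dplyr::summarise(end_normalized = mean(tail(.data$normalized, end_window)),
                         .groups = "drop"),
      by = "domain"
    )
  structure(
    list(series = series, bleach_index = bi, rebased = rebased,
         normalized = normalized, recovery_summary = summary,
         end_window = end_window),
    class = "frap_result"
  )
}

#' @export
print.frap_result <- function(x, ...) {
  cat(sprintf("<frap_result> bleach at frame %d\n", x$bleach_index))
  print(x$recovery_summary)
  invisible(x)
}

#' @rdname frap_analyze
#' @param x A `frap_result`.
#' @param ... Unused.
#' @export
tidy.frap_result <- function(x, ...) {
  raw <- frap_long(x$series) |> dplyr::rename(raw_quantity = "quantity")
  raw |>
    dplyr::left_join(x$rebased, by = c("frame", "time_s", "domain")) |>
    dplyr::left_join(
      dplyr::rename(x$normalized, prebleach_normalized = "normalized"),
      by = c("frame", "time_s", "domain")
    ) |>
    dplyr::arrange(.data$domain, .data$frame)
}

#' @rdname frap_analyze
#' @export
glance.frap_result <- function(x, ...) {
  s <- x$recovery_summary
  get <- function(dom, col) s[[col]][s$domain == dom]
  tibble(
    bleach_index = x$bleach_index,
    n_prebleach = x$series$n_prebleach,
    anterior_end_rebased = get("anterior", "end_rebased"),
    posterior_end_rebased = get("posterior", "end_rebased"),
    anterior_end_normalized = get("anterior", "end_normalized"),
    posterior_end_normalized = get("posterior", "end_normalized"),
    anterior_trend_sign = get("anterior", "trend_sign"),
    posterior_trend_sign = get("posterior", "trend_sign")
  )
}
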