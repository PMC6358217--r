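#' Normalised polarity metrics for one oocyte
#'
#' Applies the two-step normalisation: raw quantities of the three membrane
#' domains (the two laterals are pooled into LPM) and the cytoplasm are
#' divided by the total oocyte signal `APM + LPM + PPM + cytoplasm`, giving
#' compartment fractions that sum to 1; the membrane fractions are then
#' divided by their membrane lengths, giving densities (which, unlike the
#' fractions, need not sum to 1). From the densities:
#' \describe{
#'   \item{posterior exclusion ratio}{LPM density / PPM density — above 1
#'     the protein is excluded from the posterior membrane, below 1 it
#'     accumulates there.}
#'   \item{asymmetry ratio}{APM density / PPM density — the antero-posterior
#'     polarisation.}
#' }
#'
#' @param apm,lateral1,lateral2,ppm `domain_measurement`s (APM after
#'   [correct_anterior()] when nurse-cell data are available).
#' @param cytoplasm A `cytoplasm_measurement`.
#' @return A `polarity_metrics` object; [tidy()] returns it as a one-row
#'   tibble. A PPM density of exactly 0 yields `Inf` ratios and sets the
#'   `ppm_density_zero` flag rather than erroring, so batch tables remain
#'   rectangular.
#' @export
compute_metrics <- function(apm, lateral1, lateral2, ppm, cytoplasm) {
  for (m in list(apm, lateral1, lateral2, ppm)) {
    stopifnot(inherits(m, "domain_measurement"))
  }
  stopifnot(inherits(cytoplasm, "cytoplasm_measurement"))
  q_apm <- apm$quantity
  q_lpm <- lateral1$quantity + lateral2$quantity
  q_ppm <- ppm$quantity
  q_cyto <- cytoplasm$quantity
  len_apm <- apm$length
  len_lpm <- lateral1$length + lateral2$length
  len_ppm <- ppm$length
  total <- q_apm + q_lpm + q_ppm + q_cyto
  if (!is.finite(total) || total <= 0) {
    abort("Invalid input: total oocyte quantity must be positive.")
  }
  fractions <- c(APM = q_apm, LPM = q_lpm, PPM = q_ppm, cytoplasm = q_cyto) / total
  densities <- c(
    APM = fractions[["APM"]] / len_apm,
    LPM = fractions[["LPM"]] / len_lpm,
    PPM = fractions[["PPM"]] / len_ppm
  )
  ppm_zero <- densities[["PPM"]] == 0
  if (ppm_zero) {
    warn("PPM density is 0; exclusion and asymmetry ratios reported as Inf.")
  }
  ratio <- function(num) if (ppm_zero) Inf else num / densities[["PPM"]]
  structure(
    list(
      quantities = c(APM = q_apm, LPM = q_lpm, PPM = q_ppm, cytoplasm = q_cyto),
      lengths = c(APM = len_apm, LPM = len_lpm, PPM = len_ppm),
      fractions = fractions,
      densities = densities,
      exclusion_ratio = ratio(densities[["LPM"]]),
      asymmetry_ratio = ratio(densities[["APM"]]),
      cytoplasm_fraction = fractions[["cytoplasm"]],
      ppm_density_zero = ppm_zero
    ),
    class = "polarity_metrics"
  )
}

#' @export
print.polarity_metrics <- function(x, ...) {
  cat("<polarity_metrics>\n")
  cat(sprintf("  fractions: APM %.4f, LPM %.4f, PPM %.4f, cytoplasm %.4f\n",
              x$fractions[["APM"]], x$fractions[["LPM"]],
              x$fractions[["PPM"]], x$fractions[["cytoplasm"]]))
  cat(sprintf("  exclusion ratio (LPM/PPM density): %.3f\n", x$exclusion_ratio))
  cat(sprintf("  asymmetry ratio (APM/PPM density): %.3f\n", x$asymmetry_ratio))
  invisible(x)
}

#' @rdname compute_metrics
#' @param x A `polarity_metrics` object.
#' @param ... Unused.
#' @export
tidy.polarity_metrics <- function(x, ...) {
  tibble(
    quantity_apm = x$quantities[["APM"]],
    quantity_lpm = x$quantities[["LPM"]],
    quantity_ppm = x$quantities[["PPM"]],
    quantity_cytoplasm = x$quantities[["cytoplasm"]],
    length_apm = x$lengths[["APM"]],
    length_lpm = x$lengths[["LPM"]],
    length_ppm = x$lengths[["PPM"]],
    fraction_apm = x$fractions[["APM"]],
    fraction_lpm = x$fractions[["LPM"]],
    fraction_ppm = x$fractions[["PPM"]],
    fraction_cytoplasm = x$fractions[["cytoplasm"]],
    density_apm = x$densities[["APM"]],
    density_lpm = x$densities[["LPM"]],
    density_ppm = x$densities[["PPM"]],
    exclusion_ratio = x$exclusion_ratio,
    asymmetry_ratio = x$asymmetry_ratio,
    cytoplasm_fraction = x$cytoplasm_fraction,
    ppm_density_zero = x$ppm_density_zero
  )
}

#' Analysis configuration
#'
#' Bundles the tunable parameters of the quantification pipeline. All
#' lengths are pixels unless noted.
#'
#' @param band_width Membrane measurement band width (odd, px).
#' @param posterior_fraction Posterior share of the non-anterior perimeter.
#' @param margin Cytoplasm erosion margin (px); keep `>= band_width / 2`.
#' @param nurse_correction `"difference"` or `"simple"`, see
#'   [estimate_nurse_background()].
#' @param snap_radius Anchor snap/consistency radius (px).
#' @param threshold_percentile Tracing threshold percentile.
#' @param closing_size Morphological closing diameter (px) for tracing.
#' @param smoothing_window Arc-length smoothing window (vertices).
#' @param pixel_size Micrometres per pixel.
#' @return A named list of class `oopolar_config`.
#' @export
oopolar_config <- function(band_width = 3, posterior_fraction = 0.2, margin = 3,
                           nurse_correction = c("difference", "simple"),
                           snap_radius = 5, threshold_percentile = 0.75,
                           closing_size = 5, smoothing_window = 5,
                           pixel_size = 1) {
  structure(
    list(
      band_width = band_width,
      posterior_fraction = posterior_fraction,
      margin = margin,
      nurse_correction = match.arg(nurse_correction),
      snap_radius = snap_radius,
      threshold_percentile = threshold_percentile,
      closing_size = closing_size,
      smoothing_window = smoothing_window,
      pixel_size = pixel_size
    ),
    class = "oopolar_config"
  )
}

#' Read an analysis configuration from a YAML file
#'
#' Unset keys fall back to the [oopolar_config()] defaults.
#'
#' @param path YAML file path.
#' @return An `oopolar_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(oopolar_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    warn(sprintf("Ignoring unknown config keys: %s", paste(unknown, collapse = ", ")))
    vals <- vals[intersect(names(vals), known)]
  }
  do.call(oopolar_config, vals)
}

#' Quantify cortical polarity of one oocyte
#'
#' End-to-end pipeline: snap the anchors onto the membrane ridge, trace the
#' perimeter, partition it into the four domains, measure each domain and
#' the cytoplasm, optionally remove the nurse-cell membrane contribution
#' from the anterior signal, and compute the normalised polarity metrics.
#'
#' @param image Numeric matrix (single-channel image).
#' @param anchors [anchor_points()] (unsnapped is fine).
#' @param config An [oopolar_config()].
#' @param simple_mean,double_mean Optional nurse-cell simple/double membrane
#'   means; when both are given the anterior correction is applied.
#' @param nucleus_mask Optional logical matrix excluded from the cytoplasm.
#' @return An `oocyte_quantification` object. [tidy()] returns the one-row
#'   metrics tibble; `$profile` holds the along-membrane intensity profile
#'   (`index`, `arc_position`, `domain`, `intensity`).
#' @export
quantify_oocyte <- function(image, anchors, config = oopolar_config(),
                            simple_mean = NULL, double_mean = NULL,
                            nucleus_mask = NULL) {
  check_image(image)
  snapped <- snap_anchors(image, anchors, snap_radius = config$snap_radius)
  trace <- trace_perimeter(
    image, snapped,
    threshold_percentile = config$threshold_percentile,
    closing_size = config$closing_size,
    snap_radius = config$snap_radius,
    smoothing_window = config$smoothing_window,
    pixel_size = config$pixel_size
  )
  partition <- partition_domains(trace, snapped,
                                 posterior_fraction = config$posterior_fraction)
  meas <- lapply(
    c(anterior = "anterior", lateral1 = "lateral1",
      lateral2 = "lateral2", posterior = "posterior"),
    function(d) measure_domain(image, partition, d, band_width = config$band_width)
  )
  nb <- NULL
  apm <- meas$anterior
  if (!is.null(simple_mean) && !is.null(double_mean)) {
    nb <- estimate_nurse_background(simple_mean, double_mean,
                                    mode = config$nurse_correction)
    apm <- correct_anterior(apm, nb)
  }
  cyto <- measure_cytoplasm(image, partition, margin = config$margin,
                            nucleus_mask = nucleus_mask)
  metrics <- compute_metrics(apm, meas$lateral1, meas$lateral2,
                             meas$posterior, cyto)
  profile <- dplyr::arrange(
    dplyr::bind_rows(lapply(meas, function(m) m$profile)),
    .data$index
  )
  structure(
    list(
      metrics = metrics,
      profile = profile,
      partition = partition,
      anchors = snapped,
      nurse_background = nb,
      anterior_raw = meas$anterior,
      anterior_used = apm,
      cytoplasm = cyto,
      config = config
    ),
    class = "oocyte_quantification"
  )
}

#' @export
print.oocyte_quantification <- function(x, ...) {
  cat("<oocyte_quantification>\n")
  print(x$metrics)
  invisible(x)
}

#' @rdname quantify_oocyte
#' @param x An `oocyte_quantification`.
#' @param ... Unused.
#' @export
tidy.oocyte_quantification <- function(x, ...) {
  out <- tidy(x$metrics)
  out$perimeter_px <- perimeter(x$partition$trace)
  out$nurse_contribution <- if (is.null(x$nurse_background)) NA_real_ else x$nurse_background$contribution
  out
}

#' @rdname quantify_oocyte
#' @export
glance.oocyte_quantification <- function(x, ...) {
  tibble(
    n_trace_points = x$partition$trace$n,
    perimeter_px = perimeter(x$partition$trace),
    cytoplasm_area = x$cytoplasm$area,
    corrected = !is.null(x$nurse_background)
  )
}

#' Quantify a batch of oocytes from a manifest
#'
#' The manifest is a data frame (or CSV path) with columns `image` and
#' `anchors` (file paths) and optionally `genotype`, `stage`, `simple_mean`,
#' `double_mean` plus any other metadata, carried through to the output.
#'
#' @param manifest Data frame or CSV path.
#' @param config An [oopolar_config()].
#' @return A tibble with one row per oocyte: metadata plus all quantities,
#'   lengths, fractions, densities and ratios.
#' @export
quantify_batch <- function(manifest, config = oopolar_config()) {
  if (is.character(manifest)) manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  manifest <- as_tibble(manifest)
  if (!all(c("image", "anchors") %in% names(manifest))) {
    abort("Manifest needs `image` and `anchors` columns.")
  }
  rows <- purrr::map(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    img <- read_image(m$image)
    anc <- read_anchors(m$anchors)
    q <- quantify_oocyte(
      img, anc, config,
      simple_mean = if ("simple_mean" %in% names(m)) m$simple_mean else NULL,
      double_mean = if ("double_mean" %in% names(m)) m$double_mean else NULL
    )
    dplyr::bind_cols(
      dplyr::select(m, -dplyr::any_of(c("image", "anchors"))),
      tidy(q)
    )
  })
  dplyr::bind_rows(rows)
}
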