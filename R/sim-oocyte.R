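#' Synthetic stage-9 oocyte specification
#'
#' Describes the geometry and photometry of a simulated oocyte image: an
#' elliptical membrane band with distinct mean intensities on the anterior,
#' lateral and posterior arcs, diffuse cytoplasm, and (optionally) an
#' apposed nurse-cell compartment at the anterior pole contributing a second
#' membrane to the anterior interface plus standalone simple and double
#' nurse-nurse membranes for the background estimator. The anterior pole
#' faces left (towards the nurse cells), the posterior right.
#'
#' @param dim Image size `(rows, cols)`.
#' @param center Oocyte centre `(row, col)`; default places the oocyte
#'   slightly right of centre, leaving room for the nurse compartment.
#' @param semi_axes Ellipse semi-axes `(a, b)` in px, `a` along columns.
#' @param anterior_half_angle Half-extent of the anterior arc, degrees of
#'   ellipse parameter around 180.
#' @param posterior_half_angle Half-extent of the posterior arc (degrees
#'   around 0), or `NULL` to solve it so the posterior arc is exactly
#'   `posterior_fraction` of the non-anterior perimeter.
#' @param posterior_fraction Target posterior share used when
#'   `posterior_half_angle` is `NULL`.
#' @param membrane_width Band thickness in px.
#' @param membrane_means Named grey levels `c(APM=, LPM=, PPM=)` painted on
#'   the oocyte's own membrane arcs.
#' @param cytoplasm_mean,background Grey levels.
#' @param nurse List: `present`, `membrane_mean` (per-membrane amplitude),
#'   `cytoplasm_mean`, `extent` (px depth of the nurse compartment).
#' @param noise List: `gaussian_sd` (read noise) and `poisson` (shot noise
#'   flag).
#' @return An `oocyte_spec` object.
#' @export
oocyte_spec <- function(dim = c(180, 240), center = NULL,
                        semi_axes = c(a = 80, b = 52),
                        anterior_half_angle = 30,
                        posterior_half_angle = NULL,
                        posterior_fraction = 0.2,
                        membrane_width = 5,
                        membrane_means = c(APM = 200, LPM = 200, PPM = 200),
                        cytoplasm_mean = 50, background = 10,
                        nurse = list(present = TRUE, membrane_mean = 60,
                                     cytoplasm_mean = 25, extent = 40),
                        noise = list(gaussian_sd = 2, poisson = TRUE)) {
  if (is.null(center)) center <- c(dim[1] / 2, dim[2] / 2 + 30)
  a <- unname(semi_axes[1]); b <- unname(semi_axes[2])
  if (a <= 0 || b <= 0 || membrane_width < 1) {
    abort("Spec error: semi-axes must be positive and membrane_width >= 1.")
  }
  if (!all(c("APM", "LPM", "PPM") %in% names(membrane_means)) ||
      any(membrane_means < 0) || cytoplasm_mean < 0 || background < 0) {
    abort("Spec error: all means must be non-negative, with APM/LPM/PPM named.")
  }
  nurse <- utils::modifyList(
    list(present = TRUE, membrane_mean = 60, cytoplasm_mean = 25, extent = 40),
    nurse
  )
  noise <- utils::modifyList(list(gaussian_sd = 2, poisson = TRUE), noise)
  aa <- anterior_half_angle * pi / 180
  if (is.null(posterior_half_angle)) {
    ap <- solve_posterior_angle(a, b, aa, posterior_fraction)
  } else {
    ap <- posterior_half_angle * pi / 180
  }
  if (aa <= 0 || ap <= 0 || aa + ap >= pi) {
    abort("Spec error: anterior and posterior arcs are inconsistent.")
  }
  structure(
    list(dim = dim, center = center, a = a, b = b,
         anterior_half = aa, posterior_half = ap,
         membrane_width = membrane_width,
         membrane_means = membrane_means,
         cytoplasm_mean = cytoplasm_mean, background = background,
         nurse = nurse, noise = noise),
    class = "oocyte_spec"
  )
}

# arc length of the ellipse (a cos t, b sin t) between parameters t1 < t2
ellipse_arc <- function(a, b, t1, t2) {
  integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
            t1, t2, rel.tol = 1e-10)$value
}

ellipse_perimeter <- function(a, b) 4 * ellipse_arc(a, b, 0, pi / 2)

# posterior half-angle giving: posterior arc = fraction * (P - anterior arc)
solve_posterior_angle <- function(a, b, anterior_half, fraction) {
  P <- ellipse_perimeter(a, b)
  ant <- 2 * ellipse_arc(a, b, pi - anterior_half, pi)
  target <- fraction * (P - ant)
  uniroot(function(ap) 2 * ellipse_arc(a, b, 0, ap) - target,
          c(1e-3, pi - anterior_half - 1e-3), tol = 1e-10)$root
}

wrap_pi <- function(t) {
  ((t + pi) %% (2 * pi)) - pi
}

#' Render a synthetic oocyte image with analytic ground truth
#'
#' Paints the oocyte described by an [oocyte_spec()], applies Poisson (shot)
#' and Gaussian (read) noise, and returns the image together with the truth
#' needed for parameter-recovery tests: anchor points at the true domain
#' boundaries, a label matrix, continuous arc lengths, painted means, true
#' compartment fractions, densities, and the exclusion and asymmetry ratios
#' (which, by the density definition, equal the painted LPM/PPM and APM/PPM
#' mean ratios exactly).
#'
#' @param spec An [oocyte_spec()].
#' @param seed Integer seed; identical `(spec, seed)` give bit-identical
#'   images.
#' @return List with `image` (noisy), `clean` (noiseless) and `truth`.
#' @export
make_oocyte <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "oocyte_spec"))
  nr <- spec$dim[1]; nc <- spec$dim[2]
  cy <- spec$center[1]; cx <- spec$center[2]
  a <- spec$a; b <- spec$b; w <- spec$membrane_width
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  dx <- cols - cx
  dy <- rows - cy
  rho <- sqrt((dx / a)^2 + (dy / b)^2)
  t <- atan2(dy / b, dx / a)
  R <- sqrt((a * cos(t))^2 + (b * sin(t))^2)
  band <- abs(rho - 1) * R <= w / 2
  cyto <- (1 - rho) * R > w / 2 & rho < 1
  is_ant <- abs(wrap_pi(t - pi)) <= spec$anterior_half
  is_post <- abs(t) <= spec$posterior_half
  mm <- spec$membrane_means
  img <- matrix(spec$background, nr, nc)
  labels <- matrix(0L, nr, nc)
  img[cyto] <- spec$cytoplasm_mean
  labels[cyto] <- 4L
  img[band & !is_ant & !is_post] <- mm[["LPM"]]
  labels[band & !is_ant & !is_post] <- 2L
  img[band & is_post] <- mm[["PPM"]]
  labels[band & is_post] <- 3L
  apm_paint <- mm[["APM"]] + if (isTRUE(spec$nurse$present)) spec$nurse$membrane_mean else 0
  img[band & is_ant] <- apm_paint
  labels[band & is_ant] <- 1L
  simple_mask <- double_mask <- matrix(FALSE, nr, nc)
  if (isTRUE(spec$nurse$present)) {
    wedge <- rho > 1 & abs(wrap_pi(t - pi)) <= spec$anterior_half + 0.15 &
      (rho - 1) * R <= spec$nurse$extent
    nc_mask <- wedge & !band
    img[nc_mask] <- spec$nurse$cytoplasm_mean
    labels[nc_mask] <- 5L
    strip <- function(col_off) {
      cc <- round(cx - a - col_off)
      rr <- round(cy) + (-12:12)
      ok <- rr >= 1 & rr <= nr & cc >= 2 & cc <= nc - 1
      m <- matrix(FALSE, nr, nc)
      if (any(ok)) m[cbind(rep(rr[ok], 2), rep(c(cc, cc + 1), each = sum(ok)))] <- TRUE
      m
    }
    simple_mask <- strip(12)
    double_mask <- strip(22)
    img[simple_mask] <- spec$nurse$cytoplasm_mean + spec$nurse$membrane_mean
    labels[simple_mask] <- 6L
    img[double_mask] <- spec$nurse$cytoplasm_mean + 2 * spec$nurse$membrane_mean
    labels[double_mask] <- 7L
  }
  clean <- img
  img <- with_seed_if(seed, {
    out <- clean
    if (isTRUE(spec$noise$poisson)) {
      out <- matrix(rpois(length(out), lambda = out), nr, nc)
    }
    if (spec$noise$gaussian_sd > 0) {
      out <- out + matrix(rnorm(length(out), 0, spec$noise$gaussian_sd), nr, nc)
    }
    pmax(out, 0)
  })
  # analytic truth (pre-noise)
  pt <- function(tt) c(cy + b * sin(tt), cx + a * cos(tt))
  anchors <- anchor_points(
    a1 = round_half_up(pt(pi + spec$anterior_half)),
    a2 = round_half_up(pt(pi - spec$anterior_half)),
    p = round_half_up(pt(0))
  )
  P <- ellipse_perimeter(a, b)
  len_ant <- 2 * ellipse_arc(a, b, pi - spec$anterior_half, pi)
  len_post <- 2 * ellipse_arc(a, b, 0, spec$posterior_half)
  len_lat <- P - len_ant - len_post
  cyto_area <- sum(cyto)
  q <- c(APM = mm[["APM"]] * len_ant, LPM = mm[["LPM"]] * len_lat,
         PPM = mm[["PPM"]] * len_post,
         cytoplasm = spec$cytoplasm_mean * cyto_area)
  total <- sum(q)
  fractions <- q / total
  densities <- c(APM = fractions[["APM"]] / len_ant,
                 LPM = fractions[["LPM"]] / len_lat,
                 PPM = fractions[["PPM"]] / len_post)
  truth <- list(
    anchors = anchors,
    labels = labels,
    simple_mask = simple_mask,
    double_mask = double_mask,
    membrane_means = mm,
    anterior_painted_mean = apm_paint,
    nurse_contribution = if (isTRUE(spec$nurse$present)) spec$nurse$membrane_mean else 0,
    simple_mean = if (isTRUE(spec$nurse$present))
      spec$nurse$cytoplasm_mean + spec$nurse$membrane_mean else NA_real_,
    double_mean = if (isTRUE(spec$nurse$present))
      spec$nurse$cytoplasm_mean + 2 * spec$nurse$membrane_mean else NA_real_,
    perimeter = P,
    lengths = c(APM = len_ant, LPM = len_lat, PPM = len_post),
    posterior_fraction = len_post / (P - len_ant),
    cytoplasm_area = cyto_area,
    quantities = q,
    fractions = fractions,
    densities = densities,
    exclusion_ratio = mm[["LPM"]] / mm[["PPM"]],
    asymmetry_ratio = mm[["APM"]] / mm[["PPM"]],
    seed = seed
  )
  list(image = img, clean = clean, truth = truth)
}
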