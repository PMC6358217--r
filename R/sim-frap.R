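#' Synthetic FRAP stack with programmed recovery kinetics
#'
#' Renders a time-lapse of a synthetic oocyte in which the anterior membrane
#' is photobleached after `n_prebleach` frames and then recovers along a
#' saturating exponential towards `plateau` (as a fraction of the pre-bleach
#' level), while the posterior membrane declines exponentially towards
#' `floor`. Lateral membrane and cytoplasm are constant. The nurse
#' compartment is off by default so the anterior quantity needs no
#' correction when measuring recovery curves.
#'
#' @param spec An [oocyte_spec()]; its noise settings apply per frame.
#' @param n_frames Total frames.
#' @param bleach_index 1-based index of the first post-bleach frame; must
#'   leave at least `n_prebleach` frames before it.
#' @param n_prebleach Pre-bleach frame count (default 6).
#' @param frame_interval_s Seconds between frames.
#' @param anterior_recovery List `plateau` (fraction of pre-bleach, >= 0),
#'   `rate` (1/s, >= 0), `depth` (fraction remaining immediately after the
#'   bleach).
#' @param posterior_decay List `floor` (fraction, >= 0) and `rate` (1/s).
#' @param seed Integer seed.
#' @return List `stack` (row x col x frame array), `times`, `truth`
#'   (per-frame true anterior/posterior means, kinetic parameters, anchors).
#' @export
make_frap_stack <- function(spec = oocyte_spec(nurse = list(present = FALSE)),
                            n_frames = 26, bleach_index = 7, n_prebleach = 6,
                            frame_interval_s = 2,
                            anterior_recovery = list(plateau = 0.6, rate = 0.25,
                                                     depth = 0.1),
                            posterior_decay = list(floor = 0.5, rate = 0.08),
                            seed = NULL) {
  stopifnot(inherits(spec, "oocyte_spec"))
  ar <- utils::modifyList(list(plateau = 0.6, rate = 0.25, depth = 0.1),
                          anterior_recovery)
  pd <- utils::modifyList(list(floor = 0.5, rate = 0.08), posterior_decay)
  if (ar$plateau < 0 || ar$rate < 0 || ar$depth < 0 || pd$floor < 0 || pd$rate < 0) {
    abort("Spec error: kinetic parameters must be non-negative.")
  }
  if (n_prebleach < 1 || bleach_index < n_prebleach + 1 || n_frames <= bleach_index) {
    abort("Spec error: need n_prebleach pre-bleach frames before bleach_index and frames after it.")
  }
  base <- make_oocyte(
    oocyte_spec(
      dim = spec$dim, center = spec$center,
      semi_axes = c(a = spec$a, b = spec$b),
      anterior_half_angle = spec$anterior_half * 180 / pi,
      posterior_half_angle = spec$posterior_half * 180 / pi,
      membrane_width = spec$membrane_width,
      membrane_means = spec$membrane_means,
      cytoplasm_mean = spec$cytoplasm_mean, background = spec$background,
      nurse = spec$nurse,
      noise = list(gaussian_sd = 0, poisson = FALSE)
    )
  )
  labels <- base$truth$labels
  apm_mask <- labels == 1L
  ppm_mask <- labels == 3L
  A0 <- spec$membrane_means[["APM"]]
  P0 <- spec$membrane_means[["PPM"]]
  times <- (seq_len(n_frames) - 1) * frame_interval_s
  tau <- pmax(0, (seq_len(n_frames) - bleach_index)) * frame_interval_s
  pre <- seq_len(n_frames) < bleach_index
  ant_mean <- ifelse(pre, A0,
                     A0 * (ar$plateau - (ar$plateau - ar$depth) * exp(-ar$rate * tau)))
  post_mean <- ifelse(pre, P0,
                      P0 * (pd$floor + (1 - pd$floor) * exp(-pd$rate * tau)))
  nr <- spec$dim[1]; nc <- spec$dim[2]
  stack <- with_seed_if(seed, {
    out <- array(0, c(nr, nc, n_frames))
    for (i in seq_len(n_frames)) {
      f <- base$clean
      f[apm_mask] <- ant_mean[i]
      f[ppm_mask] <- post_mean[i]
      if (isTRUE(spec$noise$poisson)) {
        f <- matrix(rpois(length(f), lambda = f), nr, nc)
      }
      if (spec$noise$gaussian_sd > 0) {
        f <- f + matrix(rnorm(length(f), 0, spec$noise$gaussian_sd), nr, nc)
      }
      out[, , i] <- pmax(f, 0)
    }
    out
  })
  truth <- list(
    anchors = base$truth$anchors,
    bleach_index = bleach_index,
    n_prebleach = n_prebleach,
    times = times,
    anterior_mean = ant_mean,
    posterior_mean = post_mean,
    anterior_recovery = ar,
    posterior_decay = pd,
    expected_normalized_plateau = ar$plateau,
    lengths = base$truth$lengths,
    seed = seed
  )
  list(stack = stack, times = times, truth = truth)
}
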