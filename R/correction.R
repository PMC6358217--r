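#' Estimate the nurse-cell contribution to the anterior signal
#'
#' The anterior membrane signal is the sum of the oocyte's own anterior
#' plasma membrane and the apposed nurse-cell plasma membrane. Measuring a
#' simple (one-membrane) and a double (two apposed membranes) nurse-cell
#' interface in the same image gives the net signal of one extra membrane
#' with the diffuse background cancelled: `contribution = double - simple`.
#' The `"simple"` mode instead subtracts the raw simple-membrane mean, which
#' double-counts diffuse background but mirrors a literal reading of the
#' original protocol.
#'
#' @param simple_mean Mean grey level of a single nurse-cell membrane.
#' @param double_mean Mean grey level of a nurse-nurse double membrane.
#' @param mode `"difference"` (default) or `"simple"`.
#' @return A `nurse_background` object with the per-unit-length
#'   `contribution` (clamped at 0 with a warning when negative).
#' @export
estimate_nurse_background <- function(simple_mean, double_mean,
                                      mode = c("difference", "simple")) {
  mode <- match.arg(mode)
  if (!is_scalar_number(simple_mean) || !is_scalar_number(double_mean) ||
      simple_mean < 0 || double_mean < 0) {
    abort("`simple_mean` and `double_mean` must be single non-negative numbers.")
  }
  contribution <- switch(mode,
    difference = double_mean - simple_mean,
    simple = simple_mean
  )
  clamped <- FALSE
  if (contribution < 0) {
    warn(sprintf(
      "Double-membrane mean (%.3f) below simple-membrane mean (%.3f); nurse contribution clamped to 0.",
      double_mean, simple_mean
    ))
    contribution <- 0
    clamped <- TRUE
  }
  structure(
    list(simple_mean = simple_mean, double_mean = double_mean,
         contribution = contribution, mode = mode, clamped = clamped),
    class = "nurse_background"
  )
}

#' @export
print.nurse_background <- function(x, ...) {
  cat(sprintf("<nurse_background> simple %.3f, double %.3f -> contribution %.3f (%s)\n",
              x$simple_mean, x$double_mean, x$contribution, x$mode))
  invisible(x)
}

#' Correct the anterior measurement for the nurse-cell membrane
#'
#' Subtracts the nurse-cell per-unit-length contribution from the anterior
#' mean intensity (clamping at 0 with a warning) and recomputes the raw
#' quantity; the domain length is unchanged.
#'
#' @param anterior A `domain_measurement` with label `"anterior"`.
#' @param nurse_background A [estimate_nurse_background()] result.
#' @return The corrected `domain_measurement` (with a `corrected` flag).
#' @export
correct_anterior <- function(anterior, nurse_background) {
  stopifnot(inherits(anterior, "domain_measurement"),
            inherits(nurse_background, "nurse_background"))
  if (anterior$label != "anterior") {
    abort("`correct_anterior()` expects the anterior domain measurement.")
  }
  corrected <- anterior$mean_intensity - nurse_background$contribution
  if (corrected < 0) {
    warn(sprintf(
      "Nurse contribution (%.3f) exceeds the anterior mean (%.3f); corrected mean clamped to 0.",
      nurse_background$contribution, anterior$mean_intensity
    ))
    corrected <- 0
  }
  out <- anterior
  out$mean_intensity <- corrected
  out$quantity <- corrected * anterior$length
  out$corrected <- TRUE
  out$nurse_contribution <- nurse_background$contribution
  out
}
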