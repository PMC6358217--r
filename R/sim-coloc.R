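#' Synthetic punctum pair with a programmed colocalized fraction
#'
#' Emulates the dotted vesicular structures used for colocalization: `n`
#' Gaussian puncta per channel inside a disc mask, of which
#' `round(n * coloc_fraction)` share their centres across channels; the
#' remaining channel-1 puncta are placed more than `4 * punctum_sigma` from
#' every channel-2 centre, so their supports are disjoint. Gaussian read
#' noise is added to both channels.
#'
#' @param n_puncta Puncta per channel.
#' @param coloc_fraction Programmed shared-centre fraction in `[0, 1]`.
#' @param punctum_sigma Gaussian radius (px).
#' @param intensity Peak amplitude (grey levels).
#' @param noise_sd Gaussian noise SD.
#' @param dim Image size.
#' @param min_sep Minimum centre separation within a channel (px).
#' @param seed Integer seed.
#' @return List `ch1`, `ch2`, `mask`, `truth` (centres, programmed fraction,
#'   per-channel punctum-core masks: the 1-sigma discs around the centres).
#' @export
make_coloc_pair <- function(n_puncta = 200, coloc_fraction = 0.5,
                            punctum_sigma = 2, intensity = 150, noise_sd = 2,
                            dim = c(256, 256), min_sep = 3 * punctum_sigma,
                            seed = NULL) {
  if (coloc_fraction < 0 || coloc_fraction > 1) {
    abort("`coloc_fraction` must be in [0, 1].")
  }
  nr <- dim[1]; nc <- dim[2]
  cen <- c(nr, nc) / 2
  radius <- min(nr, nc) / 2 - 8
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  mask <- (rows - cen[1])^2 + (cols - cen[2])^2 <= radius^2
  inner <- radius - 4 * punctum_sigma
  with_seed_if(seed, {
    draw_point <- function() {
      repeat {
        p <- runif(2, -1, 1) * inner
        if (sum(p^2) <= inner^2) return(cen + p)
      }
    }
    place <- function(n, avoid = NULL, avoid_dist = 0) {
      pts <- matrix(0, 0, 2)
      tries <- 0L
      while (nrow(pts) < n) {
        tries <- tries + 1L
        if (tries > 200L * n + 1000L) {
          abort("Placement error: mask too small to place puncta disjointly.")
        }
        p <- draw_point()
        ok <- TRUE
        if (nrow(pts) > 0 &&
            min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) < min_sep^2) ok <- FALSE
        if (ok && !is.null(avoid) && nrow(avoid) > 0 &&
            min((avoid[, 1] - p[1])^2 + (avoid[, 2] - p[2])^2) < avoid_dist^2) ok <- FALSE
        if (ok) pts <- rbind(pts, p)
      }
      pts
    }
    centers2 <- place(n_puncta)
    n_share <- round(n_puncta * coloc_fraction)
    shared <- centers2[seq_len(n_share), , drop = FALSE]
    lone1 <- if (n_puncta - n_share > 0) {
      place(n_puncta - n_share, avoid = centers2,
            avoid_dist = 4 * punctum_sigma + min_sep / 2)
    } else {
      matrix(0, 0, 2)
    }
    centers1 <- rbind(shared, lone1)
    paint <- function(centers) {
      img <- matrix(0, nr, nc)
      rad <- ceiling(4 * punctum_sigma)
      for (i in seq_len(nrow(centers))) {
        r0 <- max(1, floor(centers[i, 1] - rad)):min(nr, ceiling(centers[i, 1] + rad))
        c0 <- max(1, floor(centers[i, 2] - rad)):min(nc, ceiling(centers[i, 2] + rad))
        d2 <- outer((r0 - centers[i, 1])^2, (c0 - centers[i, 2])^2, "+")
        img[r0, c0] <- img[r0, c0] + intensity * exp(-d2 / (2 * punctum_sigma^2))
      }
      img
    }
    ch1 <- paint(centers1)
    ch2 <- paint(centers2)
    # punctum label = the 1-sigma core, where the Gaussian still carries
    # >= 61% of the peak amplitude (the 2-4 sigma skirt fades into noise)
    punctum_mask <- function(centers) {
      m <- matrix(FALSE, nr, nc)
      for (i in seq_len(nrow(centers))) {
        m <- m | ((rows - centers[i, 1])^2 + (cols - centers[i, 2])^2 <=
                    punctum_sigma^2)
      }
      m
    }
    truth <- list(
      centers1 = centers1, centers2 = centers2,
      n_shared = n_share,
      coloc_fraction = n_share / n_puncta,
      mask1 = punctum_mask(centers1),
      mask2 = punctum_mask(centers2),
      seed = seed
    )
    if (noise_sd > 0) {
      ch1 <- pmax(ch1 + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc), 0)
      ch2 <- pmax(ch2 + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc), 0)
    }
    list(ch1 = ch1, ch2 = ch2, mask = mask, truth = truth)
  })
}
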