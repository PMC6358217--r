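# membrane_geometry: anchor snapping, perimeter tracing, domain partition.

test_that("anchors validate their inputs and round-trip through CSV", {
  expect_error(anchor_points(c(1, 2), c(1, 2), c(3, 4)), "distinct")
  expect_error(anchor_points(c(1, NA), c(1, 2), c(3, 4)), "finite")
  expect_error(anchor_points(1, c(1, 2), c(3, 4)), "a1")

  a <- anchor_points(c(10, 20), c(30, 40), c(50, 60))
  path <- withr::local_tempfile(fileext = ".csv")
  write_anchors(a, path)
  on_disk <- read.csv(path)
  expect_equal(on_disk$row, c(9, 29, 49))  # 0-based on disk
  b <- read_anchors(path)
  expect_equal(b$a1, a$a1)
  expect_equal(b$p, a$p)
  expect_equal(tidy(a)$label, c("a1", "a2", "p"))
})

test_that("snapping is a fixed point on the brightest pixel and identity at radius 0", {
  img <- matrix(0, 40, 40)
  img[20, 20] <- 120
  img[15, 30] <- 80
  img[30, 15] <- 80
  a <- anchor_points(c(20, 20), c(15, 30), c(30, 15))
  s <- snap_anchors(img, a, snap_radius = 5, background_percentile = 0.5)
  expect_equal(s$a1, c(20, 20))
  expect_equal(s$a2, c(15, 30))
  expect_equal(s$p, c(30, 15))
  expect_equal(snap_anchors(img, anchor_points(c(22, 22), a$a2, a$p),
                            snap_radius = 0)$a1, c(22, 22))
})

test_that("snapping agrees with an exhaustive-search oracle on a noiseless ring", {
  # ring of value 100 on background 0; anchors placed a few px off the ring
  nr <- 60; nc <- 60
  rows <- matrix(rep(1:nr, nc), nr, nc)
  cols <- matrix(rep(1:nc, each = nr), nr, nc)
  d <- sqrt((rows - 30)^2 + (cols - 30)^2)
  img <- ifelse(abs(d - 20) <= 1, 100, 0)
  at <- list(a1 = c(30, 13), a2 = c(13, 30), p = c(30, 47))  # 3 px inside
  s <- snap_anchors(img, anchor_points(at$a1, at$a2, at$p), snap_radius = 5)
  for (nm in names(at)) {
    expect_equal(s[[nm]], snap_oracle(img, at[[nm]], 5), info = nm)
    expect_equal(img[s[[nm]][1], s[[nm]][2]], 100, info = nm)  # on the ring
  }
})

test_that("snapping errors on out-of-bounds anchors and featureless windows", {
  img <- matrix(0, 40, 40)
  img[10:30, 10:30] <- 100
  inside <- anchor_points(c(10, 10), c(30, 30), c(10, 30))
  expect_error(
    snap_anchors(img, anchor_points(c(0, 5), c(30, 30), c(10, 30)), 5),
    "bounds"
  )
  # anchor `p` sits in far background: no pixel above the background
  # percentile within its window
  a <- anchor_points(c(10, 10), c(30, 30), c(3, 38))
  expect_error(snap_anchors(img, a, snap_radius = 2), "p")
})

test_that("traced ellipse stays within 1 px of the analytic contour and 2% of Ramanujan", {
  # the noiseless band: semi-axes 80 x 50, band value 200, background 20
  sp <- plain_spec(semi_axes = c(a = 80, b = 50), cytoplasm_mean = 20,
                   background = 20,
                   membrane_means = c(APM = 200, LPM = 200, PPM = 200))
  oo <- make_oocyte(sp)
  snapped <- snap_anchors(oo$image, oo$truth$anchors)
  tr <- trace_perimeter(oo$image, snapped)
  v <- tidy(tr)
  # analytic distance from the ellipse: |rho - 1| * local radius
  dxa <- (v$col - sp$center[2]) / 80
  dyb <- (v$row - sp$center[1]) / 50
  rho <- sqrt(dxa^2 + dyb^2)
  tt <- atan2(dyb, dxa)
  rad <- sqrt((80 * cos(tt))^2 + (50 * sin(tt))^2)
  expect_lt(max(abs(rho - 1) * rad), 1)
  expect_lt(abs(perimeter(tr) / ramanujan_perimeter(80, 50) - 1), 0.02)
  # contract: closed 8-connected pixel path, counter-clockwise, near a1
  expect_equal(tr$points[nrow(tr$points), ], tr$points[1, ])
  expect_gt(tr$signed_area, 0)
  expect_lt(sqrt(sum((tr$points[1, ] - snapped$a1)^2)), 5 + 1e-9)
})

test_that("tracing errors on degenerate images", {
  a <- anchor_points(c(5, 5), c(10, 10), c(15, 15))
  expect_error(trace_perimeter(matrix(7, 40, 40), a), "constant")
  # anchors far from the only structure -> tracing error naming the limit
  img <- matrix(0, 60, 60)
  img[20:40, 20:40] <- 100
  far <- anchor_points(c(2, 2), c(2, 58), c(58, 58))
  expect_error(trace_perimeter(img, far), "Tracing error")
})

test_that("membrane_trace enforces its invariants", {
  expect_error(membrane_trace(rbind(c(1, 1), c(1, 2))), "3 distinct")
  expect_error(membrane_trace(rbind(c(1, 1), c(1, 2), c(1, 4))), "8-connected")
  expect_error(
    membrane_trace(rbind(c(1, 1), c(1, 2), c(2, 2), c(1, 2))),
    "self-intersecting"
  )
  expect_error(
    membrane_trace(rbind(c(1.5, 1.5), c(1.5, 2.5), c(1.5, 3.5))),
    "no area"
  )
  tr <- membrane_trace(rbind(c(1, 1), c(1, 2), c(2, 2), c(2, 1)),
                       smoothing_window = 1)
  expect_equal(perimeter(tr), 4)
  expect_equal(tr$n, 4)
})

test_that("traces round-trip through CSV (0-based on disk)", {
  tr <- membrane_trace(rbind(c(3, 3), c(3, 4), c(4, 4), c(4, 3)),
                       smoothing_window = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  expect_equal(read.csv(path)$row[1], 2)
  tr2 <- read_trace(path, smoothing_window = 1)
  expect_equal(trace_points <- tidy(tr2), tidy(tr))
})

test_that("densify_polygon produces a valid 8-connected pixel trace", {
  sq <- rbind(c(10, 10), c(10, 30), c(30, 30), c(30, 10))
  tr <- densify_polygon(sq, smoothing_window = 1)
  expect_equal(tr$kind, "pixel")
  expect_equal(perimeter(tr), 80)
  steps <- diff(tr$points)
  expect_true(all(pmax(abs(steps[, 1]), abs(steps[, 2])) == 1))
})

test_that("circle partition matches the symmetry example (60/120/60/120)", {
  # circumference-360 circle, a1/a2 at +-30 degrees from the top, p at the
  # bottom, posterior_fraction 0.2 -> anterior 60, posterior 60, laterals 120
  v <- circle_polygon()
  tr <- membrane_trace(v)
  r <- 360 / (2 * pi)
  pt <- function(deg) c(100 - r * cos(deg * pi / 180),
                        100 + r * sin(deg * pi / 180))
  anchors <- anchor_points(pt(-30), pt(30), pt(180))
  part <- partition_domains(tr, anchors, posterior_fraction = 0.2)
  seg <- part$segments
  lens <- setNames(seg$length_px, seg$domain)
  # the polygon perimeter is marginally below 360 (chords, not arcs)
  expect_equal(unname(lens["anterior"]), 60, tolerance = 1e-3)
  expect_equal(unname(lens["posterior"]), 60, tolerance = 1e-3)
  expect_equal(unname(lens["lateral1"]), 120, tolerance = 1e-3)
  expect_equal(unname(lens["lateral2"]), 120, tolerance = 1e-3)
  expect_equal(sum(lens), perimeter(tr), tolerance = 1e-12)
})

test_that("partition segments are disjoint, contiguous, exhaustive, and sum to the perimeter", {
  for (seed in 1:4) {
    oo <- make_oocyte(oocyte_spec(), seed = seed)
    snapped <- snap_anchors(oo$image, oo$truth$anchors)
    tr <- trace_perimeter(oo$image, snapped)
    part <- partition_domains(tr, snapped)
    seg <- part$segments
    idx <- unlist(Map(seq.int, seg$start_index, seg$end_index))
    expect_equal(sort(idx), seq_len(part$trace$n))     # exhaustive + disjoint
    expect_equal(sum(seg$length_px), perimeter(part$trace), tolerance = 1e-9)
    expect_true(all(seg$length_px > 0))
  }
})

test_that("lateral1 is adjacent to a1 and labels are stable across calls", {
  v <- circle_polygon()
  tr <- membrane_trace(v)
  r <- 360 / (2 * pi)
  pt <- function(deg) c(100 - r * cos(deg * pi / 180),
                        100 + r * sin(deg * pi / 180))
  anchors <- anchor_points(pt(-30), pt(30), pt(180))
  p1 <- partition_domains(tr, anchors)
  p2 <- partition_domains(tr, anchors)
  expect_identical(p1$segments, p2$segments)
  expect_equal(p1$segments$domain,
               c("anterior", "lateral2", "posterior", "lateral1"))
  # lateral1 is the arc ending back at a1 (vertex 1): it owns the last vertex
  lat1 <- p1$segments[p1$segments$domain == "lateral1", ]
  expect_equal(lat1$end_index, p1$trace$n)
})

test_that("most posterior-segment vertices fall on the painted posterior arc", {
  oo <- make_oocyte(oocyte_spec(membrane_means = c(APM = 500, LPM = 200,
                                                   PPM = 100)), seed = 11)
  q <- quantify_generated(oo)
  seg <- q$partition$segments
  post <- seg[seg$domain == "posterior", ]
  v <- tidy(q$partition$trace)
  pv <- v[post$start_index:post$end_index, ]
  labs <- oo$truth$labels[cbind(pv$row, pv$col)]
  expect_gte(mean(labs == 3L), 0.95)
})

test_that("partition rejects invalid anchors and overlapping arcs", {
  v <- circle_polygon()
  tr <- membrane_trace(v)
  r <- 360 / (2 * pi)
  pt <- function(deg) c(100 - r * cos(deg * pi / 180),
                        100 + r * sin(deg * pi / 180))
  # p so close to a2 that they land on the same vertex -> invalid anchors
  expect_error(
    partition_domains(tr, anchor_points(pt(-30), pt(30), pt(30.2))),
    "coincident"
  )
  # off-centre p with a large fraction: the posterior arc, centred on p,
  # would reach back into the anterior arc
  expect_error(
    partition_domains(tr, anchor_points(pt(-30), pt(30), pt(120)),
                      posterior_fraction = 0.9),
    "overlap"
  )
  expect_error(
    partition_domains(tr, anchor_points(pt(-30), pt(30), pt(180)),
                      posterior_fraction = 1.2),
    "between 0 and 1"
  )
})

test_that("partition lengths are stable (within 1%) under 90-degree rotation", {
  oo <- make_oocyte(oocyte_spec(), seed = 3)
  q <- quantify_generated(oo)
  imgr <- rot_image_cw(oo$image)
  ar <- rot_anchors_cw(oo$truth$anchors, nrow(oo$image))
  sr <- snap_anchors(imgr, ar)
  tr <- trace_perimeter(imgr, sr)
  pr <- partition_domains(tr, sr)
  l0 <- setNames(q$partition$segments$length_px, q$partition$segments$domain)
  l1 <- setNames(pr$segments$length_px, pr$segments$domain)
  expect_true(all(abs(l1[names(l0)] / l0 - 1) < 0.01))
})
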