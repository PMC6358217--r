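# domain_quantification: band measurement, cytoplasm, nurse correction,
# normalised metrics, end-to-end pipeline and batch mode.

make_circle_partition <- function() {
  v <- circle_polygon(center = c(50, 50), r = 30, n = 240)
  tr <- densify_polygon(v)
  pt <- function(deg) c(50 - 30 * cos(deg * pi / 180),
                        50 + 30 * sin(deg * pi / 180))
  anchors <- anchor_points(pt(-30), pt(30), pt(180))
  partition_domains(tr, anchors)
}

test_that("measure_domain on constant and zero images is exact", {
  part <- make_circle_partition()
  uniform <- matrix(7, 100, 100)
  m <- measure_domain(uniform, part, "anterior")
  expect_equal(m$mean_intensity, 7)
  expect_equal(m$quantity, 7 * m$length)
  expect_equal(m$profile$intensity, rep(7, nrow(m$profile)))

  z <- measure_domain(matrix(0, 100, 100), part, "posterior")
  expect_equal(z$mean_intensity, 0)
  expect_equal(z$quantity, 0)
})

test_that("measure_domain validates band width and domain name", {
  part <- make_circle_partition()
  img <- matrix(1, 100, 100)
  expect_error(measure_domain(img, part, "anterior", band_width = 2), "odd")
  expect_error(measure_domain(img, part, "apical"), "Unknown domain")
})

test_that("recovered band mean matches the painted truth within 3 sd / sqrt(N)", {
  # Gaussian read noise only, so the band mean estimator is unbiased with
  # known sd; the tolerance is the spec'd 3-sigma band around 200.
  sp <- oocyte_spec(membrane_means = c(APM = 200, LPM = 200, PPM = 200),
                    background = 20, nurse = list(present = FALSE),
                    noise = list(gaussian_sd = 5, poisson = FALSE))
  oo <- make_oocyte(sp, seed = 21)
  snapped <- snap_anchors(oo$image, oo$truth$anchors)
  part <- partition_domains(trace_perimeter(oo$image, snapped), snapped)
  for (dom in c("anterior", "lateral1", "lateral2", "posterior")) {
    m <- measure_domain(oo$image, part, dom, band_width = 3)
    n_samples <- 3 * nrow(m$profile)
    expect_lt(abs(m$mean_intensity - 200), 3 * 5 / sqrt(n_samples))
  }
})

test_that("a band reaching outside the image is clipped with a warning", {
  v <- rbind(c(1, 5), c(1, 20), c(15, 20), c(15, 5))
  tr <- densify_polygon(v, smoothing_window = 1)
  part <- partition_domains(tr, anchor_points(c(1, 8), c(1, 17), c(15, 12)))
  img <- matrix(1, 30, 30)
  expect_warning(measure_domain(img, part, "anterior"), "clipped")
})

test_that("measure_cytoplasm recovers uniform and generated interiors", {
  part <- make_circle_partition()
  img <- matrix(3, 100, 100)
  cm <- measure_cytoplasm(img, part, margin = 3)
  expect_equal(cm$mean_intensity, 3)
  expect_equal(cm$quantity, 3 * cm$area)
  # the eroded region excludes the membrane: every mask pixel sits inside
  # the circle by more than the band half-width
  idx <- which(cm$mask, arr.ind = TRUE)
  d <- sqrt((idx[, 1] - 50)^2 + (idx[, 2] - 50)^2)
  expect_lt(max(d), 30 - 1.5)

  oo <- make_oocyte(oocyte_spec(), seed = 5)
  q <- quantify_generated(oo)
  expect_lt(abs(q$cytoplasm$mean_intensity / 50 - 1), 0.02)
})

test_that("measure_cytoplasm honours the nucleus mask and degenerate margins", {
  part <- make_circle_partition()
  img <- matrix(3, 100, 100)
  nucleus <- matrix(FALSE, 100, 100)
  nucleus[40:60, 40:60] <- TRUE
  full <- measure_cytoplasm(img, part, margin = 3)
  excl <- measure_cytoplasm(img, part, margin = 3, nucleus_mask = nucleus)
  expect_equal(excl$mean_intensity, 3)
  expect_equal(excl$area, full$area - sum(nucleus & full$mask))
  expect_error(measure_cytoplasm(img, part, margin = 40), "Degenerate")
})

test_that("nurse background estimator follows the simple/double arithmetic", {
  expect_equal(estimate_nurse_background(40, 40)$contribution, 0)
  # background 30 + one membrane 60 = 90; + two membranes = 150
  nb <- estimate_nurse_background(90, 150)
  expect_equal(nb$contribution, 60)
  expect_false(nb$clamped)
  expect_warning(nb2 <- estimate_nurse_background(100, 80), "clamped")
  expect_equal(nb2$contribution, 0)
  expect_true(nb2$clamped)
  # literal mode subtracts the raw simple-membrane mean
  expect_equal(estimate_nurse_background(90, 150, mode = "simple")$contribution, 90)
  expect_error(estimate_nurse_background(-1, 10), "non-negative")
})

test_that("correct_anterior subtracts, clamps, and recomputes the quantity", {
  ant <- fake_measurement("anterior", 260, 50)
  nb <- estimate_nurse_background(85, 145)  # contribution 60
  out <- correct_anterior(ant, nb)
  expect_equal(out$mean_intensity, 200)
  expect_equal(out$quantity, 200 * 50)
  expect_equal(out$length, 50)
  # zero contribution leaves the measurement unchanged
  same <- correct_anterior(ant, estimate_nurse_background(40, 40))
  expect_equal(same$mean_intensity, ant$mean_intensity)
  expect_equal(same$quantity, ant$quantity)
  # over-subtraction clamps at zero with a warning
  low <- fake_measurement("anterior", 50, 10)
  big <- estimate_nurse_background(20, 100)  # contribution 80
  expect_warning(cl <- correct_anterior(low, big), "clamped")
  expect_equal(cl$mean_intensity, 0)
  expect_equal(cl$quantity, 0)
  expect_error(correct_anterior(fake_measurement("posterior", 1, 1), nb),
               "anterior")
})

test_that("compute_metrics reproduces forced fraction arithmetic and pools laterals", {
  # quantities APM 2, LPM 3 (1.8 + 1.2), PPM 1, cytoplasm 4
  m <- compute_metrics(
    apm = fake_measurement("anterior", 0.2, 10),
    lateral1 = fake_measurement("lateral1", 0.15, 12),
    lateral2 = fake_measurement("lateral2", 0.15, 8),
    ppm = fake_measurement("posterior", 0.2, 5),
    cytoplasm = fake_cytoplasm(0.004, 1000)
  )
  expect_equal(unname(m$fractions), c(2, 3, 1, 4) / 10)
  expect_equal(m$lengths[["LPM"]], 20)
  expect_equal(m$cytoplasm_fraction, 0.4)
  # densities = fraction / length; ratios from densities
  expect_equal(m$densities[["LPM"]], 0.3 / 20)
  expect_equal(m$exclusion_ratio, (0.3 / 20) / (0.1 / 5))
  expect_equal(m$asymmetry_ratio, (0.2 / 10) / (0.1 / 5))
  td <- tidy(m)
  expect_equal(nrow(td), 1)
  expect_equal(td$fraction_apm + td$fraction_lpm + td$fraction_ppm +
                 td$fraction_cytoplasm, 1)
})

test_that("equal densities give ratios of exactly 1", {
  m <- compute_metrics(
    apm = fake_measurement("anterior", 5, 40),
    lateral1 = fake_measurement("lateral1", 5, 70),
    lateral2 = fake_measurement("lateral2", 5, 50),
    ppm = fake_measurement("posterior", 5, 30),
    cytoplasm = fake_cytoplasm(2, 500)
  )
  expect_equal(m$exclusion_ratio, 1)
  expect_equal(m$asymmetry_ratio, 1)
})

test_that("zero PPM density flags Inf ratios; zero total errors", {
  expect_warning(
    m <- compute_metrics(
      apm = fake_measurement("anterior", 5, 40),
      lateral1 = fake_measurement("lateral1", 5, 70),
      lateral2 = fake_measurement("lateral2", 5, 50),
      ppm = fake_measurement("posterior", 0, 30),
      cytoplasm = fake_cytoplasm(2, 500)
    ),
    "Inf"
  )
  expect_true(m$ppm_density_zero)
  expect_identical(m$exclusion_ratio, Inf)
  expect_identical(m$asymmetry_ratio, Inf)
  expect_error(
    compute_metrics(
      apm = fake_measurement("anterior", 0, 40),
      lateral1 = fake_measurement("lateral1", 0, 70),
      lateral2 = fake_measurement("lateral2", 0, 50),
      ppm = fake_measurement("posterior", 0, 30),
      cytoplasm = fake_cytoplasm(0, 500)
    ),
    "positive"
  )
})

test_that("uncorrected anterior density strictly exceeds corrected on nurse oocytes", {
  oo <- make_oocyte(oocyte_spec(), seed = 9)
  q <- quantify_generated(oo)
  expect_gt(q$anterior_raw$mean_intensity, q$anterior_used$mean_intensity)
  expect_gt(q$nurse_background$contribution, 0)
})

test_that("quantify_oocyte recovers programmed truths end to end", {
  oo <- make_oocyte(oocyte_spec(membrane_means = c(APM = 500, LPM = 200,
                                                   PPM = 100)), seed = 2)
  q <- quantify_generated(oo)
  td <- tidy(q)
  expect_lt(abs(td$exclusion_ratio / 2 - 1), 0.15)
  expect_lt(abs(td$asymmetry_ratio / 5 - 1), 0.15)
  expect_lt(abs(td$perimeter_px / oo$truth$perimeter - 1), 0.02)
  expect_lt(abs(q$anterior_used$mean_intensity / 500 - 1), 0.10)
  # profile covers every trace vertex exactly once, in arc order
  expect_equal(q$profile$index, seq_len(q$partition$trace$n))
  expect_true(glance(q)$corrected)
})

test_that("config validates, reads YAML, and warns about unknown keys", {
  cfg <- oopolar_config(band_width = 5, posterior_fraction = 0.25)
  expect_s3_class(cfg, "oopolar_config")
  expect_equal(cfg$nurse_correction, "difference")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("band_width: 5", "margin: 4", "nurse_correction: simple"), path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$band_width, 5)
  expect_equal(cfg2$margin, 4)
  expect_equal(cfg2$nurse_correction, "simple")
  writeLines(c("band_width: 3", "bogus_key: 1"), path)
  expect_warning(read_config(path), "bogus_key")
})

test_that("quantify_batch runs a manifest of TIFFs with metadata carried through", {
  dir <- withr::local_tempdir()
  rows <- lapply(1:2, function(i) {
    oo <- make_oocyte(oocyte_spec(), seed = i)
    img_path <- file.path(dir, sprintf("oocyte%d.tif", i))
    anc_path <- file.path(dir, sprintf("oocyte%d_anchors.csv", i))
    write_image(oo$image, img_path)
    write_anchors(oo$truth$anchors, anc_path)
    data.frame(
      image = img_path, anchors = anc_path,
      genotype = c("wt", "mut")[i], stage = "9B",
      simple_mean = measure_mask_mean(oo$image, oo$truth$simple_mask),
      double_mean = measure_mask_mean(oo$image, oo$truth$double_mask)
    )
  })
  manifest <- do.call(rbind, rows)
  out <- quantify_batch(manifest)
  expect_equal(nrow(out), 2)
  expect_equal(out$genotype, c("wt", "mut"))
  expect_true(all(c("exclusion_ratio", "asymmetry_ratio",
                    "fraction_cytoplasm") %in% names(out)))
  expect_equal(out$fraction_apm + out$fraction_lpm + out$fraction_ppm +
                 out$fraction_cytoplasm, c(1, 1))
  # CSV manifests are accepted too
  man_path <- file.path(dir, "manifest.csv")
  write.csv(manifest, man_path, row.names = FALSE)
  out2 <- quantify_batch(man_path)
  expect_equal(out2$exclusion_ratio, out$exclusion_ratio)
})

test_that("images round-trip through 16-bit TIFF", {
  img <- matrix(sample(0:4000, 600, replace = TRUE), 20, 30)
  path <- withr::local_tempfile(fileext = ".tif")
  write_image(img, path)
  expect_equal(read_image(path), img + 0)
  stack <- array(sample(0:4000, 1200, replace = TRUE), c(10, 10, 12))
  write_image(stack, path)
  back <- read_image(path)
  expect_equal(dim(back), c(10, 10, 12))
  expect_equal(back, stack + 0)
})
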