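test_that("flattening removes per-row tilt and is idempotent", {
  # pure per-row linear tilt on a flat surface
  n <- 96
  set.seed(2)
  tilt <- rnorm(n, 0, 0.5)
  off <- rnorm(n, 0, 0.3)
  x <- (seq_len(n) - 0.5) / n - 0.5
  h <- outer(off, rep(1, n)) + outer(tilt, x)
  fl <- flatten_map(height_map(h, 4), order = 1)
  row_slopes <- apply(unclass(fl), 1, function(r) coef(lm(r ~ x))[2])
  expect_lt(max(abs(row_slopes)), 1e-6)

  # order 0 on an offset-free flat map is the identity up to a mean shift
  flat <- height_map(matrix(5, 96, 96), 4)
  f0 <- flatten_map(flat, order = 0, refine = FALSE)
  expect_lt(diff(range(unclass(f0))), 1e-12)

  # synthetic scene: post-flatten heights match the artifact-free truth
  g <- gen_height_map(small_two_phase_scene(n = 256), seed = 7)
  fl1 <- flatten_map(g$map, order = 1)
  err <- unclass(fl1) - unclass(g$truth$clean_map)
  err <- err - mean(err)
  expect_lt(sqrt(mean(err^2)), 0.05)

  # idempotence
  fl2 <- flatten_map(fl1, order = 1)
  expect_lt(sqrt(mean((unclass(fl2) - unclass(fl1))^2)), 1e-6)
})

test_that("a fully excluded scanline falls back to all pixels, warning", {
  h <- matrix(rnorm(96 * 96, 0, 0.1), 96, 96)
  excl <- matrix(FALSE, 96, 96)
  excl[10, ] <- TRUE
  expect_warning(flatten_map(height_map(h, 4), order = 1, exclude = excl,
                             refine = FALSE),
                 "fully excluded")
})

test_that("segmentation recovers the plateau structure", {
  g <- gen_height_map(small_two_phase_scene(), seed = 9)
  seg <- segment_heights(flatten_map(g$map))
  ch <- seg$class_heights
  expect_equal(unname(ch[c("substrate", "fluid", "solid")]), c(0, 4, 5),
               tolerance = 0.15)

  # constant map -> a single class
  seg1 <- segment_heights(height_map(matrix(4, 96, 96) +
                                       matrix(rnorm(96^2, 0, 0.01), 96), 4))
  expect_equal(length(seg1$class_heights), 1)

  # label map has the source shape and class count respects the request
  expect_equal(dim(seg$labels), dim(g$map))
  seg3 <- segment_heights(flatten_map(g$map), n_classes = 3,
                          detect_rough = FALSE, detect_bumps = FALSE)
  expect_lte(length(seg3$class_heights), 3)
})

test_that("rough LPS domains are recovered by local texture", {
  g <- gen_height_map(scene_preset("LPS-DMPC"), seed = 3)
  seg <- segment_heights(flatten_map(g$map, order = 1))
  expect_true("rough" %in% seg$classes)
  tr <- g$truth$labels == which(g$truth$classes == "rough")
  dr <- seg$labels == match("rough", seg$classes)
  jac <- sum(tr & dr) / sum(tr | dr)
  expect_gte(jac, 0.8)
})

test_that("coverage fractions normalise and use the chosen denominator", {
  g <- gen_height_map(small_two_phase_scene(), seed = 11)
  seg <- segment_heights(flatten_map(g$map), detect_rough = FALSE,
                         detect_bumps = FALSE)
  for (den in c("lipid", "total")) {
    cov <- coverage_fractions(seg, denominator = den)
    expect_equal(sum(cov$fraction), 1, tolerance = 1e-9)
  }
  cov <- coverage_fractions(seg)
  expect_false("substrate" %in% cov$class)
  expect_equal(cov$fraction[cov$class == "solid"], 0.65, tolerance = 0.03)
  expect_equal(cov$fraction[cov$class == "fluid"], 0.35, tolerance = 0.03)

  # all-fluid scene
  sc <- scene_spec("fluid", pixels_per_side = 96, image_size_um = 0.375,
                   phases = tibble::tibble(class = "fluid", height_nm = 4,
                                           coverage = 1, texture_sd = 0.05),
                   scanline = list(offset_sd = 0, tilt_sd = 0))
  gf <- gen_height_map(sc, seed = 12)
  segf <- segment_heights(gf$map, detect_rough = FALSE,
                          detect_bumps = FALSE)
  covf <- coverage_fractions(segf, denominator = "lipid")
  expect_equal(sum(covf$fraction[covf$class != "substrate"]), 1,
               tolerance = 1e-9)

  # substrate-only segmentation has no lipid denominator
  bare <- segment_heights(height_map(matrix(rnorm(96^2, 0, 0.02), 96), 4))
  expect_error(coverage_fractions(bare), "undefined")
})

test_that("rough coverage responds monotonically to the generated area", {
  fracs <- c(0.11, 0.30, 0.56)
  rec <- vapply(seq_along(fracs), function(i) {
    lipid_total <- 0.9
    sc <- scene_spec(
      "ramp", pixels_per_side = 256, image_size_um = 1,
      phases = tibble::tibble(
        class = c("solid", "rough"),
        height_nm = c(5, 5.5),
        coverage = lipid_total * c(1 - fracs[i], fracs[i]),
        texture_sd = c(0.08, 1.16)))
    g <- gen_height_map(sc, seed = 40 + i)
    seg <- segment_heights(flatten_map(g$map, order = 1))
    cov <- coverage_fractions(seg, denominator = "lipid")
    r <- cov$fraction[cov$class == "rough"]
    if (length(r) == 0) 0 else r
  }, numeric(1))
  expect_true(all(diff(rec) > 0))
})

test_that("R_q matches its closed forms and invariances", {
  flat <- height_map(matrix(3, 128, 128), 4)
  expect_equal(roughness_rq(flat), 0)

  set.seed(5)
  tex <- height_map(matrix(rnorm(512^2, 4, 0.77), 512), 3.9)
  expect_equal(roughness_rq(tex), 0.77, tolerance = 0.05)

  # sinusoid of amplitude A has R_q = A / sqrt(2)
  x <- (seq_len(512) - 0.5) * 3.9
  sine <- height_map(outer(rep(1, 512), 0.4 * sin(2 * pi * x / 15)), 3.9)
  expect_equal(roughness_rq(sine), 0.4 / sqrt(2), tolerance = 0.002)

  # translation invariance and linear height scaling
  expect_equal(roughness_rq(set_heights_test(tex, unclass(tex) + 10)),
               roughness_rq(tex))
  expect_equal(roughness_rq(set_heights_test(tex, unclass(tex) * 3)),
               3 * roughness_rq(tex), tolerance = 1e-9)

  expect_error(roughness_rq(flat, mask = matrix(FALSE, 128, 128)), "100")
})

test_that("profiles interpolate heights along a segment", {
  flat <- height_map(matrix(2.5, 128, 128), 4)
  pr <- extract_profile(flat, c(10, 100), c(480, 100))
  expect_true(all(abs(pr$height_nm - 2.5) < 1e-12))
  expect_equal(max(pr$distance_nm), 470)

  # a step edge appears in the profile at the step height
  h <- matrix(0, 128, 128)
  h[, 65:128] <- 5
  step <- height_map(h, 4)
  pr2 <- extract_profile(step, c(10, 256), c(500, 256))
  expect_equal(min(pr2$height_nm), 0)
  expect_equal(max(pr2$height_nm), 5)

  expect_error(extract_profile(flat, c(10, 10), c(10, 10)), "zero-length")
  expect_error(extract_profile(flat, c(-5, 10), c(100, 10)), "inside")
})

test_that("stripe periodicity is recovered to one frequency bin", {
  g <- gen_height_map(scene_preset("OM-DMPC-STRIPES"), seed = 9)
  fl <- flatten_map(g$map, order = 1)
  sp <- stripe_period(fl)
  # one FFT bin at the 15 nm peak of a 2 um frame
  bin <- 15^2 / 2000
  expect_equal(sp$dominant_wavelength_nm, 15, tolerance = bin)
  expect_equal(sp$dominant_amplitude_nm, 0.4, tolerance = 0.08)

  # rotation by 90 degrees leaves the wavelength unchanged
  rot <- height_map(t(unclass(fl))[ncol(fl):1, ], pixel_size(fl))
  expect_equal(stripe_period(rot)$dominant_wavelength_nm,
               sp$dominant_wavelength_nm, tolerance = 1e-6)

  # white noise shows no periodicity
  set.seed(77)
  wn <- height_map(matrix(rnorm(256^2, 0, 0.1), 256), 7.8)
  spn <- stripe_period(wn)
  expect_true(is.na(spn$dominant_wavelength_nm))
})

test_that("vesicle detection sizes caps by the shared convention", {
  empty <- height_map(matrix(rnorm(128^2, 0, 0.05), 128), 4)
  expect_equal(nrow(detect_vesicles(empty)), 0)

  sc <- scene_spec("one-cap", pixels_per_side = 128, image_size_um = 0.25,
                   phases = NULL, substrate_texture_sd = 0,
                   vesicles = list(count = 1, diameter_mean_nm = 40,
                                   diameter_sd_nm = 0, min_diameter_nm = 2,
                                   cap_ratio = 0.4),
                   scanline = list(offset_sd = 0, tilt_sd = 0))
  g <- gen_height_map(sc, seed = 15)
  det <- detect_vesicles(g$map)
  expect_equal(nrow(det), 1)
  expect_equal(det$diameter_nm, 40, tolerance = 2 * pixel_size(g$map))

  # a field drawn from the wide vesicle distribution recovers its mean
  gv <- gen_height_map(scene_preset("LPS-VESICLES"), seed = 16)
  dv <- detect_vesicles(flatten_map(gv$map, order = 1))
  expect_gte(nrow(dv), 150)
  expect_equal(mean(dv$diameter_nm), 29, tolerance = 0.15 * 29)
})
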