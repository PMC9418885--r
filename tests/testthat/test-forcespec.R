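test_that("preprocessing filters, keeps separation, and removes baseline", {
  cv <- make_ramp_curve(noise_sd = 0)
  # window 1 is the identity on forces
  expect_equal(preprocess_curve(cv, window = 1)$force_nN, cv$force_nN)
  expect_equal(preprocess_curve(cv, window = 5)$separation_nm,
               cv$separation_nm)

  # a single-sample spike is removed by a 5-sample median
  spiked <- cv
  spiked$force_nN[200] <- spiked$force_nN[200] + 1
  pf <- preprocess_curve(fd_curve(spiked$separation_nm, spiked$force_nN),
                         window = 5)
  clean <- preprocess_curve(cv, window = 5)
  expect_lt(max(abs(pf$force_nN - clean$force_nN)), 1e-9)

  # constant offset is subtracted: far-field mean returns to ~0
  off <- fd_curve(cv$separation_nm, cv$force_nN + 0.2)
  po <- preprocess_curve(off, window = 5)
  far <- po$separation_nm > 30
  expect_lt(abs(mean(po$force_nN[far])), 1e-9)

  expect_error(preprocess_curve(cv, window = 4), "odd")
})

test_that("contact point is located at the force onset", {
  cv <- preprocess_curve(make_ramp_curve(contact_nm = 20), window = 1)
  expect_equal(find_contact_point(cv), 20, tolerance = 0.05)

  set.seed(1)
  noise <- fd_curve(seq(40, 0, by = -0.02),
                    rnorm(2001, 0, 0.05), direction = "approach")
  expect_error(find_contact_point(preprocess_curve(noise)),
               class = "slbquant_no_contact")

  g <- gen_force_curve(force_preset("DMPC-20C"), seed = 11)
  cp <- find_contact_point(preprocess_curve(g$curve))
  expect_lt(abs(cp - g$truth$contact_point_nm), 2 * 0.02 + 1e-9)
})

test_that("noiseless detection equals generator truth exactly", {
  for (sc in c("DMPC-20C", "DMPC-30C", "LPS-DMPC", "OM-DMPC",
               "LPS-VESICLE")) {
    for (seed in 1:5) {
      g <- gen_force_curve(force_preset(sc), seed = seed, noise_sd = 0)
      ev <- detect_steps(preprocess_curve(g$curve, window = 1))
      expect_equal(nrow(ev), nrow(g$truth$events), info = sc)
      expect_equal(ev$rupture_force_nN, g$truth$events$rupture_force_nN,
                   tolerance = 1e-9, info = sc)
      expect_equal(ev$thickness_nm, g$truth$events$thickness_nm,
                   tolerance = 1e-9, info = sc)
      expect_equal(ev$yield_separation_nm,
                   g$truth$events$yield_separation_nm,
                   tolerance = 1e-9, info = sc)
    }
  }
})

test_that("flat curves yield no events and retract curves are rejected", {
  flat <- fd_curve(seq(40, 0.02, by = -0.02),
                   rep(0, 2000), direction = "approach")
  expect_equal(nrow(detect_steps(preprocess_curve(flat, window = 1))), 0)
  rt <- fd_curve(seq(0.02, 40, by = 0.02), rep(0, 2000),
                 direction = "retract")
  expect_error(detect_steps(rt), "approach")
  expect_error(detect_unfolding(flat), "retract")
})

test_that("the 0.1 nN / 0.1 nm gates drop sub-threshold events", {
  g <- make_step_curve(tibble::tibble(force = c(0.5, 0.05),
                                      thickness = c(4, 3)))
  ev <- detect_steps(preprocess_curve(g$curve, window = 1),
                     min_force = 0.1, min_thickness = 0.1)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$rupture_force_nN, 0.5, tolerance = 0.02)

  # ruptures thinner than the thickness gate are dropped too
  g2 <- make_step_curve(tibble::tibble(force = c(0.6, 0.8),
                                       thickness = c(0.3, 4)))
  ev2 <- detect_steps(preprocess_curve(g2$curve, window = 1),
                      min_thickness = 1)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$rupture_force_nN, 0.8, tolerance = 0.02)
})

test_that("raising min_force never increases the number of events", {
  for (seed in 1:8) {
    g <- gen_force_curve(force_preset("LPS-DMPC"), seed = seed)
    pp <- preprocess_curve(g$curve)
    counts <- vapply(c(0.1, 0.3, 0.6, 1.0, 1.8),
                     function(mf) nrow(detect_steps(pp, min_force = mf)),
                     integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("thickness is positive and events are ordered by separation", {
  for (seed in 1:10) {
    g <- gen_force_curve(force_preset("LPS-DMPC"), seed = seed)
    ev <- detect_steps(preprocess_curve(g$curve))
    expect_true(all(ev$thickness_nm > 0))
    expect_true(all(diff(ev$yield_separation_nm) < 0) || nrow(ev) < 2)
  }
})

test_that("classification labels alpha before beta and gates gamma", {
  gb <- gen_curve_batch(force_preset("LPS-DMPC"), 60, seed = 21)
  batch <- analyze_curves(gb$curves, setpoint_warn = FALSE)
  ev <- tidy(batch)
  per_curve <- split(ev, ev$curve_id)
  for (cv in per_curve) {
    # exactly one beta per curve and it is the final (smallest-separation)
    expect_equal(sum(cv$label == "beta") + sum(cv$label == "gamma"), 1)
    if (nrow(cv) > 1) {
      expect_true(all(cv$label[-nrow(cv)] == "alpha"))
      expect_equal(cv$label[nrow(cv)], "beta")
    }
  }

  # a single high-force rupture in an OM-DMPC batch is gamma
  go <- gen_curve_batch(force_preset("OM-DMPC"), 60, seed = 22)
  bo <- analyze_curves(go$curves, setpoint_warn = FALSE)
  evo <- tidy(bo)
  high <- evo[evo$rupture_force_nN > 2 &
                evo$curve_id %in% names(which(table(evo$curve_id) == 1)), ]
  expect_true(all(high$label == "gamma"))

  # no events -> warning, empty labelling
  flat <- fd_curve(seq(40, 0.02, by = -0.02), rep(0, 2000),
                   direction = "approach")
  expect_warning(b0 <- analyze_curves(list(flat), setpoint_warn = FALSE),
                 "classify")
  expect_equal(nrow(tidy(b0)), 0)
})

test_that("batch summaries report the standard batch statistics", {
  g1 <- make_step_curve(tibble::tibble(force = 2.0, thickness = 5))
  b <- analyze_curves(list(g1$curve), setpoint_warn = FALSE)
  s <- summarize_curves(b)
  expect_equal(s$mean_final_rupture_force_nN, 2.0, tolerance = 0.02)
  expect_equal(s$sd_final_rupture_force_nN, 0)
  expect_equal(s$mean_step_count, 1)

  gb <- gen_curve_batch(force_preset("LPS-DMPC"), 200, seed = 31)
  bb <- analyze_curves(gb$curves, setpoint_warn = FALSE)
  sb <- summarize_curves(bb)
  # beta sometimes occurs without alpha: the 5% absence rate plus the
  # detection loss of the low-force alpha tail
  expect_gt(sb$beta_without_alpha_frac, 0.01)
  expect_lt(sb$beta_without_alpha_frac, 0.2)
  ps <- population_stats(bb)
  expect_true(all(c("alpha", "beta") %in% ps$label))
  expect_lt(ps$mean_force_nN[ps$label == "alpha"],
            ps$mean_force_nN[ps$label == "beta"])
})

test_that("unfolding releases are found at truth positions", {
  p <- force_preset("OM-DMPC")
  r <- gen_retract_curve(p, seed = 13, unfolding = TRUE, n_sawteeth = 2)
  u <- detect_unfolding(r$curve)
  expect_equal(nrow(u), 2)
  expect_equal(u$release_separation_nm, r$truth$release_separation_nm,
               tolerance = 0.05)

  r0 <- gen_retract_curve(p, seed = 14, unfolding = FALSE)
  expect_equal(nrow(detect_unfolding(r0$curve)), 0)

  set.seed(99)
  noise <- fd_curve(seq(0.02, 40, by = 0.02), rnorm(2000, 0, 0.03),
                    direction = "retract")
  expect_equal(nrow(detect_unfolding(noise)), 0)
})
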