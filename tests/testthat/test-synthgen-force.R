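test_that("noise-free curves equal their piecewise analytic form", {
  # independent oracle: rebuild the expected force at every sample directly
  # from the truth record for a single-layer preset without prelude
  p <- force_preset("DMPC-20C")
  g <- gen_force_curve(p, seed = 42, noise_sd = 0)
  ev <- g$truth$events
  expect_equal(nrow(ev), 1) # single-step process at 20 C
  s <- g$curve$separation_nm
  k <- p$contact_stiffness
  expected <- numeric(length(s))
  on_ramp <- s >= ev$yield_separation_nm & s < ev$contact_separation_nm
  expected[on_ramp] <- k * (ev$contact_separation_nm - s[on_ramp])
  sub <- s <= 0
  expected[sub] <- 10 * (-s[sub]) # substrate stiffness
  expect_equal(g$curve$force_nN, expected, tolerance = 1e-12)
  # yield sample carries exactly the recorded rupture force
  i_y <- which(s == ev$yield_separation_nm)
  expect_equal(g$curve$force_nN[i_y], ev$rupture_force_nN)
})

test_that("same seed regenerates bit-identical data across all generators", {
  p <- force_preset("LPS-DMPC")
  a <- gen_force_curve(p, seed = 7)
  b <- gen_force_curve(p, seed = 7)
  expect_identical(a$curve$force_nN, b$curve$force_nN)
  expect_identical(a$truth$events, b$truth$events)
  expect_false(identical(a$curve$force_nN,
                         gen_force_curve(p, seed = 8)$curve$force_nN))

  ra <- gen_retract_curve(p, seed = 3, unfolding = TRUE)
  rb <- gen_retract_curve(p, seed = 3, unfolding = TRUE)
  expect_identical(ra$curve$force_nN, rb$curve$force_nN)

  sc <- small_two_phase_scene()
  ia <- gen_height_map(sc, seed = 5)
  ib <- gen_height_map(sc, seed = 5)
  expect_identical(unclass(ia$map), unclass(ib$map))
  expect_identical(ia$truth$labels, ib$truth$labels)

  inst <- instrument_spec()
  d <- size_distribution(40, 1)
  ca <- gen_correlogram(d, inst, noise_sd = 0.01, seed = 2)
  cb <- gen_correlogram(d, inst, noise_sd = 0.01, seed = 2)
  expect_identical(ca$g2, cb$g2)
})

test_that("absent layers produce a smooth monotone loading curve", {
  p <- scenario_preset("none",
                       list(layer_spec(1, 0.1, 5, 0.3, presence = 0)),
                       contact_stiffness = 0.5, noise_sd = 0)
  g <- gen_force_curve(p, seed = 1)
  expect_equal(nrow(g$truth$events), 0)
  # monotone non-decreasing in acquisition order, no discontinuous drop
  expect_true(all(diff(g$curve$force_nN) >= -1e-12))
})

test_that("vesicle-compression curves have three regimes and one rupture", {
  p <- force_preset("LPS-VESICLE")
  g <- gen_force_curve(p, seed = 9, noise_sd = 0)
  tr <- g$truth$events
  expect_equal(nrow(tr), 1)
  s <- g$curve$separation_nm
  f <- g$curve$force_nN
  # gentle rise beyond 12 nm, steep between 12 nm and yield
  soft <- s > 13 & s < 29
  stiff <- s > tr$yield_separation_nm + 0.3 & s < 11
  slope <- function(reg) {
    cf <- coef(lm(f[reg] ~ s[reg]))
    unname(-cf[2])
  }
  expect_equal(slope(soft), 0.1, tolerance = 1e-6)
  expect_equal(slope(stiff), 1.0, tolerance = 1e-6)
  expect_equal(tr$rupture_force_nN, 6, tolerance = 0.4) # ~6 nN rupture
  # rupture thickness spans down to the substrate
  expect_equal(tr$thickness_nm, tr$yield_separation_nm)
})

test_that("presets are validated", {
  expect_error(scenario_preset("bad", list(layer_spec(9, 0.5, 5, 0.3)),
                               contact_stiffness = 0.5, max_force = 10),
               "max_force")
  expect_error(scenario_preset("bad", list(layer_spec(1, 0.1, 5, 0.3,
                                                      presence = 1.4)),
                               contact_stiffness = 0.5),
               "presence")
  expect_error(scenario_preset("bad", list(layer_spec(1, 0.1, -2, 0.3)),
                               contact_stiffness = 0.5),
               "thickness")
})

test_that("retract curves carry an adhesion well and requested sawteeth", {
  p <- force_preset("OM-DMPC")
  r0 <- gen_retract_curve(p, seed = 4, unfolding = FALSE, noise_sd = 0)
  f <- r0$curve$force_nN
  expect_equal(nrow(r0$truth), 0)
  # single smooth adhesion minimum
  i_min <- which.min(f)
  expect_true(all(diff(f[seq_len(i_min)]) <= 1e-9))
  expect_true(all(diff(f[i_min:length(f)]) >= -1e-9))

  r2 <- gen_retract_curve(p, seed = 4, unfolding = TRUE, n_sawteeth = 2)
  expect_equal(nrow(r2$truth), 2)
  expect_true(all(diff(r2$truth$release_separation_nm) > 0))
})
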