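test_that("the forward model follows Siegert and Stokes-Einstein", {
  inst <- instrument_spec(temperature_K = 298)
  lg <- lag_grid(1e-7, 0.1, 80)
  d40 <- size_distribution(40, 1)
  cg <- g2_model(d40, inst, lg)

  # closed-form decay rate 2 q^2 D(40 nm) at the stated geometry
  q <- 4 * pi * inst$refractive_index * sin(pi / 4) / (457e-9)
  D <- 1.380649e-23 * 298 / (3 * pi * inst$viscosity_Pa_s * 40e-9)
  pred <- 1 + inst$coherence_beta * exp(-2 * q^2 * D * lg)
  expect_equal(cg$g2, pred, tolerance = 1e-12)

  # Siegert limit: g2 -> 1 + beta as tau -> 0
  tiny <- g2_model(d40, inst, c(1e-12, 1e-11, 1e-10))
  expect_equal(tiny$g2, rep(1 + inst$coherence_beta, 3), tolerance = 1e-6)

  # field correlation is linear in the mixture weights
  d30 <- size_distribution(30, 1)
  d120 <- size_distribution(120, 1)
  mix <- size_distribution(c(30, 120), c(0.5, 0.5))
  g1_of <- function(cg) sqrt((cg$g2 - 1) / inst$coherence_beta)
  expect_equal(g1_of(g2_model(mix, inst, lg)),
               0.5 * g1_of(g2_model(d30, inst, lg)) +
                 0.5 * g1_of(g2_model(d120, inst, lg)),
               tolerance = 1e-9)

  # noiseless g2 is monotone non-increasing and generated g2 stays above
  # 1 - 3 noise_sd
  expect_true(all(diff(cg$g2) <= 1e-12))
  for (seed in 1:5) {
    noisy <- gen_correlogram(d40, inst, lg, noise_sd = 0.01, seed = seed)
    expect_true(all(noisy$g2 >= 1 - 3 * 0.01))
  }
})

test_that("generator and inversion share one forward model", {
  inst <- instrument_spec()
  d <- size_distribution(c(25, 80), c(0.3, 0.7))
  lg <- lag_grid(1e-7, 0.5, 60)
  a <- g2_model(d, inst, lg)
  b <- gen_correlogram(d, inst, lg, noise_sd = 0, seed = 1)
  expect_identical(a$g2, b$g2)
})

test_that("inputs are validated", {
  inst <- instrument_spec()
  expect_error(size_distribution(c(-5, 10), c(0.5, 0.5)), "positive")
  expect_error(size_distribution(c(10, 10), c(0.5, 0.5)), "increasing")
  expect_error(g2_model(size_distribution(40, 1), inst, c(2e-3, 1e-3)),
               "increasing")
  expect_error(instrument_spec(angle_deg = 200), "angle")
  expect_error(instrument_spec(coherence_beta = 0), "beta")
  expect_error(water_properties(500), "273")
})

test_that("MEM round trip recovers a monodisperse mode within a grid cell", {
  inst <- instrument_spec(temperature_K = 298)
  grid <- diameter_grid()
  cell <- log(grid[2] / grid[1])

  # noiseless forward data on the inversion grid
  w <- as.numeric(abs(grid - 40) == min(abs(grid - 40)))
  dg <- size_distribution(grid, w)
  corr0 <- g2_model(dg, inst, lag_grid())
  fit0 <- invert_mem(corr0, inst, grid = grid)
  expect_lte(fit0$chi2, fit0$chi2_target + 1e-6)
  mode0 <- peak_stats(fit0$distribution)$diameter_nm[1]
  expect_lte(abs(log(mode0 / 40)), 1.5 * cell)

  # 1% noise
  corr <- gen_correlogram(size_distribution(40, 1), inst, lag_grid(),
                          noise_sd = 0.01, seed = 11)
  fit <- invert_mem(corr, inst, grid = grid)
  mode <- peak_stats(fit$distribution)$diameter_nm[1]
  expect_lte(abs(log(mode / 40)), 1.5 * cell)
  expect_true(all(fit$distribution$weight >= 0))
  expect_equal(sum(fit$distribution$weight), 1, tolerance = 1e-9)
})

test_that("a decay-free correlogram pushes mass to the largest diameters", {
  inst <- instrument_spec()
  flat <- correlogram(lag_grid(), rep(1 + inst$coherence_beta, 240),
                      noise_sd = 0.01)
  fit <- invert_mem(flat, inst)
  expect_true(fit$at_upper_edge)
  expect_equal(peak_stats(fit$distribution)$diameter_nm[1],
               max(fit$distribution$diameter_nm))
})

test_that("well-separated bimodal distributions are resolved at low noise", {
  inst <- instrument_spec(temperature_K = 298)
  grid <- diameter_grid()
  cell <- log(grid[2] / grid[1])
  db <- size_distribution(c(30, 300), c(0.5, 0.5))
  corr <- gen_correlogram(db, inst, lag_grid(), noise_sd = 0.001, seed = 12)
  fit <- invert_mem(corr, inst, grid = grid)
  pk <- peak_stats(fit$distribution)
  expect_gte(nrow(pk), 2)
  pd <- sort(pk$diameter_nm[1:2])
  expect_lte(abs(log(pd[1] / 30)), 1.5 * cell)
  expect_lte(abs(log(pd[2] / 300)), 1.5 * cell)
})

test_that("components closer than the resolution limit merge between them", {
  # at 1% noise a 4x diameter ratio sits below the Laplace-inversion
  # resolution limit: the maximum-entropy solution is a single mode lying
  # between the two true components
  inst <- instrument_spec(temperature_K = 298)
  db <- size_distribution(c(30, 120), c(0.5, 0.5))
  corr <- gen_correlogram(db, inst, lag_grid(), noise_sd = 0.01, seed = 12)
  fit <- invert_mem(corr, inst)
  pk <- peak_stats(fit$distribution)
  expect_gte(pk$diameter_nm[1], 30)
  expect_lte(pk$diameter_nm[1], 120)
})

test_that("relaxing the chi-square target never decreases entropy", {
  inst <- instrument_spec(temperature_K = 298)
  corr <- gen_correlogram(size_distribution(40, 1), inst, lag_grid(),
                          noise_sd = 0.01, seed = 21)
  ents <- vapply(c(1, 2, 4), function(tg) {
    invert_mem(corr, inst, chi2_target = tg)$entropy
  }, numeric(1))
  expect_true(all(diff(ents) >= -1e-6))
})

test_that("peak statistics report modes with their basin mass", {
  grid <- diameter_grid(10, 100, 20)
  delta <- size_distribution(grid, as.numeric(seq_along(grid) == 10))
  pk <- peak_stats(delta)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$mass_fraction, 1)

  unif <- size_distribution(grid, rep(1, 20))
  expect_equal(nrow(peak_stats(unif)), 0)

  w <- dnorm(log(grid), log(20), 0.2) + 0.6 * dnorm(log(grid), log(70), 0.2)
  bimo <- size_distribution(grid, w / sum(w))
  pk2 <- peak_stats(bimo)
  expect_equal(nrow(pk2), 2)
  expect_equal(sum(pk2$mass_fraction), 1, tolerance = 1e-9)
})

test_that("optional number weighting divides intensity weights by d^6", {
  inst <- instrument_spec()
  corr <- gen_correlogram(size_distribution(40, 1), inst, lag_grid(),
                          noise_sd = 0.01, seed = 31)
  fit <- invert_mem(corr, inst, number_weighted = TRUE)
  wi <- fit$distribution$weight
  wn <- fit$number_distribution$weight
  conv <- wi / fit$distribution$diameter_nm^6
  expect_equal(wn, conv / sum(conv), tolerance = 1e-12)
})
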