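# shared fixtures built in code at test time

# a plain linear loading ramp: zero force above `contact_nm`, slope k below
make_ramp_curve <- function(contact_nm = 20, k = 0.5, s_max = 40,
                            ds = 0.02, noise_sd = 0) {
  s <- seq(s_max, -2, by = -ds)
  f <- ifelse(s < contact_nm, k * (contact_nm - s), 0)
  if (noise_sd > 0) f <- f + rnorm(length(f), 0, noise_sd)
  fd_curve(s, f, direction = "approach")
}

# a flat curve with hand-placed one-sample drops (for gate tests)
make_step_curve <- function(drops, ds = 0.02, k = 0.5) {
  # drops: tibble(force, thickness); builds a synthetic multi-layer ramp
  layers <- lapply(seq_len(nrow(drops)), function(i) {
    layer_spec(drops$force[i], 0, drops$thickness[i], 0)
  })
  preset <- scenario_preset("custom", layers, contact_stiffness = k,
                            noise_sd = 0)
  gen_force_curve(preset, seed = 1, noise_sd = 0)
}

small_two_phase_scene <- function(n = 128, texture_sd = 0.05) {
  scene_spec("two-phase", pixels_per_side = n, image_size_um = 0.5,
             phases = tibble::tibble(class = c("fluid", "solid"),
                                     height_nm = c(4, 5),
                                     coverage = 0.85 * c(0.35, 0.65),
                                     texture_sd = texture_sd),
             scanline = list(offset_sd = 0.3, tilt_sd = 0.5))
}

set_heights_test <- function(map, h) height_map(h, pixel_size(map))

expect_tbl_equal <- function(a, b, tolerance = 1e-12) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tolerance)
}
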