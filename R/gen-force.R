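#' Simulate an AFM approach force-distance curve with known rupture truth
#'
#' Emulates breakthrough force spectroscopy on a layered membrane: zero
#' force (plus noise) during free travel, piecewise-linear elastic loading
#' after contact, and for every membrane layer present an instantaneous
#' rupture - the force drops to the baseline and the tip advances by the
#' layer's rupture thickness before force rises again on the next layer
#' (or the substrate). The approach terminates when the force setpoint is
#' reached on the substrate.
#'
#' Separations follow the approach convention: tip-sample separation in nm,
#' decreasing in acquisition order, with the hard substrate contact at 0 nm
#' (slightly negative values represent substrate indentation). Rupture
#' events are realised on the sampling grid: the drawn rupture force is
#' rounded to the nearest loading-ramp sample and the drawn thickness to a
#' whole number of samples, and the truth record stores these realised
#' values, so a noise-free curve equals its piecewise analytic form at
#' every sample and exact event recovery is well defined.
#'
#' @param preset a [scenario_preset()] (see [force_preset()]).
#' @param seed integer seed; curves are bit-identical for identical seeds.
#' @param noise_sd force noise sd in nN; defaults to the preset's value.
#' @param ds separation sampling step, nm.
#' @param free_travel free-travel distance before first contact, nm.
#' @param substrate_stiffness loading stiffness on the bare substrate, nN/nm.
#' @return a list with elements `curve` (an [fd_curve()]) and `truth`
#'   (list: `events` tibble with `layer`, `rupture_force_nN`,
#'   `thickness_nm`, `yield_separation_nm`, `contact_separation_nm`;
#'   `contact_point_nm`; `preset`; `seed`; `ds`).
#' @export
gen_force_curve <- function(preset, seed, noise_sd = NULL, ds = 0.02,
                            free_travel = 15, substrate_stiffness = 10) {
  stopifnot(inherits(preset, "scenario_preset"))
  noise_sd <- noise_sd %||% preset$noise_sd
  set.seed(sub_seed(seed))

  if (!is.null(preset$vesicle)) {
    return(gen_vesicle_curve(preset, seed, noise_sd, ds, free_travel,
                             substrate_stiffness))
  }

  n_lay <- length(preset$layers)
  present <- if (n_lay > 0) {
    as.logical(rbinom(n_lay, 1, vapply(preset$layers, `[[`, 0, "presence")))
  } else logical(0)

  # build the breakpoint chain from the substrate upwards, on the integer grid
  i_contact_below <- 0L # substrate contact at separation 0
  segs <- list()        # per present layer: integer breakpoints + slopes
  idx <- which(present)
  for (j in rev(idx)) {
    ly <- preset$layers[[j]]
    k <- ly$stiffness %||% preset$contact_stiffness
    f_draw <- rnorm_trunc(1, ly$mean_rupture_force, ly$sd_rupture_force,
                          lower = 0.05)
    t_draw <- rnorm_trunc(1, ly$mean_thickness, ly$sd_thickness, lower = 0.2)
    i_thick <- max(1L, as.integer(round(t_draw / ds)))
    if (is.null(ly$prelude)) {
      i_soft <- 0L; k_soft <- k
      i_stiff <- max(1L, as.integer(round(f_draw / (k * ds))))
      f_soft <- 0
    } else {
      k_soft <- k * ly$prelude$stiffness_ratio
      i_soft <- max(1L, as.integer(round(ly$prelude$force_nN / (k_soft * ds))))
      f_soft <- k_soft * i_soft * ds
      i_stiff <- max(1L, as.integer(round((f_draw - f_soft) / (k * ds))))
    }
    f_real <- f_soft + k * i_stiff * ds
    i_yield <- i_contact_below + i_thick
    i_contact <- i_yield + i_stiff + i_soft
    segs[[length(segs) + 1L]] <- list(
      layer = j, i_yield = i_yield, i_contact = i_contact,
      i_soft = i_soft, k = k, k_soft = k_soft,
      f_real = f_real, i_thick = i_thick)
    i_contact_below <- i_contact
  }
  segs <- rev(segs) # encounter order (outermost first)

  i_top <- i_contact_below + as.integer(round(free_travel / ds))
  i_sub_end <- -as.integer(ceiling(preset$max_force /
                                     (substrate_stiffness * ds)))
  ii <- seq.int(i_top, i_sub_end, by = -1L)
  force <- numeric(length(ii))

  # substrate ramp
  sub_reg <- ii <= 0L
  force[sub_reg] <- substrate_stiffness * (-ii[sub_reg]) * ds
  # layer loading ramps (half-open: yield sample on the ramp, contact at 0)
  for (sg in segs) {
    stiff_reg <- ii >= sg$i_yield & ii < (sg$i_contact - sg$i_soft)
    force[stiff_reg] <- sg$f_real -
      sg$k * (ii[stiff_reg] - sg$i_yield) * ds
    if (sg$i_soft > 0L) {
      soft_reg <- ii >= (sg$i_contact - sg$i_soft) & ii < sg$i_contact
      force[soft_reg] <- sg$k_soft * (sg$i_contact - ii[soft_reg]) * ds
    }
  }

  # terminate at the setpoint
  cut <- which(force >= preset$max_force)[1]
  if (!is.na(cut)) {
    ii <- ii[seq_len(cut)]
    force <- force[seq_len(cut)]
  }
  if (noise_sd > 0) force <- force + rnorm(length(force), 0, noise_sd)

  events <- if (length(segs) > 0) {
    tibble(
      layer = map_int(segs, "layer"),
      rupture_force_nN = map_dbl(segs, "f_real"),
      thickness_nm = map_dbl(segs, ~ .x$i_thick * ds),
      yield_separation_nm = map_dbl(segs, ~ .x$i_yield * ds),
      contact_separation_nm = map_dbl(segs, ~ .x$i_contact * ds)
    )
  } else {
    tibble(layer = integer(), rupture_force_nN = double(),
           thickness_nm = double(), yield_separation_nm = double(),
           contact_separation_nm = double())
  }

  curve <- fd_curve(ii * ds, force, direction = "approach",
                    metadata = list(sample = preset$name,
                                    temperature_C = preset$temperature_C,
                                    setpoint_nN = preset$max_force))
  list(curve = curve,
       truth = list(events = events,
                    contact_point_nm = i_contact_below * ds,
                    preset = preset$name, seed = seed, ds = ds))
}

# three-regime vesicle compression: soft loading from `contact_nm`, stiff
# loading from `stiff_from_nm`, single rupture near the drawn force, then
# bare substrate
gen_vesicle_curve <- function(preset, seed, noise_sd, ds, free_travel,
                              substrate_stiffness) {
  v <- preset$vesicle
  k_soft <- v$soft_stiffness
  k_stiff <- k_soft * v$stiffness_ratio
  i_contact <- as.integer(round(v$contact_nm / ds))
  i_knee <- as.integer(round(v$stiff_from_nm / ds))
  f_knee <- k_soft * (i_contact - i_knee) * ds

  f_draw <- rnorm_trunc(1, v$rupture_force$mean, v$rupture_force$sd,
                        lower = f_knee + 0.5)
  i_yield <- i_knee - as.integer(round((f_draw - f_knee) / (k_stiff * ds)))
  i_yield <- max(i_yield, 1L)
  f_real <- f_knee + k_stiff * (i_knee - i_yield) * ds

  i_top <- i_contact + as.integer(round(free_travel / ds))
  i_sub_end <- -as.integer(ceiling(preset$max_force /
                                     (substrate_stiffness * ds)))
  ii <- seq.int(i_top, i_sub_end, by = -1L)
  force <- numeric(length(ii))
  soft_reg <- ii >= i_knee & ii < i_contact
  force[soft_reg] <- k_soft * (i_contact - ii[soft_reg]) * ds
  stiff_reg <- ii >= i_yield & ii < i_knee
  force[stiff_reg] <- f_knee + k_stiff * (i_knee - ii[stiff_reg]) * ds
  sub_reg <- ii <= 0L
  force[sub_reg] <- substrate_stiffness * (-ii[sub_reg]) * ds

  cut <- which(force >= preset$max_force)[1]
  if (!is.na(cut)) {
    ii <- ii[seq_len(cut)]
    force <- force[seq_len(cut)]
  }
  if (noise_sd > 0) force <- force + rnorm(length(force), 0, noise_sd)

  events <- tibble(
    layer = 1L, rupture_force_nN = f_real,
    thickness_nm = i_yield * ds, yield_separation_nm = i_yield * ds,
    contact_separation_nm = i_contact * ds)
  curve <- fd_curve(ii * ds, force, direction = "approach",
                    metadata = list(sample = preset$name,
                                    temperature_C = preset$temperature_C,
                                    setpoint_nN = preset$max_force))
  list(curve = curve,
       truth = list(events = events, contact_point_nm = i_contact * ds,
                    preset = preset$name, seed = seed, ds = ds))
}

#' Simulate an AFM retract curve with optional protein-unfolding sawteeth
#'
#' Retraction from the surface shows a smooth adhesion well near contact.
#' With `unfolding = TRUE`, sawtooth events - a gradual attractive force
#' ramp followed by an abrupt release to the baseline - are superimposed at
#' random separations, as seen when membrane proteins unfold under the
#' retracting tip.
#'
#' @inheritParams gen_force_curve
#' @param unfolding add unfolding sawteeth?
#' @param n_sawteeth number of sawteeth when `unfolding = TRUE`.
#' @param s_max retraction range, nm.
#' @return list with `curve` (retract [fd_curve()]) and `truth`
#'   (tibble of release positions/forces).
#' @export
gen_retract_curve <- function(preset, seed, unfolding = FALSE,
                              n_sawteeth = 2, noise_sd = NULL, ds = 0.02,
                              s_max = 60) {
  stopifnot(inherits(preset, "scenario_preset"))
  noise_sd <- noise_sd %||% preset$noise_sd
  set.seed(sub_seed(seed, 7L))

  ii <- seq.int(0L, as.integer(round(s_max / ds)))
  s <- ii * ds
  a_depth <- runif(1, 0.3, 0.8)
  s0 <- 2
  force <- -a_depth * (s / s0) * exp(1 - s / s0) # smooth adhesion well

  truth <- tibble(release_separation_nm = double(),
                  release_force_nN = double())
  if (unfolding && n_sawteeth > 0) {
    rel <- sort(runif(n_sawteeth, 12, s_max - 10))
    rel <- round(rel / ds) * ds
    rise <- 6 # nm of gradual force build-up before each release
    f_u <- runif(n_sawteeth, 0.25, 0.6)
    for (e in seq_len(n_sawteeth)) {
      reg <- s > (rel[e] - rise) & s <= rel[e]
      force[reg] <- force[reg] - f_u[e] * (s[reg] - (rel[e] - rise)) / rise
    }
    truth <- tibble(release_separation_nm = rel, release_force_nN = f_u)
  }
  if (noise_sd > 0) force <- force + rnorm(length(force), 0, noise_sd)
  curve <- fd_curve(s, force, direction = "retract",
                    metadata = list(sample = preset$name,
                                    temperature_C = preset$temperature_C))
  list(curve = curve, truth = truth)
}

#' Simulate a batch of approach curves from one scenario preset
#'
#' @inheritParams gen_force_curve
#' @param n number of curves.
#' @param ... passed on to [gen_force_curve()].
#' @return a list with `curves` (list of [fd_curve()]s) and `truth`
#'   (list of per-curve truth records).
#' @export
gen_curve_batch <- function(preset, n, seed, ...) {
  runs <- map(seq_len(n), function(i) {
    gen_force_curve(preset, seed = sub_seed(seed, i), ...)
  })
  list(curves = map(runs, "curve"), truth = map(runs, "truth"))
}
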