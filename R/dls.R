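#' DLS instrument specification
#'
#' Optical and sample parameters of the dynamic light scattering setup:
#' laser wavelength 457 nm and scattering angle 90 degrees by default (the
#' goniometer geometry used for vesicle sizing), temperature, solvent
#' viscosity and refractive index, and the coherence factor beta of the
#' Siegert relation. When `viscosity_Pa_s` or `refractive_index` are
#' omitted they are taken from the water property table at the given
#' temperature (see [water_properties()]).
#'
#' @param wavelength_nm laser vacuum wavelength, nm.
#' @param angle_deg scattering angle, degrees in (0, 180).
#' @param temperature_K sample temperature, K.
#' @param viscosity_Pa_s solvent dynamic viscosity, Pa s.
#' @param refractive_index solvent refractive index.
#' @param coherence_beta Siegert coherence factor in (0, 1].
#' @return a list of class `instrument_spec`.
#' @export
instrument_spec <- function(wavelength_nm = 457, angle_deg = 90,
                            temperature_K = 298.15,
                            viscosity_Pa_s = NULL, refractive_index = NULL,
                            coherence_beta = 0.8) {
  wp <- water_properties(temperature_K)
  viscosity_Pa_s <- viscosity_Pa_s %||% wp$viscosity_Pa_s
  refractive_index <- refractive_index %||% wp$refractive_index
  stopifnot_scalar_num(wavelength_nm, "wavelength_nm", positive = TRUE)
  stopifnot_scalar_num(temperature_K, "temperature_K", positive = TRUE)
  stopifnot_scalar_num(viscosity_Pa_s, "viscosity_Pa_s", positive = TRUE)
  if (angle_deg <= 0 || angle_deg >= 180) abort("angle must be in (0, 180)")
  if (coherence_beta <= 0 || coherence_beta > 1) {
    abort("coherence_beta must be in (0, 1]")
  }
  structure(list(wavelength_nm = wavelength_nm, angle_deg = angle_deg,
                 temperature_K = temperature_K,
                 viscosity_Pa_s = viscosity_Pa_s,
                 refractive_index = refractive_index,
                 coherence_beta = coherence_beta),
            class = "instrument_spec")
}

#' Water viscosity and refractive index at a given temperature
#'
#' Tabulated solvent constants: dynamic viscosity from the Vogel equation
#' for liquid water and the refractive index of water in the blue-green
#' range (457 nm), linearly adjusted for temperature.
#'
#' @param temperature_K temperature, K (valid 273-373 K).
#' @return list with `viscosity_Pa_s` and `refractive_index`.
#' @export
water_properties <- function(temperature_K) {
  if (temperature_K < 273 || temperature_K > 373) {
    abort("water property table covers 273-373 K")
  }
  # Vogel equation for water, mPa s
  visc <- exp(-3.7188 + 578.919 / (temperature_K - 137.546)) * 1e-3
  # n of water at 457 nm, ~1.3397 at 293 K, dn/dT ~ -1e-4 / K
  n <- 1.3397 - 1e-4 * (temperature_K - 293.15)
  list(viscosity_Pa_s = visc, refractive_index = n)
}

#' Particle size distributions on a diameter grid
#'
#' Intensity-weighted particle-diameter distribution: strictly increasing
#' diameters (nm, conventionally log-spaced) with non-negative weights
#' summing to 1.
#'
#' @param diameter_nm strictly increasing diameters, nm.
#' @param weight non-negative weights; normalised to sum 1.
#' @return a tibble of class `size_distribution`.
#' @export
size_distribution <- function(diameter_nm, weight) {
  if (any(diameter_nm <= 0)) abort("diameters must be positive")
  if (any(diff(diameter_nm) <= 0)) {
    abort("diameters must be strictly increasing")
  }
  if (any(weight < 0)) abort("weights must be non-negative")
  s <- sum(weight)
  if (s <= 0) abort("weights must not be all zero")
  out <- tibble(diameter_nm = as.double(diameter_nm),
                weight = as.double(weight) / s)
  structure(out, class = c("size_distribution", class(out)))
}

#' Default log-spaced diameter grid
#' @param from,to grid range, nm.
#' @param n number of points.
#' @return numeric vector of diameters.
#' @export
diameter_grid <- function(from = 1, to = 1000, n = 60) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Scattering vector magnitude of an instrument
#' @param inst an [instrument_spec()].
#' @return q in 1/m.
#' @export
scattering_q <- function(inst) {
  4 * pi * inst$refractive_index *
    sin(inst$angle_deg * pi / 360) / (inst$wavelength_nm * 1e-9)
}

#' Stokes-Einstein diffusion coefficient
#' @param diameter_nm sphere diameter, nm.
#' @param inst an [instrument_spec()].
#' @return D in m^2/s.
#' @export
stokes_einstein_D <- function(diameter_nm, inst) {
  .kB * inst$temperature_K /
    (3 * pi * inst$viscosity_Pa_s * diameter_nm * 1e-9)
}

#' Forward-model a DLS intensity autocorrelation function
#'
#' Computes g2(tau) for spherical particles via the Siegert relation,
#' `g2 = 1 + beta |g1|^2`, with the field correlation
#' `g1(tau) = sum_i w_i exp(-q^2 D_i tau)`, `q` from the instrument
#' geometry and `D_i` from Stokes-Einstein. This single forward model is
#' shared by the synthetic-correlogram generator and the inversion.
#'
#' @param dist a [size_distribution()].
#' @param inst an [instrument_spec()].
#' @param lags positive, strictly increasing lag times, s.
#' @return a tibble of class `correlogram` (`lag_s`, `g2`) with attributes
#'   `noise_sd` (0) and `beta`.
#' @export
g2_model <- function(dist, inst, lags = lag_grid()) {
  stopifnot(inherits(dist, "size_distribution"),
            inherits(inst, "instrument_spec"))
  if (any(lags <= 0) || any(diff(lags) <= 0)) {
    abort("lags must be positive and strictly increasing")
  }
  q <- scattering_q(inst)
  gamma <- q^2 * stokes_einstein_D(dist$diameter_nm, inst) # decay rates, 1/s
  g1 <- as.vector(exp(-outer(lags, gamma)) %*% dist$weight)
  correlogram(lags, 1 + inst$coherence_beta * g1^2, noise_sd = 0,
              beta = inst$coherence_beta)
}

#' Default logarithmic lag-time grid
#'
#' 240 log-spaced channels over 1e-7 to 1 s, the channel layout of a
#' multi-tau hardware correlator.
#'
#' @param from,to lag range, s.
#' @param n number of lags.
#' @return numeric vector of lag times.
#' @export
lag_grid <- function(from = 1e-7, to = 1, n = 240) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Correlogram objects
#' @param lag_s positive increasing lag times, s.
#' @param g2 intensity autocorrelation values.
#' @param noise_sd known or estimated additive noise sd.
#' @param beta coherence factor used/assumed.
#' @return tibble of class `correlogram`.
#' @export
correlogram <- function(lag_s, g2, noise_sd = NA_real_, beta = NA_real_) {
  if (any(lag_s <= 0) || any(diff(lag_s) <= 0)) {
    abort("lags must be positive and strictly increasing")
  }
  if (!all(is.finite(g2))) abort("g2 must be finite")
  out <- tibble(lag_s = as.double(lag_s), g2 = as.double(g2))
  structure(out, noise_sd = noise_sd, beta = beta,
            class = c("correlogram", class(out)))
}

#' Generate a noisy synthetic correlogram from a known size distribution
#'
#' Evaluates the shared forward model ([g2_model()]) and adds Gaussian
#' noise of standard deviation `noise_sd` to g2.
#'
#' @inheritParams g2_model
#' @param noise_sd additive Gaussian noise sd on g2.
#' @param seed integer seed.
#' @return a `correlogram` with the truth distribution stored in attribute
#'   `truth`.
#' @export
gen_correlogram <- function(dist, inst, lags = lag_grid(), noise_sd = 0.01,
                            seed = 1) {
  clean <- g2_model(dist, inst, lags)
  set.seed(sub_seed(seed, 211L))
  g2 <- clean$g2 + if (noise_sd > 0) rnorm(length(lags), 0, noise_sd) else 0
  out <- correlogram(lags, g2, noise_sd = noise_sd,
                     beta = inst$coherence_beta)
  attr(out, "truth") <- dist
  out
}
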