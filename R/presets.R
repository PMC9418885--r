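#' Force-spectroscopy scenario presets
#'
#' A scenario preset bundles the parameters of one membrane system as
#' probed by AFM breakthrough force spectroscopy: the stack of rupturable
#' layers (each with a rupture-force and rupture-thickness distribution and
#' a presence probability), the elastic contact stiffness, the force
#' setpoint and the measurement noise level.
#'
#' Built-in presets encode the measured membrane systems:
#' \describe{
#'   \item{`DMPC-20C`}{gel/solid-dominated DMPC bilayer at 20 C; single
#'     rupture at 1.3 +/- 0.3 nN, thickness ~5 nm.}
#'   \item{`DMPC-30C`}{fluid DMPC bilayer at 30 C; single rupture at
#'     0.34 +/- 0.08 nN, thickness ~4 nm.}
#'   \item{`LPS-DMPC`}{LPS-doped DMPC: a low-force oligosaccharide-layer
#'     rupture (population alpha, 0.5 +/- 0.2 nN, present in 95% of
#'     curves) followed by the bilayer rupture (population beta,
#'     1.4 +/- 0.5 nN). The alpha force scale is a model default; the
#'     reported data localise it only qualitatively below the beta cluster.}
#'   \item{`OM-DMPC`}{outer-membrane extract in DMPC: thicker (~6 nm)
#'     bilayer, single high-force rupture at 2.03 +/- 0.41 nN preceded by
#'     an elastic-compression prelude.}
#'   \item{`LPS-VESICLE`}{compression of an adsorbed LPS vesicle: soft
#'     loading from 30 nm (vesicle collapse), stiff loading from 12 nm
#'     (double bilayer), rupture near 6 nN.}
#' }
#'
#' @param name one of the built-in preset names (see Details).
#' @return a list of class `scenario_preset`.
#' @export
force_preset <- function(name = c("DMPC-20C", "DMPC-30C", "LPS-DMPC",
                                  "OM-DMPC", "LPS-VESICLE")) {
  name <- match.arg(name)
  p <- switch(
    name,
    "DMPC-20C" = list(
      layers = list(layer_spec(1.3, 0.3, 5.0, 0.4)),
      contact_stiffness = 0.5, noise_sd = 0.05, temperature_C = 20
    ),
    "DMPC-30C" = list(
      layers = list(layer_spec(0.34, 0.08, 4.0, 0.3)),
      contact_stiffness = 0.25, noise_sd = 0.02, temperature_C = 30
    ),
    "LPS-DMPC" = list(
      layers = list(
        layer_spec(0.5, 0.2, 3.0, 0.5, presence = 0.95), # alpha (model default)
        layer_spec(1.4, 0.5, 5.0, 0.4)                   # beta
      ),
      contact_stiffness = 0.5, noise_sd = 0.05, temperature_C = 20
    ),
    "OM-DMPC" = list(
      layers = list(
        layer_spec(2.03, 0.41, 6.0, 0.5,
                   prelude = list(force_nN = 0.3, stiffness_ratio = 0.1))
      ),
      contact_stiffness = 0.6, noise_sd = 0.05, temperature_C = 20
    ),
    "LPS-VESICLE" = list(
      vesicle = list(
        contact_nm = 30, stiff_from_nm = 12,
        soft_stiffness = 0.1, stiffness_ratio = 10, # stiff = soft * ratio
        rupture_force = list(mean = 6, sd = 0.5)
      ),
      layers = list(),
      contact_stiffness = 1.0, noise_sd = 0.05, temperature_C = 20
    )
  )
  scenario_preset(name = name, layers = p$layers,
                  contact_stiffness = p$contact_stiffness,
                  noise_sd = p$noise_sd,
                  temperature_C = p$temperature_C,
                  vesicle = p$vesicle)
}

#' @param mean_rupture_force,sd_rupture_force rupture-force distribution, nN.
#' @param mean_thickness,sd_thickness rupture-thickness distribution, nm
#'   (yield point to the subsequent force increase).
#' @param presence probability that the layer is encountered by a given
#'   curve (Bernoulli per curve).
#' @param stiffness optional per-layer loading stiffness, nN/nm; defaults to
#'   the preset contact stiffness.
#' @param prelude optional soft elastic-compression prelude:
#'   `list(force_nN, stiffness_ratio)` - loading starts at
#'   `stiffness * stiffness_ratio` until `force_nN` is reached.
#' @rdname force_preset
#' @export
layer_spec <- function(mean_rupture_force, sd_rupture_force,
                       mean_thickness, sd_thickness,
                       presence = 1, stiffness = NULL, prelude = NULL) {
  list(mean_rupture_force = mean_rupture_force,
       sd_rupture_force = sd_rupture_force,
       mean_thickness = mean_thickness,
       sd_thickness = sd_thickness,
       presence = presence, stiffness = stiffness, prelude = prelude)
}

#' @param layers list of [layer_spec()]s, outermost (first-contacted) first.
#' @param contact_stiffness elastic loading stiffness, nN/nm.
#' @param max_force force setpoint terminating the approach, nN.
#' @param noise_sd force noise standard deviation, nN.
#' @param temperature_C acquisition temperature, C.
#' @param vesicle optional three-regime vesicle-compression parameters
#'   (see `LPS-VESICLE` in Details).
#' @rdname force_preset
#' @export
scenario_preset <- function(name, layers, contact_stiffness,
                            max_force = 10, noise_sd = 0.05,
                            temperature_C = 20, vesicle = NULL) {
  stopifnot_scalar_num(contact_stiffness, "contact_stiffness", positive = TRUE)
  stopifnot_scalar_num(max_force, "max_force", positive = TRUE)
  stopifnot_scalar_num(noise_sd, "noise_sd")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  for (ly in layers) {
    if (ly$presence < 0 || ly$presence > 1) {
      abort("layer presence probability must lie in [0, 1]")
    }
    if (ly$sd_rupture_force < 0 || ly$sd_thickness < 0) {
      abort("layer standard deviations must be >= 0")
    }
    if (ly$mean_thickness <= 0) abort("layer mean thickness must be > 0")
    if (max_force <= ly$mean_rupture_force + 4 * ly$sd_rupture_force) {
      abort(paste0(
        "max_force must exceed every layer's mean rupture force + 4 sd ",
        "so curves reach the setpoint"))
    }
  }
  if (!is.null(vesicle)) {
    if (max_force <= vesicle$rupture_force$mean + 4 * vesicle$rupture_force$sd)
      abort("max_force must exceed the vesicle rupture force + 4 sd")
  }
  structure(list(name = name, layers = layers,
                 contact_stiffness = contact_stiffness,
                 max_force = max_force, noise_sd = noise_sd,
                 temperature_C = temperature_C, vesicle = vesicle),
            class = "scenario_preset")
}

#' @export
print.scenario_preset <- function(x, ...) {
  cat(sprintf("<scenario_preset> %s: %d layer(s), k = %g nN/nm, setpoint %g nN, noise %g nN\n",
              x$name, length(x$layers), x$contact_stiffness, x$max_force,
              x$noise_sd))
  invisible(x)
}

#' Names of the built-in force-spectroscopy presets
#' @return character vector of preset names.
#' @export
list_force_presets <- function() {
  c("DMPC-20C", "DMPC-30C", "LPS-DMPC", "OM-DMPC", "LPS-VESICLE")
}
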