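#' Force-distance curve objects
#'
#' A force-distance (FD) curve is one approach or retract trace of an AFM
#' force-spectroscopy measurement: tip-sample separation (nm) against
#' cantilever force (nN). Curves are stored as tibbles with columns
#' `separation_nm` and `force_nN`, a `direction` attribute
#' (`"approach"` or `"retract"`) and an acquisition metadata list
#' (velocity, temperature, sample label, force setpoint).
#'
#' During an approach the separation decreases sample by sample (the rows
#' are in acquisition order); during a retract it increases.
#'
#' @param separation_nm numeric vector, tip-sample separation in nm.
#' @param force_nN numeric vector, force in nN, same length.
#' @param direction `"approach"` or `"retract"`.
#' @param metadata named list of acquisition metadata; defaults cover the
#'   standard acquisition (velocity 0.5 um/s, setpoint 10 nN).
#' @return a tibble of class `fd_curve`.
#' @export
fd_curve <- function(separation_nm, force_nN,
                     direction = c("approach", "retract"),
                     metadata = list()) {
  direction <- match.arg(direction)
  if (length(separation_nm) != length(force_nN)) {
    abort("separation and force must have equal length")
  }
  if (length(separation_nm) < 16) abort("a curve needs at least 16 samples")
  if (!all(is.finite(separation_nm)) || !all(is.finite(force_nN))) {
    abort("curves must contain finite values only")
  }
  d <- diff(separation_nm)
  if (direction == "approach" && any(d >= 0)) {
    abort("approach separation must be strictly decreasing")
  }
  if (direction == "retract" && any(d <= 0)) {
    abort("retract separation must be strictly increasing")
  }
  meta <- modifyList(
    list(velocity_um_s = 0.5, temperature_C = 20, sample = NA_character_,
         setpoint_nN = 10),
    metadata
  )
  out <- tibble(separation_nm = as.double(separation_nm),
                force_nN = as.double(force_nN))
  structure(out,
            direction = direction, metadata = meta,
            class = c("fd_curve", class(out)))
}

#' @export
print.fd_curve <- function(x, ...) {
  meta <- attr(x, "metadata")
  cat(sprintf("<fd_curve> %s, %d samples, sample = %s\n",
              curve_direction(x), nrow(x),
              meta$sample %||% NA_character_))
  NextMethod()
}

#' Direction of a force-distance curve
#' @param curve an [fd_curve()].
#' @return `"approach"` or `"retract"`.
#' @export
curve_direction <- function(curve) {
  attr(curve, "direction") %||% "approach"
}

#' @rdname curve_direction
#' @export
curve_metadata <- function(curve) attr(curve, "metadata") %||% list()

# rebuild attributes after dplyr operations strip the subclass
as_fd_curve <- function(df, template) {
  fd_curve(df$separation_nm, df$force_nN,
           direction = curve_direction(template),
           metadata = curve_metadata(template))
}
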