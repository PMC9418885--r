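#' Median-filter a force curve and remove its force baseline
#'
#' Running-median filtering of the force channel (separation untouched)
#' followed by baseline subtraction: the mean force over the far-separation
#' region (the first `baseline_frac` of samples in acquisition order, i.e.
#' the free-travel part of an approach) is removed so the non-contact force
#' is centred on zero.
#'
#' @param curve an [fd_curve()].
#' @param window odd median window length in samples; `1` leaves forces
#'   untouched.
#' @param baseline_frac fraction of the far-separation samples used for the
#'   baseline estimate.
#' @return the filtered, baseline-subtracted [fd_curve()] with attribute
#'   `noise_sd` (robust far-field noise estimate, nN) and
#'   `preprocessed = TRUE`.
#' @export
preprocess_curve <- function(curve, window = 5, baseline_frac = 0.15) {
  stopifnot(inherits(curve, "fd_curve"))
  if (window < 1 || !is_odd(window) || window >= nrow(curve)) {
    abort("`window` must be odd, >= 1 and smaller than the curve length")
  }
  f <- curve$force_nN
  if (window > 1) f <- as.numeric(runmed(f, window, endrule = "keep"))

  n_far <- max(8L, as.integer(baseline_frac * length(f)))
  far <- if (curve_direction(curve) == "approach") {
    seq_len(n_far)                       # largest separations come first
  } else {
    seq.int(length(f) - n_far + 1L, length(f))
  }
  base <- mean(f[far])
  f <- f - base
  # robust noise estimate from the raw far-field first differences
  raw_far <- curve$force_nN[far]
  noise <- mad(diff(raw_far)) / sqrt(2)

  out <- fd_curve(curve$separation_nm, f,
                  direction = curve_direction(curve),
                  metadata = curve_metadata(curve))
  attr(out, "noise_sd") <- noise
  # residual noise of the filtered signal (what step detection sees):
  # amplitude scale and one-sample difference scale
  attr(out, "noise_sd_filtered") <- mad(f[far])
  attr(out, "diff_noise") <- sd(diff(f[far]))
  attr(out, "window") <- window
  attr(out, "preprocessed") <- TRUE
  out
}

#' Locate the contact point of an approach curve
#'
#' The contact point is the largest separation at which the force exceeds
#' `threshold_sd` times the far-field noise and stays above that level
#' towards contact (a short persistence run guards against isolated noise
#' excursions).
#'
#' @param curve a preprocessed approach [fd_curve()].
#' @param threshold_sd noise-sd multiplier for the force threshold.
#' @param persistence number of consecutive above-threshold samples required.
#' @return contact separation in nm.
#' @export
find_contact_point <- function(curve, threshold_sd = 4, persistence = 5) {
  stopifnot(inherits(curve, "fd_curve"))
  if (curve_direction(curve) != "approach") abort("approach curve required")
  f <- curve$force_nN
  noise <- attr(curve, "noise_sd") %||% (mad(diff(f)) / sqrt(2))
  thr <- max(threshold_sd * noise, 1e-12)
  above <- f > thr
  n <- length(f)
  persistence <- min(persistence, n)
  # first sample (in acquisition order) from which `persistence` consecutive
  # samples are all above threshold
  cs <- cumsum(as.integer(above))
  i_last <- n - persistence + 1L
  ok <- (cs[seq_len(i_last) + persistence - 1L] -
           c(0L, cs)[seq_len(i_last)]) == persistence
  if (!any(ok)) {
    abort("no contact found: force never exceeds the threshold",
          class = "slbquant_no_contact")
  }
  i0 <- which(ok)[1]
  s <- curve$separation_nm
  # refine with a local changepoint fit: in a window around the threshold
  # crossing, model the force as zero above the contact point and linear
  # below it, and pick the changepoint minimising the residual sum of
  # squares. For a candidate at sample c the optimal-slope SSE is
  # sum(f^2) - A_c^2 / B_c with A_c = sum_{i>=c} f_i (s_c - s_i) and
  # B_c = sum_{i>=c} (s_c - s_i)^2, so the best c maximises A^2/B.
  lo <- max(1L, i0 - 150L)
  hi <- min(n, i0 + 150L)
  # truncate at the force maximum so a rupture drop inside the window
  # cannot corrupt the loading-line part of the fit
  hi <- lo + which.max(f[lo:hi]) - 1L
  fw <- f[lo:hi]
  W <- length(fw)
  if (W >= 16) {
    ii <- seq_len(W)
    sf0 <- rev(cumsum(rev(fw)))        # suffix sums of f
    sf1 <- rev(cumsum(rev(fw * ii)))   # suffix sums of f * i
    si1 <- rev(cumsum(rev(ii)))
    si2 <- rev(cumsum(rev(ii^2)))
    si0 <- rev(cumsum(rev(rep(1, W))))
    A <- sf1 - ii * sf0
    B <- si2 - 2 * ii * si1 + ii^2 * si0
    stat <- ifelse(A > 0 & B > 0, A^2 / B, -Inf)
    c_best <- which.max(stat)
    if (is.finite(stat[c_best])) return(s[lo + c_best - 1L])
  }
  s[i0]
}

#' Detect membrane-rupture steps in an approach force curve
#'
#' Scans the filtered force in acquisition order for maximal contiguous
#' force drops during loading. A drop opens an event when the one-sample
#' force decrease exceeds a trigger (hysteresis: the event must close -
#' force recovery - before a new one can open). Each event records the
#' rupture force (filtered force at the last sample before the drop, the
#' point of yield), the force drop, and the rupture thickness: the
#' separation distance from the yield point to the subsequent force
#' increase. Events with rupture force below `min_force` or thickness below
#' `min_thickness` are discarded, mirroring the standard analysis gates
#' (0.1 nN and 0.1 nm).
#'
#' The force at yield is estimated by fitting the loading line to the
#' filtered samples immediately before the yield point and evaluating it
#' at the yield sample. A running median clips the tip of a loading
#' sawtooth (the half-window samples before the drop are pulled down
#' towards earlier ramp values), so reading the filtered value directly
#' would bias the rupture force low by half a window of loading; the local
#' line fit restores an unbiased estimate while retaining the filter's
#' robustness to spikes.
#'
#' @param curve a preprocessed approach [fd_curve()] (see
#'   [preprocess_curve()]).
#' @param min_force minimum rupture force, nN.
#' @param min_thickness minimum rupture thickness, nm.
#' @param gate_on `"yield"` gates on the force at yield (default);
#'   `"drop"` gates on the drop magnitude instead.
#' @param trigger_drop one-sample force decrease opening a candidate event;
#'   default `max(min_force / 2, 5 * filtered-noise sd)`.
#' @return tibble of rupture events: `index_in_curve`,
#'   `yield_separation_nm`, `rupture_force_nN`, `force_drop_nN`,
#'   `thickness_nm`, ordered by decreasing separation.
#' @export
detect_steps <- function(curve, min_force = 0.1, min_thickness = 0.1,
                         gate_on = c("yield", "drop"), trigger_drop = NULL) {
  stopifnot(inherits(curve, "fd_curve"))
  gate_on <- match.arg(gate_on)
  if (curve_direction(curve) != "approach") {
    abort("detect_steps() requires an approach curve; see detect_unfolding()")
  }
  if (!isTRUE(attr(curve, "preprocessed"))) {
    curve <- preprocess_curve(curve, window = 5)
  }
  f <- curve$force_nN
  s <- curve$separation_nm
  n <- length(f)
  noise_f <- attr(curve, "noise_sd_filtered") %||%
    attr(curve, "noise_sd") %||% 0
  diff_noise <- attr(curve, "diff_noise") %||% noise_f
  window <- attr(curve, "window") %||% 5
  trig <- trigger_drop %||% max(min_force / 2, 7 * diff_noise)
  rise_thr <- max(4 * noise_f, 1e-9)

  df <- diff(f) # f[i+1] - f[i]; a rupture is a strongly negative step
  drop_idx <- which(df < -trig)
  empty <- tibble(index_in_curve = integer(), yield_separation_nm = double(),
                  rupture_force_nN = double(), force_drop_nN = double(),
                  thickness_nm = double())
  if (length(drop_idx) == 0) return(empty)

  # merge contiguous trigger samples into one drop run (hysteresis)
  runs <- split(drop_idx, cumsum(c(1L, diff(drop_idx) > 2L)))
  events <- list()
  last_close <- 0L
  for (r in runs) {
    i_yield <- r[1]             # last sample before the drop
    i_end <- max(r) + 1L        # first post-drop sample
    if (i_yield <= last_close) next # still inside the previous event
    f_yield <- yield_force_fit(f, i_yield, window, last_close, rise_thr)
    f_floor <- min(f[r[1]:i_end])
    # recontact: last sample at/below the rise threshold (relative to the
    # post-drop floor) before force rises again and stays up
    j <- i_end
    floor_ref <- max(f_floor, 0)
    while (j < n && f[j] <= floor_ref + rise_thr) j <- j + 1L
    i_recontact <- j - 1L
    if (j >= n && f[n] <= floor_ref + rise_thr) i_recontact <- n
    thick <- s[i_yield] - s[i_recontact]
    drop <- f_yield - f_floor
    gate_val <- if (gate_on == "yield") f_yield else drop
    if (gate_val > min_force && thick > min_thickness) {
      events[[length(events) + 1L]] <- tibble(
        index_in_curve = i_yield,
        yield_separation_nm = s[i_yield],
        rupture_force_nN = f_yield,
        force_drop_nN = drop,
        thickness_nm = thick)
    }
    last_close <- i_recontact
  }
  if (length(events) == 0) return(empty)
  out <- bind_rows(events)
  arrange(out, desc(.data$yield_separation_nm))
}

# force at yield from a local loading-line fit: fit the filtered force over
# the samples of the current loading ramp (excluding the half median window
# clipped by the filter) and evaluate the line at the yield sample
yield_force_fit <- function(f, i_yield, window, last_close, rise_thr,
                            lookback = 30L) {
  clip <- window %/% 2L
  lo <- last_close + 1L
  # start of the current loading ramp: last sample at/below the baseline
  below <- which(f[lo:i_yield] <= rise_thr)
  start <- if (length(below) > 0) lo + max(below) else lo
  idx <- seq.int(start, max(start, i_yield - clip))
  if (length(idx) > lookback) idx <- idx[seq.int(length(idx) - lookback + 1L,
                                                 length(idx))]
  if (length(idx) < 4L) return(f[i_yield])
  cf <- stats::lm.fit(cbind(1, idx), f[idx])$coefficients
  if (anyNA(cf)) return(f[i_yield])
  unname(cf[1] + cf[2] * i_yield)
}

#' Detect protein-unfolding releases in a retract curve
#'
#' Finds sawtooth releases - a gradual attractive force build-up followed
#' by an abrupt force jump back to the baseline - in a retraction trace.
#' The smooth adhesion well itself produces no one-sample jump and is not
#' reported. No polymer-elasticity model is fitted.
#'
#' @param curve a retract [fd_curve()].
#' @param min_force minimum release force magnitude, nN.
#' @param window median filter window.
#' @return tibble of releases: `release_separation_nm`, `release_force_nN`.
#' @export
detect_unfolding <- function(curve, min_force = 0.1, window = 5) {
  stopifnot(inherits(curve, "fd_curve"))
  if (curve_direction(curve) != "retract") {
    abort("detect_unfolding() requires a retract curve")
  }
  if (!isTRUE(attr(curve, "preprocessed"))) {
    curve <- preprocess_curve(curve, window = window)
  }
  f <- curve$force_nN
  s <- curve$separation_nm
  diff_noise <- attr(curve, "diff_noise") %||%
    attr(curve, "noise_sd") %||% 0
  trig <- max(min_force / 2, 7 * diff_noise)
  df <- diff(f) # abrupt release: strongly positive jump
  jump_idx <- which(df > trig)
  if (length(jump_idx) == 0) {
    return(tibble(release_separation_nm = double(),
                  release_force_nN = double()))
  }
  runs <- split(jump_idx, cumsum(c(1L, diff(jump_idx) > 2L)))
  out <- map(runs, function(r) {
    i <- r[1]
    f_rel <- -f[i] # release force magnitude (force is attractive, negative)
    if (f_rel <= min_force) return(NULL)
    tibble(release_separation_nm = s[i], release_force_nN = f_rel)
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(release_separation_nm = double(),
                  release_force_nN = double()))
  }
  arrange(out, .data$release_separation_nm)
}
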