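#' Analyse a batch of force curves: detect, measure and classify ruptures
#'
#' Runs the full per-curve pipeline - median filtering and baseline removal,
#' contact-point estimation, rupture-step detection at the force/thickness
#' gates - over a list of approach curves, then classifies the detected
#' events into the rupture populations alpha (initial low-force steps),
#' beta (bilayer rupture, the final step of a multi-step curve) and gamma
#' (single high-force combined ruptures).
#'
#' @param curves list of approach [fd_curve()]s (e.g. from
#'   [gen_curve_batch()]), or a single curve.
#' @param min_force,min_thickness detection gates (nN, nm); events below
#'   either are discarded.
#' @param window median-filter window (odd, samples).
#' @param classify label events into populations? See [classify_events()].
#' @param gamma_gate optional fixed force gate (nN) separating single-step
#'   beta from gamma events; default fits it from the data.
#' @param setpoint_warn warn about curves that never reach their setpoint.
#' @return an object of class `fs_batch`: list with `events` (one row per
#'   rupture event, with `curve_id` and, after classification, `label`),
#'   `curves` (one row per curve: `curve_id`, `step_count`,
#'   `contact_point_nm`, `final_rupture_force_nN`), `params`, `gamma_gate`.
#' @export
analyze_curves <- function(curves, min_force = 0.1, min_thickness = 0.1,
                           window = 5, classify = TRUE, gamma_gate = NULL,
                           setpoint_warn = TRUE) {
  if (inherits(curves, "fd_curve")) curves <- list(curves)
  res <- imap(curves, function(cv, i) {
    pp <- preprocess_curve(cv, window = window)
    cp <- tryCatch(find_contact_point(pp), slbquant_no_contact = function(e) NA_real_)
    ev <- detect_steps(pp, min_force = min_force,
                       min_thickness = min_thickness)
    setp <- curve_metadata(cv)$setpoint_nN %||% NA_real_
    reached <- if (is.na(setp)) TRUE else max(pp$force_nN) >= 0.95 * setp
    list(events = ev, contact = cp, reached = reached)
  })
  short <- sum(!purrr::map_lgl(res, "reached"))
  if (setpoint_warn && short > 0) {
    warn(sprintf("%d curve(s) never reached the force setpoint; analysed as-is",
                 short))
  }
  events <- imap(res, function(r, i) {
    if (nrow(r$events) == 0) return(NULL)
    mutate(r$events, curve_id = i, .before = 1)
  })
  events <- bind_rows(events)
  if (nrow(events) == 0) {
    events <- tibble(curve_id = integer(), index_in_curve = integer(),
                     yield_separation_nm = double(),
                     rupture_force_nN = double(), force_drop_nN = double(),
                     thickness_nm = double())
  }
  curves_tbl <- tibble(
    curve_id = seq_along(curves),
    contact_point_nm = map_dbl(res, "contact"),
    step_count = map_int(res, ~ nrow(.x$events)),
    final_rupture_force_nN = map_dbl(res, function(r) {
      if (nrow(r$events) == 0) NA_real_ else {
        r$events$rupture_force_nN[nrow(r$events)]
      }
    })
  )
  batch <- structure(
    list(events = events, curves = curves_tbl,
         params = list(min_force = min_force, min_thickness = min_thickness,
                       window = window),
         gamma_gate = gamma_gate),
    class = "fs_batch")
  if (classify) batch <- classify_events(batch, gamma_gate = gamma_gate)
  batch
}

#' Classify rupture events into populations alpha, beta and gamma
#'
#' Within a multi-step curve every event but the last is labelled `alpha`
#' (initial ruptures, e.g. the hydrated LPS oligosaccharide layer) and the
#' final event `beta` (bilayer rupture). A single-step curve is labelled
#' `beta` when its rupture force lies below the gamma force gate and
#' `gamma` (single high-force combined rupture, characteristic of
#' OM-protein-reinforced bilayers) otherwise.
#'
#' The gate is fitted as the midpoint between the two force modes of the
#' single-step events (one-dimensional two-component Gaussian mixture via
#' \pkg{mclust}). When the batch has fewer than `min_single` single-step
#' events, or the mixture does not support two separated modes (BIC prefers
#' one component or the modes are closer than 0.5 nN), a fixed fallback
#' gate is used instead.
#'
#' @param batch an `fs_batch` from [analyze_curves()].
#' @param gamma_gate optional fixed gate, nN; skips the mixture fit.
#' @param fallback_gate fixed gate used when no reliable mixture fit is
#'   possible, nN.
#' @param min_single minimum number of single-step events for a mixture fit.
#' @return the batch with an added `label` column on `events` and the gate
#'   stored in `gamma_gate`.
#' @export
classify_events <- function(batch, gamma_gate = NULL, fallback_gate = 1.7,
                            min_single = 20) {
  stopifnot(inherits(batch, "fs_batch"))
  ev <- batch$events
  if (nrow(ev) == 0) {
    warn("no rupture events to classify")
    batch$events$label <- character(0)
    return(batch)
  }
  steps_per_curve <- table(ev$curve_id)
  single_ids <- as.integer(names(steps_per_curve)[steps_per_curve == 1])
  single_forces <- ev$rupture_force_nN[ev$curve_id %in% single_ids]

  gate <- gamma_gate
  if (is.null(gate)) {
    gate <- fallback_gate
    if (length(single_forces) >= min_single) {
      fit <- Mclust(single_forces, G = 1:2, modelNames = "V",
                    verbose = FALSE)
      if (!is.null(fit) && fit$G == 2) {
        mu <- sort(fit$parameters$mean)
        if (diff(mu) > 0.5) gate <- mean(mu)
      }
    }
  }

  ev <- ev |>
    group_by(.data$curve_id) |>
    mutate(label = dplyr::case_when(
      n() > 1 & row_number() < n() ~ "alpha",
      n() > 1 ~ "beta",
      .data$rupture_force_nN < gate ~ "beta",
      TRUE ~ "gamma")) |>
    ungroup()
  batch$events <- ev
  batch$gamma_gate <- gate
  batch
}

#' Summary statistics of an analysed force-curve batch
#'
#' Per-batch statistics in the form these experiments are reported in: mean and sd of the
#' final rupture force, mean number of rupture steps per curve, population
#' counts, and the fraction of curves whose bilayer rupture (beta) occurs
#' without a preceding alpha event.
#'
#' @param batch an `fs_batch` from [analyze_curves()].
#' @return one-row tibble: `n_curves`, `n_events`,
#'   `mean_final_rupture_force_nN`, `sd_final_rupture_force_nN`,
#'   `mean_step_count`, `n_alpha`, `n_beta`, `n_gamma`,
#'   `beta_without_alpha_frac`.
#' @export
summarize_curves <- function(batch) {
  stopifnot(inherits(batch, "fs_batch"))
  cv <- batch$curves
  ev <- batch$events
  if (nrow(cv) < 1) abort("at least one curve is required")
  has_lab <- "label" %in% names(ev) && nrow(ev) > 0
  with_events <- cv$step_count > 0
  bwa <- if (has_lab) {
    per <- ev |> group_by(.data$curve_id) |>
      summarise(has_beta = any(.data$label == "beta"),
                has_alpha = any(.data$label == "alpha"))
    if (sum(per$has_beta) > 0) {
      sum(per$has_beta & !per$has_alpha) / sum(per$has_beta)
    } else NA_real_
  } else NA_real_
  final <- cv$final_rupture_force_nN[with_events]
  tibble(
    n_curves = nrow(cv),
    n_events = nrow(ev),
    mean_final_rupture_force_nN = mean(final),
    sd_final_rupture_force_nN = if (length(final) > 1) sd(final) else 0,
    mean_step_count = mean(cv$step_count),
    n_alpha = if (has_lab) sum(ev$label == "alpha") else NA_integer_,
    n_beta = if (has_lab) sum(ev$label == "beta") else NA_integer_,
    n_gamma = if (has_lab) sum(ev$label == "gamma") else NA_integer_,
    beta_without_alpha_frac = bwa
  )
}

#' Per-population centroids of the rupture force-thickness map
#'
#' @param batch a classified `fs_batch`.
#' @return tibble with one row per population: `label`, `n`,
#'   `mean_force_nN`, `mean_thickness_nm`.
#' @export
population_stats <- function(batch) {
  stopifnot(inherits(batch, "fs_batch"))
  ev <- batch$events
  if (!"label" %in% names(ev) || nrow(ev) == 0) {
    return(tibble(label = character(), n = integer(),
                  mean_force_nN = double(), mean_thickness_nm = double()))
  }
  ev |> group_by(.data$label) |>
    summarise(n = n(),
              mean_force_nN = mean(.data$rupture_force_nN),
              mean_thickness_nm = mean(.data$thickness_nm)) |>
    ungroup()
}

#' @export
print.fs_batch <- function(x, ...) {
  cat(sprintf("<fs_batch> %d curves, %d rupture events (gate %.3g nN)\n",
              nrow(x$curves), nrow(x$events),
              x$gamma_gate %||% NA_real_))
  print(summarize_curves(x))
  invisible(x)
}
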