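#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an analysed force-curve batch
#'
#' One row per rupture event: curve id, yield separation, rupture force,
#' force drop, thickness and (when classified) the population label -
#' the tabular force-thickness map ready for export or plotting.
#'
#' @param x an `fs_batch` from [analyze_curves()].
#' @param ... ignored.
#' @return a tibble.
#' @export
tidy.fs_batch <- function(x, ...) as_tibble(x$events)

#' @rdname tidy.fs_batch
#' @export
glance.fs_batch <- function(x, ...) summarize_curves(x)

#' Tidy a MEM inversion
#'
#' @param x a `mem_fit` from [invert_mem()].
#' @param ... ignored.
#' @return `tidy()`: the recovered size distribution as a tibble;
#'   `glance()`: one row with `chi2`, `chi2_target`, `entropy`, `alpha`,
#'   `converged` and edge flags.
#' @export
tidy.mem_fit <- function(x, ...) as_tibble(x$distribution)

#' @rdname tidy.mem_fit
#' @export
glance.mem_fit <- function(x, ...) {
  tibble(chi2 = x$chi2, chi2_target = x$chi2_target, entropy = x$entropy,
         alpha = x$alpha, converged = x$converged,
         at_upper_edge = x$at_upper_edge, at_lower_edge = x$at_lower_edge)
}

#' Tidy a segmentation label map
#'
#' @param x a `seg_labels` from [segment_heights()].
#' @param ... ignored.
#' @return one row per pixel: `row`, `col`, `class`.
#' @export
tidy.seg_labels <- function(x, ...) {
  tibble(row = as.vector(row(x$labels)), col = as.vector(col(x$labels)),
         class = x$classes[as.vector(x$labels)])
}

#' @rdname tidy.seg_labels
#' @export
glance.seg_labels <- function(x, ...) {
  cnt <- tabulate(x$labels, nbins = length(x$classes))
  tibble(n_classes = length(x$classes),
         n_level_classes = length(x$class_heights),
         substrate_frac = if ("substrate" %in% x$classes) {
           cnt[match("substrate", x$classes)] / sum(cnt)
         } else 0)
}

#' Tidy a pipeline run report
#'
#' @param x a `run_report` from [run_pipeline()].
#' @param ... ignored.
#' @return `tidy()`: the per-scenario comparison table; `glance()`: one
#'   row with run-level counts and the config hash.
#' @export
tidy.run_report <- function(x, ...) x$batches

#' @rdname tidy.run_report
#' @export
glance.run_report <- function(x, ...) {
  tibble(n_scenarios = nrow(x$batches),
         n_events = nrow(x$events),
         all_force_ok = all(x$batches$force_ok),
         all_steps_ok = all(x$batches$steps_ok),
         config_hash = x$config_hash)
}
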