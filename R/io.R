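#' Read and write force-curve TSV files
#'
#' Curves travel as tab-separated text with columns `segment`
#' (`approach`/`retract`), `separation_nm` and `force_nN`; a batch file
#' adds a leading `curve_id` column. A generic two-column dialect
#' (separation, force - any header, tab/comma/space separated) is also
#' accepted by the reader and interpreted as a single approach curve.
#'
#' @param curves a single [fd_curve()] or list of curves.
#' @param path file path.
#' @return `write_curves_tsv()` returns `path` invisibly;
#'   `read_curves_tsv()` returns a list of [fd_curve()]s.
#' @export
write_curves_tsv <- function(curves, path) {
  if (inherits(curves, "fd_curve")) curves <- list(curves)
  tb <- imap(curves, function(cv, i) {
    tibble(curve_id = i, segment = curve_direction(cv),
           separation_nm = cv$separation_nm, force_nN = cv$force_nN)
  }) |> bind_rows()
  readr::write_tsv(tb, path)
  invisible(path)
}

#' @rdname write_curves_tsv
#' @export
read_curves_tsv <- function(path) {
  tb <- readr::read_delim(path, show_col_types = FALSE, trim_ws = TRUE)
  if (all(c("segment", "separation_nm", "force_nN") %in% names(tb))) {
    if (!"curve_id" %in% names(tb)) tb$curve_id <- 1L
    split(tb, tb$curve_id) |>
      map(function(d) {
        fd_curve(d$separation_nm, d$force_nN,
                 direction = as.character(d$segment[1]))
      }) |> unname()
  } else if (ncol(tb) >= 2) {
    # generic two-column dialect: separation then force
    s <- tb[[1]]
    dirn <- if (s[2] < s[1]) "approach" else "retract"
    list(fd_curve(s, tb[[2]], direction = dirn))
  } else {
    abort("unrecognised curve file layout")
  }
}

#' Read and write height maps as plain-text matrices with JSON sidecars
#'
#' The portable text format stores the height matrix (nm) as whitespace-
#' separated rows; a JSON sidecar (`<path>.json`) carries the pixel size
#' and metadata. A 32-bit float TIFF writer/reader is available through
#' the optional \pkg{tiff} package.
#'
#' @param map a [height_map()].
#' @param path file path (text matrix).
#' @return `write_height_map_txt()` returns `path` invisibly;
#'   `read_height_map_txt()` returns a [height_map()].
#' @export
write_height_map_txt <- function(map, path) {
  stopifnot(inherits(map, "height_map"))
  h <- unclass(map)
  attributes(h) <- list(dim = dim(h))
  utils::write.table(h, path, row.names = FALSE, col.names = FALSE)
  side <- list(pixel_size_nm = pixel_size(map),
               metadata = attr(map, "metadata") %||% list())
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_height_map_txt
#' @export
read_height_map_txt <- function(path) {
  h <- as.matrix(utils::read.table(path))
  dimnames(h) <- NULL
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    height_map(h, side$pixel_size_nm, as.list(side$metadata))
  } else {
    height_map(h, 1)
  }
}

#' @rdname write_height_map_txt
#' @export
write_height_map_tiff <- function(map, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the `tiff` package is required for TIFF output")
  }
  tiff::writeTIFF(unclass(map) / 1, path, bits.per.sample = 32L,
                  reduce = TRUE)
  side <- list(pixel_size_nm = pixel_size(map),
               metadata = attr(map, "metadata") %||% list())
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read and write correlograms as two-column TSV
#' @param corr a [correlogram()].
#' @param path file path.
#' @return the path (write) or a `correlogram` (read).
#' @export
write_correlogram_tsv <- function(corr, path) {
  readr::write_tsv(tibble(lag_s = corr$lag_s, g2 = corr$g2), path)
  invisible(path)
}

#' @rdname write_correlogram_tsv
#' @export
read_correlogram_tsv <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  correlogram(tb[[1]], tb[[2]])
}

#' Write a size distribution as CSV
#' @param dist a [size_distribution()].
#' @param path file path.
#' @export
write_distribution_csv <- function(dist, path) {
  readr::write_csv(tibble(diameter_nm = dist$diameter_nm,
                          weight = dist$weight), path)
  invisible(path)
}

#' Write truth records or reports as JSON
#' @param x a list or tibble.
#' @param path file path.
#' @export
write_truth_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
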