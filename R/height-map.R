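#' Calibrated AFM height maps
#'
#' A height map is a 2D raster of topographical heights in nm, row-major
#' with the origin at the top-left pixel, plus the lateral pixel size in nm
#' and acquisition metadata. Pixel centres sit at `(col - 0.5) * pixel_size`
#' (x) and `(row - 0.5) * pixel_size` (y, increasing downwards).
#'
#' @param heights numeric matrix of heights, nm (at least 64 x 64).
#' @param pixel_size_nm lateral pixel size, nm.
#' @param metadata named list (sample label, temperature, ...).
#' @return a matrix of class `height_map`.
#' @export
height_map <- function(heights, pixel_size_nm, metadata = list()) {
  if (!is.matrix(heights) || !is.numeric(heights)) {
    abort("`heights` must be a numeric matrix")
  }
  if (any(dim(heights) < 64)) abort("height maps must be at least 64 x 64")
  if (!all(is.finite(heights))) abort("heights must be finite")
  stopifnot_scalar_num(pixel_size_nm, "pixel_size_nm", positive = TRUE)
  structure(heights, pixel_size_nm = pixel_size_nm, metadata = metadata,
            class = c("height_map", "matrix", "array"))
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %d x %d px, %.3g nm/px (%.2g x %.2g um), range [%.2f, %.2f] nm\n",
              nrow(x), ncol(x), attr(x, "pixel_size_nm"),
              ncol(x) * attr(x, "pixel_size_nm") / 1000,
              nrow(x) * attr(x, "pixel_size_nm") / 1000,
              min(x), max(x)))
  invisible(x)
}

#' @rdname height_map
#' @param map a `height_map`.
#' @export
pixel_size <- function(map) attr(map, "pixel_size_nm")

# preserve class/attributes when replacing the height values
set_heights <- function(map, h) {
  height_map(h, pixel_size(map), attr(map, "metadata") %||% list())
}

#' Specify a synthetic AFM scene
#'
#' A scene describes one synthetic topography: flat lipid phase plateaus
#' with Gaussian texture over a substrate at 0 nm, optionally a rough
#' (LPS-like) phase, a periodic stripe texture, spherical-cap vesicles and
#' per-scanline tilt/offset artifacts.
#'
#' @param name scene label.
#' @param pixels_per_side image size in pixels (square).
#' @param image_size_um physical side length, um (the standard frame is
#'   2 x 2 um).
#' @param phases tibble/data.frame with columns `class`, `height_nm`,
#'   `coverage` (fraction of the total image area; the remainder is
#'   substrate) and `texture_sd` (nm). May be `NULL` for a bare substrate.
#' @param stripe `NULL` or `list(period_nm, amplitude_nm, orientation_rad)`;
#'   the sinusoid is applied on all lipid-phase pixels.
#' @param vesicles `NULL` or `list(count, diameter_mean_nm, diameter_sd_nm,
#'   min_diameter_nm, cap_ratio)`; diameters follow the equal-area
#'   half-maximum convention shared with [detect_vesicles()].
#' @param scanline `list(offset_sd, tilt_sd)`: per-row height offset sd
#'   (nm) and across-row tilt sd (nm over the full width).
#' @param substrate_texture_sd substrate roughness, nm.
#' @return a list of class `scene_spec`.
#' @export
scene_spec <- function(name, pixels_per_side = 512, image_size_um = 2,
                       phases = NULL, stripe = NULL, vesicles = NULL,
                       scanline = list(offset_sd = 0.3, tilt_sd = 0.5),
                       substrate_texture_sd = 0.05) {
  if (!is.null(phases)) {
    phases <- as_tibble(phases)
    if (any(phases$coverage < 0)) abort("phase coverages must be >= 0")
    if (sum(phases$coverage) > 1 + 1e-9) {
      abort("phase coverages must sum to <= 1 (remainder is substrate)")
    }
    if (any(phases$height_nm <= 0)) abort("phase heights must be > 0")
  }
  if (!is.null(stripe)) {
    side_nm <- image_size_um * 1000
    if (stripe$period_nm >= side_nm) {
      abort("stripe period must be smaller than the image side length")
    }
  }
  structure(list(name = name, pixels_per_side = pixels_per_side,
                 image_size_um = image_size_um, phases = phases,
                 stripe = stripe, vesicles = vesicles, scanline = scanline,
                 substrate_texture_sd = substrate_texture_sd),
            class = "scene_spec")
}

#' Built-in synthetic scene presets
#'
#' \describe{
#'   \item{`DMPC-20C`}{two-phase DMPC patch: solid plateau at 5 nm and
#'     fluid plateau at 4 nm covering 65%/35% of the lipid area
#'     (85% total lipid coverage), smooth texture.}
#'   \item{`DMPC-SMOOTH`}{single full-coverage plateau with Gaussian
#'     texture of sd 0.77 nm - the roughness scale of a smooth DMPC SLB.}
#'   \item{`LPS-DMPC`}{fluid/solid DMPC phases plus a rough LPS domain
#'     (texture sd 1.16 nm).}
#'   \item{`OM-DMPC-STRIPES`}{full-coverage 6 nm plateau carrying the
#'     15 nm period / 0.4 nm amplitude stripe texture.}
#'   \item{`LPS-VESICLES`}{bare substrate with spherical-cap vesicles whose
#'     half-max diameters have mean 29 nm and sd 22 nm.}
#' }
#'
#' @param name preset name.
#' @param pixels_per_side,image_size_um frame geometry overrides.
#' @return a [scene_spec()].
#' @export
scene_preset <- function(name = c("DMPC-20C", "DMPC-SMOOTH", "LPS-DMPC",
                                  "OM-DMPC-STRIPES", "LPS-VESICLES"),
                         pixels_per_side = 512, image_size_um = 2) {
  name <- match.arg(name)
  sc <- switch(
    name,
    "DMPC-20C" = scene_spec(
      name, pixels_per_side, image_size_um,
      phases = tibble(class = c("fluid", "solid"),
                      height_nm = c(4, 5),
                      coverage = 0.85 * c(0.35, 0.65),
                      texture_sd = c(0.08, 0.08))),
    "DMPC-SMOOTH" = scene_spec(
      name, pixels_per_side, image_size_um,
      phases = tibble(class = "lipid", height_nm = 4, coverage = 1,
                      texture_sd = 0.77)),
    "LPS-DMPC" = scene_spec(
      name, pixels_per_side, image_size_um,
      phases = tibble(class = c("fluid", "solid", "rough"),
                      height_nm = c(4, 5, 5.5),
                      coverage = c(0.27, 0.38, 0.20),
                      texture_sd = c(0.08, 0.08, 1.16))),
    "OM-DMPC-STRIPES" = scene_spec(
      name, pixels_per_side, image_size_um,
      phases = tibble(class = "lipid", height_nm = 6, coverage = 1,
                      texture_sd = 0.1),
      stripe = list(period_nm = 15, amplitude_nm = 0.4,
                    orientation_rad = 0.5)),
    "LPS-VESICLES" = scene_spec(
      name, pixels_per_side, image_size_um,
      phases = NULL,
      vesicles = list(count = 220, diameter_mean_nm = 29,
                      diameter_sd_nm = 22, min_diameter_nm = 2,
                      cap_ratio = 0.4),
      scanline = list(offset_sd = 0.1, tilt_sd = 0.2))
  )
  sc
}

#' Generate a synthetic AFM height map with known ground truth
#'
#' Builds the scene bottom-up: a substrate plane at 0 nm, blob-shaped
#' phase regions (carved from smoothed Gaussian random fields by exact
#' pixel-count quantiles, so realised coverages match the requested ones to
#' one pixel), per-class plateau heights plus Gaussian texture, an optional
#' stripe sinusoid on the lipid phases, spherical-cap vesicles placed
#' without overlap on the substrate, and finally per-scanline linear
#' tilt/offset artifacts. The truth record keeps the label map, realised
#' coverages, the artifact-free height field and the vesicle table.
#'
#' @param scene a [scene_spec()] or preset name (see [scene_preset()]).
#' @param seed integer seed; maps are bit-identical for identical seeds.
#' @return list with `map` (a [height_map()]) and `truth` (list:
#'   `labels` integer matrix, `classes` level names, `coverages` tibble,
#'   `clean_map` artifact-free [height_map()], `vesicles` tibble, `scene`).
#' @export
gen_height_map <- function(scene, seed) {
  if (is.character(scene)) scene <- scene_preset(scene)
  stopifnot(inherits(scene, "scene_spec"))
  set.seed(sub_seed(seed, 101L))
  n <- scene$pixels_per_side
  px <- scene$image_size_um * 1000 / n
  npix <- n * n

  labels <- matrix(1L, n, n) # 1 = substrate
  classes <- "substrate"
  heights <- matrix(rnorm(npix, 0, scene$substrate_texture_sd), n, n)

  if (!is.null(scene$phases) && nrow(scene$phases) > 0) {
    ph <- scene$phases
    k_pix <- round(ph$coverage * npix)
    if (sum(k_pix) > npix) {
      abort("requested coverages cannot be tiled into the pixel grid")
    }
    # blob-shaped lipid footprint: top-k pixels of a smoothed random field
    field <- EBImage::gblur(matrix(rnorm(npix), n, n), sigma = n / 24)
    lipid_idx <- order(field, decreasing = TRUE)[seq_len(sum(k_pix))]
    # split the lipid footprint into phases with a second smooth field
    field2 <- EBImage::gblur(matrix(rnorm(npix), n, n), sigma = n / 24)
    ord <- lipid_idx[order(field2[lipid_idx], decreasing = TRUE)]
    stop_at <- cumsum(k_pix)
    start_at <- c(1L, head(stop_at, -1) + 1L)
    for (i in seq_len(nrow(ph))) {
      if (k_pix[i] == 0) next
      idx <- ord[seq.int(start_at[i], stop_at[i])]
      labels[idx] <- length(classes) + 1L
      heights[idx] <- ph$height_nm[i] +
        rnorm(length(idx), 0, ph$texture_sd[i])
      classes <- c(classes, ph$class[i])
    }
  }

  if (!is.null(scene$stripe)) {
    st <- scene$stripe
    xc <- ((col(labels) - 0.5) * px)
    yc <- ((row(labels) - 0.5) * px)
    u <- xc * cos(st$orientation_rad) + yc * sin(st$orientation_rad)
    phase <- runif(1, 0, 2 * pi)
    wave <- st$amplitude_nm * sin(2 * pi * u / st$period_nm + phase)
    on_lipid <- labels > 1L
    if (!any(on_lipid)) on_lipid[] <- TRUE
    heights[on_lipid] <- heights[on_lipid] + wave[on_lipid]
  }

  ves_tbl <- tibble(x_nm = double(), y_nm = double(),
                    diameter_nm = double(), cap_height_nm = double())
  if (!is.null(scene$vesicles)) {
    vv <- scene$vesicles
    res <- place_vesicles(heights, labels, vv, px)
    heights <- res$heights
    labels <- res$labels
    if (!("vesicle" %in% classes) && nrow(res$vesicles) > 0) {
      classes <- c(classes, "vesicle")
      labels[labels == -1L] <- length(classes)
    }
    ves_tbl <- res$vesicles
  }

  clean <- heights
  sl <- scene$scanline
  if (!is.null(sl) && (sl$offset_sd > 0 || sl$tilt_sd > 0)) {
    off <- rnorm(n, 0, sl$offset_sd)
    tilt <- rnorm(n, 0, sl$tilt_sd)
    xrel <- (seq_len(n) - 0.5) / n - 0.5 # -0.5 .. 0.5 across the row
    heights <- heights + outer(off, rep(1, n)) + outer(tilt, xrel)
  }

  counts <- tabulate(labels, nbins = length(classes))
  cov <- tibble(class = classes, pixels = counts,
                fraction_total = counts / npix)
  lipid <- cov$class != "substrate"
  cov$fraction_lipid <- ifelse(lipid, cov$pixels / max(sum(cov$pixels[lipid]), 1),
                               NA_real_)

  meta <- list(sample = scene$name, seed = seed)
  list(map = height_map(heights, px, meta),
       truth = list(labels = labels, classes = classes, coverages = cov,
                    clean_map = height_map(clean, px, meta),
                    vesicles = ves_tbl, scene = scene))
}

# draw vesicle diameters (lognormal with the requested mean/sd moments,
# strictly positive; draws below the detectability floor are rejected) and
# place non-overlapping spherical caps on substrate pixels
place_vesicles <- function(heights, labels, vv, px) {
  n <- nrow(heights)
  m <- ncol(heights)
  cv2 <- (vv$diameter_sd_nm / vv$diameter_mean_nm)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(vv$diameter_mean_nm) - sdlog^2 / 2

  placed <- list()
  tries <- 0L
  max_tries <- 200L * vv$count
  cx <- cy <- rf <- numeric(0)
  while (length(placed) < vv$count && tries < max_tries) {
    tries <- tries + 1L
    d <- rlnorm(1, meanlog, sdlog)
    if (d < vv$min_diameter_nm) next
    h_cap <- vv$cap_ratio * d
    r_sph <- (d^2 + h_cap^2) / (4 * h_cap)         # sphere radius
    r_foot <- sqrt(2 * r_sph * h_cap - h_cap^2)    # footprint radius
    x <- runif(1, r_foot + px, m * px - r_foot - px)
    y <- runif(1, r_foot + px, n * px - r_foot - px)
    if (length(cx) > 0 &&
        any(sqrt((cx - x)^2 + (cy - y)^2) < (rf + r_foot + 2 * px))) next
    cx <- c(cx, x); cy <- c(cy, y); rf <- c(rf, r_foot)
    placed[[length(placed) + 1L]] <-
      list(x = x, y = y, d = d, h = h_cap, r_sph = r_sph, r_foot = r_foot)
  }
  for (p in placed) {
    jc <- floor((p$x - p$r_foot) / px) : ceiling((p$x + p$r_foot) / px)
    ir <- floor((p$y - p$r_foot) / px) : ceiling((p$y + p$r_foot) / px)
    jc <- jc[jc >= 1 & jc <= m]
    ir <- ir[ir >= 1 & ir <= n]
    xs <- (jc - 0.5) * px
    ys <- (ir - 0.5) * px
    rr <- outer((ys - p$y)^2, (xs - p$x)^2, `+`)
    inside <- rr < p$r_foot^2
    cap <- sqrt(pmax(p$r_sph^2 - rr, 0)) - (p$r_sph - p$h)
    block <- heights[ir, jc, drop = FALSE]
    block[inside] <- block[inside] + cap[inside]
    heights[ir, jc] <- block
    lb <- labels[ir, jc, drop = FALSE]
    lb[inside] <- -1L # tagged, renamed to the vesicle class by the caller
    labels[ir, jc] <- lb
  }
  ves <- if (length(placed) > 0) {
    tibble(x_nm = map_dbl(placed, "x"), y_nm = map_dbl(placed, "y"),
           diameter_nm = map_dbl(placed, "d"),
           cap_height_nm = map_dbl(placed, "h"))
  } else {
    tibble(x_nm = double(), y_nm = double(), diameter_nm = double(),
           cap_height_nm = double())
  }
  list(heights = heights, labels = labels, vesicles = ves)
}
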