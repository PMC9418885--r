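#' Level an AFM height map (scan-line artifact removal)
#'
#' Per-scanline polynomial levelling followed by global plane removal and
#' substrate referencing, the standard post-processing chain for AFM
#' topographies. Each row's polynomial (order 0-2) is fitted robustly on
#' the row's interquartile pixels, which keeps plateau steps from biasing
#' the fit. With `refine = TRUE` (default) a second pass segments the
#' levelled map into height classes and refits every row on the residuals
#' from the per-class plateau heights, using all pixels - this removes the
#' residual row offsets that a single robust pass leaves on images whose
#' rows mix phases. Finally the modal height bin (the substrate, or the
#' dominant plateau on full-coverage images) is shifted to 0 nm.
#'
#' @param map a [height_map()].
#' @param order polynomial order per scanline: 0, 1 or 2.
#' @param exclude optional logical matrix of pixels to exclude from the
#'   fits (e.g. known defects); a fully excluded line is fitted on all its
#'   pixels with a warning.
#' @param refine run the segmentation-guided second pass?
#' @return the levelled [height_map()].
#' @export
flatten_map <- function(map, order = 1, exclude = NULL, refine = TRUE) {
  stopifnot(inherits(map, "height_map"))
  if (!order %in% 0:2) abort("`order` must be 0, 1 or 2")
  h <- unclass(map)
  attributes(h) <- list(dim = dim(h))
  n <- nrow(h); m <- ncol(h)
  x <- seq_len(m) / m - 0.5
  X <- stats::poly(x, degree = max(order, 1), raw = TRUE)

  fit_rows <- function(h, keep_fun) {
    Xf <- cbind(1, X[, seq_len(max(order, 1)), drop = FALSE])
    if (order == 0) Xf <- Xf[, 1, drop = FALSE]
    for (i in seq_len(n)) {
      row <- h[i, ]
      keep <- keep_fun(i, row)
      if (!any(keep)) {
        warn(sprintf("scanline %d fully excluded; fitted on all pixels", i))
        keep <- rep(TRUE, m)
      }
      if (order == 0) {
        h[i, ] <- row - median(row[keep])
        next
      }
      # iteratively robust: fit, trim 4-MAD outliers, refit
      for (pass in 1:2) {
        cf <- stats::lm.fit(Xf[keep, , drop = FALSE], row[keep])$coefficients
        cf[is.na(cf)] <- 0
        res <- row - drop(Xf %*% cf)
        tol <- 4 * mad(res[keep]) + 1e-12
        keep2 <- keep & abs(res) <= tol
        if (sum(keep2) > ncol(Xf) + 2) keep <- keep2
      }
      h[i, ] <- row - drop(Xf %*% cf)
    }
    h
  }

  # pass 1: scanline alignment from adjacent-row differences. Adjacent rows
  # share almost the same phase layout, so their difference cancels the
  # surface structure and isolates the per-row artifact increment; fitting
  # the increments (with outlier trimming at phase boundaries) and
  # accumulating them aligns the rows without plateau bias.
  if (order == 0) {
    h <- fit_rows(h, function(i, row) {
      keep <- if (is.null(exclude)) rep(TRUE, m) else !exclude[i, ]
      if (!any(keep)) return(keep)
      keep
    })
  } else {
    Xd <- cbind(1, X[, seq_len(order), drop = FALSE])
    inc <- matrix(0, n, order + 1)
    for (i in 2:n) {
      d <- h[i, ] - h[i - 1, ]
      keep <- if (is.null(exclude)) rep(TRUE, m) else {
        !exclude[i, ] & !exclude[i - 1, ]
      }
      if (sum(keep) < order + 2) {
        if (!is.null(exclude) && !any(!exclude[i, ])) {
          warn(sprintf("scanline %d fully excluded; fitted on all pixels", i))
        }
        keep <- rep(TRUE, m)
      }
      for (pass in 1:2) {
        cf <- stats::lm.fit(Xd[keep, , drop = FALSE], d[keep])$coefficients
        cf[is.na(cf)] <- 0
        res <- d - drop(Xd %*% cf)
        tol <- 4 * mad(res[keep]) + 1e-12
        keep2 <- keep & abs(res) <= tol
        if (sum(keep2) >= order + 2) keep <- keep2
      }
      inc[i, ] <- cf
    }
    art <- apply(inc, 2, cumsum)
    h <- h - art %*% t(Xd)
  }

  # global plane removal
  xc <- as.vector(col(h)) / m - 0.5
  yc <- as.vector(row(h)) / n - 0.5
  cf <- stats::lm.fit(cbind(1, xc, yc), as.vector(h))$coefficients
  h <- h - matrix(cf[1] + cf[2] * xc + cf[3] * yc, n, m)

  # pass 2: per-class plateau residuals. Row fits and the plane refit both
  # operate on heights minus the per-class plateau, so phase structure that
  # correlates with position cannot bias them.
  if (refine) {
    for (iter in 1:4) { # resegment and refit until the rows settle
      seg <- tryCatch(
        segment_heights(set_heights(map, h), n_classes = "auto",
                        detect_rough = FALSE, detect_bumps = FALSE),
        error = function(e) NULL)
      if (is.null(seg) || length(seg$class_heights) < 1) break
      plateau <- seg$class_heights[seg$labels]
      dim(plateau) <- dim(h)
      resid <- h - plateau
      hr <- fit_rows(resid, function(i, row) {
        if (is.null(exclude)) rep(TRUE, m) else !exclude[i, ]
      })
      for (pass in 1:2) { # robust plane on the residual field
        cf <- stats::lm.fit(cbind(1, xc, yc), as.vector(hr))$coefficients
        plane <- matrix(cf[1] + cf[2] * xc + cf[3] * yc, n, m)
        res <- hr - plane
        keep <- abs(res) <= 4 * mad(res)
        cf <- stats::lm.fit(cbind(1, xc[keep], yc[keep]),
                            as.vector(hr)[keep])$coefficients
        hr <- hr - matrix(cf[1] + cf[2] * xc + cf[3] * yc, n, m)
      }
      h_new <- plateau + hr
      delta <- sqrt(mean((h_new - h)^2))
      h <- h_new
      if (delta < 1e-4) break
    }
  }

  # substrate reference: shift the lowest well-populated height level to 0
  # (the substrate when present, else the dominant plateau)
  br <- seq(min(h) - 0.1, max(h) + 0.1, by = 0.1)
  cnt <- tabulate(findInterval(h, br), nbins = length(br))
  pop <- cnt >= 0.01 * length(h)
  if (!any(pop)) pop <- cnt == max(cnt)
  runs <- split(which(pop), cumsum(c(1L, diff(which(pop)) > 1L)))
  lowest <- runs[[1]]
  ref <- sum((br[lowest] + 0.05) * cnt[lowest]) / sum(cnt[lowest])
  h <- h - ref
  set_heights(map, h)
}

# multi-level Otsu thresholding on a fixed histogram: exhaustive search of
# k-1 thresholds maximising the between-class variance
multi_otsu <- function(x, k, bins = 256) {
  if (k < 2) return(numeric(0))
  if (k > 4) abort("multi_otsu supports up to 4 classes")
  if (k == 4) bins <- 128
  rng <- range(x)
  if (diff(rng) == 0) return(numeric(0))
  br <- seq(rng[1], rng[2], length.out = bins + 1)
  cnt <- tabulate(findInterval(x, br, all.inside = TRUE), nbins = bins)
  p <- cnt / sum(cnt)
  mids <- (br[-1] + br[-(bins + 1)]) / 2
  P <- cumsum(p)
  S <- cumsum(p * mids)
  # between-class contribution of bins (a, b]
  bc <- function(a, b) {
    w <- P[b] - ifelse(a == 0, 0, P[a])
    s <- S[b] - ifelse(a == 0, 0, S[a])
    ifelse(w > 0, s^2 / w, 0)
  }
  best <- -Inf; best_t <- NULL
  if (k == 2) {
    t1 <- seq_len(bins - 1)
    val <- bc(0, t1) + bc(t1, bins)
    i <- which.max(val)
    best_t <- t1[i]
  } else if (k == 3) {
    for (t1 in seq_len(bins - 2)) {
      t2 <- seq.int(t1 + 1, bins - 1)
      val <- bc(0, t1) + bc(t1, t2) + bc(t2, bins)
      i <- which.max(val)
      if (val[i] > best) { best <- val[i]; best_t <- c(t1, t2[i]) }
    }
  } else {
    for (t1 in seq_len(bins - 3)) {
      for (t2 in seq.int(t1 + 1, bins - 2)) {
        t3 <- seq.int(t2 + 1, bins - 1)
        val <- bc(0, t1) + bc(t1, t2) + bc(t2, t3) + bc(t3, bins)
        i <- which.max(val)
        if (val[i] > best) { best <- val[i]; best_t <- c(t1, t2, t3[i]) }
      }
    }
  }
  br[best_t + 1]
}

# count well-separated modes of the height histogram (kernel density),
# used by the automatic class-count choice
count_height_modes <- function(x, max_modes = 4) {
  d <- stats::density(x, bw = max(0.12, stats::bw.nrd0(x) / 2), n = 512)
  y <- d$y
  pk <- which(diff(sign(diff(y))) == -2) + 1
  pk <- pk[y[pk] > 0.05 * max(y)]
  # merge peaks not separated by a real dip (valley above 60% of lower peak)
  if (length(pk) > 1) {
    keep <- rep(TRUE, length(pk))
    for (i in seq_len(length(pk) - 1)) {
      valley <- min(y[pk[i]:pk[i + 1]])
      if (valley > 0.6 * min(y[pk[i]], y[pk[i + 1]])) {
        keep[i + which.min(c(y[pk[i + 1]], y[pk[i]])) - 1] <- FALSE
      }
    }
    pk <- pk[keep]
  }
  min(max(length(pk), 1), max_modes)
}

#' Segment a height map into phase classes
#'
#' Pixels are assigned to height-level classes by multi-level Otsu
#' thresholding of the height histogram (default; a Gaussian mixture via
#' \pkg{mclust} is available as `method = "mixture"`). With
#' `n_classes = "auto"` the class count is the number of well-separated
#' modes of the height distribution. Classes are ordered by height; the
#' lowest class is called `substrate` when it lies near 0 nm, and the
#' lipid levels above it are named `fluid` and `solid` (low/high) or
#' `lipid` when only one level exists.
#'
#' Two texture-based classes refine the level classes: `rough` collects
#' lipid pixels whose local height variance (5x5 window) exceeds
#' `rough_factor` times the smooth-lipid reference variance (LPS-rich
#' domains), and `bump` collects connected components protruding above the
#' top plateau.
#'
#' @param map a flattened [height_map()] (see [flatten_map()]).
#' @param n_classes integer number of height classes (including the
#'   substrate) or `"auto"`.
#' @param method `"otsu"` (deterministic, default) or `"mixture"`.
#' @param detect_rough,detect_bumps enable the texture classes.
#' @param rough_factor local-variance multiple defining `rough`.
#' @return an object of class `seg_labels`: list with `labels` (integer
#'   matrix), `classes` (names, by class index), `class_heights` (named,
#'   nm, level classes only) and `pixel_size_nm`.
#' @export
segment_heights <- function(map, n_classes = "auto",
                            method = c("otsu", "mixture"),
                            detect_rough = TRUE, detect_bumps = TRUE,
                            rough_factor = 3) {
  stopifnot(inherits(map, "height_map"))
  method <- match.arg(method)
  h <- as.vector(unclass(map))
  k <- if (identical(n_classes, "auto")) count_height_modes(h) else n_classes
  if (k < 1) abort("`n_classes` must be >= 1")

  if (k == 1 || diff(range(h)) < 1e-9) {
    if (!identical(n_classes, "auto") && n_classes > 1 &&
        diff(range(h)) < 1e-9) {
      warn("degenerate height histogram: a single class was produced")
    }
    k <- 1
    thr <- numeric(0)
  } else if (method == "otsu") {
    thr <- multi_otsu(h, k)
  } else {
    fit <- Mclust(sample_for_mclust(h), G = k, modelNames = "V",
                  verbose = FALSE)
    mu <- sort(fit$parameters$mean)
    thr <- (mu[-1] + mu[-length(mu)]) / 2
  }
  lab <- findInterval(h, thr) + 1L
  class_heights <- vapply(seq_len(k), function(i) median(h[lab == i]), 0)

  # class names by height order
  nm <- if (abs(class_heights[1]) < 1 && k > 1) {
    lip <- switch(min(k - 1, 3), "lipid", c("fluid", "solid"),
                  c("fluid", "solid", "upper"))
    c("substrate", lip)
  } else if (k == 1) {
    if (abs(class_heights[1]) < 1) "substrate" else "lipid"
  } else {
    switch(min(k, 3), "lipid", c("fluid", "solid"),
           c("fluid", "solid", "upper"))[seq_len(min(k, 3))]
  }
  if (length(nm) < k) nm <- c(nm, paste0("level", seq.int(length(nm) + 1, k)))
  names(class_heights) <- nm

  labm <- matrix(lab, nrow(map), ncol(map))
  classes <- nm

  if (detect_rough && any(labm > 1L) && k > 1) {
    lv <- local_variance(unclass(map), 5)
    lipid <- labm > 1L
    # smooth-class reference variance: a low quantile keeps the reference
    # anchored on the smooth population even when rough domains dominate
    ref <- quantile(lv[lipid], 0.2, names = FALSE)
    rough <- lipid & lv > rough_factor * ref
    if (any(rough)) {
      # step edges between smooth plateaus also carry high local variance,
      # but only in a band as wide as the window; morphological opening
      # with a brush wider than that band keeps bulk rough domains and
      # discards the edge bands
      rough <- EBImage::opening(rough * 1L,
                                EBImage::makeBrush(7, "disc")) > 0
    }
    if (any(rough)) {
      classes <- c(classes, "rough")
      labm[rough] <- length(classes)
    }
  }
  if (detect_bumps && k > 1) {
    top <- max(class_heights)
    hm <- unclass(map)
    tex <- mad(hm[labm == which.max(class_heights)])
    bump <- matrix(hm > top + max(1, 4 * tex), nrow(map), ncol(map))
    if ("rough" %in% classes) {
      # the tail of a rough domain's texture is not a discrete bump
      bump <- bump & labm != match("rough", classes)
    }
    if (any(bump)) {
      cc <- EBImage::bwlabel(bump)
      sizes <- tabulate(cc[cc > 0])
      big <- which(sizes >= 4)
      if (length(big) > 0) {
        classes <- c(classes, "bump")
        labm[matrix(cc %in% big, nrow(map), ncol(map))] <- length(classes)
      }
    }
  }

  structure(list(labels = labm, classes = classes,
                 class_heights = class_heights,
                 pixel_size_nm = pixel_size(map)),
            class = "seg_labels")
}

sample_for_mclust <- function(x, n_max = 20000) {
  if (length(x) <= n_max) return(x)
  x[seq.int(1, length(x), length.out = n_max)]
}

# per-pixel variance in a w x w box via cumulative-sum box filtering
local_variance <- function(h, w = 5) {
  s1 <- box_sum(h, w)
  s2 <- box_sum(h * h, w)
  cnt <- box_sum(matrix(1, nrow(h), ncol(h)), w)
  m <- s1 / cnt
  pmax(s2 / cnt - m^2, 0) * cnt / pmax(cnt - 1, 1)
}

box_sum <- function(h, w) {
  r <- (w - 1) / 2
  n <- nrow(h); m <- ncol(h)
  P <- rbind(0, apply(h, 2, cumsum))           # (n+1) x m
  lo <- pmax(seq_len(n) - r, 1)
  hi <- pmin(seq_len(n) + r, n)
  v <- P[hi + 1, , drop = FALSE] - P[lo, , drop = FALSE]
  P2 <- cbind(0, t(apply(v, 1, cumsum)))       # n x (m+1)
  lo2 <- pmax(seq_len(m) - r, 1)
  hi2 <- pmin(seq_len(m) + r, m)
  P2[, hi2 + 1, drop = FALSE] - P2[, lo2, drop = FALSE]
}

#' @export
print.seg_labels <- function(x, ...) {
  cnt <- tabulate(x$labels, nbins = length(x$classes))
  cat("<seg_labels>", paste(sprintf("%s: %d px", x$classes, cnt),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Surface coverage fractions of segmented phases
#'
#' Pixel-count area fractions per class. With `denominator = "lipid"`
#' (default, the convention used for reported phase splits) the substrate is excluded and
#' fractions are relative to the lipid-covered area; `"total"` uses the
#' whole frame.
#'
#' @param labels a `seg_labels` from [segment_heights()].
#' @param denominator `"lipid"` or `"total"`.
#' @return tibble with `class`, `pixels`, `fraction`.
#' @export
coverage_fractions <- function(labels, denominator = c("lipid", "total")) {
  stopifnot(inherits(labels, "seg_labels"))
  denominator <- match.arg(denominator)
  cnt <- tabulate(labels$labels, nbins = length(labels$classes))
  tb <- tibble(class = labels$classes, pixels = cnt)
  if (denominator == "lipid") {
    tb <- filter(tb, .data$class != "substrate")
    if (sum(tb$pixels) == 0) {
      abort("no lipid-covered pixels: coverage over lipid area is undefined")
    }
  }
  mutate(tb, fraction = .data$pixels / sum(.data$pixels))
}

#' Root-mean-square surface roughness R_q
#'
#' RMS deviation of the masked heights about their mean, the standard
#' AFM roughness statistic.
#'
#' @param map a [height_map()].
#' @param mask optional logical matrix selecting the evaluated region
#'   (default: whole frame). At least 100 pixels are required.
#' @return roughness in nm.
#' @export
roughness_rq <- function(map, mask = NULL) {
  stopifnot(inherits(map, "height_map"))
  h <- unclass(map)
  v <- if (is.null(mask)) as.vector(h) else h[mask]
  if (length(v) < 100) abort("R_q needs at least 100 pixels in the mask")
  sqrt(mean((v - mean(v))^2))
}

#' Extract a height profile along a line segment
#'
#' Bilinearly interpolated height-distance function along the segment from
#' `from` to `to` (nm coordinates, x right / y down, origin at the
#' top-left corner).
#'
#' @param map a [height_map()].
#' @param from,to numeric `c(x_nm, y_nm)` endpoints inside the map.
#' @param n number of samples; default one per pixel traversed.
#' @return tibble with `distance_nm`, `height_nm`, `x_nm`, `y_nm`.
#' @export
extract_profile <- function(map, from, to, n = NULL) {
  stopifnot(inherits(map, "height_map"))
  px <- pixel_size(map)
  len <- sqrt(sum((to - from)^2))
  if (len <= 0) abort("zero-length profile segment")
  lim_x <- ncol(map) * px
  lim_y <- nrow(map) * px
  if (any(c(from, to) < 0) || from[1] > lim_x || to[1] > lim_x ||
      from[2] > lim_y || to[2] > lim_y) {
    abort("profile endpoints must lie inside the map")
  }
  n <- n %||% max(2L, ceiling(len / px) + 1L)
  tt <- seq(0, 1, length.out = n)
  xs <- from[1] + tt * (to[1] - from[1])
  ys <- from[2] + tt * (to[2] - from[2])
  tibble(distance_nm = tt * len,
         height_nm = bilinear_at(unclass(map), px, xs, ys),
         x_nm = xs, y_nm = ys)
}

bilinear_at <- function(h, px, xs, ys) {
  # pixel centres at (j - 0.5) px; clamp to the centre grid
  cx <- pmin(pmax(xs / px + 0.5, 1), ncol(h))
  cy <- pmin(pmax(ys / px + 0.5, 1), nrow(h))
  j0 <- pmin(floor(cx), ncol(h) - 1); i0 <- pmin(floor(cy), nrow(h) - 1)
  fx <- cx - j0; fy <- cy - i0
  idx <- function(i, j) h[cbind(i, j)]
  (1 - fx) * (1 - fy) * idx(i0, j0) + fx * (1 - fy) * idx(i0, j0 + 1) +
    (1 - fx) * fy * idx(i0 + 1, j0) + fx * fy * idx(i0 + 1, j0 + 1)
}

#' Dominant stripe periodicity of a surface texture
#'
#' Estimates the dominant spatial wavelength of a periodic surface texture
#' from the 2D power spectrum of the (plane-detrended, Hann-windowed)
#' height field. The dominant wavelength is the non-DC spectral peak; its
#' sinusoid-equivalent amplitude is recovered from the unwindowed spectrum
#' by Parseval bookkeeping over the peak's neighbourhood. When no peak
#' rises sufficiently above the spectral background the result reports no
#' periodicity (`NA` wavelength) rather than an error.
#'
#' @param map a [height_map()].
#' @param mask optional logical matrix; analysis is restricted to the
#'   mask's bounding box, with off-mask pixels replaced by the mask mean.
#' @param min_snr peak-to-mean spectral power ratio required to call a
#'   periodicity.
#' @return an object of class `texture_spectrum`: list with
#'   `dominant_wavelength_nm`, `dominant_amplitude_nm`, `orientation_rad`,
#'   `peak_snr`, and `spectrum` (tibble `wavelength_nm`, `power`, radially
#'   collapsed).
#' @export
stripe_period <- function(map, mask = NULL, min_snr = 20) {
  stopifnot(inherits(map, "height_map"))
  px <- pixel_size(map)
  h <- unclass(map)
  attributes(h) <- list(dim = dim(h))
  if (!is.null(mask)) {
    rr <- range(which(apply(mask, 1, any)))
    cc <- range(which(apply(mask, 2, any)))
    h <- h[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
    msk <- mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
    h[!msk] <- mean(h[msk])
  }
  n <- nrow(h); m <- ncol(h)
  # plane detrend
  xc <- as.vector(col(h)) / m - 0.5
  yc <- as.vector(row(h)) / n - 0.5
  cf <- stats::lm.fit(cbind(1, xc, yc), as.vector(h))$coefficients
  h <- h - matrix(cf[1] + cf[2] * xc + cf[3] * yc, n, m)

  hann <- function(k) 0.5 - 0.5 * cos(2 * pi * (seq_len(k) - 1) / (k - 1))
  w <- outer(hann(n), hann(m))
  Pw <- Mod(fft(h * w))^2

  fy <- ifelse(seq_len(n) - 1 <= n / 2, seq_len(n) - 1, seq_len(n) - 1 - n) / n
  fx <- ifelse(seq_len(m) - 1 <= m / 2, seq_len(m) - 1, seq_len(m) - 1 - m) / m
  fr <- sqrt(outer(fy^2, fx^2, `+`)) # cycles per pixel
  sel <- fr > 2.5 / max(n, m)        # exclude DC and near-DC bins
  pk <- which(Pw == max(Pw[sel]) & sel, arr.ind = TRUE)[1, , drop = TRUE]
  snr <- max(Pw[sel]) / mean(Pw[sel])

  # radially collapsed spectrum
  nb <- 120
  rb <- cut(fr[sel], breaks = seq(0, max(fr), length.out = nb + 1))
  rad <- tapply(Pw[sel], rb, mean)
  mid <- (seq(0, max(fr), length.out = nb + 1)[-1] +
            seq(0, max(fr), length.out = nb + 1)[-(nb + 1)]) / 2
  spec <- tibble(wavelength_nm = px / mid, power = as.numeric(rad)) |>
    filter(is.finite(.data$power))

  if (snr < min_snr) {
    return(structure(list(dominant_wavelength_nm = NA_real_,
                          dominant_amplitude_nm = NA_real_,
                          orientation_rad = NA_real_, peak_snr = snr,
                          spectrum = spec),
                     class = "texture_spectrum"))
  }
  f_pk <- c(fy[pk[1]], fx[pk[2]])
  f_mag <- sqrt(sum(f_pk^2))
  lambda <- px / f_mag
  orient <- atan2(f_pk[1], f_pk[2])

  # amplitude from the unwindowed spectrum: sum |H|^2 over the peak's
  # neighbourhood; the conjugate half-plane contributes the factor 2
  H0 <- fft(h)
  P0 <- Mod(H0)^2
  iy <- ((pk[1] - 1) + (-2:2)) %% n + 1
  ix <- ((pk[2] - 1) + (-2:2)) %% m + 1
  band <- sum(P0[iy, ix])
  amp <- 2 * sqrt(band) / (n * m)

  structure(list(dominant_wavelength_nm = lambda,
                 dominant_amplitude_nm = amp,
                 orientation_rad = orient, peak_snr = snr, spectrum = spec),
            class = "texture_spectrum")
}

#' @export
print.texture_spectrum <- function(x, ...) {
  if (is.na(x$dominant_wavelength_nm)) {
    cat(sprintf("<texture_spectrum> no periodicity (peak SNR %.1f)\n",
                x$peak_snr))
  } else {
    cat(sprintf(
      "<texture_spectrum> wavelength %.2f nm, amplitude %.3f nm, orientation %.2f rad (SNR %.0f)\n",
      x$dominant_wavelength_nm, x$dominant_amplitude_nm, x$orientation_rad,
      x$peak_snr))
  }
  invisible(x)
}

#' Detect and size vesicle caps in a height map
#'
#' Connected components protruding above `min_height` are treated as
#' vesicle caps. Each component's diameter follows the equal-area-disc
#' convention at half-maximum height: the diameter of the disc whose area
#' equals the component's area at half its peak height - the same
#' convention the synthetic generator uses for its cap sizes.
#'
#' @param map a flattened [height_map()].
#' @param min_height detection threshold above the substrate, nm.
#' @param min_area_px discard components smaller than this (noise specks).
#' @return tibble with one row per detection: `x_nm`, `y_nm`,
#'   `diameter_nm`, `max_height_nm`, `area_px`.
#' @export
detect_vesicles <- function(map, min_height = 2, min_area_px = 4) {
  stopifnot(inherits(map, "height_map"))
  px <- pixel_size(map)
  h <- unclass(map)
  attributes(h) <- list(dim = dim(h))
  bw <- h > min_height
  empty <- tibble(x_nm = double(), y_nm = double(), diameter_nm = double(),
                  max_height_nm = double(), area_px = integer())
  if (!any(bw)) return(empty)
  cc <- EBImage::bwlabel(bw)
  idx_by_comp <- split(which(cc > 0), cc[cc > 0])
  out <- map(idx_by_comp, function(idx) {
    if (length(idx) < min_area_px) return(NULL)
    hv <- h[idx]
    hmax <- max(hv)
    half <- idx[hv >= hmax / 2]
    area <- length(half)
    rows <- (half - 1) %% nrow(h) + 1
    cols <- (half - 1) %/% nrow(h) + 1
    tibble(x_nm = (mean(cols) - 0.5) * px, y_nm = (mean(rows) - 0.5) * px,
           diameter_nm = 2 * sqrt(area * px^2 / pi),
           max_height_nm = hmax, area_px = length(idx))
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) return(empty)
  out
}
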