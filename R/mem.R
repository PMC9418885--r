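#' Maximum-entropy inversion of a DLS correlogram
#'
#' Recovers an intensity-weighted particle size distribution from a
#' measured g2(tau) by the maximum entropy method: among all weight
#' vectors p on the diameter grid, choose the one maximising the Shannon
#' entropy relative to a uniform prior m,
#' `S = -sum_i p_i log(p_i / m_i)`, subject to the fit constraint
#' `chi^2 <= chi2_target * n_lags`, where
#' `chi^2 = sum_j ((g2_model_j - g2_j) / sigma_j)^2` uses the shared
#' forward model of [g2_model()].
#'
#' The constrained problem is solved along a regularisation path: for a
#' trial multiplier alpha the penalised objective `chi^2 - alpha S` is
#' minimised over the softmax parametrisation of p (quasi-Newton, warm
#' started), and alpha is bisected until chi^2 meets the target - the
#' classic maximum-entropy trade-off between fit and smoothness. The
#' iteration scheme and stopping tolerances are fixed, so the result is
#' deterministic given its inputs.
#'
#' @param corr a [correlogram()]; its `noise_sd` attribute (or
#'   `noise_sd` argument) provides sigma.
#' @param inst an [instrument_spec()].
#' @param grid diameter grid, nm (default 60 log-spaced points 1-1000 nm).
#' @param chi2_target reduced chi-square target (per lag).
#' @param noise_sd override for the noise sd; defaults to the
#'   correlogram's estimate, floored at 1e-4 for noiseless input.
#' @param prior prior weights m (default uniform).
#' @param max_bisect bisection steps on the multiplier.
#' @param maxit inner quasi-Newton iterations.
#' @param number_weighted also return number weights (intensity weights
#'   divided by d^6, renormalised)? Off by default: DLS measures
#'   intensity weights.
#' @return an object of class `mem_fit`: list with `distribution`
#'   (a [size_distribution()]; intensity weights), `chi2`, `chi2_target`,
#'   `entropy`, `alpha`, `converged`, `fitted` (modelled correlogram),
#'   `observed`, and optionally `number_distribution`.
#' @export
invert_mem <- function(corr, inst, grid = diameter_grid(),
                       chi2_target = 1, noise_sd = NULL, prior = NULL,
                       max_bisect = 40, maxit = 5000,
                       number_weighted = FALSE) {
  stopifnot(inherits(corr, "correlogram"), inherits(inst, "instrument_spec"))
  if (nrow(corr) < 20) abort("at least 20 lags are required")
  tau <- corr$lag_s
  y <- corr$g2
  sigma <- noise_sd %||% attr(corr, "noise_sd")
  if (is.null(sigma) || is.na(sigma) || sigma <= 0) sigma <- 1e-4
  sigma <- max(sigma, 1e-6)
  beta <- inst$coherence_beta
  n_lags <- length(tau)
  ng <- length(grid)
  m <- prior %||% rep(1 / ng, ng)
  m <- m / sum(m)

  q <- scattering_q(inst)
  gamma <- q^2 * stokes_einstein_D(grid, inst)
  K <- exp(-outer(tau, gamma)) # n_lags x ng kernel

  target <- chi2_target * n_lags

  chi2_of <- function(p) {
    g1 <- as.vector(K %*% p)
    sum(((1 + beta * g1^2 - y) / sigma)^2)
  }
  entropy_of <- function(p) -sum(ifelse(p > 0, p * log(p / m), 0))

  penalty <- function(p, alpha) {
    g1 <- as.vector(K %*% p)
    r <- (1 + beta * g1^2 - y)
    sum((r / sigma)^2) + alpha * sum(p * log(pmax(p, 1e-300) / m))
  }
  # exponentiated-gradient (multiplicative) minimisation of
  # chi^2 - alpha S over the simplex, with backtracking line search;
  # multiplicative updates keep weights positive and let vanished grid
  # nodes regrow, the standard iteration family for maximum entropy
  solve_alpha <- function(alpha, p0) {
    p <- pmax(p0, 1e-300)
    p <- p / sum(p)
    fcur <- penalty(p, alpha)
    eta <- 1 / (abs(max_grad_scale) + alpha + 1)
    for (it in seq_len(maxit)) {
      g1 <- as.vector(K %*% p)
      r <- (1 + beta * g1^2 - y) / sigma^2
      gp <- as.vector(crossprod(K, 4 * beta * r * g1)) # d chi2 / d p
      gs <- log(pmax(p, 1e-300) / m) + 1               # d(-S) / d p
      g <- gp + alpha * gs
      g <- g - sum(p * g) # project onto the simplex tangent
      improved <- FALSE
      for (bt in 1:40) {
        pn <- p * exp(-eta * g)
        pn <- pmax(pn, 1e-300)
        pn <- pn / sum(pn)
        fn <- penalty(pn, alpha)
        if (is.finite(fn) && fn < fcur) { improved <- TRUE; break }
        eta <- eta / 2
      }
      if (!improved) break
      if ((fcur - fn) < 1e-10 * (abs(fcur) + 1e-12)) {
        p <- pn; fcur <- fn
        break
      }
      p <- pn
      fcur <- fn
      eta <- eta * 1.5
    }
    p
  }
  max_grad_scale <- sum(1 / sigma^2) * 4 * beta / n_lags

  # bracket the multiplier: chi^2 grows with alpha (stronger smoothing)
  log_lo <- -6; log_hi <- 10
  p_lo <- solve_alpha(10^log_lo, m)
  chi_lo <- chi2_of(p_lo)
  converged <- TRUE
  alpha_best <- 10^log_lo
  if (chi_lo > target) {
    # even near-unregularised fitting cannot reach the target
    converged <- FALSE
    p <- p_lo
  } else {
    p_hi <- solve_alpha(10^log_hi, p_lo)
    chi_hi <- chi2_of(p_hi)
    if (chi_hi <= target) {
      p <- p_hi # maximal smoothing already satisfies the constraint
      alpha_best <- 10^log_hi
    } else {
      pcur <- p_lo
      p <- p_lo
      for (it in seq_len(max_bisect)) {
        mid <- (log_lo + log_hi) / 2
        pcur <- solve_alpha(10^mid, pcur)
        chi_mid <- chi2_of(pcur)
        if (chi_mid <= target) {
          p <- pcur
          alpha_best <- 10^mid
          log_lo <- mid
        } else {
          log_hi <- mid
        }
        if (abs(log_hi - log_lo) < 1e-3) break
      }
    }
  }
  dist <- size_distribution(grid, p)
  fit_corr <- g2_model(dist, inst, tau)
  i_pk <- which.max(p)
  out <- structure(
    list(distribution = dist, chi2 = chi2_of(p),
         chi2_target = target, entropy = entropy_of(p),
         alpha = alpha_best, converged = converged,
         at_upper_edge = i_pk >= ng - 1L, at_lower_edge = i_pk <= 2L,
         fitted = fit_corr, observed = corr,
         sigma = sigma),
    class = "mem_fit")
  if (number_weighted) {
    wn <- p / dist$diameter_nm^6
    out$number_distribution <- size_distribution(grid, wn / sum(wn))
  }
  out
}

softmax <- function(u) {
  u <- u - max(u)
  p <- exp(u)
  p / sum(p)
}

#' @export
print.mem_fit <- function(x, ...) {
  cat(sprintf(
    "<mem_fit> chi2 = %.3g (target %.3g), entropy = %.4f, %s\n",
    x$chi2, x$chi2_target, x$entropy,
    if (x$converged) "converged" else "NOT converged"))
  pk <- peak_stats(x$distribution)
  if (nrow(pk) > 0) {
    cat("  modes:\n")
    print(pk)
  }
  invisible(x)
}

#' Modes of a size distribution with their basin masses
#'
#' Local maxima of the weight vector, each reported with the integrated
#' mass of its watershed basin (weights are assigned to the nearest peak
#' descending along the grid; basin boundaries sit at local minima).
#' Modes whose basin mass falls below `floor` are dropped.
#'
#' @param dist a [size_distribution()].
#' @param floor minimum basin mass fraction for a reported mode.
#' @return tibble with `diameter_nm`, `mass_fraction`, sorted by
#'   decreasing mass.
#' @export
peak_stats <- function(dist, floor = 0.02) {
  stopifnot(inherits(dist, "size_distribution"))
  w <- dist$weight
  d <- dist$diameter_nm
  n <- length(w)
  if (n < 3) {
    return(tibble(diameter_nm = d[which.max(w)], mass_fraction = 1))
  }
  left <- c(-Inf, w[-n])
  right <- c(w[-1], -Inf)
  peaks <- which(w > left & w > right) # strict: a flat profile has no mode
  if (length(peaks) == 0) {
    return(tibble(diameter_nm = double(), mass_fraction = double()))
  }
  if (length(peaks) == 1) {
    basins <- rep(1L, n)
  } else {
    # basin boundaries at the minima between consecutive peaks
    bounds <- map_dbl(seq_len(length(peaks) - 1), function(i) {
      seg <- peaks[i]:peaks[i + 1]
      seg[which.min(w[seg])]
    })
    basins <- findInterval(seq_len(n), bounds + 0.5) + 1L
  }
  out <- tibble(diameter_nm = d[peaks],
                mass_fraction = as.numeric(tapply(w, basins, sum)[
                  as.character(seq_along(peaks))]))
  out <- filter(out, .data$mass_fraction >= floor)
  arrange(out, desc(.data$mass_fraction))
}
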