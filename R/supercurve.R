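#' Fit a joint logistic response curve ("SuperCurve") to one slide
#'
#' Pools every spot on an antibody slide into a single sigmoid response
#' model and reads each sample's relative log2 concentration off that
#' curve. With `u = x_s - step` the effective log2 amount printed in a
#' spot, the model is
#'
#'   intensity = alpha + beta * logistic(gamma * (u - mu)) + error,
#'
#' where alpha is background, beta the dynamic range (> 0), gamma the slope
#' per log2 unit (> 0) and mu the curve midpoint on the effective-amount
#' axis. Because every x_s can be shifted by a constant absorbed into mu,
#' x is identified only up to location; the fit re-centers x to mean 0 and
#' lets mu carry the location, which makes the estimates exactly
#' equivariant under a common shift of the true concentrations.
#'
#' The objective sum((intensity - model)^2) is minimized by block
#' coordinate descent: (1) given x, refit the curve (alpha, beta linear
#' given gamma, mu; gamma, mu by derivative-free search started at the
#' current values, so the objective cannot increase); (2) given the curve,
#' refine each x_s by unidimensional search (the objective is unimodal in
#' x_s for a monotone curve); a proposal is kept only if it does not
#' increase that sample's residual sum; (3) re-center x to mean 0, moving
#' the offset into mu so predictions are unchanged. Iteration stops when
#' the relative RSS decrease falls below `tol` (or the fit is numerically
#' exact), else at `max_iter` with `converged = FALSE`.
#'
#' Replicate spots at the same (sample, step) enter the objective
#' individually. A sample whose intensities are identical across steps at
#' an interior signal level cannot be placed on the sigmoid reliably; the
#' fit proceeds and the sample is listed in `diagnostics$flat_samples`.
#'
#' @param slide a [slide_measurements()] table with >= 2 samples.
#' @param tol relative RSS tolerance (default 1e-8).
#' @param max_iter maximum outer iterations (default 200).
#' @return list of class `supercurve_fit`: `alpha`, `beta`, `gamma`, `mu`,
#'   `x` (named, mean 0), `rss`, `r_squared`, `converged`, `iterations`,
#'   `rss_trace`, `diagnostics`, `antibody`.
#' @export
fit_supercurve <- function(slide, tol = 1e-8, max_iter = 200L) {
  slide <- validate_slide_measurements(slide)
  samples <- unique(slide$sample_id)
  if (length(samples) < 2L) stop("need >= 2 samples to fit a slide")
  y <- slide$intensity
  step <- slide$dilution_step
  sid <- slide$sample_id
  tss <- sum((y - mean(y))^2)

  # init: background = min, range = observed range, unit slope; x from the
  # standardized per-sample mean intensity
  ms <- tapply(y, sid, mean)[samples]
  x <- if (stats::sd(ms) > 0) as.numeric(scale(ms)) else rep(0, length(samples))
  names(x) <- samples
  alpha <- min(y); beta <- max(diff(range(y)), 1e-6); gamma <- 1
  mu <- mean(x[sid] - step)

  curve_rss <- function(par, u) {
    # profile alpha, beta (linear) at fixed (log gamma, mu)
    g <- exp(par[1])
    z <- stats::plogis(g * (u - par[2]))
    vz <- stats::var(z)
    if (!is.finite(vz) || vz < 1e-14) {
      b <- 1e-8
    } else {
      b <- stats::cov(y, z) / vz
      if (b <= 0) b <- 1e-8
    }
    a <- mean(y) - b * mean(z)
    sum((y - a - b * z)^2)
  }
  curve_coef <- function(par, u) {
    g <- exp(par[1])
    z <- stats::plogis(g * (u - par[2]))
    vz <- stats::var(z)
    b <- if (!is.finite(vz) || vz < 1e-14) 1e-8 else stats::cov(y, z) / vz
    if (b <= 0) b <- 1e-8
    a <- mean(y) - b * mean(z)
    list(alpha = a, beta = b, gamma = g, mu = par[2])
  }

  rss_of <- function(a, b, g, m, xv)
    sum((y - a - b * stats::plogis(g * (xv[sid] - step - m)))^2)

  rss <- rss_of(alpha, beta, gamma, mu, x)
  rss_trace <- rss
  converged <- FALSE
  iter <- 0L
  idx_by_sample <- split(seq_along(y), sid)[samples]

  while (iter < max_iter) {
    iter <- iter + 1L
    prev <- rss

    # (1) curve update given x
    u <- x[sid] - step
    opt <- stats::optim(c(log(gamma), mu), curve_rss, u = u,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-13, maxit = 400))
    cf <- curve_coef(opt$par, u)
    if (opt$value <= rss) {
      alpha <- cf$alpha; beta <- cf$beta; gamma <- cf$gamma; mu <- cf$mu
      rss <- opt$value
    }

    # (2) per-sample 1-D refinement
    half_width <- 4 + 12 / gamma
    for (s in samples) {
      ii <- idx_by_sample[[s]]
      ys <- y[ii]; st <- step[ii]
      f1 <- function(xs)
        sum((ys - alpha - beta * stats::plogis(gamma * (xs - st - mu)))^2)
      cur <- f1(x[[s]])
      o <- stats::optimize(f1, interval = x[[s]] + c(-half_width, half_width),
                           tol = 1e-10)
      if (o$objective <= cur) x[[s]] <- o$minimum
    }
    # (3) re-center, moving the offset into mu (predictions unchanged)
    c0 <- mean(x)
    x <- x - c0
    mu <- mu - c0
    rss <- rss_of(alpha, beta, gamma, mu, x)
    rss_trace <- c(rss_trace, rss)

    if (prev - rss <= tol * prev || rss <= 1e-20 * max(tss, 1)) {
      converged <- TRUE
      break
    }
  }
  if (iter == 1L && rss >= rss_trace[1]) converged <- FALSE

  # flat interior samples: no spread across steps but signal well inside
  # the dynamic range, so position on the sigmoid is unidentified
  flat <- vapply(samples, function(s) {
    ii <- idx_by_sample[[s]]
    m <- tapply(y[ii], step[ii], mean)
    lo <- alpha + 0.1 * beta; hi <- alpha + 0.9 * beta
    max(m) - min(m) < 1e-8 * max(beta, 1) && mean(m) > lo && mean(m) < hi
  }, logical(1))

  fit <- list(antibody = slide$antibody[1],
              alpha = alpha, beta = beta, gamma = gamma, mu = mu,
              x = x, rss = rss,
              r_squared = if (tss > 0) max(0, min(1, 1 - rss / tss)) else 1,
              converged = converged, iterations = iter,
              rss_trace = rss_trace,
              diagnostics = list(flat_samples = samples[flat]))
  class(fit) <- "supercurve_fit"
  fit
}

#' @export
print.supercurve_fit <- function(x, ...) {
  cat(sprintf(
    "supercurve_fit [%s]: alpha=%.3g beta=%.3g gamma=%.3g | %d samples | R2=%.4f | %s in %d iter\n",
    x$antibody, x$alpha, x$beta, x$gamma, length(x$x), x$r_squared,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Quantify a set of slides into a protein-by-sample matrix
#'
#' Fits one SuperCurve per slide and assembles the per-sample relative
#' log2 concentrations into an [expression_matrix()] (one row per
#' antibody). Slides may cover different sample subsets; combinations not
#' present on a slide are missing in the matrix.
#'
#' @param slides non-empty list of [slide_measurements()].
#' @inheritParams fit_supercurve
#' @return [expression_matrix()]; attribute `diagnostics` is a data.frame
#'   with per-slide alpha, beta, gamma, r_squared, converged, iterations.
#' @export
quantify_slides <- function(slides, tol = 1e-8, max_iter = 200L) {
  if (length(slides) == 0L) stop("empty slide list")
  fits <- lapply(slides, fit_supercurve, tol = tol, max_iter = max_iter)
  antibodies <- vapply(fits, `[[`, character(1), "antibody")
  if (anyDuplicated(antibodies))
    stop("duplicate antibody names across slides")
  samples <- unique(unlist(lapply(fits, function(f) names(f$x))))
  vals <- matrix(NA_real_, length(fits), length(samples),
                 dimnames = list(antibodies, samples))
  for (i in seq_along(fits)) vals[i, names(fits[[i]]$x)] <- fits[[i]]$x
  base <- stats::setNames(samples, samples)
  for (sl in slides) {
    b <- tapply(sl$base_sample_id, sl$sample_id, `[`, 1)
    base[names(b)] <- b
  }
  diag_df <- data.frame(
    antibody = antibodies,
    alpha = vapply(fits, `[[`, numeric(1), "alpha"),
    beta = vapply(fits, `[[`, numeric(1), "beta"),
    gamma = vapply(fits, `[[`, numeric(1), "gamma"),
    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    iterations = vapply(fits, `[[`, integer(1), "iterations"),
    stringsAsFactors = FALSE)
  em <- expression_matrix(vals, base_sample = base)
  attr(em, "diagnostics") <- diag_df
  em
}
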