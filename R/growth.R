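#' Generalized least squares for longitudinal tumor volumes
#'
#' Fits the mean model `volume ~ group + day + group:day` (treatment, time
#' and their interaction) with residual covariance block-diagonal per
#' mouse under a named working correlation structure: `independence`,
#' `compound_symmetry` (exchangeable, parameter rho) or `ar1` (rho between
#' consecutive measurements of the same mouse). Estimation is maximum
#' likelihood: for each candidate rho, coefficients and sigma2 are
#' profiled out in closed form via per-mouse whitening, and rho is found
#' by bounded one-dimensional search of the profile log-likelihood on
#' (-0.99, 0.99). ML (not REML) likelihoods make AIC comparable across
#' correlation structures at a fixed mean model.
#'
#' @param data a `growth_data` data.frame with columns `mouse`, `group`,
#'   `day`, `volume` (e.g. from [generate_growth_curves()] or
#'   [read_growth_tsv()]).
#' @param structure correlation structure name.
#' @param log_volume model log(volume + 1) instead of raw mm3.
#' @return list of class `gls_fit`: `coefficients`, `vcov` (residual-df
#'   scaled), `sigma2` (ML), `rho` (NA for independence), `structure`,
#'   `log_likelihood`, `aic`, `n_obs`, `n_mean_params`, `n_cov_params`,
#'   `df_residual`, `groups`, `xlevels`.
#' @export
fit_gls <- function(data, structure = c("independence", "compound_symmetry",
                                        "ar1"), log_volume = FALSE) {
  structure <- match.arg(structure)
  req <- c("mouse", "group", "day", "volume")
  if (!all(req %in% names(data)))
    stop("growth data needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(data[c("mouse", "day")]))
    stop("one record per (mouse, day) required")
  g_per_mouse <- tapply(as.character(data$group), data$mouse,
                        function(g) length(unique(g)))
  if (any(g_per_mouse > 1L)) stop("a mouse must belong to exactly one group")
  if (length(unique(data$day)) < 2L) stop("need >= 2 days")
  mice_per_group <- tapply(data$mouse, data$group,
                           function(m) length(unique(m)))
  if (any(mice_per_group < 2L)) stop("need >= 2 mice per group")
  days_per_group <- tapply(data$day, data$group,
                           function(d) length(unique(d)))
  if (any(days_per_group < 2L))
    stop("singular design: a group observed on < 2 days")

  data <- data[order(data$mouse, data$day), , drop = FALSE]
  data$group <- factor(data$group)
  y <- if (log_volume) log(data$volume + 1) else data$volume
  X <- stats::model.matrix(~ group * day, data = data)
  n <- length(y); p <- ncol(X)
  blocks <- split(seq_len(n), data$mouse)

  profile_fit <- function(rho)
    gls_profile(y, X, blocks, structure, rho)

  if (structure == "independence") {
    rho <- NA_real_
    fit <- profile_fit(0)
  } else {
    obj <- function(r) {
      f <- profile_fit(r)
      if (is.null(f)) -1e300 else f$ll
    }
    opt <- stats::optimize(obj, interval = c(-0.99, 0.99), maximum = TRUE,
                           tol = 1e-8)
    rho <- opt$maximum
    fit <- profile_fit(rho)
  }
  n_cov <- if (structure == "independence") 1L else 2L
  XtX_inv <- chol2inv(chol(crossprod(fit$Xw)))
  dimnames(XtX_inv) <- list(colnames(X), colnames(X))
  df_res <- n - p
  vcov <- fit$rss / df_res * XtX_inv

  res <- list(coefficients = fit$coef, vcov = vcov,
              sigma2 = fit$sigma2, rho = rho, structure = structure,
              log_likelihood = fit$ll,
              aic = -2 * fit$ll + 2 * (p + n_cov),
              n_obs = n, n_mean_params = p, n_cov_params = n_cov,
              df_residual = df_res,
              groups = levels(data$group),
              day_range = range(data$day),
              log_volume = log_volume)
  class(res) <- "gls_fit"
  res
}

# Profiled ML GLS at a fixed correlation parameter: whitens each mouse's
# block with the cholesky of its working correlation matrix, then OLS.
# Returns NULL when the correlation matrix is not positive definite.
gls_profile <- function(y, X, blocks, structure, rho) {
  n <- length(y)
  Xw <- X; yw <- y; logdet <- 0
  if (structure != "independence") {
    for (ix in blocks) {
      d <- length(ix)
      if (d == 1L) next
      C <- if (structure == "ar1")
        rho^abs(outer(seq_len(d), seq_len(d), "-"))
      else matrix(rho, d, d) + diag(1 - rho, d)
      U <- tryCatch(chol(C), error = function(e) NULL)
      if (is.null(U)) return(NULL)
      logdet <- logdet + 2 * sum(log(diag(U)))
      Xw[ix, ] <- backsolve(U, X[ix, , drop = FALSE], transpose = TRUE)
      yw[ix] <- backsolve(U, y[ix], transpose = TRUE)
    }
  }
  f <- stats::lm.fit(Xw, yw)
  rss <- sum(f$residuals^2)
  sigma2 <- rss / n
  ll <- -n / 2 * (log(2 * pi) + 1 + log(sigma2)) - logdet / 2
  list(ll = ll, coef = f$coefficients, rss = rss, sigma2 = sigma2,
       Xw = Xw, logdet = logdet)
}

# profile log-likelihood of a growth dataset at a fixed rho (test hook)
gls_profile_ll <- function(data, structure, rho, log_volume = FALSE) {
  data <- data[order(data$mouse, data$day), , drop = FALSE]
  data$group <- factor(data$group)
  y <- if (log_volume) log(data$volume + 1) else data$volume
  X <- stats::model.matrix(~ group * day, data = data)
  blocks <- split(seq_along(y), data$mouse)
  f <- gls_profile(y, X, blocks, structure, rho)
  if (is.null(f)) -Inf else f$ll
}

#' @export
print.gls_fit <- function(x, ...) {
  cat(sprintf("gls_fit [%s]: logLik=%.2f AIC=%.2f rho=%s sigma=%.3g (%d obs, %d groups)\n",
              x$structure, x$log_likelihood, x$aic,
              if (is.na(x$rho)) "-" else sprintf("%.3f", x$rho),
              sqrt(x$sigma2), x$n_obs, length(x$groups)))
  invisible(x)
}

#' Select the working correlation structure by AIC
#'
#' Fits independence, compound symmetry and AR(1) and returns the
#' minimum-AIC fit; AIC ties (difference < 1e-9) are broken towards the
#' structure with fewer covariance parameters.
#'
#' @inheritParams fit_gls
#' @return the winning `gls_fit`; attribute `aic_table` holds all three.
#' @export
select_structure <- function(data, log_volume = FALSE) {
  structures <- c("independence", "compound_symmetry", "ar1")
  fits <- lapply(structures, fit_gls, data = data, log_volume = log_volume)
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  ncov <- vapply(fits, `[[`, integer(1), "n_cov_params")
  best <- order(aics - min(aics) >= 1e-9, ncov,
                match(structures, structures))[1]
  # order(): FALSE (= within tie band) sorts first, then fewer cov params
  win <- fits[[best]]
  attr(win, "aic_table") <- data.frame(structure = structures, aic = aics,
                                       log_likelihood = vapply(fits, `[[`,
                                         numeric(1), "log_likelihood"),
                                       n_cov_params = ncov,
                                       stringsAsFactors = FALSE)
  win
}

#' Tukey HSD contrasts of model-predicted group means at a day
#'
#' Predicts each group's mean volume at the evaluation day from the fitted
#' mean model, forms all unordered pairwise differences, and adjusts with
#' the studentized-range distribution (k = number of groups, residual
#' degrees of freedom = n_obs - n_mean_params). With two groups this
#' reduces to the unadjusted two-sided t-test.
#'
#' @param fit a [fit_gls()] result.
#' @param evaluation_day day at which to compare groups; must lie within
#'   the observed day range (a study's headline comparison day, e.g. 21).
#' @return data.frame of class `tukey_contrasts`: `group1`, `group2`,
#'   `estimate` (group1 - group2), `se`, `t_ratio`, `p_adjusted`.
#' @export
tukey_hsd <- function(fit, evaluation_day) {
  stopifnot(inherits(fit, "gls_fit"))
  k <- length(fit$groups)
  if (k < 2L) stop("need >= 2 groups")
  if (evaluation_day < fit$day_range[1] || evaluation_day > fit$day_range[2])
    stop("evaluation_day outside the observed day range [",
         fit$day_range[1], ", ", fit$day_range[2], "]")
  nd <- data.frame(group = factor(fit$groups, levels = fit$groups),
                   day = evaluation_day)
  Xp <- stats::model.matrix(~ group * day, data = nd)
  pairs <- utils::combn(k, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    cvec <- Xp[i1, ] - Xp[i2, ]
    est <- sum(cvec * fit$coefficients)
    se <- sqrt(drop(t(cvec) %*% fit$vcov %*% cvec))
    tr <- est / se
    data.frame(group1 = fit$groups[i1], group2 = fit$groups[i2],
               estimate = est, se = se, t_ratio = tr,
               p_adjusted = stats::ptukey(abs(tr) * sqrt(2), nmeans = k,
                                          df = fit$df_residual,
                                          lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("tukey_contrasts", "data.frame")
  attr(out, "evaluation_day") <- evaluation_day
  out
}
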