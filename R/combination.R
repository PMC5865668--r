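#' Normalize raw viability signal against control wells
#'
#' Viability is well signal divided by the mean untreated-control signal
#' (MTS-style plates).
#'
#' @param signal numeric well signals (treated wells).
#' @param control_signals signals of >= 1 control well.
#' @param doses doses aligned with `signal`.
#' @param label drug / combination label.
#' @return a [dose_response()].
#' @export
normalize_viability <- function(signal, control_signals, doses,
                                label = "drug") {
  if (length(control_signals) < 1L) stop("need >= 1 control well")
  cm <- mean(control_signals)
  if (!is.finite(cm) || cm <= 0) stop("non-positive control mean")
  dose_response(label = label, doses = doses, viability = signal / cm)
}

#' Fit the median-effect (Chou) model to a dose-response series
#'
#' The median-effect law fa / (1 - fa) = (D / Dm)^m linearizes to
#' log10(fa / (1 - fa)) = m * log10(D) - m * log10(Dm), so the fit is
#' ordinary least squares of the logit-effect on log dose. The affected
#' fraction is fa = 1 - viability; points with fa outside
#' (fa_clip, 1 - fa_clip) carry no information about the line (the logit
#' diverges) and are excluded but counted. Dm is the dose of half effect,
#' the IC50 analog.
#'
#' @param dr a [dose_response()].
#' @param fa_clip exclusion band half-width (default 0.005).
#' @return list of class `median_effect_fit`: `label`, `m`, `Dm`, `ic50`,
#'   `log10_ic50`, `r_squared`, `n_points_used`, `n_points_clipped`,
#'   `monotone` (FALSE when the fitted slope is non-positive, with a
#'   warning).
#' @export
fit_median_effect <- function(dr, fa_clip = 0.005) {
  stopifnot(inherits(dr, "dose_response"))
  fa <- 1 - dr$viability
  use <- fa > fa_clip & fa < 1 - fa_clip
  if (sum(use) < 2L)
    stop("fewer than 2 usable points after clipping fa to (",
         fa_clip, ", ", 1 - fa_clip, ")")
  yy <- log10(fa[use] / (1 - fa[use]))
  xx <- log10(dr$dose[use])
  fit <- stats::lm(yy ~ xx)
  cf <- stats::coef(fit)
  m <- unname(cf[2]); b <- unname(cf[1])
  monotone <- TRUE
  if (!is.finite(m) || m <= 0) {
    warning("non-monotone dose-response: fitted median-effect slope <= 0")
    monotone <- FALSE
  }
  Dm <- 10^(-b / m)
  tss <- sum((yy - mean(yy))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  structure(list(label = dr$label[1], m = m, Dm = Dm, ic50 = Dm,
                 log10_ic50 = log10(Dm),
                 r_squared = r2,
                 n_points_used = sum(use), n_points_clipped = sum(!use),
                 monotone = monotone),
            class = "median_effect_fit")
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat(sprintf("median_effect_fit [%s]: m=%.4g Dm=%.4g (log10 IC50 %.3f) R2=%.4f, %d points\n",
              x$label, x$m, x$Dm, x$log10_ic50, x$r_squared, x$n_points_used))
  invisible(x)
}

# dose required for effect level fa under a median-effect fit
required_dose <- function(fit, fa) fit$Dm * (fa / (1 - fa))^(1 / fit$m)

#' Chou-Talalay interaction index for a fixed-ratio combination
#'
#' Loewe-additivity score at effect level `fa`: with `Dc` the total
#' combination dose producing the effect and `D1(fa)`, `D2(fa)` the
#' single-agent doses producing it alone,
#' `IAI = (Dc * r1) / D1(fa) + (Dc * r2) / D2(fa)` (the mutually exclusive
#' two-term index, no cross-term). Values below 1 trend towards synergism,
#' above 1 towards antagonism; values within 0.05 of 1 (inclusive) are
#' labelled additive.
#'
#' @param fit_drug1,fit_drug2 single-agent [fit_median_effect()] results.
#' @param fit_combo fit of the fixed-ratio combination, doses on the total
#'   (summed) concentration scale.
#' @param r1 fraction of the total combination dose contributed by drug 1
#'   (`r2 = 1 - r1`); default 0.5 (a 1:1 ratio).
#' @param fa effect level in (0, 1); default 0.5, the IC50 level.
#' @param band half-width of the additive band (default 0.05).
#' @return list of class `combination_result`: `iai`, `fa`, `r1`, `r2`,
#'   `label` in synergism / additive / antagonism.
#' @export
interaction_index <- function(fit_drug1, fit_drug2, fit_combo, r1 = 0.5,
                              fa = 0.5, band = 0.05) {
  if (fa <= 0 || fa >= 1) stop("fa must lie strictly inside (0, 1)")
  if (r1 < 0 || r1 > 1) stop("r1 must lie in [0, 1]")
  Dc <- required_dose(fit_combo, fa)
  iai <- (Dc * r1) / required_dose(fit_drug1, fa) +
    (Dc * (1 - r1)) / required_dose(fit_drug2, fa)
  structure(list(iai = iai, fa = fa, r1 = r1, r2 = 1 - r1,
                 label = synergy_label(iai, band)),
            class = "combination_result")
}

#' Synergy call for an interaction index
#'
#' Partition of (0, Inf): `additive` iff |iai - 1| <= band (boundaries
#' inclusive), `synergism` below, `antagonism` above.
#' @param iai interaction index value(s), > 0.
#' @param band additive half-width (default 0.05).
#' @return character label(s).
#' @export
synergy_label <- function(iai, band = 0.05) {
  if (any(iai <= 0)) stop("interaction index must be > 0")
  # small float slack so the printed band edges 0.95 / 1.05 land inside
  ifelse(abs(iai - 1) <= band + 1e-12, "additive",
         ifelse(iai < 1, "synergism", "antagonism"))
}

#' @export
print.combination_result <- function(x, ...) {
  cat(sprintf("combination_result: IAI=%.4f at fa=%.2f (ratio %.2f:%.2f) -> %s\n",
              x$iai, x$fa, x$r1, x$r2, x$label))
  invisible(x)
}

#' Relative IC50 percentiles across cell lines
#'
#' Percentile (0-100) of each cell line's IC50 across all lines tested,
#' computed on ascending log10(IC50): `100 * (rank - 1) / (n - 1)`, ties
#' receiving the mean of their ranks.
#'
#' @param ic50 named vector of IC50 values (> 0), one per cell line.
#' @return named percentile vector.
#' @export
relative_ic50_percentiles <- function(ic50) {
  if (length(ic50) < 2L) stop("need >= 2 cell lines")
  r <- rank(log10(ic50), ties.method = "average")
  100 * (r - 1) / (length(ic50) - 1)
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Rank-sum statistic of the first group, with the p-value computed by
#' full enumeration of group assignments when the total n is <= 10 and no
#' ties are present, and by the normal approximation with tie correction
#' otherwise. Two-sided p doubles the smaller tail (capped at 1).
#'
#' @param values numeric outcomes (e.g. IC50 percentiles).
#' @param groups two-level group labels aligned with `values`.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (tail of the first group's rank sum).
#' @return list of class `wilcoxon_result`: `statistic` (rank sum of the
#'   first level), `p_value`, `method`.
#' @export
compare_groups_wilcoxon <- function(values, groups,
                                    alternative = c("two.sided", "less",
                                                    "greater")) {
  alternative <- match.arg(alternative)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  n1 <- sum(groups == levels(groups)[1])
  n2 <- sum(groups == levels(groups)[2])
  if (n1 < 1L || n2 < 1L) stop("empty group")
  r <- rank(values, ties.method = "average")
  w <- sum(r[groups == levels(groups)[1]])
  n <- n1 + n2

  if (n <= 10L && !anyDuplicated(values)) {
    sums <- apply(utils::combn(n, n1), 2, function(ix) sum(r[ix]))
    p_le <- mean(sums <= w); p_ge <- mean(sums >= w)
    method <- "exact enumeration"
  } else {
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) {                 # every value tied: no evidence either way
      p_le <- p_ge <- 1
    } else {
      z <- (w - mu) / sqrt(sig2)
      p_le <- stats::pnorm(z); p_ge <- stats::pnorm(z, lower.tail = FALSE)
    }
    method <- "normal approximation with tie correction"
  }
  p <- switch(alternative,
              less = p_le, greater = p_ge,
              two.sided = min(1, 2 * min(p_le, p_ge)))
  structure(list(statistic = w, p_value = p, method = method,
                 n = c(n1 = n1, n2 = n2), alternative = alternative),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("wilcoxon_result: W=%g p=%.4g (%s, %s)\n",
              x$statistic, x$p_value, x$method, x$alternative))
  invisible(x)
}
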