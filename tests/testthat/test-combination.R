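test_that("viability normalization divides by the control mean", {
  dr <- normalize_viability(c(100, 55, 0), c(100, 120), doses = c(1, 2, 4))
  expect_equal(dr$viability, c(100, 55, 0) / 110)
  expect_equal(normalize_viability(110, c(100, 120), 1)$viability, 1.0)
  expect_equal(normalize_viability(0, c(100, 120), 1)$viability, 0)
  expect_error(normalize_viability(1, numeric(0), 1), "control")
  expect_error(normalize_viability(1, c(-2, 2), 1), "non-positive")
})

test_that("median-effect fit recovers exact parameters", {
  doses <- 0.0625 * 2^(0:7)
  fit <- fit_median_effect(generate_dose_response(1.2, 0.5, doses, 0))
  expect_equal(fit$m, 1.2, tolerance = 1e-10)
  expect_equal(fit$Dm, 0.5, tolerance = 1e-10)
  expect_equal(fit$log10_ic50, log10(0.5), tolerance = 1e-10)
  expect_equal(fit$n_points_used, 8L)

  # fa = 0.5 observed exactly at dose 2 with slope 2 -> Dm = 2
  fit2 <- fit_median_effect(generate_dose_response(2, 2, c(1, 2, 4), 0))
  expect_equal(fit2$Dm, 2, tolerance = 1e-10)

  # closed-form two-point check of the median-effect line
  dd <- c(0.25, 16)
  dr <- generate_dose_response(1.5, 0.7, dd, 0)
  f3 <- fit_median_effect(dr)
  y <- log10((1 - dr$viability) / dr$viability)
  x <- log10(dd)
  slope <- diff(y) / diff(x)
  intercept <- y[1] - slope * x[1]
  expect_equal(f3$m, slope, tolerance = 1e-12)
  expect_equal(f3$Dm, 10^(-intercept / slope), tolerance = 1e-12)

  # clipping: saturated points are excluded and counted
  dr4 <- generate_dose_response(2, 1, c(1e-4, 0.5, 1, 2, 1e4), 0)
  f4 <- fit_median_effect(dr4, fa_clip = 0.005)
  expect_equal(f4$n_points_used, 3L)
  expect_equal(f4$n_points_clipped, 2L)
  expect_error(fit_median_effect(
    generate_dose_response(2, 1, c(1e-6, 1e6), 0)), "fewer than 2")
  # inverted response is flagged, not fatal
  inv <- dose_response("inv", c(1, 2, 4), c(0.2, 0.5, 0.8))
  expect_warning(f5 <- fit_median_effect(inv), "non-monotone")
  expect_false(f5$monotone)
})

test_that("sham self-combination is exactly additive", {
  doses <- 0.0625 * 2^(0:7)
  f <- fit_median_effect(generate_dose_response(1.2, 0.5, doses, 0))
  ci <- interaction_index(f, f, f, r1 = 0.5, fa = 0.5)
  expect_equal(ci$iai, 1, tolerance = 1e-10)
  expect_equal(ci$label, "additive")
  expect_error(interaction_index(f, f, f, fa = 1), "fa must")
})

test_that("a numerically constructed Loewe-additive mixture scores IAI ~ 1", {
  # half-log series bracketing the mixture IC50 keeps points in the
  # informative effect range
  doses <- 0.8 * 2^seq(-1.75, 1.75, by = 0.5)
  f1 <- fit_median_effect(generate_dose_response(1.2, 0.5, doses, 0))
  f2 <- fit_median_effect(generate_dose_response(1.8, 2.0, doses, 0))
  fc <- fit_median_effect(
    generate_additive_combination(1.2, 0.5, 1.8, 2.0, doses, r1 = 0.5))
  ci <- interaction_index(f1, f2, fc, r1 = 0.5, fa = 0.5)
  expect_equal(ci$iai, 1, tolerance = 0.02)

  # ratio symmetry: swapping drugs and the ratio leaves IAI unchanged
  ci_sw <- interaction_index(f2, f1, fc, r1 = 0.5, fa = 0.5)
  expect_equal(ci_sw$iai, ci$iai, tolerance = 1e-12)

  # common dose rescaling leaves IAI unchanged (unit invariance)
  scale_fit <- function(f, k) { f$Dm <- f$Dm * k; f$ic50 <- f$Dm; f }
  ci_sc <- interaction_index(scale_fit(f1, 10), scale_fit(f2, 10),
                             scale_fit(fc, 10), r1 = 0.5, fa = 0.5)
  expect_equal(ci_sc$iai, ci$iai, tolerance = 1e-12)
})

test_that("synergy labels partition (0, Inf) with inclusive 0.95/1.05", {
  expect_equal(synergy_label(c(0.94, 0.95, 1, 1.05, 1.06)),
               c("synergism", "additive", "additive", "additive",
                 "antagonism"))
  expect_equal(synergy_label(0.90), "synergism")
  iai <- seq(0.01, 3, by = 0.001)
  lab <- synergy_label(iai)
  expect_true(all(lab %in% c("synergism", "additive", "antagonism")))
  expect_error(synergy_label(-1), "> 0")
})

test_that("relative IC50 percentiles follow the rank formula", {
  x <- c(a = 10, b = 1, c = 100, d = 1000, e = 0.1)
  pct <- relative_ic50_percentiles(x)
  expect_equal(unname(pct[order(x)]), c(0, 25, 50, 75, 100))
  expect_equal(unname(pct["e"]), 0)
  expect_equal(unname(pct["d"]), 100)
  # two tied middle values of four share the mean rank -> both 50
  tie <- relative_ic50_percentiles(c(1, 5, 5, 9))
  expect_equal(unname(tie), c(0, 50, 50, 100))
  expect_error(relative_ic50_percentiles(3), ">= 2")
})

test_that("Wilcoxon rank-sum: exact enumeration and approximation", {
  r <- compare_groups_wilcoxon(c(1, 2, 3, 4), c("g1", "g1", "g2", "g2"),
                               alternative = "less")
  expect_equal(r$p_value, 1 / 6)      # 4!/(2!2!) = 6 assignments
  expect_equal(r$method, "exact enumeration")
  r2 <- compare_groups_wilcoxon(c(1, 2, 3, 4), c("g1", "g1", "g2", "g2"))
  expect_equal(r2$p_value, 1 / 3)

  # identical single-element groups carry no evidence
  expect_equal(compare_groups_wilcoxon(c(5, 5), c("a", "b"))$p_value, 1)

  # label permutation symmetry
  set.seed(17)
  x <- rnorm(8); g <- rep(c("A", "B"), each = 4)
  pa <- compare_groups_wilcoxon(x, g)$p_value
  pb <- compare_groups_wilcoxon(x, rev(g))$p_value
  expect_equal(pa, pb, tolerance = 1e-12)

  # large / tied samples agree with the reference implementation
  set.seed(18)
  y <- round(rnorm(30), 1)
  gy <- rep(c("A", "B"), c(14, 16))
  ours <- compare_groups_wilcoxon(y, gy)
  ref <- wilcox.test(y[gy == "A"], y[gy == "B"], exact = FALSE,
                     correct = FALSE)
  expect_equal(ours$method, "normal approximation with tie correction")
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  expect_error(compare_groups_wilcoxon(1:3, c("a", "a", "a")), "two groups")
})
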