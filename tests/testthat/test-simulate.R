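test_that("slide generator honours the logistic model and its limits", {
  cfg <- noise_free_config(seed = 7)

  # saturation: far above the dynamic range every step reads alpha + beta
  sl <- generate_slide(cfg, c(hi = 25))
  expect_true(all(abs(sl$intensity - (cfg$slide_alpha + cfg$slide_beta)) <
                    1e-3 * cfg$slide_beta))

  # dilution shift identity: x + 1 at step j + 1 equals x at step j
  sl2 <- generate_slide(cfg, c(a = 1, b = 2))
  ia <- sl2[sl2$sample_id == "a", ]
  ib <- sl2[sl2$sample_id == "b", ]
  for (j in 0:3)
    expect_equal(ib$intensity[ib$dilution_step == j + 1],
                 ia$intensity[ia$dilution_step == j])

  # rejected inputs
  expect_error(generate_slide(cfg, c(a = NaN, b = 1)), "finite")
  expect_error(generate_slide(cfg, c(1, 2)), "named")
})

test_that("generators are deterministic given the config seed", {
  cfg <- simulation_config(seed = 7, slide_noise_sd = 10)
  tr <- c(a = 0, b = 1, c = 2)
  expect_identical(generate_slide(cfg, tr), generate_slide(cfg, tr))
  expect_identical(generate_cohort_matrix(cfg), generate_cohort_matrix(cfg))
  expect_identical(generate_growth_curves(cfg), generate_growth_curves(cfg))
  expect_identical(generate_dose_response(1.2, 0.5, c(1, 2), 0.05, seed = 3),
                   generate_dose_response(1.2, 0.5, c(1, 2), 0.05, seed = 3))
  # and a different seed changes the draw
  cfg2 <- simulation_config(seed = 8, slide_noise_sd = 10)
  expect_false(identical(generate_slide(cfg2, tr)$intensity,
                         generate_slide(cfg, tr)$intensity))
})

test_that("cohort matrix plants the advertised log2 shifts", {
  cfg <- simulation_config(seed = 11)
  em <- generate_cohort_matrix(cfg)
  truth <- attr(em, "truth")
  # signed-fold convention: the printed fold-changes 1.64 (Keap1) and
  # -3.41 (TTF-1) become log2 shifts of +-log2(|fold|)
  expect_equal(unname(truth["Keap1"]), log2(1.64), tolerance = 1e-12)
  expect_equal(unname(truth["TTF-1"]), -log2(3.41), tolerance = 1e-12)
  expect_equal(unname(truth["Keap1"]), 0.714, tolerance = 1e-3)
  expect_equal(unname(truth["TTF-1"]), -1.770, tolerance = 1e-3)

  # noise-free fold +2: every SCC value exceeds every non-SCC by exactly 1
  cfg0 <- simulation_config(seed = 2, protein_noise_sd = 0,
                            effect_table = data.frame(protein = "P1", fold = 2),
                            n_scc = 5, n_nonscc = 7, duplicate_fraction = 0)
  em0 <- generate_cohort_matrix(cfg0)
  scc <- em0$values[1, em0$histology == "SCC"]
  non <- em0$values[1, em0$histology == "non-SCC"]
  expect_true(all(abs(outer(scc, non, `-`) - 1) < 1e-12))

  # |fold| < 1 violates the signed-fold convention
  expect_error(simulation_config(
    effect_table = data.frame(protein = "bad", fold = 0.5)), "fold")
})

test_that("planted shifts are recovered empirically within 3 sd / sqrt(n)", {
  cfg <- simulation_config(seed = 5, n_scc = 60, n_nonscc = 60,
                           duplicate_fraction = 0)
  em <- generate_cohort_matrix(cfg)
  truth <- attr(em, "truth")
  scc <- em$histology == "SCC"
  dif <- rowMeans(em$values[, scc]) - rowMeans(em$values[, !scc])
  tol <- 3 * cfg$protein_noise_sd / sqrt(60)
  expect_true(all(abs(dif - truth[names(dif)]) < tol * sqrt(2)))
})

test_that("duplicates share a base id and appear with independent noise", {
  cfg <- simulation_config(seed = 9, n_scc = 20, n_nonscc = 80,
                           duplicate_fraction = 0.10)
  em <- generate_cohort_matrix(cfg)
  expect_equal(ncol(em$values), 110)                 # 100 base + 10 dups
  expect_equal(length(unique(em$base_sample)), 100)
  dup_cols <- names(em$base_sample)[duplicated(em$base_sample)]
  for (dc in dup_cols) {
    mate <- setdiff(names(em$base_sample)[em$base_sample ==
                                            em$base_sample[dc]], dc)
    expect_false(identical(em$values[, dc], em$values[, mate]))
    expect_identical(unname(em$histology[dc]), unname(em$histology[mate]))
  }
})

test_that("dose-response generator follows the median-effect law", {
  # fa = 0.5 at the median-effect dose, any slope
  for (m in c(0.5, 1, 3)) {
    dr <- generate_dose_response(m, Dm = 2, doses = 2, noise_sd = 0)
    expect_equal(dr$viability, 0.5, tolerance = 1e-12)
  }
  # closed form: m = 1, Dm = 1, D = 3 -> fa = 1 / (1 + 1/3) = 0.75
  dr <- generate_dose_response(1, 1, doses = 3, noise_sd = 0)
  expect_equal(1 - dr$viability, 0.75, tolerance = 1e-12)
  expect_error(generate_dose_response(1, 1, doses = c(1, -2)), "positive")
  expect_error(generate_dose_response(-1, 1, doses = 1), "m must")
})

test_that("growth generator: deterministic means, floored volumes", {
  cfg <- simulation_config(seed = 3, growth_sigma = 0)
  gd <- generate_growth_curves(cfg)
  # sigma = 0: all mice in a group share the trajectory
  for (g in unique(gd$group)) {
    sub <- gd[gd$group == g, ]
    traj <- split(sub$volume, sub$mouse)
    for (tr in traj[-1]) expect_equal(tr, traj[[1]])
  }
  # flat slopes from the 200 mm3 randomization volume
  cfg0 <- simulation_config(seed = 3, growth_sigma = 0,
                            growth_slopes = c(a = 0, b = 0))
  expect_true(all(generate_growth_curves(cfg0)$volume == 200))
  expect_error(simulation_config(growth_rho = 1), "rho")
})

test_that("growth residual correlation matches the requested structure", {
  # AR(1): empirical lag-1 correlation within 0.02 at 10,000 mice
  cfg <- simulation_config(seed = 21, growth_structure = "ar1",
                           growth_rho = 0.6, growth_sigma = 30,
                           growth_slopes = c(g1 = 10, g2 = 10, g3 = 10,
                                             g4 = 10),
                           growth_n_per_group = 2500)
  gd <- generate_growth_curves(cfg)
  days <- sort(unique(gd$day))
  resid <- matrix(gd$volume - (200 + 10 * gd$day), ncol = length(days),
                  byrow = TRUE)
  lag1 <- mean(diag(cor(resid)[-1, -ncol(resid)]))
  expect_equal(lag1, 0.6, tolerance = 0.02)

  # rho = 0 under CS behaves as independence
  cfg0 <- simulation_config(seed = 22, growth_structure = "compound_symmetry",
                            growth_rho = 0, growth_sigma = 30,
                            growth_slopes = c(g1 = 10, g2 = 10, g3 = 10,
                                              g4 = 10),
                            growth_n_per_group = 2500)
  gd0 <- generate_growth_curves(cfg0)
  resid0 <- matrix(gd0$volume - (200 + 10 * gd0$day), ncol = length(days),
                   byrow = TRUE)
  off <- cor(resid0)[upper.tri(diag(length(days)))]
  expect_true(max(abs(off)) < 0.04)
})
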