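# hand-coded pooled-variance two-sample t oracle
pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tt, p = 2 * pt(-abs(tt), n1 + n2 - 2))
}

two_group_fixture <- function(seed = 1, n1 = 4, n2 = 5, nprot = 3) {
  set.seed(seed)
  v <- matrix(rnorm(nprot * (n1 + n2)), nprot,
              dimnames = list(paste0("p", seq_len(nprot)),
                              paste0("s", seq_len(n1 + n2))))
  hist <- setNames(c(rep("SCC", n1), rep("non-SCC", n2)), colnames(v))
  tiny_matrix(v, histology = hist)
}

test_that("two_group_test matches the pooled-t oracle and conventions", {
  em <- two_group_fixture(seed = 42)
  res <- two_group_test(em)
  for (i in 1:3) {
    a <- em$values[i, em$histology == "SCC"]
    b <- em$values[i, em$histology == "non-SCC"]
    o <- pooled_t(a, b)
    expect_equal(res$t_statistic[i], o$t, tolerance = 1e-12)
    expect_equal(res$p_value[i], o$p, tolerance = 1e-12)
    expect_equal(res$degrees_of_freedom[i], 7)
  }
  # near-separated groups: huge |t|, tiny p, exact against the oracle
  set.seed(9)
  v <- matrix(c(rep(0, 4), rep(1, 4)) + rnorm(8, 0, 1e-6), nrow = 1,
              dimnames = list("p", paste0("s", 1:8)))
  hist <- setNames(c(rep("SCC", 4), rep("non-SCC", 4)), colnames(v))
  r1 <- two_group_test(tiny_matrix(v, histology = hist))
  o <- pooled_t(v[1, 1:4], v[1, 5:8])
  expect_equal(r1$t_statistic, o$t, tolerance = 1e-10)
  expect_lt(r1$p_value, 1e-6)
})

test_that("fold-change sign convention reproduces the table semantics", {
  expect_equal(signed_fold(0), 1)
  expect_equal(signed_fold(1), 2)
  # a 3.41-fold drop prints as -3.41
  expect_equal(round(signed_fold(-1.770), 2), -3.41)
  expect_equal(signed_fold(-log2(3.41)), -3.41, tolerance = 1e-12)
  # identical groups: t = 0, p = 1, fold = +1
  v <- matrix(rep(c(1, 2, 3, 1, 2, 3), each = 1), nrow = 1, byrow = TRUE,
              dimnames = list("p", paste0("s", 1:6)))
  hist <- setNames(rep(c("SCC", "non-SCC"), each = 3), colnames(v))
  v[1, 4:6] <- v[1, 1:3]
  r <- two_group_test(tiny_matrix(v, histology = hist))
  expect_equal(r$t_statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$fold_change_signed, 1)
})

test_that("label swap antisymmetry: t and delta negate, p unchanged", {
  em <- two_group_fixture(seed = 7, n1 = 5, n2 = 6, nprot = 4)
  r12 <- two_group_test(em)
  r21 <- two_group_test(em, group1 = "non-SCC", group2 = "SCC")
  expect_equal(r21$t_statistic, -r12$t_statistic, tolerance = 1e-12)
  expect_equal(r21$delta_log2, -r12$delta_log2, tolerance = 1e-12)
  expect_equal(r21$p_value, r12$p_value, tolerance = 1e-12)
  expect_equal(sign(r21$fold_change_signed), -sign(r12$fold_change_signed))
})

test_that("proteins with too few usable samples are dropped, not fatal", {
  em <- two_group_fixture(seed = 3, n1 = 3, n2 = 3, nprot = 2)
  em$values[2, em$histology == "SCC"][2:3] <- NA
  r <- two_group_test(em)
  expect_equal(r$protein, "p1")
  expect_equal(attr(r, "dropped"), "p2")
})

test_that("BUM density is a proper density and lambda = 1 is uniform", {
  set.seed(2)
  for (i in 1:20) {
    lambda <- runif(1); a <- runif(1)
    f <- function(p) rppaflow:::bum_density(p, lambda, a)
    expect_equal(integrate(f, 0, 1, rel.tol = 1e-11)$value, 1,
                 tolerance = 1e-9)
  }
  p <- runif(50)
  expect_equal(rppaflow:::bum_loglik(p, 1, 0.5), 0)
})

test_that("BUM fit: uniform p-values give pi0_upper near 1", {
  set.seed(11)
  fit <- fit_bum(runif(5000))
  expect_gte(fit$pi0_upper, 0.95)
  expect_error(fit_bum(c(0, runif(20))), "\\(0, 1\\]")
  expect_error(fit_bum(runif(5)), ">= 10")
})

test_that("BUM fit matches a dense grid-search ML oracle within 0.05", {
  set.seed(12)
  p <- c(runif(4000), rbeta(1000, 0.3, 1))
  fit <- fit_bum(p)
  # 200 x 200 grid oracle over (lambda, a)
  lam_grid <- seq(0.0025, 0.9975, length.out = 200)
  a_grid <- seq(0.0025, 0.9975, length.out = 200)
  pe <- pmin(p, 1 - 1e-12)
  best <- c(-Inf, NA, NA)
  for (a in a_grid) {
    t_i <- a * pe^(a - 1)
    ll <- vapply(lam_grid, function(l) sum(log(l + (1 - l) * t_i)),
                 numeric(1))
    j <- which.max(ll)
    if (ll[j] > best[1]) best <- c(ll[j], lam_grid[j], a)
  }
  expect_lt(abs(fit$lambda_mix - best[2]), 0.05)
  expect_lt(abs(fit$a_shape - best[3]), 0.05)
  expect_gte(fit$log_likelihood, best[1] - 1e-6)
})

test_that("FDR cutoff: algebraic identities, bisection vs grid scan", {
  fit <- structure(list(lambda_mix = 0.8, a_shape = 0.3,
                        pi0_upper = 0.8 + 0.2 * 0.3),
                   class = "bum_fit")
  expect_equal(bum_fdr(fit, 1), fit$pi0_upper, tolerance = 1e-12)
  # monotone non-decreasing in tau for a < 1
  taus <- seq(1e-6, 1, length.out = 1000)
  expect_true(all(diff(bum_fdr(fit, taus)) >= -1e-12))

  dec <- fdr_cutoff(fit, 0.01)
  grid <- seq(1e-9, 1, length.out = 1e6)
  tau_grid <- max(grid[bum_fdr(fit, grid) <= 0.01])
  expect_lt(abs(dec$tau_cutoff - tau_grid), 1.1e-6)   # grid spacing ~1e-6

  # pure null: FDR(tau) = 1 everywhere, nothing called
  null_fit <- structure(list(lambda_mix = 1, a_shape = 0.5, pi0_upper = 1),
                        class = "bum_fit")
  d0 <- fdr_cutoff(null_fit, 0.01, p_values = runif(100))
  expect_equal(d0$tau_cutoff, 0)
  expect_equal(d0$n_significant, 0L)
  expect_error(fdr_cutoff(fit, 1.5), "nominal_q")
})

test_that("select_top filters, orders, and has the promised power", {
  res <- data.frame(protein = c("b", "a", "c"),
                    p_value = c(0.04, 0.01, 0.06))
  expect_equal(select_top(res, 0.05), c("a", "b"))
  expect_equal(select_top(data.frame(protein = "x", p_value = 0.5), 0.05),
               character(0))
  # ties break by name
  res2 <- data.frame(protein = c("z", "y"), p_value = c(0.01, 0.01))
  expect_equal(select_top(res2, 0.05), c("y", "z"))

  # power: 30 planted effects at fold 1.5 among 200 proteins, 34 vs 106
  set.seed(19)
  nprot <- 200; n1 <- 34; n2 <- 106
  planted <- paste0("p", 1:30)
  v <- matrix(rnorm(nprot * (n1 + n2), 0, 0.5), nprot,
              dimnames = list(paste0("p", 1:nprot),
                              paste0("s", 1:(n1 + n2))))
  v[1:30, 1:n1] <- v[1:30, 1:n1] + log2(1.5)
  hist <- setNames(c(rep("SCC", n1), rep("non-SCC", n2)), colnames(v))
  hits <- select_top(two_group_test(tiny_matrix(v, histology = hist)), 0.05)
  recall <- mean(planted %in% hits)
  expect_gte(recall, 0.80)
})

test_that("hierarchical clustering is deterministic and oracle-exact", {
  # identical rows merge first at height 0
  v <- rbind(p1 = c(1, 2, 3, 4), p2 = c(1, 2, 3, 4), p3 = c(4, 3, 2, 1),
             p4 = c(1, 3, 2, 4))
  colnames(v) <- paste0("s", 1:4)
  cl <- hierarchical_cluster(tiny_matrix(v))
  expect_equal(cl$rows$height[1], 0, tolerance = 1e-12)
  expect_equal(sort(cl$rows$merge[1, ]), c(-2, -1))

  # positive rescaling of rows leaves the tree unchanged
  v2 <- v * c(2, 5, 0.1, 7)
  cl2 <- hierarchical_cluster(tiny_matrix(v2))
  expect_equal(cl2$rows$merge, cl$rows$merge)
  expect_equal(cl2$rows$height, cl$rows$height, tolerance = 1e-12)

  # 4-row fixture against the brute-force agglomeration oracle
  set.seed(23)
  m <- matrix(rnorm(4 * 6), 4, dimnames = list(paste0("p", 1:4),
                                               paste0("s", 1:6)))
  cl3 <- hierarchical_cluster(tiny_matrix(m))
  d0 <- 1 - cor(t(m)); diag(d0) <- 0
  orc <- oracle_agglomerate(d0)
  expect_equal(cl3$rows$height, orc$heights, tolerance = 1e-12)
  for (s in seq_along(orc$partitions))
    expect_identical(canon(hclust_partitions(cl3$rows)[[s]]),
                     canon(orc$partitions[[s]]))

  # zero-variance row sits at maximal distance and is reported
  v3 <- rbind(p1 = c(1, 1, 1, 1), p2 = c(1, 2, 3, 4), p3 = c(2, 1, 4, 3))
  colnames(v3) <- paste0("s", 1:4)
  cl4 <- hierarchical_cluster(tiny_matrix(v3))
  expect_true("p1" %in% cl4$zero_variance)
  expect_equal(max(cl4$rows$height), 2, tolerance = 1e-12)

  # missing values are imputed by row median, not fatal
  v4 <- v; v4[1, 2] <- NA
  expect_silent(hierarchical_cluster(tiny_matrix(v4)))
})

test_that("dendrograms are written as readable Newick", {
  v <- rbind(p1 = c(1, 2, 3, 4), p2 = c(2, 3, 4, 6), p3 = c(4, 3, 2, 1))
  colnames(v) <- paste0("s", 1:4)
  cl <- hierarchical_cluster(tiny_matrix(v))
  f <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(cl$rows, f)
  tr <- ape::read.tree(f)
  expect_setequal(tr$tip.label, c("p1", "p2", "p3"))
})
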