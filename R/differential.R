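#' Per-protein two-group comparison (SCC vs non-SCC)
#'
#' Pooled-variance two-sample t-test per protein on the log2 scale, with
#' the signed fold-change display convention used for RPPA tables: for a
#' mean log2 difference `delta` (group1 minus group2), the fold-change is
#' `2^delta` when delta >= 0 and `-2^(-delta)` otherwise, so a value of
#' -3.41 reads "3.41-fold lower in group 1". Proteins with fewer than two
#' usable samples in either group are omitted (and listed in the
#' `dropped` attribute), not an error.
#'
#' @param em an [expression_matrix()] with histology annotations (or pass
#'   `group` explicitly).
#' @param group optional named vector of group labels per sample;
#'   defaults to `em$histology`.
#' @param group1,group2 the two labels to contrast (difference is
#'   group1 - group2); default SCC vs non-SCC.
#' @param welch use the Welch (unequal-variance) test instead of the
#'   pooled-variance test.
#' @return data.frame of class `group_comparison`: `protein`,
#'   `delta_log2`, `fold_change_signed`, `t_statistic`,
#'   `degrees_of_freedom`, `p_value`.
#' @export
two_group_test <- function(em, group = NULL, group1 = "SCC",
                           group2 = "non-SCC", welch = FALSE) {
  stopifnot(inherits(em, "expression_matrix"))
  if (is.null(group)) group <- em$histology
  if (is.null(group)) stop("no group labels available")
  group <- group[colnames(em$values)]
  i1 <- which(!is.na(group) & group == group1)
  i2 <- which(!is.na(group) & group == group2)
  if (length(i1) < 2L || length(i2) < 2L)
    stop("need >= 2 samples per group")

  out <- do.call(rbind, lapply(rownames(em$values), function(p) {
    a <- stats::na.omit(em$values[p, i1])
    b <- stats::na.omit(em$values[p, i2])
    if (length(a) < 2L || length(b) < 2L) return(NULL)
    n1 <- length(a); n2 <- length(b)
    delta <- mean(a) - mean(b)
    if (welch) {
      va <- stats::var(a) / n1; vb <- stats::var(b) / n2
      se2 <- va + vb
      df <- se2^2 / (va^2 / (n1 - 1) + vb^2 / (n2 - 1))
      tt <- delta / sqrt(se2)
    } else {
      sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
        (n1 + n2 - 2)
      df <- n1 + n2 - 2
      tt <- delta / sqrt(sp2 * (1 / n1 + 1 / n2))
    }
    if (!is.finite(tt)) { tt <- 0; pv <- 1 } else
      pv <- 2 * stats::pt(-abs(tt), df)
    data.frame(protein = p, delta_log2 = delta,
               fold_change_signed = signed_fold(delta),
               t_statistic = tt, degrees_of_freedom = df, p_value = pv,
               stringsAsFactors = FALSE)
  }))
  dropped <- setdiff(rownames(em$values), out$protein)
  rownames(out) <- NULL
  class(out) <- c("group_comparison", "data.frame")
  attr(out, "dropped") <- dropped
  attr(out, "groups") <- c(group1, group2)
  out
}

#' Signed fold-change from a log2 difference
#'
#' Maps `delta = 0` to +1; magnitude is always >= 1 and the sign carries
#' the direction.
#' @param delta_log2 numeric log2 difference(s).
#' @return signed fold-change(s).
#' @export
signed_fold <- function(delta_log2)
  ifelse(delta_log2 >= 0, 2^delta_log2, -2^(-delta_log2))

# log-density and log-likelihood of the beta-uniform mixture
# f(p) = lambda + (1 - lambda) * a * p^(a - 1), 0 < a < 1
bum_density <- function(p, lambda, a)
  lambda + (1 - lambda) * a * p^(a - 1)

bum_loglik <- function(p, lambda, a) sum(log(bum_density(p, lambda, a)))

#' Fit a beta-uniform mixture (BUM) to p-values
#'
#' Models the p-value distribution as lambda * Uniform(0,1) +
#' (1 - lambda) * Beta(a, 1) with a < 1, by maximum likelihood over
#' logit-transformed coordinates with a 5 x 5 multistart grid. The uniform
#' floor of the density yields the conservative null-proportion bound
#' `pi0_upper = lambda + (1 - lambda) * a` used for FDR estimation.
#'
#' @param p p-values in (0, 1]; n >= 10. Values equal to 1 are nudged to
#'   1 - 1e-12 before taking logs.
#' @return list of class `bum_fit`: `lambda_mix`, `a_shape`, `pi0_upper`,
#'   `log_likelihood`, `n`.
#' @export
fit_bum <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  if (length(p) < 10L) stop("need >= 10 p-values")
  p <- pmin(p, 1 - 1e-12)

  nll <- function(par) {
    lambda <- stats::plogis(par[1]); a <- stats::plogis(par[2])
    -bum_loglik(p, lambda, a)
  }
  starts <- expand.grid(l = stats::qlogis(seq(0.1, 0.9, length.out = 5)),
                        a = stats::qlogis(seq(0.1, 0.9, length.out = 5)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(c(starts$l[i], starts$a[i]), nll,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 500))
    if (is.null(best) || o$value < best$value) best <- o
  }
  lambda <- stats::plogis(best$par[1]); a <- stats::plogis(best$par[2])
  structure(list(lambda_mix = lambda, a_shape = a,
                 pi0_upper = lambda + (1 - lambda) * a,
                 log_likelihood = -best$value, n = length(p)),
            class = "bum_fit")
}

#' @export
print.bum_fit <- function(x, ...) {
  cat(sprintf("bum_fit: lambda=%.4f a=%.4f pi0_upper=%.4f logLik=%.2f (n=%d)\n",
              x$lambda_mix, x$a_shape, x$pi0_upper, x$log_likelihood, x$n))
  invisible(x)
}

#' Model-based FDR estimate of a BUM fit at threshold tau
#'
#' `FDR(tau) = pi0_upper * tau / F(tau)` where `F` is the fitted mixture
#' CDF `lambda * tau + (1 - lambda) * tau^a`. At `tau = 1` this equals
#' `pi0_upper`. Non-decreasing in tau for `a < 1`.
#'
#' @param fit a [fit_bum()] result.
#' @param tau threshold(s) in (0, 1].
#' @return estimated FDR value(s).
#' @export
bum_fdr <- function(fit, tau) {
  with(fit, pi0_upper * tau / (lambda_mix * tau + (1 - lambda_mix) * tau^a_shape))
}

#' P-value cutoff achieving a nominal model-based FDR
#'
#' Finds the largest tau in (0, 1] with `bum_fdr(fit, tau) <= nominal_q`
#' by monotone bisection (the estimate is non-decreasing in tau for
#' a < 1). If no tau qualifies the cutoff is 0 and nothing is called
#' significant. Supplying the tested p-values (and protein names) fills in
#' the rejection set.
#'
#' @param fit a [fit_bum()] result.
#' @param nominal_q nominal FDR in (0, 1); the headline analyses use 0.01.
#' @param p_values optional p-values to threshold.
#' @param proteins optional names aligned with `p_values`.
#' @return list of class `fdr_decision`: `nominal_q`, `tau_cutoff`,
#'   `n_significant`, `significant`.
#' @export
fdr_cutoff <- function(fit, nominal_q, p_values = NULL, proteins = NULL) {
  stopifnot(inherits(fit, "bum_fit"))
  if (nominal_q <= 0 || nominal_q >= 1) stop("nominal_q must be in (0, 1)")
  if (fit$pi0_upper <= 0) stop("degenerate BUM fit: pi0_upper = 0")
  f <- function(tau) bum_fdr(fit, tau)
  lo <- 1e-12
  if (f(lo) > nominal_q) {
    tau <- 0
  } else if (f(1) <= nominal_q) {
    tau <- 1
  } else {
    hi <- 1
    for (i in 1:200) {             # bisection to ~1e-16 relative
      mid <- (lo + hi) / 2
      if (f(mid) <= nominal_q) lo <- mid else hi <- mid
      if (hi - lo < 1e-15) break
    }
    tau <- lo
  }
  sig <- character(0); nsig <- NA_integer_
  if (!is.null(p_values)) {
    hit <- p_values <= tau
    nsig <- sum(hit)
    sig <- if (!is.null(proteins)) proteins[hit] else character(0)
  }
  structure(list(nominal_q = nominal_q, tau_cutoff = tau,
                 n_significant = nsig, significant = sig),
            class = "fdr_decision")
}

#' @export
print.fdr_decision <- function(x, ...) {
  cat(sprintf("fdr_decision: q=%g tau=%.3g n_significant=%s\n",
              x$nominal_q, x$tau_cutoff, format(x$n_significant)))
  invisible(x)
}

#' Select top differential proteins
#'
#' Proteins with p below the threshold, ordered by ascending p with ties
#' broken by protein name.
#'
#' @param results a [two_group_test()] table.
#' @param p_threshold inclusion threshold (strict `<`); default 0.05.
#' @return character vector of protein names.
#' @export
select_top <- function(results, p_threshold = 0.05) {
  if (nrow(results) == 0L) stop("empty results")
  hit <- results[results$p_value < p_threshold, , drop = FALSE]
  hit$protein[order(hit$p_value, hit$protein)]
}

#' Agglomerative clustering of a restricted expression matrix
#'
#' Average-linkage hierarchical clustering of rows and of columns with
#' distance 1 - Pearson correlation, the common convention for RPPA
#' heatmaps. Missing values are imputed by row median first. A
#' zero-variance row or column (undefined correlation) is placed at the
#' maximum distance (2) from everything and reported. Merges are
#' deterministic: equal-distance ties go to the pair containing the lowest
#' original index.
#'
#' @param em an [expression_matrix()] (restrict to the top proteins
#'   beforehand, e.g. via [select_top()]), with >= 2 rows and columns.
#' @param linkage `"average"` (default) or `"complete"` / `"single"`.
#' @return list of class `cluster_result`: `rows` and `cols`, each an
#'   `hclust`-compatible object; `zero_variance` lists degenerate labels.
#' @export
hierarchical_cluster <- function(em, linkage = "average") {
  stopifnot(inherits(em, "expression_matrix"))
  v <- em$values
  if (nrow(v) < 2L || ncol(v) < 2L) stop("need >= 2 proteins and >= 2 samples")
  for (i in seq_len(nrow(v))) {
    mi <- is.na(v[i, ])
    if (any(mi)) v[i, mi] <- stats::median(v[i, ], na.rm = TRUE)
  }
  zv <- character(0)
  dis <- function(m) {      # rows of m are objects
    sds <- apply(m, 1, stats::sd)
    bad <- sds == 0 | !is.finite(sds)
    d <- matrix(2, nrow(m), nrow(m))
    if (any(!bad)) {
      cc <- suppressWarnings(stats::cor(t(m[!bad, , drop = FALSE])))
      d[!bad, !bad] <- 1 - cc
    }
    diag(d) <- 0
    zv <<- c(zv, rownames(m)[bad])
    d
  }
  res <- list(rows = agglomerate(dis(v), rownames(v), linkage),
              cols = agglomerate(dis(t(v)), colnames(v), linkage))
  res$zero_variance <- zv
  class(res) <- "cluster_result"
  res
}

# Deterministic agglomeration with Lance-Williams updates; returns an
# hclust-compatible object. Tie rule: smallest distance wins; among equal
# distances, the pair whose smaller member index (then larger member
# index) is lowest, indices referring to original leaf order.
agglomerate <- function(d, labels, linkage = "average") {
  n <- nrow(d)
  active <- seq_len(n)
  id <- -seq_len(n)                    # hclust convention: leaves negative
  size <- rep(1L, n)
  minleaf <- seq_len(n)                # for deterministic tie-breaking
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- NULL
    for (ai in seq_along(active)[-length(active)]) {
      for (bi in seq((ai + 1L), length(active))) {
        i <- active[ai]; j <- active[bi]
        key <- c(d[i, j], min(minleaf[i], minleaf[j]),
                 max(minleaf[i], minleaf[j]))
        if (is.null(best) ||
            key[1] < best$key[1] - 1e-12 ||
            (abs(key[1] - best$key[1]) <= 1e-12 &&
             (key[2] < best$key[2] ||
              (key[2] == best$key[2] && key[3] < best$key[3]))))
          best <- list(i = i, j = j, key = key)
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort_pair(id[i], id[j])
    height[step] <- d[i, j]
    for (k in setdiff(active, c(i, j))) {
      d[i, k] <- d[k, i] <- switch(linkage,
        average = (size[i] * d[i, k] + size[j] * d[j, k]) / (size[i] + size[j]),
        complete = max(d[i, k], d[j, k]),
        single = min(d[i, k], d[j, k]),
        stop("unknown linkage: ", linkage))
    }
    size[i] <- size[i] + size[j]
    minleaf[i] <- min(minleaf[i], minleaf[j])
    id[i] <- step
    active <- setdiff(active, j)
  }
  hc <- list(merge = merge, height = height,
             order = leaf_order(merge, n), labels = labels,
             method = linkage, dist.method = "1 - pearson",
             call = match.call())
  class(hc) <- "hclust"
  hc
}

sort_pair <- function(a, b) {
  # hclust orders singletons (negative) before clusters, else by value
  if (a < 0 && b < 0) c(min(a, b), max(a, b))
  else if (a < 0) c(a, b)
  else if (b < 0) c(b, a)
  else c(min(a, b), max(a, b))
}

leaf_order <- function(merge, n) {
  expand <- function(node)
    if (node < 0) -node
    else c(expand(merge[node, 1]), expand(merge[node, 2]))
  expand(nrow(merge))
}

#' Write a clustering tree in Newick format
#'
#' @param hc an `hclust`-compatible object (e.g. `$rows` of
#'   [hierarchical_cluster()]).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
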