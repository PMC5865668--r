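# shared fixture builders; everything is generated in code, nothing stored

noise_free_config <- function(seed = 1L, ...)
  simulation_config(seed = seed, slide_noise_sd = 0, protein_noise_sd = 0,
                    ...)

# small expression matrix with explicit values (proteins x samples)
tiny_matrix <- function(values, histology = NULL, base = NULL) {
  expression_matrix(values, histology = histology, base_sample = base)
}

# a well-spread random slide: truth centered on the middle dilution step
random_slide <- function(seed, n_samples = 5, noise_sd = 25,
                         gamma = 1, beta = 1000) {
  set.seed(seed)
  truth <- stats::setNames(rnorm(n_samples, 2, 1),
                           sprintf("S%02d", seq_len(n_samples)))
  cfg <- simulation_config(seed = seed + 1000L, slide_noise_sd = noise_sd,
                           slide_gamma = gamma, slide_beta = beta)
  list(slide = generate_slide(cfg, truth), truth = truth)
}

# brute-force average-linkage agglomeration oracle: keeps explicit member
# lists and recomputes the mean pairwise original distance at every step
oracle_agglomerate <- function(d0) {
  n <- nrow(d0)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in seq((i + 1L), length(clusters))) {
        dd <- mean(d0[clusters[[i]], clusters[[j]]])
        key <- c(dd, min(clusters[[i]], clusters[[j]]),
                 max(min(clusters[[i]]), min(clusters[[j]])))
        if (is.null(best) || dd < best$d - 1e-12 ||
            (abs(dd - best$d) <= 1e-12 &&
             min(unlist(clusters[c(i, j)])) <
               min(unlist(clusters[c(best$i, best$j)]))))
          best <- list(i = i, j = j, d = dd)
      }
    }
    heights <- c(heights, best$d)
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    clusters[[best$i]] <- merged
    clusters[[best$j]] <- NULL
    partitions[[length(partitions) + 1L]] <-
      lapply(clusters, sort)
  }
  list(heights = heights, partitions = partitions)
}

# partition of leaves after each merge step of an hclust object
hclust_partitions <- function(hc) {
  n <- nrow(hc$merge) + 1L
  members <- as.list(seq_len(n))
  clusters <- lapply(seq_len(n), identity)
  alive <- rep(TRUE, n)
  node <- vector("list", nrow(hc$merge))
  out <- list()
  for (s in seq_len(nrow(hc$merge))) {
    get_m <- function(id) if (id < 0) -id else node[[id]]
    m <- sort(c(get_m(hc$merge[s, 1]), get_m(hc$merge[s, 2])))
    node[[s]] <- m
    # rebuild current partition: maximal formed clusters
    formed <- node[seq_len(s)]
    leaves_in <- unlist(formed[!vapply(seq_len(s), function(k)
      any(vapply(seq_len(s)[-k], function(j)
        all(node[[k]] %in% node[[j]]), logical(1))), logical(1))])
    tops <- formed[!vapply(seq_len(s), function(k)
      any(vapply(seq_len(s)[-k], function(j)
        all(node[[k]] %in% node[[j]]), logical(1))), logical(1))]
    singletons <- setdiff(seq_len(n), unlist(tops))
    out[[s]] <- lapply(c(tops, as.list(singletons)), sort)
  }
  out
}

# canonical form of a partition for set comparison
canon <- function(part) {
  part <- lapply(part, sort)
  part[order(vapply(part, `[`, numeric(1), 1))]
}
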