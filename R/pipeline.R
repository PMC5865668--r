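#' Construct a Loewe-additive fixed-ratio combination curve
#'
#' Builds the dose-response of a hypothetical combination that is exactly
#' additive in the Loewe sense: at total dose D split d1 = r1 D,
#' d2 = (1 - r1) D, the affected fraction solves the isobole equation
#' d1 / D1(fa) + d2 / D2(fa) = 1 with Di(fa) the single-agent
#' median-effect dose requirements. Used by the generator (and as an
#' independent numerical oracle: a correct interaction index on this curve
#' is 1).
#'
#' @param m1,Dm1,m2,Dm2 single-agent median-effect parameters (> 0).
#' @param doses total-dose grid (> 0).
#' @param r1 dose fraction of component 1 (default 0.5).
#' @param noise_sd viability noise sd; `seed` its RNG seed.
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @param label combination label.
#' @return a [dose_response()] with the `ratio` attribute set.
#' @export
generate_additive_combination <- function(m1, Dm1, m2, Dm2, doses, r1 = 0.5,
                                          noise_sd = 0, seed = 1L,
                                          label = "combo") {
  if (any(c(m1, Dm1, m2, Dm2) <= 0)) stop("median-effect parameters must be > 0")
  if (any(doses <= 0)) stop("doses must be strictly positive")
  D1 <- function(fa) Dm1 * (fa / (1 - fa))^(1 / m1)
  D2 <- function(fa) Dm2 * (fa / (1 - fa))^(1 / m2)
  fa <- vapply(doses, function(D) {
    g <- function(f) r1 * D / D1(f) + (1 - r1) * D / D2(f) - 1
    stats::uniroot(g, c(1e-12, 1 - 1e-12), tol = 1e-14)$root
  }, numeric(1))
  viability <- 1 - fa
  if (noise_sd > 0)
    viability <- pmin(pmax(viability +
      with_seed(seed, stats::rnorm(length(doses), 0, noise_sd)), 0), 1.2)
  dose_response(label = label, doses = doses, viability = viability,
                ratio = r1)
}

log_msg <- function(quiet, ...) if (!quiet) message("[rppaflow] ", ...)

#' Run the full simulated pipeline
#'
#' Generates every input with [simulation_config()] ground truth, then
#' runs quantification, normalization, differential expression with BUM
#' FDR control, combination scoring and growth modelling, writing all
#' artifacts (plain TSV, Newick for dendrograms) under `out_dir`.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if needed).
#' @param nominal_q FDR level for the differential stage (default 0.01).
#' @param p_threshold top-hit threshold (default 0.05).
#' @param fa effect level for interaction indices (default 0.5).
#' @param evaluation_day day for the growth contrasts (default 21).
#' @param quiet suppress progress messages.
#' @return invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config, out_dir, nominal_q = 0.01,
                         p_threshold = 0.05, fa = 0.5, evaluation_day = 21,
                         quiet = FALSE) {
  validate_simulation_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  log_msg(quiet, "R ", as.character(getRversion()), ", rppaflow ",
          as.character(utils::packageVersion("rppaflow")),
          ", seed ", config$seed)

  # -- simulate ------------------------------------------------------------
  em_true <- generate_cohort_matrix(config)
  truth <- attr(em_true, "truth")
  slides <- lapply(seq_len(nrow(em_true$values)), function(i) {
    p <- rownames(em_true$values)[i]
    generate_slide(replace_seed(config, config$seed + i),
                   truth = em_true$values[i, ], antibody = p)
  })
  write_slide_tsv(slides, pth("slides.tsv"))
  write_matrix_tsv(em_true, pth("matrix.tsv"))
  utils::write.table(data.frame(protein = names(truth), shift_log2 = truth),
                     pth("matrix.truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  log_msg(quiet, "simulated ", length(slides), " slides, ",
          ncol(em_true$values), " sample columns")

  plates <- list(
    generate_dose_response(1.2, 0.5, config$dose_grid, noise_sd = 0.02,
                           seed = config$seed + 101L, label = "drugA"),
    generate_dose_response(1.8, 2.0, config$dose_grid, noise_sd = 0.02,
                           seed = config$seed + 102L, label = "drugB"),
    generate_additive_combination(1.2, 0.5, 1.8, 2.0, config$dose_grid,
                                  noise_sd = 0.02, seed = config$seed + 103L,
                                  label = "drugA+drugB"))
  write_plate_tsv(plates, pth("plates.tsv"))
  growth <- generate_growth_curves(config)
  write_growth_tsv(growth, pth("growth.tsv"))

  # -- quantify ------------------------------------------------------------
  em_hat <- quantify_slides(slides)
  # histology travels with the sample ids from the generated cohort
  em_hat <- expression_matrix(em_hat$values,
                              histology = em_true$histology,
                              base_sample = em_true$base_sample)
  write_matrix_tsv(em_hat, pth("quantified.tsv"))

  # -- normalize -----------------------------------------------------------
  em_norm <- normalize_matrix(em_hat)
  write_matrix_tsv(em_norm, pth("normalized.tsv"))
  log_msg(quiet, "normalized matrix: ", nrow(em_norm$values), " x ",
          ncol(em_norm$values))

  # -- differential --------------------------------------------------------
  res <- two_group_test(em_norm)
  bum <- fit_bum(res$p_value)
  dec <- fdr_cutoff(bum, nominal_q, p_values = res$p_value,
                    proteins = res$protein)
  res$significant_at_fdr <- res$p_value <= dec$tau_cutoff
  utils::write.table(res, pth("differential.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  top <- select_top(res, p_threshold)
  if (length(top) >= 2L && ncol(em_norm$values) >= 2L) {
    cl <- hierarchical_cluster(
      expression_matrix(em_norm$values[top, , drop = FALSE]))
    write_dendrogram_newick(cl$rows, pth("proteins.nwk"))
    write_dendrogram_newick(cl$cols, pth("samples.nwk"))
  }
  log_msg(quiet, length(top), " proteins at p < ", p_threshold, "; ",
          dec$n_significant, " significant at FDR ", nominal_q)

  # -- combination ---------------------------------------------------------
  combo_report <- combination_report(read_plate_tsv(pth("plates.tsv")),
                                     fa = fa)
  utils::write.table(combo_report, pth("combination.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # -- growth --------------------------------------------------------------
  gfit <- select_structure(growth)
  contrasts <- tukey_hsd(gfit, evaluation_day)
  utils::write.table(attr(gfit, "aic_table"), pth("growth.aic.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(contrasts, pth("growth.contrasts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_msg(quiet, "growth structure: ", gfit$structure, " (AIC ",
          sprintf("%.1f", gfit$aic), ")")

  invisible(list(slides = pth("slides.tsv"), matrix = pth("matrix.tsv"),
                 quantified = pth("quantified.tsv"),
                 normalized = pth("normalized.tsv"),
                 differential = pth("differential.tsv"),
                 combination = pth("combination.tsv"),
                 growth_aic = pth("growth.aic.tsv"),
                 growth_contrasts = pth("growth.contrasts.tsv")))
}

replace_seed <- function(config, seed) {
  config$seed <- as.integer(seed %% .Machine$integer.max)
  config
}

#' Median-effect and interaction report for a set of plates
#'
#' Fits every dose-response series; labels of the form `"A+B"` are treated
#' as fixed-ratio combinations of the series labelled `A` and `B` and get
#' an interaction index and synergy call at effect level `fa`.
#'
#' @param plates named list of [dose_response()] (e.g. [read_plate_tsv()]).
#' @param fa effect level (default 0.5).
#' @return data.frame: label, m, Dm, log10_ic50, r_squared, iai, synergy.
#' @export
combination_report <- function(plates, fa = 0.5) {
  fits <- lapply(plates, fit_median_effect)
  names(fits) <- vapply(fits, `[[`, character(1), "label")
  rows <- lapply(names(fits), function(lb) {
    f <- fits[[lb]]
    iai <- NA_real_; lab <- NA_character_
    parts <- strsplit(lb, "+", fixed = TRUE)[[1]]
    if (length(parts) == 2L && all(parts %in% names(fits))) {
      r1 <- attr(plates[[lb]], "ratio")
      if (is.null(r1) || is.na(r1)) r1 <- 0.5
      ci <- interaction_index(fits[[parts[1]]], fits[[parts[2]]], f,
                              r1 = r1, fa = fa)
      iai <- ci$iai; lab <- ci$label
    }
    data.frame(label = lb, m = f$m, Dm = f$Dm, log10_ic50 = f$log10_ic50,
               r_squared = f$r_squared, iai = iai, synergy = lab,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

cli_usage <- function() {
  paste0(
    "usage: rppaflow <subcommand> [--key value ...]\n",
    "subcommands:\n",
    "  simulate  --seed S --out DIR [--config FILE] [--quiet]\n",
    "  quantify  --slides FILE --out FILE [--tol T] [--max-iter N]\n",
    "  normalize --matrix FILE --out FILE [--skip-loading]\n",
    "  diffexp   --matrix FILE --out FILE [--q 0.01] [--p-threshold 0.05]\n",
    "  concord   --discovery FILE --validation FILE --out FILE\n",
    "  combo     --plate FILE --out FILE [--fa 0.5]\n",
    "  growth    --growth FILE --out FILE [--day 21] [--log-volume]\n",
    "  all       --seed S --out DIR [--config FILE] [--quiet]\n")
}

parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      out[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      out[[key]] <- TRUE          # bare flag
      i <- i + 1L
    }
  }
  out
}

config_from_file <- function(path, seed) {
  kv <- if (!is.null(path)) read_config(path) else list()
  et <- default_effect_table()
  if (!is.null(kv$n_proteins)) et <- utils::head(et, as.integer(kv$n_proteins))
  args <- list(seed = seed, effect_table = et)
  for (k in c("n_scc", "n_nonscc", "protein_noise_sd", "slide_alpha",
              "slide_beta", "slide_gamma", "slide_noise_sd",
              "dilution_steps", "duplicate_fraction", "dose_grid",
              "growth_v0", "growth_structure", "growth_rho", "growth_sigma",
              "growth_n_per_group", "growth_days"))
    if (!is.null(kv[[k]])) args[[k]] <- kv[[k]]
  do.call(simulation_config, args)
}

#' Command-line entry point
#'
#' Subcommand interface over the whole pipeline (see the package script
#' `inst/scripts/rppaflow` for Rscript usage). Returns the exit status
#' instead of quitting so it is testable in-process; any stage error is
#' reported on stderr and yields a nonzero status.
#'
#' @param args character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return integer exit status, invisibly (0 = success).
#' @export
rppa_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    message(cli_usage())
    return(invisible(2L))
  }
  sub <- args[1]
  known <- c("simulate", "quantify", "normalize", "diffexp", "concord",
             "combo", "growth", "all")
  if (!sub %in% known) {
    message("unknown subcommand: ", sub, "\n", cli_usage())
    return(invisible(2L))
  }
  status <- tryCatch({
    o <- parse_cli_args(args[-1])
    quiet <- isTRUE(o$quiet)
    need <- function(k) {
      if (is.null(o[[k]])) stop("missing required option --", k)
      o[[k]]
    }
    switch(sub,
      simulate = {
        cfg <- config_from_file(o$config, as.integer(need("seed")))
        dir.create(need("out"), showWarnings = FALSE, recursive = TRUE)
        em <- generate_cohort_matrix(cfg)
        slides <- lapply(seq_len(nrow(em$values)), function(i)
          generate_slide(replace_seed(cfg, cfg$seed + i),
                         truth = em$values[i, ],
                         antibody = rownames(em$values)[i]))
        write_slide_tsv(slides, file.path(o$out, "slides.tsv"))
        write_matrix_tsv(em, file.path(o$out, "matrix.tsv"))
        truth <- attr(em, "truth")
        utils::write.table(
          data.frame(protein = names(truth), shift_log2 = truth),
          file.path(o$out, "matrix.truth.tsv"), sep = "\t",
          quote = FALSE, row.names = FALSE)
        write_plate_tsv(list(
          generate_dose_response(1.2, 0.5, cfg$dose_grid, 0.02,
                                 cfg$seed + 101L, "drugA"),
          generate_dose_response(1.8, 2.0, cfg$dose_grid, 0.02,
                                 cfg$seed + 102L, "drugB"),
          generate_additive_combination(1.2, 0.5, 1.8, 2.0, cfg$dose_grid,
                                        noise_sd = 0.02,
                                        seed = cfg$seed + 103L,
                                        label = "drugA+drugB")),
          file.path(o$out, "plates.tsv"))
        write_growth_tsv(generate_growth_curves(cfg),
                         file.path(o$out, "growth.tsv"))
        log_msg(quiet, "simulate: wrote ", o$out, " (seed ", cfg$seed, ")")
      },
      quantify = {
        slides <- read_slide_tsv(need("slides"))
        em <- quantify_slides(slides,
                              tol = as.numeric(o$tol %||% 1e-8),
                              max_iter = as.integer(o[["max-iter"]] %||% 200L))
        write_matrix_tsv(em, need("out"))
        utils::write.table(attr(em, "diagnostics"),
                           paste0(o$out, ".diagnostics.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        log_msg(quiet, "quantify: ", nrow(em$values), " slides, ",
                ncol(em$values), " samples")
      },
      normalize = {
        em <- read_matrix_tsv(need("matrix"))
        write_matrix_tsv(normalize_matrix(em,
                                          skip_loading = isTRUE(o[["skip-loading"]])),
                         need("out"))
      },
      diffexp = {
        em <- read_matrix_tsv(need("matrix"))
        res <- two_group_test(em)
        bum <- fit_bum(res$p_value)
        dec <- fdr_cutoff(bum, as.numeric(o$q %||% 0.01),
                          p_values = res$p_value, proteins = res$protein)
        res$significant_at_fdr <- res$p_value <= dec$tau_cutoff
        utils::write.table(res, need("out"), sep = "\t", quote = FALSE,
                           row.names = FALSE)
        top <- select_top(res, as.numeric(o[["p-threshold"]] %||% 0.05))
        if (length(top) >= 2L) {
          cl <- hierarchical_cluster(
            expression_matrix(em$values[top, , drop = FALSE]))
          write_dendrogram_newick(cl$rows, paste0(o$out, ".proteins.nwk"))
          write_dendrogram_newick(cl$cols, paste0(o$out, ".samples.nwk"))
        }
        log_msg(quiet, "diffexp: ", nrow(res), " proteins, ",
                dec$n_significant, " significant at FDR ", dec$nominal_q)
      },
      concord = {
        dis <- utils::read.delim(need("discovery"), stringsAsFactors = FALSE)
        val <- utils::read.delim(need("validation"), stringsAsFactors = FALSE)
        tab <- concordance_table(dis, val)
        utils::write.table(tab, need("out"), sep = "\t", quote = FALSE,
                           row.names = FALSE)
        cnt <- attr(tab, "counts")
        log_msg(quiet, "concord: ",
                paste(sprintf("%s=%d", names(cnt), cnt), collapse = " "))
      },
      combo = {
        plates <- read_plate_tsv(need("plate"))
        rep <- combination_report(plates, fa = as.numeric(o$fa %||% 0.5))
        utils::write.table(rep, need("out"), sep = "\t", quote = FALSE,
                           row.names = FALSE)
      },
      growth = {
        gd <- read_growth_tsv(need("growth"))
        gfit <- select_structure(gd, log_volume = isTRUE(o[["log-volume"]]))
        contrasts <- tukey_hsd(gfit, as.numeric(o$day %||% 21))
        utils::write.table(contrasts, need("out"), sep = "\t", quote = FALSE,
                           row.names = FALSE)
        utils::write.table(attr(gfit, "aic_table"),
                           paste0(o$out, ".aic.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        log_msg(quiet, "growth: selected ", gfit$structure)
      },
      all = {
        cfg <- config_from_file(o$config, as.integer(need("seed")))
        run_pipeline(cfg, need("out"), quiet = quiet)
      })
    0L
  }, error = function(e) {
    message("rppaflow error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
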