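#' Simulation configuration for the synthetic-data generator
#'
#' Bundles every design constant the generator needs: cohort sizes, the
#' planted protein effects (signed fold-changes, fold magnitude >= 1), the
#' slide response-curve parameters, dilution design, duplicate fraction,
#' the dose grid for viability plates, and the xenograft growth design.
#'
#' Defaults reproduce the study design this package emulates: a 5-point
#' serial dilution series (an undiluted anchor plus 1:2 .. 1:16, i.e. log2
#' offsets 0, -1, ..., -4), 34 squamous (SCC) vs 106 non-squamous samples,
#' about ten percent of samples printed in duplicate, and xenograft groups
#' of n = 5 mice randomized once tumors reach roughly 200 mm3.
#'
#' @param seed integer seed; every draw made by a generator call flows from
#'   one RNG stream initialized from this value (no global state is touched).
#' @param n_scc,n_nonscc cohort sizes (each >= 2).
#' @param effect_table data.frame with columns `protein` and `fold` (signed
#'   fold-change, |fold| >= 1; negative means lower in SCC). The default is
#'   the set of targetable markers differentially expressed between the
#'   histologies, with their reported fold-changes.
#' @param protein_noise_sd per-measurement Gaussian noise, log2 units.
#' @param slide_alpha,slide_beta,slide_gamma,slide_noise_sd logistic
#'   response-curve background, dynamic range (> 0), slope per log2 unit
#'   (> 0), and additive intensity noise for simulated slides.
#' @param dilution_steps number of dilution points per sample (>= 3).
#' @param duplicate_fraction fraction of samples printed twice (in `[0,1]`).
#' @param dose_grid strictly positive dose vector for viability plates.
#' @param growth_v0 starting tumor volume, mm3.
#' @param growth_slopes named per-group mean growth slopes, mm3 per day.
#' @param growth_structure within-mouse residual correlation structure, one
#'   of `"independence"`, `"compound_symmetry"`, `"ar1"`.
#' @param growth_rho correlation parameter (|rho| < 1; ignored for
#'   independence).
#' @param growth_sigma residual standard deviation, mm3.
#' @param growth_n_per_group mice per group (>= 2).
#' @param growth_days sorted measurement days.
#' @return An object of class `"simulation_config"` (a validated list).
#' @export
simulation_config <- function(seed = 1L,
                              n_scc = 34L,
                              n_nonscc = 106L,
                              effect_table = default_effect_table(),
                              protein_noise_sd = 0.5,
                              slide_alpha = 100,
                              slide_beta = 1000,
                              slide_gamma = 1,
                              slide_noise_sd = 10,
                              dilution_steps = 5L,
                              duplicate_fraction = 0.10,
                              dose_grid = 0.0625 * 2^(0:7),
                              growth_v0 = 200,
                              growth_slopes = c(vehicle = 40, drugA = 30,
                                                drugB = 28, combination = 12),
                              growth_structure = "ar1",
                              growth_rho = 0.6,
                              growth_sigma = 40,
                              growth_n_per_group = 5L,
                              growth_days = seq(0L, 21L, by = 3L)) {
  cfg <- list(seed = as.integer(seed),
              n_scc = as.integer(n_scc), n_nonscc = as.integer(n_nonscc),
              effect_table = effect_table,
              protein_noise_sd = protein_noise_sd,
              slide_alpha = slide_alpha, slide_beta = slide_beta,
              slide_gamma = slide_gamma, slide_noise_sd = slide_noise_sd,
              dilution_steps = as.integer(dilution_steps),
              duplicate_fraction = duplicate_fraction,
              dose_grid = dose_grid,
              growth_v0 = growth_v0, growth_slopes = growth_slopes,
              growth_structure = match.arg(growth_structure,
                                           c("independence",
                                             "compound_symmetry", "ar1")),
              growth_rho = growth_rho, growth_sigma = growth_sigma,
              growth_n_per_group = as.integer(growth_n_per_group),
              growth_days = as.integer(growth_days))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

#' Default planted effect table
#'
#' Signed fold-changes (SCC relative to non-SCC) for the targetable markers
#' the differential module is expected to rediscover; negative values mean
#' lower in SCC (e.g. TTF-1, a marker of adenocarcinoma).
#'
#' @return data.frame with columns `protein`, `fold`.
#' @export
default_effect_table <- function() {
  data.frame(
    protein = c("Keap1", "Nrf2", "CHK2", "pCHK2", "Rb", "MSH2", "PARP",
                "IGF1R", "TrkB", "Src3",
                "TTF-1", "pEGFR", "Met", "pMet", "Axl", "FGFR",
                "pMek", "Rab25", "p70S6K", "PKCa", "JNK2", "p90RSK", "mTOR"),
    fold = c(1.64, 1.10, 1.41, 1.28, 1.34, 1.28, 1.37,
             1.23, 1.56, 1.12,
             -3.41, -1.11, -1.17, -1.08, -1.13, -1.14,
             -1.14, -1.28, -1.15, -1.26, -1.12, -1.09, -1.08),
    stringsAsFactors = FALSE)
}

validate_simulation_config <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (cfg$n_scc < 2L || cfg$n_nonscc < 2L)
    stop("cohort sizes must be >= 2")
  if (cfg$slide_beta <= 0) stop("slide_beta must be > 0")
  if (cfg$slide_gamma <= 0) stop("slide_gamma must be > 0")
  if (cfg$slide_noise_sd < 0 || cfg$protein_noise_sd < 0 ||
      cfg$growth_sigma < 0)
    stop("noise standard deviations must be >= 0")
  if (cfg$dilution_steps < 3L) stop("dilution_steps must be >= 3")
  if (cfg$duplicate_fraction < 0 || cfg$duplicate_fraction > 1)
    stop("duplicate_fraction must lie in [0, 1]")
  if (any(cfg$dose_grid <= 0)) stop("dose_grid must be strictly positive")
  et <- cfg$effect_table
  if (!is.data.frame(et) || !all(c("protein", "fold") %in% names(et)))
    stop("effect_table needs columns 'protein' and 'fold'")
  if (any(!is.finite(et$fold)) || any(abs(et$fold) < 1))
    stop("signed fold-changes require |fold| >= 1 (fold 0 or |fold| < 1 is invalid)")
  if (cfg$growth_structure != "independence" && abs(cfg$growth_rho) >= 1)
    stop("|rho| must be < 1")
  if (cfg$growth_n_per_group < 2L) stop("growth_n_per_group must be >= 2")
  if (is.unsorted(cfg$growth_days)) stop("growth_days must be sorted ascending")
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config: seed", x$seed, "|", x$n_scc, "SCC vs",
      x$n_nonscc, "non-SCC |", nrow(x$effect_table), "planted effects |",
      x$dilution_steps, "dilution steps | dup fraction",
      x$duplicate_fraction, "\n")
  invisible(x)
}

# One private RNG stream per generator call: run `expr` under a local seed
# without disturbing the caller's .Random.seed.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate one antibody slide from known log2 concentrations
#'
#' Emits spot intensities for a dilution series: for sample s with true
#' relative log2 concentration x_s, the spot at dilution step j (an
#' undiluted anchor at j = 0 and two-fold dilutions after it) has
#' intensity alpha + beta * plogis(gamma * (x_s - j)) plus Gaussian noise.
#' Ground truth is stored alongside so fits can be scored.
#'
#' @param config a [simulation_config()].
#' @param truth named numeric vector: sample id -> true relative log2
#'   concentration (finite).
#' @param antibody slide/antibody name.
#' @param replicates spots per (sample, step).
#' @return A `slide_measurements` object (see [slide_measurements()]) with a
#'   `truth` attribute.
#' @export
generate_slide <- function(config, truth, antibody = "AB1", replicates = 1L) {
  validate_simulation_config(config)
  if (is.null(names(truth)) || any(!nzchar(names(truth))))
    stop("truth must be a named vector (sample id -> log2 concentration)")
  if (any(!is.finite(truth)))
    stop("non-finite truth values are not allowed")
  steps <- seq_len(config$dilution_steps) - 1L
  grid <- expand.grid(sample_id = names(truth), dilution_step = steps,
                      replicate = seq_len(replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$sample_id, grid$dilution_step, grid$replicate), ,
               drop = FALSE]
  rownames(grid) <- NULL
  x <- truth[grid$sample_id]
  mu <- config$slide_alpha +
    config$slide_beta * stats::plogis(config$slide_gamma * (x - grid$dilution_step))
  noise <- with_seed(config$seed,
                     stats::rnorm(nrow(grid), 0, config$slide_noise_sd))
  grid$intensity <- pmax(as.numeric(mu + noise), 0)
  sl <- slide_measurements(antibody = antibody,
                           sample_id = grid$sample_id,
                           dilution_step = grid$dilution_step,
                           replicate = grid$replicate,
                           intensity = grid$intensity)
  attr(sl, "truth") <- truth
  sl
}

#' Simulate a two-cohort protein expression matrix with planted effects
#'
#' Baseline log2 values are drawn per protein; SCC samples are shifted by
#' log2(|fold|) with the sign of the planted fold-change (negative fold =
#' lower in SCC); Gaussian noise is added per measurement. A fraction of
#' samples is emitted twice (independent noise) sharing a base-sample
#' identifier, emulating on-slide duplicates.
#'
#' @param config a [simulation_config()].
#' @return An [expression_matrix()] with histology annotations and
#'   base-sample ids; attribute `truth` holds the planted log2 shifts
#'   (named by protein; 0 for unplanted proteins), attribute `baseline`
#'   the per-protein baselines.
#' @export
generate_cohort_matrix <- function(config) {
  validate_simulation_config(config)
  et <- config$effect_table
  proteins <- et$protein
  shifts <- sign(et$fold) * log2(abs(et$fold))
  names(shifts) <- proteins

  n <- config$n_scc + config$n_nonscc
  base_ids <- sprintf("S%03d", seq_len(n))
  histology <- c(rep("SCC", config$n_scc), rep("non-SCC", config$n_nonscc))
  names(histology) <- base_ids

  # baselines centered on the middle of the dilution design so a printed
  # series spans the response curve's dynamic range (a calibrated assay)
  with_seed(config$seed, {
    baseline <- stats::rnorm(length(proteins),
                             mean = (config$dilution_steps - 1) / 2, sd = 1)
    names(baseline) <- proteins
    n_dup <- round(config$duplicate_fraction * n)
    dup_base <- if (n_dup > 0) sample(base_ids, n_dup) else character(0)

    col_base <- c(base_ids, dup_base)
    rep_tag <- c(rep("", n), rep("-r2", length(dup_base)))
    sample_id <- paste0(col_base, ifelse(nzchar(rep_tag), rep_tag, ""))
    # duplicates of a base sample share truth but get independent noise
    mu <- outer(baseline, rep(1, length(col_base))) +
      outer(shifts, as.numeric(histology[col_base] == "SCC"))
    vals <- mu + matrix(stats::rnorm(length(mu), 0, config$protein_noise_sd),
                        nrow = nrow(mu))
    dimnames(vals) <- list(proteins, sample_id)
  })

  em <- expression_matrix(vals,
                          histology = stats::setNames(histology[col_base],
                                                      sample_id),
                          base_sample = stats::setNames(col_base, sample_id))
  attr(em, "truth") <- shifts
  attr(em, "baseline") <- baseline
  em
}

#' Simulate a median-effect dose-response series
#'
#' The affected fraction follows the median-effect law
#' fa(D) = 1 / (1 + (Dm / D)^m); viability = 1 - fa plus Gaussian noise,
#' clipped to `[0, 1.2]` (signal can exceed untreated control slightly).
#'
#' @param m median-effect slope (> 0).
#' @param Dm median-effect dose (> 0); the IC50 analog.
#' @param doses strictly positive dose vector.
#' @param noise_sd viability noise sd.
#' @param seed integer seed.
#' @param label drug / combination label.
#' @return A `dose_response` object (see [dose_response()]).
#' @export
generate_dose_response <- function(m, Dm, doses, noise_sd = 0, seed = 1L,
                                   label = "drug") {
  if (m <= 0) stop("m must be > 0")
  if (Dm <= 0) stop("Dm must be > 0")
  if (any(doses <= 0)) stop("doses must be strictly positive")
  fa <- 1 / (1 + (Dm / doses)^m)
  viability <- 1 - fa
  if (noise_sd > 0)
    viability <- viability +
      with_seed(seed, stats::rnorm(length(doses), 0, noise_sd))
  viability <- pmin(pmax(viability, 0), 1.2)
  dose_response(label = label, doses = doses, viability = viability)
}

#' Simulate longitudinal xenograft tumor-volume trajectories
#'
#' Mean volume grows linearly, V0 + slope_g * day, from a common starting
#' volume (default 200 mm3, the randomization threshold). Within-mouse
#' residuals are drawn under the named correlation structure (independence,
#' compound symmetry, or AR(1) across consecutive measurements) with sd
#' sigma; volumes are floored at 0.
#'
#' @param config a [simulation_config()] (growth_* fields are used).
#' @return data.frame of class `growth_data`: columns `mouse`, `group`,
#'   `day`, `volume`; attribute `truth` holds the generating parameters.
#' @export
generate_growth_curves <- function(config) {
  validate_simulation_config(config)
  groups <- names(config$growth_slopes)
  days <- config$growth_days
  d <- length(days)
  npg <- config$growth_n_per_group
  rho <- config$growth_rho

  R <- switch(config$growth_structure,
    independence = diag(d),
    compound_symmetry = matrix(rho, d, d) + diag(1 - rho, d),
    ar1 = rho^abs(outer(seq_len(d), seq_len(d), "-")))
  L <- chol(R)

  res <- with_seed(config$seed, {
    out <- vector("list", length(groups) * npg)
    k <- 0L
    for (g in groups) {
      mu <- config$growth_v0 + config$growth_slopes[[g]] * days
      for (i in seq_len(npg)) {
        k <- k + 1L
        eps <- as.numeric(crossprod(L, stats::rnorm(d))) * config$growth_sigma
        out[[k]] <- data.frame(
          mouse = sprintf("%s_m%02d", g, i), group = g, day = days,
          volume = pmax(mu + eps, 0), stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
  rownames(res) <- NULL
  class(res) <- c("growth_data", "data.frame")
  attr(res, "truth") <- list(v0 = config$growth_v0,
                             slopes = config$growth_slopes,
                             structure = config$growth_structure,
                             rho = rho, sigma = config$growth_sigma)
  res
}
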