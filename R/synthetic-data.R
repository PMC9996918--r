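# Synthetic peak tables with known ground truth.
#
# The generator emulates the structure the downstream analysis assumes: two
# balanced populations, log-normal per-metabolite peak areas, a subset of
# metabolites with true between-population shifts expressed in units of the
# metabolite's log-scale SD, round-robin assignment of metabolites to
# acquisition methods, and deterministic left-censoring to mimic
# below-detection missingness.

# Fixed spreads of the per-metabolite baseline mean and SD multiplier; these
# make the coefficient of variation vary across metabolites so that
# ALR-reference selection is non-degenerate.
.MU_SPREAD <- 1.5
.SD_MULT_RANGE <- c(0.5, 1.5)

#' Simulation configuration
#'
#' Parameters of the synthetic two-population peak-table generator. Defaults
#' describe the study design the pipeline targets: 13 animals per divergent
#' population, a few hundred metabolites quantified by four UPLC-MS/MS
#' methods, and a small panel of truly shifted metabolites.
#'
#' @param n_per_group samples per population (>= 3).
#' @param n_metabolites total metabolites.
#' @param n_informative metabolites carrying a true between-population shift.
#' @param effect_sd true shift in units of the metabolite's log-scale SD;
#'   scalar or vector of length `n_informative` (signed; positive = higher in
#'   population H).
#' @param n_methods number of acquisition methods (round-robin assignment).
#' @param missing_rate target fraction of left-censored entries, in [0, 1).
#' @param base_log_mean,base_log_sd centre of the per-metabolite log-intensity
#'   means, and base log-scale SD (per-metabolite SDs are uniform multiples
#'   of it in 0.5..1.5).
#' @param seed integer RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 13, n_metabolites = 200,
                       n_informative = 10, effect_sd = 2,
                       n_methods = 4, missing_rate = 0.1,
                       base_log_mean = 16, base_log_sd = 0.8,
                       seed = 1) {
  cfg <- list(n_per_group = n_per_group, n_metabolites = n_metabolites,
              n_informative = n_informative, effect_sd = effect_sd,
              n_methods = n_methods, missing_rate = missing_rate,
              base_log_mean = base_log_mean, base_log_sd = base_log_sd,
              seed = seed)
  for (f in c("n_per_group", "n_metabolites", "n_informative", "n_methods",
              "missing_rate", "base_log_mean", "base_log_sd", "seed")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop(sprintf("invalid configuration field `%s`: must be a finite number", f))
  }
  if (cfg$n_per_group < 3)
    stop("invalid configuration field `n_per_group`: need at least 3 per group")
  if (cfg$n_informative > cfg$n_metabolites)
    stop("invalid configuration field `n_informative`: exceeds n_metabolites")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("invalid configuration field `missing_rate`: must be in [0, 1)")
  if (!all(is.finite(cfg$effect_sd)))
    stop("invalid configuration field `effect_sd`: must be finite")
  if (!length(cfg$effect_sd) %in% c(1L, cfg$n_informative) )
    stop("invalid configuration field `effect_sd`: length must be 1 or n_informative")
  if (cfg$n_methods < 1 || cfg$n_methods != round(cfg$n_methods))
    stop("invalid configuration field `n_methods`: must be a positive integer")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic peak table with ground truth
#'
#' Draws a complete (no missing entries) table of strictly positive
#' intensities. Per metabolite j, log-intensities are Normal with mean
#' `mu_j` (itself Normal around `base_log_mean`) and SD `sigma_j`; the first
#' `n_informative` randomly chosen metabolites have their population-H log
#' mean shifted by `effect_sd * sigma_j`. Metabolites are assigned to
#' methods round-robin. Identical seeds give bit-identical output.
#'
#' @param config a [sim_config()].
#' @return A list with elements `table` (a [peak_table()]) and `truth` (a
#'   data.frame with `metabolite_id` and `true_effect` in log-scale SD units;
#'   non-informative metabolites have true effect exactly 0).
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  n <- 2L * config$n_per_group
  p <- config$n_metabolites
  pop <- rep(c("L", "H"), each = config$n_per_group)
  mu <- rnorm(p, config$base_log_mean, .MU_SPREAD)
  sigma <- config$base_log_sd *
    runif(p, .SD_MULT_RANGE[1], .SD_MULT_RANGE[2])
  informative <- sort(sample.int(p, config$n_informative))
  effects <- numeric(p)
  effects[informative] <- rep_len(config$effect_sd, config$n_informative)
  logx <- matrix(rnorm(n * p), n, p)
  logx <- sweep(logx, 2, sigma, "*")
  logx <- sweep(logx, 2, mu, "+")
  shift <- outer(as.numeric(pop == "H"), effects * sigma)
  logx <- logx + shift
  vals <- exp(logx)
  met_ids <- sprintf("M%03d", seq_len(p))
  method <- paste0("method", ((seq_len(p) - 1L) %% config$n_methods) + 1L)
  tab <- peak_table(vals, population = pop, method = method,
                    metabolite_ids = met_ids)
  truth <- data.frame(metabolite_id = met_ids, true_effect = effects,
                      stringsAsFactors = FALSE)
  list(table = tab, truth = truth)
}

#' Left-censor a complete peak table
#'
#' Flags as missing every entry strictly below the per-method intensity
#' quantile at `missing_rate`, emulating below-detection censoring. The
#' censoring is deterministic given the table: the threshold is a quantile of
#' the observed intensities of each method, so the censoring oracle is exact.
#' The uncensored matrix is retained in the `"hidden"` attribute for
#' ground-truth checks.
#'
#' @param table a complete [peak_table()].
#' @param config a [sim_config()] (only `missing_rate` is used) or a single
#'   numeric rate.
#' @return A [peak_table()] with `NA` at censored positions and attribute
#'   `"hidden"` holding the complete matrix.
#' @export
inject_missingness <- function(table, config) {
  stopifnot(inherits(table, "peak_table"))
  rate <- if (is.numeric(config)) config[[1]] else config$missing_rate
  if (!is.numeric(rate) || !is.finite(rate) || rate < 0 || rate >= 1)
    stop("invalid configuration field `missing_rate`: must be in [0, 1)")
  if (anyNA(table$values)) stop("input table must be complete")
  vals <- table$values
  if (rate > 0) {
    for (m in unique(table$method)) {
      cols <- which(table$method == m)
      v <- vals[, cols, drop = FALSE]
      thr <- quantile(v, probs = rate, names = FALSE)
      v[v < thr] <- NA_real_
      vals[, cols] <- v
    }
  }
  out <- peak_table(vals, population = table$population,
                    method = table$method, sample_ids = table$sample_ids,
                    metabolite_ids = table$metabolite_ids)
  attr(out, "hidden") <- table$values
  out
}

#' Write simulation ground truth as TSV
#' @param truth the `truth` data.frame from [generate_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
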