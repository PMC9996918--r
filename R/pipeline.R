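# End-to-end orchestration: simulate (or load) -> preprocess -> PLS-DA
# selection + validation -> Bayesian relevance -> joined overlap report, with
# a machine-readable manifest. A single global seed fans out to per-stage
# seeds by fixed offsets.

.STAGE_SEED_OFFSETS <- c(simulate = 0L, plsda_tune = 1000L,
                         plsda_validate = 2000L, plsda_permute = 3000L,
                         bayes = 4000L)

#' Pipeline run configuration
#'
#' @param sim a [sim_config()] describing the synthetic input, or `NULL` when
#'   `table` is supplied to [run_all()] directly.
#' @param missing_threshold missingness filter threshold.
#' @param folds,tune_repeats,val_repeats,perm_repeats,max_ncomp PLS-DA
#'   settings (tuning and validation repeats default to the protocol's 100
#'   and 10,000; scale down for quick runs).
#' @param gibbs a [gibbs_config()] (its seed is overridden by `seed`).
#' @param alpha cumulative-PEP threshold.
#' @param seed global seed; every stage derives its own seed from it by a
#'   fixed offset.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), missing_threshold = 0.20,
                       folds = 4, tune_repeats = 100, val_repeats = 10000,
                       perm_repeats = 1000, max_ncomp = 10,
                       gibbs = gibbs_config(), alpha = 0.05, seed = 1) {
  structure(list(sim = sim, missing_threshold = missing_threshold,
                 folds = folds, tune_repeats = tune_repeats,
                 val_repeats = val_repeats, perm_repeats = perm_repeats,
                 max_ncomp = max_ncomp, gibbs = gibbs, alpha = alpha,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Join Bayesian relevance and PLS-DA selection
#'
#' Per metabolite of the Bayesian table: the relevance flag, whether the
#' metabolite was retained by the final PLS-DA model, and the intersection
#' flag; the set counts are attached as the `"counts"` attribute.
#'
#' @param bayes_table output of [run_bayes()].
#' @param plsda_model final model from [plsda_select()] (or a character
#'   vector of selected metabolite ids).
#' @return Data.frame with `metabolite_id`, `bayes_relevant`, `pls_selected`,
#'   `both`, `either`.
#' @export
overlap_report <- function(bayes_table, plsda_model) {
  sel <- if (is.character(plsda_model)) plsda_model else
    plsda_model$retained_ids
  if (!all(sel %in% bayes_table$metabolite_id))
    stop("metabolite universes of the two analyses do not match")
  out <- data.frame(metabolite_id = bayes_table$metabolite_id,
                    bayes_relevant = bayes_table$relevant,
                    pls_selected = bayes_table$metabolite_id %in% sel,
                    stringsAsFactors = FALSE)
  out$both <- out$bayes_relevant & out$pls_selected
  out$either <- out$bayes_relevant | out$pls_selected
  attr(out, "counts") <- c(bayes = sum(out$bayes_relevant),
                           pls = sum(out$pls_selected),
                           both = sum(out$both))
  out
}

#' Run the full analysis pipeline
#'
#' Sequences simulate (unless a peak table is given) -> preprocess -> PLS-DA
#' tuning/VIP selection -> confusion-matrix and permutation validation ->
#' per-metabolite Bayesian relevance -> overlap report, writing every stage's
#' tables (TSV), reports (JSON) and a manifest to `out_dir`. Runs are
#' byte-identical given the same config and seed.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param table optional [peak_table()] to analyse instead of simulating.
#' @return Invisibly, a list with `matrix`, `selection`, `validation`,
#'   `permutation`, `bayes`, `overlap`, `manifest`.
#' @export
run_all <- function(config = run_config(), out_dir, table = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- config$seed + .STAGE_SEED_OFFSETS
  manifest <- list(seed = config$seed, stages = list())
  t_all <- proc.time()[3]
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      seed = if (name %in% names(seeds)) unname(seeds[name]) else NA,
      wall_time_s = round(proc.time()[3] - t0, 3))
    res
  }

  truth <- NULL
  if (is.null(table)) {
    simres <- stage("simulate", {
      cfg <- config$sim; cfg$seed <- seeds[["simulate"]]
      res <- generate_dataset(cfg)
      res$table <- inject_missingness(res$table, cfg)
      res
    })
    table <- simres$table
    truth <- simres$truth
    write_peak_table(table, file.path(out_dir, "peak_table.tsv"))
    write_ground_truth(truth, file.path(out_dir, "ground_truth.tsv"))
  }

  prep <- stage("preprocess", preprocess(table, config$missing_threshold))
  write_transformed_matrix(prep$matrix,
                           file.path(out_dir, "transformed_matrix.tsv"))
  jsonlite::write_json(prep$report,
                       file.path(out_dir, "preprocess_report.json"),
                       auto_unbox = TRUE, digits = NA)

  y <- prep$matrix$population
  sel <- stage("plsda_tune", plsda_select(
    prep$matrix, y, folds = config$folds, repeats = config$tune_repeats,
    max_ncomp = config$max_ncomp, seed = seeds[["plsda_tune"]]))
  write.table(sel$trace, file.path(out_dir, "selection_trace.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(metabolite_id = sel$model$retained_ids,
                         vip = sel$model$vip),
              file.path(out_dir, "vip.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  val <- stage("plsda_validate", plsda_validate(
    sel$model, prep$matrix, y, folds = config$folds,
    repeats = config$val_repeats, seed = seeds[["plsda_validate"]]))
  perm <- stage("plsda_permute", plsda_permute(
    sel$model, prep$matrix, y, folds = config$folds,
    repeats = config$perm_repeats, seed = seeds[["plsda_permute"]]))
  jsonlite::write_json(
    list(n_components = sel$model$n_components,
         retained = sel$model$retained_ids,
         ber = unname(sel$cv$ber_by_ncomp[sel$cv$chosen_ncomp]),
         confusion_percent = as.data.frame(val$confusion),
         accuracy = val$accuracy, precision = val$precision,
         permuted_confusion_percent = as.data.frame(perm$confusion),
         permuted_tp_percent = perm$permuted_tp_percent),
    file.path(out_dir, "plsda_report.json"), auto_unbox = TRUE, digits = NA)

  gcfg <- config$gibbs; gcfg$seed <- seeds[["bayes"]]
  bay <- stage("bayes", run_bayes(prep$matrix, gcfg, alpha = config$alpha))
  ov <- stage("overlap", overlap_report(bay, sel$model))
  final <- merge(bay, ov, by = "metabolite_id", sort = FALSE)
  write.table(format(final, digits = 15),
              file.path(out_dir, "bayes_results.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  manifest$total_wall_time_s <- round(proc.time()[3] - t_all, 3)
  manifest$counts <- as.list(attr(ov, "counts"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(matrix = prep$matrix, preprocess_report = prep$report,
                 selection = sel, validation = val, permutation = perm,
                 bayes = bay, overlap = ov, truth = truth,
                 manifest = manifest))
}
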