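# Compositional preprocessing: missingness filter, per-method half-minimum
# imputation, additive log-ratio (ALR) transform against the
# lowest-coefficient-of-variation reference, Procrustes isometry check, and
# autoscaling to unit-SD columns.

#' Remove metabolites with excessive missingness
#'
#' A metabolite is considered uninformative and removed when its fraction of
#' missing values exceeds `threshold` in at least one population: a metabolite
#' that is mostly below detection in one group cannot support a two-group
#' contrast. Column order of the survivors is preserved.
#'
#' @param table a [peak_table()].
#' @param threshold maximal tolerated missing fraction per population,
#'   in (0, 1); default 0.20.
#' @return The filtered [peak_table()], with attribute `"removed"` listing the
#'   dropped metabolite ids.
#' @export
filter_missing <- function(table, threshold = 0.20) {
  stopifnot(inherits(table, "peak_table"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("`threshold` must be in (0, 1)")
  pops <- unique(table$population)
  for (pp in c("H", "L"))
    if (sum(table$population == pp) == 0)
      stop(sprintf("population '%s' has zero samples", pp))
  miss_frac <- sapply(pops, function(pp) {
    colMeans(is.na(table$values[table$population == pp, , drop = FALSE]))
  })
  drop <- apply(miss_frac > threshold, 1, any)
  removed <- table$metabolite_ids[drop]
  if (any(drop))
    message(sprintf("filter_missing: removed %d of %d metabolites (> %.0f%% missing in a population)",
                    sum(drop), length(drop), 100 * threshold))
  out <- peak_table(table$values[, !drop, drop = FALSE],
                    population = table$population,
                    method = table$method[!drop],
                    sample_ids = table$sample_ids,
                    metabolite_ids = table$metabolite_ids[!drop])
  attr(out, "removed") <- removed
  out
}

#' Half-minimum imputation per acquisition method
#'
#' Every missing entry of metabolite j is replaced by half of the minimum
#' observed intensity across all metabolites and samples of the UPLC-MS/MS
#' method j belongs to. Observed values are never altered.
#'
#' @param table a [peak_table()].
#' @return A complete [peak_table()].
#' @export
impute_half_min <- function(table) {
  stopifnot(inherits(table, "peak_table"))
  vals <- table$values
  for (m in unique(table$method)) {
    cols <- which(table$method == m)
    v <- vals[, cols, drop = FALSE]
    obs <- v[!is.na(v)]
    if (!length(obs))
      stop(sprintf("imputation impossible: method '%s' has no observed values", m))
    v[is.na(v)] <- 0.5 * min(obs)
    vals[, cols] <- v
  }
  peak_table(vals, population = table$population, method = table$method,
             sample_ids = table$sample_ids,
             metabolite_ids = table$metabolite_ids)
}

#' Select the ALR reference metabolite
#'
#' Returns the metabolite with the lowest coefficient of variation (SD/mean of
#' the raw post-imputation intensities, across all samples). Ties are broken
#' by column order (first wins) for determinism.
#'
#' @param table a complete [peak_table()] with at least two metabolites.
#' @return The reference metabolite id (character scalar).
#' @export
select_alr_reference <- function(table) {
  stopifnot(inherits(table, "peak_table"))
  if (anyNA(table$values)) stop("table must be complete (impute first)")
  if (ncol(table$values) < 2) stop("need at least two metabolites")
  mu <- colMeans(table$values)
  if (any(mu == 0)) stop("coefficient of variation undefined: zero-mean column")
  cv <- apply(table$values, 2, sd) / mu
  table$metabolite_ids[which.min(cv)]
}

#' Additive log-ratio transform
#'
#' Column j of the result holds `log(x_j) - log(x_ref)` per sample (natural
#' logarithm); the reference column itself is excluded, so a table of p
#' metabolites yields p - 1 log-ratios. Ratios are invariant to per-sample
#' multiplicative scaling, which removes the compositional (closure)
#' constraint of peak-area data.
#'
#' @param table a complete, strictly positive [peak_table()].
#' @param reference_id metabolite id used as the ALR denominator.
#' @return Numeric matrix, samples x (p - 1).
#' @export
alr_transform <- function(table, reference_id) {
  stopifnot(inherits(table, "peak_table"))
  if (anyNA(table$values)) stop("table must be complete (impute first)")
  bad <- which(table$values <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("nonpositive intensity at sample '%s', metabolite '%s'",
                 table$sample_ids[bad[1, 1]], table$metabolite_ids[bad[1, 2]]))
  ref <- match(reference_id, table$metabolite_ids)
  if (is.na(ref)) stop("reference metabolite not found in table")
  lx <- log(table$values)
  out <- lx[, -ref, drop = FALSE] - lx[, ref]
  rownames(out) <- table$sample_ids
  out
}

#' Symmetric Procrustes correlation of two configurations
#'
#' Correlation-like agreement statistic `sqrt(1 - m2)` where `m2` is the
#' minimized symmetric Procrustes sum of squares after translation, rotation
#' and uniform scaling (vegan's `procrustes(..., symmetric = TRUE)`).
#'
#' @param x,y numeric matrices with matching row (sample) counts.
#' @return Correlation in [0, 1].
#' @export
procrustes_corr <- function(x, y) {
  if (nrow(x) != nrow(y)) stop("configurations have mismatched sample counts")
  k <- min(ncol(x), ncol(y))
  pr <- vegan::procrustes(x[, seq_len(k), drop = FALSE],
                          y[, seq_len(k), drop = FALSE], symmetric = TRUE)
  sqrt(max(0, 1 - pr$ss))
}

#' Isometry check of the ALR transform
#'
#' The ALR transform is not an isometry of the simplex; how much the sample
#' geometry is distorted depends on the reference. This check compares the
#' principal coordinates of the ALR matrix with those of the centered log-ratio
#' (CLR) transform of the same table (the isometric reference geometry) and
#' reports their Procrustes correlation. Values close to 1 indicate the ALR
#' representation preserves the sample configuration; a warning (never an
#' error) is emitted below `warn_below`.
#'
#' @param alr samples x (p-1) ALR matrix derived from `table`.
#' @param table the complete [peak_table()] the ALR came from.
#' @param warn_below warning threshold on the correlation (default 0.95).
#' @return The Procrustes correlation, a scalar in [0, 1].
#' @export
procrustes_check <- function(alr, table, warn_below = 0.95) {
  stopifnot(inherits(table, "peak_table"))
  if (nrow(alr) != nrow(table$values))
    stop("ALR matrix and table have mismatched sample counts")
  lx <- log(table$values)
  clr <- lx - rowMeans(lx)
  k <- min(nrow(alr) - 1L, ncol(alr), ncol(clr))
  pco_alr <- cmdscale(dist(alr), k = k)
  pco_clr <- cmdscale(dist(clr), k = k)
  r <- procrustes_corr(pco_alr, pco_clr)
  if (r < warn_below)
    warning(sprintf("ALR/CLR Procrustes correlation %.3f below %.2f: ALR geometry is distorted",
                    r, warn_below))
  r
}

#' Autoscale a matrix to zero-mean, unit-SD columns
#'
#' Centers each column and divides by its sample SD (n - 1 denominator), so
#' that downstream effects are expressed in units of each variable's SD. The
#' pre-scaling means and SDs are retained for provenance and un-scaling.
#'
#' @param x numeric matrix (e.g. an ALR matrix), >= 2 rows, no constant
#'   column.
#' @param population optional per-sample class labels carried along.
#' @param reference_id optional id of the ALR reference carried along.
#' @return An object of class `transformed_matrix`: list with `values`
#'   (autoscaled matrix), `reference_id`, `column_means`, `column_sds`,
#'   `population`, `sample_ids`.
#' @export
autoscale <- function(x, population = NULL, reference_id = NA_character_) {
  if (nrow(x) < 2) stop("need at least two samples to autoscale")
  mu <- colMeans(x)
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop(sprintf("cannot autoscale constant column '%s'",
                 colnames(x)[which(sds == 0)[1]]))
  vals <- sweep(sweep(x, 2, mu), 2, sds, "/")
  structure(
    list(values = vals, reference_id = reference_id,
         column_means = mu, column_sds = sds,
         population = population, sample_ids = rownames(x)),
    class = "transformed_matrix")
}

#' @export
print.transformed_matrix <- function(x, ...) {
  cat(sprintf("transformed_matrix: %d samples x %d log-ratios (reference: %s)\n",
              nrow(x$values), ncol(x$values), x$reference_id))
  invisible(x)
}

#' Full preprocessing pipeline
#'
#' Runs filter -> half-minimum imputation -> ALR-reference selection -> ALR ->
#' Procrustes isometry check -> autoscaling, preserving sample count and
#' order throughout.
#'
#' @param table a [peak_table()].
#' @param missing_threshold per-population missingness filter threshold.
#' @param warn_below Procrustes warning threshold.
#' @return List with `matrix` (a `transformed_matrix`) and `report` (list:
#'   `n_input`, `n_removed`, `removed_ids`, `reference_id`,
#'   `procrustes_corr`).
#' @export
preprocess <- function(table, missing_threshold = 0.20, warn_below = 0.95) {
  filtered <- filter_missing(table, missing_threshold)
  complete <- impute_half_min(filtered)
  ref <- select_alr_reference(complete)
  alr <- alr_transform(complete, ref)
  pc <- procrustes_check(alr, complete, warn_below = warn_below)
  tm <- autoscale(alr, population = complete$population, reference_id = ref)
  list(matrix = tm,
       report = list(n_input = ncol(table$values),
                     n_removed = length(attr(filtered, "removed")),
                     removed_ids = attr(filtered, "removed"),
                     reference_id = ref,
                     procrustes_corr = pc))
}

#' Write a transformed matrix as TSV
#' @param tm a `transformed_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transformed_matrix <- function(tm, path) {
  df <- data.frame(sample_id = tm$sample_ids, population = tm$population,
                   tm$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
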