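#' Peak-intensity table
#'
#' Container for a samples x metabolites table of positive peak intensities,
#' with per-sample population labels (two classes, \code{"L"} = resilient /
#' low environmental variance, \code{"H"} = non-resilient / high environmental
#' variance) and a per-metabolite acquisition-method label (each metabolite is
#' quantified by exactly one UPLC-MS/MS method). Missing (below-detection)
#' entries are stored as \code{NA} in \code{values}.
#'
#' @param values numeric matrix, samples in rows, metabolites in columns;
#'   observed entries must be strictly positive, missing entries \code{NA}.
#' @param population character or factor of length \code{nrow(values)} with
#'   levels \code{"H"} and \code{"L"}.
#' @param method character of length \code{ncol(values)} giving the
#'   acquisition method of each metabolite.
#' @param sample_ids,metabolite_ids optional identifiers; default to the
#'   dimnames of \code{values} or generated names.
#'
#' @return An object of class \code{peak_table}: a list with elements
#'   \code{values}, \code{population}, \code{method}, \code{sample_ids},
#'   \code{metabolite_ids}.
#' @export
peak_table <- function(values, population, method,
                       sample_ids = NULL, metabolite_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  n <- nrow(values); p <- ncol(values)
  if (is.null(sample_ids))
    sample_ids <- if (!is.null(rownames(values))) rownames(values) else
      sprintf("S%02d", seq_len(n))
  if (is.null(metabolite_ids))
    metabolite_ids <- if (!is.null(colnames(values))) colnames(values) else
      sprintf("M%03d", seq_len(p))
  population <- as.character(population)
  if (length(population) != n)
    stop("`population` must have one label per sample")
  if (!all(population %in% c("H", "L")))
    stop("population labels must be 'H' or 'L'")
  method <- as.character(method)
  if (length(method) != p)
    stop("`method` must have one label per metabolite")
  obs <- values[!is.na(values)]
  if (length(obs) && any(obs <= 0))
    stop("all observed intensities must be strictly positive")
  dimnames(values) <- list(sample_ids, metabolite_ids)
  structure(
    list(values = values, population = population, method = method,
         sample_ids = sample_ids, metabolite_ids = metabolite_ids),
    class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  nm <- sum(is.na(x$values))
  cat(sprintf("peak_table: %d samples x %d metabolites (%d methods)\n",
              nrow(x$values), ncol(x$values), length(unique(x$method))))
  cat(sprintf("  populations: H=%d L=%d; missing entries: %d (%.1f%%)\n",
              sum(x$population == "H"), sum(x$population == "L"),
              nm, 100 * nm / length(x$values)))
  invisible(x)
}

#' @export
dim.peak_table <- function(x) dim(x$values)

#' Write / read a peak table as TSV
#'
#' The table layout is: first column `sample_id`, second column `population`,
#' then one column per metabolite; missing entries are written as empty
#' fields. The metabolite-to-method map is written as a two-column companion
#' TSV (`metabolite_id`, `method`).
#'
#' @param table a [peak_table()].
#' @param path path of the intensity TSV.
#' @param methods_path path of the companion method-map TSV; default
#'   `<path>` with a `.methods.tsv` suffix.
#' @return `write_peak_table` returns `path` invisibly; `read_peak_table`
#'   returns a [peak_table()].
#' @export
write_peak_table <- function(table, path,
                             methods_path = paste0(path, ".methods.tsv")) {
  stopifnot(inherits(table, "peak_table"))
  df <- data.frame(sample_id = table$sample_ids,
                   population = table$population,
                   table$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  write.table(data.frame(metabolite_id = table$metabolite_ids,
                         method = table$method),
              methods_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_table
#' @param sep field separator of the intensity file (companion map is always
#'   tab-separated).
#' @export
read_peak_table <- function(path, methods_path = paste0(path, ".methods.tsv"),
                            sep = "\t") {
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = c("", "NA"))
  mm <- read.delim(methods_path, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(vals) <- "double"
  meth <- mm$method[match(colnames(vals), mm$metabolite_id)]
  if (anyNA(meth)) stop("method map does not cover every metabolite")
  peak_table(vals, population = df$population, method = meth,
             sample_ids = df$sample_id, metabolite_ids = colnames(vals))
}
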