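# PLS-DA from scratch: NIPALS PLS2 against a centered two-column class
# indicator, Mahalanobis-distance classification in score space, VIP scores,
# balanced-error-rate (BER) cross-validation, iterative VIP < 1 pruning, and
# confusion-matrix / permutation validation.

.CLASSES <- c("H", "L")
.RIDGE <- 1e-8   # ridge on the pooled score covariance for invertibility

.as_matrix <- function(x) {
  if (inherits(x, "transformed_matrix")) x$values else as.matrix(x)
}

.check_labels <- function(y, n) {
  y <- as.character(y)
  if (length(y) != n) stop("labels must match the number of samples")
  if (!all(y %in% .CLASSES)) stop("labels must be 'H' or 'L'")
  if (length(unique(y)) < 2) stop("need both classes present")
  y
}

# centered two-column one-hot class indicator
.dummy_y <- function(y) {
  Y <- sapply(.CLASSES, function(cl) as.numeric(y == cl))
  sweep(Y, 2, colMeans(Y))
}

#' Fit a PLS-DA model
#'
#' Partial least squares against a column-centered two-column class-indicator
#' matrix, extracted component-by-component with NIPALS (X is deflated by the
#' rank-one score/loading product after each component). Class centroids and
#' the pooled within-class covariance of the training scores are stored for
#' Mahalanobis-distance prediction.
#'
#' @param X numeric matrix (samples x variables) or a `transformed_matrix`;
#'   columns are centered internally (training means stored), so
#'   cross-validation folds are centered on their own training data.
#' @param y class labels, `"H"`/`"L"`, at least two samples per class.
#' @param ncomp number of components requested; reduced automatically if X is
#'   deflated to numerical rank exhaustion first.
#' @param max_iter,tol NIPALS inner-loop controls.
#' @return Object of class `plsda` with elements `weights` (normalized, p x a),
#'   `x_loadings`, `x_scores`, `y_loadings`, `n_components`, `x_center`,
#'   `retained_ids`, `classes`, `centroids`, `score_cov`, `explained_y`
#'   (per-component y-variance, used by VIP), `y`.
#' @export
plsda_fit <- function(X, y, ncomp = 2, max_iter = 500, tol = 1e-12) {
  X <- .as_matrix(X)
  y <- .check_labels(y, nrow(X))
  if (min(table(y)) < 2) stop("need at least two samples per class")
  if (ncomp < 1) stop("ncomp must be >= 1")
  ncomp <- min(ncomp, nrow(X) - 1L, ncol(X))
  x_center <- colMeans(X)
  Xd <- sweep(X, 2, x_center)
  Yd <- .dummy_y(y)
  p <- ncol(X)
  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, nrow(X), ncomp)
  Q <- matrix(0, 2, ncomp)
  ssy <- numeric(ncomp)
  a <- 0L
  for (comp in seq_len(ncomp)) {
    if (sum(Yd^2) < tol || sum(Xd^2) < tol) break
    u <- Yd[, which.max(colSums(Yd^2))]
    tt_old <- rep(Inf, nrow(X))
    tt <- NULL
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)[, 1]
      nw <- sqrt(sum(w^2))
      if (nw < tol) break
      w <- w / nw
      tt <- (Xd %*% w)[, 1]
      sst <- sum(tt^2)
      if (sst < tol) break
      q <- crossprod(Yd, tt)[, 1] / sst
      u <- (Yd %*% q)[, 1] / sum(q^2)
      if (sum((tt - tt_old)^2) / max(sst, tol) < tol) { converged <- TRUE; break }
      tt_old <- tt
    }
    if (is.null(tt) || sum(tt^2) < tol) break
    if (!converged && it == max_iter)
      stop(sprintf("NIPALS did not converge for component %d", comp))
    a <- comp
    sst <- sum(tt^2)
    pl <- crossprod(Xd, tt)[, 1] / sst
    W[, a] <- w; P[, a] <- pl; Tm[, a] <- tt; Q[, a] <- q
    ssy[a] <- sum(q^2) * sst   # y-variance captured by component a
    Xd <- Xd - tcrossprod(tt, pl)
    Yd <- Yd - tcrossprod(tt, q)
  }
  if (a == 0L) stop("no PLS component could be extracted")
  keep <- seq_len(a)
  W <- W[, keep, drop = FALSE]; P <- P[, keep, drop = FALSE]
  Tm <- Tm[, keep, drop = FALSE]; Q <- Q[, keep, drop = FALSE]
  rownames(W) <- rownames(P) <- colnames(X)
  centroids <- rbind(H = colMeans(Tm[y == "H", , drop = FALSE]),
                     L = colMeans(Tm[y == "L", , drop = FALSE]))
  dev <- Tm - centroids[y, , drop = FALSE]
  score_cov <- crossprod(dev) / (nrow(X) - 2L)
  structure(
    list(weights = W, x_loadings = P, x_scores = Tm, y_loadings = Q,
         n_components = a, x_center = x_center,
         retained_ids = colnames(X), classes = .CLASSES,
         centroids = centroids, score_cov = score_cov,
         explained_y = ssy[keep], y = y),
    class = "plsda")
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("plsda: %d components, %d variables, %d samples (H=%d, L=%d)\n",
              x$n_components, nrow(x$weights), nrow(x$x_scores),
              sum(x$y == "H"), sum(x$y == "L")))
  invisible(x)
}

# rotation projecting centered X onto the first k score columns
.rotation <- function(model, k) {
  Wk <- model$weights[, seq_len(k), drop = FALSE]
  Pk <- model$x_loadings[, seq_len(k), drop = FALSE]
  Wk %*% solve(crossprod(Pk, Wk))
}

#' Predict classes with a fitted PLS-DA model
#'
#' Projects new samples into the training score space and assigns each to the
#' class whose training-score centroid is nearest under the Mahalanobis
#' distance with the pooled within-class score covariance (ridge-regularized
#' for invertibility).
#'
#' @param object a fitted [plsda_fit()] model.
#' @param newdata matrix or `transformed_matrix` with the model's variables.
#' @param ncomp number of leading components to use (default: all fitted).
#' @param ... unused.
#' @return Character vector of predicted labels.
#' @export
predict.plsda <- function(object, newdata, ncomp = object$n_components, ...) {
  Xn <- .as_matrix(newdata)
  if (ncol(Xn) != length(object$x_center))
    stop("newdata columns do not match the fitted model")
  k <- min(ncomp, object$n_components)
  Tn <- sweep(Xn, 2, object$x_center) %*% .rotation(object, k)
  S <- object$score_cov[seq_len(k), seq_len(k), drop = FALSE] +
    diag(.RIDGE, k)
  Sinv <- solve(S)
  d2 <- sapply(object$classes, function(cl) {
    dev <- sweep(Tn, 2, object$centroids[cl, seq_len(k)])
    rowSums((dev %*% Sinv) * dev)
  })
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
  object$classes[max.col(-d2, ties.method = "first")]
}

#' @rdname predict.plsda
#' @param model a fitted [plsda_fit()] model.
#' @export
plsda_predict <- function(model, newdata, ncomp = model$n_components) {
  predict(model, newdata, ncomp = ncomp)
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt(p * sum_a SS_a (w_ja / ||w_a||)^2 / sum_a SS_a)` where `SS_a`
#' is the y-variance explained by component a and p the number of variables;
#' the mean squared VIP over variables is exactly 1.
#'
#' @param model a fitted [plsda_fit()] model.
#' @return Named numeric vector of VIP scores.
#' @export
plsda_vip <- function(model) {
  stopifnot(inherits(model, "plsda"))
  ss <- model$explained_y
  if (sum(ss) <= 0) stop("VIP undefined: model explains no y-variance")
  W2 <- model$weights^2   # columns already unit-norm
  p <- nrow(W2)
  setNames(sqrt(p * as.numeric(W2 %*% ss) / sum(ss)), rownames(W2))
}

# balanced error rate: unweighted mean of per-class misclassification rates
.ber <- function(true, pred) {
  mean(sapply(unique(true), function(cl) mean(pred[true == cl] != cl)))
}

# stratified fold assignment; returns integer folds 1..k per sample
.assign_folds <- function(y, folds) {
  f <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    f[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

# one repeat of k-fold CV: pooled out-of-fold predictions for each ncomp
# in 1..max_ncomp (columns). Redraws the fold assignment if any training
# split lacks a class.
.cv_predict_once <- function(X, y, folds, max_ncomp) {
  repeat {
    f <- .assign_folds(y, folds)
    ok <- all(sapply(seq_len(folds), function(k)
      length(unique(y[f != k])) == 2))
    if (ok) break
    message("redrawing fold assignment: a training split lacked a class")
  }
  pred <- matrix(NA_character_, length(y), max_ncomp)
  for (k in seq_len(folds)) {
    tr <- f != k
    fitc <- min(max_ncomp, sum(tr) - 1L, ncol(X))
    m <- plsda_fit(X[tr, , drop = FALSE], y[tr], ncomp = fitc)
    for (a in seq_len(max_ncomp))
      pred[!tr, a] <- predict(m, X[!tr, , drop = FALSE],
                              ncomp = min(a, m$n_components))
  }
  pred
}

#' Tune the number of PLS-DA components by balanced error rate
#'
#' Repeated stratified k-fold cross-validation; for each candidate component
#' count the BER of the pooled out-of-fold predictions is computed per repeat
#' and averaged. The chosen component count attains the minimum mean BER
#' (ties favour fewer components).
#'
#' @param X matrix or `transformed_matrix`.
#' @param y class labels.
#' @param max_ncomp largest candidate component count (capped at samples - 2
#'   and the variable count).
#' @param folds folds per repeat (default 4).
#' @param repeats CV repeats (default 100).
#' @param seed RNG seed.
#' @return Object of class `plsda_cv`: list with `ber_by_ncomp`,
#'   `chosen_ncomp`, `folds`, `repeats`, `seed`.
#' @export
plsda_tune <- function(X, y, max_ncomp = 10, folds = 4, repeats = 100,
                       seed = 1) {
  X <- .as_matrix(X)
  y <- .check_labels(y, nrow(X))
  max_ncomp <- max(1L, min(max_ncomp, nrow(X) - 2L, ncol(X)))
  set.seed(seed)
  ber <- matrix(NA_real_, repeats, max_ncomp)
  for (r in seq_len(repeats)) {
    pred <- .cv_predict_once(X, y, folds, max_ncomp)
    ber[r, ] <- apply(pred, 2, function(pp) .ber(y, pp))
  }
  mean_ber <- colMeans(ber)
  structure(
    list(ber_by_ncomp = mean_ber,
         chosen_ncomp = which.min(mean_ber),
         folds = folds, repeats = repeats, seed = seed),
    class = "plsda_cv")
}

#' @export
print.plsda_cv <- function(x, ...) {
  cat(sprintf("plsda_cv: %d-fold x %d repeats; chosen %d component(s), BER %.4f\n",
              x$folds, x$repeats, x$chosen_ncomp,
              x$ber_by_ncomp[x$chosen_ncomp]))
  invisible(x)
}

#' Iterative VIP-based variable selection
#'
#' Alternates (i) tuning the component count by cross-validated BER, (ii)
#' fitting on the current variables, and (iii) removing every variable with
#' VIP < 1, until no variable falls below 1, the cross-validated BER stops
#' improving, or fewer than two variables would remain. The returned model is
#' the iteration with the minimum cross-validated BER (ties favour fewer
#' variables).
#'
#' @param X matrix or `transformed_matrix`.
#' @param y class labels.
#' @param folds,repeats cross-validation settings per iteration.
#' @param max_ncomp tuning grid upper bound.
#' @param seed RNG seed (each iteration offsets it deterministically).
#' @return List with `model` (the winning [plsda_fit()] fit, with `vip`
#'   attached), `cv` (its `plsda_cv`), and `trace` (data.frame: iteration,
#'   n_vars, ncomp, ber) with the retained variable sets as the
#'   `"variable_sets"` attribute.
#' @export
plsda_select <- function(X, y, folds = 4, repeats = 100, max_ncomp = 10,
                         seed = 1) {
  X <- .as_matrix(X)
  y <- .check_labels(y, nrow(X))
  if (ncol(X) < 2) stop("need at least two variables")
  vars <- colnames(X)
  if (is.null(vars)) vars <- colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  models <- list(); cvs <- list(); var_sets <- list()
  trace <- data.frame(iteration = integer(), n_vars = integer(),
                      ncomp = integer(), ber = numeric())
  it <- 0L
  repeat {
    it <- it + 1L
    Xc <- X[, vars, drop = FALSE]
    cv <- plsda_tune(Xc, y, max_ncomp = max_ncomp, folds = folds,
                     repeats = repeats, seed = seed + it - 1L)
    m <- plsda_fit(Xc, y, ncomp = cv$chosen_ncomp)
    vip <- plsda_vip(m)
    models[[it]] <- m; cvs[[it]] <- cv; var_sets[[it]] <- vars
    trace <- rbind(trace, data.frame(
      iteration = it, n_vars = length(vars), ncomp = m$n_components,
      ber = cv$ber_by_ncomp[cv$chosen_ncomp]))
    drop <- vars[vip < 1]
    if (length(drop) == 0L) break
    if (length(vars) - length(drop) < 2L) break
    if (it > 1L && trace$ber[it] > trace$ber[it - 1L]) break
    vars <- setdiff(vars, drop)
  }
  cand <- which(trace$ber == min(trace$ber))
  best <- cand[which.min(trace$n_vars[cand])]
  model <- models[[best]]
  model$vip <- plsda_vip(model)
  attr(trace, "variable_sets") <- var_sets
  list(model = model, cv = cvs[[best]], trace = trace)
}

# turn an accumulated 2x2 count matrix (rows = true class H/L, cols =
# predicted) into the validation report; class L (resilient) is the positive
.confusion_report <- function(counts, folds, repeats, seed,
                              permuted = FALSE) {
  pct <- sweep(counts, 1, rowSums(counts), "/") * 100
  tp <- counts["L", "L"]; fn <- counts["L", "H"]
  fp <- counts["H", "L"]; tn <- counts["H", "H"]
  structure(
    list(confusion = pct, counts = counts,
         accuracy = (tp + tn) / sum(counts),
         precision = tp / (tp + fp),
         permuted = permuted,
         permuted_tp_percent = if (permuted) pct["L", "L"] else NA_real_,
         folds = folds, repeats = repeats, seed = seed),
    class = "plsda_validation")
}

#' Confusion-matrix report from raw counts
#'
#' Utility turning a 2x2 table of prediction counts (rows: true class H then
#' L; columns: predicted H then L) into class-wise percentages, accuracy and
#' precision, with the resilient class L as the true positive.
#'
#' @param counts 2x2 numeric matrix with dimnames `c("H","L")` both ways.
#' @return A `plsda_validation` object.
#' @export
confusion_report <- function(counts) {
  stopifnot(is.matrix(counts), all(dim(counts) == 2))
  dimnames(counts) <- list(.CLASSES, .CLASSES)
  .confusion_report(counts, folds = NA, repeats = NA, seed = NA)
}

#' @export
print.plsda_validation <- function(x, ...) {
  cat(if (isTRUE(x$permuted)) "permuted confusion matrix" else
    "confusion matrix", "(row %):\n")
  print(round(x$confusion, 2))
  if (isTRUE(x$permuted))
    cat(sprintf("permuted true-positive percentage: %.1f%%\n",
                x$permuted_tp_percent))
  else
    cat(sprintf("accuracy %.3f, precision %.3f (positive class: L, resilient)\n",
                x$accuracy, x$precision))
  invisible(x)
}

.accumulate_cv_counts <- function(X, y, ncomp, folds) {
  pred <- .cv_predict_once(X, y, folds, ncomp)[, ncomp]
  counts <- matrix(0, 2, 2, dimnames = list(.CLASSES, .CLASSES))
  for (cl in .CLASSES)
    for (pr in .CLASSES)
      counts[cl, pr] <- sum(y == cl & pred == pr)
  counts
}

#' Validate a final PLS-DA model by repeated cross-validation
#'
#' Aggregates out-of-fold predictions over repeated stratified k-fold
#' cross-validation (refitting on each training split, restricted to the
#' model's retained variables and component count) into a confusion matrix of
#' class-wise percentages; accuracy and precision take the resilient class L
#' as the true positive.
#'
#' @param model a fitted [plsda_fit()] model (e.g. from [plsda_select()]).
#' @param X matrix or `transformed_matrix` containing the model's variables.
#' @param y class labels.
#' @param folds folds (default 4).
#' @param repeats CV repeats (default 10000; scale down for quick checks).
#' @param seed RNG seed.
#' @return A `plsda_validation` object.
#' @export
plsda_validate <- function(model, X, y, folds = 4, repeats = 10000,
                           seed = 1) {
  X <- .as_matrix(X)
  y <- .check_labels(y, nrow(X))
  if (!all(model$retained_ids %in% colnames(X)))
    stop("X is missing variables retained by the model")
  Xr <- X[, model$retained_ids, drop = FALSE]
  set.seed(seed)
  counts <- matrix(0, 2, 2, dimnames = list(.CLASSES, .CLASSES))
  for (r in seq_len(repeats))
    counts <- counts + .accumulate_cv_counts(Xr, y, model$n_components, folds)
  .confusion_report(counts, folds, repeats, seed)
}

#' Permuted-confusion validation (label-randomization null)
#'
#' Per repeat the class labels are permuted uniformly at random (preserving
#' the class counts) and one round of stratified k-fold cross-validated
#' prediction is run; counts are aggregated against the permuted labels. For
#' balanced classes the permuted true-positive percentage is expected at the
#' 50% chance level, so values far above it on the real labels indicate a
#' non-spurious classifier.
#'
#' @inheritParams plsda_validate
#' @param repeats number of label permutations (default 1000).
#' @return A `plsda_validation` object with `permuted_tp_percent`.
#' @export
plsda_permute <- function(model, X, y, folds = 4, repeats = 1000, seed = 1) {
  X <- .as_matrix(X)
  y <- .check_labels(y, nrow(X))
  if (!all(model$retained_ids %in% colnames(X)))
    stop("X is missing variables retained by the model")
  Xr <- X[, model$retained_ids, drop = FALSE]
  set.seed(seed)
  counts <- matrix(0, 2, 2, dimnames = list(.CLASSES, .CLASSES))
  for (r in seq_len(repeats)) {
    yp <- sample(y)
    counts <- counts + .accumulate_cv_counts(Xr, yp, model$n_components, folds)
  }
  .confusion_report(counts, folds, repeats, seed, permuted = TRUE)
}
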