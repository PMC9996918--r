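sep_data <- function(n_per = 8, p = 6, gap = 6, noise = 0.3, seed = 31) {
  # classes perfectly separated along variable 1, the rest pure noise
  set.seed(seed)
  y <- rep(c("H", "L"), each = n_per)
  X <- matrix(rnorm(2 * n_per * p, sd = noise), 2 * n_per, p,
              dimnames = list(NULL, paste0("V", 1:p)))
  X[y == "H", 1] <- X[y == "H", 1] + gap
  list(X = X, y = y)
}

test_that("a perfectly separable variable dominates component 1 and trains to BER 0", {
  d <- sep_data()
  m <- plsda_fit(d$X, d$y, ncomp = 2)
  expect_equal(which.max(abs(m$weights[, 1])), c(V1 = 1L))
  expect_identical(predict(m, d$X), d$y)
  expect_equal(metabodisc:::.ber(d$y, predict(m, d$X)), 0)
})

test_that("component-1 weights equal the dominant singular vector of X'Y", {
  set.seed(32)
  X <- matrix(rnorm(8 * 5), 8, 5)
  y <- rep(c("H", "L"), each = 4)
  m <- plsda_fit(X, y, ncomp = 1)
  Xc <- scale(X, scale = FALSE)
  Yd <- scale(cbind(y == "H", y == "L"), scale = FALSE)
  u1 <- svd(crossprod(Xc, Yd))$u[, 1]
  cosine <- abs(sum(m$weights[, 1] * u1)) /
    sqrt(sum(m$weights[, 1]^2) * sum(u1^2))
  expect_gt(cosine, 1 - 1e-10)
})

test_that("fitting is equivariant to simultaneous row permutation", {
  d <- sep_data(noise = 1.5, gap = 1.5, seed = 33)
  set.seed(34); perm <- sample(nrow(d$X))
  m1 <- plsda_fit(d$X, d$y, ncomp = 2)
  m2 <- plsda_fit(d$X[perm, ], d$y[perm], ncomp = 2)
  expect_equal(m2$weights, m1$weights, tolerance = 1e-8)
  Xnew <- d$X + 0.1
  expect_identical(predict(m1, Xnew), predict(m2, Xnew))
})

test_that("prediction reproduces brute-force Mahalanobis assignment", {
  d <- sep_data(n_per = 10, p = 8, gap = 2, noise = 1, seed = 35)
  m <- plsda_fit(d$X, d$y, ncomp = 2)
  set.seed(36)
  Xn <- matrix(rnorm(40 * 8), 40, 8)
  Tn <- sweep(Xn, 2, m$x_center) %*%
    (m$weights %*% solve(crossprod(m$x_loadings, m$weights)))
  S <- m$score_cov + diag(1e-8, 2)
  lab <- apply(Tn, 1, function(t) {
    d2 <- sapply(c("H", "L"), function(cl)
      t(t - m$centroids[cl, ]) %*% solve(S) %*% (t - m$centroids[cl, ]))
    names(which.min(d2))
  })
  expect_identical(predict(m, Xn), unname(lab))
  # a sample whose scores land exactly on a class centroid gets that class:
  # x = x_center + P t* has scores t* because (P t*)' W (P'W)^-1 = t*'
  for (cl in c("H", "L")) {
    xc <- m$x_center + (m$x_loadings %*% m$centroids[cl, ])[, 1]
    expect_identical(predict(m, matrix(xc, 1)), cl)
  }
  # one component collapses to nearest centroid on the scalar score
  m1 <- plsda_fit(d$X, d$y, ncomp = 1)
  t1 <- sweep(Xn, 2, m1$x_center) %*%
    (m1$weights %*% solve(crossprod(m1$x_loadings, m1$weights)))
  nc <- ifelse(abs(t1 - m1$centroids["H", 1]) <
                 abs(t1 - m1$centroids["L", 1]), "H", "L")
  expect_identical(predict(m1, Xn), as.vector(nc))
})

test_that("VIP satisfies its normalization and closed forms", {
  d <- sep_data(n_per = 10, p = 7, gap = 2, noise = 1, seed = 37)
  m2 <- plsda_fit(d$X, d$y, ncomp = 2)
  v <- plsda_vip(m2)
  expect_equal(sum(v^2), 7, tolerance = 1e-8)   # mean VIP^2 = 1
  # single component: VIP_j = sqrt(p) |w_j| / ||w||
  m1 <- plsda_fit(d$X, d$y, ncomp = 1)
  expect_equal(plsda_vip(m1),
               sqrt(7) * abs(m1$weights[, 1]) /
                 sqrt(sum(m1$weights[, 1]^2)),
               tolerance = 1e-10)
  # two components: direct evaluation of the VIP formula
  ss <- m2$explained_y
  w <- m2$weights
  oracle <- sqrt(7 * (w^2 %*% ss) / sum(ss))[, 1]
  expect_equal(v, oracle, tolerance = 1e-10)
})

test_that("scores and VIP agree with the mixOmics reference implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(38)
  X <- matrix(rnorm(26 * 30), 26, 30,
              dimnames = list(NULL, paste0("V", 1:30)))
  y <- rep(c("H", "L"), each = 13)
  X[y == "H", 1:5] <- X[y == "H", 1:5] + 1
  m <- plsda_fit(X, y, ncomp = 2)
  mo <- mixOmics::plsda(X, factor(y), ncomp = 2, scale = FALSE)
  cs <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  expect_gt(cs(m$x_scores[, 1], mo$variates$X[, 1]), 0.999)
  expect_gt(cs(m$x_scores[, 2], mo$variates$X[, 2]), 0.999)
  expect_equal(unname(plsda_vip(m)), unname(mixOmics::vip(mo)[, 2]),
               tolerance = 1e-8)
})

test_that("balanced error rate averages the class-wise error rates", {
  true <- rep(c("H", "L"), each = 10)
  pred <- true
  pred[1] <- "L"                      # 10% error in H
  pred[11:13] <- "H"                  # 30% error in L
  expect_equal(metabodisc:::.ber(true, pred), 0.2)
})

test_that("cross-validated tuning finds separable data and is deterministic", {
  d <- sep_data(n_per = 13, p = 10, gap = 5, noise = 0.5, seed = 39)
  cv <- plsda_tune(d$X, d$y, max_ncomp = 3, repeats = 20, seed = 40)
  expect_lte(cv$ber_by_ncomp[cv$chosen_ncomp], 0.02)
  expect_true(all(cv$ber_by_ncomp >= 0 & cv$ber_by_ncomp <= 1))
  expect_equal(cv$chosen_ncomp, unname(which.min(cv$ber_by_ncomp)))
  cv2 <- plsda_tune(d$X, d$y, max_ncomp = 3, repeats = 20, seed = 40)
  expect_identical(cv, cv2)
})

test_that("cross-validated BER averaged over label randomizations hits the 50% chance level", {
  # a single fixed label assignment has dataset-level variance around 0.5;
  # the chance level emerges over many fresh randomizations, so aggregate
  # permuted-CV predictions and read the BER off the pooled confusion matrix
  set.seed(41)
  X <- matrix(rnorm(26 * 20), 26, 20,
              dimnames = list(NULL, paste0("V", 1:20)))
  y <- rep(c("H", "L"), each = 13)
  m <- plsda_fit(X, y, ncomp = 1)
  perm <- plsda_permute(m, X, y, repeats = 200, seed = 42)
  ber <- (perm$confusion["H", "L"] + perm$confusion["L", "H"]) / 200
  expect_equal(ber, 0.5, tolerance = 0.08)
})

test_that("iterative VIP selection terminates, keeps the best iteration, and enriches signal", {
  d <- generate_dataset(sim_config(n_metabolites = 80, n_informative = 8,
                                   seed = 43))
  prep <- suppressMessages(preprocess(inject_missingness(d$table, 0.05)))
  sel <- plsda_select(prep$matrix, prep$matrix$population,
                      repeats = 15, seed = 44)
  expect_equal(min(sel$trace$ber),
               unname(sel$cv$ber_by_ncomp[sel$cv$chosen_ncomp]))
  expect_true(all(diff(sel$trace$n_vars) < 0))
  expect_identical(sort(sel$model$retained_ids),
                   sort(attr(sel$trace, "variable_sets")[[
                     which(sel$trace$ber == min(sel$trace$ber))[1]]]))
  inf <- d$truth$metabolite_id[d$truth$true_effect != 0]
  frac_sel <- mean(inf %in% sel$model$retained_ids)
  expect_gt(frac_sel, length(sel$model$retained_ids) / 80)  # enriched
})

test_that("validation reports confusion percentages, accuracy and precision", {
  # formula arithmetic: TP=9, FN=2, FP=1, TN=8 with L the positive class
  counts <- matrix(c(8, 2, 1, 9), 2, 2)
  rep9 <- confusion_report(counts)
  expect_equal(rep9$precision, 0.9)
  expect_equal(rep9$accuracy, 17 / 20)
  expect_equal(unname(rowSums(rep9$confusion)), c(100, 100), tolerance = 0.01)

  # perfect classifier: diagonal 100%, accuracy and precision 1
  d <- sep_data(n_per = 13, p = 6, gap = 6, noise = 0.3, seed = 45)
  m <- plsda_fit(d$X, d$y, ncomp = 1)
  val <- plsda_validate(m, d$X, d$y, repeats = 25, seed = 46)
  expect_equal(unname(diag(val$confusion)), c(100, 100))
  expect_equal(val$accuracy, 1)
  expect_equal(val$precision, 1)
})

test_that("validation percentages are Monte-Carlo stable across seeds", {
  d <- sep_data(n_per = 13, p = 8, gap = 1.6, noise = 1, seed = 47)
  m <- plsda_fit(d$X, d$y, ncomp = 1)
  v1 <- plsda_validate(m, d$X, d$y, repeats = 500, seed = 48)
  v2 <- plsda_validate(m, d$X, d$y, repeats = 500, seed = 49)
  expect_lt(max(abs(v1$confusion - v2$confusion)), 2)
})

test_that("label permutation preserves class counts and its report exposes the TP rate", {
  d <- sep_data(n_per = 13, p = 6, gap = 4, noise = 0.5, seed = 50)
  m <- plsda_fit(d$X, d$y, ncomp = 1)
  perm <- plsda_permute(m, d$X, d$y, repeats = 50, seed = 51)
  # each permuted repeat contributes 13 samples per class row
  expect_equal(unname(rowSums(perm$counts)), c(50 * 13, 50 * 13))
  expect_equal(perm$permuted_tp_percent, perm$confusion["L", "L"])
})
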