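# Fixtures are generated in code; nothing is read from disk.

# small hand-crafted peak table: n samples per group, p metabolites,
# log-normal intensities, optional NA positions
make_table <- function(n_per_group = 13, p = 8, n_methods = 2, seed = 10) {
  set.seed(seed)
  n <- 2 * n_per_group
  vals <- matrix(exp(rnorm(n * p, 5, 1)), n, p)
  peak_table(vals,
             population = rep(c("L", "H"), each = n_per_group),
             method = paste0("m", ((seq_len(p) - 1) %% n_methods) + 1))
}

# brute-force symmetric Procrustes correlation via the SVD trace formula
oracle_procrustes <- function(x, y) {
  cx <- scale(x, scale = FALSE); cy <- scale(y, scale = FALSE)
  cx <- cx / sqrt(sum(cx^2)); cy <- cy / sqrt(sum(cy^2))
  sum(svd(crossprod(cx, cy))$d)
}

# brute-force narrowest-window HPD by explicit loop
oracle_hpd <- function(draws, prob = 0.95) {
  x <- sort(draws); n <- length(x); m <- ceiling(prob * n)
  best <- c(x[1], x[n]); bw <- Inf
  for (i in seq_len(n - m + 1)) {
    w <- x[i + m - 1] - x[i]
    if (w < bw) { bw <- w; best <- c(x[i], x[i + m - 1]) }
  }
  best
}

# closed-form flat-prior two-sample posterior of D = mu_H - mu_L:
# location-scale t with n1 + n2 - 2 df
analytic_posterior <- function(y, labels) {
  yh <- y[labels == "H"]; yl <- y[labels == "L"]
  df <- length(y) - 2
  sp <- sqrt((sum((yh - mean(yh))^2) + sum((yl - mean(yl))^2)) / df)
  list(location = mean(yh) - mean(yl),
       scale = sp * sqrt(1 / length(yh) + 1 / length(yl)),
       df = df)
}
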