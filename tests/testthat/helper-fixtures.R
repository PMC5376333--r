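# Shared builders for small in-code fixtures and independent oracles.

# Newick for a star (single polytomy) tree with common depth.
star_newick <- function(labels, depth = 1) {
  paste0("(", paste0(labels, ":", depth, collapse = ","), ");")
}

star_tree <- function(n = 4, depth = 1) {
  parse_newick(star_newick(paste0("s", seq_len(n)), depth))
}

# Textbook SMA fit from sample moments (independent closed-form oracle).
sma_oracle <- function(x, y) {
  sxy <- stats::cov(x, y)
  s <- sign(sxy)
  if (s == 0) s <- 1
  b1 <- s * stats::sd(y) / stats::sd(x)
  b0 <- mean(y) - b1 * mean(x)
  list(beta0 = b0, beta1 = b1,
       r2 = sxy^2 / (stats::var(x) * stats::var(y)))
}

# Brute-force matrix-normal log-density oracle: builds the full nm x nm
# Kronecker covariance and evaluates the Gaussian density directly, with the
# rate matrix at its ML value.  Deliberately naive (dense solve()).
matnorm_loglik_oracle <- function(C, X) {
  X <- as.matrix(X)
  n <- nrow(X); m <- ncol(X)
  one <- rep(1, n)
  Ci <- solve(C)
  a <- drop(solve(t(one) %*% Ci %*% one) %*% t(one) %*% Ci %*% X)
  E <- X - one %*% t(a)
  R <- t(E) %*% Ci %*% E / n
  S <- kronecker(R, C)
  e <- as.vector(E)
  drop(-0.5 * (length(e) * log(2 * pi) +
               as.numeric(determinant(S, logarithm = TRUE)$modulus) +
               t(e) %*% solve(S) %*% e))
}

# Species-mean bivariate traits under the allometric lambda-BM model:
# x ~ root + BM dev, y = intercept + slope * x + residual-axis dev.
sim_allometric_xy <- function(tree, lambda = 0.7, slope = 1.4,
                              intercept = -2.45, rate_x = 0.05,
                              rate_resid = 1e-4, root_x = 3.4) {
  dev <- sim_traits_lambda_bm(tree, lambda = lambda,
                              R = diag(c(rate_x, rate_resid)),
                              root_state = c(0, 0))
  x <- root_x + dev[, 1]
  y <- intercept + slope * x + dev[, 2]
  list(x = setNames(x, rownames(dev)), y = setNames(y, rownames(dev)))
}

# Minimal specimen table written to a temp file; returns the path.
write_toy_specimens <- function(lines, sep = ",") {
  path <- tempfile(fileext = if (sep == ",") ".csv" else ".tsv")
  writeLines(lines, path)
  path
}
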