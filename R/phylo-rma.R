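# Statistical core: GLS phylogenetic means, profile likelihood of the
# bivariate Brownian-motion model, Pagel's lambda ML estimation, the RMA
# line, isometry tests, slope confidence intervals, and the lambda LRT.

# Cholesky of a covariance matrix with an actionable error message.
.chol_or_stop <- function(C) {
  tryCatch(chol(C),
           error = function(e)
             stop("phylogenetic covariance matrix is not positive definite (",
                  conditionMessage(e),
                  "); check for duplicated tips or zero-length terminal branches",
                  call. = FALSE))
}

# GLS mean given a precomputed upper Cholesky factor U (C = U'U).
.gls_mean_chol <- function(U, X) {
  n <- nrow(X)
  Ci1 <- backsolve(U, backsolve(U, rep(1, n), transpose = TRUE))
  drop(crossprod(Ci1, X)) / sum(Ci1)
}

#' GLS phylogenetic mean (root-state estimate)
#'
#' Computes `a = (1' C^-1 1)^-1 1' C^-1 X`, one entry per trait column: the
#' generalized-least-squares estimate of the ancestral (root) trait value
#' that weights tips by their phylogenetic non-independence.  With `C` the
#' identity this reduces to the arithmetic column mean, and it is invariant
#' to rescaling `C` by any positive constant.
#'
#' @param C Positive-definite phylogenetic covariance matrix.
#' @param X Numeric vector or n x m matrix of tip values, rows aligned with
#'   the rows of `C`.
#' @return Numeric vector of length m.
#' @export
gls_mean <- function(C, X) {
  X <- as.matrix(X)
  if (nrow(X) != nrow(C)) stop("rows of X must align with C", call. = FALSE)
  .gls_mean_chol(.chol_or_stop(C), X)
}

#' Profile log-likelihood of traits under a given covariance structure
#'
#' Evaluates the log-likelihood of an n x m trait matrix under the
#' matrix-normal model with among-species covariance `C_lambda` and the
#' evolutionary rate matrix profiled out at its ML value
#' `R_ML = E' C^-1 E / n` (E being residuals from the GLS means):
#' \deqn{\ell = -\tfrac12 [\, nm\log(2\pi) + n\log|R_{ML}| + m\log|C| + nm \,].}
#' This is the quantity maximized over Pagel's lambda and differenced in the
#' lambda likelihood-ratio test.  The value is invariant to adding a constant
#' to any trait column.
#'
#' @param C_lambda Positive-definite (lambda-transformed) covariance matrix.
#' @param X Numeric vector or n x m matrix of trait values (log scale).
#' @return Log-likelihood (natural log), a scalar.
#' @export
profile_loglik <- function(C_lambda, X) {
  X <- as.matrix(X)
  n <- nrow(X); m <- ncol(X)
  if (n != nrow(C_lambda)) stop("rows of X must align with C_lambda", call. = FALSE)
  if (n < 2L) stop("at least 2 tips required", call. = FALSE)
  U <- .chol_or_stop(C_lambda)
  logdetC <- 2 * sum(log(diag(U)))
  a <- .gls_mean_chol(U, X)
  E <- X - rep(a, each = n)
  M <- backsolve(U, E, transpose = TRUE)       # M'M = E' C^-1 E
  R_ml <- crossprod(M) / n
  ld <- determinant(R_ml, logarithm = TRUE)
  if (ld$sign <= 0 || !is.finite(ld$modulus)) {
    v <- diag(R_ml)
    bad <- colnames(X)[v <= .Machine$double.eps * max(v, 1)]
    if (!length(bad)) bad <- "(collinear trait columns)"
    stop("degenerate trait column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  -0.5 * (n * m * log(2 * pi) + n * as.numeric(ld$modulus) + m * logdetC + n * m)
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Maximizes [profile_loglik()] over lambda in \[0, 1\] for traits `X` on
#' `tree`, using a 21-point grid pre-scan followed by bounded scalar
#' optimization (tolerance 1e-8) on the bracketing interval, with explicit
#' endpoint evaluation at 0 and 1.  On a star phylogeny the covariance does
#' not depend on lambda; the likelihood is then flat and lambda is reported
#' as 0 with `identifiable = FALSE`.
#'
#' @param tree A `"phylo"` object.
#' @param X Numeric vector or n x m matrix of tip trait values, with
#'   rownames (or names) matching `tree$tip.label`.
#' @param tol Convergence tolerance for the scalar optimization.
#' @param grid_n Number of pre-scan grid points on \[0, 1\].
#' @return List with `lambda_hat`, `loglik_hat`, `loglik0` (log-likelihood at
#'   lambda = 0) and `identifiable`.
#' @export
estimate_lambda <- function(tree, X, tol = 1e-8, grid_n = 21L) {
  X <- as.matrix(X)
  C <- vcv_matrix(tree)
  lbl <- rownames(X)
  if (!is.null(lbl)) {
    if (!setequal(lbl, rownames(C)))
      stop("rownames of X do not match tree tips", call. = FALSE)
    X <- X[rownames(C), , drop = FALSE]
  } else if (nrow(X) != nrow(C)) {
    stop("X has ", nrow(X), " rows but the tree has ", nrow(C), " tips",
         call. = FALSE)
  }
  if (nrow(X) < 3L) stop("lambda estimation requires at least 3 species", call. = FALSE)
  f <- function(l) profile_loglik(lambda_transform(C, l), X)
  grid <- seq(0, 1, length.out = grid_n)
  vals <- vapply(grid, f, numeric(1))
  if (!all(is.finite(vals)))
    stop("non-finite likelihood on the lambda grid (degenerate traits or tree)",
         call. = FALSE)
  if (diff(range(vals)) < 1e-10) {
    return(list(lambda_hat = 0, loglik_hat = vals[1L], loglik0 = vals[1L],
                identifiable = FALSE))
  }
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(grid_n, i + 1L)]
  opt <- optimize(f, interval = c(lo, hi), maximum = TRUE, tol = tol)
  cand <- c(opt$maximum, grid[i], 0, 1)
  cv <- c(opt$objective, vals[i], vals[1L], vals[grid_n])
  best <- which.max(cv)
  list(lambda_hat = cand[best], loglik_hat = cv[best], loglik0 = vals[1L],
       identifiable = TRUE)
}

#' RMA line from GLS means and an evolutionary rate matrix
#'
#' The reduced-major-axis slope is `sign(R_xy) * sqrt(R_yy / R_xx)` and the
#' intercept passes the line through the GLS phylogenetic means.  Slope,
#' intercept, and squared evolutionary correlation are invariant to the
#' divisor used for `R`.
#'
#' @param a Length-2 vector of GLS means (x, y).
#' @param R 2 x 2 evolutionary rate/covariance matrix (x, y).
#' @return List with `beta0`, `beta1`, `r2_corr`.
#' @export
rma_line <- function(a, R) {
  if (length(a) != 2L || !all(dim(R) == 2L))
    stop("rma_line expects a length-2 mean vector and a 2x2 rate matrix", call. = FALSE)
  if (R[1, 1] <= 0 || R[2, 2] <= 0)
    stop("rate matrix has a nonpositive variance; traits degenerate", call. = FALSE)
  s <- sign(R[1, 2])
  if (s == 0) {
    warning("evolutionary covariance is exactly 0; slope sign set positive",
            call. = FALSE)
    s <- 1
  }
  beta1 <- s * sqrt(R[2, 2] / R[1, 1])
  beta0 <- a[2] - beta1 * a[1]
  list(beta0 = unname(beta0), beta1 = unname(beta1),
       r2_corr = unname(R[1, 2]^2 / (R[1, 1] * R[2, 2])))
}

#' Coefficient of determination of a fitted line
#'
#' `R^2 = 1 - SS_residual / SS_total` for the fitted values
#' `beta0 + beta1 * x`.  By default both sums of squares are ordinary
#' (`SS_total` about the arithmetic mean of `y`); `ss = "gls"` instead
#' weights both by `C^-1` and centers on the GLS mean.  RMA lines do not
#' minimize vertical residuals, so the value can be negative for poor fits.
#'
#' @param x,y Numeric vectors (log10 traits), same order.
#' @param beta0,beta1 Fitted intercept and slope.
#' @param ss `"ordinary"` (default) or `"gls"`.
#' @param C Covariance matrix, required for `ss = "gls"`.
#' @return Scalar R-squared.
#' @export
line_r2 <- function(x, y, beta0, beta1, ss = c("ordinary", "gls"), C = NULL) {
  ss <- match.arg(ss)
  e <- y - (beta0 + beta1 * x)
  if (ss == "ordinary") {
    sstot <- sum((y - mean(y))^2)
    ssres <- sum(e^2)
  } else {
    if (is.null(C)) stop("C is required for ss = \"gls\"", call. = FALSE)
    U <- .chol_or_stop(C)
    ag <- .gls_mean_chol(U, as.matrix(y))
    w <- function(v) sum(backsolve(U, v, transpose = TRUE)^2)
    sstot <- w(y - ag)
    ssres <- w(e)
  }
  if (sstot <= 0) stop("zero total sum of squares in y", call. = FALSE)
  1 - ssres / sstot
}

# Resolve a df policy to a number.  Clarke's (1980) approximation
# 2 + (n-2)/(1 + r2/2) is what phyl.RMA-style software reports.
.resolve_df <- function(df, n, r2_corr) {
  if (is.numeric(df)) return(df)
  switch(match.arg(df, c("n-2", "n-1", "clarke")),
         "n-2" = n - 2,
         "n-1" = n - 1,
         "clarke" = 2 + (n - 2) / (1 + r2_corr / 2))
}

#' t-test of the RMA slope against a predicted exponent
#'
#' Tests deviation of the fitted scaling exponent from the dimensional
#' prediction `h` (1 for length-on-length isometry) using the log-slope SMA
#' statistic
#' \deqn{T = |\log|\beta_1| - \log h| \,/\, \sqrt{(1 - r^2)/df},}
#' two-sided against a t distribution.  The statistic is symmetric in
#' `beta1` vs `1/beta1` when `h = 1`.
#'
#' @param beta1 Fitted RMA slope.
#' @param r2_corr Squared (evolutionary) correlation between the traits.
#' @param n Number of species.
#' @param h Predicted exponent (> 0), default 1.
#' @param df Degrees of freedom: `"n-2"` (default), `"n-1"`, `"clarke"`, or a
#'   number.
#' @return List with `t_stat`, `df`, `p_slope`, and `degenerate` (TRUE when
#'   `r2_corr = 1` with `beta1 != h`, in which case p = 0).
#' @export
slope_test <- function(beta1, r2_corr, n, h = 1, df = "n-2") {
  if (!is.numeric(h) || h <= 0) stop("predicted exponent h must be > 0", call. = FALSE)
  if (n < 3L) stop("slope test requires n >= 3", call. = FALSE)
  dfv <- .resolve_df(df, n, r2_corr)
  # Clarke's policy follows phyl.RMA-style software: the statistic keeps the
  # n-2 denominator, only the reference distribution uses Clarke's df.
  df_stat <- if (identical(df, "clarke")) n - 2 else dfv
  dl <- abs(log(abs(beta1)) - log(h))
  if (r2_corr >= 1) {
    if (dl == 0) return(list(t_stat = 0, df = dfv, p_slope = 1, degenerate = FALSE))
    return(list(t_stat = Inf, df = dfv, p_slope = 0, degenerate = TRUE))
  }
  t_stat <- dl / sqrt((1 - r2_corr) / df_stat)
  list(t_stat = t_stat, df = dfv,
       p_slope = 2 * pt(t_stat, df = dfv, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Confidence interval for the RMA slope
#'
#' Standard SMA interval: with `B = F(1 - alpha; 1, df) (1 - r^2)/df`, the
#' bounds are `beta1 * (sqrt(B + 1) -/+ sqrt(B))`.  The interval always
#' contains `beta1` and satisfies `ci_low * ci_high = beta1^2`.
#'
#' @inheritParams slope_test
#' @param alpha Significance level (default 0.05 for a 95% interval).
#' @return List with `ci_low`, `ci_high`, `degenerate` (TRUE when the
#'   interval collapses because `r2_corr >= 1`).
#' @export
slope_ci <- function(beta1, r2_corr, n, alpha = 0.05, df = "n-2") {
  if (n < 3L) stop("slope CI requires n >= 3", call. = FALSE)
  if (beta1 <= 0) stop("slope CI assumes beta1 > 0 (log-data slopes)", call. = FALSE)
  dfv <- .resolve_df(df, n, r2_corr)
  if (r2_corr >= 1)
    return(list(ci_low = beta1, ci_high = beta1, degenerate = TRUE))
  B <- qf(1 - alpha, 1, dfv) * (1 - r2_corr) / dfv
  list(ci_low = beta1 * (sqrt(B + 1) - sqrt(B)),
       ci_high = beta1 * (sqrt(B + 1) + sqrt(B)),
       degenerate = FALSE)
}

#' Likelihood-ratio test of phylogenetic signal (lambda vs lambda = 0)
#'
#' `Delta = 2 (loglik_hat - loglik0)`, clipped at 0, compared to a
#' chi-squared reference with 1 df.  Because lambda = 0 sits on the boundary
#' of the parameter space, the plain chi-squared reference is conservative;
#' `boundary = TRUE` uses the 50:50 mixture of chi-squared 0 and 1 df
#' instead.
#'
#' @param loglik_hat Log-likelihood at the lambda ML estimate.
#' @param loglik0 Log-likelihood at lambda = 0.
#' @param boundary Use the boundary mixture reference (default FALSE).
#' @return List with `lrt_stat` and `p_lambda`.
#' @export
lambda_lrt <- function(loglik_hat, loglik0, boundary = FALSE) {
  if (loglik_hat < loglik0 - 1e-8)
    stop("loglik_hat < loglik0: lambda was not maximized", call. = FALSE)
  d <- max(0, 2 * (loglik_hat - loglik0))
  p <- pchisq(d, df = 1, lower.tail = FALSE)
  if (boundary) p <- if (d == 0) 1 else 0.5 * p
  list(lrt_stat = d, p_lambda = p)
}

#' Phylogenetic reduced-major-axis regression
#'
#' Fits the RMA line of `y` on `x` (both on log10 scale) across species
#' related by `tree`, with the phylogenetic covariance structure modulated by
#' Pagel's lambda estimated by maximum likelihood on the bivariate data.
#' The returned fit bundles the line, the squared evolutionary correlation
#' and the ordinary R-squared, the lambda estimate with its likelihood-ratio
#' test against lambda = 0, and the isometry t-test and confidence interval
#' for the slope against the predicted exponent `h`.
#'
#' Species are matched by name: the tree is pruned internally to the species
#' present (with finite values) in both `x` and `y`.
#'
#' @param tree A `"phylo"` object.
#' @param x,y Named numeric vectors of species trait values on log10 scale
#'   (names are species labels matching tree tips).
#' @param h Predicted scaling exponent under the dimensional null (default 1,
#'   isometry for length-on-length).
#' @param lambda Optional fixed lambda in \[0, 1\]; `NULL` (default) estimates
#'   it by ML.
#' @param df Degrees-of-freedom policy for the slope test and CI: `"n-2"`
#'   (default), `"n-1"`, `"clarke"`, or a number.
#' @param alpha Significance level for the slope CI.
#' @param r2_ss Sum-of-squares convention for [line_r2()].
#' @param boundary_lrt Use the boundary mixture reference in [lambda_lrt()].
#' @return An object of class `"rma_fit"`: a list with elements `beta0`,
#'   `beta1`, `r2_corr`, `r2_line`, `lambda_hat`, `lambda_identifiable`,
#'   `loglik_hat`, `loglik0`, `ci_low`, `ci_high`, `t_stat`, `df`, `p_slope`,
#'   `lrt_stat`, `p_lambda`, `h`, `n`, `alpha`, `species`, `means`, `R`,
#'   `residuals`, `data`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):0.5,(C:1,D:1):0.5);")
#' x <- c(A = 2.0, B = 2.2, C = 2.6, D = 2.9)
#' y <- c(A = 1.1, B = 1.4, C = 1.9, D = 2.3)
#' fit <- phyl_rma(tr, x, y, h = 1)
#' fit$beta1
#' @export
phyl_rma <- function(tree, x, y, h = 1, lambda = NULL, df = "n-2",
                     alpha = 0.05, r2_ss = c("ordinary", "gls"),
                     boundary_lrt = FALSE) {
  r2_ss <- match.arg(r2_ss)
  if (is.null(names(x)) || is.null(names(y)))
    stop("x and y must be named by species", call. = FALSE)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  common <- intersect(intersect(names(x), names(y)), tree$tip.label)
  dropped <- setdiff(union(names(x), names(y)), c(common, ""))
  if (length(common) < 3L)
    stop("need at least 3 species shared between tree and both traits, got ",
         length(common),
         if (length(dropped)) paste0(" (unmatched: ",
                                     paste(head(dropped, 10), collapse = ", "), ")"),
         call. = FALSE)
  tree <- prune_to_taxa(tree, common)
  ord <- tree$tip.label
  X <- cbind(x = x[ord], y = y[ord])
  rownames(X) <- ord
  n <- length(ord)

  C <- vcv_matrix(tree)
  if (is.null(lambda)) {
    est <- estimate_lambda(tree, X)
  } else {
    ll <- function(l) profile_loglik(lambda_transform(C, l), X)
    est <- list(lambda_hat = lambda, loglik_hat = ll(lambda), loglik0 = ll(0),
                identifiable = TRUE)
  }
  Cl <- lambda_transform(C, est$lambda_hat)
  U <- .chol_or_stop(Cl)
  a <- .gls_mean_chol(U, X)
  E <- X - rep(a, each = n)
  M <- backsolve(U, E, transpose = TRUE)
  R <- crossprod(M) / (n - 1)
  line <- rma_line(a, R)
  r2p <- line_r2(X[, "x"], X[, "y"], line$beta0, line$beta1,
                  ss = r2_ss, C = Cl)
  st <- slope_test(line$beta1, line$r2_corr, n, h = h, df = df)
  ci <- slope_ci(abs(line$beta1), line$r2_corr, n, alpha = alpha, df = df)
  lrt <- lambda_lrt(est$loglik_hat, est$loglik0, boundary = boundary_lrt)
  resid <- X[, "y"] - (line$beta0 + line$beta1 * X[, "x"])

  structure(list(
    beta0 = line$beta0, beta1 = line$beta1,
    r2_corr = line$r2_corr, r2_line = r2p,
    lambda_hat = est$lambda_hat, lambda_identifiable = est$identifiable,
    loglik_hat = est$loglik_hat, loglik0 = est$loglik0,
    ci_low = ci$ci_low, ci_high = ci$ci_high, ci_degenerate = ci$degenerate,
    t_stat = st$t_stat, df = st$df, p_slope = st$p_slope,
    slope_degenerate = st$degenerate,
    lrt_stat = lrt$lrt_stat, p_lambda = lrt$p_lambda,
    h = h, n = n, alpha = alpha, r2_ss = r2_ss,
    species = ord, means = a, R = R, residuals = resid, data = X
  ), class = "rma_fit")
}

#' @export
print.rma_fit <- function(x, digits = 3, ...) {
  cat("Phylogenetic RMA regression (", x$n, " species)\n", sep = "")
  cat(sprintf("  beta0 = %.*f   beta1 = %.*f   95%% CI [%.*f, %.*f]\n",
              digits, x$beta0, digits, x$beta1,
              digits, x$ci_low, digits, x$ci_high))
  cat(sprintf("  R2 = %.*f   r2(evol. corr.) = %.*f\n",
              digits, x$r2_line, digits, x$r2_corr))
  cat(sprintf("  lambda = %.*f%s   LRT vs lambda=0: stat = %.*f, p = %.4g\n",
              digits, x$lambda_hat,
              if (!x$lambda_identifiable) " (unidentifiable)" else "",
              digits, x$lrt_stat, x$p_lambda))
  cat(sprintf("  slope test vs h = %g: t = %.*f, df = %.4g, p = %.4g\n",
              x$h, digits, x$t_stat, x$df, x$p_slope))
  invisible(x)
}

#' @export
coef.rma_fit <- function(object, ...) {
  c(beta0 = object$beta0, beta1 = object$beta1)
}

#' Flatten an RMA fit to a one-row data frame
#'
#' Columns mirror a scaling-table row: variable pair, n, R2, intercept,
#' slope, CI bounds, predicted exponent, lambda, slope-test and lambda-LRT
#' p-values.
#'
#' @param x An `"rma_fit"` object.
#' @param pair Label for the variable pair (e.g. `"VL_vs_BL"`).
#' @param ... Unused.
#' @param row.names,optional Ignored (data.frame method signature).
#' @export
as.data.frame.rma_fit <- function(x, row.names = NULL, optional = FALSE,
                                  pair = "y_vs_x", ...) {
  data.frame(pair = pair, n = x$n, R2 = x$r2_line,
             beta0 = x$beta0, beta1 = x$beta1,
             ci_low = x$ci_low, ci_high = x$ci_high,
             predicted_exponent = x$h, lambda = x$lambda_hat,
             t_stat = x$t_stat, df = x$df, p_slope = x$p_slope,
             lrt_stat = x$lrt_stat, p_lambda = x$p_lambda,
             stringsAsFactors = FALSE)
}

#' Scatter plot of a phylogenetic RMA fit
#'
#' Plots the species values with the fitted RMA line (solid) and the
#' predicted isometric line through the GLS means (dashed).
#'
#' @param x An `"rma_fit"` object.
#' @param ... Passed to [plot()].
#' @export
plot.rma_fit <- function(x, ...) {
  d <- x$data
  args <- list(x = d[, "x"], y = d[, "y"],
               xlab = "log10 x", ylab = "log10 y", pch = 19)
  args <- modifyList(args, list(...))
  do.call(graphics::plot, args)
  graphics::abline(a = x$beta0, b = x$beta1, lwd = 2)
  graphics::abline(a = x$means[2] - x$h * x$means[1], b = x$h,
                   lty = 2, col = "red")
  invisible(x)
}
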