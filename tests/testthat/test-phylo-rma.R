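test_that("gls_mean reduces to the arithmetic mean under identity covariance", {
  C <- diag(3)
  expect_equal(unname(gls_mean(C, c(1, 2, 3))), 2)
})

test_that("gls_mean is invariant to rescaling the covariance", {
  tr <- sim_yule_tree(8, 1, seed = 2)
  C <- vcv_matrix(tr)
  X <- sim_traits_lambda_bm(tr, 1, diag(c(1, 0.5)), seed = 3)
  expect_equal(gls_mean(C, X), gls_mean(5.7 * C, X), tolerance = 1e-12)
})

test_that("gls_mean matches brute-force matrix algebra", {
  C <- matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3)
  x <- c(1, 1, 4)
  one <- rep(1, 3)
  oracle <- drop(solve(t(one) %*% solve(C) %*% one) %*% t(one) %*% solve(C) %*% x)
  expect_equal(unname(gls_mean(C, x)), oracle, tolerance = 1e-10)
})

test_that("profile_loglik matches its closed form and is location invariant", {
  # x = (-1, 1), C = I2: a = 0, R_ML = 1 -> -ln(2*pi) - 1
  expect_equal(profile_loglik(diag(2), c(-1, 1)), -log(2 * pi) - 1,
               tolerance = 1e-12)
  tr <- sim_yule_tree(7, 1, seed = 5)
  C <- vcv_matrix(tr)
  X <- sim_traits_lambda_bm(tr, 1, diag(c(1, 2)), seed = 6)
  X_shift <- X
  X_shift[, 2] <- X_shift[, 2] + 17.3
  expect_equal(profile_loglik(C, X_shift), profile_loglik(C, X),
               tolerance = 1e-10)
})

test_that("profile_loglik errors on degenerate trait columns", {
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_error(profile_loglik(diag(3), X), "degenerate.*b")
})

test_that("estimate_lambda flags unidentifiable lambda on a star tree", {
  st <- star_tree(6)
  X <- sim_traits_lambda_bm(st, 1, diag(c(1, 1)), seed = 9)
  est <- estimate_lambda(st, X)
  expect_false(est$identifiable)
  expect_equal(est$lambda_hat, 0)
  expect_equal(est$loglik_hat, est$loglik0)
})

test_that("rma_line computes slope, intercept and correlation from R", {
  out <- rma_line(c(0, 0), matrix(c(1, 1.9, 1.9, 4), 2))
  expect_equal(out$beta1, 2)
  expect_equal(out$beta0, 0)
  expect_equal(out$r2_corr, 1.9^2 / 4)
  # divisor invariance: any positive rescaling of R leaves the line unchanged
  out_k <- rma_line(c(0, 0), 3.1 * matrix(c(1, 1.9, 1.9, 4), 2))
  expect_equal(out_k[c("beta0", "beta1", "r2_corr")],
               out[c("beta0", "beta1", "r2_corr")])
})

test_that("lambda = 0 on a unit-depth star tree matches hand-computed moments", {
  st <- star_tree(4)
  x <- setNames(c(0, 1, 2, 3), st$tip.label)
  y <- setNames(c(0, 2, 1, 3), st$tip.label)
  fit <- phyl_rma(st, x, y, h = 1, lambda = 0)
  expect_equal(fit$beta1, 1, tolerance = 1e-12)
  expect_equal(fit$beta0, 0, tolerance = 1e-12)
  expect_equal(fit$r2_corr, 0.64, tolerance = 1e-12)   # (4/5)^2
  expect_equal(fit$r2_line, 0.6, tolerance = 1e-12)   # 1 - 2/5
  expect_equal(unname(fit$residuals[st$tip.label]), c(0, 1, -1, 0),
               tolerance = 1e-12)
})

test_that("swapping x and y inverts the RMA slope", {
  tr <- sim_yule_tree(10, 1, seed = 12)
  xy <- sim_allometric_xy(tr)
  f1 <- phyl_rma(tr, xy$x, xy$y, lambda = 1)
  f2 <- phyl_rma(tr, xy$y, xy$x, lambda = 1)
  expect_equal(f1$beta1 * f2$beta1, 1, tolerance = 1e-10)
})

test_that("line_r2 handles exact fits, flat lines, and zero variance", {
  x <- c(0, 1, 2, 3)
  expect_equal(line_r2(x, 2 * x + 1, beta0 = 1, beta1 = 2), 1)
  y <- c(0, 2, 1, 3)
  expect_equal(line_r2(x, y, beta0 = mean(y), beta1 = 0), 0)
  expect_error(line_r2(x, rep(2, 4), beta0 = 2, beta1 = 0), "total sum of squares")
})

test_that("slope test matches a quadrature oracle and its symmetries", {
  expect_equal(slope_test(1.37, 0.5, 20, h = 1.37)$p_slope, 1)
  expect_equal(slope_test(1.37, 0.5, 20, h = 1.37)$t_stat, 0)

  st <- slope_test(1, 0.64, 4, h = 2)
  expect_equal(st$t_stat, log(2) / sqrt(0.36 / 2), tolerance = 1e-12)
  # p-value via numeric integration of the t density (independent of pt)
  tdens <- function(u, df) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  }
  p_oracle <- 2 * stats::integrate(tdens, st$t_stat, Inf, df = 2,
                                   rel.tol = 1e-10)$value
  expect_equal(st$p_slope, p_oracle, tolerance = 1e-8)

  # p invariant to beta1 -> 1/beta1 when h = 1
  expect_equal(slope_test(1.8, 0.4, 15, h = 1)$p_slope,
               slope_test(1 / 1.8, 0.4, 15, h = 1)$p_slope, tolerance = 1e-12)
  expect_error(slope_test(1.2, 0.4, 15, h = 0), "h must be")
  deg <- slope_test(1.5, 1, 10, h = 1)
  expect_true(deg$degenerate)
  expect_equal(deg$p_slope, 0)
})

test_that("slope CI collapses at r2 = 1 and satisfies its algebraic identity", {
  ci <- slope_ci(1.4, 1, 10)
  expect_true(ci$degenerate)
  expect_equal(c(ci$ci_low, ci$ci_high), c(1.4, 1.4))
  set.seed(4)
  for (i in 1:20) {
    b <- runif(1, 0.2, 3); r2 <- runif(1, 0, 0.99); n <- sample(4:50, 1)
    ci <- slope_ci(b, r2, n)
    expect_true(ci$ci_low <= b && b <= ci$ci_high)
    expect_equal(ci$ci_low * ci$ci_high, b^2, tolerance = 1e-10)
  }
})

test_that("the 95% slope CI covers the generating slope in lambda-BM simulations", {
  set.seed(101)
  n_rep <- 500
  hits <- 0L
  for (i in seq_len(n_rep)) {
    tr <- sim_yule_tree(50, 1)
    xy <- sim_allometric_xy(tr, lambda = 0.5, slope = 1.4)
    fit <- phyl_rma(tr, xy$x, xy$y)
    # population RMA slope implied by the generator (residual axis widens y)
    hits <- hits + (fit$ci_low <= 1.4 && 1.4 <= fit$ci_high)
  }
  expect_gte(hits / n_rep, 0.90)
})

test_that("lambda LRT follows the chi-squared reference", {
  z <- lambda_lrt(-10, -10)
  expect_equal(z$lrt_stat, 0)
  expect_equal(z$p_lambda, 1)
  z <- lambda_lrt(-8.0792705, -10)  # Delta = 3.841459, the 5% chi2_1 quantile
  expect_equal(z$p_lambda, 0.05, tolerance = 1e-5)
  expect_error(lambda_lrt(-11, -10), "not maximized")
  zb <- lambda_lrt(-9, -10, boundary = TRUE)
  expect_equal(zb$p_lambda, 0.5 * pchisq(2, 1, lower.tail = FALSE))
})

test_that("phyl_rma agrees with the established phyl.RMA implementation", {
  skip_if_not_installed("phytools")
  set.seed(21)
  for (i in 1:3) {
    tr <- sim_yule_tree(20, 1)
    X <- sim_traits_lambda_bm(tr, lambda = c(0.3, 0.7, 1)[i],
                              R = matrix(c(0.05, 0.02, 0.02, 0.04), 2),
                              root_state = c(3, 1))
    x <- setNames(X[, 1], rownames(X)); y <- setNames(X[, 2], rownames(X))
    fit <- phyl_rma(tr, x, y, h = 1, df = "clarke")
    # phytools optimizes lambda with a coarser tolerance; compare the ML
    # estimates loosely, then the full algebra exactly at a common lambda
    ref_ml <- phytools::phyl.RMA(x, y, tr, method = "lambda", h0 = 1)
    expect_lt(abs(fit$lambda_hat - ref_ml$lambda), 5e-3)
    ref <- phytools::phyl.RMA(x, y, tr, method = "lambda", h0 = 1,
                              fixed = TRUE, lambda = fit$lambda_hat)
    expect_equal(fit$beta0, unname(ref$RMA.beta[1]), tolerance = 1e-8)
    expect_equal(fit$beta1, unname(ref$RMA.beta[2]), tolerance = 1e-8)
    expect_equal(fit$r2_corr, unname(ref$test["r2"]), tolerance = 1e-8)
    expect_equal(fit$t_stat, unname(ref$test["T"]), tolerance = 1e-8)
    expect_equal(fit$df, unname(ref$test["df"]), tolerance = 1e-8)
    expect_equal(fit$p_slope, unname(ref$test["P"]), tolerance = 1e-8)
  }
})

test_that("unit rescaling of x shifts the intercept and nothing else", {
  tr <- sim_yule_tree(15, 1, seed = 31)
  xy <- sim_allometric_xy(tr)
  f1 <- phyl_rma(tr, xy$x, xy$y)
  f2 <- phyl_rma(tr, xy$x + 3, xy$y)  # e.g. raw-unit change before log10
  expect_equal(f2$beta1, f1$beta1, tolerance = 1e-9)
  expect_equal(f2$beta0, f1$beta0 - 3 * f1$beta1, tolerance = 1e-8)
  expect_equal(f2$r2_corr, f1$r2_corr, tolerance = 1e-9)
  expect_equal(f2$lambda_hat, f1$lambda_hat, tolerance = 1e-6)
  expect_equal(f2$p_slope, f1$p_slope, tolerance = 1e-8)
})

test_that("phyl_rma is deterministic and reports aligned species metadata", {
  tr <- sim_yule_tree(12, 1, seed = 41)
  xy <- sim_allometric_xy(tr)
  f1 <- phyl_rma(tr, xy$x, xy$y)
  f2 <- phyl_rma(tr, xy$x, xy$y)
  expect_identical(f1[setdiff(names(f1), "call")], f2[setdiff(names(f2), "call")])
  expect_equal(f1$n, 12L)
  expect_setequal(f1$species, tr$tip.label)
  # extra species in traits but absent from tree are ignored
  x2 <- c(xy$x, ghost = 3.2); y2 <- c(xy$y, ghost = 1.5)
  f3 <- phyl_rma(tr, x2, y2)
  expect_equal(f3$beta1, f1$beta1)
  expect_error(phyl_rma(tr, xy$x[1:2], xy$y[1:2]), "at least 3")
})
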