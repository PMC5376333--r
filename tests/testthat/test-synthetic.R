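test_that("sim_yule_tree produces reproducible ultrametric trees", {
  tr <- sim_yule_tree(5, 1, seed = 1)
  expect_equal(length(tr$tip.label), 5)
  d <- ape::node.depth.edgelength(tr)[1:5]
  expect_lt(diff(range(d)), 1e-9)

  a <- ape::write.tree(sim_yule_tree(9, 2, seed = 123))
  b <- ape::write.tree(sim_yule_tree(9, 2, seed = 123))
  expect_identical(a, b)
  expect_error(sim_yule_tree(1), "n_species")
  expect_error(sim_yule_tree(5, 0), "birth_rate")
})

test_that("mean Yule tree depth matches the analytic expectation", {
  set.seed(2024)
  n <- 20; b <- 1.5
  depths <- replicate(1000, {
    tr <- sim_yule_tree(n, b)
    ape::node.depth.edgelength(tr)[1]
  })
  expected <- sum(1 / (b * 2:n))
  expect_equal(mean(depths), expected, tolerance = 0.05)
})

test_that("sim_traits_lambda_bm handles degenerate and independent cases", {
  tr <- sim_yule_tree(6, 1, seed = 5)
  X <- sim_traits_lambda_bm(tr, 1, matrix(0, 2, 2), root_state = c(3, -1),
                            seed = 6)
  expect_equal(unname(X), cbind(rep(3, 6), rep(-1, 6)))
  expect_error(sim_traits_lambda_bm(tr, 1, matrix(c(1, 2, 2, 1), 2)),
               "positive semidefinite")

  # lambda = 0: traits independent across tips
  set.seed(7)
  tr8 <- sim_yule_tree(8, 1)
  pair <- replicate(2000, {
    x <- sim_traits_lambda_bm(tr8, 0, matrix(1))
    x[c(1, 2)]
  })
  expect_lt(abs(cor(pair[1, ], pair[2, ])), 0.05)
})

test_that("tip variances and covariances match the lambda-scaled covariance", {
  set.seed(31)
  tr <- sim_yule_tree(6, 1)
  lam <- 0.6
  C <- lambda_transform(vcv_matrix(tr), lam)
  draws <- replicate(2000, sim_traits_lambda_bm(tr, lam, matrix(1))[, 1])
  # use the most closely related pair so the relative MC error is smallest
  ij <- which(C == max(C[upper.tri(C)]), arr.ind = TRUE)[1, ]
  expect_equal(var(draws[ij[1], ]), C[ij[1], ij[1]], tolerance = 0.1)
  expect_equal(cov(draws[ij[1], ], draws[ij[2], ]), C[ij[1], ij[2]],
               tolerance = 0.2)
})

test_that("the GLS-centered rate estimator recovers the generating rate matrix", {
  set.seed(41)
  tr <- sim_yule_tree(100, 1)
  lam <- 0.7
  R_true <- matrix(c(0.05, 0.02, 0.02, 0.03), 2)
  C <- lambda_transform(vcv_matrix(tr), lam)
  U <- chol(C)
  n <- 100
  acc <- matrix(0, 2, 2)
  reps <- 500
  for (i in seq_len(reps)) {
    X <- sim_traits_lambda_bm(tr, lam, R_true)
    a <- gls_mean(C, X)
    E <- X - rep(a, each = n)
    M <- backsolve(U, E, transpose = TRUE)
    acc <- acc + crossprod(M) / n
  }
  expect_equal(acc / reps, R_true, tolerance = 0.05)
})

test_that("specimen generation with no noise recovers species means exactly", {
  cfg <- sim_config(n_species = 10, within_species_cv = 0,
                    specimens_per_species = c(1, 1), submm_fold_prob = 0,
                    seed = 3)
  sim <- sim_allometric_specimens(cfg)
  m <- species_means(sim$specimens, "body_length_cm")
  got <- setNames(log10(m$body_length_cm * 10), m$species)
  want <- sim$species_means[names(got), "log_bl_mm"]
  expect_equal(got, want, tolerance = 1e-12)
  vl <- species_means(sim$specimens, "vaginal_length_cm")
  expect_equal(setNames(log10(vl$vaginal_length_cm * 10), vl$species),
               sim$species_means[vl$species, "log_vl_mm"], tolerance = 1e-12)
})

test_that("generated specimen tables exercise the fold-cleaning rules", {
  cfg <- sim_config(n_species = 15, submm_fold_prob = 0.3, seed = 11)
  sim <- sim_allometric_specimens(cfg)
  all_folds <- unlist(lapply(strsplit(sim$specimens$fold_lengths_mm, ";"),
                             as.numeric))
  expect_true(any(all_folds < 1))  # sub-millimeter folds present
  # and the loader applies the cleaning rules to them
  path <- tempfile(fileext = ".tsv")
  write.table(sim$specimens, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- load_specimens(path)
  i <- which(vapply(rec$fold_lengths_mm, function(v) any(v < 0.5), logical(1)))[1]
  expect_equal(rec$cumulative_fold_length_mm[i],
               clean_folds(rec$fold_lengths_mm[[i]])$cumulative_mm)
})

test_that("end-to-end recovery of the generating slope on a large dataset", {
  cfg <- sim_config(n_species = 100, within_species_cv = 0.05, seed = 2025)
  sim <- sim_allometric_specimens(cfg)
  rep <- suppressWarnings(run_study(study_config(sim$tree, sim$specimens)))
  expect_lt(abs(rep$fits$VL_vs_BL$beta1 - cfg$slope_true), 0.1)
  expect_lt(abs(rep$fits$VL_vs_BL$lambda_hat - cfg$lambda_true), 0.2)
  expect_lt(abs(rep$fits$VFL_vs_BL$beta1 - cfg$vfl_slope), 0.15)
})

test_that("make_fixture writes the 20-species / 59-specimen study design", {
  dir <- file.path(tempdir(), "fixture-a")
  fx <- make_fixture(dir, seed = 42)
  expect_true(all(file.exists(fx$paths)))
  expect_equal(nrow(fx$specimens), 59)
  expect_equal(length(unique(fx$specimens$species)), 20)
  expect_equal(length(fx$tree$tip.label), 20)
  manifest <- jsonlite::read_json(fx$paths[["manifest"]], simplifyVector = TRUE)
  expect_equal(manifest$n_specimens, 59)

  # recovery within the tolerances the manifest documents
  rep <- suppressWarnings(run_study(study_config(fx$paths[["tree"]],
                                                 fx$paths[["specimens"]])))
  expect_lt(abs(rep$fits$VL_vs_BL$beta1 - manifest$parameters$slope_true),
            manifest$recovery_tolerances$slope)
  expect_lt(abs(rep$fits$VL_vs_BL$lambda_hat - manifest$parameters$lambda_true),
            manifest$recovery_tolerances$lambda)
})

test_that("specimen totals are adjusted deterministically and validated", {
  expect_error(sim_allometric_specimens(
    sim_config(n_species = 5, total_specimens = 100,
               specimens_per_species = c(1, 5), seed = 1)), "unreachable")
  cfg <- sim_config(n_species = 8, total_specimens = 30,
                    specimens_per_species = c(1, 5), seed = 2)
  sim <- sim_allometric_specimens(cfg)
  expect_equal(nrow(sim$specimens), 30)
})
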