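test_that("metrics follow their definitions", {
  y <- c(5, 6, 7, 8)
  expect_identical(rmse(y, y), 0)
  expect_identical(r2(y, y), 1)
  expect_identical(accuracy_1log(y, y), 1)
  # one error of 0.5 (inside +/- 1 log) and one of 1.5 (outside)
  expect_identical(accuracy_1log(c(5.5, 8), c(5, 6.5)), 0.5)
  # the boundary |error| = 1 counts as accurate (inclusive)
  expect_identical(accuracy_1log(5, 6), 1)
  # predicting the mean gives R2 = 0
  expect_equal(r2(y, rep(mean(y), 4)), 0)
  expect_error(rmse(y, y[1:2]), "equal")
  expect_error(r2(rep(2, 4), y), "constant")
})

test_that("repeated k-fold returns repeats x k fold RMSE values, seeded", {
  prob <- random_problem(n = 40, p = 4, seed = 3, noise = 0.3)
  spec <- model_spec("m", "single", "A", lv_range = 2:4)
  blocks <- list(A = prob$X)
  out <- repeated_kfold_rmse(spec, list(n_lv = 3), blocks, prob$y, seed = 5)
  expect_length(out$values, 30L)  # default 3 repeats x 10 folds
  expect_equal(out$mean, mean(out$values))
  rerun <- repeated_kfold_rmse(spec, list(n_lv = 3), blocks, prob$y, seed = 5)
  expect_identical(out$values, rerun$values)
  other <- repeated_kfold_rmse(spec, list(n_lv = 3), blocks, prob$y, seed = 6)
  expect_false(identical(out$values, other$values))
  expect_error(repeated_kfold_rmse(spec, list(n_lv = 3),
                                   list(A = prob$X[1:5, ]), prob$y[1:5],
                                   k = 10), "fewer rows")
})

test_that("noiseless linear data gives essentially zero RMSEcv", {
  prob <- random_problem(n = 40, p = 4, seed = 4, noise = 0)
  spec <- model_spec("m", "single", "A", lv_range = 4)
  out <- repeated_kfold_rmse(spec, list(n_lv = 4), list(A = prob$X), prob$y,
                             seed = 1)
  expect_lt(out$mean, 1e-8)
})

test_that("tuning recovers the intrinsic latent dimension", {
  withr::with_seed(6, {
    n <- 60
    t_scores <- matrix(rnorm(n * 2), n, 2)
    loadings <- matrix(rnorm(2 * 12), 2, 12)
    X <- t_scores %*% loadings + matrix(rnorm(n * 12, sd = 1e-3), n, 12)
    y <- as.numeric(t_scores %*% c(1.5, -2)) + rnorm(n, sd = 1e-3)
  })
  spec <- model_spec("m", "single", "A", lv_range = 1:3)
  tuned <- tune(spec, list(A = X), y, k = 5, seed = 2)
  expect_identical(as.integer(tuned$best_params$n_lv), 2L)
})

test_that("random search over the whole grid equals exhaustive search", {
  prob <- random_problem(n = 40, p = 6, seed = 7, noise = 0.4)
  ex <- model_spec("m", "single", "A", lv_range = 2:6)
  rnd <- model_spec("m", "single", "A", lv_range = 2:6, search = "random",
                    n_iter = 5L)
  t_ex <- tune(ex, list(A = prob$X), prob$y, seed = 3)
  t_rnd <- tune(rnd, list(A = prob$X), prob$y, seed = 3)
  expect_identical(t_ex$best_params, t_rnd$best_params)
  expect_identical(t_ex$rmsecv, t_rnd$rmsecv)
})

test_that("RMSEcv ties break toward fewer latent variables", {
  withr::with_seed(8, {
    base <- matrix(rnorm(80), 40, 2)
    X <- cbind(base, base %*% matrix(rnorm(4), 2, 2))  # rank 2
    y <- as.numeric(base %*% c(1, 2)) + rnorm(40, sd = 0.1)
  })
  # beyond rank exhaustion every candidate fits identically -> tie
  spec <- model_spec("m", "single", "A", lv_range = 3:4)
  tuned <- suppressWarnings(tune(spec, list(A = X), y, seed = 4))
  expect_identical(as.integer(tuned$best_params$n_lv), 3L)
  # argmin construction: selected RMSEcv is the table minimum
  expect_equal(tuned$rmsecv, min(tuned$table$rmsecv))
})

test_that("mid-fusion candidate grids respect the meta-rank constraint", {
  spec <- model_spec("mid", "mid", c("MSI", "FTIR"),
                     base_lv_ranges = list(MSI = 2:3, FTIR = 2:3),
                     meta_lv_range = 2:6)
  grid <- candidate_grid(spec)
  expect_true(all(grid$meta_lv <= grid$lv_MSI + grid$lv_FTIR))
  expect_identical(sort(names(grid)), c("lv_FTIR", "lv_MSI", "meta_lv"))
})

test_that("batch-on-batch evaluation scores every condition's test set", {
  ds <- simulate_dataset(two_condition_config(seed = 15))
  plan <- make_partition(ds, "batch_on_batch", conditions = "aerobic")
  specs <- list(model_spec("msi", "single", "MSI", lv_range = c(2L, 4L)))
  res <- batch_on_batch_evaluate(ds, specs, plan, repeats = 1L, k = 5L,
                                 seed = 9)
  expect_setequal(res$test_set, c("aerobic", "vacuum"))
  expect_identical(res$n[res$test_set == "aerobic"],
                   length(plan$test_sets$aerobic))
  expect_identical(res$n[res$test_set == "vacuum"],
                   length(plan$test_sets$vacuum))
  rerun <- batch_on_batch_evaluate(ds, specs, plan, repeats = 1L, k = 5L,
                                   seed = 9)
  expect_equal(res, rerun, ignore_attr = TRUE)
})

test_that("training-side fits are untouched by test-set perturbation", {
  ds <- simulate_dataset(two_condition_config(seed = 16))
  plan <- make_partition(ds, "batch_on_batch", conditions = "aerobic")
  specs <- list(model_spec("msi", "single", "MSI", lv_range = c(2L, 3L)),
                model_spec("early", "early", c("MSI", "MSIF"),
                           lv_range = c(2L, 3L)))
  res_a <- batch_on_batch_evaluate(ds, specs, plan, repeats = 1L, k = 5L,
                                   seed = 2)
  # perturb every test row of every block
  ds2 <- ds
  test_idx <- ds$metadata$sample_id %in% plan$test_ids
  for (mod in names(ds2$blocks)) {
    ds2$blocks[[mod]]$matrix[test_idx, ] <-
      ds2$blocks[[mod]]$matrix[test_idx, ] * 1.5 + 0.3
  }
  res_b <- batch_on_batch_evaluate(ds2, specs, plan, repeats = 1L, k = 5L,
                                   seed = 2)
  expect_identical(serialize(attr(res_a, "models"), NULL),
                   serialize(attr(res_b, "models"), NULL))
  expect_identical(res_a$rmsecv, res_b$rmsecv)
})

test_that("nested CV yields repeats x outer_k matched records per model", {
  ds <- simulate_dataset(tiny_sim_config(seed = 17))
  specs <- list(model_spec("msi", "single", "MSI", lv_range = c(2L, 4L)),
                model_spec("msif", "single", "MSIF", lv_range = c(2L, 3L)))
  res <- nested_cv(ds, specs, repeats = 2L, outer_k = 3L, inner_k = 3L,
                   seed = 31)
  expect_identical(nrow(res), 2L * 3L * 2L)
  for (id in c("msi", "msif")) {
    expect_identical(sum(res$model_id == id), 6L)
  }
  # seed-matching: both models share every (repeat, fold) test set
  a <- res[res$model_id == "msi", c("rep", "fold", "n")]
  b <- res[res$model_id == "msif", c("rep", "fold", "n")]
  expect_identical(a[order(a$rep, a$fold), ], b[order(b$rep, b$fold), ],
                   ignore_attr = TRUE)
  # outer folds partition the dataset within each repeat
  assignments <- attr(res, "assignments")
  for (r in seq_along(assignments)) {
    expect_setequal(unlist(assignments[[r]]), ds$metadata$sample_id)
    expect_identical(sum(lengths(assignments[[r]])), nrow(ds$metadata))
  }
  rerun <- nested_cv(ds, specs, repeats = 2L, outer_k = 3L, inner_k = 3L,
                     seed = 31)
  expect_identical(as.data.frame(res), as.data.frame(rerun))
})

test_that("every strategy is near-exact on noiseless affine synthetic data", {
  ds <- simulate_dataset(noiseless_config(seed = 18))
  specs <- list(
    model_spec("msi", "single", "MSI", lv_range = 1L),
    model_spec("early", "early", c("MSI", "MSIF"), lv_range = 1L),
    model_spec("mid", "mid", c("MSI", "MSIF"),
               base_lv_ranges = list(MSI = 1L, MSIF = 1L), meta_lv_range = 1L),
    model_spec("late", "late", c("MSI", "MSIF"),
               base_lv_ranges = list(MSI = 1L, MSIF = 1L), oof_folds = 5L)
  )
  res <- nested_cv(ds, specs, recipe = list(), repeats = 1L, outer_k = 2L,
                   inner_k = 3L, seed = 5)
  expect_lt(max(res$rmse), 1e-6)
})

test_that("fold results summarise and round-trip as tidy CSV", {
  ds <- simulate_dataset(tiny_sim_config(seed = 19))
  specs <- list(model_spec("msi", "single", "MSI", lv_range = c(2L, 4L)))
  res <- nested_cv(ds, specs, repeats = 1L, outer_k = 3L, inner_k = 3L,
                   seed = 2)
  s <- summarise_fold_results(res)
  expect_identical(s$n_folds, 3L)
  expect_equal(s$rmse_mean, mean(res$rmse))
  expect_equal(s$acc_pct_mean, 100 * mean(res$accuracy))
  path <- withr::local_tempfile(fileext = ".csv")
  write_fold_results(res, path)
  re <- read_fold_results(path)
  expect_equal(re$rmse, res$rmse, tolerance = 1e-14)
  expect_identical(re$model_id, res$model_id)
})
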