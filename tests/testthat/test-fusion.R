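make_fusion_blocks <- function(n = 40, seed = 1, noise = 0.2) {
  withr::with_seed(seed, {
    y <- runif(n, 4, 9)
    list(
      y = y,
      blocks = list(
        MSI = matrix(rnorm(n * 12, sd = 1), n, 12) + y,
        FTIR = matrix(rnorm(n * 10, sd = 1), n, 10) + y,
        MSIF = matrix(rnorm(n * 4, sd = 1.5), n, 4) + y
      )
    )
  })
}

test_that("early fusion standardises, concatenates, and fits one PLS", {
  fx <- make_fusion_blocks(seed = 3)
  m <- fit_early_fusion(fx$blocks, fx$y, n_lv = 4)
  expect_identical(sum(m$block_widths), 26L)
  expect_identical(length(m$meta$x_mean), 26L)
  # single-modality early "fusion" equals plain PLS on the z-scored block
  one <- fit_early_fusion(fx$blocks["MSI"], fx$y, n_lv = 3)
  z <- apply_standardiser(fit_standardiser(fx$blocks$MSI), fx$blocks$MSI)
  plain <- fit_pls(z, fx$y, 3)
  expect_equal(predict_fusion(one, fx$blocks["MSI"]),
               pls_predict(plain, z), tolerance = 1e-10)
})

test_that("early fusion predictions are invariant to modality order", {
  fx <- make_fusion_blocks(seed = 4)
  a <- fit_early_fusion(fx$blocks, fx$y, 4)
  b <- fit_early_fusion(fx$blocks[c("MSIF", "MSI", "FTIR")], fx$y, 4)
  expect_equal(predict_fusion(a, fx$blocks), predict_fusion(b, fx$blocks),
               tolerance = 1e-9)
})

test_that("mid fusion concatenates base scores into a second PLS", {
  fx <- make_fusion_blocks(n = 60, seed = 5)
  m <- fit_mid_fusion(fx$blocks[c("MSI", "FTIR")], fx$y,
                      base_lvs = c(MSI = 9, FTIR = 6), meta_lv = 6)
  # meta input width = sum of base latent-variable counts (here 9 + 6 = 15)
  expect_identical(length(m$meta$x_mean), 15L)
  expect_identical(m$meta$n_lv, 6L)
  expect_error(fit_mid_fusion(fx$blocks[c("MSI", "FTIR")], fx$y,
                              c(MSI = 2, FTIR = 2), meta_lv = 5),
               "exceeds")
})

test_that("full-rank mid fusion equals least squares on the concatenated scores", {
  fx <- make_fusion_blocks(n = 50, seed = 6)
  base_lvs <- c(MSI = 3, FTIR = 4)
  m <- fit_mid_fusion(fx$blocks[c("MSI", "FTIR")], fx$y, base_lvs, meta_lv = 7)
  base <- lapply(names(base_lvs), function(nm) {
    fit_pls(fx$blocks[[nm]], fx$y, base_lvs[[nm]])
  })
  scores <- do.call(cbind, lapply(seq_along(base), function(i) {
    pls_transform(base[[i]], fx$blocks[[names(base_lvs)[i]]])
  }))
  ols <- stats::lm.fit(cbind(1, scores), fx$y)
  expect_equal(predict_fusion(m, fx$blocks), as.numeric(ols$fitted.values),
               tolerance = 1e-8)
})

test_that("single-modality mid fusion at full meta rank equals the base model", {
  fx <- make_fusion_blocks(n = 45, seed = 7)
  m <- fit_mid_fusion(fx$blocks["MSI"], fx$y, c(MSI = 4), meta_lv = 4)
  single <- fit_pls(fx$blocks$MSI, fx$y, 4)
  expect_equal(predict_fusion(m, fx$blocks["MSI"]),
               pls_predict(single, fx$blocks$MSI), tolerance = 1e-8)
})

test_that("late-fusion OOF matrix and meta weights follow the stacking contract", {
  fx <- make_fusion_blocks(n = 60, seed = 8)
  m <- fit_late_fusion(fx$blocks, fx$y, c(MSI = 4, FTIR = 5, MSIF = 3),
                       oof_folds = 20, seed = 11)
  expect_identical(dim(m$oof), c(60L, 3L))
  expect_false(anyNA(m$oof))
  # meta weights equal the closed-form least-squares solution on the OOF matrix
  beta <- qr.solve(cbind(1, m$oof), fx$y)
  expect_equal(unname(m$meta_coef), unname(beta), tolerance = 1e-10)
})

test_that("a perfectly predictive single base model gets weights (0, 1)", {
  withr::with_seed(9, {
    X <- matrix(rnorm(120), 40, 3)
    y <- as.numeric(X %*% c(1, -2, 0.5))  # exact linear response
    m <- fit_late_fusion(list(A = X), y, c(A = 3), oof_folds = 10, seed = 2)
    expect_equal(unname(m$meta_coef), c(0, 1), tolerance = 1e-8)
  })
})

test_that("late prediction is the meta-weighted combination of base predictions", {
  const_model <- function(value, p) {
    structure(list(n_lv = 1L, x_mean = rep(0, p), y_mean = value,
                   coefficients = rep(0, p), feature_names = NULL),
              class = "pls_model")
  }
  fake <- structure(
    list(strategy = "late", modalities = c("A", "B"),
         base_models = list(A = const_model(6, 2), B = const_model(8, 2)),
         meta_coef = c(0, 0.5, 0.5)),
    class = "fusion_model"
  )
  blocks <- list(A = matrix(0, 1, 2), B = matrix(0, 1, 2))
  expect_equal(predict_fusion(fake, blocks), 7)
  expect_error(predict_fusion(fake, blocks["A"]), "missing modality")
})

test_that("late fusion is deterministic given its seed and differs across seeds", {
  fx <- make_fusion_blocks(n = 50, seed = 10)
  lvs <- c(MSI = 3, FTIR = 4, MSIF = 2)
  a <- fit_late_fusion(fx$blocks, fx$y, lvs, oof_folds = 10, seed = 5)
  b <- fit_late_fusion(fx$blocks, fx$y, lvs, oof_folds = 10, seed = 5)
  expect_identical(a$meta_coef, b$meta_coef)
  c <- fit_late_fusion(fx$blocks, fx$y, lvs, oof_folds = 10, seed = 6)
  expect_false(identical(a$fold_assignment, c$fold_assignment))
})

test_that("early and mid fusion are invariant to training-row order", {
  fx <- make_fusion_blocks(n = 40, seed = 12)
  perm <- withr::with_seed(2, sample(40))
  pblocks <- lapply(fx$blocks, function(m) m[perm, , drop = FALSE])
  a <- fit_early_fusion(fx$blocks, fx$y, 4)
  b <- fit_early_fusion(pblocks, fx$y[perm], 4)
  expect_equal(predict_fusion(a, fx$blocks), predict_fusion(b, fx$blocks),
               tolerance = 1e-9)
  am <- fit_mid_fusion(fx$blocks, fx$y, c(MSI = 3, FTIR = 3, MSIF = 2), 4)
  bm <- fit_mid_fusion(pblocks, fx$y[perm], c(MSI = 3, FTIR = 3, MSIF = 2), 4)
  expect_equal(predict_fusion(am, fx$blocks), predict_fusion(bm, fx$blocks),
               tolerance = 1e-9)
})

test_that("a signal-free modality's late-fusion weight shrinks toward zero", {
  cfg <- sim_config(
    conditions = "aerobic", condition_rate_factors = c(aerobic = 1),
    temperatures = c(0, 5, 10),
    sampling_times = list(`0` = seq(0, 216, 24), `5` = seq(0, 216, 24),
                          `10` = seq(0, 120, 24)),
    replicates_range = c(3L, 5L), ftir_downsample = 60L, seed = 21,
    signal = signal_params(
      tvc_amplitude = c(ftir = 0.012, msi = 0.02, msif = 0),
      unique_sd = c(ftir = 0.4, msi = 0.35, msif = 0),
      shared_weight = c(ftir = 0.004, msi = 0.006, msif = 0)
    )
  )
  ds <- preprocess_dataset(simulate_dataset(cfg))
  blocks <- block_matrices(ds)
  m <- fit_late_fusion(blocks, ds$metadata$tvc,
                       c(MSI = 8, FTIR = 8, MSIF = 4), oof_folds = 10,
                       seed = 3)
  expect_lt(abs(m$meta_coef[["MSIF"]]), abs(m$meta_coef[["MSI"]]))
})

test_that("fusion models survive a JSON round trip", {
  fx <- make_fusion_blocks(n = 30, seed = 14)
  path <- withr::local_tempfile(fileext = ".json")
  early <- fit_early_fusion(fx$blocks, fx$y, 3)
  fusion_to_json(early, path)
  expect_equal(predict_fusion(fusion_from_json(path), fx$blocks),
               predict_fusion(early, fx$blocks), tolerance = 1e-12)
  late <- fit_late_fusion(fx$blocks, fx$y, c(MSI = 3, FTIR = 3, MSIF = 2),
                          oof_folds = 5, seed = 4)
  fusion_to_json(late, path)
  re <- fusion_from_json(path)
  expect_equal(predict_fusion(re, fx$blocks), predict_fusion(late, fx$blocks),
               tolerance = 1e-12)
  expect_equal(re$oof, late$oof, ignore_attr = TRUE, tolerance = 1e-15)
})
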