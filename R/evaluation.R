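# Metrics, hyperparameter search, batch-on-batch validation, and the
# repeated nested cross-validation driver. All model families are evaluated
# on the identical, seed-matched series of data splits so fold-level results
# are directly pairable across models.

#' Regression metrics
#'
#' `rmse` is the root mean squared error; `r2` is the test-set coefficient of
#' determination `1 - SS_res / SS_tot` (can be negative when the model
#' underperforms the mean predictor); `accuracy_1log` is the fraction of
#' predictions within +/- 1 log CFU/g of the observed value (inclusive), a
#' domain convention for microbial count prediction.
#'
#' @param y observed values
#' @param yhat predicted values (same length)
#' @return a single number
#' @export
#' @examples
#' rmse(c(5.5, 8), c(5, 6.5))
#' accuracy_1log(c(5.5, 8), c(5, 6.5))
rmse <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) == 0L) {
    stop("`y` and `yhat` must have equal nonzero length", call. = FALSE)
  }
  sqrt(mean((y - yhat)^2))
}

#' @rdname rmse
#' @export
r2 <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 2L) {
    stop("`r2` needs equal lengths >= 2", call. = FALSE)
  }
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("`y` is constant; R2 undefined", call. = FALSE)
  1 - sum((y - yhat)^2) / ss_tot
}

#' @rdname rmse
#' @export
accuracy_1log <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) == 0L) {
    stop("`y` and `yhat` must have equal nonzero length", call. = FALSE)
  }
  mean(abs(y - yhat) <= 1.0)
}

eval_metrics <- function(y, yhat) {
  data.frame(rmse = rmse(y, yhat), r2 = r2(y, yhat),
             accuracy = accuracy_1log(y, yhat), n = length(y))
}

#' Standard latent-variable search ranges
#'
#' The default per-modality latent-variable ranges: MSI 2-17, FTIR 2-20,
#' MSIF 2-7, early fusion 2-20, mid-fusion meta layer 2-17. All are
#' overridable wherever a spec is built.
#' @return named list of integer vectors
#' @export
default_lv_ranges <- function() {
  list(MSI = 2:17, FTIR = 2:20, MSIF = 2:7, early = 2:20, meta = 2:17)
}

#' Declare a model to evaluate
#'
#' A model spec names a strategy, its modalities and its hyperparameter
#' search space; the evaluation drivers fit and tune it inside their
#' resampling schemes.
#'
#' @param id unique model label used in result tables
#' @param strategy `"single"` (one PLS on one modality), `"early"`, `"mid"`
#'   or `"late"` fusion
#' @param modalities modality name (single) or >= 2 names (fusion)
#' @param lv_range integer candidates for the PLS latent-variable count
#'   (single and early strategies)
#' @param base_lv_ranges named list of integer candidate ranges, one per
#'   modality (mid and late strategies)
#' @param meta_lv_range integer candidates for the mid-fusion meta layer
#' @param oof_folds out-of-fold count of the late-fusion stacking layer
#' @param search `"exhaustive"` evaluates every candidate; `"random"` draws
#'   `n_iter` distinct candidates uniformly (seeded by the tuning seed)
#' @param n_iter candidate draws for random search
#' @return an object of class `model_spec`
#' @export
#' @examples
#' model_spec("msi", "single", "MSI", lv_range = 2:17)
#' model_spec("mid_all", "mid", c("MSI", "FTIR", "MSIF"),
#'            base_lv_ranges = list(MSI = 2:17, FTIR = 2:20, MSIF = 2:7),
#'            meta_lv_range = 2:17, search = "random", n_iter = 2500)
model_spec <- function(id, strategy = c("single", "early", "mid", "late"),
                       modalities, lv_range = NULL, base_lv_ranges = NULL,
                       meta_lv_range = NULL, oof_folds = 20L,
                       search = c("exhaustive", "random"), n_iter = NULL) {
  strategy <- match.arg(strategy)
  search <- match.arg(search)
  if (strategy == "single" && length(modalities) != 1L) {
    stop("single-sensor specs take exactly one modality", call. = FALSE)
  }
  if (strategy != "single" && length(modalities) < 2L) {
    stop("fusion specs need at least two modalities", call. = FALSE)
  }
  if (strategy %in% c("single", "early") && length(lv_range %||% integer()) == 0L) {
    stop("`lv_range` must be a nonempty integer range", call. = FALSE)
  }
  if (strategy %in% c("mid", "late")) {
    if (!all(modalities %in% names(base_lv_ranges %||% list()))) {
      stop("`base_lv_ranges` must name every modality", call. = FALSE)
    }
    if (strategy == "mid" && length(meta_lv_range %||% integer()) == 0L) {
      stop("mid fusion needs `meta_lv_range`", call. = FALSE)
    }
  }
  if (search == "random" && (is.null(n_iter) || n_iter < 1L)) {
    stop("random search needs `n_iter` >= 1", call. = FALSE)
  }
  structure(
    list(id = id, strategy = strategy, modalities = modalities,
         lv_range = lv_range, base_lv_ranges = base_lv_ranges,
         meta_lv_range = meta_lv_range, oof_folds = as.integer(oof_folds),
         search = search, n_iter = n_iter),
    class = "model_spec"
  )
}

#' The study's standard model roster
#'
#' Builds the default comparison set over the given modalities: one
#' single-sensor PLS per modality, early fusion, mid fusion and late fusion
#' over all of them, with the standard search ranges (random search with
#' the stated iteration counts for the larger fusion grids, exhaustive
#' elsewhere).
#'
#' @param modalities modality names, in the fixed (MSI, FTIR, MSIF) layout
#'   order by default
#' @param lv_ranges per-modality ranges, see [default_lv_ranges()]
#' @param oof_folds late-fusion OOF fold count
#' @return named list of [model_spec()] objects
#' @export
standard_model_specs <- function(modalities = c("MSI", "FTIR", "MSIF"),
                                 lv_ranges = default_lv_ranges(),
                                 oof_folds = 20L) {
  base_ranges <- lv_ranges[modalities]
  specs <- lapply(modalities, function(m) {
    model_spec(tolower(m), "single", m, lv_range = lv_ranges[[m]])
  })
  names(specs) <- tolower(modalities)
  specs$early <- model_spec("early", "early", modalities,
                            lv_range = lv_ranges$early)
  mid_grid <- prod(vapply(base_ranges, length, 1L)) * length(lv_ranges$meta)
  mid_iter <- if (length(modalities) >= 3L) 2500L else 1500L
  specs$mid <- model_spec("mid", "mid", modalities,
                          base_lv_ranges = base_ranges,
                          meta_lv_range = lv_ranges$meta,
                          search = if (mid_grid > 3000) "random" else "exhaustive",
                          n_iter = mid_iter)
  late_grid <- prod(vapply(base_ranges, length, 1L))
  specs$late <- model_spec("late", "late", modalities,
                           base_lv_ranges = base_ranges,
                           oof_folds = oof_folds,
                           search = if (late_grid > 600) "random" else "exhaustive",
                           n_iter = 400L)
  specs
}

#' Candidate hyperparameter grid of a spec
#'
#' Single/early: one `n_lv` column. Mid: one `lv_<modality>` column per
#' modality plus `meta_lv`, with candidates violating
#' `meta_lv <= sum(base LVs)` removed. Late: `lv_<modality>` columns.
#'
#' @param spec a [model_spec()]
#' @return data.frame of candidate rows
#' @export
candidate_grid <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$strategy %in% c("single", "early")) {
    return(data.frame(n_lv = as.integer(spec$lv_range)))
  }
  ranges <- lapply(spec$base_lv_ranges[spec$modalities], as.integer)
  names(ranges) <- paste0("lv_", spec$modalities)
  if (spec$strategy == "mid") {
    ranges$meta_lv <- as.integer(spec$meta_lv_range)
  }
  grid <- expand.grid(ranges, KEEP.OUT.ATTRS = FALSE)
  if (spec$strategy == "mid") {
    keep <- grid$meta_lv <= rowSums(grid[, paste0("lv_", spec$modalities),
                                         drop = FALSE])
    grid <- grid[keep, , drop = FALSE]
    rownames(grid) <- NULL
  }
  grid
}

params_as_list <- function(params) {
  if (is.data.frame(params)) as.list(params[1L, , drop = FALSE]) else as.list(params)
}

#' Fit one candidate model
#'
#' @param spec a [model_spec()]
#' @param params one row of [candidate_grid()] (or an equivalent named list)
#' @param blocks named list of matrices covering the spec's modalities
#' @param y response vector
#' @param seed seed for the late-fusion OOF shuffle (ignored otherwise)
#' @return a fitted object of class `sensorfuse_fit`
#' @export
fit_spec <- function(spec, params, blocks, y, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  params <- params_as_list(params)
  blocks <- blocks[spec$modalities]
  model <- switch(spec$strategy,
    single = fit_pls(blocks[[1L]], y, params$n_lv),
    early = fit_early_fusion(blocks, y, params$n_lv),
    mid = {
      base <- unlist(params[paste0("lv_", spec$modalities)])
      names(base) <- spec$modalities
      fit_mid_fusion(blocks, y, base, params$meta_lv)
    },
    late = {
      base <- unlist(params[paste0("lv_", spec$modalities)])
      names(base) <- spec$modalities
      fit_late_fusion(blocks, y, base, oof_folds = spec$oof_folds, seed = seed)
    }
  )
  structure(list(spec = spec, params = params, model = model),
            class = "sensorfuse_fit")
}

#' Predict from a fitted candidate
#' @param fit a `sensorfuse_fit`
#' @param blocks named list of matrices
#' @return numeric vector
#' @export
predict_spec <- function(fit, blocks) {
  stopifnot(inherits(fit, "sensorfuse_fit"))
  if (fit$spec$strategy == "single") {
    pls_predict(fit$model, blocks[[fit$spec$modalities]])
  } else {
    predict_fusion(fit$model, blocks)
  }
}

kfold_assignment <- function(n, k, seed) {
  if (n < k) stop("fewer rows than folds", call. = FALSE)
  withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
}

# Per-fold RMSE of one candidate over a list of fold assignments.
candidate_fold_rmse <- function(spec, params, blocks, y, assignments, seed) {
  out <- numeric(0)
  for (folds in assignments) {
    for (f in sort(unique(folds))) {
      hold <- folds == f
      train_blocks <- lapply(blocks, function(m) m[!hold, , drop = FALSE])
      fit <- fit_spec(spec, params, train_blocks, y[!hold], seed = seed)
      yhat <- predict_spec(fit, lapply(blocks, function(m) m[hold, , drop = FALSE]))
      out <- c(out, rmse(y[hold], yhat))
    }
  }
  out
}

#' Repeated k-fold cross-validated RMSE of one candidate
#'
#' Splits the data `repeats` times into `k` folds (seed-derived, one derived
#' seed per repeat), computes the held-out RMSE of every fold, and returns
#' the mean and standard deviation over the `repeats * k` fold values
#' (RMSEcv). Defaults follow the batch-validation tuning scheme: 3 repeats
#' of 10-fold.
#'
#' @inheritParams fit_spec
#' @param repeats repeat count
#' @param k fold count
#' @param seed integer seed; fold assignments are a pure function of
#'   (n rows, repeats, k, seed)
#' @return list with `mean`, `sd` and the vector `values` of fold RMSEs
#' @export
repeated_kfold_rmse <- function(spec, params, blocks, y, repeats = 3L,
                                k = 10L, seed = 1L) {
  blocks <- blocks[spec$modalities]
  n <- check_blocks(blocks, y)
  assignments <- lapply(seq_len(repeats), function(r) {
    kfold_assignment(n, k, derive_seed(seed, r - 1L))
  })
  vals <- candidate_fold_rmse(spec, params_as_list(params), blocks, y,
                              assignments, seed = derive_seed(seed, 104729L))
  list(mean = mean(vals), sd = stats::sd(vals), values = vals)
}

#' Tune a model spec by cross-validated grid or random search
#'
#' Evaluates candidates from [candidate_grid()] under a shared, seeded
#' k-fold scheme (identical folds for every candidate) and returns the
#' candidate minimising mean fold RMSE (RMSEcv). Random search draws
#' `n_iter` distinct candidates uniformly without replacement. Ties are
#' broken toward fewer total latent variables, then lexicographic candidate
#' order.
#'
#' @inheritParams repeated_kfold_rmse
#' @return list with `best_params` (named list), `rmsecv`, `rmsecv_sd`, and
#'   the full candidate `table`
#' @export
tune <- function(spec, blocks, y, repeats = 1L, k = 5L, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  blocks <- blocks[spec$modalities]
  n <- check_blocks(blocks, y)
  grid <- candidate_grid(spec)
  if (spec$search == "random" && spec$n_iter < nrow(grid)) {
    pick <- withr::with_seed(derive_seed(seed, 15485863L),
                             sample(nrow(grid), spec$n_iter))
    grid <- grid[sort(pick), , drop = FALSE]
    rownames(grid) <- NULL
  }
  assignments <- lapply(seq_len(repeats), function(r) {
    kfold_assignment(n, k, derive_seed(seed, r - 1L))
  })
  fit_seed <- derive_seed(seed, 104729L)
  stats_tab <- t(vapply(seq_len(nrow(grid)), function(i) {
    vals <- candidate_fold_rmse(spec, as.list(grid[i, , drop = FALSE]),
                                blocks, y, assignments, seed = fit_seed)
    c(mean(vals), stats::sd(vals))
  }, numeric(2)))
  grid$rmsecv <- stats_tab[, 1]
  grid$rmsecv_sd <- stats_tab[, 2]
  lv_cols <- setdiff(names(grid), c("rmsecv", "rmsecv_sd"))
  total_lv <- rowSums(grid[, lv_cols, drop = FALSE])
  ord <- do.call(order, c(list(grid$rmsecv, total_lv),
                          unname(grid[, lv_cols, drop = FALSE])))
  best <- ord[1L]
  list(best_params = as.list(grid[best, lv_cols, drop = FALSE]),
       rmsecv = grid$rmsecv[best], rmsecv_sd = grid$rmsecv_sd[best],
       table = grid)
}

#' Batch-on-batch evaluation
#'
#' For each model spec: preprocess the training partition (batch 1) and
#' every test set (batch 2, per condition) separately with the recipe, tune
#' the spec by repeated k-fold RMSEcv on the training rows, refit the best
#' candidate on the full training partition, and score it on each
#' per-condition test set — including conditions the model was not trained
#' on, as a cross-condition robustness probe.
#'
#' @param dataset a [multimodal_dataset()]
#' @param specs list of [model_spec()] objects
#' @param plan a [make_partition()] plan
#' @param recipe preprocessing recipe, see [default_recipe()]
#' @param repeats,k repeated k-fold tuning scheme (default 3 x 10-fold)
#' @param seed integer seed
#' @return data.frame with one row per (model, test set): `model_id`,
#'   `test_set`, `rmse`, `r2`, `accuracy`, `n`, `rmsecv`, `rmsecv_sd`,
#'   `params` (JSON). The fitted models are attached as attribute
#'   `"models"`.
#' @export
batch_on_batch_evaluate <- function(dataset, specs, plan,
                                    recipe = default_recipe(),
                                    repeats = 3L, k = 10L, seed = 1L) {
  stopifnot(inherits(dataset, "multimodal_dataset"),
            inherits(plan, "partition_plan"))
  train_ds <- preprocess_dataset(subset_dataset(dataset, plan$train_ids), recipe)
  test_sets <- plan$test_sets[vapply(plan$test_sets, length, 1L) > 0L]
  test_ds <- lapply(test_sets, function(ids) {
    preprocess_dataset(subset_dataset(dataset, ids), recipe)
  })
  y_train <- train_ds$metadata$tvc
  train_blocks <- block_matrices(train_ds)
  rows <- list()
  models <- list()
  for (spec in specs) {
    tuned <- tune(spec, train_blocks, y_train, repeats = repeats, k = k,
                  seed = seed)
    fit <- fit_spec(spec, tuned$best_params, train_blocks, y_train,
                    seed = derive_seed(seed, 104729L))
    models[[spec$id]] <- fit
    for (nm in names(test_ds)) {
      yhat <- predict_spec(fit, block_matrices(test_ds[[nm]]))
      m <- eval_metrics(test_ds[[nm]]$metadata$tvc, yhat)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(model_id = spec$id, test_set = nm), m,
        data.frame(rmsecv = tuned$rmsecv, rmsecv_sd = tuned$rmsecv_sd,
                   params = as.character(jsonlite::toJSON(tuned$best_params,
                                                          auto_unbox = TRUE)))
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "models") <- models
  out
}

#' Repeated nested cross-validation
#'
#' Runs `repeats` repeats of `outer_k`-fold nested cross-validation. Per
#' repeat, the rows are shuffled with a repeat-derived seed (`seed + repeat`)
#' and split into `outer_k` folds; per outer fold, every spec is tuned by
#' `inner_k`-fold RMSEcv on the remaining data, refit with its best
#' candidate on all inner rows, and scored on the held-out outer fold.
#' Every spec sees the identical series of outer splits, so fold records are
#' pairable model-to-model. Preprocessing is applied to the fold's training
#' and test rows separately inside each fold.
#'
#' @inheritParams batch_on_batch_evaluate
#' @param repeats repeat count (default 10)
#' @param outer_k outer fold count (default 5; 10 x 5 yields 50 assessment
#'   records per model)
#' @param inner_k inner tuning fold count (default 5)
#' @return a `fold_results` data.frame with one row per (model, repeat,
#'   outer fold): `model_id`, `rep`, `fold`, `rmse`, `r2`, `accuracy`, `n`,
#'   `params` (JSON). The per-repeat outer test-ID assignments are attached
#'   as attribute `"assignments"`.
#' @export
nested_cv <- function(dataset, specs, recipe = default_recipe(),
                      repeats = 10L, outer_k = 5L, inner_k = 5L, seed = 1L) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  ids <- dataset$metadata$sample_id
  n <- length(ids)
  if (n < outer_k) stop("fewer rows than outer folds", call. = FALSE)
  rows <- list()
  assignments <- list()
  for (r in seq_len(repeats)) {
    rep_seed <- derive_seed(seed, r)
    folds <- kfold_assignment(n, outer_k, rep_seed)
    assignments[[r]] <- lapply(seq_len(outer_k), function(f) ids[folds == f])
    for (f in seq_len(outer_k)) {
      test_ids <- ids[folds == f]
      train_ids <- ids[folds != f]
      train_ds <- preprocess_dataset(subset_dataset(dataset, train_ids), recipe)
      test_ds <- preprocess_dataset(subset_dataset(dataset, test_ids), recipe)
      train_blocks <- block_matrices(train_ds)
      test_blocks <- block_matrices(test_ds)
      y_train <- train_ds$metadata$tvc
      y_test <- test_ds$metadata$tvc
      inner_seed <- derive_seed(rep_seed, 7919L * f)
      for (spec in specs) {
        tuned <- tune(spec, train_blocks, y_train, repeats = 1L, k = inner_k,
                      seed = inner_seed)
        fit <- fit_spec(spec, tuned$best_params, train_blocks, y_train,
                        seed = derive_seed(inner_seed, 104729L))
        yhat <- predict_spec(fit, test_blocks)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(model_id = spec$id, rep = r, fold = f),
          eval_metrics(y_test, yhat),
          data.frame(params = as.character(jsonlite::toJSON(tuned$best_params,
                                                            auto_unbox = TRUE)))
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "assignments") <- assignments
  attr(out, "seed") <- seed
  class(out) <- c("fold_results", class(out))
  out
}

#' Summarise nested-CV fold results per model
#'
#' Mean and standard deviation of RMSE, accuracy (reported as a percentage)
#' and R2 over all (repeat, fold) records of each model.
#'
#' @param results a `fold_results` data.frame from [nested_cv()]
#' @return data.frame with one row per model
#' @export
summarise_fold_results <- function(results) {
  stopifnot(is.data.frame(results))
  split_res <- split(results, results$model_id)
  out <- do.call(rbind, lapply(split_res, function(d) {
    data.frame(model_id = d$model_id[1L], n_folds = nrow(d),
               rmse_mean = mean(d$rmse), rmse_sd = stats::sd(d$rmse),
               acc_pct_mean = 100 * mean(d$accuracy),
               acc_pct_sd = 100 * stats::sd(d$accuracy),
               r2_mean = mean(d$r2), r2_sd = stats::sd(d$r2))
  }))
  rownames(out) <- NULL
  out[order(out$rmse_mean), , drop = FALSE]
}

#' Write / read fold results as tidy CSV
#' @param results a `fold_results` data.frame
#' @param path CSV file path
#' @export
write_fold_results <- function(results, path) {
  data.table::fwrite(as.data.frame(results), path)
  invisible(path)
}

#' @rdname write_fold_results
#' @export
read_fold_results <- function(path) {
  out <- as.data.frame(data.table::fread(path))
  class(out) <- c("fold_results", class(out))
  out
}
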