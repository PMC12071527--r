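# The three multi-sensor fusion architectures:
#   early - per-block z-score standardisation, horizontal concatenation, one PLS;
#   mid   - per-modality PLS models, concatenated latent scores, second PLS;
#   late  - stacked generalisation: a linear meta-learner trained on
#           out-of-fold base-model predictions, bases refit on all rows.

concat_blocks <- function(blocks) {
  do.call(cbind, unname(blocks))
}

check_blocks <- function(blocks, y = NULL, min_mod = 1L) {
  if (is.null(names(blocks)) || any(names(blocks) == "")) {
    stop("`blocks` must be a named list of matrices", call. = FALSE)
  }
  if (length(blocks) < min_mod) {
    stop(sprintf("need at least %d modality block(s)", min_mod), call. = FALSE)
  }
  n <- unique(vapply(blocks, nrow, 1L))
  if (length(n) != 1L) stop("blocks have differing row counts", call. = FALSE)
  if (!is.null(y) && n != length(y)) {
    stop("block rows must match length of `y`", call. = FALSE)
  }
  invisible(n)
}

#' Fit an early (low-level) fusion model
#'
#' Each block is z-score standardised with statistics fitted on the training
#' rows, the standardised blocks are concatenated horizontally in the given
#' modality order, and a single PLS model is fit on the combined matrix.
#'
#' @param blocks named list of numeric matrices (aligned rows, one entry per
#'   modality)
#' @param y response vector (TVC, log CFU/g)
#' @param n_lv latent-variable count of the single PLS model
#' @return an object of class `fusion_model` (strategy `"early"`)
#' @export
fit_early_fusion <- function(blocks, y, n_lv) {
  check_blocks(blocks, y)
  standardisers <- lapply(blocks, fit_standardiser)
  z <- mapply(apply_standardiser, standardisers, blocks, SIMPLIFY = FALSE)
  model <- fit_pls(concat_blocks(z), y, n_lv)
  structure(
    list(strategy = "early", modalities = names(blocks),
         standardisers = standardisers, meta = model,
         block_widths = vapply(blocks, ncol, 1L)),
    class = "fusion_model"
  )
}

#' Fit a mid-level (feature) fusion model
#'
#' Fits one PLS model per modality with its own latent-variable count, uses
#' them to transform the raw blocks into their latent score spaces,
#' concatenates the scores horizontally (width `sum(base_lvs)`), and fits a
#' second PLS model with `meta_lv` latent variables on the concatenated
#' score matrix. The base models are fit on the full training partition
#' before score extraction.
#'
#' @inheritParams fit_early_fusion
#' @param base_lvs named integer vector, one latent-variable count per
#'   modality (names must match `blocks`)
#' @param meta_lv latent-variable count of the second-layer PLS
#'   (<= `sum(base_lvs)`)
#' @return an object of class `fusion_model` (strategy `"mid"`)
#' @export
fit_mid_fusion <- function(blocks, y, base_lvs, meta_lv) {
  check_blocks(blocks, y)
  if (!all(names(blocks) %in% names(base_lvs))) {
    stop("`base_lvs` must name every modality", call. = FALSE)
  }
  if (meta_lv > sum(base_lvs[names(blocks)])) {
    stop("`meta_lv` exceeds the concatenated score width", call. = FALSE)
  }
  base <- lapply(stats::setNames(names(blocks), names(blocks)), function(nm) {
    fit_pls(blocks[[nm]], y, base_lvs[[nm]])
  })
  scores <- lapply(names(blocks), function(nm) {
    pls_transform(base[[nm]], blocks[[nm]])
  })
  meta <- fit_pls(concat_blocks(stats::setNames(scores, names(blocks))), y,
                  meta_lv)
  structure(
    list(strategy = "mid", modalities = names(blocks), base_models = base,
         meta = meta),
    class = "fusion_model"
  )
}

#' Out-of-fold fold assignment
#' @keywords internal
oof_fold_assignment <- function(n, k, seed) {
  withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Fit a late (decision) fusion model by stacked generalisation
#'
#' Training rows are shuffled once with the seed and split into `oof_folds`
#' folds. For each fold, per-modality base PLS models fit on the complement
#' predict the held-out rows, yielding one out-of-fold (OOF) prediction per
#' training row per modality. An ordinary least-squares meta-learner (with
#' intercept, unconstrained weights) regresses `y` on the OOF prediction
#' matrix. The base models are then refit on all training rows for
#' inference; prediction applies the meta coefficients to the refit base
#' predictions.
#'
#' @inheritParams fit_mid_fusion
#' @param oof_folds fold count for the OOF construction (default 20)
#' @param seed integer seed controlling the fold shuffle
#' @return an object of class `fusion_model` (strategy `"late"`) carrying
#'   `meta_coef` (intercept + one weight per modality) and the OOF matrix
#'   `oof` for audit
#' @export
fit_late_fusion <- function(blocks, y, base_lvs, oof_folds = 20L, seed = 1L) {
  n <- check_blocks(blocks, y)
  oof_folds <- as.integer(oof_folds)
  if (oof_folds < 2L || oof_folds > n) {
    stop("`oof_folds` must be in [2, n training rows]", call. = FALSE)
  }
  if (!all(names(blocks) %in% names(base_lvs))) {
    stop("`base_lvs` must name every modality", call. = FALSE)
  }
  folds <- oof_fold_assignment(n, oof_folds, seed)
  if (min(tabulate(folds, oof_folds)) < 2L) {
    stop("every OOF fold needs at least 2 rows", call. = FALSE)
  }
  oof <- matrix(NA_real_, n, length(blocks),
                dimnames = list(NULL, names(blocks)))
  for (f in seq_len(oof_folds)) {
    hold <- folds == f
    for (nm in names(blocks)) {
      m <- fit_pls(blocks[[nm]][!hold, , drop = FALSE], y[!hold],
                   base_lvs[[nm]])
      oof[hold, nm] <- pls_predict(m, blocks[[nm]][hold, , drop = FALSE])
    }
  }
  meta_fit <- stats::lm.fit(cbind(`(Intercept)` = 1, oof), y)
  # aliased (perfectly collinear) OOF columns get weight 0, not NA
  meta_fit$coefficients[is.na(meta_fit$coefficients)] <- 0
  base <- lapply(stats::setNames(names(blocks), names(blocks)), function(nm) {
    fit_pls(blocks[[nm]], y, base_lvs[[nm]])
  })
  structure(
    list(strategy = "late", modalities = names(blocks), base_models = base,
         meta_coef = meta_fit$coefficients, oof = oof, oof_folds = oof_folds,
         fold_assignment = folds, seed = seed),
    class = "fusion_model"
  )
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("<fusion_model> %s fusion of %s\n", x$strategy,
              paste(x$modalities, collapse = " + ")))
  invisible(x)
}

#' Predict from a fusion model
#'
#' Routes through the strategy-specific path: early models standardise and
#' concatenate, mid models transform through the base models into score
#' space, late models combine base predictions with the meta coefficients.
#'
#' @param model a `fusion_model`
#' @param blocks named list of matrices covering every modality of the model
#' @return numeric vector of predictions
#' @export
predict_fusion <- function(model, blocks) {
  stopifnot(inherits(model, "fusion_model"))
  missing_mod <- setdiff(model$modalities, names(blocks))
  if (length(missing_mod)) {
    stop("missing modality block(s): ", paste(missing_mod, collapse = ", "),
         call. = FALSE)
  }
  blocks <- blocks[model$modalities]
  check_blocks(blocks)
  switch(model$strategy,
    early = {
      z <- mapply(apply_standardiser, model$standardisers, blocks,
                  SIMPLIFY = FALSE)
      pls_predict(model$meta, concat_blocks(z))
    },
    mid = {
      scores <- lapply(model$modalities, function(nm) {
        pls_transform(model$base_models[[nm]], blocks[[nm]])
      })
      pls_predict(model$meta, concat_blocks(scores))
    },
    late = {
      preds <- vapply(model$modalities, function(nm) {
        pls_predict(model$base_models[[nm]], blocks[[nm]])
      }, numeric(nrow(blocks[[1]])))
      preds <- matrix(preds, ncol = length(model$modalities))
      as.numeric(model$meta_coef[1] + preds %*% model$meta_coef[-1])
    }
  )
}

#' Serialise / restore a fusion model as JSON
#'
#' Includes the OOF prediction matrix of late models for audit. A reloaded
#' model reproduces predictions exactly.
#'
#' @param model a `fusion_model`
#' @param path optional file path
#' @return JSON string, or for the reader a `fusion_model`
#' @export
fusion_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "fusion_model"))
  obj <- unclass(model)
  for (nm in c("standardisers", "base_models", "meta")) {
    if (!nm %in% names(obj)) next
    obj[[nm]] <- if (nm == "meta") unclass(obj[[nm]]) else lapply(obj[[nm]], unclass)
  }
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname fusion_to_json
#' @param json JSON string or file path produced by [fusion_to_json()]
#' @export
fusion_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  restore_pls <- function(m) {
    for (nm in c("weights", "x_loadings", "rotation", "scores")) {
      m[[nm]] <- as.matrix(m[[nm]])
    }
    m$feature_names <- if (length(m$feature_names)) {
      as.character(m$feature_names)
    } else {
      NULL
    }
    class(m) <- "pls_model"
    m
  }
  if ("meta" %in% names(obj)) obj$meta <- restore_pls(obj[["meta"]])
  if ("base_models" %in% names(obj)) {
    obj$base_models <- lapply(obj[["base_models"]], restore_pls)
  }
  if ("standardisers" %in% names(obj)) {
    obj$standardisers <- lapply(obj[["standardisers"]], function(s) {
      class(s) <- "standardiser"
      s
    })
  }
  if ("oof" %in% names(obj)) obj$oof <- as.matrix(obj[["oof"]])
  class(obj) <- "fusion_model"
  obj
}
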