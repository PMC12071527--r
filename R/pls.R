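# Single-response partial least squares regression (NIPALS PLS1), the base
# learner for every model in the pipeline. Centering only: spectra are
# already row-normalised by SNV, and z-scoring is applied explicitly where
# the fusion strategy calls for it (early fusion), so no per-feature scaling
# happens inside PLS itself.

#' Fit a PLS1 regression by NIPALS
#'
#' Mean-centres `X` and `y` and extracts `n_lv` latent variables. PLS1 needs
#' no inner iteration: per component the weight vector is closed-form,
#' `w = X'y / ||X'y||`, followed by scores `t = X w`, loadings
#' `p = X't / t't`, `q = y't / t't`, and deflation of `X`. The regression
#' coefficients `b = W (P'W)^-1 q` make prediction a single affine map. If
#' the residual `||X'y||` underflows before `n_lv` components (rank
#' exhaustion), the model is truncated with a warning.
#'
#' @param X numeric predictor matrix (>= 3 rows)
#' @param y numeric response vector, one value per row of `X`
#' @param n_lv number of latent variables, in
#'   `[1, min(ncol(X), nrow(X) - 1)]`
#' @return an object of class `pls_model` with elements `n_lv`, `x_mean`,
#'   `y_mean`, `weights` (W), `x_loadings` (P), `y_loadings` (q),
#'   `coefficients` (b), and the training score matrix `scores` (T)
#' @export
#' @examples
#' X <- matrix(rnorm(60), 20, 3)
#' y <- X[, 1] - 2 * X[, 2] + rnorm(20, sd = 0.1)
#' m <- fit_pls(X, y, n_lv = 2)
#' pls_predict(m, X[1:3, ])
fit_pls <- function(X, y, n_lv) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (n != length(y)) stop("rows of `X` must match length of `y`", call. = FALSE)
  if (n < 3L) stop("need at least 3 training rows", call. = FALSE)
  n_lv <- as.integer(n_lv)
  if (n_lv < 1L || n_lv > min(p, n - 1L)) {
    stop(sprintf("`n_lv` must be in [1, %d]", min(p, n - 1L)), call. = FALSE)
  }
  if (stats::sd(y) == 0) stop("`y` has zero variance", call. = FALSE)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- X - rep(x_mean, each = n)
  f <- y - y_mean
  W <- matrix(0, p, n_lv)
  P <- matrix(0, p, n_lv)
  q <- numeric(n_lv)
  TT <- matrix(0, n, n_lv)
  norm0 <- NA_real_
  a_done <- 0L
  for (a in seq_len(n_lv)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (a == 1L) norm0 <- nw
    if (nw < 1e-12 * norm0 || nw == 0) {
      warning(sprintf("rank exhausted after %d latent variable(s); truncating",
                      a_done), call. = FALSE)
      break
    }
    w <- w / nw
    t_a <- as.numeric(E %*% w)
    tt <- sum(t_a^2)
    p_a <- as.numeric(crossprod(E, t_a)) / tt
    q[a] <- sum(f * t_a) / tt
    E <- E - tcrossprod(t_a, p_a)
    W[, a] <- w
    P[, a] <- p_a
    TT[, a] <- t_a
    a_done <- a
  }
  if (a_done == 0L) stop("no usable latent variable (X'y is zero)", call. = FALSE)
  W <- W[, seq_len(a_done), drop = FALSE]
  P <- P[, seq_len(a_done), drop = FALSE]
  q <- q[seq_len(a_done)]
  TT <- TT[, seq_len(a_done), drop = FALSE]
  R <- W %*% solve(crossprod(P, W))
  b <- as.numeric(R %*% q)
  structure(
    list(n_lv = a_done, x_mean = x_mean, y_mean = y_mean,
         weights = W, x_loadings = P, y_loadings = q,
         rotation = R, coefficients = b, scores = TT,
         feature_names = colnames(X)),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent variable(s), %d features\n",
              x$n_lv, length(x$x_mean)))
  invisible(x)
}

check_axis <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$x_mean)) {
    stop("feature count does not match the fitted model", call. = FALSE)
  }
  if (!is.null(model$feature_names) && !is.null(colnames(X)) &&
      !identical(colnames(X), model$feature_names)) {
    stop("feature axis does not match the fitted model", call. = FALSE)
  }
  X
}

#' Project new rows into a model's latent space
#'
#' Computes `T_new = (X - x_mean) W (P'W)^-1`; on the training matrix this
#' reproduces the stored scores.
#'
#' @param model a fitted [fit_pls()] model
#' @param X numeric matrix on the training feature axis
#' @return scores matrix, rows x `n_lv`
#' @export
pls_transform <- function(model, X) {
  stopifnot(inherits(model, "pls_model"))
  X <- check_axis(model, X)
  (X - rep(model$x_mean, each = nrow(X))) %*% model$rotation
}

#' Predict from a fitted PLS model
#'
#' `y_mean + (X - x_mean) b`; identical (to numerical precision) to
#' projecting into the latent space and regressing on the stored
#' y-loadings.
#'
#' @inheritParams pls_transform
#' @return numeric vector of predictions
#' @export
pls_predict <- function(model, X) {
  stopifnot(inherits(model, "pls_model"))
  X <- check_axis(model, X)
  as.numeric(model$y_mean +
               (X - rep(model$x_mean, each = nrow(X))) %*% model$coefficients)
}

#' Serialise / restore a PLS model as JSON
#'
#' Arrays are written as nested lists at full precision, so a reloaded model
#' reproduces predictions exactly.
#'
#' @param model a `pls_model`
#' @param path optional file path
#' @return JSON string, or for the reader a `pls_model`
#' @export
pls_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "pls_model"))
  js <- jsonlite::toJSON(unclass(model), auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname pls_to_json
#' @param json JSON string or file path produced by [pls_to_json()]
#' @export
pls_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  for (nm in c("weights", "x_loadings", "rotation", "scores")) {
    obj[[nm]] <- as.matrix(obj[[nm]])
  }
  obj$feature_names <- if (length(obj$feature_names)) {
    as.character(obj$feature_names)
  } else {
    NULL
  }
  class(obj) <- "pls_model"
  obj
}
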