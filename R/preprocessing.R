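# Spectral preprocessing: standard normal variate, Savitzky-Golay smoothing,
# fingerprint-region restriction, and train-fitted z-score standardisation.
# SNV and Savitzky-Golay act row-by-row, so applying them to training and
# test partitions separately is leak-free by construction; the standardiser
# is the only fitted transform and is always fit on training rows only.

block_or_matrix <- function(x) {
  if (inherits(x, "spectral_block")) x$matrix
  else if (is.matrix(x) && is.numeric(x)) x
  else stop("expected a spectral_block or numeric matrix", call. = FALSE)
}

rebuild_like <- function(x, m, wavenumbers = "keep") {
  if (!inherits(x, "spectral_block")) return(m)
  wn <- if (identical(wavenumbers, "keep")) x$wavenumbers else wavenumbers
  spectral_block(m, x$modality, wn)
}

#' Standard normal variate (SNV) transform
#'
#' Centres and scales each spectrum (row) to mean 0 and unit standard
#' deviation (n - 1 denominator), removing per-spectrum additive offsets and
#' multiplicative gains. Idempotent, and invariant to affine transforms
#' `a * x + b` (a > 0) of a row.
#'
#' @param x a [spectral_block()] or numeric matrix with >= 2 columns
#' @return an object of the same type with SNV-transformed rows
#' @export
#' @examples
#' snv(rbind(a = c(1, 2, 3)))
snv <- function(x) {
  m <- block_or_matrix(x)
  if (ncol(m) < 2L) stop("SNV needs at least 2 features per row", call. = FALSE)
  mu <- rowMeans(m)
  centred <- m - mu
  s <- sqrt(rowSums(centred^2) / (ncol(m) - 1L))
  bad <- which(s <= 0 | !is.finite(s))
  if (length(bad)) {
    stop("zero-variance row(s): ",
         paste(rownames(m)[bad] %||% bad, collapse = ", "), call. = FALSE)
  }
  rebuild_like(x, centred / s)
}

sgolay_smoothing_kernel <- function(window, polyorder) {
  h <- signal::sgolay(p = polyorder, n = window)
  as.numeric(h[(window + 1L) %/% 2L, ])
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing of each row over a uniform
#' feature grid. Edges are handled by antisymmetric (point-symmetric)
#' reflection padding, which preserves polynomials up to the filter degree at
#' the boundaries: a row sampled from a straight line passes through
#' unchanged, interior and edges alike. Derivative order is 0 (smoothing
#' only).
#'
#' @param x a [spectral_block()] or numeric matrix; an attached wavenumber
#'   axis is checked for uniform spacing
#' @param window odd window length (default 11)
#' @param polyorder polynomial order < window (default 1)
#' @return an object of the same type, dimensions unchanged
#' @export
savitzky_golay <- function(x, window = 11L, polyorder = 1L) {
  m <- block_or_matrix(x)
  window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L) stop("`window` must be odd", call. = FALSE)
  if (polyorder >= window) stop("`polyorder` must be smaller than `window`",
                                call. = FALSE)
  if (window > ncol(m)) stop("`window` exceeds the feature count", call. = FALSE)
  if (inherits(x, "spectral_block") && !is.null(x$wavenumbers)) {
    d <- diff(x$wavenumbers)
    if (max(abs(d - mean(d))) > 1e-6 * abs(mean(d))) {
      stop("feature grid is not uniform; Savitzky-Golay smoothing needs a ",
           "uniform axis", call. = FALSE)
    }
  }
  h <- sgolay_smoothing_kernel(window, polyorder)
  half <- (window - 1L) %/% 2L
  p <- ncol(m)
  # antisymmetric reflection about the first/last sample of each row
  left <- 2 * m[, 1L] - m[, (half + 1L):2L, drop = FALSE]
  right <- 2 * m[, p] - m[, (p - 1L):(p - half), drop = FALSE]
  padded <- cbind(left, m, right)
  out <- matrix(0, nrow(m), p)
  for (k in seq_len(window)) {
    out <- out + h[k] * padded[, k:(k + p - 1L), drop = FALSE]
  }
  dimnames(out) <- dimnames(m)
  rebuild_like(x, out)
}

#' Restrict an FTIR block to a wavenumber window
#'
#' Keeps the features whose wavenumber lies in the closed interval
#' `[lo, hi]`, preserving axis order. Defaults select the 2000-900 cm-1
#' spoilage fingerprint region.
#'
#' @param x a [spectral_block()] carrying a wavenumber axis
#' @param lo,hi interval bounds in cm-1
#' @return a [spectral_block()] with the restricted axis
#' @export
restrict_range <- function(x, lo = 900, hi = 2000) {
  if (!inherits(x, "spectral_block") || is.null(x$wavenumbers)) {
    stop("`x` must be a spectral_block with a wavenumber axis", call. = FALSE)
  }
  if (lo > hi) stop("`lo` must not exceed `hi`", call. = FALSE)
  keep <- which(x$wavenumbers >= lo & x$wavenumbers <= hi)
  if (length(keep) == 0L) {
    stop(sprintf("no features in [%g, %g] cm-1", lo, hi), call. = FALSE)
  }
  spectral_block(x$matrix[, keep, drop = FALSE], x$modality,
                 x$wavenumbers[keep])
}

#' Fit a per-feature z-score standardiser
#'
#' Records per-column means and standard deviations (n - 1 denominator) of a
#' training matrix. Constant columns are rejected. Apply the fitted object to
#' training or test matrices with [apply_standardiser()]; test matrices are
#' scaled with the training statistics, never re-fit.
#'
#' @param m numeric training matrix (>= 2 rows)
#' @return an object of class `standardiser`
#' @export
fit_standardiser <- function(m) {
  m <- block_or_matrix(m)
  if (nrow(m) < 2L) stop("standardiser needs >= 2 training rows", call. = FALSE)
  mu <- colMeans(m)
  s <- apply(m, 2, stats::sd)
  bad <- which(s <= 0 | !is.finite(s))
  if (length(bad)) {
    stop("constant training column(s): ",
         paste(colnames(m)[bad] %||% bad, collapse = ", "), call. = FALSE)
  }
  structure(list(mean = mu, sd = s, fitted_on = nrow(m)),
            class = "standardiser")
}

#' @rdname fit_standardiser
#' @param s a fitted `standardiser`
#' @export
apply_standardiser <- function(s, m) {
  stopifnot(inherits(s, "standardiser"))
  m <- block_or_matrix(m)
  if (ncol(m) != length(s$mean)) {
    stop("feature count does not match the fitted standardiser", call. = FALSE)
  }
  sweep(sweep(m, 2, s$mean, "-"), 2, s$sd, "/")
}

#' Preprocessing recipes
#'
#' A recipe is a named list (one entry per modality) of ordered step lists.
#' Each step is `recipe_step(name, ...)` where `name` is one of `"snv"`,
#' `"savitzky_golay"`, `"restrict_range"`. The default recipe follows the
#' study chain: FTIR gets SNV, then Savitzky-Golay (window 11, order 1),
#' then restriction to 2000-900 cm-1 (restriction last, so smoothing edge
#' effects fall outside the fingerprint region); MSI and MSIF get SNV.
#'
#' @param name step name
#' @param ... step parameters
#' @return `recipe_step`: a step descriptor; `default_recipe`: a recipe list
#' @export
recipe_step <- function(name, ...) {
  name <- match.arg(name, c("snv", "savitzky_golay", "restrict_range"))
  list(name = name, args = list(...))
}

#' @rdname recipe_step
#' @export
default_recipe <- function() {
  list(
    FTIR = list(recipe_step("snv"),
                recipe_step("savitzky_golay", window = 11L, polyorder = 1L),
                recipe_step("restrict_range", lo = 900, hi = 2000)),
    MSI = list(recipe_step("snv")),
    MSIF = list(recipe_step("snv"))
  )
}

#' Read a per-modality recipe from a YAML list
#'
#' Expects one key per modality, each an ordered list of `{step: name, ...}`
#' entries, mirroring [default_recipe()].
#'
#' @param x a list parsed from YAML (e.g. `yaml::read_yaml(...)$recipe`)
#' @return a recipe list
#' @export
recipe_from_list <- function(x) {
  lapply(x, function(steps) {
    lapply(steps, function(s) {
      do.call(recipe_step, c(list(name = s$step), s[setdiff(names(s), "step")]))
    })
  })
}

apply_steps <- function(block, steps) {
  for (s in steps) {
    block <- switch(s$name,
      snv = snv(block),
      savitzky_golay = do.call(savitzky_golay, c(list(block), s$args)),
      restrict_range = do.call(restrict_range, c(list(block), s$args))
    )
  }
  block
}

#' Apply a preprocessing recipe to a dataset
#'
#' Applies each modality's step chain to its block. All supported steps are
#' per-row transforms, so calling this separately on training and test
#' partitions (as the evaluation drivers do) cannot leak information across
#' the split. Modalities without a recipe entry pass through unchanged.
#'
#' @param dataset a [multimodal_dataset()]
#' @param recipe a recipe list, see [default_recipe()]
#' @return a [multimodal_dataset()] with transformed blocks
#' @export
preprocess_dataset <- function(dataset, recipe = default_recipe()) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  blocks <- dataset$blocks
  for (nm in names(blocks)) {
    if (!is.null(recipe[[nm]])) {
      blocks[[nm]] <- apply_steps(blocks[[nm]], recipe[[nm]])
    }
  }
  multimodal_dataset(blocks, dataset$metadata)
}
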