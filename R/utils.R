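`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a child seed from a run seed
#'
#' Keeps derived seeds inside the 32-bit integer range so they are valid
#' arguments to [set.seed()].
#' @param seed base integer seed
#' @param offset non-negative integer offset
#' @return an integer seed
#' @keywords internal
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% .Machine$integer.max)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
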