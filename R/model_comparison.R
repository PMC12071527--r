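# Paired model comparison over seed-matched cross-validation folds:
# Wilcoxon signed-rank tests (exact and tie-aware for small n) with
# Holm-Bonferroni family-wise correction and star-tier annotation.

# Exact null distribution of W+ for rank magnitudes `ranks` (midranks
# allowed): probabilities over doubled rank sums 0..2*sum(ranks), built by
# convolution over the 2^n equiprobable sign assignments.
wplus_exact_distribution <- function(ranks) {
  doubled <- as.integer(round(2 * ranks))
  total <- sum(doubled)
  prob <- numeric(total + 1L)
  prob[1L] <- 1
  for (d in doubled) {
    shifted <- c(rep(0, d), prob[seq_len(total + 1L - d)])
    prob <- (prob + shifted) / 2
  }
  prob  # prob[i] = P(2 * W+ = i - 1)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Computes differences `a - b`, drops exact zeros (Wilcoxon's classical
#' treatment), ranks the absolute differences with midranks for ties, and
#' reports `W = min(W+, W-)`. For `n <= exact_limit` pairs the two-sided
#' p-value is exact — computed from the tie-aware null distribution of `W+`
#' over all 2^n sign assignments, as `min(1, 2 * min(P(W+ <= w), P(W+ >= w)))`.
#' For larger n a normal approximation with continuity correction and
#' tie-corrected variance is used.
#'
#' @param a,b paired numeric vectors of equal length (>= 5 nonzero
#'   differences after zero removal)
#' @param exact_limit largest n for which the exact distribution is used
#'   (default 25)
#' @return list with `statistic` (W), `w_plus`, `w_minus`, `p_value`
#'   (two-sided), `n` (pairs used), `method` (`"exact"` or `"normal"`), and
#'   `direction` (which argument has the smaller values on balance: `"a"`,
#'   `"b"`)
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 7))
wilcoxon_signed_rank <- function(a, b, exact_limit = 25L) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length",
                                   call. = FALSE)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all paired differences are zero", call. = FALSE)
  if (n < 5L) stop("need at least 5 nonzero paired differences", call. = FALSE)
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  w <- min(w_plus, w_minus)
  if (n <= exact_limit) {
    prob <- wplus_exact_distribution(r)
    idx <- as.integer(round(2 * w_plus)) + 1L
    p_le <- sum(prob[seq_len(idx)])
    p_ge <- sum(prob[idx:length(prob)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- sign(w_plus - mu) * 0.5
    z <- (w_plus - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = w, w_plus = w_plus, w_minus = w_minus, p_value = p, n = n,
       method = method,
       direction = if (w_plus < w_minus) "a" else if (w_plus > w_minus) "b" else "tie")
}

#' Holm-Bonferroni step-down adjustment
#'
#' Sorts the p-values ascending, multiplies the i-th smallest by
#' `m - i + 1`, enforces monotonicity by cumulative maximum, caps at 1 and
#' restores the input order. Delegates to [stats::p.adjust()] with
#' `method = "holm"`, which implements exactly this procedure.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`
#' @return adjusted p-values, same order as the input
#' @export
#' @examples
#' holm_bonferroni(c(0.01, 0.04, 0.03))
holm_bonferroni <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "holm")
}

significance_tier <- function(p) {
  ifelse(is.na(p), "ns",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

#' Pairwise model comparison over matched folds
#'
#' Pulls the per-(repeat, fold) RMSE vectors of each model pair from a
#' seed-matched [nested_cv()] result, runs one Wilcoxon signed-rank test per
#' pair, and applies Holm-Bonferroni adjustment across the declared family
#' (default: all tested pairs). A pair with identical fold RMSEs is
#' annotated `"no-difference"` rather than raising an error. Tiers follow
#' the 0.05 / 0.01 / 0.001 thresholds on the adjusted p-value, and
#' `favours_non_fusion` flags pairs whose lower-median model is a
#' single-sensor model.
#'
#' @param results a `fold_results` data.frame
#' @param pairs optional list of length-2 character vectors of model IDs;
#'   default: all unordered pairs present
#' @param fusion_ids model IDs regarded as fusion models (default: IDs whose
#'   records carry more than one modality, inferred as non-single via the
#'   `model_id` values `early`, `mid`, `late`; override for custom rosters)
#' @return a `comparison_report` data.frame with columns `model_a`,
#'   `model_b`, `n_pairs`, `statistic`, `p_raw`, `p_holm`, `lower_median`,
#'   `tier`, `favours_non_fusion`, `note`
#' @export
compare_models <- function(results, pairs = NULL,
                           fusion_ids = c("early", "mid", "late")) {
  stopifnot(is.data.frame(results))
  models <- unique(results$model_id)
  if (is.null(pairs)) {
    if (length(models) < 2L) {
      warning("fewer than two models; empty comparison report", call. = FALSE)
      pairs <- list()
    } else {
      cmb <- utils::combn(models, 2L, simplify = FALSE)
      pairs <- cmb
    }
  }
  key <- function(d) order(d$rep, d$fold)
  rows <- lapply(pairs, function(pr) {
    if (!all(pr %in% models)) {
      stop("model(s) missing from results: ",
           paste(setdiff(pr, models), collapse = ", "), call. = FALSE)
    }
    da <- results[results$model_id == pr[1L], , drop = FALSE]
    db <- results[results$model_id == pr[2L], , drop = FALSE]
    da <- da[key(da), , drop = FALSE]
    db <- db[key(db), , drop = FALSE]
    if (nrow(da) != nrow(db) ||
        !all(da$rep == db$rep & da$fold == db$fold)) {
      stop("fold records of ", pr[1L], " and ", pr[2L], " are not matched",
           call. = FALSE)
    }
    if (all(da$rmse == db$rmse)) {
      return(data.frame(model_a = pr[1L], model_b = pr[2L], n_pairs = 0L,
                        statistic = NA_real_, p_raw = NA_real_,
                        lower_median = NA_character_,
                        note = "no-difference", stringsAsFactors = FALSE))
    }
    wt <- wilcoxon_signed_rank(da$rmse, db$rmse)
    lower <- if (stats::median(da$rmse) <= stats::median(db$rmse)) pr[1L] else pr[2L]
    data.frame(model_a = pr[1L], model_b = pr[2L], n_pairs = wt$n,
               statistic = wt$statistic, p_raw = wt$p_value,
               lower_median = lower, note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) {
    out <- data.frame(model_a = character(), model_b = character(),
                      n_pairs = integer(), statistic = numeric(),
                      p_raw = numeric(), lower_median = character(),
                      note = character(), p_holm = numeric(),
                      tier = character(), favours_non_fusion = logical())
    class(out) <- c("comparison_report", class(out))
    return(out)
  }
  ok <- !is.na(out$p_raw)
  out$p_holm <- NA_real_
  out$p_holm[ok] <- holm_bonferroni(out$p_raw[ok])
  out$tier <- significance_tier(out$p_holm)
  out$favours_non_fusion <- !is.na(out$lower_median) &
    !(out$lower_median %in% fusion_ids) & out$tier != "ns"
  class(out) <- c("comparison_report", class(out))
  out
}

#' Render a comparison report as a star matrix
#'
#' Text heat-map of significance tiers for all pairs, mirroring the panel
#' layout of pairwise comparison figures: `***`, `**`, `*` or `ns` per cell,
#' with `(nf)` marking comparisons significant in favour of a non-fusion
#' model.
#'
#' @param report a `comparison_report`
#' @return character vector of lines (also printed invisibly-friendly)
#' @export
format_star_matrix <- function(report) {
  stopifnot(inherits(report, "comparison_report"))
  models <- unique(c(report$model_a, report$model_b))
  m <- matrix("", length(models), length(models),
              dimnames = list(models, models))
  for (i in seq_len(nrow(report))) {
    lab <- report$tier[i]
    if (isTRUE(report$favours_non_fusion[i])) lab <- paste0(lab, "(nf)")
    m[report$model_a[i], report$model_b[i]] <- lab
    m[report$model_b[i], report$model_a[i]] <- lab
  }
  diag(m) <- "-"
  widths <- pmax(nchar(models), 7L)
  header <- paste0(formatC("", width = max(nchar(models))), " ",
                   paste(mapply(formatC, models, width = widths),
                         collapse = " "))
  body <- vapply(seq_along(models), function(i) {
    paste0(formatC(models[i], width = max(nchar(models))), " ",
           paste(mapply(formatC, m[i, ], width = widths), collapse = " "))
  }, character(1))
  c(header, body)
}

#' Write a comparison report to CSV plus a star-matrix text file
#' @param report a `comparison_report`
#' @param csv_path CSV output path
#' @param matrix_path optional text output path for [format_star_matrix()]
#' @export
write_comparison_report <- function(report, csv_path, matrix_path = NULL) {
  data.table::fwrite(as.data.frame(report), csv_path)
  if (!is.null(matrix_path)) {
    writeLines(format_star_matrix(report), matrix_path)
  }
  invisible(csv_path)
}
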