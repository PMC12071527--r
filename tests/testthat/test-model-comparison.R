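test_that("exact Wilcoxon p-values match brute-force sign enumeration", {
  cases <- list(
    withr::with_seed(1, list(a = rnorm(8), b = rnorm(8))),
    withr::with_seed(2, list(a = round(rnorm(10), 1),
                             b = round(rnorm(10), 1))),  # ties in |d|
    withr::with_seed(3, list(a = rnorm(12, 0.5), b = rnorm(12))),
    list(a = c(3, 3, 4, 5, 6, 7), b = c(1, 1, 2, 2, 2, 2))  # heavy ties
  )
  for (cs in cases) {
    got <- wilcoxon_signed_rank(cs$a, cs$b)
    expect_equal(got$p_value, brute_force_wilcoxon_p(cs$a, cs$b),
                 tolerance = 1e-12)
  }
})

test_that("five uniformly positive differences give the exact p of 2/32", {
  out <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))
  expect_equal(out$p_value, 0.0625)
  expect_identical(out$statistic, 0)
  expect_identical(out$method, "exact")
})

test_that("tie-free exact p-values agree with the standard implementation", {
  withr::with_seed(5, {
    a <- rnorm(15)
    b <- rnorm(15, 0.4)
  })
  got <- wilcoxon_signed_rank(a, b)
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("the large-sample path uses the tie-corrected normal approximation", {
  withr::with_seed(6, {
    a <- rnorm(60)
    b <- rnorm(60, 0.3)
  })
  got <- wilcoxon_signed_rank(a, b)
  expect_identical(got$method, "normal")
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                            correct = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("degenerate and swapped inputs behave predictably", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_error(wilcoxon_signed_rank(x, x), "zero")
  expect_error(wilcoxon_signed_rank(x, x[1:3]), "equal length")
  expect_error(wilcoxon_signed_rank(x[1:4], x[1:4] + 1), "at least 5")
  withr::with_seed(7, {
    a <- rnorm(10)
    b <- rnorm(10, 0.5)
  })
  ab <- wilcoxon_signed_rank(a, b)
  ba <- wilcoxon_signed_rank(b, a)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-14)
  expect_false(identical(ab$direction, ba$direction))
})

test_that("Holm adjustment matches the hand-computed step-down cases", {
  expect_equal(holm_bonferroni(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_bonferroni(0.2), 0.2)  # m = 1: unchanged
  # 0.5 * 2 = 1.0; cumulative maximum lifts 0.9 * 1 to 1.0 as well
  expect_equal(holm_bonferroni(c(0.5, 0.9)), c(1, 1))
  expect_error(holm_bonferroni(c(0.5, 1.2)), "0, 1")
})

test_that("Holm adjustment is order-invariant and never increases significance", {
  withr::with_seed(8, {
    p <- runif(9)
    perm <- sample(9)
  })
  adj <- holm_bonferroni(p)
  expect_equal(holm_bonferroni(p[perm])[order(perm)], adj)
  expect_true(all(adj >= p))
  for (alpha in c(0.05, 0.01, 0.001)) {
    expect_lte(sum(adj < alpha), sum(p < alpha))
  }
})

# a fold-results table where `better` beats `worse` on every matched fold and
# `peer` is statistically indistinguishable from `better`
fake_fold_results <- function() {
  grid <- expand.grid(rep = 1:10, fold = 1:5)
  base <- withr::with_seed(9, runif(50, 0.4, 0.8))
  delta <- withr::with_seed(10, runif(50, 0.01, 0.05))
  jitter <- withr::with_seed(11, rnorm(50, sd = 0.001))
  mk <- function(id, rmse) {
    data.frame(model_id = id, rep = grid$rep, fold = grid$fold, rmse = rmse,
               r2 = 0.8, accuracy = 0.9, n = 20)
  }
  structure(rbind(mk("late", base), mk("msi", base + delta),
                  mk("peer", base + jitter)),
            class = c("fold_results", "data.frame"))
}

test_that("pairwise comparison flags dominance at the *** tier", {
  res <- fake_fold_results()
  rep <- compare_models(res, pairs = list(c("late", "msi")))
  expect_identical(nrow(rep), 1L)
  # family of one pair: adjusted equals raw
  expect_equal(rep$p_holm, rep$p_raw)
  # 50 uniformly signed differences: exact-tier significance
  expect_identical(rep$tier, "***")
  expect_identical(rep$lower_median, "late")
  expect_false(rep$favours_non_fusion)
})

test_that("comparison families are Holm-adjusted and direction-annotated", {
  res <- fake_fold_results()
  rep <- compare_models(res)
  expect_identical(nrow(rep), 3L)
  ok <- !is.na(rep$p_raw)
  expect_true(all(rep$p_holm[ok] >= rep$p_raw[ok]))
  peer_row <- rep[rep$model_a == "msi" & rep$model_b == "peer" |
                    rep$model_a == "peer" & rep$model_b == "msi", ]
  # msi loses to peer too, and peer is not a fusion model
  expect_true(peer_row$lower_median == "peer")
  expect_true(peer_row$favours_non_fusion)
  expect_error(compare_models(res, pairs = list(c("late", "absent"))),
               "missing")
  lines <- format_star_matrix(rep)
  expect_length(lines, 4L)  # header + one row per model
  expect_match(paste(lines, collapse = "\n"), "\\*\\*\\*")
})

test_that("identical fold RMSEs yield a no-difference annotation, not an error", {
  res <- fake_fold_results()
  dup <- res[res$model_id == "late", ]
  dup$model_id <- "late_copy"
  res2 <- structure(rbind(res, dup), class = class(res))
  rep <- compare_models(res2, pairs = list(c("late", "late_copy")))
  expect_identical(rep$note, "no-difference")
  expect_identical(rep$tier, "ns")
  expect_true(is.na(rep$p_raw))
})

test_that("a single-model table gives an empty report with a warning", {
  res <- fake_fold_results()
  solo <- res[res$model_id == "late", ]
  expect_warning(rep <- compare_models(solo), "fewer than two")
  expect_identical(nrow(rep), 0L)
})
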