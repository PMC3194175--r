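test_that("gold collapsing merges affirmed and ambiguous into not_negated", {
  expect_identical(collapse_gold(c("negated", "affirmed", "ambiguous")),
                   c("negated", "not_negated", "not_negated"))
  expect_error(collapse_gold("maybe"), "unknown gold label")
})

test_that("confusion counts match hand enumeration", {
  gold <- c("negated", "negated", "not_negated", "not_negated",
            "not_negated")
  cc <- confusion_counts(gold, gold)
  expect_identical(c(cc$tp, cc$fp, cc$fn, cc$tn), c(2L, 0L, 0L, 3L))
  all_neg <- confusion_counts(rep("negated", 5), gold)
  expect_identical(c(all_neg$tp, all_neg$fp), c(2L, 3L))
  # mixed 10-pair fixture, verified by explicit counting
  pred <- c("negated", "negated", "not_negated", "negated", "not_negated",
            "not_negated", "negated", "not_negated", "negated",
            "not_negated")
  gld <- c("negated", "not_negated", "negated", "negated", "not_negated",
           "negated", "not_negated", "not_negated", "negated",
           "not_negated")
  cc2 <- confusion_counts(pred, gld)
  expect_identical(c(cc2$tp, cc2$fp, cc2$fn, cc2$tn), c(3L, 2L, 2L, 3L))
  ref <- hand_metrics(pred, gld)
  m <- negation_metrics(cc2)
  expect_equal(m$estimate[m$metric == "precision"], ref$precision)
  expect_equal(m$estimate[m$metric == "npv"], ref$npv)
})

test_that("id alignment failures are reported", {
  expect_error(confusion_counts("negated", c("negated", "negated")),
               "equal length")
  expect_error(
    confusion_counts("negated", "negated", ids = "a", gold_ids = "b"),
    "mismatch.*a|a.*mismatch")
})

test_that("metrics reproduce exact ratios and flag empty denominators", {
  cc <- structure(list(tp = 3L, fp = 1L, fn = 1L, tn = 5L),
                  class = "confusion_counts")
  m <- negation_metrics(cc)
  est <- setNames(m$estimate, m$metric)
  expect_equal(unname(est["precision"]), 0.75)
  expect_equal(unname(est["recall"]), 0.75)
  expect_equal(unname(est["specificity"]), 5 / 6, tolerance = 1e-12)
  expect_equal(unname(est["npv"]), 5 / 6, tolerance = 1e-12)
  # integer identity: precision * (tp + fp) = tp
  expect_equal(est["precision"] * 4, 3, ignore_attr = TRUE)
  none <- structure(list(tp = 0L, fp = 0L, fn = 2L, tn = 3L),
                    class = "confusion_counts")
  m0 <- negation_metrics(none)
  expect_false(m0$defined[m0$metric == "precision"])
  expect_true(is.na(m0$estimate[m0$metric == "precision"]))
  bad <- structure(list(tp = -1L, fp = 0L, fn = 0L, tn = 0L),
                   class = "confusion_counts")
  expect_error(negation_metrics(bad), "non-negative")
})

test_that("Wald intervals reproduce the published recall interval closely", {
  # recall 81.9% on n = 269 printed as (77.3 - 86.4)
  ci <- 0.819 + c(-1, 1) * stats::qnorm(0.975) *
    sqrt(0.819 * (1 - 0.819) / 269)
  tp <- round(0.819 * 269)  # 220
  cc <- structure(list(tp = tp, fp = 0L, fn = 269L - tp, tn = 0L),
                  class = "confusion_counts")
  m <- negation_metrics(cc)
  r <- m[m$metric == "recall", ]
  expect_equal(r$ci_low, ci[1], tolerance = 2e-3)
  expect_equal(r$ci_high, ci[2], tolerance = 2e-3)
  expect_equal(100 * r$ci_low, 77.3, tolerance = 0.1)
  expect_equal(100 * r$ci_high, 86.4, tolerance = 0.15)
  expect_true(r$ci_low <= r$estimate && r$estimate <= r$ci_high)
})

test_that("Wald interval width shrinks toward zero with n", {
  widths <- vapply(c(10, 100, 1000, 1e5), function(n) {
    tp <- round(0.8 * n)
    cc <- structure(list(tp = tp, fp = n - tp, fn = 0L, tn = 0L),
                    class = "confusion_counts")
    m <- negation_metrics(cc)
    diff(c(m$ci_low[1], m$ci_high[1]))
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_lt(widths[4], 0.01)
})

test_that("per-trigger statistics group, count and order correctly", {
  decisions <- data.frame(
    label = c(rep("negated", 4), "negated", "negated", "not_negated"),
    trigger = c(rep("ingen", 4), "aldrig", "aldrig", NA),
    stringsAsFactors = FALSE)
  gold <- c("negated", "negated", "negated", "not_negated",
            "negated", "negated", "negated")
  ts <- trigger_stats(decisions, gold)
  expect_identical(ts$trigger, c("aldrig", "ingen"))  # precision order
  expect_identical(ts$occurrences, c(2L, 4L))
  expect_identical(ts$correct, c(2L, 3L))
  expect_equal(ts$precision, c(1.0, 0.75))
  # not_negated pairs contribute to no trigger
  expect_false(any(is.na(ts$trigger)))
  empty <- trigger_stats(data.frame(label = "not_negated",
                                    trigger = NA_character_), "negated")
  expect_identical(nrow(empty), 0L)
})

test_that("percent agreement counts matching positions", {
  expect_equal(percent_agreement(letters[1:5], letters[1:5]), 1.0)
  expect_equal(percent_agreement(rep("a", 4), rep("b", 4)), 0.0)
  expect_equal(percent_agreement(c(rep("x", 7), "y"),
                                 c(rep("x", 7), "z")), 0.875)
  expect_error(percent_agreement("a", c("a", "b")), "equal length")
})

test_that("Cohen's kappa matches closed-form values", {
  a <- c(rep("neg", 25), rep("pos", 25))
  b <- c(rep("neg", 20), rep("pos", 5), rep("neg", 10), rep("pos", 15))
  expect_equal(cohens_kappa(a, b), 0.40, tolerance = 1e-12)
  # symmetric total disagreement
  a2 <- c(rep("x", 5), rep("y", 5))
  b2 <- c(rep("y", 5), rep("x", 5))
  expect_equal(cohens_kappa(a2, b2), -1.0)
  # perfect non-constant agreement
  expect_equal(cohens_kappa(a, a), 1.0)
  # invariant under label swapping
  swap <- function(v) ifelse(v == "neg", "pos", "neg")
  expect_equal(cohens_kappa(swap(a), swap(b)), cohens_kappa(a, b))
  expect_warning(k <- cohens_kappa(rep("a", 3), rep("a", 3)), "undefined")
  expect_true(is.na(k))
})

test_that("the two-proportion chi-squared matches the closed form and R", {
  res <- chi2_two_proportions(40, 50, 30, 50)
  expect_equal(res$statistic, 100 * (40 * 20 - 30 * 10)^2 /
                 (70 * 30 * 50 * 50), tolerance = 1e-12)
  expect_equal(res$statistic, 4.7619, tolerance = 1e-4)
  expect_equal(res$p_value, 0.0291, tolerance = 1e-3)
  # cross-check against the built-in Pearson test without correction
  tab <- matrix(c(40, 10, 30, 20), nrow = 2)
  ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  # identical proportions give the null result
  null <- chi2_two_proportions(10, 20, 10, 20)
  expect_equal(null$statistic, 0)
  expect_equal(null$p_value, 1)
  # symmetry in the two groups
  expect_equal(chi2_two_proportions(37, 60, 21, 45)$statistic,
               chi2_two_proportions(21, 45, 37, 60)$statistic)
  # degenerate pooled proportion
  expect_equal(chi2_two_proportions(0, 10, 0, 10)$p_value, 1)
  expect_equal(chi2_two_proportions(10, 10, 10, 10)$statistic, 0)
  # 1-df quantile identity at the 1% level
  expect_identical(chi2_two_proportions(45, 50, 25, 50)$p_value < 0.01,
                   chi2_two_proportions(45, 50, 25, 50)$statistic >
                     stats::qchisq(0.99, df = 1))
  expect_error(chi2_two_proportions(5, 0, 1, 2), "positive")
  expect_error(chi2_two_proportions(5, 4, 1, 2), "successes")
})

test_that("a gold-label predictor scores perfectly in evaluate_groups", {
  lex <- swedish_lexicon("refined")
  corp <- generate_fixture_corpus(fixture_config(n_sentences = 150,
                                                 seed = 3), lex)
  groups <- split_by_trigger_presence(corp$pairs, lex)
  res <- evaluate_groups(groups$with_trigger, groups$without_trigger,
                         corp$gold[, c("id", "label")], lex)
  # the engine IS the gold constructor for non-ambiguous records, so
  # recall must be perfect; precision suffers only from hedged ambiguity
  m <- res$with_trigger
  expect_equal(m$estimate[m$metric == "recall"], 1.0)
  expect_true(m$estimate[m$metric == "precision"] <= 1.0)
  expect_identical(res$without_trigger$metric, "npv")
  expect_true(all(res$trigger_stats$correct <= res$trigger_stats$occurrences))
})
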