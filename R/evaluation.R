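# Evaluation harness: gold-label collapsing, confusion counts, metrics with
# Wald confidence intervals, per-trigger statistics, inter-rater agreement
# and the chi-squared comparison of two proportions.

GOLD_LABELS <- c("affirmed", "negated", "ambiguous")

#' Collapse three-class gold labels to two classes
#'
#' Scoring is binary: `negated` stays `negated`; `affirmed` and `ambiguous`
#' collapse to `not_negated`.
#'
#' @param label character vector of gold labels.
#' @return a character vector over `negated`/`not_negated`.
#' @export
collapse_gold <- function(label) {
  label <- as.character(label)
  bad <- setdiff(unique(label), GOLD_LABELS)
  if (length(bad) > 0L) {
    stop("unknown gold label: ", paste(bad, collapse = ", "))
  }
  ifelse(label == "negated", "negated", "not_negated")
}

#' Confusion counts for binary negation decisions
#'
#' The positive class is `negated`.  When `ids` and `gold_ids` are given,
#' predictions are aligned to the gold standard by pair id and any
#' mismatch is an error listing the unmatched ids.
#'
#' @param predicted character vector over `negated`/`not_negated`.
#' @param gold character vector over `negated`/`not_negated`.
#' @param ids,gold_ids optional pair identifiers for alignment.
#' @return a list of class `confusion_counts` with fields `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion_counts <- function(predicted, gold, ids = NULL, gold_ids = NULL) {
  if (!is.null(ids) || !is.null(gold_ids)) {
    if (is.null(ids) || is.null(gold_ids)) {
      stop("supply both ids and gold_ids, or neither")
    }
    unmatched <- c(setdiff(ids, gold_ids), setdiff(gold_ids, ids))
    if (length(unmatched) > 0L || anyDuplicated(ids) ||
        anyDuplicated(gold_ids)) {
      stop("prediction/gold id mismatch: ",
           paste(unique(unmatched), collapse = ", "))
    }
    gold <- gold[match(ids, gold_ids)]
  }
  if (length(predicted) != length(gold)) {
    stop("predicted and gold must have equal length")
  }
  ok <- c("negated", "not_negated")
  if (!all(predicted %in% ok) || !all(gold %in% ok)) {
    stop("labels must be 'negated' or 'not_negated'")
  }
  structure(list(tp = sum(predicted == "negated" & gold == "negated"),
                 fp = sum(predicted == "negated" & gold == "not_negated"),
                 fn = sum(predicted == "not_negated" & gold == "negated"),
                 tn = sum(predicted == "not_negated" & gold == "not_negated")),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%d fp=%d fn=%d tn=%d (n=%d)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

wald_ci <- function(p, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  c(max(0, p - half), min(1, p + half))
}

#' Detection metrics with confidence intervals
#'
#' Precision (positive predictive value), recall (sensitivity),
#' specificity and negative predictive value, each with a 95% Wald
#' interval `p +/- z * sqrt(p(1-p)/n)` on its own denominator, clipped to
#' `[0, 1]`.  A metric with an empty denominator is reported as `NA` and
#' flagged in the `defined` column.
#'
#' @param counts a [confusion_counts()] object (negative counts are an
#'   error).
#' @param ci_method interval method; only `"wald"` is built in.
#' @param conf_level confidence level.
#' @return a data frame of class `metric_report` with columns `metric`,
#'   `estimate`, `ci_low`, `ci_high`, `n`, `defined`.
#' @export
negation_metrics <- function(counts, ci_method = "wald",
                             conf_level = 0.95) {
  stopifnot(inherits(counts, "confusion_counts"))
  ci_method <- match.arg(ci_method, "wald")
  with(counts, {
    if (any(c(tp, fp, fn, tn) < 0)) {
      stop("confusion counts must be non-negative")
    }
    spec <- list(precision = c(tp, tp + fp),
                 recall = c(tp, tp + fn),
                 specificity = c(tn, tn + fp),
                 npv = c(tn, tn + fn))
    rows <- lapply(names(spec), function(mname) {
      num <- spec[[mname]][1]
      den <- spec[[mname]][2]
      if (den == 0) {
        data.frame(metric = mname, estimate = NA_real_, ci_low = NA_real_,
                   ci_high = NA_real_, n = 0L, defined = FALSE,
                   stringsAsFactors = FALSE)
      } else {
        p <- num / den
        ci <- wald_ci(p, den, conf_level)
        data.frame(metric = mname, estimate = p, ci_low = ci[1],
                   ci_high = ci[2], n = as.integer(den), defined = TRUE,
                   stringsAsFactors = FALSE)
      }
    })
    structure(do.call(rbind, rows),
              class = c("metric_report", "data.frame"))
  })
}

#' @export
print.metric_report <- function(x, digits = 1, ...) {
  pretty <- c(precision = "Precision (positive predictive value)",
              recall = "Recall (sensitivity)",
              specificity = "Specificity",
              npv = "Negative predictive value")
  for (i in seq_len(nrow(x))) {
    if (!x$defined[i]) {
      cat(sprintf("%-40s undefined (empty denominator)\n",
                  pretty[x$metric[i]]))
    } else {
      cat(sprintf("%-40s %5.*f (%.*f - %.*f)  [n=%d]\n",
                  pretty[x$metric[i]],
                  digits, 100 * x$estimate[i],
                  digits, 100 * x$ci_low[i],
                  digits, 100 * x$ci_high[i], x$n[i]))
    }
  }
  invisible(x)
}

#' Per-trigger frequency and precision
#'
#' Groups negated decisions by their deciding trigger phrase (each decision
#' is attributed to exactly one trigger, the engine's nearest winner).
#' `occurrences` counts decisions the phrase decided, `correct` those whose
#' collapsed gold label is `negated`.  Sorted by precision, then
#' occurrences, descending.  Pairs predicted `not_negated` contribute to no
#' phrase.
#'
#' @param decisions a data frame with columns `label` and `trigger` (the
#'   deciding phrase, `NA` when not negated).
#' @param gold character vector of collapsed gold labels aligned with
#'   `decisions`.
#' @return a data frame with columns `trigger`, `occurrences`, `correct`,
#'   `precision`.
#' @export
trigger_stats <- function(decisions, gold) {
  if (nrow(decisions) != length(gold)) {
    stop("decisions and gold must have equal length")
  }
  sel <- decisions$label == "negated" & !is.na(decisions$trigger)
  if (!any(sel)) {
    return(data.frame(trigger = character(0), occurrences = integer(0),
                      correct = integer(0), precision = numeric(0),
                      stringsAsFactors = FALSE))
  }
  trig <- decisions$trigger[sel]
  hit <- gold[sel] == "negated"
  occ <- tapply(hit, trig, length)
  cor <- tapply(hit, trig, sum)
  out <- data.frame(trigger = names(occ),
                    occurrences = as.integer(occ),
                    correct = as.integer(cor),
                    precision = as.numeric(cor / occ),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$precision, -out$occurrences, out$trigger), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percent agreement between two raters
#'
#' @param a,b equal-length label vectors.
#' @return the fraction of positions with equal labels.
#' @export
percent_agreement <- function(a, b) {
  if (length(a) != length(b) || length(a) == 0L) {
    stop("a and b must be non-empty and of equal length")
  }
  mean(a == b)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with the
#' expected agreement `p_e` from the product of marginal label proportions.
#' When both raters use one identical constant label, kappa is undefined
#' and `NA` is returned with a warning.
#'
#' @param a,b equal-length label vectors.
#' @return kappa in `[-1, 1]`, or `NA` when undefined.
#' @export
cohens_kappa <- function(a, b) {
  if (length(a) != length(b) || length(a) == 0L) {
    stop("a and b must be non-empty and of equal length")
  }
  labels <- sort(unique(c(a, b)))
  n <- length(a)
  po <- mean(a == b)
  pa <- table(factor(a, levels = labels)) / n
  pb <- table(factor(b, levels = labels)) / n
  pe <- sum(pa * pb)
  if (length(labels) < 2L) {
    warning("kappa undefined: a single shared constant label")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Chi-squared test for two proportions
#'
#' Pearson chi-squared on the 2x2 table, one degree of freedom, no
#' continuity correction.  A pooled proportion of exactly 0 or 1 yields the
#' degenerate statistic 0 with p-value 1.
#'
#' @param x1,n1 successes and trials in the first group.
#' @param x2,n2 successes and trials in the second group.
#' @return a list with `statistic`, `p_value` and `df`.
#' @export
chi2_two_proportions <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) {
    stop("trial counts must be positive")
  }
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) {
    stop("successes must lie in [0, trials]")
  }
  x1 <- as.numeric(x1); n1 <- as.numeric(n1)
  x2 <- as.numeric(x2); n2 <- as.numeric(n2)
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled == 0 || pooled == 1) {
    return(list(statistic = 0, p_value = 1, df = 1L))
  }
  stat <- (n1 + n2) * (x1 * (n2 - x2) - x2 * (n1 - x1))^2 /
    ((x1 + x2) * (n1 + n2 - x1 - x2) * n1 * n2)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L)
}

run_engine_on_pairs <- function(pairs, lexicon, options,
                                min_compound_len = 5L) {
  n <- nrow(pairs)
  label <- character(n)
  trigger <- rep(NA_character_, n)
  distance <- rep(NA_integer_, n)
  rationale <- character(n)
  for (i in seq_len(n)) {
    d <- classify_negation(pairs$sentence[i], pairs$proposition[i],
                           lexicon, options,
                           min_compound_len = min_compound_len)
    label[i] <- d$label
    rationale[i] <- d$rationale
    if (!is.null(d$trigger)) {
      trigger[i] <- d$trigger$text
      distance[i] <- d$distance
    }
  }
  data.frame(id = pairs$id, label = label, trigger = trigger,
             distance = distance, rationale = rationale,
             stringsAsFactors = FALSE)
}

#' Two-group evaluation of the detection engine
#'
#' Runs the engine on both pair groups and scores against the collapsed
#' gold standard.  The trigger-bearing group is scored on all four metrics;
#' the trigger-free group -- where, by construction, essentially every
#' prediction is `not_negated` -- is scored on negative predictive value
#' only.  Per-trigger frequency and precision are tallied across both
#' groups.
#'
#' @param with_trigger,without_trigger pair data frames (columns `id`,
#'   `sentence`, `proposition`) from [split_by_trigger_presence()].
#' @param gold a data frame with columns `id` and `label` over
#'   `affirmed`/`negated`/`ambiguous`, covering every pair id.
#' @param lexicon a [trigger_lexicon()].
#' @param options an [engine_options()] list, or `NULL` for defaults with
#'   the lexicon's profile.
#' @param min_compound_len passed to [classify_negation()].
#' @return a list with `with_trigger` (full [negation_metrics()] report),
#'   `without_trigger` (NPV-only report), `trigger_stats`, the per-group
#'   `decisions`, and the per-group `confusion` counts.
#' @export
evaluate_groups <- function(with_trigger, without_trigger, gold, lexicon,
                            options = NULL, min_compound_len = 5L) {
  if (is.null(options)) {
    options <- engine_options(profile = lexicon_profile(lexicon))
  }
  score_group <- function(pairs) {
    if (nrow(pairs) == 0L) {
      return(NULL)
    }
    dec <- run_engine_on_pairs(pairs, lexicon, options, min_compound_len)
    g <- gold$label[match(pairs$id, gold$id)]
    if (anyNA(g)) {
      stop("gold labels missing for ids: ",
           paste(pairs$id[is.na(g)], collapse = ", "))
    }
    list(decisions = dec, gold = collapse_gold(g))
  }
  g1 <- score_group(with_trigger)
  g2 <- score_group(without_trigger)
  report1 <- conf1 <- NULL
  if (!is.null(g1)) {
    conf1 <- confusion_counts(g1$decisions$label, g1$gold)
    report1 <- negation_metrics(conf1)
  } else {
    warning("empty with-trigger group; metrics undefined")
  }
  report2 <- conf2 <- NULL
  if (!is.null(g2)) {
    conf2 <- confusion_counts(g2$decisions$label, g2$gold)
    report2 <- negation_metrics(conf2)
    report2 <- report2[report2$metric == "npv", , drop = FALSE]
    class(report2) <- c("metric_report", "data.frame")
  } else {
    warning("empty without-trigger group; NPV undefined")
  }
  all_dec <- rbind(if (!is.null(g1)) g1$decisions,
                   if (!is.null(g2)) g2$decisions)
  all_gold <- c(if (!is.null(g1)) g1$gold, if (!is.null(g2)) g2$gold)
  stats_tbl <- if (is.null(all_dec)) {
    trigger_stats(data.frame(label = character(0),
                             trigger = character(0)), character(0))
  } else {
    trigger_stats(all_dec, all_gold)
  }
  list(with_trigger = report1,
       without_trigger = report2,
       trigger_stats = stats_tbl,
       decisions = list(with_trigger = if (!is.null(g1)) g1$decisions,
                        without_trigger = if (!is.null(g2)) g2$decisions),
       confusion = list(with_trigger = conf1, without_trigger = conf2))
}
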