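# Shared test helpers: quick lexicon construction and independent
# hand-coded reference computations.

lex_of <- function(...) {
  # lex_of("inga tecken" = "PREN", men = "CONJ")
  entries <- c(...)
  trigger_lexicon(names(entries), unname(entries))
}

# Reference metric computation by explicit counting, independent of
# confusion_counts()/negation_metrics().
hand_metrics <- function(predicted, gold) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(predicted)) {
    if (predicted[i] == "negated" && gold[i] == "negated") tp <- tp + 1
    if (predicted[i] == "negated" && gold[i] == "not_negated") fp <- fp + 1
    if (predicted[i] == "not_negated" && gold[i] == "negated") fn <- fn + 1
    if (predicted[i] == "not_negated" && gold[i] == "not_negated") tn <- tn + 1
  }
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

# Brute-force enumeration of single adjacent (verb, adverb) swaps.
hand_swaps <- function(phrase, adverbs = c("inte", "ej", "icke", "aldrig")) {
  toks <- strsplit(phrase, " ", fixed = TRUE)[[1]]
  out <- phrase
  if (length(toks) >= 2) {
    for (i in 1:(length(toks) - 1)) {
      if (toks[i + 1] %in% adverbs && !(toks[i] %in% adverbs)) {
        v <- toks
        v[i] <- toks[i + 1]
        v[i + 1] <- toks[i]
        out <- c(out, paste(v, collapse = " "))
      }
    }
  }
  unique(out)
}

# A sentence with a PREN trigger at an exact word distance from the term.
sentence_at_distance <- function(trigger, distance, term,
                                 filler = "status") {
  paste(c(trigger, rep(filler, distance - 1), term), collapse = " ")
}
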