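# Core negation detection: tokenisation, trigger occurrence matching with
# pseudo-negation masking, the "utan" disambiguation rule, and the bounded
# scope-window decision.

#' Engine options
#'
#' @param scope_limit maximum word distance (in non-punctuation tokens,
#'   adjacency = 1) at which a trigger still negates a proposition; the
#'   classic window is one to six words.
#' @param use_conjunction_cut terminate a trigger's scope at a
#'   scope-limiting conjunction occurring strictly between trigger and
#'   proposition.
#' @param profile `"refined"` activates the Swedish disambiguation rule for
#'   `utan` (see [apply_utan_rule()]); `"baseline"` leaves every trigger
#'   occurrence active.
#' @param count_punctuation if `TRUE`, punctuation tokens count toward the
#'   word window; by default they do not.
#' @return a list of class `engine_options`.
#' @export
engine_options <- function(scope_limit = 6L,
                           use_conjunction_cut = TRUE,
                           profile = c("refined", "baseline"),
                           count_punctuation = FALSE) {
  profile <- match.arg(profile)
  scope_limit <- as.integer(scope_limit)
  if (is.na(scope_limit) || scope_limit < 1L) {
    stop("scope_limit must be a positive integer")
  }
  structure(list(scope_limit = scope_limit,
                 use_conjunction_cut = isTRUE(use_conjunction_cut),
                 profile = profile,
                 count_punctuation = isTRUE(count_punctuation)),
            class = "engine_options")
}

is_punct_char <- function(ch) {
  grepl("^[[:punct:]]$", ch)
}

#' Tokenize a sentence
#'
#' Splits on whitespace; leading and trailing punctuation characters of each
#' chunk become separate one-character punctuation tokens, while internal
#' hyphens stay inside their token.  Character offsets are 0-based and
#' half-open, and the tokens plus skipped whitespace reconstruct the text.
#' Downstream matching is case-insensitive; surfaces are preserved.
#'
#' @param text a non-empty string.
#' @param id optional sentence identifier carried through the pipeline.
#' @return an object of class `sentence_record`: a list with `id`, `text`
#'   and a `tokens` data frame (`surface`, `start`, `end`, `lower`,
#'   `punct`).
#' @export
tokenize_sentence <- function(text, id = NA_character_) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    stop("cannot tokenize empty or whitespace-only text")
  }
  chunk_pos <- gregexpr("\\S+", text)[[1]]
  chunks <- regmatches(text, gregexpr("\\S+", text))[[1]]
  surface <- character(0)
  start <- integer(0)
  for (ci in seq_along(chunks)) {
    chunk <- chunks[ci]
    s <- chunk_pos[ci]  # 1-based character position
    chars <- strsplit(chunk, "", fixed = TRUE)[[1]]
    lo <- 1L
    hi <- length(chars)
    lead <- character(0)
    while (lo < hi && is_punct_char(chars[lo])) {
      lead <- c(lead, chars[lo])
      lo <- lo + 1L
    }
    trail <- character(0)
    while (hi > lo && is_punct_char(chars[hi])) {
      trail <- c(chars[hi], trail)
      hi <- hi - 1L
    }
    pieces <- c(lead, paste(chars[lo:hi], collapse = ""), trail)
    offs <- s + c(seq_along(lead) - 1L, lo - 1L,
                  hi - 1L + seq_along(trail))
    surface <- c(surface, pieces)
    start <- c(start, offs)
  }
  tokens <- data.frame(surface = surface,
                       start = start - 1L,
                       end = start - 1L + nchar(surface),
                       lower = tolower(surface),
                       punct = vapply(surface, function(tk) {
                         grepl("^[[:punct:]]+$", tk)
                       }, logical(1), USE.NAMES = FALSE),
                       stringsAsFactors = FALSE)
  structure(list(id = id, text = text, tokens = tokens),
            class = "sentence_record")
}

#' @export
print.sentence_record <- function(x, ...) {
  cat(sprintf("<sentence_record%s> %s\n",
              if (is.na(x$id)) "" else paste0(" ", x$id), x$text))
  cat("tokens:", paste(x$tokens$surface, collapse = " | "), "\n")
  invisible(x)
}

empty_occurrences <- function() {
  data.frame(text = character(0), category = character(0),
             start = integer(0), end = integer(0),
             masked = logical(0), mask_rationale = character(0),
             stringsAsFactors = FALSE)
}

# Greedy left-to-right longest-match scan of one category group.
# Token spans are 1-based half-open [start, end).
scan_phrases <- function(lower_tokens, phrases, categories) {
  if (length(phrases) == 0L) {
    return(empty_occurrences())
  }
  phrase_tokens <- strsplit(phrases, " ", fixed = TRUE)
  lens <- lengths(phrase_tokens)
  by_len <- split(seq_along(phrases), lens)
  lookup <- lapply(by_len, function(idx) {
    stats::setNames(categories[idx], phrases[idx])
  })
  lengths_desc <- sort(unique(lens), decreasing = TRUE)
  n <- length(lower_tokens)
  out_text <- character(0)
  out_cat <- character(0)
  out_start <- integer(0)
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (L in lengths_desc) {
      if (i + L - 1L > n) next
      key <- paste(lower_tokens[i:(i + L - 1L)], collapse = " ")
      tab <- lookup[[as.character(L)]]
      hit <- which(names(tab) == key)
      if (length(hit) > 0L) {
        # Same text under both PREN and POST is resolved in favour of PREN.
        cat_hit <- if (length(hit) > 1L && "PREN" %in% tab[hit]) {
          "PREN"
        } else {
          tab[[hit[1]]]
        }
        out_text <- c(out_text, key)
        out_cat <- c(out_cat, cat_hit)
        out_start <- c(out_start, i)
        i <- i + L
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  if (length(out_text) == 0L) {
    return(empty_occurrences())
  }
  data.frame(text = out_text, category = out_cat, start = out_start,
             end = out_start + lengths(strsplit(out_text, " ", fixed = TRUE)),
             masked = FALSE, mask_rationale = NA_character_,
             stringsAsFactors = FALSE)
}

spans_overlap <- function(s1, e1, s2, e2) {
  pmax(s1, s2) < pmin(e1, e2)
}

#' Find trigger occurrences in a sentence
#'
#' Case-insensitive, token-boundary, longest-match-first, left-to-right,
#' non-overlapping matching of the lexicon's phrases.  Negation triggers
#' (`PREN`/`POST`) and pseudo-negations (`PSEU`) are matched in separate
#' passes, so a negation trigger contained in a pseudo phrase is still
#' reported -- with `masked = TRUE` and rationale `pseudo_masked`.
#' Pseudo-negation and conjunction occurrences are returned for provenance;
#' they never negate.
#'
#' @param sentence a [tokenize_sentence()] record.
#' @param lexicon a non-empty [trigger_lexicon()].
#' @return a data frame of occurrences with columns `text`, `category`,
#'   `start`, `end` (1-based half-open token spans), `masked`,
#'   `mask_rationale`, sorted by span.
#' @export
find_triggers <- function(sentence, lexicon) {
  stopifnot(inherits(sentence, "sentence_record"),
            inherits(lexicon, "trigger_lexicon"))
  if (nrow(lexicon) == 0L) {
    stop("empty trigger lexicon")
  }
  lower <- sentence$tokens$lower
  neg <- lexicon$category %in% c("PREN", "POST")
  pseu <- lexicon$category == "PSEU"
  conj <- lexicon$category == "CONJ"
  occ_neg <- scan_phrases(lower, lexicon$text[neg], lexicon$category[neg])
  occ_pseu <- scan_phrases(lower, lexicon$text[pseu], lexicon$category[pseu])
  occ_conj <- scan_phrases(lower, lexicon$text[conj], lexicon$category[conj])
  if (nrow(occ_neg) > 0L && nrow(occ_pseu) > 0L) {
    for (i in seq_len(nrow(occ_neg))) {
      if (any(spans_overlap(occ_neg$start[i], occ_neg$end[i],
                            occ_pseu$start, occ_pseu$end))) {
        occ_neg$masked[i] <- TRUE
        occ_neg$mask_rationale[i] <- "pseudo_masked"
      }
    }
  }
  occ <- rbind(occ_neg, occ_pseu, occ_conj)
  occ <- occ[order(occ$start, occ$end), , drop = FALSE]
  rownames(occ) <- NULL
  occ
}

#' Disambiguate "utan" as conjunction versus negation
#'
#' The Swedish preposition *utan* ("without") negates, but *utan* is also a
#' conjunction ("but") -- and in that use it is very often preceded by
#' *inte* earlier in the sentence ("han är inte pigg utan trött").  Under
#' the refined profile, any occurrence of the bare trigger `utan` with an
#' `inte` token at an earlier position is masked with rationale
#' `rule_masked`.  Under the baseline profile the occurrences are returned
#' unchanged.
#'
#' @param sentence a [tokenize_sentence()] record.
#' @param occurrences occurrence data frame from [find_triggers()].
#' @param profile `"refined"` or `"baseline"`.
#' @return the occurrence data frame, possibly with added masks.
#' @export
apply_utan_rule <- function(sentence, occurrences, profile = "refined") {
  if (!identical(profile, "refined") || nrow(occurrences) == 0L) {
    return(occurrences)
  }
  inte_pos <- which(sentence$tokens$lower == "inte")
  if (length(inte_pos) == 0L) {
    return(occurrences)
  }
  target <- which(occurrences$text == "utan" &
                    occurrences$category %in% c("PREN", "POST") &
                    !occurrences$masked)
  for (i in target) {
    if (any(inte_pos < occurrences$start[i])) {
      occurrences$masked[i] <- TRUE
      occurrences$mask_rationale[i] <- "rule_masked"
    }
  }
  occurrences
}

word_distance <- function(tokens, from, to, count_punctuation) {
  # Count of tokens in the half-open index range [from, to), punctuation
  # excluded unless requested, plus one (adjacent = distance 1).
  if (to <= from) {
    return(1L)
  }
  idx <- from:(to - 1L)
  n_between <- if (count_punctuation) {
    length(idx)
  } else {
    sum(!tokens$punct[idx])
  }
  n_between + 1L
}

new_decision <- function(label, rationale, prop_span, trigger = NULL,
                         distance = NA_integer_) {
  structure(list(label = label,
                 trigger = trigger,
                 proposition_span = as.integer(prop_span),
                 distance = if (is.na(distance)) NULL else as.integer(distance),
                 rationale = rationale),
            class = "negation_decision")
}

#' @export
print.negation_decision <- function(x, ...) {
  cat(sprintf("<negation_decision> %s (%s)%s\n", x$label, x$rationale,
              if (is.null(x$trigger)) "" else {
                sprintf(" via '%s' [%s] at distance %d",
                        x$trigger$text, x$trigger$category, x$distance)
              }))
  invisible(x)
}

#' Decide the negation status of one proposition
#'
#' A proposition is negated when it lies within the scope window (one to
#' `scope_limit` words, counting non-punctuation tokens and with adjacency
#' as distance 1) after an unmasked pre-negation trigger or before an
#' unmasked post-negation trigger, with no scope-terminating conjunction
#' strictly between trigger and proposition (when the conjunction cut is
#' active).  The nearest qualifying trigger wins; a pre-negation beats a
#' post-negation at equal distance.  Non-negated decisions carry the most
#' informative rationale: `out_of_scope` over `conjunction_cut` over
#' `pseudo_masked`/`rule_masked` over `no_trigger`.
#'
#' @param sentence a [tokenize_sentence()] record.
#' @param proposition_span 1-based half-open token span `c(start, end)` of
#'   the proposition within the sentence.
#' @param occurrences occurrence data frame from [find_triggers()] (after
#'   [apply_utan_rule()] for the refined profile).
#' @param options an [engine_options()] list.
#' @return a `negation_decision`: a list with `label` (`"negated"` or
#'   `"not_negated"`), `trigger` (deciding occurrence or `NULL`),
#'   `proposition_span`, `distance` (present when negated) and `rationale`.
#' @export
decide_negation <- function(sentence, proposition_span, occurrences,
                            options = engine_options()) {
  stopifnot(inherits(sentence, "sentence_record"))
  n <- nrow(sentence$tokens)
  ps <- as.integer(proposition_span[1])
  pe <- as.integer(proposition_span[2])
  if (is.na(ps) || is.na(pe) || ps < 1L || pe > n + 1L || pe <= ps) {
    stop(sprintf("proposition span [%s, %s) out of bounds for %d tokens",
                 proposition_span[1], proposition_span[2], n))
  }
  occ <- occurrences[occurrences$category %in% c("PREN", "POST"), ,
                     drop = FALSE]
  conj <- occurrences[occurrences$category == "CONJ", , drop = FALSE]

  best <- NULL            # deciding trigger row index
  best_dist <- NA_integer_
  saw_out_of_scope <- FALSE
  saw_cut <- FALSE
  mask_reason <- NULL

  if (nrow(occ) > 0L) {
    for (i in seq_len(nrow(occ))) {
      pre <- occ$category[i] == "PREN"
      if (pre && occ$end[i] > ps) next       # must end at/before proposition
      if (!pre && occ$start[i] < pe) next    # must start at/after proposition
      gap <- if (pre) c(occ$end[i], ps) else c(pe, occ$start[i])
      d <- word_distance(sentence$tokens, gap[1], gap[2],
                         options$count_punctuation)
      in_window <- d >= 1L && d <= options$scope_limit
      cut <- options$use_conjunction_cut && nrow(conj) > 0L &&
        any(conj$start >= gap[1] & conj$end <= gap[2])
      if (occ$masked[i]) {
        if (in_window && is.null(mask_reason)) {
          mask_reason <- occ$mask_rationale[i]
        }
        next
      }
      if (!in_window) {
        saw_out_of_scope <- TRUE
        next
      }
      if (cut) {
        saw_cut <- TRUE
        next
      }
      better <- is.null(best) || d < best_dist ||
        (d == best_dist && pre && occ$category[best] == "POST")
      if (better) {
        best <- i
        best_dist <- d
      }
    }
  }

  if (!is.null(best)) {
    trig <- as.list(occ[best, c("text", "category", "start", "end",
                                "masked")])
    return(new_decision("negated",
                        if (occ$category[best] == "PREN") {
                          "pre_trigger_in_scope"
                        } else {
                          "post_trigger_in_scope"
                        },
                        c(ps, pe), trigger = trig, distance = best_dist))
  }
  rationale <- if (saw_out_of_scope) {
    "out_of_scope"
  } else if (saw_cut) {
    "conjunction_cut"
  } else if (!is.null(mask_reason)) {
    mask_reason
  } else {
    "no_trigger"
  }
  new_decision("not_negated", rationale, c(ps, pe))
}

#' Classify a (sentence, proposition) pair end to end
#'
#' Tokenises the sentence, locates the first occurrence of the proposition
#' (exact token sequence or, for single-token terms, containment in a
#' compound token), finds trigger occurrences, applies the `utan`
#' disambiguation under the refined profile, and decides.
#'
#' @param sentence_text the sentence as a string.
#' @param proposition_text the proposition; must occur in the sentence.
#' @param lexicon a [trigger_lexicon()]; its profile is used when `options`
#'   is `NULL`.
#' @param options an [engine_options()] list, or `NULL` to use defaults
#'   with the lexicon's profile.
#' @param min_compound_len minimum character length for a single-token term
#'   to match inside a longer compound token.
#' @return a `negation_decision`; see [decide_negation()].
#' @export
#' @examples
#' lex <- swedish_lexicon("refined")
#' classify_negation("Pat har inga tecken på pneumoni", "pneumoni", lex)
classify_negation <- function(sentence_text, proposition_text, lexicon,
                              options = NULL, min_compound_len = 5L) {
  if (is.null(options)) {
    options <- engine_options(profile = lexicon_profile(lexicon))
  }
  sentence <- tokenize_sentence(sentence_text)
  matches <- match_terms(sentence, tolower(squish(proposition_text)),
                         min_compound_len = min_compound_len)
  if (nrow(matches) == 0L) {
    stop(sprintf("proposition '%s' not found in sentence '%s'",
                 proposition_text, sentence_text))
  }
  occ <- find_triggers(sentence, lexicon)
  occ <- apply_utan_rule(sentence, occ, profile = options$profile)
  decide_negation(sentence, c(matches$start[1], matches$end[1]), occ,
                  options)
}
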