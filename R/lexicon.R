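# Trigger lexicon: data model and triggers-file I/O.

TRIGGER_CATEGORIES <- c("PREN", "POST", "PSEU", "CONJ")
TRIGGER_ORIGINS <- c("base", "quantifier_form", "adjective_inflection",
                     "verb_inflection", "word_order_variant", "manual")

squish <- function(x) {
  gsub("\\s+", " ", trimws(x))
}

n_tokens <- function(text) {
  lengths(strsplit(text, " ", fixed = TRUE))
}

#' Construct a trigger lexicon
#'
#' A trigger lexicon is the set of categorised cue phrases the detection
#' engine scans for: pre-negations (`PREN`) negate a proposition that follows
#' them, post-negations (`POST`) one that precedes them, pseudo-negations
#' (`PSEU`) look like negations but must not negate, and conjunctions
#' (`CONJ`) terminate a trigger's scope.  Entries are stored in
#' non-increasing token-length order so that matching is longest-match-first.
#'
#' @param text character vector of cue phrases; lowercased and
#'   whitespace-normalised on construction.
#' @param category character vector (recycled) of category tags, each one of
#'   `"PREN"`, `"POST"`, `"PSEU"`, `"CONJ"`.
#' @param origin how each entry came to be (`"base"` for hand-listed entries,
#'   otherwise the morphological expansion that generated it).
#' @param lemma for generated entries, the phrase they were generated from;
#'   must be `NA` exactly when `origin == "base"`.
#' @param profile lexicon profile: `"baseline"` keeps every cue as-is;
#'   `"refined"` marks the lexicon as subject to the "utan" disambiguation
#'   rule (and is the profile of the packaged set without "icke").
#' @return an object of class `trigger_lexicon`, a data frame with columns
#'   `text`, `category`, `origin`, `lemma`, ordered longest-phrase-first.
#' @seealso [read_trigger_file()], [swedish_lexicon()], [expand_lexicon()]
#' @export
#' @examples
#' trigger_lexicon(c("inga tecken", "inga", "men"), c("PREN", "PREN", "CONJ"))
trigger_lexicon <- function(text, category, origin = "base",
                            lemma = NA_character_,
                            profile = c("baseline", "refined")) {
  profile <- match.arg(profile)
  text <- tolower(squish(as.character(text)))
  if (length(text) == 0L) {
    stop("a trigger lexicon needs at least one entry")
  }
  if (any(!nzchar(text))) {
    stop("trigger phrases must be non-empty")
  }
  category <- rep_len(as.character(category), length(text))
  bad <- setdiff(unique(category), TRIGGER_CATEGORIES)
  if (length(bad) > 0L) {
    stop("unknown trigger category: ", paste(bad, collapse = ", "))
  }
  origin <- rep_len(as.character(origin), length(text))
  bad <- setdiff(unique(origin), TRIGGER_ORIGINS)
  if (length(bad) > 0L) {
    stop("unknown trigger origin: ", paste(bad, collapse = ", "))
  }
  lemma <- rep_len(as.character(lemma), length(text))
  if (any(origin == "base" & !is.na(lemma))) {
    stop("base entries must not carry a lemma")
  }
  if (any(origin != "base" & is.na(lemma))) {
    stop("generated entries must carry the lemma they came from")
  }
  key <- paste(text, category)
  if (anyDuplicated(key)) {
    stop("duplicate (text, category) entries: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  lex <- data.frame(text = text, category = category, origin = origin,
                    lemma = lemma, stringsAsFactors = FALSE)
  lex <- lex[order(-n_tokens(lex$text), lex$text, lex$category), , drop = FALSE]
  rownames(lex) <- NULL
  structure(lex, class = c("trigger_lexicon", "data.frame"), profile = profile)
}

#' @export
print.trigger_lexicon <- function(x, ...) {
  cat(sprintf("<trigger_lexicon> %d entries (%s profile): %s\n",
              nrow(x), attr(x, "profile"),
              paste(sprintf("%s %d", names(tab <- table(x$category)), tab),
                    collapse = ", ")))
  print(as.data.frame(x), ...)
  invisible(x)
}

lexicon_profile <- function(lexicon) {
  p <- attr(lexicon, "profile")
  if (is.null(p)) "baseline" else p
}

#' Read a triggers file
#'
#' Parses the tab-separated triggers-file dialect: one `phrase<TAB>[TAG]`
#' entry per line with `TAG` one of `PREN`, `POST`, `PSEU`, `CONJ`; blank
#' lines and lines starting with `#` are ignored; phrases are lowercased and
#' whitespace-normalised.  Duplicate `(phrase, tag)` lines are collapsed to a
#' single entry with a warning.
#'
#' @param path path to a UTF-8 triggers file.
#' @inheritParams trigger_lexicon
#' @return a [trigger_lexicon()].
#' @export
read_trigger_file <- function(path, profile = c("baseline", "refined")) {
  profile <- match.arg(profile)
  if (!file.exists(path)) {
    stop("triggers file not found: ", path)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    stop("no trigger entries in file: ", path)
  }
  m <- regmatches(lines[idx],
                  regexec("^([^\t]+)\t+\\[([A-Za-z]+)\\]\\s*$", lines[idx]))
  texts <- character(length(idx))
  tags <- character(length(idx))
  for (i in seq_along(idx)) {
    parts <- m[[i]]
    if (length(parts) != 3L) {
      stop(sprintf("malformed trigger line %d in %s: %s",
                   idx[i], path, lines[idx[i]]))
    }
    phrase <- tolower(squish(parts[2]))
    tag <- toupper(parts[3])
    if (!nzchar(phrase)) {
      stop(sprintf("empty trigger phrase at line %d in %s", idx[i], path))
    }
    if (!tag %in% TRIGGER_CATEGORIES) {
      stop(sprintf("unknown trigger tag [%s] at line %d in %s",
                   tag, idx[i], path))
    }
    texts[i] <- phrase
    tags[i] <- tag
  }
  key <- paste(texts, tags)
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    warning("collapsing duplicate trigger entries: ",
            paste(dups, collapse = "; "))
    first <- !duplicated(key)
    texts <- texts[first]
    tags <- tags[first]
  }
  trigger_lexicon(texts, tags, profile = profile)
}

#' Write a triggers file
#'
#' Emits one `phrase<TAB>[TAG]` line per entry, sorted by category then
#' phrase.  Reading the file back reproduces the lexicon's
#' `(text, category)` set exactly.
#'
#' @param lexicon a non-empty [trigger_lexicon()].
#' @param path output path (UTF-8).
#' @return `path`, invisibly.
#' @export
write_trigger_file <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "trigger_lexicon"))
  if (nrow(lexicon) == 0L) {
    stop("refusing to write an empty trigger lexicon")
  }
  ord <- order(lexicon$category, lexicon$text)
  lines <- sprintf("%s\t[%s]", lexicon$text[ord], lexicon$category[ord])
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Load a packaged Swedish trigger lexicon
#'
#' The packaged sets are reconstructed from the published per-trigger tables
#' of the Swedish adaptation study, plus pseudo-negation and conjunction
#' entries of the kinds the algorithm family uses.  The `refined` profile
#' drops the trigger `icke` (in clinical Swedish it almost always opens a
#' disease name such as "icke allergisk astma") and activates the runtime
#' disambiguation rule for `utan`; see [apply_utan_rule()].
#'
#' @param profile `"refined"` (default) or `"baseline"`.
#' @return a [trigger_lexicon()].
#' @export
swedish_lexicon <- function(profile = c("refined", "baseline")) {
  profile <- match.arg(profile)
  path <- system.file("extdata",
                      sprintf("triggers_swedish_%s.txt", profile),
                      package = "swenegex", mustWork = TRUE)
  read_trigger_file(path, profile = profile)
}

#' Keep the most frequent negation triggers
#'
#' Counts case-insensitive token-boundary occurrences of each candidate
#' phrase in a reference corpus and keeps the `k` most frequent `PREN`/`POST`
#' entries (ties broken by longer phrase first, then lexicographically).
#' Pseudo-negations and conjunctions guard precision rather than recall and
#' are always retained regardless of rank.
#'
#' @param candidates a [trigger_lexicon()] of candidate entries.
#' @param corpus character vector of sentences (held-out text, not the
#'   evaluation set).
#' @param k number of `PREN`/`POST` entries to keep; must be positive and at
#'   most the number of such candidates.
#' @return a [trigger_lexicon()] with the selected entries.
#' @export
select_by_frequency <- function(candidates, corpus, k) {
  stopifnot(inherits(candidates, "trigger_lexicon"))
  if (!is.numeric(k) || length(k) != 1L || k <= 0L) {
    stop("k must be a positive integer")
  }
  k <- as.integer(k)
  if (length(corpus) == 0L || all(!nzchar(trimws(corpus)))) {
    stop("corpus must contain at least one non-empty sentence")
  }
  neg <- candidates$category %in% c("PREN", "POST")
  if (k > sum(neg)) {
    stop(sprintf("k = %d exceeds the %d PREN/POST candidates", k, sum(neg)))
  }
  corpus_tokens <- lapply(corpus[nzchar(trimws(corpus))], function(s) {
    tolower(tokenize_sentence(s)$tokens$surface)
  })
  counts <- vapply(candidates$text, function(phrase) {
    ptoks <- strsplit(phrase, " ", fixed = TRUE)[[1]]
    L <- length(ptoks)
    total <- 0L
    for (toks in corpus_tokens) {
      i <- 1L
      while (i + L - 1L <= length(toks)) {
        if (all(toks[i:(i + L - 1L)] == ptoks)) {
          total <- total + 1L
          i <- i + L
        } else {
          i <- i + 1L
        }
      }
    }
    total
  }, integer(1))
  idx_neg <- which(neg)
  ord <- idx_neg[order(-counts[idx_neg], -nchar(candidates$text[idx_neg]),
                       candidates$text[idx_neg])]
  keep <- sort(c(ord[seq_len(k)], which(!neg)))
  trigger_lexicon(candidates$text[keep], candidates$category[keep],
                  candidates$origin[keep], candidates$lemma[keep],
                  profile = lexicon_profile(candidates))
}
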