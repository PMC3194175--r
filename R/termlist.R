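# Proposition term lists: ICD-10 style cleaning, compound-aware matching,
# and construction of (sentence, proposition) evaluation pairs.

#' Default Swedish clarifier phrases
#'
#' Clarifier phrases of the kind classification exports append to a term
#' ("not specified", "other specified forms") that would defeat simple
#' string matching and are stripped by [clean_term()].  The set is
#' user-extensible.
#'
#' @return a character vector of clarifier phrases.
#' @export
default_clarifiers <- function() {
  c("ej specificerad", "ej specificerat", "ospecificerad", "ospecificerat",
    "andra specificerade former", "utan närmare specifikation", "uns")
}

clean_one_term <- function(raw, clarifiers) {
  s <- raw
  # Drop parenthesised spans, innermost first so nesting unwinds.
  repeat {
    s2 <- gsub("\\([^()]*\\)", " ", s)
    if (identical(s2, s)) break
    s <- s2
  }
  if (grepl("(", s, fixed = TRUE)) {
    warning("unbalanced parenthesis in term: ", raw)
    s <- sub("\\(.*$", " ", s)
  }
  s <- tolower(squish(s))
  for (cl in clarifiers) {
    escaped <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", tolower(cl))
    pat <- paste0("(,\\s*)?\\b", escaped, "\\b(\\s*,)?")
    s <- gsub(pat, " ", s, perl = TRUE)
  }
  s <- squish(gsub("^[ ,]+|[ ,]+$", "", squish(s)))
  if (!nzchar(s)) NA_character_ else s
}

#' Clean a raw term description
#'
#' Removes parenthesised material (including nested parentheses), strips
#' configured clarifier phrases together with adjacent commas, collapses
#' whitespace and lowercases.  Returns `NA` when nothing is left.  An
#' unbalanced opening parenthesis is removed to the end of the string with
#' a warning.  The operation is idempotent.
#'
#' @param raw character vector of raw descriptions.
#' @param clarifiers clarifier phrases to strip; see [default_clarifiers()].
#' @return a character vector of cleaned terms (`NA` where empty).
#' @export
#' @examples
#' clean_term("Astma (allergisk)")             # "astma"
#' clean_term("Pneumoni, ej specificerad")     # "pneumoni"
clean_term <- function(raw, clarifiers = default_clarifiers()) {
  vapply(as.character(raw), clean_one_term, character(1),
         clarifiers = clarifiers, USE.NAMES = FALSE)
}

#' Build a proposition term table
#'
#' @param surface character vector of cleaned term surfaces.
#' @param source where the terms come from (`"icd10"`, `"ksh97p"`,
#'   `"mesh"`, `"user"`).
#' @param code optional classification codes.
#' @return a data frame of class `proposition_terms` with columns
#'   `surface`, `source`, `code`, deduplicated on `surface`.
#' @export
proposition_terms <- function(surface,
                              source = c("user", "icd10", "ksh97p", "mesh"),
                              code = NA_character_) {
  source <- match.arg(source)
  surface <- tolower(squish(as.character(surface)))
  code <- rep_len(as.character(code), length(surface))
  ok <- !is.na(surface) & nzchar(surface)
  df <- data.frame(surface = surface[ok], source = source,
                   code = code[ok], stringsAsFactors = FALSE)
  df <- df[!duplicated(df$surface), , drop = FALSE]
  if (nrow(df) == 0L) {
    stop("no usable terms")
  }
  rownames(df) <- NULL
  structure(df, class = c("proposition_terms", "data.frame"))
}

#' Read and clean a term list file
#'
#' Plain UTF-8, one term per line, optionally `code<TAB>description` as in
#' classification exports; `#` starts a comment.  Each description passes
#' through [clean_term()]; terms that clean to nothing are dropped.
#'
#' @param path path to the term file.
#' @inheritParams proposition_terms
#' @param clarifiers clarifier phrases passed to [clean_term()].
#' @return a [proposition_terms()] table.
#' @export
read_term_file <- function(path, source = "user",
                           clarifiers = default_clarifiers()) {
  if (!file.exists(path)) {
    stop("term file not found: ", path)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (length(lines) == 0L) {
    stop("no terms in file: ", path)
  }
  has_code <- grepl("\t", lines, fixed = TRUE)
  code <- ifelse(has_code, sub("\t.*$", "", lines), NA_character_)
  desc <- ifelse(has_code, sub("^[^\t]*\t", "", lines), lines)
  cleaned <- clean_term(desc, clarifiers)
  keep <- !is.na(cleaned)
  proposition_terms(cleaned[keep], source = source, code = code[keep])
}

#' Locate proposition terms in a sentence
#'
#' Exact case-insensitive token-sequence matches are always reported.  In
#' addition, a single-token term of at least `min_compound_len` characters
#' matches inside a longer token (Swedish compounds: "astma" inside
#' "astmabesvär"), flagged `compound = TRUE`.  Overlapping matches of
#' different terms are all reported, sorted by span.
#'
#' @param sentence a [tokenize_sentence()] record.
#' @param terms a [proposition_terms()] table or a character vector of term
#'   surfaces.
#' @param min_compound_len minimum term length for compound matching; use
#'   `Inf` to disable compound matching altogether.
#' @return a data frame with columns `term`, `start`, `end` (1-based
#'   half-open token spans) and `compound`.
#' @export
match_terms <- function(sentence, terms, min_compound_len = 5L) {
  stopifnot(inherits(sentence, "sentence_record"))
  if (is.character(terms)) {
    terms <- proposition_terms(terms)
  }
  if (nrow(terms) == 0L) {
    stop("no terms to match")
  }
  if (!is.infinite(min_compound_len) && min_compound_len < 1L) {
    stop("min_compound_len must be at least 1")
  }
  lower <- sentence$tokens$lower
  n <- length(lower)
  out <- list()
  for (term in terms$surface) {
    ttoks <- strsplit(term, " ", fixed = TRUE)[[1]]
    L <- length(ttoks)
    if (L <= n) {
      for (i in seq_len(n - L + 1L)) {
        if (all(lower[i:(i + L - 1L)] == ttoks)) {
          out[[length(out) + 1L]] <-
            data.frame(term = term, start = i, end = i + L,
                       compound = FALSE, stringsAsFactors = FALSE)
        }
      }
    }
    if (L == 1L && !is.infinite(min_compound_len) &&
        nchar(term) >= min_compound_len) {
      hits <- which(lower != term &
                      vapply(lower, function(tk) {
                        grepl(term, tk, fixed = TRUE)
                      }, logical(1), USE.NAMES = FALSE))
      for (i in hits) {
        out[[length(out) + 1L]] <-
          data.frame(term = term, start = i, end = i + 1L,
                     compound = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(term = character(0), start = integer(0),
                      end = integer(0), compound = logical(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build (sentence, proposition) evaluation pairs
#'
#' One record per proposition match: a sentence containing several
#' propositions appears once per proposition; sentences without matches are
#' excluded.  Order is deterministic (sentence order, then span order).
#'
#' @param sentences a list of [tokenize_sentence()] records.
#' @param terms a [proposition_terms()] table or character vector.
#' @param min_compound_len passed to [match_terms()].
#' @return a data frame with columns `id`, `sentence`, `proposition`,
#'   `start`, `end`, `compound`.
#' @export
build_pairs <- function(sentences, terms, min_compound_len = 5L) {
  out <- list()
  for (sent in sentences) {
    stopifnot(inherits(sent, "sentence_record"))
    m <- match_terms(sent, terms, min_compound_len)
    if (nrow(m) == 0L) next
    out[[length(out) + 1L]] <-
      data.frame(id = sent$id, sentence = sent$text, proposition = m$term,
                 start = m$start, end = m$end, compound = m$compound,
                 stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(id = character(0), sentence = character(0),
                      proposition = character(0), start = integer(0),
                      end = integer(0), compound = logical(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Split pairs by trigger presence
#'
#' Mirrors the two-group evaluation design: a pair belongs to the
#' `with_trigger` group when its sentence contains at least one negation or
#' pseudo-negation occurrence (`PREN`/`POST`/`PSEU`, masked or not);
#' conjunctions alone do not qualify.  The partition is exhaustive and
#' disjoint.
#'
#' @param pairs a pair data frame from [build_pairs()] (columns `id`,
#'   `sentence`, `proposition` at least).
#' @param lexicon a [trigger_lexicon()].
#' @return a list with elements `with_trigger` and `without_trigger`.
#' @export
split_by_trigger_presence <- function(pairs, lexicon) {
  if (nrow(pairs) == 0L) {
    return(list(with_trigger = pairs, without_trigger = pairs))
  }
  sent_has <- vapply(unique(pairs$sentence), function(s) {
    occ <- find_triggers(tokenize_sentence(s), lexicon)
    any(occ$category %in% c("PREN", "POST", "PSEU"))
  }, logical(1))
  has <- sent_has[pairs$sentence]
  list(with_trigger = pairs[has, , drop = FALSE],
       without_trigger = pairs[!has, , drop = FALSE])
}
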