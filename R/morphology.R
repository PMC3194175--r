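# Swedish morphological expansion of trigger lexicons: negative-quantifier
# gender/number forms, suffix-rule adjective and verb inflection, and
# subordinate-clause word-order inversion.

DEFAULT_NEG_ADVERBS <- c("inte", "ej", "icke", "aldrig")
NEG_QUANTIFIERS <- c("inga", "ingen", "inget")

#' Construct an inflection paradigm
#'
#' A paradigm is an ordered list of suffix rules `pattern -> replacements`:
#' the first rule whose `pattern` ends the lemma wins, the matched suffix is
#' replaced by each replacement in turn (an empty replacement reproduces the
#' stem), and the lemma itself is always part of the result.  An empty
#' pattern is the catch-all and terminates every paradigm.  `overrides` are
#' closed inflection groups for irregulars: expanding any member of a group
#' yields the whole group.
#'
#' @param pos part of speech the paradigm inflects: `"adjective"`, `"verb"`
#'   or `"quantifier"`.
#' @param rules list of `list(pattern =, replacements =)` entries; the last
#'   entry must have `pattern = ""`.
#' @param overrides named list mapping a lemma to a character vector of its
#'   irregular forms.
#' @return an object of class `inflection_paradigm`.
#' @export
inflection_paradigm <- function(pos = c("adjective", "verb", "quantifier"),
                                rules, overrides = list()) {
  pos <- match.arg(pos)
  stopifnot(is.list(rules), length(rules) >= 1L)
  for (r in rules) {
    if (!is.list(r) || !all(c("pattern", "replacements") %in% names(r))) {
      stop("each rule needs a 'pattern' and a 'replacements' field")
    }
  }
  if (nzchar(rules[[length(rules)]]$pattern)) {
    rules <- c(rules, list(list(pattern = "", replacements = character(0))))
  }
  structure(list(pos = pos, rules = rules, overrides = overrides),
            class = "inflection_paradigm")
}

#' @export
print.inflection_paradigm <- function(x, ...) {
  cat(sprintf("<inflection_paradigm> %s: %d rules, %d override groups\n",
              x$pos, length(x$rules), length(x$overrides)))
  invisible(x)
}

#' Swedish forms of the negative quantifier "no"
#'
#' Swedish quantifiers carry gender and number concord, so the English
#' negative quantifier *no* corresponds to three surface forms: common
#' gender `ingen`, neuter `inget` and plural `inga`.
#'
#' @return the character set `c("inga", "ingen", "inget")`.
#' @export
expand_quantifier_no <- function() {
  NEG_QUANTIFIERS
}

#' Inflect a lemma through a suffix-rule paradigm
#'
#' Irregular lemmas listed in the paradigm's override groups expand to their
#' full group; otherwise the first matching suffix rule applies.  The result
#' always contains the lemma itself.
#'
#' @param lemma a single non-empty lowercase token.
#' @param paradigm an [inflection_paradigm()].
#' @return a character vector of unique forms including `lemma`.
#' @export
#' @examples
#' inflect("visa", default_paradigms()$verb)    # visa visar visade visat
#' inflect("klar", default_paradigms()$adjective)
inflect <- function(lemma, paradigm) {
  stopifnot(inherits(paradigm, "inflection_paradigm"))
  if (!is.character(lemma) || length(lemma) != 1L || is.na(lemma) ||
      !nzchar(lemma)) {
    stop("lemma must be a single non-empty token")
  }
  for (group_head in names(paradigm$overrides)) {
    group <- unique(c(group_head, paradigm$overrides[[group_head]]))
    if (lemma %in% group) {
      return(sort(unique(c(lemma, group))))
    }
  }
  for (rule in paradigm$rules) {
    pat <- rule$pattern
    if (!nzchar(pat) || endsWith(lemma, pat)) {
      stem <- if (nzchar(pat)) {
        substr(lemma, 1L, nchar(lemma) - nchar(pat))
      } else {
        lemma
      }
      forms <- paste0(stem, rule$replacements)
      return(sort(unique(c(lemma, forms[nzchar(forms)]))))
    }
  }
  lemma
}

#' Read an inflection rules file
#'
#' Parses the plain-text paradigm format: section headers `[adjective]`,
#' `[verb]` and `[overrides]`, rule lines `suffix-pattern<TAB>rep1,rep2,...`
#' (empty pattern = catch-all, empty replacement = bare stem), override
#' lines `lemma<TAB>form1,form2,...`.
#'
#' @param path path to a UTF-8 rules file.
#' @return a named list of [inflection_paradigm()] objects, one per
#'   part-of-speech section, each sharing the file's override groups.
#' @export
read_paradigm_file <- function(path) {
  if (!file.exists(path)) {
    stop("paradigm rules file not found: ", path)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  section <- NA_character_
  rules <- list(adjective = list(), verb = list())
  overrides <- list()
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    if (grepl("^\\[", trimws(ln))) {
      section <- sub("^\\[(.*)\\]$", "\\1", trimws(ln))
      next
    }
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) parts <- c(parts, "")
    pat <- trimws(parts[1])
    reps <- strsplit(parts[2], ",", fixed = TRUE)[[1]]
    reps <- trimws(reps)
    if (identical(section, "overrides")) {
      overrides[[pat]] <- reps[nzchar(reps)]
    } else if (section %in% c("adjective", "verb")) {
      rules[[section]] <- c(rules[[section]],
                            list(list(pattern = pat, replacements = reps)))
    } else {
      stop("rule line outside a known section in ", path, ": ", ln)
    }
  }
  out <- list()
  for (pos in names(rules)) {
    if (length(rules[[pos]]) > 0L) {
      out[[pos]] <- inflection_paradigm(pos, rules[[pos]], overrides)
    }
  }
  out
}

#' Default packaged Swedish paradigms
#'
#' First-conjugation verb rule (`-a` to `-a/-ar/-ade/-at`), a two-rule
#' adjective paradigm (`-t`-final lemmas add only `-a`; otherwise `-t` and
#' `-a` are added), and closed override groups for the irregular verbs
#' *ha*, *se* and *kunna*.
#'
#' @return a named list with `adjective` and `verb` paradigms.
#' @export
default_paradigms <- function() {
  read_paradigm_file(system.file("extdata", "paradigms_sv.txt",
                                 package = "swenegex", mustWork = TRUE))
}

#' Word-order inversion variants of a trigger phrase
#'
#' Swedish places the negating adverb before the verb in subordinate clauses
#' ("... som inte har ..."), so a trigger phrase like "har inte" also occurs
#' as "inte har".  For every adjacent (verb, adverb) bigram whose second
#' token is a negating adverb, the phrase with that bigram swapped is added.
#'
#' @param phrase a trigger phrase as a single space-separated string.
#' @param adverbs the negating adverbs that license inversion.
#' @return a character vector of unique phrases including `phrase` itself.
#'   A single-token phrase is returned unchanged with a notice.
#' @export
#' @examples
#' word_order_variants("har inte")   # "har inte" "inte har"
word_order_variants <- function(phrase, adverbs = DEFAULT_NEG_ADVERBS) {
  stopifnot(is.character(phrase), length(phrase) == 1L)
  phrase <- tolower(squish(phrase))
  toks <- strsplit(phrase, " ", fixed = TRUE)[[1]]
  if (length(toks) < 2L) {
    message("nothing to invert in single-token phrase: ", phrase)
    return(phrase)
  }
  out <- phrase
  for (i in seq_len(length(toks) - 1L)) {
    if (toks[i + 1L] %in% adverbs && !toks[i] %in% adverbs) {
      swapped <- toks
      swapped[c(i, i + 1L)] <- toks[c(i + 1L, i)]
      out <- c(out, paste(swapped, collapse = " "))
    }
  }
  unique(out)
}

#' Default part-of-speech annotations for the packaged lexicon
#'
#' Maps the tokens of the packaged Swedish trigger set that undergo
#' expansion to their part of speech: the three negative-quantifier forms,
#' and the verb forms of *ha* and *visa* that appear in the packaged
#' phrases.  Users expanding their own lexicons supply their own map.
#'
#' @return a named character vector `token -> pos`.
#' @export
default_pos_annotations <- function() {
  c(ingen = "quantifier", inga = "quantifier", inget = "quantifier",
    ha = "verb", har = "verb", hade = "verb", haft = "verb",
    visa = "verb", visar = "verb", visade = "verb", visat = "verb")
}

token_variants <- function(token, pos, paradigms) {
  switch(pos,
         quantifier = if (token %in% NEG_QUANTIFIERS) {
           NEG_QUANTIFIERS
         } else {
           token
         },
         adjective = inflect(token, paradigms$adjective),
         verb = inflect(token, paradigms$verb),
         token)
}

#' Expand a trigger lexicon with Swedish morphological variants
#'
#' Applies, in order: token-level inflection (quantifier gender/number
#' forms, adjective and verb paradigms, taking the cross-product over a
#' phrase's annotated tokens) and then word-order inversion for phrases
#' containing a negating adverb.  Base entries are always retained;
#' generated entries record their origin and the phrase they came from.
#' Pseudo-negations are expanded exactly like negation triggers, so that a
#' pseudo form masks every inflected negation form it subsumes.  The
#' expansion is idempotent.
#'
#' @param base a non-empty [trigger_lexicon()].
#' @param paradigms named list with `adjective` and `verb`
#'   [inflection_paradigm()]s; defaults to the packaged Swedish rules.
#' @param pos_annotations named character vector mapping phrase tokens to
#'   `"quantifier"`, `"adjective"` or `"verb"`; unannotated tokens are left
#'   alone.
#' @param adverbs negating adverbs that license word-order inversion.
#' @param max_variants cap on the number of inflection variants a single
#'   base entry may generate; exceeding it is an error naming the entry.
#' @return an expanded [trigger_lexicon()] containing every base entry.
#' @export
expand_lexicon <- function(base,
                           paradigms = default_paradigms(),
                           pos_annotations = default_pos_annotations(),
                           adverbs = DEFAULT_NEG_ADVERBS,
                           max_variants = 64L) {
  stopifnot(inherits(base, "trigger_lexicon"))
  if (nrow(base) == 0L) {
    stop("cannot expand an empty lexicon")
  }
  text <- base$text
  category <- base$category
  origin <- base$origin
  lemma <- base$lemma

  add_entry <- function(txt, cat, org, lem) {
    if (!any(text == txt & category == cat)) {
      text <<- c(text, txt)
      category <<- c(category, cat)
      origin <<- c(origin, org)
      lemma <<- c(lemma, lem)
    }
  }

  # Pass 1: token-level inflection, cross-product over annotated tokens.
  for (i in seq_len(nrow(base))) {
    toks <- strsplit(base$text[i], " ", fixed = TRUE)[[1]]
    pos <- unname(pos_annotations[toks])
    variant_sets <- vector("list", length(toks))
    for (j in seq_along(toks)) {
      variant_sets[[j]] <- if (is.na(pos[j])) {
        toks[j]
      } else {
        token_variants(toks[j], pos[j], paradigms)
      }
    }
    n_combos <- prod(lengths(variant_sets))
    if (n_combos > max_variants) {
      stop(sprintf("entry '%s' would expand to %d variants (cap %d)",
                   base$text[i], n_combos, max_variants))
    }
    if (n_combos == 1L) next
    combos <- do.call(expand.grid,
                      c(variant_sets,
                        list(stringsAsFactors = FALSE,
                             KEEP.OUT.ATTRS = FALSE)))
    for (r in seq_len(nrow(combos))) {
      variant <- paste(unlist(combos[r, ], use.names = FALSE), collapse = " ")
      if (variant == base$text[i]) next
      changed <- which(unlist(combos[r, ], use.names = FALSE) != toks)[1]
      org <- switch(pos[changed],
                    quantifier = "quantifier_form",
                    adjective = "adjective_inflection",
                    verb = "verb_inflection")
      add_entry(variant, base$category[i], org, base$text[i])
    }
  }

  # Pass 2: word-order inversion over base and generated entries.
  n_now <- length(text)
  for (i in seq_len(n_now)) {
    toks <- strsplit(text[i], " ", fixed = TRUE)[[1]]
    if (length(toks) < 2L || !any(toks %in% adverbs)) next
    variants <- suppressMessages(word_order_variants(text[i], adverbs))
    for (v in setdiff(variants, text[i])) {
      add_entry(v, category[i], "word_order_variant", text[i])
    }
  }

  trigger_lexicon(text, category, origin, lemma,
                  profile = lexicon_profile(base))
}
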