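test_that("tokenisation splits punctuation and keeps offsets faithful", {
  s <- tokenize_sentence("Extremities showed no cyanoses.")
  expect_identical(nrow(s$tokens), 5L)
  expect_identical(s$tokens$surface[5], ".")
  expect_true(s$tokens$punct[5])
  expect_identical(nrow(tokenize_sentence("icke allergisk astma")$tokens), 3L)
  expect_error(tokenize_sentence(""), "empty")
  expect_error(tokenize_sentence("   "), "empty")
  # offsets reconstruct the text
  for (txt in c("Pat mår bra, (inga besvär) idag.", "a-b c... (d)")) {
    s <- tokenize_sentence(txt)
    for (i in seq_len(nrow(s$tokens))) {
      expect_identical(substr(txt, s$tokens$start[i] + 1, s$tokens$end[i]),
                       s$tokens$surface[i])
    }
    expect_true(all(diff(s$tokens$start) > 0))
  }
})

test_that("trigger matching is longest-match-first and non-overlapping", {
  lex <- lex_of(inga = "PREN", "inga tecken" = "PREN")
  occ <- find_triggers(tokenize_sentence("inga tecken på pneumoni"), lex)
  expect_identical(nrow(occ), 1L)
  expect_identical(occ$text, "inga tecken")
  expect_identical(c(occ$start, occ$end), c(1L, 3L))
})

test_that("pseudo-negations mask the negation triggers they contain", {
  lex <- lex_of(inte = "PREN", "inte säkert om" = "PSEU")
  occ <- find_triggers(tokenize_sentence("inte säkert om pneumoni"), lex)
  inte <- occ[occ$text == "inte", ]
  expect_true(inte$masked)
  expect_identical(inte$mask_rationale, "pseudo_masked")
  expect_true("inte säkert om" %in% occ$text)  # provenance retained
})

test_that("sentences without lexicon phrases yield no negation triggers", {
  occ <- find_triggers(tokenize_sentence("pat mår bra idag"),
                       swedish_lexicon("refined"))
  expect_identical(nrow(occ[occ$category %in% c("PREN", "POST"), ]), 0L)
})

test_that("the utan rule masks only inte-preceded occurrences, refined only", {
  lex <- lex_of(utan = "PREN", inte = "PREN")
  s1 <- tokenize_sentence("han är inte pigg utan trött")
  occ1 <- apply_utan_rule(s1, find_triggers(s1, lex), profile = "refined")
  utan1 <- occ1[occ1$text == "utan", ]
  expect_true(utan1$masked)
  expect_identical(utan1$mask_rationale, "rule_masked")
  s2 <- tokenize_sentence("pat utan feber")
  occ2 <- apply_utan_rule(s2, find_triggers(s2, lex), profile = "refined")
  expect_false(occ2$masked[occ2$text == "utan"])
  # baseline profile is a no-op
  occ3 <- apply_utan_rule(s1, find_triggers(s1, lex), profile = "baseline")
  expect_false(any(occ3$masked))
  # sentences without utan are untouched
  s4 <- tokenize_sentence("inte bra idag")
  expect_identical(apply_utan_rule(s4, find_triggers(s4, lex)),
                   find_triggers(s4, lex))
})

test_that("the scope decision follows the worked adjacency example", {
  lex <- lex_of(no = "PREN")
  s <- tokenize_sentence("Extremities showed no cyanoses.")
  occ <- find_triggers(s, lex)
  d <- decide_negation(s, c(4L, 5L), occ)
  expect_identical(d$label, "negated")
  expect_identical(d$distance, 1L)
  expect_identical(d$rationale, "pre_trigger_in_scope")
  expect_identical(d$trigger$text, "no")
})

test_that("seven intervening words put a trigger out of scope", {
  lex <- lex_of(inga = "PREN")
  s <- tokenize_sentence(sentence_at_distance("inga", 8, "feber"))
  occ <- find_triggers(s, lex)
  d <- decide_negation(s, c(9L, 10L), occ, engine_options(scope_limit = 6))
  expect_identical(d$label, "not_negated")
  expect_identical(d$rationale, "out_of_scope")
  expect_null(d$distance)
})

test_that("a conjunction strictly between trigger and proposition cuts scope", {
  lex <- lex_of(inga = "PREN", men = "CONJ")
  s <- tokenize_sentence("inga besvär men viss feber")
  occ <- find_triggers(s, lex)
  d <- decide_negation(s, c(5L, 6L), occ)
  expect_identical(d$label, "not_negated")
  expect_identical(d$rationale, "conjunction_cut")
  # without the cut the same pair is negated at distance 4
  d2 <- decide_negation(s, c(5L, 6L), occ,
                        engine_options(use_conjunction_cut = FALSE))
  expect_identical(d2$label, "negated")
  expect_identical(d2$distance, 4L)
})

test_that("post-negation triggers negate a preceding proposition", {
  lex <- lex_of(osannolik = "POST")
  s <- tokenize_sentence("pneumoni bedöms vara osannolik")
  occ <- find_triggers(s, lex)
  d <- decide_negation(s, c(1L, 2L), occ)
  expect_identical(d$label, "negated")
  expect_identical(d$rationale, "post_trigger_in_scope")
  expect_identical(d$distance, 3L)
})

test_that("punctuation does not count toward the word window by default", {
  lex <- lex_of(inga = "PREN")
  s <- tokenize_sentence("inga , , , tecken feber")
  occ <- find_triggers(s, lex)
  d <- decide_negation(s, c(6L, 7L), occ, engine_options(scope_limit = 2))
  expect_identical(d$label, "negated")
  expect_identical(d$distance, 2L)
  d2 <- decide_negation(s, c(6L, 7L), occ,
                        engine_options(scope_limit = 2,
                                       count_punctuation = TRUE))
  expect_identical(d2$label, "not_negated")
})

test_that("the nearest trigger wins and PREN beats POST on ties", {
  lex <- lex_of(inga = "PREN", osannolik = "POST")
  s <- tokenize_sentence("inga status feber status osannolik")
  occ <- find_triggers(s, lex)
  d <- decide_negation(s, c(3L, 4L), occ)
  # both at distance 2: PREN wins
  expect_identical(d$trigger$category, "PREN")
  s2 <- tokenize_sentence("inga status status feber osannolik")
  d2 <- decide_negation(s2, c(4L, 5L), find_triggers(s2, lex))
  expect_identical(d2$trigger$category, "POST")  # nearer (1 vs 3)
})

test_that("span validation rejects out-of-bounds propositions", {
  s <- tokenize_sentence("pat mår bra")
  occ <- find_triggers(s, swedish_lexicon("refined"))
  expect_error(decide_negation(s, c(0L, 1L), occ), "out of bounds")
  expect_error(decide_negation(s, c(3L, 5L), occ), "out of bounds")
  expect_error(decide_negation(s, c(2L, 2L), occ), "out of bounds")
})

test_that("end-to-end classification handles the icke profiles", {
  expect_identical(
    classify_negation("Pat har inga tecken på pneumoni", "pneumoni",
                      swedish_lexicon("refined"))$label,
    "negated")
  expect_identical(
    classify_negation("icke allergisk astma", "astma",
                      swedish_lexicon("baseline"))$label,
    "negated")
  expect_identical(
    classify_negation("icke allergisk astma", "astma",
                      swedish_lexicon("refined"))$label,
    "not_negated")
  expect_error(
    classify_negation("pat mår bra", "pneumoni", swedish_lexicon()),
    "pneumoni")
})

test_that("negation is monotone in the scope limit", {
  lex <- swedish_lexicon("refined")
  set.seed(42)
  fill <- c("status", "kontroll", "lugn", "stabil")
  for (rep in 1:40) {
    trig <- sample(lex$text[lex$category == "PREN"], 1)
    d <- sample(1:8, 1)
    txt <- paste(c(trig, sample(fill, d - 1, replace = TRUE), "feber"),
                 collapse = " ")
    labels <- vapply(1:9, function(k) {
      classify_negation(txt, "feber", lex,
                        engine_options(scope_limit = k))$label
    }, character(1))
    # once negated at k, negated at every larger k
    neg <- labels == "negated"
    expect_true(all(neg[which(neg)[1]:length(neg)]) || !any(neg))
    expect_true(all(neg[d:9]))  # distance d is inside every window >= d
  }
})

test_that("a masked occurrence never produces a negated decision", {
  lex <- swedish_lexicon("refined")
  sentences <- c("inte säkert om pneumoni",
                 "kan inte utesluta astma",
                 "han är inte pigg utan trött sedan feber")
  for (txt in sentences) {
    s <- tokenize_sentence(txt)
    occ <- apply_utan_rule(s, find_triggers(s, lex))
    term <- c("pneumoni", "astma", "feber")[match(txt, sentences)]
    m <- match_terms(s, term)
    d <- decide_negation(s, c(m$start[1], m$end[1]), occ)
    if (d$label == "negated") {
      expect_false(d$trigger$masked)
    }
  }
})

test_that("refined-profile masking only adds masks relative to baseline", {
  lex_b <- swedish_lexicon("baseline")
  set.seed(11)
  corp <- generate_fixture_corpus(fixture_config(n_sentences = 120,
                                                 seed = 11), lex_b)
  for (i in seq_len(nrow(corp$pairs))) {
    s <- tokenize_sentence(corp$pairs$sentence[i])
    occ <- find_triggers(s, lex_b)
    base_masked <- occ$masked
    ref_masked <- apply_utan_rule(s, occ, profile = "refined")$masked
    expect_true(all(ref_masked[base_masked]))  # refined never unmasks
  }
})
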