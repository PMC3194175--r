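---
title: "Trigger-phrase negation detection for Swedish clinical text: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trigger-phrase negation detection for Swedish clinical text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swenegex)
```

## The problem and the model

Patient records reason by exclusion: most mentions of diseases and symptoms
in assessment text are *pertinent negatives*. `swenegex` decides, for a
(sentence, proposition) pair, whether the proposition is negated, using the
classic trigger-phrase model: a lexicon of categorised cues and a bounded
word-distance scope window, with no parsing. The model's assumptions are
that (i) negation in clinical Swedish is overwhelmingly expressed through a
small closed set of cue phrases, (ii) a cue's scope rarely extends beyond a
few words, and (iii) scope does not cross sentence boundaries. These
assumptions are what make the method cheap and portable; they are also its
known failure modes (hedged uncertainty, long-range scope, temporality).

Formally, with a proposition at token span $p$ and an unmasked pre-negation
trigger ending before $p$ (symmetrically, a post-negation starting after
$p$), the word distance $d$ is one plus the number of non-punctuation
tokens strictly between trigger and proposition, and the pair is negated
iff $1 \le d \le k$ (default $k = 6$) and no scope-terminating conjunction
lies strictly between. The nearest qualifying trigger decides; a
pre-negation beats a post-negation at equal distance.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `scope_limit` | 6 words | maximum trigger-to-proposition distance; 6 is the classic window |
| `use_conjunction_cut` | `TRUE` | terminate scope at CONJ cues (*men*, *dock*, ...) |
| `profile` | `"refined"` | `"refined"` drops *icke* from the packaged set and masks *inte*-preceded *utan* |
| `count_punctuation` | `FALSE` | whether punctuation tokens consume window positions |
| `min_compound_len` | 5 chars | shortest single-token term allowed to match inside a compound token |

Two of these settle questions the trigger-phrase literature leaves open,
and both are deliberately exposed rather than hard-coded: whether the
window counts punctuation, and whether the trigger's own tokens count. We
count neither, with adjacency as distance 1 — the strictest reading
consistent with the canonical worked example ("Extremities showed **no**
*cyanoses*", distance 1, negated). The conjunction cut defaults to on,
matching the later-generation behaviour of the algorithm family; turning it
off recovers the original scope rule.

## The packaged lexicon and its provenance

The packaged Swedish trigger sets (`swedish_lexicon("baseline")`,
`"refined"`) are reconstructions. The pre-negation entries are the phrases
printed in the published per-trigger evaluation tables of the Swedish
adaptation work (*inga*, *ingen*, *inget*, *inte*, *ej*, *aldrig*, *utan*,
*förnekar*, *avsaknad av*, *inga tecken*, ...), plus their attested
word-order and tense variants. The post-negation, pseudo-negation and
conjunction entries are reconstructed by category description (the original
full 41-entry list was only ever distributed at a now-unreachable URL), so
*osannolik*, *kan uteslutas*, *inte säkert om*, *utan tvekan*, *men*,
*dock*, etc. are this package's own choices of representative members.
Users with their own triggers file in the `phrase<TAB>[TAG]` dialect can
load it with `read_trigger_file()`.

The refined profile encodes the two published Swedish refinements: *icke*
is removed (in clinical Swedish it almost always opens a disease name —
*icke allergisk astma* is a present disease), and *utan* is masked when
*inte* occurs earlier in the sentence, where it is the conjunction "but".
The *utan* rule is applied at sentence granularity (any earlier *inte*
token), which is exactly how the rule is stated; a window-bounded variant
would mask less and was not adopted.

## Morphological expansion

English trigger lists translate into Swedish lemmas, not surface forms, so
`expand_lexicon()` generates: the three concord forms of the negative
quantifier (*ingen/inga/inget*); adjective and verb inflections through
ordered suffix rules (first matching rule wins, catch-all terminates every
paradigm) plus closed override groups for irregulars (*ha/har/hade/haft*,
*se/ser/såg/sett*, *kunna/kan/kunde/kunnat*); and word-order inversion for
phrases containing a negating adverb (*har inte* → *inte har*), reflecting
Swedish subordinate-clause order. The suffix-rule inflector is a built-in,
rule-table-driven component behind a pluggable interface (paradigms are
plain-text files; see `read_paradigm_file()`), so a full morphological
analyser can be substituted. Pseudo-negations are expanded identically to
negations — a pseudo form must mask every inflected negation form it
subsumes. Expansion is idempotent, never removes a base entry, and caps
variants per entry at 64 to guard against pathological cross-products (the
packaged entries generate at most a handful each).

Note that the do-construction difference between English and Swedish needs
no special handling: *de vet inte* places *inte* directly in front of any
following proposition, which the window rule already covers.

## Term lists and compound matching

ICD-10-style exports append clarifiers that defeat string matching;
`clean_term()` strips parenthesised material (nested included; an
unbalanced parenthesis truncates with a warning), removes configured
clarifier phrases (*ej specificerad*, *ospecificerad*, *andra specificerade
former*, ...) with adjacent commas, collapses whitespace and lowercases.
Swedish compounds hide propositions inside longer tokens (*astmabesvär*),
so `match_terms()` additionally matches single-token terms of at least
`min_compound_len` characters as substrings of longer tokens. The
5-character floor is a precision guard: shorter terms (e.g. *natt*) would
fire spuriously inside unrelated words. Compound detection by substring is
deliberately naive — no decompounding — and is known to over- and
under-match in real text.

## Evaluation harness

Gold labels are three-class (affirmed / negated / ambiguous); scoring
collapses affirmed and ambiguous into *not negated*, mirroring the
published evaluation design, and proceeds on two groups: pairs whose
sentence contains at least one PREN/POST/PSEU occurrence, and the rest.
The trigger-bearing group is scored on precision, recall, specificity and
NPV; the trigger-free group on NPV only (essentially every prediction
there is *not negated*). Confidence intervals are Wald,
$p \pm 1.96\sqrt{p(1-p)/n}$ on each metric's own denominator, clipped to
$[0,1]$ — the published intervals for this task are reproduced to within
about 0.1–0.2 percentage points, and the CI method is a named argument so
a score-interval variant can be added without interface change. Cohen's
$\kappa$ uses marginal-product expected agreement; the two-proportion
$\chi^2$ is Pearson's on the 2×2 table, one degree of freedom, no
continuity correction (the plain reading of "the χ²-test"), computed in
double precision. Per-trigger statistics attribute each negated decision
to exactly one phrase — the engine's nearest-winner — so occurrence counts
are mutually exclusive.

## The synthetic corpus generator

No clinical data ships with the package; `generate_fixture_corpus()`
produces structural stand-ins for assessment-field sentences from a filler
vocabulary chosen to be disjoint from every trigger token and term. Record
templates cover: in-window negations (PREN and POST, distances sampled
from a right-skewed distribution over 1–8), out-of-window triggers,
conjunction-cut constructions, pseudo-negations, *icke*-compound disease
names, hedged-uncertainty phrasings, and trigger-free affirmations.
Defaults emulate the published two-group design at its scale: 900 pairs,
30% negated (269/900 in the study), ≈62% trigger-bearing (558/900), 12%
ambiguous (≈ the physicians' 71 ambiguous of 558 trigger-group sentences),
3% pseudo-negation records (pseudo-negations were rare in the study data),
10% compound-embedded propositions (unstated in the source; Swedish
compounding is common), with seed-deterministic output.

Gold labels for non-ambiguous records are derived with `oracle_label()`, a
brute-force plain-loop restatement of the scope rule sharing no decision
code with the engine — so "gold = oracle" holds by construction and the
engine-vs-oracle comparison is a genuine dual-route check. Ambiguous
records mirror the error classes that cost the published system precision:
hedged negations (*ingen säker ...*) that a trigger detector wrongly
fires on, pseudo-negation hedges, and trigger-free uncertainty markers.

Two consequences follow and should temper interpretation. First, synthetic
recall is 1.0 by construction: the generator never produces the
false-negative classes seen in real text (past-tense conditions treated as
negated, triggers beyond the window that human readers still resolve, a
pre-negation after its proposition). Second, precision below 1.0 comes
only from the planted hedge and *icke* fixtures. Passing tests on this
corpus therefore demonstrate that the implementation realises the
specified rule exactly — not that the rule achieves any particular accuracy
on real Swedish clinical text, which is access-restricted and whose
published headline figures (precision ≈ 75%, recall ≈ 82%) this package
does not claim to reproduce.

## Numerical and degenerate-input choices

Matching ties (one position, equal length, different category) resolve
PREN over POST; multiple proposition occurrences use the first, while pair
construction emits one record per occurrence. Metrics with empty
denominators are `NA` and flagged, never 0. $\kappa$ on a single shared
constant label is `NA` with a warning; a pooled proportion of exactly 0 or
1 gives the degenerate $\chi^2$ of 0 with $p = 1$. Empty sentences,
empty lexicons, out-of-bounds spans and malformed trigger lines are
errors naming the offending input. The generator restores the caller's
RNG state.

## Problem sizes used in the checks

The test suite verifies engine–oracle agreement on 10,000 generated pairs
(5,000 per profile) and pipeline-metric identity on a 1,000-record corpus;
the acceptance script uses the default 900-pair corpus and verifies the
oracle on all pairs under both profiles. These sizes give three-sigma
resolution on the generator's rates while keeping a full run in minutes on
a single core.

## Known limitations

Cross-sentence negation, historical/hypothetical/experiencer context,
uncertainty detection and temporality are out of scope. The packaged
POST/PSEU/CONJ entries are reconstructions, not the historical list. The
rule-table inflector covers only what trigger expansion needs, not general
Swedish morphology. Compound matching is substring containment, not
decompounding. Synthetic fixtures are structural, not linguistic, and
cannot certify real-world accuracy.
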