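---
title: "Mining opinions from Persian patient feedback: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining opinions from Persian patient feedback: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(persent)
```

`persent` turns short free-text hospital feedback written in Persian into
sentence-, document-, section- and topic-level sentiment summaries. This
vignette is the package's own account of the methods: the models and
their assumptions, the parameters that matter, the numerical choices, and
what the synthetic-data-based tests do and do not establish about real
corpora.

## The normalization model

Persian web text is orthographically unstable. The same word can appear
with Arabic code points (ي U+064A for ی U+06CC, ك U+0643 for ک U+06A9),
with or without the half-space (zero-width non-joiner, U+200C) that joins
affixes to stems, stretched with kashida (ـ U+0640), with a suffix
detached by a full space (`مناسب تر` for `مناسبتر`), with a prefix split
from its verb (`می رود` for `می‌رود`), with homophone spellings
(`اطاق` for `اتاق`), or missing the initial long alef (`اب` for `آب`).
Unless these variants are collapsed, lexicon lookups and topic-model
vocabularies fragment.

`normalize_comment()` applies rule-driven repairs in a fixed order:

1. **Characters**: Arabic code points → Persian, diacritics stripped,
   kashida removed, and the initial-آ restoration applied to an explicit
   word list. The order matters: kashida is removed first so elongated
   mapped words still match, and character unification precedes every
   word-level map so the maps only need canonical code points.
2. **Spacing**: runs of spaces/tabs collapse, half-spaces stranded next
   to spaces are dropped.
3. **Affixes**: a listed suffix standing alone after a word is attached
   (`مناسب تر` → `مناسبتر`); a listed prefix standing alone before a word
   is joined with a half-space (`می رود` → `می‌رود`).
4. **Spelling**: whole-word variant and split-compound keys map to their
   canonical forms (`اطاق` → `اتاق`, `پیر مرد` → `پیرمرد`).
5. **Sentences are split before punctuation is removed.** Terminators
   (`.`, `!`, `?`, `؟`, `؛`, newline) are both sentence boundaries and
   punctuation; splitting first and stripping afterwards keeps the
   boundaries without leaking terminator characters into tokens. A
   trailing fragment without a terminator is its own sentence.
6. **Tokenization** splits on spaces only — the half-space is
   word-internal and never separates a token.
7. An optional, deliberately conservative **spell-check**: a token absent
   from the vocabulary is corrected only when exactly one vocabulary word
   sits at edit distance 1. It is off by default because a lexicon-based
   scorer is harmed far more by a wrong correction than by an unmatched
   token.
8. **Negation detection**, then **stopword removal** (surface-form
   lookup against an editable list), then **stemming**.

The stemmer strips the longest listed suffix, at most twice, and never
empties a token. It is list-driven rather than morphological: for
sentiment lookup and topic vocabulary the goal is collapsing inflected
forms, not linguistic analysis, and a heavier stemmer can be swapped in
by editing the suffix inventory. Whether to stem before or after stopword
removal is in principle open; the pipeline removes stopwords first so the
stopword list can be written in surface forms.

Every operation is idempotent (`O(O(x)) = O(x)`), order-preserving, and
only merges tokens via the affix/compound rules — properties the test
suite checks on generated corpora.

## Negation

Persian negates by gluing a particle to the word: رفتم → نرفتم. The
package treats ن، نا، ضد as shifters. A token is negated only when

* it starts with a shifter,
* it is not itself a lexicon term or a listed protected word
  (نگران is "worried", not a negated گران), and
* the shifter-stripped remainder is *known* — a lexicon term, a stem of
  one, or a supplied vocabulary word.

The known-remainder guard keeps names and ordinary ن-initial words from
being misread as negations. A negated token's lexicon strength has its
sign inverted, the standard shifter semantics for strength lexicons; the
alternatives (damping or zeroing) would make "not good" weaker than
"bad", which the rating-conditional tests contradict. Scope is the
shifted token only — the particle is morphological here, so window-based
scope would overreach.

## Sentiment scoring

Each term carries an integer strength in −5..−1 or +1..+5; zero is
forbidden so that absence from the lexicon is the only way to be neutral.
Per sentence the scorer records the maximum positive strength and the
minimum negative strength among its tokens; the polarity is whichever has
larger absolute value, and an exact tie is neutral — with symmetric
evidence the symmetric answer is zero.

A document's score is the arithmetic mean of its *nonzero* sentence
polarities divided by 5, giving the conventional reporting scale of −1
(most pessimistic) to +1 (most optimistic); a document whose every
sentence is neutral scores 0. Neutral sentences are excluded from the
mean so that opinionated sentences are not diluted by descriptive ones,
which dominate longer comments.

Groups of reviews (a section, a topic) aggregate by the
usefulness-weighted average `V = Σ uᵢ sᵢ / Σ uᵢ`. Hospital feedback forms
collect no usefulness votes, so all weights default to 1 and `V` is the
plain mean; the interface accepts arbitrary non-negative weights for
platforms that do have them. Classification uses the score's sign, with
an optional neutral band for callers who want to abstain near zero.

## Topic modeling

`fit_lda()` implements latent Dirichlet allocation with collapsed Gibbs
sampling: token `n` in document `d` with word `w` is reassigned with
probability proportional to `(n_dt + α)(n_tw + β)/(n_t + Vβ)`. Defaults
follow common practice for short informal text: `α = 50/k`, `β = 0.01`,
1000 sweeps with the first 500 discarded as burn-in. Point estimates of
the topic–word matrix φ and document–topic matrix θ are the smoothed
count ratios averaged over every post-burn-in sweep, which is less noisy
than a single final sample. All randomness flows through R's RNG, so a
fit is bit-reproducible from its seed. A per-sweep token log-likelihood
trace is kept for convergence diagnostics; on generated corpora its
50-sweep moving average is non-decreasing.

Choosing the topic count is, in practice, a human judgement. As an
automatic stand-in, `select_k()` fits each candidate `k` from the same
seed and ranks them by mean UMass coherence,
`Σ log((D(wᵢ,wⱼ)+1)/D(wⱼ))` over top-10 word pairs: topics whose defining
words actually co-occur in documents score near zero, while topics that
mix unrelated vocabulary (the signature of too few or too many topics)
are driven strongly negative. Exact ties resolve to the smaller `k`. The
full per-`k` table and fitted models are returned so an analyst can still
review candidates manually; topic labels are intentionally left to
humans — the package reports top words and accepts a label map.

## Evaluation protocol

Expert 1–5 satisfaction ratings collapse to binary ground truth: ratings
3–5 are positive, 1–2 negative. The corpus splits 90:10, stratified by
label with largest-remainder seat allocation, reproducibly per seed; the
held-out 10% is scored. The lexicon scorer has no trainable weights — the
split exists because the protocol's shape calls for one, and the training
portion is where a neutral band or lexicon extensions would be tuned.
Reports contain the confusion matrix, precision `TP/(TP+FP)`, recall
`TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
`(TP+TN)/total` and F-measure `2PR/(P+R)`, laid out per feedback section.
Zero-denominator metrics are reported as `NA`, never as errors.
Neutral-scored comments are dropped from the binary metrics by default
(configurable to majority-class assignment). AUC is the rank-based
Mann–Whitney statistic on the continuous document score — the probability
that a random positive outscores a random negative, ties counted one
half — and is invariant under monotone transformations of the score.

## The synthetic-data generator

Real patient corpora are typically private, so the generator is the
package's test bed: it produces corpora whose correct answers are known
by construction.

What it emulates, and the defaults it is calibrated to:

* **Shape**: comments average 41.3 words in 3.9 sentences (sentence count
  is 1 + Poisson, word count Gaussian with 12% coefficient of variation,
  injected tokens budgeted against the target so the means hold).
* **Sections and ratings**: three feedback sections in equal shares;
  ratings 1–5 drawn with probabilities (0.10, 0.12, 0.18, 0.30, 0.30), a
  positive skew typical of satisfaction forms. Ages are cosmetic
  metadata from three bins (under 30: 8.9%, 30–60: 63.6%, over 60:
  27.5%).
* **Topics**: `k` planted topics over disjoint 120-word blocks of a real
  Persian word list (extended with half-space compounds), Dirichlet(0.5)
  weights within a block and 5% leakage mass spread over the whole
  vocabulary; documents draw a Dirichlet θ sharply concentrated on one
  topic. This is the "well-separated topics" regime in which topic
  recovery is a meaningful test rather than a coin flip.
* **Sentiment**: each scoring sentence (first sentence always; others at
  the injection rate, default 0.7) receives one lexicon term whose
  strength realizes the rating's intended polarity — ratings 5/4/3 inject
  +4..+5 / +2..+3 / +1, ratings 2/1 inject −1..−2 / −3..−5 — so on clean
  text the rating→label rule is recoverable with accuracy 1 by
  construction, and document scores land in rating-consistent bands
  (e.g. rating 5 ≥ +0.8, rating 3 exactly +0.2).
* **Negation**: a comment is written in a negating style with probability
  `negation_rate`, treated as a per-author trait: *all* its injected
  sentiment appears as shifter-attached opposite-strength terms plus a
  weaker plain term of the opposite sign. Scored with negation handling
  the intended polarity is recovered exactly; scored without it the
  weaker distractor wins with the wrong sign. This makes the ablation
  sharp: disabling negation handling costs roughly the negation rate in
  accuracy, rather than a diffuse sub-percent effect.
* **Surface noise**: six independent corruption classes (Arabic
  character forms, extra spaces/tabs, detached suffixes, split prefixes,
  kashida elongation, spelling variants including dropped آ) applied at
  configurable rates, at most one word-level class per word so classes
  never interact. The normalization pipeline provably inverts all of
  them: `normalize(corrupt(x)) = normalize(x)`.
* **Out-of-lexicon rate**: injected terms replaced by unknown words, the
  generator's model of lexicon incompleteness.

What it does **not** emulate: fluent Persian syntax, sarcasm and irony
(a known failure mode of lexicon scoring), rater disagreement, topic
drift over time, or the actual distribution of any real hospital's
complaints. Passing tests therefore demonstrate that the pipeline's
mechanics are correct relative to its lexicon — not that any particular
lexicon captures real patients' language. Scores on real text are
lexicon-dependent, and the bundled 70-term demo lexicon is a fixture,
not a resource.

## Numerical and interface choices

* Ties: sentence polarity ties → neutral; dominant-topic ties → lowest
  index; top-word and frequency ties → lexicographic (radix order on
  UTF-8); coherence ties in the k sweep → smaller k.
* Strength 0 is rejected at lexicon load so "absent = neutral" is
  unambiguous; duplicate terms are errors, not silent overwrites.
* All text is handled as UTF-8; the half-space is U+200C throughout.
* Degenerate inputs raise typed conditions (`persent_empty_document`,
  `persent_range_error`, ...) rather than generic errors, and corpus
  functions can drop empty documents with a warning instead of failing.
* Artifacts are JSON-lines (per-comment records) and CSV (tables),
  written atomically, with a manifest recording seeds and settings;
  identical configuration reproduces byte-identical artifacts.

## Problem sizes used by the checks

The package's own verification runs at desk scale, chosen to finish in
seconds while leaving no statistical ambiguity: scorer-vs-oracle
equivalence on 1,000 random token lists; normalization round trips on
over 1,000 generated sentences across all noise classes; label recovery
on 500-comment corpora (clean, and with 10% negation styling plus 20%
out-of-lexicon terms); topic recovery and the k sweep on a 500-document,
50-word, 3-topic corpus; metric formulas on 200 random confusion
matrices; AUC against exhaustive pair counting on vectors up to length
12. `scripts/acceptance.R` re-runs all of these from scratch for any
seed.

## Known limitations

Sentence-level max-abs scoring ignores intensity accumulation (three
mild compliments score like one); negation scope is a single token, so
analytic negation of a distant word (`تمیز نبود`) is not flipped;
the list-driven stemmer under-stems unseen inflections; and coherence is
only a proxy for human topic review. These are deliberate boundaries of
a transparent, rule-based design rather than accidental gaps.
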