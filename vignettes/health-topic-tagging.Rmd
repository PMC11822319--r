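---
title: "Methods: lexicon-based health-topic tagging of forum posts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lexicon-based health-topic tagging of forum posts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(httag)
```

## The method

`httag` implements a purely lexical procedure for characterising
health-related discussion in Reddit-style forum corpora. It makes three
modelling commitments, all deliberate:

1. **Selection by proximity query.** A post is "about getting tested or
   checked" when, in its tokenized title-plus-body text, one can pick one
   occurrence from each of the groups {get, got},
   {test, tested, check, checked}, and {for} such that the chosen token
   positions span at most 4 (`max − min ≤ 4`, 0-based token indices). The
   span is measured in tokens, not characters, and the matcher is exact:
   it is equivalent to enumerating every tuple of occurrences (the test
   suite checks this against a brute-force oracle), implemented as a
   linear-time minimum-window sweep.
2. **One topic per post, by keyword evidence.** A keyword lexicon maps each
   topic to one parent medical discipline (chapter-level groupings modeled
   on the ICD-10) and to a set of trigger phrases. Posts and phrases are
   both passed through the same lemmatizer, and a phrase hits when its
   lemma sequence occurs contiguously in the post's lemma sequence. The
   assigned topic maximises, in order: distinct phrases hit, total
   occurrences, earliest lexicon position. Posts with no hits receive the
   reserved `nonmedical` fallback.
3. **Frequencies as the analytic unit.** All downstream analysis is
   counting: relative frequencies of topics, disciplines, and subreddits;
   cumulative frequency by rank; per-subreddit top-5 reports; and top-5
   coverage summaries across subreddit groups.

The method assumes that a small set of hand-curated phrases per topic
captures most on-topic posts, that a single label per post is an acceptable
simplification (multi-topic posts exist and get exactly one label), and
that lemma-level exact matching is sufficient (no spelling correction, no
embeddings, no negation handling). These assumptions are the method's
defining boundary, not an oversight.

## Tokenization and lemmatization

Tokenization splits on any non-alphanumeric run and lowercases; positions
are indices in the resulting sequence. There is no stop-word removal —
removing "get" or "for" would destroy the very phrases selection depends
on — and no HTML/markdown stripping beyond what the splitting implies.

Lemmatization is rule-based: a small irregular-form table, then plural
rules (`-ies → -y`, sibilant `-es`, final `-s`), then `-ed`/`-ing`
stripping with doubled-consonant undoubling, applied only when the
remaining stem keeps at least three characters and a vowel. The contract is
that regular inflections collapse ("tests", "tested", "testing" → "test";
"checked" → "check"). Because the *same* function is applied to keyword
phrases at lexicon load and to post tokens at assignment time, matching
requires only consistency, not dictionary-perfect lemmas: a stem like
"smoking" → "smok" still matches, since both sides reduce identically.
Tokens containing digits ("a1c") and tokens of three or fewer characters
pass through unchanged.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| query window | 4 tokens | the "within 4 words" selection semantics |
| query groups | get/got; test/tested/check/checked; for | the testing-and-checking phrasing the method targets |
| tie-break cascade | distinct → total → lexicon order | distinct phrases are stronger evidence than repetitions; file order last so users control priority by ordering the lexicon |
| top-n for coverage | 5 | "top 5 topics per subreddit" is the reporting unit |
| interval mode | `mean_pm_sd` | matches the source study's printed intervals (see below) |
| percent rounding | 2 decimals, half-up | reproduces conventionally printed percentages (e.g. 83.125 → 83.13; base R's banker's rounding would give 83.12) |

The interval convention deserves a note. The published study labels its
coverage intervals "95% CI", but the printed numbers equal mean ± 1·SD
capped to [0, 100%] (0.703 ± 0.383 → 32%–100%; 0.411 ± 0.129 →
28.2%–54%). `coverage_stats()` therefore defaults to that convention
(`mean_pm_sd`) so its output is comparable with the published tables, and
additionally offers `normal_sem` (mean ± 1.96·SD/√k, capped), the
conventional normal-theory interval. The two disagree whenever k ≠ ~4;
users quoting intervals should say which mode they used.

Similarly, published accuracy summaries pair SD and SEM values that are
mutually inconsistent with the stated number of runs; `accuracy_stats()`
simply implements the standard definitions (sample SD, SEM = SD/√runs) and
reports `NA` for a single run.

## The default lexicon

`default_lexicon()` ships 82 topics in 17 disciplines, including the
reserved `nonmedical` fallback and the non-ICD-10 topics (medical billing)
grouped under "medical; other". The topic→discipline structure follows the
published taxonomy for health discussion on Reddit; since the full keyword
file of that study is unpublished, the keyword lists here are a
*reconstruction*: seeded from the phrases quoted in the study (e.g.
"antibiotics", "gonorrhea", "chlamydia", "bacterial vaginosis" for STIs;
"difficulty urinating"/"difficulty peeing" for benign prostatic
hypertrophy) and completed with clinically conventional terms. Two editorial
constraints were imposed: every topic→discipline pair printed in the
study's tables is honored exactly, and the keyword lists are pairwise
disjoint after lemmatization (`validate_lexicon()` reports zero findings),
so assignment on clean input is tie-free. Real-world use should extend the
keyword lists; `validate_lexicon()` flags the collisions and
prefix-shadowing that extension tends to introduce.

## The synthetic corpus generator

`generate_corpus()` exists so selection, assignment, analytics, and review
tooling can be exercised with known ground truth. Each post is a bag of
nonsense filler tokens (constructed disjoint from every lexicon keyword and
query term, so noise cannot create hits) into which the generator plants,
for relevant posts, 1–3 keyword phrases of a topic drawn from a mixture,
and, at a configurable rate, a query-satisfying trigger phrase ("get tested
for", …). Defaults mirror the study conditions at roughly 1/100 scale:
3500 posts; 16% of posts in excluded subreddits (all irrelevant); 15.5% of
included-subreddit posts irrelevant — jointly ≈ 29% irrelevant before
subreddit filtering and 15.5% after, the false-positive-rate drop the
subreddit filter is for. A `confusable_rate` option plants a second topic's
keyword to exercise tie-breaking.

What the generator does *not* emulate is natural language: no grammar, no
paraphrase, no misspellings, no negation ("tested negative"), no topic
drift within a post. Passing the planted-recovery test therefore shows the
machinery is correct — tokenizer, lemmatizer, matcher, tie-break, and
plumbing compose without loss — not that the lexicon would reach any
particular accuracy on real Reddit text; that is what the blinded
manual-review tooling is for.

## Numerical and degenerate-input choices

- Overlapping occurrences of the same phrase count once per start position.
- Frequency tables refuse empty assignment sets (undefined denominator)
  and excluded rows; ties in count order alphabetically.
- `coverage_stats()` refuses groups smaller than 2 (SD undefined) and
  subreddits without assignments.
- Subreddit names normalize by stripping *all* leading "r/" prefixes and
  lowercasing, making normalization idempotent even on degenerate names.
- The pipeline aborts atomically: a failing stage names itself and removes
  partial outputs, and rerunning an identical configuration reproduces all
  outputs byte for byte.
- Review sampling uses a seeded RNG that saves and restores the caller's
  RNG state, so library calls never perturb user-level reproducibility.

## Problem sizes used by the test suite

The suite generates all fixtures in code: unit tests use corpora of
40–600 posts and lexicons of 3–10 topics; the property checks use 1000
random token sequences (≤ 200 tokens) against an exhaustive proximity
oracle, 200 seeded review draws for sampling uniformity, and one
3500-post zero-noise corpus for planted-topic recovery (observed: 100%
recovered; the acceptance bar is ≥ 95%). These sizes were chosen as the
smallest that make the binomial tolerances meaningful.

## Known limitations

- Single-label assignment: multi-topic posts get one topic; the
  `hit_report` option exposes the full hit table but the label is one.
- The lemmatizer is rule-based English; clinical jargon, misspellings, and
  non-English text pass through unlemmatized (and simply fail to match).
- Keyword evidence is presence-based; sarcasm, negation, and quoting are
  invisible to it.
- The shipped subreddit lists and keyword lists are reconstructions and
  should be treated as configuration, not ground truth.
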