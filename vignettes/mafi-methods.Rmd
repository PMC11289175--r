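---
title: "Quantifying mouth and facial informativeness from speechreading data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mouth and facial informativeness from speechreading data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mafi)
```

## The problem

Mouth and facial movements carry information about speech: a /b/ is easy to
spot on the lips, a /k/ is not. Word-level visual informativeness cannot be
read off single phonemes, because coarticulation, word length and lexical
competition all intervene. The operationalization implemented here is
behavioral: show people silent videos of a speaker producing single words,
let them type their best guess, and measure how *phonologically close* the
guesses are to the target. Words whose mouth and facial movements are
informative attract guesses close to the target; uninformative words attract
distant guesses.

The per-word score — the MaFI score — is the negated mean normalized
phonological distance between a target and its guesses. It is 0 when every
guess was the target and grows more negative as guesses drift away.

## The distance model

Both target and response are represented as sequences of IPA segments, each
segment a vector of articulatory feature values in $\{-1, 0, +1\}$
(voice, anterior, labial, high, back, nasal, ...). The distance between two
words is a minimum-cost edit distance computed by dynamic programming,
where:

* **substitution** of segment $a$ by segment $b$ costs
  $\sum_f w_f\,\lvert v_f(a) - v_f(b)\rvert$ — each feature contributes its
  weight $w_f$ per unit of change, so a full $+1 \leftrightarrow -1$ flip
  costs $2 w_f$;
* **insertion/deletion** of $a$ costs its weighted feature mass
  $\sum_f w_f\,\lvert v_f(a)\rvert$, i.e. a substitution against a silent
  all-zero segment (a flat constant penalty is available via
  `indel_penalty` for sensitivity analyses);
* the total cost is divided by the phoneme count of the longer word, so
  long words are not penalized for offering more opportunities to err.

The weights encode visual/phonological salience asymmetries: voicing,
invisible on the face, costs 0.125 per unit, while place features
(anterior, labial, high, back) cost 0.25. Hence /bæt/–/pæt/ (voicing only)
costs $2 \times 0.125 = 0.25$, normalized $0.25/3 = 0.083$, while
/bæt/–/kæt/ costs $2(0.125) + 4 \times 2(0.25) = 2.25$, normalized $0.75$ —
an order of magnitude apart, although both responses share two of three
phonemes with the target. The companion metrics (segment Levenshtein
distance, whole-word accuracy, percent phonemes correct) cannot make that
distinction; they are computed for comparison by the same pipeline.

Percent phonemes correct needs a tie-break: among minimum unit-cost
alignments we take the one with the most identical matches, which makes the
statistic deterministic (`bat` vs `cat` and `bat` vs `pat` both give
$2/3$).

## The feature system

The package ships a ~57-segment English IPA inventory over 21 articulatory
features with the standard published per-feature weights, built in
`data-raw/build_fixtures.R`. Affricates (tʃ, dʒ), length-marked vowels (uː)
and common diphthongs (aɪ, əʊ, ...) are single table rows; the tokenizer
segments IPA strings by greedy longest match after NFC Unicode
normalization, so "phoneme count" is well defined and concatenating the
output segments reproduces the input. Both /r/ and /ɹ/ are present as
distinct rows with identical vectors, since English transcription practice
varies. Users can substitute their own table and weights
(`load_feature_table()`); the shipped fixture covers what the bundled
lexicon needs, not the full IPA.

Pronunciations come from a word → IPA lexicon (`load_lexicon()`), which
replaces an external grapheme-to-phoneme transcriber. Out-of-lexicon
responses are excluded and reported rather than penalized — a conservative
choice that keeps a thin lexicon from masquerading as poor speechreading.

## Saliency coding

Two phoneme-level features are coded: **frontness** (bilabials /b, p, m/
and labio-dentals /f, v/) and **roundness** (/r, w, u, o, ɔ/, with
length-marked and diphthongized vowels inheriting their base symbol's
status, and any segment whose table `round` feature is +1 also counting).
Viseme classes group visually near-identical phonemes: {f} = /f, v/ (lower
lip tuck), {ch} = /ʃ, tʃ, dʒ/ (protrusion), {w} = /w/ (protrusion + lip
rounding), {p} = /b, p, m/ (labial closure), {j} = /j/ and {r} = /r, ɹ/
(lip rounding). The inventory is overridable from CSV because viseme
boundaries are fuzzy across speakers.

The informativeness load of a word is the count of salient phonemes (or of
segments in feature-bearing viseme classes) divided by its phoneme count;
a hypothetical phoneme qualifying as both front and round would count once
per property, and loads are capped at 1. Position within the word is
deliberately ignored: position-weighted saliency is a plausible refinement
but not part of this quantification.

## Statistical procedures

`prepare_design()` joins norms, saliency profiles and lexical covariates
(log-frequency, age of acquisition, phonological neighborhood density,
phoneme count), dummy-codes the feature indicators to 0/1 and standardizes
the continuous covariates; words missing a covariate are dropped listwise
and reported. `fit_ols()` fits ordinary least squares (the "hierarchical"
analysis is a nested baseline-vs-target comparison, not a multilevel
model), and `compare_models()` performs the Gaussian likelihood-ratio test
$2(\ell_{target} - \ell_{baseline}) \sim \chi^2_{df}$ with $df$ the number
of added predictors — the same comparison `anova()` makes on nested `lm`
fits. No multiple-testing correction is applied. `correlate_norms()`
computes Pearson correlations between norm sets on their shared words with
Fisher-z confidence intervals, the procedure used to compare norms across
speaker and perceiver variants of English.

The published regression coefficients and cross-variant correlations were
estimated from a human response corpus that this package does not bundle;
the test suite validates the *procedures* on simulated data instead:
injected frontness/roundness effects are recovered within two standard
errors at 500 words, viseme-structured confusion noise produces a positive
viseme-load coefficient with a significant likelihood-ratio improvement
over the lexical baseline, and with a pure-noise added predictor the LRT
p-values are uniform over 200 null replicates.

## The response simulator

`simulate_corpus()` generates speechreading guesses under a per-segment
confusion model: each target segment is kept with probability `p_correct`
(default 0.5 — speechreading is hard and whole-word accuracy low), deleted
with probability `p_delete` (default 0.1), and otherwise substituted;
substitutions stay within the segment's viseme class with probability
`p_within_viseme` (default 0.9 — errors are overwhelmingly visual
confusions) and otherwise draw uniformly from the same broad category
(consonant vs non-consonant, via the table's `cons` feature). Insertions
are off by default (`p_insert = 0`). Guesses are rendered back to IPA and
registered as pseudo-words in a working lexicon, so simulated corpora flow
through the exact scoring path as real data. Everything is deterministic
given the model seed. Pseudo-word targets from `simulate_lexicon()`
alternate consonants and vowels and span 1–12 segments, the phoneme-count
range typical of word corpora these norms are built for.

The simulator emulates the *structure* the scoring method is designed to
detect — viseme-level confusability, per-segment independence — and not the
lexical dynamics of real guessing: human responses are real words shaped by
neighborhood competition, frequency and orthography, and errors are
correlated across positions by coarticulation. Passing tests therefore
demonstrate that the pipeline measures what it claims under a known
generative process, not that simulated norms match human norms.

## Numerical and reproducibility choices

* Full floating point throughout; rounding (4 decimals in norm files, 2 in
  displays) happens only at serialization. The printed convention for
  percent phonemes correct truncates, so $2/3$ prints as 0.66.
* Norm files are deterministic: alphabetical word order, fixed rounding,
  UTF-8 — identical inputs give byte-identical files.
* Degenerate inputs fail loudly: empty-vs-empty normalized distance,
  empty targets, zero-variance covariates, rank-deficient designs and
  non-nested model comparisons are errors, not NAs.
* Duplicate words across studies are merged by averaging per-study means,
  not by pooling raw responses, so an oversampled study cannot dominate.
* Test problem sizes (100–500 simulated words, 6–20 simulated participants,
  200 null replicates) were chosen as the smallest sizes at which the
  statistical properties under test are stable across seeds.

## Limitations

The bundled inventory and lexicon are English-only and monophthong-biased;
diphthongs are treated as single long segments rather than glide sequences.
The simulator ignores coarticulation, speaker variability and lexical
competition. Neighborhood density is an input covariate (a one-edit counter
is provided for synthetic work only). And MaFI is a property of a
word-in-a-recording: norms generalize across speakers only to the extent
the cross-variant correlation analysis supports.
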