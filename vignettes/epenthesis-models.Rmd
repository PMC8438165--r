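---
title: "Modeling illusory vowel epenthesis from surface phonotactics and the lexicon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling illusory vowel epenthesis from surface phonotactics and the lexicon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(epenthr)
```

## The problem

Listeners of languages with strict CV phonotactics routinely report hearing
a vowel inside a consonant cluster that contains none — Japanese listeners
hear [ebzo] as [ebuzo]. Three mechanisms have been proposed to pick the
illusory vowel: phonetic minimality (the shortest vowel), phonotactic
predictability (the vowel most expected after the preceding consonant), and
phonological alternations (the vowel that most often alternates with zero
in the lexicon). Japanese is the interesting test case because its
high-vowel devoicing process routinely produces genuine surface clusters:
short [i, u] lose phonation between voiceless consonants and sometimes
leave no acoustic trace at all, i.e. they delete.

This package implements the computational side of that research program as
a reproducible pipeline over phone-level annotated corpora: a phonotactic
constraint learner, a conditional-surprisal model, a lexicon builder with
an alternation learner, and a synthetic corpus generator with recountable
ground truth that stands in for restricted speech corpora.

## Data model and pre-processing

A corpus (`read_corpus()`, `write_corpus()`) is a sequence of intonational
phrases; each phrase holds word tokens with an orthography identifier, a
syntactic category and a surface phone sequence. Phonotactic learning uses
only the unsegmented phrase-level phone stream (`phone_streams()`); the
lexical modules additionally use the word annotations. The surface vowel
inventory crosses five qualities with voicing and length, giving 20 vowel
types (`phone_inventory()`): devoiced vowels are *distinct surface
segments*, not annotations, so that devoicing is something the models can
learn rather than presuppose.

Two pre-processing transforms mirror how such corpora are prepared:

* `collapse_palatalization()` merges coarticulatory ("phonetic")
  palatalization annotations into the corresponding phonologically
  palatalized consonant. Phonetically palatalized consonants occur almost
  only before [i, iː], so keeping them distinct gives them degenerate
  near-zero-surprisal distributions that no naive listener could be
  expected to track.
* `apply_deletion()` removes each devoiced vowel independently with
  probability `rate` (default 0.10), emulating deletion that transcribers
  systematically do not mark. The deletion stream visits devoiced tokens
  in corpus order under a caller-supplied seed, so results are exactly
  reproducible. Deleted vowels leave no placeholder. Whether long devoiced
  vowels are eligible is a switch (`include_long`, default `TRUE`): corpus
  annotation practice does not settle the question, so the same rate is
  applied to all devoiced vowels by default.

Placeless codas N and Q are carried verbatim: their surface place is fully
predictable from the following segment, and they are never deletion or
collapse targets.

## Phonotactic learning from observed/expected ratios

Over the unsegmented phrase streams, `count_biphones()` tallies every
ordered pair of adjacent segments (pairs never span phrases). For a
biphone *xy* the observed/expected ratio divides its observed probability
by the product of its two positional marginals,

$$\mathrm{O/E}(xy) = \frac{\Pr(xy)}{\sum\Pr(xY)\,\sum\Pr(Xy)},$$

which is 1 exactly when the two positions combine independently.
`induce_constraints()` turns ratios into constraints: O/E strictly below
`theta_under` (default 0.75) induces a markedness constraint (the biphone
needs repair), strictly above `theta_over` (default 1.25) a Contiguity
constraint (keep it intact); constraint strength is the biphone's expected
probability. Numerical conventions worth stating:

* Inequalities are strict; a ratio exactly at a threshold induces nothing.
* No smoothing: an unobserved biphone has O/E 0 — and a markedness
  constraint — only when both marginals are positive; otherwise its
  expectation is undefined and it is excluded.
* Boundary symbols participate when streams carry them
  (`with_boundaries = TRUE`), so consonant–boundary biphones can be
  evaluated. The boundary used is the intonational-phrase edge, since at
  this stage speech is unsegmented; a word-level boundary mode would
  presuppose the segmentation the learner is meant to deliver, so it is
  available only by building streams from single-word phrases.
* Report ordering (`constraint_report()`) is by descending strength with
  lexicographic `(x, y)` tie-breaks.

## Conditional surprisal of successors

`successor_distribution()` estimates, from the same adjacency counts, the
distribution of the next segment given the current one, and
`surprisal()` returns $-\log_2 \Pr(\mathrm{successor} \mid
\mathrm{context})$ in bits. Two modeling commitments matter:

* The successor set is *unrestricted* — consonants, vowels, boundary.
  Ranking epenthetic-vowel candidates (`rank_vowel_candidates()`) filters
  to vowels but does **not** renormalize: the probability of a vowel is
  its raw share among all successors. Restricting the candidate set a
  priori is precisely the analytic assumption the model avoids.
* Unobserved successors in an observed context have no finite surprisal
  and are reported as `NA` ("absent"), never as a pseudo-count number.

`smoothing_report()` quantifies why epenthesis pays: for a cluster
C1C2 it compares the direct surprisal s(C2|C1) against the path
s(v|C1) + s(C2|v) through an epenthesized vowel, flagging whether the path
sum is lower. Both components and the sum are reported; no single scalar
is privileged, since the perceptual claim concerns the smoothing of the
surprisal peak, not a particular aggregation.

## The lexicon and alternation learning

`build_lexicon()` keys entries by (orthography identifier, syntactic
category) — a meaning proxy — and counts every distinct surface phone
sequence per entry. Homophones with different keys never merge; words
emptied entirely by deletion are skipped with a warning rather than stored
as zero-length forms.

`diff_ops()` aligns an entry's baseline (most frequent) form with each
alternate by recursively taking the longest contiguous matching block
(earliest block on ties) and reads off per-segment `equal` / `replace` /
`delete` / `insert` operations that transform the *alternate into the
baseline* — so a vowel missing from a deleted variant surfaces as a
nothing-to-vowel insertion. Multi-segment mismatch stretches are
decomposed positionally into single-segment operations, overhang becoming
insertions or deletions, because operation surprisal is defined over
single segments. `contextualize_ops()` conditions each operation on the
baseline segment preceding its site (word boundary for site 1); the
context is read from the baseline side of the alignment.

`collect_operations()` weights each comparison's operations by the
alternate's token count, compares the baseline (and every non-alternating
word) to itself weighted by its own count, and — when an alternate ties
the baseline in frequency — runs the comparison in both directions at half
weight each, preserving total weight mass while giving equally probable
forms equal standing. Operation surprisal (`op_surprisal()`) normalizes
per context over *all* observed operation signatures, equal operations and
self-comparisons included: the keep-equal bias of a mostly
non-alternating lexicon is part of the distribution being learned, and it
is what makes vowel deletion itself a high-surprisal operation. A switch
for excluding self-comparisons from the denominator was considered and
rejected: the learned bias toward faithfulness is the empirical content of
the weighting scheme, not a nuisance term.

`zero_to_vowel_report()` ranks, per consonant context, the insertion
signatures with the lowest surprisal; contexts without any insertion get
dash rows.

## The synthetic generator and what it emulates

`generate_corpus()` draws a lexicon of CV(ː)-structured word types with
fixed underlying forms, assembles phrases from token draws, devoices
eligible short high vowels, deletes devoiced vowels, and returns the
corpus together with ground truth: the planted lexicon, the planted
conditional vowel-quality distributions, per-context devoicing/deletion
tallies, and the consonant-consonant biphone types that exist only because
of deletion. `recount_ground_truth()` re-derives the tallies from the
corpus and reports any mismatch.

Default study conditions, chosen once:

* `deletion_rate = 0.10` — the pre-processing convention for devoiced
  vowels; 0.30 is the documented sensitivity alternative.
* `devoicing_rate = 0.9` — high-vowel devoicing between voiceless
  consonants is near-categorical in spontaneous Japanese; a rate short of
  1 leaves the voiced variants that alternation learning needs.
* Eligibility: short [i, u] after a voiceless consonant, followed by a
  voiceless consonant or the phrase edge. Phrase-final devoicing (as in
  the formal copula) is included so consonant–boundary alternation
  contexts exist. Long vowels are never devoiced by the generator.
* 25,000 phrases at 2–6 words each (~10^5 word tokens) and 3,000 word
  types — the type/token ratio of a densely annotated spontaneous-speech
  core corpus, scaled to desk size.
* Palatalized consonants draw vowels from an [i]-biased distribution
  (0.70); plain consonants from context distributions whose modal vowel
  differs by consonant (u after k/s, o after t, e after d, a after h),
  echoing the attested asymmetries the learners should recover.
* `homophony_rate = 0.03` plants form-identical lexemes under distinct
  keys, exercising homophone separation.
* Token frequencies are sub-Zipfian (`zipf_exponent = 0.5`). With a full
  Zipf profile over 3,000 types, the handful of top types carries so much
  weight that the token-weighted vowel distribution after a consonant is
  effectively a draw of a few dozen lexical items, and its mode need not
  match the planted distribution at all. Since the generator's purpose is
  ground-truth recovery — the planted conditional distributions must be
  what a consistent learner estimates from the corpus — the frequency
  profile is flattened until token-weighted estimates are faithful to the
  planted lexicon-wide regularities. The cost is realism about
  function-word dominance, noted under limitations.

Word forms are fixed per type, so devoicing and deletion create true
surface alternations of the same lexeme — the structure alternation
learning requires — rather than independent per-token resamplings.

## Verification strategy and problem sizes

The test suite checks, among others:

* exact agreement of O/E and conditional surprisal with brute-force
  enumeration, exhaustively for every stream of length ≤ 6 over a
  four-symbol alphabet plus a seeded sample of lengths 7–12;
* convergence of all well-sampled O/E ratios to 1 (within ±0.1) on an
  i.i.d. phone corpus of 10^6 segments, where independence holds by
  construction;
* reconstruction of the baseline from 10^4 random edit scripts;
* recovery on the default synthetic corpus: every deletion-created
  cluster with true O/E below 0.75 is flagged as marked; the
  lowest-surprisal vowel *quality* per well-sampled context matches the
  planted mode (quality, because devoicing deliberately splits a
  quality's probability mass across voiced/devoiced/long surface labels —
  the same splitting that makes devoiced vowels top candidates after
  voiceless fricatives in real corpora); and the lowest-surprisal
  nothing-to-vowel insertion after each voiceless consonant is the
  devoiced variant of that context's planted high vowel, while deletion
  operations are never the most expected operation anywhere.

Deletion-rate estimation uses a corpus with at least 10^5 devoiced tokens
and a three-binomial-standard-error band. These sizes keep the full suite
in the minutes range on a single core while leaving the statistical checks
well-powered.

## A worked run

```{r}
gen <- generate_corpus(synthetic_config(n_word_types = 300, n_phrases = 800))
streams <- phone_streams(gen$corpus, with_boundaries = TRUE)
bt <- count_biphones(streams)
rep <- constraint_report(induce_constraints(bt), k = 3)
rep$markedness[, c("kind", "x", "y", "strength", "oe")]
```

```{r}
d <- successor_distribution(phone_streams(gen$corpus))
rank_vowel_candidates(d, "sh", k = 3)
```

```{r}
lex <- build_lexicon(gen$corpus)
at <- collect_operations(lex)
head(zero_to_vowel_report(at, k = 3), 8)
```

`run_pipeline()` chains all stages over one configuration and writes a
TSV per stage plus a manifest with a configuration hash; a thin
command-line wrapper ships in `inst/scripts/epenthesis-lab.R`.

## Limitations

* The generator makes no attempt at phonetic realism (no durations,
  spectra, pitch accent, or loanword strata) and flattens the
  token-frequency profile of natural speech; passing recovery tests shows
  the learners are consistent estimators under the planted process, not
  that real-corpus estimates are unbiased.
* Constraint induction and surprisal share one estimation of adjacency
  counts; conclusions about their divergence on real data (where the two
  analyses weight contexts differently) are outside what the synthetic
  checks can show.
* The alternation learner conditions on the single preceding segment
  only; no feature-based generalization across contexts is attempted, so
  contexts with no observed alternation stay empty (dash rows) rather
  than inheriting from similar consonants.
* Homophone separation relies on the orthography identifier as a meaning
  proxy; genuinely ambiguous orthography collapses meanings just as it
  would for a corpus-based learner.
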