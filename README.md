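# epenthr

Information-theoretic models of illusory vowel epenthesis.

Listeners of strict-CV languages perceive vowels inside consonant clusters
that contain none: Japanese listeners hear [ebzo] as [ebuzo]. Which vowel
gets hallucinated has been attributed to three kinds of knowledge — the
phonetically shortest vowel, the phonotactically most predictable vowel in
that context, and the vowel that most often alternates with zero in the
lexicon. Japanese sharpens the puzzle because high-vowel devoicing between
voiceless consonants routinely *creates* surface clusters, sometimes
deleting the vowel outright. `epenthr` implements the computational side
of this research program for phone-level annotated speech corpora, aimed
at phonologists and psycholinguists who want each mechanism as a testable,
reproducible model.

The package provides:

* **Corpus I/O and pre-processing** — a JSON-Lines phrase/word/phone
  dialect with a 20-vowel surface inventory (quality × voicing × length;
  devoiced vowels are segment types of their own), palatalization
  collapse, and probabilistic deletion of devoiced vowels (default rate
  0.10).
* **Phonotactic constraint induction** — biphone counting over
  unsegmented intonational phrases and observed/expected ratios

  O/E(xy) = Pr(xy) / (ΣPr(xY) · ΣPr(Xy)),

  with markedness constraints induced strictly below O/E 0.75 and
  Contiguity constraints strictly above 1.25, strength = E(xy).
* **Conditional surprisal** — s(y|x) = −log₂ Pr(y|x) in bits over
  unrestricted successor sets, per-context epenthetic-vowel rankings, and
  the cluster-smoothing comparison s(C2|C1) vs. s(v|C1) + s(C2|v).
* **Lexicon building and alternation learning** — (orthography, category)
  keyed surface-form counts; longest-matching-block edit operations that
  transform each alternate into its baseline (so vowel–zero alternations
  surface as ∅→v insertions), frequency-weighted, conditioned on the
  preceding segment, with operation surprisal −log₂ Pr(op | context).
* **A synthetic corpus generator** with recountable ground truth
  (planted lexicon, conditional vowel distributions, devoicing/deletion
  tallies, deletion-created cluster types), standing in for restricted
  corpora.
* **A pipeline driver** (`run_pipeline()`, plus a thin CLI wrapper in
  `inst/scripts/epenthesis-lab.R`) that runs every stage on the same
  pre-processed corpus and writes per-stage TSVs and a manifest.

## Worked example

```r
library(epenthr)

gen <- generate_corpus(synthetic_config(n_word_types = 300, n_phrases = 800))
d   <- successor_distribution(phone_streams(gen$corpus))

rank_vowel_candidates(d, "sh", k = 3)
#>   context successor count     pr bits
#> 1      sh         i   139 0.4041 1.31
#> 2      sh        i0    74 0.2151 2.22
#> 3      sh        i:    33 0.0959 3.38
```

After the palatalized fricative `sh`, the three lowest-surprisal vowels
are all front high — voiced [i] at 1.31 bits, devoiced [i°] at 2.22 —
recovering the planted [i]-bias of palatalized consonants: a listener
relying on phonotactic predictability would epenthesize [i] here, not the
language-wide default [u].

```r
smoothing_report(d, "k", "t", "u0")
#> direct C1->C2 surprisal: 8.235 bits
#> epenthetic path: s(v|C1) = 2.489 + s(C2|v) = 1.685 = 4.175 bits
#> smoothing: yes
```

The cluster [kt] exists in this corpus only where a devoiced vowel
deleted, so the direct transition costs 8.2 bits; inserting [u°] smooths
the peak to 4.2 bits even summing both steps — the information-theoretic
rationale for perceptual repair.

```r
lex <- build_lexicon(gen$corpus)
at  <- collect_operations(lex)
head(zero_to_vowel_report(at, k = 3), 6)
#>   context rank vowel weight bits
#> 1       b   NA  <NA>     NA   NA
#> 2       C    1    i0    1.0 6.00
#> 3       C    2    u0    1.0 6.00
#> 4      ch    1    i0    5.5 5.00
#> 5      ch    2     i    2.0 6.46
#> 6      ch    3    u0    2.0 6.46
```

The alternation learner finds nothing-to-vowel insertions only after
voiceless consonants (dash rows elsewhere, e.g. after [b]), and after the
palatalized [ʧ] the most expected insertion is the devoiced [i°] — the
vowel that actually alternates with zero there.

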