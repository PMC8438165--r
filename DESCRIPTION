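Package: epenthr
Title: Information-Theoretic Models of Illusory Vowel Epenthesis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how listeners come to perceive illusory
    vowels inside phonotactically illegal consonant clusters, using
    Japanese high-vowel devoicing and deletion as the model system.
    Implements three learners over phone-level annotated speech corpora:
    a phonotactic constraint inducer based on observed/expected ratios of
    adjacent segment pairs over unsegmented intonational phrases, a
    conditional-surprisal model that ranks epenthetic-vowel candidates
    per consonant context, and a lexicon-driven alternation learner that
    mines frequency-weighted edit operations between surface forms of
    the same lexeme. A synthetic corpus generator with recountable
    ground truth stands in for restricted speech corpora, and a pipeline
    driver orchestrates all stages with reproducible seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
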