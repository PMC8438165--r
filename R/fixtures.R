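#' Toy lexicon corpus
#'
#' Builds, in code, the small corpus whose lexicon illustrates
#' meaning-keyed surface-form counting: three homophonous words — a verb
#' "did", a noun "down" and a noun "tongue", all surfacing as \[ʃi°ta\] /
#' \[ʃta\] / \[ʃita\] variants — plus two fully homophonous lexemes sharing
#' the orthography `aru` ("exists", a verb, and "a certain...", an
#' adjective) that only their syntactic category distinguishes. Surface
#' multiplicities: did 7/2/1, down 4/1, tongue 1/1, exists 10,
#' a-certain 5. Each token occupies its own one-word phrase.
#'
#' A pre-rendered copy ships at
#' `system.file("extdata", "toy_lexicon_table3.jsonl", package = "epenthr")`.
#'
#' @param inventory Phone inventory.
#' @return An `ep_corpus` of 32 one-word phrases.
#' @export
toy_lexicon_corpus <- function(inventory = phone_inventory()) {
  spec <- list(
    list(orth = "did", pos = "Verb",
         forms = list(list(c("sh", "i0", "t", "a"), 7L),
                      list(c("sh", "t", "a"), 2L),
                      list(c("sh", "i", "t", "a"), 1L))),
    list(orth = "down", pos = "Noun",
         forms = list(list(c("sh", "i0", "t", "a"), 4L),
                      list(c("sh", "i", "t", "a"), 1L))),
    list(orth = "tongue", pos = "Noun",
         forms = list(list(c("sh", "i0", "t", "a"), 1L),
                      list(c("sh", "t", "a"), 1L))),
    list(orth = "aru", pos = "Verb",
         forms = list(list(c("a", "r", "u"), 10L))),
    list(orth = "aru", pos = "Adjective",
         forms = list(list(c("a", "r", "u"), 5L))))
  phrases <- list()
  for (entry in spec)
    for (fm in entry$forms)
      for (i in seq_len(fm[[2]]))
        phrases[[length(phrases) + 1L]] <-
          phrase(sprintf("toy%03d", length(phrases) + 1L),
                 list(word_token(entry$orth, entry$pos, fm[[1]])))
  corpus(phrases, inventory)
}
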