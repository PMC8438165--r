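# Small corpus builders shared across test files.

`%||%` <- function(x, y) if (is.null(x)) y else x

mk_corpus <- function(...) {
  phone_seqs <- list(...)
  phrases <- lapply(seq_along(phone_seqs), function(i) {
    words <- lapply(phone_seqs[[i]], function(ph)
      word_token(paste(ph, collapse = ""), "Noun", ph))
    phrase(sprintf("p%03d", i), words)
  })
  corpus(phrases)
}

# corpus with `n` devoiced high vowels in su0-words
mk_devoiced_corpus <- function(n_words, per_phrase = 50L) {
  w <- word_token("su", "Noun", c("s", "u0"))
  n_phr <- ceiling(n_words / per_phrase)
  phrases <- lapply(seq_len(n_phr), function(i)
    phrase(sprintf("p%05d", i), rep(list(w), per_phrase)))
  corpus(phrases)
}

label_counts <- function(corpus) {
  streams <- phone_streams(corpus)
  table(unlist(streams))
}
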