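#' Corpus containers
#'
#' A corpus is an ordered sequence of intonational phrases; each phrase is an
#' ordered sequence of word tokens; each word token carries an orthography
#' identifier (a stand-in for the orthographic form), a syntactic-category
#' label, and its ordered surface phone labels. Phonotactic learning operates
#' on the unsegmented phrase-level phone stream; the lexicon modules use the
#' word-level annotations.
#'
#' @param orth_id Orthography identifier.
#' @param pos Syntactic-category label.
#' @param phones Character vector of phone labels (non-empty, no boundary).
#' @return `word_token`/`phrase`/`corpus` return objects of the
#'   corresponding class.
#' @export
word_token <- function(orth_id, pos, phones) {
  stopifnot(is.character(phones))
  structure(list(orth_id = orth_id, pos = pos, phones = phones),
            class = "ep_word")
}

#' @rdname word_token
#' @param phrase_id Phrase identifier.
#' @param words List of word tokens.
#' @export
phrase <- function(phrase_id, words) {
  structure(list(phrase_id = phrase_id, words = words), class = "ep_phrase")
}

#' @rdname word_token
#' @param phrases List of phrases.
#' @param inventory Phone inventory data frame; see [phone_inventory()].
#' @export
corpus <- function(phrases, inventory = phone_inventory()) {
  structure(list(phrases = phrases, inventory = inventory),
            class = "ep_corpus")
}

#' @export
print.ep_corpus <- function(x, ...) {
  fl <- corpus_flatten(x)
  cat("<ep_corpus> ", length(x$phrases), " phrases, ",
      length(fl$orth_id), " word tokens, ", length(fl$labels),
      " phones, inventory of ", nrow(x$inventory), " labels\n", sep = "")
  invisible(x)
}

# Flat view: all phone labels in corpus order plus the run-length structure
# needed to rebuild the nesting. Internal work-horse for the transforms and
# the synthetic generator.
corpus_flatten <- function(corpus) {
  phr <- corpus$phrases
  words <- unlist(lapply(phr, `[[`, "words"), recursive = FALSE)
  n_words <- vapply(phr, function(p) length(p$words), integer(1))
  labels <- unlist(lapply(words, `[[`, "phones"), use.names = FALSE)
  n_phones <- vapply(words, function(w) length(w$phones), integer(1))
  list(labels = labels,
       n_phones = n_phones,
       n_words = n_words,
       orth_id = vapply(words, `[[`, character(1), "orth_id"),
       pos = vapply(words, `[[`, character(1), "pos"),
       phrase_id = vapply(phr, `[[`, character(1), "phrase_id"))
}

corpus_unflatten <- function(fl, inventory) {
  nw <- length(fl$n_phones)
  word_of_phone <- rep.int(seq_len(nw), fl$n_phones)
  phones_by_word <- split(fl$labels, factor(word_of_phone, levels = seq_len(nw)))
  words <- mapply(function(o, p, ph) {
    structure(list(orth_id = o, pos = p, phones = as.character(ph)),
              class = "ep_word")
  }, fl$orth_id, fl$pos, phones_by_word, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  np <- length(fl$n_words)
  phrase_of_word <- rep.int(seq_len(np), fl$n_words)
  words_by_phrase <- split(words, factor(phrase_of_word, levels = seq_len(np)))
  phrases <- mapply(function(id, ws) {
    structure(list(phrase_id = id, words = ws), class = "ep_phrase")
  }, fl$phrase_id, words_by_phrase, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  corpus(phrases, inventory)
}

validate_corpus <- function(corpus, allow_empty_words = FALSE) {
  fl <- corpus_flatten(corpus)
  unknown <- setdiff(unique(fl$labels), corpus$inventory$label)
  if (length(unknown) > 0)
    stop("unknown phone label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  bound <- corpus$inventory$label[corpus$inventory$kind == "boundary"]
  if (any(fl$labels %in% bound))
    stop("boundary phones may not appear inside phrases", call. = FALSE)
  if (!allow_empty_words && any(fl$n_phones == 0L))
    stop("word token with empty phone sequence", call. = FALSE)
  if (any(fl$n_words == 0L))
    stop("phrase with no words", call. = FALSE)
  invisible(corpus)
}

#' Read and write corpora
#'
#' The on-disk dialect is JSON Lines: one phrase per line, of the form
#' `{"phrase_id": str, "words": [{"orth_id": str, "pos": str,
#' "phones": [str, ...]}]}`. Reading validates every phone label against the
#' inventory and reports the offending line and field on malformed input;
#' `write_corpus(read_corpus(f))` is byte-identical to `f` for files written
#' by `write_corpus`.
#'
#' @param path File path.
#' @param inventory Phone inventory the labels must belong to.
#' @return `read_corpus` returns an `ep_corpus`.
#' @export
read_corpus <- function(path, inventory = phone_inventory()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  phrases <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE,
                         simplifyDataFrame = FALSE, simplifyMatrix = FALSE),
      error = function(e) stop("line ", i, ": malformed JSON (",
                               conditionMessage(e), ")", call. = FALSE))
    for (f in c("phrase_id", "words"))
      if (is.null(rec[[f]]))
        stop("line ", i, ": missing field '", f, "'", call. = FALSE)
    words <- lapply(seq_along(rec$words), function(j) {
      w <- rec$words[[j]]
      for (f in c("orth_id", "pos", "phones"))
        if (is.null(w[[f]]))
          stop("line ", i, ", word ", j, ": missing field '", f, "'",
               call. = FALSE)
      word_token(w$orth_id, w$pos, as.character(unlist(w$phones)))
    })
    phrases[[i]] <- phrase(rec$phrase_id, words)
  }
  validate_corpus(corpus(phrases, inventory))
}

#' @rdname read_corpus
#' @param corpus An `ep_corpus`.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(corpus$phrases, function(p) {
    rec <- list(
      phrase_id = p$phrase_id,
      words = lapply(p$words, function(w)
        list(orth_id = w$orth_id, pos = w$pos, phones = I(w$phones))))
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Collapse phonetic palatalization
#'
#' Speech corpora sometimes annotate coarticulatory ("phonetic")
#' palatalization of coronal and dorsal consonants before high front vowels
#' separately from contrastive ("phonological") palatalization. On the
#' surface the two are not meaningfully distinct to a listener without a
#' lexicon, and because phonetically palatalized consonants occur almost
#' exclusively before \[i, i:\], keeping them separate gives them degenerate,
#' near-zero-surprisal successor distributions. This transform relabels each
#' phonetically palatalized consonant to its phonologically palatalized
#' counterpart and drops the phonetic labels from the inventory.
#'
#' @param corpus An `ep_corpus`.
#' @return The relabelled corpus; total phone count is conserved.
#' @export
collapse_palatalization <- function(corpus) {
  inv <- corpus$inventory
  phonetic <- !is.na(inv$palatal_source) & inv$palatal_source == "phonetic"
  if (!any(phonetic)) return(corpus)
  map <- inv$counterpart[phonetic]
  names(map) <- inv$label[phonetic]
  missing <- is.na(map) | !(map %in% inv$label)
  if (any(missing))
    stop("phonetically palatalized consonant(s) with no phonological ",
         "counterpart: ", paste(names(map)[missing], collapse = ", "),
         call. = FALSE)
  fl <- corpus_flatten(corpus)
  hit <- fl$labels %in% names(map)
  fl$labels[hit] <- unname(map[fl$labels[hit]])
  corpus_unflatten(fl, inv[!phonetic, , drop = FALSE])
}

#' Delete devoiced vowels probabilistically
#'
#' Devoiced vowels often leave no acoustic or articulatory trace, but
#' phone-level transcriptions systematically retain them. This transform
#' removes each devoiced vowel token independently with probability `rate`,
#' emulating surface deletion before any counting or lexicon building.
#' Deleted vowels leave no placeholder. The pseudorandom stream visits
#' devoiced-vowel tokens in corpus order, so the same `(corpus, rate, seed)`
#' always yields the same output.
#'
#' @param corpus An `ep_corpus`.
#' @param rate Deletion probability in \[0, 1\].
#' @param seed Integer seed for the deletion stream.
#' @param include_long Should long devoiced vowels also be eligible?
#'   Defaults to `TRUE` (same rate for all devoiced vowels).
#' @return The corpus with some devoiced vowels removed. Words whose phones
#'   were all deleted remain as empty word tokens (downstream lexicon
#'   building skips them). Attributes `n_candidates` and `n_deleted` record
#'   the number of eligible and removed tokens.
#' @export
apply_deletion <- function(corpus, rate = 0.10, seed = 1L,
                           include_long = TRUE) {
  if (!is.numeric(rate) || length(rate) != 1 || is.na(rate) ||
      rate < 0 || rate > 1)
    stop("rate must be a probability in [0, 1]", call. = FALSE)
  inv <- corpus$inventory
  dev <- inv$label[inv$kind == "vowel" & inv$voicing == "devoiced" &
                     (include_long | inv$length == "short")]
  fl <- corpus_flatten(corpus)
  cand <- fl$labels %in% dev
  n_cand <- sum(cand)
  drop <- logical(length(fl$labels))
  if (n_cand > 0 && rate > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
    drop[cand] <- stats::runif(n_cand) < rate
  }
  keep <- !drop
  word_of_phone <- rep.int(seq_along(fl$n_phones), fl$n_phones)
  fl$n_phones <- tabulate(word_of_phone[keep], nbins = length(fl$n_phones))
  fl$labels <- fl$labels[keep]
  out <- corpus_unflatten(fl, inv)
  attr(out, "n_candidates") <- n_cand
  attr(out, "n_deleted") <- sum(drop)
  out
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Phrase-level phone streams
#'
#' Concatenates each phrase's word phone sequences into a single unsegmented
#' stream — the unit over which phonotactic statistics are computed. Word
#' boundaries are never exposed; if `with_boundaries`, a single boundary
#' label is prepended and appended to each phrase stream.
#'
#' @param corpus An `ep_corpus`.
#' @param with_boundaries Add a boundary label at both phrase edges?
#' @param boundary The boundary label.
#' @return A list of character vectors, one per phrase, in corpus order.
#' @export
phone_streams <- function(corpus, with_boundaries = FALSE, boundary = "#") {
  fl <- corpus_flatten(corpus)
  np <- length(fl$n_words)
  if (np == 0) return(list())
  phrase_of_word <- rep.int(seq_len(np), fl$n_words)
  phones_per_phrase <- as.integer(
    rowsum(fl$n_phones, phrase_of_word, reorder = FALSE))
  phrase_of_phone <- rep.int(seq_len(np), phones_per_phrase)
  streams <- split(fl$labels, factor(phrase_of_phone, levels = seq_len(np)))
  streams <- unname(lapply(streams, as.character))
  if (with_boundaries)
    streams <- lapply(streams, function(s) c(boundary, s, boundary))
  streams
}
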