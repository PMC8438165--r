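#' Build a surface-form lexicon
#'
#' Simulates meaning-based lexical learning: each distinct combination of
#' orthography identifier and syntactic category is one lexeme (homophones
#' with different orthography or category stay separate), and every distinct
#' surface phone sequence of that lexeme gets its own token count. The
#' corpus should already be pre-processed (palatalization collapsed,
#' devoiced-vowel deletion applied) so that the lexicon records genuine
#' surface variation, e.g. \[sh i0 t a\] ~ \[sh t a\] ~ \[sh i t a\] for one
#' verb.
#'
#' Word tokens whose phone sequence was emptied by deletion are skipped with
#' a warning; they are counted in the `n_skipped` field.
#'
#' @param corpus A pre-processed `ep_corpus`.
#' @return An `ep_lexicon`: a list with `entries` (named list of entries,
#'   each with `orth_id`, `pos`, `gloss` and a named integer vector `forms`
#'   mapping space-joined phone labels to token counts) and `n_skipped`.
#' @export
build_lexicon <- function(corpus) {
  fl <- corpus_flatten(corpus)
  nw <- length(fl$orth_id)
  word_of_phone <- rep.int(seq_len(nw), fl$n_phones)
  forms <- vapply(split(fl$labels, factor(word_of_phone, levels = seq_len(nw))),
                  paste, character(1), collapse = " ")
  empty <- fl$n_phones == 0L
  n_skipped <- sum(empty)
  if (n_skipped > 0)
    warning(n_skipped, " word token(s) with empty phone sequence skipped",
            call. = FALSE)
  keys <- paste(fl$orth_id, fl$pos, sep = "\x1f")[!empty]
  forms <- forms[!empty]
  orth <- fl$orth_id[!empty]
  pos <- fl$pos[!empty]
  first <- !duplicated(keys)
  key_levels <- keys[first]
  entries <- mapply(function(o, p, fs) {
    tab <- table(fs)
    list(orth_id = o, pos = p, gloss = NA_character_,
         forms = stats::setNames(as.integer(tab), names(tab)))
  }, orth[first], pos[first],
    split(forms, factor(keys, levels = key_levels)),
    SIMPLIFY = FALSE)
  names(entries) <- key_levels
  structure(list(entries = entries, n_skipped = n_skipped),
            class = "ep_lexicon")
}

#' @export
print.ep_lexicon <- function(x, ...) {
  vs <- variation_summary(x)
  cat("<ep_lexicon> ", vs[["n_entries"]], " entries (",
      vs[["n_multiform"]], " with multiple surface forms), ",
      sum(vapply(x$entries, function(e) sum(e$forms), integer(1))),
      " tokens\n", sep = "")
  invisible(x)
}

#' Baseline (most frequent) surface form of an entry
#'
#' The baseline form anchors alternation learning: it is the surface form
#' with the highest token count. When several forms tie for the maximum,
#' all are returned in `tied_forms` (lexicographic order); a tie signals
#' that alternation extraction should run in both directions so that no
#' accidental ordering bias enters the learned statistics.
#'
#' @param entry A lexicon entry (element of `lexicon$entries`).
#' @return A list with `form` (first tied form in lexicographic order),
#'   `count`, and `tied_forms`.
#' @export
baseline_form <- function(entry) {
  if (length(entry$forms) == 0) stop("entry has no forms", call. = FALSE)
  m <- max(entry$forms)
  tied <- sort(names(entry$forms)[entry$forms == m])
  list(form = tied[1], count = unname(m), tied_forms = tied)
}

#' Lexicon variation summary
#'
#' @param lexicon An `ep_lexicon`.
#' @return A named integer vector: `n_entries` (distinct lexemes) and
#'   `n_multiform` (lexemes with more than one surface form).
#' @export
variation_summary <- function(lexicon) {
  n_forms <- vapply(lexicon$entries, function(e) length(e$forms), integer(1))
  c(n_entries = length(n_forms), n_multiform = sum(n_forms > 1L))
}

#' Tabulate a lexicon
#'
#' @param lexicon An `ep_lexicon`.
#' @return A data frame `(orth_id, pos, form, count)`, one row per surface
#'   form of each entry.
#' @export
lexicon_table <- function(lexicon) {
  rows <- lapply(lexicon$entries, function(e) {
    data.frame(orth_id = e$orth_id, pos = e$pos,
               form = names(e$forms), count = unname(e$forms),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$orth_id, out$pos, -out$count, out$form), , drop = FALSE]
}
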