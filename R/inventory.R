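#' Surface phone inventory
#'
#' Builds the default surface segment inventory used throughout the package.
#' Segments fall into four kinds: consonants, vowels, placeless codas and the
#' phrase/word boundary symbol. The vowel sub-inventory crosses five qualities
#' (a, e, i, o, u) with voicing (voiced vs. devoiced) and length (short vs.
#' long), giving 20 surface vowels. Devoiced vowels are genuine surface
#' segment types here, not annotations on their voiced counterparts: keeping
#' them distinct is what lets the downstream models learn devoicing rather
#' than presuppose it.
#'
#' Labels are ASCII-safe. Vowels are written as quality plus an optional `0`
#' (devoiced) and an optional `:` (long), e.g. `u`, `u0`, `u:`, `u0:`.
#' Palatalized consonants carry their own labels (`sh`, `ch`, `jh`, `C`,
#' `py`, `ky`, `by`, `gy`, `tj`, `dj`, `Fj`); `F` is the bilabial fricative,
#' `C` the palatal fricative, `B` the bilabial approximant. The moraic nasal
#' `N` and the geminate first-half `Q` are placeless codas whose surface
#' place is fully predictable from the following segment; they are carried
#' verbatim and never participate in deletion or palatalization collapse.
#' `#` is the boundary symbol.
#'
#' Pre-collapse corpora may additionally contain *phonetically* palatalized
#' consonants (coarticulatory palatalization before high front vowels),
#' labelled with a `_j` suffix (`s_j`, `t_j`, `d_j`, `k_j`, `g_j`, `h_j`).
#' Each names its *phonologically* palatalized counterpart in the
#' `counterpart` column; [collapse_palatalization()] merges the two.
#'
#' @return A data frame with one row per segment and columns `label`,
#'   `kind` (`"consonant"`, `"vowel"`, `"placeless_coda"`, `"boundary"`),
#'   `quality`, `voicing`, `length` (vowels only), `palatalized`,
#'   `palatal_source` (`"none"`, `"phonetic"`, `"phonological"`),
#'   `counterpart` (phonetic-palatalized consonants only) and `voiceless`
#'   (consonants only).
#' @export
#' @examples
#' inv <- phone_inventory()
#' sum(inv$kind == "vowel")  # 20
phone_inventory <- function() {
  qualities <- c("a", "e", "i", "o", "u")
  vow <- expand.grid(quality = qualities,
                     voicing = c("voiced", "devoiced"),
                     length = c("short", "long"),
                     stringsAsFactors = FALSE)
  vow$label <- paste0(vow$quality,
                      ifelse(vow$voicing == "devoiced", "0", ""),
                      ifelse(vow$length == "long", ":", ""))

  plain <- c("p", "t", "k", "b", "d", "g", "ts", "dz", "F", "s", "h",
             "m", "n", "r", "w", "y", "kw", "B")
  pal <- c("sh", "ch", "jh", "C", "py", "ky", "by", "gy", "tj", "dj", "Fj")
  phon_pal <- data.frame(label = c("s_j", "t_j", "d_j", "k_j", "g_j", "h_j"),
                         counterpart = c("sh", "ch", "jh", "ky", "gy", "C"),
                         stringsAsFactors = FALSE)
  voiceless <- c("p", "t", "k", "ts", "s", "sh", "h", "C", "ch", "F",
                 "py", "ky", "tj", "kw", "Fj", "s_j", "t_j", "k_j", "h_j")

  cons <- data.frame(label = c(plain, pal, phon_pal$label),
                     stringsAsFactors = FALSE)
  cons$palatalized <- cons$label %in% c(pal, phon_pal$label)
  cons$palatal_source <- ifelse(cons$label %in% phon_pal$label, "phonetic",
                                ifelse(cons$palatalized, "phonological",
                                       "none"))
  cons$counterpart <- phon_pal$counterpart[match(cons$label, phon_pal$label)]
  cons$voiceless <- cons$label %in% voiceless

  inv <- data.frame(
    label = c(vow$label, cons$label, "N", "Q", "#"),
    kind = c(rep("vowel", nrow(vow)), rep("consonant", nrow(cons)),
             "placeless_coda", "placeless_coda", "boundary"),
    quality = c(vow$quality, rep(NA_character_, nrow(cons) + 3L)),
    voicing = c(vow$voicing, rep(NA_character_, nrow(cons) + 3L)),
    length = c(vow$length, rep(NA_character_, nrow(cons) + 3L)),
    palatalized = c(rep(NA, nrow(vow)), cons$palatalized, NA, NA, NA),
    palatal_source = c(rep(NA_character_, nrow(vow)), cons$palatal_source,
                       NA, NA, NA),
    counterpart = c(rep(NA_character_, nrow(vow)), cons$counterpart,
                    NA, NA, NA),
    voiceless = c(rep(NA, nrow(vow)), cons$voiceless, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  rownames(inv) <- NULL
  inv
}

#' Label subsets of an inventory
#'
#' Convenience selectors over a [phone_inventory()]-shaped data frame.
#'
#' @param inventory A phone inventory data frame.
#' @return A character vector of labels.
#' @export
vowel_labels <- function(inventory = phone_inventory()) {
  inventory$label[inventory$kind == "vowel"]
}

#' @rdname vowel_labels
#' @export
consonant_labels <- function(inventory = phone_inventory()) {
  inventory$label[inventory$kind == "consonant"]
}

#' @rdname vowel_labels
#' @export
devoiced_labels <- function(inventory = phone_inventory()) {
  inventory$label[inventory$kind == "vowel" &
                    inventory$voicing == "devoiced"]
}

#' @rdname vowel_labels
#' @export
voiceless_labels <- function(inventory = phone_inventory()) {
  inventory$label[inventory$kind == "consonant" &
                    !is.na(inventory$voiceless) & inventory$voiceless]
}

#' Vowel quality of a label
#'
#' Strips voicing and length marks from vowel labels; non-vowel labels map
#' to `NA`.
#'
#' @param labels Character vector of phone labels.
#' @param inventory A phone inventory data frame.
#' @return Character vector of qualities (`"a"` ... `"u"`) or `NA`.
#' @export
vowel_quality <- function(labels, inventory = phone_inventory()) {
  inventory$quality[match(labels, inventory$label)]
}

#' Read and write inventory files
#'
#' The on-disk inventory format is a JSON object mapping each label to its
#' attribute set. Validation enforces the kind-specific attribute rules:
#' vowels carry quality/voicing/length and never a palatalization flag;
#' consonants carry palatalization attributes and never vowel attributes.
#'
#' @param path File path.
#' @return For `read_inventory`, an inventory data frame.
#' @export
read_inventory <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- lapply(names(raw), function(lab) {
    a <- raw[[lab]]
    kind <- a$kind %||% stop("inventory entry '", lab, "': missing kind",
                             call. = FALSE)
    if (kind == "vowel") {
      if (!is.null(a$palatalized) || !is.null(a$palatal_source))
        stop("inventory entry '", lab,
             "': vowels may not carry palatalization attributes",
             call. = FALSE)
      if (is.null(a$quality) || is.null(a$voicing) || is.null(a$length))
        stop("inventory entry '", lab,
             "': vowels require quality, voicing and length", call. = FALSE)
    } else {
      if (!is.null(a$quality) || !is.null(a$voicing) || !is.null(a$length))
        stop("inventory entry '", lab,
             "': only vowels carry quality/voicing/length", call. = FALSE)
    }
    data.frame(label = lab, kind = kind,
               quality = a$quality %||% NA_character_,
               voicing = a$voicing %||% NA_character_,
               length = a$length %||% NA_character_,
               palatalized = a$palatalized %||% NA,
               palatal_source = a$palatal_source %||% NA_character_,
               counterpart = a$counterpart %||% NA_character_,
               voiceless = a$voiceless %||% NA,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname read_inventory
#' @param inventory An inventory data frame.
#' @export
write_inventory <- function(inventory, path) {
  entries <- lapply(seq_len(nrow(inventory)), function(i) {
    r <- inventory[i, ]
    e <- list(kind = r$kind)
    if (r$kind == "vowel") {
      e$quality <- r$quality; e$voicing <- r$voicing; e$length <- r$length
    } else if (r$kind == "consonant") {
      e$palatalized <- r$palatalized
      e$palatal_source <- r$palatal_source
      if (!is.na(r$counterpart)) e$counterpart <- r$counterpart
      e$voiceless <- r$voiceless
    }
    e
  })
  names(entries) <- inventory$label
  writeLines(jsonlite::toJSON(entries, auto_unbox = TRUE, pretty = TRUE,
                              na = "null"),
             path)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
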