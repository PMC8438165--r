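#' Edit operations between a baseline and an alternate form
#'
#' Aligns two phone sequences by recursively locating the longest contiguous
#' matching block (earliest block on ties), the classic
#' Ratcliff–Obershelp strategy, and reads off per-segment operations that
#' transform the *alternate* into the *baseline*. With that direction a
#' vowel present in the baseline but missing in the alternate surfaces as an
#' insertion — the nothing-to-vowel alternation that deletion processes
#' create in a lexicon.
#'
#' Non-matching stretches are decomposed into single-segment operations:
#' positions paired off the front become `replace` (or `equal` when the
#' labels coincide); baseline overhang becomes `insert` and alternate
#' overhang becomes `delete`. Applying the operations to the alternate
#' always reconstructs the baseline exactly.
#'
#' @param baseline Character vector of phone labels (non-empty).
#' @param alternate Character vector of phone labels.
#' @return A data frame of class `edit_ops` with columns `kind` (`equal`,
#'   `replace`, `delete`, `insert`), `from` (alternate-side label or `NA`),
#'   `to` (baseline-side label or `NA`) and `site` (1-based baseline
#'   position governing the operation's context), in baseline order.
#' @export
#' @examples
#' diff_ops(c("sh", "i0", "t", "a"), c("sh", "t", "a"))
diff_ops <- function(baseline, alternate) {
  if (length(baseline) == 0) stop("baseline must be non-empty", call. = FALSE)
  blocks <- matching_blocks(alternate, baseline)
  ops <- list()
  ai <- 1L  # next unconsumed alternate position
  bi <- 1L  # next unconsumed baseline position
  emit_gap <- function(a_lo, a_hi, b_lo, b_hi) {
    la <- a_hi - a_lo + 1L
    lb <- b_hi - b_lo + 1L
    k <- min(la, lb)
    out <- list()
    if (k > 0) {
      from <- alternate[a_lo + seq_len(k) - 1L]
      to <- baseline[b_lo + seq_len(k) - 1L]
      out[[length(out) + 1L]] <- data.frame(
        kind = ifelse(from == to, "equal", "replace"),
        from = from, to = to, site = b_lo + seq_len(k) - 1L,
        stringsAsFactors = FALSE)
    }
    if (lb > la) {
      idx <- (b_lo + k):b_hi
      out[[length(out) + 1L]] <- data.frame(
        kind = "insert", from = NA_character_, to = baseline[idx],
        site = idx, stringsAsFactors = FALSE)
    } else if (la > lb) {
      idx <- (a_lo + k):a_hi
      out[[length(out) + 1L]] <- data.frame(
        kind = "delete", from = alternate[idx], to = NA_character_,
        site = rep(b_lo + k, length(idx)), stringsAsFactors = FALSE)
    }
    out
  }
  for (r in seq_len(nrow(blocks))) {
    a0 <- blocks$a[r]; b0 <- blocks$b[r]; sz <- blocks$size[r]
    if (a0 > ai || b0 > bi)
      ops <- c(ops, emit_gap(ai, a0 - 1L, bi, b0 - 1L))
    if (sz > 0) {
      idx <- b0 + seq_len(sz) - 1L
      ops[[length(ops) + 1L]] <- data.frame(
        kind = "equal", from = alternate[a0 + seq_len(sz) - 1L],
        to = baseline[idx], site = idx, stringsAsFactors = FALSE)
    }
    ai <- a0 + sz
    bi <- b0 + sz
  }
  out <- do.call(rbind, c(ops, list(make.row.names = FALSE)))
  class(out) <- c("edit_ops", "data.frame")
  out
}

# Longest contiguous matching blocks between sequences a and b, in order.
# Ties favour the block starting earliest in a, then earliest in b. A final
# zero-size sentinel block at (length(a)+1, length(b)+1) closes the scan.
matching_blocks <- function(a, b) {
  res <- list()
  recurse <- function(alo, ahi, blo, bhi) {
    m <- longest_match(a, b, alo, ahi, blo, bhi)
    if (m$size > 0) {
      recurse(alo, m$a - 1L, blo, m$b - 1L)
      res[[length(res) + 1L]] <<- m
      recurse(m$a + m$size, ahi, m$b + m$size, bhi)
    }
  }
  recurse(1L, length(a), 1L, length(b))
  res[[length(res) + 1L]] <- list(a = length(a) + 1L, b = length(b) + 1L,
                                  size = 0L)
  data.frame(a = vapply(res, `[[`, integer(1), "a"),
             b = vapply(res, `[[`, integer(1), "b"),
             size = vapply(res, `[[`, integer(1), "size"))
}

longest_match <- function(a, b, alo, ahi, blo, bhi) {
  best_a <- alo; best_b <- blo; best_size <- 0L
  if (alo > ahi || blo > bhi)
    return(list(a = best_a, b = best_b, size = best_size))
  b2j <- split(blo:bhi, b[blo:bhi])
  j2len <- integer(0)
  for (i in alo:ahi) {
    newj2len <- integer(0)
    for (j in b2j[[a[i]]] %||% integer(0)) {
      prev_len <- j2len[as.character(j - 1L)]
      k <- (if (length(prev_len) == 1 && !is.na(prev_len))
        unname(prev_len) else 0L) + 1L
      newj2len[as.character(j)] <- k
      if (k > best_size) {
        best_a <- i - k + 1L; best_b <- j - k + 1L; best_size <- k
      }
    }
    j2len <- newj2len
  }
  list(a = best_a, b = best_b, size = best_size)
}

#' Attach preceding-segment contexts to edit operations
#'
#' Each operation is conditioned on the baseline segment immediately
#' preceding its site; operations at the first baseline position get the
#' word-boundary context. The context is read from the baseline side of the
#' alignment (for insertions the preceding aligned segment is shared by both
#' forms, so the choice only matters in adjacent-edit corner cases).
#'
#' @param ops An `edit_ops` data frame from [diff_ops()].
#' @param baseline The baseline phone sequence the ops were computed from.
#' @param boundary Label used for the word-boundary context.
#' @return The ops with a `context` column added.
#' @export
contextualize_ops <- function(ops, baseline, boundary = "#") {
  ctx <- baseline[pmax(ops$site - 1L, 1L)]
  ctx[ops$site <= 1L] <- boundary
  ops$context <- ctx
  ops
}

#' Collect frequency-weighted alternation operations from a lexicon
#'
#' For every lexical entry, compares the baseline (most frequent) surface
#' form against each alternate form and accumulates the contextualized edit
#' operations, each weighted by the alternate's token count. The baseline is
#' also compared to itself, weighted by its own count — as are
#' non-alternating entries — so that the learned operation distribution
#' carries the corpus-wide bias toward keeping segments unchanged. When an
#' alternate ties the baseline in frequency, the comparison runs in both
#' directions with half the weight each, preserving total weight mass while
#' giving equally probable forms equal standing.
#'
#' @param lexicon An `ep_lexicon`.
#' @param boundary Word-boundary context label.
#' @return An `alternation_table`: `stats`, a data frame
#'   `(context, kind, from, to, weight)` aggregated over the lexicon, and
#'   `totals`, the per-context weight sums.
#' @export
collect_operations <- function(lexicon, boundary = "#") {
  pieces <- vector("list", length(lexicon$entries))
  pi <- 0L
  for (e in lexicon$entries) {
    bf <- baseline_form(e)
    b_seq <- strsplit(bf$form, " ", fixed = TRUE)[[1]]
    for (fi in seq_along(e$forms)) {
      f_str <- names(e$forms)[fi]
      cnt <- e$forms[[fi]]
      f_seq <- strsplit(f_str, " ", fixed = TRUE)[[1]]
      if (f_str == bf$form) {
        ops <- contextualize_ops(diff_ops(b_seq, b_seq), b_seq, boundary)
        ops$weight <- cnt
        pieces[[pi <- pi + 1L]] <- ops
      } else if (cnt == bf$count) {
        ops1 <- contextualize_ops(diff_ops(b_seq, f_seq), b_seq, boundary)
        ops1$weight <- cnt / 2
        ops2 <- contextualize_ops(diff_ops(f_seq, b_seq), f_seq, boundary)
        ops2$weight <- cnt / 2
        pieces[[pi <- pi + 1L]] <- ops1
        pieces[[pi <- pi + 1L]] <- ops2
      } else {
        ops <- contextualize_ops(diff_ops(b_seq, f_seq), b_seq, boundary)
        ops$weight <- cnt
        pieces[[pi <- pi + 1L]] <- ops
      }
    }
  }
  all_ops <- do.call(rbind, c(pieces[seq_len(pi)], list(make.row.names = FALSE)))
  key <- paste(all_ops$context, all_ops$kind,
               ifelse(is.na(all_ops$from), "\x1e", all_ops$from),
               ifelse(is.na(all_ops$to), "\x1e", all_ops$to), sep = "\x1f")
  w <- rowsum(all_ops$weight, key, reorder = TRUE)
  parts <- strsplit(rownames(w), "\x1f", fixed = TRUE)
  stats <- data.frame(
    context = vapply(parts, `[[`, character(1), 1L),
    kind = vapply(parts, `[[`, character(1), 2L),
    from = vapply(parts, `[[`, character(1), 3L),
    to = vapply(parts, `[[`, character(1), 4L),
    weight = as.numeric(w),
    stringsAsFactors = FALSE)
  stats$from[stats$from == "\x1e"] <- NA_character_
  stats$to[stats$to == "\x1e"] <- NA_character_
  totals <- rowsum(stats$weight, stats$context, reorder = TRUE)
  structure(list(stats = stats,
                 totals = stats::setNames(as.numeric(totals), rownames(totals))),
            class = "alternation_table")
}

#' @export
print.alternation_table <- function(x, ...) {
  cat("<alternation_table> ", nrow(x$stats), " operation signatures over ",
      length(x$totals), " contexts, total weight ", sum(x$totals), "\n",
      sep = "")
  invisible(x)
}

#' Surprisal of an alternation operation
#'
#' How unexpected it is for the grammar to perform a given operation after a
#' given context: the negative base-2 log of the operation's weight share
#' among *all* operation signatures observed in that context (equal
#' operations included — the keep-equal bias is part of the distribution).
#'
#' @param table An `alternation_table`.
#' @param context Context label (must have positive total weight).
#' @param kind Operation kind (`equal`, `replace`, `delete`, `insert`).
#' @param from,to Operation segments (`NA` for the empty side).
#' @return Bits, or `NA_real_` for a signature unobserved in this context.
#' @export
op_surprisal <- function(table, context, kind, from = NA, to = NA) {
  total <- table$totals[context]
  if (is.na(total)) stop("unknown context: ", context, call. = FALSE)
  s <- table$stats
  hit <- s$context == context & s$kind == kind &
    (is.na(from) & is.na(s$from) |
       (!is.na(from) & !is.na(s$from) & s$from == from)) &
    (is.na(to) & is.na(s$to) | (!is.na(to) & !is.na(s$to) & s$to == to))
  if (!any(hit)) return(NA_real_)
  -log2(s$weight[hit][1] / unname(total))
}

#' Ranked nothing-to-vowel alternations per context
#'
#' For each consonant context, the `k` vowel-insertion signatures with the
#' lowest operation surprisal, ascending (ties broken lexicographically by
#' vowel label). Contexts with no insertion signature are reported with
#' dash rows (`NA` vowel and bits) — these are contexts in which the
#' lexicon offers no zero-to-vowel alternation at all.
#'
#' @param table An `alternation_table`.
#' @param k Candidates per context.
#' @param inventory Phone inventory used to identify vowels and consonants.
#' @param contexts Contexts to report; defaults to all consonant labels
#'   occurring as contexts in the table.
#' @return A data frame `(context, rank, vowel, weight, bits)`; dash rows
#'   have `rank = NA`.
#' @export
zero_to_vowel_report <- function(table, k = 3L,
                                 inventory = phone_inventory(),
                                 contexts = NULL) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  vows <- vowel_labels(inventory)
  cons <- consonant_labels(inventory)
  if (is.null(contexts))
    contexts <- intersect(names(table$totals), cons)
  rows <- lapply(contexts, function(cx) {
    d <- table$stats[table$stats$context == cx &
                       table$stats$kind == "insert" &
                       table$stats$to %in% vows, , drop = FALSE]
    if (nrow(d) == 0)
      return(data.frame(context = cx, rank = NA_integer_,
                        vowel = NA_character_, weight = NA_real_,
                        bits = NA_real_, stringsAsFactors = FALSE))
    d$bits <- -log2(d$weight / unname(table$totals[cx]))
    d <- d[order(d$bits, d$to), , drop = FALSE]
    d <- utils::head(d, k)
    data.frame(context = cx, rank = seq_len(nrow(d)), vowel = d$to,
               weight = d$weight, bits = d$bits, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}
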