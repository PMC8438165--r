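#' Conditional successor distributions
#'
#' For each context phone, the distribution over the phone that immediately
#' follows it, estimated from the same adjacency counts as the phonotactic
#' learner. Successors are *all* segment kinds — consonants, vowels,
#' boundary — not a pre-restricted vowel set: restricting candidates a
#' priori is exactly the assumption the surprisal analysis avoids, and
#' consonant successors are needed for the cluster-smoothing comparison.
#'
#' @param streams List of character vectors (e.g. from [phone_streams()]).
#' @return A `context_distribution` with the count table and per-context
#'   totals.
#' @export
successor_distribution <- function(streams) {
  bt <- count_biphones(streams)
  counts <- bt$counts
  names(counts) <- c("context", "successor", "n")
  totals <- rowsum(counts$n, counts$context, reorder = TRUE)
  structure(list(counts = counts,
                 totals = stats::setNames(as.integer(totals),
                                          rownames(totals))),
            class = "context_distribution")
}

#' @export
print.context_distribution <- function(x, ...) {
  cat("<context_distribution> ", length(x$totals), " contexts, ",
      sum(x$totals), " transitions\n", sep = "")
  invisible(x)
}

#' Conditional surprisal of a successor
#'
#' Surprisal is the negative base-2 logarithm of the conditional probability
#' of a successor given its context, in bits: the amount of information
#' needed to predict the successor. A certain successor has 0 bits; an
#' unobserved successor in an observed context has no finite surprisal and
#' is reported as `NA` (absent), never as a number — no pseudo-counts are
#' applied.
#'
#' @param dist A `context_distribution`.
#' @param context Context phone label; must have been observed.
#' @param successor Successor phone label.
#' @return Surprisal in bits, or `NA_real_` if the successor was never
#'   observed in this context.
#' @export
#' @examples
#' d <- successor_distribution(list(c("k", "u", "k", "i")))
#' surprisal(d, "k", "u")  # 1 bit: Pr(u | k) = 1/2
surprisal <- function(dist, context, successor) {
  total <- dist$totals[context]
  if (is.na(total))
    stop("unknown context: ", context, call. = FALSE)
  hit <- dist$counts$context == context & dist$counts$successor == successor
  if (!any(hit)) return(NA_real_)
  -log2(dist$counts$n[hit][1] / unname(total))
}

#' Rank epenthetic-vowel candidates for a context
#'
#' Returns the `k` vowel successors with the lowest surprisal after the
#' given context, in ascending order of surprisal (ties broken
#' lexicographically by label). The conditional probabilities are the raw
#' conditionals among all successors — the vowel view is a filter, not a
#' renormalization. When fewer than `k` vowels were observed, all are
#' returned and the result is flagged (reports show dash cells).
#'
#' @param dist A `context_distribution`.
#' @param context Context phone label; must have been observed.
#' @param k Number of candidates.
#' @param inventory Phone inventory used to identify vowel labels.
#' @return A data frame `(context, successor, count, pr, bits)` with
#'   attribute `flagged` when fewer than `k` vowels were available.
#' @export
rank_vowel_candidates <- function(dist, context, k = 3L,
                                  inventory = phone_inventory()) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  total <- dist$totals[context]
  if (is.na(total))
    stop("unknown context: ", context, call. = FALSE)
  vows <- vowel_labels(inventory)
  d <- dist$counts[dist$counts$context == context &
                     dist$counts$successor %in% vows, , drop = FALSE]
  d$pr <- d$n / unname(total)
  d$bits <- -log2(d$pr)
  d <- d[order(d$bits, d$successor), , drop = FALSE]
  flagged <- nrow(d) < k
  d <- utils::head(d, k)
  out <- data.frame(context = rep(context, nrow(d)),
                    successor = d$successor, count = d$n,
                    pr = d$pr, bits = d$bits, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "flagged") <- flagged
  out
}

#' Surprisal smoothing by epenthesis
#'
#' Compares the direct surprisal of a consonant-consonant transition with
#' the two-step path through an epenthesized vowel: `s(c2 | c1)` versus
#' `s(v | c1) + s(c2 | v)`. When the path sum is lower than the direct
#' surprisal, inserting the vowel smooths the surprisal peak that the
#' illegal cluster creates. Unobserved transitions have infinite surprisal
#' and are flagged rather than given a number.
#'
#' @param dist A `context_distribution`.
#' @param c1,c2 The cluster's consonant labels.
#' @param v The candidate epenthetic vowel label.
#' @return A list of class `smoothing_report` with components `direct`
#'   (`s(c2|c1)`), `v_given_c1`, `c2_given_v`, `path_sum`, `smoothed`
#'   (logical; `path_sum < direct`, treating `NA` components as infinite)
#'   and `infinite_members` (labels of unobserved transitions).
#' @export
smoothing_report <- function(dist, c1, c2, v) {
  s_or_na <- function(ctx, succ)
    tryCatch(surprisal(dist, ctx, succ), error = function(e) NA_real_)
  direct <- s_or_na(c1, c2)
  s1 <- s_or_na(c1, v)
  s2 <- s_or_na(v, c2)
  inf <- c(if (is.na(direct)) paste0(c1, "->", c2),
           if (is.na(s1)) paste0(c1, "->", v),
           if (is.na(s2)) paste0(v, "->", c2))
  path_sum <- if (is.na(s1) || is.na(s2)) NA_real_ else s1 + s2
  direct_eff <- if (is.na(direct)) Inf else direct
  path_eff <- if (is.na(path_sum)) Inf else path_sum
  structure(list(direct = direct, v_given_c1 = s1, c2_given_v = s2,
                 path_sum = path_sum,
                 smoothed = is.finite(path_eff) && path_eff < direct_eff,
                 infinite_members = inf %||% character(0)),
            class = "smoothing_report")
}

#' @export
print.smoothing_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "inf (unobserved)" else sprintf("%.3f", v)
  cat("direct C1->C2 surprisal: ", fmt(x$direct), " bits\n",
      "epenthetic path: s(v|C1) = ", fmt(x$v_given_c1),
      " + s(C2|v) = ", fmt(x$c2_given_v),
      " = ", fmt(x$path_sum), " bits\n",
      "smoothing: ", if (x$smoothed) "yes" else "no", "\n", sep = "")
  invisible(x)
}
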