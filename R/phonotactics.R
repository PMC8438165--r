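#' Count biphones over phrase streams
#'
#' Tallies every ordered pair of adjacent phone labels within each stream.
#' Pairs never span two streams: the last phone of one intonational phrase
#' and the first of the next are not adjacent in any linguistically
#' meaningful sense.
#'
#' @param streams List of character vectors (e.g. from [phone_streams()]).
#' @return A `biphone_table`: counts, total, joint probabilities and the two
#'   positional marginals (first-position and second-position), which are
#'   the expectation components of the observed/expected ratio.
#' @export
#' @examples
#' bt <- count_biphones(list(c("k", "a", "k", "a", "t", "a")))
#' bt$total  # 5
count_biphones <- function(streams) {
  lens <- lengths(streams)
  streams <- streams[lens >= 2L]
  if (length(streams) == 0)
    stop("no stream of length >= 2: no biphones to count", call. = FALSE)
  lens <- lengths(streams)
  flat <- unlist(streams, use.names = FALSE)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  x <- flat[-ends]
  y <- flat[-starts]
  key <- paste(x, y, sep = "\x1f")
  tab <- table(key)
  parts <- strsplit(names(tab), "\x1f", fixed = TRUE)
  counts <- data.frame(
    x = vapply(parts, `[[`, character(1), 1L),
    y = vapply(parts, `[[`, character(1), 2L),
    n = as.integer(tab),
    stringsAsFactors = FALSE)
  counts <- counts[order(counts$x, counts$y), , drop = FALSE]
  rownames(counts) <- NULL
  new_biphone_table(counts)
}

new_biphone_table <- function(counts) {
  total <- sum(counts$n)
  pr <- counts$n / total
  fm <- rowsum(pr, counts$x, reorder = TRUE)
  sm <- rowsum(pr, counts$y, reorder = TRUE)
  structure(list(counts = counts, total = total,
                 first_marginal = stats::setNames(as.numeric(fm),
                                                  rownames(fm)),
                 second_marginal = stats::setNames(as.numeric(sm),
                                                   rownames(sm))),
            class = "biphone_table")
}

#' @export
print.biphone_table <- function(x, ...) {
  cat("<biphone_table> ", nrow(x$counts), " biphone types, ",
      x$total, " tokens\n", sep = "")
  invisible(x)
}

biphone_pr <- function(table, x, y) {
  hit <- table$counts$x == x & table$counts$y == y
  if (any(hit)) table$counts$n[hit][1] / table$total else 0
}

#' Observed/expected ratio kernel
#'
#' The O/E ratio divides a biphone's observed probability by the probability
#' expected if the two biphone positions combined independently — the
#' product of the first-position marginal of `x` and the second-position
#' marginal of `y`. A ratio of 1 means the biphone occurred exactly as often
#' as expected; 3 means three times as often.
#'
#' `oe_value` evaluates the ratio from its probability components directly
#' (useful for worked examples and reports); `oe_ratio` evaluates it for a
#' biphone of a counted table. Both error when a marginal is zero, in which
#' case the expectation is undefined.
#'
#' @param pr_xy Observed joint probability of the biphone.
#' @param first_marginal Summed probability of all biphones starting with `x`.
#' @param second_marginal Summed probability of all biphones ending with `y`.
#' @return A nonnegative ratio.
#' @export
#' @examples
#' oe_value(0.3, 0.5, 0.2)  # 3: observed three times as often as expected
oe_value <- function(pr_xy, first_marginal, second_marginal) {
  if (!is.finite(first_marginal) || first_marginal <= 0 ||
      !is.finite(second_marginal) || second_marginal <= 0)
    stop("expected probability undefined: zero positional marginal",
         call. = FALSE)
  if (pr_xy < 0) stop("pr_xy must be nonnegative", call. = FALSE)
  pr_xy / (first_marginal * second_marginal)
}

#' @rdname oe_value
#' @param table A `biphone_table`.
#' @param x,y Phone labels of the biphone.
#' @export
oe_ratio <- function(table, x, y) {
  fm <- table$first_marginal[x]
  sm <- table$second_marginal[y]
  if (is.na(fm) || is.na(sm))
    stop("expected probability undefined for (", x, ", ", y,
         "): zero positional marginal", call. = FALSE)
  oe_value(biphone_pr(table, x, y), unname(fm), unname(sm))
}

#' Constraint-induction thresholds
#'
#' Biphones with O/E strictly below `theta_under` induce markedness
#' constraints (flag the biphone as requiring repair); biphones with O/E
#' strictly above `theta_over` induce Contiguity constraints (keep the
#' biphone intact). Values exactly at a threshold induce nothing.
#'
#' @param theta_under Underrepresentation threshold, in (0, 1).
#' @param theta_over Overrepresentation threshold, above 1.
#' @return A `thresholds` object.
#' @export
thresholds <- function(theta_under = 0.75, theta_over = 1.25) {
  if (!(theta_under > 0 && theta_under < 1 && theta_over > 1))
    stop("need 0 < theta_under < 1 < theta_over", call. = FALSE)
  structure(list(theta_under = theta_under, theta_over = theta_over),
            class = "ep_thresholds")
}

#' Induce phonotactic constraints from O/E ratios
#'
#' Frequency-driven constraint induction: every biphone whose expectation is
#' defined (both positional marginals positive) is scored by its O/E ratio;
#' underrepresented biphones induce markedness constraints and
#' overrepresented ones induce Contiguity constraints. A biphone that never
#' occurs but whose positions both occur gets O/E = 0 and hence a markedness
#' constraint. Constraint strength is the biphone's expected probability
#' `E(xy)`.
#'
#' @param table A `biphone_table`.
#' @param th A [thresholds()] object.
#' @return A data frame with columns `kind` (`"markedness"`/`"contiguity"`),
#'   `x`, `y`, `strength` and `oe`, of class `constraint_set`.
#' @export
induce_constraints <- function(table, th = thresholds()) {
  fm <- table$first_marginal
  sm <- table$second_marginal
  grid <- expand.grid(x = names(fm), y = names(sm),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  E <- unname(fm[grid$x] * sm[grid$y])
  obs_key <- paste(table$counts$x, table$counts$y, sep = "\x1f")
  idx <- match(paste(grid$x, grid$y, sep = "\x1f"), obs_key)
  O <- ifelse(is.na(idx), 0, table$counts$n[idx] / table$total)
  oe <- O / E
  kind <- ifelse(oe < th$theta_under, "markedness",
                 ifelse(oe > th$theta_over, "contiguity", NA_character_))
  out <- data.frame(kind = kind, x = grid$x, y = grid$y,
                    strength = E, oe = oe, stringsAsFactors = FALSE)
  out <- out[!is.na(out$kind), , drop = FALSE]
  out <- out[order(out$x, out$y), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("constraint_set", "data.frame")
  out
}

#' Rank induced constraints by strength
#'
#' Returns the top-`k` Contiguity and top-`k` markedness constraints,
#' ordered by descending strength (expected probability), ties broken
#' lexicographically by `(x, y)` — the reporting convention for
#' "strongest induced constraints" tables.
#'
#' @param constraints A `constraint_set` from [induce_constraints()].
#' @param k Number of constraints per table.
#' @return A list with data frames `contiguity` and `markedness`; each
#'   carries attribute `flagged = TRUE` when fewer than `k` constraints of
#'   that kind exist.
#' @export
constraint_report <- function(constraints, k = 5L) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  pick <- function(kind) {
    d <- constraints[constraints$kind == kind, , drop = FALSE]
    d <- d[order(-d$strength, d$x, d$y), , drop = FALSE]
    flagged <- nrow(d) < k
    d <- utils::head(d, k)
    rownames(d) <- NULL
    attr(d, "flagged") <- flagged
    d
  }
  list(contiguity = pick("contiguity"), markedness = pick("markedness"))
}
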