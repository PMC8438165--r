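# Brute-force oracles, kept deliberately naive and independent of the
# package's counting paths.

# O/E by materializing every biphone token and counting marginals explicitly
oracle_oe <- function(streams, x, y) {
  xs <- character(0)
  ys <- character(0)
  for (s in streams) {
    if (length(s) < 2) next
    for (i in seq_len(length(s) - 1)) {
      xs <- c(xs, s[i])
      ys <- c(ys, s[i + 1])
    }
  }
  n <- length(xs)
  o <- sum(xs == x & ys == y) / n
  e <- (sum(xs == x) / n) * (sum(ys == y) / n)
  o / e
}

oracle_surprisal <- function(streams, ctx, succ) {
  xs <- character(0)
  ys <- character(0)
  for (s in streams) {
    if (length(s) < 2) next
    for (i in seq_len(length(s) - 1)) {
      xs <- c(xs, s[i])
      ys <- c(ys, s[i + 1])
    }
  }
  -log2(sum(xs == ctx & ys == succ) / sum(xs == ctx))
}

# Replay an edit script against the alternate form, consuming its segments
# one by one; returns the rebuilt sequence.
apply_edit_script <- function(alternate, ops) {
  out <- character(0)
  ai <- 1
  for (i in seq_len(nrow(ops))) {
    kind <- ops$kind[i]
    if (kind == "equal" || kind == "replace") {
      stopifnot(identical(alternate[ai], ops$from[i]))
      out <- c(out, ops$to[i])
      ai <- ai + 1
    } else if (kind == "delete") {
      stopifnot(identical(alternate[ai], ops$from[i]))
      ai <- ai + 1
    } else {  # insert
      out <- c(out, ops$to[i])
    }
  }
  stopifnot(ai == length(alternate) + 1)
  out
}
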