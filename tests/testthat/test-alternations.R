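test_that("diff operations reproduce the vowel-zero worked example", {
  ops <- diff_ops(c("sh", "i0", "t", "a"), c("sh", "t", "a"))
  expect_equal(ops$kind, c("equal", "insert", "equal", "equal"))
  expect_equal(ops$to, c("sh", "i0", "t", "a"))

  ops2 <- diff_ops(c("sh", "i0", "t", "a"), c("sh", "i", "t", "a"))
  expect_equal(ops2$kind, c("equal", "replace", "equal", "equal"))
  expect_equal(ops2$from[2], "i")
  expect_equal(ops2$to[2], "i0")

  self <- diff_ops(c("a", "k", "a"), c("a", "k", "a"))
  expect_true(all(self$kind == "equal"))
})

test_that("edit scripts always rebuild the baseline from the alternate", {
  set.seed(13)
  alphabet <- c("k", "t", "u", "a", "s", "i0")
  for (i in 1:300) {
    b <- sample(alphabet, sample(1:8, 1), replace = TRUE)
    a <- sample(alphabet, sample(0:8, 1), replace = TRUE)
    ops <- diff_ops(b, a)
    expect_identical(apply_edit_script(a, ops), b)
  }
})

test_that("contexts come from the preceding baseline segment", {
  b <- c("a", "k", "a")
  ops <- contextualize_ops(diff_ops(b, b), b)
  expect_equal(ops$context, c("#", "a", "k"))

  b2 <- c("sh", "i0", "t", "a")
  ops2 <- contextualize_ops(diff_ops(b2, c("sh", "t", "a")), b2)
  expect_equal(ops2$context[ops2$kind == "insert"], "sh")

  # word-initial edit sites take the boundary context
  ops3 <- contextualize_ops(diff_ops(c("u", "k", "a"), c("k", "a")),
                            c("u", "k", "a"))
  expect_equal(ops3$context[ops3$kind == "insert"], "#")
})

test_that("operation collection weights by token frequency", {
  # single-entry lexicon: the 'did' row alone
  co <- corpus(c(rep(list(phrase("a", list(word_token("did", "Verb",
                                                      c("sh", "i0", "t", "a"))))), 7),
                 rep(list(phrase("b", list(word_token("did", "Verb",
                                                      c("sh", "t", "a"))))), 2),
                 list(phrase("c", list(word_token("did", "Verb",
                                                  c("sh", "i", "t", "a")))))))
  at <- collect_operations(build_lexicon(co))
  s <- at$stats
  w <- function(kind, from, to, ctx) {
    hit <- s$kind == kind & s$context == ctx &
      (is.na(from) & is.na(s$from) | !is.na(s$from) & s$from %in% from) &
      (is.na(to) & is.na(s$to) | !is.na(s$to) & s$to %in% to)
    sum(s$weight[hit])
  }
  expect_equal(w("insert", NA, "i0", "sh"), 2)
  expect_equal(w("replace", "i", "i0", "sh"), 1)
  expect_equal(w("equal", "i0", "i0", "sh"), 7)
  # total weight: 10 comparisons x 4 ops, minus the two 3-phone alternates
  expect_equal(sum(s$weight), 7 * 4 + 2 * 4 + 1 * 4)

  # the operation-surprisal arithmetic on the same table: context sh has
  # total weight 10, the insert carries 2
  expect_equal(op_surprisal(at, "sh", "insert", NA, "i0"), -log2(0.2))
  expect_error(op_surprisal(at, "zz", "insert", NA, "i0"), "unknown context")
  expect_true(is.na(op_surprisal(at, "sh", "insert", NA, "o")))
  # single-signature contexts are certain
  expect_equal(op_surprisal(at, "i0", "equal", "t", "t"), 0)
})

test_that("non-alternating entries contribute pure equal mass", {
  co <- mk_corpus(list(c("a", "r", "u")), list(c("a", "r", "u")))
  at <- collect_operations(build_lexicon(co))
  expect_true(all(at$stats$kind == "equal"))
  expect_equal(sum(at$stats$weight), 2 * 3)
})

test_that("tied baselines run both directions at half weight", {
  co <- mk_corpus(list(c("sh", "i0", "t", "a"))) # 1x devoiced form
  co$phrases <- c(co$phrases,
                  mk_corpus(list(c("sh", "t", "a")))$phrases)
  co$phrases[[2]]$words[[1]]$orth_id <- co$phrases[[1]]$words[[1]]$orth_id
  at <- collect_operations(build_lexicon(co))
  s <- at$stats
  expect_equal(s$weight[s$kind == "insert"], 0.5)
  expect_equal(s$weight[s$kind == "delete"], 0.5)
  # mass conservation: self 4 + two half-weighted 4-op scripts
  expect_equal(sum(s$weight), 4 + 0.5 * 4 + 0.5 * 4)
})

test_that("keep-equal bias holds when a minority of tokens alternate", {
  at <- collect_operations(build_lexicon(toy_lexicon_corpus()))
  s <- at$stats
  expect_gt(sum(s$weight[s$kind == "equal"]),
            sum(s$weight[s$kind != "equal"]))
})

test_that("nothing-to-vowel reports rank inserts and dash empty contexts", {
  stats <- data.frame(
    context = c("p", "p", "p", "p", "g"),
    kind = c("insert", "insert", "insert", "equal", "equal"),
    from = c(NA, NA, NA, "a", "a"), to = c("u", "u0", "i", "a", "a"),
    weight = c(8, 5, 1, 6, 3), stringsAsFactors = FALSE)
  at <- structure(list(stats = stats,
                       totals = c(g = 3, p = 20)),
                  class = "alternation_table")
  z <- zero_to_vowel_report(at, k = 3)
  zp <- z[z$context == "p", ]
  expect_equal(zp$vowel, c("u", "u0", "i"))
  expect_equal(zp$bits[1], -log2(8 / 20))
  zg <- z[z$context == "g", ]
  expect_true(is.na(zg$vowel))

  # equal weights tie lexicographically with equal surprisal
  stats2 <- data.frame(context = "g", kind = "insert", from = NA,
                       to = c("u", "a"), weight = c(2, 2),
                       stringsAsFactors = FALSE)
  at2 <- structure(list(stats = stats2, totals = c(g = 8)),
                   class = "alternation_table")
  z2 <- zero_to_vowel_report(at2, k = 3)
  expect_equal(z2$vowel, c("a", "u"))
  expect_equal(z2$bits[1], z2$bits[2])
})
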