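test_that("successor distributions and surprisal follow the counts", {
  d <- successor_distribution(list(c("k", "a", "k", "u")))
  expect_equal(surprisal(d, "k", "a"), 1)
  expect_equal(surprisal(d, "k", "u"), 1)

  # devoiced vowels are successor types of their own
  d2 <- successor_distribution(list(c("s", "u0", "t", "a")))
  cc <- d2$counts[d2$counts$context == "s", ]
  expect_identical(cc$successor, "u0")

  d3 <- successor_distribution(list(c("k", "u"), c("k", "u"), c("k", "u"),
                                    c("k", "i")))
  expect_equal(surprisal(d3, "k", "u"), -log2(0.75))
  d4 <- successor_distribution(list(c("t", "a"), c("t", "a")))
  expect_equal(surprisal(d4, "t", "a"), 0)

  expect_error(surprisal(d, "zz", "a"), "unknown context")
  expect_true(is.na(surprisal(d3, "k", "o")))
})

test_that("surprisal matches a brute-force oracle and renormalizes to one", {
  set.seed(12)
  alphabet <- c("k", "i", "s", "o")
  for (rep_i in 1:40) {
    streams <- lapply(1:2, function(i)
      sample(alphabet, sample(2:12, 1), replace = TRUE))
    d <- tryCatch(successor_distribution(streams), error = function(e) NULL)
    if (is.null(d)) next
    for (r in seq_len(nrow(d$counts)))
      expect_equal(surprisal(d, d$counts$context[r], d$counts$successor[r]),
                   oracle_surprisal(streams, d$counts$context[r],
                                    d$counts$successor[r]))
    # sum of 2^-surprisal over successors is 1 for every context
    for (cx in names(d$totals)) {
      cc <- d$counts[d$counts$context == cx, ]
      s <- vapply(cc$successor, function(sc) surprisal(d, cx, sc), numeric(1))
      expect_equal(sum(2^(-s)), 1)
    }
  }
})

test_that("vowel candidates rank by ascending surprisal with lexical ties", {
  streams <- c(rep(list(c("sh", "i0")), 8), rep(list(c("sh", "i")), 3),
               list(c("sh", "o")))
  d <- successor_distribution(streams)
  r <- rank_vowel_candidates(d, "sh", 3)
  expect_identical(r$successor, c("i0", "i", "o"))
  expect_false(attr(r, "flagged"))

  # uniform tie resolves lexicographically
  d2 <- successor_distribution(list(c("k", "a"), c("k", "i"), c("k", "u")))
  r2 <- rank_vowel_candidates(d2, "k", 3)
  expect_identical(r2$successor, c("a", "i", "u"))
  expect_equal(unique(r2$bits), log2(3))

  # fewer vowels than requested is flagged (dash cells downstream);
  # consonant successors are filtered, not renormalized
  d3 <- successor_distribution(list(c("k", "u", "k", "t")))
  r3 <- rank_vowel_candidates(d3, "k", 3)
  expect_equal(nrow(r3), 1)
  expect_true(attr(r3, "flagged"))
  expect_equal(r3$pr, 1 / 2)
})

test_that("successor totals agree with the phonotactic row sums", {
  streams <- list(c("k", "a", "t", "a", "s", "u0"), c("k", "u", "t", "o"))
  d <- successor_distribution(streams)
  bt <- count_biphones(streams)
  row_sums <- rowsum(bt$counts$n, bt$counts$x)
  for (cx in names(d$totals))
    expect_equal(unname(d$totals[cx]), unname(row_sums[cx, 1]))
})

test_that("epenthesis smooths a surprisal peak when the path sum is lower", {
  # dyadic construction: pr(t|k)=2^-9, pr(u|k)=2^-2, pr(t|u)=2^-3
  streams <- c(list(c("k", "t")), rep(list(c("k", "u")), 128),
               rep(list(c("k", "a")), 383),
               list(c("u", "t")), rep(list(c("u", "a")), 7))
  d <- successor_distribution(streams)
  sm <- smoothing_report(d, "k", "t", "u")
  expect_equal(sm$direct, 9)
  expect_equal(sm$path_sum, 5)
  expect_true(sm$smoothed)
  expect_length(sm$infinite_members, 0)

  # equality boundary: pr(t|k) = pr(u|k) * pr(t|u) gives no smoothing
  streams2 <- c(list(c("k", "t")), rep(list(c("k", "u")), 2),
                list(c("k", "a")), list(c("u", "t")), list(c("u", "a")))
  sm2 <- smoothing_report(successor_distribution(streams2), "k", "t", "u")
  expect_equal(sm2$direct, sm2$path_sum)
  expect_false(sm2$smoothed)

  # unobserved transition members are flagged as infinite, not numeric
  sm3 <- smoothing_report(d, "k", "t", "a")
  expect_true(is.na(sm3$path_sum))
  expect_true("a->t" %in% sm3$infinite_members)
  expect_false(sm3$smoothed)
})
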