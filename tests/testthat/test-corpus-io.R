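test_that("corpus files round-trip through read and write", {
  co <- mk_corpus(list(c("k", "a", "t", "a")))
  expect_length(co$phrases, 1)
  expect_length(co$phrases[[1]]$words, 1)
  expect_length(co$phrases[[1]]$words[[1]]$phones, 4)

  co <- mk_corpus(list(c("sh", "i0", "t", "a"), c("a", "r", "u")),
                  list(c("k", "u0", "t", "o:"), c("d", "a", "N")))
  f <- withr::local_tempfile()
  write_corpus(co, f)
  co2 <- read_corpus(f)
  expect_equal(co2$phrases, co$phrases)
  f2 <- withr::local_tempfile()
  write_corpus(co2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("malformed corpus and inventory files are rejected with locations", {
  f <- withr::local_tempfile()
  writeLines(c('{"phrase_id":"p1","words":[{"orth_id":"w","pos":"N","phones":["k","a"]}]}',
               '{"phrase_id":"p2"}'), f)
  expect_error(read_corpus(f), "line 2.*words")

  writeLines('{"phrase_id":"p1","words":[{"orth_id":"w","pos":"N","phones":["k","zz"]}]}',
             f)
  expect_error(read_corpus(f), "zz")

  # vowels may not carry a palatalization flag
  inv_file <- withr::local_tempfile()
  writeLines('{"a": {"kind":"vowel","quality":"a","voicing":"voiced",
               "length":"short","palatalized":true}}', inv_file)
  expect_error(read_inventory(inv_file), "palatalization")
})

test_that("phonetic palatalization collapses onto phonological labels", {
  co <- mk_corpus(list(c("s_j", "i", "t", "a")), list(c("sh", "a", "t", "a")))
  out <- collapse_palatalization(co)
  s1 <- phone_streams(out)
  expect_identical(s1[[1]][1], "sh")
  expect_identical(s1[[2]][1], "sh")
  expect_false(any(out$inventory$palatal_source == "phonetic", na.rm = TRUE))

  # merged label frequency = sum of variant frequencies, total count conserved
  co10 <- do.call(mk_corpus, c(
    rep(list(list(c("s_j", "i"))), 6),
    rep(list(list(c("sh", "a"))), 4)))
  before <- label_counts(co10)
  after <- label_counts(collapse_palatalization(co10))
  expect_equal(unname(after[["sh"]]),
               unname(before[["s_j"]] + before[["sh"]]))
  expect_equal(sum(after), sum(before))

  # identity when nothing is phonetically palatalized
  expect_equal(collapse_palatalization(mk_corpus(list(c("k", "a"))))$phrases,
               mk_corpus(list(c("k", "a")))$phrases)

  # counterpart missing from the inventory
  co_bad <- mk_corpus(list(c("s_j", "i")))
  co_bad$inventory <- co_bad$inventory[co_bad$inventory$label != "sh", ]
  expect_error(collapse_palatalization(co_bad), "counterpart")
})

test_that("deletion removes only devoiced vowels, at the requested rate", {
  co <- mk_corpus(list(c("s", "u0", "t", "a"), c("k", "i0", "s", "u")))

  expect_equal(apply_deletion(co, rate = 0, seed = 1)$phrases, co$phrases)

  gone <- apply_deletion(co, rate = 1, seed = 1)
  expect_false(any(unlist(phone_streams(gone)) %in% devoiced_labels()))

  # all non-devoiced labels conserved at any rate
  big <- mk_devoiced_corpus(5000)
  out <- apply_deletion(big, rate = 0.3, seed = 42)
  expect_equal(label_counts(out)[["s"]], label_counts(big)[["s"]])

  # determinism
  out2 <- apply_deletion(big, rate = 0.3, seed = 42)
  expect_identical(out$phrases, out2$phrases)
  out3 <- apply_deletion(big, rate = 0.3, seed = 43)
  expect_false(identical(out$phrases, out3$phrases))

  expect_error(apply_deletion(co, rate = 1.2, seed = 1), "probability")

  # empirical fraction near the nominal rate (3 binomial SEs)
  n <- 20000
  big <- mk_devoiced_corpus(n)
  out <- apply_deletion(big, rate = 0.10, seed = 7)
  frac <- 1 - sum(unlist(phone_streams(out)) == "u0") / n
  expect_lt(abs(frac - 0.10), 3 * sqrt(0.1 * 0.9 / n))
})

test_that("phone streams concatenate words and add boundaries at edges only", {
  co <- mk_corpus(list(c("k", "a"), c("t", "a")))
  expect_identical(phone_streams(co, with_boundaries = TRUE),
                   list(c("#", "k", "a", "t", "a", "#")))
  expect_identical(phone_streams(co), list(c("k", "a", "t", "a")))

  co3 <- mk_corpus(list(c("k", "a")), list(c("t", "a")), list(c("m", "o")))
  expect_length(phone_streams(co3), 3)
  expect_identical(phone_streams(corpus(list())), list())
})
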