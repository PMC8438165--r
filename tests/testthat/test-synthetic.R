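# small configs keep the unit suite quick; the acceptance suite exercises
# the full default scale
small_cfg <- function(...) {
  synthetic_config(n_word_types = 300L, n_phrases = 800L, ...)
}

test_that("generation is a pure function of the configuration", {
  g1 <- generate_corpus(small_cfg(seed = 5))
  g2 <- generate_corpus(small_cfg(seed = 5))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_corpus(g1$corpus, f1); write_corpus(g2$corpus, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(g1$truth$cc_types_from_deletion,
                   g2$truth$cc_types_from_deletion)
  g3 <- generate_corpus(small_cfg(seed = 6))
  expect_false(identical(readLines(f1), {
    f3 <- withr::local_tempfile(); write_corpus(g3$corpus, f3); readLines(f3)
  }))
})

test_that("without devoicing and deletion the corpus is cleanly CV", {
  g <- generate_corpus(small_cfg(seed = 5, devoicing_rate = 0,
                                 deletion_rate = 0))
  labs <- unlist(phone_streams(g$corpus))
  expect_false(any(labs %in% devoiced_labels()))
  inv <- g$corpus$inventory
  cons <- consonant_labels(inv)
  streams <- phone_streams(g$corpus)
  bt <- count_biphones(streams)
  expect_false(any(bt$counts$x %in% cons & bt$counts$y %in% cons))
  expect_equal(g$truth$n_devoiced, 0)
  expect_length(g$truth$cc_types_from_deletion, 0)
})

test_that("planted conditional vowel distributions are realized", {
  cvd <- default_vowel_distributions()
  cvd$k <- c(a = 0.2, e = 0.05, i = 0.1, o = 0.05, u = 0.6)
  g <- generate_corpus(synthetic_config(seed = 9, n_word_types = 3000L,
                                        n_phrases = 2000L,
                                        context_vowel_distributions = cvd,
                                        devoicing_rate = 0,
                                        deletion_rate = 0))
  # count at the planted-lexicon level, where the draws are binomial
  forms <- strsplit(g$truth$lexicon$form, " ", fixed = TRUE)
  flat <- unlist(forms)
  n <- length(flat)
  prev <- c(NA, flat[-n])
  wid <- rep(seq_along(forms), lengths(forms))
  prev[c(TRUE, wid[-1] != wid[-n])] <- NA
  after_k <- flat[!is.na(prev) & prev == "k"]
  p_hat <- mean(vowel_quality(after_k) == "u")
  n_k <- length(after_k)
  expect_gt(n_k, 200)
  expect_lt(abs(p_hat - 0.6), 3 * sqrt(0.6 * 0.4 / n_k))
})

test_that("ground truth recounts cleanly and detects tampering", {
  g <- generate_corpus(small_cfg(seed = 5))
  expect_length(recount_ground_truth(g$corpus, g$truth), 0)

  tampered <- g$corpus
  found <- FALSE
  for (i in seq_along(tampered$phrases)) {
    w <- tampered$phrases[[i]]$words[[1]]
    j <- which(w$phones %in% devoiced_labels())
    if (length(j) > 0) {
      w$phones[j[1]] <- sub("0", "", w$phones[j[1]], fixed = TRUE)
      tampered$phrases[[i]]$words[[1]] <- w
      found <- TRUE
      break
    }
  }
  expect_true(found)
  expect_gt(length(recount_ground_truth(tampered, g$truth)), 0)
})

test_that("deletion and devoicing tallies match the planted rates", {
  g <- generate_corpus(synthetic_config(seed = 17, n_word_types = 1000L,
                                        n_phrases = 6000L))
  tr <- g$truth
  # deleted / devoiced ~ deletion_rate
  se_del <- sqrt(0.1 * 0.9 / tr$n_devoiced)
  expect_lt(abs(tr$n_deleted / tr$n_devoiced - 0.10), 3 * se_del)
  # devoiced / eligible ~ devoicing_rate, so deleted / eligible ~ product
  p <- 0.10 * 0.9
  se_prod <- sqrt(p * (1 - p) / tr$n_eligible)
  expect_lt(abs(tr$n_deleted / tr$n_eligible - p), 3 * se_prod)
  # tallies are internally consistent
  expect_equal(sum(tr$devoiced_by_context), tr$n_devoiced)
  expect_equal(sum(tr$deleted_by_context), tr$n_deleted)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(deletion_rate = 1.5), "\\[0, 1\\]")
  expect_error(synthetic_config(
    word_length_distribution = c("1" = 0.5, "2" = 0.2)), "normalized")
  expect_error(synthetic_config(
    context_vowel_distributions = list(k = c(a = 1))), "default")
})
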