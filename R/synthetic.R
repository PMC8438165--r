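#' Synthetic corpus configuration
#'
#' Describes a CV-structured speech corpus with a productive high-vowel
#' devoicing process and probabilistic deletion of devoiced vowels, the
#' setting in which illusory epenthesis is studied. Word types get fixed
#' underlying CV(:) phone forms, so devoicing and deletion create genuine
#' surface *alternations* of the same lexeme rather than independent
#' per-token resamplings. Defaults give roughly 10^5 word tokens.
#'
#' Devoicing targets short high vowels (\[i, u\]) whose flanking segments
#' are voiceless — either a voiceless consonant on both sides or a voiceless
#' consonant followed by the phrase edge (phrase-final devoicing, as in the
#' formal copula). Deletion then removes devoiced vowels at
#' `deletion_rate`, the pre-processing convention for transcripts that
#' always write devoiced vowels out. Palatalized consonants draw their
#' vowels from an \[i\]-biased distribution; homophony across distinct
#' (orthography, category) lexemes is planted at `homophony_rate`.
#'
#' @param seed Integer seed; the whole corpus is a pure function of the
#'   configuration (deletion uses a seed derived from this one).
#' @param n_word_types Number of distinct lexemes.
#' @param word_length_distribution Named probabilities over word lengths in
#'   CV morae.
#' @param consonant_distribution Named probabilities over consonant labels.
#' @param context_vowel_distributions Named list mapping consonant labels to
#'   probability vectors over vowel qualities `a,e,i,o,u`; must contain a
#'   `default` element used for consonants without their own entry.
#' @param devoicing_rate Probability an eligible short high vowel devoices.
#' @param deletion_rate Probability a devoiced vowel deletes.
#' @param long_vowel_rate Probability a vowel slot is long.
#' @param n_phrases Number of intonational phrases.
#' @param words_per_phrase_distribution Named probabilities over phrase
#'   lengths in words.
#' @param pos_labels Syntactic-category labels sampled per word type.
#' @param homophony_rate Probability a word type reuses an earlier type's
#'   phone form.
#' @param zipf_exponent Token frequencies follow rank^(-exponent).
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(
    seed = 101L,
    n_word_types = 3000L,
    word_length_distribution = c("1" = 0.10, "2" = 0.40, "3" = 0.35,
                                 "4" = 0.15),
    consonant_distribution = default_consonant_distribution(),
    context_vowel_distributions = default_vowel_distributions(),
    devoicing_rate = 0.9,
    deletion_rate = 0.10,
    long_vowel_rate = 0.08,
    n_phrases = 25000L,
    words_per_phrase_distribution = c("2" = 0.15, "3" = 0.25, "4" = 0.25,
                                      "5" = 0.20, "6" = 0.15),
    pos_labels = c("Noun", "Verb", "Adjective", "Adverb"),
    homophony_rate = 0.03,
    zipf_exponent = 0.5) {
  cfg <- list(seed = as.integer(seed), n_word_types = as.integer(n_word_types),
              word_length_distribution = word_length_distribution,
              consonant_distribution = consonant_distribution,
              context_vowel_distributions = context_vowel_distributions,
              devoicing_rate = devoicing_rate, deletion_rate = deletion_rate,
              long_vowel_rate = long_vowel_rate,
              n_phrases = as.integer(n_phrases),
              words_per_phrase_distribution = words_per_phrase_distribution,
              pos_labels = pos_labels, homophony_rate = homophony_rate,
              zipf_exponent = zipf_exponent)
  check_dist <- function(d, what) {
    if (any(d < 0) || abs(sum(d) - 1) > 1e-8)
      stop(what, " must be a normalized probability distribution",
           call. = FALSE)
  }
  check_dist(cfg$word_length_distribution, "word_length_distribution")
  check_dist(cfg$consonant_distribution, "consonant_distribution")
  check_dist(cfg$words_per_phrase_distribution,
             "words_per_phrase_distribution")
  if (is.null(cfg$context_vowel_distributions$default))
    stop("context_vowel_distributions needs a 'default' element",
         call. = FALSE)
  for (nm in names(cfg$context_vowel_distributions))
    check_dist(cfg$context_vowel_distributions[[nm]],
               paste0("context_vowel_distributions$", nm))
  for (r in c("devoicing_rate", "deletion_rate", "long_vowel_rate",
              "homophony_rate"))
    if (cfg[[r]] < 0 || cfg[[r]] > 1)
      stop(r, " must be in [0, 1]", call. = FALSE)
  class(cfg) <- "synthetic_config"
  cfg
}

#' @rdname synthetic_config
#' @export
default_consonant_distribution <- function() {
  w <- c(t = 0.12, k = 0.12, s = 0.09, n = 0.09, r = 0.08, m = 0.07,
         d = 0.06, g = 0.05, h = 0.05, b = 0.04, sh = 0.04, p = 0.03,
         ts = 0.03, w = 0.03, y = 0.03, ch = 0.025, F = 0.02, jh = 0.02,
         C = 0.012, ky = 0.012, gy = 0.01, py = 0.006, dz = 0.01)
  w / sum(w)
}

#' @rdname synthetic_config
#' @export
default_vowel_distributions <- function() {
  pal <- c(a = 0.10, e = 0.05, i = 0.70, o = 0.05, u = 0.10)
  list(default = c(a = 0.25, e = 0.10, i = 0.10, o = 0.15, u = 0.40),
       t = c(a = 0.25, e = 0.15, i = 0.08, o = 0.40, u = 0.12),
       d = c(a = 0.25, e = 0.40, i = 0.05, o = 0.20, u = 0.10),
       k = c(a = 0.20, e = 0.05, i = 0.10, o = 0.15, u = 0.50),
       s = c(a = 0.20, e = 0.05, i = 0.15, o = 0.10, u = 0.50),
       h = c(a = 0.45, e = 0.12, i = 0.13, o = 0.25, u = 0.05),
       sh = pal, ch = pal, jh = pal, C = pal, ky = pal, gy = pal, py = pal)
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 65536 * 1009 + k * 7919 + 17) %% 2147483647)
}

#' Generate a synthetic corpus with ground truth
#'
#' Draws a lexicon of CV-structured word types, assembles intonational
#' phrases from Zipf-distributed word tokens, applies devoicing to eligible
#' short high vowels and then deletion to devoiced vowels, and returns both
#' the finished corpus and a ground-truth record sufficient to verify every
#' downstream learner: the planted lexicon and conditional vowel
#' distributions, per-context devoicing and deletion tallies, and the set of
#' consonant-consonant biphone types that exist only because a vowel was
#' deleted.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `corpus` (an `ep_corpus`) and `truth`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(config$seed)
  inv <- phone_inventory()
  voiceless <- voiceless_labels(inv)

  # fixed underlying forms per word type
  wld <- config$word_length_distribution
  L <- sample(as.integer(names(wld)), config$n_word_types, TRUE, wld)
  M <- sum(L)
  type_of_mora <- rep.int(seq_along(L), L)
  cd <- config$consonant_distribution
  cons <- sample(names(cd), M, TRUE, cd)
  cvd <- config$context_vowel_distributions
  q <- character(M)
  for (cc in unique(cons)) {
    d <- cvd[[cc]] %||% cvd$default
    idx <- which(cons == cc)
    q[idx] <- sample(names(d), length(idx), TRUE, d)
  }
  long <- stats::runif(M) < config$long_vowel_rate
  vlab <- paste0(q, ifelse(long, ":", ""))
  phones <- as.vector(rbind(cons, vlab))
  forms <- split(phones, factor(rep(type_of_mora, each = 2L),
                                levels = seq_along(L)))
  forms <- unname(lapply(forms, as.character))
  hom <- stats::runif(config$n_word_types) < config$homophony_rate
  hom[1] <- FALSE
  hom_src <- rep(NA_integer_, config$n_word_types)
  for (i in which(hom)) {
    src <- sample.int(i - 1L, 1L)
    forms[[i]] <- forms[[src]]
    hom_src[i] <- src
  }
  orth <- sprintf("w%05d", seq_along(L))
  pos <- sample(config$pos_labels, config$n_word_types, TRUE)

  # token stream
  wppd <- config$words_per_phrase_distribution
  wpp <- sample(as.integer(names(wppd)), config$n_phrases, TRUE, wppd)
  n_tok <- sum(wpp)
  zw <- seq_along(L)^(-config$zipf_exponent)
  tok_type <- sample.int(config$n_word_types, n_tok, TRUE, zw / sum(zw))
  tok_forms <- forms[tok_type]
  n_phones_tok <- lengths(tok_forms)
  labels <- unlist(tok_forms, use.names = FALSE)

  # devoicing at phrase assembly (context crosses word boundaries)
  phrase_of_token <- rep.int(seq_len(config$n_phrases), wpp)
  phrase_of_phone <- rep.int(phrase_of_token, n_phones_tok)
  n <- length(labels)
  prev <- c(NA_character_, labels[-n])
  prev[c(TRUE, phrase_of_phone[-1] != phrase_of_phone[-n])] <- NA
  nxt <- c(labels[-1], NA_character_)
  phrase_final <- c(phrase_of_phone[-n] != phrase_of_phone[-1], TRUE)
  nxt[phrase_final] <- NA
  eligible <- labels %in% c("i", "u") &
    !is.na(prev) & prev %in% voiceless &
    (phrase_final | nxt %in% voiceless)
  devoiced <- eligible & stats::runif(n) < config$devoicing_rate
  labels[devoiced] <- paste0(labels[devoiced], "0")
  dev_by_ctx <- tab_to_named(table(prev[devoiced]))

  fl <- list(labels = labels, n_phones = as.integer(n_phones_tok),
             n_words = as.integer(wpp),
             orth_id = orth[tok_type], pos = pos[tok_type],
             phrase_id = sprintf("ph%06d", seq_len(config$n_phrases)))
  corp <- corpus_unflatten(fl, inv)

  if (config$deletion_rate > 0) {
    corp <- apply_deletion(corp, rate = config$deletion_rate,
                           seed = derive_seed(config$seed, 1L))
  } else {
    attr(corp, "n_candidates") <- sum(devoiced)
    attr(corp, "n_deleted") <- 0L
  }
  post_dev_by_ctx <- devoiced_context_tally(corp)
  del_by_ctx <- dev_by_ctx
  del_by_ctx[] <- dev_by_ctx - ifelse(is.na(post_dev_by_ctx[names(dev_by_ctx)]),
                                      0L, post_dev_by_ctx[names(dev_by_ctx)])

  cc_types <- character(0)
  if (attr(corp, "n_deleted") > 0) {
    bt <- count_biphones(phone_streams(corp))
    cons_all <- c(consonant_labels(inv), "N", "Q")
    is_cc <- bt$counts$x %in% cons_all & bt$counts$y %in% cons_all
    cc_types <- paste(bt$counts$x[is_cc], bt$counts$y[is_cc])
  }

  truth <- list(
    lexicon = data.frame(orth_id = orth, pos = pos,
                         form = vapply(forms, paste, character(1),
                                       collapse = " "),
                         homophone_of = ifelse(is.na(hom_src), NA_character_,
                                               orth[pmax(hom_src, 1L)]),
                         stringsAsFactors = FALSE),
    context_vowel_distributions = cvd,
    devoiced_by_context = dev_by_ctx,
    deleted_by_context = del_by_ctx,
    n_eligible = sum(eligible),
    n_devoiced = sum(devoiced),
    n_deleted = attr(corp, "n_deleted"),
    cc_types_from_deletion = sort(cc_types),
    config = config)
  list(corpus = corp, truth = truth)
}

tab_to_named <- function(tb) {
  stats::setNames(as.integer(tb), names(tb))
}

# devoiced-vowel tokens per preceding-segment context, within phrases
devoiced_context_tally <- function(corpus) {
  dev <- devoiced_labels(corpus$inventory)
  streams <- phone_streams(corpus)
  lens <- lengths(streams)
  streams <- streams[lens >= 1L]
  flat <- unlist(streams, use.names = FALSE)
  lens <- lengths(streams)
  stream_of <- rep.int(seq_along(streams), lens)
  n <- length(flat)
  prev <- c(NA_character_, flat[-n])
  prev[c(TRUE, stream_of[-1] != stream_of[-n])] <- NA
  mask <- flat %in% dev & !is.na(prev)
  tab_to_named(table(prev[mask]))
}

#' Verify a ground-truth record against its corpus
#'
#' Re-tallies devoiced vowels (overall and per preceding-segment context)
#' and consonant-consonant biphone types from the corpus and compares them
#' with the ground-truth record produced alongside it. Any discrepancy is
#' reported as a message in the returned vector; a freshly generated pair
#' yields an empty vector.
#'
#' @param corpus An `ep_corpus` from [generate_corpus()].
#' @param truth The matching ground-truth record.
#' @return Character vector of mismatch descriptions (empty if consistent).
#' @export
recount_ground_truth <- function(corpus, truth) {
  mismatches <- character(0)
  post <- devoiced_context_tally(corpus)
  expected_total <- truth$n_devoiced - truth$n_deleted
  if (sum(post) != expected_total)
    mismatches <- c(mismatches, sprintf(
      "devoiced total: corpus has %d, truth implies %d",
      sum(post), expected_total))
  exp_ctx <- truth$devoiced_by_context - truth$deleted_by_context
  for (cx in names(exp_ctx)) {
    got <- if (is.na(post[cx])) 0L else post[[cx]]
    if (got != exp_ctx[[cx]])
      mismatches <- c(mismatches, sprintf(
        "devoiced after %s: corpus has %d, truth implies %d",
        cx, got, exp_ctx[[cx]]))
  }
  inv <- corpus$inventory
  cons_all <- c(consonant_labels(inv), "N", "Q")
  bt <- tryCatch(count_biphones(phone_streams(corpus)), error = function(e) NULL)
  cc_obs <- if (is.null(bt)) character(0) else {
    is_cc <- bt$counts$x %in% cons_all & bt$counts$y %in% cons_all
    sort(paste(bt$counts$x[is_cc], bt$counts$y[is_cc]))
  }
  extra <- setdiff(cc_obs, truth$cc_types_from_deletion)
  gone <- setdiff(truth$cc_types_from_deletion, cc_obs)
  if (length(extra) > 0)
    mismatches <- c(mismatches, paste("CC biphone type(s) not in truth:",
                                      paste(extra, collapse = ", ")))
  if (length(gone) > 0)
    mismatches <- c(mismatches, paste("truth CC biphone type(s) absent:",
                                      paste(gone, collapse = ", ")))
  mismatches
}
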