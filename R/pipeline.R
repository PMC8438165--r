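#' Run the full epenthesis-learning pipeline
#'
#' Orchestrates corpus acquisition (a JSON-Lines file or the synthetic
#' generator), pre-processing, phonotactic constraint induction, conditional
#' surprisal, lexicon building and alternation learning, writing one TSV per
#' stage plus a manifest. All stages see the *same* pre-processed corpus.
#' File-sourced corpora are pre-processed here (palatalization collapse,
#' then devoiced-vowel deletion with a seed derived from the run seed);
#' synthetic corpora arrive with deletion already applied by the generator,
#' so no second deletion is performed. Stage seeds are derived from the
#' single run seed, so adding a stage never perturbs earlier stages'
#' randomness. Re-running with the same configuration reproduces the bundle
#' bit for bit; the manifest records a hash of the configuration alongside
#' per-stage row counts.
#'
#' @param config Either a list or a path to a YAML file with fields:
#'   `corpus` (path to a JSON-Lines corpus) *or* `synthetic` (a list of
#'   [synthetic_config()] arguments) — exactly one; optional `seed`
#'   (default 1), `deletion_rate` (default 0.10; file sources only),
#'   `theta_under`/`theta_over` (default 0.75/1.25), `top_k_constraints`
#'   (default 5), `top_k_vowels` (default 3), `boundaries` (default `TRUE`).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the stage objects and the manifest. On
#'   any stage failure the partial outputs are removed and the error names
#'   the failing stage.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  has_file <- !is.null(config$corpus)
  has_synth <- !is.null(config$synthetic)
  if (has_file == has_synth)
    stop("config must name exactly one corpus source ",
         "('corpus' file or 'synthetic' settings)", call. = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  th <- thresholds(config$theta_under %||% 0.75,
                   config$theta_over %||% 1.25)
  k_con <- as.integer(config$top_k_constraints %||% 5L)
  k_vow <- as.integer(config$top_k_vowels %||% 3L)
  boundaries <- isTRUE(config$boundaries %||% TRUE)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(out_dir, c("biphones.tsv", "constraints.tsv",
                                "surprisal.tsv", "candidates.tsv",
                                "lexicon.tsv", "operations.tsv",
                                "zero_to_vowel.tsv", "manifest.json"))
  names(files) <- basename(files)
  written <- character(0)
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      unlink(written)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(df, file) {
    utils::write.table(df, files[[file]], sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "-", fileEncoding = "UTF-8")
    written <<- c(written, files[[file]])
    nrow(df)
  }

  truth <- NULL
  corp <- stage("corpus", {
    if (has_file) {
      x <- read_corpus(config$corpus)
      x <- collapse_palatalization(x)
      apply_deletion(x, rate = config$deletion_rate %||% 0.10,
                     seed = derive_seed(seed, 1L))
    } else {
      sc <- do.call(synthetic_config,
                    c(list(seed = derive_seed(seed, 2L)), config$synthetic))
      gen <- generate_corpus(sc)
      truth <- gen$truth
      gen$corpus
    }
  })
  inv <- corp$inventory

  streams <- stage("streams", phone_streams(corp, with_boundaries = boundaries))

  bt <- stage("phonotactics", count_biphones(streams))
  n_bi <- stage("phonotactics", {
    cdf <- bt$counts
    cdf$pr <- cdf$n / bt$total
    cdf$E <- unname(bt$first_marginal[cdf$x] * bt$second_marginal[cdf$y])
    cdf$OE <- cdf$pr / cdf$E
    names(cdf)[names(cdf) == "n"] <- "count"
    n1 <- emit(cdf, "biphones.tsv")
    n2 <- emit(induce_constraints(bt, th), "constraints.tsv")
    c(n1, n2)
  })

  n_sup <- stage("surprisal", {
    dist <- successor_distribution(streams)
    sdf <- dist$counts
    sdf$pr <- sdf$n / unname(dist$totals[sdf$context])
    sdf$bits <- -log2(sdf$pr)
    names(sdf)[names(sdf) == "n"] <- "count"
    n1 <- emit(sdf, "surprisal.tsv")
    ctxs <- intersect(names(dist$totals), consonant_labels(inv))
    cand <- do.call(rbind, c(lapply(ctxs, function(cx) {
      d <- rank_vowel_candidates(dist, cx, k = k_vow, inventory = inv)
      if (nrow(d) == 0)
        d <- data.frame(context = cx, successor = NA_character_,
                        count = NA_integer_, pr = NA_real_, bits = NA_real_,
                        stringsAsFactors = FALSE)
      d$rank <- seq_len(nrow(d))
      d
    }), list(make.row.names = FALSE)))
    n2 <- emit(cand, "candidates.tsv")
    c(n1, n2)
  })

  lex <- stage("lexicon", build_lexicon(corp))
  n_lex <- emit(lexicon_table(lex), "lexicon.tsv")

  n_alt <- stage("alternations", {
    at <- collect_operations(lex)
    odf <- at$stats
    odf$bits <- -log2(odf$weight / unname(at$totals[odf$context]))
    n1 <- emit(odf, "operations.tsv")
    n2 <- emit(zero_to_vowel_report(at, k = k_vow, inventory = inv),
               "zero_to_vowel.tsv")
    c(n1, n2)
  })

  manifest <- list(
    config_hash = rlang::hash(config),
    seed = seed,
    source = if (has_file) "file" else "synthetic",
    stages = list(biphones = n_bi[1], constraints = n_bi[2],
                  surprisal = n_sup[1], candidates = n_sup[2],
                  lexicon = n_lex, operations = n_alt[1],
                  zero_to_vowel = n_alt[2]))
  jsonlite::write_json(manifest, files[["manifest.json"]],
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(corpus = corp, truth = truth, lexicon = lex,
                 biphones = bt, manifest = manifest, files = files))
}
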