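#' Synthetic interview-corpus configuration
#'
#' The generator emulates the statistical structure of transcribed interview
#' strata: heavy class imbalance between records with and without latent
#' needs, a heavy-tailed (Zipf-like) background vocabulary shared by the two
#' classes, a small set of class-discriminative words upweighted in the
#' needs class, and many idiosyncratic words each confined to a single record
#' — the noise the Z-score selection is meant to strip. Defaults mirror the
#' caregiver stratum: 343 needs / 7231 no-needs records, a noun vocabulary in
#' the low thousands, and negative-binomial record lengths.
#'
#' @param n_yes,n_no Records per class (defaults 343 / 7231).
#' @param vocab_background Background vocabulary size (default 3000).
#' @param vocab_discriminative Planted discriminative words (default 20).
#' @param vocab_idiosyncratic Single-record words (default 1500).
#' @param effect Relative frequency multiplier (>= 1) of discriminative words
#'   in the needs class (default 3).
#' @param record_length List with `mean` and `dispersion` of the
#'   negative-binomial token count per record (defaults 30 / 5).
#' @param role_mix Fraction of records assigned role `"patient"`
#'   (default 0.2, roughly the patient share of the interview records).
#' @param marker_prob Probability a needs record embeds a marker adverb
#'   (default 0.9).
#' @param zipf_exponent Exponent of the background rank-frequency law
#'   (default 1.1).
#' @param disc_mass Total probability mass of the discriminative words in the
#'   no-needs class before the effect multiplier (default 0.15).
#' @param seed Integer seed; the corpus is fully reproducible from it.
#' @return A validated `synth_config`.
#' @export
synth_config <- function(n_yes = 343, n_no = 7231,
                         vocab_background = 3000,
                         vocab_discriminative = 20,
                         vocab_idiosyncratic = 1500,
                         effect = 3,
                         record_length = list(mean = 30, dispersion = 5),
                         role_mix = 0.2,
                         marker_prob = 0.9,
                         zipf_exponent = 1.1,
                         disc_mass = 0.15,
                         seed = 1L) {
  stopifnot(n_yes >= 1, n_no >= 1, effect >= 1,
            vocab_background >= 0, vocab_discriminative >= 0,
            vocab_idiosyncratic >= 0,
            role_mix >= 0, role_mix <= 1,
            marker_prob >= 0, marker_prob <= 1,
            disc_mass >= 0, disc_mass < 1,
            record_length$mean > 0, record_length$dispersion > 0)
  if (vocab_background + vocab_discriminative == 0) {
    rlang::abort("need a non-empty sampling vocabulary (background + discriminative)")
  }
  structure(list(n_yes = n_yes, n_no = n_no,
                 vocab_background = vocab_background,
                 vocab_discriminative = vocab_discriminative,
                 vocab_idiosyncratic = vocab_idiosyncratic,
                 effect = effect, record_length = record_length,
                 role_mix = role_mix, marker_prob = marker_prob,
                 zipf_exponent = zipf_exponent, disc_mass = disc_mass,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' The planted discriminative vocabulary
#'
#' Returns the exact morpheme keys the generator upweights in the needs
#' class, for recovery tests; disjoint from the background (`bg...`) and
#' idiosyncratic (`uq...`) vocabularies by construction.
#'
#' @param config A [synth_config()].
#' @return Character vector of length `vocab_discriminative`.
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$vocab_discriminative == 0) return(character(0))
  sprintf("disc%03d", seq_len(config$vocab_discriminative))
}

#' Generate a synthetic labelled corpus
#'
#' Record lengths are drawn from a negative binomial; token identities from a
#' class-conditional multinomial mixing the Zipf background with the planted
#' discriminative words (upweighted by `effect` in the needs class and
#' renormalized); each idiosyncratic word is appended once to one uniformly
#' chosen record. Needs records additionally embed one expectation-adverb
#' marker with probability `marker_prob`, so the annotation step is
#' exercisable end to end. Text is emitted in fixture-tokenizer format
#' (`surface/名詞`, markers as `surface/副詞`), byte-identical across runs
#' with the same config.
#'
#' @param config A [synth_config()].
#' @param truth_path Optional path; when given, a JSON sidecar with the
#'   planted vocabulary and a config echo is written there.
#' @return A corpus with `n_yes + n_no` labelled records.
#' @export
generate_corpus <- function(config, truth_path = NULL) {
  stopifnot(inherits(config, "synth_config"))
  bg <- if (config$vocab_background > 0)
    sprintf("bg%04d", seq_len(config$vocab_background)) else character(0)
  disc <- planted_truth(config)
  p_bg <- if (length(bg) > 0) {
    p <- seq_along(bg)^(-config$zipf_exponent)
    (p / sum(p)) * (1 - config$disc_mass)
  } else numeric(0)
  p_disc <- if (length(disc) > 0)
    rep(config$disc_mass / length(disc), length(disc)) else numeric(0)
  if (length(disc) == 0) {
    p_bg <- p_bg / sum(p_bg)
  }
  vocab <- c(bg, disc)
  p_no <- c(p_bg, p_disc)
  p_yes <- c(p_bg, p_disc * config$effect)
  p_yes <- p_yes / sum(p_yes)
  n <- config$n_yes + config$n_no
  labels <- c(rep("yes", config$n_yes), rep("no", config$n_no))
  markers <- c("やっぱり", "やっぱ", "やはり", "あるといい")

  withr::with_seed(config$seed, {
    lens <- pmax(1L, stats::rnbinom(n, size = config$record_length$dispersion,
                                    mu = config$record_length$mean))
    texts <- character(n)
    for (i in seq_len(n)) {
      p <- if (labels[i] == "yes") p_yes else p_no
      toks <- sample(vocab, size = lens[i], replace = TRUE, prob = p)
      texts[i] <- paste0(toks, "/名詞", collapse = " ")
    }
    if (config$vocab_idiosyncratic > 0) {
      uq <- sprintf("uq%05d", seq_len(config$vocab_idiosyncratic))
      host <- sample.int(n, length(uq), replace = TRUE)
      for (j in seq_along(uq)) {
        texts[host[j]] <- paste(texts[host[j]], paste0(uq[j], "/名詞"))
      }
    }
    embed <- labels == "yes" & stats::runif(n) < config$marker_prob
    if (any(embed)) {
      mk <- sample(markers, sum(embed), replace = TRUE)
      texts[embed] <- paste(texts[embed], paste0(mk, "/副詞"))
    }
    roles <- ifelse(stats::runif(n) < config$role_mix, "patient", "caregiver")
  })

  out <- corpus(
    tibble::tibble(
      record_id = sprintf("r%05d", seq_len(n)),
      role = roles, text = texts, marker_flag = NA,
      label = labels,
      annotator_labels = vector("list", n)
    ),
    metadata = list(source = "synthetic", seed = config$seed,
                    config = unclass(config))
  )
  if (!is.null(truth_path)) {
    jsonlite::write_json(
      list(planted = planted_truth(config), config = unclass(config)),
      truth_path, auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
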