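#' Tokenizer backends
#'
#' Morphological analysis is pluggable behind a single contract: a tokenizer
#' takes UTF-8 text and returns a tibble of `(surface, pos, base)` triples.
#' Two backends satisfy it:
#'
#' * `fixture_tokenizer()` — parses pre-tagged text of the form
#'   `surface/POS` or `surface/POS/base`, whitespace separated. This is the
#'   backend used throughout the test suite and by the synthetic corpus
#'   generator, so no external morphological analyzer is ever required.
#' * `mecab_tokenizer()` — adapter over a MeCab command-line binary for real
#'   Japanese text. Errors with guidance if the binary is not on the PATH.
#'
#' @return A tokenizer handle for [tokenize()].
#' @export
fixture_tokenizer <- function() {
  structure(list(backend = "fixture"), class = "needs_tokenizer")
}

#' @rdname fixture_tokenizer
#' @param binary Path to the `mecab` executable.
#' @export
mecab_tokenizer <- function(binary = Sys.which("mecab")) {
  if (is.na(binary) || !nzchar(binary)) {
    rlang::abort(paste0(
      "MeCab binary not found; install MeCab or use fixture_tokenizer() ",
      "with pre-tagged 'surface/POS' text"))
  }
  structure(list(backend = "mecab", binary = unname(binary)),
            class = "needs_tokenizer")
}

empty_tokens <- function() {
  tibble::tibble(surface = character(0), pos = character(0),
                 base = character(0))
}

#' Tokenize text into morphemes
#'
#' Deterministic for a fixed text and analyzer. Text is NFC-normalized before
#' analysis so counts are stable across Unicode composition variants.
#'
#' @param text A UTF-8 string.
#' @param analyzer A tokenizer handle ([fixture_tokenizer()] or
#'   [mecab_tokenizer()]).
#' @return A tibble with columns `surface`, `pos` (full part-of-speech tag),
#'   `base` (dictionary form, `NA` when unavailable); empty text gives zero
#'   rows.
#' @export
tokenize <- function(text, analyzer = fixture_tokenizer()) {
  stopifnot(inherits(analyzer, "needs_tokenizer"))
  text <- stringi::stri_trans_nfc(text)
  if (is.na(text) || !nzchar(trimws(text))) return(empty_tokens())
  switch(analyzer$backend,
         fixture = tokenize_fixture(text),
         mecab = tokenize_mecab(text, analyzer$binary))
}

tokenize_fixture <- function(text) {
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  parts <- strsplit(toks, "/", fixed = TRUE)
  tibble::tibble(
    surface = purrr::map_chr(parts, 1),
    pos = purrr::map_chr(parts, function(p) {
      if (length(p) >= 2) p[2] else "未知語"
    }),
    base = purrr::map_chr(parts, function(p) {
      if (length(p) >= 3 && nzchar(p[3]) && p[3] != "*") p[3] else NA_character_
    })
  )
}

tokenize_mecab <- function(text, binary) {
  out <- system2(binary, stdout = TRUE, input = text)
  out <- out[out != "EOS" & nzchar(out)]
  if (length(out) == 0) return(empty_tokens())
  surface <- sub("\t.*$", "", out)
  feats <- strsplit(sub("^[^\t]*\t", "", out), ",", fixed = TRUE)
  tibble::tibble(
    surface = surface,
    pos = purrr::map_chr(feats, 1),
    base = purrr::map_chr(feats, function(f) {
      if (length(f) >= 7 && nzchar(f[7]) && f[7] != "*") f[7] else NA_character_
    })
  )
}

#' Extract noun keys from a token list
#'
#' Keeps tokens whose first part-of-speech field equals `noun_tag` and maps
#' each to its morpheme key: the dictionary (base) form when available, else
#' the surface form. Order is preserved.
#'
#' @param tokens A token tibble from [tokenize()].
#' @param noun_tag Part-of-speech tag to keep (default 名詞, the noun tag).
#' @return Character vector of morpheme keys.
#' @export
extract_nouns <- function(tokens, noun_tag = "名詞") {
  if (nrow(tokens) == 0) return(character(0))
  pos1 <- purrr::map_chr(strsplit(tokens$pos, "[,-]"), 1)
  keep <- tokens[pos1 == noun_tag, , drop = FALSE]
  as.character(ifelse(is.na(keep$base), keep$surface, keep$base))
}

morpheme_keys <- function(tokens, unit = c("nouns", "all_morphemes"),
                          noun_tag = "名詞") {
  unit <- rlang::arg_match(unit)
  if (unit == "nouns") {
    extract_nouns(tokens, noun_tag)
  } else {
    ifelse(is.na(tokens$base), tokens$surface, tokens$base)
  }
}

#' Per-class morpheme count tables
#'
#' Aggregates morpheme occurrences over all records of one latent-need class
#' and stores, alongside the counts, the mean `mu` and standard deviation
#' `sigma` of the counts over the class vocabulary — the standardization
#' constants of the class Z-scores.
#'
#' @param records A corpus (or subset) whose records all carry the label
#'   matching `class_tag`.
#' @param class_tag `"needs_yes"` or `"needs_no"`.
#' @param analyzer Tokenizer handle.
#' @param unit Counting unit: `"nouns"` (default; downstream vectorization is
#'   over nouns) or `"all_morphemes"`.
#' @param sigma_type `"population"` (default; divide by the vocabulary size N)
#'   or `"sample"` (N − 1).
#' @return A `count_table`: list with `class_tag`, named numeric `counts`,
#'   `mu`, `sigma`, and the `unit` used.
#' @export
build_count_table <- function(records, class_tag = c("needs_yes", "needs_no"),
                              analyzer = fixture_tokenizer(),
                              unit = c("nouns", "all_morphemes"),
                              sigma_type = c("population", "sample")) {
  class_tag <- rlang::arg_match(class_tag)
  unit <- rlang::arg_match(unit)
  sigma_type <- rlang::arg_match(sigma_type)
  want <- if (class_tag == "needs_yes") "yes" else "no"
  bad <- which(is.na(records$label) | records$label != want)
  if (nrow(records) == 0) {
    rlang::abort(paste0("no records for class ", class_tag))
  }
  if (length(bad) > 0) {
    rlang::abort(paste0("record(s) with label not matching ", class_tag, ": ",
                        paste(utils::head(records$record_id[bad], 5),
                              collapse = ", ")))
  }
  keys <- unlist(purrr::map(records$text, function(t) {
    morpheme_keys(tokenize(t, analyzer), unit)
  }), use.names = FALSE)
  count_table_from_keys(keys, class_tag, unit, sigma_type)
}

count_table_from_keys <- function(keys, class_tag, unit = "nouns",
                                  sigma_type = "population") {
  if (length(keys) == 0) {
    rlang::abort(paste0("empty vocabulary for class ", class_tag,
                        " (no tokens of the configured unit)"))
  }
  counts <- c(table(keys))
  counts <- counts[order(names(counts))]
  storage.mode(counts) <- "double"
  mu <- mean(counts)
  n <- length(counts)
  sigma <- if (sigma_type == "population") {
    sqrt(sum((counts - mu)^2) / n)
  } else {
    stats::sd(counts)
  }
  structure(list(class_tag = class_tag, counts = counts, mu = mu,
                 sigma = sigma, unit = unit, sigma_type = sigma_type),
            class = "count_table")
}
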