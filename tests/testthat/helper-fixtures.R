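# fixtures are built in code: no binary data, no external tokenizer

# a small labelled corpus in fixture-tokenizer format (surface/POS[/base])
toy_corpus <- function() {
  corpus(tibble::tibble(
    record_id = c("r1", "r2", "r3", "r4"),
    role = c("patient", "patient", "caregiver", "caregiver"),
    text = c("薬/名詞 が/助詞 欲しい/形容詞 薬/名詞",
             "散歩/名詞 は/助詞 いい/形容詞",
             "施設/名詞 の/助詞 情報/名詞",
             ""),
    label = c("yes", "yes", "no", "no")
  ))
}

# random corpus for round-trip property tests; annotator labels optional
# because the CSV dialect does not carry them
random_corpus <- function(n, seed, with_annotators = FALSE) {
  withr::with_seed(seed, {
    words <- c("w1", "w2", "いい", "やっぱり", "薬", "comma,quote\"x")
    ann <- lapply(seq_len(n), function(i) {
      if (!with_annotators || runif(1) < 0.5) return(NULL)
      k <- sample(1:3, 1)
      tibble::tibble(annotator_id = paste0("a", seq_len(k)),
                     label = sample(c("yes", "no"), k, replace = TRUE))
    })
    corpus(tibble::tibble(
      record_id = paste0("rec", seq_len(n)),
      role = sample(c("patient", "caregiver"), n, replace = TRUE),
      text = vapply(seq_len(n), function(i) {
        paste(sample(words, sample(0:6, 1), replace = TRUE), collapse = " ")
      }, character(1)),
      marker_flag = sample(c(TRUE, FALSE, NA), n, replace = TRUE),
      label = sample(c("yes", "no", NA), n, replace = TRUE),
      annotator_labels = ann
    ))
  })
}

# count table straight from morpheme keys, bypassing tokenization
keys_table <- function(keys, class_tag) {
  latentneeds:::count_table_from_keys(keys, class_tag)
}

# z_table with prescribed scores, for algebraic oracles
manual_ztable <- function(z, class_tag, mu = 1, sigma = 1) {
  structure(list(class_tag = class_tag, z = z, mu = mu, sigma = sigma,
                 degenerate = FALSE), class = "z_table")
}

# small balanced labelled corpus with a perfectly separating word
separable_corpus <- function(n_per_class = 10) {
  ids <- paste0("s", seq_len(2 * n_per_class))
  corpus(tibble::tibble(
    record_id = ids,
    role = "caregiver",
    text = c(rep("signal/名詞 filler/名詞", n_per_class),
             rep("noise/名詞 filler/名詞", n_per_class)),
    label = rep(c("yes", "no"), each = n_per_class)
  ))
}
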