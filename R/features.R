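#' TF-IDF document-term matrix over a kept vocabulary
#'
#' Turns records into importance-weighted vectors: term frequency times
#' inverse document frequency, restricted to the kept (selected) vocabulary.
#' Two dialects:
#'
#' * `smooth` (default): weight = tf x (ln((1 + N)/(1 + df)) + 1), rows
#'   L2-normalized — the de-facto standard in common machine-learning
#'   libraries.
#' * `raw`: weight = tf x ln(N/df), no normalization — the literal
#'   "term frequency times inverse document frequency" reading; a term
#'   present in every document gets weight 0.
#'
#' Records whose tokens all fall outside the vocabulary yield a zero row
#' (reported with a message, not an error).
#'
#' @param records A labelled corpus (or subset).
#' @param vocabulary Character vector of kept morpheme keys (column order of
#'   the result).
#' @param analyzer Tokenizer handle.
#' @param unit Counting unit passed to the tokenizer ("nouns" or
#'   "all_morphemes").
#' @param variant `"smooth"` or `"raw"`.
#' @param idf Optional precomputed idf vector aligned with `vocabulary`; used
#'   to transform held-out records with document frequencies fitted elsewhere
#'   (strict, leakage-free mode). Default `NULL` fits idf on `records`.
#' @return A `doc_term_matrix`: list with `weights` (records x terms dense
#'   matrix, dimnames set), `record_ids`, `vocabulary`, `labels` (aligned,
#'   may contain `NA`), `variant`, and the fitted `idf`.
#' @export
tfidf <- function(records, vocabulary, analyzer = fixture_tokenizer(),
                  unit = c("nouns", "all_morphemes"),
                  variant = c("smooth", "raw"), idf = NULL) {
  unit <- rlang::arg_match(unit)
  variant <- rlang::arg_match(variant)
  if (length(vocabulary) == 0) rlang::abort("kept vocabulary must be non-empty")
  if (anyDuplicated(vocabulary)) rlang::abort("vocabulary has duplicate keys")
  n <- nrow(records)
  tf <- matrix(0, nrow = n, ncol = length(vocabulary),
               dimnames = list(records$record_id, vocabulary))
  for (i in seq_len(n)) {
    keys <- morpheme_keys(tokenize(records$text[i], analyzer), unit)
    keys <- keys[keys %in% vocabulary]
    if (length(keys) > 0) {
      tab <- table(keys)
      tf[i, names(tab)] <- as.numeric(tab)
    }
  }
  if (is.null(idf)) {
    df <- colSums(tf > 0)
    idf <- switch(variant,
      smooth = log((1 + n) / (1 + df)) + 1,
      raw = ifelse(df > 0, log(n / df), 0)
    )
  } else {
    stopifnot(length(idf) == length(vocabulary))
    idf <- stats::setNames(as.numeric(idf), vocabulary)
  }
  w <- sweep(tf, 2, idf, `*`)
  if (variant == "smooth") {
    norms <- sqrt(rowSums(w^2))
    nz <- norms > 0
    w[nz, ] <- w[nz, , drop = FALSE] / norms[nz]
  }
  n_zero <- sum(rowSums(tf) == 0)
  if (n_zero > 0) {
    rlang::inform(paste0(n_zero, " record(s) had no in-vocabulary tokens ",
                         "(zero rows)"))
  }
  structure(list(weights = w,
                 record_ids = records$record_id,
                 vocabulary = vocabulary,
                 labels = records$label,
                 variant = variant,
                 idf = idf),
            class = "doc_term_matrix")
}

#' Balance classes by random undersampling
#'
#' Keeps every record of the minority class and a seeded uniform random subset
#' (without replacement) of the majority class of equal size, so both latent
#' need classes have the same record count. Already-balanced input is returned
#' unchanged.
#'
#' @param records A labelled corpus (every record must have `label` set).
#' @param seed Integer seed; fixes the majority subset.
#' @return The balanced corpus subset, in original record order;
#'   `2 x min(class sizes)` records.
#' @export
undersample <- function(records, seed) {
  if (anyNA(records$label)) {
    rlang::abort("undersample requires every record to have a label")
  }
  n_yes <- sum(records$label == "yes")
  n_no <- sum(records$label == "no")
  if (n_yes == 0 || n_no == 0) {
    rlang::abort("both classes must be present to undersample")
  }
  if (n_yes == n_no) return(records)
  minority <- if (n_yes < n_no) "yes" else "no"
  majority <- setdiff(c("yes", "no"), minority)
  maj_idx <- which(records$label == majority)
  keep_maj <- withr::with_seed(seed,
    sample(maj_idx, size = min(n_yes, n_no), replace = FALSE))
  keep <- sort(c(which(records$label == minority), keep_maj))
  records[keep, , drop = FALSE]
}

#' Stratified train/test split
#'
#' Splits records by position into training and test sets. Per class, the
#' test count is `ceiling((1 - train_fraction) x class size)` (this rounding
#' reproduces 480/206 from 686 and 88/38 from 126 at 70/30); assignment is
#' uniform random and seeded.
#'
#' @param records A labelled record set (normally the balanced output of
#'   [undersample()]).
#' @param train_fraction In (0, 1); default 0.7.
#' @param seed Integer seed.
#' @param stratified Stratify by label (default TRUE).
#' @return A `data_split`: list with `train` and `test` record-id vectors,
#'   `train_fraction`, `seed`.
#' @export
split_records <- function(records, train_fraction = 0.7, seed,
                          stratified = TRUE) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  if (anyNA(records$label)) {
    rlang::abort("split requires every record to have a label")
  }
  groups <- if (stratified) split(records$record_id, records$label) else
    list(all = records$record_id)
  small <- names(groups)[purrr::map_int(groups, length) < 2]
  if (length(small) > 0) {
    rlang::abort(paste0("class(es) with fewer than 2 records: ",
                        paste(small, collapse = ", ")))
  }
  test <- withr::with_seed(seed, unlist(purrr::map(groups, function(ids) {
    # round before ceiling: (1 - 0.7) * 30 is 9.000000000000002 in floating
    # point and must give 9, not 10
    n_test <- ceiling(round((1 - train_fraction) * length(ids), 9))
    sample(ids, size = n_test, replace = FALSE)
  }), use.names = FALSE))
  train <- setdiff(records$record_id, test)
  structure(list(train = train, test = test,
                 train_fraction = train_fraction, seed = seed),
            class = "data_split")
}

#' Export / import a document-term matrix
#'
#' Writes the weights as a sparse Matrix Market file with sidecar TSVs for the
#' row ids/labels and the vocabulary, and reads the triple back.
#'
#' @param dtm A `doc_term_matrix`.
#' @param dir Output directory (created if absent). Files: `weights.mtx`,
#'   `records.tsv`, `vocabulary.tsv`.
#' @return `write_dtm`: the directory, invisibly. `read_dtm`: the
#'   reconstructed `doc_term_matrix` (idf is not persisted).
#' @export
write_dtm <- function(dtm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(dtm$weights, sparse = TRUE),
                  file.path(dir, "weights.mtx"))
  readr::write_tsv(
    tibble::tibble(record_id = dtm$record_ids, label = dtm$labels),
    file.path(dir, "records.tsv"), na = "", progress = FALSE)
  readr::write_tsv(tibble::tibble(morpheme = dtm$vocabulary),
                   file.path(dir, "vocabulary.tsv"), progress = FALSE)
  invisible(dir)
}

#' @rdname write_dtm
#' @export
read_dtm <- function(dir) {
  w <- as.matrix(Matrix::readMM(file.path(dir, "weights.mtx")))
  rows <- readr::read_tsv(file.path(dir, "records.tsv"),
                          col_types = "cc", na = "", progress = FALSE)
  vocab <- readr::read_tsv(file.path(dir, "vocabulary.tsv"),
                           col_types = "c", progress = FALSE)$morpheme
  dimnames(w) <- list(rows$record_id, vocab)
  structure(list(weights = w, record_ids = rows$record_id,
                 vocabulary = vocab, labels = rows$label,
                 variant = NA_character_, idf = NULL),
            class = "doc_term_matrix")
}
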