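#' Resolved pipeline configuration
#'
#' Every field has a documented default; the resolved list is embedded
#' verbatim in the comparison report so runs are auditable. All randomness
#' flows from the single `seed`: undersampling uses `seed + 1`, the split
#' `seed + 2`, and model k (in `families` order) `seed + 10 + k`.
#'
#' @param unit Counting unit, `"nouns"` (default) or `"all_morphemes"`.
#' @param strategy,fraction Selection rule, see [select_morphemes()].
#' @param variant TF-IDF dialect, see [tfidf()].
#' @param mode `"pooled"` (default): morpheme selection and idf are
#'   fitted on the full labelled corpus before sampling and splitting,
#'   reproducing the method order of the original workflow; `"strict"`: both
#'   are fitted on the training fold only (leakage-free).
#' @param train_fraction Train share of the balanced sample (default 0.7).
#' @param families Model families to compare (default all three).
#' @param role_filter Optional `"patient"` or `"caregiver"` to restrict the
#'   corpus to one stratum.
#' @param seed Top-level integer seed.
#' @return A named list (class `pipeline_config`).
#' @export
pipeline_config <- function(unit = "nouns",
                            strategy = "fraction_of_max",
                            fraction = 0.25,
                            variant = "smooth",
                            mode = c("pooled", "strict"),
                            train_fraction = 0.7,
                            families = c("naive_bayes", "svm",
                                         "random_forest"),
                            role_filter = NULL,
                            seed = 1L) {
  mode <- rlang::arg_match(mode)
  families <- match.arg(families, c("naive_bayes", "svm", "random_forest"),
                        several.ok = TRUE)
  structure(list(unit = unit, strategy = strategy, fraction = fraction,
                 variant = variant, mode = mode,
                 train_fraction = train_fraction, families = families,
                 role_filter = role_filter, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full latent-need extraction pipeline
#'
#' Executes annotate -> tokenize/count -> Z-score selection (plus a
#' no-selection arm) -> TF-IDF -> undersample -> split -> train the model
#' families -> evaluate -> compare. Stage counts (records in, marker-flagged,
#' labelled, sampled, split sizes, vocabulary before/after selection) are
#' collected in `counts` so a run can be audited stage by stage.
#'
#' @param x A labelled corpus.
#' @param config A [pipeline_config()].
#' @param lexicon Marker lexicon for the annotation stage.
#' @param analyzer Tokenizer handle.
#' @param outdir Optional run directory; when given, intermediate artifacts
#'   (annotated corpus, selection audit, document-term matrices, predictions,
#'   report JSON, manifest) are written under it.
#' @return A list: `report` (a [compare_report()] tibble), `metrics` (long
#'   tibble with one row per condition x family), `selection`
#'   (`selection_result`), `counts` (stage log), `config` (resolved).
#' @export
run_pipeline <- function(x, config = pipeline_config(),
                         lexicon = default_marker_lexicon(),
                         analyzer = fixture_tokenizer(),
                         outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  counts <- list(records_in = nrow(x))
  if (!is.null(config$role_filter)) {
    x <- x[x$role == config$role_filter, , drop = FALSE]
    counts$records_role <- nrow(x)
  }
  x <- annotate_markers(x, lexicon)
  counts$marker_flagged <- sum(x$marker_flag, na.rm = TRUE)
  lab <- x[!is.na(x$label), , drop = FALSE]
  counts$labelled <- nrow(lab)
  if (nrow(lab) == 0) {
    rlang::abort("corpus has no records with the 'label' field set; the pipeline trains on gold labels")
  }
  counts$labelled_yes <- sum(lab$label == "yes")
  counts$labelled_no <- sum(lab$label == "no")

  role_tag <- config$role_filter %||% "all"
  sampled <- undersample(lab, seed = config$seed + 1L)
  counts$sampled <- nrow(sampled)
  spl <- split_records(sampled, train_fraction = config$train_fraction,
                       seed = config$seed + 2L)
  counts$train <- length(spl$train)
  counts$test <- length(spl$test)

  if (config$mode == "pooled") {
    fit_set <- lab
  } else {
    fit_set <- sampled[sampled$record_id %in% spl$train, , drop = FALSE]
  }
  ctA <- build_count_table(fit_set[fit_set$label == "yes", , drop = FALSE],
                           "needs_yes", analyzer, unit = config$unit)
  ctB <- build_count_table(fit_set[fit_set$label == "no", , drop = FALSE],
                           "needs_no", analyzer, unit = config$unit)
  diff <- z_difference(zscores(ctA), zscores(ctB))
  sel <- select_morphemes(diff, strategy = config$strategy,
                          fraction = config$fraction)
  full_vocab <- sort(names(diff$scores))
  counts$vocab_full <- length(full_vocab)
  counts$vocab_kept <- length(sel$kept)

  arms <- list(with_z = sort(sel$kept), without_z = full_vocab)
  vectorize <- function(vocab) {
    if (config$mode == "pooled") {
      dtm <- suppressMessages(
        tfidf(sampled, vocab, analyzer, unit = config$unit,
              variant = config$variant))
      list(train = dtm, test = dtm)
    } else {
      tr <- sampled[sampled$record_id %in% spl$train, , drop = FALSE]
      te <- sampled[sampled$record_id %in% spl$test, , drop = FALSE]
      dtr <- suppressMessages(
        tfidf(tr, vocab, analyzer, unit = config$unit,
              variant = config$variant))
      dte <- suppressMessages(
        tfidf(te, vocab, analyzer, unit = config$unit,
              variant = config$variant, idf = dtr$idf))
      list(train = dtr, test = dte)
    }
  }

  rows <- list()
  preds <- list()
  for (arm in names(arms)) {
    mats <- vectorize(arms[[arm]])
    for (k in seq_along(config$families)) {
      fam <- config$families[k]
      spec <- model_spec(fam, seed = config$seed + 10L + k)
      model <- train_model(mats$train, spec, ids = spl$train)
      pred <- predict_model(model, mats$test, ids = spl$test)
      truth <- mats$test$labels[match(spl$test, mats$test$record_ids)]
      cm <- confusion(truth, pred)
      rows[[paste(arm, fam)]] <- tibble::tibble(
        role = role_tag, family = fam, condition = arm, cm = list(cm))
      preds[[paste(arm, fam)]] <- tibble::tibble(
        record_id = spl$test, true = truth, predicted = pred,
        condition = arm, family = fam)
    }
  }
  results <- dplyr::bind_rows(rows)
  report <- compare_report(results, config = unclass(config))
  long <- dplyr::bind_cols(results[, c("role", "family", "condition")],
                           dplyr::bind_rows(purrr::map(results$cm,
                                                       metrics_row)))
  out <- list(report = report, metrics = long, selection = sel,
              counts = counts, config = config)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_corpus(x, file.path(outdir, "corpus_annotated.jsonl"), "jsonl")
    selection_audit(diff, sel, file.path(outdir, "selection.tsv"))
    readr::write_tsv(dplyr::bind_rows(preds),
                     file.path(outdir, "predictions.tsv"), progress = FALSE)
    readr::write_tsv(long, file.path(outdir, "metrics.tsv"), progress = FALSE)
    jsonlite::write_json(
      list(config = unclass(config), counts = counts,
           report = as.data.frame(report)),
      file.path(outdir, "report.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
    jsonlite::write_json(
      list(files = list.files(outdir), created = "run_pipeline"),
      file.path(outdir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
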