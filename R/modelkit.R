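#' Classifier specifications
#'
#' The three comparison families, with documented defaults (the otherwise unspecified
#' hyperparameters are common library defaults, recorded in every report):
#' multinomial Naive Bayes with add-one smoothing (`alpha = 1`); SVM with a
#' linear kernel and cost 1 (the text-classification convention on TF-IDF
#' features; RBF available via `hyperparameters`); random forest with 100
#' trees.
#'
#' @param family `"naive_bayes"`, `"svm"`, or `"random_forest"`.
#' @param hyperparameters Named list overriding the family defaults.
#' @param seed Integer seed consumed by stochastic fits (random forest).
#' @return A `model_spec`.
#' @export
model_spec <- function(family = c("naive_bayes", "svm", "random_forest"),
                       hyperparameters = list(), seed = 1L) {
  family <- rlang::arg_match(family)
  defaults <- switch(family,
    naive_bayes = list(alpha = 1),
    svm = list(kernel = "linear", cost = 1),
    random_forest = list(ntree = 100)
  )
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(family = family, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "model_spec")
}

dtm_rows <- function(dtm, ids = NULL) {
  if (is.null(ids)) {
    list(x = dtm$weights, y = dtm$labels)
  } else {
    miss <- setdiff(ids, dtm$record_ids)
    if (length(miss) > 0) {
      rlang::abort(paste0("record id(s) not in matrix: ",
                          paste(utils::head(miss, 5), collapse = ", ")))
    }
    idx <- match(ids, dtm$record_ids)
    list(x = dtm$weights[idx, , drop = FALSE], y = dtm$labels[idx])
  }
}

#' Train a classifier on a document-term matrix
#'
#' Deterministic given `spec$seed`. The fitted model carries a fingerprint of
#' the training vocabulary; [predict_model()] refuses matrices whose
#' vocabulary differs, which catches mixed-up selection arms.
#'
#' @param dtm A `doc_term_matrix` with labels.
#' @param spec A [model_spec()].
#' @param ids Optional record ids restricting the rows used (e.g. the train
#'   half of a [split_records()] result).
#' @return A `trained_model`.
#' @export
train_model <- function(dtm, spec, ids = NULL) {
  stopifnot(inherits(dtm, "doc_term_matrix"), inherits(spec, "model_spec"))
  d <- dtm_rows(dtm, ids)
  if (anyNA(d$y)) rlang::abort("training rows must all be labelled")
  y <- factor(d$y, levels = c("no", "yes"))
  if (length(unique(d$y)) < 2) {
    rlang::abort("training data contain a single class; need both yes and no")
  }
  hp <- spec$hyperparameters
  fit <- switch(spec$family,
    naive_bayes = fit_multinomial_nb(d$x, y, alpha = hp$alpha),
    svm = withr::with_seed(spec$seed,
      e1071::svm(x = d$x, y = y, kernel = hp$kernel, cost = hp$cost,
                 scale = FALSE)),
    random_forest = withr::with_seed(spec$seed,
      randomForest::randomForest(x = d$x, y = y, ntree = hp$ntree))
  )
  structure(list(spec = spec, fit = fit,
                 vocab_hash = rlang::hash(dtm$vocabulary),
                 levels = levels(y)),
            class = "trained_model")
}

# Multinomial Naive Bayes with additive smoothing on nonnegative weights
# (TF-IDF values act as fractional counts). Closed form: per class c,
# log P(t|c) = log((S_tc + alpha) / (sum_t S_tc + alpha * V)).
fit_multinomial_nb <- function(x, y, alpha = 1) {
  classes <- levels(y)
  v <- ncol(x)
  log_prior <- log(table(y)[classes] / length(y))
  log_cond <- sapply(classes, function(cl) {
    s <- colSums(x[y == cl, , drop = FALSE])
    log((s + alpha) / (sum(s) + alpha * v))
  })
  structure(list(log_prior = as.numeric(log_prior),
                 log_cond = log_cond, classes = classes, alpha = alpha),
            class = "multinomial_nb")
}

predict_multinomial_nb <- function(fit, x) {
  scores <- x %*% fit$log_cond +
    matrix(fit$log_prior, nrow = nrow(x), ncol = length(fit$classes),
           byrow = TRUE)
  # ties resolve to the first class in level order ("no"), deterministically
  fit$classes[apply(scores, 1, which.max)]
}

#' Predict latent-need labels
#'
#' @param model A `trained_model`.
#' @param dtm A `doc_term_matrix` built over the same vocabulary.
#' @param ids Optional record ids restricting the rows scored (e.g. the test
#'   half of a split).
#' @return Character vector of `"yes"`/`"no"`, one per row; empty input gives
#'   an empty vector.
#' @export
predict_model <- function(model, dtm, ids = NULL) {
  stopifnot(inherits(model, "trained_model"),
            inherits(dtm, "doc_term_matrix"))
  if (rlang::hash(dtm$vocabulary) != model$vocab_hash) {
    rlang::abort("vocabulary fingerprint mismatch: matrix was built over a different vocabulary than the model was trained on")
  }
  d <- dtm_rows(dtm, ids)
  if (nrow(d$x) == 0) return(character(0))
  # random_forest breaks 50-50 vote ties with the RNG; seed the predict call
  # so fixed seed + fixed input gives byte-identical predictions
  out <- withr::with_seed(model$spec$seed, switch(model$spec$family,
    naive_bayes = predict_multinomial_nb(model$fit, d$x),
    svm = as.character(stats::predict(model$fit, d$x)),
    random_forest = as.character(stats::predict(model$fit, d$x))
  ))
  unname(out)
}

#' Persist and restore a trained model
#'
#' Single-file artifact embedding the spec and vocabulary fingerprint.
#'
#' @param model A `trained_model`.
#' @param path File path (`.rds`).
#' @export
write_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "trained_model"))
  model
}

#' Export predictions as TSV
#'
#' @param record_ids,true,predicted Aligned vectors.
#' @param path Output TSV path.
#' @export
write_predictions <- function(record_ids, true, predicted, path) {
  readr::write_tsv(
    tibble::tibble(record_id = record_ids, true = true,
                   predicted = predicted),
    path, progress = FALSE)
  invisible(path)
}
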