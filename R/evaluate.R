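#' Confusion matrices
#'
#' Standard 2x2 counts with latent need = "yes" as the positive class: TP
#' counts needs records correctly found.
#'
#' @param true,predicted Equal-length non-empty label vectors
#'   (`"yes"`/`"no"`).
#' @param positive Positive class (default `"yes"`).
#' @return A `confusion_matrix`: list with `TP`, `FP`, `FN`, `TN`,
#'   `positive`.
#' @export
confusion <- function(true, predicted, positive = "yes") {
  if (length(true) != length(predicted)) {
    rlang::abort("true and predicted labels have different lengths")
  }
  if (length(true) == 0) rlang::abort("empty label vectors")
  confusion_counts(
    TP = sum(true == positive & predicted == positive),
    FP = sum(true != positive & predicted == positive),
    FN = sum(true == positive & predicted != positive),
    TN = sum(true != positive & predicted != positive),
    positive = positive
  )
}

#' @rdname confusion
#' @param TP,FP,FN,TN Nonnegative integer counts (for matrices given directly,
#'   e.g. published result tables).
#' @export
confusion_counts <- function(TP, FP, FN, TN, positive = "yes") {
  counts <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  if (any(counts < 0) || any(counts != round(counts))) {
    rlang::abort("confusion counts must be nonnegative integers")
  }
  structure(list(TP = as.integer(TP), FP = as.integer(FP),
                 FN = as.integer(FN), TN = as.integer(TN),
                 positive = positive),
            class = "confusion_matrix")
}

# round half away from zero, the convention of the printed result tables
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Metrics from a confusion matrix
#'
#' accuracy = (TP+TN)/total, precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F-measure = 2PR/(P+R). A zero denominator sets the corresponding
#' `flags$*_undefined` and reports 0. Rounded (2 dp, half away from zero)
#' counterparts match the precision at which such tables are printed.
#'
#' @param cm A `confusion_matrix`.
#' @return A `metrics_report`: list with `accuracy`, `precision`, `recall`,
#'   `f_measure`, a `rounded` sublist at 2 dp, and `flags`.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$TP; fp <- cm$FP; fn <- cm$FN; tn <- cm$TN
  total <- tp + fp + fn + tn
  if (total == 0) rlang::abort("all-zero confusion matrix")
  precision_undefined <- (tp + fp) == 0
  recall_undefined <- (tp + fn) == 0
  precision <- if (precision_undefined) 0 else tp / (tp + fp)
  recall <- if (recall_undefined) 0 else tp / (tp + fn)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  accuracy <- (tp + tn) / total
  structure(list(
    accuracy = accuracy, precision = precision, recall = recall,
    f_measure = f,
    rounded = list(accuracy = round_half_away(accuracy),
                   precision = round_half_away(precision),
                   recall = round_half_away(recall),
                   f_measure = round_half_away(f)),
    flags = list(precision_undefined = precision_undefined,
                 recall_undefined = recall_undefined)
  ), class = "metrics_report")
}

metrics_row <- function(cm) {
  m <- metrics(cm)
  tibble::tibble(
    accuracy = m$rounded$accuracy, precision = m$rounded$precision,
    recall = m$rounded$recall, f_measure = m$rounded$f_measure,
    TN = cm$TN, FP = cm$FP, FN = cm$FN, TP = cm$TP
  )
}

#' With/without-selection comparison report
#'
#' Tabulates the evaluation of every (role, model family) cell side by side
#' for the two conditions — with the Z-score morpheme selection and without —
#' and marks which condition has the higher rounded F-measure. Cells missing
#' one condition are rendered absent, not an error.
#'
#' @param results A tibble with columns `role`, `family`, `condition`
#'   (`"with_z"`/`"without_z"`) and a list column `cm` of
#'   `confusion_matrix` objects (as produced by [run_pipeline()]), or the
#'   equivalent long metrics tibble with `f_measure` already present.
#' @param config Optional named list (resolved configuration, seeds, mode)
#'   embedded in the report attributes.
#' @return A `comparison_report` tibble: one row per role x family with
#'   rounded metrics and confusion counts for each condition and a `better`
#'   column (`"with_z"`, `"without_z"`, `"tie"`).
#' @export
compare_report <- function(results, config = list()) {
  stopifnot(all(c("role", "family", "condition") %in% names(results)))
  if ("cm" %in% names(results)) {
    met <- dplyr::bind_rows(purrr::map(results$cm, metrics_row))
    results <- dplyr::bind_cols(
      results[, c("role", "family", "condition")], met)
  }
  have_pair <- any(duplicated(results[, c("role", "family")]))
  if (!have_pair && length(unique(results$condition)) < 2) {
    rlang::warn("no complete with/without pair present in results")
  }
  wide <- tidyr_pivot(results)
  wide$better <- dplyr::case_when(
    is.na(wide$f_measure_with_z) | is.na(wide$f_measure_without_z) ~
      NA_character_,
    wide$f_measure_with_z > wide$f_measure_without_z ~ "with_z",
    wide$f_measure_with_z < wide$f_measure_without_z ~ "without_z",
    TRUE ~ "tie"
  )
  structure(wide, config = config,
            class = c("comparison_report", class(wide)))
}

# wide layout without importing tidyr: one row per role x family
tidyr_pivot <- function(results) {
  cells <- unique(results[, c("role", "family")])
  value_cols <- setdiff(names(results), c("role", "family", "condition"))
  out <- purrr::pmap_dfr(cells, function(role, family) {
    row <- tibble::tibble(role = role, family = family)
    for (cond in c("with_z", "without_z")) {
      sub <- results[results$role == role & results$family == family &
                       results$condition == cond, , drop = FALSE]
      for (col in value_cols) {
        row[[paste0(col, "_", cond)]] <-
          if (nrow(sub) == 1) sub[[col]][1] else NA_real_
      }
    }
    row
  })
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Latent-need classification: with vs without Z-score selection\n")
  NextMethod()
  cfg <- attr(x, "config")
  if (length(cfg) > 0) {
    cat("config:", jsonlite::toJSON(cfg, auto_unbox = TRUE), "\n")
  }
  invisible(x)
}
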