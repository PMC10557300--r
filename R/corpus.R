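#' Interview-record corpora
#'
#' A corpus is a tibble with one row per *record* — all sentences a subject
#' utters in answer to one interviewer question, the unit of classification.
#' Columns:
#' \describe{
#'   \item{record_id}{unique non-empty string}
#'   \item{role}{`"patient"` or `"caregiver"`}
#'   \item{text}{UTF-8 transcript text (may be empty)}
#'   \item{marker_flag}{logical; `TRUE` if an expectation-adverb marker was
#'     found (see [annotate_markers()]); `NA` if not yet annotated}
#'   \item{label}{gold latent-need label, `"yes"`/`"no"`, or `NA` if unlabelled.
#'     The label comes from human review; the pipeline trains on `label`,
#'     never on `marker_flag`, which is only a candidate indicator.}
#'   \item{annotator_labels}{list column; each element a data frame with
#'     columns `annotator_id`, `label`, or `NULL`}
#' }
#'
#' @param records A data frame with at least `record_id`, `role`, `text`.
#' @param metadata Named list stored as the `"metadata"` attribute
#'   (e.g. source, generator seed).
#' @return A validated corpus tibble (class `needs_corpus`).
#' @export
corpus <- function(records, metadata = list()) {
  records <- tibble::as_tibble(records)
  required <- c("record_id", "role", "text")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    rlang::abort(paste0("corpus is missing required column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (!"marker_flag" %in% names(records)) records$marker_flag <- NA
  if (!"label" %in% names(records)) records$label <- NA_character_
  if (!"annotator_labels" %in% names(records)) {
    records$annotator_labels <- vector("list", nrow(records))
  }
  records$record_id <- as.character(records$record_id)
  records$role <- as.character(records$role)
  records$text <- stringi::stri_trans_nfc(as.character(records$text))
  records$marker_flag <- as.logical(records$marker_flag)
  records$label <- as.character(records$label)
  validate_corpus(records)
  records <- records[, c("record_id", "role", "text", "marker_flag",
                         "label", "annotator_labels")]
  structure(records,
            metadata = metadata,
            class = c("needs_corpus", class(tibble::tibble())))
}

validate_corpus <- function(records) {
  if (anyNA(records$record_id) || any(records$record_id == "")) {
    rlang::abort("record_id must be non-empty for every record")
  }
  dup <- records$record_id[duplicated(records$record_id)]
  if (length(dup) > 0) {
    rlang::abort(paste0("duplicate record_id: ",
                        paste(unique(dup), collapse = ", ")))
  }
  bad_role <- setdiff(unique(records$role), c("patient", "caregiver"))
  if (length(bad_role) > 0) {
    rlang::abort(paste0("unknown role value(s): ",
                        paste(bad_role, collapse = ", "),
                        " (expected patient or caregiver)"))
  }
  bad_label <- setdiff(stats::na.omit(unique(records$label)), c("yes", "no"))
  if (length(bad_label) > 0) {
    rlang::abort(paste0("label must be yes, no or unset; got: ",
                        paste(bad_label, collapse = ", ")))
  }
  invisible(records)
}

corpus_metadata <- function(x) attr(x, "metadata") %||% list()

#' Read a corpus from JSONL or CSV
#'
#' JSONL carries the full record including `annotator_labels`; CSV carries the
#' flat columns `record_id`, `role`, `text`, `marker_flag`, `label` (comma
#' separated, quoted fields, header row, UTF-8 without BOM). Unset labels are
#' stored as JSON `null` / empty CSV field, never as `"no"`.
#'
#' @param path File path.
#' @param format `"jsonl"` or `"csv"`.
#' @return A corpus tibble; the number of records read is reported with a
#'   message.
#' @export
read_corpus <- function(path, format = c("jsonl", "csv")) {
  format <- rlang::arg_match(format)
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  out <- switch(format,
    jsonl = read_corpus_jsonl(path),
    csv   = read_corpus_csv(path)
  )
  rlang::inform(paste0("read ", nrow(out), " record(s) from ", path))
  out
}

read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- purrr::imap(lines, function(line, i) {
    obj <- tryCatch(jsonlite::fromJSON(line, simplifyVector = TRUE),
                    error = function(e) {
                      rlang::abort(paste0("malformed JSONL at line ", i, ": ",
                                          conditionMessage(e)))
                    })
    for (key in c("record_id", "role", "text")) {
      if (is.null(obj[[key]])) {
        rlang::abort(paste0("malformed JSONL at line ", i,
                            ": missing key '", key, "'"))
      }
    }
    obj
  })
  ann <- purrr::map(recs, function(obj) {
    al <- obj$annotator_labels
    if (is.null(al) || (is.data.frame(al) && nrow(al) == 0)) return(NULL)
    if (!is.data.frame(al)) al <- as.data.frame(al, stringsAsFactors = FALSE)
    tibble::as_tibble(al[, c("annotator_id", "label")])
  })
  scalar_chr <- function(key) {
    purrr::map_chr(recs, function(o) {
      v <- o[[key]]
      if (is.null(v) || length(v) == 0 || is.na(v[1])) NA_character_ else as.character(v[1])
    })
  }
  tbl <- tibble::tibble(
    record_id = scalar_chr("record_id"),
    role = scalar_chr("role"),
    text = purrr::map_chr(recs, function(o) as.character(o$text %||% "")),
    marker_flag = purrr::map_lgl(recs, function(o) {
      v <- o$marker_flag
      if (is.null(v) || length(v) == 0) NA else as.logical(v[1])
    }),
    label = scalar_chr("label"),
    annotator_labels = ann
  )
  corpus(tbl, metadata = list(source = path))
}

read_corpus_csv <- function(path) {
  tbl <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = "", progress = FALSE, show_col_types = FALSE
  )
  for (key in c("record_id", "role", "text")) {
    if (!key %in% names(tbl)) {
      rlang::abort(paste0("CSV corpus is missing column '", key, "'"))
    }
  }
  tbl$text[is.na(tbl$text)] <- ""
  if ("marker_flag" %in% names(tbl)) {
    tbl$marker_flag <- as.logical(tbl$marker_flag)
  }
  corpus(tbl, metadata = list(source = path))
}

#' Write a corpus to JSONL or CSV
#'
#' The written file is re-readable by [read_corpus()] with full fidelity,
#' including unset optional fields (serialized as JSON `null` / empty CSV
#' fields, never coerced to `"no"`).
#'
#' @param x A corpus.
#' @param path Output file path.
#' @param format `"jsonl"` or `"csv"`. CSV does not carry `annotator_labels`.
#' @export
write_corpus <- function(x, path, format = c("jsonl", "csv")) {
  format <- rlang::arg_match(format)
  if (nrow(x) == 0) rlang::abort("refusing to write an empty corpus")
  if (format == "jsonl") {
    lines <- purrr::pmap_chr(
      list(x$record_id, x$role, x$text, x$marker_flag, x$label,
           x$annotator_labels),
      function(id, role, text, flag, label, ann) {
        obj <- list(record_id = id, role = role, text = text,
                    marker_flag = flag, label = label)
        if (!is.null(ann) && nrow(ann) > 0) obj$annotator_labels <- ann
        jsonlite::toJSON(obj, auto_unbox = TRUE, na = "null")
      }
    )
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, useBytes = TRUE)
  } else {
    flat <- tibble::as_tibble(x)[, c("record_id", "role", "text",
                                     "marker_flag", "label")]
    readr::write_csv(flat, path, na = "", progress = FALSE)
  }
  invisible(path)
}

#' Marker lexica of expectation adverbs
#'
#' Records containing an adverb that signals an "expectation" are candidate
#' carriers of a latent need. The default lexicon holds the surface strings
#' used for the dementia interview corpora: "it would be good to have"
#' (あるといい), "good" (いい), "after all" (やっぱり), and "still"
#' (やっぱ / やはり).
#'
#' @return Character vector of marker strings (class `marker_lexicon`).
#' @export
default_marker_lexicon <- function() {
  marker_lexicon(c("あるといい", "いい", "やっぱり", "やっぱ", "やはり"))}

#' @rdname default_marker_lexicon
#' @param markers Character vector of non-empty marker strings; duplicates are
#'   rejected.
#' @export
marker_lexicon <- function(markers) {
  markers <- stringi::stri_trans_nfc(as.character(markers))
  if (length(markers) == 0) rlang::abort("marker lexicon must be non-empty")
  if (anyNA(markers) || any(markers == "")) {
    rlang::abort("marker lexicon must not contain empty strings")
  }
  if (anyDuplicated(markers)) {
    rlang::abort(paste0("duplicate marker(s): ",
                        paste(unique(markers[duplicated(markers)]),
                              collapse = ", ")))
  }
  structure(markers, class = "marker_lexicon")
}

#' @rdname default_marker_lexicon
#' @param path Plain-text file, one marker per line, UTF-8; lines starting
#'   with `#` are comments, blank lines are skipped.
#' @export
read_marker_lexicon <- function(path) {
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  marker_lexicon(lines)
}

#' Flag records that contain a marker adverb
#'
#' Sets `marker_flag` to `TRUE` iff at least one marker occurs as a plain
#' substring of the record text (no tokenization: markers are surface strings,
#' and a short marker inside a longer one must still flag). The flag is
#' boolean, so multiple hits are not double-counted. Idempotent; text is
#' never modified.
#'
#' @param x A corpus.
#' @param lexicon A [marker_lexicon()]; defaults to [default_marker_lexicon()].
#' @return The corpus with `marker_flag` filled in for every record.
#' @export
annotate_markers <- function(x, lexicon = default_marker_lexicon()) {
  if (length(lexicon) == 0) rlang::abort("marker lexicon must be non-empty")
  flag <- rep(FALSE, nrow(x))
  for (m in lexicon) {
    flag <- flag | stringr::str_detect(x$text, stringr::fixed(m))
  }
  x$marker_flag <- flag
  x
}

#' Reconcile independent annotator labels
#'
#' Emulates the two-researcher review step: records where all annotators agree
#' get `label` set to the agreed value; records with disagreeing annotators are
#' left unset and listed in the report (resolution is a human step, not
#' performed here); records with no annotator labels are listed as unlabelled.
#'
#' @param x A corpus whose records carry `annotator_labels`.
#' @return A list with `corpus` (labels filled where unanimous) and `report`
#'   (tibble of record_id, status `"disagreement"`/`"unlabelled"`, and the
#'   labels given).
#' @export
reconcile_labels <- function(x) {
  status <- character(0); ids <- character(0); given <- character(0)
  for (i in seq_len(nrow(x))) {
    ann <- x$annotator_labels[[i]]
    labs <- if (is.null(ann)) character(0) else as.character(ann$label)
    if (length(labs) == 0) {
      ids <- c(ids, x$record_id[i]); status <- c(status, "unlabelled")
      given <- c(given, "")
    } else if (length(unique(labs)) == 1) {
      x$label[i] <- labs[1]
    } else {
      ids <- c(ids, x$record_id[i]); status <- c(status, "disagreement")
      given <- c(given, paste(labs, collapse = ","))
      x$label[i] <- NA_character_
    }
  }
  list(corpus = x,
       report = tibble::tibble(record_id = ids, status = status,
                               annotator_labels = given))
}
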