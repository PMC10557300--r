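#' Per-class Z-scores of morpheme counts
#'
#' For each morpheme m in the class vocabulary,
#' z(m) = (count(m) - mu) / sigma, where mu and sigma are the mean and
#' standard deviation of occurrence counts over all morphemes of the class.
#' When sigma is 0 (all counts equal) the table is degenerate: all z are 0
#' and a warning is emitted — selection is then driven by the other class.
#'
#' @param table A `count_table` from [build_count_table()].
#' @return A `z_table`: list with `class_tag`, named numeric `z`, `mu`,
#'   `sigma`, and logical `degenerate`.
#' @export
zscores <- function(table) {
  stopifnot(inherits(table, "count_table"))
  if (length(table$counts) == 0) rlang::abort("empty count table")
  degenerate <- table$sigma == 0
  z <- if (degenerate) {
    rlang::warn(paste0("sigma is 0 for ", table$class_tag,
                       "; all Z-scores set to 0 (degenerate class)"))
    stats::setNames(rep(0, length(table$counts)), names(table$counts))
  } else {
    (table$counts - table$mu) / table$sigma
  }
  structure(list(class_tag = table$class_tag, z = z, mu = table$mu,
                 sigma = table$sigma, degenerate = degenerate),
            class = "z_table")
}

# z-score a class assigns to a morpheme it never saw: the score of count 0
zero_count_z <- function(ztab) {
  if (ztab$degenerate) 0 else (0 - ztab$mu) / ztab$sigma
}

#' Z-difference scores over the union vocabulary
#'
#' The selection statistic: for every morpheme in the union of the two class
#' vocabularies, sqrt((z_A - z_B)^2) = |z_A - z_B|, where A is the
#' latent-needs class and B the no-needs class. A morpheme absent from one
#' class gets that class's z-score at count 0, i.e. (0 - mu)/sigma — class
#' exclusive words are maximally discriminative and must remain scoreable,
#' not dropped.
#'
#' @param zA `z_table` for the needs class (`needs_yes`).
#' @param zB `z_table` for the no-needs class (`needs_no`).
#' @return A `diff_score_table`: list with named nonnegative `scores` and the
#'   aligned `zA`, `zB` vectors over the union vocabulary.
#' @export
z_difference <- function(zA, zB) {
  stopifnot(inherits(zA, "z_table"), inherits(zB, "z_table"))
  if (zA$class_tag != "needs_yes" || zB$class_tag != "needs_no") {
    rlang::abort("z_difference expects zA tagged needs_yes and zB needs_no")
  }
  if (zA$degenerate && zB$degenerate) {
    rlang::abort("both classes are degenerate (sigma = 0); no discriminative signal")
  }
  vocab <- sort(union(names(zA$z), names(zB$z)))
  za <- stats::setNames(rep(zero_count_z(zA), length(vocab)), vocab)
  za[names(zA$z)] <- zA$z
  zb <- stats::setNames(rep(zero_count_z(zB), length(vocab)), vocab)
  zb[names(zB$z)] <- zB$z
  scores <- sqrt((za - zb)^2)
  structure(list(scores = scores, zA = za, zB = zb),
            class = "diff_score_table")
}

#' Threshold-based morpheme selection
#'
#' Excludes morphemes whose Z-difference score falls strictly below a
#' threshold; ties at the threshold are kept. Three threshold strategies:
#'
#' * `fraction_of_max` (default): threshold = `fraction` x max(score) — the
#'   default reading of "scores less than 25% of the total are excluded".
#' * `quantile`: threshold = the nearest-rank `fraction`-quantile of the
#'   scores (a bottom-quartile cut at `fraction = 0.25`).
#' * `absolute`: threshold = `fraction` itself on the score scale.
#'
#' @param scores A `diff_score_table` from [z_difference()].
#' @param strategy Threshold strategy; see above.
#' @param fraction Number in \[0, 1\] (default 0.25).
#' @return A `selection_result`: list with `kept`, `excluded` (character
#'   vectors partitioning the union vocabulary), `threshold_value`,
#'   `strategy`, `fraction`.
#' @export
select_morphemes <- function(scores,
                             strategy = c("fraction_of_max", "quantile",
                                          "absolute"),
                             fraction = 0.25) {
  strategy <- rlang::arg_match(strategy)
  stopifnot(is.numeric(fraction), length(fraction) == 1,
            fraction >= 0, fraction <= 1)
  s <- scores$scores
  if (length(s) == 0) rlang::abort("empty score table")
  threshold <- switch(strategy,
    fraction_of_max = fraction * max(s),
    quantile = {
      idx <- ceiling(fraction * length(s))
      if (idx < 1) -Inf else sort(s)[idx]
    },
    absolute = fraction
  )
  excluded <- names(s)[s < threshold]
  kept <- setdiff(names(s), excluded)
  structure(list(kept = kept, excluded = excluded,
                 threshold_value = threshold, strategy = strategy,
                 fraction = fraction),
            class = "selection_result")
}

#' Export a selection audit table
#'
#' Writes one row per morpheme of the union vocabulary with its per-class
#' z-scores, difference score, and whether it was kept.
#'
#' @param scores A `diff_score_table`.
#' @param selection A `selection_result` computed from it.
#' @param path Output TSV path.
#' @return The audit tibble, invisibly written to `path` if given.
#' @export
selection_audit <- function(scores, selection, path = NULL) {
  vocab <- names(scores$scores)
  out <- tibble::tibble(
    morpheme = vocab,
    zA = unname(scores$zA[vocab]),
    zB = unname(scores$zB[vocab]),
    score = unname(scores$scores[vocab]),
    kept = vocab %in% selection$kept
  )
  if (!is.null(path)) readr::write_tsv(out, path, progress = FALSE)
  out
}
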