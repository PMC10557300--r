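test_that("z-scores standardize counts against the class vocabulary", {
  ct <- keys_table(c("a", "b", "b", "c", "c", "c"), "needs_yes")
  z <- zscores(ct)
  expect_equal(unname(z$z["c"]), (3 - 2) / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(unname(z$z["c"]), 1.2247, tolerance = 1e-4)
  expect_false(z$degenerate)
  expect_equal(mean(z$z), 0, tolerance = 1e-9)  # centering identity
})

test_that("a degenerate class (sigma = 0) yields all-zero z with a warning", {
  ct <- keys_table(c("a", "b", "c"), "needs_yes")
  expect_equal(ct$sigma, 0)
  expect_warning(z <- zscores(ct), "degenerate")
  expect_true(z$degenerate)
  expect_true(all(z$z == 0))
})

test_that("z-difference equals |zA - zB| on random tables (oracle)", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      vocabA <- paste0("m", sample(1:30, 15))
      vocabB <- paste0("m", sample(1:30, 15))
      zA <- manual_ztable(stats::setNames(rnorm(15), vocabA), "needs_yes",
                          mu = runif(1, 1, 3), sigma = runif(1, 0.5, 2))
      zB <- manual_ztable(stats::setNames(rnorm(15), vocabB), "needs_no",
                          mu = runif(1, 1, 3), sigma = runif(1, 0.5, 2))
    })
    d <- z_difference(zA, zB)
    vocab <- sort(union(vocabA, vocabB))
    expect_setequal(names(d$scores), vocab)
    # oracle: sqrt(d^2) = |d|, with absent morphemes at the class z of count 0
    za <- ifelse(vocab %in% vocabA, zA$z[vocab], (0 - zA$mu) / zA$sigma)
    zb <- ifelse(vocab %in% vocabB, zB$z[vocab], (0 - zB$mu) / zB$sigma)
    expect_equal(unname(d$scores[vocab]), abs(za - zb), tolerance = 1e-12)
    expect_true(all(d$scores >= 0))
  }
})

test_that("z-difference handles equal, opposite, and doubly degenerate input", {
  zA <- manual_ztable(c(m = 0.5), "needs_yes")
  zB <- manual_ztable(c(m = 0.5), "needs_no")
  expect_equal(unname(z_difference(zA, zB)$scores["m"]), 0)
  zB2 <- manual_ztable(c(m = -1.0), "needs_no")
  zA2 <- manual_ztable(c(m = 1.0), "needs_yes")
  expect_equal(unname(z_difference(zA2, zB2)$scores["m"]), 2.0)
  degA <- structure(list(class_tag = "needs_yes", z = c(m = 0), mu = 1,
                         sigma = 0, degenerate = TRUE), class = "z_table")
  degB <- structure(list(class_tag = "needs_no", z = c(m = 0), mu = 1,
                         sigma = 0, degenerate = TRUE), class = "z_table")
  expect_error(z_difference(degA, degB), "degenerate")
})

test_that("threshold selection follows the stated rule for each strategy", {
  d <- structure(list(scores = c(w1 = 0.1, w2 = 0.5, w3 = 1.0, w4 = 2.0)),
                 class = "diff_score_table")
  sel <- select_morphemes(d, "fraction_of_max", 0.25)
  expect_equal(sel$threshold_value, 0.5)
  expect_setequal(sel$excluded, "w1")
  expect_setequal(sel$kept, c("w2", "w3", "w4"))  # tie at threshold kept

  expect_setequal(select_morphemes(d, "fraction_of_max", 0)$kept,
                  names(d$scores))
  expect_setequal(select_morphemes(d, "quantile", 0.5)$excluded, "w1")
  expect_setequal(select_morphemes(d, "absolute", 0.6)$excluded,
                  c("w1", "w2"))

  flat <- structure(list(scores = c(a = 1, b = 1, c = 1)),
                    class = "diff_score_table")
  for (s in c("fraction_of_max", "quantile", "absolute")) {
    expect_length(select_morphemes(flat, s, if (s == "absolute") 1 else
      0.25)$excluded, 0)
  }
})

test_that("selection partitions the vocabulary and shrinks with the fraction", {
  for (seed in 1:10) {
    scores <- withr::with_seed(seed, structure(
      list(scores = stats::setNames(abs(rnorm(40)), paste0("m", 1:40))),
      class = "diff_score_table"))
    prev_kept <- NULL
    for (f in c(0, 0.1, 0.25, 0.5, 0.9, 1)) {
      for (strategy in c("fraction_of_max", "quantile")) {
        sel <- select_morphemes(scores, strategy, f)
        expect_setequal(c(sel$kept, sel$excluded), names(scores$scores))
        expect_length(intersect(sel$kept, sel$excluded), 0)
      }
      sel <- select_morphemes(scores, "fraction_of_max", f)
      if (!is.null(prev_kept)) expect_true(all(sel$kept %in% prev_kept))
      prev_kept <- sel$kept
    }
  }
})

test_that("planted discriminative words outscore background on average", {
  for (seed in c(2, 7)) {
    cfg <- synth_config(n_yes = 120, n_no = 120, vocab_background = 200,
                        vocab_discriminative = 10, vocab_idiosyncratic = 50,
                        effect = 4, seed = seed)
    co <- generate_corpus(cfg)
    ctA <- build_count_table(co[co$label == "yes", ], "needs_yes")
    ctB <- build_count_table(co[co$label == "no", ], "needs_no")
    d <- z_difference(zscores(ctA), zscores(ctB))
    planted <- intersect(planted_truth(cfg), names(d$scores))
    background <- setdiff(names(d$scores), planted)
    expect_gt(mean(d$scores[planted]), mean(d$scores[background]))
  }
})

test_that("the selection audit table lines up morphemes, scores and verdicts", {
  ct <- keys_table(c("a", "a", "b", "c", "c", "c"), "needs_yes")
  ct2 <- keys_table(c("a", "b", "b", "d"), "needs_no")
  d <- z_difference(zscores(ct), zscores(ct2))
  sel <- select_morphemes(d)
  path <- withr::local_tempfile(fileext = ".tsv")
  audit <- selection_audit(d, sel, path)
  expect_setequal(audit$morpheme, names(d$scores))
  expect_equal(audit$score, abs(audit$zA - audit$zB), tolerance = 1e-12)
  expect_equal(sum(audit$kept), length(sel$kept))
  expect_true(file.exists(path))
})
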