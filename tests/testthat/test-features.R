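test_that("smooth TF-IDF matches the hand-computed two-document case", {
  co <- corpus(tibble::tibble(
    record_id = c("d1", "d2"), role = "patient",
    text = c("a/名詞 a/名詞 b/名詞", "b/名詞"), label = c("yes", "no")))
  dtm <- tfidf(co, c("a", "b"), variant = "smooth")
  # N=2: idf(a) = ln(3/2)+1 (df 1), idf(b) = ln(3/3)+1 = 1 (df 2)
  raw_d1 <- c(2 * (log(3 / 2) + 1), 1)
  expect_equal(unname(dtm$weights["d1", ]), raw_d1 / sqrt(sum(raw_d1^2)),
               tolerance = 1e-12)
  expect_equal(unname(dtm$weights["d2", ]), c(0, 1), tolerance = 1e-12)
  expect_equal(sqrt(rowSums(dtm$weights^2)), c(d1 = 1, d2 = 1),
               tolerance = 1e-9)
})

test_that("raw TF-IDF zeroes ubiquitous terms; empty records give zero rows", {
  co <- corpus(tibble::tibble(
    record_id = c("d1", "d2"), role = "patient",
    text = c("a/名詞 b/名詞", "a/名詞"), label = c("yes", "no")))
  dtm <- tfidf(co, c("a", "b"), variant = "raw")
  expect_equal(unname(dtm$weights[, "a"]), c(0, 0))  # df = N -> idf 0
  expect_equal(unname(dtm$weights["d1", "b"]), 1 * log(2 / 1))

  with_empty <- corpus(tibble::tibble(
    record_id = c("d1", "d2"), role = "patient",
    text = c("a/名詞", ""), label = c("yes", "no")))
  expect_message(dtm2 <- tfidf(with_empty, c("a"), variant = "smooth"),
                 "no in-vocabulary tokens")
  expect_equal(unname(dtm2$weights["d2", ]), 0)
})

test_that("doubling a term count never lowers its unnormalized weight", {
  for (seed in 1:5) {
    co <- withr::with_seed(seed, corpus(tibble::tibble(
      record_id = paste0("d", 1:4), role = "patient",
      text = replicate(4, paste(paste0(sample(c("a", "b", "c"), 5,
                                              replace = TRUE), "/名詞"),
                                collapse = " ")),
      label = c("yes", "no", "yes", "no"))))
    doubled <- co
    doubled$text[1] <- paste(co$text[1], "a/名詞")
    for (variant in c("smooth", "raw")) {
      w1 <- tfidf(co, c("a", "b", "c"), variant = "raw")
      w2 <- tfidf(doubled, c("a", "b", "c"), variant = "raw")
      expect_gte(w2$weights["d1", "a"], w1$weights["d1", "a"])
    }
  }
})

test_that("undersampling balances classes at the published stratum sizes", {
  caregiver <- corpus(tibble::tibble(
    record_id = paste0("c", 1:7574), role = "caregiver", text = "x/名詞",
    label = rep(c("yes", "no"), c(343, 7231))))
  bal <- undersample(caregiver, seed = 1)
  expect_equal(nrow(bal), 686)
  expect_equal(sum(bal$label == "yes"), 343)
  expect_equal(sum(bal$label == "no"), 343)

  patient <- corpus(tibble::tibble(
    record_id = paste0("p", 1:2073), role = "patient", text = "x/名詞",
    label = rep(c("yes", "no"), c(63, 2010))))
  expect_equal(nrow(undersample(patient, seed = 1)), 126)
})

test_that("undersampling keeps every minority record and is seeded", {
  for (seed in 1:5) {
    co <- random_corpus(40, seed = 200 + seed)
    co$label <- withr::with_seed(seed, sample(c("yes", "no"), 40, TRUE,
                                              prob = c(0.2, 0.8)))
    if (min(table(co$label)) == 0) next
    bal <- undersample(co, seed = 9)
    tab <- table(bal$label)
    expect_equal(unname(tab["yes"]), unname(tab["no"]))
    minority <- names(which.min(table(co$label)))
    expect_setequal(bal$record_id[bal$label == minority],
                    co$record_id[co$label == minority])
    expect_identical(bal, undersample(co, seed = 9))
    expect_identical(undersample(bal, seed = 1), bal)  # balanced: unchanged
  }
  single <- corpus(tibble::tibble(record_id = "a", role = "patient",
                                  text = "x", label = "yes"))
  expect_error(undersample(single, seed = 1), "both classes")
})

test_that("the stratified split reproduces the published 70/30 counts", {
  bal686 <- corpus(tibble::tibble(
    record_id = paste0("c", 1:686), role = "caregiver", text = "x/名詞",
    label = rep(c("yes", "no"), each = 343)))
  spl <- split_records(bal686, train_fraction = 0.7, seed = 4)
  expect_length(spl$train, 480)
  expect_length(spl$test, 206)

  bal126 <- corpus(tibble::tibble(
    record_id = paste0("p", 1:126), role = "patient", text = "x/名詞",
    label = rep(c("yes", "no"), each = 63)))
  spl2 <- split_records(bal126, train_fraction = 0.7, seed = 4)
  expect_length(spl2$train, 88)
  expect_length(spl2$test, 38)

  bal10 <- corpus(tibble::tibble(
    record_id = paste0("x", 1:10), role = "patient", text = "x/名詞",
    label = rep(c("yes", "no"), each = 5)))
  spl3 <- split_records(bal10, seed = 1)
  expect_length(spl3$test, 4)   # ceiling(0.3 * 5) = 2 per class
  expect_length(spl3$train, 6)
})

test_that("splits partition the input with per-class ceiling test counts", {
  for (seed in 1:5) {
    co <- random_corpus(30, seed = 300 + seed)
    co$label <- rep(c("yes", "no"), 15)
    spl <- split_records(co, train_fraction = 0.7, seed = seed)
    expect_setequal(c(spl$train, spl$test), co$record_id)
    expect_length(intersect(spl$train, spl$test), 0)
    per_class <- table(co$label[match(spl$test, co$record_id)])
    expect_true(all(per_class == ceiling(0.3 * 15)))
    spl_b <- split_records(co, train_fraction = 0.7, seed = seed + 1000)
    expect_length(spl_b$test, length(spl$test))  # counts stable across seeds
  }
  tiny <- corpus(tibble::tibble(record_id = c("a", "b"), role = "patient",
                                text = "x", label = c("yes", "no")))
  expect_error(split_records(tiny, seed = 1), "fewer than 2")
})

test_that("document-term matrices survive the MTX round trip", {
  co <- toy_corpus()
  dtm <- suppressMessages(tfidf(co, c("薬", "散歩", "施設", "情報")))
  dir <- withr::local_tempdir()
  write_dtm(dtm, dir)
  back <- read_dtm(dir)
  expect_equal(back$weights, dtm$weights, tolerance = 1e-12)
  expect_equal(back$record_ids, dtm$record_ids)
  expect_equal(back$vocabulary, dtm$vocabulary)
  expect_equal(back$labels, dtm$labels)
})
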