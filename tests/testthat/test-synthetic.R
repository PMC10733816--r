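test_that("a clean corpus (p = 0) has no ledger entries and validates", {
  corpus <- generate_corpus(generator_config(n_reports = 5, seed = 12,
                                             cascade_noise_p = 0))
  expect_true(all(vapply(corpus$ledgers, nrow, integer(1)) == 0L))
  for (doc in corpus$documents)
    expect_identical(validate_document(doc), character())
  # p = 0 corruption is the identity
  d <- corpus$documents[[1]]
  out <- corrupt_cascade(d, p = 0, seed = 1)
  expect_identical(out$document$text, d$text)
  expect_identical(nrow(out$ledger), 0L)
})

test_that("generation is a pure function of configuration and seed", {
  c1 <- generate_corpus(generator_config(n_reports = 4, seed = 31))
  c2 <- generate_corpus(generator_config(n_reports = 4, seed = 31))
  for (i in seq_along(c1$documents)) {
    expect_identical(write_report(c1$documents[[i]]),
                     write_report(c2$documents[[i]]))
    expect_identical(c1$ledgers[[i]], c2$ledgers[[i]])
  }
  c3 <- generate_corpus(generator_config(n_reports = 4, seed = 32))
  expect_false(identical(c1$documents[[1]]$text, c3$documents[[1]]$text))
})

test_that("sentence and report lengths track the configured statistics", {
  corpus <- generate_corpus(generator_config(n_reports = 25, seed = 9))
  toks <- corpus_tokens(corpus$documents)
  per_sent <- dplyr::count(toks, doc_id, sentence_id)
  expect_lt(abs(mean(per_sent$n) - 11), 3)
  per_doc <- dplyr::count(toks, doc_id)
  expect_lt(abs(mean(per_doc$n) - 755) / 755, 0.15)
})

test_that("forced corruption produces the printed fused surface with a ledger entry", {
  doc <- deid_document("d", "The Psychiatry Chief attended today.")
  out <- corrupt_cascade(doc, p = 1, seed = 4)
  expect_match(out$document$text, "PsychiatryChief")
  expect_gte(nrow(out$ledger), 1L)
  # every ledger position is a destroyed boundary restorable by the rules
  toks <- preprocess_document(out$document)
  expect_identical(recovery_rate(out$ledger, toks), 1)
})

test_that("corrupted documents stay valid and ledger sites map to real positions", {
  corpus <- generate_corpus(generator_config(n_reports = 10, seed = 21,
                                             cascade_noise_p = 0.4))
  total <- 0L
  for (i in seq_along(corpus$documents)) {
    doc <- corpus$documents[[i]]
    led <- corpus$ledgers[[i]]
    total <- total + nrow(led)
    expect_identical(validate_document(doc), character())
    if (nrow(led)) {
      expect_true(all(led$position > 0 & led$position < nchar(doc$text)))
      expect_true(all(led$kind %in% c("deleted-space", "digit-word-fusion",
                                      "comma-joined-ids")))
    }
  }
  expect_gt(total, 0L)
})

test_that("comma-joined identifier sites are always recovered by rule R1", {
  corpus <- generate_corpus(generator_config(n_reports = 30, seed = 33,
                                             cascade_noise_p = 1))
  checked <- 0L
  for (i in seq_along(corpus$documents)) {
    led <- corpus$ledgers[[i]]
    led <- led[led$kind == "comma-joined-ids", ]
    if (!nrow(led)) next
    toks <- preprocess_document(corpus$documents[[i]])
    expect_identical(recovery_rate(led, toks), 1)
    checked <- checked + nrow(led)
  }
  expect_gt(checked, 5L)
})

test_that("without cascade rules no injected boundary is recovered", {
  corpus <- generate_corpus(generator_config(n_reports = 8, seed = 44,
                                             cascade_noise_p = 0.8))
  offs <- preprocess_config(cascade_rules = FALSE)
  rates <- purrr::imap_dbl(corpus$ledgers, function(led, i) {
    if (!nrow(led)) return(NA_real_)
    recovery_rate(led, preprocess_document(corpus$documents[[i]], offs))
  })
  rates <- rates[!is.na(rates)]
  expect_gt(length(rates), 0L)
  expect_identical(unique(rates), 0)
})

test_that("a written synthetic corpus round trips through the corpus reader", {
  dir <- withr::local_tempdir()
  cfg <- generator_config(n_reports = 9, seed = 3)
  corpus <- write_synthetic_corpus(cfg, dir)
  expect_identical(length(list.files(dir, pattern = "\\.xml$")), 9L)
  expect_true(file.exists(file.path(dir, "ledger.tsv")))
  splits <- read_corpus(dir, manifest = file.path(dir, "manifest.tsv"))
  expect_identical(lengths(splits)[c("train", "validation", "test")],
                   c(train = 3L, validation = 3L, test = 3L))
  back <- splits$train[[1]]
  orig <- corpus$documents[[match(back$doc_id,
                                  vapply(corpus$documents, `[[`,
                                         character(1), "doc_id"))]]
  expect_identical(back$text, orig$text)
})
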