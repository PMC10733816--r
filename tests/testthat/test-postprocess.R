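test_that("the six date shapes are detected and incomplete dates are not", {
  for (d in c("1/12/2000", "1-12-2000", "Jan/12/2000", "12/Jan/2000",
              "Jan-12-2000", "12-Jan-2000")) {
    hits <- detect_dates(paste("seen on", d, "today"))
    expect_identical(nrow(hits), 1L)
    expect_identical(hits$text, d)
    expect_identical(hits$category, "DATE")
  }
  expect_identical(nrow(detect_dates("ratio 13/13 noted")), 0L)
  expect_identical(nrow(detect_dates("13/13")), 0L)
})

test_that("phone detection requires exactly ten digits with boundary guards", {
  for (p in c("1234567890", "123.456.7890", "123-456-7890")) {
    hits <- detect_phones(paste("call", p, "now"))
    expect_identical(hits$text, p)
    expect_identical(hits$subcategory, "PHONE")
    expect_identical(nchar(gsub("\\D", "", hits$text)), 10L)
  }
  expect_identical(nrow(detect_phones("id 12345678901 end")), 0L)
  expect_identical(nrow(detect_phones("9123456789012")), 0L)
})

test_that("URL detection accepts scheme and www forms, not dotted words", {
  expect_identical(detect_urls("see http://example.org/x please")$text,
                   "http://example.org/x")
  expect_identical(detect_urls("at www.hospital.org.")$text,
                   "www.hospital.org")
  expect_identical(nrow(detect_urls("report.Dr reviewed")), 0L)
})

test_that("detector hits are deterministic, sorted, and non-overlapping", {
  txt <- "on 1/12/2000 call 123.456.7890 or visit www.lab.org; Jan-12-2000."
  h1 <- detect_rules(txt)
  h2 <- detect_rules(txt)
  expect_identical(h1, h2)
  expect_true(all(diff(h1$start) > 0))
  if (nrow(h1) > 1)
    expect_true(all(h1$start[-1] >= h1$end[-nrow(h1)]))
})

test_that("merge policy: disjoint adds, containment replaces, category conflict defers", {
  rule_hit <- function(cat, sub, s, e, txt, id = "R")
    tibble::tibble(category = cat, subcategory = sub, start = s, end = e,
                   text = txt, rule_id = id)
  # disjoint rule hit is added
  m <- merge_entities(empty_entities(),
                      rule_hit("DATE", NA, 0L, 8L, "1/1/2000"))
  expect_identical(nrow(m), 1L)
  # containing same-category hit replaces the model span
  model <- entity_tbl("DATE", NA, 5L, 9L, "2000")
  m2 <- merge_entities(model, rule_hit("DATE", NA, 5L, 14L, "2000-01-01"))
  expect_identical(m2$start, 5L)
  expect_identical(m2$end, 14L)
  # different category: model wins
  model3 <- entity_tbl("NAME", "DOCTOR", 5L, 9L, "Smit")
  m3 <- merge_entities(model3, rule_hit("DATE", NA, 5L, 9L, "Smit"))
  expect_identical(m3$category, "NAME")
  # covered characters of same-category model entities never shrink
  withr::with_seed(6, {
    for (rep in 1:25) {
      model_e <- random_entities(4, 60)
      hits <- dplyr::mutate(random_entities(3, 60), rule_id = "R")
      merged <- merge_entities(model_e, hits)
      for (cat in unique(model_e$category)) {
        cover <- function(e) {
          e <- e[e$category == cat, ]
          sum(e$end - e$start)
        }
        expect_gte(cover(merged), cover(model_e))
      }
      if (nrow(merged) > 1)
        expect_true(all(merged$start[-1] >= merged$end[-nrow(merged)]))
    }
  })
})

test_that("finalize composes decode and rules into a valid document", {
  txt <- "Nothing to see here."
  toks <- preprocess_document(deid_document("d", txt))
  toks$label <- rep("O", nrow(toks))
  out <- finalize_document("d", txt, toks, inventory = NULL)
  expect_identical(nrow(out$entities), 0L)

  # a date the tagger missed is recovered by the rules
  txt2 <- "Reviewed Jan-12-2000 by the team."
  toks2 <- preprocess_document(deid_document("d", txt2))
  toks2$label <- rep("O", nrow(toks2))
  out2 <- finalize_document("d", txt2, toks2)
  expect_identical(out2$entities$category, "DATE")
  expect_identical(out2$entities$text, "Jan-12-2000")
  expect_identical(validate_document(out2), character())
})
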