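test_that("strict and relaxed predicates behave as specified on the HMs case", {
  gold <- entity_tbl("NAME", "DOCTOR", 0L, 2L, "HM")
  pred <- entity_tbl("NAME", "DOCTOR", 0L, 3L, "HMs")
  expect_false(match_strict(pred, gold))
  expect_true(match_relaxed(pred, gold, tol = 2))
  expect_true(match_relaxed(pred, gold, tol = 1))
  # tol = 0 coincides with strict for same-type spans
  expect_identical(match_relaxed(pred, gold, tol = 0),
                   match_strict(pred, gold))
  # same span, different subcategory, subcategory granularity
  p2 <- entity_tbl("NAME", "PATIENT", 0L, 2L, "HM")
  expect_false(match_strict(p2, gold))
  expect_true(match_strict(p2, gold, granularity = "category"))
})

test_that("relaxed matching is monotone in the tolerance", {
  withr::with_seed(14, {
    for (rep in 1:50) {
      g <- list(start = sample(0:20, 1))
      g$end <- g$start + sample(1:6, 1)
      p <- list(start = sample(0:20, 1))
      p$end <- p$start + sample(1:6, 1)
      g <- c(g, list(category = "DATE", subcategory = NA_character_))
      p <- c(p, list(category = "DATE", subcategory = NA_character_))
      res <- vapply(c(0, 1, 2, 5), function(tol)
        match_relaxed(p, g, tol = tol), logical(1))
      expect_true(all(diff(res) >= 0))
    }
  })
})

test_that("the spanning-prediction scenario yields 1 FP and 2 FN under strict matching", {
  gold <- doc_ids()
  pred <- deid_document("ids", gold$text,
                        entity_tbl("ID", "IDNUM", 0L, 17L, gold$text))
  rep <- micro_evaluate(pred, gold, mode = "strict")
  expect_identical(rep$overall$tp, 0L)
  expect_identical(rep$overall$fp, 1L)
  expect_identical(rep$overall$fn, 2L)
})

test_that("perfect predictions score 1 and doc mismatches error", {
  docs <- small_corpus(n = 4)$documents
  rep <- micro_evaluate(docs, docs, mode = "strict")
  expect_identical(rep$overall$precision, 1)
  expect_identical(rep$overall$recall, 1)
  expect_identical(rep$overall$f1, 1)
  expect_error(micro_evaluate(docs[1:2], docs[3:4], mode = "strict"),
               "doc_id mismatch")
})

test_that("counts conserve totals and relaxed dominates strict", {
  withr::with_seed(88, {
    for (rep in 1:30) {
      txt <- strrep("x", 120)
      gold <- deid_document("d", txt, random_entities(6, 120),
                            warn_overlap = FALSE)
      pred <- deid_document("d", txt, random_entities(6, 120),
                            warn_overlap = FALSE)
      rs <- micro_evaluate(pred, gold, mode = "strict")
      rr <- micro_evaluate(pred, gold, mode = "relaxed", tol = 2)
      expect_identical(rs$overall$tp + rs$overall$fn,
                       nrow(gold$entities))
      expect_identical(rs$overall$tp + rs$overall$fp,
                       nrow(pred$entities))
      expect_identical(rr$overall$tp + rr$overall$fn,
                       nrow(gold$entities))
      expect_gte(rr$overall$tp, rs$overall$tp)
      expect_gte(rr$overall$f1, rs$overall$f1)
      # per-type rows sum to the pooled counts
      expect_identical(sum(rs$counts$tp), rs$overall$tp)
      expect_identical(sum(rs$counts$fp), rs$overall$fp)
      expect_identical(sum(rs$counts$fn), rs$overall$fn)
    }
  })
})

test_that("greedy matching attains the exhaustive maximum on non-overlapping sets", {
  withr::with_seed(19, {
    for (rep in 1:40) {
      txt <- strrep("x", 80)
      gold <- random_entities(sample(2:8, 1), 80)
      pred <- random_entities(sample(2:8, 1), 80)
      for (mode in c("strict", "relaxed")) {
        repd <- micro_evaluate(
          deid_document("d", txt, pred, warn_overlap = FALSE),
          deid_document("d", txt, gold, warn_overlap = FALSE),
          mode = mode, tol = 2)
        adj <- matrix(FALSE, nrow(gold), nrow(pred))
        for (g in seq_len(nrow(gold))) {
          for (p in seq_len(nrow(pred))) {
            adj[g, p] <- if (mode == "strict")
              match_strict(pred[p, ], gold[g, ]) else
              match_relaxed(pred[p, ], gold[g, ], tol = 2)
          }
        }
        expect_identical(repd$overall$tp, max_matching_bruteforce(adj))
      }
    }
  })
})

test_that("empty gold and prediction sets give flagged zeros, not errors", {
  d <- deid_document("d", "plain text")
  rep <- micro_evaluate(d, d, mode = "strict")
  expect_identical(rep$overall$precision, 0)
  expect_identical(rep$overall$recall, 0)
  expect_identical(rep$overall$f1, 0)
  expect_true(rep$overall$flagged)

  # empty predictions against real gold: recall 0, precision flagged-0
  g <- deid_document("d", "xxxxx", entity_tbl("DATE", NA, 0L, 4L, "xxxx"))
  p <- deid_document("d", "xxxxx")
  r2 <- micro_evaluate(p, g, mode = "strict")
  expect_identical(r2$overall$recall, 0)
  expect_identical(r2$overall$precision, 0)
})

test_that("the per-category report pools subcategories and reproduces the overall row", {
  docs <- small_corpus(n = 3)$documents
  rep <- micro_evaluate(docs, docs, mode = "strict")
  tab <- per_category_report(rep)
  ov <- tab[tab$level == "overall", ]
  expect_identical(ov$tp, rep$overall$tp)
  cat_rows <- tab[tab$level == "category", ]
  expect_identical(sum(cat_rows$tp), rep$overall$tp)
  # single-category corpus: category row equals overall row
  g <- deid_document("d", "xxxx xxxx",
                     entity_tbl("DATE", NA, 0L, 4L, "xxxx"))
  r1 <- micro_evaluate(g, g, mode = "strict")
  t1 <- per_category_report(r1)
  expect_identical(t1[t1$level == "category", ]$f1,
                   t1[t1$level == "overall", ]$f1)
})
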