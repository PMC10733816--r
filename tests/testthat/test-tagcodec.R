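scheme <- label_scheme("BIESO")

test_that("encoding follows the BIESO single/multi-token conventions", {
  toks <- tibble::tibble(text = "39", start = 0L, end = 2L)
  ents <- entity_tbl("AGE", NA, 0L, 2L, "39")
  expect_identical(encode_labels(toks, ents, scheme)$label, "S-AGE")

  toks2 <- tibble::tibble(text = c("John", "Smith"), start = c(0L, 5L),
                          end = c(4L, 10L))
  ents2 <- entity_tbl("NAME", "PATIENT", 0L, 10L, "John Smith")
  expect_identical(encode_labels(toks2, ents2, scheme)$label,
                   c("B-NAME_PATIENT", "E-NAME_PATIENT"))
  bio <- label_scheme("BIO")
  expect_identical(encode_labels(toks2, ents2, bio)$label,
                   c("B-NAME_PATIENT", "I-NAME_PATIENT"))
})

test_that("misaligned entities are clipped outward; excluded types stay O", {
  toks <- tibble::tibble(text = c("39Sex", "y"), start = c(0L, 6L),
                         end = c(5L, 7L))
  ents <- entity_tbl("AGE", NA, 0L, 2L, "39")
  expect_identical(encode_labels(toks, ents, scheme)$label, c("S-AGE", "O"))

  ents2 <- entity_tbl("ID", "BIOID", 0L, 5L, "39Sex")
  expect_identical(encode_labels(toks, ents2, scheme)$label, c("O", "O"))
})

test_that("repair normalizes orphans deterministically and idempotently", {
  expect_identical(repair_labels("I-DATE", scheme), "S-DATE")
  expect_identical(repair_labels(c("B-ID_IDNUM", "I-NAME_DOCTOR"), scheme),
                   c("S-ID_IDNUM", "S-NAME_DOCTOR"))
  expect_identical(repair_labels(c("B-DATE", "I-DATE", "E-DATE"), scheme),
                   c("B-DATE", "I-DATE", "E-DATE"))

  withr::with_seed(17, {
    labs_pool <- scheme$alphabet
    run_valid <- function(labels) {
      # validity grammar: runs are S or B I* E of one type; O outside
      ok <- TRUE
      i <- 1L
      while (i <= length(labels)) {
        l <- labels[i]
        if (l == "O") { i <- i + 1L; next }
        pre <- sub("-.*", "", l)
        tp <- sub("^[A-Z]+-", "", l)
        if (pre == "S") { i <- i + 1L; next }
        if (pre != "B") return(FALSE)
        i <- i + 1L
        while (i <= length(labels) &&
               labels[i] == paste0("I-", tp)) i <- i + 1L
        if (i > length(labels) || labels[i] != paste0("E-", tp))
          return(FALSE)
        i <- i + 1L
      }
      ok
    }
    for (rep in 1:200) {
      labs <- sample(labs_pool, sample(1:10, 1), replace = TRUE)
      rep1 <- repair_labels(labs, scheme)
      expect_true(run_valid(rep1))
      expect_identical(repair_labels(rep1, scheme), rep1)
    }
  })
})

test_that("decode recovers aligned entities exactly (round trip, both schemes)", {
  withr::with_seed(23, {
    for (sch in list(label_scheme("BIESO"), label_scheme("BIO"))) {
      for (rep in 1:40) {
        n_tok <- sample(3:12, 1)
        starts <- cumsum(c(0L, sample(3:6, n_tok - 1, replace = TRUE)))
        ends <- starts + sample(1:3, n_tok, replace = TRUE)  # never overlap
        txt <- strrep("x", max(ends))
        toks <- tibble::tibble(text = substr(rep(txt, n_tok), starts + 1,
                                             ends),
                               start = starts, end = ends)
        # pick disjoint token runs as entities
        k <- sample(0:3, 1)
        ents <- empty_entities()
        used <- rep(FALSE, n_tok)
        for (j in seq_len(k)) {
          free <- which(!used)
          if (!length(free)) break
          a <- sample(free, 1)
          b <- min(a + sample(0:2, 1), n_tok)
          if (any(used[a:b])) next
          used[a:b] <- TRUE
          tp <- shi_type_unkey(sample(sch$types, 1))
          ents <- dplyr::bind_rows(ents, tibble::tibble(
            category = tp$category, subcategory = tp$subcategory,
            start = starts[a], end = ends[b],
            text = substr(txt, starts[a] + 1, ends[b])))
        }
        tagged <- encode_labels(toks, ents, sch)
        got <- decode_labels(tagged, txt, sch)
        want <- entity_tbl(ents$category, ents$subcategory, ents$start,
                           ents$end, ents$text)
        expect_identical(as.data.frame(got), as.data.frame(want))
      }
    }
  })
})

test_that("decode agrees with the independent reference decoder on random labels", {
  withr::with_seed(41, {
    sch <- label_scheme("BIESO", types = c("DATE", "AGE", "ID_IDNUM"))
    for (rep in 1:500) {
      n_tok <- sample(1:8, 1)
      starts <- seq(0L, by = 3L, length.out = n_tok)
      ends <- starts + 2L
      labs <- sample(sch$alphabet, n_tok, replace = TRUE)
      tagged <- tibble::tibble(text = "xx", start = starts, end = ends,
                               label = labs)
      got <- decode_labels(tagged, strrep("x", max(ends)), sch)
      want <- reference_decode(labs, starts, ends, "BIESO")
      expect_identical(got$start, want$start)
      expect_identical(got$end, want$end)
      expect_identical(shi_type_key(got$category, got$subcategory),
                       want$type)
      # decoded spans never overlap
      if (nrow(got) > 1L)
        expect_true(all(got$start[-1] >= got$end[-nrow(got)]))
    }
  })
})
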