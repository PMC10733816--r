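key <- surrogate_key(2024)

test_that("name surrogates are consistent, distinct from originals, case-preserving", {
  expect_identical(surrogate_name("HM", key), surrogate_name("HM", key))
  dicts <- default_dictionaries()
  withr::with_seed(3, {
    names_pool <- c(sample(dicts$surnames, 400, replace = TRUE),
                    sample(dicts$given_names, 400, replace = TRUE),
                    replicate(200, paste0(
                      sample(LETTERS, 1),
                      paste(sample(letters, 5, TRUE), collapse = ""))))
    for (nm in sample(names_pool, 1000, replace = TRUE)) {
      repl <- surrogate_name(nm, key)
      expect_false(tolower(repl) == tolower(nm))
    }
  })
  # ALLCAPS originals yield ALLCAPS replacements
  expect_match(surrogate_name("SMITH", key), "^[A-Z]+$")
  expect_match(surrogate_name("Smith", key), "^[A-Z][a-z]+")
})

test_that("bucket selection follows the alphabet shift composed with the keyed map", {
  k0 <- surrogate_key(5, alpha_shift = 25)
  # reconstruct: initial -> shifted -> mapped; replacement must start there
  for (nm in c("Alpha", "Mint", "Zed")) {
    init <- match(toupper(substr(nm, 1, 1)), LETTERS)
    target <- LETTERS[k0$alpha_map[((init - 1 + 25) %% 26) + 1]]
    expect_identical(toupper(substr(surrogate_name(nm, k0), 1, 1)), target)
  }
})

test_that("date surrogates shift backward preserving format and intervals", {
  k365 <- surrogate_key(1, date_shift = 365)
  expect_identical(surrogate_date("1/12/2000", k365), "2/12/1999")
  # format preservation: dd-Mon-yyyy stays dd-Mon-yyyy, padding kept
  k30 <- surrogate_key(1, date_shift = 30)
  expect_match(surrogate_date("12-Jan-2000", k30),
               "^\\d{1,2}-[A-Z][a-z]{2}-\\d{4}$")
  expect_match(surrogate_date("05/03/2011", k30), "^\\d{2}/\\d{2}/\\d{4}$")
  # common shift preserves pairwise day differences
  d1 <- surrogate_date("10/06/2010", k30)
  d2 <- surrogate_date("20/06/2010", k30)
  parse_dmy <- function(x) {
    f <- as.integer(strsplit(x, "/")[[1]])
    as.Date(sprintf("%04d-%02d-%02d", f[3], f[2], f[1]))
  }
  expect_identical(as.integer(parse_dmy(d2) - parse_dmy(d1)), 10L)
  # calendar oracle: recovered shift equals the key's shift
  expect_identical(as.integer(as.Date("2010-06-10") - parse_dmy(d1)), 30L)
})

test_that("structured surrogates preserve exact character patterns", {
  r <- surrogate_structured("12G00123", "ID_IDNUM", key)
  expect_match(r, "^\\d{2}[A-Z]\\d{5}$")
  expect_false(r == "12G00123")
  r2 <- surrogate_structured("123-456-7890", "CONTACT_PHONE", key)
  expect_identical(substr(r2, 4, 4), "-")
  expect_identical(substr(r2, 8, 8), "-")
  expect_match(r2, "^\\d{3}-\\d{3}-\\d{4}$")
  # keyed determinism vs key sensitivity
  expect_identical(surrogate_structured("12G00123", "ID_IDNUM", key),
                   surrogate_structured("12G00123", "ID_IDNUM", key))
  others <- vapply(1:200, function(s)
    surrogate_structured("12G00123", "ID_IDNUM", surrogate_key(s)),
    character(1))
  expect_gt(length(unique(others)), 150)
})

test_that("age jitter stays within two years and locations swap within dictionaries", {
  ages <- vapply(1:50, function(s)
    surrogate_other("39", "AGE", NA, surrogate_key(s)), character(1))
  expect_true(all(ages %in% c("37", "38", "40", "41")))
  dicts <- default_dictionaries()
  city <- surrogate_other("Melbourne", "LOCATION", "CITY", key)
  expect_true(city %in% dicts$cities)
  expect_identical(surrogate_other("Melbourne", "LOCATION", "CITY", key),
                   city)
})

test_that("document surrogation preserves structure and never leaks surfaces", {
  empty <- deid_document("e", "No entities at all.")
  out <- apply_surrogates(empty, key)
  expect_identical(out$text, empty$text)

  corpus <- small_corpus(n = 10, seed = 555)
  for (doc in corpus$documents) {
    out <- apply_surrogates(doc, key)
    expect_identical(nrow(out$entities), nrow(doc$entities))
    expect_identical(validate_document(out), character())
    expect_length(attr(out, "leaks"), 0L)
    # non-entity text is unchanged: strip entity spans from both sides
    strip <- function(d) {
      kept <- strsplit(d$text, "")[[1]]
      for (i in seq_len(nrow(d$entities)))
        kept[(d$entities$start[i] + 1):d$entities$end[i]] <- NA
      paste(kept[!is.na(kept)], collapse = "")
    }
    expect_identical(strip(out), strip(doc))
    # consistency: identical (surface, type) pairs map identically
    map <- attr(out, "surrogate_map")
    per <- dplyr::distinct(map)
    expect_false(any(duplicated(paste(per$original, per$type))))
  }
})
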