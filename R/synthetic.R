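#' Default per-report SHI entity rates for the synthetic generator
#'
#' Expected entity counts per report by type (Poisson means). The defaults
#' give roughly 18 SHI entities per report across six modeled categories,
#' with dates and clinician names most frequent and PROFESSION deliberately
#' rare, spanning the breadth of the annotation taxonomy.
#'
#' @return Named numeric vector keyed by type.
#' @export
default_entity_rates <- function() {
  c(DATE = 4, NAME_DOCTOR = 2.5, NAME_PATIENT = 1.5,
    ID_IDNUM = 3, ID_MEDICALRECORD = 1.5,
    LOCATION_HOSPITAL = 1.5, LOCATION_CITY = 0.8, LOCATION_STREET = 0.5,
    LOCATION_ZIP = 0.5, LOCATION_STATE = 0.4,
    CONTACT_PHONE = 0.8, CONTACT_URL = 0.3,
    AGE = 0.8, PROFESSION = 0.4)
}

#' Synthetic corpus generator configuration
#'
#' The generator emulates the structure of a de-identification corpus of
#' pathology reports: templated sentences averaging 11 tokens, reports
#' averaging 755 tokens, slot-filled SHI entities with exact gold offsets,
#' and optional cascaded-token noise (deleted spaces, digit-word fusions,
#' comma-joined identifier pairs) injected at rate `cascade_noise_p` per
#' eligible site.
#'
#' @param n_reports Number of reports.
#' @param seed Generation seed; generation is a pure function of
#'   `(config, seed)`.
#' @param rates Per-type Poisson means, see [default_entity_rates()].
#' @param mean_sentence_tokens Target mean sentence length in tokens.
#' @param mean_report_tokens Target mean report length in tokens.
#' @param cascade_noise_p Per-site corruption probability in `[0, 1]`.
#' @param dictionaries Slot-filler dictionaries ([default_dictionaries()]).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_reports = 100L, seed = 1L,
                             rates = default_entity_rates(),
                             mean_sentence_tokens = 11,
                             mean_report_tokens = 755,
                             cascade_noise_p = 0.05,
                             dictionaries = default_dictionaries()) {
  stopifnot(all(rates >= 0), cascade_noise_p >= 0, cascade_noise_p <= 1)
  structure(list(n_reports = as.integer(n_reports), seed = as.integer(seed),
                 rates = rates,
                 mean_sentence_tokens = mean_sentence_tokens,
                 mean_report_tokens = mean_report_tokens,
                 cascade_noise_p = cascade_noise_p,
                 dictionaries = dictionaries),
            class = "generator_config")
}

# ---- slot fillers (consume the active RNG stream) ------------------------

.render_random_date <- function() {
  d <- sample(1:28, 1); m <- sample(1:12, 1); y <- sample(1985:2020, 1)
  mon <- month.abb[m]
  shape <- sample(6L, 1)
  pad <- function(v) if (stats::runif(1) < 0.3) sprintf("%02d", v) else v
  switch(shape,
         paste(pad(d), pad(m), y, sep = "/"),
         paste(pad(d), pad(m), y, sep = "-"),
         paste(mon, pad(d), y, sep = "/"),
         paste(pad(d), mon, y, sep = "/"),
         paste(mon, pad(d), y, sep = "-"),
         paste(pad(d), mon, y, sep = "-"))
}

.render_random_phone <- function() {
  ds <- paste0(sample(2:9, 1),
               paste(sample(0:9, 9, TRUE), collapse = ""))
  switch(sample(3L, 1),
         ds,
         paste(substr(ds, 1, 3), substr(ds, 4, 6), substr(ds, 7, 10),
               sep = "."),
         paste(substr(ds, 1, 3), substr(ds, 4, 6), substr(ds, 7, 10),
               sep = "-"))
}

.fill_slot <- function(type, dicts) {
  pick <- function(x) x[sample.int(length(x), 1)]
  switch(type,
    NAME_PATIENT = ,
    NAME_DOCTOR = if (stats::runif(1) < 0.7)
      c(pick(dicts$given_names), pick(dicts$surnames))
    else pick(dicts$surnames),
    PROFESSION = pick(dicts$professions),
    LOCATION_HOSPITAL = strsplit(pick(dicts$hospitals), " ")[[1]],
    LOCATION_CITY = pick(dicts$cities),
    LOCATION_STREET = c(as.character(sample(1:99, 1)),
                        strsplit(pick(dicts$streets), " ")[[1]]),
    LOCATION_ZIP = sprintf("%04d", sample(800:7999, 1)),
    LOCATION_STATE = strsplit(pick(dicts$states), " ")[[1]],
    AGE = as.character(sample(18:95, 1)),
    DATE = .render_random_date(),
    CONTACT_PHONE = .render_random_phone(),
    CONTACT_URL = if (stats::runif(1) < 0.5)
      paste0("www.", tolower(gsub(" ", "", pick(dicts$cities))), ".org")
    else paste0("http://results.", tolower(pick(dicts$cities)), ".org/report"),
    ID_IDNUM = sprintf("%02d%s%05d", sample(10:99, 1), pick(LETTERS),
                       sample(0:99999, 1)),
    ID_MEDICALRECORD = sprintf("%07d", sample(1000000:9999999, 1)),
    stop("no filler for type ", type)
  )
}

# entity sentence templates: "{TYPE}" marks the slot
.entity_templates <- function() {
  list(
    DATE = list(
      c("Specimen", "collected", "on", "{DATE}", "and", "processed",
        "routinely", "."),
      c("The", "report", "was", "issued", "on", "{DATE}", "by", "the",
        "duty", "pathologist", "."),
      c("Previous", "biopsy", "dated", "{DATE}", "was", "reviewed", "for",
        "comparison", ".")),
    NAME_DOCTOR = list(
      c("The", "case", "was", "discussed", "with", "Dr", "{NAME_DOCTOR}",
        "at", "the", "multidisciplinary", "meeting", "."),
      c("Report", "electronically", "authorised", "by", "Dr",
        "{NAME_DOCTOR}", "."),
      c("Referring", "clinician", ":", "Dr", "{NAME_DOCTOR}", ".")),
    NAME_PATIENT = list(
      c("Patient", "{NAME_PATIENT}", "presented", "for", "review", "of",
        "the", "lesion", "."),
      c("Re", ":", "{NAME_PATIENT}", ".")),
    PROFESSION = list(
      c("The", "patient", "is", "employed", "as", "a", "{PROFESSION}",
        "and", "reports", "no", "exposures", ".")),
    LOCATION_HOSPITAL = list(
      c("Referred", "from", "{LOCATION_HOSPITAL}", "for", "further",
        "assessment", "."),
      c("Slides", "were", "forwarded", "to", "{LOCATION_HOSPITAL}", "for",
        "expert", "opinion", ".")),
    LOCATION_CITY = list(
      c("The", "patient", "recently", "relocated", "to", "{LOCATION_CITY}",
        "with", "family", ".")),
    LOCATION_STREET = list(
      c("Residing", "at", "{LOCATION_STREET}", "at", "the", "time", "of",
        "admission", ".")),
    LOCATION_ZIP = list(
      c("Postcode", "recorded", "as", "{LOCATION_ZIP}", "on", "the",
        "request", "form", ".")),
    LOCATION_STATE = list(
      c("Transferred", "from", "the", "{LOCATION_STATE}", "health",
        "service", "network", ".")),
    AGE = list(
      c("Age", ":", "{AGE}", "Sex", ":", "M"),
      c("The", "patient", "is", "{AGE}", "years", "old", "with", "a",
        "significant", "history", ".")),
    CONTACT_PHONE = list(
      c("Laboratory", "contact", "number", ":", "{CONTACT_PHONE}", "for",
        "enquiries", ".")),
    CONTACT_URL = list(
      c("Results", "are", "available", "at", "{CONTACT_URL}", "for",
        "registered", "users", ".")),
    ID_IDNUM = list(
      c("Lab", "No", ":", "{ID_IDNUM}", "."),
      c("Specimen", "identifier", "{ID_IDNUM}", "was", "assigned", "at",
        "accession", ".")),
    ID_IDNUM_PAIR = list(
      c("Lab", "Nos", ":", "{ID_IDNUM}", ",", "{ID_IDNUM}", ".")),
    ID_MEDICALRECORD = list(
      c("MRN", ":", "{ID_MEDICALRECORD}", "."),
      c("Medical", "record", "number", "{ID_MEDICALRECORD}", "was",
        "confirmed", "at", "reception", "."))
  )
}

.filler_templates <- function() {
  list(
    c("MACROSCOPIC", "DESCRIPTION", ":"),
    c("MICROSCOPIC", "DESCRIPTION", ":"),
    c("The", "specimen", "was", "received", "fresh", "and", "sectioned",
      "serially", "at", "three", "levels", "."),
    c("Sections", "show", "fragments", "of", "benign", "glandular",
      "tissue", "with", "no", "cytological", "atypia", "."),
    c("There", "is", "no", "evidence", "of", "malignancy", "in", "any",
      "of", "the", "sampled", "material", "."),
    c("Immunohistochemical", "stains", "were", "performed", "and",
      "reviewed", "with", "appropriate", "controls", "."),
    c("The", "surgical", "margins", "appear", "clear", "of", "tumour",
      "involvement", "on", "all", "examined", "levels", "."),
    c("A", "single", "fragment", "of", "tan", "tissue", "measuring", "up",
      "to", "12", "mm", "is", "submitted", "in", "toto", "."),
    c("Correlation", "with", "the", "clinical", "findings", "and",
      "imaging", "is", "recommended", "."),
    c("No", "granulomas", "or", "viral", "inclusions", "are", "identified",
      "in", "the", "examined", "sections", "."),
    c("Representative", "sections", "are", "embedded", "in", "four",
      "blocks", "following", "standard", "protocol", "."),
    c("The", "appearances", "are", "consistent", "with", "chronic",
      "nonspecific", "inflammation", "of", "mild", "degree", "."),
    c("Deeper", "levels", "were", "examined", "and", "show", "similar",
      "histological", "features", "throughout", "."),
    c("The", "overall", "features", "favour", "a", "reactive", "process",
      "rather", "than", "a", "neoplastic", "one", "."))
}

# build one report's sentences; returns list(tokens, sentence_id, ents)
.build_report_sentences <- function(cfg) {
  ents_templates <- .entity_templates()
  fillers <- .filler_templates()
  sent <- list()
  ents <- list()
  # entity-bearing sentences
  for (type in names(cfg$rates)) {
    k <- stats::rpois(1, cfg$rates[[type]])
    while (k > 0L) {
      if (type == "ID_IDNUM" && k >= 2L && stats::runif(1) < 0.4) {
        tpl <- ents_templates$ID_IDNUM_PAIR[[1]]
        k <- k - 2L
      } else {
        tpls <- ents_templates[[type]]
        tpl <- tpls[[sample.int(length(tpls), 1)]]
        k <- k - 1L
      }
      toks <- character(); slots <- list()
      for (t in tpl) {
        if (grepl("^\\{", t)) {
          stype <- gsub("[{}]", "", t)
          filler <- .fill_slot(stype, cfg$dictionaries)
          slots[[length(slots) + 1L]] <-
            list(type = stype, from = length(toks) + 1L,
                 to = length(toks) + length(filler))
          toks <- c(toks, filler)
        } else {
          toks <- c(toks, t)
        }
      }
      sent[[length(sent) + 1L]] <- list(tokens = toks, slots = slots)
    }
  }
  n_entity_tokens <- sum(vapply(sent, function(s) length(s$tokens), integer(1)))
  target <- max(80, round(stats::rnorm(1, cfg$mean_report_tokens,
                                       cfg$mean_report_tokens / 6)))
  mean_filler <- mean(lengths(fillers))
  n_fill <- max(3L, round((target - n_entity_tokens) / mean_filler))
  for (i in seq_len(n_fill)) {
    tpl <- fillers[[sample.int(length(fillers), 1)]]
    sent[[length(sent) + 1L]] <- list(tokens = tpl, slots = list())
  }
  sent[sample.int(length(sent))]
}

# typography: no space before closing punctuation
.no_space_before <- c(".", ",", ";", ":", ")", "?", "!")

# assemble sentences into text + gold entities with exact offsets
.assemble_report <- function(doc_id, sentences) {
  tokens <- unlist(lapply(sentences, `[[`, "tokens"))
  sent_len <- vapply(sentences, function(s) length(s$tokens), integer(1))
  sent_id <- rep(seq_along(sentences), sent_len)
  first_of_sent <- !duplicated(sent_id)
  sep <- ifelse(first_of_sent, "\n", ifelse(tokens %in% .no_space_before,
                                            "", " "))
  sep[1] <- ""
  widths <- nchar(tokens)
  starts <- cumsum(nchar(sep) + widths) - widths          # 0-based
  text <- paste0(sep, tokens, collapse = "")
  offset <- c(0L, cumsum(sent_len))
  ents <- list()
  for (si in seq_along(sentences)) {
    for (sl in sentences[[si]]$slots) {
      from <- offset[si] + sl$from; to <- offset[si] + sl$to
      tp <- shi_type_unkey(sl$type)
      s <- starts[from]; e <- starts[to] + widths[to]
      ents[[length(ents) + 1L]] <- tibble::tibble(
        category = tp$category, subcategory = tp$subcategory,
        start = as.integer(s), end = as.integer(e),
        text = substr0(text, s, e))
    }
  }
  ents <- if (length(ents)) dplyr::bind_rows(ents) else empty_entities()
  # drop exact duplicate placements (possible when two identical fillers land
  # in the same report at identical offsets is impossible, but identical
  # (start,end,type) could arise only through duplicated slots; guard anyway)
  ents <- ents[!duplicated(ents[, c("start", "end", "category",
                                    "subcategory")]), ]
  deid_document(doc_id, text, ents, warn_overlap = FALSE)
}

#' Inject cascaded-token noise into a document
#'
#' With probability `p` per eligible site, deletes the space between two
#' capitalizable words (`"Psychiatry Chief"` to `"PsychiatryChief"`), fuses
#' a number with a following capitalized word (`"39 Sex"` to `"39Sex"`), or
#' joins two adjacent identifier entities across their comma
#' (`"12G00123, 12N01234"` to `"12G00123,12N01234"`). Spaces inside entity
#' spans are never deleted, so gold surfaces stay intact; offsets are
#' recomputed for the shortened text and the returned ledger records, for
#' every corrupted site, the character position in the corrupted text at
#' which a token boundary was destroyed.
#'
#' @param doc A [deid_document()].
#' @param p Per-site corruption probability.
#' @param seed Seed for site selection.
#' @return List with elements `document` (corrupted, still valid) and
#'   `ledger` (tibble `kind`, `position`).
#' @export
corrupt_cascade <- function(doc, p, seed = 1L) {
  text <- doc$text
  e <- doc$entities
  inside_entity <- function(pos) {
    nrow(e) > 0L && any(e$start <= pos & pos < e$end)
  }
  sites <- list()
  m <- stringr::str_locate_all(text, "[[:lower:]]{2} [[:upper:]][[:lower:]]")[[1]]
  if (nrow(m)) sites <- c(sites, lapply(m[, "start"] + 1L, function(sp)
    list(kind = "deleted-space", space = as.integer(sp))))
  m <- stringr::str_locate_all(text, "[[:digit:]] [[:upper:]][[:lower:]]")[[1]]
  if (nrow(m)) sites <- c(sites, lapply(m[, "start"], function(sp)
    list(kind = "digit-word-fusion", space = as.integer(sp))))
  if (nrow(e) >= 2L) {
    idc <- which(e$category == "ID")
    for (i in idc) {
      j <- which(e$category == "ID" & e$start == e$end[i] + 2L)
      if (length(j) && substr0(text, e$end[i], e$end[i] + 2L) == ", ")
        sites <- c(sites, list(list(kind = "comma-joined-ids",
                                    space = e$end[i] + 1L)))
    }
  }
  # site$space is the 0-based index of the space character to delete
  sites <- sites[!vapply(sites, function(s) inside_entity(s$space), logical(1))]
  if (!length(sites) || p <= 0) {
    return(list(document = doc,
                ledger = tibble::tibble(kind = character(),
                                        position = integer())))
  }
  pos <- vapply(sites, `[[`, integer(1), "space")
  kind <- vapply(sites, `[[`, character(1), "kind")
  ord <- order(pos)
  pos <- pos[ord]; kind <- kind[ord]
  dup <- duplicated(pos)
  pos <- pos[!dup]; kind <- kind[!dup]
  hit <- with_seed(seed, stats::runif(length(pos)) < p)
  pos <- pos[hit]; kind <- kind[hit]
  if (!length(pos)) {
    return(list(document = doc,
                ledger = tibble::tibble(kind = character(),
                                        position = integer())))
  }
  shift <- function(o) o - findInterval(o - 1L, pos)
  keep_idx <- setdiff(seq_len(nchar(text)) - 1L, pos)
  chs <- strsplit(text, "", fixed = TRUE)[[1]]
  new_text <- paste(chs[keep_idx + 1L], collapse = "")
  new_e <- e
  if (nrow(e)) {
    new_e$start <- vapply(e$start, shift, integer(1))
    new_e$end <- vapply(e$end, shift, integer(1))
    new_e$text <- substr0(new_text, new_e$start, new_e$end)
  }
  ledger <- tibble::tibble(kind = kind,
                           position = vapply(pos, shift, integer(1)))
  list(document = deid_document(doc$doc_id, new_text, new_e,
                                warn_overlap = FALSE),
       ledger = ledger)
}

#' Generate a synthetic annotated corpus
#'
#' Reports are assembled from templated pathology-flavoured sentences with
#' SHI slots filled from the configured dictionaries and format generators
#' (dates in six lexical shapes, 10-digit phones in three, identifiers
#' shaped like `12G00123`). Gold offsets are exact; every document passes
#' [validate_document()] before and after the optional cascaded-token
#' corruption. Generation is a pure function of the configuration and its
#' seed.
#'
#' @param cfg A [generator_config()].
#' @return List with elements `documents` (list of corrupted
#'   [deid_document()]s), `ledgers` (per-document noise tibbles) and
#'   `clean_documents` (pre-corruption versions).
#' @export
generate_corpus <- function(cfg = generator_config()) {
  clean <- with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_reports), function(i) {
      .assemble_report(sprintf("synth-%04d", i), .build_report_sentences(cfg))
    })
  })
  corrupted <- lapply(seq_along(clean), function(i) {
    corrupt_cascade(clean[[i]], cfg$cascade_noise_p,
                    seed = (cfg$seed + 7919L * i) %% 2147483647L)
  })
  list(documents = lapply(corrupted, `[[`, "document"),
       ledgers = lapply(corrupted, `[[`, "ledger"),
       clean_documents = clean)
}

#' Fraction of injected noise sites repaired by preprocessing
#'
#' For each ledger entry, checks whether the preprocessed token table has a
#' token boundary at the recorded position, i.e. whether [split_cascaded()]
#' restored the destroyed boundary.
#'
#' @param ledger Noise ledger tibble (`kind`, `position`).
#' @param tokens Preprocessed token tibble for the same document.
#' @return Fraction in `[0, 1]`; `NaN` for an empty ledger.
#' @export
recovery_rate <- function(ledger, tokens) {
  if (!nrow(ledger)) return(NaN)
  mean(ledger$position %in% tokens$start)
}

#' Write a synthetic corpus to disk
#'
#' Writes dialect XML reports plus `ledger.tsv` (doc, kind, position) and a
#' three-way split `manifest.tsv`.
#'
#' @param cfg A [generator_config()].
#' @param dir Output directory.
#' @return The corpus list from [generate_corpus()], invisibly.
#' @export
write_synthetic_corpus <- function(cfg, dir) {
  corpus <- generate_corpus(cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_corpus(corpus$documents, dir)
  led <- dplyr::bind_rows(purrr::imap(corpus$ledgers, function(l, i) {
    if (!nrow(l)) return(NULL)
    dplyr::mutate(l, doc = corpus$documents[[i]]$doc_id, .before = 1)
  }))
  if (is.null(led) || !nrow(led))
    led <- tibble::tibble(doc = character(), kind = character(),
                          position = integer())
  utils::write.table(led, file.path(dir, "ledger.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- sort(vapply(corpus$documents,
                       function(d) paste0(d$doc_id, ".xml"), character(1)))
  ord <- with_seed(cfg$seed, sample.int(length(files)))
  split <- character(length(files))
  split[ord] <- rep_len(c("train", "validation", "test"), length(files))
  utils::write.table(tibble::tibble(filename = files, split = split),
                     file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(corpus)
}
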