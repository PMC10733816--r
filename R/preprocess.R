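#' Preprocessing configuration
#'
#' @param cascade_rules Apply the cascaded-token repair rules ([split_cascaded()])
#'   after base tokenization.
#' @param min_camel_fragment Minimum alphabetic run length on each side of a
#'   lowercase-to-uppercase boundary before the camel-case rule fires; guards
#'   against shredding names like "McDonald".
#' @param abbreviations Words whose trailing period does not end a sentence.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(cascade_rules = TRUE, min_camel_fragment = 2L,
                              abbreviations = default_abbreviations()) {
  stopifnot(min_camel_fragment >= 1L)
  structure(list(cascade_rules = isTRUE(cascade_rules),
                 min_camel_fragment = as.integer(min_camel_fragment),
                 abbreviations = tolower(abbreviations)),
            class = "preprocess_config")
}

#' @rdname preprocess_config
#' @export
default_abbreviations <- function() {
  c("dr", "mr", "mrs", "ms", "prof", "st", "vs", "no", "etc", "approx",
    "dept", "spec", "lab", "fig", "e.g", "i.e")
}

#' Segment text into sentences
#'
#' Sentence breaks occur at newlines and after terminal punctuation
#' (`. ! ?`) followed by whitespace, unless the preceding word is a known
#' abbreviation. Bounds are trimmed to non-whitespace, so the returned
#' sentences cover all non-whitespace text without overlapping. There is no
#' length cap: a single unbroken line yields a single sentence however long.
#'
#' @param text Document text.
#' @param abbreviations Lower-cased abbreviation list.
#' @return Tibble with 0-based, end-exclusive columns `start`, `end`, one row
#'   per sentence, in document order. Empty text gives zero rows.
#' @export
#' @examples
#' segment_sentences("No SHI here. Seen 1/12/2000.")
segment_sentences <- function(text, abbreviations = default_abbreviations()) {
  out <- tibble::tibble(start = integer(), end = integer())
  if (is.na(text) || !nzchar(text)) return(out)
  n <- nchar(text)
  # break before these 0-based positions
  breaks <- c(0L, n)
  nl <- stringr::str_locate_all(text, "\n")[[1]]
  if (nrow(nl)) breaks <- c(breaks, as.integer(nl[, "end"]))
  term <- stringr::str_locate_all(text, "[.!?]+(?=[ \t])")[[1]]
  if (nrow(term)) {
    keep <- vapply(seq_len(nrow(term)), function(i) {
      pre <- substr0(text, max(0L, term[i, "start"] - 13L), term[i, "start"] - 1L)
      word <- tolower(stringr::str_extract(pre, "[[:alpha:].]+$"))
      is.na(word) || !(sub("\\.+$", "", word) %in% tolower(abbreviations))
    }, logical(1))
    breaks <- c(breaks, as.integer(term[keep, "end"]))
  }
  breaks <- sort(unique(pmin(pmax(breaks, 0L), n)))
  starts <- breaks[-length(breaks)]
  ends <- breaks[-1]
  res <- purrr::map2(starts, ends, function(s, e) {
    chunk <- substr0(text, s, e)
    lead <- nchar(stringr::str_extract(chunk, "^\\s*"))
    trail <- nchar(stringr::str_extract(chunk, "\\s*$"))
    s2 <- s + lead; e2 <- e - trail
    if (s2 < e2) c(s2, e2) else NULL
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(out)
  m <- do.call(rbind, res)
  tibble::tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
}

# Token regex: alphanumeric runs that may carry comma/semicolon/period joins
# strictly between alphanumerics (clinical "cascaded" forms like
# "12G00123,12N01234", "JMH.Does", decimals), otherwise single punctuation
# characters. Colons, slashes, dashes etc. always detach.
.token_pattern <- "[[:alnum:]]+(?:[.,;][[:alnum:]]+)*|\\S"

#' Tokenize a sentence, span-faithfully
#'
#' Splits on whitespace and detaches punctuation, except that commas,
#' semicolons and periods flanked by alphanumerics remain attached — those
#' are exactly the "cascaded token" forms that [split_cascaded()] repairs
#' (and decimals, which it leaves alone). Every token's text equals the
#' document substring at its span.
#'
#' @param sentence_text Text of one sentence.
#' @param offset_base 0-based offset of the sentence within the document.
#' @return Tibble with columns `text`, `start`, `end` (document offsets).
#' @export
#' @examples
#' tokenize("MRN:1234567")$text
tokenize <- function(sentence_text, offset_base = 0L) {
  m <- stringr::str_locate_all(sentence_text, .token_pattern)[[1]]
  if (!nrow(m)) return(tibble::tibble(text = character(), start = integer(),
                                      end = integer()))
  start <- as.integer(m[, "start"]) - 1L + as.integer(offset_base)
  end <- as.integer(m[, "end"]) + as.integer(offset_base)
  tibble::tibble(
    text = stringr::str_sub(sentence_text, m[, "start"], m[, "end"]),
    start = start, end = end
  )
}

# Split one token's text into fragment boundaries per rules R1-R4.
# Returns relative cut positions (0 < cut < nchar) at which to subdivide,
# integer(0) when the token survives intact.
.cascade_cuts <- function(text, min_camel = 2L) {
  n <- nchar(text)
  if (n < 2L) return(integer())
  ch <- strsplit(text, "", fixed = TRUE)[[1]]
  is_alpha <- grepl("[[:alpha:]]", ch)
  is_digit <- grepl("[[:digit:]]", ch)
  is_lower <- grepl("[[:lower:]]", ch)
  is_upper <- grepl("[[:upper:]]", ch)
  cuts <- integer()
  # R1: detach a comma/semicolon strictly inside the token
  for (j in which(ch %in% c(",", ";"))) cuts <- c(cuts, j - 1L, j)
  # R2: detach an internal period whose neighbours are both alphabetic
  # ("JMH.Does"; decimals like "3.5" are left alone)
  for (j in which(ch == ".")) {
    if (j > 1L && j < n && is_alpha[j - 1L] && is_alpha[j + 1L])
      cuts <- c(cuts, j - 1L, j)
  }
  for (i in seq_len(n - 1L)) {
    # R3: lowercase -> uppercase camel boundary ("PsychiatryChief"),
    # guarded by the trailing-lowercase run and right-fragment length
    # so "McDonald" survives
    if (is_lower[i] && is_upper[i + 1L]) {
      run <- 0L; j <- i
      while (j >= 1L && is_lower[j]) { run <- run + 1L; j <- j - 1L }
      k <- i + 1L; ralpha <- 0L
      while (k <= n && is_alpha[k]) { ralpha <- ralpha + 1L; k <- k + 1L }
      if (run >= min_camel && ralpha >= min_camel) cuts <- c(cuts, i)
    }
    # R4: digit -> letter only when the letter side opens Uppercase-lowercase
    # ("39Sex" splits; "12G00123" must not)
    if (is_digit[i] && is_upper[i + 1L] && i + 2L <= n && is_lower[i + 2L])
      cuts <- c(cuts, i)
  }
  sort(unique(cuts[cuts > 0L & cuts < n]))
}

#' Repair incorrectly cascaded tokens
#'
#' Applies the cascaded-token splitting rules to a token table: (R1) detach a
#' comma or semicolon strictly inside a token; (R2) detach a period whose
#' neighbours are both alphabetic; (R3) split a lowercase-to-uppercase
#' camel-case boundary when both alphabetic fragments are long enough;
#' (R4) split a digit-to-letter boundary only when the letter side begins an
#' Uppercase-then-lowercase word. Child spans tile the parent span exactly;
#' document text is never modified, so all offsets remain valid. The
#' operation is idempotent.
#'
#' @param tokens Token tibble from [tokenize()] (columns `text`, `start`,
#'   `end`; extra columns such as `sentence_id` are carried through).
#' @param min_camel_fragment See [preprocess_config()].
#' @return Token tibble of the same shape, with cascaded tokens subdivided.
#' @export
#' @examples
#' split_cascaded(tokenize("Age: 39Sex"))$text
split_cascaded <- function(tokens, min_camel_fragment = 2L) {
  n <- nrow(tokens)
  if (!n) return(tokens)
  # fast screen: only tokens that can possibly trigger a rule
  cand <- which(grepl(
    "[,;]|[[:alpha:]]\\.[[:alpha:]]|[[:lower:]][[:upper:]]|[0-9][[:upper:]][[:lower:]]",
    tokens$text))
  if (!length(cand)) return(tokens)
  cuts_list <- lapply(cand, function(i)
    .cascade_cuts(tokens$text[i], min_camel_fragment))
  has_cut <- lengths(cuts_list) > 0L
  cand <- cand[has_cut]
  if (!length(cand)) return(tokens)
  cuts_list <- cuts_list[has_cut]
  counts <- rep(1L, n)
  counts[cand] <- lengths(cuts_list) + 1L
  out <- tokens[rep(seq_len(n), counts), ]
  pos <- cumsum(counts) - counts + 1L  # first output row per input token
  for (k in seq_along(cand)) {
    i <- cand[k]
    bounds <- c(0L, cuts_list[[k]], nchar(tokens$text[i]))
    rows <- pos[i] + seq_len(counts[i]) - 1L
    out$text[rows] <- substr0(tokens$text[i], bounds[-length(bounds)],
                              bounds[-1])
    out$start[rows] <- tokens$start[i] + bounds[-length(bounds)]
    out$end[rows] <- tokens$start[i] + bounds[-1]
  }
  out
}

#' Preprocess a document end to end
#'
#' Sentence segmentation, tokenization and (optionally) cascaded-token
#' repair, composed. The document text is never altered; all output spans
#' index into `doc$text`.
#'
#' @param doc A [deid_document()].
#' @param cfg A [preprocess_config()].
#' @return Token tibble with columns `sentence_id`, `text`, `start`, `end`.
#' @export
preprocess_document <- function(doc, cfg = preprocess_config()) {
  sents <- segment_sentences(doc$text, cfg$abbreviations)
  if (!nrow(sents))
    return(tibble::tibble(sentence_id = integer(), text = character(),
                          start = integer(), end = integer()))
  toks <- purrr::map2(sents$start, sents$end, function(s, e) {
    tokenize(substr0(doc$text, s, e), offset_base = s)
  })
  out <- dplyr::bind_rows(toks, .id = "sentence_id")
  out$sentence_id <- as.integer(out$sentence_id)
  out <- out[c("sentence_id", "text", "start", "end")]
  if (cfg$cascade_rules) out <- split_cascaded(out, cfg$min_camel_fragment)
  out
}

#' Sentence bounds of a preprocessed token table
#'
#' @param tokens Token tibble with a `sentence_id` column.
#' @return Tibble with `sentence_id`, `start`, `end` per sentence.
#' @export
sentence_bounds <- function(tokens) {
  dplyr::summarise(dplyr::group_by(tokens, .data$sentence_id),
                   start = min(.data$start), end = max(.data$end),
                   .groups = "drop")
}
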