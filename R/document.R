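#' @importFrom rlang .data
#' @importFrom generics tidy glance
NULL

# 0-based, end-exclusive substring in code points (stand-off convention).
substr0 <- function(text, start, end) substr(rep_len(text, length(start)), start + 1L, end)

#' Build an entity-span tibble
#'
#' Entity spans are the package's tabular currency: one row per SHI mention,
#' with 0-based end-exclusive character offsets into the owning document's
#' text (counted in Unicode code points, newlines included).
#'
#' @param category,subcategory SHI types per [shi_taxonomy()]; `subcategory`
#'   may be `NA` for categories without one.
#' @param start,end Integer character offsets, 0-based, end-exclusive.
#' @param text Surface strings; must equal the document substring.
#' @return Tibble with columns `category`, `subcategory`, `start`, `end`,
#'   `text`, sorted by `(start, end, category, subcategory)`.
#' @export
#' @examples
#' entity_tbl("NAME", "DOCTOR", 11, 13, "HM")
entity_tbl <- function(category = character(), subcategory = NA_character_,
                       start = integer(), end = integer(), text = character()) {
  out <- tibble::tibble(
    category = as.character(category),
    subcategory = rep_len(as.character(subcategory), length(category)),
    start = as.integer(start), end = as.integer(end),
    text = as.character(text)
  )
  sort_entities(out)
}

sort_entities <- function(entities) {
  dplyr::arrange(entities, .data$start, .data$end, .data$category,
                 dplyr::coalesce(.data$subcategory, ""))
}

empty_entities <- function() entity_tbl()

#' Construct a clinical document with stand-off annotations
#'
#' @param doc_id Opaque document identifier.
#' @param text Full note text (one string).
#' @param entities Entity tibble as built by [entity_tbl()]; may be empty.
#' @param warn_overlap Warn when gold entities overlap (permitted but unusual).
#' @return A `deid_document` object.
#' @export
#' @examples
#' d <- deid_document("r1", "Seen by Dr HM today",
#'                    entity_tbl("NAME", "DOCTOR", 11, 13, "HM"))
#' d
deid_document <- function(doc_id, text, entities = empty_entities(),
                          warn_overlap = TRUE) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L,
            is.character(text), length(text) == 1L)
  entities <- sort_entities(tibble::as_tibble(entities))
  doc <- structure(list(doc_id = doc_id, text = text, entities = entities),
                   class = "deid_document")
  if (warn_overlap && nrow(entities_overlapping(doc)) > 0L)
    warning("document '", doc_id, "' has overlapping entities", call. = FALSE)
  doc
}

#' @export
print.deid_document <- function(x, ...) {
  cat("<deid_document '", x$doc_id, "': ", nchar(x$text), " chars, ",
      nrow(x$entities), " entities>\n", sep = "")
  if (nrow(x$entities)) print(x$entities, n = 5)
  invisible(x)
}

#' Validate a document against the stand-off invariants
#'
#' Checks every entity row for: offsets inside the text, `start < end`,
#' non-empty surface, surface equal to the document substring, a legal
#' taxonomy type, sort order, and absence of duplicate
#' `(start, end, category, subcategory)` rows. The validator reports and
#' never throws.
#'
#' @param doc A [deid_document()].
#' @return Character vector of violation descriptions; empty when the
#'   document is valid. Each violation names the offending entity row.
#' @export
validate_document <- function(doc) {
  v <- character()
  e <- doc$entities
  n <- nchar(doc$text)
  if (nrow(e) == 0L) return(v)
  for (i in seq_len(nrow(e))) {
    lab <- sprintf("entity %d (%s)", i, shi_type_key(e$category[i], e$subcategory[i]))
    if (is.na(e$start[i]) || e$start[i] < 0L)
      v <- c(v, paste(lab, ": start out of bounds"))
    if (is.na(e$end[i]) || e$end[i] > n)
      v <- c(v, paste(lab, ": end out of bounds"))
    if (!is.na(e$start[i]) && !is.na(e$end[i]) && e$start[i] >= e$end[i])
      v <- c(v, paste(lab, ": empty or inverted span"))
    if (is.na(e$text[i]) || !nzchar(e$text[i]))
      v <- c(v, paste(lab, ": empty surface text"))
    if (!is.na(e$start[i]) && !is.na(e$end[i]) &&
        e$start[i] >= 0L && e$end[i] <= n && e$start[i] < e$end[i] &&
        !identical(substr0(doc$text, e$start[i], e$end[i]), e$text[i]))
      v <- c(v, paste(lab, ": text mismatch with document substring"))
    if (!valid_shi_type(e$category[i], e$subcategory[i]))
      v <- c(v, paste(lab, ": unknown SHI type"))
  }
  key <- paste(e$start, e$end, e$category, e$subcategory)
  if (anyDuplicated(key))
    v <- c(v, sprintf("entity %d: duplicate (start,end,type) triple",
                      which(duplicated(key))[1]))
  if (!identical(e$start, sort_entities(e)$start) ||
      !identical(e$end, sort_entities(e)$end))
    v <- c(v, "entities: not in (start, end, type) sort order")
  v
}

#' Find overlapping entity pairs
#'
#' Character ranges are half-open, so spans `[0,5)` and `[5,9)` are adjacent,
#' not overlapping.
#'
#' @param doc A [deid_document()].
#' @return Tibble with columns `i`, `j` (1-based entity row indices, `i < j`)
#'   for every intersecting pair.
#' @export
entities_overlapping <- function(doc) {
  e <- doc$entities
  out <- tibble::tibble(i = integer(), j = integer())
  if (nrow(e) < 2L) return(out)
  pairs <- utils::combn(nrow(e), 2L)
  hit <- e$start[pairs[1, ]] < e$end[pairs[2, ]] &
         e$start[pairs[2, ]] < e$end[pairs[1, ]]
  tibble::tibble(i = pairs[1, hit], j = pairs[2, hit])
}
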