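.gL <- "(?<![[:alnum:]])"
.gR <- "(?![[:alnum:]])"

#' Built-in rule inventory for post-detection
#'
#' One row per registered regular-expression rule: six date shapes
#' (numeric day/month with slash or dash separators, and 3-letter month
#' names on either side of the day), three 10-digit phone shapes, and
#' scheme- or `www.`-prefixed URLs. Day and month numeric fields are 1-2
#' digits, years exactly 4 digits; the patterns are lexical — no calendar
#' validation. Sites can extend the inventory with their own rows before
#' passing it to [detect_rules()].
#'
#' @return Tibble with columns `id`, `category`, `subcategory`, `pattern`
#'   (PCRE).
#' @export
default_rule_inventory <- function() {
  d <- "\\d{1,2}"; y <- "\\d{4}"
  tibble::tribble(
    ~id, ~category, ~subcategory, ~pattern,
    "DATE_DMY_SLASH",    "DATE", NA, paste0(.gL, d, "/", d, "/", y, .gR),
    "DATE_DMY_DASH",     "DATE", NA, paste0(.gL, d, "-", d, "-", y, .gR),
    "DATE_MON_DD_SLASH", "DATE", NA, paste0(.gL, .mon, "/", d, "/", y, .gR),
    "DATE_DD_MON_SLASH", "DATE", NA, paste0(.gL, d, "/", .mon, "/", y, .gR),
    "DATE_MON_DD_DASH",  "DATE", NA, paste0(.gL, .mon, "-", d, "-", y, .gR),
    "DATE_DD_MON_DASH",  "DATE", NA, paste0(.gL, d, "-", .mon, "-", y, .gR),
    "PHONE_PLAIN", "CONTACT", "PHONE", paste0(.gL, "\\d{10}", .gR),
    "PHONE_DOT",   "CONTACT", "PHONE",
      paste0(.gL, "\\d{3}\\.\\d{3}\\.\\d{4}", .gR),
    "PHONE_DASH",  "CONTACT", "PHONE",
      paste0(.gL, "\\d{3}-\\d{3}-\\d{4}", .gR),
    "URL_SCHEME", "CONTACT", "URL",
      "(?:https?|ftp)://[^[:space:]<>\"']+",
    "URL_WWW", "CONTACT", "URL",
      "(?<![[:alnum:]])www\\.[[:alnum:]][[:alnum:].-]*\\.[[:alpha:]]{2,}(?:/[^[:space:]<>\"']*)?"
  )
}

#' Run regular-expression rules over raw text
#'
#' Matches every rule in the inventory against the text and resolves
#' overlaps by longest match (ties to the earlier start, then inventory
#' order), so hits are deterministic, position-sorted and non-overlapping.
#' Trailing sentence punctuation is trimmed from URL hits.
#'
#' @param text Document text.
#' @param inventory Rule tibble as in [default_rule_inventory()].
#' @return Entity tibble with an extra `rule_id` column ("rule hits").
#' @export
detect_rules <- function(text, inventory = default_rule_inventory()) {
  hits <- purrr::pmap(inventory, function(id, category, subcategory, pattern) {
    m <- stringr::str_locate_all(text, stringr::regex(pattern))[[1]]
    if (!nrow(m)) return(NULL)
    surf <- stringr::str_sub(text, m[, "start"], m[, "end"])
    start <- as.integer(m[, "start"]) - 1L
    end <- as.integer(m[, "end"])
    if (startsWith(id, "URL")) {
      trimmed <- sub("[.,;:!?)]+$", "", surf)
      end <- end - (nchar(surf) - nchar(trimmed))
      surf <- trimmed
    }
    tibble::tibble(category = category, subcategory = subcategory,
                   start = start, end = end, text = surf, rule_id = id)
  })
  hits <- dplyr::bind_rows(hits)
  if (is.null(hits) || !nrow(hits))
    return(dplyr::mutate(empty_entities(), rule_id = character()))
  # longest-match, non-overlapping resolution
  hits <- hits[order(-(hits$end - hits$start), hits$start), ]
  keep <- logical(nrow(hits))
  taken_start <- integer(); taken_end <- integer()
  for (i in seq_len(nrow(hits))) {
    if (!any(hits$start[i] < taken_end & hits$end[i] > taken_start)) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, hits$start[i])
      taken_end <- c(taken_end, hits$end[i])
    }
  }
  hits <- hits[keep, ]
  hits[order(hits$start, hits$end), ]
}

#' @rdname detect_rules
#' @export
detect_dates <- function(text, inventory = default_rule_inventory()) {
  detect_rules(text, inventory[inventory$category == "DATE", ])
}

#' @rdname detect_rules
#' @export
detect_phones <- function(text, inventory = default_rule_inventory()) {
  detect_rules(text, inventory[!is.na(inventory$subcategory) &
                                 inventory$subcategory == "PHONE", ])
}

#' @rdname detect_rules
#' @export
detect_urls <- function(text, inventory = default_rule_inventory()) {
  detect_rules(text, inventory[!is.na(inventory$subcategory) &
                                 inventory$subcategory == "URL", ])
}

#' Merge model entities with rule hits
#'
#' The rules are additive recall, not an override: (1) a rule hit disjoint
#' from every model entity is added; (2) a rule hit that strictly contains a
#' same-category model entity replaces it; (3) on any other overlap the
#' model entity wins. The result is sorted and non-overlapping.
#'
#' @param model_entities Entity tibble from the tagger.
#' @param rule_hits Rule-hit tibble from [detect_rules()].
#' @return Entity tibble.
#' @export
merge_entities <- function(model_entities, rule_hits) {
  model_entities <- sort_entities(tibble::as_tibble(model_entities))
  if (!nrow(rule_hits)) return(model_entities)
  kept_model <- rep(TRUE, nrow(model_entities))
  added <- list()
  for (i in seq_len(nrow(rule_hits))) {
    rs <- rule_hits$start[i]; re <- rule_hits$end[i]
    ov <- which(model_entities$start < re & model_entities$end > rs)
    if (!length(ov)) {
      added[[length(added) + 1L]] <- rule_hits[i, ]
      next
    }
    same <- model_entities$category[ov] == rule_hits$category[i]
    contains <- model_entities$start[ov] >= rs & model_entities$end[ov] <= re &
      (model_entities$end[ov] - model_entities$start[ov]) < (re - rs)
    if (all(same & contains)) {
      kept_model[ov] <- FALSE
      added[[length(added) + 1L]] <- rule_hits[i, ]
    } # else: model wins, rule hit dropped
  }
  cols <- c("category", "subcategory", "start", "end", "text")
  added <- dplyr::bind_rows(added)
  out <- dplyr::bind_rows(model_entities[kept_model, cols],
                          if (nrow(added)) added[, cols] else NULL)
  sort_entities(out)
}

#' Assemble the final annotated document from predictions and rules
#'
#' Prediction labels are repaired and decoded to spans, merged with the
#' rule hits detected on the raw text, and packaged as a validated
#' document.
#'
#' @param doc_id Document id for the output.
#' @param text Raw document text.
#' @param tagged Token tibble with a `label` column (may be empty for
#'   rules-only operation).
#' @param scheme A [label_scheme()].
#' @param inventory Rule inventory; `NULL` disables post-detection.
#' @return A [deid_document()] that passes [validate_document()].
#' @export
finalize_document <- function(doc_id, text, tagged = NULL,
                              scheme = label_scheme(),
                              inventory = default_rule_inventory()) {
  model_entities <- if (!is.null(tagged) && nrow(tagged))
    decode_labels(tagged, text, scheme) else empty_entities()
  merged <- if (!is.null(inventory))
    merge_entities(model_entities, detect_rules(text, inventory))
  else model_entities
  doc <- deid_document(doc_id, text, merged, warn_overlap = FALSE)
  viol <- validate_document(doc)
  if (length(viol))
    stop("finalize_document produced an invalid document: ",
         paste(viol, collapse = "; "), call. = FALSE)
  doc
}
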