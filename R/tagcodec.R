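#' Encode entity spans as per-token scheme labels
#'
#' Assigns one BIO/BIESO label per token. Under BIESO a single-token entity
#' becomes `S-<type>`; a multi-token entity becomes `B ... I* ... E`;
#' everything else is `O`. Entities whose boundaries do not coincide with
#' token boundaries are clipped *outward* to the minimal covering token run
#' (preserving recall; this is precisely the damage the cascade rules exist
#' to prevent). When two entities compete for a token the longer span wins.
#' Entities whose type is outside the scheme's inventory (the default
#' exclusion list, for instance) are left unlabelled.
#'
#' @param tokens Token tibble (`text`, `start`, `end`, optional
#'   `sentence_id`).
#' @param entities Entity tibble ([entity_tbl()]).
#' @param scheme A [label_scheme()].
#' @return The token tibble with a `label` column appended.
#' @export
encode_labels <- function(tokens, entities, scheme = label_scheme()) {
  labels <- rep("O", nrow(tokens))
  if (!nrow(tokens) || !nrow(entities)) {
    tokens$label <- labels
    return(tokens)
  }
  ord <- order(-(entities$end - entities$start), entities$start)
  taken <- logical(nrow(tokens))
  for (r in ord) {
    s <- entities$start[r]; e <- entities$end[r]
    key <- shi_type_key(entities$category[r], entities$subcategory[r])
    if (!key %in% scheme$types) next
    idx <- which(tokens$start < e & tokens$end > s)
    if (!length(idx)) next
    idx <- seq(min(idx), max(idx))
    if (any(taken[idx])) next  # longest-span-wins: earlier (longer) keeps it
    taken[idx] <- TRUE
    L <- length(idx)
    labels[idx] <-
      if (scheme$name == "BIESO") {
        if (L == 1L) paste0("S-", key)
        else c(paste0("B-", key), rep(paste0("I-", key), L - 2L), paste0("E-", key))
      } else {
        c(paste0("B-", key), rep(paste0("I-", key), L - 1L))
      }
  }
  tokens$label <- labels
  tokens
}

# Segment a label vector into runs under the repair convention:
# a run starts at any non-O label, extends while the next label carries the
# same type with a continuation prefix (I/E for BIESO, I for BIO), and for
# BIESO closes as soon as an E is consumed. Returns list of index vectors.
.label_runs <- function(labels, scheme_name) {
  pre <- label_prefix(labels)
  typ <- label_type(labels)
  runs <- list()
  i <- 1L; n <- length(labels)
  while (i <= n) {
    if (pre[i] == "O") { i <- i + 1L; next }
    j <- i
    if (scheme_name == "BIESO") {
      # S closes immediately; otherwise extend over I/E of the same type,
      # closing as soon as an E has been consumed
      while (j < n && pre[j] != "S" && pre[j] != "E" &&
             pre[j + 1L] %in% c("I", "E") && identical(typ[j + 1L], typ[i])) {
        j <- j + 1L
      }
    } else {
      while (j < n && pre[j + 1L] == "I" && identical(typ[j + 1L], typ[i])) {
        j <- j + 1L
      }
    }
    runs[[length(runs) + 1L]] <- i:j
    i <- j + 1L
  }
  runs
}

#' Normalize a free label sequence to scheme validity
#'
#' Classifiers can emit label sequences that violate the scheme grammar
#' (an `I` with no opening `B`, a `B` never closed). `repair_labels()`
#' rewrites each maximal same-type run with the canonical prefix pattern:
#' an isolated token becomes `S` (BIESO) or `B` (BIO); longer runs become
#' `B I* E` / `B I*`. The operation is deterministic, idempotent, and the
#' identity on already-valid sequences.
#'
#' @param labels Character vector of labels in the scheme alphabet.
#' @param scheme A [label_scheme()].
#' @return Valid label vector of the same length.
#' @export
#' @examples
#' repair_labels(c("I-DATE"), label_scheme())
repair_labels <- function(labels, scheme = label_scheme()) {
  out <- labels
  for (run in .label_runs(labels, scheme$name)) {
    key <- label_type(labels[run[1]])
    L <- length(run)
    out[run] <-
      if (scheme$name == "BIESO") {
        if (L == 1L) paste0("S-", key)
        else c(paste0("B-", key), rep(paste0("I-", key), L - 2L), paste0("E-", key))
      } else {
        c(paste0("B-", key), rep(paste0("I-", key), L - 1L))
      }
  }
  out
}

#' Decode per-token labels back to entity spans
#'
#' Invalid sequences are first passed through [repair_labels()]; maximal
#' valid runs then become entities whose `start` is the first token's start,
#' `end` the last token's end, and whose surface is read from the document
#' text. Runs never cross sentence boundaries when a `sentence_id` column is
#' present. Decoded spans never overlap.
#'
#' @param tagged Token tibble with a `label` column.
#' @param doc_text The owning document's text (for surfaces).
#' @param scheme A [label_scheme()].
#' @return Entity tibble ([entity_tbl()]).
#' @export
decode_labels <- function(tagged, doc_text, scheme = label_scheme()) {
  if (!nrow(tagged)) return(empty_entities())
  gkey <- if ("sentence_id" %in% names(tagged)) {
    if ("doc_id" %in% names(tagged))
      paste(tagged$doc_id, tagged$sentence_id) else
      as.character(tagged$sentence_id)
  } else "s"
  groups <- split(seq_len(nrow(tagged)), factor(gkey, levels = unique(gkey)))
  ents <- purrr::map(groups, function(idx) {
    labs <- repair_labels(tagged$label[idx], scheme)
    runs <- .label_runs(labs, scheme$name)
    if (!length(runs)) return(NULL)
    purrr::map(runs, function(run) {
      rows <- idx[run]
      key <- label_type(labs[run[1]])
      tp <- shi_type_unkey(key)
      s <- tagged$start[rows[1]]; e <- tagged$end[rows[length(rows)]]
      tibble::tibble(category = tp$category, subcategory = tp$subcategory,
                     start = s, end = e, text = substr0(doc_text, s, e))
    }) |> dplyr::bind_rows()
  })
  ents <- dplyr::bind_rows(ents)
  if (!nrow(ents)) return(empty_entities())
  sort_entities(ents)
}

#' Export a tagged token table as two-column CoNLL-style TSV
#'
#' @param tagged Token tibble with a `label` column.
#' @param path Output file; sentences separated by blank lines.
#' @return `path`, invisibly.
#' @export
write_conll <- function(tagged, path) {
  gkey <- if ("sentence_id" %in% names(tagged)) {
    if ("doc_id" %in% names(tagged))
      paste(tagged$doc_id, tagged$sentence_id) else
      as.character(tagged$sentence_id)
  } else "s"
  groups <- split(seq_len(nrow(tagged)), factor(gkey, levels = unique(gkey)))
  lines <- unlist(purrr::map(groups, function(idx) {
    c(paste(tagged$text[idx], tagged$label[idx], sep = "\t"), "")
  }))
  writeLines(lines, path)
  invisible(path)
}
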