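entity_type_at <- function(entities, granularity) {
  if (granularity == "category") entities$category
  else shi_type_key(entities$category, entities$subcategory)
}

#' Span matching predicates
#'
#' Strict matching requires identical start and end offsets and the same
#' type at the configured granularity. Relaxed matching requires the same
#' type, overlapping spans, and both boundary deltas within `tol`
#' characters; with `tol = 0` it coincides with strict matching.
#'
#' @param pred,gold One-row entity tibbles (or lists with `start`, `end`,
#'   `category`, `subcategory`).
#' @param granularity `"subcategory"` (default) or `"category"`.
#' @param tol Non-negative per-boundary character tolerance.
#' @return Logical scalar.
#' @export
match_strict <- function(pred, gold, granularity = "subcategory") {
  pred$start == gold$start && pred$end == gold$end &&
    identical(entity_type_at(pred, granularity),
              entity_type_at(gold, granularity))
}

#' @rdname match_strict
#' @export
match_relaxed <- function(pred, gold, tol = 2L, granularity = "subcategory") {
  stopifnot(tol >= 0)
  identical(entity_type_at(pred, granularity),
            entity_type_at(gold, granularity)) &&
    pred$start < gold$end && gold$start < pred$end &&
    abs(pred$start - gold$start) <= tol && abs(pred$end - gold$end) <= tol
}

# Greedy one-to-one assignment in offset order with gold-order priority.
# Returns list(tp_types, fp_types, fn_types) at the given granularity.
.match_doc <- function(pred, gold, mode, granularity, tol) {
  pred <- sort_entities(pred); gold <- sort_entities(gold)
  ptype <- entity_type_at(pred, granularity)
  gtype <- entity_type_at(gold, granularity)
  used <- logical(nrow(pred))
  matched_gold <- logical(nrow(gold))
  for (g in seq_len(nrow(gold))) {
    for (p in seq_len(nrow(pred))) {
      if (used[p]) next
      ok <- if (mode == "strict")
        pred$start[p] == gold$start[g] && pred$end[p] == gold$end[g] &&
          ptype[p] == gtype[g]
      else
        ptype[p] == gtype[g] &&
          pred$start[p] < gold$end[g] && gold$start[g] < pred$end[p] &&
          abs(pred$start[p] - gold$start[g]) <= tol &&
          abs(pred$end[p] - gold$end[g]) <= tol
      if (ok) {
        used[p] <- TRUE
        matched_gold[g] <- TRUE
        break
      }
    }
  }
  list(tp = gtype[matched_gold], fp = ptype[!used], fn = gtype[!matched_gold])
}

#' Micro-averaged span evaluation
#'
#' Pools true positives, false positives and false negatives over all
#' documents and types before computing precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)` and `F1 = 2PR/(P+R)`. Matching is one-to-one and greedy in
#' offset order with gold-order priority. Cells with a zero denominator are
#' reported as 0 and flagged.
#'
#' @param pred,gold Named lists of [deid_document()]s (names or `doc_id`s
#'   pair them), or two single documents.
#' @param mode `"strict"` or `"relaxed"`.
#' @param granularity Type depth for matching: `"subcategory"` or
#'   `"category"`.
#' @param tol Relaxed per-boundary character tolerance.
#' @return A `deid_eval` object; see [tidy.deid_eval()], [glance.deid_eval()]
#'   and [per_category_report()].
#' @export
#' @examples
#' gold <- deid_document("d", "12G00123,12N01234",
#'   entity_tbl(c("ID", "ID"), "IDNUM", c(0, 9), c(8, 17),
#'              c("12G00123", "12N01234")))
#' pred <- deid_document("d", gold$text,
#'   entity_tbl("ID", "IDNUM", 0, 17, gold$text))
#' glance(micro_evaluate(pred, gold, mode = "strict"))
micro_evaluate <- function(pred, gold, mode = c("strict", "relaxed"),
                           granularity = c("subcategory", "category"),
                           tol = 2L) {
  mode <- match.arg(mode)
  granularity <- match.arg(granularity)
  if (inherits(pred, "deid_document")) pred <- list(pred)
  if (inherits(gold, "deid_document")) gold <- list(gold)
  pid <- vapply(pred, `[[`, character(1), "doc_id")
  gid <- vapply(gold, `[[`, character(1), "doc_id")
  if (anyDuplicated(pid) || anyDuplicated(gid))
    stop("duplicate doc_ids within a document set", call. = FALSE)
  unpaired <- c(setdiff(pid, gid), setdiff(gid, pid))
  if (length(unpaired))
    stop("doc_id mismatch between prediction and gold sets: ",
         paste(unpaired, collapse = ", "), call. = FALSE)
  res <- purrr::map(gid, function(id) {
    .match_doc(pred[[match(id, pid)]]$entities, gold[[match(id, gid)]]$entities,
               mode, granularity, tol)
  })
  tally <- function(field) {
    x <- unlist(purrr::map(res, field))
    if (!length(x)) return(tibble::tibble(type = character(), n = integer()))
    dplyr::count(tibble::tibble(type = x), .data$type)
  }
  counts <- dplyr::full_join(
    dplyr::rename(tally("tp"), tp = "n"),
    dplyr::full_join(dplyr::rename(tally("fp"), fp = "n"),
                     dplyr::rename(tally("fn"), fn = "n"), by = "type"),
    by = "type"
  )
  counts <- dplyr::mutate(counts, dplyr::across(c("tp", "fp", "fn"),
                                                ~ dplyr::coalesce(.x, 0L)))
  counts <- dplyr::arrange(counts, .data$type)
  counts <- .add_metrics(counts)
  overall <- .add_metrics(tibble::tibble(type = "OVERALL",
                                         tp = sum(counts$tp),
                                         fp = sum(counts$fp),
                                         fn = sum(counts$fn)))
  structure(list(counts = counts, overall = overall, mode = mode,
                 granularity = granularity, tol = tol,
                 n_docs = length(gold)),
            class = "deid_eval")
}

.add_metrics <- function(counts) {
  dplyr::mutate(counts,
    precision = ifelse(.data$tp + .data$fp > 0, .data$tp / (.data$tp + .data$fp), 0),
    recall = ifelse(.data$tp + .data$fn > 0, .data$tp / (.data$tp + .data$fn), 0),
    f1 = ifelse(.data$precision + .data$recall > 0,
                2 * .data$precision * .data$recall /
                  (.data$precision + .data$recall), 0),
    flagged = (.data$tp + .data$fp == 0) | (.data$tp + .data$fn == 0)
  )
}

#' @export
print.deid_eval <- function(x, ...) {
  cat("<deid_eval: ", x$mode, " matching, ", x$granularity, " granularity",
      if (x$mode == "relaxed") paste0(", tol=", x$tol), ", ", x$n_docs,
      " documents>\n", sep = "")
  o <- x$overall
  cat(sprintf("  TP=%d FP=%d FN=%d  P=%.4f R=%.4f F1=%.4f\n",
              o$tp, o$fp, o$fn, o$precision, o$recall, o$f1))
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x A `deid_eval` object.
#' @param ... Unused.
#' @return `tidy()`: one row per type with counts and metrics.
#'   `glance()`: a single pooled row.
#' @method tidy deid_eval
#' @export
tidy.deid_eval <- function(x, ...) x$counts

#' @rdname tidy.deid_eval
#' @method glance deid_eval
#' @export
glance.deid_eval <- function(x, ...) {
  dplyr::mutate(x$overall[, c("tp", "fp", "fn", "precision", "recall", "f1")],
                mode = x$mode, granularity = x$granularity, tol = x$tol,
                n_docs = x$n_docs)
}

#' Per-category and per-subcategory breakdown
#'
#' Expands a subcategory-granularity report into one row per subcategory
#' plus pooled per-category rows and the overall row; the overall row
#' equals the pooled counts.
#'
#' @param report A `deid_eval` object.
#' @return Tibble with columns `level`, `type`, counts and metrics.
#' @export
per_category_report <- function(report) {
  sub <- dplyr::mutate(report$counts, level = "type")
  bycat <- dplyr::mutate(report$counts,
                         category = sub("_.*$", "", .data$type))
  bycat <- dplyr::summarise(dplyr::group_by(bycat, .data$category),
                            tp = sum(.data$tp), fp = sum(.data$fp),
                            fn = sum(.data$fn), .groups = "drop")
  bycat <- dplyr::mutate(.add_metrics(dplyr::rename(bycat, type = "category")),
                         level = "category")
  overall <- dplyr::mutate(report$overall, level = "overall")
  dplyr::bind_rows(sub, bycat, overall)[, c("level", "type", "tp", "fp", "fn",
                                            "precision", "recall", "f1",
                                            "flagged")]
}

#' Plot per-type F1 from an evaluation report
#'
#' @param object A `deid_eval` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot deid_eval
#' @export
autoplot.deid_eval <- function(object, ...) {
  d <- object$counts
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$type, .data$f1),
                                  y = .data$f1)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$overall$f1, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "micro F1",
                  title = paste0("Span F1 by type (", object$mode, ")"),
                  subtitle = "dashed line: pooled micro F1") +
    ggplot2::theme_minimal()
}

#' Write an evaluation report as TSV
#'
#' @param report A `deid_eval` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  utils::write.table(per_category_report(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
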