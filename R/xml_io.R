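#' Read an i2b2-style stand-off XML report
#'
#' The dialect is a root element whose name begins with `deId`, containing a
#' `<TEXT>` element (CDATA, preserved verbatim — no whitespace
#' normalization) followed by a `<TAGS>` element whose children are named by
#' SHI category and carry `start`, `end`, `text`, `TYPE` and `id`
#' attributes. `TYPE` holds the subcategory, or repeats the category name
#' for categories without one.
#'
#' @param x Path to an XML file, or a single XML string.
#' @param doc_id Document id; defaults to the file name without extension.
#' @param repair_offsets When a tag's `text` attribute disagrees with the
#'   substring at its offsets, relocate it to the nearest occurrence of that
#'   text instead of erroring (gold corpora do contain such
#'   inconsistencies).
#' @return A [deid_document()]; guaranteed to pass [validate_document()].
#' @export
read_report <- function(x, doc_id = NULL, repair_offsets = FALSE) {
  is_path <- length(x) == 1L && !grepl("<", x, fixed = TRUE)
  if (is.null(doc_id))
    doc_id <- if (is_path) sub("\\.xml$", "", basename(x)) else "doc"
  xml <- xml2::read_xml(x, options = c("NOBLANKS"))
  root <- xml2::xml_name(xml)
  if (!startsWith(root, "deId"))
    stop("unexpected root element <", root, ">; expected a deId* report",
         call. = FALSE)
  text_node <- xml2::xml_find_first(xml, "./TEXT")
  if (inherits(text_node, "xml_missing")) stop("report has no <TEXT> element")
  text <- xml2::xml_text(text_node)
  tags <- xml2::xml_find_all(xml, "./TAGS/*")
  if (!length(tags)) {
    return(deid_document(doc_id, text))
  }
  category <- xml2::xml_name(tags)
  type <- xml2::xml_attr(tags, "TYPE")
  start <- as.integer(xml2::xml_attr(tags, "start"))
  end <- as.integer(xml2::xml_attr(tags, "end"))
  surface <- xml2::xml_attr(tags, "text")
  id <- xml2::xml_attr(tags, "id")
  subcategory <- ifelse(is.na(type) | type == category, NA_character_, type)
  for (i in seq_along(tags)) {
    got <- substr0(text, start[i], end[i])
    if (!identical(got, surface[i])) {
      if (repair_offsets) {
        hit <- regexpr(surface[i], text, fixed = TRUE)
        if (hit > 0) {
          start[i] <- as.integer(hit) - 1L
          end[i] <- start[i] + nchar(surface[i])
        } else {
          stop("tag ", id[i], ": text ", dQuote(surface[i]),
               " not found in document for offset repair", call. = FALSE)
        }
      } else {
        stop("tag ", id[i], ": text attribute ", dQuote(surface[i]),
             " disagrees with substring ", dQuote(got), " at [", start[i],
             ",", end[i], ")", call. = FALSE)
      }
    }
  }
  deid_document(doc_id, text,
                entity_tbl(category, subcategory, start, end, surface),
                warn_overlap = FALSE)
}

xml_escape_attr <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

cdata_wrap <- function(text) {
  # a CDATA section cannot contain "]]>"; split it across sections
  paste0("<![CDATA[", gsub("]]>", "]]]]><![CDATA[>", text, fixed = TRUE), "]]>")
}

#' Serialize a document to stand-off XML
#'
#' Serialization is deterministic: the same document always yields the same
#' bytes, and `read_report(write_report(d))` reproduces `d` field for field.
#' Invalid documents are refused with the validator's violation list.
#'
#' @param doc A [deid_document()].
#' @param path Optional output file; when `NULL` the XML is returned as a
#'   string.
#' @return The XML string (invisibly when written to `path`).
#' @export
write_report <- function(doc, path = NULL) {
  viol <- validate_document(doc)
  if (length(viol))
    stop("refusing to write invalid document '", doc$doc_id, "':\n  ",
         paste(viol, collapse = "\n  "), call. = FALSE)
  e <- doc$entities
  tag_lines <- if (nrow(e)) {
    sprintf('<%s id="P%d" start="%d" end="%d" text="%s" TYPE="%s"/>',
            e$category, seq_len(nrow(e)) - 1L, e$start, e$end,
            xml_escape_attr(e$text),
            ifelse(is.na(e$subcategory), e$category, e$subcategory))
  } else character()
  tags_block <- if (length(tag_lines))
    paste0("<TAGS>\n", paste(tag_lines, collapse = "\n"), "\n</TAGS>")
  else "<TAGS/>"
  out <- paste0('<?xml version="1.0" encoding="UTF-8"?>\n<deId>\n<TEXT>',
                cdata_wrap(doc$text), "</TEXT>\n", tags_block, "\n</deId>\n")
  if (is.null(path)) return(out)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(enc2utf8(out)), con)
  invisible(out)
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

#' Read a directory of stand-off XML reports, grouped by split
#'
#' Without a manifest, a seeded random equal three-way split
#' (train/validation/test) is produced and persisted next to the reports as
#' `manifest.tsv` (`filename<TAB>split`).
#'
#' @param dir Directory containing `*.xml` reports.
#' @param manifest Optional manifest tibble (`filename`, `split`) or path to
#'   a manifest TSV.
#' @param seed Seed for the generated split when no manifest is given.
#' @param strict Error (rather than warn and skip) on unreadable files or
#'   manifest entries that do not exist.
#' @param persist Write the generated manifest back into `dir`.
#' @return Named list of document lists (`train`, `validation`, `test`) with
#'   the manifest tibble attached as attribute `"manifest"`.
#' @export
read_corpus <- function(dir, manifest = NULL, seed = 1L, strict = FALSE,
                        persist = TRUE) {
  if (is.character(manifest) && length(manifest) == 1L)
    manifest <- utils::read.delim(manifest, header = FALSE,
                                  col.names = c("filename", "split"))
  if (is.null(manifest)) {
    files <- sort(list.files(dir, pattern = "\\.xml$"))
    ord <- with_seed(seed, sample.int(length(files)))
    split <- character(length(files))
    split[ord] <- rep_len(c("train", "validation", "test"), length(files))
    manifest <- tibble::tibble(filename = files, split = split)
    if (persist)
      utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  manifest <- tibble::as_tibble(manifest)
  stopifnot(all(manifest$split %in% c("train", "validation", "test")))
  out <- list(train = list(), validation = list(), test = list())
  skipped <- 0L
  for (i in seq_len(nrow(manifest))) {
    path <- file.path(dir, manifest$filename[i])
    doc <- tryCatch(read_report(path), error = function(e) {
      if (strict) stop("failed reading ", path, ": ", conditionMessage(e),
                       call. = FALSE)
      e
    })
    if (inherits(doc, "error") || inherits(doc, "condition")) {
      skipped <- skipped + 1L
      next
    }
    out[[manifest$split[i]]] <- c(out[[manifest$split[i]]], list(doc))
  }
  if (skipped > 0L)
    warning(skipped, " report(s) skipped as unreadable", call. = FALSE)
  attr(out, "manifest") <- manifest
  out
}

#' Write a list of documents as XML reports
#'
#' @param docs List of [deid_document()]s.
#' @param dir Output directory (created if needed).
#' @return Tibble of written filenames, invisibly.
#' @export
write_corpus <- function(docs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(docs, function(d) {
    f <- paste0(d$doc_id, ".xml")
    write_report(d, file.path(dir, f))
    f
  }, character(1))
  invisible(tibble::tibble(filename = files))
}
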