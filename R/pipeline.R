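#' Preprocess and gold-encode a list of documents
#'
#' @param docs List of [deid_document()]s.
#' @param cfg A [preprocess_config()].
#' @param scheme A [label_scheme()]; when supplied, gold labels are encoded
#'   into a `label` column.
#' @return Token tibble with a `doc_id` column, one row per token.
#' @export
corpus_tokens <- function(docs, cfg = preprocess_config(), scheme = NULL) {
  out <- purrr::map(docs, function(d) {
    toks <- preprocess_document(d, cfg)
    if (!is.null(scheme)) toks <- encode_labels(toks, d$entities, scheme)
    dplyr::mutate(toks, doc_id = d$doc_id, .before = 1)
  })
  dplyr::bind_rows(out)
}

read_flat_corpus <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.xml$", full.names = TRUE))
  lapply(files, read_report)
}

#' Train the de-identification tagger on an annotated corpus
#'
#' Trains corpus embeddings and the reference tagger on the training split
#' with early stopping on the validation split, then refits on the combined
#' training and validation material for the selected number of epochs, and
#' finally evaluates on the test split (strict and relaxed).
#'
#' @param corpus A directory of reports (read with [read_corpus()]) or a
#'   list with `train` / `validation` / `test` document lists.
#' @param seed Seed controlling the split (if generated), embedding and
#'   tagger training.
#' @param scheme,preprocess_cfg,feature_cfg Module configurations.
#' @param embedding_dim Dimension of the corpus-trained embeddings.
#' @param epochs,patience Training schedule.
#' @param model_path Optional path to write the fitted model file.
#' @param refit Refit on train+validation after early stopping (set
#'   `FALSE` to keep the phase-one model and halve the cost).
#' @return List with `model`, `metrics` (strict/relaxed `deid_eval`), and
#'   `best_epoch`.
#' @export
run_train <- function(corpus, seed = 1L, scheme = label_scheme(),
                      preprocess_cfg = preprocess_config(),
                      feature_cfg = feature_config(),
                      embedding_dim = 25L, epochs = 20L, patience = 5L,
                      model_path = NULL, refit = TRUE) {
  if (is.character(corpus)) corpus <- read_corpus(corpus, seed = seed)
  if (!length(corpus$train) || !length(corpus$validation) ||
      !length(corpus$test))
    stop("empty split: train/validation/test must all be non-empty",
         call. = FALSE)
  tr <- corpus_tokens(corpus$train, preprocess_cfg, scheme)
  va <- corpus_tokens(corpus$validation, preprocess_cfg, scheme)
  emb <- train_embeddings(dplyr::bind_rows(tr, va), d = embedding_dim,
                          seed = seed)
  model <- train_tagger(tr, validation = va, scheme = scheme,
                        feature_cfg = feature_cfg, tables = list(emb),
                        seed = seed, epochs = epochs, patience = patience)
  best <- model$best_epoch
  if (refit) {
    model <- train_tagger(dplyr::bind_rows(tr, va), validation = NULL,
                          scheme = scheme, feature_cfg = feature_cfg,
                          tables = list(emb), seed = seed,
                          epochs = max(1L, best), patience = patience)
  }
  pred_docs <- purrr::map(corpus$test, function(d) {
    deid_document_from_model(d, model, preprocess_cfg)
  })
  metrics <- list(
    strict = micro_evaluate(pred_docs, corpus$test, mode = "strict"),
    relaxed = micro_evaluate(pred_docs, corpus$test, mode = "relaxed")
  )
  if (!is.null(model_path)) write_tagger(model, model_path)
  list(model = model, metrics = metrics, best_epoch = best)
}

# run one raw document through preprocess -> predict -> postprocess
deid_document_from_model <- function(doc, model = NULL,
                                     preprocess_cfg = preprocess_config(),
                                     inventory = default_rule_inventory()) {
  toks <- preprocess_document(doc, preprocess_cfg)
  tagged <- if (!is.null(model)) predict(model, toks) else NULL
  finalize_document(doc$doc_id, doc$text, tagged,
                    scheme = if (!is.null(model)) model$scheme
                             else label_scheme(),
                    inventory = inventory)
}

#' De-identify a directory of reports
#'
#' Reads each report (stand-off XML, or plain `.txt` notes), runs
#' preprocess - predict - postprocess, and writes annotated XML to the
#' output directory together with a `manifest.tsv` of per-file entity
#' counts and the seed.
#'
#' @param input_dir Directory of `*.xml` or `*.txt` inputs.
#' @param out_dir Output directory.
#' @param model A `deid_tagger`, a model file path, or `NULL` for
#'   rules-only operation.
#' @param preprocess_cfg,inventory Module configurations.
#' @param strict Fail (after processing) if any file errored.
#' @param seed Recorded in the manifest.
#' @return Manifest tibble, invisibly.
#' @export
run_deid <- function(input_dir, out_dir, model = NULL,
                     preprocess_cfg = preprocess_config(),
                     inventory = default_rule_inventory(),
                     strict = FALSE, seed = NA_integer_) {
  if (is.character(model)) model <- read_tagger(model)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- sort(list.files(input_dir, pattern = "\\.(xml|txt)$"))
  rows <- purrr::map(files, function(f) {
    path <- file.path(input_dir, f)
    res <- tryCatch({
      doc <- if (grepl("\\.xml$", f)) read_report(path)
      else deid_document(sub("\\.txt$", "", f),
                         paste(readLines(path, warn = FALSE),
                               collapse = "\n"))
      out <- deid_document_from_model(doc, model, preprocess_cfg, inventory)
      write_report(out, file.path(out_dir, paste0(out$doc_id, ".xml")))
      tibble::tibble(filename = f, status = "ok",
                     n_entities = nrow(out$entities))
    }, error = function(e) {
      message("failed on ", f, ": ", conditionMessage(e))
      tibble::tibble(filename = f, status = "error", n_entities = NA_integer_)
    })
    res
  })
  manifest <- dplyr::bind_rows(rows)
  manifest$seed <- seed
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (strict && any(manifest$status == "error"))
    stop(sum(manifest$status == "error"), " file(s) failed", call. = FALSE)
  invisible(manifest)
}

#' Replace annotated SHI with surrogates across a directory
#'
#' Applies [apply_surrogates()] per report and writes the surrogated XML.
#' The manifest records the per-document date shifts and the leak-scan
#' result; any surviving original surface is an error.
#'
#' @param input_dir Directory of annotated `*.xml` reports.
#' @param out_dir Output directory.
#' @param seed Master surrogate seed.
#' @param dictionaries Replacement dictionaries.
#' @return Manifest tibble, invisibly.
#' @export
run_surrogate <- function(input_dir, out_dir, seed = 1L,
                          dictionaries = default_dictionaries()) {
  key <- surrogate_key(seed, dictionaries = dictionaries)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- sort(list.files(input_dir, pattern = "\\.xml$"))
  rows <- purrr::map(files, function(f) {
    doc <- read_report(file.path(input_dir, f))
    out <- apply_surrogates(doc, key)
    write_report(out, file.path(out_dir, f))
    tibble::tibble(filename = f, n_entities = nrow(out$entities),
                   date_shift = key_for_document(key, doc$doc_id)$date_shift,
                   leaks = length(attr(out, "leaks")))
  })
  manifest <- dplyr::bind_rows(rows)
  manifest$seed <- seed
  manifest$date_shift_range <- "1-730"
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (any(manifest$leaks > 0))
    stop("surrogate leak detected in: ",
         paste(manifest$filename[manifest$leaks > 0], collapse = ", "),
         call. = FALSE)
  invisible(manifest)
}

#' Evaluate predicted against gold report directories
#'
#' @param gold_dir,pred_dir Directories of stand-off XML paired by file
#'   name / doc id.
#' @param mode,granularity,tol See [micro_evaluate()].
#' @param out Optional TSV report path.
#' @return A `deid_eval` object.
#' @export
run_evaluate <- function(gold_dir, pred_dir, mode = "strict",
                         granularity = "subcategory", tol = 2L, out = NULL) {
  gold <- read_flat_corpus(gold_dir)
  pred <- read_flat_corpus(pred_dir)
  report <- micro_evaluate(pred, gold, mode = mode,
                           granularity = granularity, tol = tol)
  if (!is.null(out)) write_eval_report(report, out)
  report
}
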