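#' @useDynLib deidr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct an embedding table
#'
#' @param vocab Character vector of tokens.
#' @param vectors Numeric matrix, one row per vocab entry.
#' @param oov Out-of-vocabulary policy: `"zeros"` (the designated OOV vector
#'   is all zeros) — lookups are total either way.
#' @return An `embedding_table` object.
#' @export
embedding_table <- function(vocab, vectors, oov = "zeros") {
  vectors <- as.matrix(vectors)
  stopifnot(length(vocab) == nrow(vectors), !anyDuplicated(vocab))
  rownames(vectors) <- NULL
  structure(list(vocab = vocab, vectors = vectors, dim = ncol(vectors),
                 oov = oov),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat("<embedding_table: ", length(x$vocab), " tokens, d=", x$dim, ">\n",
      sep = "")
  invisible(x)
}

# total lookup: n x d matrix, zeros for OOV
embedding_lookup <- function(table, tokens) {
  idx <- match(tokens, table$vocab)
  out <- matrix(0, nrow = length(tokens), ncol = table$dim)
  hit <- !is.na(idx)
  out[hit, ] <- table$vectors[idx[hit], , drop = FALSE]
  out
}

#' Load word vectors from plain text
#'
#' One `token v1 v2 ... vd` line per entry; an optional `count dim` header
#' line (the common vector-file layout) is tolerated. Ragged dimensions are
#' an error naming the offending line.
#'
#' @param path Vector file path.
#' @return An [embedding_table()].
#' @export
load_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty vector file: ", path)
  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  skip <- length(first) == 2L &&
    !anyNA(suppressWarnings(as.numeric(first))) &&
    all(as.numeric(first) == round(as.numeric(first)))
  if (skip) lines <- lines[-1]
  parts <- strsplit(trimws(lines), "\\s+")
  d <- length(parts[[1]]) - 1L
  bad <- which(lengths(parts) != d + 1L)
  if (length(bad))
    stop("ragged vector file ", path, ": line ", bad[1] + skip,
         " has ", lengths(parts)[bad[1]] - 1L, " values, expected ", d,
         call. = FALSE)
  vocab <- vapply(parts, `[[`, character(1), 1L)
  vec <- matrix(as.numeric(unlist(lapply(parts, `[`, -1L))),
                ncol = d, byrow = TRUE)
  if (anyNA(vec)) stop("non-numeric vector values in ", path)
  embedding_table(vocab, vec)
}

#' Write an embedding table as plain text
#'
#' @param table An [embedding_table()].
#' @param path Output path.
#' @param header Write the `count dim` header line.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(table, path, header = TRUE) {
  lines <- paste(table$vocab,
                 apply(table$vectors, 1, paste, collapse = " "))
  if (header) lines <- c(paste(length(table$vocab), table$dim), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Train word embeddings on a tokenized corpus
#'
#' Skip-gram with negative sampling, single-threaded and deterministic
#' under a fixed seed. The vocabulary covers every token occurring at
#' least `min_count` times, ordered by frequency.
#'
#' @param sentences List of character vectors (tokens per sentence), or a
#'   token tibble with `sentence_id` (and optionally `doc_id`) columns.
#' @param d Embedding dimension.
#' @param seed Training seed.
#' @param window Maximum context window each side (sampled dynamically).
#' @param negative Negative samples per context pair.
#' @param epochs Passes over the corpus.
#' @param min_count Minimum token frequency for vocabulary inclusion.
#' @param alpha Initial learning rate (linearly decayed).
#' @return An [embedding_table()].
#' @export
train_embeddings <- function(sentences, d = 25L, seed = 1L, window = 5L,
                             negative = 5L, epochs = 5L, min_count = 2L,
                             alpha = 0.025) {
  stopifnot(d > 0)
  if (is.data.frame(sentences)) {
    key <- if ("doc_id" %in% names(sentences))
      paste(sentences$doc_id, sentences$sentence_id) else
      as.character(sentences$sentence_id)
    sentences <- split(sentences$text, factor(key, levels = unique(key)))
  }
  stopifnot(length(sentences) >= 1L)
  tokens <- unlist(sentences, use.names = FALSE)
  tab <- table(tokens)
  tab <- tab[tab >= min_count]
  if (!length(tab)) stop("no token reaches min_count = ", min_count)
  vocab <- names(sort(tab, decreasing = TRUE))
  counts <- as.integer(tab[vocab])
  ids <- lapply(sentences, function(s) {
    i <- match(s, vocab)
    i[is.na(i)] <- 0L
    i - 1L  # 0-based, -1 = OOV
  })
  vec <- sgns_train_cpp(ids, counts, as.integer(d), as.integer(window),
                        as.integer(negative), as.integer(epochs),
                        alpha, as.integer(seed))
  embedding_table(vocab, vec)
}

# 3-letter month alternation, case-insensitive by construction (shared with
# the rule inventory in postprocess)
.mon <- "(?:[Jj][Aa][Nn]|[Ff][Ee][Bb]|[Mm][Aa][Rr]|[Aa][Pp][Rr]|[Mm][Aa][Yy]|[Jj][Uu][Nn]|[Jj][Uu][Ll]|[Aa][Uu][Gg]|[Ss][Ee][Pp]|[Oo][Cc][Tt]|[Nn][Oo][Vv]|[Dd][Ee][Cc])"

.orth_names <- c("ALL_CAPS", "INIT_CAP", "ALL_LOWER", "ALL_DIGITS",
                 "CONTAINS_DIGIT", "ALPHA_NUM_MIX", "HAS_DASH", "HAS_SLASH",
                 "HAS_DOT", "HAS_AT", "LEN_1", "LEN_2_4", "LEN_GE_5",
                 "MATCHES_DATE_PATTERN", "MATCHES_PHONE_PATTERN",
                 "MATCHES_ZIP_PATTERN", "MATCHES_ID_PATTERN",
                 "SHAPE_Xx", "SHAPE_XX", "SHAPE_dd")

.date_full <- paste0(
  "^(\\d{1,2}[/-]\\d{1,2}[/-]\\d{4}",
  "|", .mon, "[/-]\\d{1,2}[/-]\\d{4}",
  "|\\d{1,2}[/-]", .mon, "[/-]\\d{4})$")
.phone_full <- "^(\\d{10}|\\d{3}\\.\\d{3}\\.\\d{4}|\\d{3}-\\d{3}-\\d{4})$"

#' Orthographic one-hot features of tokens
#'
#' Fixed-order binary surface-form indicators: capitalization and digit
#' patterns, punctuation content, length buckets, full-string date / phone /
#' postcode / identifier pattern matches, and token shape flags.
#'
#' @param token_text Character vector of tokens.
#' @return Binary matrix `length(token_text)` x 20 with feature names as
#'   column names.
#' @export
#' @examples
#' orthographic_features(c("HM", "12G00123", "2000"))
orthographic_features <- function(token_text) {
  x <- token_text
  n <- nchar(x)
  has_alpha <- grepl("[[:alpha:]]", x)
  has_digit <- grepl("[0-9]", x)
  m <- cbind(
    ALL_CAPS = grepl("^[[:upper:]]+$", x),
    INIT_CAP = grepl("^[[:upper:]]", x),
    ALL_LOWER = grepl("^[[:lower:]]+$", x),
    ALL_DIGITS = grepl("^[0-9]+$", x),
    CONTAINS_DIGIT = has_digit,
    ALPHA_NUM_MIX = has_alpha & has_digit,
    HAS_DASH = grepl("-", x, fixed = TRUE),
    HAS_SLASH = grepl("/", x, fixed = TRUE),
    HAS_DOT = grepl(".", x, fixed = TRUE),
    HAS_AT = grepl("@", x, fixed = TRUE),
    LEN_1 = n == 1L,
    LEN_2_4 = n >= 2L & n <= 4L,
    LEN_GE_5 = n >= 5L,
    MATCHES_DATE_PATTERN = grepl(.date_full, x, perl = TRUE),
    MATCHES_PHONE_PATTERN = grepl(.phone_full, x),
    MATCHES_ZIP_PATTERN = grepl("^\\d{4,5}$", x),
    MATCHES_ID_PATTERN = grepl("^\\d{2}[A-Z]\\d{5}$", x),
    SHAPE_Xx = grepl("^[[:upper:]][[:lower:]]+$", x),
    SHAPE_XX = grepl("^[[:upper:]]{2,}$", x),
    SHAPE_dd = grepl("^\\d{2}$", x)
  )
  storage.mode(m) <- "double"
  m
}

#' Feature configuration for the sequence tagger
#'
#' Each token is represented by the concatenated embeddings of itself and
#' its `window` neighbours each side (zero padding at sentence
#' boundaries), concatenated with its own orthographic one-hots, passed
#' through a rectified-linear activation.
#'
#' @param window Tokens each side (default 2).
#' @param orthographic Include the 20 orthographic flags.
#' @return A `feature_config` list. Total feature length is
#'   `(2 * window + 1) * sum(dims) + 20 * orthographic`.
#' @export
feature_config <- function(window = 2L, orthographic = TRUE) {
  stopifnot(window >= 0L)
  structure(list(window = as.integer(window),
                 orthographic = isTRUE(orthographic)),
            class = "feature_config")
}

feature_length <- function(cfg, tables) {
  total_d <- sum(vapply(tables, `[[`, numeric(1), "dim"))
  (2L * cfg$window + 1L) * total_d + if (cfg$orthographic) 20L else 0L
}

# corpus-scale feature builder: tokens_tbl must have `text` and a sentence
# grouping (doc_id + sentence_id if present). Returns n x F matrix after the
# rectified-linear activation.
build_features <- function(tokens_tbl, cfg, tables) {
  n <- nrow(tokens_tbl)
  if (!is.list(tables) || inherits(tables, "embedding_table"))
    tables <- list(tables)
  group <- if ("sentence_id" %in% names(tokens_tbl)) {
    if ("doc_id" %in% names(tokens_tbl))
      paste(tokens_tbl$doc_id, tokens_tbl$sentence_id)
    else as.character(tokens_tbl$sentence_id)
  } else rep("s", n)
  emb <- do.call(cbind, lapply(tables, embedding_lookup,
                               tokens = tokens_tbl$text))
  total_d <- ncol(emb)
  shifts <- seq(-cfg$window, cfg$window)
  blocks <- lapply(shifts, function(s) {
    if (s == 0L) return(emb)
    idx <- seq_len(n) + s
    valid <- idx >= 1L & idx <= n
    valid[valid] <- group[idx[valid]] == group[valid]
    out <- matrix(0, n, total_d)
    out[valid, ] <- emb[idx[valid], , drop = FALSE]
    out
  })
  X <- do.call(cbind, blocks)
  if (cfg$orthographic) X <- cbind(X, orthographic_features(tokens_tbl$text))
  X[X < 0] <- 0  # rectified-linear activation
  X
}

#' Feature vectors for one sentence
#'
#' @param sentence_tokens Token tibble (or character vector) for a single
#'   sentence.
#' @param cfg A [feature_config()].
#' @param tables One [embedding_table()] or a list of tables whose vectors
#'   are concatenated per token.
#' @return Numeric matrix, one row per token, nonnegative (post
#'   activation).
#' @export
featurize <- function(sentence_tokens, cfg = feature_config(), tables) {
  if (is.character(sentence_tokens))
    sentence_tokens <- tibble::tibble(text = sentence_tokens)
  build_features(sentence_tokens, cfg, tables)
}
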