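# Deterministic 31-bit rolling hash of strings + integers; the keyed source
# of all surrogate randomness (platform-independent, no global RNG use).
key_hash <- function(...) {
  parts <- paste(vapply(list(...), paste, character(1), collapse = "\x1f"),
                 collapse = "\x1f")
  h <- 0
  for (c in utf8ToInt(parts)) h <- (h * 131 + c) %% 2147483647
  as.integer(h)
}

# keyed integer in 1..n
keyed_int <- function(n, ...) 1L + key_hash(...) %% as.integer(n)

#' Construct a surrogate key
#'
#' A surrogate key bundles everything replacement needs: the master seed,
#' the per-document date shift (1-730 days, applied backward), the fixed
#' alphabet shift `k` (1-25) and the keyed random alphabet map used for
#' name replacement, and the replacement dictionaries. All derived
#' quantities are deterministic functions of the seed, so the same key
#' always produces the same surrogates.
#'
#' @param seed Master integer seed.
#' @param date_shift Day shift override (1-730); derived from the seed when
#'   `NULL`.
#' @param alpha_shift Alphabet shift override (1-25); derived when `NULL`.
#' @param dictionaries See [default_dictionaries()].
#' @return A `surrogate_key` object.
#' @export
surrogate_key <- function(seed, date_shift = NULL, alpha_shift = NULL,
                          dictionaries = default_dictionaries()) {
  seed <- as.integer(seed)
  if (is.null(date_shift)) date_shift <- keyed_int(730L, seed, "date_shift")
  if (is.null(alpha_shift)) alpha_shift <- keyed_int(25L, seed, "alpha_shift")
  stopifnot(date_shift >= 1, date_shift <= 730,
            alpha_shift >= 1, alpha_shift <= 25)
  alpha_map <- with_seed(key_hash(seed, "alpha_map"), sample(26L))
  structure(list(seed = seed, date_shift = as.integer(date_shift),
                 alpha_shift = as.integer(alpha_shift),
                 alpha_map = alpha_map, dictionaries = dictionaries),
            class = "surrogate_key")
}

# per-document key: same master mappings, document-specific date shift
key_for_document <- function(key, doc_id) {
  key$date_shift <- keyed_int(730L, key$seed, "doc_date_shift", doc_id)
  key
}

.case_like <- function(template, x) {
  if (grepl("^[[:upper:]]+$", template) && nchar(template) > 1L) toupper(x)
  else if (grepl("^[[:lower:]]", template)) tolower(x)
  else x
}

#' Generate a name surrogate
#'
#' The original initial letter is shifted by the key's fixed alphabet shift
#' (wrapping), mapped through the keyed random alphabet map, and a
#' replacement starting with the resulting letter is drawn deterministically
#' from the dictionary bucket. Multi-word names are replaced word by word
#' (given names from the given-name list, final word from the surname
#' list); the original's case pattern (Title/ALLCAPS) is preserved and the
#' replacement never equals the original.
#'
#' @param name Original name surface (alphabetic initial).
#' @param key A [surrogate_key()].
#' @param salt Collision-avoidance salt used by [apply_surrogates()] to
#'   re-draw when a replacement matches another original surface.
#' @return Replacement name string.
#' @export
surrogate_name <- function(name, key, salt = 0L) {
  words <- strsplit(trimws(name), "\\s+")[[1]]
  stopifnot(length(words) >= 1L)
  out <- vapply(seq_along(words), function(i) {
    w <- words[i]
    init <- toupper(substr(w, 1, 1))
    if (!init %in% LETTERS) return(w)  # non-alphabetic fragment kept
    shifted <- ((match(init, LETTERS) - 1L + key$alpha_shift) %% 26L) + 1L
    target <- LETTERS[key$alpha_map[shifted]]
    dict <- if (i < length(words) && length(words) > 1L)
      key$dictionaries$given_names else key$dictionaries$surnames
    bucket <- dict[toupper(substr(dict, 1, 1)) == target]
    if (!length(bucket)) { # nearest non-empty letter bucket
      for (off in 1:25) {
        for (cand in LETTERS[c((match(target, LETTERS) - 1L + off) %% 26L + 1L,
                               (match(target, LETTERS) - 1L - off) %% 26L + 1L)]) {
          bucket <- dict[toupper(substr(dict, 1, 1)) == cand]
          if (length(bucket)) break
        }
        if (length(bucket)) break
      }
      message("empty dictionary bucket for initial ", target,
              "; fell back to nearest letter")
    }
    pick <- keyed_int(length(bucket), key$seed, "NAME", tolower(w), i, salt)
    repl <- bucket[pick]
    if (tolower(repl) == tolower(w))
      repl <- bucket[(pick %% length(bucket)) + 1L]
    if (tolower(repl) == tolower(w)) repl <- paste0(repl, "e")
    .case_like(w, repl)
  }, character(1))
  paste(out, collapse = " ")
}

# lexical date parse against the detector shapes; NULL when unparseable.
# Numeric forms read day-first.
.parse_date <- function(text) {
  mnames <- c("jan", "feb", "mar", "apr", "may", "jun",
              "jul", "aug", "sep", "oct", "nov", "dec")
  sep <- if (grepl("/", text, fixed = TRUE)) "/" else
    if (grepl("-", text, fixed = TRUE)) "-" else return(NULL)
  f <- strsplit(text, sep, fixed = TRUE)[[1]]
  if (length(f) != 3L) return(NULL)
  is_mon <- tolower(f) %in% mnames
  num <- suppressWarnings(as.integer(f))
  style <- NULL; d <- m <- y <- NA_integer_
  if (!any(is_mon)) {
    if (any(is.na(num))) return(NULL)
    if (nchar(f[3]) != 4L) return(NULL)
    d <- num[1]; m <- num[2]; y <- num[3]; style <- "dmy"
  } else if (is_mon[1] && !is.na(num[2]) && nchar(f[3]) == 4L) {
    m <- match(tolower(f[1]), mnames); d <- num[2]; y <- num[3]; style <- "mdy"
  } else if (is_mon[2] && !is.na(num[1]) && nchar(f[3]) == 4L) {
    m <- match(tolower(f[2]), mnames); d <- num[1]; y <- num[3]; style <- "dmy_mon"
  } else return(NULL)
  if (is.na(d) || is.na(m) || is.na(y) || m < 1 || m > 12 || d < 1 || d > 31)
    return(NULL)
  date <- as.Date(sprintf("%04d-%02d-%02d", y, m, d))
  if (is.na(date)) return(NULL)
  list(date = date, sep = sep, style = style,
       pad_d = nchar(f[if (style == "mdy") 2 else 1]) == 2L,
       pad_m = style == "dmy" && nchar(f[2]) == 2L,
       mon_case = if (any(is_mon)) f[is_mon][1] else NULL)
}

.render_date <- function(p, date) {
  d <- as.integer(format(date, "%d")); m <- as.integer(format(date, "%m"))
  y <- format(date, "%Y")
  fd <- if (p$pad_d) sprintf("%02d", d) else as.character(d)
  if (p$style == "dmy") {
    fm <- if (p$pad_m) sprintf("%02d", m) else as.character(m)
    paste(fd, fm, y, sep = p$sep)
  } else {
    mon <- .case_like(p$mon_case, format(date, "%b"))
    mon <- substr(mon, 1, 3)
    if (p$style == "mdy") paste(mon, fd, y, sep = p$sep)
    else paste(fd, mon, y, sep = p$sep)
  }
}

#' Generate a date surrogate
#'
#' The date is parsed lexically against the recognized shapes (numeric
#' fields read day-first), shifted backward by the key's per-document day
#' shift, and re-rendered in the same shape: same separator, same month
#' style and case, zero padding preserved. Because the shift is shared
#' across a document, all pairwise day differences between its dates are
#' preserved. Unparseable dates fall back to format-preserving digit
#' randomization.
#'
#' @param date_text Original date surface.
#' @param key A [surrogate_key()].
#' @return Replacement date string in the same format.
#' @export
#' @examples
#' k <- surrogate_key(1, date_shift = 365)
#' surrogate_date("1/12/2000", k)
surrogate_date <- function(date_text, key) {
  p <- .parse_date(date_text)
  if (is.null(p)) {
    message("unparseable date ", dQuote(date_text),
            "; using digit randomization")
    return(surrogate_structured(date_text, "DATE", key))
  }
  .render_date(p, p$date - key$date_shift)
}

#' Format-preserving surrogate for identifiers and contact strings
#'
#' Each digit becomes a keyed-random digit, each letter a keyed-random
#' letter of the same case; punctuation and layout are unchanged, so the
#' replacement has exactly the original's length and character pattern.
#' Keyed by `(text, type, seed)`: identical inputs map identically within a
#' run, and the replacement always differs from the original.
#'
#' @param text Original surface.
#' @param shi_type Type key used in the hash (e.g. `"ID_IDNUM"`).
#' @param key A [surrogate_key()].
#' @param salt Collision-avoidance salt (see [surrogate_name()]).
#' @return Replacement string.
#' @export
surrogate_structured <- function(text, shi_type, key, salt = 0L) {
  ch <- strsplit(text, "", fixed = TRUE)[[1]]
  mutable <- grepl("[0-9A-Za-z]", ch)
  if (!any(mutable)) return(text)
  for (inner in 10L * salt + 0:9) {
    out <- ch
    rnd <- with_seed(key_hash(key$seed, shi_type, text, inner), {
      list(d = sample(0:9, sum(mutable), replace = TRUE),
           l = sample(letters, sum(mutable), replace = TRUE))
    })
    j <- 0L
    for (i in which(mutable)) {
      j <- j + 1L
      out[i] <- if (grepl("[0-9]", ch[i])) as.character(rnd$d[j])
      else if (grepl("[[:upper:]]", ch[i])) toupper(rnd$l[j])
      else rnd$l[j]
    }
    res <- paste(out, collapse = "")
    if (!identical(res, text)) return(res)
  }
  res
}

#' Surrogates for ages, locations and remaining categories
#'
#' Ages receive a keyed jitter of up to two years (never zero, floored at
#' 1), rendered with the original digit count when possible. Locations are
#' replaced from the dictionary of their subcategory (hospital for
#' hospital, city for city, ...), falling back to a generic location list;
#' ZIP codes are digit-randomized. Professions are swapped within the
#' profession dictionary. Anything else falls back to format-preserving
#' randomization.
#'
#' @param text Original surface.
#' @param category,subcategory SHI type of the entity.
#' @param key A [surrogate_key()].
#' @param salt Collision-avoidance salt (see [surrogate_name()]).
#' @return Replacement string.
#' @export
surrogate_other <- function(text, category, subcategory, key, salt = 0L) {
  if (category == "AGE") {
    age <- suppressWarnings(as.integer(gsub("[^0-9]", "", text)))
    if (is.na(age)) return(surrogate_structured(text, "AGE", key))
    jitter <- c(-2L, -1L, 1L, 2L)[keyed_int(4L, key$seed, "AGE", text)]
    new_age <- max(1L, age + jitter)
    if (new_age == age) new_age <- max(1L, age - jitter)
    return(as.character(new_age))
  }
  if (category == "LOCATION" && identical(subcategory, "ZIP"))
    return(surrogate_structured(text, "LOCATION_ZIP", key, salt))
  dict <- if (category == "LOCATION")
    location_dictionary(key$dictionaries, subcategory)
  else if (category == "PROFESSION") key$dictionaries$professions
  else NULL
  if (is.null(dict))
    return(surrogate_structured(text, shi_type_key(category, subcategory),
                                key, salt))
  pick <- keyed_int(length(dict), key$seed, category, tolower(text), salt)
  repl <- dict[pick]
  if (tolower(repl) == tolower(text)) repl <- dict[(pick %% length(dict)) + 1L]
  .case_like(text, repl)
}

surrogate_for <- function(text, category, subcategory, key, salt = 0L) {
  switch(category,
         NAME = surrogate_name(text, key, salt),
         DATE = surrogate_date(text, key),
         ID = ,
         CONTACT = surrogate_structured(
           text, shi_type_key(category, subcategory), key, salt),
         surrogate_other(text, category, subcategory, key, salt))
}

#' Replace every annotated entity in a document with a surrogate
#'
#' Entities are replaced per category (names by dictionary mapping, dates
#' by the per-document backward day shift, IDs and contacts by
#' format-preserving randomization, ages by jitter, locations by
#' dictionary swap), the text is re-flowed and all offsets recomputed.
#' Non-entity text is unchanged byte for byte. Overlapping entities are
#' processed longest-first and contained duplicates dropped. The output
#' passes [validate_document()] and is scanned for leaks: any original
#' entity surface of three or more characters still present in the output
#' text is recorded in the `"leaks"` attribute.
#'
#' @param doc A [deid_document()] with entities.
#' @param key A [surrogate_key()]; its date shift is re-derived per
#'   document from `(seed, doc_id)`.
#' @return A new [deid_document()] with surrogate text and updated offsets;
#'   attributes `"surrogate_map"` (tibble original/type/replacement) and
#'   `"leaks"` (character vector, empty when clean).
#' @export
apply_surrogates <- function(doc, key) {
  key <- key_for_document(key, doc$doc_id)
  e <- doc$entities
  if (!nrow(e)) {
    out <- doc
    attr(out, "surrogate_map") <- tibble::tibble(original = character(),
                                                 type = character(),
                                                 replacement = character())
    attr(out, "leaks") <- character()
    return(out)
  }
  # drop entities strictly contained in a longer one (longest-first priority)
  len <- e$end - e$start
  keep <- vapply(seq_len(nrow(e)), function(j) {
    !any(e$start <= e$start[j] & e$end >= e$end[j] & len > len[j])
  }, logical(1))
  if (!all(keep))
    message(sum(!keep), " contained duplicate entit(ies) dropped in '",
            doc$doc_id, "'")
  e <- sort_entities(e[keep, ])
  # any remaining (partial) overlaps: keep the earlier span
  cur <- -1L
  keep2 <- vapply(seq_len(nrow(e)), function(i) {
    if (e$start[i] < cur) return(FALSE)
    cur <<- e$end[i]
    TRUE
  }, logical(1))
  if (!all(keep2))
    message(sum(!keep2), " partially overlapping entit(ies) skipped in '",
            doc$doc_id, "'")
  e <- e[keep2, ]
  # any replacement colliding with a different original surface in this
  # document would survive the leak scan; re-salt the keyed draw until clear
  # (dates are exempt: the shared per-document shift must stay intact)
  avoid <- tolower(unique(e$text[nchar(e$text) >= 3L]))
  contains_avoided <- function(r) {
    any(vapply(avoid, function(a) grepl(a, tolower(r), fixed = TRUE),
               logical(1)))
  }
  repl <- vapply(seq_len(nrow(e)), function(i) {
    r <- surrogate_for(e$text[i], e$category[i], e$subcategory[i], key)
    if (e$category[i] != "DATE") {
      s <- 0L
      while (contains_avoided(r) && s < 10L) {
        s <- s + 1L
        r <- surrogate_for(e$text[i], e$category[i], e$subcategory[i], key, s)
      }
    }
    r
  }, character(1))
  # re-flow text and offsets
  pieces <- character(2L * nrow(e) + 1L)
  new_start <- new_end <- integer(nrow(e))
  cursor_old <- 0L; cursor_new <- 0L
  for (i in seq_len(nrow(e))) {
    gap <- substr0(doc$text, cursor_old, e$start[i])
    pieces[2L * i - 1L] <- gap
    pieces[2L * i] <- repl[i]
    new_start[i] <- cursor_new + nchar(gap)
    new_end[i] <- new_start[i] + nchar(repl[i])
    cursor_new <- new_end[i]
    cursor_old <- e$end[i]
  }
  pieces[2L * nrow(e) + 1L] <- substr0(doc$text, cursor_old, nchar(doc$text))
  new_text <- paste(pieces, collapse = "")
  out <- deid_document(doc$doc_id, new_text,
                       entity_tbl(e$category, e$subcategory, new_start,
                                  new_end, repl),
                       warn_overlap = FALSE)
  originals <- unique(e$text[nchar(e$text) >= 3L])
  leaks <- originals[vapply(originals, function(s)
    grepl(s, new_text, fixed = TRUE), logical(1))]
  attr(out, "surrogate_map") <- tibble::tibble(
    original = e$text, type = shi_type_key(e$category, e$subcategory),
    replacement = repl)
  attr(out, "leaks") <- leaks
  out
}
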