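#' SHI category and subcategory taxonomy
#'
#' The sensitive health information (SHI) taxonomy used throughout the
#' package: eight top-level categories, five of which carry subcategories.
#' Annotation depth is at the subcategory level where one exists; the
#' combination is written `CATEGORY_SUBCATEGORY` in token labels (e.g.
#' `ID_IDNUM`) and the subcategory alone is carried in the XML `TYPE`
#' attribute.
#'
#' @return A tibble with columns `category` and `subcategory` (`NA` for
#'   categories without subcategories), one row per annotatable type.
#' @export
#' @examples
#' shi_taxonomy()
shi_taxonomy <- function() {
  subs <- list(
    NAME       = c("PATIENT", "DOCTOR", "USERNAME"),
    PROFESSION = NA_character_,
    LOCATION   = c("HOSPITAL", "ORGANIZATION", "STREET", "CITY", "STATE",
                   "COUNTRY", "ZIP", "OTHER", "ROOM"),
    AGE        = NA_character_,
    DATE       = NA_character_,
    CONTACT    = c("PHONE", "FAX", "EMAIL", "URL", "IPADDRESS"),
    ID         = c("SSN", "MEDICALRECORD", "HEALTHPLAN", "ACCOUNT", "LICENSE",
                   "VEHICLE", "DEVICE", "BIOID", "IDNUM"),
    OTHER      = NA_character_
  )
  tibble::tibble(
    category = rep(names(subs), lengths(subs)),
    subcategory = unlist(subs, use.names = FALSE)
  )
}

#' @rdname shi_taxonomy
#' @export
shi_categories <- function() unique(shi_taxonomy()$category)

#' Subcategories excluded from model training by default
#'
#' `LOCATION:ROOM` and `ID:BIOID` are representable in documents and in the
#' XML dialect but are dropped from the label alphabet by default because
#' they are vanishingly rare in practice. Pass a different exclusion list to
#' [label_scheme()] to change this.
#'
#' @return Character vector of `CATEGORY_SUBCATEGORY` keys.
#' @export
default_type_exclusions <- function() c("LOCATION_ROOM", "ID_BIOID")

#' Canonical type key for a category/subcategory pair
#'
#' @param category,subcategory Character vectors (recycled).
#' @return `CATEGORY` or `CATEGORY_SUBCATEGORY` strings.
#' @export
shi_type_key <- function(category, subcategory = NA_character_) {
  out <- as.character(category)
  sub <- rep_len(as.character(subcategory), length(out))
  has <- !is.na(sub) & nzchar(sub)
  out[has] <- paste0(out[has], "_", sub[has])
  out
}

#' Split a type key back into category and subcategory
#'
#' @param key Character vector of `CATEGORY[_SUBCATEGORY]` keys.
#' @return Tibble with columns `category`, `subcategory`.
#' @export
shi_type_unkey <- function(key) {
  category <- sub("_.*$", "", key)
  subcategory <- ifelse(grepl("_", key), sub("^[^_]*_", "", key), NA_character_)
  tibble::tibble(category = category, subcategory = subcategory)
}

# TRUE for rows present in the taxonomy (subcategory NA allowed only where the
# category has none, except a bare category is also a legal annotation when
# the dialect omits depth).
valid_shi_type <- function(category, subcategory) {
  tax <- shi_taxonomy()
  ok_cat <- category %in% tax$category
  key <- shi_type_key(category, subcategory)
  all_keys <- shi_type_key(tax$category, tax$subcategory)
  ok_cat & (is.na(subcategory) | key %in% all_keys)
}

#' Construct a token-label scheme over the SHI taxonomy
#'
#' Builds the label alphabet for a BIO or BIESO tagging scheme: the cross of
#' scheme prefixes with the in-scope type keys, plus the outside label `"O"`.
#' BIESO marks Beginning / Inside / Ending tokens of multi-token SHI mentions,
#' Single-token mentions, and Outside tokens; BIO folds E and S into I and B.
#'
#' @param name `"BIESO"` (default) or `"BIO"`.
#' @param types Character vector of type keys in scope. Defaults to every
#'   taxonomy type at subcategory depth minus [default_type_exclusions()].
#' @param exclusions Type keys to drop from the default inventory.
#' @return A `label_scheme` object: list with `name`, `prefixes`, `types`,
#'   `alphabet`.
#' @export
#' @examples
#' sch <- label_scheme("BIESO")
#' head(sch$alphabet)
label_scheme <- function(name = c("BIESO", "BIO"), types = NULL,
                         exclusions = default_type_exclusions()) {
  name <- match.arg(name)
  if (is.null(types)) {
    tax <- shi_taxonomy()
    types <- setdiff(shi_type_key(tax$category, tax$subcategory), exclusions)
  }
  prefixes <- if (name == "BIESO") c("B", "I", "E", "S") else c("B", "I")
  alphabet <- c("O", as.vector(t(outer(prefixes, types, paste, sep = "-"))))
  structure(list(name = name, prefixes = prefixes, types = types,
                 alphabet = alphabet),
            class = "label_scheme")
}

#' @export
print.label_scheme <- function(x, ...) {
  cat("<label_scheme ", x$name, ": ", length(x$types), " types, ",
      length(x$alphabet), " labels>\n", sep = "")
  invisible(x)
}

label_prefix <- function(labels) ifelse(labels == "O", "O", sub("-.*$", "", labels))
label_type <- function(labels) ifelse(labels == "O", NA_character_, sub("^[A-Z]+-", "", labels))
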