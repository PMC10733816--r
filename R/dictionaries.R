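#' Synthetic replacement dictionaries
#'
#' Deterministically constructed, entirely fictional word lists used both by
#' the surrogate generator (replacement buckets) and by the synthetic corpus
#' generator (slot fillers). Surnames and given names are built from
#' per-letter stems crossed with suffixes, guaranteeing at least 10 entries
#' per initial letter for every letter A-Z; each location subcategory list
#' has at least 20 entries. No list contains real person names. Sites can
#' supply their own dictionaries with the same element names.
#'
#' @return Named list of character vectors: `surnames`, `given_names`,
#'   `cities`, `hospitals`, `streets`, `states`, `countries`,
#'   `organizations`, `professions`, `generic_locations`.
#' @export
default_dictionaries <- function() {
  letters_up <- LETTERS
  stem_mid <- c("ar", "en", "or", "il", "ad", "um", "es", "ob", "ud", "an")
  surname_suffix <- c("son", "field", "worth", "by", "ham",
                      "stead", "wick", "mere", "dale", "ford")
  surnames <- as.vector(vapply(letters_up, function(L) {
    paste0(L, stem_mid, surname_suffix)
  }, character(10)))
  given_suffix <- c("a", "el", "in", "o", "ys", "ia", "ett", "ric", "una", "eth")
  given_names <- as.vector(vapply(letters_up, function(L) {
    paste0(L, stem_mid, given_suffix)
  }, character(10)))
  city_stems <- paste0(rep(letters_up, each = 2),
                       rep(c("ald", "erris"), 26))
  cities <- paste0(city_stems, rep(c("ville", "port", "ton", "haven"),
                                   length.out = length(city_stems)))
  hospitals <- paste0(cities[seq(1, 52, 2)], " ",
                      rep(c("General Hospital", "Medical Centre",
                            "District Hospital", "Community Clinic"),
                          length.out = 26))
  streets <- paste0(surnames[seq(5, 260, 11)], " ",
                    rep(c("Street", "Road", "Avenue", "Lane", "Crescent"),
                        length.out = 24))
  states <- paste0(c("North", "South", "East", "West", "Upper", "Lower",
                     "New", "Old", "Central", "Outer", "Inner", "Far",
                     "High", "Low", "Mid", "Grand", "Little", "Great",
                     "Port", "Cape"), " ",
                   rep(c("Aldermark", "Bexley", "Corwin", "Delmont"),
                       each = 5))
  countries <- paste0(c("Nor", "Sud", "Est", "Vest", "Alt", "Bel", "Cor",
                        "Dal", "Fen", "Gal", "Hol", "Ist", "Jor", "Kel",
                        "Lun", "Mor", "Nev", "Ost", "Pel", "Quin"),
                      rep(c("landia", "mark", "onia", "avia"),
                          each = 5))
  organizations <- paste0(cities[seq(2, 80, 4)], " ",
                          rep(c("Pathology Services", "Health Network",
                                "Diagnostics Group", "Research Institute"),
                              length.out = 20))
  # note: must not contain words used verbatim in report templates (e.g.
  # "pathologist"), or a non-entity occurrence defeats the leak scan
  professions <- c("horticulturist", "cardiologist", "radiographer", "teacher",
                   "engineer", "farmer", "nurse", "accountant", "plumber",
                   "electrician", "librarian", "pharmacist", "carpenter",
                   "surveyor", "florist", "mechanic", "chef", "journalist",
                   "physiotherapist", "archivist")
  generic_locations <- cities[seq(1, 40, 2)]
  list(surnames = surnames, given_names = given_names, cities = cities,
       hospitals = hospitals, streets = streets, states = states,
       countries = countries, organizations = organizations,
       professions = professions, generic_locations = generic_locations)
}

# location dictionary element for a subcategory, with generic fallback
location_dictionary <- function(dicts, subcategory) {
  key <- switch(ifelse(is.na(subcategory), "OTHER", subcategory),
                HOSPITAL = "hospitals", CITY = "cities", STREET = "streets",
                STATE = "states", COUNTRY = "countries",
                ORGANIZATION = "organizations", NULL)
  if (is.null(key) || is.null(dicts[[key]]) || !length(dicts[[key]]))
    dicts$generic_locations
  else dicts[[key]]
}
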