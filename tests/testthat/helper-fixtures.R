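# shared fixtures, built in code

doc_hm <- function() {
  deid_document("hm", "Seen by Dr HM today",
                entity_tbl("NAME", "DOCTOR", 11L, 13L, "HM"))
}

doc_ids <- function() {
  deid_document("ids", "12G00123,12N01234",
                entity_tbl(c("ID", "ID"), "IDNUM", c(0L, 9L), c(8L, 17L),
                           c("12G00123", "12N01234")))
}

# random non-overlapping entity set over a synthetic alphabet of types;
# spans are token-ish chunks inside [0, len)
random_entities <- function(n, len, types = c("DATE", "AGE", "ID_IDNUM",
                                              "NAME_DOCTOR")) {
  starts <- sort(sample.int(len - 3L, n))
  ends <- pmin(starts + sample(1:3, n, replace = TRUE), len)
  keep <- c(TRUE, ends[-n][seq_len(n - 1)] <= starts[-1])
  starts <- starts[keep]; ends <- ends[keep]
  tp <- shi_type_unkey(sample(types, length(starts), replace = TRUE))
  entity_tbl(tp$category, tp$subcategory, starts, ends,
             strrep("x", ends - starts))
}

# small deterministic corpus shared where a handful of reports suffice
small_corpus <- function(n = 12, seed = 404, p = 0.05) {
  generate_corpus(generator_config(n_reports = n, seed = seed,
                                   cascade_noise_p = p))
}

# independent maximum bipartite matching size by exhaustive recursion
max_matching_bruteforce <- function(adj) {
  # adj: logical matrix gold x pred
  ng <- nrow(adj)
  best <- 0L
  recur <- function(g, used_pred, size) {
    if (size + (ng - g + 1L) <= best) return()
    if (g > ng) {
      best <<- max(best, size)
      return()
    }
    recur(g + 1L, used_pred, size)  # skip this gold
    for (p in which(adj[g, ])) {
      if (!used_pred[p]) {
        used_pred[p] <- TRUE
        recur(g + 1L, used_pred, size + 1L)
        used_pred[p] <- FALSE
      }
    }
  }
  if (ng > 0L && ncol(adj) > 0L) recur(1L, rep(FALSE, ncol(adj)), 0L)
  best
}

# independent finite-state reference decoder used as the codec oracle:
# implements the declared run semantics directly on raw labels, sharing no
# code with decode_labels/repair_labels. A run opens at any non-O label,
# extends over continuation prefixes (I/E for BIESO, I for BIO) of the same
# type, and closes once an S or E has been consumed.
reference_decode <- function(labels, starts, ends, scheme_name = "BIESO") {
  out <- list()
  i <- 1L; n <- length(labels)
  while (i <= n) {
    if (labels[i] == "O") { i <- i + 1L; next }
    pre <- sub("-.*", "", labels[i])
    tp <- sub("^[A-Z]+-", "", labels[i])
    j <- i
    if (scheme_name == "BIESO") {
      while (pre != "S" && pre != "E" && j < n) {
        nx <- labels[j + 1L]
        if (nx == "O") break
        npre <- sub("-.*", "", nx)
        if (!(npre %in% c("I", "E")) || sub("^[A-Z]+-", "", nx) != tp) break
        j <- j + 1L
        pre <- npre
      }
    } else {
      while (j < n) {
        nx <- labels[j + 1L]
        if (!startsWith(nx, "I-") || sub("^[A-Z]+-", "", nx) != tp) break
        j <- j + 1L
      }
    }
    out[[length(out) + 1L]] <- list(type = tp, from = i, to = j)
    i <- j + 1L
  }
  if (!length(out)) return(tibble::tibble(start = integer(), end = integer(),
                                          type = character()))
  tibble::tibble(
    start = vapply(out, function(r) starts[r$from], integer(1)),
    end = vapply(out, function(r) ends[r$to], integer(1)),
    type = vapply(out, function(r) r$type, character(1))
  )
}
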