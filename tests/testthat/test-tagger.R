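# tiny labeled corpus where the class is determined by the token surface
make_separable <- function(n_sent = 40) {
  purrr::map_dfr(seq_len(n_sent), function(i) {
    tibble::tibble(doc_id = "d", sentence_id = i,
                   text = c("filler", "99", "filler"),
                   start = c(0L, 7L, 10L), end = c(6L, 9L, 16L),
                   label = c("O", "S-AGE", "O"))
  })
}

test_that("linearly separable data trains to perfect accuracy", {
  tab <- embedding_table(c("filler", "99"), diag(2))
  m <- suppressWarnings(
    train_tagger(make_separable(), scheme = label_scheme(),
                 feature_cfg = feature_config(window = 1),
                 tables = list(tab), seed = 1, epochs = 10))
  pred <- predict(m, make_separable())
  expect_identical(pred$label, make_separable()$label)
})

test_that("training and the model file are deterministic under a fixed seed", {
  tab <- embedding_table(c("filler", "99"), diag(2))
  fit <- function() train_tagger(make_separable(), scheme = label_scheme(),
                                 feature_cfg = feature_config(window = 1),
                                 tables = list(tab), seed = 42, epochs = 3)
  m1 <- fit(); m2 <- fit()
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_tagger(m1, f1); write_tagger(m2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(read_tagger(f1)$W, m1$W)
})

test_that("constrained decoding equals exhaustive enumeration on small lattices", {
  sch <- label_scheme("BIESO", types = "DATE")  # 5 labels
  con_types <- sch$alphabet
  vocab <- c("u", "v", "w", "x", "y", "z")
  withr::with_seed(8, {
    tab <- embedding_table(vocab, matrix(stats::rnorm(12), 6, 2))
    base <- suppressWarnings(train_tagger(
      tibble::tibble(doc_id = "d", sentence_id = 1,
                     text = c("x", "y"), start = c(0L, 2L), end = c(1L, 3L),
                     label = c("B-DATE", "E-DATE")),
      scheme = sch, feature_cfg = feature_config(window = 1),
      tables = list(tab), seed = 1, epochs = 2))
    for (rep in 1:25) {
      T_len <- sample(1:6, 1)
      # random model scores: perturb weights, keep transitions; distinct
      # token surfaces keep per-position emissions in general position so
      # the argmax sequence is unique
      m <- base
      m$W <- matrix(stats::rnorm(length(base$W)), nrow(base$W))
      m$b <- stats::rnorm(length(base$b))
      toks <- tibble::tibble(doc_id = "d", sentence_id = 1,
                             text = sample(vocab, T_len),
                             start = 2L * (seq_len(T_len) - 1L),
                             end = 2L * seq_len(T_len) - 1L)
      got <- predict(m, toks)$label

      # exhaustive: score every label sequence under the same quantities
      X <- featurize(toks, m$feature_cfg, m$tables)
      Z <- sweep(X %*% m$W, 2, m$b, "+")
      LS <- Z - apply(Z, 1, max) -
        log(rowSums(exp(Z - apply(Z, 1, max))))
      S <- sweep(LS, 2, m$log_prior, "-")
      cn <- deidr:::scheme_constraints(sch)
      trans <- m$trans; trans[!cn$allowed] <- -Inf
      init <- m$init; init[!cn$start] <- -Inf
      fin <- m$fin; fin[!cn$end] <- -Inf
      seqs <- expand.grid(rep(list(seq_along(con_types)), T_len))
      score <- apply(seqs, 1, function(lab) {
        s <- init[lab[1]] + fin[lab[T_len]] +
          sum(S[cbind(seq_len(T_len), lab)])
        if (T_len > 1)
          s <- s + sum(trans[cbind(lab[-T_len], lab[-1])])
        s
      })
      bestseq <- as.integer(seqs[which.max(score), ])
      expect_identical(got, con_types[bestseq])
    }
  })
})

test_that("predictions are always scheme-valid: decode never needs repair", {
  sch <- label_scheme("BIESO", types = c("DATE", "AGE", "ID_IDNUM"))
  tab <- embedding_table(c("x", "y"), matrix(c(1, 0, 0, 1), 2))
  withr::with_seed(12, {
    base <- suppressWarnings(train_tagger(
      tibble::tibble(doc_id = "d", sentence_id = 1,
                     text = c("x", "y"), start = c(0L, 2L), end = c(1L, 3L),
                     label = c("S-DATE", "O")),
      scheme = sch, feature_cfg = feature_config(window = 1),
      tables = list(tab), seed = 1, epochs = 2))
    for (rep in 1:30) {
      m <- base
      m$W <- matrix(stats::rnorm(length(base$W), sd = 3), nrow(base$W))
      m$b <- stats::rnorm(length(base$b), sd = 3)
      n <- sample(1:9, 1)
      toks <- tibble::tibble(doc_id = "d",
                             sentence_id = rep(1:2, length.out = n),
                             text = sample(c("x", "y"), n, TRUE),
                             start = 2L * (seq_len(n) - 1L),
                             end = 2L * seq_len(n) - 1L)
      toks <- dplyr::arrange(toks, sentence_id)
      lab <- predict(m, toks)$label
      for (ix in split(seq_len(n), toks$sentence_id)) {
        expect_identical(repair_labels(lab[ix], sch), lab[ix])
      }
    }
  })
})

test_that("degenerate single-class data trains with a warning", {
  tab <- embedding_table("x", matrix(1, 1, 2))
  expect_warning(
    train_tagger(tibble::tibble(doc_id = "d", sentence_id = 1, text = "x",
                                start = 0L, end = 1L, label = "O"),
                 tables = list(tab), seed = 1, epochs = 1),
    "single label class")
})

test_that("feature mismatch between model and input is an error", {
  tab <- embedding_table("x", matrix(1, 1, 2))
  m <- suppressWarnings(
    train_tagger(tibble::tibble(doc_id = "d", sentence_id = 1, text = "x",
                                start = 0L, end = 1L, label = "O"),
                 tables = list(tab), seed = 1, epochs = 1))
  m$feature_cfg <- feature_config(window = 4)
  expect_error(predict(m, tibble::tibble(doc_id = "d", sentence_id = 1,
                                         text = "x", start = 0L, end = 1L)),
               "mismatch")
})
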