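# BIESO/BIO validity structures for constrained decoding:
# allowed transitions, start labels, end labels (logical).
scheme_constraints <- function(scheme) {
  alpha <- scheme$alphabet
  L <- length(alpha)
  pre <- label_prefix(alpha)
  typ <- label_type(alpha)
  allowed <- matrix(FALSE, L, L, dimnames = list(alpha, alpha))
  openers <- pre %in% c("O", "B", "S")
  for (i in seq_len(L)) {
    same_type <- !is.na(typ) & !is.na(typ[i]) & typ == typ[i]
    allowed[i, ] <- if (scheme$name == "BIESO") {
      if (pre[i] %in% c("O", "E", "S")) openers
      else pre %in% c("I", "E") & same_type  # open B/I must continue
    } else {
      if (pre[i] == "O") pre %in% c("O", "B")
      else pre %in% c("O", "B") | (pre == "I" & same_type)
    }
  }
  start_ok <- if (scheme$name == "BIESO") openers else pre %in% c("O", "B")
  end_ok <- if (scheme$name == "BIESO") pre %in% c("O", "E", "S")
            else rep(TRUE, L)
  list(allowed = allowed, start = start_ok, end = end_ok)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

log_softmax_rows <- function(Z) {
  M <- apply(Z, 1, max)
  Z - M - log(rowSums(exp(Z - M)))
}

# emission scores for lattice decoding: log P(label | x) - log P(label).
# Dividing out the label prior converts the discriminative posterior into a
# likelihood-proportional score, so the (generative) transition
# log-probabilities do not double-count the heavy class imbalance toward O.
.emission_scores <- function(model, X) {
  Z <- sweep(X %*% model$W, 2, model$b, "+")
  sweep(log_softmax_rows(Z), 2, model$log_prior, "-")
}

# constrained Viterbi over precomputed emission scores; key groups sentences
.decode_scores <- function(S, key, model) {
  con <- scheme_constraints(model$scheme)
  trans <- model$trans; trans[!con$allowed] <- -Inf
  init <- model$init; init[!con$start] <- -Inf
  fin <- model$fin; fin[!con$end] <- -Inf
  # sentences are contiguous row blocks; decode the whole batch in one call
  stopifnot(!is.unsorted(match(key, unique(key))))
  lens <- rle(key)$lengths
  viterbi_decode_batch_cpp(S, lens, trans, init, fin)
}

# strict span-level micro F1 between two label vectors over the same tokens
.span_f1 <- function(pred_labels, gold_labels, tokens, scheme) {
  key_of <- function(labels) {
    tg <- tokens
    tg$label <- labels
    ents <- decode_labels(tg, doc_text = "", scheme = scheme)
    # surfaces are irrelevant here; match on offsets + type only
    paste(ents$start, ents$end, ents$category, ents$subcategory)
  }
  p <- key_of(pred_labels); g <- key_of(gold_labels)
  tp <- sum(p %in% g)
  if (!length(p) && !length(g)) return(1)
  if (tp == 0) return(0)
  prec <- tp / length(p); rec <- tp / length(g)
  2 * prec * rec / (prec + rec)
}

#' Train the reference window-feature sequence tagger
#'
#' A linear per-token scorer (multinomial logistic regression over the
#' window-embedding + orthographic features) trained by minibatch Adam,
#' plus label-transition scores estimated from training bigrams. Decoding
#' combines both by exact dynamic programming with scheme-invalid
#' transitions forbidden, so predictions are valid label sequences by
#' construction. Early stopping monitors token-level accuracy on the
#' validation split and keeps the best-scoring epoch's weights.
#' Deterministic under a fixed seed.
#'
#' @param train Token tibble with columns `doc_id`, `sentence_id`, `text`,
#'   `start`, `end`, `label`.
#' @param validation Optional token tibble of the same shape; without it,
#'   training runs all epochs.
#' @param scheme A [label_scheme()].
#' @param feature_cfg A [feature_config()].
#' @param tables Embedding table(s) used for features (stored in the
#'   model).
#' @param seed Training seed.
#' @param epochs Maximum epochs (default 20).
#' @param patience Early-stopping patience in epochs (default 5).
#' @param batch_size Minibatch size in tokens.
#' @param lr Adam step size.
#' @return A `deid_tagger` object.
#' @export
train_tagger <- function(train, validation = NULL, scheme = label_scheme(),
                         feature_cfg = feature_config(), tables,
                         seed = 1L, epochs = 20L, patience = 5L,
                         batch_size = 4096L, lr = 0.05) {
  stopifnot(nrow(train) >= 1L, "label" %in% names(train))
  bad <- setdiff(unique(train$label), scheme$alphabet)
  if (length(bad)) stop("labels outside scheme alphabet: ",
                        paste(bad, collapse = ", "))
  if (length(unique(train$label)) == 1L)
    warning("degenerate training data: single label class", call. = FALSE)
  alpha <- scheme$alphabet
  L <- length(alpha)
  y <- match(train$label, alpha)
  X <- build_features(train, feature_cfg, tables)
  Fdim <- ncol(X)
  Xv <- if (!is.null(validation)) build_features(validation, feature_cfg,
                                                 tables)
  yv <- if (!is.null(validation)) match(validation$label, alpha)

  # label prior and transition statistics (independent of the weights)
  prior_count <- tabulate(y, nbins = L) + 1
  log_prior <- log(prior_count / sum(prior_count))
  skey <- paste(train$doc_id %||% "d", train$sentence_id)
  trans_count <- matrix(1, L, L, dimnames = list(alpha, alpha))
  init_count <- rep(1, L)
  fin_count <- rep(1, L)
  for (ix in split(seq_len(nrow(train)), factor(skey, levels = unique(skey)))) {
    labs <- y[ix]
    init_count[labs[1]] <- init_count[labs[1]] + 1
    fin_count[labs[length(labs)]] <- fin_count[labs[length(labs)]] + 1
    if (length(labs) > 1L) {
      for (k in seq_len(length(labs) - 1L)) {
        trans_count[labs[k], labs[k + 1L]] <-
          trans_count[labs[k], labs[k + 1L]] + 1
      }
    }
  }
  proto <- list(scheme = scheme, log_prior = log_prior,
                trans = log(trans_count / rowSums(trans_count)),
                init = log(init_count / sum(init_count)),
                fin = log(fin_count / sum(fin_count)))
  vkey <- if (!is.null(validation))
    paste(validation$doc_id %||% "d", validation$sentence_id)

  W <- matrix(0, Fdim, L)
  b <- rep(0, L)
  mW <- vW <- matrix(0, Fdim, L)
  mb <- vb <- rep(0, L)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  n <- nrow(X)
  history <- tibble::tibble(epoch = integer(), train_loss = numeric(),
                            val_accuracy = numeric(), val_f1 = numeric())
  best <- list(W = W, b = b, f1 = -Inf, acc = -Inf, epoch = 0L)
  since_improve <- 0L
  ran_epochs <- 0L
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      total_loss <- 0
      for (start_i in seq(1L, n, by = batch_size)) {
        idx <- ord[start_i:min(start_i + batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        Z <- sweep(Xb %*% W, 2, b, "+")
        P <- softmax_rows(Z)
        picked <- P[cbind(seq_along(idx), y[idx])]
        total_loss <- total_loss - sum(log(pmax(picked, 1e-12)))
        G <- P
        G[cbind(seq_along(idx), y[idx])] <-
          G[cbind(seq_along(idx), y[idx])] - 1
        G <- G / length(idx)
        gW <- crossprod(Xb, G)
        gb <- colSums(G)
        step <- step + 1L
        mW <- beta1 * mW + (1 - beta1) * gW
        vW <- beta2 * vW + (1 - beta2) * gW^2
        mb <- beta1 * mb + (1 - beta1) * gb
        vb <- beta2 * vb + (1 - beta2) * gb^2
        cor1 <- 1 - beta1^step; cor2 <- 1 - beta2^step
        W <- W - lr * (mW / cor1) / (sqrt(vW / cor2) + eps)
        b <- b - lr * (mb / cor1) / (sqrt(vb / cor2) + eps)
      }
      ran_epochs <- ep
      val_acc <- NA_real_
      val_f1 <- NA_real_
      if (!is.null(Xv)) {
        # early stopping monitors validation span micro-F1 under the full
        # constrained decoder (token accuracy is recorded alongside)
        m <- c(proto, list(W = W, b = b))
        Sv <- .emission_scores(m, Xv)
        pred_idx <- .decode_scores(Sv, vkey, m)
        val_acc <- mean(pred_idx == yv)
        val_f1 <- .span_f1(alpha[pred_idx], validation$label, validation,
                           scheme)
        if (val_f1 > best$f1 + 1e-12) {
          best <- list(W = W, b = b, f1 = val_f1, acc = val_acc, epoch = ep)
          since_improve <- 0L
        } else {
          since_improve <- since_improve + 1L
        }
      }
      history <- dplyr::bind_rows(history, tibble::tibble(
        epoch = ep, train_loss = total_loss / n, val_accuracy = val_acc,
        val_f1 = val_f1))
      if (!is.null(Xv) && since_improve >= patience) break
    }
  })
  if (!is.null(Xv)) {
    W <- best$W; b <- best$b
  }
  structure(c(proto, list(
    W = W, b = b,
    feature_cfg = feature_cfg, tables = tables,
    history = history, seed = as.integer(seed),
    epochs_trained = ran_epochs,
    best_epoch = if (!is.null(Xv)) best$epoch else ran_epochs,
    val_accuracy = if (!is.null(Xv)) best$acc else NA_real_,
    val_f1 = if (!is.null(Xv)) best$f1 else NA_real_)),
    class = "deid_tagger")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.deid_tagger <- function(x, ...) {
  cat("<deid_tagger: ", length(x$scheme$alphabet), " labels (",
      x$scheme$name, "), ", nrow(x$W), " features, best epoch ",
      x$best_epoch, "/", x$epochs_trained, sep = "")
  if (!is.na(x$val_accuracy))
    cat(sprintf(", val span F1 %.4f", x$val_f1))
  cat(">\n")
  invisible(x)
}

#' Predict labels for preprocessed tokens
#'
#' Computes per-token label scores and decodes the highest-scoring label
#' sequence per sentence by exact Viterbi dynamic programming over the
#' label lattice, with scheme-invalid transitions (and invalid start/end
#' labels) assigned probability zero. Decoded sequences therefore never
#' need repair.
#'
#' @param object A `deid_tagger`.
#' @param tokens Token tibble (`doc_id` optional, `sentence_id`, `text`,
#'   `start`, `end`).
#' @param ... Unused.
#' @return The token tibble with a `label` column.
#' @export
predict.deid_tagger <- function(object, tokens, ...) {
  if (!nrow(tokens)) {
    tokens$label <- character()
    return(tokens)
  }
  X <- build_features(tokens, object$feature_cfg, object$tables)
  if (ncol(X) != nrow(object$W))
    stop("feature configuration mismatch: model expects ", nrow(object$W),
         " features, got ", ncol(X), call. = FALSE)
  S <- .emission_scores(object, X)
  key <- if ("doc_id" %in% names(tokens))
    paste(tokens$doc_id, tokens$sentence_id) else
    as.character(tokens$sentence_id)
  tokens$label <- object$scheme$alphabet[.decode_scores(S, key, object)]
  tokens
}

#' Save / load a tagger model file
#'
#' The model file is a single self-describing archive (label inventory,
#' feature configuration, embedding tables, weights, training metadata)
#' that reloads bit-exactly.
#'
#' @param model A `deid_tagger`.
#' @param path Model file path.
#' @return `write_tagger()`: `path` invisibly; `read_tagger()`: the model.
#' @export
write_tagger <- function(model, path) {
  stopifnot(inherits(model, "deid_tagger"))
  saveRDS(model, path, version = 3)
  invisible(path)
}

#' @rdname write_tagger
#' @export
read_tagger <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "deid_tagger"))
  model
}

#' Tidy and glance methods for the tagger
#'
#' `tidy()` returns one row per label with its bias and weight norm;
#' `glance()` returns a one-row training summary.
#'
#' @param x A `deid_tagger`.
#' @param ... Unused.
#' @method tidy deid_tagger
#' @export
tidy.deid_tagger <- function(x, ...) {
  tibble::tibble(label = x$scheme$alphabet, bias = x$b,
                 weight_norm = sqrt(colSums(x$W^2)))
}

#' @rdname tidy.deid_tagger
#' @method glance deid_tagger
#' @export
glance.deid_tagger <- function(x, ...) {
  tibble::tibble(n_labels = length(x$scheme$alphabet),
                 n_features = nrow(x$W), scheme = x$scheme$name,
                 epochs_trained = x$epochs_trained,
                 best_epoch = x$best_epoch,
                 val_accuracy = x$val_accuracy, val_f1 = x$val_f1,
                 seed = x$seed)
}

#' Plot the tagger's training history
#'
#' @param object A `deid_tagger`.
#' @param ... Unused.
#' @return A ggplot of loss and validation accuracy per epoch.
#' @method autoplot deid_tagger
#' @export
autoplot.deid_tagger <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_accuracy"),
                           names_to = "metric")
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}
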