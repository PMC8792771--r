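#' Train skip-gram word embeddings on a note corpus
#'
#' A compact, fully seeded implementation of skip-gram with negative
#' sampling (the word2vec objective), written with vectorized mini-batch
#' updates so training is deterministic given the seed.  Context pairs use
#' the standard dynamic window (a pair at distance `d` is kept with
#' probability `(window - d + 1) / window`), negatives are drawn from the
#' unigram distribution raised to the 3/4 power, and the learning rate
#' decays linearly over training.
#'
#' @param token_lists List of character vectors (one per note), typically
#'   the `tokens` column of [preprocess_notes()].
#' @param dim Embedding dimension (default 200).
#' @param window Maximum context window (default 10).
#' @param min_count Minimum corpus frequency for a token to be embedded
#'   (default 2).
#' @param epochs Training epochs (default 5).
#' @param negative Negative samples per positive pair (default 5).
#' @param learning_rate Initial learning rate (default 0.05).
#' @param batch_size Pairs per mini-batch update; the default (`NULL`)
#'   scales with corpus size (about one percent of the candidate pairs,
#'   clamped to 64..4096) so small corpora still receive many updates.
#' @param seed Integer seed.
#' @return An object of class `word2vec_model`: list with `vectors` (a
#'   `V x dim` matrix with token rownames) and `config`.
#' @export
train_word2vec <- function(token_lists, dim = 200, window = 10,
                           min_count = 2, epochs = 5, negative = 5,
                           learning_rate = 0.05, batch_size = NULL,
                           seed = 1L) {
  stopifnot(dim >= 1, window >= 1, min_count >= 1, epochs >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  vocab <- build_vocabulary(token_lists, min_count = min_count)
  tokens <- names(vocab)
  V <- length(vocab)
  ids <- lapply(token_lists, function(x) {
    v <- unname(vocab[x])
    v[!is.na(v)]
  })
  ids <- ids[lengths(ids) >= 2]
  if (length(ids) == 0) {
    abort("corpus has no note with two in-vocabulary tokens")
  }

  # enumerate all candidate (center, context) pairs once
  acc_c <- list()
  acc_o <- list()
  acc_d <- list()
  for (s in ids) {
    L <- length(s)
    for (d in seq_len(min(window, L - 1))) {
      i <- seq_len(L - d)
      acc_c[[length(acc_c) + 1]] <- c(s[i], s[i + d])
      acc_o[[length(acc_o) + 1]] <- c(s[i + d], s[i])
      acc_d[[length(acc_d) + 1]] <- rep.int(d, 2L * (L - d))
    }
  }
  centers <- unlist(acc_c, use.names = FALSE)
  contexts <- unlist(acc_o, use.names = FALSE)
  dist <- unlist(acc_d, use.names = FALSE)
  keep_prob <- (window - dist + 1) / window
  if (is.null(batch_size)) {
    batch_size <- min(4096L, max(64L, ceiling(length(centers) / 100)))
  }

  freq <- attr(vocab, "freq")
  noise_cum <- cumsum(freq^0.75)
  noise_cum <- noise_cum / noise_cum[V]

  W_in <- matrix(runif(V * dim, -0.5, 0.5) / dim, nrow = V)
  W_out <- matrix(0, nrow = V, ncol = dim)

  # aggregate duplicate-row gradients by their mean: one averaged update
  # per distinct token per mini-batch keeps frequent tokens stable
  agg_mean <- function(grad, idx) {
    agg <- rowsum(grad, idx)
    ids <- as.integer(rownames(agg))
    list(ids = ids, grad = agg / tabulate(idx, nbins = V)[ids])
  }

  total_pairs <- sum(keep_prob) * epochs # expected update count
  seen <- 0
  for (epoch in seq_len(epochs)) {
    kept <- which(runif(length(centers)) < keep_prob)
    kept <- kept[sample.int(length(kept))]
    for (off in seq(1, length(kept), by = batch_size)) {
      batch <- kept[off:min(off + batch_size - 1, length(kept))]
      B <- length(batch)
      lr <- max(learning_rate * (1 - seen / total_pairs), learning_rate * 0.01)
      ctr <- centers[batch]
      # one stacked system: the positive context then `negative` noise draws
      out_idx <- c(
        contexts[batch],
        findInterval(runif(B * negative), noise_cum) + 1L
      )
      rep_idx <- rep.int(seq_len(B), negative + 1L)
      U <- W_in[ctr, , drop = FALSE]
      Urep <- U[rep_idx, , drop = FALSE]
      Vall <- W_out[out_idx, , drop = FALSE]
      g <- 1 / (1 + exp(-rowSums(Urep * Vall)))
      g[seq_len(B)] <- g[seq_len(B)] - 1
      dU <- rowsum(g * Vall, rep_idx)
      upd <- agg_mean(dU, ctr)
      W_in[upd$ids, ] <- W_in[upd$ids, ] - lr * upd$grad
      upd <- agg_mean(g * Urep, out_idx)
      W_out[upd$ids, ] <- W_out[upd$ids, ] - lr * upd$grad
      seen <- seen + B
    }
  }
  rownames(W_in) <- tokens
  structure(
    list(
      vectors = W_in,
      config = list(
        dim = dim, window = window, min_count = min_count,
        epochs = epochs, negative = negative,
        learning_rate = learning_rate, seed = seed
      )
    ),
    class = "word2vec_model"
  )
}

#' @export
print.word2vec_model <- function(x, ...) {
  cat(
    "<word2vec_model> ", nrow(x$vectors), " tokens x ",
    ncol(x$vectors), " dims\n",
    sep = ""
  )
  invisible(x)
}

cosine_sim <- function(a, b) {
  sum(a * b) / sqrt(sum(a * a) * sum(b * b))
}

#' Nearest neighbours of a token in embedding space
#'
#' Ranks all other vocabulary tokens by descending cosine similarity to
#' the query token.  Out-of-vocabulary queries raise an error that lists
#' the closest vocabulary entries by edit distance, as a convenience.
#'
#' @param model A `word2vec_model`.
#' @param token Query token.
#' @param k Number of neighbours (default 10).
#' @return A tibble with columns `token` and `similarity`, `k` rows.
#' @export
nearest_neighbors <- function(model, token, k = 10) {
  M <- model$vectors
  if (!(token %in% rownames(M))) {
    near <- head(rownames(M)[order(utils::adist(token, rownames(M)))], 5)
    abort(paste0(
      "token '", token, "' is not in the embedding vocabulary; ",
      "closest entries: ", paste(near, collapse = ", ")
    ))
  }
  if (k <= 0) {
    return(tibble(token = character(), similarity = numeric()))
  }
  q <- M[token, ]
  norms <- sqrt(rowSums(M * M))
  sims <- as.vector(M %*% q) / (norms * sqrt(sum(q * q)))
  sims[norms == 0] <- -Inf
  sims[rownames(M) == token] <- -Inf
  ord <- order(-sims)
  take <- head(ord, k)
  tibble(token = rownames(M)[take], similarity = unname(sims[take]))
}

#' Materialize the embedding layer matrix for a vocabulary
#'
#' Builds the `(V + 1) x dim` lookup table consumed by the classifier:
#' row 1 is the all-zero padding row (token id 0), row `i + 1` holds the
#' embedding of the token with vocabulary id `i`, and tokens without a
#' trained vector get a zero row.
#'
#' @param model A `word2vec_model`.
#' @param vocab An `edss_vocabulary` built under the same `min_count`
#'   regime.
#' @return A numeric matrix of shape `(length(vocab) + 1) x dim`.
#' @export
embedding_layer_matrix <- function(model, vocab) {
  dim <- ncol(model$vectors)
  M <- matrix(0, nrow = length(vocab) + 1, ncol = dim)
  common <- intersect(names(vocab), rownames(model$vectors))
  M[vocab[common] + 1L, ] <- model$vectors[common, , drop = FALSE]
  M
}

#' Write embeddings in the word2vec text format
#'
#' Header line "V dim", then one line per token: the token followed by its
#' whitespace-separated vector components.
#'
#' @param model A `word2vec_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_word2vec <- function(model, path) {
  M <- model$vectors
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(M), ncol(M)), con)
  lines <- paste(
    rownames(M),
    apply(M, 1, function(r) paste(format(r, digits = 17), collapse = " "))
  )
  writeLines(lines, con)
  invisible(path)
}

#' Read embeddings from the word2vec text format
#'
#' @param path Path to a text-format embedding file.
#' @return A `word2vec_model` (with an empty training config).
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  header <- as.integer(strsplit(trimws(lines[[1]]), "\\s+")[[1]])
  body <- strsplit(trimws(lines[-1]), "\\s+")
  tokens <- vapply(body, `[[`, character(1), 1)
  M <- t(vapply(
    body, function(x) as.numeric(x[-1]),
    numeric(header[[2]])
  ))
  rownames(M) <- tokens
  stopifnot(nrow(M) == header[[1]])
  structure(list(vectors = M, config = list(dim = header[[2]])),
    class = "word2vec_model"
  )
}
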