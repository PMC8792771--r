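#' Configuration for the convolutional text classifier
#'
#' The architecture is the standard sentence-classification CNN: an
#' embedding lookup feeds parallel 1-d convolutions (one branch per kernel
#' size), each branch is max-pooled over time, the pooled features are
#' concatenated, passed through dropout and a fully connected layer, and
#' normalized with softmax over the class list.
#'
#' @param max_len Input sequence length (default 1000).
#' @param embedding_dim Embedding dimension (default 200).
#' @param kernel_sizes Convolution kernel widths (default `c(3, 4, 5)`).
#' @param filters Filters per kernel size (default 100).
#' @param dropout_rate Dropout on the concatenated pooled features during
#'   training (default 0.5).
#' @param learning_rate RMSprop learning rate (default 1e-3).
#' @param batch_size Mini-batch size (default 32).
#' @param max_epochs Maximum training epochs (default 30).
#' @param patience Early stopping: number of consecutive epochs without
#'   validation-loss improvement tolerated before stopping (default 3;
#'   0 stops at the first non-improving epoch).
#' @param finetune_embeddings Update the embedding table during training?
#'   Default `FALSE` (the matrix is frozen as supplied; the padding row is
#'   never updated either way).
#' @param abstain_threshold If non-`NULL`, unknown is not a trained class;
#'   instead the model abstains at prediction time when the maximum class
#'   probability falls below this value.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return A list of class `cnn_config`.
#' @export
cnn_config <- function(max_len = 1000, embedding_dim = 200,
                       kernel_sizes = c(3, 4, 5), filters = 100,
                       dropout_rate = 0.5, learning_rate = 1e-3,
                       batch_size = 32, max_epochs = 30, patience = 3,
                       finetune_embeddings = FALSE,
                       abstain_threshold = NULL, seed = 1L) {
  stopifnot(
    max_len >= 1, embedding_dim >= 1, length(kernel_sizes) >= 1,
    all(kernel_sizes >= 1), all(kernel_sizes <= max_len), filters >= 1,
    dropout_rate >= 0, dropout_rate < 1, patience >= 0
  )
  structure(
    list(
      max_len = as.integer(max_len),
      embedding_dim = as.integer(embedding_dim),
      kernel_sizes = as.integer(kernel_sizes),
      filters = as.integer(filters), dropout_rate = dropout_rate,
      learning_rate = learning_rate, batch_size = as.integer(batch_size),
      max_epochs = as.integer(max_epochs), patience = as.integer(patience),
      finetune_embeddings = isTRUE(finetune_embeddings),
      abstain_threshold = abstain_threshold, seed = as.integer(seed)
    ),
    class = "cnn_config"
  )
}

#' Build an (untrained) convolutional text classifier
#'
#' @param config A [cnn_config()].
#' @param embedding_matrix `(V + 1) x embedding_dim` lookup table from
#'   [embedding_layer_matrix()]; row 1 is the padding row.
#' @param class_values Ordered class list as a numeric vector; `NA`
#'   denotes the unknown (abstention) class and is conventionally last.
#'   At least two classes are required.
#' @return An object of class `text_cnn`.
#' @export
build_text_cnn <- function(config, embedding_matrix,
                           class_values = c(edss_classes(), NA)) {
  stopifnot(length(class_values) >= 2)
  if (ncol(embedding_matrix) != config$embedding_dim) {
    abort("embedding matrix column count does not match embedding_dim")
  }
  if (!all(is.finite(embedding_matrix))) {
    abort("embedding matrix contains non-finite values")
  }
  if (!is.null(config$abstain_threshold) && anyNA(class_values)) {
    class_values <- class_values[!is.na(class_values)]
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  d <- config$embedding_dim
  fl <- config$filters
  n_classes <- length(class_values)
  glorot <- function(n_in, n_out, nr, nc) {
    lim <- sqrt(6 / (n_in + n_out))
    matrix(runif(nr * nc, -lim, lim), nrow = nr)
  }
  W <- lapply(config$kernel_sizes, function(k) {
    glorot(k * d, fl, k * d, fl)
  })
  b <- lapply(config$kernel_sizes, function(k) numeric(fl))
  n_feat <- fl * length(config$kernel_sizes)
  structure(
    list(
      config = config, E = embedding_matrix,
      W = W, b = b,
      Wd = glorot(n_feat, n_classes, n_feat, n_classes),
      bd = numeric(n_classes),
      class_values = class_values,
      history = NULL, trained = FALSE
    ),
    class = "text_cnn"
  )
}

#' @export
print.text_cnn <- function(x, ...) {
  cfg <- x$config
  cat("<text_cnn> kernels [", paste(cfg$kernel_sizes, collapse = ", "),
    "] x ", cfg$filters, " filters, ", length(x$class_values),
    " classes, ", if (x$trained) "trained" else "untrained", "\n",
    sep = ""
  )
  invisible(x)
}

# forward pass over a batch; returns everything needed for backprop
cnn_forward <- function(model, X, dropout_mask = NULL) {
  cfg <- model$config
  B <- nrow(X)
  L <- ncol(X)
  d <- cfg$embedding_dim
  fl <- cfg$filters
  Xemb <- model$E[as.vector(t(X)) + 1L, , drop = FALSE]
  branches <- vector("list", length(cfg$kernel_sizes))
  pooled <- matrix(0, B, fl * length(cfg$kernel_sizes))
  for (ki in seq_along(cfg$kernel_sizes)) {
    k <- cfg$kernel_sizes[[ki]]
    nw <- L - k + 1L
    starts <- as.vector(outer(seq_len(nw), (seq_len(B) - 1L) * L, `+`))
    Xwin <- do.call(cbind, lapply(seq_len(k) - 1L, function(j) {
      Xemb[starts + j, , drop = FALSE]
    }))
    Z <- Xwin %*% model$W[[ki]]
    Z <- Z + rep(model$b[[ki]], each = nrow(Z))
    A <- Z
    A[A < 0] <- 0
    # max over time per note block of nw rows, tracking argmax ("first")
    arr <- array(A, dim = c(nw, B, fl))
    pool <- matrix(arr[1, , ], B, fl)
    widx <- matrix(1L, B, fl)
    if (nw > 1) {
      for (w in 2:nw) {
        slab <- matrix(arr[w, , ], B, fl)
        upd <- slab > pool
        pool[upd] <- slab[upd]
        widx[upd] <- w
      }
    }
    cols <- (ki - 1L) * fl + seq_len(fl)
    pooled[, cols] <- pool
    branches[[ki]] <- list(
      Xwin = Xwin, A = A, widx = widx, nw = nw,
      starts = starts
    )
  }
  P <- pooled
  if (!is.null(dropout_mask)) P <- P * dropout_mask
  logits <- P %*% model$Wd
  logits <- logits + rep(model$bd, each = B)
  m <- apply(logits, 1, max)
  ex <- exp(logits - m)
  probs <- ex / rowSums(ex)
  list(probs = probs, P = P, branches = branches, Xemb = Xemb)
}

# RMSprop update in place; returns list(param, cache)
rmsprop_step <- function(param, grad, cache, lr, rho = 0.9, eps = 1e-8) {
  cache <- rho * cache + (1 - rho) * grad^2
  list(param = param - lr * grad / (sqrt(cache) + eps), cache = cache)
}

#' Train the convolutional text classifier
#'
#' Mini-batch RMSprop on the categorical cross-entropy, with early
#' stopping on the validation loss: training halts at `max_epochs` or
#' after `patience + 1` consecutive epochs without improvement, and the
#' weights from the best validation epoch are retained.
#'
#' @param model An untrained (or previously trained) `text_cnn`.
#' @param X Integer sequence matrix `n x max_len` (training notes).
#' @param y Numeric label vector (`NA` = unknown class), length `n`.
#' @param X_val,y_val Validation set, disjoint from training at the
#'   patient level (the caller's responsibility; see
#'   [patient_split()]).
#' @return The trained `text_cnn`, with a `history` tibble (per-epoch
#'   train/validation losses) and `stopped_epoch`/`best_epoch` fields.
#' @export
train_text_cnn <- function(model, X, y, X_val, y_val) {
  cfg <- model$config
  yi <- class_index(y, model$class_values)
  yv <- class_index(y_val, model$class_values)
  if (anyNA(yi) || anyNA(yv)) {
    abort("label outside the model's class list")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 1L)

  n_feat <- cfg$filters * length(cfg$kernel_sizes)
  caches <- list(
    W = lapply(model$W, function(w) w * 0), b = lapply(model$b, function(x) x * 0),
    Wd = model$Wd * 0, bd = model$bd * 0, E = if (cfg$finetune_embeddings) model$E * 0
  )
  best <- list(loss = Inf, epoch = 0L, W = model$W, b = model$b,
               Wd = model$Wd, bd = model$bd, E = model$E)
  history <- list()
  bad_epochs <- 0L
  n <- nrow(X)
  C <- length(model$class_values)

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    total_loss <- 0
    n_batches <- 0L
    for (off in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[off:min(off + cfg$batch_size - 1, n)]
      B <- length(idx)
      Xb <- X[idx, , drop = FALSE]
      yb <- yi[idx]
      mask <- NULL
      if (cfg$dropout_rate > 0) {
        keep <- 1 - cfg$dropout_rate
        mask <- matrix(
          (runif(B * n_feat) < keep) / keep,
          B, n_feat
        )
      }
      fw <- cnn_forward(model, Xb, dropout_mask = mask)
      p_true <- pmax(fw$probs[cbind(seq_len(B), yb)], 1e-12)
      total_loss <- total_loss + -mean(log(p_true))
      n_batches <- n_batches + 1L

      dlogits <- fw$probs
      dlogits[cbind(seq_len(B), yb)] <-
        dlogits[cbind(seq_len(B), yb)] - 1
      dlogits <- dlogits / B
      dWd <- crossprod(fw$P, dlogits)
      dbd <- colSums(dlogits)
      dP <- dlogits %*% t(model$Wd)
      if (!is.null(mask)) dP <- dP * mask

      lr <- cfg$learning_rate
      dE <- NULL
      if (cfg$finetune_embeddings) dE <- model$E * 0
      for (ki in seq_along(cfg$kernel_sizes)) {
        br <- fw$branches[[ki]]
        fl <- cfg$filters
        cols <- (ki - 1L) * fl + seq_len(fl)
        dpool <- dP[, cols, drop = FALSE]
        rows_g <- as.vector(br$widx + (seq_len(B) - 1L) * br$nw)
        cols_g <- rep(seq_len(fl), each = B)
        active <- br$A[cbind(rows_g, cols_g)] > 0
        vals <- as.vector(dpool) * active
        Xsel <- br$Xwin[rows_g, , drop = FALSE]
        dW <- t(rowsum(Xsel * vals, cols_g, reorder = TRUE))
        db <- colSums(matrix(vals, B, fl))
        if (cfg$finetune_embeddings) {
          contrib <- vals * t(model$W[[ki]])[cols_g, , drop = FALSE]
          k <- cfg$kernel_sizes[[ki]]
          d <- cfg$embedding_dim
          gstarts <- br$starts[rows_g]
          for (j in seq_len(k)) {
            block <- contrib[, (j - 1L) * d + seq_len(d), drop = FALSE]
            agg <- rowsum(block, gstarts + j - 1L)
            emb_rows <- Xb[cbind(
              ((as.integer(rownames(agg)) - 1L) %/% ncol(Xb)) + 1L,
              ((as.integer(rownames(agg)) - 1L) %% ncol(Xb)) + 1L
            )] + 1L
            token_agg <- rowsum(agg, emb_rows)
            tid <- as.integer(rownames(token_agg))
            keep_rows <- tid != 1L # never update the padding row
            dE[tid[keep_rows], ] <- dE[tid[keep_rows], , drop = FALSE] +
              token_agg[keep_rows, , drop = FALSE]
          }
        }
        up <- rmsprop_step(model$W[[ki]], dW, caches$W[[ki]], lr)
        model$W[[ki]] <- up$param
        caches$W[[ki]] <- up$cache
        up <- rmsprop_step(model$b[[ki]], db, caches$b[[ki]], lr)
        model$b[[ki]] <- up$param
        caches$b[[ki]] <- up$cache
      }
      up <- rmsprop_step(model$Wd, dWd, caches$Wd, lr)
      model$Wd <- up$param
      caches$Wd <- up$cache
      up <- rmsprop_step(model$bd, dbd, caches$bd, lr)
      model$bd <- up$param
      caches$bd <- up$cache
      if (cfg$finetune_embeddings) {
        up <- rmsprop_step(model$E, dE, caches$E, lr)
        model$E <- up$param
        caches$E <- up$cache
      }
    }
    train_loss <- total_loss / n_batches
    val_probs <- predict_proba(model, X_val)
    pv <- pmax(val_probs[cbind(seq_along(yv), yv)], 1e-12)
    val_loss <- -mean(log(pv))
    improved <- val_loss < best$loss - 1e-10
    history[[epoch]] <- tibble(
      epoch = epoch, train_loss = train_loss,
      val_loss = val_loss, improved = improved
    )
    if (improved) {
      best <- list(loss = val_loss, epoch = epoch, W = model$W, b = model$b,
                   Wd = model$Wd, bd = model$bd, E = model$E)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs > cfg$patience) break
    }
  }
  model$W <- best$W
  model$b <- best$b
  model$Wd <- best$Wd
  model$bd <- best$bd
  model$E <- best$E
  model$history <- bind_rows(history)
  model$best_epoch <- best$epoch
  model$stopped_epoch <- nrow(model$history)
  model$best_val_loss <- best$loss
  model$trained <- TRUE
  model
}

# map labels (NA = unknown) to 1-based class indices
class_index <- function(y, class_values) {
  idx <- match(round(as.numeric(y) * 2), round(class_values * 2),
    incomparables = NULL
  )
  if (anyNA(class_values)) {
    idx[is.na(y)] <- which(is.na(class_values))
  }
  idx
}

#' Class-probability predictions
#'
#' Forward pass in inference mode (dropout disabled, deterministic).
#'
#' @param model A `text_cnn`.
#' @param X Integer sequence matrix with `max_len` columns.
#' @param batch_size Notes per forward batch (default 64).
#' @return A numeric matrix `nrow(X) x n_classes`; rows sum to 1.
#' @export
predict_proba <- function(model, X, batch_size = 64) {
  if (ncol(X) != model$config$max_len) {
    abort("sequence length does not match the model's max_len")
  }
  out <- matrix(0, nrow(X), length(model$class_values))
  for (off in seq(1, nrow(X), by = batch_size)) {
    idx <- off:min(off + batch_size - 1, nrow(X))
    out[idx, ] <- cnn_forward(model, X[idx, , drop = FALSE])$probs
  }
  out
}

#' Turn a class distribution into a label
#'
#' Argmax decoding with ties broken toward the lower EDSS class (class
#' values are ordered ascending, unknown last).  Returns `NA` when the
#' unknown class wins, or — in threshold mode — when the maximum
#' probability falls below the configured abstention threshold.
#'
#' @param probs A probability vector or matrix (rows = notes).
#' @param class_values Ordered class values (`NA` = unknown class).
#' @param abstain_threshold Optional abstention threshold.
#' @return Numeric label vector (`NA` = unknown).
#' @export
predict_label <- function(probs, class_values,
                          abstain_threshold = NULL) {
  if (is.vector(probs)) probs <- matrix(probs, nrow = 1)
  idx <- max.col(probs, ties.method = "first")
  out <- class_values[idx]
  if (!is.null(abstain_threshold)) {
    out[probs[cbind(seq_len(nrow(probs)), idx)] < abstain_threshold] <- NA
  }
  out
}

#' @export
predict.text_cnn <- function(object, newdata, ...) {
  probs <- predict_proba(object, newdata)
  tibble(
    value = predict_label(
      probs, object$class_values,
      object$config$abstain_threshold
    ),
    prob = probs[cbind(seq_len(nrow(probs)), max.col(probs, "first"))]
  )
}

#' Train an EDSS classifier end to end from a notes table
#'
#' Convenience wrapper that preprocesses, builds the vocabulary if needed,
#' encodes, splits off a patient-level validation set, and trains.  The
#' returned model carries the vocabulary and preprocessing configuration,
#' so it can predict directly from raw notes.
#'
#' @param notes A notes tibble with reference labels (`edss` for the
#'   total-score model, a system column for a subscore model).
#' @param target `"total"` or a functional-system name.
#' @param embedding A `word2vec_model` (from [train_word2vec()]).
#' @param vocab Optional pre-built vocabulary; built from `notes` with the
#'   preprocessing `min_count` otherwise.
#' @param config A [cnn_config()].
#' @param preprocess A [preprocess_config()] (its `max_len` is overridden
#'   by the CNN config).
#' @param val_fraction Patient fraction held out for early stopping.
#' @param max_subscore Subscore range upper end when `target` is a system.
#' @return A trained `text_cnn` with `$vocab`, `$preprocess`, `$target`.
#' @export
train_edss_cnn <- function(notes, target = "total", embedding,
                           vocab = NULL, config = cnn_config(),
                           preprocess = preprocess_config(),
                           val_fraction = 0.1, max_subscore = 6) {
  if (!("tokens" %in% names(notes))) {
    notes <- preprocess_notes(notes, preprocess)
  }
  label_col <- if (target == "total") "edss" else target
  stopifnot(label_col %in% names(notes))
  if (is.null(vocab)) {
    vocab <- build_vocabulary(notes$tokens, preprocess$min_count)
  }
  class_values <- if (target == "total") {
    c(edss_classes(), NA)
  } else {
    c(0:max_subscore, NA)
  }
  if (!is.null(config$abstain_threshold)) {
    keep <- !is.na(notes[[label_col]])
    notes <- notes[keep, , drop = FALSE]
  }
  split <- patient_split(notes,
    test_fraction = val_fraction,
    seed = config$seed
  )
  tr <- split$.split == "train"
  X <- encode_sequences(notes$tokens, vocab, config$max_len)
  y <- as.numeric(notes[[label_col]])
  emb <- embedding_layer_matrix(embedding, vocab)
  model <- build_text_cnn(config, emb, class_values)
  model <- train_text_cnn(
    model, X[tr, , drop = FALSE], y[tr],
    X[!tr, , drop = FALSE], y[!tr]
  )
  model$vocab <- vocab
  model$preprocess <- preprocess
  model$target <- target
  model
}
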