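# Shared fixtures: small corpora and models are generated in code, once
# per test run, and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

small_corpus <- function() {
  fixture("small_corpus", simulate_notes(synth_config(n_patients = 40, seed = 101)))
}

# a quickly trained tiny total-score classifier for cascade tests
tiny_cnn <- function() {
  fixture("tiny_cnn", {
    corpus <- preprocess_notes(small_corpus())
    emb <- train_word2vec(corpus$tokens,
      dim = 16, window = 5, min_count = 2,
      epochs = 2, seed = 5
    )
    cfg <- cnn_config(
      max_len = 100, embedding_dim = 16, kernel_sizes = c(2, 3),
      filters = 16, max_epochs = 2, patience = 1, seed = 5
    )
    train_edss_cnn(corpus, target = "total", embedding = emb, config = cfg)
  })
}

# brute-force confusion-matrix oracle, independent of the package's
# vectorized implementations: explicit loops over notes and classes
oracle_metrics <- function(estimate, truth, class_values, tolerance = 0) {
  n <- length(truth)
  acc_hits <- 0
  for (i in seq_len(n)) {
    if (is.na(estimate[i]) && is.na(truth[i])) {
      acc_hits <- acc_hits + 1
    } else if (!is.na(estimate[i]) && !is.na(truth[i]) &&
      abs(estimate[i] - truth[i]) <= tolerance + 1e-9) {
      acc_hits <- acc_hits + 1
    }
  }
  known <- which(!is.na(truth))
  conv_hits <- 0
  for (i in known) {
    if (!is.na(estimate[i]) && abs(estimate[i] - truth[i]) <= tolerance + 1e-9) {
      conv_hits <- conv_hits + 1
    }
  }
  precs <- c()
  recs <- c()
  f1s <- c()
  for (v in class_values) {
    tp <- 0
    fp <- 0
    fn <- 0
    for (i in known) {
      pe <- !is.na(estimate[i]) && abs(estimate[i] - v) < 1e-9
      te <- abs(truth[i] - v) < 1e-9
      if (pe && te) tp <- tp + 1
      if (pe && !te) fp <- fp + 1
      if (!pe && te) fn <- fn + 1
    }
    if (tp + fp + fn == 0) next
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    precs <- c(precs, p)
    recs <- c(recs, r)
    f1s <- c(f1s, if (p + r > 0) 2 * p * r / (p + r) else 0)
  }
  list(
    accuracy = acc_hits / n,
    converted_accuracy = if (length(known)) conv_hits / length(known) else NA,
    macro_precision = mean(precs), macro_recall = mean(recs),
    macro_f1 = mean(f1s)
  )
}

# exhaustive Pitman enumeration by explicit loop over all 2^n patterns
oracle_pitman_exact <- function(a, b) {
  n <- length(a)
  d <- (a - b) / n
  obs <- sum(d)
  count <- 0
  for (bits in 0:(2^n - 1)) {
    signs <- ifelse(bitwAnd(bitwShiftR(bits, 0:(n - 1)), 1L) == 1L, -1, 1)
    if (abs(sum(signs * d)) >= abs(obs) - 1e-12) count <- count + 1
  }
  count / 2^n
}
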