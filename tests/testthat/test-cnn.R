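# a linearly separable toy problem: class decided by which token family
# dominates the note
toy_problem <- function(n = 120, seed = 31) {
  withr::with_seed(seed, {
    fams <- list(c("alpha", "beta", "gamma"), c("delta", "epsilon", "zeta"))
    toks <- vector("list", n)
    y <- integer(n)
    for (i in seq_len(n)) {
      y[i] <- i %% 2
      toks[[i]] <- sample(fams[[y[i] + 1]], 6, replace = TRUE)
    }
    vocab <- build_vocabulary(toks, 1)
    X <- encode_sequences(toks, vocab, 10)
    E <- matrix(stats::rnorm((length(vocab) + 1) * 8, sd = 0.3), ncol = 8)
    E[1, ] <- 0
    list(X = X, y = y, E = E)
  })
}

toy_config <- function(...) {
  defaults <- list(
    max_len = 10, embedding_dim = 8, kernel_sizes = c(2, 3), filters = 8,
    dropout_rate = 0.2, learning_rate = 5e-3, max_epochs = 15,
    patience = 3, seed = 5
  )
  do.call(cnn_config, utils::modifyList(defaults, list(...)))
}

test_that("architecture arithmetic: branches, feature width, output length", {
  cfg <- cnn_config(
    max_len = 20, embedding_dim = 4, kernel_sizes = c(3, 4, 5),
    filters = 100
  )
  E <- matrix(0, 7, 4)
  m <- build_text_cnn(cfg, E, class_values = c(edss_classes(), NA))
  expect_length(m$W, 3)
  expect_equal(nrow(m$Wd), 300) # concatenated feature length
  expect_equal(ncol(m$Wd), 20) # 19 half-step classes + unknown
  expect_equal(dim(m$W[[1]]), c(3 * 4, 100))
  expect_error(
    build_text_cnn(cnn_config(embedding_dim = 5), E),
    "embedding"
  )
})

test_that("the output is a valid distribution for arbitrary inputs", {
  tp <- toy_problem()
  cfg <- toy_config()
  m <- build_text_cnn(cfg, tp$E, class_values = 0:1)
  # all-padding input
  p0 <- predict_proba(m, matrix(0L, 1, 10))
  expect_equal(sum(p0), 1, tolerance = 1e-6)
  # property: random sequences, including OOV-free ids
  withr::with_seed(2, {
    for (i in 1:20) {
      X <- matrix(sample(0:(nrow(tp$E) - 1), 10, replace = TRUE), 1)
      p <- predict_proba(m, X)
      expect_true(all(p >= 0))
      expect_equal(sum(p), 1, tolerance = 1e-6)
    }
  })
  expect_error(predict_proba(m, matrix(0L, 1, 9)), "max_len")
})

test_that("inference is deterministic and training is seed-reproducible", {
  tp <- toy_problem()
  cfg <- toy_config(max_epochs = 4)
  m <- build_text_cnn(cfg, tp$E, class_values = 0:1)
  f1 <- train_text_cnn(m, tp$X[1:80, ], tp$y[1:80], tp$X[81:120, ], tp$y[81:120])
  f2 <- train_text_cnn(m, tp$X[1:80, ], tp$y[1:80], tp$X[81:120, ], tp$y[81:120])
  expect_identical(f1$history, f2$history)
  p1 <- predict_proba(f1, tp$X[1:5, ])
  p2 <- predict_proba(f1, tp$X[1:5, ])
  expect_identical(p1, p2)
})

test_that("a separable toy problem is learned to perfect training accuracy", {
  tp <- toy_problem()
  cfg <- toy_config()
  m <- build_text_cnn(cfg, tp$E, class_values = 0:1)
  fit <- train_text_cnn(m, tp$X[1:100, ], tp$y[1:100], tp$X[101:120, ], tp$y[101:120])
  pred <- predict_label(predict_proba(fit, tp$X[1:100, ]), fit$class_values)
  expect_equal(mean(pred == tp$y[1:100]), 1.0)
  # argmax on a training exemplar equals its label
  expect_equal(
    predict_label(predict_proba(fit, tp$X[1, , drop = FALSE]), fit$class_values),
    tp$y[1]
  )
})

test_that("early stopping retains the best-validation weights and obeys patience", {
  tp <- toy_problem()
  fit <- train_text_cnn(
    build_text_cnn(toy_config(), tp$E, class_values = 0:1),
    tp$X[1:80, ], tp$y[1:80], tp$X[81:120, ], tp$y[81:120]
  )
  h <- fit$history
  expect_equal(fit$best_epoch, h$epoch[which.min(h$val_loss)])
  expect_equal(fit$best_val_loss, min(h$val_loss))
  # retained weights reproduce the best validation loss exactly
  probs <- predict_proba(fit, tp$X[81:120, ])
  yi <- tp$y[81:120] + 1L
  val_loss <- -mean(log(pmax(probs[cbind(seq_along(yi), yi)], 1e-12)))
  expect_equal(val_loss, fit$best_val_loss, tolerance = 1e-10)
  # patience 0 stops at the first non-improving epoch
  fit0 <- train_text_cnn(
    build_text_cnn(toy_config(patience = 0, max_epochs = 30), tp$E,
      class_values = 0:1
    ),
    tp$X[1:80, ], tp$y[1:80], tp$X[81:120, ], tp$y[81:120]
  )
  h0 <- fit0$history
  first_bad <- which(!h0$improved)[1]
  if (!is.na(first_bad)) expect_equal(nrow(h0), first_bad)
})

test_that("label decoding breaks ties toward the lower class and maps unknown to NA", {
  cls <- c(edss_classes(), NA)
  one_hot <- rep(0, 20)
  one_hot[match(4.5, cls)] <- 1
  expect_equal(predict_label(one_hot, cls), 4.5)
  tie <- rep(0, 20)
  tie[match(2.0, cls)] <- 0.5
  tie[match(3.0, cls)] <- 0.5
  expect_equal(predict_label(tie, cls), 2.0)
  unk <- rep(0, 20)
  unk[20] <- 1
  expect_true(is.na(predict_label(unk, cls)))
  # threshold mode abstains under the configured confidence
  expect_true(is.na(predict_label(rep(0.05, 20), cls, abstain_threshold = 0.5)))
})

test_that("labels outside the class list are rejected before training", {
  tp <- toy_problem()
  m <- build_text_cnn(toy_config(), tp$E, class_values = 0:1)
  expect_error(
    train_text_cnn(m, tp$X[1:10, ], c(rep(0, 9), 7), tp$X[11:20, ], tp$y[11:20]),
    "class list"
  )
})

test_that("the padding row stays zero through training unless fine-tuning", {
  tp <- toy_problem()
  fit <- train_text_cnn(
    build_text_cnn(toy_config(max_epochs = 3), tp$E, class_values = 0:1),
    tp$X[1:80, ], tp$y[1:80], tp$X[81:120, ], tp$y[81:120]
  )
  expect_equal(fit$E[1, ], rep(0, 8))
  expect_identical(fit$E, tp$E) # frozen by default
  fit_ft <- train_text_cnn(
    build_text_cnn(toy_config(max_epochs = 3, finetune_embeddings = TRUE),
      tp$E,
      class_values = 0:1
    ),
    tp$X[1:80, ], tp$y[1:80], tp$X[81:120, ], tp$y[81:120]
  )
  expect_equal(fit_ft$E[1, ], rep(0, 8)) # padding row never updated
  expect_false(identical(fit_ft$E[-1, ], tp$E[-1, ])) # others move
})
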