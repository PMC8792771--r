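test_that("accuracy handles tolerance and unknown predictions as specified", {
  expect_equal(accuracy_score(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(accuracy_score(4, 3, tolerance = 1), 1.0) # subscore +/-1
  expect_equal(accuracy_score(c(2.0, 2.5, NA), c(2.0, 3.0, 4.0)), 1 / 3)
  expect_error(accuracy_score(numeric(0), numeric(0)), "empty")
})

test_that("converted accuracy scores only known-reference notes", {
  truth <- c(rep(NA, 4), 1, 1, 1, 1, 1, 2)
  est <- c(rep(NA, 4), 1, 1, 1, 1, 1, 1)
  expect_equal(converted_accuracy(est, truth), 5 / 6)
  expect_equal(
    converted_accuracy(c(1, 2), c(1, 2)),
    accuracy_score(c(1, 2), c(1, 2))
  )
  expect_error(converted_accuracy(c(1, 2), c(NA, NA)), "no known")
})

test_that("unknown rate counts abstentions", {
  expect_equal(unknown_rate(c(1, 2, 3)), 0)
  expect_equal(unknown_rate(c(NA, NA)), 1)
  expect_equal(unknown_rate(c(rep(NA, 99), rep(1, 3394))), 99 / 3493)
  expect_error(unknown_rate(numeric(0)), "empty")
})

test_that("macro metrics match the hand-computed confusion example", {
  # refs A A B B C, preds A B B C C with A=1, B=2, C=3
  truth <- c(1, 1, 2, 2, 3)
  est <- c(1, 2, 2, 3, 3)
  mm <- macro_metrics(est, truth, class_values = 1:3)
  expect_equal(mm$macro_precision, (1 + 0.5 + 0.5) / 3)
  expect_equal(mm$macro_recall, (0.5 + 0.5 + 1) / 3)
  perfect <- macro_metrics(1:3, 1:3, 1:3)
  expect_equal(perfect$macro_f1, 1.0)
  # class absent from both predictions and references drops out
  mm4 <- macro_metrics(est, truth, class_values = 1:4)
  expect_equal(mm4$macro_precision, mm$macro_precision)
  expect_equal(nrow(mm4$per_class), 3)
  # macro F1 bounded by per-class F1 range
  expect_gte(mm$macro_f1, min(mm$per_class$f1))
  expect_lte(mm$macro_f1, max(mm$per_class$f1))
})

test_that("abstention hurts recall and accuracy but not precision", {
  truth <- c(1, 1, 1, 2, 2, 2)
  est <- c(1, NA, NA, 2, NA, NA)
  mm <- macro_metrics(est, truth, 1:2)
  expect_equal(mm$macro_precision, 1.0)
  expect_equal(mm$macro_recall, 1 / 3)
  expect_equal(accuracy_score(est, truth), 1 / 3)
})

test_that("vectorized metrics agree with the brute-force oracle on random vectors", {
  cls <- c(edss_classes(), NA)
  withr::with_seed(42, {
    for (rep in 1:60) {
      n <- sample(5:120, 1)
      truth <- sample(cls, n, replace = TRUE)
      est <- sample(cls, n, replace = TRUE)
      if (all(is.na(truth))) truth[1] <- 1.0
      orc <- oracle_metrics(est, truth, edss_classes())
      expect_equal(accuracy_score(est, truth), orc$accuracy)
      expect_equal(converted_accuracy(est, truth), orc$converted_accuracy)
      mm <- macro_metrics(est, truth, edss_classes())
      expect_equal(mm$macro_precision, orc$macro_precision)
      expect_equal(mm$macro_recall, orc$macro_recall)
      expect_equal(mm$macro_f1, orc$macro_f1)
    }
  })
})

test_that("the evaluation report bundles all metrics and tidies", {
  d <- tibble::tibble(ref = c(2, 3, 4, NA), pred = c(2, 2.5, NA, NA))
  ev <- evaluate_edss(d, truth = "ref", estimate = "pred")
  expect_s3_class(ev, "edss_eval")
  expect_equal(ev$accuracy, 2 / 4) # both-unknown note counts correct
  expect_equal(ev$converted_accuracy, 1 / 3)
  expect_equal(ev$unknown_prediction_rate, 0.5)
  g <- glance(ev)
  expect_equal(g$n_notes, 4)
  expect_true(all(c("macro_precision", "macro_recall", "macro_f1") %in% names(g)))
  expect_s3_class(tidy(ev), "tbl_df")
})

test_that("Pitman exact enumeration matches hand results and the loop oracle", {
  expect_equal(pitman_test(c(1, 1, 1), c(0, 0, 0))$p_value, 2 / 8)
  expect_equal(pitman_test(c(1, 0, 1), c(1, 0, 1))$p_value, 1.0)
  withr::with_seed(13, {
    for (rep in 1:10) {
      n <- sample(3:10, 1)
      a <- rbinom(n, 1, 0.7)
      b <- rbinom(n, 1, 0.5)
      expect_equal(
        pitman_test(a, b)$p_value,
        oracle_pitman_exact(a, b)
      )
    }
  })
})

test_that("Monte-Carlo Pitman p-values converge to the exact answer", {
  withr::with_seed(8, {
    for (rep in 1:6) {
      n <- sample(8:12, 1)
      a <- rbinom(n, 1, 0.8)
      b <- rbinom(n, 1, 0.4)
      exact <- pitman_test(a, b)$p_value
      mc <- pitman_test(a, b,
        n_permutations = 10000, seed = rep,
        exact_limit = 0
      )$p_value
      se <- sqrt(exact * (1 - exact) / 10000)
      expect_lt(abs(mc - exact), 3 * se + 1 / 10001)
    }
  })
  # MC p-value can never be smaller than 1/(B+1)
  a <- rep(1, 30)
  b <- rep(0, 30)
  p <- pitman_test(a, b, n_permutations = 1000, seed = 1)$p_value
  expect_gte(p, 1 / 1001)
})

test_that("the macro-F1 permutation test is exact on tiny problems and symmetric", {
  withr::with_seed(5, {
    truth <- c(1, 1, 2, 2, 3, 3)
    pa <- c(1, 1, 2, 2, 3, 2)
    pb <- c(1, 2, 2, 1, 3, 3)
    res <- pitman_f1_test(pa, pb, truth, class_values = 1:3)
    expect_equal(res$method, "exact")
    expect_gte(res$p_value, 0)
    expect_lte(res$p_value, 1)
    # identical predictions give statistic 0 and p = 1
    same <- pitman_f1_test(pa, pa, truth, class_values = 1:3)
    expect_equal(same$statistic, 0)
    expect_equal(same$p_value, 1)
    # swapping the models flips the sign of the statistic, same p
    flip <- pitman_f1_test(pb, pa, truth, class_values = 1:3)
    expect_equal(flip$statistic, -res$statistic)
    expect_equal(flip$p_value, res$p_value)
  })
})

test_that("patient-level splits never leak a patient across partitions", {
  notes <- tibble::tibble(
    note_id = as.character(1:20),
    patient_id = rep(sprintf("p%02d", 1:10), each = 2)
  )
  sp <- patient_split(notes, 0.2, seed = 3)
  test_p <- unique(sp$patient_id[sp$.split == "test"])
  train_p <- unique(sp$patient_id[sp$.split == "train"])
  expect_length(intersect(test_p, train_p), 0)
  expect_equal(sum(sp$.split == "test"), 4) # 2 patients x 2 notes
  sp2 <- patient_split(notes, 0.2, seed = 3)
  expect_identical(sp$.split, sp2$.split)
  expect_error(
    patient_split(tibble::tibble(patient_id = "p1", note_id = "a"), 0.2, 1),
    "at least 2"
  )
})

test_that("k-fold assignment partitions patients into disjoint folds", {
  notes <- tibble::tibble(
    note_id = as.character(1:40),
    patient_id = rep(sprintf("p%02d", 1:20), each = 2)
  )
  f <- patient_folds(notes, k = 10, seed = 2)
  per_fold <- tapply(f$patient_id, f$.fold, function(x) unique(x))
  expect_length(per_fold, 10)
  expect_true(all(lengths(per_fold) == 2))
  expect_setequal(unlist(per_fold), unique(notes$patient_id))
  # a patient never spans folds
  expect_true(all(tapply(f$.fold, f$patient_id, function(x) length(unique(x))) == 1))
  expect_identical(patient_folds(notes, 10, seed = 2)$.fold, f$.fold)
  expect_error(patient_folds(notes, k = 1), "at least 2")
  expect_error(patient_folds(notes, k = 21), "more folds")
})
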