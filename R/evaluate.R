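#' Prediction accuracy with optional tolerance
#'
#' Fraction of notes predicted correctly.  A known prediction is correct
#' when it lies within `tolerance` score points of a known reference
#' (`tolerance = 0`, exact match, for the total EDSS score; `tolerance =
#' 1` for functional-system subscores).  An unknown (`NA`) prediction
#' against a known reference is incorrect; a note whose reference is
#' itself unknown is scored correct only by an unknown prediction (the
#' unknown class is a label like any other in this strict regime — see
#' [converted_accuracy()] for the complementary regime).
#'
#' @param estimate Numeric predictions (`NA` = unknown).
#' @param truth Numeric references (`NA` = unknown), same length.
#' @return A rate in `[0, 1]`.
#' @param tolerance Non-negative tolerance in score points.
#' @export
accuracy_score <- function(estimate, truth, tolerance = 0) {
  stopifnot(length(estimate) == length(truth))
  if (length(truth) == 0) abort("cannot score an empty prediction set")
  both_na <- is.na(estimate) & is.na(truth)
  hit <- !is.na(estimate) & !is.na(truth) &
    abs(estimate - truth) <= tolerance + 1e-9
  mean(both_na | hit)
}

#' Accuracy over notes with a known reference
#'
#' The post-hoc "converted" accuracy: unknown-reference notes are dropped
#' before scoring, so the rate reflects only notes for which a valid
#' score exists in the reference standard.
#'
#' @inheritParams accuracy_score
#' @return A rate in `[0, 1]`.
#' @export
converted_accuracy <- function(estimate, truth, tolerance = 0) {
  known <- !is.na(truth)
  if (!any(known)) abort("no known references to score against")
  accuracy_score(estimate[known], truth[known], tolerance)
}

#' Unknown-prediction rate
#'
#' @param estimate Numeric predictions (`NA` = unknown).
#' @return Fraction of predictions that abstain.
#' @export
unknown_rate <- function(estimate) {
  if (length(estimate) == 0) abort("empty prediction set")
  mean(is.na(estimate))
}

#' Macro-averaged precision, recall and F1
#'
#' Each scored class contributes its own precision (`TP / (TP + FP)`),
#' recall (`TP / (TP + FN)`) and F1 (the harmonic mean of the two); the
#' macro metrics are the unweighted means across classes.  Unknown is not
#' a scored class: notes whose reference is unknown are excluded, and an
#' unknown prediction against a known reference counts as a false
#' negative for the reference class without creating a false positive
#' anywhere — abstention costs recall and accuracy, never precision.
#' Classes absent from both predictions and references are dropped from
#' the mean; a scored class with a zero denominator contributes 0.
#'
#' @inheritParams accuracy_score
#' @param class_values Numeric class list (e.g. [edss_classes()]).
#' @return A list with `macro_precision`, `macro_recall`, `macro_f1` and
#'   a `per_class` tibble of counts and per-class metrics.
#' @export
macro_metrics <- function(estimate, truth, class_values = edss_classes()) {
  if (length(class_values) == 0) abort("empty class list")
  stopifnot(length(estimate) == length(truth))
  known <- !is.na(truth)
  estimate <- estimate[known]
  truth <- truth[known]
  eq <- function(x, v) !is.na(x) & abs(x - v) < 1e-9
  per <- lapply(class_values, function(v) {
    tp <- sum(eq(estimate, v) & eq(truth, v))
    fp <- sum(eq(estimate, v) & !eq(truth, v))
    fn <- sum(eq(truth, v) & !eq(estimate, v))
    tibble(class = v, tp = tp, fp = fp, fn = fn)
  })
  tab <- bind_rows(per)
  tab <- tab[tab$tp + tab$fp + tab$fn > 0, , drop = FALSE]
  if (nrow(tab) == 0) {
    return(list(
      macro_precision = NaN, macro_recall = NaN, macro_f1 = NaN,
      per_class = tab
    ))
  }
  prec <- ifelse(tab$tp + tab$fp > 0, tab$tp / (tab$tp + tab$fp), 0)
  rec <- ifelse(tab$tp + tab$fn > 0, tab$tp / (tab$tp + tab$fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  tab$precision <- prec
  tab$recall <- rec
  tab$f1 <- f1
  list(
    macro_precision = mean(prec), macro_recall = mean(rec),
    macro_f1 = mean(f1), per_class = tab
  )
}

#' Full evaluation report for one target
#'
#' Computes the complete metric panel for a prediction column against a
#' reference column: strict accuracy, converted accuracy,
#' unknown-prediction rate, macro precision/recall/F1 and the per-class
#' confusion counts.
#'
#' @param data A data frame holding predictions and references, aligned
#'   row-wise (join on `note_id` upstream).
#' @param truth,estimate Column names (strings or bare names via `{{ }}`
#'   are not needed; pass strings) of the reference and prediction.
#' @param tolerance Score tolerance (0 for total EDSS, 1 for subscores).
#' @param class_values Scored class list.
#' @return An object of class `edss_eval`.
#' @export
#' @examples
#' d <- tibble::tibble(ref = c(2, 3, 4), pred = c(2, 2.5, NA))
#' glance(evaluate_edss(d, truth = "ref", estimate = "pred"))
evaluate_edss <- function(data, truth = "edss", estimate = "value",
                          tolerance = 0, class_values = edss_classes()) {
  tr <- data[[truth]]
  es <- data[[estimate]]
  if (is.null(tr) || is.null(es)) abort("truth/estimate column not found")
  mm <- macro_metrics(es, tr, class_values)
  structure(
    list(
      n_notes = length(tr),
      accuracy = accuracy_score(es, tr, tolerance),
      converted_accuracy = if (any(!is.na(tr))) {
        converted_accuracy(es, tr, tolerance)
      } else {
        NA_real_
      },
      unknown_prediction_rate = unknown_rate(es),
      macro_precision = mm$macro_precision,
      macro_recall = mm$macro_recall,
      macro_f1 = mm$macro_f1,
      per_class = mm$per_class,
      tolerance = tolerance
    ),
    class = "edss_eval"
  )
}

#' @export
print.edss_eval <- function(x, ...) {
  cat("<edss_eval> n =", x$n_notes, "\n")
  cat(sprintf(
    "  accuracy %.3f | converted %.3f | unknown rate %.3f\n",
    x$accuracy, x$converted_accuracy, x$unknown_prediction_rate
  ))
  cat(sprintf(
    "  macro P/R/F1 %.3f / %.3f / %.3f (tolerance %g)\n",
    x$macro_precision, x$macro_recall, x$macro_f1, x$tolerance
  ))
  invisible(x)
}

#' Pitman permutation test on paired correctness outcomes
#'
#' Two-sided paired permutation test of the accuracy difference between
#' two models evaluated on the identical note set.  Under the null the
#' two models are exchangeable within each note, so the reference
#' distribution is obtained by independently swapping the two outcomes
#' within pairs.  All `2^n` swap patterns are enumerated exactly when
#' `n <= exact_limit`; otherwise `n_permutations` random patterns are
#' drawn and the observed pattern is included in the reference set, so
#' the Monte-Carlo p-value is never below `1 / (n_permutations + 1)`.
#'
#' @param correct_a,correct_b Per-note 0/1 correctness indicators of the
#'   two models, aligned.
#' @param n_permutations Monte-Carlo sample size (default 10000).
#' @param seed Seed for the Monte-Carlo draw.
#' @param exact_limit Largest `n` enumerated exactly (default 20).
#' @return A list with `statistic` (accuracy difference, model A minus
#'   model B), `p_value`, and `method`.
#' @export
#' @examples
#' pitman_test(c(1, 1, 1), c(0, 0, 0))$p_value # 2/8
pitman_test <- function(correct_a, correct_b, n_permutations = 10000,
                        seed = 1L, exact_limit = 20) {
  stopifnot(length(correct_a) == length(correct_b))
  n <- length(correct_a)
  if (n < 1) abort("need at least one pair")
  d <- (as.numeric(correct_a) - as.numeric(correct_b)) / n
  obs <- sum(d)
  eps <- 1e-12
  if (n <= exact_limit) {
    sums <- 0
    for (di in d) sums <- c(sums + di, sums - di)
    p <- mean(abs(sums) >= abs(obs) - eps)
    method <- "exact"
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    signs <- matrix(
      sample(c(-1, 1), n_permutations * n, replace = TRUE),
      nrow = n_permutations
    )
    stats <- abs(as.vector(signs %*% d))
    p <- (1 + sum(stats >= abs(obs) - eps)) / (n_permutations + 1)
    method <- "monte_carlo"
  }
  list(statistic = obs, p_value = p, method = method, n = n)
}

#' Pitman permutation test on the macro-F1 difference
#'
#' Macro F1 does not decompose into per-note correctness, so the
#' permutation swaps the two models' predicted labels within each pair
#' and recomputes both macro F1 scores per permutation.
#'
#' @param pred_a,pred_b Aligned label predictions of the two models
#'   (`NA` = unknown).
#' @param truth Aligned references.
#' @param class_values Scored class list.
#' @inheritParams pitman_test
#' @param exact_limit Largest `n` enumerated exactly (default 14; the
#'   statistic costs a full metric recomputation per pattern).
#' @return A list with `statistic` (macro-F1 difference), `p_value`,
#'   `method`.
#' @export
pitman_f1_test <- function(pred_a, pred_b, truth,
                           class_values = edss_classes(),
                           n_permutations = 10000, seed = 1L,
                           exact_limit = 14) {
  n <- length(truth)
  stopifnot(length(pred_a) == n, length(pred_b) == n)
  if (n < 1) abort("need at least one pair")
  stat <- function(swap) {
    a <- ifelse(swap, pred_b, pred_a)
    b <- ifelse(swap, pred_a, pred_b)
    macro_metrics(a, truth, class_values)$macro_f1 -
      macro_metrics(b, truth, class_values)$macro_f1
  }
  obs <- stat(rep(FALSE, n))
  eps <- 1e-12
  if (n <= exact_limit) {
    patterns <- 0:(2^n - 1)
    stats <- vapply(patterns, function(bits) {
      stat(as.logical(bitwAnd(bitwShiftR(bits, 0:(n - 1)), 1L)))
    }, numeric(1))
    p <- mean(abs(stats) >= abs(obs) - eps)
    method <- "exact"
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    count <- 0L
    for (i in seq_len(n_permutations)) {
      s <- runif(n) < 0.5
      if (abs(stat(s)) >= abs(obs) - eps) count <- count + 1L
    }
    p <- (1 + count) / (n_permutations + 1)
    method <- "monte_carlo"
  }
  list(statistic = obs, p_value = p, method = method, n = n)
}

#' Patient-level train/test split
#'
#' Randomly partitions patients (never individual notes) into train and
#' test sets, so no patient contributes notes to both sides — the
#' leakage-free splitting required when several notes share a patient.
#'
#' @param notes A data frame with a `patient_id` column.
#' @param test_fraction Fraction of patients assigned to the test side
#'   (default 0.20).
#' @param seed Integer seed.
#' @return The input tibble with a `.split` column (`"train"`/`"test"`);
#'   attribute `note_fractions` records the realized note-level split.
#' @export
patient_split <- function(notes, test_fraction = 0.20, seed = 1L) {
  patients <- unique(notes$patient_id)
  if (length(patients) < 2) abort("need at least 2 patients to split")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_test <- min(
    max(1L, round(length(patients) * test_fraction)),
    length(patients) - 1L
  )
  test_patients <- sample(patients, n_test)
  out <- as_tibble(notes)
  out$.split <- ifelse(out$patient_id %in% test_patients, "test", "train")
  attr(out, "note_fractions") <- prop.table(table(out$.split))
  out
}

#' Patient-level k-fold assignment
#'
#' Partitions patients into `k` folds of near-equal patient counts; fold
#' `i` serves as the validation set of round `i` and the remaining folds
#' as its training set.
#'
#' @param notes A data frame with a `patient_id` column.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return The input tibble with a `.fold` integer column in `1..k`.
#' @export
patient_folds <- function(notes, k = 10, seed = 1L) {
  patients <- unique(notes$patient_id)
  if (k < 2) abort("k must be at least 2")
  if (k > length(patients)) abort("more folds than patients")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  shuffled <- sample(patients)
  fold_of <- setNames(rep_len(seq_len(k), length(patients)), shuffled)
  out <- as_tibble(notes)
  out$.fold <- unname(fold_of[out$patient_id])
  out
}
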