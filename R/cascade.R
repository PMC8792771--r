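#' Predict EDSS scores for a corpus (rule, CNN, or combined cascade)
#'
#' The combined model mirrors the two-step design: the rule-based
#' extractor first checks whether the score is explicitly written; when
#' it finds one, that value is returned verbatim and the classifier is
#' never invoked, otherwise the note is passed to the CNN.  On notes with
#' an explicit mention the cascade output is therefore bit-identical to
#' the rule output, whatever the classifier — and retraining the CNN can
#' never change those predictions.
#'
#' @param notes A notes tibble (raw or preprocessed).
#' @param mode `"combined"` (default), `"rule"` or `"cnn"`.
#' @param model A trained `text_cnn` from [train_edss_cnn()] (required
#'   unless `mode = "rule"`).
#' @param rules Subscore rules (used for `target` other than "total").
#' @param target `"total"` or a functional-system name; must match the
#'   model's training target in CNN modes.
#' @return A tibble with `note_id`, `target`, `value` (`NA` = unknown)
#'   and `source` (`"rule"` or `"cnn"`), one row per note in input order.
#' @export
predict_edss <- function(notes, mode = c("combined", "rule", "cnn"),
                         model = NULL, rules = load_subscore_rules(),
                         target = "total") {
  mode <- match.arg(mode)
  if (mode != "rule" && is.null(model)) {
    abort(paste0("mode '", mode, "' needs a trained classifier"))
  }
  if (!is.null(model) && !is.null(model$target) && model$target != target) {
    abort("classifier was trained for a different target")
  }
  pp <- if (!is.null(model) && !is.null(model$preprocess)) {
    model$preprocess
  } else {
    preprocess_config()
  }
  if (!all(c("sentences", "tokens") %in% names(notes))) {
    notes <- preprocess_notes(notes, pp)
  }

  rule_value <- rep(NA_real_, nrow(notes))
  if (mode != "cnn") {
    rule_value <- if (target == "total") {
      vapply(notes$sentences, extract_total_edss, numeric(1))
    } else {
      vapply(
        notes$sentences,
        function(s) as.numeric(extract_subscore(s, target, rules)),
        numeric(1)
      )
    }
  }

  value <- rule_value
  source <- rep("rule", nrow(notes))
  need_cnn <- switch(mode,
    rule = rep(FALSE, nrow(notes)),
    cnn = rep(TRUE, nrow(notes)),
    combined = is.na(rule_value)
  )
  if (any(need_cnn)) {
    X <- encode_sequences(
      notes$tokens[need_cnn], model$vocab,
      model$config$max_len
    )
    probs <- predict_proba(model, X)
    value[need_cnn] <- predict_label(
      probs, model$class_values,
      model$config$abstain_threshold
    )
    source[need_cnn] <- "cnn"
  }
  tibble(
    note_id = notes$note_id, target = target,
    value = value, source = source
  )
}

#' Per-source prediction counts
#'
#' @param predictions Output of [predict_edss()].
#' @return A tibble counting predictions by `source`, with the unknown
#'   rate within each source.
#' @export
prediction_sources <- function(predictions) {
  predictions %>%
    group_by(.data$source) %>%
    summarise(
      n = dplyr::n(),
      unknown_rate = mean(is.na(.data$value)),
      .groups = "drop"
    )
}
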