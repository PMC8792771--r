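test_that("the generator is a deterministic function of its configuration", {
  c1 <- simulate_notes(synth_config(n_patients = 25, seed = 9))
  c2 <- simulate_notes(synth_config(n_patients = 25, seed = 9))
  expect_identical(c1, c2)
  c3 <- simulate_notes(synth_config(n_patients = 25, seed = 10))
  expect_false(identical(c1$text, c3$text))
})

test_that("a degenerate class distribution fixes every label", {
  dist <- setNames(
    rep(0, 19),
    sprintf("%.1f", edss_classes())
  )
  dist[["3.0"]] <- 1
  corpus <- simulate_notes(synth_config(
    n_patients = 20, class_distribution = dist,
    drift_prob = 0, p_label_missing = 0, seed = 4
  ))
  expect_true(all(corpus$true_edss == 3.0))
  expect_true(all(corpus$edss == 3.0))
})

test_that("explicit-mention metadata is consistent with the rendered text", {
  corpus <- small_corpus()
  for (i in seq_len(nrow(corpus))) {
    has_digit_mention <- nrow(find_edss_mentions(
      split_sentences(strip_boilerplate(corpus$text[[i]]))[[1]]
    )) > 0
    expect_equal(has_digit_mention, corpus$explicit[[i]])
  }
  # spelled-out notes carry the keyword but no digit score
  sp <- corpus[corpus$spelled_out, ]
  if (nrow(sp) > 0) {
    expect_true(all(grepl("EDSS", sp$text)))
    expect_false(any(sp$explicit))
  }
})

test_that("explicit non-distractor notes round-trip through the rule extractor for all 19 classes", {
  cfg <- synth_config(
    n_patients = 150, p_explicit = 1, p_distractor = 0,
    p_label_missing = 0, drift_prob = 0.3, seed = 77
  )
  corpus <- simulate_notes(cfg)
  pp <- preprocess_notes(corpus)
  got <- vapply(pp$sentences, extract_total_edss, numeric(1))
  expect_equal(got, corpus$true_edss)
  expect_gte(length(unique(corpus$true_edss)), 15) # wide class coverage
  # and force full coverage: render one explicit note per class
  tpl <- load_note_templates()
  rules <- load_subscore_rules()
  for (value in edss_classes()) {
    note <- tibble::tibble(
      note_id = "x", patient_id = "p",
      text = paste0("EDSS is ", sprintf("%.1f", value), " in this visit.")
    )
    expect_equal(
      extract_total_edss(preprocess_notes(note)$sentences[[1]]),
      value
    )
  }
})

test_that("a preceding distractor defeats the first-occurrence rule, by design", {
  cfg <- synth_config(
    n_patients = 200, p_explicit = 1, p_distractor = 1,
    p_label_missing = 0, seed = 31
  )
  corpus <- simulate_notes(cfg)
  pp <- preprocess_notes(corpus)
  got <- vapply(pp$sentences, extract_total_edss, numeric(1))
  # the extractor recovers the earlier (previous-visit) value, never the truth
  expect_true(all(got == corpus$distractor_value))
  expect_true(all(got != corpus$true_edss))
})

test_that("p_explicit 0 silences the extractor entirely", {
  corpus <- simulate_notes(synth_config(
    n_patients = 40, p_explicit = 0,
    p_spelled_out = 0, seed = 6
  ))
  pp <- preprocess_notes(corpus)
  got <- vapply(pp$sentences, extract_total_edss, numeric(1))
  expect_true(all(is.na(got)))
})

test_that("realized corpus statistics concentrate at the configured rates", {
  cfg <- synth_config(n_patients = 1600, seed = 2024) # ~5600 notes
  corpus <- simulate_notes(cfg)
  n <- nrow(corpus)
  expect_gte(n, 5000)
  binom_se <- function(p) sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(corpus$explicit) - 0.623), 3 * binom_se(0.623))
  expect_lt(abs(mean(corpus$label_missing) - 0.05), 3 * binom_se(0.05))
  low <- mean(corpus$true_edss <= 4)
  high <- mean(corpus$true_edss > 6)
  expect_lt(abs(low - 0.795), 3 * binom_se(0.795))
  expect_lt(abs(high - 0.079), 3 * binom_se(0.079))
  # longitudinal plausibility: consecutive notes drift at most one half-step
  drift_ok <- corpus %>%
    dplyr::group_by(patient_id) %>%
    dplyr::summarise(
      ok = all(abs(diff(match(true_edss, edss_classes()))) <= 1),
      .groups = "drop"
    )
  expect_true(all(drift_ok$ok))
})

test_that("rendered finding sentences are recovered by the subscore rules", {
  cfg <- synth_config(
    n_patients = 60, subscore_noise = 0, p_label_missing = 0,
    seed = 55
  )
  corpus <- simulate_notes(cfg)
  pp <- preprocess_notes(corpus)
  rules <- load_subscore_rules()
  for (system in c("cerebellar", "pyramidal", "sensory", "visual")) {
    got <- vapply(
      pp$sentences,
      function(s) as.numeric(extract_subscore(s, system, rules)), numeric(1)
    )
    ref <- corpus[[system]]
    nonzero <- ref > 0
    # score-bearing finding sentences round-trip exactly
    expect_true(all(got[nonzero] == ref[nonzero]))
    # absent findings are dictated as normal exam lines: the rule abstains
    expect_true(all(is.na(got[!nonzero])))
  }
})

test_that("corpus files round-trip through the interchange formats", {
  corpus <- small_corpus()
  dir <- tempfile()
  write_corpus(corpus, dir)
  notes <- read_notes_jsonl(file.path(dir, "notes.jsonl"))
  expect_equal(notes$note_id, corpus$note_id)
  expect_equal(notes$text, corpus$text)
  expect_equal(notes$edss, corpus$edss)
  expect_equal(notes$cerebellar, as.numeric(corpus$cerebellar))
  labels <- read_labels_csv(file.path(dir, "labels.csv"))
  expect_equal(labels$edss, corpus$edss)
  # jsonl writer/reader inverse on a hand-built table
  tmp <- tempfile(fileext = ".jsonl")
  small <- tibble::tibble(
    note_id = c("a", "b"), patient_id = c("p", "q"),
    text = c("line one.\nline two.", "unicode é text"), edss = c(2, NA)
  )
  write_notes_jsonl(small, tmp)
  back <- read_notes_jsonl(tmp)
  expect_equal(back$text, small$text)
  expect_equal(back$edss, small$edss)
})
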