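#' Load the synthetic-note template library
#'
#' @param path Path to a template YAML file; default is the shipped library.
#' @return A named list of template components.
#' @export
load_note_templates <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "note_templates.yaml", package = "edssnlp")
  }
  yaml::read_yaml(path)
}

#' Default EDSS class distribution
#'
#' The label distribution the generator draws from, shaped to the class
#' imbalance typical of MS clinic populations: 79.5% of scores in 0.0-4.0,
#' 7.9% above 6.0, and the remaining 12.6% in 4.5-6.0, spread uniformly
#' within each band.
#'
#' @return A named numeric vector over [edss_classes()] summing to 1.
#' @export
default_class_distribution <- function() {
  cls <- edss_classes()
  p <- numeric(length(cls))
  low <- cls <= 4
  mid <- cls > 4 & cls <= 6
  high <- cls > 6
  p[low] <- 0.795 / sum(low)
  p[mid] <- 0.126 / sum(mid)
  p[high] <- 0.079 / sum(high)
  setNames(p, sprintf("%.1f", cls))
}

#' Synthetic corpus configuration
#'
#' Defaults encode the statistical structure of a large single-centre MS
#' clinic corpus: explicit "EDSS <number>" dictation in 62.3% of notes,
#' heavy class imbalance (see [default_class_distribution()]), occasional
#' conflicting double mentions, occasional spelled-out scores, and
#' per-system finding sentences phrased as keyword plus severity adjective.
#'
#' @param n_patients Number of patients.
#' @param notes_per_patient Integer vector to sample each patient's note
#'   count from (uniformly).  Default `1:6` (mean 3.5 notes/patient).
#' @param class_distribution Named probability vector over the 19 classes.
#' @param p_explicit Probability a note carries an explicit digit mention.
#' @param p_distractor Given explicit: probability of an additional,
#'   earlier, different-valued mention (the known first-occurrence trap).
#' @param p_spelled_out Given not explicit: probability the score is
#'   written as words ("EDSS was three"), defeating numeric extraction.
#' @param p_label_missing Probability the reference total label is
#'   withheld (an unlabeled note; trains/tests the unknown class).
#' @param subscore_noise Per-system probability that the finding sentence
#'   is omitted even though the subscore is on record.
#' @param drift_prob Probability that a patient's score moves up (and,
#'   independently, down) one half-step class between consecutive notes.
#' @param seed Integer seed; the whole corpus is a deterministic function
#'   of the configuration including this seed.
#' @param templates Template library from [load_note_templates()].
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_patients = 300,
                         notes_per_patient = 1:6,
                         class_distribution = default_class_distribution(),
                         p_explicit = 0.623,
                         p_distractor = 0.10,
                         p_spelled_out = 0.10,
                         p_label_missing = 0.05,
                         subscore_noise = 0.30,
                         drift_prob = 0.05,
                         seed = 42L,
                         templates = load_note_templates()) {
  stopifnot(
    n_patients >= 1,
    abs(sum(class_distribution) - 1) < 1e-8,
    all(class_distribution >= 0),
    all(c(
      p_explicit, p_distractor, p_spelled_out, p_label_missing,
      subscore_noise, drift_prob
    ) >= 0),
    all(c(
      p_explicit, p_distractor, p_spelled_out, p_label_missing,
      subscore_noise, drift_prob
    ) <= 1)
  )
  structure(
    list(
      n_patients = as.integer(n_patients),
      notes_per_patient = as.integer(notes_per_patient),
      class_distribution = class_distribution,
      p_explicit = p_explicit, p_distractor = p_distractor,
      p_spelled_out = p_spelled_out, p_label_missing = p_label_missing,
      subscore_noise = subscore_noise, drift_prob = drift_prob,
      seed = as.integer(seed), templates = templates
    ),
    class = "synth_config"
  )
}

# spell out a half-step value: 3 -> "three", 6.5 -> "six point five"
spell_edss <- function(value) {
  ones <- c(
    "zero", "one", "two", "three", "four", "five", "six", "seven",
    "eight", "nine", "ten"
  )
  whole <- floor(value + 1e-9)
  word <- ones[whole + 1]
  if (abs(value - whole) > 1e-9) word <- paste(word, "point five")
  word
}

edss_band <- function(value) {
  if (value < 1) {
    "b0"
  } else if (value <= 2.5) {
    "b1"
  } else if (value <= 4) {
    "b2"
  } else if (value <= 5.5) {
    "b3"
  } else if (value <= 6.5) {
    "b4"
  } else {
    "b5"
  }
}

fill <- function(template, ...) {
  subs <- list(...)
  for (key in names(subs)) {
    template <- gsub(paste0("{", key, "}"), subs[[key]], template,
      fixed = TRUE
    )
  }
  template
}

pick <- function(x) if (length(x) == 1) x[[1]] else x[[sample.int(length(x), 1)]]

# render one note; `flags` carries mention type and per-system subscores
render_note <- function(value, flags, templates, rules) {
  tpl <- templates
  digit <- sprintf("%.1f", value)
  header <- fill(pick(tpl$headers),
    patient = pick(tpl$patients), mrn = sample.int(9e6, 1) + 1e6,
    date = sprintf(
      "%02d/%02d/%d", sample.int(12, 1), sample.int(28, 1),
      sample(2015:2019, 1)
    ),
    phone = sprintf(
      "416-%03d-%04d", sample.int(999, 1),
      sample.int(9999, 1)
    ),
    doc = sample.int(1e5, 1)
  )
  footer <- fill(pick(tpl$footers),
    physician = pick(tpl$physicians),
    date = sprintf(
      "%02d/%02d/%d", sample.int(12, 1), sample.int(28, 1),
      sample(2015:2019, 1)
    )
  )
  body <- pick(tpl$openers)
  # findings first: the first matching sentence decides each subscore
  for (system in names(flags$subscores)) {
    s <- flags$subscores[[system]]
    if (is.na(s) || flags$omit_finding[[system]]) next
    if (s == 0) {
      body <- c(body, tpl$finding_absent[[system]])
    } else if (system == "bowel_bladder" && s == rules$bowel_bladder$default_score &&
      isTRUE(flags$use_catheter)) {
      body <- c(body, tpl$catheter_sentence)
    } else {
      adjective <- names(rules[[system]]$severity_map)[s]
      sent <- fill(tpl$finding_sentences[[system]], adjective = adjective)
      substr(sent, 1, 1) <- toupper(substr(sent, 1, 1))
      body <- c(body, sent)
    }
  }
  # qualitative class-anchor phrases substitute for a dictated score:
  # they appear only when the note does not state the score as a digit
  if (!flags$explicit) {
    body <- c(body, pick(tpl$class_phrases[[digit]]))
  }
  body <- c(body, fill(pick(tpl$band_fillers),
    band = pick(tpl$band_vocab[[edss_band(value)]])
  ))
  if (flags$explicit) {
    if (flags$distractor) {
      body <- c(body, fill(pick(tpl$distractor_pair),
        prev = sprintf("%.1f", flags$prev_value), value = digit
      ))
    } else {
      body <- c(body, fill(pick(tpl$explicit_current), value = digit))
    }
  } else if (flags$spelled_out) {
    body <- c(body, fill(pick(tpl$spelled_out), words = spell_edss(value)))
  }
  body <- c(body, pick(tpl$closers))
  paste(c(header, paste(body, collapse = " "), footer), collapse = "\n")
}

#' Generate a synthetic clinic-note corpus
#'
#' Draws per-patient EDSS trajectories from the configured class
#' distribution (with a small half-step random walk between consecutive
#' visits), renders each note from the template library, and returns the
#' corpus together with full generation metadata, so every downstream
#' component can be tested against known ground truth.  Regeneration with
#' an identical configuration (including seed) is byte-identical.
#'
#' @param config A [synth_config()].
#' @param rules Subscore rules used to phrase finding sentences
#'   consistently with the shipped extractor rules.
#' @return A tibble with columns `note_id`, `patient_id`, `text`, the
#'   reference labels `edss` and one column per functional system (`NA`
#'   when withheld/absent), and the metadata columns `true_edss`,
#'   `explicit`, `distractor`, `distractor_value`, `spelled_out`,
#'   `label_missing`.
#' @export
#' @examples
#' corpus <- simulate_notes(synth_config(n_patients = 5, seed = 1))
#' corpus[1, c("note_id", "edss", "explicit")]
simulate_notes <- function(config = synth_config(),
                           rules = load_subscore_rules()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  cls <- edss_classes()
  probs <- config$class_distribution[sprintf("%.1f", cls)]
  n_notes_pp <- sample(config$notes_per_patient, config$n_patients,
    replace = TRUE
  )
  systems <- names(rules)

  n_total <- sum(n_notes_pp)
  out <- list(
    note_id = sprintf("N%05d", seq_len(n_total)),
    patient_id = character(n_total), text = character(n_total),
    edss = numeric(n_total), true_edss = numeric(n_total),
    explicit = logical(n_total), distractor = logical(n_total),
    distractor_value = rep(NA_real_, n_total),
    spelled_out = logical(n_total), label_missing = logical(n_total)
  )
  sub_out <- lapply(setNames(systems, systems), function(s) {
    rep(NA_integer_, n_total)
  })

  k <- 0
  for (p in seq_len(config$n_patients)) {
    patient_id <- sprintf("P%04d", p)
    ci <- sample.int(length(cls), 1, prob = probs)
    for (v in seq_len(n_notes_pp[[p]])) {
      if (v > 1) {
        step <- sample(c(-1L, 0L, 1L), 1,
          prob = c(
            config$drift_prob, 1 - 2 * config$drift_prob,
            config$drift_prob
          )
        )
        ci <- min(max(ci + step, 1L), length(cls))
      }
      value <- cls[[ci]]
      explicit <- runif(1) < config$p_explicit
      spelled <- !explicit && runif(1) < config$p_spelled_out
      distractor <- explicit && runif(1) < config$p_distractor
      prev_value <- NA_real_
      if (distractor) {
        others <- cls[cls != value]
        # distractors are clinically adjacent previous-visit scores
        w <- 1 / (abs(others - value) + 0.5)
        prev_value <- sample(others, 1, prob = w)
      }
      subs <- setNames(vector("list", length(systems)), systems)
      omit <- setNames(vector("list", length(systems)), systems)
      for (system in systems) {
        max_s <- rules[[system]]$max_score
        s <- round(value / 2 + sample(c(-1, 0, 1), 1, prob = c(.2, .6, .2)))
        subs[[system]] <- as.integer(min(max(s, 0), max_s))
        omit[[system]] <- runif(1) < config$subscore_noise
      }
      flags <- list(
        explicit = explicit, spelled_out = spelled,
        distractor = distractor, prev_value = prev_value,
        subscores = subs, omit_finding = omit,
        use_catheter = runif(1) < 0.5
      )
      text <- render_note(value, flags, config$templates, rules)
      label_missing <- runif(1) < config$p_label_missing
      k <- k + 1
      out$patient_id[[k]] <- patient_id
      out$text[[k]] <- text
      out$edss[[k]] <- if (label_missing) NA_real_ else value
      out$true_edss[[k]] <- value
      out$explicit[[k]] <- explicit
      out$distractor[[k]] <- distractor
      out$distractor_value[[k]] <- prev_value
      out$spelled_out[[k]] <- spelled
      out$label_missing[[k]] <- label_missing
      if (!label_missing) {
        for (system in systems) sub_out[[system]][[k]] <- subs[[system]]
      }
    }
  }
  as_tibble(c(out, sub_out))
}

#' Write a generated corpus to disk
#'
#' Produces the three interchange files: `notes.jsonl` (text + labels),
#' `labels.csv` (label table) and `metadata.csv` (generation ground truth
#' and flags).
#'
#' @param corpus A tibble from [simulate_notes()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_notes_jsonl(corpus, file.path(dir, "notes.jsonl"))
  labels <- corpus[, c(
    "note_id", "patient_id", "edss",
    intersect(functional_systems(), names(corpus))
  )]
  write_labels_csv(labels, file.path(dir, "labels.csv"))
  meta_cols <- c(
    "note_id", "patient_id", "true_edss", "explicit", "distractor",
    "distractor_value", "spelled_out", "label_missing"
  )
  readr::write_csv(corpus[, intersect(meta_cols, names(corpus))],
    file.path(dir, "metadata.csv"),
    progress = FALSE
  )
  invisible(dir)
}

# save/restore the global RNG state so seeded generators do not disturb
# the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
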