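#' Load functional-system subscore rules
#'
#' Reads a YAML rule file (one block per functional system, see the shipped
#' `subscore_rules.yaml`) and validates every rule: a known system name, a
#' `max_score` of 5 or 6, every severity score within `[0, max_score]`, and
#' a severity map that is monotone non-decreasing in the stated adjective
#' order.  An empty file yields an empty rule set with a warning.
#'
#' @param path Path to a rule YAML file; default is the shipped rule set.
#' @return A named list of class `subscore_rules`, one element per system,
#'   each with `max_score`, `finding_patterns`, `severity_map`,
#'   `default_score`.
#' @export
load_subscore_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "subscore_rules.yaml", package = "edssnlp")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || length(raw) == 0) {
    warn("rule file is empty; no subscore rules loaded")
    return(structure(list(), class = "subscore_rules"))
  }
  rules <- list()
  for (system in names(raw)) {
    r <- raw[[system]]
    if (!(system %in% functional_systems())) {
      abort(paste0("rule '", system, "': unknown functional system"))
    }
    max_score <- as.integer(r$max_score)
    if (!isTRUE(max_score %in% c(5L, 6L))) {
      abort(paste0("rule '", system, "': max_score must be 5 or 6"))
    }
    sev <- unlist(r$severity_map)
    sev <- setNames(as.integer(sev), names(sev))
    if (any(sev < 0 | sev > max_score)) {
      abort(paste0(
        "rule '", system, "': severity score outside [0, ",
        max_score, "]"
      ))
    }
    if (length(sev) > 1 && any(diff(sev) < 0)) {
      abort(paste0("rule '", system, "': severity_map is not monotone"))
    }
    default_score <- as.integer(r$default_score)
    if (default_score < 0 || default_score > max_score) {
      abort(paste0("rule '", system, "': default_score outside range"))
    }
    rules[[system]] <- list(
      max_score = max_score,
      finding_patterns = as.character(r$finding_patterns),
      severity_map = sev,
      default_score = default_score
    )
  }
  structure(rules, class = "subscore_rules")
}

#' Find explicit total-EDSS score mentions
#'
#' Scans rule-path sentences for co-occurrences of the keyword "EDSS"
#' (case-insensitive substring) with a numeric value in `[0.0, 10.0]`.
#' Numbers are accepted in integer ("6") or decimal ("6.5") form; values
#' off the half-step grid (e.g. "6.25") and spelled-out numbers ("three")
#' are not mentions — the latter is a deliberate, known failure mode of
#' the rule approach.  Mentions are returned in document order, and within
#' a sentence in left-to-right order.
#'
#' @param sentences Character vector of sentences for one note, in order
#'   (from [split_sentences()]).
#' @return A tibble with columns `sentence_index`, `value`, `start` (the
#'   character offset of the number within its sentence).
#' @export
#' @examples
#' find_edss_mentions(c(
#'   "EDSS was 5.0 in the previous visit.",
#'   "EDSS is 6.0 in this visit."
#' ))
find_edss_mentions <- function(sentences) {
  out <- list()
  hits <- grepl("edss", sentences, ignore.case = TRUE, fixed = FALSE)
  for (i in which(hits)) {
    m <- gregexpr("(?<![0-9.])[0-9]+(\\.[0-9]+)?(?![0-9])",
      sentences[[i]],
      perl = TRUE
    )[[1]]
    if (m[1] == -1L) next
    vals <- as.numeric(regmatches(sentences[[i]], list(m))[[1]])
    keep <- is_half_step(vals)
    if (!any(keep)) next
    out[[length(out) + 1]] <- tibble(
      sentence_index = i,
      value = vals[keep],
      start = as.integer(m)[keep]
    )
  }
  if (length(out) == 0) {
    return(tibble(
      sentence_index = integer(), value = numeric(),
      start = integer()
    ))
  }
  bind_rows(out)
}

#' Extract the total EDSS score from one note (rule path)
#'
#' Implements the first-occurrence rule: the score reported is the numeric
#' value of the first sentence in which "EDSS" and an in-range number
#' co-occur, taking the left-most in-range number when the sentence holds
#' several.  Returns `NA` (unknown) when no mention exists — the rule
#' extractor abstains rather than guessing.
#'
#' @param sentences Character vector of sentences for one note.
#' @return A single numeric EDSS value, or `NA` if no explicit mention.
#' @export
#' @examples
#' extract_total_edss(c(
#'   "EDSS was 5.0 in the previous visit.",
#'   "EDSS is 6.0 in this visit."
#' )) # 5.0: the rule takes the first mention, not the current score
extract_total_edss <- function(sentences) {
  mentions <- find_edss_mentions(sentences)
  if (nrow(mentions) == 0) {
    return(unknown)
  }
  mentions$value[[1]]
}

#' Extract one functional-system subscore from one note (rule path)
#'
#' The first sentence matching any of the system's finding patterns
#' (case-insensitive) decides the score: if a severity adjective from the
#' rule's `severity_map` occurs in that same sentence, its mapped score is
#' returned (the most severe matching adjective wins when several occur);
#' otherwise the rule's `default_score`.  No matching sentence means the
#' extractor abstains (`NA`).  Negation ("no ataxia") is deliberately not
#' handled — the rule model reproduces that limitation faithfully.
#'
#' @param sentences Character vector of sentences for one note.
#' @param system A functional-system name (see [functional_systems()]).
#' @param rules A `subscore_rules` object from [load_subscore_rules()].
#' @return Integer subscore in `[0, max_score]`, or `NA`.
#' @export
extract_subscore <- function(sentences, system,
                             rules = load_subscore_rules()) {
  rule <- rules[[system]]
  if (is.null(rule)) {
    abort(paste0("no rule loaded for system '", system, "'"))
  }
  low <- tolower(sentences)
  pat <- paste0(tolower(rule$finding_patterns), collapse = "|")
  hit <- which(grepl(pat, low))[1]
  if (is.na(hit)) {
    return(NA_integer_)
  }
  adjectives <- names(rule$severity_map)
  present <- vapply(
    adjectives,
    function(a) grepl(paste0("\\b", a, "\\b"), low[[hit]]),
    logical(1)
  )
  if (any(present)) {
    # adjectives are listed weakest-to-strongest; take the strongest present
    return(unname(rule$severity_map[[max(which(present))]]))
  }
  rule$default_score
}

#' Rule-based extraction over a corpus
#'
#' Applies the total-score extractor and, optionally, every
#' functional-system subscore extractor to each note of a (preprocessed)
#' corpus.
#'
#' @param notes A notes tibble; if it lacks a `sentences` list-column it is
#'   passed through [preprocess_notes()] first.
#' @param rules Subscore rules, or `NULL` to skip subscores.
#' @param systems Which functional systems to extract (default: all that
#'   have rules).
#' @return A tibble with `note_id`, `edss_total`, one column per extracted
#'   system, and `source = "rule"`.  Unknown scores are `NA`.
#' @export
extract_edss <- function(notes, rules = load_subscore_rules(),
                         systems = names(rules)) {
  if (!("sentences" %in% names(notes))) {
    notes <- preprocess_notes(notes)
  }
  out <- tibble(
    note_id = notes$note_id,
    edss_total = vapply(notes$sentences, extract_total_edss, numeric(1))
  )
  for (system in systems) {
    out[[system]] <- vapply(
      notes$sentences,
      function(s) as.integer(extract_subscore(s, system, rules)),
      integer(1)
    )
  }
  out$source <- "rule"
  out
}
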