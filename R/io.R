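#' Read a note corpus from JSON-lines
#'
#' The native interchange format: one JSON object per line with keys
#' `note_id`, `patient_id`, `text` and optionally `labels` (an object with
#' `total` and per-system subscore keys; missing or `null` values mean
#' unknown).
#'
#' @param path Path to a `.jsonl` file.
#' @return A tibble with columns `note_id`, `patient_id`, `text`, `edss`
#'   and one column per functional system (all-`NA` when no labels are
#'   present).
#' @export
read_notes_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  get_chr <- function(r, k) as.character(r[[k]] %||% NA_character_)
  lab_num <- function(r, k) {
    v <- r$labels[[k]]
    if (is.null(v) || length(v) == 0) NA_real_ else as.numeric(v)
  }
  out <- tibble(
    note_id = vapply(recs, get_chr, character(1), k = "note_id"),
    patient_id = vapply(recs, get_chr, character(1), k = "patient_id"),
    text = vapply(recs, get_chr, character(1), k = "text"),
    edss = vapply(recs, lab_num, numeric(1), k = "total")
  )
  for (system in functional_systems()) {
    out[[system]] <- vapply(recs, lab_num, numeric(1), k = system)
  }
  out
}

#' Write a note corpus as JSON-lines
#'
#' Inverse of [read_notes_jsonl()].  Label fields that are entirely absent
#' from the table are omitted; `NA` labels are written as `null`.
#'
#' @param notes A notes tibble (`note_id`, `patient_id`, `text`, optional
#'   label columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_notes_jsonl <- function(notes, path) {
  systems <- intersect(functional_systems(), names(notes))
  has_total <- "edss" %in% names(notes)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(notes))) {
    rec <- list(
      note_id = notes$note_id[[i]],
      patient_id = notes$patient_id[[i]],
      text = notes$text[[i]]
    )
    if (has_total || length(systems)) {
      labels <- list()
      if (has_total) labels$total <- notes$edss[[i]]
      for (s in systems) labels[[s]] <- notes[[s]][[i]]
      rec$labels <- labels
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null", na = "null", digits = NA), con)
  }
  invisible(path)
}

#' Read a label table from CSV
#'
#' Columns: `note_id`, `patient_id`, `edss_total`, one column per
#' functional system.  Empty cells are unknown (`NA`).
#'
#' @param path Path to a CSV file.
#' @return A tibble with `edss_total` renamed to `edss`.
#' @export
read_labels_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("edss_total" %in% names(tab)) tab <- rename(tab, edss = "edss_total")
  tab$note_id <- as.character(tab$note_id)
  if ("patient_id" %in% names(tab)) {
    tab$patient_id <- as.character(tab$patient_id)
  }
  tab
}

#' Write a label table to CSV
#'
#' @param labels A tibble with `note_id` and label columns (`edss` is
#'   written as `edss_total`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(labels, path) {
  if ("edss" %in% names(labels)) {
    labels <- rename(labels, edss_total = "edss")
  }
  readr::write_csv(labels, path, progress = FALSE)
  invisible(path)
}
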