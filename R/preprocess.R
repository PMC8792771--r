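#' Frozen English stop-word list
#'
#' Returns the stop-word list shipped with the package (a frozen copy of the
#' NLTK English default list), read from `inst/extdata` so that results do
#' not depend on any run-time download.
#'
#' @return Character vector of stop words.
#' @export
edss_stopwords <- function() {
  path <- system.file("extdata", "stopwords_english.txt", package = "edssnlp")
  readLines(path, encoding = "UTF-8")
}

#' Default boilerplate patterns
#'
#' Loads the shipped boilerplate/identifier pattern file (or a user-supplied
#' one of the same shape).  Patterns come in two flavours: `line_patterns`
#' drop whole matching lines (headers, footers, fax/document numbers,
#' signatures), `inline_patterns` are excised wherever they occur (phone
#' numbers, dates).
#'
#' @param path Path to a YAML pattern file; default is the shipped file.
#' @return A list with elements `line_patterns` and `inline_patterns`.
#' @export
boilerplate_patterns <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "boilerplate_patterns.yaml",
      package = "edssnlp"
    )
  }
  pats <- yaml::read_yaml(path)
  pats$line_patterns <- as.character(pats$line_patterns %||% character())
  pats$inline_patterns <- as.character(pats$inline_patterns %||% character())
  pats
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Preprocessing configuration
#'
#' @param max_len Maximum encoded sequence length in tokens; shorter notes
#'   are zero-padded, longer notes truncated at the end.  Default 1000.
#' @param min_count Minimum corpus frequency for a token to receive a
#'   vocabulary id.  Default 2.
#' @param stoplist Character vector of stop words; defaults to the frozen
#'   list from [edss_stopwords()].
#' @param patterns Boilerplate pattern list as returned by
#'   [boilerplate_patterns()].
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(max_len = 1000, min_count = 2,
                              stoplist = edss_stopwords(),
                              patterns = boilerplate_patterns()) {
  stopifnot(max_len >= 1, min_count >= 1)
  structure(
    list(
      max_len = as.integer(max_len), min_count = as.integer(min_count),
      stoplist = stoplist, patterns = patterns
    ),
    class = "preprocess_config"
  )
}

#' Strip boilerplate and identifiers from raw note text
#'
#' Removes header/footer lines and inline identifier patterns.  With no
#' matching pattern the text is returned unchanged; the order of the
#' surviving text is always preserved.
#'
#' @param text Character vector of raw note texts.
#' @param patterns Pattern list from [boilerplate_patterns()].
#' @return Character vector of cleaned texts, same length as `text`.
#' @export
#' @examples
#' strip_boilerplate("Fax: 416-555-0199\nEDSS is 3.0 today.")
strip_boilerplate <- function(text, patterns = boilerplate_patterns()) {
  vapply(text, function(txt) {
    lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
    for (p in patterns$line_patterns) {
      lines <- lines[!grepl(p, lines, ignore.case = TRUE, perl = TRUE)]
    }
    for (p in patterns$inline_patterns) {
      lines <- gsub(p, " ", lines, ignore.case = TRUE, perl = TRUE)
    }
    lines <- lines[trimws(lines) != ""]
    paste(trimws(lines), collapse = "\n")
  }, character(1), USE.NAMES = FALSE)
}

#' Lowercase letter-only tokenization
#'
#' The model-path normalization: lowercases, removes every non-letter
#' character (digits, punctuation, symbols), collapses whitespace, and
#' splits into word tokens.  Note that this deliberately destroys numeric
#' score mentions; the rule path works on [split_sentences()] output
#' instead, where punctuation and digits are retained.
#'
#' @param text Character vector (already boilerplate-stripped).
#' @return A list of character vectors, one per input element.
#' @export
#' @examples
#' tokenize_letters("EDSS is 6.0 today!!")
tokenize_letters <- function(text) {
  text <- tolower(text)
  text <- gsub("[^a-z]+", " ", text, perl = TRUE)
  lapply(strsplit(trimws(text), "\\s+"), function(x) x[nzchar(x)])
}

#' Remove stop words from a token vector
#'
#' Order-preserving filter against a stop-word list.
#'
#' @param tokens Character vector of tokens (or a list of such vectors).
#' @param stoplist Character vector of stop words.
#' @return Filtered tokens, same container shape as the input.
#' @export
remove_stopwords <- function(tokens, stoplist = edss_stopwords()) {
  if (is.list(tokens)) {
    return(lapply(tokens, function(x) x[!(x %in% stoplist)]))
  }
  tokens[!(tokens %in% stoplist)]
}

#' Split text into sentences, protecting decimal numbers
#'
#' Splits on `.`, `!` or `?` followed by whitespace or end of text.  A
#' period flanked by digits (as in "5.0") is never followed by whitespace,
#' so decimal scores survive intact.  Newlines also terminate sentences.
#' Concatenating the output (modulo whitespace) reconstructs the input.
#'
#' @param text Character vector (boilerplate-stripped, punctuation retained).
#' @return A list of character vectors of sentences, one per input element.
#' @export
#' @examples
#' split_sentences("EDSS was 5.0 in the previous visit. EDSS is 6.0 in this visit.")
split_sentences <- function(text) {
  lapply(text, function(txt) {
    pieces <- strsplit(txt, "(?<=[.!?])\\s+|\\n+", perl = TRUE)[[1]]
    pieces <- trimws(pieces)
    pieces[nzchar(pieces)]
  })
}

#' Build a token vocabulary from a corpus
#'
#' Assigns contiguous positive integer ids to every token whose corpus
#' frequency reaches `min_count`, ordered by decreasing frequency with
#' alphabetical tie-break (deterministic).  Id 0 is reserved for padding
#' and is never assigned; out-of-vocabulary tokens encode to 0.
#'
#' @param token_lists List of character vectors (one per note).
#' @param min_count Minimum corpus frequency (default 2).
#' @return A named integer vector of class `edss_vocabulary` mapping token
#'   to id, with attributes `min_count` and `freq`.
#' @export
build_vocabulary <- function(token_lists, min_count = 2) {
  stopifnot(min_count >= 1)
  if (length(token_lists) == 0) {
    abort("cannot build a vocabulary from an empty corpus")
  }
  all_tokens <- unlist(token_lists, use.names = FALSE)
  if (length(all_tokens) == 0) {
    abort("cannot build a vocabulary from an empty corpus")
  }
  freq <- table(all_tokens)
  freq <- freq[freq >= min_count]
  if (length(freq) == 0) {
    abort("no token reaches min_count; vocabulary would be empty")
  }
  ord <- order(-as.integer(freq), names(freq))
  tokens <- names(freq)[ord]
  vocab <- setNames(seq_along(tokens), tokens)
  structure(vocab,
    min_count = as.integer(min_count),
    freq = as.integer(freq)[ord], class = "edss_vocabulary"
  )
}

#' @export
print.edss_vocabulary <- function(x, ...) {
  cat(
    "<edss_vocabulary> ", length(x), " tokens (min_count = ",
    attr(x, "min_count"), ")\n",
    sep = ""
  )
  invisible(x)
}

#' Encode token lists as fixed-length integer sequences
#'
#' Maps tokens to vocabulary ids (out-of-vocabulary tokens to 0), truncates
#' to the first `max_len` tokens, and zero-pads shorter notes, so every row
#' has length exactly `max_len`.
#'
#' @param token_lists List of character vectors.
#' @param vocab Vocabulary from [build_vocabulary()].
#' @param max_len Sequence length (default 1000).
#' @return An integer matrix with `length(token_lists)` rows and `max_len`
#'   columns.
#' @export
encode_sequences <- function(token_lists, vocab, max_len = 1000) {
  stopifnot(max_len >= 1)
  out <- matrix(0L, nrow = length(token_lists), ncol = max_len)
  for (i in seq_along(token_lists)) {
    toks <- token_lists[[i]]
    if (length(toks) == 0) next
    toks <- toks[seq_len(min(length(toks), max_len))]
    ids <- unname(vocab[toks])
    ids[is.na(ids)] <- 0L
    out[i, seq_along(ids)] <- as.integer(ids)
  }
  rownames(out) <- names(token_lists)
  out
}

#' Preprocess a corpus of notes
#'
#' Runs the fixed cleaning pipeline on a notes table and returns it with
#' two parallel views attached as list-columns: `sentences` (rule path —
#' boilerplate-stripped text with punctuation and digits retained, split
#' into sentences) and `tokens` (model path — lowercase letter-only tokens
#' with stop words removed).  Applying the pipeline to its own output is a
#' no-op.
#'
#' @param notes A data frame with at least `note_id`, `patient_id`, `text`.
#' @param config A [preprocess_config()].
#' @return The input as a tibble with list-columns `sentences` and `tokens`.
#' @export
#' @examples
#' notes <- tibble::tibble(
#'   note_id = "n1", patient_id = "p1",
#'   text = "Fax: 416-555-0199\nEDSS is 3.0 today. Mild ataxia on exam."
#' )
#' preprocess_notes(notes)$tokens
preprocess_notes <- function(notes, config = preprocess_config()) {
  stopifnot(all(c("note_id", "patient_id", "text") %in% names(notes)))
  if (anyDuplicated(notes$note_id)) {
    abort("note_id must be unique within a corpus")
  }
  stripped <- strip_boilerplate(notes$text, config$patterns)
  toks <- remove_stopwords(tokenize_letters(stripped), config$stoplist)
  out <- as_tibble(notes)
  out$sentences <- split_sentences(stripped)
  out$tokens <- toks
  out
}
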