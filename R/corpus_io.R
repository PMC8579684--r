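## Corpus input/output: clinical notes, target-section filtering, and
## sentence segmentation.
##
## A corpus is a plain list of `clinical_note` objects.  On disk a corpus is
## one record per note-section -- JSONL ({"note_id","patient_id","section",
## "text"}) or CSV with the same columns, UTF-8.

#' Construct a clinical note
#'
#' A `clinical_note` is the unit the pipeline ingests: identifiers plus an
#' ordered list of named sections of free text.  Notes typically retain only
#' the History of Present Illness and Impression/Report/Plan sections (see
#' [filter_sections()]), where teaching and reviewing of inhaler technique is
#' documented.
#'
#' @param note_id Non-empty string, unique within a corpus.
#' @param patient_id Non-empty string; required so corpora can be split at the
#'   patient level without leakage.
#' @param sections A `data.frame` with character columns `section` and `text`
#'   (a possibly empty string per section), in document order.
#' @return An object of class `clinical_note`.
#' @export
clinical_note <- function(note_id, patient_id, sections) {
  if (!is.character(note_id) || length(note_id) != 1L || !nzchar(note_id)) {
    stop_("'note_id' must be a single non-empty string")
  }
  if (!is.character(patient_id) || length(patient_id) != 1L || !nzchar(patient_id)) {
    stop_("'patient_id' must be a single non-empty string")
  }
  if (!is.data.frame(sections) || !all(c("section", "text") %in% names(sections))) {
    stop_("'sections' must be a data.frame with columns 'section' and 'text'")
  }
  sections <- data.frame(
    section = as.character(sections$section),
    text = as.character(sections$text),
    stringsAsFactors = FALSE
  )
  structure(
    list(note_id = note_id, patient_id = patient_id, sections = sections),
    class = "clinical_note"
  )
}

#' @export
print.clinical_note <- function(x, ...) {
  cat("<clinical_note> ", x$note_id, " (patient ", x$patient_id, ")\n", sep = "")
  for (i in seq_len(nrow(x$sections))) {
    txt <- x$sections$text[i]
    if (nchar(txt) > 60) txt <- paste0(substr(txt, 1, 57), "...")
    cat("  [", x$sections$section[i], "] ", txt, "\n", sep = "")
  }
  invisible(x)
}

required_record_fields <- c("note_id", "patient_id", "section", "text")

#' Read a note corpus from JSONL or CSV
#'
#' Each record is one note-section with fields `note_id`, `patient_id`,
#' `section`, `text`.  Records sharing a `note_id` are grouped into one
#' [clinical_note()] with sections in file order, so the record count is
#' conserved as the total section count.
#'
#' @param path Path to the file.
#' @param format `"jsonl"` or `"csv"`; default guessed from the file
#'   extension.
#' @return A list of `clinical_note` objects (a corpus).
#' @seealso [write_corpus()] for the inverse.
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (!file.exists(path)) stop_("file not found: ", path)
  recs <- switch(format,
    jsonl = read_section_records_jsonl(path),
    csv = read_section_records_csv(path)
  )
  records_to_corpus(recs)
}

read_section_records_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  recs <- vector("list", length(lines_keep))
  for (k in seq_along(lines_keep)) {
    i <- lines_keep[k]
    rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) {
      stop_("line ", i, ": invalid JSON: ", conditionMessage(e))
    })
    missing <- setdiff(required_record_fields, names(rec))
    if (length(missing)) {
      stop_("line ", i, ": missing required field(s): ",
            paste(missing, collapse = ", "))
    }
    recs[[k]] <- data.frame(
      note_id = as.character(rec$note_id),
      patient_id = as.character(rec$patient_id),
      section = as.character(rec$section),
      text = as.character(rec$text),
      line = i,
      stringsAsFactors = FALSE
    )
  }
  if (!length(recs)) {
    return(data.frame(note_id = character(), patient_id = character(),
                      section = character(), text = character(),
                      line = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, recs)
}

read_section_records_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", encoding = "UTF-8")
  missing <- setdiff(required_record_fields, names(df))
  if (length(missing)) {
    stop_("missing required column(s): ", paste(missing, collapse = ", "))
  }
  for (f in required_record_fields) {
    bad <- which(is.na(df[[f]]))
    if (length(bad)) {
      stop_("line ", bad[1] + 1L, ": missing required field: ", f)
    }
  }
  df$line <- seq_len(nrow(df)) + 1L  # header is line 1
  df[c(required_record_fields, "line")]
}

records_to_corpus <- function(recs) {
  if (!nrow(recs)) return(list())
  for (f in required_record_fields) {
    bad <- which(!nzchar(recs$note_id) | is.na(recs$note_id))
    if (length(bad)) stop_("line ", recs$line[bad[1]], ": empty note_id")
  }
  key <- paste(recs$note_id, recs$section, sep = "\r")
  if (anyDuplicated(key)) {
    d <- recs[duplicated(key), , drop = FALSE]
    stop_("duplicate (note_id, section) record(s), first at line ", d$line[1],
          ": (", d$note_id[1], ", ", d$section[1], ")")
  }
  ids <- unique(recs$note_id)
  corpus <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    sub <- recs[recs$note_id == ids[k], , drop = FALSE]
    pid <- unique(sub$patient_id)
    if (length(pid) != 1L) {
      stop_("note_id '", ids[k], "' maps to multiple patient_ids: ",
            paste(pid, collapse = ", "))
    }
    corpus[[k]] <- clinical_note(ids[k], pid, sub[c("section", "text")])
  }
  corpus
}

#' Write a note corpus to JSONL or CSV
#'
#' One record per note-section; [read_corpus()] on the result reconstructs an
#' equal corpus (round trip).
#'
#' @param corpus List of `clinical_note` objects.
#' @inheritParams read_corpus
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  recs <- corpus_records(corpus)
  if (format == "jsonl") {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(recs))) {
      writeLines(jsonlite::toJSON(as.list(recs[i, , drop = FALSE]),
                                  auto_unbox = TRUE), con)
    }
  } else {
    utils::write.csv(recs, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

## Flatten a corpus to its on-disk record form (one row per note-section).
corpus_records <- function(corpus) {
  if (!length(corpus)) {
    return(data.frame(note_id = character(), patient_id = character(),
                      section = character(), text = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(corpus, function(note) {
    stopifnot(inherits(note, "clinical_note"))
    n <- nrow(note$sections)
    data.frame(
      note_id = rep(note$note_id, n),
      patient_id = rep(note$patient_id, n),
      section = note$sections$section,
      text = note$sections$text,
      stringsAsFactors = FALSE
    )
  }))
}

#' Default section-name patterns for the target note sections
#'
#' Inhaler-technique teaching is documented almost exclusively in the History
#' of Present Illness and Impression/Report/Plan sections, so those are the
#' shipped defaults.  Header spellings vary across EHRs; matching is
#' case-insensitive regular-expression search, and "Impression/Report/Plan"
#' is matched by any of its three parts.
#'
#' @return Character vector of regular expressions.
#' @export
default_section_patterns <- function() {
  c("history of present illness", "\\bhpi\\b",
    "impression", "report", "plan")
}

#' Keep only the target sections of a note
#'
#' @param note A `clinical_note`.
#' @param keep Character vector of section-name patterns (case-insensitive
#'   regular expressions); a section is kept if any pattern matches its name.
#' @return The note with only matching sections, original order preserved.  A
#'   note with zero matching sections is returned with an empty section list
#'   (and a message, so degenerate notes are visible in logs).
#' @export
filter_sections <- function(note, keep = default_section_patterns()) {
  stopifnot(inherits(note, "clinical_note"))
  if (!length(keep)) stop_("'keep' must be a non-empty character vector")
  hit <- vapply(note$sections$section, function(nm) {
    any(vapply(keep, function(p) grepl(p, nm, ignore.case = TRUE), logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  if (!any(hit)) {
    message("note '", note$note_id, "': no sections matched; returning empty note")
  }
  note$sections <- note$sections[hit, , drop = FALSE]
  rownames(note$sections) <- NULL
  note
}

#' @rdname filter_sections
#' @param corpus A list of `clinical_note` objects.
#' @export
filter_corpus_sections <- function(corpus, keep = default_section_patterns()) {
  lapply(corpus, filter_sections, keep = keep)
}

## Tokens before a period that do not end a sentence.  Clinical text is dense
## in dosing abbreviations; the list is configurable via segment_sentences().
default_abbreviations <- function() {
  c("dr", "mr", "mrs", "ms", "st", "vs", "etc", "approx",
    "b.i.d", "t.i.d", "q.i.d", "q.d", "p.r.n", "p.o", "i.e", "e.g",
    "yo", "y.o", "pt", "hx", "fu", "f.u")
}

#' Segment a note's sections into sentences
#'
#' Deterministic rule-based segmentation: sentences end at runs of `.!?`
#' followed by whitespace (or end of text), except after known clinical
#' abbreviations ("Dr.", "b.i.d.", ...).  Offsets are 0-based half-open into
#' the section text; sentence text is trimmed of surrounding whitespace.
#' `sentence_index` is 0-based and strictly increasing within the note,
#' continuing across sections.
#'
#' @param note A `clinical_note`.
#' @param abbreviations Lower-case tokens (without the final period) that do
#'   not terminate a sentence.
#' @return A `data.frame` with columns `note_id`, `patient_id`, `section`,
#'   `sentence_index`, `text`, `start`, `end`.  Empty sections yield zero
#'   rows.
#' @export
segment_sentences <- function(note, abbreviations = default_abbreviations()) {
  stopifnot(inherits(note, "clinical_note"))
  out <- list()
  idx <- 0L
  for (i in seq_len(nrow(note$sections))) {
    spans <- split_sentence_spans(note$sections$text[i], abbreviations)
    if (nrow(spans)) {
      spans$note_id <- note$note_id
      spans$patient_id <- note$patient_id
      spans$section <- note$sections$section[i]
      spans$sentence_index <- idx + seq_len(nrow(spans)) - 1L
      idx <- idx + nrow(spans)
      out[[length(out) + 1L]] <- spans
    }
  }
  if (!length(out)) {
    return(data.frame(note_id = character(), patient_id = character(),
                      section = character(), sentence_index = integer(),
                      text = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df[c("note_id", "patient_id", "section", "sentence_index",
       "text", "start", "end")]
}

#' @rdname segment_sentences
#' @param corpus A list of `clinical_note` objects.
#' @export
segment_corpus <- function(corpus, abbreviations = default_abbreviations()) {
  parts <- lapply(corpus, segment_sentences, abbreviations = abbreviations)
  df <- do.call(rbind, parts)
  if (is.null(df)) df <- segment_sentences(clinical_note("x", "x",
    data.frame(section = character(), text = character())))
  rownames(df) <- NULL
  df
}

## Core splitter: returns data.frame(text, start, end) with 0-based half-open
## offsets into `text`.
split_sentence_spans <- function(text, abbreviations) {
  empty <- data.frame(text = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(trimws(text))) return(empty)

  m <- gregexpr("[.!?]+(?=\\s|$)", text, perl = TRUE)[[1]]
  ends <- integer(0)  # 1-based index of last char of each sentence terminator
  if (m[1] != -1) {
    lens <- attr(m, "match.length")
    for (k in seq_along(m)) {
      pos <- m[k]
      before <- substr(text, 1, pos - 1L)
      # token immediately preceding the punctuation run
      has_tok <- grepl("[A-Za-z][A-Za-z.]*$", before, perl = TRUE)
      tok <- if (has_tok) {
        tolower(sub(".*?([A-Za-z][A-Za-z.]*)$", "\\1", before, perl = TRUE))
      } else ""
      is_abbrev <- has_tok && tok %in% abbreviations &&
        substr(text, pos, pos) == "."
      if (!is_abbrev) ends <- c(ends, pos + lens[k] - 1L)
    }
  }
  n <- nchar(text)
  if (!length(ends) || ends[length(ends)] < n) {
    # trailing fragment without terminator
    if (nzchar(trimws(substr(text, if (length(ends)) ends[length(ends)] + 1L else 1L, n)))) {
      ends <- c(ends, n)
    }
  }
  starts <- c(1L, ends[-length(ends)] + 1L)
  rows <- lapply(seq_along(ends), function(k) {
    s <- starts[k]; e <- ends[k]
    # trim whitespace, keeping offsets in step
    while (s <= e && grepl("^\\s$", substr(text, s, s))) s <- s + 1L
    while (e >= s && grepl("^\\s$", substr(text, e, e))) e <- e - 1L
    if (s > e) return(NULL)
    data.frame(text = substr(text, s, e), start = s - 1L, end = e,
               stringsAsFactors = FALSE)  # 0-based half-open
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}
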