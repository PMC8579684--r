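## Distant supervision: rule-generated weak labels over an unlabeled corpus,
## patient-level train/validation splitting, and the JSONL sentence dialect.
##
## Weak labels are exactly the rule engine's sentence decisions; they carry
## provenance "weak" so they can never be silently mixed with gold labels.

#' Weakly label a corpus with the rule engine
#'
#' Every sentence receives the label the combination rules assign it
#' (`present` iff any rule fires), with provenance `"weak"`.
#'
#' @param corpus Either a list of [clinical_note()] objects (section-filtered
#'   with [filter_corpus_sections()]; segmented internally) or an
#'   already-segmented sentence `data.frame` from [segment_corpus()].
#' @param lexicon A [keyword_lexicon()].
#' @param rules A [combination_rules()] object.
#' @param source_corpus_id Optional identifier recorded in the dataset.
#' @return An object of class `weak_dataset`: list with `items` (labeled
#'   sentence `data.frame`, provenance `"weak"`), `prevalence` (fraction of
#'   present labels; `NaN` for an empty corpus, never zero) and
#'   `source_corpus_id`.
#' @export
weak_label <- function(corpus, lexicon = keyword_lexicon(),
                       rules = combination_rules(),
                       source_corpus_id = NA_character_) {
  sentences <- if (is.data.frame(corpus)) corpus else segment_corpus(corpus)
  if (!nrow(sentences)) {
    items <- cbind(sentences,
                   data.frame(label = character(), provenance = character(),
                              stringsAsFactors = FALSE))
    return(structure(list(items = items, prevalence = NaN,
                          source_corpus_id = source_corpus_id),
                     class = "weak_dataset"))
  }
  matched <- vapply(sentences$text, function(txt) {
    evaluate_rules(txt, lexicon, rules)$matched
  }, logical(1), USE.NAMES = FALSE)
  items <- sentences
  items$label <- ifelse(matched, "present", "absent")
  items$provenance <- "weak"
  structure(list(items = items,
                 prevalence = mean(matched),
                 source_corpus_id = source_corpus_id),
            class = "weak_dataset")
}

#' @export
print.weak_dataset <- function(x, ...) {
  cat("<weak_dataset> ", nrow(x$items), " sentences, prevalence ",
      format(x$prevalence, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Split labeled sentences into train and validation sets
#'
#' With `unit = "patient"` (the default) whole patients are assigned to one
#' side, so no patient's sentences leak across the split; `unit =
#' "sentence"` splits rows directly.  The split is a deterministic function
#' of the seed, disjoint and exhaustive.
#'
#' @param dataset A `weak_dataset` or a labeled sentence `data.frame`.
#' @param validation_fraction Proportion in (0, 1) held out (the
#'   conventional validation cut is about 12%).
#' @param unit `"patient"` or `"sentence"`.
#' @param seed Integer seed.
#' @return List with `train` and `validation` sentence `data.frame`s.
#' @export
stratify_split <- function(dataset, validation_fraction = 0.12,
                           unit = c("patient", "sentence"), seed) {
  unit <- match.arg(unit)
  if (missing(seed) || !is_count(seed)) stop_("'seed' is mandatory (integer)")
  if (!is.numeric(validation_fraction) || validation_fraction <= 0 ||
      validation_fraction >= 1) {
    stop_("'validation_fraction' must lie strictly between 0 and 1")
  }
  items <- if (inherits(dataset, "weak_dataset")) dataset$items else dataset
  stopifnot(is.data.frame(items))
  if (unit == "patient") {
    pats <- unique(items$patient_id)
    if (length(pats) < 2L) {
      stop_("patient-level split needs at least 2 patients; got ",
            length(pats))
    }
    n_val <- round(validation_fraction * length(pats))
    n_val <- max(1L, min(length(pats) - 1L, n_val))
    val_pats <- with_seed(seed, sample(pats, n_val))
    in_val <- items$patient_id %in% val_pats
  } else {
    n <- nrow(items)
    if (n < 2L) stop_("sentence-level split needs at least 2 sentences")
    n_val <- max(1L, min(n - 1L, round(validation_fraction * n)))
    val_idx <- with_seed(seed, sample(n, n_val))
    in_val <- seq_len(n) %in% val_idx
  }
  list(train = items[!in_val, , drop = FALSE],
       validation = items[in_val, , drop = FALSE])
}

#' Read or write labeled sentences as JSONL
#'
#' One record per sentence: `{"note_id", "patient_id", "section",
#' "sentence_index", "text", "label", "provenance"}`, UTF-8.
#'
#' @param sentences A labeled sentence `data.frame`.
#' @param path File path.
#' @return The writer returns `path` invisibly; the reader returns the
#'   sentence `data.frame`.
#' @export
write_sentences <- function(sentences, path) {
  stopifnot(is.data.frame(sentences))
  cols <- intersect(c("note_id", "patient_id", "section", "sentence_index",
                      "text", "label", "provenance"), names(sentences))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(sentences))) {
    writeLines(jsonlite::toJSON(as.list(sentences[i, cols, drop = FALSE]),
                                auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_sentences
#' @export
read_sentences <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(note_id = character(), patient_id = character(),
                      section = character(), sentence_index = integer(),
                      text = character(), label = character(),
                      provenance = character(), stringsAsFactors = FALSE))
  }
  recs <- lapply(lines, function(l) {
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, recs)
  if ("sentence_index" %in% names(df)) {
    df$sentence_index <- as.integer(df$sentence_index)
  }
  rownames(df) <- NULL
  df
}
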