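## Document-level evaluation: existential aggregation of sentence labels and
## precision / recall / F1 / F2 / F0.5 / accuracy with "present" as the
## positive class.

#' Aggregate sentence labels to document labels
#'
#' A note is labeled `present` iff any of its sentences is labeled `present`
#' (existential OR); `absent` otherwise, including notes whose sentences are
#' all absent and notes contributing zero sentences elsewhere in the
#' pipeline.
#'
#' @param sentence_labels A `data.frame` with columns `note_id` and `label`
#'   (values `"present"`/`"absent"`).
#' @return Named character vector mapping `note_id` to `"present"` or
#'   `"absent"`, in first-appearance order.
#' @export
aggregate_document_labels <- function(sentence_labels) {
  stopifnot(is.data.frame(sentence_labels),
            all(c("note_id", "label") %in% names(sentence_labels)))
  bad <- setdiff(unique(sentence_labels$label), c("present", "absent"))
  if (length(bad)) stop_("unknown label(s): ", paste(bad, collapse = ", "))
  ids <- unique(sentence_labels$note_id)
  pres <- vapply(ids, function(id) {
    any(sentence_labels$label[sentence_labels$note_id == id] == "present")
  }, logical(1))
  stats::setNames(ifelse(pres, "present", "absent"), ids)
}

#' F-beta score
#'
#' `fbeta = (1 + beta^2) * P * R / (beta^2 * P + R)`.  `beta = 2` weighs
#' recall higher than precision (false negatives costlier); `beta = 0.5`
#' weighs precision higher (false positives costlier); `beta = 1` is the
#' harmonic mean.
#'
#' @param precision,recall Proportions in \[0, 1\]; vectorized.
#' @param beta Positive real.
#' @return The F-beta score; `NA` (with a warning) where precision and recall
#'   are both zero, for which the score is undefined.
#' @examples
#' fbeta(0.861, 0.815, 1)    # 0.837 to 3 decimals
#' fbeta(0.942, 0.868, 0.5)  # 0.926 to 3 decimals
#' @export
fbeta <- function(precision, recall, beta = 1) {
  stopifnot(is.numeric(beta), length(beta) == 1L, beta > 0)
  if (any(precision < 0 | precision > 1 | recall < 0 | recall > 1, na.rm = TRUE)) {
    stop_("precision and recall must lie in [0, 1]")
  }
  num <- (1 + beta^2) * precision * recall
  den <- beta^2 * precision + recall
  out <- ifelse(den == 0, NA_real_, num / den)
  if (any(den == 0, na.rm = TRUE)) {
    warning("F-beta undefined where precision and recall are both zero; ",
            "returning NA", call. = FALSE)
  }
  out
}

#' Compare predicted and gold document labels
#'
#' Computes the document-level confusion matrix (positive class `present`)
#' and precision, recall, F1, F2, F0.5 and accuracy.  Ratios with zero
#' denominators (e.g. precision under an all-absent predictor) are reported
#' as `NA`, never silently as zero.
#'
#' @param predicted_docs,gold_docs Named character vectors as returned by
#'   [aggregate_document_labels()]; the two must cover the same `note_id`
#'   key set.
#' @return An object of class `metrics_report`: list with integer fields
#'   `tp`, `fp`, `fn`, `tn` and numeric fields `precision`, `recall`, `f1`,
#'   `f2`, `f0_5`, `accuracy` (full precision; printing rounds half-up to 3
#'   decimals).
#' @export
evaluate <- function(predicted_docs, gold_docs) {
  if (is.null(names(predicted_docs)) || is.null(names(gold_docs))) {
    stop_("document label vectors must be named by note_id")
  }
  miss_p <- setdiff(names(gold_docs), names(predicted_docs))
  miss_g <- setdiff(names(predicted_docs), names(gold_docs))
  if (length(miss_p) || length(miss_g)) {
    stop_("note_id mismatch; missing from predictions: ",
          paste(miss_p, collapse = ", "),
          "; missing from gold: ", paste(miss_g, collapse = ", "))
  }
  p <- predicted_docs[names(gold_docs)] == "present"
  g <- gold_docs == "present"
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g); tn <- sum(!p & !g)
  metrics_report(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' @rdname evaluate
#' @param tp,fp,fn,tn Confusion counts, for building a report directly.
#' @export
metrics_report <- function(tp, fp, fn, tn) {
  stopifnot(is_count(tp), is_count(fp), is_count(fn), is_count(tn))
  total <- tp + fp + fn + tn
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  f <- function(beta) {
    if (is.na(precision) || is.na(recall) ||
        (precision == 0 && recall == 0)) NA_real_
    else suppressWarnings(fbeta(precision, recall, beta))
  }
  structure(list(
    tp = as.integer(tp), fp = as.integer(fp),
    fn = as.integer(fn), tn = as.integer(tn),
    precision = precision, recall = recall,
    f1 = f(1), f2 = f(2), f0_5 = f(0.5),
    accuracy = ratio(tp + tn, total)
  ), class = "metrics_report")
}

## round-half-up, matching how results tables are conventionally printed
round_half_up <- function(x, digits = 3) {
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

fmt3 <- function(x) {
  ifelse(is.na(x), "   NA", sprintf("%.3f", round_half_up(x, 3)))
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>  documents:", x$tp + x$fp + x$fn + x$tn, "\n")
  cat(sprintf("  confusion  tp=%d fp=%d fn=%d tn=%d\n", x$tp, x$fp, x$fn, x$tn))
  cat("  precision recall f1    f2    f0.5  accuracy\n")
  cat(" ", fmt3(x$precision), "   ", fmt3(x$recall), fmt3(x$f1), fmt3(x$f2),
      fmt3(x$f0_5), fmt3(x$accuracy), "\n")
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn,
             precision = x$precision, recall = x$recall,
             f1 = x$f1, f2 = x$f2, f0_5 = x$f0_5, accuracy = x$accuracy)
}

#' Aligned comparison table for several models
#'
#' @param reports Named list of `metrics_report` objects (names are model
#'   labels).
#' @return A character vector of aligned lines (printed columns: model,
#'   precision, recall, F1, F2, F0.5, accuracy), invisibly; also printed.
#' @export
metrics_table <- function(reports) {
  stopifnot(is.list(reports), !is.null(names(reports)))
  w <- max(nchar(names(reports)), nchar("Model"))
  hdr <- sprintf("%-*s  Precision  Recall  F1     F2     F0.5   Accuracy",
                 w, "Model")
  lines <- c(hdr, vapply(names(reports), function(nm) {
    r <- reports[[nm]]
    sprintf("%-*s  %s      %s  %s  %s  %s  %s", w, nm,
            fmt3(r$precision), fmt3(r$recall), fmt3(r$f1), fmt3(r$f2),
            fmt3(r$f0_5), fmt3(r$accuracy))
  }, character(1), USE.NAMES = FALSE))
  cat(lines, sep = "\n")
  cat("\n")
  invisible(lines)
}

#' Published document-level benchmark scores
#'
#' The document-level precision/recall/F-score/accuracy table reported for
#' the seven models (rules, two fine-tuned encoders, their
#' distant-supervision variants, and the two hybrids) on the original
#' clinical corpus.  That corpus is protected health information and cannot
#' be redistributed, so these scores are shipped only for arithmetic
#' consistency checking: each row's printed F1/F2/F0.5 must be recovered by
#' [fbeta()] from its printed precision and recall.
#'
#' @return A `data.frame` with columns `model`, `precision`, `recall`, `f1`,
#'   `f2`, `f0_5`, `accuracy`.
#' @export
benchmark_metrics <- function() {
  utils::read.csv(system.file("extdata", "benchmark_metrics.csv",
                              package = "inhalertech", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Serialize a metrics report to JSON
#'
#' @param x A `metrics_report`.
#' @param path Optional file path; if omitted, the JSON string is returned.
#' @export
metrics_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "metrics_report"))
  json <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA,
                           na = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}
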