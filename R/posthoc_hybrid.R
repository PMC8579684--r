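## Post-hoc rule correction of classifier predictions (hybrid model).
##
## Two families of overrides are applied to the sentence labels a trained
## classifier emits:
##   N2P  patterns applied to model-negative sentences; a match overwrites
##        the label to present (the model missed an explicit description).
##   P2N  a trigger pattern plus a blocking term, applied to model-positive
##        sentences; trigger present and blocker absent overwrites the label
##        to absent (e.g. "discussed ..." without any mention of technique
##        is usually not technique teaching).
## Overrides act once, against the original model label -- a flipped label is
## never re-examined (no chaining).

#' The post-hoc override rule set
#'
#' The shipped defaults are the deployed override patterns, stored verbatim:
#' one N2P regex requiring a teaching verb followed by "use of" a delivery
#' device, and one P2N rule triggered by "discussed"/"discussion" with
#' blocking term "technique".  All matching is case-insensitive.
#'
#' @param n2p Character vector of regular expressions applied to
#'   model-absent sentences.
#' @param p2n List of `list(trigger = <regex>, blocker = <term>)` applied to
#'   model-present sentences.
#' @param blocker_mode `"stem"` (default): the blocker matches the stem
#'   "techni" at a word start, covering "technique"/"techniques";
#'   `"exact"`: the blocker must match as an exact word.
#' @return An object of class `posthoc_rules`.
#' @export
posthoc_rules <- function(
    n2p = "(instructed|reviewed|discussed).*(use\\sof\\sMDI|use\\sof\\sspacer|use\\sof\\snebulizer|use\\sof\\sinhaler)",
    p2n = list(list(trigger = "(discussed|discussion)", blocker = "technique")),
    blocker_mode = c("stem", "exact")) {
  blocker_mode <- match.arg(blocker_mode)
  n2p <- as.character(n2p)
  for (p in n2p) validate_regex(p)
  if (!is.list(p2n)) stop_("'p2n' must be a list of trigger/blocker pairs")
  for (r in p2n) {
    if (is.null(r$trigger) || is.null(r$blocker)) {
      stop_("each p2n rule needs 'trigger' and 'blocker'")
    }
    validate_regex(r$trigger)
  }
  structure(list(n2p = n2p, p2n = p2n, blocker_mode = blocker_mode),
            class = "posthoc_rules")
}

validate_regex <- function(pattern) {
  ok <- tryCatch({ grepl(pattern, "", perl = TRUE); TRUE },
                 error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok) stop_("malformed pattern: ", pattern)
  invisible(pattern)
}

#' @export
print.posthoc_rules <- function(x, ...) {
  cat("<posthoc_rules>\n")
  for (p in x$n2p) cat("  N2P: ", p, "\n", sep = "")
  for (r in x$p2n) {
    cat("  P2N: ", r$trigger, "  AND no indication of \"", r$blocker, "\"\n",
        sep = "")
  }
  invisible(x)
}

blocker_present <- function(blocker, text, mode) {
  if (mode == "stem" && identical(tolower(blocker), "technique")) {
    # stem match at a word start covers technique/techniques
    return(grepl("\\btechni", text, ignore.case = TRUE, perl = TRUE))
  }
  pat <- if (mode == "exact") paste0("\\b", blocker, "\\b") else
    paste0("\\b", blocker)
  grepl(pat, text, ignore.case = TRUE, perl = TRUE)
}

#' Apply a negative-to-positive override to one sentence
#'
#' If the model label is `absent` and any N2P pattern matches
#' (case-insensitively), the label is overwritten to `present`; otherwise it
#' is returned unchanged.  N2P never fires on model-positive sentences.
#'
#' @param sentence_text The sentence.
#' @param model_label `"present"` or `"absent"` (the classifier's label).
#' @param ruleset A [posthoc_rules()] object.
#' @return The (possibly overwritten) label.
#' @export
apply_n2p <- function(sentence_text, model_label, ruleset = posthoc_rules()) {
  stopifnot(inherits(ruleset, "posthoc_rules"),
            model_label %in% c("present", "absent"))
  if (model_label != "absent") return(model_label)
  for (p in ruleset$n2p) {
    if (grepl(p, sentence_text, ignore.case = TRUE, perl = TRUE)) {
      return("present")
    }
  }
  model_label
}

#' Apply a positive-to-negative override to one sentence
#'
#' If the model label is `present`, a P2N trigger matches, and the rule's
#' blocking term is absent from the sentence (case-insensitively), the label
#' is overwritten to `absent`; otherwise it is returned unchanged.
#'
#' @inheritParams apply_n2p
#' @return The (possibly overwritten) label.
#' @export
apply_p2n <- function(sentence_text, model_label, ruleset = posthoc_rules()) {
  stopifnot(inherits(ruleset, "posthoc_rules"),
            model_label %in% c("present", "absent"))
  if (model_label != "present") return(model_label)
  for (r in ruleset$p2n) {
    if (grepl(r$trigger, sentence_text, ignore.case = TRUE, perl = TRUE) &&
        !blocker_present(r$blocker, sentence_text, ruleset$blocker_mode)) {
      return("absent")
    }
  }
  model_label
}

#' Apply the post-hoc overrides to a batch of model predictions
#'
#' Single pass over the predictions: N2P rules are evaluated on model-absent
#' sentences and P2N rules on model-present sentences, always against the
#' ORIGINAL model label; a flipped label is not re-examined, so the operation
#' is idempotent.  Rows whose provenance is already `"hybrid"` pass through
#' unchanged.  Every flip is recorded (sentence row, direction, firing
#' pattern) in the `"flips"` attribute of the result.
#'
#' @param predictions A `data.frame` of labeled sentences with columns
#'   `text`, `label` and `provenance` (`"model"`, or `"hybrid"` for already
#'   corrected rows).
#' @param ruleset A [posthoc_rules()] object.
#' @return The predictions with corrected `label` and provenance `"hybrid"`;
#'   attribute `"flips"` is a `data.frame(row, direction, pattern)`.
#' @export
hybridize <- function(predictions, ruleset = posthoc_rules()) {
  stopifnot(is.data.frame(predictions),
            all(c("text", "label", "provenance") %in% names(predictions)) ||
              nrow(predictions) == 0L)
  if (nrow(predictions) == 0L) {
    out <- predictions
    attr(out, "flips") <- data.frame(row = integer(), direction = character(),
                                     pattern = character(),
                                     stringsAsFactors = FALSE)
    return(out)
  }
  bad <- setdiff(unique(predictions$provenance), c("model", "hybrid"))
  if (length(bad)) {
    stop_("hybridize() expects model (or already-hybrid) predictions; got ",
          "provenance: ", paste(bad, collapse = ", "))
  }
  out <- predictions
  flips <- list()
  for (i in seq_len(nrow(predictions))) {
    if (predictions$provenance[i] != "model") next  # already corrected
    lab <- predictions$label[i]
    txt <- predictions$text[i]
    if (lab == "absent") {
      for (p in ruleset$n2p) {
        if (grepl(p, txt, ignore.case = TRUE, perl = TRUE)) {
          out$label[i] <- "present"
          flips[[length(flips) + 1L]] <-
            data.frame(row = i, direction = "N2P", pattern = p,
                       stringsAsFactors = FALSE)
          break
        }
      }
    } else {
      for (r in ruleset$p2n) {
        if (grepl(r$trigger, txt, ignore.case = TRUE, perl = TRUE) &&
            !blocker_present(r$blocker, txt, ruleset$blocker_mode)) {
          out$label[i] <- "absent"
          flips[[length(flips) + 1L]] <-
            data.frame(row = i, direction = "P2N", pattern = r$trigger,
                       stringsAsFactors = FALSE)
          break
        }
      }
    }
  }
  out$provenance <- "hybrid"
  attr(out, "flips") <- if (length(flips)) do.call(rbind, flips) else
    data.frame(row = integer(), direction = character(),
               pattern = character(), stringsAsFactors = FALSE)
  out
}

#' Read or write a post-hoc rule configuration
#'
#' YAML with an `n2p:` pattern list and a `p2n:` list of trigger/blocker
#' mappings.  Writing the shipped default reproduces its pattern strings
#' character for character.
#'
#' @param path File path.
#' @return For the reader, a [posthoc_rules()] object; for the writer,
#'   `path` invisibly.
#' @export
read_posthoc_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  posthoc_rules(
    n2p = as.character(cfg$n2p %||% character()),
    p2n = lapply(cfg$p2n %||% list(), function(r) {
      list(trigger = r$trigger, blocker = r$blocker)
    }),
    blocker_mode = cfg$blocker_mode %||% "stem"
  )
}

#' @rdname read_posthoc_config
#' @param ruleset A [posthoc_rules()] object.
#' @export
write_posthoc_config <- function(ruleset, path) {
  stopifnot(inherits(ruleset, "posthoc_rules"))
  yaml::write_yaml(list(
    n2p = as.list(ruleset$n2p),
    p2n = lapply(ruleset$p2n, function(r) {
      list(trigger = r$trigger, blocker = r$blocker)
    }),
    blocker_mode = ruleset$blocker_mode
  ), path)
  invisible(path)
}
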