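## Synthetic clinical-note generator.
##
## Real notes documenting inhaler-technique review are protected health
## information, so every pipeline stage is exercised on generated corpora
## that reproduce the statistical structure the pipeline assumes: two
## retained sections per note, a tiny sentence-level positive prevalence
## (0.4% train / 0.56% test / 0.124% distant-supervision), positives split
## into explicit (keyword-bearing, rule-matchable) and implicit (no teaching
## keyword) kinds, and hard negatives (keyword-bearing sentences that do not
## describe technique teaching, i.e. rule false positives by construction).

#' The shipped sentence template bank
#'
#' Templates carry their gold label and kind.  `{name}` and `{device}` slots
#' are filled at generation time.  The bank is validated on construction by
#' running the rule engine over every instantiation: explicit positives must
#' fire the combination rules, implicit positives and filler must not, and
#' hard negatives must fire (that is what makes them hard).
#'
#' @param validate Run the rule-engine validation (default `TRUE`).
#' @return An object of class `template_bank`.
#' @export
template_bank <- function(validate = TRUE) {
  bank <- structure(list(
    explicit_positive = c(
      "Discussed correct inhaler technique",
      "Reviewed {device} use with the patient",
      "{name} received asthma education and instruction in appropriate metered-dose inhaler technique",
      "Demonstrated proper use of the {device} and observed a return demonstration",
      "Provided instruction on use of the {device} at today's visit",
      "Taught {name} how to use the {device} with a spacer",
      "Reinforced spacer use and checked {name}'s technique",
      "We will teach daily medication techniques at each follow up",
      "Checked inhaler technique which was adequate",
      "Educated mom on proper {device} technique"
    ),
    implicit_positive = c(
      "Mom voices no concerns about his technique in using the inhaler",
      "{name} was also aided with an appropriate sized mask, and instructed",
      "I also did some training today regarding the use of albuterol with a spacer",
      "{name} is using a mask and a spacer appropriately",
      "She is comfortable with her spacer technique",
      "Our nurse went in before me and checked on his technique and compliance"
    ),
    hard_negative = c(
      "Discussed 3rd neb treatment here versus one upon home",
      "We reviewed her medications and discussed labeling the Flovent with a green sticker for a daily inhaler",
      "Checked the refill history for her rescue inhaler",
      "Reviewed that the nebulizer was delivered by the equipment company"
    ),
    filler = c(
      "Lungs clear to auscultation bilaterally",
      "{name} presents for follow up of asthma",
      "No wheezing or retractions on exam today",
      "Continue current medications as prescribed",
      "Mother reports improved symptom control over the past month",
      "Return to clinic in 3 months or sooner if symptoms worsen",
      "Denies fever, cough, or shortness of breath",
      "Plan to repeat spirometry at the next visit",
      "Weight and height are tracking along the 50th percentile",
      "Sleep is undisturbed and activity level is normal"
    ),
    slots = list(
      name = c("Alex", "Jordan", "Sam", "Riley", "Morgan", "Casey"),
      device = c("inhaler", "spacer", "nebulizer", "MDI")
    )
  ), class = "template_bank")
  if (validate) validate_template_bank(bank)
  bank
}

## Every instantiation of a template (one slot value at a time).
template_instances <- function(template, slots) {
  out <- template
  for (slot in names(slots)) {
    tag <- paste0("{", slot, "}")
    hit <- grepl(tag, out, fixed = TRUE)
    if (any(hit)) {
      out <- c(out[!hit], unlist(lapply(out[hit], function(t) {
        vapply(slots[[slot]], function(v) gsub(tag, v, t, fixed = TRUE),
               character(1))
      })))
    }
  }
  out
}

#' Validate a template bank against the rule engine
#'
#' @param bank A `template_bank`.
#' @param lexicon,rules Rule system used for validation.
#' @return `bank`, invisibly; errors describe the offending template.
#' @export
validate_template_bank <- function(bank, lexicon = keyword_lexicon(),
                                   rules = combination_rules()) {
  stopifnot(inherits(bank, "template_bank"))
  fires <- function(text) evaluate_rules(text, lexicon, rules)$matched
  check <- function(kind, want_fire) {
    for (tpl in bank[[kind]]) {
      for (txt in template_instances(tpl, bank$slots)) {
        if (fires(txt) != want_fire) {
          stop_(kind, " template ", if (want_fire) "must" else "must not",
                " fire the rules: \"", txt, "\"")
        }
      }
    }
  }
  check("explicit_positive", TRUE)
  check("implicit_positive", FALSE)
  check("hard_negative", TRUE)
  check("filler", FALSE)
  invisible(bank)
}

#' @export
print.template_bank <- function(x, ...) {
  cat("<template_bank>",
      length(x$explicit_positive), "explicit-positive,",
      length(x$implicit_positive), "implicit-positive,",
      length(x$hard_negative), "hard-negative,",
      length(x$filler), "filler templates\n")
  invisible(x)
}

#' Configuration for a synthetic corpus
#'
#' The positive sentence rates of the shipped profiles are the prevalences
#' the pipeline is designed around: 0.4% for a gold training corpus, 0.56%
#' for a gold test corpus, and 0.124% for a large distant-supervision
#' corpus.  Positives are placed with exact-count rounding (not Bernoulli
#' draws) by default so tiny prevalences are testable at desk scale.
#'
#' @param n_patients Number of patients.
#' @param notes_per_patient Integer range `c(lo, hi)` sampled uniformly.
#' @param sentences_per_note Integer range `c(lo, hi)` sampled uniformly.
#' @param positive_sentence_rate Proportion of sentences that are gold
#'   positive.
#' @param implicit_fraction Fraction of positives drawn from implicit
#'   (non-rule-matchable) templates; `0` makes the corpus fully separable by
#'   rules.  Defaults to 0.25 for the gold profiles and 0 for the
#'   `"distant"` profile (a weak-labeling corpus is summarized by its
#'   rule-matchable positives, so its nominal prevalence is the rule-label
#'   prevalence).
#' @param hard_negative_rate Fraction of negative sentences drawn from
#'   keyword-bearing hard-negative templates.  Defaults to 0.02 for the
#'   gold profiles and 0 for the `"distant"` profile.
#' @param placement `"exact"` (round to an exact positive count) or
#'   `"bernoulli"` (independent draws).
#' @param seed Mandatory integer seed; generation is a pure function of the
#'   configuration.
#' @param profile Convenience: `"train"`, `"test"` or `"distant"` fills
#'   `positive_sentence_rate` with 0.004, 0.0056 or 0.00124 respectively
#'   when the rate is not given explicitly.
#' @return An object of class `synthetic_corpus_config`.
#' @export
synthetic_corpus_config <- function(n_patients = 50,
                                    notes_per_patient = c(1L, 4L),
                                    sentences_per_note = c(8L, 20L),
                                    positive_sentence_rate = NULL,
                                    implicit_fraction = NULL,
                                    hard_negative_rate = NULL,
                                    placement = c("exact", "bernoulli"),
                                    seed,
                                    profile = c("train", "test", "distant")) {
  placement <- match.arg(placement)
  profile <- match.arg(profile)
  if (missing(seed) || !is_count(seed)) stop_("'seed' is mandatory (integer)")
  if (is.null(positive_sentence_rate)) {
    positive_sentence_rate <- switch(profile,
      train = 0.004, test = 0.0056, distant = 0.00124)
  }
  if (is.null(implicit_fraction)) {
    implicit_fraction <- if (profile == "distant") 0 else 0.25
  }
  if (is.null(hard_negative_rate)) {
    hard_negative_rate <- if (profile == "distant") 0 else 0.02
  }
  if (!is_count(n_patients) || n_patients < 1) stop_("invalid 'n_patients'")
  rng_ok <- function(r) length(r) == 2 && all(r >= 1) && r[1] <= r[2]
  if (!rng_ok(notes_per_patient) || !rng_ok(sentences_per_note)) {
    stop_("ranges must be c(lo, hi) with 1 <= lo <= hi")
  }
  if (!is_prob(positive_sentence_rate) || !is_prob(implicit_fraction) ||
      !is_prob(hard_negative_rate)) {
    stop_("rates must lie in [0, 1]")
  }
  structure(list(
    n_patients = as.integer(n_patients),
    notes_per_patient = as.integer(notes_per_patient),
    sentences_per_note = as.integer(sentences_per_note),
    positive_sentence_rate = positive_sentence_rate,
    implicit_fraction = implicit_fraction,
    hard_negative_rate = hard_negative_rate,
    placement = placement,
    seed = as.integer(seed),
    profile = profile
  ), class = "synthetic_corpus_config")
}

sample_int_range <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Generate a synthetic note corpus with gold labels
#'
#' Notes carry the two target sections (History of Present Illness and
#' Impression/Report/Plan); each note's sentences are split between them.
#' Positive sentences are placed at the configured rate (exact-count
#' rounding by default) and drawn from explicit or implicit templates per
#' `implicit_fraction`; hard negatives replace a fraction of the remaining
#' filler.  Gold labels are emitted at sentence and document level, the
#' document gold being the existential OR of its sentence gold.  Output is a
#' deterministic function of the configuration (same seed, byte-identical
#' corpus).
#'
#' @param config A [synthetic_corpus_config()].
#' @param bank A [template_bank()].
#' @return A list of class `synthetic_corpus`:
#'   * `corpus` -- list of [clinical_note()] objects;
#'   * `sentences` -- gold sentence `data.frame` (`note_id`, `patient_id`,
#'     `section`, `sentence_index`, `text`, `label`, `kind`,
#'     `provenance = "gold"`);
#'   * `documents` -- named gold document-label vector;
#'   * `config` -- the configuration used.
#' @export
generate_corpus <- function(config, bank = template_bank()) {
  stopifnot(inherits(config, "synthetic_corpus_config"),
            inherits(bank, "template_bank"))
  with_seed(config$seed, generate_corpus_impl(config, bank))
}

generate_corpus_impl <- function(config, bank) {
  pids <- sprintf("P%04d", seq_len(config$n_patients))
  notes_per <- sample_int_range(config$n_patients, config$notes_per_patient)
  n_notes <- sum(notes_per)
  note_pid <- rep(pids, notes_per)
  note_ids <- sprintf("N%06d", seq_len(n_notes))
  sents_per <- sample_int_range(n_notes, config$sentences_per_note)
  S <- sum(sents_per)

  # choose gold-positive sentence slots
  if (config$placement == "exact") {
    n_pos <- round(config$positive_sentence_rate * S)
  } else {
    n_pos <- sum(stats::runif(S) < config$positive_sentence_rate)
  }
  if (n_pos > S) stop_("infeasible config: more positives than sentences")
  pos_slots <- if (n_pos > 0) sample(S, n_pos) else integer(0)
  n_implicit <- round(config$implicit_fraction * n_pos)
  implicit_slots <- if (n_implicit > 0) pos_slots[seq_len(n_implicit)] else integer(0)

  neg_slots <- setdiff(seq_len(S), pos_slots)
  n_hard <- round(config$hard_negative_rate * length(neg_slots))
  if (n_hard > length(neg_slots)) stop_("infeasible config: hard-negative rate")
  hard_slots <- if (n_hard > 0) sample(neg_slots, n_hard) else integer(0)

  kind <- rep("filler", S)
  kind[pos_slots] <- "explicit_positive"
  kind[implicit_slots] <- "implicit_positive"
  kind[hard_slots] <- "hard_negative"

  fill_slots <- function(text) {
    for (slot in names(bank$slots)) {
      tag <- paste0("{", slot, "}")
      while (grepl(tag, text, fixed = TRUE)) {
        text <- sub(tag, sample(bank$slots[[slot]], 1), text, fixed = TRUE)
      }
    }
    text
  }
  texts <- vapply(kind, function(k) {
    fill_slots(sample(bank[[k]], 1))
  }, character(1), USE.NAMES = FALSE)

  label <- ifelse(kind %in% c("explicit_positive", "implicit_positive"),
                  "present", "absent")

  # assemble notes: sentences split between the two target sections
  corpus <- vector("list", n_notes)
  sent_rows <- vector("list", n_notes)
  offset <- 0L
  for (i in seq_len(n_notes)) {
    n_i <- sents_per[i]
    idx <- offset + seq_len(n_i)
    offset <- offset + n_i
    n_hpi <- if (n_i == 1L) sample(0:1, 1) else sample(seq(1L, n_i - 1L), 1)
    secs <- c(rep("History of Present Illness", n_hpi),
              rep("Impression/Report/Plan", n_i - n_hpi))
    sec_text <- vapply(split(texts[idx], factor(secs,
        levels = c("History of Present Illness", "Impression/Report/Plan"))),
      function(v) if (length(v)) paste0(paste(v, collapse = ". "), ".") else "",
      character(1))
    corpus[[i]] <- clinical_note(note_ids[i], note_pid[i],
      data.frame(section = c("History of Present Illness",
                             "Impression/Report/Plan"),
                 text = unname(sec_text), stringsAsFactors = FALSE))
    sent_rows[[i]] <- data.frame(
      note_id = note_ids[i], patient_id = note_pid[i], section = secs,
      sentence_index = seq_len(n_i) - 1L, text = texts[idx],
      label = label[idx], kind = kind[idx], provenance = "gold",
      stringsAsFactors = FALSE)
  }
  sentences <- do.call(rbind, sent_rows)
  rownames(sentences) <- NULL
  documents <- aggregate_document_labels(sentences)

  structure(list(corpus = corpus, sentences = sentences,
                 documents = documents, config = config),
            class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  print(corpus_report(x))
  invisible(x)
}

#' Summarize a generated corpus against its gold labels
#'
#' @param x A `synthetic_corpus` (from [generate_corpus()]).
#' @return An object of class `corpus_report`: counts of patients, notes and
#'   sentences, sentence/document positive counts and prevalences, and
#'   per-kind sentence counts.
#' @export
corpus_report <- function(x) {
  stopifnot(inherits(x, "synthetic_corpus"))
  s <- x$sentences
  n_sent <- nrow(s)
  n_pos <- sum(s$label == "present")
  structure(list(
    n_patients = length(unique(s$patient_id)),
    n_notes = length(x$corpus),
    n_sentences = n_sent,
    n_positive_sentences = n_pos,
    sentence_prevalence = if (n_sent) n_pos / n_sent else NaN,
    n_positive_documents = sum(x$documents == "present"),
    document_prevalence = if (length(x$documents))
      mean(x$documents == "present") else NaN,
    kind_counts = table(factor(s$kind, levels = c(
      "explicit_positive", "implicit_positive", "hard_negative", "filler")))
  ), class = "corpus_report")
}

#' @export
print.corpus_report <- function(x, ...) {
  cat("<corpus_report>\n")
  cat(sprintf("  patients %d  notes %d  sentences %d\n",
              x$n_patients, x$n_notes, x$n_sentences))
  cat(sprintf("  positive sentences %d (prevalence %.5f)\n",
              x$n_positive_sentences, x$sentence_prevalence))
  cat(sprintf("  positive documents %d (prevalence %.4f)\n",
              x$n_positive_documents, x$document_prevalence))
  cat("  kinds:", paste(names(x$kind_counts), as.integer(x$kind_counts),
                        sep = "=", collapse = "  "), "\n")
  invisible(x)
}
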