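## Keyword-combination rule engine for inhaler-technique documentation.
##
## Four keyword groups and two combination rules classify a sentence as
## describing the teaching or review of inhaler technique:
##   group 1  action/teaching verbs (review*, discuss*, teach*, ...)
##   group 2  delivery devices (inhaler, MDI, neb, nebulizer, ...)
##   group 3  manner nouns (techniques, administrations, dosing, guidance)
##   group 4  medication classes (asthma/rescue/daily/... medication, ICS, ...)
## Rule (a) fires when groups 1 and 2 co-occur in a sentence; rule (b) when
## groups 1, 3 and 4 co-occur.  A trailing asterisk on a keyword means prefix
## matching (match any characters after the stem).

#' The default keyword lexicon
#'
#' Returns the shipped lexicon of four keyword groups.  Entries are stored
#' verbatim; expansion (slash alternatives, optional singular stems for the
#' plural-only group-3 entries) happens at match time.
#'
#' @param strict_plural If `FALSE` (default) the group-3 entries "techniques"
#'   and "administrations" also match their singular forms via the stems
#'   `technique*` / `administration*`; if `TRUE` only the literal plurals
#'   match.
#' @return An object of class `keyword_lexicon`: a list with element `groups`
#'   (list of four character vectors, names `"1"`..`"4"`) and the
#'   `strict_plural` flag.
#' @export
keyword_lexicon <- function(strict_plural = FALSE) {
  groups <- list(
    "1" = c("observ*", "reassess*", "review*", "demonstrat*", "check*",
            "educat*", "teach*", "taught", "explain*", "reinforce*",
            "discuss*", "instruction", "constraints", "how to use"),
    "2" = c("inhaler", "MDI", "neb", "nebulizer", "optichamber", "spacer"),
    "3" = c("techniques", "administrations", "dosing", "guidance"),
    "4" = c("asthma/rescue/daily/preventive/control medication", "ICS",
            "list of maintenance and rescue medications")
  )
  new_keyword_lexicon(groups, strict_plural)
}

new_keyword_lexicon <- function(groups, strict_plural = FALSE) {
  if (!is.list(groups) || length(groups) < 1L ||
      any(!vapply(groups, is.character, logical(1))) ||
      any(vapply(groups, length, integer(1)) == 0L)) {
    stop_("'groups' must be a list of non-empty character vectors")
  }
  if (is.null(names(groups))) names(groups) <- as.character(seq_along(groups))
  structure(list(groups = groups, strict_plural = isTRUE(strict_plural)),
            class = "keyword_lexicon")
}

#' @export
print.keyword_lexicon <- function(x, ...) {
  cat("<keyword_lexicon> ", length(x$groups), " groups",
      if (x$strict_plural) " (strict plurals)", "\n", sep = "")
  for (g in names(x$groups)) {
    cat("  [", g, "] ", paste(x$groups[[g]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' The default combination rules
#'
#' Rule `a` requires keyword groups 1 and 2; rule `b` requires groups 1, 3
#' and 4.  A rule fires when every required group has at least one keyword
#' match anywhere in the sentence (order-free co-occurrence).
#'
#' @return An object of class `combination_rules`: a named list mapping
#'   rule id to the integer vector of required group ids.
#' @export
combination_rules <- function() {
  new_combination_rules(list(a = c(1L, 2L), b = c(1L, 3L, 4L)))
}

new_combination_rules <- function(rules) {
  if (!is.list(rules) || is.null(names(rules)) || any(!nzchar(names(rules)))) {
    stop_("'rules' must be a named list of group-id vectors")
  }
  rules <- lapply(rules, function(g) {
    g <- as.integer(g)
    if (!length(g) || anyNA(g)) stop_("each rule needs >= 1 group id")
    g
  })
  structure(rules, class = "combination_rules")
}

#' @export
print.combination_rules <- function(x, ...) {
  cat("<combination_rules>\n")
  for (id in names(x)) {
    cat("  (", id, ") groups {", paste(unclass(x)[[id]], collapse = ", "),
        "}\n", sep = "")
  }
  invisible(x)
}

## ---- matching primitives ---------------------------------------------------

## Sentence tokens: lower-cased alphanumeric runs.  Hyphens and slashes are
## boundaries, so "metered-dose inhaler" yields a token "inhaler".
tokenize_words <- function(text) {
  regmatches(tolower(text), gregexpr("[a-z0-9]+", tolower(text)))[[1]]
}

## Expand a raw lexicon entry into one or more matchable forms.  Each form is
## either a token-sequence pattern (list of words, each possibly a prefix
## stem) or a co-occurrence set of such patterns that must all be present.
expand_entry <- function(entry, strict_plural = FALSE) {
  if (!strict_plural && entry %in% c("techniques", "administrations")) {
    entry <- paste0(sub("s$", "", entry), "*")
  }
  if (entry == "list of maintenance and rescue medications") {
    # interpreted as the stems maintenance + rescue + medication* co-occurring
    return(list(list(type = "cooccur",
                     parts = list(list("maintenance"), list("rescue"),
                                  list("medication*")))))
  }
  if (grepl("/", entry, fixed = TRUE)) {
    # slash alternatives share the trailing word(s):
    # "asthma/rescue/daily/preventive/control medication"
    words <- strsplit(entry, "\\s+")[[1]]
    alts <- strsplit(words[1], "/", fixed = TRUE)[[1]]
    rest <- words[-1]
    return(lapply(alts, function(a) {
      list(type = "seq", words = c(a, rest))
    }))
  }
  list(list(type = "seq", words = strsplit(entry, "\\s+")[[1]]))
}

## Does the token-sequence pattern occur contiguously in `tokens`?  Returns
## the matched surface string or NA.
match_seq <- function(words, tokens) {
  words <- tolower(words)
  n <- length(words); m <- length(tokens)
  if (m < n) return(NA_character_)
  prefix <- grepl("\\*$", words)
  stems <- sub("\\*$", "", words)
  for (s in seq_len(m - n + 1L)) {
    ok <- TRUE
    for (j in seq_len(n)) {
      tok <- tokens[s + j - 1L]
      if (prefix[j]) {
        if (!startsWith(tok, stems[j])) { ok <- FALSE; break }
      } else if (tok != stems[j]) { ok <- FALSE; break }
    }
    if (ok) return(paste(tokens[s:(s + n - 1L)], collapse = " "))
  }
  NA_character_
}

match_entry_tokens <- function(entry, tokens, strict_plural = FALSE) {
  for (form in expand_entry(entry, strict_plural)) {
    if (form$type == "seq") {
      hit <- match_seq(form$words, tokens)
      if (!is.na(hit)) return(hit)
    } else {  # cooccur: every part must be present somewhere in the sentence
      hits <- vapply(form$parts, function(p) match_seq(unlist(p), tokens),
                     character(1))
      if (!anyNA(hits)) return(paste(hits, collapse = " + "))
    }
  }
  NA_character_
}

#' Test one lexicon keyword against one sentence
#'
#' Matching is case-insensitive at word boundaries: tokens are alphanumeric
#' runs (hyphens and slashes separate tokens).  A trailing asterisk makes the
#' keyword a prefix stem ("discuss*" matches "discussed"); multi-word
#' keywords match as contiguous token sequences; the slash-form group-4 entry
#' expands to its alternatives ("asthma medication", "rescue medication",
#' ...).
#'
#' @param keyword A lexicon entry (see [keyword_lexicon()]).
#' @param sentence_text The sentence.
#' @param strict_plural See [keyword_lexicon()].
#' @return `TRUE` iff the keyword occurs in the sentence.
#' @examples
#' keyword_in_sentence("discuss*", "Discussed correct inhaler technique")
#' keyword_in_sentence("taught", "The patient was taut")
#' @export
keyword_in_sentence <- function(keyword, sentence_text, strict_plural = FALSE) {
  tokens <- tokenize_words(sentence_text)
  !is.na(match_entry_tokens(keyword, tokens, strict_plural))
}

#' Evaluate the combination rules on one sentence
#'
#' A rule fires iff every one of its required keyword groups has at least one
#' match anywhere in the sentence (any order, any distance within the
#' sentence).  The sentence is classified as containing inhaler-technique
#' documentation iff any rule fires.
#'
#' @param sentence_text The sentence.
#' @param lexicon A [keyword_lexicon()].
#' @param rules A [combination_rules()] object.
#' @return An object of class `rule_decision`: list with `matched` (logical),
#'   `fired_rules` (character vector of rule ids) and `matched_keywords`
#'   (named list mapping group id to matched surface strings).
#'   `matched` is `TRUE` iff `fired_rules` is non-empty.
#' @examples
#' evaluate_rules("Discussed correct inhaler technique")
#' evaluate_rules("teach daily medication technique")
#' @export
evaluate_rules <- function(sentence_text,
                           lexicon = keyword_lexicon(),
                           rules = combination_rules()) {
  stopifnot(inherits(lexicon, "keyword_lexicon"),
            inherits(rules, "combination_rules"))
  tokens <- tokenize_words(sentence_text)
  matched_keywords <- list()
  group_hit <- logical(length(lexicon$groups))
  names(group_hit) <- names(lexicon$groups)
  for (g in names(lexicon$groups)) {
    hits <- character(0)
    for (entry in lexicon$groups[[g]]) {
      h <- match_entry_tokens(entry, tokens, lexicon$strict_plural)
      if (!is.na(h)) hits <- c(hits, h)
    }
    if (length(hits)) {
      matched_keywords[[g]] <- unique(hits)
      group_hit[g] <- TRUE
    }
  }
  fired <- character(0)
  for (id in names(rules)) {
    req <- as.character(unclass(rules)[[id]])
    if (!all(req %in% names(lexicon$groups))) {
      stop_("rule '", id, "' requires group(s) absent from the lexicon")
    }
    if (all(group_hit[req])) fired <- c(fired, id)
  }
  structure(list(matched = length(fired) > 0L,
                 fired_rules = fired,
                 matched_keywords = matched_keywords),
            class = "rule_decision")
}

#' @export
print.rule_decision <- function(x, ...) {
  cat("<rule_decision> ", if (x$matched) "PRESENT" else "absent", sep = "")
  if (x$matched) cat("  fired:", paste(x$fired_rules, collapse = ", "))
  cat("\n")
  for (g in names(x$matched_keywords)) {
    cat("  group ", g, ": ", paste(x$matched_keywords[[g]], collapse = "; "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Rule-label one document from its sentences
#'
#' Document-level aggregation is existential: a note documents inhaler
#' technique iff at least one of its sentences does.
#'
#' @param sentences A sentence `data.frame` (see [segment_sentences()]) whose
#'   rows all share one `note_id`.
#' @inheritParams evaluate_rules
#' @return List with `label` (`"present"`/`"absent"`) and `decisions` (list
#'   of per-sentence [evaluate_rules()] results).
#' @export
rule_label_document <- function(sentences,
                                lexicon = keyword_lexicon(),
                                rules = combination_rules()) {
  if (nrow(sentences) && length(unique(sentences$note_id)) != 1L) {
    stop_("sentences span multiple note_ids: ",
          paste(unique(sentences$note_id), collapse = ", "))
  }
  decisions <- lapply(sentences$text, evaluate_rules,
                      lexicon = lexicon, rules = rules)
  matched <- vapply(decisions, function(d) d$matched, logical(1))
  list(label = if (any(matched)) "present" else "absent",
       decisions = decisions)
}

## ---- configuration files ---------------------------------------------------

#' Read or write a lexicon-and-rules configuration
#'
#' The configuration is human-editable YAML with a `keywords:` mapping (group
#' id to entry list), a `rules:` mapping (rule id to group-id list), and a
#' `strict_plural:` flag.  The shipped default configuration reproduces the
#' built-in lexicon verbatim.
#'
#' @param path File path.
#' @return For `read_rule_config()`, a list with elements `lexicon` and
#'   `rules`; for `write_rule_config()`, `path` invisibly.
#' @export
read_rule_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$keywords) || is.null(cfg$rules)) {
    stop_("rule config must contain 'keywords' and 'rules'")
  }
  groups <- lapply(cfg$keywords, as.character)
  lex <- new_keyword_lexicon(groups, isTRUE(cfg$strict_plural))
  rules <- new_combination_rules(cfg$rules)
  list(lexicon = lex, rules = rules)
}

#' @rdname read_rule_config
#' @param lexicon A [keyword_lexicon()].
#' @param rules A [combination_rules()] object.
#' @export
write_rule_config <- function(lexicon, rules, path) {
  stopifnot(inherits(lexicon, "keyword_lexicon"),
            inherits(rules, "combination_rules"))
  yaml::write_yaml(list(
    keywords = lexicon$groups,
    rules = lapply(unclass(rules), as.integer),
    strict_plural = lexicon$strict_plural
  ), path)
  invisible(path)
}
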