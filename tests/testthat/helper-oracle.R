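# Independent brute-force implementations used to cross-check the package.
# These deliberately share no code with the rule engine: text is normalized
# to space-separated lower-case tokens and every (keyword form, start
# position) pair is enumerated.

oracle_tokens <- function(text) {
  norm <- gsub("[^a-z0-9]+", " ", tolower(text))
  toks <- strsplit(trimws(norm), " +")[[1]]
  toks[nzchar(toks)]
}

# expand a raw lexicon entry to all its matchable word-sequence forms,
# mirroring the documented semantics by an independent route
oracle_forms <- function(entry, strict_plural = FALSE) {
  if (!strict_plural && entry == "techniques") entry <- "technique*"
  if (!strict_plural && entry == "administrations") entry <- "administration*"
  if (entry == "list of maintenance and rescue medications") {
    return(list(list(cooccur = list(c("maintenance"), c("rescue"),
                                    c("medication*")))))
  }
  if (grepl("/", entry, fixed = TRUE)) {
    w <- strsplit(entry, " +")[[1]]
    alts <- strsplit(w[1], "/", fixed = TRUE)[[1]]
    return(lapply(alts, function(a) list(seq = c(a, w[-1]))))
  }
  list(list(seq = strsplit(entry, " +")[[1]]))
}

oracle_seq_at <- function(words, toks, s) {
  for (j in seq_along(words)) {
    w <- tolower(words[j])
    tok <- toks[s + j - 1]
    if (endsWith(w, "*")) {
      stem <- substr(w, 1, nchar(w) - 1)
      if (substr(tok, 1, nchar(stem)) != stem) return(FALSE)
    } else if (tok != w) return(FALSE)
  }
  TRUE
}

oracle_seq_anywhere <- function(words, toks) {
  n <- length(words)
  if (length(toks) < n) return(FALSE)
  for (s in seq_len(length(toks) - n + 1)) {
    if (oracle_seq_at(words, toks, s)) return(TRUE)
  }
  FALSE
}

oracle_keyword <- function(entry, text, strict_plural = FALSE) {
  toks <- oracle_tokens(text)
  for (form in oracle_forms(entry, strict_plural)) {
    if (!is.null(form$seq)) {
      if (oracle_seq_anywhere(form$seq, toks)) return(TRUE)
    } else {
      if (all(vapply(form$cooccur, oracle_seq_anywhere, logical(1),
                     toks = toks))) return(TRUE)
    }
  }
  FALSE
}

# full sentence decision by exhaustive scan over every group entry
oracle_rule_match <- function(text, lexicon = keyword_lexicon(),
                              rules = combination_rules()) {
  hit <- vapply(names(lexicon$groups), function(g) {
    any(vapply(lexicon$groups[[g]], oracle_keyword, logical(1),
               text = text, strict_plural = lexicon$strict_plural))
  }, logical(1))
  any(vapply(unclass(rules), function(req) {
    all(hit[as.character(req)])
  }, logical(1)))
}

# a small labeled corpus on disk, for I/O tests
make_corpus_file <- function(path, n_notes = 10, seed = 1) {
  withr::with_seed(seed, {
    lines <- character(0)
    for (i in seq_len(n_notes)) {
      for (sec in c("HPI", "Impression/Report/Plan")) {
        lines <- c(lines, jsonlite::toJSON(list(
          note_id = sprintf("N%03d", i),
          patient_id = sprintf("P%02d", (i + 1) %/% 2),
          section = sec,
          text = paste0("Sentence one of note ", i, ". Sentence two.")
        ), auto_unbox = TRUE))
      }
    }
    writeLines(lines, path)
  })
  path
}
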