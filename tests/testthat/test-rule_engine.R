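test_that("keyword matching honors stems, boundaries and phrases", {
  expect_true(keyword_in_sentence("discuss*",
                                  "Discussed correct inhaler technique"))
  expect_false(keyword_in_sentence("taught", "The patient was taut"))
  expect_true(keyword_in_sentence("how to use",
                                  "showed her how to use the spacer"))
  # hyphens are token boundaries
  expect_true(keyword_in_sentence("inhaler", "metered-dose inhaler given"))
  # prefix never crosses a word boundary backwards
  expect_false(keyword_in_sentence("neb", "nebs sent home"))
  expect_true(keyword_in_sentence("nebulizer", "home NEBULIZER use"))
  # slash entry expands to its alternatives
  expect_true(keyword_in_sentence(
    "asthma/rescue/daily/preventive/control medication",
    "started a daily medication today"))
  expect_false(keyword_in_sentence(
    "asthma/rescue/daily/preventive/control medication",
    "medication list reviewed daily"))
})

test_that("combination rules fire on co-occurring groups", {
  d <- evaluate_rules("Discussed correct inhaler technique")
  expect_true(d$matched)
  expect_equal(d$fired_rules, "a")
  expect_true("1" %in% names(d$matched_keywords))

  d <- evaluate_rules(paste("We reviewed her medications and discussed",
                            "labeling the Flovent with a green sticker",
                            "for a daily inhaler"))
  expect_true(d$matched)
  expect_true("a" %in% d$fired_rules)

  d <- evaluate_rules("teach daily medication technique")
  expect_true(d$matched)
  expect_equal(d$fired_rules, "b")

  d <- evaluate_rules("")
  expect_false(d$matched)
  expect_length(d$fired_rules, 0L)
})

test_that("matched is exactly 'some rule fired'", {
  texts <- c("Discussed correct inhaler technique", "Doing well today",
             "spacer at home", "reviewed asthma medication guidance")
  for (txt in texts) {
    d <- evaluate_rules(txt)
    expect_identical(d$matched, length(d$fired_rules) > 0L)
  }
})

test_that("strict plural mode narrows group 3", {
  relaxed <- evaluate_rules("teach daily medication technique")
  strict <- evaluate_rules("teach daily medication technique",
                           lexicon = keyword_lexicon(strict_plural = TRUE))
  expect_true(relaxed$matched)
  expect_false(strict$matched)
  # the literal plural still matches under strict mode
  expect_true(evaluate_rules("teach daily medication techniques",
                             lexicon = keyword_lexicon(strict_plural = TRUE))$matched)
})

test_that("document label is the OR of sentence decisions", {
  sents <- data.frame(
    note_id = "N1", patient_id = "P1", section = "HPI",
    sentence_index = 0:99,
    text = c(rep("Doing well today", 99),
             "Reviewed inhaler use with the patient"))
  out <- rule_label_document(sents)
  expect_equal(out$label, "present")
  expect_length(out$decisions, 100L)

  empty <- sents[0, ]
  expect_equal(rule_label_document(empty)$label, "absent")

  mixed <- sents
  mixed$note_id[1] <- "N2"
  expect_error(rule_label_document(mixed), "multiple note_ids")
})

test_that("engine agrees with the brute-force oracle on generated text", {
  g <- generate_corpus(synthetic_corpus_config(
    n_patients = 10, notes_per_patient = c(1, 2),
    sentences_per_note = c(8, 15), positive_sentence_rate = 0.3,
    implicit_fraction = 0.3, hard_negative_rate = 0.3, seed = 9))
  texts <- g$sentences$text
  engine <- vapply(texts, function(t) evaluate_rules(t)$matched, logical(1))
  oracle <- vapply(texts, oracle_rule_match, logical(1))
  expect_identical(unname(engine), unname(oracle))
})

test_that("adding keywords never unmatches a sentence (monotonicity)", {
  lex <- keyword_lexicon()
  lex_plus <- lex
  lex_plus$groups[["1"]] <- c(lex_plus$groups[["1"]], "counsel*")
  lex_plus$groups[["2"]] <- c(lex_plus$groups[["2"]], "diskus")
  g <- generate_corpus(synthetic_corpus_config(
    n_patients = 6, notes_per_patient = c(1, 2),
    sentences_per_note = c(6, 10), positive_sentence_rate = 0.3,
    implicit_fraction = 0.2, hard_negative_rate = 0.2, seed = 21))
  for (txt in g$sentences$text) {
    if (evaluate_rules(txt, lex)$matched) {
      expect_true(evaluate_rules(txt, lex_plus)$matched)
    }
  }
})

test_that("decisions are case-invariant", {
  g <- generate_corpus(synthetic_corpus_config(
    n_patients = 5, notes_per_patient = c(1, 2),
    sentences_per_note = c(5, 8), positive_sentence_rate = 0.4,
    implicit_fraction = 0.2, hard_negative_rate = 0.2, seed = 33))
  for (txt in g$sentences$text) {
    expect_identical(evaluate_rules(toupper(txt))$matched,
                     evaluate_rules(txt)$matched)
  }
})

test_that("the shipped configuration file reproduces the built-in rules", {
  path <- system.file("extdata", "rule_config.yaml",
                      package = "inhalertech", mustWork = TRUE)
  cfg <- read_rule_config(path)
  expect_identical(cfg$lexicon$groups, keyword_lexicon()$groups)
  expect_identical(unclass(cfg$rules), unclass(combination_rules()))
  # and round-trips through write_rule_config verbatim
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_rule_config(cfg$lexicon, cfg$rules, tmp)
  expect_identical(read_rule_config(tmp)$lexicon$groups,
                   keyword_lexicon()$groups)
})
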