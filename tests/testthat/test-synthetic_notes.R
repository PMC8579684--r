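test_that("template bank kinds behave as declared under the rule engine", {
  bank <- template_bank()  # validates on construction
  expect_s3_class(bank, "template_bank")
  # spot checks of the printed sentences the bank paraphrases
  expect_true(evaluate_rules("Discussed correct inhaler technique")$matched)
  expect_false(evaluate_rules(
    "Mom voices no concerns about his technique in using the inhaler")$matched)
  hard <- "Discussed 3rd neb treatment here versus one upon home"
  expect_true(evaluate_rules(hard)$matched)          # rule false positive
  expect_equal(apply_p2n(hard, "present"), "absent") # and P2N-eligible
  # corrupting the bank is caught
  bad <- bank
  bad$filler <- c(bad$filler, "Reviewed inhaler use in clinic")
  expect_error(validate_template_bank(bad), "must not fire")
})

test_that("exact-count placement hits the configured prevalence", {
  cfg <- synthetic_corpus_config(
    n_patients = 250, notes_per_patient = c(2, 2),
    sentences_per_note = c(20, 20), positive_sentence_rate = 0.004,
    implicit_fraction = 0, hard_negative_rate = 0, seed = 7)
  g <- generate_corpus(cfg)
  expect_equal(nrow(g$sentences), 10000L)
  expect_equal(sum(g$sentences$label == "present"), 40L)
  rep <- corpus_report(g)
  expect_equal(rep$sentence_prevalence, 0.004)
  expect_equal(rep$n_sentences, 10000L)
})

test_that("rate zero yields an all-absent corpus", {
  g <- generate_corpus(synthetic_corpus_config(
    n_patients = 5, notes_per_patient = c(1, 2),
    sentences_per_note = c(4, 8), positive_sentence_rate = 0,
    implicit_fraction = 0, hard_negative_rate = 0, seed = 3))
  expect_true(all(g$sentences$label == "absent"))
  expect_true(all(g$documents == "absent"))
})

test_that("generation is a pure function of the seed", {
  cfg <- synthetic_corpus_config(n_patients = 8, seed = 99)
  expect_identical(generate_corpus(cfg), generate_corpus(cfg))
  cfg2 <- synthetic_corpus_config(n_patients = 8, seed = 100)
  expect_false(identical(generate_corpus(cfg)$sentences$text,
                         generate_corpus(cfg2)$sentences$text))
})

test_that("profiles carry the study prevalences", {
  for (pr in list(c("train", 0.004), c("test", 0.0056),
                  c("distant", 0.00124))) {
    cfg <- synthetic_corpus_config(profile = pr[[1]], seed = 1)
    expect_equal(cfg$positive_sentence_rate, as.numeric(pr[[2]]))
  }
  # the distant-supervision profile is rule-separable by construction
  ds <- synthetic_corpus_config(profile = "distant", seed = 1)
  expect_equal(ds$implicit_fraction, 0)
  expect_equal(ds$hard_negative_rate, 0)
})

test_that("corpus_report agrees with direct counting", {
  g <- generate_corpus(synthetic_corpus_config(
    n_patients = 12, notes_per_patient = c(1, 3),
    sentences_per_note = c(5, 12), positive_sentence_rate = 0.2,
    implicit_fraction = 0.4, hard_negative_rate = 0.1, seed = 31))
  rep <- corpus_report(g)
  expect_equal(rep$n_positive_sentences, sum(g$sentences$label == "present"))
  expect_equal(rep$n_positive_documents, sum(g$documents == "present"))
  expect_equal(as.integer(rep$kind_counts["explicit_positive"]),
               sum(g$sentences$kind == "explicit_positive"))
  # explicit positives are exactly the positives on which the rules fire
  pos <- g$sentences[g$sentences$label == "present", ]
  fires <- vapply(pos$text, function(t) evaluate_rules(t)$matched, logical(1))
  expect_identical(unname(fires), pos$kind == "explicit_positive")
})

test_that("implicit positives open a rule-recall gap; hard negatives cost rule precision", {
  base <- list(n_patients = 40, notes_per_patient = c(2, 2),
               sentences_per_note = c(10, 10),
               positive_sentence_rate = 0.05, seed = 55)
  rule_docs <- function(g) {
    wd <- weak_label(g$corpus)
    aggregate_document_labels(wd$items)
  }
  g0 <- generate_corpus(do.call(synthetic_corpus_config,
    c(base, list(implicit_fraction = 0, hard_negative_rate = 0))))
  r0 <- evaluate(rule_docs(g0), g0$documents)
  expect_equal(r0$recall, 1)  # fully separable: rules recover every document

  g1 <- generate_corpus(do.call(synthetic_corpus_config,
    c(base, list(implicit_fraction = 0.6, hard_negative_rate = 0))))
  r1 <- evaluate(rule_docs(g1), g1$documents)
  expect_lt(r1$recall, 1)
  expect_lte(r1$recall, r0$recall)

  g2 <- generate_corpus(do.call(synthetic_corpus_config,
    c(base, list(implicit_fraction = 0, hard_negative_rate = 0.2))))
  r2 <- evaluate(rule_docs(g2), g2$documents)
  expect_lt(r2$precision, 1)  # keyword-bearing negatives are rule FPs
})

test_that("notes retain exactly the two target sections", {
  g <- generate_corpus(synthetic_corpus_config(n_patients = 6, seed = 8))
  for (note in g$corpus) {
    expect_equal(note$sections$section,
                 c("History of Present Illness", "Impression/Report/Plan"))
  }
  # and the corpus round-trips through the I/O layer
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(g$corpus, path)
  expect_equal(read_corpus(path), g$corpus)
})
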