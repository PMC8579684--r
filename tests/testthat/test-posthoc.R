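test_that("N2P flips model-absent sentences matching the override", {
  expect_equal(apply_n2p("Instructed the patient on use of spacer today",
                         "absent"), "present")
  expect_equal(apply_n2p("Instructed the patient on use of spacer today",
                         "present"), "present")
  expect_equal(apply_n2p("Patient doing well", "absent"), "absent")
  # case-insensitive, and the devices are alternatives
  expect_equal(apply_n2p("REVIEWED the USE OF NEBULIZER at home", "absent"),
               "present")
})

test_that("P2N flips discussion sentences lacking any technique mention", {
  green_sticker <- paste("We reviewed her medications and discussed labeling",
                         "the Flovent with a green sticker for a daily inhaler")
  expect_equal(apply_p2n(green_sticker, "present"), "absent")
  expect_equal(apply_p2n("Discussed correct inhaler technique", "present"),
               "present")  # blocker present
  expect_equal(apply_p2n("Reviewed importance of twice daily dosing of Flovent",
                         "present"), "present")  # no trigger
  expect_equal(apply_p2n(green_sticker, "absent"), "absent")
  # the blocker stem covers the plural
  expect_equal(apply_p2n("Discussed inhaler techniques", "present"), "present")
})

test_that("hybridize applies one single-direction pass with a flip log", {
  empty <- data.frame(text = character(), label = character(),
                      provenance = character())
  expect_equal(nrow(hybridize(empty)), 0L)

  preds <- data.frame(
    text = c("Instructed the patient on use of spacer today",   # N2P fires
             "Patient doing well",                              # no change
             "Discussed follow up timing",                      # P2N fires
             "Discussed correct inhaler technique",             # blocked
             "Reviewed use of inhaler and discussed timing"),   # model-present
    label = c("absent", "absent", "present", "present", "present"),
    provenance = "model")
  out <- hybridize(preds)
  expect_equal(out$label,
               c("present", "absent", "absent", "present", "absent"))
  expect_true(all(out$provenance == "hybrid"))
  flips <- attr(out, "flips")
  expect_equal(nrow(flips), 3L)
  expect_equal(sort(unique(flips$direction)), c("N2P", "P2N"))
})

test_that("no sentence is flipped against its direction", {
  g <- generate_corpus(synthetic_corpus_config(
    n_patients = 10, notes_per_patient = c(1, 2),
    sentences_per_note = c(6, 12), positive_sentence_rate = 0.3,
    implicit_fraction = 0.3, hard_negative_rate = 0.3, seed = 14))
  preds <- g$sentences
  set.seed(14)
  preds$label <- sample(c("present", "absent"), nrow(preds), replace = TRUE)
  preds$provenance <- "model"
  out <- hybridize(preds)
  up <- preds$label == "absent" & out$label == "present"
  down <- preds$label == "present" & out$label == "absent"
  flips <- attr(out, "flips")
  expect_equal(sum(up), sum(flips$direction == "N2P"))
  expect_equal(sum(down), sum(flips$direction == "P2N"))
  # count N2P flips by an independent regex scan over model-negatives
  n2p <- "(instructed|reviewed|discussed).*(use\\sof\\sMDI|use\\sof\\sspacer|use\\sof\\snebulizer|use\\sof\\sinhaler)"
  expected_up <- sum(preds$label == "absent" &
                       grepl(n2p, preds$text, ignore.case = TRUE, perl = TRUE))
  expect_equal(sum(up), expected_up)
})

test_that("hybridize is idempotent under the no-chaining contract", {
  preds <- data.frame(
    text = c("Discussed use of inhaler at school",  # P2N would fire, then N2P
             "Instructed on use of spacer", "Doing well"),
    label = c("present", "absent", "absent"),
    provenance = "model")
  once <- hybridize(preds)
  twice <- hybridize(once)
  expect_equal(twice$label, once$label)
  expect_equal(nrow(attr(twice, "flips")), 0L)
})

test_that("gold or weak labels cannot be hybridized silently", {
  preds <- data.frame(text = "x", label = "absent", provenance = "gold")
  expect_error(hybridize(preds), "provenance")
})

test_that("the shipped override rules serialize verbatim", {
  rs <- posthoc_rules()
  expect_identical(
    rs$n2p,
    "(instructed|reviewed|discussed).*(use\\sof\\sMDI|use\\sof\\sspacer|use\\sof\\snebulizer|use\\sof\\sinhaler)")
  expect_identical(rs$p2n[[1]]$trigger, "(discussed|discussion)")
  expect_identical(rs$p2n[[1]]$blocker, "technique")
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_posthoc_config(rs, tmp)
  back <- read_posthoc_config(tmp)
  expect_identical(back$n2p, rs$n2p)
  expect_identical(back$p2n, rs$p2n)
  shipped <- read_posthoc_config(system.file(
    "extdata", "posthoc_config.yaml", package = "inhalertech",
    mustWork = TRUE))
  expect_identical(shipped$n2p, rs$n2p)
})

test_that("malformed override patterns fail at construction", {
  expect_error(posthoc_rules(n2p = "(unclosed"), "malformed")
})
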