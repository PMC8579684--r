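# helpers ---------------------------------------------------------------

tiny_spec <- function(T = 24) {
  encoder_spec(layers = 2L, hidden = 32L, heads = 2L, ffn_mult = 2L,
               max_positions = T)
}

# a from-scratch encoder needs larger rates than pretrained fine-tuning;
# the schedule shape (triangular, phase-shifted start) is unchanged
tiny_config <- function(seed, epochs = 2L, ...) {
  training_config(seed = seed, epochs = epochs, batch_size = 32L,
                  max_sequence_length = 24L, class_weights = c(1, 1),
                  lr_lower = 5e-4, lr_upper = 3e-3, lr_init = 1e-3,
                  lr_step_size = 100L, ...)
}

separable_sentences <- function(seed, n_patients = 25, rate = 0.1) {
  generate_corpus(synthetic_corpus_config(
    n_patients = n_patients, notes_per_patient = c(2, 2),
    sentences_per_note = c(10, 10), positive_sentence_rate = rate,
    implicit_fraction = 0, hard_negative_rate = 0, seed = seed))$sentences
}

# schedule ---------------------------------------------------------------

test_that("cyclical schedule starts at lr_init and spans its bounds", {
  cfg <- training_config(seed = 1)
  expect_equal(cyclical_lr(0, cfg), 3e-5)
  its <- 0:9999
  lr <- cyclical_lr(its, cfg)
  expect_true(all(lr >= 2e-5 - 1e-18 & lr <= 5e-5 + 1e-18))
  # exact bounds at the turning points, period 5000
  tp <- lr_turning_points(cfg)
  expect_equal(cyclical_lr(tp$peak, cfg), 5e-5)
  expect_equal(cyclical_lr(tp$trough, cfg), 2e-5)
  expect_equal(cyclical_lr(its, cfg), cyclical_lr(its + 5000, cfg))
  # ascending at 0
  expect_gt(cyclical_lr(1, cfg), cyclical_lr(0, cfg))
})

test_that("canonical start begins the triangle at the lower bound", {
  cfg <- training_config(seed = 1, canonical_start = TRUE)
  expect_equal(cyclical_lr(0, cfg), 2e-5)
  expect_equal(cyclical_lr(2500, cfg), 5e-5)
})

test_that("invalid learning-rate orderings fail at construction", {
  expect_error(training_config(seed = 1, lr_init = 1e-5), "lr_lower")
  expect_error(training_config(seed = 1, lr_init = 6e-5), "lr_lower")
  expect_error(training_config(seed = 1, class_weights = c(1, -1)),
               "positive")
})

# loss -------------------------------------------------------------------

test_that("weighted cross entropy matches hand-computed values", {
  expect_equal(weighted_cross_entropy(c(0, 0), "present", c(1, 1)), log(2))
  # the class-weight ratio scales per-item losses exactly
  lp <- weighted_cross_entropy(c(0, 0), "present", c(0.52, 5.52))
  la <- weighted_cross_entropy(c(0, 0), "absent", c(0.52, 5.52))
  expect_equal(lp / la, 5.52 / 0.52)
  expect_equal(weighted_cross_entropy(c(2, -2), "absent", c(1, 1)),
               -log(exp(2) / (exp(2) + exp(-2))))
})

test_that("unit weights reduce to the standard cross entropy", {
  set.seed(4)
  logits <- matrix(rnorm(20), 10, 2)
  labels <- sample(c("absent", "present"), 10, replace = TRUE)
  yidx <- match(labels, c("absent", "present"))
  plain <- -log(exp(logits[cbind(1:10, yidx)]) / rowSums(exp(logits)))
  expect_equal(weighted_cross_entropy(logits, labels, c(1, 1)), plain)
  expect_equal(weighted_cross_entropy(logits, labels, c(1, 1),
                                      reduce = "batch"), mean(plain))
})

test_that("non-finite logits are rejected", {
  expect_error(weighted_cross_entropy(c(Inf, 0), "absent"), "finite")
  expect_error(weighted_cross_entropy(c(0, NaN), "present"), "finite")
})

# tokenizer --------------------------------------------------------------

test_that("tokenize_and_pad yields fixed-length special-framed sequences", {
  tok <- word_tokenizer(c("discussed inhaler technique", "follow up"))
  ids <- tokenize_and_pad("discussed inhaler", tok, 256L)
  expect_length(ids, 256L)
  expect_equal(ids[1], 3L)              # [CLS]
  expect_equal(ids[4], 4L)              # [SEP]
  expect_true(all(ids[5:256] == 1L))    # [PAD]

  empty <- tokenize_and_pad("", tok, 8L)
  expect_equal(empty, c(3L, 4L, rep(1L, 6L)))

  long <- paste(rep("inhaler", 300), collapse = " ")
  expect_warning(tr <- tokenize_and_pad(long, tok, 256L), "truncated")
  expect_length(tr, 256L)
  expect_false(any(tr == 1L))

  # unknown words map to [UNK]
  unk <- tokenize_and_pad("zzz", tok, 4L)
  expect_equal(unk[2], 2L)
})

# encoder gradients ------------------------------------------------------

test_that("analytic gradients match finite differences", {
  withr::with_seed(42, {
    spec <- encoder_spec(layers = 2, hidden = 8, heads = 2, ffn_mult = 2,
                         max_positions = 12)
    params <- inhalertech:::init_encoder(spec, vocab_size = 15)
    ids <- matrix(sample(2:15, 3 * 7, replace = TRUE), 3, 7)
    ids[1, 6:7] <- 1L
    nreal <- rowSums(ids != 1L)
    y <- c(1L, 2L, 1L)
    cw <- c(0.52, 5.52)
    lossfun <- function(p) {
      fwd <- inhalertech:::encoder_forward(p, spec, ids, nreal)
      sum(weighted_cross_entropy(fwd$logits, c("absent", "present")[y], cw)) /
        sum(cw[y])
    }
    fwd <- inhalertech:::encoder_forward(params, spec, ids, nreal)
    grads <- inhalertech:::encoder_backward(
      params, spec, fwd$cache, inhalertech:::wce_grad(fwd$logits, y, cw))
    eps <- 1e-5
    for (nm in names(params)) {
      probe <- sample(length(params[[nm]]), min(3, length(params[[nm]])))
      for (j in probe) {
        p1 <- params; p1[[nm]][j] <- p1[[nm]][j] + eps
        p2 <- params; p2[[nm]][j] <- p2[[nm]][j] - eps
        num <- (lossfun(p1) - lossfun(p2)) / (2 * eps)
        expect_equal(grads[[nm]][j], num, tolerance = 1e-3,
                     label = paste("grad", nm))
      }
    }
  })
})

test_that("compiled kernel agrees with the reference implementation", {
  withr::with_seed(5, {
    spec <- encoder_spec(layers = 2, hidden = 16, heads = 2, ffn_mult = 2,
                         max_positions = 10)
    params <- inhalertech:::init_encoder(spec, vocab_size = 20)
    ids <- matrix(sample(2:20, 4 * 8, replace = TRUE), 4, 8)
    ids[1, 7:8] <- 1L; ids[3, 5:8] <- 1L
    nreal <- rowSums(ids != 1L)
    y <- c(1L, 2L, 2L, 1L); cw <- c(0.52, 5.52)
    dm <- matrix(rbinom(4 * 16, 1, 0.9) / 0.9, 4, 16)
    for (mask in list(NULL, dm)) {
      fwdR <- inhalertech:::encoder_forward(params, spec, ids, nreal, mask)
      gR <- inhalertech:::encoder_backward(
        params, spec, fwdR$cache, inhalertech:::wce_grad(fwdR$logits, y, cw))
      res <- inhalertech:::encoder_train_step(params, spec, ids, nreal,
                                              mask, y, cw)
      expect_equal(res$logits, fwdR$logits, tolerance = 1e-12,
                   ignore_attr = TRUE)
      for (nm in names(gR)) {
        expect_equal(res$grads[[nm]], gR[[nm]], tolerance = 1e-10,
                     ignore_attr = TRUE)
      }
    }
  })
})

# training ---------------------------------------------------------------

test_that("training on separable sentences reaches high validation F1", {
  sents <- separable_sentences(seed = 61, n_patients = 100)  # 2000 sentences
  m <- train_classifier(sents, tiny_config(seed = 9, epochs = 10),
                        tiny_spec())
  expect_s3_class(m, "sentence_classifier")
  expect_gte(max(m$history$epochs$val_f1, na.rm = TRUE), 0.9)
})

test_that("training is reproducible and logs the cyclical schedule", {
  sents <- separable_sentences(seed = 62, n_patients = 10)
  cfg <- tiny_config(seed = 7, epochs = 2)
  m1 <- train_classifier(sents, cfg, tiny_spec())
  m2 <- train_classifier(sents, cfg, tiny_spec())
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  n_iter <- length(m1$history$lr)
  expect_equal(m1$history$lr, cyclical_lr(seq_len(n_iter) - 1, cfg))
})

test_that("degenerate training inputs are rejected", {
  sents <- separable_sentences(seed = 63, n_patients = 10)
  neg_only <- sents[sents$label == "absent", ]
  expect_error(train_classifier(neg_only, tiny_config(seed = 1),
                                tiny_spec()), "single class")
  one_patient <- sents[sents$patient_id == sents$patient_id[1], ]
  expect_error(train_classifier(one_patient, tiny_config(seed = 1),
                                tiny_spec()), "at least 2 patients")
})

test_that("prediction is deterministic, order-preserving and provenanced", {
  sents <- separable_sentences(seed = 64, n_patients = 20)
  m <- train_classifier(sents, tiny_config(seed = 11, epochs = 3),
                        tiny_spec())
  held <- separable_sentences(seed = 65, n_patients = 10)
  expect_equal(predict(m, character(0)), character(0))
  p1 <- predict(m, held)
  p2 <- predict(m, held)
  expect_identical(p1$label, p2$label)
  expect_true(all(p1$provenance == "model"))
  expect_equal(p1$text, held$text)
  # better than always predicting the majority class
  acc <- mean(p1$label == held$label)
  expect_gt(acc, mean(held$label == "absent"))
  # probabilities and logits are consistent with labels
  pr <- predict(m, held$text, type = "prob")
  expect_identical(p1$label, ifelse(pr > 0.5, "present", "absent"))
})

test_that("inverse-prevalence weights balance the class mass", {
  labels <- c(rep("absent", 90), rep("present", 10))
  w <- inverse_prevalence_weights(labels)
  expect_equal(unname(w["absent"] * 90), unname(w["present"] * 10))
  expect_error(inverse_prevalence_weights(rep("absent", 5)), "both classes")
})

test_that("checkpoints round-trip with a JSON sidecar", {
  sents <- separable_sentences(seed = 66, n_patients = 10)
  m <- train_classifier(sents, tiny_config(seed = 2, epochs = 1), tiny_spec())
  path <- withr::local_tempfile(fileext = ".rds")
  save_classifier(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_classifier(path)
  held <- separable_sentences(seed = 67, n_patients = 5)
  expect_identical(predict(m2, held$text), predict(m, held$text))
})
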