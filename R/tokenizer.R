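## Word-level tokenizer for the sentence classifier.
##
## Sentences are lower-cased and split into alphanumeric runs (the same
## token definition the rule engine uses).  The vocabulary is fitted on the
## training corpus; four special tokens are reserved:
##   [PAD] = 1, [UNK] = 2, [CLS] = 3, [SEP] = 4   (1-based ids).

PAD_ID <- 1L
UNK_ID <- 2L
CLS_ID <- 3L
SEP_ID <- 4L

#' Fit a word tokenizer on a set of sentences
#'
#' @param texts Character vector of training sentences.
#' @param max_vocab Optional cap on vocabulary size (most frequent kept),
#'   counting the four special tokens.
#' @param min_count Minimum token frequency to enter the vocabulary.
#' @return An object of class `word_tokenizer`.
#' @export
word_tokenizer <- function(texts, max_vocab = Inf, min_count = 1L) {
  toks <- unlist(lapply(texts, tokenize_words), use.names = FALSE)
  tab <- sort(table(toks), decreasing = TRUE)
  tab <- tab[tab >= min_count]
  keep <- names(tab)
  if (is.finite(max_vocab) && length(keep) > max_vocab - 4L) {
    keep <- keep[seq_len(max_vocab - 4L)]
  }
  vocab <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]", keep)
  index <- new.env(parent = emptyenv())
  for (i in seq_along(vocab)) assign(vocab[i], i, envir = index)
  structure(list(vocab = vocab, index = index), class = "word_tokenizer")
}

#' @export
print.word_tokenizer <- function(x, ...) {
  cat("<word_tokenizer> vocabulary size", length(x$vocab), "\n")
  invisible(x)
}

token_ids <- function(tokenizer, tokens) {
  vapply(tokens, function(t) {
    v <- mget(t, envir = tokenizer$index, ifnotfound = list(UNK_ID))[[1]]
    as.integer(v)
  }, integer(1), USE.NAMES = FALSE)
}

#' Tokenize one sentence to a fixed-length id sequence
#'
#' The sequence is `[CLS] tokens [SEP]` padded with `[PAD]` to exactly
#' `max_sequence_length` ids; longer sentences are truncated (with a
#' warning -- in practice clinical sentences fit comfortably).
#'
#' @param sentence_text The sentence.
#' @param tokenizer A [word_tokenizer()].
#' @param max_sequence_length Total sequence length in tokens (default 256).
#' @return Integer vector of length `max_sequence_length`.
#' @export
tokenize_and_pad <- function(sentence_text, tokenizer,
                             max_sequence_length = 256L) {
  stopifnot(inherits(tokenizer, "word_tokenizer"),
            max_sequence_length >= 2L)
  ids <- token_ids(tokenizer, tokenize_words(sentence_text))
  room <- max_sequence_length - 2L
  if (length(ids) > room) {
    warning("sentence truncated from ", length(ids), " to ", room,
            " tokens", call. = FALSE)
    ids <- ids[seq_len(room)]
  }
  seq_ids <- c(CLS_ID, ids, SEP_ID)
  c(seq_ids, rep(PAD_ID, max_sequence_length - length(seq_ids)))
}

## Batch encoding: B x max_sequence_length integer matrix.
encode_batch <- function(texts, tokenizer, max_sequence_length) {
  t(vapply(texts, tokenize_and_pad, integer(max_sequence_length),
           tokenizer = tokenizer,
           max_sequence_length = max_sequence_length, USE.NAMES = FALSE))
}
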