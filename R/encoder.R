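## A small transformer sentence encoder written with plain matrix algebra:
## token + position embeddings, pre-norm multi-head self-attention blocks
## with GELU feed-forward sublayers, masked mean pooling, and a dropout +
## linear two-logit classification head.  Forward and backward passes are
## implemented by hand so training has no dependency beyond base R; the
## backward pass is verified against finite differences in the test suite.
##
## The same training harness accepts any encoder honoring this interface
## (init / forward / backward over a flat named parameter list), so a
## pretrained contextual encoder can be dropped in where one is available;
## the from-scratch architecture below is what the tests exercise.

#' Describe a sentence encoder
#'
#' Either a from-scratch architecture (the default: a tiny transformer whose
#' size is set by `layers`, `hidden`, `heads`) or, via `name`, a reference to
#' a pretrained encoder honoring the same interface.
#'
#' @param layers Number of transformer blocks.
#' @param hidden Hidden width (must be divisible by `heads`).
#' @param heads Attention heads.
#' @param ffn_mult Feed-forward width as a multiple of `hidden`.
#' @param max_positions Largest supported sequence length.
#' @param name Optional name-or-path of a pretrained encoder implementing
#'   the encoder interface; `NULL` (default) selects the from-scratch
#'   transformer.
#' @return An object of class `encoder_spec`.
#' @export
encoder_spec <- function(layers = 2L, hidden = 64L, heads = 2L,
                         ffn_mult = 4L, max_positions = 256L, name = NULL) {
  stopifnot(is_count(layers), layers >= 1, is_count(hidden),
            is_count(heads), heads >= 1, is_count(ffn_mult),
            is_count(max_positions))
  if (hidden %% heads != 0) stop_("'hidden' must be divisible by 'heads'")
  structure(list(layers = as.integer(layers), hidden = as.integer(hidden),
                 heads = as.integer(heads), ffn_mult = as.integer(ffn_mult),
                 max_positions = as.integer(max_positions), name = name),
            class = "encoder_spec")
}

#' @export
print.encoder_spec <- function(x, ...) {
  if (!is.null(x$name)) {
    cat("<encoder_spec> pretrained:", x$name, "\n")
  } else {
    cat(sprintf("<encoder_spec> %d layers, hidden %d, %d heads, ffn x%d\n",
                x$layers, x$hidden, x$heads, x$ffn_mult))
  }
  invisible(x)
}

## ---- parameters ------------------------------------------------------------

## Parameters live in a flat named list of matrices/vectors; layer-l weights
## are prefixed "L<l>.".  Gaussian init (sd 0.02), unit layer-norm gains.
init_encoder <- function(spec, vocab_size, n_classes = 2L) {
  d <- spec$hidden; f <- spec$ffn_mult * d
  g <- function(nr, nc = NULL, sd = 0.02) {
    if (is.null(nc)) stats::rnorm(nr, 0, sd)
    else matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
  }
  p <- list(emb = g(vocab_size, d), pos = g(spec$max_positions, d))
  for (l in seq_len(spec$layers)) {
    pre <- paste0("L", l, ".")
    p[[paste0(pre, "Wq")]] <- g(d, d); p[[paste0(pre, "bq")]] <- numeric(d)
    p[[paste0(pre, "Wk")]] <- g(d, d); p[[paste0(pre, "bk")]] <- numeric(d)
    p[[paste0(pre, "Wv")]] <- g(d, d); p[[paste0(pre, "bv")]] <- numeric(d)
    p[[paste0(pre, "Wo")]] <- g(d, d); p[[paste0(pre, "bo")]] <- numeric(d)
    p[[paste0(pre, "ln1g")]] <- rep(1, d); p[[paste0(pre, "ln1b")]] <- numeric(d)
    p[[paste0(pre, "ln2g")]] <- rep(1, d); p[[paste0(pre, "ln2b")]] <- numeric(d)
    p[[paste0(pre, "W1")]] <- g(d, f); p[[paste0(pre, "b1")]] <- numeric(f)
    p[[paste0(pre, "W2")]] <- g(f, d); p[[paste0(pre, "b2")]] <- numeric(d)
  }
  p$lnfg <- rep(1, d); p$lnfb <- numeric(d)
  p$Wc <- g(d, n_classes); p$bc <- numeric(n_classes)
  p
}

n_parameters <- function(params) {
  sum(vapply(params, length, integer(1)))
}

## ---- primitives ------------------------------------------------------------

## column-wise bias add / gain scale without sweep()'s aperm overhead
bias_add <- function(M, b) M + rep(b, each = nrow(M))
col_scale <- function(M, g) M * rep(g, each = nrow(M))

ln_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  istd <- 1 / sqrt(rowMeans(Xc * Xc) + eps)
  xhat <- Xc * istd
  list(out = bias_add(col_scale(xhat, g), b),
       xhat = xhat, istd = istd)
}

ln_bwd <- function(dy, xhat, istd, g) {
  dxhat <- col_scale(dy, g)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  list(dx = (dxhat - m1 - xhat * m2) * istd,
       dg = colSums(dy * xhat), db = colSums(dy))
}

## GELU in its logistic (sigmoid) approximation: x * sigmoid(1.702 x)
gelu <- function(x) {
  s <- 1 / (1 + exp(-1.702 * x))
  x * s
}
gelu_grad <- function(x) {
  s <- 1 / (1 + exp(-1.702 * x))
  s * (1 + 1.702 * x * (1 - s))
}

softmax_rows <- function(S) {
  if (ncol(S) == 1L) return(matrix(1, nrow(S), 1L))
  rmax <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - rmax)
  E / rowSums(E)
}

## ---- forward / backward ----------------------------------------------------

## ids: B x T integer matrix (T may be trimmed to the batch's longest real
## sequence); nreal: non-pad length per example.  dropout_mask: NULL for
## inference, else a B x hidden matrix of 0/(1/(1-p)) factors applied to the
## pooled representation.
encoder_forward <- function(params, spec, ids, nreal, dropout_mask = NULL) {
  B <- nrow(ids); T <- ncol(ids)
  d <- spec$hidden; H <- spec$heads; dh <- d %/% H
  if (T > spec$max_positions) stop_("sequence longer than max_positions")
  flat_ids <- as.vector(t(ids))
  group <- rep(seq_len(B), each = T)
  maskvec <- unlist(lapply(nreal, function(nr) c(rep(1, nr), rep(0, T - nr))),
                    use.names = FALSE)
  X <- params$emb[flat_ids, , drop = FALSE] +
    params$pos[rep(seq_len(T), B), , drop = FALSE]
  layer_cache <- vector("list", spec$layers)
  for (l in seq_len(spec$layers)) {
    P <- function(nm) params[[paste0("L", l, ".", nm)]]
    ln1 <- ln_fwd(X, P("ln1g"), P("ln1b"))
    A <- ln1$out
    Q <- bias_add(A %*% P("Wq"), P("bq"))
    K <- bias_add(A %*% P("Wk"), P("bk"))
    V <- bias_add(A %*% P("Wv"), P("bv"))
    O <- matrix(0, B * T, d)
    attn <- vector("list", B)
    for (b in seq_len(B)) {
      nr <- nreal[b]
      rows <- (b - 1L) * T + seq_len(nr)
      Pb <- vector("list", H)
      for (h in seq_len(H)) {
        cols <- (h - 1L) * dh + seq_len(dh)
        S <- tcrossprod(Q[rows, cols, drop = FALSE],
                        K[rows, cols, drop = FALSE]) / sqrt(dh)
        Pw <- softmax_rows(S)
        Pb[[h]] <- Pw
        O[rows, cols] <- Pw %*% V[rows, cols, drop = FALSE]
      }
      attn[[b]] <- Pb
    }
    AO <- bias_add(O %*% P("Wo"), P("bo"))
    X1 <- X + AO
    ln2 <- ln_fwd(X1, P("ln2g"), P("ln2b"))
    M <- ln2$out
    H1 <- bias_add(M %*% P("W1"), P("b1"))
    G <- gelu(H1)
    FF <- bias_add(G %*% P("W2"), P("b2"))
    X2 <- X1 + FF
    layer_cache[[l]] <- list(ln1 = ln1, A = A, Q = Q, K = K, V = V, O = O,
                             attn = attn, ln2 = ln2, M = M, H1 = H1, G = G)
    X <- X2
  }
  lnf <- ln_fwd(X, params$lnfg, params$lnfb)
  pooled <- rowsum(lnf$out * maskvec, group) / nreal
  pd <- if (is.null(dropout_mask)) pooled else pooled * dropout_mask
  logits <- bias_add(pd %*% params$Wc, params$bc)
  list(logits = logits,
       cache = list(ids = ids, flat_ids = flat_ids, nreal = nreal,
                    group = group, maskvec = maskvec, B = B, T = T,
                    layers = layer_cache, lnf = lnf, pooled = pooled,
                    pd = pd, dropout_mask = dropout_mask))
}

encoder_backward <- function(params, spec, cache, dlogits) {
  B <- cache$B; T <- cache$T
  d <- spec$hidden; H <- spec$heads; dh <- d %/% H
  nreal <- cache$nreal
  grads <- list()
  grads$Wc <- crossprod(cache$pd, dlogits)
  grads$bc <- colSums(dlogits)
  dpd <- tcrossprod(dlogits, params$Wc)
  dpooled <- if (is.null(cache$dropout_mask)) dpd else dpd * cache$dropout_mask
  dY <- (dpooled / nreal)[cache$group, , drop = FALSE] * cache$maskvec
  lb <- ln_bwd(dY, cache$lnf$xhat, cache$lnf$istd, params$lnfg)
  grads$lnfg <- lb$dg; grads$lnfb <- lb$db
  dX <- lb$dx
  for (l in rev(seq_len(spec$layers))) {
    P <- function(nm) params[[paste0("L", l, ".", nm)]]
    gset <- function(nm, val) grads[[paste0("L", l, ".", nm)]] <<- val
    cc <- cache$layers[[l]]
    # feed-forward sublayer (residual: X2 = X1 + FF)
    dFF <- dX
    dG <- tcrossprod(dFF, P("W2"))
    gset("W2", crossprod(cc$G, dFF)); gset("b2", colSums(dFF))
    dH1 <- dG * gelu_grad(cc$H1)
    gset("W1", crossprod(cc$M, dH1)); gset("b1", colSums(dH1))
    dM <- tcrossprod(dH1, P("W1"))
    lb2 <- ln_bwd(dM, cc$ln2$xhat, cc$ln2$istd, P("ln2g"))
    gset("ln2g", lb2$dg); gset("ln2b", lb2$db)
    dX1 <- dX + lb2$dx
    # attention sublayer (residual: X1 = X + AO)
    dAO <- dX1
    dO <- tcrossprod(dAO, P("Wo"))
    gset("Wo", crossprod(cc$O, dAO)); gset("bo", colSums(dAO))
    dQ <- matrix(0, B * T, d); dK <- matrix(0, B * T, d)
    dV <- matrix(0, B * T, d)
    for (b in seq_len(B)) {
      nr <- nreal[b]
      rows <- (b - 1L) * T + seq_len(nr)
      for (h in seq_len(H)) {
        cols <- (h - 1L) * dh + seq_len(dh)
        Pw <- cc$attn[[b]][[h]]
        dOh <- dO[rows, cols, drop = FALSE]
        Vh <- cc$V[rows, cols, drop = FALSE]
        dP <- tcrossprod(dOh, Vh)
        dV[rows, cols] <- crossprod(Pw, dOh)
        dS <- Pw * (dP - rowSums(dP * Pw))
        dQ[rows, cols] <- dS %*% cc$K[rows, cols, drop = FALSE] / sqrt(dh)
        dK[rows, cols] <- crossprod(dS, cc$Q[rows, cols, drop = FALSE]) / sqrt(dh)
      }
    }
    gset("Wq", crossprod(cc$A, dQ)); gset("bq", colSums(dQ))
    gset("Wk", crossprod(cc$A, dK)); gset("bk", colSums(dK))
    gset("Wv", crossprod(cc$A, dV)); gset("bv", colSums(dV))
    dA <- tcrossprod(dQ, P("Wq")) + tcrossprod(dK, P("Wk")) +
      tcrossprod(dV, P("Wv"))
    lb1 <- ln_bwd(dA, cc$ln1$xhat, cc$ln1$istd, P("ln1g"))
    gset("ln1g", lb1$dg); gset("ln1b", lb1$db)
    dX <- dX1 + lb1$dx
  }
  # embeddings
  rs <- rowsum(dX, cache$flat_ids)
  demb <- matrix(0, nrow(params$emb), d)
  demb[as.integer(rownames(rs)), ] <- rs
  grads$emb <- demb
  rp <- rowsum(dX, rep(seq_len(T), B))
  dpos <- matrix(0, nrow(params$pos), d)
  dpos[seq_len(T), ] <- rp
  grads$pos <- dpos
  grads
}

## ---- compiled fast path ----------------------------------------------------

## The per-batch forward/backward also exists as a compiled kernel
## (src/encoder_core.cpp) mirroring the R reference above; the test suite
## asserts the two paths agree.  Training and prediction use the kernel.

drop_row <- function(g) if (is.matrix(g) && nrow(g) == 1L) drop(g) else g

encoder_train_step <- function(params, spec, ids, nreal, dmask, yidx,
                               class_weights) {
  res <- enc_batch(params, ids, as.integer(nreal), spec$layers, spec$heads,
                   if (is.null(dmask)) matrix(0, 0, 0) else dmask,
                   !is.null(dmask), as.integer(yidx),
                   as.numeric(class_weights), TRUE)
  res$grads <- lapply(res$grads, drop_row)
  res
}

encoder_logits <- function(params, spec, ids, nreal) {
  enc_batch(params, ids, as.integer(nreal), spec$layers, spec$heads,
            matrix(0, 0, 0), FALSE, integer(0), c(1, 1), FALSE)$logits
}

## ---- optimizer -------------------------------------------------------------

## Decoupled weight decay applied to projection matrices only (not to
## embeddings, biases or layer-norm parameters), BERT-style.
adamw_init <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(m = zero, v = zero, t = 0L)
}

adamw_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       weight_decay = 0.01) {
  state$t <- state$t + 1L
  t <- state$t
  decay <- grepl("\\.(Wq|Wk|Wv|Wo|W1|W2)$|^Wc$", names(params))
  for (i in seq_along(params)) {
    nm <- names(params)[i]
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    upd <- mhat / (sqrt(vhat) + eps)
    if (decay[i]) upd <- upd + weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}
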