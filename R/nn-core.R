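# Encoder internals: embeddings, multi-head self-attention, layer norm,
# feed-forward, and their exact backward passes. All math is plain R
# matrix code over BLAS; gradients are verified against central finite
# differences in the test suite.

LN_EPS <- 1e-5

# Row-wise softmax; `S` may contain -Inf in masked columns.
softmax_rows <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

layernorm_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  sd <- sqrt(rowMeans(xc * xc) + LN_EPS)
  xhat <- xc / sd
  L <- nrow(x); d <- ncol(x)
  y <- xhat * rep(g, each = L) + rep(b, each = L)
  list(y = y, xhat = xhat, sd = sd)
}

layernorm_bwd <- function(dy, cache, g) {
  L <- nrow(dy)
  dxhat <- dy * rep(g, each = L)
  xhat <- cache$xhat
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / cache$sd
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

gelu_fwd <- function(x) x * pnorm(x)
gelu_grad <- function(x) pnorm(x) + x * dnorm(x)

# Dropout mask scaled by 1/(1-p) (inverted dropout); NULL when inactive.
make_dropout <- function(dim1, dim2, p) {
  if (p <= 0) return(NULL)
  matrix((runif(dim1 * dim2) >= p) / (1 - p), dim1, dim2)
}

# Forward pass through the encoder stack for one token sequence.
# ids: 0-based token ids. Returns final hidden states H (L x d), the
# per-layer caches needed for backward, and (optionally) the full
# attention stack.
encoder_fwd <- function(model, ids, train = FALSE, keep_attention = FALSE) {
  cfg <- model$config
  pr <- model$params
  L <- length(ids)
  if (L > cfg$max_positions) {
    abort(sprintf("Input length %d exceeds max_positions %d.", L, cfg$max_positions))
  }
  if (any(ids < 0L | ids >= cfg$vocab_size)) abort("Token id outside vocabulary.")
  d <- cfg$hidden_dim
  nh <- cfg$n_heads
  dh <- d %/% nh
  drop_p <- if (train) cfg$dropout else 0

  pad_mask <- ids == 0L  # PAD id is 0 by construction
  X <- pr$tok_emb[ids + 1L, , drop = FALSE] + pr$pos_emb[seq_len(L), , drop = FALSE]
  emb_drop <- make_dropout(L, d, drop_p)
  if (!is.null(emb_drop)) X <- X * emb_drop

  caches <- vector("list", cfg$n_layers)
  attn <- if (keep_attention) vector("list", cfg$n_layers) else NULL

  for (l in seq_len(cfg$n_layers)) {
    p <- pr$layers[[l]]
    Q <- X %*% p$Wq + rep(p$bq, each = L)
    K <- X %*% p$Wk + rep(p$bk, each = L)
    V <- X %*% p$Wv + rep(p$bv, each = L)
    A_heads <- vector("list", nh)
    C <- matrix(0, L, d)
    for (h in seq_len(nh)) {
      idx <- ((h - 1L) * dh + 1L):(h * dh)
      S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(dh)
      if (any(pad_mask)) S[, pad_mask] <- -Inf
      A <- softmax_rows(S)
      A_heads[[h]] <- A
      C[, idx] <- A %*% V[, idx, drop = FALSE]
    }
    O <- C %*% p$Wo + rep(p$bo, each = L)
    o_drop <- make_dropout(L, d, drop_p)
    if (!is.null(o_drop)) O <- O * o_drop
    R1 <- X + O
    ln1 <- layernorm_fwd(R1, p$ln1_g, p$ln1_b)
    X1 <- ln1$y
    Hff <- X1 %*% p$W1 + rep(p$b1, each = L)
    G <- gelu_fwd(Hff)
    F2 <- G %*% p$W2 + rep(p$b2, each = L)
    f_drop <- make_dropout(L, d, drop_p)
    if (!is.null(f_drop)) F2 <- F2 * f_drop
    R2 <- X1 + F2
    ln2 <- layernorm_fwd(R2, p$ln2_g, p$ln2_b)
    caches[[l]] <- list(X = X, Q = Q, K = K, V = V, A = A_heads, C = C,
                        o_drop = o_drop, ln1 = ln1, X1 = X1, Hff = Hff, G = G,
                        f_drop = f_drop, ln2 = ln2)
    if (keep_attention) attn[[l]] <- A_heads
    X <- ln2$y
  }
  list(H = X, caches = caches, emb_drop = emb_drop, ids = ids,
       pad_mask = pad_mask, attn = attn)
}

# Backward through the encoder given dL/dH. Accumulates parameter
# gradients into `grads` (a list shaped like params) and returns the
# updated list. Embedding gradients are scattered by token id.
encoder_bwd <- function(model, fwd, dH, grads) {
  cfg <- model$config
  pr <- model$params
  L <- length(fwd$ids)
  d <- cfg$hidden_dim
  nh <- cfg$n_heads
  dh <- d %/% nh
  dX <- dH
  for (l in rev(seq_len(cfg$n_layers))) {
    ca <- fwd$caches[[l]]
    p <- pr$layers[[l]]
    gl <- grads$layers[[l]]

    b2 <- layernorm_bwd(dX, ca$ln2, p$ln2_g)
    gl$ln2_g <- gl$ln2_g + b2$dg
    gl$ln2_b <- gl$ln2_b + b2$db
    dR2 <- b2$dx
    dF2 <- if (is.null(ca$f_drop)) dR2 else dR2 * ca$f_drop
    dX1 <- dR2
    gl$W2 <- gl$W2 + crossprod(ca$G, dF2)
    gl$b2 <- gl$b2 + colSums(dF2)
    dG <- tcrossprod(dF2, p$W2)
    dHff <- dG * gelu_grad(ca$Hff)
    gl$W1 <- gl$W1 + crossprod(ca$X1, dHff)
    gl$b1 <- gl$b1 + colSums(dHff)
    dX1 <- dX1 + tcrossprod(dHff, p$W1)

    b1 <- layernorm_bwd(dX1, ca$ln1, p$ln1_g)
    gl$ln1_g <- gl$ln1_g + b1$dg
    gl$ln1_b <- gl$ln1_b + b1$db
    dR1 <- b1$dx
    dO <- if (is.null(ca$o_drop)) dR1 else dR1 * ca$o_drop
    dXres <- dR1

    gl$Wo <- gl$Wo + crossprod(ca$C, dO)
    gl$bo <- gl$bo + colSums(dO)
    dC <- tcrossprod(dO, p$Wo)
    dQ <- matrix(0, L, d); dK <- matrix(0, L, d); dV <- matrix(0, L, d)
    for (h in seq_len(nh)) {
      idx <- ((h - 1L) * dh + 1L):(h * dh)
      A <- ca$A[[h]]
      dCh <- dC[, idx, drop = FALSE]
      Vh <- ca$V[, idx, drop = FALSE]
      dA <- tcrossprod(dCh, Vh)
      dV[, idx] <- crossprod(A, dCh)
      dS <- A * (dA - rowSums(dA * A))
      dS <- dS / sqrt(dh)
      dQ[, idx] <- dS %*% ca$K[, idx, drop = FALSE]
      dK[, idx] <- crossprod(dS, ca$Q[, idx, drop = FALSE])
    }
    gl$Wq <- gl$Wq + crossprod(ca$X, dQ); gl$bq <- gl$bq + colSums(dQ)
    gl$Wk <- gl$Wk + crossprod(ca$X, dK); gl$bk <- gl$bk + colSums(dK)
    gl$Wv <- gl$Wv + crossprod(ca$X, dV); gl$bv <- gl$bv + colSums(dV)
    dX <- dXres + tcrossprod(dQ, p$Wq) + tcrossprod(dK, p$Wk) + tcrossprod(dV, p$Wv)
    grads$layers[[l]] <- gl
  }
  if (!is.null(fwd$emb_drop)) dX <- dX * fwd$emb_drop
  # Scatter into embedding tables.
  agg <- rowsum(dX, group = fwd$ids, reorder = FALSE)
  rows <- as.integer(rownames(agg)) + 1L
  grads$tok_emb[rows, ] <- grads$tok_emb[rows, , drop = FALSE] + agg
  grads$pos_emb[seq_len(L), ] <- grads$pos_emb[seq_len(L), , drop = FALSE] + dX
  grads
}

# --- parameter plumbing -----------------------------------------------

zero_like_params <- function(params) {
  zl <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  out <- lapply(params, function(p) {
    if (is.list(p)) lapply(p, function(q) if (is.list(q)) lapply(q, zl) else zl(q)) else zl(p)
  })
  out$layers <- lapply(params$layers, function(lay) lapply(lay, zl))
  out
}

# Flatten params/grads (nested lists of numerics) to one vector and back;
# used by the optimizer and the finite-difference tests.
flatten_params <- function(params) {
  unlist(params, use.names = FALSE)
}

unflatten_params <- function(template, vec) {
  rel <- utils::relist(vec, skeleton = template)
  # relist drops matrix dims; restore them
  restore <- function(tpl, val) {
    if (is.list(tpl)) {
      mapply(restore, tpl, val, SIMPLIFY = FALSE)
    } else if (is.matrix(tpl)) {
      matrix(val, nrow(tpl), ncol(tpl))
    } else {
      as.numeric(val)
    }
  }
  restore(template, rel)
}

# Decoupled-weight-decay Adam over the flattened parameter vector.
adam_init <- function(params) {
  v <- flatten_params(params)
  list(m = numeric(length(v)), v = numeric(length(v)), t = 0L)
}

adam_step <- function(params, grads, state, lr = 3e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0, scale = 1) {
  g <- flatten_params(grads) * scale
  x <- flatten_params(params)
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g * g
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  x <- x - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * x)
  list(params = unflatten_params(params, x), state = state)
}
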