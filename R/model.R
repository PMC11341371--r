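#' Configure the sequence model
#'
#' The architecture is a BERT-style encoder over k-mer tokens: learned
#' token and absolute position embeddings feed a stack of Transformer
#' encoder layers (multi-head self-attention + feed-forward, post-layer
#' norm), whose output drives three heads: a masked-language-model head
#' for pre-training, a TextCNN head (three parallel 1-D convolutions,
#' max-pooled, concatenated into one fully connected layer) for EPI
#' classification, and a small domain-discriminator MLP behind a
#' gradient reversal layer for adversarial transfer.
#'
#' Defaults are sized so the model trains on a single CPU core; the
#' `"paper"` preset switches to a large-encoder geometry
#' (hidden 768, 12 heads) suitable for GPU-backed ports.
#'
#' @param vocab An [new_vocab()] object (fixes vocabulary size and k).
#' @param n_layers Number of encoder layers (default 4).
#' @param n_heads Attention heads; must divide `hidden_dim`.
#' @param hidden_dim Embedding/encoder width.
#' @param ff_dim Feed-forward inner width.
#' @param max_positions Maximum assembled input length (must cover
#'   CLS + enhancer tokens + SEP + promoter tokens; 4,992 for the
#'   standard 3,000/2,000-bp windows).
#' @param dropout Dropout probability (training mode only).
#' @param cnn_widths Three distinct TextCNN window widths.
#' @param cnn_filters Filters per width.
#' @param n_classes Output classes (2: non-interacting / interacting).
#' @param pool Feature fed to the domain discriminator: `"cls"` (CLS
#'   position vector) or `"mean"` (mean over positions).
#' @param preset `"default"` or `"paper"`.
#' @return A `model_config` list.
#' @export
model_config <- function(vocab, n_layers = 4L, n_heads = 4L, hidden_dim = 128L,
                         ff_dim = 256L, max_positions = 4992L, dropout = 0.1,
                         cnn_widths = c(4L, 5L, 6L), cnn_filters = 64L,
                         n_classes = 2L, pool = c("cls", "mean"),
                         preset = c("default", "paper")) {
  preset <- match.arg(preset)
  pool <- match.arg(pool)
  if (preset == "paper") {
    n_layers <- 4L; n_heads <- 12L; hidden_dim <- 768L; ff_dim <- 3072L
  }
  if (length(cnn_widths) != 3L || anyDuplicated(cnn_widths)) {
    abort("`cnn_widths` must be three distinct widths.")
  }
  if (n_layers < 1L) abort("`n_layers` must be >= 1.")
  if (hidden_dim %% n_heads != 0L) abort("`hidden_dim` must be divisible by `n_heads`.")
  structure(
    list(vocab_size = vocab$size, k = vocab$k,
         n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
         hidden_dim = as.integer(hidden_dim), ff_dim = as.integer(ff_dim),
         max_positions = as.integer(max_positions), dropout = dropout,
         cnn_widths = as.integer(sort(cnn_widths)), cnn_filters = as.integer(cnn_filters),
         n_classes = as.integer(n_classes), pool = pool, dom_hidden = 32L),
    class = "model_config"
  )
}

#' Serialize a model configuration as YAML
#'
#' @param config A [model_config()].
#' @param path File path.
#' @return `write_model_config()` returns `path` invisibly;
#'   `read_model_config()` returns a `model_config`.
#' @export
write_model_config <- function(config, path) {
  stopifnot(inherits(config, "model_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  raw <- yaml::read_yaml(path)
  vocab_stub <- list(size = raw$vocab_size, k = raw$k)
  cfg <- model_config(
    vocab_stub, n_layers = raw$n_layers, n_heads = raw$n_heads,
    hidden_dim = raw$hidden_dim, ff_dim = raw$ff_dim,
    max_positions = raw$max_positions, dropout = raw$dropout,
    cnn_widths = raw$cnn_widths, cnn_filters = raw$cnn_filters,
    n_classes = raw$n_classes, pool = raw$pool
  )
  cfg
}

#' Initialize a model with random weights
#'
#' Weights are drawn N(0, 0.02^2) (layer-norm gains 1, biases 0),
#' seed-deterministically.
#'
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return An object of class `epi_model` holding `config` and `params`.
#' @export
new_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  d <- config$hidden_dim
  sd0 <- 0.02
  mk <- function(nr, nc) matrix(rnorm(nr * nc, sd = sd0), nr, nc)
  params <- with_seed(seed, {
    layers <- lapply(seq_len(config$n_layers), function(l) {
      list(Wq = mk(d, d), bq = numeric(d), Wk = mk(d, d), bk = numeric(d),
           Wv = mk(d, d), bv = numeric(d), Wo = mk(d, d), bo = numeric(d),
           ln1_g = rep(1, d), ln1_b = numeric(d),
           W1 = mk(d, config$ff_dim), b1 = numeric(config$ff_dim),
           W2 = mk(config$ff_dim, d), b2 = numeric(d),
           ln2_g = rep(1, d), ln2_b = numeric(d))
    })
    cnn <- lapply(config$cnn_widths, function(w) {
      list(W = mk(w * d, config$cnn_filters), b = numeric(config$cnn_filters))
    })
    list(
      tok_emb = mk(config$vocab_size, d),
      pos_emb = mk(config$max_positions, d),
      layers = layers,
      mlm_W = mk(d, config$vocab_size), mlm_b = numeric(config$vocab_size),
      cnn = cnn,
      fc_W = mk(3L * config$cnn_filters, config$n_classes), fc_b = numeric(config$n_classes),
      dom_W1 = mk(d, config$dom_hidden), dom_b1 = numeric(config$dom_hidden),
      dom_W2 = mk(config$dom_hidden, 2L), dom_b2 = numeric(2L)
    )
  })
  structure(list(config = config, params = params,
                 vocab_sig = sprintf("k%d_v%d", config$k, config$vocab_size)),
            class = "epi_model")
}

#' @export
print.epi_model <- function(x, ...) {
  cfg <- x$config
  n_par <- length(flatten_params(x$params))
  cat(sprintf(
    "<epi_model> %d layers x %d heads, hidden %d, ff %d, vocab %d (k=%d), %s parameters\n",
    cfg$n_layers, cfg$n_heads, cfg$hidden_dim, cfg$ff_dim, cfg$vocab_size, cfg$k,
    format(n_par, big.mark = ",")
  ))
  invisible(x)
}

# ---- heads ------------------------------------------------------------

# TextCNN head forward over encoder output H (L x d).
cnn_head_fwd <- function(model, H) {
  cfg <- model$config
  pr <- model$params
  L <- nrow(H); d <- ncol(H)
  pooled <- numeric(0)
  caches <- vector("list", length(cfg$cnn_widths))
  for (wi in seq_along(cfg$cnn_widths)) {
    w <- cfg$cnn_widths[wi]
    if (L < w) abort(sprintf("Input length %d shorter than CNN width %d.", L, w))
    nt <- L - w + 1L
    U <- do.call(cbind, lapply(seq_len(w), function(j) H[j:(nt + j - 1L), , drop = FALSE]))
    Z <- U %*% pr$cnn[[wi]]$W + rep(pr$cnn[[wi]]$b, each = nt)
    Zr <- pmax(Z, 0)
    amax <- max.col(t(Zr), ties.method = "first")  # argmax position per filter
    pmaxv <- Zr[cbind(amax, seq_len(ncol(Zr)))]
    caches[[wi]] <- list(U = U, Z = Z, amax = amax, nt = nt, w = w)
    pooled <- c(pooled, pmaxv)
  }
  logits <- drop(pooled %*% pr$fc_W) + pr$fc_b
  list(pooled = pooled, logits = logits, caches = caches)
}

# Backward from d(logits) to dH plus head parameter grads.
cnn_head_bwd <- function(model, H, head, dlogits, grads) {
  cfg <- model$config
  pr <- model$params
  L <- nrow(H); d <- ncol(H)
  grads$fc_W <- grads$fc_W + outer(head$pooled, dlogits)
  grads$fc_b <- grads$fc_b + dlogits
  dpooled <- drop(pr$fc_W %*% dlogits)
  dH <- matrix(0, L, d)
  offset <- 0L
  for (wi in seq_along(cfg$cnn_widths)) {
    ca <- head$caches[[wi]]
    nf <- cfg$cnn_filters
    dp <- dpooled[(offset + 1L):(offset + nf)]
    offset <- offset + nf
    dZ <- matrix(0, ca$nt, nf)
    sel <- cbind(ca$amax, seq_len(nf))
    dZ[sel] <- dp
    dZ <- dZ * (ca$Z > 0)
    grads$cnn[[wi]]$W <- grads$cnn[[wi]]$W + crossprod(ca$U, dZ)
    grads$cnn[[wi]]$b <- grads$cnn[[wi]]$b + colSums(dZ)
    dU <- tcrossprod(dZ, pr$cnn[[wi]]$W)
    for (j in seq_len(ca$w)) {
      cols <- ((j - 1L) * d + 1L):(j * d)
      dH[j:(ca$nt + j - 1L), ] <- dH[j:(ca$nt + j - 1L), , drop = FALSE] +
        dU[, cols, drop = FALSE]
    }
  }
  list(dH = dH, grads = grads)
}

softmax_vec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# Domain discriminator forward from the pooled feature vector.
dom_head_fwd <- function(model, f) {
  pr <- model$params
  h_pre <- drop(f %*% pr$dom_W1) + pr$dom_b1
  h <- pmax(h_pre, 0)
  logits <- drop(h %*% pr$dom_W2) + pr$dom_b2
  list(h_pre = h_pre, h = h, logits = logits)
}

dom_head_bwd <- function(model, f, head, dlogits, grads) {
  pr <- model$params
  grads$dom_W2 <- grads$dom_W2 + outer(head$h, dlogits)
  grads$dom_b2 <- grads$dom_b2 + dlogits
  dh <- drop(pr$dom_W2 %*% dlogits) * (head$h_pre > 0)
  grads$dom_W1 <- grads$dom_W1 + outer(f, dh)
  grads$dom_b1 <- grads$dom_b1 + dh
  list(df = drop(pr$dom_W1 %*% dh), grads = grads)
}

pool_feature <- function(model, H) {
  if (model$config$pool == "cls") H[1L, ] else colMeans(H)
}

# Spread a pooled-feature gradient back over positions.
unpool_grad <- function(model, df, L) {
  d <- length(df)
  dH <- matrix(0, L, d)
  if (model$config$pool == "cls") {
    dH[1L, ] <- df
  } else {
    dH <- matrix(rep(df, each = L) / L, L, d)
  }
  dH
}

# ---- gradient reversal layer -----------------------------------------

#' Gradient reversal layer
#'
#' `grl_apply()` is the identity in the forward direction; during
#' backpropagation the gradient flowing through it is negated and scaled
#' by `lambda` (`grl_backward()`), which is what drives the encoder
#' toward domain-indistinguishable features in adversarial training.
#'
#' @param x Numeric vector/matrix of features.
#' @param lambda Nonnegative reversal strength.
#' @return `grl_apply()` returns `x` unchanged; `grl_backward()` returns
#'   `-lambda * grad`.
#' @export
#' @examples
#' grl_apply(c(1, 2), lambda = 0.5)        # identity
#' grl_backward(c(6), lambda = 1)          # -6
grl_apply <- function(x, lambda) {
  if (lambda < 0) abort("`lambda` must be nonnegative.")
  x
}

#' @rdname grl_apply
#' @param grad Gradient arriving from downstream.
#' @export
grl_backward <- function(grad, lambda) {
  if (lambda < 0) abort("`lambda` must be nonnegative.")
  -lambda * grad
}

# ---- public forward passes -------------------------------------------

#' Classify enhancer-promoter token sequences
#'
#' Runs the encoder and TextCNN head in evaluation mode (no dropout).
#'
#' @param model An `epi_model`.
#' @param tokens An `epi_tokens` or list of them.
#' @param return_attention If `TRUE`, attach the full attention stack
#'   (per layer, per head) of each input.
#' @return Tibble with one row per input: `p_interact`, `logit0`,
#'   `logit1`, and (optionally) an `attention` list-column of
#'   `attention_stack` objects.
#' @export
forward_classify <- function(model, tokens, return_attention = FALSE) {
  if (inherits(tokens, "epi_tokens")) tokens <- list(tokens)
  res <- lapply(tokens, function(tk) {
    fwd <- encoder_fwd(model, tk$ids, train = FALSE, keep_attention = return_attention)
    head <- cnn_head_fwd(model, fwd$H)
    probs <- softmax_vec(head$logits)
    list(p = probs[2L], logits = head$logits,
         attn = if (return_attention) new_attention_stack(fwd$attn) else NULL)
  })
  out <- tibble(
    p_interact = vapply(res, `[[`, numeric(1L), "p"),
    logit0 = vapply(res, function(r) r$logits[1L], numeric(1L)),
    logit1 = vapply(res, function(r) r$logits[2L], numeric(1L))
  )
  if (return_attention) out$attention <- lapply(res, `[[`, "attn")
  out
}

#' Masked-language-model forward pass
#'
#' @param model An `epi_model`.
#' @param ids 0-based token ids (typically containing MASK).
#' @return Matrix `L x vocab_size` of per-position probability
#'   distributions (rows sum to 1).
#' @export
forward_mlm <- function(model, ids) {
  fwd <- encoder_fwd(model, ids, train = FALSE)
  logits <- fwd$H %*% model$params$mlm_W + rep(model$params$mlm_b, each = nrow(fwd$H))
  softmax_rows(logits)
}

#' Encoder output for a token sequence
#'
#' Token embedding + learned absolute position embedding, passed through
#' the encoder stack. Exposed for embedding-space inspection and as the
#' feature source of the domain discriminator.
#'
#' @param model An `epi_model`.
#' @param tokens An `epi_tokens` or raw 0-based id vector.
#' @return Matrix `L x hidden_dim`.
#' @export
embed_tokens <- function(model, tokens) {
  ids <- if (inherits(tokens, "epi_tokens")) tokens$ids else as.integer(tokens)
  encoder_fwd(model, ids, train = FALSE)$H
}

# ---- combined per-sample loss/gradient -------------------------------

# One forward + backward for a single sample. Any subset of heads may be
# active: `class_label` (0/1) turns on the classifier CE, `mlm_targets`
# (0-based ids with NA at unmasked positions) the MLM CE, and
# `domain_label` (0 = source, 1 = target, with `lambda`) the
# domain head, whose encoder gradient passes through the GRL
# (`reverse = FALSE` is available for wiring diagnostics).
sample_grads <- function(model, ids, grads, class_label = NULL,
                         mlm_targets = NULL, domain_label = NULL,
                         lambda = 0.1, reverse = TRUE, train = TRUE) {
  fwd <- encoder_fwd(model, ids, train = train)
  H <- fwd$H
  L <- nrow(H)
  dH <- matrix(0, L, model$config$hidden_dim)
  losses <- list(class = NA_real_, mlm = NA_real_, domain = NA_real_)
  p_int <- NA_real_

  if (!is.null(class_label)) {
    head <- cnn_head_fwd(model, H)
    probs <- softmax_vec(head$logits)
    y <- class_label + 1L
    losses$class <- -log(max(probs[y], 1e-12))
    p_int <- probs[2L]
    dlogits <- probs
    dlogits[y] <- dlogits[y] - 1
    bk <- cnn_head_bwd(model, H, head, dlogits, grads)
    dH <- dH + bk$dH
    grads <- bk$grads
  }

  if (!is.null(mlm_targets)) {
    sel <- which(!is.na(mlm_targets))
    if (length(sel) == 0L) abort("No masked positions in `mlm_targets`.")
    logits <- H %*% model$params$mlm_W + rep(model$params$mlm_b, each = L)
    P <- softmax_rows(logits)
    tgt <- mlm_targets[sel] + 1L
    losses$mlm <- mean(-log(pmax(P[cbind(sel, tgt)], 1e-12)))
    dlog <- matrix(0, L, ncol(P))
    dlog[sel, ] <- P[sel, , drop = FALSE] / length(sel)
    dlog[cbind(sel, tgt)] <- dlog[cbind(sel, tgt)] - 1 / length(sel)
    grads$mlm_W <- grads$mlm_W + crossprod(H, dlog)
    grads$mlm_b <- grads$mlm_b + colSums(dlog)
    dH <- dH + tcrossprod(dlog, model$params$mlm_W)
  }

  if (!is.null(domain_label)) {
    f <- pool_feature(model, H)
    f_in <- grl_apply(f, lambda)
    dhead <- dom_head_fwd(model, f_in)
    probs <- softmax_vec(dhead$logits)
    y <- domain_label + 1L
    losses$domain <- -log(max(probs[y], 1e-12))
    dlogits <- probs
    dlogits[y] <- dlogits[y] - 1
    bk <- dom_head_bwd(model, f_in, dhead, dlogits, grads)
    grads <- bk$grads
    df_enc <- if (reverse) grl_backward(bk$df, lambda) else bk$df
    dH <- dH + unpool_grad(model, df_enc, L)
  }

  grads <- encoder_bwd(model, fwd, dH, grads)
  list(grads = grads, losses = losses, p_interact = p_int)
}
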