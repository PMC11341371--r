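test_that("analytic gradients match central finite differences", {
  v <- new_vocab(1)
  m <- tiny_model(seed = 42, vocab = v)
  ids <- c(2L, ns$encode_kmers("ACGTAGGT", v), 3L, ns$encode_kmers("TTACG", v))
  mlm_t <- rep(NA_integer_, length(ids))
  mlm_t[c(3L, 7L)] <- c(6L, 8L)

  loss_fn <- function(model) {
    fwd <- ns$encoder_fwd(model, ids, train = FALSE)
    H <- fwd$H
    head <- ns$cnn_head_fwd(model, H)
    lc <- -log(ns$softmax_vec(head$logits)[2L])
    logits <- H %*% model$params$mlm_W + rep(model$params$mlm_b, each = nrow(H))
    P <- ns$softmax_rows(logits)
    sel <- which(!is.na(mlm_t))
    lm <- mean(-log(P[cbind(sel, mlm_t[sel] + 1L)]))
    f <- ns$pool_feature(model, H)
    ld <- -log(ns$softmax_vec(ns$dom_head_fwd(model, f)$logits)[1L])
    # domain arm at unit weight: with reverse = FALSE the GRL scaling is
    # bypassed, so the analytic gradients correspond to weight 1
    lc + lm + ld
  }

  grads <- ns$zero_like_params(m$params)
  sg <- ns$sample_grads(m, ids, grads, class_label = 1L, mlm_targets = mlm_t,
                        domain_label = 0L, lambda = 1, reverse = FALSE,
                        train = FALSE)
  ga <- ns$flatten_params(sg$grads)
  x0 <- ns$flatten_params(m$params)

  idx <- withr::with_seed(7, sort(sample(length(x0), 150)))
  eps <- 1e-5
  gn <- vapply(idx, function(j) {
    xp <- x0; xp[j] <- xp[j] + eps
    xm <- x0; xm[j] <- xm[j] - eps
    mp <- m; mp$params <- ns$unflatten_params(m$params, xp)
    mm <- m; mm$params <- ns$unflatten_params(m$params, xm)
    (loss_fn(mp) - loss_fn(mm)) / (2 * eps)
  }, numeric(1L))
  rel <- abs(gn - ga[idx]) / pmax(1e-6, abs(gn) + abs(ga[idx]))
  expect_lt(max(rel), 1e-3)
})

test_that("attention rows are stochastic at init and after training steps", {
  v <- new_vocab(1)
  m <- tiny_model(seed = 1, vocab = v)
  ids <- c(2L, ns$encode_kmers("ACGTAGGTAC", v), 3L, ns$encode_kmers("GGTACA", v))
  check_stochastic <- function(model) {
    fwd <- ns$encoder_fwd(model, ids, keep_attention = TRUE)
    for (lay in fwd$attn) {
      for (A in lay) {
        expect_true(all(A >= 0))
        expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-5)
      }
    }
  }
  check_stochastic(m)
  # a few optimizer steps must preserve stochasticity
  opt <- ns$adam_init(m$params)
  withr::with_seed(3, {
    for (i in 1:5) {
      g <- ns$zero_like_params(m$params)
      sg <- ns$sample_grads(m, ids, g, class_label = i %% 2L)
      up <- ns$adam_step(m$params, sg$grads, opt, lr = 1e-2)
      m$params <- up$params
      opt <- up$state
    }
  })
  check_stochastic(m)
})

test_that("classifier outputs are normalized, deterministic and repeatable", {
  v <- new_vocab(1)
  m <- tiny_model(seed = 2, vocab = v)
  tk1 <- assemble_pair("ACGTAGGT", "TTACGG", v)
  tk2 <- assemble_pair("ACGTAGGT", "TTACGG", v)
  out <- forward_classify(m, list(tk1, tk2))
  p0 <- 1 - out$p_interact
  expect_equal(out$p_interact[1L], out$p_interact[2L])  # duplicate inputs agree
  expect_true(all(out$p_interact >= 0 & out$p_interact <= 1))
  expect_equal(exp(out$logit0) / (exp(out$logit0) + exp(out$logit1)), p0,
               tolerance = 1e-12)
  out2 <- forward_classify(m, tk1)
  expect_identical(out$p_interact[1L], out2$p_interact[1L])  # bit-reproducible
})

test_that("untrained MLM distributions are near-uniform and normalized", {
  v <- tiny_vocab()
  cfg <- model_config(v, n_layers = 1L, n_heads = 2L, hidden_dim = 16L,
                      ff_dim = 16L, max_positions = 64L, dropout = 0,
                      cnn_widths = c(2L, 3L, 4L), cnn_filters = 2L)
  m <- new_model(cfg, seed = 3)
  ids <- rep(v$specials[["MASK"]], 30L)
  P <- forward_mlm(m, ids)
  expect_equal(rowSums(P), rep(1, 30L), tolerance = 1e-9)
  # cross-entropy of near-uniform logits is about ln(vocab size)
  ce <- mean(-log(P[cbind(1:30, rep(6L, 30L))]))
  expect_equal(ce, log(v$size), tolerance = 0.1 * log(v$size))
})

test_that("embeddings react to token content and position", {
  v <- new_vocab(1)
  m <- tiny_model(seed = 4, vocab = v)
  ids1 <- c(2L, 5L, 6L, 7L, 8L, 3L)
  ids2 <- ids1; ids2[3L] <- 8L
  H1 <- embed_tokens(m, ids1)
  H2 <- embed_tokens(m, ids2)
  expect_equal(dim(H1), c(6L, m$config$hidden_dim))
  expect_gt(max(abs(H1 - H2)), 0)
  # same token at a shifted position (PAD elsewhere) embeds differently
  a <- c(2L, 6L, 0L, 0L)
  b <- c(2L, 0L, 6L, 0L)
  expect_gt(max(abs(embed_tokens(m, a)[2L, ] - embed_tokens(m, b)[3L, ])), 0)
})

test_that("gradient reversal layer is forward-identity with reversed scaled gradient", {
  x <- c(1.5, -2, 3)
  expect_identical(grl_apply(x, lambda = 1), x)
  expect_identical(grl_apply(x, lambda = 0), x)
  # f(x) = x^2 at x = 3: df/dx = 6; through the GRL it must be -lambda * 6
  f_grad <- 2 * 3
  expect_equal(grl_backward(f_grad, lambda = 1), -6)
  expect_equal(grl_backward(f_grad, lambda = 0.5), -3)
  expect_equal(grl_backward(f_grad, lambda = 0), 0)
  expect_error(grl_apply(x, lambda = -1), "nonnegative")
})

test_that("tiny model memorizes a handful of pairs (full path sanity)", {
  v <- new_vocab(1)
  m <- tiny_model(seed = 6, vocab = v)
  withr::with_seed(11, {
    n <- 6L
    toks <- lapply(1:n, function(i) {
      assemble_pair(paste(sample(c("A", "C", "G", "T"), 12, TRUE), collapse = ""),
                    paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = ""), v)
    })
    labels <- rep(c(0L, 1L), 3L)
    opt <- ns$adam_init(m$params)
    for (step in 1:300) {
      g <- ns$zero_like_params(m$params)
      for (i in 1:n) {
        sg <- ns$sample_grads(m, toks[[i]]$ids, g, class_label = labels[i])
        g <- sg$grads
      }
      up <- ns$adam_step(m$params, g, opt, lr = 5e-3, scale = 1 / n)
      m$params <- up$params
      opt <- up$state
    }
  })
  p <- forward_classify(m, toks)$p_interact
  expect_identical(as.integer(p >= 0.5), labels)
})

test_that("input validation: overlong input and out-of-vocab ids error", {
  v <- new_vocab(1)
  m <- tiny_model(seed = 7, vocab = v)
  expect_error(embed_tokens(m, rep(5L, m$config$max_positions + 1L)), "max_positions")
  expect_error(embed_tokens(m, c(2L, 99L)), "vocabulary")
})
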