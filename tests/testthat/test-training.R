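test_that("pre-training corpus tiles genomes without overlap, capped at max_len", {
  g <- c(c1 = rand_dna(100000, seed = 41))
  corpus <- build_pretrain_corpus(g, max_len = 5000)
  expect_length(corpus, 20L)
  expect_true(all(nchar(corpus) == 5000L))
  expect_identical(paste(corpus, collapse = ""), g[[1L]])  # exact non-overlapping tiling

  g2 <- c(c1 = strrep("ACGT", 10))
  c2 <- build_pretrain_corpus(g2, max_len = 10, min_len = 5)
  expect_true(all(nchar(c2) <= 10L))
  expect_identical(paste(c2, collapse = ""), g2[[1L]])

  expect_length(build_pretrain_corpus(c(c1 = strrep("N", 500))), 0L)
  expect_length(build_pretrain_corpus(character(0)), 0L)
  # N runs split the tiling and never appear in chunks
  gN <- c(c1 = paste0(rand_dna(400, 42), strrep("N", 50), rand_dna(300, 43)))
  cN <- build_pretrain_corpus(gN, max_len = 250, min_len = 10)
  expect_false(any(grepl("N", cN)))
  expect_true(all(nchar(cN) <= 250L))
})

test_that("masking selects 15% of usable tokens and never specials", {
  v <- tiny_vocab()
  ids <- assemble_pair(rand_dna(105, seed = 44), rand_dna(20, seed = 45), v)$ids
  # 100 + 15 usable tokens
  usable <- sum(ids >= 5L)
  mk <- mask_tokens(ids, v, rate = 0.15, seed = 3)
  expect_equal(nrow(mk$plan), round(0.15 * usable))
  expect_equal(sum(!is.na(mk$targets)), round(0.15 * usable))
  # 20 usable tokens -> 3 selected
  ids20 <- c(2L, ns$encode_kmers(rand_dna(25, seed = 46), v), 3L)
  expect_equal(nrow(mask_tokens(ids20, v, seed = 1)$plan), 3L)
  # determinism
  expect_identical(mask_tokens(ids, v, seed = 9), mask_tokens(ids, v, seed = 9))
  expect_error(mask_tokens(c(2L, 3L), v), "maskable")
})

test_that("masking never hits special positions across many trials", {
  v <- tiny_vocab()
  ids <- assemble_pair(rand_dna(40, seed = 47), rand_dna(30, seed = 48), v)$ids
  special_pos <- which(ids < 5L) - 1L
  hit <- FALSE
  for (s in 1:400) {
    mk <- mask_tokens(ids, v, seed = s)
    if (any(mk$plan$position %in% special_pos)) hit <- TRUE
    # masked ids only change at plan positions
    changed <- which(mk$masked_ids != ids) - 1L
    expect_true(all(changed %in% mk$plan$position))
  }
  expect_false(hit)
})

test_that("masking actions follow the 80/10/10 rule in aggregate", {
  v <- tiny_vocab()
  ids <- assemble_pair(rand_dna(400, seed = 49), rand_dna(300, seed = 50), v)$ids
  acts <- unlist(lapply(1:30, function(s) mask_tokens(ids, v, seed = s)$plan$action))
  freq <- table(acts) / length(acts)
  expect_lt(abs(freq[["MASK"]] - 0.8), 0.03)
  expect_lt(abs(freq[["random"]] - 0.1), 0.03)
  expect_lt(abs(freq[["keep"]] - 0.1), 0.03)
})

test_that("pretraining reduces MLM loss and is seed-reproducible", {
  v <- new_vocab(2)  # 21-token vocabulary keeps the toy problem tractable
  cfg <- model_config(v, n_layers = 1L, n_heads = 2L, hidden_dim = 16L,
                      ff_dim = 32L, max_positions = 40L, dropout = 0,
                      cnn_widths = c(2L, 3L, 4L), cnn_filters = 2L)
  corpus <- vapply(1:30, function(i) rand_dna(60, seed = 900 + i), character(1L))
  m <- new_model(cfg, seed = 10)
  pt <- pretrain(m, corpus, v, steps = 60, batch_size = 4, lr = 3e-3,
                 max_tokens = 30, val_every = 30, seed = 5)
  expect_lt(mean(tail(pt$trace$loss, 5)), pt$trace$loss[1L])
  pt2 <- pretrain(new_model(cfg, seed = 10), corpus, v, steps = 60, batch_size = 4,
                  lr = 3e-3, max_tokens = 30, val_every = 30, seed = 5)
  expect_identical(pt$trace$loss, pt2$trace$loss)
  # learning rate 0 leaves the weights untouched (loss still varies with
  # the random masking of each step)
  m0 <- new_model(cfg, seed = 10)
  pt0 <- pretrain(m0, corpus, v, steps = 10, batch_size = 4,
                  lr = 0, max_tokens = 30, val_every = 100, seed = 5)
  expect_identical(ns$flatten_params(pt0$model$params),
                   ns$flatten_params(m0$params))
})

test_that("pretraining memorizes a single short sequence", {
  v <- new_vocab(2)
  cfg <- model_config(v, n_layers = 1L, n_heads = 2L, hidden_dim = 16L,
                      ff_dim = 32L, max_positions = 40L, dropout = 0,
                      cnn_widths = c(2L, 3L, 4L), cnn_filters = 2L)
  m <- new_model(cfg, seed = 11)
  seqs <- rand_dna(21, seed = 77)  # 20 tokens
  pt <- pretrain(m, rep(seqs, 4L), v, steps = 400, batch_size = 2, lr = 3e-3,
                 max_tokens = 20, val_every = 200, patience = 10, seed = 6)
  # every masked token must be recovered top-1
  ids <- c(v$specials[["CLS"]], ns$encode_kmers(seqs, v))
  ok <- TRUE
  for (s in 1:5) {
    mk <- mask_tokens(ids, v, seed = s)
    P <- forward_mlm(pt$model, mk$masked_ids)
    sel <- which(!is.na(mk$targets))
    pred <- max.col(P[sel, , drop = FALSE]) - 1L
    ok <- ok && all(pred == mk$targets[sel])
  }
  expect_true(ok)
})

test_that("augment_balance equalizes classes with provenance and overlap", {
  ds <- tiny_dataset(seed = 24, n_pos = 10, n_neg = 100)
  bal <- augment_balance(ds$pairs, ds$genome, shift_bound = 50, seed = 3)
  expect_equal(sum(bal$label == 1L), 100L)
  expect_equal(sum(bal$label == 0L), 100L)
  expect_equal(sum(bal$augmented), 90L)
  # originals retained untouched
  expect_true(all(ds$pairs$record %in% bal$record[!bal$augmented]))
  # augmented windows overlap their source by >= length - shift_bound
  aug <- bal[bal$augmented, ]
  src <- bal[match(aug$source_record, bal$record), ]
  ov <- pmin(aug$enh_end, src$enh_end) - pmax(aug$enh_start, src$enh_start)
  len <- aug$enh_end - aug$enh_start
  expect_true(all(ov >= len - 50L))
  # re-extracted sequences match their shifted coordinates
  re <- add_pair_sequences(aug[, setdiff(names(aug), c("enh_seq", "prom_seq"))],
                           ds$genome)
  expect_identical(re$enh_seq, aug$enh_seq)
  # already balanced input is returned unchanged (modulo bookkeeping columns)
  even <- ds$pairs[c(which(ds$pairs$label == 1L)[1:5], which(ds$pairs$label == 0L)[1:5]), ]
  bal2 <- augment_balance(even, ds$genome, seed = 4)
  expect_equal(nrow(bal2), 10L)
  expect_false(any(bal2$augmented))
})

test_that("finetune enforces vocabulary agreement", {
  ds <- tiny_dataset(seed = 25, n_pos = 4, n_neg = 8)
  m <- tiny_model(seed = 12, vocab = new_vocab(1))
  expect_error(finetune(m, ds$pairs, ds$pairs, tiny_vocab(), epochs = 1),
               "mismatch")
})

test_that("permuted labels give chance-level validation AUROC", {
  v <- tiny_vocab()
  ds <- tiny_dataset(seed = 26, n_pos = 25, n_neg = 50)
  pairs <- ds$pairs
  pairs$label <- withr::with_seed(13, sample(pairs$label))
  parts <- split_dataset(pairs, c(0.7, 0.3, 0), seed = 2)
  parts$.split[parts$.split == "test"] <- "validation"
  train <- parts[parts$.split == "train", ]
  val <- parts[parts$.split == "validation", ]
  m <- desk_model(v, seed = 14)
  fit <- finetune(m, train, val, v, epochs = 1, batch_size = 8, lr = 1e-3, seed = 15)
  expect_gt(glance(fit)$auroc, 0.25)
  expect_lt(glance(fit)$auroc, 0.75)
})

test_that("domain loss matches analytic values in degenerate cases", {
  v <- new_vocab(1)
  m <- tiny_model(seed = 16, vocab = v)
  ids <- c(2L, 5L, 6L, 7L, 3L, 8L)
  # force uniform domain predictions: zero the domain head
  m$params$dom_W1[] <- 0; m$params$dom_b1[] <- 0
  m$params$dom_W2[] <- 0; m$params$dom_b2[] <- 0
  g <- ns$zero_like_params(m$params)
  sg <- ns$sample_grads(m, ids, g, domain_label = 0L, lambda = 0.1, train = FALSE)
  expect_equal(sg$losses$domain, log(2), tolerance = 1e-12)
  # a confident correct domain head drives the loss toward zero
  m$params$dom_b2 <- c(50, -50)
  sg2 <- ns$sample_grads(m, ids, g, domain_label = 0L, lambda = 0.1, train = FALSE)
  expect_lt(sg2$losses$domain, 1e-8)
})

test_that("GRL wiring: domain-only encoder gradients flip sign exactly", {
  v <- new_vocab(1)
  m <- tiny_model(seed = 17, vocab = v)
  ids <- c(2L, 5L, 6L, 7L, 3L, 8L)
  g1 <- ns$sample_grads(m, ids, ns$zero_like_params(m$params), domain_label = 1L,
                        lambda = 1, reverse = TRUE, train = FALSE)$grads
  g2 <- ns$sample_grads(m, ids, ns$zero_like_params(m$params), domain_label = 1L,
                        lambda = 1, reverse = FALSE, train = FALSE)$grads
  enc1 <- ns$flatten_params(g1$layers)
  enc2 <- ns$flatten_params(g2$layers)
  cosine <- sum(enc1 * enc2) / sqrt(sum(enc1^2) * sum(enc2^2))
  expect_equal(cosine, -1)
  expect_equal(enc1, -enc2)
  # the domain head itself trains unreversed in both cases
  expect_equal(g1$dom_W2, g2$dom_W2)
  # embeddings flip too
  expect_equal(g1$tok_emb, -g2$tok_emb)
})

test_that("train_dann validates inputs and logs a consistent loss breakdown", {
  v <- tiny_vocab()
  src <- tiny_dataset(seed = 27, n_pos = 6, n_neg = 6)$pairs
  tgt <- tiny_dataset(seed = 28, n_pos = 6, n_neg = 6)$pairs
  m <- desk_model(v, seed = 18)
  expect_error(train_dann(m, src, tgt[0, ], v), "Empty target")
  fit <- train_dann(m, src, tgt, v, lambda = 0.3, epochs = 1, batch_size = 3,
                    lr = 1e-3, seed = 19)
  tr <- tidy(fit)
  expect_true(all(tr$L_class >= 0))
  expect_true(all(tr$L_domain >= 0))
  expect_equal(tr$L_total, tr$L_class + tr$lambda * tr$L_domain)
  expect_true(all(tr$lambda == 0.3))
  ramp <- train_dann(m, src, tgt, v, lambda = 0.3, schedule = "ramp", epochs = 1,
                     batch_size = 3, lr = 1e-3, seed = 19)
  expect_true(all(diff(tidy(ramp)$lambda) > 0))
  expect_lt(max(tidy(ramp)$lambda), 0.3)
})

test_that("with lambda = 0, adversarial training matches plain fine-tuning", {
  v <- tiny_vocab()
  src <- tiny_dataset(seed = 33, n_pos = 20, n_neg = 40)
  tgt <- tiny_dataset(seed = 34, n_pos = 10, n_neg = 20)
  parts <- split_dataset(src$pairs, c(0.7, 0.3, 0), seed = 5)
  train <- parts[parts$.split == "train", ]
  val <- parts[parts$.split == "validation", ]
  init <- desk_model(v, seed = 35)
  dann0 <- train_dann(init, train, tgt$pairs, v, lambda = 0, epochs = 2,
                      batch_size = 4, lr = 1e-3, seed = 36)
  plain <- finetune(init, train, val, v, epochs = 2, batch_size = 4,
                    lr = 1e-3, seed = 36)
  a_dann <- evaluate_pairs(dann0$model, val, v)$auroc
  a_plain <- evaluate_pairs(plain$model, val, v)$auroc
  expect_lt(abs(a_dann - a_plain), 0.02)
  # and the encoder receives no domain gradient at lambda = 0
  expect_true(all(tidy(dann0)$lambda == 0))
})

test_that("model configurations round-trip through YAML", {
  v <- tiny_vocab()
  cfg <- model_config(v, n_layers = 2L, n_heads = 2L, hidden_dim = 32L,
                      ff_dim = 48L, max_positions = 256L, dropout = 0.05,
                      cnn_widths = c(3L, 5L, 7L), cnn_filters = 8L)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_model_config(cfg, f)
  back <- read_model_config(f)
  expect_equal(unclass(back), unclass(cfg))
})

test_that("checkpoints round-trip and validate the vocabulary", {
  v <- new_vocab(1)
  m <- tiny_model(seed = 20, vocab = v)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  back <- load_checkpoint(f, vocab = v)
  expect_equal(back$params, m$params)
  expect_error(load_checkpoint(f, vocab = tiny_vocab()), "mismatch")
})
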