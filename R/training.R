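# Pre-training corpus construction, masking, fine-tuning, balancing and
# domain-adversarial training.

#' Build a masked-language-model pre-training corpus from a genome
#'
#' Tiles every contig, in order, into non-overlapping chunks of at most
#' `max_len` bases. Runs of N split the tiling (no chunk contains N);
#' terminal fragments shorter than `min_len` are dropped. Deterministic:
#' no randomness is involved.
#'
#' @param genome Named character vector of contigs.
#' @param max_len Maximum chunk length in bases (default 5,000).
#' @param min_len Minimum chunk length kept.
#' @return Character vector of DNA sequences (possibly empty).
#' @export
build_pretrain_corpus <- function(genome, max_len = 5000L, min_len = 30L) {
  if (length(genome) == 0L) return(character(0))
  max_len <- as.integer(max_len)
  out <- list()
  for (ci in seq_along(genome)) {
    segments <- strsplit(genome[[ci]], "N+")[[1L]]
    segments <- segments[nchar(segments) > 0L]
    for (seg in segments) {
      n <- nchar(seg)
      starts <- seq.int(1L, n, by = max_len)
      chunks <- substring(seg, starts, pmin(starts + max_len - 1L, n))
      out[[length(out) + 1L]] <- chunks[nchar(chunks) >= min_len]
    }
  }
  unlist(out) %||% character(0)
}

#' Select and apply a masking plan to a token sequence
#'
#' Selects `max(1, round(rate * n_usable))` non-special positions
#' (special tokens PAD/UNK/CLS/SEP/MASK are never maskable) and applies
#' the 80/10/10 rule: 80% become MASK, 10% a random k-mer token, 10%
#' keep their original id. Targets carry the original id at selected
#' positions and NA elsewhere.
#'
#' @param ids 0-based token id vector (may include specials).
#' @param vocab The `epi_vocab` in use.
#' @param rate Masking rate (default 0.15).
#' @param seed Integer seed; identical seeds give identical plans.
#' @return List: `masked_ids`, `targets` (NA off-plan), `plan` (tibble
#'   with 0-based `position` and `action` in MASK/random/keep).
#' @export
mask_tokens <- function(ids, vocab, rate = 0.15, seed = 1L) {
  usable <- which(ids >= 5L)
  if (length(usable) == 0L) abort("No maskable (non-special) tokens in input.")
  n_sel <- max(1L, round(rate * length(usable)))
  with_seed(seed, {
    sel <- sort(sample(usable, n_sel))
    action <- sample(c("MASK", "random", "keep"), n_sel, replace = TRUE,
                     prob = c(0.8, 0.1, 0.1))
    masked <- ids
    masked[sel[action == "MASK"]] <- vocab$specials[["MASK"]]
    n_rand <- sum(action == "random")
    if (n_rand > 0L) {
      masked[sel[action == "random"]] <- sample.int(vocab$size - 5L, n_rand, replace = TRUE) + 4L
    }
  })
  targets <- rep(NA_integer_, length(ids))
  targets[sel] <- ids[sel]
  list(masked_ids = masked, targets = targets,
       plan = tibble(position = sel - 1L, action = action))
}

# Crop a (possibly long) corpus sequence to at most `max_tokens` k-mer
# tokens starting at a random in-bounds offset, and prepend CLS.
crop_tokens <- function(seq, vocab, max_tokens) {
  ids <- encode_kmers(seq, vocab)
  if (length(ids) > max_tokens) {
    s <- sample.int(length(ids) - max_tokens + 1L, 1L)
    ids <- ids[s:(s + max_tokens - 1L)]
  }
  c(vocab$specials[["CLS"]], ids)
}

#' Pre-train a model with masked language modelling
#'
#' Each step draws a minibatch of corpus sequences, crops each to at
#' most `max_tokens` tokens, masks 15% of them and minimizes the
#' cross-entropy of the masked positions. A held-out fraction of the
#' corpus provides a validation MLM loss, checked every `val_every`
#' steps for plateau-based early stopping.
#'
#' @param model An `epi_model` (fresh from [new_model()]).
#' @param corpus Character vector of DNA sequences
#'   (see [build_pretrain_corpus()]).
#' @param vocab The `epi_vocab` in use.
#' @param steps Maximum optimizer steps.
#' @param batch_size Sequences per step.
#' @param lr Adam learning rate (linear warmup over `warmup` steps).
#' @param warmup Warmup steps.
#' @param max_tokens Crop length in tokens.
#' @param mask_rate Masking rate.
#' @param val_fraction Held-out fraction of the corpus.
#' @param val_every Steps between validation checks.
#' @param patience Consecutive non-improving checks tolerated.
#' @param seed Integer seed (full determinism on CPU).
#' @return Object of class `epi_pretrain`: `model`, `trace` (tibble
#'   `step`, `loss`, `val_loss`), `steps_run`.
#' @export
pretrain <- function(model, corpus, vocab, steps = 200L, batch_size = 8L,
                     lr = 3e-4, warmup = 20L, max_tokens = 128L,
                     mask_rate = 0.15, val_fraction = 0.1, val_every = 50L,
                     patience = 3L, seed = 1L) {
  if (length(corpus) == 0L) abort("Empty pre-training corpus.")
  check_vocab(model, vocab)
  with_seed(seed, {
    n_val <- max(1L, floor(val_fraction * length(corpus)))
    val_idx <- if (length(corpus) > 1L) sample(seq_along(corpus), n_val) else integer(0)
    train_set <- if (length(val_idx) > 0L) corpus[-val_idx] else corpus
    val_set <- corpus[val_idx]
    if (length(train_set) == 0L) { train_set <- corpus; val_set <- corpus }

    opt <- adam_init(model$params)
    trace <- vector("list", steps)
    best_val <- Inf; bad <- 0L; steps_run <- 0L
    val_loss_now <- NA_real_

    val_loss <- function() {
      tot <- 0; cnt <- 0L
      for (s in val_set[seq_len(min(8L, length(val_set)))]) {
        ids <- crop_tokens(s, vocab, max_tokens)
        mk <- mask_tokens(ids, vocab, rate = mask_rate,
                          seed = child_seed(seed, 999L + cnt))
        P <- forward_mlm(model, mk$masked_ids)
        selp <- which(!is.na(mk$targets))
        tot <- tot + mean(-log(pmax(P[cbind(selp, mk$targets[selp] + 1L)], 1e-12)))
        cnt <- cnt + 1L
      }
      tot / max(cnt, 1L)
    }

    for (st in seq_len(steps)) {
      batch <- sample(seq_along(train_set), min(batch_size, length(train_set)),
                      replace = length(train_set) < batch_size)
      grads <- zero_like_params(model$params)
      loss_sum <- 0
      for (bi in batch) {
        ids <- crop_tokens(train_set[bi], vocab, max_tokens)
        mk <- mask_tokens(ids, vocab, rate = mask_rate,
                          seed = sample.int(2^30, 1L))
        sg <- sample_grads(model, mk$masked_ids, grads, mlm_targets = mk$targets,
                           train = TRUE)
        grads <- sg$grads
        loss_sum <- loss_sum + sg$losses$mlm
      }
      loss <- loss_sum / length(batch)
      if (!is.finite(loss)) {
        abort(sprintf("MLM loss diverged (non-finite) at step %d; lower the learning rate.", st))
      }
      lr_t <- lr * min(1, st / max(1L, warmup))
      up <- adam_step(model$params, grads, opt, lr = lr_t, scale = 1 / length(batch))
      model$params <- up$params
      opt <- up$state
      steps_run <- st
      if (st %% val_every == 0L || st == steps) {
        val_loss_now <- val_loss()
        if (val_loss_now < best_val - 1e-4) {
          best_val <- val_loss_now; bad <- 0L
        } else {
          bad <- bad + 1L
        }
      }
      trace[[st]] <- tibble(step = st, loss = loss, val_loss = val_loss_now)
      if (bad >= patience) break
    }
    structure(list(model = model, trace = dplyr::bind_rows(trace[seq_len(steps_run)]),
                   steps_run = steps_run),
              class = "epi_pretrain")
  })
}

check_vocab <- function(model, vocab) {
  sig <- sprintf("k%d_v%d", vocab$k, vocab$size)
  if (!identical(model$vocab_sig, sig)) {
    abort(sprintf("Vocabulary mismatch: model built for %s, got %s.", model$vocab_sig, sig))
  }
  invisible(TRUE)
}

#' Balance classes by window-shift augmentation
#'
#' Oversamples the minority class by re-extracting each element window
#' shifted by an independent uniform integer offset in
#' `[-shift_bound, shift_bound]` around the original interval (offsets
#' that would overrun the contig are resampled). Originals are always
#' retained; augmented rows are marked `augmented = TRUE` and carry
#' `source_record`. Each augmented window overlaps its source by at
#' least `length - shift_bound` bases.
#'
#' @param pairs Training pair tibble with sequences and coordinates.
#' @param genome The genome the coordinates refer to.
#' @param shift_bound Maximum absolute shift in bases (default 50).
#' @param seed Integer seed.
#' @return Balanced tibble (equal label counts) containing all input
#'   rows plus augmented minority rows.
#' @export
augment_balance <- function(pairs, genome, shift_bound = 50L, seed = 1L) {
  n1 <- sum(pairs$label == 1L); n0 <- sum(pairs$label == 0L)
  if (n1 == 0L || n0 == 0L) abort("Need at least one record of each class.")
  if (!"record" %in% names(pairs)) pairs$record <- seq_len(nrow(pairs))
  if (!"augmented" %in% names(pairs)) pairs$augmented <- FALSE
  if (!"source_record" %in% names(pairs)) pairs$source_record <- pairs$record
  if (n1 == n0) return(pairs)
  minority <- if (n1 < n0) 1L else 0L
  need <- abs(n0 - n1)
  min_idx <- which(pairs$label == minority)
  with_seed(seed, {
    src <- rep_len(sample(min_idx), need)
    rows <- vector("list", need)
    for (j in seq_len(need)) {
      i <- src[j]
      row <- pairs[i, ]
      for (el in c("enh", "prom")) {
        st_col <- paste0(el, "_start"); en_col <- paste0(el, "_end")
        ch <- row[[paste0(el, "_chrom")]]
        clen <- nchar(genome[[ch]])
        len <- row[[en_col]] - row[[st_col]]
        for (try in 1:100) {
          off <- sample.int(2L * shift_bound + 1L, 1L) - shift_bound - 1L
          ns <- row[[st_col]] + off
          if (ns >= 0L && ns + len <= clen) break
          off <- 0L; ns <- row[[st_col]]
        }
        row[[st_col]] <- ns
        row[[en_col]] <- ns + len
        str_col <- paste0(el, "_strand")
        strand <- if (str_col %in% names(row)) row[[str_col]] else "+"
        row[[paste0(el, "_seq")]] <- extract_interval(genome, ch, ns, ns + len, strand)
      }
      row$augmented <- TRUE
      row$source_record <- pairs$record[i]
      rows[[j]] <- row
    }
    aug <- dplyr::bind_rows(rows)
    aug$record <- max(pairs$record) + seq_len(nrow(aug))
    out <- dplyr::bind_rows(pairs, aug)
  })
  out
}

#' Fine-tune a classifier on labelled enhancer-promoter pairs
#'
#' Minimizes classification cross-entropy with Adam (linear warmup),
#' evaluating AUROC/AUPR/F1 on the validation set after every epoch and
#' keeping the weights of the best validation-AUROC epoch.
#'
#' @param model Starting `epi_model` (pre-trained or fresh).
#' @param train_pairs,val_pairs Pair tibbles with `enh_seq`, `prom_seq`,
#'   `label` (train typically balanced via [augment_balance()]).
#' @param vocab The `epi_vocab` the model was built with (mismatch is an
#'   error).
#' @param epochs Training epochs.
#' @param batch_size Records per optimizer step.
#' @param lr Adam learning rate.
#' @param warmup Warmup steps.
#' @param weight_decay Decoupled weight decay.
#' @param steps_per_epoch Optional cap on optimizer steps per epoch
#'   (records are subsampled per epoch when set).
#' @param seed Integer seed.
#' @return Object of class `epi_classifier`: `model` (best weights),
#'   `trace` (per-epoch tibble: `epoch`, `train_loss`, `auroc`, `aupr`,
#'   `f1`), `best_epoch`.
#' @export
finetune <- function(model, train_pairs, val_pairs, vocab, epochs = 2L,
                     batch_size = 8L, lr = 3e-4, warmup = 20L,
                     weight_decay = 0, steps_per_epoch = NULL, seed = 1L) {
  check_vocab(model, vocab)
  n <- nrow(train_pairs)
  toks <- lapply(seq_len(n), function(i) {
    assemble_pair(train_pairs$enh_seq[i], train_pairs$prom_seq[i], vocab)$ids
  })
  labels <- train_pairs$label
  with_seed(seed, {
    opt <- adam_init(model$params)
    best <- list(auroc = -Inf, params = model$params, epoch = 0L)
    trace <- vector("list", epochs)
    gstep <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      if (!is.null(steps_per_epoch)) {
        ord <- ord[seq_len(min(n, steps_per_epoch * batch_size))]
      }
      loss_sum <- 0; nb <- 0L
      for (bs in split(ord, ceiling(seq_along(ord) / batch_size))) {
        grads <- zero_like_params(model$params)
        bl <- 0
        for (i in bs) {
          sg <- sample_grads(model, toks[[i]], grads, class_label = labels[i],
                             train = TRUE)
          grads <- sg$grads
          bl <- bl + sg$losses$class
        }
        gstep <- gstep + 1L
        lr_t <- lr * min(1, gstep / max(1L, warmup))
        up <- adam_step(model$params, grads, opt, lr = lr_t,
                        weight_decay = weight_decay, scale = 1 / length(bs))
        model$params <- up$params
        opt <- up$state
        loss_sum <- loss_sum + bl / length(bs)
        nb <- nb + 1L
        if (!is.finite(bl)) abort("Classification loss diverged (non-finite).")
      }
      ev <- evaluate_pairs(model, val_pairs, vocab)
      trace[[ep]] <- tibble(epoch = ep, train_loss = loss_sum / max(nb, 1L),
                            auroc = ev$auroc, aupr = ev$aupr, f1 = ev$f1)
      if (ev$auroc > best$auroc) {
        best <- list(auroc = ev$auroc, params = model$params, epoch = ep)
      }
    }
    model$params <- best$params
    structure(list(model = model, trace = dplyr::bind_rows(trace),
                   best_epoch = best$epoch),
              class = "epi_classifier")
  })
}

#' @export
print.epi_classifier <- function(x, ...) {
  b <- x$trace[x$trace$epoch == x$best_epoch, ]
  cat(sprintf("<epi_classifier> %d epochs; best epoch %d: AUROC %.3f, AUPR %.3f, F1 %.3f\n",
              nrow(x$trace), x$best_epoch, b$auroc, b$aupr, b$f1))
  invisible(x)
}

#' Domain-adversarial training for cross-cell-line transfer
#'
#' Implements the DANN objective: the classifier head is trained with
#' cross-entropy on *labelled source* records only; the domain
#' discriminator is trained to tell source from target on both domains;
#' and the encoder receives the domain gradient through the gradient
#' reversal layer (negated, scaled by `lambda`), pushing its features
#' toward domain indistinguishability. Per step the losses are
#' `L_class` (mean source classification NLL), `L_domain` (mean domain
#' NLL over both domains) and the bookkeeping total
#' `L_total = L_class + lambda * L_domain` (the reversal itself is
#' performed by the GRL, so the logged total is the objective each head
#' descends).
#'
#' Target labels, if present in `target_pairs`, are ignored here; they
#' are for evaluation only.
#'
#' @param model Starting `epi_model`.
#' @param source_pairs Labelled source-domain pair tibble.
#' @param target_pairs Unlabelled target-domain pair tibble (non-empty).
#' @param vocab The `epi_vocab` in use.
#' @param lambda Domain-loss balance weight (`>= 0`).
#' @param schedule `"constant"` or `"ramp"` (the standard
#'   `2 / (1 + exp(-10 p)) - 1` ramp over training progress `p`, scaled
#'   by `lambda`).
#' @param epochs Epochs over the source set.
#' @param batch_size Source records per step (the same number of target
#'   records is drawn alongside).
#' @param lr,warmup Optimizer settings.
#' @param steps_per_epoch Optional cap on steps per epoch.
#' @param seed Integer seed.
#' @return Object of class `epi_dann`: `model`, `trace` (per-step
#'   tibble: `step`, `L_class`, `L_domain`, `L_total`, `lambda`),
#'   `lambda`, `schedule`.
#' @export
train_dann <- function(model, source_pairs, target_pairs, vocab, lambda = 0.1,
                       schedule = c("constant", "ramp"), epochs = 2L,
                       batch_size = 4L, lr = 3e-4, warmup = 20L,
                       steps_per_epoch = NULL, seed = 1L) {
  schedule <- match.arg(schedule)
  if (lambda < 0) abort("`lambda` must be nonnegative.")
  if (nrow(target_pairs) == 0L) abort("Empty target set: DANN needs unlabelled target records.")
  check_vocab(model, vocab)
  ns <- nrow(source_pairs); nt <- nrow(target_pairs)
  stoks <- lapply(seq_len(ns), function(i) {
    assemble_pair(source_pairs$enh_seq[i], source_pairs$prom_seq[i], vocab)$ids
  })
  ttoks <- lapply(seq_len(nt), function(i) {
    assemble_pair(target_pairs$enh_seq[i], target_pairs$prom_seq[i], vocab)$ids
  })
  slab <- source_pairs$label
  with_seed(seed, {
    opt <- adam_init(model$params)
    steps_ep <- if (is.null(steps_per_epoch)) ceiling(ns / batch_size) else steps_per_epoch
    total_steps <- epochs * steps_ep
    trace <- vector("list", total_steps)
    gstep <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(ns)
      for (st in seq_len(steps_ep)) {
        sb <- ord[(((st - 1L) * batch_size + seq_len(batch_size) - 1L) %% ns) + 1L]
        sb <- unique(sb)
        tb <- sample.int(nt, length(sb), replace = nt < length(sb))
        gstep <- gstep + 1L
        p <- gstep / total_steps
        lam <- if (schedule == "constant") lambda else lambda * (2 / (1 + exp(-10 * p)) - 1)
        grads <- zero_like_params(model$params)
        lc <- 0; ld <- 0
        for (i in sb) {
          sg <- sample_grads(model, stoks[[i]], grads, class_label = slab[i],
                             domain_label = 0L, lambda = lam, train = TRUE)
          grads <- sg$grads
          lc <- lc + sg$losses$class
          ld <- ld + sg$losses$domain
        }
        for (j in tb) {
          sg <- sample_grads(model, ttoks[[j]], grads, domain_label = 1L,
                             lambda = lam, train = TRUE)
          grads <- sg$grads
          ld <- ld + sg$losses$domain
        }
        lc <- lc / length(sb)
        ld <- ld / (length(sb) + length(tb))
        if (!is.finite(lc + ld)) abort("DANN loss diverged (non-finite).")
        lr_t <- lr * min(1, gstep / max(1L, warmup))
        up <- adam_step(model$params, grads, opt, lr = lr_t,
                        scale = 1 / (length(sb) + length(tb)))
        model$params <- up$params
        opt <- up$state
        trace[[gstep]] <- tibble(step = gstep, L_class = lc, L_domain = ld,
                                 L_total = lc + lam * ld, lambda = lam)
      }
    }
    structure(list(model = model, trace = dplyr::bind_rows(trace),
                   lambda = lambda, schedule = schedule),
              class = "epi_dann")
  })
}

#' @export
print.epi_dann <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf("<epi_dann> %d steps, lambda %.3g (%s); final L_class %.3f, L_domain %.3f\n",
              nrow(x$trace), x$lambda, x$schedule, last$L_class, last$L_domain))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores weights, configuration and the vocabulary
#' signature, so a mismatched tokenizer is detected at load time.
#'
#' @param model An `epi_model`.
#' @param path Checkpoint file path.
#' @param vocab Optional `epi_vocab` to validate against on load.
#' @return `save_checkpoint()` returns `path` invisibly;
#'   `load_checkpoint()` returns the `epi_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "epi_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, vocab = NULL) {
  model <- readRDS(path)
  if (!inherits(model, "epi_model")) abort("Not an epi_model checkpoint.")
  if (!is.null(vocab)) check_vocab(model, vocab)
  model
}
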