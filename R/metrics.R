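# Classification metrics.

#' Area under the ROC curve
#'
#' Thin wrapper over [pROC::roc()] (direction fixed so that higher
#' scores mean the positive class).
#'
#' @param labels 0/1 vector.
#' @param scores Numeric scores (e.g. interaction probabilities).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  if (length(unique(labels)) < 2L) abort("AUROC needs both classes present.")
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Area under the precision-recall curve (average precision)
#'
#' Average precision: mean of the precision values at the rank of each
#' positive, scanning scores in decreasing order (ties broken by stable
#' order).
#'
#' @inheritParams auroc
#' @return AUPR in `[0, 1]`.
#' @export
aupr <- function(labels, scores) {
  ord <- order(-scores)
  y <- labels[ord]
  if (sum(y) == 0L) abort("AUPR needs at least one positive.")
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  sum(prec[y == 1L]) / sum(y)
}

#' F1 score at a probability threshold
#'
#' @inheritParams auroc
#' @param threshold Decision threshold on the score.
#' @return F1 in `[0, 1]` (0 when no positive predictions).
#' @export
f1_score <- function(labels, scores, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  if (tp == 0L) return(0)
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}

#' Score a pair table with a trained model
#'
#' @param model An `epi_model` (or the `$model` of a fitted classifier).
#' @param pairs Pair tibble with `enh_seq` / `prom_seq`.
#' @param vocab The `epi_vocab` in use.
#' @return `pairs` with a `p_interact` column appended.
#' @export
predict_pairs <- function(model, pairs, vocab) {
  toks <- lapply(seq_len(nrow(pairs)), function(i) {
    assemble_pair(pairs$enh_seq[i], pairs$prom_seq[i], vocab)
  })
  pairs$p_interact <- forward_classify(model, toks)$p_interact
  pairs
}

#' Evaluate a model on a labelled pair table
#'
#' @inheritParams predict_pairs
#' @return One-row tibble: `auroc`, `aupr`, `f1`, `n`.
#' @export
evaluate_pairs <- function(model, pairs, vocab) {
  scored <- predict_pairs(model, pairs, vocab)
  tibble(
    auroc = auroc(scored$label, scored$p_interact),
    aupr = aupr(scored$label, scored$p_interact),
    f1 = f1_score(scored$label, scored$p_interact),
    n = nrow(scored)
  )
}
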