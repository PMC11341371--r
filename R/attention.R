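# Attention containers and per-base attention profiles.

new_attention_stack <- function(layers) {
  structure(list(layers = layers), class = "attention_stack")
}

#' @export
print.attention_stack <- function(x, ...) {
  L <- nrow(x$layers[[1L]][[1L]])
  cat(sprintf("<attention_stack> %d layers x %d heads, %d x %d positions\n",
              length(x$layers), length(x$layers[[1L]]), L, L))
  invisible(x)
}

#' Average attention heads of one encoder layer
#'
#' Element-wise mean of the per-head attention matrices; the mean of
#' row-stochastic matrices is itself row-stochastic.
#'
#' @param stack An `attention_stack` (from
#'   `forward_classify(..., return_attention = TRUE)`).
#' @param layer Layer index, default the last layer.
#' @return An `L x L` row-stochastic matrix.
#' @export
average_heads <- function(stack, layer = NULL) {
  stopifnot(inherits(stack, "attention_stack"))
  layer <- layer %||% length(stack$layers)
  heads <- stack$layers[[layer]]
  dims <- vapply(heads, dim, integer(2L))
  if (any(dims != dims[, 1L])) abort("Attention heads have mismatched shapes.")
  Reduce(`+`, heads) / length(heads)
}

#' Per-token attention profile from an averaged attention matrix
#'
#' `direction = "emitted"` scores token i by the mean of row i (the
#' attention it pays out); over *all* columns of a row-stochastic matrix
#' this is identically `1/L`, so restrict `targets` for an informative
#' emitted profile. `direction = "received"` scores token i by the mean
#' of column i (the attention paid to it), which is the informative
#' choice for motif calling and the default of the discovery pipeline.
#'
#' @param matrix `L x L` averaged attention matrix.
#' @param roles Per-position role factor (CLS/ENH/SEP/PROM), as in
#'   `epi_tokens$roles`.
#' @param direction `"emitted"` (row means) or `"received"` (column
#'   means).
#' @param targets Which opposite-axis positions to average over:
#'   `"all"`, `"enhancer"`, `"promoter"`.
#' @return Tibble with 0-based `position`, `role`, `score`. Special
#'   tokens are scored but flagged `special = TRUE` so motif calling can
#'   drop them.
#' @export
token_profile <- function(matrix, roles, direction = c("emitted", "received"),
                          targets = c("all", "enhancer", "promoter")) {
  direction <- match.arg(direction)
  targets <- match.arg(targets)
  L <- nrow(matrix)
  stopifnot(length(roles) == L)
  sel <- switch(targets,
    all = rep(TRUE, L),
    enhancer = roles == "ENH",
    promoter = roles == "PROM"
  )
  score <- if (direction == "emitted") {
    rowMeans(matrix[, sel, drop = FALSE])
  } else {
    colMeans(matrix[sel, , drop = FALSE])
  }
  tibble(position = seq_len(L) - 1L, role = as.character(roles),
         score = unname(score), special = roles %in% c("CLS", "SEP"))
}

#' Decompose per-token attention into per-base attention
#'
#' Each base receives the mean score of all k-mer tokens covering it
#' (1 to k tokens at the element edges).
#'
#' @param token_scores Numeric vector of per-token scores for one
#'   element (length `element_len - k + 1`).
#' @param k k-mer length.
#' @param element_len Element length in bases.
#' @return Numeric vector of `element_len` per-base raw scores.
#' @export
base_decompose <- function(token_scores, k, element_len) {
  nt <- element_len - k + 1L
  if (length(token_scores) != nt) {
    abort(sprintf("Expected %d token scores for length %d and k = %d, got %d.",
                  nt, element_len, k, length(token_scores)))
  }
  cum <- c(0, cumsum(token_scores))
  pos <- seq_len(element_len)
  lo <- pmax(1L, pos - k + 1L)   # first covering token (1-based)
  hi <- pmin(nt, pos)            # last covering token
  (cum[hi + 1L] - cum[lo]) / (hi - lo + 1L)
}

#' Normalize a per-base attention profile
#'
#' The default `"shift-max"` method applies
#' `(score - min) / max` with min/max taken over all bases of the
#' element pair — note the divisor is the maximum, not `max - min`, so
#' the profile lands in `[0, 1]` with the argmin base at exactly 0 and
#' the argmax base at `1 - min/max`. `"minmax"` is the conventional
#' `(score - min) / (max - min)` alternative.
#'
#' @param raw Numeric vector of nonnegative per-base raw scores.
#' @param method `"shift-max"` or `"minmax"`.
#' @return Normalized vector in `[0, 1]`.
#' @export
normalize_profile <- function(raw, method = c("shift-max", "minmax")) {
  method <- match.arg(method)
  if (length(raw) == 0L) abort("Empty profile.")
  mx <- max(raw); mn <- min(raw)
  if (mx <= 0) abort("Normalization undefined: profile maximum is not positive.")
  if (method == "shift-max") (raw - mn) / mx else {
    if (mx == mn) rep(0, length(raw)) else (raw - mn) / (mx - mn)
  }
}

#' Per-base attention profiles for one enhancer-promoter pair
#'
#' Full pipeline from an attention stack to `base_attention_profile`
#' objects: average heads of the chosen layer, score tokens
#' (attention received by default), decompose to bases per element, and
#' normalize jointly over the pair (the min and max are taken over all
#' bases of both elements, matching the per-pair normalization of the
#' discovery procedure).
#'
#' @param stack `attention_stack` for one record.
#' @param tokens The matching `epi_tokens`.
#' @param layer Encoder layer (default last).
#' @param direction Passed to [token_profile()]; default `"received"`.
#' @param method Passed to [normalize_profile()].
#' @return Named list with `enhancer` and `promoter`
#'   `base_attention_profile` objects (fields `role`, `raw`,
#'   `normalized`, `length`).
#' @export
pair_attention_profiles <- function(stack, tokens, layer = NULL,
                                    direction = "received",
                                    method = "shift-max") {
  M <- average_heads(stack, layer)
  prof <- token_profile(M, tokens$roles, direction = direction, targets = "all")
  k <- tokens$k
  seg <- function(role_tok) {
    sc <- prof$score[prof$role == role_tok]
    len <- length(sc) + k - 1L
    base_decompose(sc, k, len)
  }
  raw_e <- seg("ENH")
  raw_p <- seg("PROM")
  all_raw <- c(raw_e, raw_p)
  mx <- max(all_raw); mn <- min(all_raw)
  norm_all <- normalize_profile(all_raw, method = method)
  out <- list(
    enhancer = structure(list(role = "enhancer", raw = raw_e,
                              normalized = norm_all[seq_along(raw_e)],
                              length = length(raw_e)),
                         class = "base_attention_profile"),
    promoter = structure(list(role = "promoter", raw = raw_p,
                              normalized = norm_all[length(raw_e) + seq_along(raw_p)],
                              length = length(raw_p)),
                         class = "base_attention_profile")
  )
  out
}

#' @export
print.base_attention_profile <- function(x, ...) {
  cat(sprintf("<base_attention_profile> %s, %d bases, normalized range [%.3f, %.3f]\n",
              x$role, x$length, min(x$normalized), max(x$normalized)))
  invisible(x)
}

#' @method as_tibble base_attention_profile
#' @export
as_tibble.base_attention_profile <- function(x, ...) {
  tibble(role = x$role, position = seq_len(x$length) - 1L,
         raw = x$raw, normalized = x$normalized)
}

#' Call high-attention regions from a normalized profile
#'
#' Maximal runs of bases with normalized score at or above `threshold`,
#' kept when at least `min_len` bases long.
#'
#' @param profile A `base_attention_profile` or a numeric normalized
#'   vector.
#' @param threshold Score threshold in (0, 1).
#' @param min_len Minimum region length in bases.
#' @param role Role tag recorded on regions when `profile` is a bare
#'   vector.
#' @return Tibble with `role`, 0-based half-open `start`/`end`, `peak`
#'   (max score), `mean_score`, and `peak_pos` (0-based argmax).
#' @export
call_regions <- function(profile, threshold = 0.5, min_len = 6L, role = NA_character_) {
  if (inherits(profile, "base_attention_profile")) {
    role <- profile$role
    x <- profile$normalized
  } else {
    x <- profile
  }
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must be in (0, 1).")
  above <- x >= threshold
  if (!any(above)) {
    return(tibble(role = character(), start = integer(), end = integer(),
                  peak = numeric(), mean_score = numeric(), peak_pos = integer()))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  if (!any(keep)) {
    return(tibble(role = character(), start = integer(), end = integer(),
                  peak = numeric(), mean_score = numeric(), peak_pos = integer()))
  }
  s <- starts[keep]; e <- ends[keep]
  tibble(
    role = role,
    start = s - 1L,
    end = e,
    peak = vapply(seq_along(s), function(i) max(x[s[i]:e[i]]), numeric(1L)),
    mean_score = vapply(seq_along(s), function(i) mean(x[s[i]:e[i]]), numeric(1L)),
    peak_pos = vapply(seq_along(s), function(i) s[i] + which.max(x[s[i]:e[i]]) - 2L, integer(1L))
  )
}

#' High-attention regions for a set of records
#'
#' Convenience driver: runs the model with attention on each record,
#' builds per-base profiles and calls regions on both elements.
#'
#' @param model Trained `epi_model` (e.g. `fit$model` of a classifier).
#' @param pairs Pair tibble with `enh_seq`/`prom_seq` (and `record` ids;
#'   row numbers are used otherwise).
#' @param vocab The `epi_vocab` in use.
#' @param threshold Fixed normalized-score threshold in (0, 1), or
#'   `NULL` (default) for a per-record adaptive threshold at the
#'   `1 - top_frac` quantile of each element pair's normalized profile.
#'   The adaptive mode is robust to records whose profile is dominated
#'   by one extreme position (which pins the normalization and pushes
#'   the rest of the profile toward 0).
#' @param min_len Minimum region length in bases.
#' @param top_frac Fraction of bases treated as high-attention in
#'   adaptive mode.
#' @param margin Bases of element context kept around each region (the
#'   `context` column) for downstream candidate extraction.
#' @param direction Attention direction for [token_profile()].
#' @return Tibble of regions with a `record` column, the element
#'   subsequence of each region in `seq`, and its margin-padded
#'   neighbourhood in `context`.
#' @export
attention_regions <- function(model, pairs, vocab, threshold = NULL, min_len = 6L,
                              top_frac = 0.3, margin = 4L, direction = "received") {
  recs <- if ("record" %in% names(pairs)) pairs$record else seq_len(nrow(pairs))
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    tk <- assemble_pair(pairs$enh_seq[i], pairs$prom_seq[i], vocab)
    cls <- forward_classify(model, tk, return_attention = TRUE)
    prof <- pair_attention_profiles(cls$attention[[1L]], tk, direction = direction)
    nz <- c(prof$enhancer$normalized, prof$promoter$normalized)
    thr <- threshold %||%
      min(max(unname(stats::quantile(nz, 1 - top_frac)), min(nz[nz > 0])),
          max(nz) * 0.999)
    regs <- dplyr::bind_rows(
      call_regions(prof$enhancer, thr, min_len),
      call_regions(prof$promoter, thr, min_len)
    )
    if (nrow(regs) > 0L) {
      regs$record <- recs[i]
      regs$seq <- vapply(seq_len(nrow(regs)), function(j) {
        src <- if (regs$role[j] == "enhancer") pairs$enh_seq[i] else pairs$prom_seq[i]
        substr(src, regs$start[j] + 1L, regs$end[j])
      }, character(1L))
      # region sequence padded by `margin` bases of element context on
      # each side; candidate extraction tolerates boundary wobble
      regs$context <- vapply(seq_len(nrow(regs)), function(j) {
        src <- if (regs$role[j] == "enhancer") pairs$enh_seq[i] else pairs$prom_seq[i]
        substr(src, max(1L, regs$start[j] + 1L - margin),
               min(nchar(src), regs$end[j] + margin))
      }, character(1L))
    }
    out[[i]] <- regs
  }
  dplyr::bind_rows(out)
}

#' Positional density of high-attention regions
#'
#' Histogram of region midpoints along the element, per role — the
#' positional-preference summary (e.g. promoter regions concentrating
#' around the TSS offset).
#'
#' @param regions Region tibble (from [call_regions()] /
#'   [attention_regions()]).
#' @param element_len Element length in bases.
#' @param bins Number of equal-width bins over `[0, element_len)`.
#' @return Tibble `role`, `bin_start`, `bin_end`, `midpoint`, `count`;
#'   total count equals the number of regions.
#' @export
position_density <- function(regions, element_len, bins = 50L) {
  edges <- seq(0, element_len, length.out = bins + 1L)
  roles <- unique(regions$role)
  if (length(roles) == 0L) roles <- NA_character_
  out <- lapply(roles, function(r) {
    mid <- with(regions[which(regions$role %in% r), ], (start + end) / 2)
    idx <- pmin(pmax(findInterval(mid, edges, rightmost.closed = TRUE), 1L), bins)
    cnt <- tabulate(idx, nbins = bins)
    tibble(role = r, bin_start = edges[-length(edges)], bin_end = edges[-1L],
           midpoint = (edges[-length(edges)] + edges[-1L]) / 2, count = cnt)
  })
  dplyr::bind_rows(out)
}
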