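# Motif enrichment, merging, PWM export and high-attention k-mer pair
# mining.

#' Hypergeometric enrichment p-value
#'
#' Upper-tail probability of drawing at least `k` positive pairs among
#' the `n` pairs containing a candidate sequence, from `N` pairs of
#' which `K` are positive:
#' `p = sum_{k'=k}^{min(K,n)} C(K,k') C(N-K,n-k') / C(N,n)`.
#' Computed in log space via `phyper`, so it is stable for large `N`.
#'
#' @param k Positive pairs containing the sequence.
#' @param K All positive pairs.
#' @param n Pairs containing the sequence.
#' @param N All pairs.
#' @return p-value in (0, 1]; `k = 0` gives exactly 1.
#' @export
#' @examples
#' enrichment_pvalue(4, 5, 4, 10)  # 5/210
enrichment_pvalue <- function(k, K, n, N) {
  ok <- k >= 0 & n >= 0 & K >= 0 & N >= 1 & k <= pmin(K, n) & n <= N & K <= N
  if (!all(ok)) abort("Inconsistent counts: need 0 <= k <= min(K, n), n <= N, K <= N.")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# ---- PWM --------------------------------------------------------------

new_pwm <- function(mat, support, role = NA_character_, name = NULL,
                    p_value = NA_real_) {
  stopifnot(is.matrix(mat), ncol(mat) == 4L)
  colnames(mat) <- c("A", "C", "G", "T")
  rs <- rowSums(mat)
  if (any(abs(rs - 1) > 1e-9)) abort("PWM rows must each sum to 1.")
  consensus <- paste(colnames(mat)[max.col(mat, ties.method = "first")], collapse = "")
  structure(list(matrix = mat, consensus = consensus, support = support,
                 role = role, name = name %||% consensus, p_value = p_value),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s  width %d  support %d  role %s\n",
              x$consensus, nrow(x$matrix), x$support, x$role))
  invisible(x)
}

#' Tidy a position weight matrix
#'
#' @param x A `pwm`.
#' @param ... Unused.
#' @return Long tibble: `position` (1-based), `base`, `prob`.
#' @method tidy pwm
#' @export
tidy.pwm <- function(x, ...) {
  tibble(
    position = rep(seq_len(nrow(x$matrix)), times = 4L),
    base = rep(colnames(x$matrix), each = nrow(x$matrix)),
    prob = as.vector(x$matrix)
  )
}

# Best ungapped alignment of string b against string a among offsets
# overlapping by at least `overlap_min` bases: fewest mismatches first,
# then longest overlap, then smallest shift. Returns the offset of b's
# start relative to a's start (can be negative), the overlap length and
# the mismatch count.
best_overlap <- function(a, b, overlap_min = 1L) {
  na <- nchar(a); nb <- nchar(b)
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  best <- NULL
  for (off in (-nb + 1L):(na - 1L)) {
    ia <- max(1L, off + 1L):min(na, off + nb)
    ib <- ia - off
    ov <- length(ia)
    if (ov < overlap_min) next
    mm <- sum(ca[ia] != cb[ib])
    better <- is.null(best) ||
      mm < best$mismatch ||
      (mm == best$mismatch && ov > best$overlap) ||
      (mm == best$mismatch && ov == best$overlap && abs(off) < abs(best$offset))
    if (better) best <- list(offset = off, overlap = ov, mismatch = mm)
  }
  best %||% list(offset = 0L, overlap = 0L, mismatch = Inf)
}

# Decide whether candidate string b merges with cluster consensus a.
can_merge <- function(a, b, overlap_min, mismatch_max) {
  if (grepl(b, a, fixed = TRUE) || grepl(a, b, fixed = TRUE)) return(TRUE)
  al <- best_overlap(a, b, overlap_min)
  al$overlap >= overlap_min && al$mismatch <= mismatch_max
}

# Build a cluster PWM from its instances in the positive sequences,
# extended by `ctx` bases of flanking context on each side of the
# cluster frame, then trimmed by conservation: starting from the core
# columns, the consensus grows outward while the majority-base frequency
# stays at or above `trim_thresh`. Conserved context (the rest of a
# motif only partially covered by the seed candidates) survives; random
# flanks are trimmed away.
extend_cluster_pwm <- function(members, offsets, width, hay_pos, ctx = 4L,
                               trim_thresh = 0.55, pseudo = 0.1) {
  total <- width + 2L * ctx
  counts <- matrix(pseudo, total, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
  n_inst <- 0L
  for (seqs in hay_pos) {
    frames <- integer(0)
    for (mi in seq_along(members)) {
      p <- regexpr(members[mi], seqs, fixed = TRUE)
      if (p > 0L) frames <- c(frames, p - offsets[mi])
    }
    for (fs in unique(frames)) {
      lo <- fs - ctx
      chars <- strsplit(substr(seqs, max(1L, lo), fs + width + ctx - 1L), "",
                        fixed = TRUE)[[1L]]
      col0 <- max(1L, lo) - lo  # leading columns clipped at the sequence start
      for (j in seq_along(chars)) {
        cc <- match(chars[j], c("A", "C", "G", "T"))
        row <- col0 + j
        if (!is.na(cc) && row <= total) counts[row, cc] <- counts[row, cc] + 1
      }
      n_inst <- n_inst + 1L
    }
  }
  freq <- counts / rowSums(counts)
  # grow outward from the seed core while flank columns stay conserved;
  # the core itself is never shrunk (it earned its significance), so
  # low-complexity motifs with degenerate self-alignments survive
  lo <- ctx + 1L; hi <- ctx + width
  while (lo > 1L && max(freq[lo - 1L, ]) >= trim_thresh) lo <- lo - 1L
  while (hi < total && max(freq[hi + 1L, ]) >= trim_thresh) hi <- hi + 1L
  list(freq = freq[lo:hi, , drop = FALSE], n_instances = n_inst)
}

# Candidate words of one region: every `word_len`-mer of its
# margin-padded context plus the (at most `max_width` wide) subsequence
# of the region centred on the attention peak. Short fragments let the
# enrichment filter recognise a conserved core even when region
# boundaries wobble; the peak window keeps longer exact matches
# available.
region_words <- function(seq, peak_pos, start, word_len = 6L, max_width = 12L,
                         context = NULL) {
  ctx <- context %||% seq
  wc <- nchar(ctx)
  words <- if (wc >= word_len) {
    substring(ctx, 1:(wc - word_len + 1L), word_len:wc)
  } else {
    character(0)
  }
  w <- nchar(seq)
  if (w > max_width) {
    centre <- peak_pos - start + 1L
    lo <- max(1L, min(centre - max_width %/% 2L, w - max_width + 1L))
    words <- c(words, substr(seq, lo, lo + max_width - 1L))
  } else {
    words <- c(words, seq)
  }
  unique(words)
}

#' Discover motifs from high-attention regions
#'
#' The discovery pipeline: (1) decompose each positive-record region
#' into candidate words (its `word_len`-mers plus a window of at most
#' `max_width` bases around the attention peak); (2) count for every
#' distinct candidate the pairs containing it (substring match in the
#' same element role) among positives (`k`) and overall (`n`), and
#' score enrichment with the upper-tail hypergeometric test against `K`
#' positives of `N` total pairs; (3) keep candidates passing the
#' (Benjamini-Hochberg adjusted, by default) `p_cutoff` with support
#' `k >= min_support`; (4) greedily merge candidates (most-supported
#' first) when one is a substring of the other or their best ungapped
#' alignment overlaps by at least `overlap_min` bases with at most
#' `mismatch_max` mismatches; (5) extend each cluster with flanking
#' context from its instances in the positive sequences, trim by
#' per-position conservation, and merge clusters whose extended
#' consensi agree (fragments of one motif converge here); (6) return
#' per-motif position weight matrices built from the extended aligned
#' instances.
#'
#' Support of a merged motif is the number of distinct positive pairs
#' containing at least one member candidate.
#'
#' @param regions Region tibble from [attention_regions()] run on
#'   *positive* records (columns `role`, `seq`, `peak_pos`, `start`,
#'   `record`).
#' @param pairs Pair tibble with `enh_seq`, `prom_seq`, `label` for the
#'   whole analysis universe (positives and negatives).
#' @param p_cutoff Significance cutoff.
#' @param min_support Minimum number of positive pairs containing a
#'   candidate; guards against nominally significant singletons.
#' @param max_width Peak-window width cap in bases.
#' @param word_len Candidate word length.
#' @param overlap_min,mismatch_max Merge parameters.
#' @param adjust `"BH"` (default) applies Benjamini-Hochberg within
#'   each role before the cutoff — with hundreds of candidate words a
#'   raw cutoff would admit chance hits; `"none"` uses raw p-values.
#' @return List with `motifs` (list of `pwm` objects, sorted by support)
#'   and `candidates` (tibble: `role`, `seq`, `k`, `K`, `n`, `N`,
#'   `p_value`, `kept`, `motif`).
#' @export
discover_motifs <- function(regions, pairs, p_cutoff = 0.005, min_support = 5L,
                            max_width = 12L, word_len = 6L,
                            overlap_min = 6L, mismatch_max = 1L,
                            adjust = c("BH", "none")) {
  adjust <- match.arg(adjust)
  N <- nrow(pairs)
  K <- sum(pairs$label == 1L)
  empty <- list(motifs = list(),
                candidates = tibble(role = character(), seq = character(),
                                    k = integer(), K = integer(), n = integer(),
                                    N = integer(), p_value = numeric(),
                                    kept = logical(), motif = character()))
  if (is.null(regions) || nrow(regions) == 0L) return(empty)

  # (1) candidate words per region
  ctxs <- if ("context" %in% names(regions)) regions$context else regions$seq
  cand <- dplyr::bind_rows(lapply(seq_len(nrow(regions)), function(i) {
    tibble(role = regions$role[i],
           seq = region_words(regions$seq[i], regions$peak_pos[i],
                              regions$start[i], word_len, max_width,
                              context = ctxs[i]))
  }))
  cand <- dplyr::distinct(cand, .data$role, .data$seq)

  # (2) containment counts over the full universe
  stats_for <- function(role, s) {
    hay <- if (role == "enhancer") pairs$enh_seq else pairs$prom_seq
    hit <- stringr::str_detect(hay, stringr::fixed(s))
    c(k = sum(hit & pairs$label == 1L), n = sum(hit))
  }
  kk <- integer(nrow(cand)); nn <- integer(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    st <- stats_for(cand$role[i], cand$seq[i])
    kk[i] <- st[["k"]]; nn[i] <- st[["n"]]
  }
  cand$k <- kk; cand$K <- K; cand$n <- nn; cand$N <- N
  cand$p_value <- enrichment_pvalue(cand$k, K, cand$n, N)

  # (3) significance + support filter
  p_eff <- if (adjust == "BH") {
    unsplit(lapply(split(cand$p_value, cand$role), stats::p.adjust, method = "BH"),
            cand$role)
  } else {
    cand$p_value
  }
  cand$kept <- p_eff <= p_cutoff & cand$k >= min_support
  cand$motif <- NA_character_

  motifs <- list()
  for (role in unique(cand$role)) {
    sel <- which(cand$kept & cand$role == role)
    if (length(sel) == 0L) next
    sel <- sel[order(-cand$k[sel], cand$p_value[sel])]
    clusters <- list()
    for (i in sel) {
      s <- cand$seq[i]
      placed <- FALSE
      for (ci in seq_along(clusters)) {
        if (can_merge(clusters[[ci]]$ref, s, overlap_min, mismatch_max)) {
          al <- best_overlap(clusters[[ci]]$ref, s,
                             min(overlap_min, nchar(s), nchar(clusters[[ci]]$ref)))
          clusters[[ci]]$members <- c(clusters[[ci]]$members, s)
          clusters[[ci]]$offsets <- c(clusters[[ci]]$offsets, al$offset)
          clusters[[ci]]$weights <- c(clusters[[ci]]$weights, cand$k[i])
          cand$motif[i] <- clusters[[ci]]$id
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        id <- sprintf("%s_%d", substr(role, 1L, 4L), length(clusters) + 1L)
        clusters[[length(clusters) + 1L]] <- list(
          ref = s, id = id, members = s, offsets = 0L, weights = cand$k[i]
        )
        cand$motif[i] <- id
      }
    }
    hay <- if (role == "enhancer") pairs$enh_seq else pairs$prom_seq
    hay_pos <- hay[pairs$label == 1L]
    cons_of <- function(freq) {
      paste(c("A", "C", "G", "T")[max.col(freq, ties.method = "first")],
            collapse = "")
    }
    # context-extend each cluster, take its conservation-trimmed
    # consensus, and run a second merge pass on those consensi (clusters
    # seeded by different fragments of one motif converge here)
    finals <- list()
    for (cl in clusters) {
      off0 <- cl$offsets - min(cl$offsets)
      ext <- extend_cluster_pwm(cl$members, off0,
                                max(off0 + nchar(cl$members)), hay_pos)
      cons <- cons_of(ext$freq)
      placed <- FALSE
      for (fi in seq_along(finals)) {
        if (can_merge(finals[[fi]]$consensus, cons, overlap_min, mismatch_max)) {
          finals[[fi]]$members <- union(finals[[fi]]$members, cl$members)
          finals[[fi]]$ids <- c(finals[[fi]]$ids, cl$id)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        finals[[length(finals) + 1L]] <- list(consensus = cons,
                                              members = cl$members,
                                              ids = cl$id)
      }
    }
    for (fi in seq_along(finals)) {
      f <- finals[[fi]]
      # re-anchor every member on the final consensus; members whose
      # best near-full-length alignment still mismatches are left out
      # of the PWM (they reached this motif through a merge chain)
      als <- lapply(f$members, function(m) {
        ov <- max(4L, min(nchar(m), nchar(f$consensus)) - 2L)
        best_overlap(f$consensus, m, ov)
      })
      ok <- vapply(als, function(a) a$mismatch <= mismatch_max, logical(1L))
      mem <- f$members[ok]
      offs <- vapply(als[ok], `[[`, integer(1L), "offset")
      if (length(mem) == 0L) {
        mem <- f$members[1L]
        offs <- 0L
      }
      ext <- extend_cluster_pwm(mem, offs, nchar(f$consensus), hay_pos)
      hit <- Reduce(`|`, lapply(f$members, function(m) {
        stringr::str_detect(hay_pos, stringr::fixed(m))
      }))
      id <- sprintf("%s_m%d", substr(role, 1L, 4L), fi)
      cand$motif[!is.na(cand$motif) & cand$motif %in% f$ids] <- id
      motifs[[id]] <- new_pwm(
        ext$freq, support = sum(hit), role = role, name = id,
        p_value = min(cand$p_value[!is.na(cand$motif) & cand$motif == id],
                      na.rm = TRUE)
      )
    }
  }
  ord <- order(-vapply(motifs, `[[`, numeric(1L), "support"))
  list(motifs = motifs[ord], candidates = cand)
}

#' Label high-attention regions as common or specific
#'
#' A region is *common* when its candidate merged into a motif whose
#' support reaches `min_support` positive pairs and whose enrichment
#' passes `p_cutoff`; regions that stayed unmerged, under-supported or
#' non-significant are *specific*. Returns per-record counts of each
#' label.
#'
#' @param regions Region tibble (positive records).
#' @param discovery Result of [discover_motifs()] on the same regions.
#' @param min_support,p_cutoff Thresholds mirroring the discovery
#'   defaults.
#' @param max_width,word_len Candidate parameters used during discovery.
#' @return List with `regions` (input + `motif`, `label` columns) and
#'   `per_record` (tibble `record`, `n_common`, `n_specific`).
#' @export
classify_common_specific <- function(regions, discovery, min_support = 5L,
                                     p_cutoff = 0.005, max_width = 12L,
                                     word_len = 6L) {
  cand <- discovery$candidates
  motif_support <- vapply(discovery$motifs, `[[`, numeric(1L), "support")
  motif_p <- vapply(discovery$motifs, `[[`, numeric(1L), "p_value")
  good <- names(discovery$motifs)[motif_support >= min_support & motif_p <= p_cutoff]

  key <- paste(cand$role, cand$seq)
  ctxs <- if ("context" %in% names(regions)) regions$context else regions$seq
  out <- regions
  out$motif <- NA_character_
  for (i in seq_len(nrow(regions))) {
    words <- region_words(regions$seq[i], regions$peak_pos[i], regions$start[i],
                          word_len, max_width, context = ctxs[i])
    hits <- cand$motif[match(paste(regions$role[i], words), key)]
    hits <- hits[!is.na(hits) & hits %in% good]
    if (length(hits) > 0L) out$motif[i] <- hits[1L]
  }
  out$label <- ifelse(!is.na(out$motif), "common", "specific")
  per_record <- dplyr::summarise(
    dplyr::group_by(out, .data$record),
    n_common = sum(.data$label == "common"),
    n_specific = sum(.data$label == "specific"),
    .groups = "drop"
  )
  list(regions = out, per_record = per_record)
}

# ---- MEME minimal format ---------------------------------------------

#' Export position weight matrices in MEME minimal format
#'
#' @param pwms List of `pwm` objects (possibly empty).
#' @param path Output file path.
#' @param background Background letter frequencies (A, C, G, T).
#' @return `path`, invisibly.
#' @export
export_meme <- function(pwms, path, background = rep(0.25, 4L)) {
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
             "Background letter frequencies",
             sprintf("A %.5f C %.5f G %.5f T %.5f", background[1L], background[2L],
                     background[3L], background[4L]), "")
  for (pw in pwms) {
    stopifnot(inherits(pw, "pwm"))
    if (any(abs(rowSums(pw$matrix) - 1) > 1e-9)) {
      abort(sprintf("PWM %s has a position not summing to 1.", pw$name))
    }
    lines <- c(lines,
               sprintf("MOTIF %s", pw$name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       nrow(pw$matrix), max(1L, pw$support)),
               apply(pw$matrix, 1L, function(r) sprintf(" %.6f %.6f %.6f %.6f",
                                                        r[1L], r[2L], r[3L], r[4L])),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname export_meme
#' @return `read_meme()` returns a list of `pwm` objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  if (!grepl("^MEME version", lines[1L])) abort("Not a MEME minimal file.")
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (startsWith(lines[i], "MOTIF ")) {
      name <- sub("^MOTIF\\s+", "", lines[i])
      hdr <- lines[i + 1L]
      w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
      ns <- as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", hdr))
      rows <- lines[(i + 2L):(i + 1L + w)]
      mat <- do.call(rbind, lapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1L]])))
      mat <- mat / rowSums(mat)  # absorb printed rounding
      out[[name]] <- new_pwm(mat, support = ns, name = name)
      i <- i + 1L + w
    }
    i <- i + 1L
  }
  out
}

# ---- high-attention k-mer pair mining --------------------------------

#' Mine high-attention enhancer/promoter k-mer pairs
#'
#' For every record, each cross-segment cell of the head-averaged
#' last-layer attention matrix (enhancer-token row, promoter-token
#' column) with attention at or above `threshold` contributes one count
#' to the (enhancer k-mer, promoter k-mer) pair. Counts accumulate
#' separately over positive and negative records; the `top_m` pairs by
#' count within each class are compared, and pairs on the positive top
#' list but absent from the negative top list are flagged
#' `exclusive_to_pos`.
#'
#' @param model Trained `epi_model`.
#' @param pairs Pair tibble with `enh_seq`, `prom_seq`, `label`.
#' @param vocab The `epi_vocab` in use.
#' @param threshold Attention cell threshold; default `10 / L` (ten
#'   times the uniform row weight), computed per record. Must be
#'   positive.
#' @param top_m Size of the per-class top list.
#' @param include_promoter_rows Also count (promoter row, enhancer
#'   column) cells; default `FALSE` (cross-segment, enhancer-to-promoter
#'   only).
#' @return Tibble `kmer_a`, `kmer_b`, `count_pos`, `count_neg`,
#'   `in_top_pos`, `in_top_neg`, `exclusive_to_pos`, sorted by
#'   `count_pos`.
#' @export
mine_kmer_pairs <- function(model, pairs, vocab, threshold = NULL, top_m = 1000L,
                            include_promoter_rows = FALSE) {
  if (!is.null(threshold) && threshold <= 0) abort("`threshold` must be positive.")
  env_pos <- new.env(hash = TRUE, parent = emptyenv())
  env_neg <- new.env(hash = TRUE, parent = emptyenv())
  bump <- function(env, keys) {
    for (kk in keys) {
      env[[kk]] <- (env[[kk]] %||% 0L) + 1L
    }
  }
  for (i in seq_len(nrow(pairs))) {
    tk <- assemble_pair(pairs$enh_seq[i], pairs$prom_seq[i], vocab)
    cls <- forward_classify(model, tk, return_attention = TRUE)
    M <- average_heads(cls$attention[[1L]])
    L <- nrow(M)
    thr <- threshold %||% (10 / L)
    er <- which(tk$roles == "ENH")
    pc <- which(tk$roles == "PROM")
    sub <- M[er, pc, drop = FALSE]
    hits <- which(sub >= thr, arr.ind = TRUE)
    keys <- character(0)
    if (nrow(hits) > 0L) {
      ka <- vocab$tokens[tk$ids[er[hits[, 1L]]] + 1L]
      kb <- vocab$tokens[tk$ids[pc[hits[, 2L]]] + 1L]
      keys <- paste(ka, kb, sep = "|")
    }
    if (include_promoter_rows) {
      sub2 <- M[pc, er, drop = FALSE]
      hits2 <- which(sub2 >= thr, arr.ind = TRUE)
      if (nrow(hits2) > 0L) {
        ka <- vocab$tokens[tk$ids[er[hits2[, 2L]]] + 1L]
        kb <- vocab$tokens[tk$ids[pc[hits2[, 1L]]] + 1L]
        keys <- c(keys, paste(ka, kb, sep = "|"))
      }
    }
    if (length(keys) > 0L) {
      bump(if (pairs$label[i] == 1L) env_pos else env_neg, keys)
    }
  }
  all_keys <- union(ls(env_pos), ls(env_neg))
  if (length(all_keys) == 0L) {
    return(tibble(kmer_a = character(), kmer_b = character(),
                  count_pos = integer(), count_neg = integer(),
                  in_top_pos = logical(), in_top_neg = logical(),
                  exclusive_to_pos = logical()))
  }
  cp <- vapply(all_keys, function(kk) env_pos[[kk]] %||% 0L, integer(1L))
  cn <- vapply(all_keys, function(kk) env_neg[[kk]] %||% 0L, integer(1L))
  parts <- strsplit(all_keys, "|", fixed = TRUE)
  out <- tibble(
    kmer_a = vapply(parts, `[[`, character(1L), 1L),
    kmer_b = vapply(parts, `[[`, character(1L), 2L),
    count_pos = unname(cp), count_neg = unname(cn)
  )
  top_set <- function(cnt) {
    pos_keys <- all_keys[cnt > 0L]
    cnts <- cnt[cnt > 0L]
    pos_keys[order(-cnts, pos_keys)][seq_len(min(top_m, length(pos_keys)))]
  }
  tp <- top_set(cp); tn <- top_set(cn)
  out$in_top_pos <- all_keys %in% tp
  out$in_top_neg <- all_keys %in% tn
  out$exclusive_to_pos <- out$in_top_pos & !out$in_top_neg
  out[order(-out$count_pos, -out$count_neg), ]
}
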