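# Synthetic EPI benchmark generator. Every other module is testable
# against datasets from here: sequences live on a real (synthetic)
# genome, so window extraction, shift augmentation and chromosome-aware
# splitting all behave as they would on real data, while a truth table
# records exactly which motif was planted where.

#' Generate a random genome
#'
#' Bases are drawn i.i.d. with `P(G) + P(C) = gc`, split evenly within
#' each pair. Fully seed-deterministic.
#'
#' @param n_contigs Number of contigs.
#' @param contig_len Length of each contig in bases.
#' @param gc Background GC fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @return Named character vector of contigs (`chr1`, `chr2`, ...).
#' @export
make_genome <- function(n_contigs = 1L, contig_len = 100000L, gc = 0.5, seed = 1L) {
  if (!is.numeric(gc) || gc < 0 || gc > 1) abort("`gc` must be in [0, 1].")
  if (any(contig_len < 1L)) abort("`contig_len` must be >= 1.")
  lens <- rep_len(as.integer(contig_len), n_contigs)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(seed, {
    seqs <- vapply(lens, function(L) {
      paste(sample(names(probs), L, replace = TRUE, prob = probs), collapse = "")
    }, character(1L))
  })
  setNames(seqs, paste0("chr", seq_len(n_contigs)))
}

#' Specify a synthetic EPI dataset
#'
#' Captures the generative conditions of one synthetic cell line:
#' element window sizes (defaults follow the standard 3,000-bp enhancer
#' and 2,000-bp promoter convention), class counts with severe imbalance,
#' the planted enhancer-side and promoter-side consensus motifs, the
#' probability that a positive carries each motif, the per-base
#' substitution rate inside planted copies, and the background GC.
#'
#' @param n_pos,n_neg Positive / negative record counts.
#' @param enh_len,prom_len Element window lengths in bases.
#' @param enh_motif,prom_motif Consensus motif strings (`NULL` = draw a
#'   random consensus of `motif_len` bases from the seed).
#' @param motif_len Length used when drawing random consensi.
#' @param plant_prob Probability that a positive record carries each
#'   motif (planted independently per element).
#' @param mutation_rate Per-base substitution probability within planted
#'   instances.
#' @param gc Background GC fraction.
#' @param cell_line Tag recorded on every generated record.
#' @param seed Integer seed.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_pos = 200L, n_neg = 2000L,
                       enh_len = 3000L, prom_len = 2000L,
                       enh_motif = NULL, prom_motif = NULL, motif_len = 8L,
                       plant_prob = 1, mutation_rate = 0.05,
                       gc = 0.5, cell_line = "synthA", seed = 1L) {
  if (plant_prob < 0 || plant_prob > 1) abort("`plant_prob` must be in [0, 1].")
  if (gc < 0 || gc > 1) abort("`gc` must be in [0, 1].")
  if (is.null(enh_motif)) {
    enh_motif <- with_seed(child_seed(seed, 11L),
                           paste(sample(c("A", "C", "G", "T"), motif_len, TRUE), collapse = ""))
  }
  if (is.null(prom_motif)) {
    prom_motif <- with_seed(child_seed(seed, 13L),
                            paste(sample(c("A", "C", "G", "T"), motif_len, TRUE), collapse = ""))
  }
  structure(
    list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
         enh_len = as.integer(enh_len), prom_len = as.integer(prom_len),
         enh_motif = toupper(enh_motif), prom_motif = toupper(prom_motif),
         plant_prob = plant_prob, mutation_rate = mutation_rate,
         gc = gc, cell_line = cell_line, seed = as.integer(seed)),
    class = "synth_spec"
  )
}

# Mutate a motif copy with i.i.d. substitutions (always to a different base).
mutate_motif <- function(motif, rate) {
  if (rate <= 0) return(motif)
  ch <- strsplit(motif, "", fixed = TRUE)[[1L]]
  hit <- runif(length(ch)) < rate
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                      character(1L))
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic EPI dataset with planted motifs
#'
#' Lays element windows side by side (with flanks) on fresh contigs of a
#' synthetic genome, plants mutated copies of the enhancer/promoter
#' consensus motifs at uniform random interior positions of positive
#' records, and leaves negatives as pure background. The class imbalance
#' of the spec is preserved, and a truth table records every planted
#' instance so recovery assertions can be exact.
#'
#' Planted positions avoid the outermost `k - 1` bases (default `k = 6`)
#' of each element so every instance is fully covered by k-mer tokens.
#'
#' @param spec A [synth_spec()].
#' @param n_contigs Number of contigs the windows are spread over.
#' @param flank Background flank around each window in bases (headroom
#'   for window-shift augmentation).
#' @return List with `genome` (named contigs), `pairs` (pair tibble with
#'   `enh_seq`/`prom_seq` attached) and `truth` (per-record tibble:
#'   `record`, `label`, `enh_motif`, `enh_pos`, `prom_motif`, `prom_pos`;
#'   positions 0-based within the element, NA when nothing was planted).
#' @export
generate_epi_dataset <- function(spec, n_contigs = 4L, flank = 60L) {
  stopifnot(inherits(spec, "synth_spec"))
  if (nchar(spec$enh_motif) > spec$enh_len || nchar(spec$prom_motif) > spec$prom_len) {
    abort("Planted motif longer than its element window.")
  }
  n <- spec$n_pos + spec$n_neg
  k_guard <- 5L  # keep instances inside full k-mer coverage for k = 6
  with_seed(spec$seed, {
    labels <- c(rep(1L, spec$n_pos), rep(0L, spec$n_neg))
    probs <- c(A = (1 - spec$gc) / 2, C = spec$gc / 2, G = spec$gc / 2, T = (1 - spec$gc) / 2)
    rand_seq <- function(L) paste(sample(names(probs), L, TRUE, prob = probs), collapse = "")

    contig_of <- rep_len(seq_len(n_contigs), n)
    slot_len <- (spec$enh_len + 2L * flank) + (spec$prom_len + 2L * flank)
    enh_start <- integer(n); prom_start <- integer(n)
    enh_seq <- character(n); prom_seq <- character(n)
    truth <- tibble(
      record = seq_len(n), label = labels,
      enh_motif = NA_character_, enh_pos = NA_integer_,
      prom_motif = NA_character_, prom_pos = NA_integer_
    )

    plant <- function(seq, motif, L) {
      pos <- sample(seq.int(k_guard, L - nchar(motif) - k_guard), 1L)  # 0-based
      inst <- mutate_motif(motif, spec$mutation_rate)
      substr(seq, pos + 1L, pos + nchar(inst)) <- inst
      list(seq = seq, pos = pos, inst = inst)
    }

    for (i in seq_len(n)) {
      es <- rand_seq(spec$enh_len)
      ps <- rand_seq(spec$prom_len)
      if (labels[i] == 1L) {
        if (runif(1L) < spec$plant_prob) {
          pl <- plant(es, spec$enh_motif, spec$enh_len)
          es <- pl$seq; truth$enh_motif[i] <- pl$inst; truth$enh_pos[i] <- pl$pos
        }
        if (runif(1L) < spec$plant_prob) {
          pl <- plant(ps, spec$prom_motif, spec$prom_len)
          ps <- pl$seq; truth$prom_motif[i] <- pl$inst; truth$prom_pos[i] <- pl$pos
        }
      }
      slot <- (cumsum(contig_of == contig_of[i])[i] - 1L)  # slot index on its contig
      base <- slot * slot_len
      enh_start[i] <- base + flank
      prom_start[i] <- base + flank + spec$enh_len + 2L * flank
      enh_seq[i] <- es
      prom_seq[i] <- ps
    }

    # Assemble contigs: flank | enh | flank | flank | prom | flank | ...
    genome <- vapply(seq_len(n_contigs), function(ci) {
      idx <- which(contig_of == ci)
      parts <- unlist(lapply(idx, function(i) {
        c(rand_seq(flank), enh_seq[i], rand_seq(flank),
          rand_seq(flank), prom_seq[i], rand_seq(flank))
      }))
      paste(parts, collapse = "")
    }, character(1L))
    names(genome) <- paste0("chr", seq_len(n_contigs))

    pairs <- tibble(
      enh_chrom = paste0("chr", contig_of),
      enh_start = enh_start,
      enh_end = enh_start + spec$enh_len,
      prom_chrom = paste0("chr", contig_of),
      prom_start = prom_start,
      prom_end = prom_start + spec$prom_len,
      label = labels,
      cell_line = spec$cell_line,
      enh_seq = enh_seq,
      prom_seq = prom_seq
    )
    # Shuffle record order so class blocks are not positional artefacts.
    ord <- sample.int(n)
    pairs <- pairs[ord, ]
    truth <- truth[ord, ]
    truth$record <- seq_len(n)
    pairs$record <- seq_len(n)
  })
  list(genome = genome, pairs = as_tibble(pairs), truth = as_tibble(truth), spec = spec)
}

#' Generate a source/target dataset pair with controllable domain shift
#'
#' Emulates cross-cell-line heterogeneity: the target cell line reuses a
#' fraction of the source motifs and replaces the rest with fresh random
#' consensi, and the two backgrounds may differ in GC. Target labels are
#' generated (so transfer can be *evaluated*) but are flagged
#' evaluation-only; adversarial training must not consume them.
#'
#' @param spec_src,spec_tgt [synth_spec()]s for the two domains.
#' @param shared_motif_fraction Fraction of the source motifs reused by
#'   the target (with the two motifs here, 0.5 keeps the enhancer motif
#'   and replaces the promoter motif; 0 replaces both; 1 keeps both).
#' @return List with `source` and `target` dataset lists (as from
#'   [generate_epi_dataset()]); the target carries
#'   `attr(target$pairs, "labels_evaluation_only") = TRUE`.
#' @export
generate_domain_shift <- function(spec_src, spec_tgt, shared_motif_fraction = 0.5) {
  if (shared_motif_fraction < 0 || shared_motif_fraction > 1) {
    abort("`shared_motif_fraction` must be in [0, 1].")
  }
  n_keep <- round(shared_motif_fraction * 2)
  if (n_keep >= 1L) spec_tgt$enh_motif <- spec_src$enh_motif
  if (n_keep >= 2L) spec_tgt$prom_motif <- spec_src$prom_motif
  if (n_keep < 2L && spec_tgt$prom_motif == spec_src$prom_motif) {
    spec_tgt$prom_motif <- with_seed(child_seed(spec_tgt$seed, 17L),
                                     paste(sample(c("A", "C", "G", "T"),
                                                  nchar(spec_src$prom_motif), TRUE), collapse = ""))
  }
  if (n_keep < 1L && spec_tgt$enh_motif == spec_src$enh_motif) {
    spec_tgt$enh_motif <- with_seed(child_seed(spec_tgt$seed, 19L),
                                    paste(sample(c("A", "C", "G", "T"),
                                                 nchar(spec_src$enh_motif), TRUE), collapse = ""))
  }
  src <- generate_epi_dataset(spec_src)
  tgt <- generate_epi_dataset(spec_tgt)
  attr(tgt$pairs, "labels_evaluation_only") <- TRUE
  list(source = src, target = tgt)
}
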