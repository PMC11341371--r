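#' Read a FASTA genome into a named character vector
#'
#' Wraps [Biostrings::readDNAStringSet()] and returns plain uppercase
#' character sequences keyed by contig id (the first whitespace-delimited
#' word of each header). All downstream functions in this package take
#' genomes in this form.
#'
#' @param path Path to a (possibly line-wrapped) FASTA file.
#' @return Named character vector, one uppercase DNA string per contig.
#'   Alphabet is restricted to A/C/G/T/N.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgt"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) abort(sprintf("Malformed FASTA file %s: %s", path, conditionMessage(e)))
  )
  if (length(set) == 0L) abort(sprintf("FASTA file %s contains no records.", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(sprintf(
      "Duplicate contig id(s) in %s: %s", path,
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(sprintf(
      "Contig(s) with characters outside A/C/G/T/N: %s",
      paste(ids[bad], collapse = ", ")
    ))
  }
  setNames(seqs, ids)
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of DNA sequences.
#' @param path Output file path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  set <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(width))
  invisible(path)
}

#' Extract a genomic interval as a DNA string
#'
#' Coordinates are 0-based half-open (BED convention) throughout the
#' package. Minus-strand intervals are reverse-complemented.
#'
#' @param genome Named character vector, as from [read_fasta()].
#' @param chrom Contig id.
#' @param start,end 0-based half-open coordinates, `0 <= start < end`.
#' @param strand `"+"` or `"-"`.
#' @return DNA string of length `end - start`.
#' @export
extract_interval <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) abort(sprintf("Unknown contig: %s", chrom))
  if (!strand %in% c("+", "-")) abort("`strand` must be \"+\" or \"-\".")
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end) {
    abort(sprintf("Invalid interval [%s, %s): need 0 <= start < end.", start, end))
  }
  clen <- nchar(genome[[chrom]])
  if (end > clen) {
    abort(sprintf("Interval [%d, %d) exceeds contig %s length %d.", start, end, chrom, clen))
  }
  s <- substr(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- revcomp(s)
  s
}

#' Extract a promoter window around a transcription start site
#'
#' The promoter window spans `upstream` bases upstream and `downstream`
#' bases downstream of the TSS in transcription orientation (defaults
#' 1,500 / 500, total 2,000 bp). On the minus strand the window is
#' mirrored and the sequence reverse-complemented, so position 0 of the
#' returned string is always the most upstream base. Windows that
#' overrun the contig are rejected rather than padded.
#'
#' @param genome Named character vector of contigs.
#' @param chrom Contig id.
#' @param tss 0-based position of the transcription start site.
#' @param strand `"+"` or `"-"`.
#' @param upstream,downstream Window extents in bases.
#' @return DNA string of length `upstream + downstream`.
#' @export
extract_promoter <- function(genome, chrom, tss, strand = "+",
                             upstream = 1500L, downstream = 500L) {
  tss <- as.integer(tss)
  upstream <- as.integer(upstream); downstream <- as.integer(downstream)
  if (strand == "+") {
    extract_interval(genome, chrom, tss - upstream, tss + downstream, "+")
  } else if (strand == "-") {
    extract_interval(genome, chrom, tss - downstream, tss + upstream, "-")
  } else {
    abort("`strand` must be \"+\" or \"-\".")
  }
}

pair_cols <- c(
  "enh_chrom", "enh_start", "enh_end",
  "prom_chrom", "prom_start", "prom_end",
  "label", "cell_line"
)

#' Read an enhancer-promoter pair table
#'
#' Expects a tab-separated file with header columns `enh_chrom`,
#' `enh_start`, `enh_end`, `prom_chrom`, `prom_start`, `prom_end`,
#' `label`, `cell_line`. Coordinates are 0-based half-open; `label` is 0
#' (non-interacting) or 1 (interacting).
#'
#' @param path Path to the TSV file.
#' @return A tibble with one row per pair and the columns above
#'   (coordinates integer, label integer, cell_line character).
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) abort(sprintf("Pair table not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(pair_cols, names(raw))
  if (length(missing) > 0L) {
    abort(sprintf("Pair table %s lacks column(s): %s", path, paste(missing, collapse = ", ")))
  }
  int_cols <- c("enh_start", "enh_end", "prom_start", "prom_end", "label")
  for (cl in int_cols) {
    v <- suppressWarnings(as.integer(raw[[cl]]))
    num <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- which(is.na(v) | is.na(num) | v != num)
    if (length(bad) > 0L) {
      # +1 for the header row so the message points at the file line
      abort(sprintf("Non-integer value in column %s at line %d of %s.", cl, bad[1L] + 1L, path))
    }
    raw[[cl]] <- v
  }
  bad_label <- which(!raw$label %in% c(0L, 1L))
  if (length(bad_label) > 0L) {
    abort(sprintf("label must be 0 or 1; offending line %d of %s.", bad_label[1L] + 1L, path))
  }
  as_tibble(raw[pair_cols])
}

#' Write an enhancer-promoter pair table
#'
#' Inverse of [read_pairs()].
#'
#' @param pairs Tibble with the standard pair columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  missing <- setdiff(pair_cols, names(pairs))
  if (length(missing) > 0L) {
    abort(sprintf("`pairs` lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  readr::write_tsv(pairs[pair_cols], path, progress = FALSE)
  invisible(path)
}

#' Attach element sequences to a pair table
#'
#' Extracts the enhancer and promoter windows of every record from a
#' genome and adds them as `enh_seq` / `prom_seq` columns. Strand columns
#' (`enh_strand`, `prom_strand`) are honoured when present and assumed
#' `"+"` otherwise.
#'
#' @param pairs Pair tibble, as from [read_pairs()].
#' @param genome Named character vector of contigs.
#' @return `pairs` with `enh_seq` and `prom_seq` character columns added.
#' @export
add_pair_sequences <- function(pairs, genome) {
  n <- nrow(pairs)
  es <- if ("enh_strand" %in% names(pairs)) pairs$enh_strand else rep("+", n)
  ps <- if ("prom_strand" %in% names(pairs)) pairs$prom_strand else rep("+", n)
  pairs$enh_seq <- vapply(seq_len(n), function(i) {
    extract_interval(genome, pairs$enh_chrom[i], pairs$enh_start[i], pairs$enh_end[i], es[i])
  }, character(1L))
  pairs$prom_seq <- vapply(seq_len(n), function(i) {
    extract_interval(genome, pairs$prom_chrom[i], pairs$prom_start[i], pairs$prom_end[i], ps[i])
  }, character(1L))
  pairs
}

#' Split a pair table into train / validation / test sets
#'
#' Adds a `.split` factor column. `mode = "random"` shuffles records with
#' the given seed and sizes the splits by floor-then-distribute (largest
#' fractional remainders, ties to the earlier split), so 100 records at
#' (0.8, 0.1, 0.1) give exactly 80/10/10. `mode = "by_chromosome"`
#' assigns whole enhancer chromosomes to one split each (greedy
#' largest-chromosome-first into the most under-filled split), which
#' avoids sequence leakage between splits.
#'
#' @param pairs Pair tibble.
#' @param ratios Numeric vector of three fractions summing to 1.
#' @param seed Integer seed; identical seeds give identical splits.
#' @param mode `"random"` or `"by_chromosome"`.
#' @return `pairs` with a `.split` factor column
#'   (levels train/validation/test).
#' @export
split_dataset <- function(pairs, ratios = c(0.8, 0.1, 0.1), seed = 1L,
                          mode = c("random", "by_chromosome")) {
  mode <- match.arg(mode)
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-9 || any(ratios < 0)) {
    abort("`ratios` must be three nonnegative fractions summing to 1.")
  }
  n <- nrow(pairs)
  if (n < 3L) abort("Need at least 3 records to form three splits.")
  lv <- c("train", "validation", "test")
  if (mode == "random") {
    base <- floor(ratios * n)
    rem <- n - sum(base)
    if (rem > 0L) {
      frac <- ratios * n - base
      add <- order(frac, seq_along(frac), decreasing = c(TRUE, FALSE), method = "radix")[seq_len(rem)]
      base[add] <- base[add] + 1L
    }
    perm <- with_seed(seed, sample.int(n))
    lab <- character(n)
    lab[perm] <- rep(lv, times = base)
    pairs$.split <- factor(lab, levels = lv)
  } else {
    chroms <- pairs$enh_chrom
    sizes <- sort(table(chroms), decreasing = TRUE)
    if (length(sizes) < 3L) abort("by_chromosome split needs at least 3 enhancer chromosomes.")
    filled <- c(train = 0, validation = 0, test = 0)
    target <- ratios * n
    assign_to <- character(length(sizes))
    names(assign_to) <- names(sizes)
    for (ch in names(sizes)) {
      deficit <- target - filled
      pick <- which.max(deficit)
      assign_to[ch] <- lv[pick]
      filled[pick] <- filled[pick] + sizes[[ch]]
    }
    pairs$.split <- factor(assign_to[chroms], levels = lv)
  }
  pairs
}
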