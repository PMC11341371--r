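#' Build a k-mer vocabulary
#'
#' The vocabulary holds five special tokens (PAD, UNK, CLS, SEP, MASK) at
#' the lowest ids 0..4, followed by all `4^k` k-mers in lexicographic
#' order, for a total of `4^k + 5` ids. Ids are 0-based and stable across
#' runs, so serialized vocabularies and checkpoints are interchangeable.
#'
#' @param k k-mer length (default 6).
#' @return An object of class `epi_vocab`: list with `k`, `size`,
#'   `specials` (named id vector), `tokens` (id-ordered token strings).
#' @export
#' @examples
#' v <- new_vocab(k = 1)
#' v$size  # 4 + 5
new_vocab <- function(k = 6L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) abort("`k` must be a positive integer.")
  specials <- c(PAD = 0L, UNK = 1L, CLS = 2L, SEP = 3L, MASK = 4L)
  n_kmers <- 4L^k
  bases <- c("A", "C", "G", "T")
  grids <- rev(rep(list(bases), k))
  kmers <- do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
  structure(
    list(
      k = k,
      size = n_kmers + 5L,
      specials = specials,
      tokens = c(names(specials), kmers)
    ),
    class = "epi_vocab"
  )
}

#' @export
print.epi_vocab <- function(x, ...) {
  cat(sprintf("<epi_vocab> k = %d, %d ids (5 specials + %d k-mers)\n",
              x$k, x$size, x$size - 5L))
  invisible(x)
}

#' Convert a vocabulary to a token/id tibble
#'
#' @param x An `epi_vocab`.
#' @param ... Unused.
#' @return Tibble with columns `token` and (0-based) `id`.
#' @method as_tibble epi_vocab
#' @export
as_tibble.epi_vocab <- function(x, ...) {
  tibble(token = x$tokens, id = seq_along(x$tokens) - 1L)
}

#' Serialize / read a vocabulary as a two-column text file
#'
#' @param vocab An `epi_vocab`.
#' @param path File path.
#' @return `write_vocab()` returns `path` invisibly; `read_vocab()`
#'   returns an `epi_vocab`.
#' @export
write_vocab <- function(vocab, path) {
  readr::write_tsv(as_tibble(vocab), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) {
  tab <- readr::read_tsv(path, col_types = "ci", progress = FALSE)
  k <- nchar(tab$token[tab$id == 5L])
  v <- new_vocab(k)
  if (!identical(v$tokens, tab$token[order(tab$id)])) {
    abort(sprintf("File %s is not a vocabulary produced by write_vocab().", path))
  }
  v
}

#' Tokenize a DNA sequence into overlapping k-mers
#'
#' A length-`L` sequence yields `L - k + 1` k-mers at stride 1, e.g.
#' `"TCGTCACT"` with `k = 6` gives `TCGTCA`, `CGTCAC`, `GTCACT`.
#'
#' @param seq DNA string.
#' @param k k-mer length.
#' @return Character vector of `nchar(seq) - k + 1` k-mers.
#' @export
kmerize <- function(seq, k = 6L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  n <- nchar(seq)
  k <- as.integer(k)
  if (n < k) abort(sprintf("Sequence length %d is shorter than k = %d.", n, k))
  substring(seq, 1:(n - k + 1L), k:n)
}

# Encode a DNA string directly to 0-based k-mer ids (lexicographic code +
# 5). Windows containing any non-ACGT base map to UNK. Avoids per-token
# string hashing; used on every training example.
encode_kmers <- function(seq, vocab) {
  k <- vocab$k
  n <- nchar(seq)
  if (n < k) abort(sprintf("Sequence length %d is shorter than k = %d.", n, k))
  code_map <- rep(NA_integer_, 256L)
  code_map[utf8ToInt("A")] <- 0L; code_map[utf8ToInt("C")] <- 1L
  code_map[utf8ToInt("G")] <- 2L; code_map[utf8ToInt("T")] <- 3L
  codes <- code_map[utf8ToInt(seq)]
  nt <- n - k + 1L
  ids <- rep(0, nt)
  bad <- rep(FALSE, nt)
  for (j in 0:(k - 1L)) {
    cj <- codes[(1L + j):(nt + j)]
    bad <- bad | is.na(cj)
    cj[is.na(cj)] <- 0L
    ids <- ids * 4 + cj
  }
  ids <- as.integer(ids) + 5L
  ids[bad] <- vocab$specials[["UNK"]]
  ids
}

#' Assemble an enhancer/promoter pair into one token sequence
#'
#' Produces `[CLS] e_1 ... e_m [SEP] p_1 ... p_n` where `e_i`/`p_j` are
#' the overlapping k-mer ids of the two elements. With the standard
#' 3,000-bp enhancer and 2,000-bp promoter windows and `k = 6` the result
#' has 4,992 positions: CLS at 0-based position 0, enhancer tokens at
#' 1..2,995, SEP at 2,996 and promoter tokens at 2,997..4,991. K-mers
#' containing non-ACGT bases map to UNK.
#'
#' @param enh_seq,prom_seq DNA strings (each at least `k` long).
#' @param vocab An `epi_vocab`.
#' @return An object of class `epi_tokens`: list with `ids` (0-based
#'   integer vector), `roles` (per-position factor CLS/ENH/SEP/PROM) and
#'   `k`.
#' @export
assemble_pair <- function(enh_seq, prom_seq, vocab) {
  e <- encode_kmers(enh_seq, vocab)
  p <- encode_kmers(prom_seq, vocab)
  ids <- c(vocab$specials[["CLS"]], e, vocab$specials[["SEP"]], p)
  roles <- factor(
    c("CLS", rep("ENH", length(e)), "SEP", rep("PROM", length(p))),
    levels = c("CLS", "ENH", "SEP", "PROM")
  )
  structure(list(ids = unname(ids), roles = roles, k = vocab$k),
            class = "epi_tokens")
}

#' @export
print.epi_tokens <- function(x, ...) {
  cat(sprintf("<epi_tokens> %d positions (%d ENH + %d PROM tokens), k = %d\n",
              length(x$ids), sum(x$roles == "ENH"), sum(x$roles == "PROM"), x$k))
  invisible(x)
}

#' Tidy a token sequence
#'
#' @param x An `epi_tokens`.
#' @param vocab Optional `epi_vocab` used to attach token strings.
#' @param ... Unused.
#' @return Tibble with 0-based `position`, `id`, `role` and (if `vocab`
#'   given) `token`.
#' @method as_tibble epi_tokens
#' @export
as_tibble.epi_tokens <- function(x, vocab = NULL, ...) {
  out <- tibble(position = seq_along(x$ids) - 1L, id = x$ids, role = as.character(x$roles))
  if (!is.null(vocab)) out$token <- vocab$tokens[out$id + 1L]
  out
}

#' Decode a token sequence back to its two DNA strings
#'
#' Reconstruction takes the first base of every k-mer plus the trailing
#' `k - 1` bases of the final k-mer of each segment, and verifies that
#' consecutive k-mers actually overlap; corrupted ids therefore raise an
#' error rather than silently producing a chimera. UNK tokens cannot be
#' decoded.
#'
#' @param tokens An `epi_tokens`.
#' @param vocab The `epi_vocab` used to assemble them.
#' @return List with `enh_seq` and `prom_seq` strings;
#'   `decode(assemble_pair(e, p, v), v)` is the identity for ACGT-only
#'   input.
#' @export
decode_pair <- function(tokens, vocab) {
  if (any(tokens$ids == vocab$specials[["UNK"]])) {
    abort("Token sequence contains UNK; the original bases are not recoverable.")
  }
  seg <- function(role) {
    ids <- tokens$ids[tokens$roles == role]
    if (length(ids) == 0L) abort(sprintf("No %s tokens present.", role))
    km <- vocab$tokens[ids + 1L]
    if (length(km) > 1L) {
      prev_suffix <- substring(km[-length(km)], 2L)
      next_prefix <- substring(km[-1L], 1L, vocab$k - 1L)
      if (!all(prev_suffix == next_prefix)) {
        abort(sprintf("Inconsistent %s token overlap: ids do not describe one sequence.", role))
      }
    }
    paste0(paste(substring(km, 1L, 1L), collapse = ""),
           substring(km[length(km)], 2L))
  }
  list(enh_seq = seg("ENH"), prom_seq = seg("PROM"))
}
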