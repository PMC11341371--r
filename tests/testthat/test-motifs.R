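# Exhaustive-enumeration oracle for the hypergeometric upper tail: draw
# every size-n subset of N pairs (K of them positive) and count subsets
# with >= k positives.
hyper_oracle <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  pos <- seq_len(K)
  hits <- colSums(matrix(draws %in% pos, nrow = n))
  mean(hits >= k)
}

test_that("enrichment p-value matches exhaustive enumeration for N <= 12", {
  expect_equal(enrichment_pvalue(4, 5, 4, 10), 5 / 210, tolerance = 1e-12)
  expect_equal(enrichment_pvalue(2, 5, 4, 10), 155 / 210, tolerance = 1e-12)
  expect_equal(enrichment_pvalue(0, 5, 4, 10), 1)
  cases <- expand.grid(N = c(5L, 9L, 12L), K = c(1L, 3L, 5L), n = c(1L, 4L, 6L))
  for (i in seq_len(nrow(cases))) {
    N <- cases$N[i]; K <- min(cases$K[i], N); n <- min(cases$n[i], N)
    for (k in 0:min(K, n)) {
      expect_equal(enrichment_pvalue(k, K, n, N), hyper_oracle(k, K, n, N),
                   tolerance = 1e-12,
                   label = sprintf("p(k=%d,K=%d,n=%d,N=%d)", k, K, n, N))
    }
  }
  expect_error(enrichment_pvalue(5, 4, 5, 10), "Inconsistent")
})

test_that("enrichment p-value is monotone non-increasing in k", {
  for (N in c(8L, 12L, 500L)) {
    K <- N %/% 3L; n <- N %/% 4L
    p <- enrichment_pvalue(0:min(K, n), K, n, N)
    expect_true(all(diff(p) <= 1e-15))
  }
})

test_that("PWM construction and MEME export round-trip", {
  mat <- matrix(c(0.7, 0.1, 0.1, 0.1,
                  0.05, 0.85, 0.05, 0.05,
                  0.25, 0.25, 0.25, 0.25), 3, 4, byrow = TRUE)
  pw <- ns$new_pwm(mat, support = 12, role = "enhancer", name = "m1")
  expect_identical(pw$consensus, "ACA")  # argmax per position, ties to first base
  f <- withr::local_tempfile(fileext = ".meme")
  export_meme(list(pw), f)
  back <- read_meme(f)
  expect_equal(back[["m1"]]$matrix, pw$matrix, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back[["m1"]]$support, 12L)
  # empty export is a valid header-only file
  f2 <- withr::local_tempfile(fileext = ".meme")
  export_meme(list(), f2)
  expect_length(read_meme(f2), 0L)
  bad <- pw; bad$matrix[1, 1] <- 0.9
  expect_error(export_meme(list(bad), f), "not summing")
})

test_that("identical candidates merge into one motif with pooled support", {
  pos_seqs <- vapply(1:10, function(i) {
    paste0(rand_dna(20, seed = 300 + i), "ACGTACGTAC", rand_dna(20, seed = 400 + i))
  }, character(1L))
  neg_seqs <- vapply(1:40, function(i) rand_dna(50, seed = 500 + i), character(1L))
  pairs <- tibble::tibble(
    enh_seq = c(pos_seqs, neg_seqs),
    prom_seq = rand_dna(30, seed = 9),
    label = c(rep(1L, 10), rep(0L, 40))
  )
  regions <- tibble::tibble(
    role = "enhancer", record = 1:10,
    start = 20L, end = 30L, peak_pos = 24L,
    seq = "ACGTACGTAC"
  )
  disc <- discover_motifs(regions, pairs, min_support = 5L)
  expect_length(disc$motifs, 1L)
  expect_identical(disc$motifs[[1L]]$consensus, "ACGTACGTAC")
  expect_equal(disc$motifs[[1L]]$support, 10L)
  expect_true(all(disc$candidates$kept))
})

test_that("discover_motifs recovers a planted consensus and rejects background", {
  ds <- tiny_dataset(seed = 21, n_pos = 40, n_neg = 160)
  planted <- ds$spec$enh_motif
  # regions built from the truth table: exact planted windows
  tr <- ds$truth[!is.na(ds$truth$enh_pos), ]
  regions <- tibble::tibble(
    role = "enhancer", record = tr$record,
    start = tr$enh_pos, end = tr$enh_pos + nchar(planted),
    peak_pos = tr$enh_pos + 3L,
    seq = tr$enh_motif
  )
  # plus random background regions that should not survive
  bg <- tibble::tibble(
    role = "enhancer", record = seq_len(20),
    start = 5L, end = 17L, peak_pos = 10L,
    seq = vapply(1:20, function(i) rand_dna(12, seed = 600 + i), character(1L))
  )
  disc <- discover_motifs(rbind(regions, bg), ds$pairs)
  expect_gte(length(disc$motifs), 1L)
  top <- disc$motifs[[1L]]
  expect_lte(ns$motif_hamming(planted, top$consensus), 1)
  expect_gte(top$support, 30L)
  # background candidates were not kept
  bg_cand <- disc$candidates[disc$candidates$seq %in% bg$seq, ]
  expect_true(all(!bg_cand$kept))
})

test_that("substring and mismatch-overlap candidates merge into one cluster", {
  expect_true(ns$can_merge("ACGTACGTAC", "GTACGT", 6, 1))       # substring
  expect_true(ns$can_merge("ACGTACGT", "CGTACGTT", 6, 1))       # overlap 7, 1 mm
  expect_false(ns$can_merge("ACGTACGT", "TTTTTTTT", 6, 1))
  al <- ns$best_overlap("ACGTACGT", "GTACGTAA", 6)
  expect_equal(al$offset, 2L)   # GTACGT lines up; overhanging AA costs nothing
  expect_equal(al$mismatch, 0L)
  expect_equal(al$overlap, 6L)
})

test_that("classify_common_specific separates planted from singleton regions", {
  ds <- tiny_dataset(seed = 22, n_pos = 30, n_neg = 90)
  planted <- ds$spec$enh_motif
  tr <- ds$truth[!is.na(ds$truth$enh_pos), ]
  common_regs <- tibble::tibble(
    role = "enhancer", record = tr$record,
    start = tr$enh_pos, end = tr$enh_pos + nchar(planted),
    peak_pos = tr$enh_pos + 3L, seq = tr$enh_motif
  )
  rand_regs <- tibble::tibble(
    role = "enhancer", record = seq_len(15),
    start = 10L, end = 22L, peak_pos = 15L,
    seq = vapply(1:15, function(i) rand_dna(12, seed = 700 + i), character(1L))
  )
  regions <- rbind(common_regs, rand_regs)
  disc <- discover_motifs(regions, ds$pairs)
  cs <- classify_common_specific(regions, disc)
  lab <- cs$regions$label
  expect_true(all(lab[seq_len(nrow(common_regs))] == "common"))
  expect_gte(mean(lab[-seq_len(nrow(common_regs))] == "specific"), 0.9)
  expect_equal(sum(cs$per_record$n_common) + sum(cs$per_record$n_specific),
               nrow(regions))
})
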