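# Attention profile math checked against hand-computed values.

row_stochastic <- function(n, seed) {
  withr::with_seed(seed, {
    M <- matrix(runif(n * n), n, n)
    M / rowSums(M)
  })
}

test_that("average_heads is the element-wise mean and stays row-stochastic", {
  A1 <- row_stochastic(5, 1)
  A2 <- row_stochastic(5, 2)
  stack <- ns$new_attention_stack(list(list(A1, A2), list(A1, A1)))
  M <- average_heads(stack)  # last layer: both heads A1
  expect_equal(M, A1)
  M1 <- average_heads(stack, layer = 1)
  expect_equal(M1, (A1 + A2) / 2)
  expect_equal(M1[2, 3], (A1[2, 3] + A2[2, 3]) / 2)
  expect_equal(rowSums(M1), rep(1, 5))
  bad <- ns$new_attention_stack(list(list(A1, row_stochastic(4, 3))))
  expect_error(average_heads(bad), "mismatch")
})

test_that("token_profile row means over all targets are exactly 1/L", {
  M <- row_stochastic(8, 4)
  roles <- factor(c("CLS", rep("ENH", 3), "SEP", rep("PROM", 3)),
                  levels = c("CLS", "ENH", "SEP", "PROM"))
  prof <- token_profile(M, roles, direction = "emitted", targets = "all")
  expect_equal(prof$score, rep(1 / 8, 8))
  # restricted targets: hand-computed means over promoter columns
  prof_p <- token_profile(M, roles, direction = "emitted", targets = "promoter")
  expect_equal(prof_p$score, rowMeans(M[, 6:8]))
  # received = column means
  prof_r <- token_profile(M, roles, direction = "received")
  expect_equal(prof_r$score, colMeans(M))
  expect_identical(prof$special, roles %in% c("CLS", "SEP"))
})

test_that("token_profile is equivariant under joint row/column permutation", {
  M <- row_stochastic(6, 5)
  roles <- factor(rep("ENH", 6), levels = c("CLS", "ENH", "SEP", "PROM"))
  perm <- c(3L, 1L, 6L, 2L, 5L, 4L)
  s1 <- token_profile(M, roles, direction = "received")$score
  s2 <- token_profile(M[perm, perm], roles, direction = "received")$score
  expect_equal(s2, s1[perm])
})

test_that("base_decompose averages covering k-mers with edge effects", {
  # k = 1: identity
  expect_equal(base_decompose(c(0.1, 0.4, 0.2), k = 1, element_len = 3),
               c(0.1, 0.4, 0.2))
  # single token: every base gets its score
  expect_equal(base_decompose(0.7, k = 6, element_len = 6), rep(0.7, 6))
  # two tokens, k = 6, length 7: ends get one token, middle the mean
  expect_equal(base_decompose(c(1, 3), k = 6, element_len = 7),
               c(1, rep(2, 5), 3))
  # general covering-count law against a direct loop
  k <- 4L; len <- 15L
  sc <- withr::with_seed(6, runif(len - k + 1L))
  direct <- vapply(seq_len(len), function(b) {
    cover <- max(1L, b - k + 1L):min(len - k + 1L, b)
    mean(sc[cover])
  }, numeric(1L))
  expect_equal(base_decompose(sc, k, len), direct)
  expect_error(base_decompose(sc, k, len + 1L), "Expected")
})

test_that("normalize_profile follows the shift-max formula exactly", {
  expect_equal(normalize_profile(c(1, 3)), c(0, 2 / 3))
  expect_equal(normalize_profile(c(0, 4)), c(0, 1))
  expect_equal(normalize_profile(rep(2.5, 4)), rep(0, 4))
  expect_error(normalize_profile(c(0, 0)), "not positive")
  # argmin is always exactly 0; output always within [0, 1]
  for (s in 1:20) {
    x <- withr::with_seed(s, runif(50, 0.1, 2))
    nz <- normalize_profile(x)
    expect_equal(nz[which.min(x)], 0)
    expect_true(all(nz >= 0 & nz <= 1))
    # invariance to positive rescaling (both min and max scale)
    expect_equal(normalize_profile(3.7 * x), nz)
  }
  expect_equal(normalize_profile(c(1, 3), method = "minmax"), c(0, 1))
})

test_that("call_regions finds maximal runs above threshold", {
  x <- rep(0.1, 30)
  expect_equal(nrow(call_regions(x, 0.5, 6)), 0L)
  x[10:17] <- 0.8  # 8-base plateau
  r <- call_regions(x, 0.5, 6, role = "enhancer")
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 9L)
  expect_equal(r$end, 17L)
  expect_equal(r$mean_score, 0.8)
  x2 <- rep(0.1, 30); x2[10:13] <- 0.9  # 4-base plateau below min_len
  expect_equal(nrow(call_regions(x2, 0.5, 6)), 0L)
  expect_error(call_regions(x, 1.2, 6), "threshold")
})

test_that("position_density conserves counts and localizes midpoints", {
  expect_true(all(position_density(
    tibble::tibble(role = character(), start = integer(), end = integer()),
    100, bins = 10)$count == 0))
  regs <- tibble::tibble(role = "promoter",
                         start = rep(1495L, 7L), end = rep(1505L, 7L))
  d <- position_density(regs, 2000, bins = 20)
  expect_equal(sum(d$count), 7L)
  hot <- d[d$count > 0, ]
  expect_equal(nrow(hot), 1L)
  # the TSS offset (1,500 for the standard window) falls in the hot bin
  expect_true(hot$bin_start <= 1500 && 1500 <= hot$bin_end)
})

test_that("per-pair profiles normalize jointly over both elements", {
  v <- new_vocab(6)
  m <- desk_model(v, seed = 3)
  tk <- assemble_pair(rand_dna(60, seed = 1), rand_dna(40, seed = 2), v)
  cls <- forward_classify(m, tk, return_attention = TRUE)
  prof <- pair_attention_profiles(cls$attention[[1L]], tk)
  expect_equal(prof$enhancer$length, 60L)
  expect_equal(prof$promoter$length, 40L)
  all_norm <- c(prof$enhancer$normalized, prof$promoter$normalized)
  expect_equal(min(all_norm), 0)
  expect_true(all(all_norm >= 0 & all_norm <= 1))
  all_raw <- c(prof$enhancer$raw, prof$promoter$raw)
  expect_equal(all_norm, (all_raw - min(all_raw)) / max(all_raw))
})
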