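# Shared fixtures, built in code at test time.

tiny_vocab <- function() new_vocab(6L)

# A deterministic random DNA string.
rand_dna <- function(n, seed = 1L, gc = 0.5) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  withr::with_seed(seed, paste(sample(names(probs), n, TRUE, prob = probs), collapse = ""))
}

# A minimal model small enough for exhaustive numeric checks.
tiny_model <- function(seed = 42L, vocab = new_vocab(1L), dropout = 0) {
  cfg <- model_config(vocab, n_layers = 2L, n_heads = 2L, hidden_dim = 8L,
                      ff_dim = 12L, max_positions = 32L, dropout = dropout,
                      cnn_widths = c(2L, 3L, 4L), cnn_filters = 3L)
  new_model(cfg, seed = seed)
}

# Tiny planted-motif dataset shared by training tests.
tiny_dataset <- function(seed = 5L, n_pos = 30L, n_neg = 60L,
                         enh_len = 80L, prom_len = 60L) {
  generate_epi_dataset(synth_spec(
    n_pos = n_pos, n_neg = n_neg, enh_len = enh_len, prom_len = prom_len,
    motif_len = 8L, plant_prob = 1, mutation_rate = 0, seed = seed
  ))
}

ns <- asNamespace("epiattn")
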