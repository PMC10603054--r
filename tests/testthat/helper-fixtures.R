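# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; nothing is read from disk.

# a tiny encoder/model configuration for fast structural tests
tiny_encoder_cfg <- function(k = 3L) {
  encoder_config(k = k, d_model = 16L, n_layers = 1L, n_heads = 2L,
                 ffn_hidden = 32L, n_positions = 128L)
}

tiny_model_cfg <- function(sample_len = 21L) {
  bindnet_config("small", encoder = tiny_encoder_cfg(),
                 align_channels = 8L, branch_channels = 2L,
                 pyramid_channels = 16L, dropout = 0,
                 sample_len = sample_len)
}

random_samples <- function(n, len = 21L, seed = 1L, with_structure = TRUE) {
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = ""), "")
    st <- if (with_structure) matrix(runif(n * len), n, len) else NULL
    fixed_samples(sequence = seqs, label = rep_len(c(1L, 0L), n),
                  structure = st)
  })
}

# O(n^2) pairwise AUC oracle (ties counted one half)
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# independent rank-slice oracle for the count normalization factor
norm_factor_oracle <- function(values, lo, hi) {
  n <- length(values)
  s <- sort(values)
  i_lo <- round(lo * n)
  i_hi <- round(hi * n)
  if (i_hi > i_lo) mean(s[(i_lo + 1):i_hi]) else s[min(ceiling(hi * n), n)]
}

# brute-force interval overlap: does [s, s+len) hit any peak row?
overlaps_any <- function(tx, s, len, peaks) {
  pk <- peaks[peaks$transcript_id == tx, , drop = FALSE]
  any(s < pk$end & s + len > pk$start)
}

expect_no_error <- function(expr) expect_error(expr, NA)
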