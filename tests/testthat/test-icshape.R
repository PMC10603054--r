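# icSHAPE reactivity scoring

test_that("replicates merge by elementwise addition", {
  cts <- rtbd_counts("tx", c(1, 2), c(3, 4), c(0, 0), c(0, 0), c(5, 5), c(0, 1))
  m <- combine_replicates(cts)
  expect_equal(m$rt_dmso, c(4, 6))
  expect_equal(m$rt_nai, c(0, 0))   # all-zero second replicate: identity
  expect_equal(m$bd_dmso, c(5, 6))
  expect_equal(combine_replicates(
    rtbd_counts("z", 0, 0, 0, 0, 0, 0))$rt_dmso, 0)
  expect_error(rtbd_counts("bad", 1:2, 1:3, 1:2, 1:2, 1:2, 1:2),
               class = "bindnet_length_mismatch")
  expect_error(rtbd_counts("neg", -1, 0, 0, 0, 0, 0),
               class = "bindnet_negative_counts")
})

test_that("count normalization divides by the upper rank-slice mean", {
  r <- normalize_counts(1:100, 0.90, 0.95)
  expect_equal(r$factor, 93)              # mean of sorted ranks 91..95
  expect_equal(r$values, (1:100) / 93)
  cst <- normalize_counts(rep(7, 40))
  expect_equal(cst$values, rep(1, 40))    # constant vector -> all ones
  # degenerate slice at n = 10 follows the explicit rank-slice rule
  r10 <- normalize_counts(1:10, 0.90, 0.95)
  expect_equal(r10$factor, norm_factor_oracle(1:10, 0.90, 0.95))
  # and the oracle agrees on random vectors
  withr::with_seed(4, {
    for (n in c(7, 23, 100, 301)) {
      v <- rpois(n, 40)
      expect_equal(normalize_counts(v)$factor, norm_factor_oracle(v, 0.9, 0.95))
    }
  })
  expect_error(normalize_counts(rep(0, 10)),
               class = "bindnet_normalization_factor")
  expect_error(normalize_counts(numeric(0)), class = "bindnet_empty_input")
})

test_that("enrichment follows (nai - alpha*dmso)/bd with a zero-bd guard", {
  expect_equal(enrichment(2, 1, 1, alpha = 0.25), 1.75)
  expect_equal(enrichment(c(4, 6), c(9, 9), c(2, 3), alpha = 0), c(2, 2))
  expect_true(is.na(enrichment(5, 1, 0, 0.25)))
  expect_error(enrichment(1:3, 1:2, 1:3), class = "bindnet_length_mismatch")
})

test_that("rescaling anchors, clamps, and nulls low coverage", {
  cfg <- icshape_config()
  e <- c(0, 1, 2, 3, 4, 10)
  bd <- rep(300, 6)
  q <- stats::quantile(e, c(0.05, 0.95), names = FALSE)
  out <- rescale_scores(e, bd, cfg)
  expect_equal(out[1], 0)                       # below q5 -> clamp at 0
  expect_equal(out[6], 1)                       # above q95 -> clamp at 1
  expect_true(all(out >= 0 & out <= 1))
  expect_equal(out[3], (e[3] - q[1]) / (q[2] - q[1]))
  # coverage rule: 199 -> NULL, 200 -> numeric (the ">=" convention)
  bd2 <- c(199, 200, 300, 300, 300, 300)
  out2 <- rescale_scores(e, bd2, cfg)
  expect_true(is.na(out2[1]))
  expect_false(is.na(out2[2]))
  expect_warning(rescale_scores(rep(NA_real_, 4), rep(300, 4), cfg),
                 class = "bindnet_all_undefined")
})

make_counts <- function(n, seed, depth = 1000) {
  withr::with_seed(seed, {
    rtbd_counts(paste0("t", seed),
                rpois(n, depth / 10), rpois(n, depth / 10),
                rpois(n, depth / 3), rpois(n, depth / 3),
                rpois(n, depth), rpois(n, depth))
  })
}

test_that("transcript scoring: range, length, scale and replicate symmetry", {
  cfg <- icshape_config(window_size = 100L, window_step = 10L)
  for (seed in 1:4) {
    n <- c(120, 250, 80, 301)[seed]   # includes shorter-than-window case
    cts <- make_counts(n, seed)
    prof <- score_transcript(cts, cfg)
    expect_length(prof, n)
    ok <- !is.na(prof)
    expect_true(all(prof[ok] >= 0 & prof[ok] <= 1))
    # doubling all counts leaves the profile unchanged
    dbl <- cts
    for (f in grep("^(rt|bd)", names(cts), value = TRUE)) dbl[[f]] <- 2L * cts[[f]]
    expect_equal(score_transcript(dbl, cfg), prof)
    # swapping the replicates of each library changes nothing
    swp <- rtbd_counts(cts$transcript_id,
                       cts$rt_dmso_rep2, cts$rt_dmso_rep1,
                       cts$rt_nai_rep2, cts$rt_nai_rep1,
                       cts$bd_dmso_rep2, cts$bd_dmso_rep1)
    expect_equal(score_transcript(swp, cfg), prof)
  }
})

test_that("scanning integer coverages: first numeric score appears at 200", {
  n <- 101L
  bd1 <- 150:250                     # merged coverage = bd1 + 0
  cts <- rtbd_counts("cov", rep(5L, n), rep(5L, n), rep(60L, n), rep(60L, n),
                     bd1, rep(0L, n))
  prof <- score_transcript(cts, icshape_config(window_size = n))
  cover <- 150:250
  expect_equal(min(cover[!is.na(prof)]), 200)
  expect_true(all(is.na(prof[cover < 200])))
})

test_that("known reactivity truth is recovered from simulated counts", {
  cfg <- synth_config(seed = 5, read_depth = 1e4)
  truth <- pmin(1, pmax(0, withr::with_seed(5, stats::runif(400))))
  cts <- simulate_rtbd("sim", truth, cfg)
  prof <- score_transcript(cts, icshape_config())
  rho <- cor(prof, truth, method = "spearman", use = "complete.obs")
  expect_gte(rho, 0.8)
})

test_that("count TSV round-trips through the reader and writer", {
  cts <- make_counts(30, 9)
  df <- data.frame(transcript_id = "t9", position = 1:30,
                   rt_dmso_1 = cts$rt_dmso_rep1, rt_dmso_2 = cts$rt_dmso_rep2,
                   rt_nai_1 = cts$rt_nai_rep1, rt_nai_2 = cts$rt_nai_rep2,
                   bd_dmso_1 = cts$bd_dmso_rep1, bd_dmso_2 = cts$bd_dmso_rep2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- read_rtbd_counts(f)
  expect_equal(back[["t9"]]$rt_nai_rep1, cts$rt_nai_rep1)
  out <- withr::local_tempfile(fileext = ".tsv")
  prof <- score_transcript(back[["t9"]], icshape_config(window_size = 30L))
  write_reactivity_tsv(list(t9 = prof), out)
  txt <- read.table(out, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(txt), 30)
  expect_true(all(txt$score == "NULL" | !is.na(suppressWarnings(as.numeric(txt$score)))))
})
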