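# Dataset construction

tx_set <- function() {
  withr::with_seed(2, {
    lens <- c(400, 150, 101, 80)
    seqs <- vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = ""), "")
    setNames(seqs, paste0("tx", seq_along(seqs)))
  })
}

test_that("peaks are fixed to 101 nt centred on the midpoint", {
  tx <- tx_set()
  # 50-nt peak mid-transcript: window centred on floor((start+end)/2)
  p <- list(transcript_id = "tx1", start = 100L, end = 150L)
  s <- fix_site_length(p, tx)
  expect_equal(s$length, 101L)
  mid <- (100L + 150L) %/% 2L
  expect_equal(s$origin$start, mid - 50L)
  expect_equal(s$sequence, substr(tx[["tx1"]], mid - 49L, mid + 51L))
  # 101-nt peak comes back unchanged
  p2 <- list(transcript_id = "tx1", start = 120L, end = 221L)
  s2 <- fix_site_length(p2, tx)
  expect_equal(s2$origin$start, 120L)
  expect_equal(s2$sequence, substr(tx[["tx1"]], 121L, 221L))
  # 150-nt peak: central 101 retained (midpoint +/- 50 oracle)
  p3 <- list(transcript_id = "tx1", start = 100L, end = 250L)
  s3 <- fix_site_length(p3, tx)
  expect_equal(s3$origin$start, (100L + 250L) %/% 2L - 50L)
  # window off the 5' end is shifted inward
  p4 <- list(transcript_id = "tx2", start = 0L, end = 20L)
  s4 <- fix_site_length(p4, tx)
  expect_equal(s4$origin$start, 0L)
  expect_equal(s4$length, 101L)
  # transcript shorter than 101: rejected with a message
  expect_message(r <- fix_site_length(list(transcript_id = "tx4",
                                           start = 10L, end = 40L), tx),
                 "rejecting")
  expect_null(r)
})

test_that("top-confidence selection with deterministic tie-breaks", {
  withr::with_seed(3, {
    peaks <- data.frame(
      transcript_id = sample(paste0("tx", 1:9), 6000, replace = TRUE),
      start = sample.int(400, 6000, replace = TRUE),
      confidence = round(rexp(6000), 3), stringsAsFactors = FALSE)
    peaks$end <- peaks$start + 50L
  })
  top <- select_positives(peaks, 5000)
  expect_equal(nrow(top), 5000)
  expect_gte(min(top$confidence), max(peaks$confidence[
    !paste(peaks$transcript_id, peaks$start) %in%
      paste(top$transcript_id, top$start)]))
  # fewer than n: all returned
  expect_equal(nrow(select_positives(peaks[1:3000, ], 5000)), 3000)
  # all-equal confidences: the first n in (transcript_id, start) order
  eq <- peaks[1:100, ]; eq$confidence <- 1
  sel <- select_positives(eq, 10)
  oracle <- eq[order(-eq$confidence, eq$transcript_id, eq$start), ][1:10, ]
  expect_equal(sel$start, oracle$start)
  expect_equal(sel$transcript_id, oracle$transcript_id)
})

test_that("negative sampling: counts, exclusion, determinism, shortfall", {
  tx <- tx_set()
  peaks <- data.frame(transcript_id = c("tx1", "tx1", "tx2"),
                      start = c(0L, 200L, 20L), end = c(120L, 280L, 60L),
                      confidence = 1, stringsAsFactors = FALSE)
  neg <- sample_negatives(tx, n = 15L, exclude = peaks, seed = 7)
  expect_length(neg, 15L)
  expect_true(all(nchar(neg$sequence) == 101L))
  expect_true(all(neg$label == 0L))
  # brute-force overlap oracle: no sampled window touches an excluded peak
  for (i in seq_len(15L)) {
    expect_false(overlaps_any(neg$origin$transcript_id[i],
                              neg$origin$start[i], 101L, peaks))
  }
  neg2 <- sample_negatives(tx, n = 15L, exclude = peaks, seed = 7)
  expect_identical(neg$sequence, neg2$sequence)
  expect_error(sample_negatives(tx, n = 10000L, seed = 1),
               class = "bindnet_insufficient_windows")
})

test_that("splits have the stated sizes and partition the input", {
  s <- random_samples(1000, len = 21)
  sp <- split_dataset(s, seed = 5)
  expect_length(sp$test, 200)        # round(0.2 * 1000)
  expect_length(sp$validation, 160)  # round(0.2 * 800)
  expect_length(sp$train, 640)
  ids <- c(sp$train$id, sp$validation$id, sp$test$id)
  expect_setequal(ids, s$id)
  expect_equal(anyDuplicated(ids), 0L)
  sp2 <- split_dataset(s, seed = 5)
  expect_identical(sp$test$id, sp2$test$id)
  # size arithmetic holds for awkward N too
  for (N in c(5, 7, 23, 101)) {
    spN <- split_dataset(random_samples(N, len = 11), seed = 2)
    expect_length(spN$test, round(0.2 * N))
    expect_length(spN$validation, round(0.2 * (N - round(0.2 * N))))
  }
})

test_that("k-mer tokenization matches the worked example", {
  tk <- tokenize("ACGUGA", k = 3)
  expect_equal(tk$tokens, c("[CLS]", "ACG", "CGU", "GUG", "UGA", "[SEP]"))
  expect_equal(tk$n_interior, 4L)
  seq101 <- paste(rep("ACGU", 26), collapse = "")
  tk101 <- tokenize(substr(seq101, 1, 101), k = 3)
  expect_equal(tk101$n_interior, 99L)
  # degenerate k = 1: tokens are the nucleotides
  expect_equal(tokenize("ACGU", k = 1)$tokens[2:5], c("A", "C", "G", "U"))
  # T silently maps to U; other symbols error with a position
  expect_equal(tokenize("ACGT", k = 3)$tokens[3], "CGU")
  expect_error(tokenize("ACGN", k = 3), class = "bindnet_alphabet")
})

test_that("structure aligns to tokens by NA-aware sliding means", {
  expect_equal(align_structure_to_tokens(rep(0.4, 10), k = 3), rep(0.4, 8))
  expect_equal(align_structure_to_tokens(rep(NA_real_, 10), k = 3), rep(-1, 8))
  p <- c(0, 1, 0, 0, rep(0, 6))
  expect_equal(align_structure_to_tokens(p, k = 3)[1], 1 / 3)
  # partial NA: mean over the defined bases only
  expect_equal(align_structure_to_tokens(c(NA, 0.6, NA, 1), k = 3),
               c(0.6, 0.8))
})

test_that("interval extraction honours BED semantics and strand", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 test", "ACGTACGTTG", ">chr2", "GGGCCC"), fa)
  iv <- data.frame(chrom = "chr1", start = 0L, end = 4L, strand = "+",
                   stringsAsFactors = FALSE)
  expect_equal(unname(extract_interval_sequences(iv, fa)), "ACGU")
  # minus strand: reverse complement, checked against the Biostrings oracle
  ivm <- data.frame(chrom = "chr1", start = 0L, end = 4L, strand = "-",
                    stringsAsFactors = FALSE)
  oracle <- chartr("T", "U", as.character(
    Biostrings::reverseComplement(Biostrings::DNAString("ACGT"))))
  expect_equal(unname(extract_interval_sequences(ivm, fa)), oracle)
  empty <- extract_interval_sequences(
    data.frame(chrom = character(0), start = integer(0), end = integer(0)), fa)
  expect_length(empty, 0L)
  bad <- data.frame(chrom = "chrX", start = 0L, end = 2L)
  expect_error(extract_interval_sequences(bad, fa),
               class = "bindnet_missing_chrom")
})

test_that("sample manifests round-trip through TSV", {
  s <- random_samples(8, len = 21)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_samples_tsv(s, f)
  back <- read_samples_tsv(f)
  expect_equal(back$sequence, s$sequence)
  expect_equal(back$label, s$label)
  expect_equal(dim(back$structure), dim(s$structure))
  expect_lt(max(abs(back$structure - s$structure)), 1e-3)
})
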