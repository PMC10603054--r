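# Dataset construction: peaks + transcriptome -> fixed-length labelled
# samples with aligned structure vectors, train/validation/test splits, and
# k-mer tokenization.
#
# Coordinate conventions: transcript/genomic intervals are 0-based half-open
# internally (BED semantics); human-facing reports are 1-based.

SAMPLE_LEN <- 101L

#' Labelled fixed-length sample container
#'
#' A column-oriented container for fixed-length (101-nt) training records:
#' sequence, binary label, optional per-base structure in [0,1] (NA =
#' missing), and provenance.
#'
#' @param sequence character vector of RNA sequences, all the same length.
#' @param label integer vector of 0/1 labels.
#' @param structure numeric matrix (samples x length) or NULL.
#' @param transcript_id,start provenance (0-based window start).
#' @return object of class `fixed_samples`: a list with fields `id`,
#'   `sequence`, `label`, `structure`, `origin`, `length`.
#' @export
fixed_samples <- function(sequence, label, structure = NULL,
                          transcript_id = NA_character_, start = NA_integer_) {
  sequence <- as_rna(sequence, "sample sequence")
  n <- length(sequence)
  len <- unique(nchar(sequence))
  assert_that(length(len) == 1L, "length_mismatch",
              "all sample sequences must share one length")
  assert_that(all(label %in% c(0L, 1L)), "labels", "labels must be 0/1")
  assert_that(length(label) == n || length(label) == 1L, "labels",
              "label must have length 1 or %d", n)
  label <- rep_len(label, n)
  if (!is.null(structure)) {
    assert_that(is.matrix(structure) && nrow(structure) == n &&
                ncol(structure) == len, "structure_shape",
                "structure must be a %d x %d matrix", n, len)
  }
  structure(list(id = sprintf("s%06d", seq_len(n)),
                 sequence = sequence,
                 label = as.integer(label),
                 structure = structure,
                 origin = data.frame(transcript_id = rep_len(transcript_id, n),
                                     start = rep_len(as.integer(start), n),
                                     stringsAsFactors = FALSE),
                 length = len),
            class = "fixed_samples")
}

#' @export
length.fixed_samples <- function(x) length(x$sequence)

#' Subset a fixed_samples container
#' @param x a `fixed_samples` object.
#' @param i index vector.
#' @param ... unused.
#' @export
`[.fixed_samples` <- function(x, i, ...) {
  out <- x
  out$id <- x$id[i]
  out$sequence <- x$sequence[i]
  out$label <- x$label[i]
  if (!is.null(x$structure)) out$structure <- x$structure[i, , drop = FALSE]
  out$origin <- x$origin[i, , drop = FALSE]
  out
}

#' @export
print.fixed_samples <- function(x, ...) {
  cat(sprintf("<fixed_samples> %d records of %d nt (%d positive, %d negative)%s\n",
              length(x), x$length, sum(x$label == 1L), sum(x$label == 0L),
              if (is.null(x$structure)) ", no structure" else ", with structure"))
  invisible(x)
}

# concatenate fixed_samples containers (ids regenerated)
#' @export
c.fixed_samples <- function(...) {
  parts <- list(...)
  len <- unique(vapply(parts, function(p) p$length, 0L))
  assert_that(length(len) == 1L, "length_mismatch",
              "cannot concatenate samples of differing lengths")
  st <- lapply(parts, function(p) p$structure)
  has_st <- !vapply(st, is.null, TRUE)
  structure_mat <- if (all(has_st)) do.call(rbind, st) else NULL
  fixed_samples(sequence = unlist(lapply(parts, function(p) p$sequence)),
                label = unlist(lapply(parts, function(p) p$label)),
                structure = structure_mat,
                transcript_id = unlist(lapply(parts, function(p) p$origin$transcript_id)),
                start = unlist(lapply(parts, function(p) p$origin$start)))
}

#' Fix a peak to the target sample length
#'
#' A region shorter than the target is extended from its midpoint to both
#' sides; a longer region is trimmed from both sides. The midpoint is
#' `floor((start+end)/2)` and the odd extra base goes to the 3' side.
#' Windows running off a transcript end are shifted inward; transcripts
#' shorter than the target are rejected.
#'
#' @param peak one-row data.frame (transcript_id, start, end, 0-based
#'   half-open) or a list with those fields.
#' @param transcripts named character vector of transcript sequences.
#' @param structure optional named list of per-base reactivity vectors.
#' @param target_len window length (101).
#' @return `fixed_samples` with one record (label 1), or NULL with a message
#'   if the transcript is too short.
#' @export
fix_site_length <- function(peak, transcripts, structure = NULL,
                            target_len = SAMPLE_LEN) {
  tx <- peak$transcript_id
  assert_that(tx %in% names(transcripts), "unknown_transcript",
              "peak references unknown transcript '%s'", tx)
  seq <- transcripts[[tx]]
  L <- nchar(seq)
  assert_that(peak$start >= 0 && peak$start < peak$end && peak$end <= L,
              "peak_coords", "invalid peak [%d,%d) on '%s' (length %d)",
              peak$start, peak$end, tx, L)
  if (L < target_len) {
    message(sprintf("rejecting peak on '%s': transcript length %d < %d",
                    tx, L, target_len))
    return(NULL)
  }
  mid <- (peak$start + peak$end) %/% 2L           # 0-based midpoint
  w0 <- mid - (target_len - 1L) %/% 2L            # extra base lands 3'
  w0 <- min(max(w0, 0L), L - target_len)          # shift inward at ends
  st <- NULL
  if (!is.null(structure) && tx %in% names(structure)) {
    st <- matrix(structure[[tx]][(w0 + 1L):(w0 + target_len)], nrow = 1L)
  }
  fixed_samples(sequence = substr(seq, w0 + 1L, w0 + target_len),
                label = 1L, structure = st, transcript_id = tx, start = w0)
}

#' Keep the n most confident peaks
#'
#' Ties are broken by (transcript_id, start) lexicographic order so selection
#' is deterministic; if fewer than `n` peaks exist, all are returned.
#'
#' @param peaks data.frame with columns transcript_id, start, end, confidence.
#' @param n number of positives to retain (default 5000).
#' @return the selected rows, ordered by decreasing confidence.
#' @export
select_positives <- function(peaks, n = 5000L) {
  ord <- order(-peaks$confidence, peaks$transcript_id, peaks$start)
  peaks[ord[seq_len(min(n, nrow(peaks)))], , drop = FALSE]
}

#' Sample negative windows from a transcriptome
#'
#' Draws `n` windows of `length` nt uniformly (without replacement) over all
#' eligible start positions of the transcript set. By default windows
#' overlapping any excluded peak are ineligible, preventing label
#' contamination.
#'
#' @param transcripts named character vector of transcript sequences.
#' @param n number of windows (default 10000).
#' @param length window length (101).
#' @param exclude data.frame of peaks to avoid, or NULL to disable exclusion.
#' @param seed integer seed.
#' @param structure optional named list of per-base reactivity vectors.
#' @return `fixed_samples` with `n` records, all label 0.
#' @export
sample_negatives <- function(transcripts, n = 10000L, length = SAMPLE_LEN,
                             exclude = NULL, seed = 1L, structure = NULL) {
  lens <- nchar(transcripts)
  ids <- names(transcripts)
  cand <- lapply(seq_along(transcripts), function(i) {
    L <- lens[i]
    if (L < length) return(integer(0))
    ok <- rep(TRUE, L - length + 1L)              # starts 0..L-length (index-1)
    if (!is.null(exclude)) {
      pk <- exclude[exclude$transcript_id == ids[i], , drop = FALSE]
      for (j in seq_len(nrow(pk))) {
        # window [s, s+length) overlaps peak [p0, p1) iff s < p1 and s+length > p0
        lo <- max(0L, pk$start[j] - length + 1L)
        hi <- min(L - length, pk$end[j] - 1L)
        if (lo <= hi) ok[(lo + 1L):(hi + 1L)] <- FALSE
      }
    }
    which(ok) - 1L
  })
  n_cand <- vapply(cand, length, 0L)
  total <- sum(n_cand)
  assert_that(total >= n, "insufficient_windows",
              "only %d eligible windows for %d requested negatives (short by %d)",
              total, n, n - total)
  withr::with_seed(derive_seed(seed, 23L), {
    pick <- sort(sample.int(total, n))
  })
  tx_of <- rep(seq_along(cand), n_cand)
  start_all <- unlist(cand, use.names = FALSE)
  tx <- tx_of[pick]
  s0 <- start_all[pick]
  seqs <- substring(transcripts[tx], s0 + 1L, s0 + length)
  st <- NULL
  if (!is.null(structure)) {
    st <- t(vapply(seq_along(tx), function(i) {
      p <- structure[[ids[tx[i]]]]
      if (is.null(p)) rep(NA_real_, length) else p[(s0[i] + 1L):(s0[i] + length)]
    }, numeric(length)))
  }
  fixed_samples(sequence = seqs, label = 0L, structure = st,
                transcript_id = ids[tx], start = s0)
}

#' Split samples into train / validation / test sets
#'
#' 20% of the samples become the independent test set; 20% of the remainder
#' becomes the validation set (both `round()`ed); the rest is the training
#' set. Shuffling is seeded, so the split is reproducible.
#'
#' @param samples a `fixed_samples` object.
#' @param seed integer seed.
#' @param test_frac,val_frac split fractions.
#' @return list with elements `train`, `validation`, `test`.
#' @export
split_dataset <- function(samples, seed = 1L, test_frac = 0.2, val_frac = 0.2) {
  n <- length(samples)
  assert_that(n >= 5L, "too_few_samples", "need at least 5 samples to split")
  withr::with_seed(derive_seed(seed, 29L), {
    perm <- sample.int(n)
  })
  n_test <- round(test_frac * n)
  n_val <- round(val_frac * (n - n_test))
  test_i <- perm[seq_len(n_test)]
  val_i <- perm[n_test + seq_len(n_val)]
  train_i <- perm[-(seq_len(n_test + n_val))]
  list(train = samples[train_i], validation = samples[val_i],
       test = samples[test_i])
}

#' Tokenize an RNA sequence into overlapping k-mers
#'
#' Overlapping k-mers by step 1, flanked by `[CLS]` and `[SEP]`. T is mapped
#' to U first; any other non-ACGU character is an error naming its position.
#'
#' @param sequence RNA string.
#' @param k k-mer size (3 by default; 1 is permitted as the degenerate case).
#' @return object of class `token_sequence`: list(tokens, k, n_interior).
#' @export
tokenize <- function(sequence, k = 3L) {
  assert_that(k >= 1L && k <= 6L, "config", "k must be in 1..6")
  s <- as_rna(sequence)
  n <- nchar(s)
  assert_that(n >= k, "too_short", "sequence length %d < k = %d", n, k)
  kmers <- substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  structure(list(tokens = c("[CLS]", kmers, "[SEP]"), k = as.integer(k),
                 n_interior = n - k + 1L),
            class = "token_sequence")
}

#' Align a per-base structure profile to k-mer tokens
#'
#' Token i covers bases i..i+k-1 and carries the mean of the non-missing
#' scores it covers; tokens covering only missing bases carry the sentinel
#' -1.
#'
#' @param profile numeric per-base reactivity (NA = missing).
#' @param k k-mer size.
#' @return numeric vector of length `length(profile) - k + 1`.
#' @export
align_structure_to_tokens <- function(profile, k = 3L) {
  n <- length(profile)
  nt <- n - k + 1L
  assert_that(nt >= 1L, "too_short", "profile shorter than k")
  out <- vapply(seq_len(nt), function(i) {
    w <- profile[i:(i + k - 1L)]
    if (all(is.na(w))) -1 else mean(w, na.rm = TRUE)
  }, 0)
  out
}

#' Extract interval sequences from a FASTA reference
#'
#' BED 0-based half-open semantics; minus-strand intervals are
#' reverse-complemented; everything is returned as RNA (T -> U).
#'
#' @param intervals data.frame with columns chrom, start, end and optionally
#'   name, strand ("+"/"-").
#' @param fasta path to a FASTA file.
#' @return named character vector of RNA sequences.
#' @export
extract_interval_sequences <- function(intervals, fasta) {
  ref <- Biostrings::readBStringSet(fasta)   # DNA or RNA letters
  names(ref) <- sub("\\s.*$", "", names(ref))
  missing <- setdiff(unique(intervals$chrom), names(ref))
  assert_that(length(missing) == 0, "missing_chrom",
              "chromosome(s) absent from FASTA: %s", paste(missing, collapse = ", "))
  if (nrow(intervals) == 0) return(stats::setNames(character(0), character(0)))
  chr_seq <- stats::setNames(as_rna(as.character(ref), "reference"), names(ref))
  assert_that(all(intervals$start >= 0 &
                  intervals$end <= nchar(chr_seq)[match(intervals$chrom, names(ref))] &
                  intervals$start < intervals$end), "interval_coords",
              "interval out of reference bounds")
  seqs <- substring(chr_seq[intervals$chrom], intervals$start + 1L,
                    intervals$end)
  if (!is.null(intervals$strand)) {
    neg <- intervals$strand == "-"
    if (any(neg)) seqs[neg] <- rna_revcomp(seqs[neg])
  }
  nm <- if (!is.null(intervals$name)) intervals$name else
    sprintf("%s:%d-%d", intervals$chrom, intervals$start, intervals$end)
  stats::setNames(unname(seqs), nm)
}

#' Read a BED6 peak file
#'
#' Column 5 (score) is taken as the peak confidence.
#'
#' @param path BED file.
#' @return data.frame with transcript_id, start, end, name, confidence, strand.
#' @export
read_peaks_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  assert_that(ncol(df) >= 5, "bed_columns", "need at least 5 BED columns")
  out <- data.frame(transcript_id = df[[1]], start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]),
                    name = if (ncol(df) >= 4) df[[4]] else ".",
                    confidence = as.numeric(df[[5]]),
                    strand = if (ncol(df) >= 6) df[[6]] else "+",
                    stringsAsFactors = FALSE)
  out
}

#' Read a transcriptome FASTA as RNA
#' @param path FASTA file (plain or gzip).
#' @return named character vector of RNA sequences.
#' @export
read_transcripts_fasta <- function(path) {
  # BString: accepts both DNA (T) and RNA (U) alphabets; as_rna validates
  x <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  assert_that(!anyDuplicated(nm), "duplicate_ids", "duplicate transcript ids in FASTA")
  stats::setNames(as_rna(as.character(x)), nm)
}

#' Build a complete labelled dataset from peaks and a transcriptome
#'
#' Selects the top-confidence peaks as positives, fixes each to 101 nt,
#' samples negatives from the remaining transcriptome, and splits into
#' train/validation/test.
#'
#' @param peaks data.frame of peaks (transcript_id, start, end, confidence).
#' @param transcripts named character vector of transcript sequences.
#' @param structure optional named list of per-base reactivity vectors.
#' @param n_pos,n_neg class sizes (5000 / 10000 by default).
#' @param exclude_positives drop negative windows overlapping any positive.
#' @param seed integer seed.
#' @return list(samples, splits) where splits = list(train, validation, test).
#' @export
build_dataset <- function(peaks, transcripts, structure = NULL,
                          n_pos = 5000L, n_neg = 10000L,
                          exclude_positives = TRUE, seed = 1L) {
  top <- select_positives(peaks, n_pos)
  pos_list <- lapply(seq_len(nrow(top)), function(i)
    fix_site_length(top[i, ], transcripts, structure))
  pos_list <- Filter(Negate(is.null), pos_list)
  assert_that(length(pos_list) > 0, "no_positives", "every positive was rejected")
  pos <- do.call(c, pos_list)
  neg <- sample_negatives(transcripts, n = n_neg,
                          exclude = if (exclude_positives) top else NULL,
                          seed = seed, structure = structure)
  if (is.null(pos$structure) != is.null(neg$structure)) {
    pos$structure <- pos$structure %||%
      matrix(NA_real_, length(pos), pos$length)
    neg$structure <- neg$structure %||%
      matrix(NA_real_, length(neg), neg$length)
  }
  samples <- c(pos, neg)
  list(samples = samples, splits = split_dataset(samples, seed = seed))
}

#' Write a sample manifest TSV
#'
#' Columns: id, sequence, label, transcript_id, start, structure (comma-
#' separated per-base scores, `NA` for missing; empty when no structure).
#' @param samples `fixed_samples`.
#' @param path output TSV.
#' @export
write_samples_tsv <- function(samples, path) {
  st <- if (is.null(samples$structure)) rep("", length(samples)) else
    apply(samples$structure, 1, function(r)
      paste(formatC(r, digits = 4, format = "g"), collapse = ","))
  df <- data.frame(id = samples$id, sequence = samples$sequence,
                   label = samples$label,
                   transcript_id = samples$origin$transcript_id,
                   start = samples$origin$start, structure = st,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample manifest TSV written by [write_samples_tsv()]
#' @param path TSV file.
#' @return `fixed_samples`.
#' @export
read_samples_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "__none__")
  st <- NULL
  if (is.character(df$structure) && any(nzchar(df$structure), na.rm = TRUE)) {
    st <- t(vapply(strsplit(df$structure, ","),
                   function(x) suppressWarnings(as.numeric(x)),
                   numeric(nchar(df$sequence[1]))))
  }
  fixed_samples(sequence = df$sequence, label = df$label, structure = st,
                transcript_id = as.character(df$transcript_id),
                start = suppressWarnings(as.integer(df$start)))
}
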