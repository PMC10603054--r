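# Synthetic-data generators.
#
# These emulate the statistical structure the predictive model assumes:
# random transcriptomes, confidence-ranked peak sets, planted sequence motifs
# with single-/double-stranded structure preferences encoded as reactivity
# profiles, and Poisson RT-stop / base-density count tables consistent with a
# known ground-truth reactivity. Everything is a pure function of
# (config, seed).

#' Synthetic-data configuration
#'
#' @param seed integer master seed; every generator draws from it.
#' @param n_transcripts number of transcripts in the synthetic transcriptome.
#' @param transcript_length_range integer range (min, max) of lengths.
#' @param motif planted RNA motif (over A/C/G/U).
#' @param motif_structure_mean mean reactivity inside the motif (high =
#'   single-stranded preference).
#' @param background_structure_mean mean reactivity outside the motif.
#' @param noise_sd standard deviation of the truncated-normal structure noise.
#' @param n_pos,n_neg class sizes for planted-motif datasets.
#' @param read_depth expected reads per base for count simulation.
#' @param background_rate baseline RT-stop rate as a fraction of depth.
#' @param gain reactivity-to-RT-stop gain as a fraction of depth.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_transcripts = 50L,
                         transcript_length_range = c(200L, 500L),
                         motif = "UGCAUG",
                         motif_structure_mean = 0.9,
                         background_structure_mean = 0.3,
                         noise_sd = 0.15,
                         n_pos = 500L, n_neg = 1000L,
                         read_depth = 100, background_rate = 0.1, gain = 1.0) {
  motif <- as_rna(motif, "motif")
  assert_that(motif_structure_mean >= 0 && motif_structure_mean <= 1 &&
              background_structure_mean >= 0 && background_structure_mean <= 1,
              "config", "structure means must lie in [0,1]")
  assert_that(read_depth >= 0, "config", "read_depth must be >= 0")
  structure(list(seed = as.integer(seed), n_transcripts = as.integer(n_transcripts),
                 transcript_length_range = as.integer(transcript_length_range),
                 motif = motif, motif_structure_mean = motif_structure_mean,
                 background_structure_mean = background_structure_mean,
                 noise_sd = noise_sd, n_pos = as.integer(n_pos),
                 n_neg = as.integer(n_neg), read_depth = read_depth,
                 background_rate = background_rate, gain = gain),
            class = "synth_config")
}

random_rna <- function(n) {
  paste(sample(RNA_BASES, n, replace = TRUE), collapse = "")
}

# truncated-normal-by-clipping structure noise
rstruct <- function(n, mean, sd) pmin(1, pmax(0, stats::rnorm(n, mean, sd)))

#' Generate a random transcriptome
#'
#' i.i.d. uniform ACGU sequences with lengths uniform over the configured
#' range; reproducible under the config seed.
#'
#' @param cfg a [synth_config()].
#' @return named character vector of RNA sequences (a transcript set).
#' @export
generate_transcriptome <- function(cfg = synth_config()) {
  withr::with_seed(derive_seed(cfg$seed, 11L), {
    if (cfg$n_transcripts == 0L) {
      return(stats::setNames(character(0), character(0)))
    }
    lens <- sample(seq.int(cfg$transcript_length_range[1],
                           cfg$transcript_length_range[2]),
                   cfg$n_transcripts, replace = TRUE)
    seqs <- vapply(lens, random_rna, "")
    stats::setNames(seqs, sprintf("synthetic_tx_%04d", seq_along(seqs)))
  })
}

#' Generate a confidence-ranked synthetic peak set
#'
#' Random intervals on a transcript set with exponential-tailed confidence
#' scores, emulating ranked binding-site peak calls.
#'
#' @param transcripts named character vector of transcript sequences.
#' @param n_peaks number of peaks to draw.
#' @param width_range integer range of peak widths.
#' @param seed integer seed.
#' @return data.frame with columns transcript_id, start, end (0-based
#'   half-open), confidence.
#' @export
generate_peaks <- function(transcripts, n_peaks = 6000L,
                           width_range = c(30L, 160L), seed = 1L) {
  lens <- nchar(transcripts)
  eligible <- names(transcripts)[lens >= width_range[1]]
  assert_that(length(eligible) > 0, "config", "no transcript can host a peak")
  withr::with_seed(derive_seed(seed, 13L), {
    tx <- sample(eligible, n_peaks, replace = TRUE)
    w <- pmin(sample(seq.int(width_range[1], width_range[2]), n_peaks, replace = TRUE),
              lens[tx])
    start <- floor(stats::runif(n_peaks) * (lens[tx] - w + 1))
    data.frame(transcript_id = tx, start = as.integer(start),
               end = as.integer(start + w),
               confidence = stats::rexp(n_peaks, rate = 0.5),
               stringsAsFactors = FALSE)
  })
}

#' Plant a motif into labelled fixed-length samples
#'
#' Positives are random 101-nt sequences carrying the configured motif at a
#' uniform offset, with per-base structure drawn around
#' `motif_structure_mean` inside the motif and `background_structure_mean`
#' outside (clipped normal noise). Negatives are random background sequences
#' with background structure; chance occurrences of the motif in negatives
#' are left in place so the negative class matches the background
#' distribution.
#'
#' @param cfg a [synth_config()].
#' @param sample_len sample length in nt (101 by default).
#' @param structure_informative if FALSE, positives get background structure
#'   too (sequence-only signal); if "only", positives are random sequences
#'   (no motif) and only the structure differs between classes.
#' @return list with `samples` (a `fixed_samples` object, see
#'   [fixed_samples()]) and `truth` (data.frame of planted 1-based offsets,
#'   NA for negatives).
#' @export
plant_motif_dataset <- function(cfg = synth_config(), sample_len = 101L,
                                structure_informative = TRUE) {
  m <- cfg$motif
  ml <- nchar(m)
  assert_that(ml < sample_len, "config", "motif must be shorter than the sample")
  struct_only <- identical(structure_informative, "only")
  withr::with_seed(derive_seed(cfg$seed, 17L), {
    n <- cfg$n_pos + cfg$n_neg
    seqs <- vapply(seq_len(n), function(i) random_rna(sample_len), "")
    labels <- rep(c(1L, 0L), c(cfg$n_pos, cfg$n_neg))
    offsets <- rep(NA_integer_, n)
    struct <- matrix(rstruct(n * sample_len, cfg$background_structure_mean,
                             cfg$noise_sd), n, sample_len, byrow = TRUE)
    for (i in seq_len(cfg$n_pos)) {
      off <- sample.int(sample_len - ml + 1L, 1L)
      offsets[i] <- off
      if (!struct_only) {
        substr(seqs[i], off, off + ml - 1L) <- m
      }
      if (!isFALSE(structure_informative)) {
        struct[i, off:(off + ml - 1L)] <-
          rstruct(ml, cfg$motif_structure_mean, cfg$noise_sd)
      }
    }
    samples <- fixed_samples(sequence = seqs, label = labels,
                             structure = struct,
                             transcript_id = sprintf("planted_%05d", seq_len(n)),
                             start = rep(0L, n))
    list(samples = samples,
         truth = data.frame(id = samples$id, label = labels, offset = offsets,
                            motif = m, stringsAsFactors = FALSE))
  })
}

#' Simulate RT-stop / base-density counts from a known reactivity truth
#'
#' Base density is Poisson(read_depth) per replicate; NAI RT-stops are
#' Poisson(read_depth * (background_rate + gain * truth)); DMSO RT-stops are
#' Poisson(read_depth * background_rate). Two independent replicates per
#' library.
#'
#' @param transcript_id identifier for the simulated transcript.
#' @param truth_reactivity numeric vector in [0,1], one value per base.
#' @param cfg a [synth_config()] (read_depth, background_rate, gain, seed).
#' @return an [rtbd_counts()] object.
#' @export
simulate_rtbd <- function(transcript_id, truth_reactivity, cfg = synth_config()) {
  assert_that(all(truth_reactivity >= 0 & truth_reactivity <= 1), "config",
              "truth reactivity must lie in [0,1]")
  n <- length(truth_reactivity)
  d <- cfg$read_depth
  withr::with_seed(derive_seed(cfg$seed, 19L), {
    nai_rate <- d * (cfg$background_rate + cfg$gain * truth_reactivity)
    dmso_rate <- rep(d * cfg$background_rate, n)
    rtbd_counts(transcript_id,
                rt_dmso_rep1 = stats::rpois(n, dmso_rate),
                rt_dmso_rep2 = stats::rpois(n, dmso_rate),
                rt_nai_rep1 = stats::rpois(n, nai_rate),
                rt_nai_rep2 = stats::rpois(n, nai_rate),
                bd_dmso_rep1 = stats::rpois(n, rep(d, n)),
                bd_dmso_rep2 = stats::rpois(n, rep(d, n)))
  })
}
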