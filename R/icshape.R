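# icSHAPE reactivity scoring from raw replicate count tables.
#
# The in-vivo reactivity of a base is the background-subtracted enrichment of
# NAI RT-stop counts over the DMSO control, normalized by DMSO base density
# (sequencing coverage), rescaled per sliding window to [0,1]. Bases with
# merged DMSO coverage below `coverage_min` are reported as NULL (NA here).

#' Per-transcript RT-stop / base-density count container
#'
#' Holds the six per-base count vectors of one transcript: RT-stop counts for
#' two DMSO (mock) and two NAI (treated) replicates, and base-density
#' (coverage) counts for the two DMSO replicates.
#'
#' @param transcript_id single string identifier.
#' @param rt_dmso_rep1,rt_dmso_rep2 non-negative integer RT-stop counts, DMSO.
#' @param rt_nai_rep1,rt_nai_rep2 non-negative integer RT-stop counts, NAI.
#' @param bd_dmso_rep1,bd_dmso_rep2 non-negative integer base densities, DMSO.
#' @return an object of class `rtbd_counts`.
#' @export
rtbd_counts <- function(transcript_id,
                        rt_dmso_rep1, rt_dmso_rep2,
                        rt_nai_rep1, rt_nai_rep2,
                        bd_dmso_rep1, bd_dmso_rep2) {
  vecs <- list(rt_dmso_rep1 = rt_dmso_rep1, rt_dmso_rep2 = rt_dmso_rep2,
               rt_nai_rep1 = rt_nai_rep1, rt_nai_rep2 = rt_nai_rep2,
               bd_dmso_rep1 = bd_dmso_rep1, bd_dmso_rep2 = bd_dmso_rep2)
  n <- unique(vapply(vecs, length, 0L))
  assert_that(length(n) == 1L, "length_mismatch",
              "transcript '%s': count vectors have differing lengths (%s)",
              transcript_id, paste(vapply(vecs, length, 0L), collapse = ","))
  assert_that(all(unlist(vecs, use.names = FALSE) >= 0), "negative_counts",
              "transcript '%s': negative counts are not allowed", transcript_id)
  structure(c(list(transcript_id = transcript_id), vecs, list(length = n)),
            class = "rtbd_counts")
}

#' icSHAPE scoring configuration
#'
#' @param alpha background-subtraction factor for the DMSO RT signal.
#' @param window_size,window_step sliding-window size and step in bases; the
#'   window starts at the 5' end and slides toward 3'.
#' @param coverage_min minimum merged DMSO base density for a base to receive
#'   a numeric score (the 200x quality cutoff; the `>=` convention is used).
#' @param norm_lo,norm_hi ascending-rank fractions bounding the slice whose
#'   mean is the count normalization factor (the "previous 90% to 95%" rule).
#' @param scale_lo,scale_hi quantile fractions anchoring the final [0,1]
#'   rescaling of the enrichment signal.
#' @return a list of class `icshape_config`.
#' @export
icshape_config <- function(alpha = 0.25, window_size = 200L, window_step = 5L,
                           coverage_min = 200L, norm_lo = 0.90, norm_hi = 0.95,
                           scale_lo = 0.05, scale_hi = 0.95) {
  assert_that(alpha >= 0, "config", "alpha must be >= 0")
  assert_that(norm_lo > 0 && norm_lo < norm_hi && norm_hi <= 1, "config",
              "need 0 < norm_lo < norm_hi <= 1")
  assert_that(scale_lo >= 0 && scale_lo < scale_hi && scale_hi <= 1, "config",
              "need 0 <= scale_lo < scale_hi <= 1")
  assert_that(window_step <= window_size, "config",
              "window_step must be <= window_size")
  structure(list(alpha = alpha, window_size = as.integer(window_size),
                 window_step = as.integer(window_step),
                 coverage_min = coverage_min,
                 norm_lo = norm_lo, norm_hi = norm_hi,
                 scale_lo = scale_lo, scale_hi = scale_hi),
            class = "icshape_config")
}

#' Merge replicate libraries by direct addition
#'
#' @param counts an [rtbd_counts()] object.
#' @return list with per-base vectors `rt_dmso`, `rt_nai`, `bd_dmso`.
#' @export
combine_replicates <- function(counts) {
  stopifnot(inherits(counts, "rtbd_counts"))
  list(rt_dmso = counts$rt_dmso_rep1 + counts$rt_dmso_rep2,
       rt_nai  = counts$rt_nai_rep1 + counts$rt_nai_rep2,
       bd_dmso = counts$bd_dmso_rep1 + counts$bd_dmso_rep2)
}

#' Normalize a count vector by its upper-rank slice mean
#'
#' Divides every entry by the mean of the sorted (ascending) values whose
#' ranks fall in `(lo*n, hi*n]`, with slice boundaries rounded to the nearest
#' integer. The slice is guaranteed non-empty: if rounding collapses it, the
#' single rank `ceiling(hi*n)` is used.
#'
#' @param values non-empty numeric vector.
#' @param lo,hi rank fractions, `0 < lo < hi <= 1`.
#' @return list with `values` (normalized) and `factor` (the divisor).
#' @export
normalize_counts <- function(values, lo = 0.90, hi = 0.95) {
  assert_that(length(values) > 0, "empty_input", "cannot normalize empty vector")
  assert_that(lo > 0 && lo < hi && hi <= 1, "config", "need 0 < lo < hi <= 1")
  n <- length(values)
  s <- sort(values)
  i_lo <- round(lo * n)
  i_hi <- round(hi * n)
  ranks <- if (i_hi > i_lo) seq.int(i_lo + 1L, i_hi) else min(ceiling(hi * n), n)
  fac <- mean(s[ranks])
  if (!is.finite(fac) || fac <= 0) {
    bn_stop("normalization_factor",
            "normalization factor %.3g is not positive; skip this window", fac)
  }
  list(values = values / fac, factor = fac)
}

#' Per-base enrichment signal
#'
#' `e_i = (rt_nai_i - alpha * rt_dmso_i) / bd_dmso_i`; bases with zero
#' denominator are undefined (NA), not an error.
#'
#' @param rt_nai,rt_dmso,bd_dmso equal-length numeric vectors (normalized).
#' @param alpha background-subtraction factor, `>= 0`.
#' @return numeric vector with NA where `bd_dmso == 0`.
#' @export
enrichment <- function(rt_nai, rt_dmso, bd_dmso, alpha = 0.25) {
  assert_that(length(rt_nai) == length(rt_dmso) &&
              length(rt_nai) == length(bd_dmso), "length_mismatch",
              "enrichment inputs must share one length")
  assert_that(alpha >= 0, "config", "alpha must be >= 0")
  e <- (rt_nai - alpha * rt_dmso) / bd_dmso
  e[bd_dmso == 0] <- NA_real_
  e
}

#' Rescale an enrichment profile to reactivity scores in [0,1]
#'
#' Anchors are the `scale_lo`/`scale_hi` quantiles of the defined enrichment
#' entries; scores are clamped to [0,1]. Bases whose *raw merged* DMSO base
#' density is below `coverage_min`, or whose enrichment is undefined, are NULL
#' (NA).
#'
#' @param e enrichment vector (NA = undefined).
#' @param bd_dmso_raw raw merged (replicate-summed) DMSO base densities.
#' @param cfg an [icshape_config()].
#' @return numeric reactivity vector in [0,1] with NA for NULL.
#' @export
rescale_scores <- function(e, bd_dmso_raw, cfg = icshape_config()) {
  ok <- is.finite(e)
  if (!any(ok)) {
    bn_warn("all_undefined", "all enrichment entries undefined; profile is all NULL")
    return(rep(NA_real_, length(e)))
  }
  q <- stats::quantile(e[ok], c(cfg$scale_lo, cfg$scale_hi), names = FALSE, type = 7)
  denom <- q[2] - q[1]
  out <- if (denom > 0) pmin(1, pmax(0, (e - q[1]) / denom)) else ifelse(ok, 0, NA_real_)
  out[!ok] <- NA_real_
  out[bd_dmso_raw < cfg$coverage_min] <- NA_real_
  out
}

# one window of the scoring pipeline; returns scores or an all-NA vector when
# a normalization factor is degenerate (window skipped)
score_window <- function(m, idx, cfg) {
  res <- tryCatch({
    rC <- normalize_counts(m$rt_dmso[idx], cfg$norm_lo, cfg$norm_hi)$values
    rT <- normalize_counts(m$rt_nai[idx],  cfg$norm_lo, cfg$norm_hi)$values
    bC <- normalize_counts(m$bd_dmso[idx], cfg$norm_lo, cfg$norm_hi)$values
    e <- enrichment(rT, rC, bC, cfg$alpha)
    withCallingHandlers(
      rescale_scores(e, m$bd_dmso[idx], cfg),
      bindnet_all_undefined = function(w) invokeRestart("muffleWarning")
    )
  }, bindnet_normalization_factor = function(cond) rep(NA_real_, length(idx)))
  res
}

#' Score one transcript: the full sliding-window icSHAPE pipeline
#'
#' Replicates are merged, then a window of `window_size` bases slides 5'->3'
#' by `window_step`; each window is normalized, background-subtracted and
#' rescaled independently. A base covered by several windows takes the mean
#' of its per-window scores (NA only if every covering window says NA).
#' Transcripts shorter than the window are processed as one window.
#'
#' @param counts an [rtbd_counts()] object.
#' @param cfg an [icshape_config()].
#' @return numeric reactivity vector (length = transcript length, NA = NULL)
#'   with attribute `transcript_id`.
#' @export
score_transcript <- function(counts, cfg = icshape_config()) {
  m <- combine_replicates(counts)
  n <- counts$length
  w <- min(cfg$window_size, n)
  starts <- seq.int(1L, max(1L, n - w + 1L), by = cfg$window_step)
  if (starts[length(starts)] + w - 1L < n) starts <- c(starts, n - w + 1L)

  acc <- numeric(n)
  cnt <- integer(n)
  for (s in starts) {
    idx <- s:(s + w - 1L)
    sc <- tryCatch(score_window(m, idx, cfg), bindnet_error = function(cond) {
      bn_stop("window", "window [%d,%d] of transcript '%s': %s",
              s, s + w - 1L, counts$transcript_id, conditionMessage(cond))
    })
    def <- !is.na(sc)
    acc[idx[def]] <- acc[idx[def]] + sc[def]
    cnt[idx[def]] <- cnt[idx[def]] + 1L
  }
  out <- ifelse(cnt > 0L, acc / pmax(cnt, 1L), NA_real_)
  attr(out, "transcript_id") <- counts$transcript_id
  out
}

#' Read a raw count table (TSV) into `rtbd_counts` objects
#'
#' Expected columns: `transcript_id`, `position` (1-based),
#' `rt_dmso_1`, `rt_dmso_2`, `rt_nai_1`, `rt_nai_2`, `bd_dmso_1`, `bd_dmso_2`.
#'
#' @param path TSV file (plain or gzip).
#' @return named list of [rtbd_counts()] objects, one per transcript.
#' @export
read_rtbd_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("transcript_id", "position", "rt_dmso_1", "rt_dmso_2",
            "rt_nai_1", "rt_nai_2", "bd_dmso_1", "bd_dmso_2")
  assert_that(all(need %in% names(df)), "tsv_columns",
              "counts TSV must have columns: %s", paste(need, collapse = ", "))
  out <- lapply(split(df, df$transcript_id), function(d) {
    d <- d[order(d$position), ]
    assert_that(identical(d$position, seq_len(nrow(d))), "positions",
                "transcript '%s': positions must be 1..n without gaps",
                d$transcript_id[1])
    rtbd_counts(d$transcript_id[1],
                d$rt_dmso_1, d$rt_dmso_2, d$rt_nai_1, d$rt_nai_2,
                d$bd_dmso_1, d$bd_dmso_2)
  })
  out[unique(df$transcript_id)]
}

#' Write reactivity profiles as TSV (literal "NULL" for missing scores)
#'
#' @param profiles named list of reactivity vectors (names = transcript ids).
#' @param path output file.
#' @export
write_reactivity_tsv <- function(profiles, path) {
  rows <- lapply(names(profiles), function(id) {
    p <- profiles[[id]]
    data.frame(transcript_id = id, position = seq_along(p),
               score = ifelse(is.na(p), "NULL", formatC(p, digits = 6, format = "g")),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
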