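# Interpretation: attention-based motif calling, PWM construction,
# token-to-nucleotide saliency spreading, and native gradient attribution.

#' Call high-attention motifs from a token attention vector
#'
#' A token qualifies when (1) its attention score strictly exceeds the
#' sequence mean and (2) it is at least 10x the floor score. Maximal runs of
#' qualifying tokens become candidate fragments; a token run `[a, b]` spans
#' nucleotides `[a, b + k - 1]`; fragments shorter than 6 nt are discarded.
#'
#' The floor is `max(min(att), 1e-8 * max(att))`: with a raw minimum of 0
#' the printed "10 times the lowest score" rule would be vacuous.
#'
#' @param att numeric attention scores over interior tokens.
#' @param sample one-record `fixed_samples` (provides the sequence).
#' @param k k-mer size used for tokenization.
#' @param min_len minimum fragment length in nt (6).
#' @return data.frame of class `motif_hits`: token_start, token_end,
#'   nt_start, nt_end (1-based inclusive), fragment, mean_score; sorted and
#'   disjoint.
#' @export
call_motifs <- function(att, sample, k = 3L, min_len = 6L) {
  assert_that(length(sample) == 1L, "shape", "call_motifs takes one sample")
  nt <- nchar(sample$sequence) - k + 1L
  assert_that(length(att) == nt, "shape",
              "attention length %d != token count %d", length(att), nt)
  floor_score <- max(min(att), 1e-8 * max(att))
  ok <- (att > mean(att)) & (att >= 10 * floor_score)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  hits <- lapply(keep, function(i) {
    a <- starts[i]; b <- ends[i]
    nt_start <- a; nt_end <- b + k - 1L
    if (nt_end - nt_start + 1L < min_len) return(NULL)
    data.frame(token_start = a, token_end = b,
               nt_start = nt_start, nt_end = nt_end,
               fragment = substr(sample$sequence, nt_start, nt_end),
               mean_score = mean(att[a:b]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), hits)) %||%
    data.frame(token_start = integer(0), token_end = integer(0),
               nt_start = integer(0), nt_end = integer(0),
               fragment = character(0), mean_score = numeric(0))
  class(out) <- c("motif_hits", "data.frame")
  out
}

#' Build a position weight matrix from aligned fragments
#'
#' Fragments are reduced to the modal length (ties resolved toward the
#' shorter length) by trimming both ends symmetrically; fragments shorter
#' than the modal length are dropped. Per-position base counts (plus an
#' optional pseudocount) are normalized to probabilities.
#'
#' @param fragments character vector of RNA fragments.
#' @param pseudocount added to every cell before normalization (0).
#' @return 4 x width probability matrix (rows A, C, G, U), class `pwm`.
#' @export
build_pwm <- function(fragments, pseudocount = 0) {
  assert_that(length(fragments) >= 1L, "empty_input", "no fragments given")
  fragments <- as_rna(fragments, "fragment")
  lens <- nchar(fragments)
  tab <- table(lens)
  modal <- as.integer(names(tab)[tab == max(tab)])[1L]
  keep <- fragments[lens >= modal]
  trimmed <- vapply(keep, function(f) {
    extra <- nchar(f) - modal
    lo <- extra %/% 2L
    substr(f, lo + 1L, lo + modal)
  }, "", USE.NAMES = FALSE)
  mat <- matrix(0, 4L, modal, dimnames = list(RNA_BASES, NULL))
  chars <- do.call(rbind, strsplit(trimmed, ""))
  for (j in seq_len(modal)) {
    cnt <- table(factor(chars[, j], levels = RNA_BASES))
    mat[, j] <- as.numeric(cnt)
  }
  mat <- mat + pseudocount
  mat <- sweep(mat, 2L, colSums(mat), "/")
  structure(mat, class = c("pwm", "matrix"))
}

#' Spread a 99-long token attention vector over 101 nucleotides
#'
#' The five-case per-nucleotide rule (1-based `i` in `[1, 101]`):
#' `Att_1` at i = 1; `(Att_1 + Att_2)/2` at i = 2;
#' `(Att_99 + Att_98)/2` at i = 100; `Att_99` at i = 101 (the printed
#' `Att_{i-1}` index is clamped to the last existing token); otherwise
#' `(Att_i + Att_{i-1} + Att_{i-2})/3`.
#'
#' @param att numeric vector of length exactly 99 (k = 3 over 101 nt).
#' @return numeric saliency vector of length 101.
#' @export
spread_attention <- function(att) {
  assert_that(length(att) == 99L, "shape",
              "expected attention length 99, got %d", length(att))
  out <- numeric(101L)
  out[1L] <- att[1L]
  out[2L] <- (att[1L] + att[2L]) / 2
  mid <- 3:99
  out[mid] <- (att[mid] + att[mid - 1L] + att[mid - 2L]) / 3
  out[100L] <- (att[99L] + att[98L]) / 2
  out[101L] <- att[99L]
  out
}

#' Expected-gradients attribution for a differentiable scorer
#'
#' Averages `(x - b) * grad f(b + a (x - b))` over seeded baselines `b` with
#' interpolation coefficients `a ~ U(0,1)` — a native reimplementation of
#' gradient-explainer-style attribution.
#'
#' @param f_grad function taking an input array and returning
#'   `list(value, grad)` with `grad` the gradient of the scalar output.
#' @param x input array.
#' @param baselines list of baseline arrays shaped like `x`.
#' @param seed integer seed for the interpolation coefficients.
#' @return attribution array shaped like `x`.
#' @export
expected_gradients <- function(f_grad, x, baselines, seed = 1L) {
  assert_that(length(baselines) >= 1L, "config", "need at least one baseline")
  withr::with_seed(derive_seed(seed, 43L), {
    alphas <- stats::runif(length(baselines))
  })
  acc <- x * 0  # same shape/class as the input
  for (i in seq_along(baselines)) {
    b <- baselines[[i]]
    g <- f_grad(b + alphas[i] * (x - b))$grad
    acc <- acc + (x - b) * g
  }
  acc / length(baselines)
}

#' Gradient saliency of a prediction w.r.t. its input features
#'
#' Attribution of the output logit with respect to the sequence embedding
#' matrix and the structure vector, expected-gradients averaged over
#' shuffled-sequence baselines, then reduced per token by the maximum over
#' feature dimensions.
#'
#' @param model a `bindnet`.
#' @param sample one-record `fixed_samples`.
#' @param n_baselines number of shuffled baselines (16).
#' @param seed integer seed.
#' @return list with `seq` and `struct`: per-token attribution vectors.
#' @export
gradient_saliency <- function(model, sample, n_baselines = 16L, seed = 1L) {
  assert_that(length(sample) == 1L, "shape", "gradient_saliency takes one sample")
  inp <- prepare_inputs(model, sample)
  struct_tok <- inp$struct_tok
  L <- ncol(struct_tok)
  # the attribution surface is the CNN stage as a function of the embedding
  # matrix and the per-token structure; the encoder provides the points
  embed_of <- function(ids_m) {
    fw <- encoder_fwd(model$params$enc, model$cfg$encoder, ids_m)
    fw$H[interior_rows(1L, ncol(ids_m)), , drop = FALSE]
  }
  grad_at <- function(X, S) {
    fw <- bindnet_fwd(model, NULL, S, train = FALSE, grad = TRUE, seq_emb = X)
    bw <- bindnet_bwd(model, fw, matrix(1, 1L, 1L))
    list(value = fw$logit[1L], seq = bw$d_seq_emb, struct = bw$d_struct)
  }
  withr::with_seed(derive_seed(seed, 47L), {
    shuffled <- lapply(seq_len(n_baselines), function(i) {
      s <- paste(sample(strsplit(sample$sequence, "")[[1L]]), collapse = "")
      tk <- tokenize(s, model$cfg$encoder$k)
      matrix(tokens_to_ids(tk$tokens, model$vocab), nrow = 1L)
    })
    alphas <- stats::runif(n_baselines)
  })
  X_ref <- embed_of(inp$ids)
  S_base <- matrix(-1, 1L, L)  # missing-structure sentinel baseline
  acc_seq <- matrix(0, nrow(X_ref), ncol(X_ref))
  acc_struct <- matrix(0, 1L, L)
  for (i in seq_len(n_baselines)) {
    X_b <- embed_of(shuffled[[i]])
    a <- alphas[i]
    g <- grad_at(X_b + a * (X_ref - X_b),
                 S_base + a * (struct_tok - S_base))
    acc_seq <- acc_seq + (X_ref - X_b) * g$seq
    acc_struct <- acc_struct + (struct_tok - S_base) * g$struct
  }
  sal_seq <- apply(acc_seq / n_baselines, 1L, max)
  sal_struct <- as.vector(acc_struct / n_baselines)
  list(seq = sal_seq, struct = sal_struct,
       att = pmax(sal_seq, sal_struct))
}

#' Per-token attention vector of a trained model for motif calling
#'
#' Two sources are available. `"gradient"` (the default) is the
#' visualization-style attention: expected-gradients attribution over the
#' full model input, reduced per token by the maximum over all feature
#' dimensions (embedding dimensions and the structure channel). `"encoder"`
#' is the CLS-row self-attention score summed over heads
#' ([cls_attention_scores()]); note that without large-scale pretraining the
#' encoder's CLS attention is only weakly localized, which is why the
#' gradient source is the default.
#'
#' High-attention segments are located with a sliding window: the gradient
#' attention vector is aggregated by a centered moving average of `smooth`
#' tokens (edge-replicated) before it is scanned for qualifying runs, so a
#' sharp attribution peak still yields a contiguous fragment. `smooth = 1`
#' disables the aggregation.
#'
#' @param model a trained `bindnet`.
#' @param sample one-record `fixed_samples`.
#' @param source "gradient" or "encoder".
#' @param smooth sliding-window width in tokens for the gradient source
#'   (odd; default 5).
#' @param ... passed to [gradient_saliency()] or [cls_attention_scores()].
#' @return numeric vector, one score per interior token.
#' @export
attention_vector <- function(model, sample,
                             source = c("gradient", "encoder"),
                             smooth = 5L, ...) {
  source <- match.arg(source)
  if (source == "gradient") {
    sliding_mean(gradient_saliency(model, sample, ...)$att, smooth)
  } else {
    enc <- encoder_view(model)
    cls_attention_scores(tokenize(sample$sequence, model$cfg$encoder$k),
                         enc, ...)
  }
}

# centered moving average with edge replication; w = 1 is the identity
sliding_mean <- function(x, w) {
  w <- as.integer(w)
  assert_that(w >= 1L && w %% 2L == 1L, "config", "smooth width must be odd")
  if (w == 1L) return(x)
  h <- (w - 1L) %/% 2L
  xp <- c(rep(x[1L], h), x, rep(x[length(x)], h))
  as.vector(stats::filter(xp, rep(1 / w, w), sides = 2L))[h + seq_along(x)]
}

# lightweight attention_encoder view over a model's encoder parameters
encoder_view <- function(model) {
  enc <- new.env(parent = emptyenv())
  enc$params <- model$params$enc
  enc$config <- model$cfg$encoder
  enc$vocab <- model$vocab
  class(enc) <- "attention_encoder"
  enc
}

#' Write PWMs in MEME minimal motif format
#'
#' @param pwms named list of `pwm` matrices.
#' @param path output file.
#' @param background background letter frequencies (uniform).
#' @export
write_meme <- function(pwms, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGU", "",
               "strands: +", "",
               "Background letter frequencies",
               paste(sprintf("%s %.3f", RNA_BASES, background),
                     collapse = " "), ""), con)
  for (nm in names(pwms)) {
    m <- pwms[[nm]]
    writeLines(c(sprintf("MOTIF %s", nm),
                 sprintf("letter-probability matrix: alength= 4 w= %d nsites= 1 E= 0",
                         ncol(m))), con)
    for (j in seq_len(ncol(m))) {
      writeLines(paste(sprintf("%.6f", m[, j]), collapse = "  "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Write motif hits as a BED-like TSV
#'
#' Columns: sample id, nt_start, nt_end (1-based inclusive), mean_score,
#' fragment.
#'
#' @param hits named list of `motif_hits` (names = sample ids).
#' @param path output TSV.
#' @export
write_motif_hits <- function(hits, path) {
  rows <- lapply(names(hits), function(id) {
    h <- hits[[id]]
    if (nrow(h) == 0L) return(NULL)
    data.frame(sample_id = id, nt_start = h$nt_start, nt_end = h$nt_end,
               mean_score = h$mean_score, fragment = h$fragment,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows)) %||%
    data.frame(sample_id = character(0), nt_start = integer(0),
               nt_end = integer(0), mean_score = numeric(0),
               fragment = character(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
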