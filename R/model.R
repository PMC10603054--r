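# The binding-prediction network.
#
# Pipeline: per-token sequence embeddings (d_model x L) and the aligned
# structure vector (1 x L) are brought to a common width by the unified
# alignment stage (Conv-BN-ReLU, kernel 1 for sequence, kernel 3 for
# structure); each stream passes through a hierarchical multi-scale residual
# network (4 parallel branches with kernels 1/3/5/7 stacked 1/2/3/4 deep,
# concatenated and added back to the input); the two streams are fused
# (concatenation by default) and reduced to a single feature vector by a
# pyramid of residual conv pairs with max-pooling (size 3, stride 2) that
# halves the length until it reaches 1; a one-unit dense layer with sigmoid
# yields the binding probability.

#' Model configuration
#'
#' Defaults are the full-size architecture; `preset = "small"` gives the
#' desk-scale variant (encoder 2 x 64, CNN widths scaled by the same factor)
#' used for joint training in tests.
#'
#' @param preset "full" or "small".
#' @param encoder an [encoder_config()].
#' @param align_channels channels after unified alignment (128).
#' @param branch_channels channels per multi-scale branch (32; the four
#'   branches concatenate back to `align_channels`).
#' @param hmrn_kernels,hmrn_depths kernel size and stacked depth per branch.
#' @param pyramid_channels channels in the pyramid predictor (256; equals
#'   `2 * align_channels` under concatenation fusion).
#' @param pyramid_kernel pyramid conv kernel size (5).
#' @param seq_kernel,struct_kernel alignment kernel sizes (1 and 3).
#' @param dropout dropout rate after each conv-block activation (0.3).
#' @param bn_momentum,bn_eps batch-norm running-estimate momentum and epsilon.
#' @param sample_len input sample length in nt (101).
#' @param fusion "concat" (default) or "add" for merging the two streams.
#' @return list of class `bindnet_config`.
#' @export
bindnet_config <- function(preset = c("full", "small"), encoder = NULL,
                           align_channels = NULL, branch_channels = NULL,
                           hmrn_kernels = c(1L, 3L, 5L, 7L),
                           hmrn_depths = c(1L, 2L, 3L, 4L),
                           pyramid_channels = NULL, pyramid_kernel = 5L,
                           seq_kernel = 1L, struct_kernel = 3L,
                           dropout = 0.3, bn_momentum = 0.1, bn_eps = 1e-5,
                           sample_len = 101L,
                           fusion = c("concat", "add")) {
  preset <- match.arg(preset)
  fusion <- match.arg(fusion)
  if (preset == "small") {
    encoder <- encoder %||% encoder_config_small()
    align_channels <- align_channels %||% 32L
    branch_channels <- branch_channels %||% 8L
  } else {
    encoder <- encoder %||% encoder_config()
    align_channels <- align_channels %||% 128L
    branch_channels <- branch_channels %||% 32L
  }
  pyramid_channels <- pyramid_channels %||%
    (if (fusion == "concat") 2L * align_channels else align_channels)
  assert_that(length(hmrn_kernels) == length(hmrn_depths), "config",
              "hmrn_kernels and hmrn_depths must have equal length")
  assert_that(all(hmrn_kernels %% 2L == 1L) && pyramid_kernel %% 2L == 1L &&
              seq_kernel %% 2L == 1L && struct_kernel %% 2L == 1L, "config",
              "all kernels must be odd")
  assert_that(align_channels == length(hmrn_kernels) * branch_channels,
              "config",
              "align_channels (%d) must equal n_branches x branch_channels (%d x %d)",
              align_channels, length(hmrn_kernels), branch_channels)
  expected <- if (fusion == "concat") 2L * align_channels else align_channels
  assert_that(pyramid_channels == expected, "config",
              "pyramid_channels must be %d under %s fusion", expected, fusion)
  structure(list(preset = preset, encoder = encoder,
                 align_channels = as.integer(align_channels),
                 branch_channels = as.integer(branch_channels),
                 hmrn_kernels = as.integer(hmrn_kernels),
                 hmrn_depths = as.integer(hmrn_depths),
                 pyramid_channels = as.integer(pyramid_channels),
                 pyramid_kernel = as.integer(pyramid_kernel),
                 seq_kernel = as.integer(seq_kernel),
                 struct_kernel = as.integer(struct_kernel),
                 dropout = dropout, bn_momentum = bn_momentum, bn_eps = bn_eps,
                 sample_len = as.integer(sample_len), fusion = fusion),
            class = "bindnet_config")
}

cnn_block_init <- function(c_in, c_out, k) {
  c(conv1d_init(c_in, c_out, k), list(bn = batchnorm_init(c_out)))
}

#' One Conv-BN-ReLU block
#'
#' 1-D convolution (no bias, symmetric padding so length is preserved),
#' batch normalization (momentum-tracked running estimates used in
#' evaluation), ReLU, then dropout in training mode.
#' @noRd
cnn_block_fwd <- function(p, X, B, L, k, st, key, train, dropout = 0,
                          momentum = 0.1, eps = 1e-5) {
  cv <- conv1d_fwd(p, X, B, L, k)
  bn <- batchnorm_fwd(p$bn, cv$out, st, key, train, momentum, eps)
  rl <- relu_fwd(bn$out)
  dp <- dropout_fwd(rl$out, dropout, train)
  list(out = dp$out,
       cache = list(cv = cv$cache, bn = bn$cache, rmask = rl$cache,
                    dmask = dp$cache))
}

cnn_block_bwd <- function(p, dY, cache) {
  d1 <- dropout_bwd(dY, cache$dmask)
  d2 <- relu_bwd(d1, cache$rmask)
  bn <- batchnorm_bwd(p$bn, d2, cache$bn)
  cv <- conv1d_bwd(p, bn$dx, cache$cv)
  list(dx = cv$dx, grads = list(W = cv$grads$W, bn = bn$grads))
}

msr_init <- function(channels, cfg) {
  branches <- lapply(seq_along(cfg$hmrn_kernels), function(j) {
    blocks <- lapply(seq_len(cfg$hmrn_depths[j]), function(i) {
      cnn_block_init(if (i == 1L) channels else cfg$branch_channels,
                     cfg$branch_channels, cfg$hmrn_kernels[j])
    })
    names(blocks) <- paste0("blk", seq_along(blocks))
    blocks
  })
  names(branches) <- paste0("br", seq_along(branches))
  branches
}

# hierarchical multi-scale residual stage: branch j applies its stacked
# blocks, outputs concatenate to the input width, residual add, ReLU
msr_fwd <- function(p, X, B, L, cfg, st, keybase, train) {
  branch_caches <- vector("list", length(p))
  outs <- vector("list", length(p))
  for (j in seq_along(p)) {
    y <- X
    bc <- vector("list", length(p[[j]]))
    for (i in seq_along(p[[j]])) {
      blk <- cnn_block_fwd(p[[j]][[i]], y, B, L, cfg$hmrn_kernels[j], st,
                           sprintf("%s.br%d.blk%d", keybase, j, i), train,
                           cfg$dropout, cfg$bn_momentum, cfg$bn_eps)
      bc[[i]] <- blk$cache
      y <- blk$out
    }
    outs[[j]] <- y
    branch_caches[[j]] <- bc
  }
  M <- do.call(cbind, outs)
  rl <- relu_fwd(X + M)
  list(out = rl$out,
       cache = list(branch = branch_caches, rmask = rl$cache))
}

msr_bwd <- function(p, dY, cache, cfg) {
  dZ <- relu_bwd(dY, cache$rmask)
  dX <- dZ  # residual path
  grads <- vector("list", length(p))
  bc <- cfg$branch_channels
  for (j in seq_along(p)) {
    cols <- (j - 1L) * bc + seq_len(bc)
    d <- dZ[, cols, drop = FALSE]
    gb <- vector("list", length(p[[j]]))
    for (i in rev(seq_along(p[[j]]))) {
      bk <- cnn_block_bwd(p[[j]][[i]], d, cache$branch[[j]][[i]])
      gb[[i]] <- bk$grads
      d <- bk$dx
    }
    names(gb) <- paste0("blk", seq_along(gb))
    grads[[j]] <- gb
    dX <- dX + d
  }
  names(grads) <- paste0("br", seq_along(grads))
  list(dx = dX, grads = grads)
}

#' Create a binding-prediction model
#'
#' Builds the encoder and all convolutional stages with Kaiming-initialized
#' weights; pyramid stages are allocated from the pooling-length schedule of
#' the configured sample length.
#'
#' @param config a [bindnet_config()].
#' @param seed integer seed.
#' @return object of class `bindnet` (an environment with `params`, `cfg`,
#'   `bn` running-statistics store, `vocab`).
#' @export
new_bindnet <- function(config = bindnet_config("small"), seed = 1L) {
  cfg <- config
  enc <- new_encoder(cfg$encoder, seed = derive_seed(seed, 37L))
  L0 <- cfg$sample_len - cfg$encoder$k + 1L
  sched <- pyramid_length_schedule(L0)
  n_stages <- length(sched) - 1L
  P <- cfg$pyramid_channels
  withr::with_seed(derive_seed(seed, 41L), {
    stages <- lapply(seq_len(max(n_stages, 1L)), function(i) {
      list(c1 = cnn_block_init(P, P, cfg$pyramid_kernel),
           c2 = cnn_block_init(P, P, cfg$pyramid_kernel))
    })
    names(stages) <- paste0("stage", seq_along(stages))
    params <- list(
      enc = enc$params,
      align_seq = cnn_block_init(cfg$encoder$d_model, cfg$align_channels,
                                 cfg$seq_kernel),
      align_str = cnn_block_init(1L, cfg$align_channels, cfg$struct_kernel),
      msr_seq = msr_init(cfg$align_channels, cfg),
      msr_str = msr_init(cfg$align_channels, cfg),
      head = linear_init(P, 1L))
    params$pyramid <- stages
  })
  m <- new.env(parent = emptyenv())
  m$params <- params
  m$cfg <- cfg
  m$vocab <- enc$vocab
  m$bn <- new.env(parent = emptyenv())
  m$schedule <- sched
  class(m) <- "bindnet"
  m
}

#' @export
print.bindnet <- function(x, ...) {
  cat(sprintf(paste0("<bindnet> %s preset: encoder %d x %d (heads %d), align %d,",
                     " pyramid %d x %d stages, %s fusion, %.2fM parameters\n"),
              x$cfg$preset, x$cfg$encoder$n_layers, x$cfg$encoder$d_model,
              x$cfg$encoder$n_heads, x$cfg$align_channels,
              x$cfg$pyramid_channels, length(x$schedule) - 1L, x$cfg$fusion,
              n_params(x$params) / 1e6))
  invisible(x)
}

# interior-row index of a (B x T) token layout: drops [CLS]/[SEP] positions
interior_rows <- function(B, T) {
  as.vector(vapply(seq_len(B), function(b) (b - 1L) * T + 2:(T - 1L),
                   integer(T - 2L)))
}

#' Forward pass of the full network (internal workhorse)
#'
#' @param model a `bindnet`.
#' @param ids integer id matrix (B x T, with specials).
#' @param struct_tok numeric structure matrix (B x L interior tokens,
#'   sentinel -1 for missing).
#' @param train training mode (batch stats, dropout on).
#' @param grad keep caches for backprop.
#' @param capture_attention encoder layer indices whose attention to keep.
#' @return list with `p`, `logit`, and caches when `grad`.
#' @noRd
bindnet_fwd <- function(model, ids, struct_tok, train = FALSE, grad = FALSE,
                        capture_attention = integer(0), seq_emb = NULL) {
  cfg <- model$cfg
  if (is.null(ids)) {
    # embedding override: B/L inferred from the structure matrix
    B <- nrow(struct_tok); L <- ncol(struct_tok); T <- L + 2L
  } else {
    B <- nrow(ids); T <- ncol(ids); L <- T - 2L
  }
  assert_that(ncol(struct_tok) == L && nrow(struct_tok) == B, "shape",
              "structure matrix must be %d x %d", B, L)
  assert_that(all(is.finite(struct_tok)), "nonfinite",
              "structure input must be finite (use -1 for missing)")
  if (is.null(seq_emb)) {
    enc_grad <- grad && !cfg$encoder$freeze
    fw <- encoder_fwd(model$params$enc, cfg$encoder, ids, grad = enc_grad,
                      capture_attention = capture_attention)
    idx <- interior_rows(B, T)
    Xs <- fw$H[idx, , drop = FALSE]
  } else {
    assert_that(nrow(seq_emb) == B * L && ncol(seq_emb) == cfg$encoder$d_model,
                "shape", "seq_emb must be (B*L) x d_model")
    fw <- list(caches = NULL, attn = list())
    idx <- NULL
    Xs <- seq_emb
  }
  Ss <- matrix(as.vector(t(struct_tok)), ncol = 1L)
  st <- model$bn
  a_seq <- cnn_block_fwd(model$params$align_seq, Xs, B, L, cfg$seq_kernel,
                         st, "align_seq", train, cfg$dropout,
                         cfg$bn_momentum, cfg$bn_eps)
  a_str <- cnn_block_fwd(model$params$align_str, Ss, B, L, cfg$struct_kernel,
                         st, "align_str", train, cfg$dropout,
                         cfg$bn_momentum, cfg$bn_eps)
  m_seq <- msr_fwd(model$params$msr_seq, a_seq$out, B, L, cfg, st, "msr_seq",
                   train)
  m_str <- msr_fwd(model$params$msr_str, a_str$out, B, L, cfg, st, "msr_str",
                   train)
  Z <- if (cfg$fusion == "concat") cbind(m_seq$out, m_str$out)
       else m_seq$out + m_str$out
  # pyramid reduction to length 1
  pyr_caches <- list()
  x <- Z
  Lc <- L
  si <- 0L
  n_alloc <- length(model$params$pyramid)
  while (Lc > 1L) {
    si <- si + 1L
    sp <- model$params$pyramid[[min(si, n_alloc)]]
    b2 <- cnn_block_fwd(sp$c2, x, B, Lc, cfg$pyramid_kernel, st,
                        sprintf("pyr%d.c2", min(si, n_alloc)), train,
                        cfg$dropout, cfg$bn_momentum, cfg$bn_eps)
    b1 <- cnn_block_fwd(sp$c1, b2$out, B, Lc, cfg$pyramid_kernel, st,
                        sprintf("pyr%d.c1", min(si, n_alloc)), train,
                        cfg$dropout, cfg$bn_momentum, cfg$bn_eps)
    rl <- relu_fwd(x + b1$out)
    pl <- maxpool_fwd(rl$out, B, Lc)
    pyr_caches[[si]] <- list(c2 = b2$cache, c1 = b1$cache, rmask = rl$cache,
                             pool = pl$cache, L = Lc)
    x <- pl$out
    Lc <- pool_out_len(Lc)
  }
  h <- x  # (B*1) x P
  hd <- linear_fwd(model$params$head, h)
  logit <- hd$out
  p <- sigmoid(as.vector(logit))
  assert_that(all(is.finite(p)), "nonfinite", "non-finite prediction")
  res <- list(p = p, logit = logit, B = B, T = T, L = L, attn = fw$attn)
  if (grad) {
    res$caches <- list(enc = fw, idx = idx, a_seq = a_seq$cache,
                       a_str = a_str$cache, m_seq = m_seq$cache,
                       m_str = m_str$cache, pyr = pyr_caches,
                       head = hd$cache, n_stages_used = si)
  }
  res
}

# backward from d_logit; returns parameter gradients mirroring model$params
# plus gradients w.r.t. the CNN-stage inputs (sequence embedding matrix and
# per-token structure) for attribution.
bindnet_bwd <- function(model, fwres, d_logit) {
  cfg <- model$cfg
  cc <- fwres$caches
  B <- fwres$B; T <- fwres$T; L <- fwres$L
  hd <- linear_bwd(model$params$head, d_logit, cc$head)
  grads <- list(head = hd$grads)
  dx <- hd$dx
  # pyramid, reversed
  n_alloc <- length(model$params$pyramid)
  pyr_grads <- lapply(seq_len(n_alloc), function(i)
    list(c1 = NULL, c2 = NULL))
  for (si in rev(seq_len(cc$n_stages_used))) {
    pc <- cc$pyr[[si]]
    sp <- model$params$pyramid[[min(si, n_alloc)]]
    d <- maxpool_bwd(dx, pc$pool)
    d <- relu_bwd(d, pc$rmask)
    b1 <- cnn_block_bwd(sp$c1, d, pc$c1)
    b2 <- cnn_block_bwd(sp$c2, b1$dx, pc$c2)
    slot <- min(si, n_alloc)
    add_g <- function(a, b) if (is.null(a)) b else tree_map2(`+`, a, b)
    pyr_grads[[slot]]$c1 <- add_g(pyr_grads[[slot]]$c1, b1$grads)
    pyr_grads[[slot]]$c2 <- add_g(pyr_grads[[slot]]$c2, b2$grads)
    dx <- d + b2$dx  # residual
  }
  names(pyr_grads) <- paste0("stage", seq_along(pyr_grads))
  grads$pyramid <- pyr_grads
  # fusion split
  A <- cfg$align_channels
  if (cfg$fusion == "concat") {
    d_seq <- dx[, seq_len(A), drop = FALSE]
    d_str <- dx[, A + seq_len(A), drop = FALSE]
  } else {
    d_seq <- dx
    d_str <- dx
  }
  ms <- msr_bwd(model$params$msr_seq, d_seq, cc$m_seq, cfg)
  mt <- msr_bwd(model$params$msr_str, d_str, cc$m_str, cfg)
  grads$msr_seq <- ms$grads
  grads$msr_str <- mt$grads
  as_ <- cnn_block_bwd(model$params$align_seq, ms$dx, cc$a_seq)
  at_ <- cnn_block_bwd(model$params$align_str, mt$dx, cc$a_str)
  grads$align_seq <- as_$grads
  grads$align_str <- at_$grads
  dXs <- as_$dx                                  # (B*L) x d_model
  dSs <- at_$dx                                  # (B*L) x 1
  if (cfg$encoder$freeze || is.null(cc$enc$caches)) {
    grads$enc <- tree_map(function(p) array(0, dim = dim(p) %||% length(p)),
                          model$params$enc)
  } else {
    dH <- matrix(0, B * T, cfg$encoder$d_model)
    dH[cc$idx, ] <- dXs
    grads$enc <- encoder_bwd(model$params$enc, cfg$encoder, cc$enc, dH)
  }
  # reorder to match params ordering
  grads <- grads[names(model$params)]
  list(grads = grads, d_seq_emb = dXs,
       d_struct = matrix(dSs, B, L, byrow = TRUE))
}

# build (ids, struct_tok) model inputs from a fixed_samples batch
prepare_inputs <- function(model, samples) {
  k <- model$cfg$encoder$k
  toks <- lapply(samples$sequence, tokenize, k = k)
  ids <- do.call(rbind, lapply(toks, function(tk)
    tokens_to_ids(tk$tokens, model$vocab)))
  L <- ncol(ids) - 2L
  if (is.null(samples$structure)) {
    struct_tok <- matrix(-1, nrow(ids), L)
  } else {
    struct_tok <- t(apply(samples$structure, 1, align_structure_to_tokens,
                          k = k))
  }
  list(ids = ids, struct_tok = struct_tok, tokens = toks)
}

#' Predict binding probabilities for samples
#'
#' Evaluation mode: dropout off, batch-norm running statistics; repeated
#' calls with the same model and inputs are deterministic.
#'
#' @param model a `bindnet`.
#' @param samples a `fixed_samples` object.
#' @param batch_size evaluation batch size.
#' @return numeric vector of probabilities in (0,1).
#' @export
predict_binding <- function(model, samples, batch_size = 64L) {
  n <- length(samples)
  out <- numeric(n)
  for (s in seq(1L, n, by = batch_size)) {
    i <- s:min(s + batch_size - 1L, n)
    inp <- prepare_inputs(model, samples[i])
    out[i] <- bindnet_fwd(model, inp$ids, inp$struct_tok, train = FALSE)$p
  }
  out
}

#' Score the effect of a single-nucleotide variant on predicted binding
#'
#' Substitutes the base, re-tokenizes, re-embeds and re-predicts; the
#' structure vector is reused unchanged (re-probing the variant's structure
#' would require new experimental data).
#'
#' @param model a `bindnet`.
#' @param sample a one-record `fixed_samples` object.
#' @param position 1-based position within the sample window.
#' @param alt_base one of A, C, G, U (T accepted).
#' @return list with `p_ref`, `p_alt`, `delta` (= p_alt - p_ref) and
#'   `note` when the alternate equals the reference.
#' @export
variant_effect <- function(model, sample, position, alt_base) {
  assert_that(length(sample) == 1L, "shape", "variant_effect takes one sample")
  len <- sample$length
  assert_that(position >= 1L && position <= len, "position",
              "position %d outside 1..%d", position, len)
  alt <- as_rna(alt_base, "alt allele")
  assert_that(nchar(alt) == 1L, "allele", "alt_base must be one base")
  ref <- substr(sample$sequence, position, position)
  p_ref <- predict_binding(model, sample)
  if (identical(alt, ref)) {
    return(list(p_ref = p_ref, p_alt = p_ref, delta = 0,
                note = "alt allele equals reference; delta is 0"))
  }
  mut <- sample
  substr(mut$sequence, position, position) <- alt
  p_alt <- predict_binding(model, mut)
  list(p_ref = p_ref, p_alt = p_alt, delta = p_alt - p_ref, note = NULL)
}

#' Save / load a model checkpoint
#'
#' Single-file archive holding the configuration, parameters, batch-norm
#' running statistics and a format version stamp.
#'
#' @param model a `bindnet`.
#' @param path checkpoint file.
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = "bindnet-checkpoint-1", cfg = model$cfg,
               params = model$params, bn = as.list(model$bn),
               schedule = model$schedule, vocab = model$vocab),
          path, version = 2)
  invisible(path)
}

#' @rdname save_model
#' @return the restored `bindnet` model.
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  assert_that(identical(x$format, "bindnet-checkpoint-1"), "checkpoint",
              "not a recognized model checkpoint")
  m <- new.env(parent = emptyenv())
  m$params <- x$params
  m$cfg <- x$cfg
  m$vocab <- x$vocab
  m$schedule <- x$schedule
  m$bn <- list2env(x$bn, new.env(parent = emptyenv()))
  class(m) <- "bindnet"
  m
}

# ---- standalone single-sample operations ----------------------------------
# Functional views of the network stages, operating on channels x length
# feature maps. Used for shape/property verification and composition; fresh
# Kaiming-initialized parameters are drawn unless `params` is supplied.

as_rows <- function(x) t(x)          # channels x L -> (1*L) x C
as_chan <- function(m) t(m)          # (1*L) x C -> channels x L

#' Apply one Conv-BN-ReLU block to a feature map
#'
#' @param x channels x length numeric matrix.
#' @param channels output channels.
#' @param kernel odd kernel size.
#' @param params optional block parameters (`W`, `bn`); fresh otherwise.
#' @param seed seed for fresh initialization.
#' @param train use batch statistics (TRUE) or identity running stats.
#' @param dropout dropout rate after the activation (0 here by default).
#' @return channels x length matrix.
#' @export
cnn_block_apply <- function(x, channels, kernel, params = NULL, seed = 1L,
                            train = FALSE, dropout = 0) {
  assert_that(all(is.finite(x)), "nonfinite", "input must be finite")
  p <- params %||% withr::with_seed(derive_seed(seed, 59L),
                                    cnn_block_init(nrow(x), channels, kernel))
  st <- new.env(parent = emptyenv())
  out <- cnn_block_fwd(p, as_rows(x), 1L, ncol(x), kernel, st, "blk", train,
                       dropout)
  as_chan(out$out)
}

#' Unified alignment of sequence and structure features
#'
#' Sequence embeddings (d_model x L) are reduced with `channels` kernels of
#' size 1; the structure vector (1 x L) is upsampled with `channels` kernels
#' of size 3; both through Conv-BN-ReLU.
#'
#' @param seq_emb d_model x L matrix (or L x d_model, auto-detected when a
#'   `d` argument is given).
#' @param struct_vec numeric vector of length L (or 1 x L matrix).
#' @param channels output channels (128).
#' @param params optional list(align_seq, align_str) parameter blocks.
#' @param seed seed for fresh initialization.
#' @return list(seq_feat, struct_feat), both channels x L.
#' @export
unified_alignment <- function(seq_emb, struct_vec, channels = 128L,
                              params = NULL, seed = 1L) {
  if (is.matrix(struct_vec)) struct_vec <- as.vector(struct_vec)
  L <- length(struct_vec)
  assert_that(ncol(seq_emb) == L, "length_mismatch",
              "sequence features have length %d but structure %d",
              ncol(seq_emb), L)
  p <- params %||% withr::with_seed(derive_seed(seed, 61L), list(
    align_seq = cnn_block_init(nrow(seq_emb), channels, 1L),
    align_str = cnn_block_init(1L, channels, 3L)))
  list(seq_feat = cnn_block_apply(seq_emb, channels, 1L, p$align_seq),
       struct_feat = cnn_block_apply(matrix(struct_vec, 1L), channels, 3L,
                                     p$align_str))
}

#' Apply a hierarchical multi-scale residual stage
#'
#' @param x channels x length matrix; channels must equal
#'   `length(kernels) * branch_channels` so the residual sum is shape-valid.
#' @param kernels,depths per-branch kernel sizes and stacked block counts.
#' @param branch_channels channels per branch.
#' @param params optional branch parameters from `msr_init`.
#' @param seed seed for fresh initialization.
#' @return channels x length matrix.
#' @export
hmrn_apply <- function(x, kernels = c(1L, 3L, 5L, 7L), depths = c(1L, 2L, 3L, 4L),
                       branch_channels = 32L, params = NULL, seed = 1L) {
  C <- nrow(x)
  assert_that(C == length(kernels) * branch_channels, "config",
              "input channels %d != %d branches x %d channels",
              C, length(kernels), branch_channels)
  cfg <- list(hmrn_kernels = as.integer(kernels),
              hmrn_depths = as.integer(depths),
              branch_channels = as.integer(branch_channels),
              dropout = 0, bn_momentum = 0.1, bn_eps = 1e-5)
  p <- params %||% withr::with_seed(derive_seed(seed, 67L), msr_init(C, cfg))
  st <- new.env(parent = emptyenv())
  out <- msr_fwd(p, as_rows(x), 1L, ncol(x), cfg, st, "msr", train = FALSE)
  as_chan(out$out)
}

#' Reduce a feature map to one feature vector with the pyramid predictor
#'
#' Repeats [two distinct Conv-BN-ReLU blocks -> residual add -> ReLU ->
#' max-pool(3, stride 2)] until the length reaches 1 (right-padding with
#' -Inf for the terminal pool).
#'
#' @param x channels x length matrix.
#' @param kernel conv kernel size (5).
#' @param params optional list of per-stage parameters (`c1`, `c2`).
#' @param seed seed for fresh initialization.
#' @return numeric vector of length `nrow(x)`.
#' @export
dprbp_apply <- function(x, kernel = 5L, params = NULL, seed = 1L) {
  C <- nrow(x)
  L <- ncol(x)
  sched <- pyramid_length_schedule(L)
  n_stages <- max(length(sched) - 1L, 1L)
  p <- params %||% withr::with_seed(derive_seed(seed, 71L),
    lapply(seq_len(n_stages), function(i)
      list(c1 = cnn_block_init(C, C, kernel),
           c2 = cnn_block_init(C, C, kernel))))
  st <- new.env(parent = emptyenv())
  m <- as_rows(x)
  si <- 0L
  while (nrow(m) > 1L) {
    si <- si + 1L
    sp <- p[[min(si, length(p))]]
    Lc <- nrow(m)
    b2 <- cnn_block_fwd(sp$c2, m, 1L, Lc, kernel, st, sprintf("p%d.2", si),
                        FALSE, 0)
    b1 <- cnn_block_fwd(sp$c1, b2$out, 1L, Lc, kernel, st, sprintf("p%d.1", si),
                        FALSE, 0)
    m <- maxpool_fwd(pmax(m + b1$out, 0), 1L, Lc)$out
  }
  as.vector(m)
}
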