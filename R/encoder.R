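# k-mer token encoder: a trainable multi-head self-attention (transformer)
# encoder producing dynamic per-token embeddings, a static one-hot fallback,
# and a loader for precomputed embedding matrices.
#
# The full-size configuration (12 layers, 768 hidden units, 12 heads) mirrors
# the BERT-family encoder the method builds on; the "small" configuration
# (2 layers, 64 units, 4 heads) is the desk-scale default for joint training.

#' Encoder configuration
#'
#' @param k k-mer size (3..6).
#' @param d_model embedding width (768 for the full-size encoder).
#' @param n_layers number of transformer layers.
#' @param n_heads attention heads per layer; must divide `d_model`.
#' @param ffn_hidden width of the position-wise feed-forward hidden layer.
#' @param n_positions maximum token-sequence length (with specials).
#' @param freeze if TRUE the encoder is not updated during joint training.
#' @return list of class `encoder_config`.
#' @export
encoder_config <- function(k = 3L, d_model = 768L, n_layers = 12L,
                           n_heads = 12L, ffn_hidden = 4L * d_model,
                           n_positions = 512L, freeze = FALSE) {
  assert_that(k %in% 3:6 || k == 1L, "config", "k must be in {3,4,5,6} (or 1)")
  assert_that(d_model %% n_heads == 0, "config",
              "d_model must be divisible by n_heads")
  structure(list(k = as.integer(k), d_model = as.integer(d_model),
                 n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 ffn_hidden = as.integer(ffn_hidden),
                 n_positions = as.integer(n_positions), freeze = freeze),
            class = "encoder_config")
}

#' Desk-scale encoder configuration (2 layers, 64 units, 4 heads)
#' @param k k-mer size.
#' @param ... overrides passed to [encoder_config()].
#' @export
encoder_config_small <- function(k = 3L, ...) {
  encoder_config(k = k, d_model = 64L, n_layers = 2L, n_heads = 4L,
                 ffn_hidden = 128L, n_positions = 128L, ...)
}

#' k-mer vocabulary for an encoder
#'
#' `[PAD]`, `[UNK]`, `[CLS]`, `[SEP]` followed by all 4^k k-mers in
#' lexicographic ACGU order.
#'
#' @param k k-mer size.
#' @return character vector of tokens.
#' @export
kmer_vocabulary <- function(k = 3L) {
  kmers <- RNA_BASES
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      kmers <- as.vector(t(outer(kmers, RNA_BASES, paste0)))
    }
  }
  c("[PAD]", "[UNK]", "[CLS]", "[SEP]", kmers)
}

tokens_to_ids <- function(tokens, vocab) {
  ids <- match(tokens, vocab)
  ids[is.na(ids)] <- 2L  # [UNK]
  ids
}

#' Create a trainable self-attention encoder
#'
#' Pre-norm transformer: token + learned positional embeddings, `n_layers`
#' blocks of multi-head self-attention and a ReLU feed-forward network with
#' residual connections, and a final layer norm.
#'
#' @param config an [encoder_config()].
#' @param seed integer seed for initialization.
#' @return object of class `attention_encoder` (an environment holding
#'   `params`, `config`, `vocab`).
#' @export
new_encoder <- function(config = encoder_config_small(), seed = 1L) {
  vocab <- kmer_vocabulary(config$k)
  d <- config$d_model
  withr::with_seed(derive_seed(seed, 31L), {
    init_mat <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.02), nr, nc)
    layers <- lapply(seq_len(config$n_layers), function(i) {
      list(ln1 = layernorm_init(d),
           Wq = init_mat(d, d), bq = numeric(d),
           Wk = init_mat(d, d), bk = numeric(d),
           Wv = init_mat(d, d), bv = numeric(d),
           Wo = init_mat(d, d), bo = numeric(d),
           ln2 = layernorm_init(d),
           W1 = init_mat(d, config$ffn_hidden), b1 = numeric(config$ffn_hidden),
           W2 = init_mat(config$ffn_hidden, d), b2 = numeric(d))
    })
    names(layers) <- paste0("l", seq_along(layers))
    params <- list(tok = init_mat(length(vocab), d),
                   pos = init_mat(config$n_positions, d),
                   layers = layers,
                   lnf = layernorm_init(d))
  })
  e <- new.env(parent = emptyenv())
  e$params <- params
  e$config <- config
  e$vocab <- vocab
  class(e) <- "attention_encoder"
  e
}

# forward pass over a batch of id matrices (B x T); returns hidden states
# ((B*T) x d), per-layer caches when grad = TRUE, and per-head attention
# matrices of the requested layers when capture_attention is given.
encoder_fwd <- function(params, cfg, ids, grad = FALSE,
                        capture_attention = integer(0)) {
  B <- nrow(ids); T <- ncol(ids)
  assert_that(T <= cfg$n_positions, "too_long",
              "token sequence length %d exceeds n_positions %d", T, cfg$n_positions)
  d <- cfg$d_model; H <- cfg$n_heads; dk <- d %/% H
  flat_ids <- as.vector(t(ids))
  X <- params$tok[flat_ids, , drop = FALSE] +
    params$pos[rep.int(seq_len(T), B), , drop = FALSE]
  caches <- if (grad) vector("list", cfg$n_layers) else NULL
  attn <- list()
  scale <- 1 / sqrt(dk)
  for (li in seq_len(cfg$n_layers)) {
    p <- params$layers[[li]]
    a <- layernorm_fwd(p$ln1, X)
    n <- nrow(X)
    Q <- a$out %*% p$Wq + bcast_col(p$bq, n)
    K <- a$out %*% p$Wk + bcast_col(p$bk, n)
    V <- a$out %*% p$Wv + bcast_col(p$bv, n)
    O <- matrix(0, n, d)
    Aarr <- array(0, c(T, T, B * H))
    for (b in seq_len(B)) {
      rb <- (b - 1L) * T + seq_len(T)
      for (h in seq_len(H)) {
        hc <- (h - 1L) * dk + seq_len(dk)
        A <- softmax_rows(tcrossprod(Q[rb, hc, drop = FALSE],
                                     K[rb, hc, drop = FALSE]) * scale)
        Aarr[, , (b - 1L) * H + h] <- A
        O[rb, hc] <- A %*% V[rb, hc, drop = FALSE]
      }
    }
    ao <- O %*% p$Wo + bcast_col(p$bo, n)
    X1 <- X + ao
    f <- layernorm_fwd(p$ln2, X1)
    u <- f$out %*% p$W1 + bcast_col(p$b1, n)
    r <- relu_fwd(u)
    X2 <- X1 + r$out %*% p$W2 + bcast_col(p$b2, n)
    if (grad) {
      caches[[li]] <- list(X = X, a = a, Q = Q, K = K, V = V, Aarr = Aarr,
                           O = O, X1 = X1, f = f, rmask = r$cache, r = r$out)
    }
    if (li %in% capture_attention) {
      attn[[as.character(li)]] <- Aarr
    }
    X <- X2
  }
  fin <- layernorm_fwd(params$lnf, X)
  list(H = fin$out, caches = caches, fin_cache = fin, X_last = X,
       attn = attn, B = B, T = T, flat_ids = flat_ids)
}

# backward: dH is the gradient w.r.t. the final hidden states
encoder_bwd <- function(params, cfg, fw, dH) {
  B <- fw$B; T <- fw$T
  d <- cfg$d_model; H <- cfg$n_heads; dk <- d %/% H
  scale <- 1 / sqrt(dk)
  grads <- tree_map(function(p) array(0, dim = dim(p) %||% length(p)), params)
  lnf <- layernorm_bwd(params$lnf, dH, fw$fin_cache$cache)
  grads$lnf <- lnf$grads
  dX <- lnf$dx
  for (li in rev(seq_len(cfg$n_layers))) {
    p <- params$layers[[li]]
    cc <- fw$caches[[li]]
    n <- nrow(dX)
    # FFN branch
    dW2 <- crossprod(cc$r, dX)
    db2 <- colSums(dX)
    du <- relu_bwd(dX %*% t(p$W2), cc$rmask)
    dW1 <- crossprod(cc$f$out, du)
    db1 <- colSums(du)
    ln2 <- layernorm_bwd(p$ln2, du %*% t(p$W1), cc$f$cache)
    dX1 <- dX + ln2$dx
    # attention branch
    dao <- dX1
    dWo <- crossprod(cc$O, dao)
    dbo <- colSums(dao)
    dO <- dao %*% t(p$Wo)
    dQ <- matrix(0, n, d); dK <- matrix(0, n, d); dV <- matrix(0, n, d)
    for (b in seq_len(B)) {
      rb <- (b - 1L) * T + seq_len(T)
      for (h in seq_len(H)) {
        hc <- (h - 1L) * dk + seq_len(dk)
        A <- fw$caches[[li]]$Aarr[, , (b - 1L) * H + h]
        dOb <- dO[rb, hc, drop = FALSE]
        dA <- tcrossprod(dOb, cc$V[rb, hc, drop = FALSE])
        dV[rb, hc] <- crossprod(A, dOb)
        dS <- A * (dA - rowSums(dA * A))
        dQ[rb, hc] <- (dS %*% cc$K[rb, hc, drop = FALSE]) * scale
        dK[rb, hc] <- (crossprod(dS, cc$Q[rb, hc, drop = FALSE])) * scale
      }
    }
    da <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
    ln1 <- layernorm_bwd(p$ln1, da, cc$a$cache)
    grads$layers[[li]] <- list(
      ln1 = ln1$grads,
      Wq = crossprod(cc$a$out, dQ), bq = colSums(dQ),
      Wk = crossprod(cc$a$out, dK), bk = colSums(dK),
      Wv = crossprod(cc$a$out, dV), bv = colSums(dV),
      Wo = dWo, bo = dbo,
      ln2 = ln2$grads,
      W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
    dX <- dX1 + ln1$dx
  }
  # embeddings
  agg <- rowsum(dX, group = fw$flat_ids)
  grads$tok[as.integer(rownames(agg)), ] <- agg
  pgrp <- rep.int(seq_len(T), B)
  paggr <- rowsum(dX, group = pgrp)
  grads$pos[as.integer(rownames(paggr)), ] <- paggr
  grads
}

#' Embed a token sequence into a per-token feature matrix
#'
#' Runs the encoder and returns the final-layer hidden states with the
#' `[CLS]`/`[SEP]` rows removed: a (token_count x d_model) matrix.
#'
#' @param tokens a [tokenize()] result (or a list of them for a batch).
#' @param encoder an `attention_encoder` or `onehot_encoder`.
#' @return numeric matrix (interior tokens x d_model), or a list of matrices
#'   when a list of token sequences is given.
#' @export
embed <- function(tokens, encoder) {
  single <- inherits(tokens, "token_sequence")
  tl <- if (single) list(tokens) else tokens
  out <- if (inherits(encoder, "onehot_encoder")) {
    lapply(tl, function(tk) {
      ids <- match(tk$tokens[-c(1L, length(tk$tokens))], encoder$vocab_kmers)
      assert_that(!anyNA(ids), "unknown_token", "token outside k-mer vocabulary")
      M <- matrix(0, length(ids), length(encoder$vocab_kmers))
      M[cbind(seq_along(ids), ids)] <- 1
      M
    })
  } else {
    stopifnot(inherits(encoder, "attention_encoder"))
    Ts <- vapply(tl, function(tk) length(tk$tokens), 0L)
    assert_that(length(unique(Ts)) == 1L, "length_mismatch",
                "batched embedding requires equal token counts")
    ids <- do.call(rbind, lapply(tl, function(tk)
      tokens_to_ids(tk$tokens, encoder$vocab)))
    fw <- encoder_fwd(encoder$params, encoder$config, ids, grad = FALSE)
    T <- fw$T
    lapply(seq_len(fw$B), function(b)
      fw$H[(b - 1L) * T + 2:(T - 1L), , drop = FALSE])
  }
  bad <- vapply(out, function(m) any(!is.finite(m)), TRUE)
  assert_that(!any(bad), "nonfinite", "embedding produced non-finite values")
  if (single) out[[1]] else out
}

#' Static one-hot fallback encoder
#'
#' Identical k-mers always receive identical (indicator) rows; d_model is
#' 4^k.
#'
#' @param k k-mer size.
#' @return object of class `onehot_encoder`.
#' @export
new_onehot_encoder <- function(k = 3L) {
  v <- kmer_vocabulary(k)
  structure(list(k = as.integer(k), vocab_kmers = v[-(1:4)],
                 d_model = 4L^k),
            class = "onehot_encoder")
}

#' Standalone multi-head scaled dot-product self-attention
#'
#' `Attention(Q,K,V) = softmax(Q K^T / sqrt(d_k)) V` per head, heads
#' concatenated and passed through the output projection `W_O`. This is the
#' bare operation (no residual, norm or biases), exposed for testing and
#' composition.
#'
#' @param X token x d matrix.
#' @param params list with `heads` (a list of `list(Wq, Wk, Wv)`, each d x
#'   d_k) and `Wo` ((h*d_k) x d_out).
#' @return token x d_out matrix.
#' @export
self_attention <- function(X, params) {
  assert_that(all(is.finite(X)), "nonfinite", "X must be finite")
  heads <- lapply(params$heads, function(h) {
    assert_that(nrow(h$Wq) == ncol(X) && nrow(h$Wk) == ncol(X) &&
                nrow(h$Wv) == ncol(X), "shape",
                "head projection rows must equal ncol(X)")
    Q <- X %*% h$Wq; K <- X %*% h$Wk; V <- X %*% h$Wv
    softmax_rows(tcrossprod(Q, K) / sqrt(ncol(h$Wk))) %*% V
  })
  cat_heads <- do.call(cbind, heads)
  assert_that(ncol(cat_heads) == nrow(params$Wo), "shape",
              "Wo rows must equal concatenated head width")
  cat_heads %*% params$Wo
}

#' CLS-row attention scores
#'
#' For each interior token i, the sum over heads of the softmax attention
#' weight that the `[CLS]` query places on token i
#' (`Score_i = sum_heads exp(Q_CLS . K_i / sqrt(d)) / sum_t exp(Q_CLS . K_t /
#' sqrt(d))`, the denominator running over all tokens, specials included).
#' Scores are read from the final layer by default and averaged when several
#' layers are requested.
#'
#' @param tokens a [tokenize()] result.
#' @param encoder an `attention_encoder`.
#' @param layers layer indices to read (default: final layer).
#' @param include_special also return the `[CLS]`/`[SEP]` entries.
#' @return numeric vector of non-negative scores (one per interior token,
#'   or per token when `include_special`).
#' @export
cls_attention_scores <- function(tokens, encoder, layers = NULL,
                                 include_special = FALSE) {
  stopifnot(inherits(encoder, "attention_encoder"))
  layers <- layers %||% encoder$config$n_layers
  ids <- matrix(tokens_to_ids(tokens$tokens, encoder$vocab), nrow = 1L)
  fw <- encoder_fwd(encoder$params, encoder$config, ids,
                    capture_attention = layers)
  T <- fw$T
  per_layer <- vapply(as.character(layers), function(li) {
    A <- fw$attn[[li]]                # T x T x H  (single sample)
    rowSums(matrix(A[1L, , ], nrow = T))   # CLS row summed over heads
  }, numeric(T))
  sc <- rowMeans(per_layer)
  if (include_special) sc else sc[2:(T - 1L)]
}

#' Save / load precomputed embedding matrices
#'
#' A store maps sample ids to (tokens x d) matrices. The container uses R's
#' native serialization, created at run time (no binary artifacts ship with
#' the package).
#'
#' @param embeddings named list of numeric matrices.
#' @param path file to write.
#' @export
save_embeddings <- function(embeddings, path) {
  assert_that(length(names(embeddings)) == length(embeddings) &&
              all(nzchar(names(embeddings))), "manifest",
              "embeddings must be a fully named list")
  d <- unique(vapply(embeddings, ncol, 0L))
  assert_that(length(d) == 1L, "shape", "all embeddings must share one width")
  saveRDS(list(d = d, ids = names(embeddings), data = embeddings),
          path, version = 2)
  invisible(path)
}

#' @rdname save_embeddings
#' @param ids sample ids to fetch (all by default).
#' @param d_model expected width; mismatch is an error.
#' @return named list of matrices.
#' @export
load_embeddings <- function(path, ids = NULL, d_model = NULL) {
  store <- readRDS(path)
  if (!is.null(d_model)) {
    assert_that(store$d == d_model, "shape",
                "store width %d does not match expected d_model %d",
                store$d, d_model)
  }
  ids <- ids %||% store$ids
  missing <- setdiff(ids, store$ids)
  assert_that(length(missing) == 0L, "missing_ids",
              "ids absent from store: %s", paste(missing, collapse = ", "))
  store$data[ids]
}
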