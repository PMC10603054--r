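# Token encoder: bare attention op, embeddings, CLS attention scores,
# precomputed stores.

test_that("bare multi-head attention matches a loop-and-softmax oracle", {
  withr::with_seed(21, {
    X <- matrix(rnorm(3 * 2), 3, 2)
    params <- list(heads = list(
      list(Wq = matrix(rnorm(4, sd = 0.5), 2, 2),
           Wk = matrix(rnorm(4, sd = 0.5), 2, 2),
           Wv = matrix(rnorm(4, sd = 0.5), 2, 2))),
      Wo = diag(2))
  })
  # independent oracle: explicit per-row softmax and weighted sum
  h <- params$heads[[1]]
  Q <- X %*% h$Wq; K <- X %*% h$Wk; V <- X %*% h$Wv
  oracle <- matrix(0, 3, 2)
  for (i in 1:3) {
    s <- numeric(3)
    for (j in 1:3) s[j] <- exp(sum(Q[i, ] * K[j, ]) / sqrt(2))
    a <- s / sum(s)
    for (j in 1:3) oracle[i, ] <- oracle[i, ] + a[j] * V[j, ]
  }
  expect_equal(self_attention(X, params), oracle %*% diag(2), tolerance = 1e-12)
  # zero fixed point: identity projections, zero input
  p0 <- list(heads = list(list(Wq = matrix(1), Wk = matrix(1), Wv = matrix(1))),
             Wo = matrix(1))
  expect_equal(self_attention(matrix(0, 2, 1), p0), matrix(0, 2, 1))
  expect_error(self_attention(matrix(Inf, 2, 1), p0), class = "bindnet_nonfinite")
})

test_that("bare attention is permutation-equivariant; the encoder is not", {
  withr::with_seed(22, {
    X <- matrix(rnorm(5 * 4), 5, 4)
    params <- list(heads = lapply(1:2, function(i)
      list(Wq = matrix(rnorm(8), 4, 2), Wk = matrix(rnorm(8), 4, 2),
           Wv = matrix(rnorm(8), 4, 2))),
      Wo = matrix(rnorm(16), 4, 4))
    perm <- sample(5)
  })
  expect_equal(self_attention(X[perm, ], params),
               self_attention(X, params)[perm, ], tolerance = 1e-10)
  # positional embeddings break equivariance in the full encoder
  enc <- new_encoder(tiny_encoder_cfg(), seed = 3)
  e1 <- embed(tokenize("ACGUACGUAC", 3), enc)
  e2 <- embed(tokenize("GUACGUACGU", 3), enc)   # same k-mers, shifted context
  expect_false(isTRUE(all.equal(e1[2, ], e2[1, ])))
})

test_that("embedding shapes, context dependence, and finiteness", {
  enc <- new_encoder(tiny_encoder_cfg(), seed = 4)
  seq101 <- substr(paste(rep("GAUCGAUACG", 11), collapse = ""), 1, 101)
  M <- embed(tokenize(seq101, 3), enc)
  expect_equal(dim(M), c(99L, 16L))
  # the same k-mer in different contexts gets different rows (dynamic)
  s <- "AAACGAAAAAAACGAAA"   # ACG at two positions with different flanks
  tk <- tokenize(s, 3)
  pos <- which(tk$tokens == "ACG") - 1L
  Md <- embed(tk, enc)
  expect_gt(max(abs(Md[pos[1], ] - Md[pos[2], ])), 1e-8)
  # one-hot fallback: identical tokens -> identical rows
  oh <- new_onehot_encoder(3)
  Mo <- embed(tk, oh)
  expect_equal(dim(Mo), c(tk$n_interior, 64L))
  expect_equal(Mo[pos[1], ], Mo[pos[2], ])
  expect_equal(rowSums(Mo), rep(1, nrow(Mo)))
  # fuzz: no NaN/Inf across random inputs
  withr::with_seed(5, {
    for (i in 1:5) {
      r <- paste(sample(c("A", "C", "G", "U"), 40, replace = TRUE), collapse = "")
      expect_true(all(is.finite(embed(tokenize(r, 3), enc))))
    }
  })
  # same seed, same encoder, same output
  enc2 <- new_encoder(tiny_encoder_cfg(), seed = 4)
  expect_identical(embed(tk, enc2), Md)
})

test_that("CLS attention scores: uniform case, conservation, and oracle", {
  cfg <- tiny_encoder_cfg()
  enc <- new_encoder(cfg, seed = 6)
  tk <- tokenize("ACGUACGUACGU", 3)
  T <- length(tk$tokens)
  H <- cfg$n_heads
  # all keys identical (zero key projection): every token gets H/T
  enc_u <- new_encoder(cfg, seed = 6)
  enc_u$params$layers$l1$Wk[] <- 0
  sc_u <- cls_attention_scores(tk, enc_u, include_special = TRUE)
  expect_equal(sc_u, rep(H / T, T), tolerance = 1e-12)
  # conservation: scores over all tokens sum to the number of heads
  sc <- cls_attention_scores(tk, enc, include_special = TRUE)
  expect_equal(sum(sc), H, tolerance = 1e-10)
  expect_length(cls_attention_scores(tk, enc), T - 2L)
  expect_true(all(sc >= 0))
  # independent reimplementation oracle for a 1-layer encoder
  p <- enc$params
  ids <- bindnet:::tokens_to_ids(tk$tokens, enc$vocab)
  X <- p$tok[ids, ] + p$pos[seq_len(T), ]
  ln <- function(x, g, b) {
    mu <- mean(x); v <- mean((x - mu)^2)
    g * (x - mu) / sqrt(v + 1e-5) + b
  }
  A <- t(vapply(seq_len(T), function(i)
    ln(X[i, ], p$layers$l1$ln1$g, p$layers$l1$ln1$b), numeric(cfg$d_model)))
  Q <- A %*% p$layers$l1$Wq + matrix(p$layers$l1$bq, T, cfg$d_model, byrow = TRUE)
  K <- A %*% p$layers$l1$Wk + matrix(p$layers$l1$bk, T, cfg$d_model, byrow = TRUE)
  dk <- cfg$d_model / H
  oracle <- numeric(T)
  for (h in seq_len(H)) {
    cols <- (h - 1) * dk + seq_len(dk)
    s <- vapply(seq_len(T), function(j)
      exp(sum(Q[1, cols] * K[j, cols]) / sqrt(dk)), 0)
    oracle <- oracle + s / sum(s)
  }
  expect_equal(sc, oracle, tolerance = 1e-10)
})

test_that("precomputed embedding stores round-trip and validate", {
  e <- list(s1 = matrix(rnorm(12), 3, 4), s2 = matrix(rnorm(20), 5, 4))
  f <- withr::local_tempfile(fileext = ".rds")
  save_embeddings(e, f)
  back <- load_embeddings(f)
  expect_identical(back, e)                       # bitwise round trip
  expect_error(load_embeddings(f, d_model = 8), class = "bindnet_shape")
  expect_error(load_embeddings(f, ids = c("s1", "nope")),
               class = "bindnet_missing_ids")
  expect_error(save_embeddings(list(matrix(0, 1, 1)), f),
               class = "bindnet_manifest")
})
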