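# Network stages and the end-to-end predictor.

test_that("conv blocks preserve length, stay non-negative, and zero out", {
  withr::with_seed(31, x <- matrix(rnorm(6 * 20), 6, 20))
  for (k in c(1L, 3L, 5L, 7L)) {
    y <- cnn_block_apply(x, channels = 5L, kernel = k, seed = k)
    expect_equal(dim(y), c(5L, 20L))
    expect_true(all(y >= 0))
  }
  # zero kernels with identity BN (eval running stats, gamma 1, beta 0)
  p0 <- list(W = matrix(0, 6 * 3, 5), bn = bindnet:::batchnorm_init(5))
  expect_true(all(cnn_block_apply(x, 5L, 3L, params = p0) == 0))
})

test_that("unified alignment produces 128-channel maps from 768-dim input", {
  withr::with_seed(32, {
    seq_emb <- matrix(rnorm(768 * 99), 768, 99)
    struct <- runif(99)
  })
  ua <- unified_alignment(seq_emb, struct, channels = 128L)
  expect_equal(dim(ua$seq_feat), c(128L, 99L))
  expect_equal(dim(ua$struct_feat), c(128L, 99L))
  # all-sentinel structure still yields finite features
  ua2 <- unified_alignment(seq_emb, rep(-1, 99), channels = 128L)
  expect_true(all(is.finite(ua2$struct_feat)))
  # channel count is independent of L
  ua3 <- unified_alignment(seq_emb[, 1:31], struct[1:31], channels = 128L)
  expect_equal(dim(ua3$seq_feat), c(128L, 31L))
  expect_error(unified_alignment(seq_emb, struct[1:50]),
               class = "bindnet_length_mismatch")
})

test_that("multi-scale residual stage: shape, zero-branch identity, receptive field", {
  withr::with_seed(33, x <- matrix(rnorm(8 * 30), 8, 30))
  y <- hmrn_apply(x, branch_channels = 2L)
  expect_equal(dim(y), dim(x))
  # zero branch convolutions (BN identity in eval) reduce to ReLU(x)
  cfg <- list(hmrn_kernels = c(1L, 3L, 5L, 7L), hmrn_depths = 1:4,
              branch_channels = 2L, dropout = 0, bn_momentum = 0.1,
              bn_eps = 1e-5)
  p <- bindnet:::msr_init(8L, cfg)
  p <- bindnet:::tree_map(function(w) w, p)
  for (j in seq_along(p)) for (i in seq_along(p[[j]])) p[[j]][[i]]$W[] <- 0
  expect_equal(hmrn_apply(x, branch_channels = 2L, params = p), pmax(x, 0),
               tolerance = 1e-12)
  expect_error(hmrn_apply(x, branch_channels = 3L), class = "bindnet_config")
  # impulse probing: j stacked blocks of kernel k spread support to
  # j*(k-1)+1 positions (positive weights, BN-identity eval mode)
  for (j in 1:4) {
    k <- c(1L, 3L, 5L, 7L)[j]
    imp <- matrix(0, 1, 41); imp[1, 21] <- 1
    y <- imp
    for (b in seq_len(j)) {
      pb <- list(W = matrix(0.7, 1 * k, 1), bn = bindnet:::batchnorm_init(1))
      y <- cnn_block_apply(y, 1L, k, params = pb)
    }
    expect_equal(sum(y > 1e-12), j * (k - 1L) + 1L)
  }
})

test_that("pyramid predictor reduces any length to one vector", {
  withr::with_seed(34, {
    for (L in c(1L, 5L, 27L, 99L)) {
      x <- matrix(rnorm(6 * L), 6, L)
      v <- dprbp_apply(x, seed = L)
      expect_length(v, 6L)
      expect_true(all(is.finite(v)))
    }
  })
})

test_that("prediction is a probability, deterministic in eval, 0.5 at zero head", {
  cfg <- tiny_model_cfg()
  m <- new_bindnet(cfg, seed = 2)
  s <- random_samples(6, len = 21, seed = 3)
  p <- predict_binding(m, s)
  expect_true(all(p > 0 & p < 1))
  expect_identical(predict_binding(m, s), p)   # eval-mode determinism
  m$params$head$W[] <- 0
  m$params$head$b[] <- 0
  expect_equal(predict_binding(m, s), rep(0.5, 6))   # sigmoid(0) exactly
  # samples without structure get the sentinel and still predict
  s2 <- random_samples(3, len = 21, seed = 4, with_structure = FALSE)
  expect_no_error(predict_binding(m, s2))
})

test_that("architecture is reproducible across constructions with one seed", {
  m1 <- new_bindnet(tiny_model_cfg(), seed = 9)
  m2 <- new_bindnet(tiny_model_cfg(), seed = 9)
  f1 <- bindnet:::tree_flatten(m1$params)
  f2 <- bindnet:::tree_flatten(m2$params)
  expect_identical(names(f1), names(f2))
  expect_identical(f1, f2)
  expect_equal(bindnet:::n_params(m1$params), bindnet:::n_params(m2$params))
})

test_that("the multi-scale module is live: perturbing it changes predictions", {
  m <- new_bindnet(tiny_model_cfg(), seed = 5)
  s <- random_samples(4, len = 21, seed = 6)
  p0 <- predict_binding(m, s)
  m$params$msr_seq$br2$blk1$W <- m$params$msr_seq$br2$blk1$W + 0.5
  expect_gt(max(abs(predict_binding(m, s) - p0)), 1e-8)
})

test_that("variant effect: identity, locality of token changes, reversal", {
  m <- new_bindnet(tiny_model_cfg(), seed = 7)
  s <- random_samples(1, len = 21, seed = 8)
  ref <- substr(s$sequence, 10, 10)
  ve0 <- variant_effect(m, s, 10, ref)
  expect_identical(ve0$delta, 0)
  expect_match(ve0$note, "equals reference")
  alt <- setdiff(c("A", "C", "G", "U"), ref)[1]
  ve <- variant_effect(m, s, 10, alt)
  expect_equal(ve$delta, ve$p_alt - ve$p_ref)
  # token-level locality: a substitution changes at most k tokens
  k <- m$cfg$encoder$k
  mut <- s
  substr(mut$sequence, 10, 10) <- alt
  t0 <- tokenize(s$sequence, k)$tokens
  t1 <- tokenize(mut$sequence, k)$tokens
  expect_lte(sum(t0 != t1), k)
  # position at the 5' edge touches fewer tokens than k would allow
  mut2 <- s
  a2 <- setdiff(c("A", "C", "G", "U"), substr(s$sequence, 1, 1))[1]
  substr(mut2$sequence, 1, 1) <- a2
  expect_lte(sum(tokenize(mut2$sequence, k)$tokens != t0), 1L)
  # applying and reverting returns exactly the reference probability
  ve_back <- variant_effect(m, mut, 10, ref)
  expect_equal(ve_back$p_alt, ve$p_ref, tolerance = 1e-12)
  expect_error(variant_effect(m, s, 99, "A"), class = "bindnet_position")
})

test_that("checkpoints round-trip exactly", {
  m <- new_bindnet(tiny_model_cfg(), seed = 11)
  s <- random_samples(5, len = 21, seed = 12)
  p <- predict_binding(m, s)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(predict_binding(m2, s), p)
  expect_error(load_model(withr::local_tempfile(fileext = ".rds",
                                                lines = "")),
               regexp = ".")
})

test_that("stage bookkeeping matches the pooling schedule for the 101-nt default", {
  cfg <- bindnet_config("small")
  m <- new_bindnet(cfg, seed = 1)
  expect_identical(m$schedule, c(99L, 49L, 24L, 11L, 5L, 2L, 1L))
  expect_length(m$params$pyramid, 6L)
})
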