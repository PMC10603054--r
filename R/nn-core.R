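# Minimal neural-network layer library on BLAS matrix operations.
#
# No deep-learning framework is assumed: every layer is a pair of functions,
# `*_fwd(params, x, ...) -> list(out, cache)` and
# `*_bwd(params, d_out, cache) -> list(dx, grads)`, with gradients verified
# by finite differences in the test suite. Batched 1-D feature maps are
# stored as dense matrices of shape (batch * length) x channels, rows
# grouped per sample with position fastest, so convolutions and projections
# become single matrix products.

kaiming <- function(fan_in, dims) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

# ---- parameter trees ------------------------------------------------------

tree_flatten <- function(x, prefix = "") {
  if (is.list(x)) {
    out <- list()
    nms <- names(x)
    for (i in seq_along(x)) {
      out <- c(out, tree_flatten(x[[i]], paste0(prefix, nms[i], ".")))
    }
    out
  } else {
    stats::setNames(list(x), substr(prefix, 1L, nchar(prefix) - 1L))
  }
}

tree_unflatten <- function(skeleton, flat, prefix = "") {
  if (is.list(skeleton)) {
    nms <- names(skeleton)
    for (i in seq_along(skeleton)) {
      skeleton[[i]] <- tree_unflatten(skeleton[[i]], flat,
                                      paste0(prefix, nms[i], "."))
    }
    skeleton
  } else {
    flat[[substr(prefix, 1L, nchar(prefix) - 1L)]]
  }
}

tree_map <- function(f, x) {
  if (is.list(x)) { for (i in seq_along(x)) x[[i]] <- tree_map(f, x[[i]]); x }
  else f(x)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) { for (i in seq_along(a)) a[[i]] <- tree_map2(f, a[[i]], b[[i]]); a }
  else f(a, b)
}

n_params <- function(tree) sum(vapply(tree_flatten(tree), length, 0L))

# ---- elementwise ----------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(d, mask) d * mask

dropout_fwd <- function(x, p, train) {
  if (!train || p <= 0) return(list(out = x, cache = NULL))
  mask <- matrix(stats::runif(length(x)) >= p, nrow(x), ncol(x)) / (1 - p)
  list(out = x * mask, cache = mask)
}
dropout_bwd <- function(d, mask) if (is.null(mask)) d else d * mask

# column-wise broadcast helpers: v has one entry per column of X
bcast_col <- function(v, n) rep(v, each = n)

# ---- linear ---------------------------------------------------------------

linear_init <- function(d_in, d_out, sd = NULL) {
  W <- if (is.null(sd)) kaiming(d_in, c(d_in, d_out)) else
    matrix(stats::rnorm(d_in * d_out, sd = sd), d_in, d_out)
  list(W = W, b = numeric(d_out))
}

linear_fwd <- function(p, X) {
  list(out = X %*% p$W + bcast_col(p$b, nrow(X)), cache = X)
}

linear_bwd <- function(p, dY, cache) {
  list(dx = dY %*% t(p$W),
       grads = list(W = crossprod(cache, dY), b = colSums(dY)))
}

# ---- layer norm (per row) -------------------------------------------------

layernorm_init <- function(d) list(g = rep(1, d), b = numeric(d))

layernorm_fwd <- function(p, X, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(out = xhat * bcast_col(p$g, nrow(X)) + bcast_col(p$b, nrow(X)),
       cache = list(xhat = xhat, inv = inv))
}

layernorm_bwd <- function(p, dY, cache) {
  n <- nrow(dY)
  xhat <- cache$xhat
  dxhat <- dY * bcast_col(p$g, n)
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, grads = list(g = colSums(dY * xhat), b = colSums(dY)))
}

# ---- 1-D convolution via im2col ------------------------------------------
# X: (B*L) x C_in; weight W: (C_in*k) x C_out laid out tap-major; odd k,
# symmetric zero padding so output length equals input length; no bias.

im2col <- function(X, B, L, k) {
  C <- ncol(X)
  if (k == 1L) return(X)
  pad <- (k - 1L) %/% 2L
  n <- B * L
  l <- rep.int(seq_len(L), B)
  out <- matrix(0, n, C * k)
  for (t in seq_len(k)) {
    sh <- t - 1L - pad
    ok <- (l + sh >= 1L) & (l + sh <= L)
    cols <- ((t - 1L) * C + 1L):(t * C)
    out[ok, cols] <- X[which(ok) + sh, , drop = FALSE]
  }
  out
}

col2im <- function(dXcol, B, L, C, k) {
  if (k == 1L) return(dXcol)
  pad <- (k - 1L) %/% 2L
  dX <- matrix(0, B * L, C)
  l <- rep.int(seq_len(L), B)
  for (t in seq_len(k)) {
    sh <- t - 1L - pad
    ok <- (l + sh >= 1L) & (l + sh <= L)
    idx <- which(ok) + sh
    cols <- ((t - 1L) * C + 1L):(t * C)
    dX[idx, ] <- dX[idx, ] + dXcol[ok, cols, drop = FALSE]
  }
  dX
}

conv1d_init <- function(c_in, c_out, k) {
  list(W = kaiming(c_in * k, c(c_in * k, c_out)))
}

conv1d_fwd <- function(p, X, B, L, k) {
  Xcol <- im2col(X, B, L, k)
  list(out = Xcol %*% p$W, cache = list(Xcol = Xcol, B = B, L = L, k = k,
                                        C = ncol(X)))
}

conv1d_bwd <- function(p, dY, cache) {
  list(dx = col2im(dY %*% t(p$W), cache$B, cache$L, cache$C, cache$k),
       grads = list(W = crossprod(cache$Xcol, dY)))
}

# ---- batch norm over (batch, position) per channel ------------------------
# Running estimates live in a mutable environment keyed by layer path so the
# same parameter tree stays a plain list of arrays.

batchnorm_init <- function(C) list(g = rep(1, C), b = numeric(C))

batchnorm_fwd <- function(p, X, st, key, train, momentum = 0.1, eps = 1e-5) {
  n <- nrow(X)
  C <- ncol(X)
  if (train) {
    mu <- colMeans(X)
    xc <- X - bcast_col(mu, n)
    v <- colMeans(xc * xc)
    ub <- if (n > 1L) v * n / (n - 1L) else v
    prev <- st[[key]] %||% list(mean = numeric(C), var = rep(1, C))
    st[[key]] <- list(mean = (1 - momentum) * prev$mean + momentum * mu,
                      var = (1 - momentum) * prev$var + momentum * ub)
  } else {
    rs <- st[[key]] %||% list(mean = numeric(C), var = rep(1, C))
    mu <- rs$mean
    v <- rs$var
    xc <- X - bcast_col(mu, n)
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * bcast_col(inv, n)
  list(out = xhat * bcast_col(p$g, n) + bcast_col(p$b, n),
       cache = list(xhat = xhat, inv = inv, train = train))
}

batchnorm_bwd <- function(p, dY, cache) {
  n <- nrow(dY)
  xhat <- cache$xhat
  grads <- list(g = colSums(dY * xhat), b = colSums(dY))
  dxhat <- dY * bcast_col(p$g, n)
  dx <- if (cache$train) {
    bcast_col(cache$inv, n) *
      (dxhat - bcast_col(colMeans(dxhat), n) -
         xhat * bcast_col(colMeans(dxhat * xhat), n))
  } else {
    dxhat * bcast_col(cache$inv, n)  # running stats are constants in eval
  }
  list(dx = dx, grads = grads)
}

# ---- max pooling, size 3 stride 2, right-padded with -Inf -----------------

pool_out_len <- function(L) if (L >= 3L) (L - 3L) %/% 2L + 1L else 1L

#' Length trajectory of the pyramid pooling stack
#'
#' Iterates `l -> floor((l-3)/2) + 1` (with terminal right-padding once
#' `l < 3`) until the length reaches 1, and returns the successive lengths
#' including the input.
#'
#' @param L starting length (>= 1).
#' @return integer vector of lengths, ending in 1.
#' @export
pyramid_length_schedule <- function(L) {
  L <- as.integer(L)
  assert_that(L >= 1L, "config", "length must be >= 1")
  out <- L
  while (L > 1L) {
    L <- pool_out_len(L)
    out <- c(out, L)
  }
  out
}

maxpool_fwd <- function(X, B, L) {
  Lout <- pool_out_len(L)
  C <- ncol(X)
  n_out <- B * Lout
  l_out <- rep.int(seq_len(Lout), B)
  b_of <- rep(seq_len(B), each = Lout)
  out <- matrix(-Inf, n_out, C)
  amax <- matrix(0L, n_out, C)
  src <- matrix(NA_integer_, n_out, 3L)
  for (t in 1:3) {
    sl <- 2L * (l_out - 1L) + t
    ok <- sl <= L
    rows <- (b_of - 1L) * L + sl
    src[ok, t] <- rows[ok]
    g <- matrix(-Inf, n_out, C)
    g[ok, ] <- X[rows[ok], , drop = FALSE]
    upd <- g > out
    amax[upd] <- t
    out[upd] <- g[upd]
  }
  list(out = out, cache = list(amax = amax, src = src, B = B, L = L, C = C,
                               Lout = Lout))
}

maxpool_bwd <- function(dY, cache) {
  dX <- matrix(0, cache$B * cache$L, cache$C)
  for (t in 1:3) {
    sel <- cache$amax == t
    if (!any(sel)) next
    rows <- cache$src[, t]
    ok <- !is.na(rows)
    contrib <- dY * sel
    dX[rows[ok], ] <- dX[rows[ok], ] + contrib[ok, , drop = FALSE]
  }
  dX
}

# ---- Adam with linear warm-up --------------------------------------------

adam_init <- function(flat_params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0, warmup_steps = 0L) {
  e <- new.env(parent = emptyenv())
  e$m <- lapply(flat_params, function(p) array(0, dim = dim(p) %||% length(p)))
  e$v <- e$m
  e$step <- 0L
  e$lr <- lr; e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps
  e$weight_decay <- weight_decay; e$warmup_steps <- as.integer(warmup_steps)
  e$last_lr <- 0
  e
}

adam_step <- function(opt, flat_params, flat_grads) {
  opt$step <- opt$step + 1L
  s <- opt$step
  lr_t <- opt$lr *
    if (opt$warmup_steps > 0L && s < opt$warmup_steps) s / opt$warmup_steps else 1
  opt$last_lr <- lr_t
  c1 <- 1 - opt$beta1^s
  c2 <- 1 - opt$beta2^s
  for (i in seq_along(flat_params)) {
    g <- flat_grads[[i]] + opt$weight_decay * flat_params[[i]]
    opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
    opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * g * g
    flat_params[[i]] <- flat_params[[i]] -
      lr_t * (opt$m[[i]] / c1) / (sqrt(opt$v[[i]] / c2) + opt$eps)
  }
  flat_params
}

# ---- finite-difference gradient check (used by the test suite) ------------

numeric_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
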