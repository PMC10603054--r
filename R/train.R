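# Training: Adam with linear warm-up, binary cross-entropy objective with L2
# weight penalty (realized once, as optimizer weight decay), early stopping
# on validation loss with best-checkpoint restoration, and AUC evaluation.

#' Training configuration
#'
#' @param batch_size mini-batch size (32).
#' @param learning_rate Adam learning rate (0.001).
#' @param weight_decay L2 weight-decay coefficient (1e-6); this is the
#'   lambda of the loss's `lambda * |W|_2` term, applied through the
#'   optimizer rather than a second explicit penalty.
#' @param warmup_steps linear warm-up horizon in optimizer steps; `NULL`
#'   means one epoch's worth of steps.
#' @param patience early-stop patience in epochs (5).
#' @param max_epochs maximum epochs.
#' @param seed integer seed governing shuffling, dropout and initialization
#'   of the optimizer state.
#' @return list of class `train_config`.
#' @export
train_config <- function(batch_size = 32L, learning_rate = 1e-3,
                         weight_decay = 1e-6, warmup_steps = NULL,
                         patience = 5L, max_epochs = 20L, seed = 1L) {
  assert_that(batch_size >= 1 && learning_rate > 0 && weight_decay >= 0,
              "config", "batch_size/learning_rate/weight_decay out of range")
  assert_that(patience <= max_epochs, "config", "patience must be <= max_epochs")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 warmup_steps = warmup_steps, patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed)),
            class = "train_config")
}

#' Binary cross-entropy with optional L2 norm penalty
#'
#' `-(1/N) sum[y log p + (1-y) log(1-p)] + lambda * ||W||_2`, probabilities
#' clamped to `[eps, 1-eps]` so the logs are finite.
#'
#' @param p predicted probabilities.
#' @param y 0/1 labels.
#' @param params optional parameter tree for the penalty term.
#' @param lambda penalty coefficient.
#' @param eps probability clamp.
#' @return scalar loss.
#' @export
bce_l2_loss <- function(p, y, params = NULL, lambda = 0, eps = 1e-7) {
  assert_that(length(p) == length(y), "shape", "p and y differ in length")
  pc <- pmin(pmax(p, eps), 1 - eps)
  loss <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  if (lambda > 0 && !is.null(params)) {
    loss <- loss + lambda *
      sqrt(sum(vapply(tree_flatten(params), function(w) sum(w^2), 0)))
  }
  loss
}

#' Area under the ROC curve
#'
#' Rank-based (Wilcoxon) estimator: the probability that a random positive
#' outscores a random negative, ties counted one half.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in [0,1].
#' @export
evaluate_auc <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  assert_that(n1 > 0 && n0 > 0, "one_class",
              "AUC needs both classes in the test set")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

deep_copy_bn <- function(bn) as.list(bn)
restore_bn <- function(model, snapshot) {
  rm(list = ls(model$bn), envir = model$bn)
  for (k in names(snapshot)) assign(k, snapshot[[k]], envir = model$bn)
}

#' Train a binding model
#'
#' Adam with linear learning-rate warm-up, mini-batch shuffling, early
#' stopping on validation loss, and restoration of the best-validation
#' checkpoint. Fully reproducible under `cfg$seed`.
#'
#' @param model a `bindnet` (modified in place and returned).
#' @param splits list with `train` and `validation` `fixed_samples`.
#' @param cfg a [train_config()].
#' @param verbose print one line per epoch.
#' @return list with `model` and `history` (class `train_history`:
#'   data.frame epoch/train_loss/val_loss/val_auc plus attributes
#'   `stopped_epoch`, `best_epoch`).
#' @export
train_bindnet <- function(model, splits, cfg = train_config(),
                          verbose = FALSE) {
  tr <- splits$train; va <- splits$validation
  assert_that(length(tr) > 0 && length(va) > 0, "empty_split",
              "train and validation sets must be non-empty")
  n <- length(tr)
  steps_per_epoch <- ceiling(n / cfg$batch_size)
  warmup <- cfg$warmup_steps %||% steps_per_epoch
  flat <- tree_flatten(model$params)
  opt <- adam_init(flat, lr = cfg$learning_rate,
                   weight_decay = cfg$weight_decay, warmup_steps = warmup)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), val_auc = numeric(0))
  best <- list(loss = Inf, epoch = 0L, params = NULL, bn = NULL)
  wait <- 0L
  stopped <- cfg$max_epochs
  withr::with_seed(cfg$seed, {
    # pre-tokenize once: ids and structure never change across epochs
    inp_tr <- prepare_inputs(model, tr)
    inp_va <- prepare_inputs(model, va)
    y_tr <- tr$label
    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample.int(n)
      tl <- 0
      for (s in seq(1L, n, by = cfg$batch_size)) {
        i <- perm[s:min(s + cfg$batch_size - 1L, n)]
        fw <- bindnet_fwd(model, inp_tr$ids[i, , drop = FALSE],
                          inp_tr$struct_tok[i, , drop = FALSE],
                          train = TRUE, grad = TRUE)
        y <- y_tr[i]
        loss <- bce_l2_loss(fw$p, y)
        if (!is.finite(loss)) {
          bn_stop("divergence", "non-finite training loss at epoch %d", epoch)
        }
        tl <- tl + loss * length(i)
        d_logit <- matrix((fw$p - y) / length(i), ncol = 1L)
        bw <- bindnet_bwd(model, fw, d_logit)
        flat <- adam_step(opt, tree_flatten(model$params),
                          tree_flatten(bw$grads))
        model$params <- tree_unflatten(model$params, flat)
      }
      train_loss <- tl / n
      p_va <- predict_batched(model, inp_va)
      val_loss <- bce_l2_loss(p_va, va$label)
      val_auc <- evaluate_auc(p_va, va$label)
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = train_loss,
                                     val_loss = val_loss, val_auc = val_auc))
      if (verbose) {
        message(sprintf("epoch %d: train %.4f  val %.4f  auc %.4f",
                        epoch, train_loss, val_loss, val_auc))
      }
      if (val_loss < best$loss - 1e-9) {
        best <- list(loss = val_loss, epoch = epoch, params = model$params,
                     bn = deep_copy_bn(model$bn))
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) { stopped <- epoch; break }
      }
      stopped <- epoch
    }
  })
  if (!is.null(best$params)) {
    model$params <- best$params
    restore_bn(model, best$bn)
  }
  attr(hist, "stopped_epoch") <- stopped
  attr(hist, "best_epoch") <- best$epoch
  attr(hist, "final_lr") <- opt$last_lr
  class(hist) <- c("train_history", "data.frame")
  list(model = model, history = hist)
}

# evaluation-mode prediction over pre-tokenized inputs
predict_batched <- function(model, inp, batch_size = 64L) {
  n <- nrow(inp$ids)
  out <- numeric(n)
  for (s in seq(1L, n, by = batch_size)) {
    i <- s:min(s + batch_size - 1L, n)
    out[i] <- bindnet_fwd(model, inp$ids[i, , drop = FALSE],
                          inp$struct_tok[i, , drop = FALSE],
                          train = FALSE)$p
  }
  out
}
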