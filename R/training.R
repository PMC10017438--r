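# Dual-mode training.  Each batch is a contiguous run of 30-s epochs from
# one PSG.  Both heads (context-free and GRU context) are evaluated from a
# single shared-trunk forward pass; both losses are backpropagated and the
# weights updated once per batch.  The GRU hidden state is carried
# (detached) across batches within a PSG and zeroed at PSG start.

#' Training configuration
#'
#' @param class_weights loss weights per stage.  The defaults
#'   `W:1, N1:2.4, N2:1, N3:1.2, REM:1.4` counteract the severe stage
#'   imbalance of overnight sleep (N1 in particular is rare and hard).
#' @param lr AdamW learning rate (default 3e-5).
#' @param beta1,beta2,eps AdamW moment coefficients.
#' @param weight_decay decoupled weight decay applied to weight matrices
#'   (not biases or normalization parameters).
#' @param n_epochs training epochs (passes over the training set).
#' @param batches_per_psg number of contiguous batches each PSG is divided
#'   into (reduced automatically for short PSGs).
#' @param polarity_flips train on polarity-flipped permutations too?
#' @param fwd_only_p fraction of batches on which the context head is
#'   trained with its forward direction only ("direction dropout"), so that
#'   forward/streaming inference sees representations it was trained on.
#' @param clip_norm optional global gradient-norm clip applied per batch
#'   (`NULL` disables; the desk-scale configuration uses 1).  Stabilizes
#'   recurrent training against rare exploding updates.
#' @param seed RNG seed controlling initialization, PSG order and dropout.
#' @return A list of class `train_config`.
#' @export
train_config <- function(class_weights = c(W = 1, N1 = 2.4, N2 = 1,
                                           N3 = 1.2, REM = 1.4),
                         lr = 3e-5, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         weight_decay = 1e-2, n_epochs = 20L,
                         batches_per_psg = 128L, polarity_flips = TRUE,
                         fwd_only_p = 0.25, clip_norm = NULL, seed = 1L) {
  stopifnot(all(class_weights > 0), setequal(names(class_weights), STAGES),
            lr > 0, batches_per_psg >= 1, n_epochs >= 1)
  structure(list(class_weights = class_weights[STAGES], lr = lr,
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 weight_decay = weight_decay, n_epochs = as.integer(n_epochs),
                 batches_per_psg = as.integer(batches_per_psg),
                 polarity_flips = isTRUE(polarity_flips),
                 fwd_only_p = fwd_only_p, clip_norm = clip_norm,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Desk-scale training configuration
#'
#' Companion to [reduced_model_config()]: a configuration for training the
#' reduced model on short synthetic nights in minutes on one CPU.  Compared
#' with the full-scale defaults it uses a larger learning rate (1e-3; the
#' 3e-5 default is calibrated to thousands of full nights), 5 training
#' epochs, 5 contiguous batches per 100-epoch night (about 20 epochs per
#' batch), and no polarity-flip augmentation (montage robustness is not the
#' point of desk-scale runs).
#'
#' @param ... overrides passed to [train_config()].
#' @export
reduced_train_config <- function(...) {
  args <- list(lr = 1e-3, n_epochs = 5L, batches_per_psg = 5L,
               polarity_flips = FALSE, clip_norm = 1)
  args[names(list(...))] <- list(...)
  do.call(train_config, args)
}

#' Class-weighted cross-entropy
#'
#' `loss = sum_i w(y_i) * (-log p_i(y_i)) / sum_i w(y_i)` (weighted-mean
#' reduction), or the per-sample terms `w(y_i) * (-log p_i(y_i))` when
#' `reduce = FALSE`.
#'
#' @param log_probs matrix `5 x n` of log-probabilities (stage order
#'   W, N1, N2, N3, REM).
#' @param targets stage labels (character) or codes 1..5; `UNKNOWN` targets
#'   are an error and must be masked upstream.
#' @param weights named per-stage weights.
#' @param reduce return the weighted mean (default) or per-sample terms.
#' @export
weighted_cross_entropy <- function(log_probs,
                                   targets,
                                   weights = c(W = 1, N1 = 2.4, N2 = 1,
                                               N3 = 1.2, REM = 1.4),
                                   reduce = TRUE) {
  log_probs <- as.matrix(log_probs)
  if (is.character(targets) || is_hypnogram(targets))
    targets <- match(as.character(targets), STAGES)
  if (anyNA(targets))
    stop("targets contain UNKNOWN/invalid stages; mask them before the loss")
  if (length(targets) != ncol(log_probs))
    stop("batch size mismatch between log_probs and targets")
  w <- unname(weights[STAGES][targets])
  nll <- -log_probs[cbind(targets, seq_along(targets))]
  if (!reduce) return(w * nll)
  sum(w * nll) / sum(w)
}

# Gradient of the reduced weighted CE w.r.t. logits; columns with NA target
# (masked epochs) get zero gradient.
wce_grad_logits <- function(log_probs, targets, weights) {
  p <- exp(log_probs)
  n <- ncol(log_probs)
  g <- matrix(0, nrow(log_probs), n)
  valid <- !is.na(targets)
  if (!any(valid)) return(g)
  w <- unname(weights[STAGES][targets])
  wsum <- sum(w[valid])
  for (i in which(valid)) {
    gi <- p[, i]
    gi[targets[i]] <- gi[targets[i]] - 1
    g[, i] <- gi * (w[i] / wsum)
  }
  g
}

#' Split a PSG into contiguous batches
#'
#' Partitions epochs `1..n` into `n_batches` contiguous runs whose sizes
#' differ by at most one, preserving temporal order.  If the PSG has fewer
#' epochs than `n_batches` the batch count is reduced (with a message).
#'
#' @param n_ep number of epochs (or an `epoched_signals` object).
#' @param n_batches requested number of batches.
#' @return List of integer index vectors.
#' @export
make_batches <- function(n_ep, n_batches = 128L) {
  if (inherits(n_ep, "epoched_signals")) n_ep <- n_epochs(n_ep)
  n_ep <- as.integer(n_ep)
  if (n_ep < 1) stop("empty PSG: no epochs to batch")
  if (n_batches > n_ep) {
    message("reducing n_batches from ", n_batches, " to ", n_ep)
    n_batches <- n_ep
  }
  base <- n_ep %/% n_batches
  rem <- n_ep %% n_batches
  sizes <- c(rep(base + 1L, rem), rep(base, n_batches - rem))
  ends <- cumsum(sizes)
  mapply(function(a, b) seq.int(a, b), ends - sizes + 1L, ends,
         SIMPLIFY = FALSE)
}

## ---- AdamW -------------------------------------------------------------

new_adamw_state <- function() {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st
}

# Decoupled weight decay on weight matrices only (biases and normalization
# parameters are left undecayed, the usual convention).
adamw_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  b1 <- cfg$beta1; b2 <- cfg$beta2
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  for (name in ls(grads)) {
    g <- grads[[name]]
    mkey <- paste0("m.", name); vkey <- paste0("v.", name)
    m <- state[[mkey]]; v <- state[[vkey]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    state[[mkey]] <- m; state[[vkey]] <- v
    upd <- (m / bc1) / (sqrt(v / bc2) + cfg$eps)
    p <- params[[name]]
    if (cfg$weight_decay > 0 && is.matrix(p))
      p <- p - cfg$lr * cfg$weight_decay * p
    params[[name]] <- p - cfg$lr * upd
  }
  invisible(NULL)
}

clip_gradients <- function(grads, max_norm) {
  total <- 0
  for (name in ls(grads)) total <- total + sum(grads[[name]]^2)
  total <- sqrt(total)
  if (total > max_norm) {
    sc <- max_norm / total
    for (name in ls(grads)) grads[[name]] <- grads[[name]] * sc
  }
  invisible(total)
}

zero_grads <- function(grads) {
  rm(list = ls(grads), envir = grads)
  invisible(NULL)
}

## ---- training loop -----------------------------------------------------

perms_for_epochs <- function(epochs, polarity_flips) {
  eeg <- epochs$channel_names[epochs$channel_roles[epochs$channel_names] ==
                                "EEG"]
  has_eog <- "HEOG" %in% epochs$channel_names
  enumerate_permutations(eeg, has_eog, polarity_flips)
}

subset_epochs <- function(x, idx) {
  if (is.null(x)) return(NULL)
  x[, , idx, drop = FALSE]
}

# One batch, one permutation: shared trunk forward, both heads' losses,
# single backward + optimizer step.  Returns the summed loss and the
# detached GRU hidden states to carry into the next batch.
train_batch <- function(model, inp, targets, hf, hb, tcfg, grads, opt) {
  tr <- trunk_fwd(model, inp$eeg, inp$eog, training = TRUE)
  cf <- cf_fwd(model, tr$y, training = TRUE)
  bidir <- runif(1) >= tcfg$fwd_only_p
  cx <- ctx_fwd_seq(model, tr$y, h0f = hf, h0b = hb, training = TRUE,
                    bidir = bidir)
  valid <- !is.na(targets)
  loss <- NA_real_
  if (any(valid)) {
    loss <- weighted_cross_entropy(cf$logp[, valid, drop = FALSE],
                                   targets[valid], tcfg$class_weights) +
            weighted_cross_entropy(cx$logp[, valid, drop = FALSE],
                                   targets[valid], tcfg$class_weights)
    if (!is.finite(loss))
      stop("non-finite training loss; aborting (check inputs/learning rate)")
    g_cf <- wce_grad_logits(cf$logp, targets, tcfg$class_weights)
    g_cx <- wce_grad_logits(cx$logp, targets, tcfg$class_weights)
    gmix <- cf_bwd(model, cf$cache, g_cf, grads) +
            ctx_bwd_seq(model, cx$cache, g_cx, grads)
    trunk_bwd(model, tr$cache, gmix, grads)
    if (!is.null(tcfg$clip_norm)) clip_gradients(grads, tcfg$clip_norm)
    adamw_step(model$params, grads, opt, tcfg)
    zero_grads(grads)
  }
  list(loss = loss, hf = cx$hTf, hb = if (bidir) cx$hTb else hb)
}

#' One training epoch over a set of PSGs
#'
#' Visits PSGs in random order; for each PSG and each signal permutation,
#' traverses the contiguous batches sequentially with the GRU hidden state
#' carried across batches (zeroed at PSG start), computing both heads'
#' losses from one shared forward pass and stepping the optimizer once per
#' batch.
#'
#' @param model a `somnostage_model` (updated in place; also returned).
#' @param psgs list of `list(epochs = <epoched_signals>, hypnogram =
#'   <hypnogram>)` pairs, e.g. from [preprocess_psg()].
#' @param tcfg a [train_config()].
#' @param opt optimizer state from `new_adamw_state()`.
#' @return List with the updated `model` and the mean batch `loss`.
#' @export
train_epoch <- function(model, psgs, tcfg, opt) {
  grads <- new_grad_env()
  losses <- c()
  for (pi in sample.int(length(psgs))) {
    psg <- psgs[[pi]]
    codes <- stage_codes(psg$hypnogram)
    batches <- make_batches(n_epochs(psg$epochs), tcfg$batches_per_psg)
    perms <- perms_for_epochs(psg$epochs, tcfg$polarity_flips)
    for (perm in perms) {
      full <- apply_permutation(psg$epochs, perm)
      hf <- matrix(0, model$cfg$gru_hidden, 1)
      hb <- matrix(0, model$cfg$gru_hidden, 1)
      for (idx in batches) {
        inp <- list(eeg = subset_epochs(full$eeg, idx),
                    eog = subset_epochs(full$eog, idx))
        r <- train_batch(model, inp, codes[idx], hf, hb, tcfg, grads, opt)
        hf <- r$hf; hb <- r$hb
        losses <- c(losses, r$loss)
      }
    }
  }
  list(model = model, loss = mean(losses, na.rm = TRUE))
}

## ---- checkpoint selection and weight averaging -------------------------

snapshot_checkpoint <- function(model, epoch, mcc = NA, f1_macro = NA) {
  list(params = as.list(model$params, sorted = TRUE),
       buffers = as.list(model$buffers, sorted = TRUE),
       epoch = epoch, mcc = mcc, f1_macro = f1_macro)
}

#' Select checkpoints balancing MCC and macro F1
#'
#' Ranks epochs by the sum of their MCC rank and macro-F1 rank (higher is
#' better) and returns the indices of the top `k`; ties go to the later
#' epoch.
#'
#' @param history list of checkpoints with `mcc` and `f1_macro` fields.
#' @param k number of checkpoints to select.
#' @return Integer indices into `history`, best first.
#' @export
select_checkpoints <- function(history, k = 3L) {
  if (!length(history)) stop("empty checkpoint history")
  if (k > length(history))
    stop("cannot select ", k, " checkpoints from ", length(history))
  mcc <- vapply(history, `[[`, numeric(1), "mcc")
  f1 <- vapply(history, `[[`, numeric(1), "f1_macro")
  score <- rank(mcc, ties.method = "average") +
           rank(f1, ties.method = "average")
  ord <- order(score, seq_along(history), decreasing = TRUE)
  ord[seq_len(k)]
}

#' Elementwise average of checkpoint weights
#'
#' @param checkpoints list of checkpoints (from identical architectures).
#' @return List with `params` and `buffers` holding the arithmetic means.
#' @export
average_weights <- function(checkpoints) {
  stopifnot(length(checkpoints) >= 1)
  avg_lists <- function(field) {
    ref <- checkpoints[[1]][[field]]
    out <- ref
    for (name in names(ref)) {
      acc <- ref[[name]]
      for (ck in checkpoints[-1]) {
        other <- ck[[field]][[name]]
        if (is.null(other) || !identical(dim(other), dim(acc)) ||
            length(other) != length(acc))
          stop("checkpoint parameter shape mismatch for ", name)
        acc <- acc + other
      }
      out[[name]] <- acc / length(checkpoints)
    }
    out
  }
  list(params = avg_lists("params"), buffers = avg_lists("buffers"))
}

restore_weights <- function(model, weights) {
  for (name in names(weights$params)) model$params[[name]] <- weights$params[[name]]
  for (name in names(weights$buffers)) model$buffers[[name]] <- weights$buffers[[name]]
  model
}

#' Train a sleep stage classifier
#'
#' Full training procedure: initializes a model, runs `n_epochs` training
#' epochs, optionally evaluates each epoch on validation PSGs (median
#' per-PSG MCC and macro F1, bidirectional inference on the first
#' EEG+EOG permutation), selects the best `select_k` checkpoints by rank sum
#' of the two metrics and averages their weights.
#'
#' @param train_psgs,val_psgs lists of `list(epochs=, hypnogram=)` pairs.
#' @param tcfg a [train_config()].
#' @param mcfg a [model_config()].
#' @param pre_cfg the [preprocess_config()] the data were prepared with.
#' @param select_k checkpoints to average (0 or `NULL` to keep the final
#'   epoch; requires validation data).
#' @param verbose print per-epoch progress.
#' @return List with `model`, `history` (per-epoch loss and validation
#'   metrics), and `selected` (indices of the averaged epochs, if any).
#' @export
fit_model <- function(train_psgs, val_psgs = NULL, tcfg = train_config(),
                      mcfg = model_config(), pre_cfg = preprocess_config(),
                      select_k = if (is.null(val_psgs)) 0L else 3L,
                      verbose = FALSE) {
  set.seed(tcfg$seed)
  model <- init_model(mcfg, pre_cfg)
  opt <- new_adamw_state()
  history <- list()
  ckpts <- list()
  for (e in seq_len(tcfg$n_epochs)) {
    r <- train_epoch(model, train_psgs, tcfg, opt)
    model <- r$model
    mcc <- f1 <- NA_real_
    if (!is.null(val_psgs)) {
      ev <- evaluate_psgs(model, val_psgs, mode = "bidirectional")
      mcc <- ev$mcc; f1 <- ev$f1_macro
    }
    history[[e]] <- list(epoch = e, loss = r$loss, mcc = mcc, f1_macro = f1)
    if (!is.null(val_psgs) && select_k > 0)
      ckpts[[e]] <- snapshot_checkpoint(model, e, mcc, f1)
    if (verbose)
      message(sprintf("epoch %d: loss=%.4f mcc=%.3f f1_macro=%.3f",
                      e, r$loss, mcc, f1))
  }
  selected <- NULL
  if (length(ckpts) && select_k > 0) {
    selected <- select_checkpoints(ckpts, min(select_k, length(ckpts)))
    model <- restore_weights(model, average_weights(ckpts[selected]))
  }
  list(model = model, history = history, selected = selected)
}

#' Median per-PSG validation metrics
#'
#' Scores each PSG with [infer()] (first EEG+EOG permutation, or the first
#' available permutation) and reports the median per-PSG MCC and macro F1.
#'
#' @param model a `somnostage_model`.
#' @param psgs list of `list(epochs=, hypnogram=)` pairs.
#' @param mode inference mode (see [infer()]).
#' @export
evaluate_psgs <- function(model, psgs, mode = "bidirectional") {
  mccs <- f1s <- accs <- numeric(length(psgs))
  for (i in seq_along(psgs)) {
    perms <- perms_for_epochs(psgs[[i]]$epochs, polarity_flips = FALSE)
    perm <- perms[[length(perms)]]   # combined EEG+EOG view if available
    res <- infer(model, psgs[[i]]$epochs, perm, mode = mode)
    cm <- confusion(psgs[[i]]$hypnogram, res$hypnogram)
    mccs[i] <- mcc(cm)
    f1s[i] <- f1_macro(cm)
    accs[i] <- accuracy(cm)
  }
  list(mcc = median(mccs), f1_macro = median(f1s), accuracy = median(accs),
       per_psg = data.frame(mcc = mccs, f1_macro = f1s, accuracy = accs))
}
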