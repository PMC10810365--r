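# Training loop: per batch, every cell line's features are encoded, translated
# to every cell line (all ordered pairs, including self), and reconstructed
# back through the reverse map to close the cycle; the three loss components
# are combined into one total and a single SGD-momentum step is taken on the
# summed gradient.  The learning rate decays by a fixed factor every
# `decay_every` optimizer steps, and early stopping monitors a held-out value.

#' Training configuration
#'
#' Defaults: base learning rate 0.01 decaying by 5% every 500 optimizer
#' steps, momentum 0.95, weight decay 1e-5, batch size 128, up to 5000
#' epochs with early-stopping patience of 300 epochs on the held-out total
#' loss.
#'
#' @param base_lr Initial learning rate.
#' @param lr_decay Multiplicative decay factor per decay interval.
#' @param decay_every Optimizer steps (or epochs, see `decay_unit`) between
#'   decays.
#' @param momentum Classical momentum coefficient in `[0, 1)`.
#' @param weight_decay L2 weight-decay coefficient.
#' @param batch_size Proteins per optimizer step.
#' @param max_epochs Hard cap on training epochs.
#' @param patience Consecutive epochs without held-out improvement before
#'   stopping.
#' @param monitor Held-out quantity to monitor: total loss or the prediction
#'   component alone.
#' @param normalization Pair-sum normalization of the prediction and cycle
#'   losses (see [prediction_loss()]).
#' @param decay_unit Whether `decay_every` counts optimizer steps (default)
#'   or epochs.
#' @param shuffle Reshuffle proteins every epoch.
#' @param seed Integer seed governing shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(base_lr = 0.01, lr_decay = 0.95, decay_every = 500L,
                         momentum = 0.95, weight_decay = 1e-5,
                         batch_size = 128L, max_epochs = 5000L,
                         patience = 300L,
                         monitor = c("total_loss", "l1"),
                         normalization = c("n", "n2"),
                         decay_unit = c("step", "epoch"),
                         shuffle = TRUE, seed = 1L) {
  monitor <- match.arg(monitor)
  normalization <- match.arg(normalization)
  decay_unit <- match.arg(decay_unit)
  if (!is_number(base_lr) || base_lr < 0) {
    abort_cycletsa("`base_lr` must be >= 0.", "cycletsa_argument_error")
  }
  if (!is_number(lr_decay) || lr_decay <= 0 || lr_decay > 1) {
    abort_cycletsa("`lr_decay` must lie in (0, 1].", "cycletsa_argument_error")
  }
  if (!is_number(momentum) || momentum < 0 || momentum >= 1) {
    abort_cycletsa("`momentum` must lie in [0, 1).", "cycletsa_argument_error")
  }
  if (!is_count(batch_size) || !is_count(max_epochs) || !is_count(patience) ||
      !is_count(decay_every)) {
    abort_cycletsa(
      "`batch_size`, `max_epochs`, `patience`, `decay_every` must be positive integers.",
      "cycletsa_argument_error")
  }
  if (!is_number(weight_decay) || weight_decay < 0) {
    abort_cycletsa("`weight_decay` must be >= 0.", "cycletsa_argument_error")
  }
  structure(list(base_lr = base_lr, lr_decay = lr_decay,
                 decay_every = as.integer(decay_every), momentum = momentum,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), monitor = monitor,
                 normalization = normalization, decay_unit = decay_unit,
                 shuffle = isTRUE(shuffle), seed = check_seed(seed)),
            class = "train_config")
}

#' Learning rate after a given number of optimizer steps
#'
#' `base_lr * lr_decay ^ floor(step / decay_every)`.
#'
#' @param step Optimizer step count (>= 0).
#' @param config A [train_config()].
#' @return The learning rate.
#' @export
#' @examples
#' lr_at(0, train_config())     # 0.01
#' lr_at(500, train_config())   # 0.0095
#' lr_at(1499, train_config())  # 0.009025
lr_at <- function(step, config = train_config()) {
  if (!is.numeric(step) || any(step < 0) || any(step != trunc(step))) {
    abort_cycletsa("`step` must be a non-negative integer.",
                   "cycletsa_argument_error")
  }
  config$base_lr * config$lr_decay^(step %/% config$decay_every)
}

zero_like <- function(params) {
  lapply(params, function(l) list(W = l$W * 0, b = l$b * 0))
}

add_into <- function(acc, grads) {
  for (l in seq_along(acc)) {
    acc[[l]]$W <- acc[[l]]$W + grads[[l]]$W
    acc[[l]]$b <- acc[[l]]$b + grads[[l]]$b
  }
  acc
}

# Forward the full cyclic graph for one aligned batch and, if `with_grads`,
# backpropagate the weighted total loss into per-module parameter gradients.
cycle_pass <- function(bundle, X_list, weights, normalization = "n",
                       training = FALSE, with_grads = FALSE) {
  n <- length(X_list)
  enc <- bundle$encoders
  dec <- bundle$decoders
  espec <- bundle$encoder_spec
  dspec <- bundle$decoder_spec
  B <- nrow(X_list[[1L]])
  f_width <- ncol(X_list[[1L]])
  keep <- with_grads

  enc_fw <- lapply(seq_len(n), function(i) {
    forward_stack(enc[[i]], espec, X_list[[i]], training = training,
                  keep_cache = keep)
  })
  Z <- lapply(enc_fw, function(x) if (keep) x$out else x)

  dec1 <- vector("list", n)   # decode(j, Z_i): translations
  enc2 <- vector("list", n)   # encode(j, translation)
  dec2 <- vector("list", n)   # decode(i, .): cycle reconstructions
  l1 <- 0; l2 <- 0
  for (i in seq_len(n)) {
    dec1[[i]] <- vector("list", n)
    enc2[[i]] <- vector("list", n)
    dec2[[i]] <- vector("list", n)
    for (j in seq_len(n)) {
      d1 <- forward_stack(dec[[j]], dspec, Z[[i]], training = training,
                          keep_cache = keep)
      yhat <- if (keep) d1$out else d1
      e2 <- forward_stack(enc[[j]], espec, yhat, training = training,
                          keep_cache = keep)
      z2 <- if (keep) e2$out else e2
      d2 <- forward_stack(dec[[i]], dspec, z2, training = training,
                          keep_cache = keep)
      xrec <- if (keep) d2$out else d2
      dec1[[i]][[j]] <- d1; enc2[[i]][[j]] <- e2; dec2[[i]][[j]] <- d2
      l1 <- l1 + mean((yhat - X_list[[j]])^2)
      l2 <- l2 + mean((xrec - X_list[[i]])^2)
    }
  }
  norm <- loss_norm(n, normalization)
  l1 <- l1 / norm
  l2 <- l2 / norm
  l3 <- latent_loss(Z)
  breakdown <- total_loss(l1, l2, l3, weights, n_cell_lines = n,
                          batch_size = B)
  if (!with_grads) return(list(breakdown = breakdown))

  g_enc <- lapply(enc, zero_like)
  g_dec <- lapply(dec, zero_like)
  dZ <- lapply(Z, function(z) z * 0)
  latent_dim <- ncol(Z[[1L]])
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      yhat <- dec1[[i]][[j]]$out
      xrec <- dec2[[i]][[j]]$out
      d_xrec <- weights$alpha2 * 2 * (xrec - X_list[[i]]) / (B * f_width * norm)
      bk2 <- backward_stack(dec[[i]], dspec, dec2[[i]][[j]]$cache, d_xrec)
      g_dec[[i]] <- add_into(g_dec[[i]], bk2$grads)
      bk_e2 <- backward_stack(enc[[j]], espec, enc2[[i]][[j]]$cache, bk2$d_in)
      g_enc[[j]] <- add_into(g_enc[[j]], bk_e2$grads)
      d_yhat <- bk_e2$d_in +
        weights$alpha1 * 2 * (yhat - X_list[[j]]) / (B * f_width * norm)
      bk1 <- backward_stack(dec[[j]], dspec, dec1[[i]][[j]]$cache, d_yhat)
      g_dec[[j]] <- add_into(g_dec[[j]], bk1$grads)
      dZ[[i]] <- dZ[[i]] + bk1$d_in
    }
  }
  Z_sum <- Reduce(`+`, Z)
  for (i in seq_len(n)) {
    dZ[[i]] <- dZ[[i]] + weights$alpha3 * 4 *
      (n * Z[[i]] - Z_sum) / (n^2 * B * latent_dim)
    bk <- backward_stack(enc[[i]], espec, enc_fw[[i]]$cache, dZ[[i]])
    g_enc[[i]] <- add_into(g_enc[[i]], bk$grads)
  }
  list(breakdown = breakdown, g_enc = g_enc, g_dec = g_dec)
}

new_opt_state <- function(bundle) {
  list(step = 0L,
       v_enc = lapply(bundle$encoders, zero_like),
       v_dec = lapply(bundle$decoders, zero_like))
}

sgd_update <- function(params, grads, velocity, lr, momentum, weight_decay) {
  for (l in seq_along(params)) {
    gW <- grads[[l]]$W + weight_decay * params[[l]]$W
    gb <- grads[[l]]$b + weight_decay * params[[l]]$b
    velocity[[l]]$W <- momentum * velocity[[l]]$W - lr * gW
    velocity[[l]]$b <- momentum * velocity[[l]]$b - lr * gb
    params[[l]]$W <- params[[l]]$W + velocity[[l]]$W
    params[[l]]$b <- params[[l]]$b + velocity[[l]]$b
  }
  list(params = params, velocity = velocity)
}

#' Run one training epoch over aligned batches
#'
#' Shuffles the aligned proteins (using the current RNG stream), chops them
#' into batches, and takes one SGD-momentum step per batch on the weighted
#' total loss with training-mode dropout active.
#'
#' @param bundle A `cycle_bundle`.
#' @param train_matrices List of aligned feature matrices, one per cell line
#'   in bundle order (equal row counts, rows aligned by protein).
#' @param weights A [loss_weights()].
#' @param config A [train_config()].
#' @param state Optimizer state from a previous call, or `NULL` to start
#'   fresh.
#' @param epoch Epoch number (used only when `decay_unit = "epoch"`).
#' @return A list with the updated `bundle`, the epoch-mean `losses`
#'   (`loss_breakdown`), the final `lr`, and the optimizer `state`.
#' @export
epoch_pass <- function(bundle, train_matrices, weights = loss_weights(),
                       config = train_config(), state = NULL, epoch = 1L) {
  stopifnot(inherits(bundle, "cycle_bundle"))
  n <- length(bundle$cell_lines)
  if (length(train_matrices) != n) {
    abort_cycletsa("One training matrix per bundle cell line is required.",
                   "cycletsa_alignment_error")
  }
  n_rows <- vapply(train_matrices, nrow, integer(1))
  if (length(unique(n_rows)) != 1L || n_rows[1L] == 0L) {
    abort_cycletsa("Training matrices must be non-empty and row-aligned.",
                   "cycletsa_alignment_error")
  }
  state <- state %||% new_opt_state(bundle)
  idx <- seq_len(n_rows[1L])
  if (config$shuffle) idx <- sample(idx)
  starts <- seq(1L, length(idx), by = config$batch_size)
  sums <- c(l1 = 0, l2 = 0, l3 = 0)
  n_seen <- 0L
  lr <- lr_at(state$step, config)
  for (s in starts) {
    rows <- idx[s:min(s + config$batch_size - 1L, length(idx))]
    X <- lapply(train_matrices, function(m) m[rows, , drop = FALSE])
    pass <- cycle_pass(bundle, X, weights, config$normalization,
                       training = TRUE, with_grads = TRUE)
    lr <- lr_at(switch(config$decay_unit, step = state$step,
                       epoch = epoch - 1L), config)
    for (i in seq_len(n)) {
      up <- sgd_update(bundle$encoders[[i]], pass$g_enc[[i]],
                       state$v_enc[[i]], lr, config$momentum,
                       config$weight_decay)
      bundle$encoders[[i]] <- up$params
      state$v_enc[[i]] <- up$velocity
      up <- sgd_update(bundle$decoders[[i]], pass$g_dec[[i]],
                       state$v_dec[[i]], lr, config$momentum,
                       config$weight_decay)
      bundle$decoders[[i]] <- up$params
      state$v_dec[[i]] <- up$velocity
    }
    state$step <- state$step + 1L
    w <- length(rows)
    sums <- sums + w * c(pass$breakdown$l1, pass$breakdown$l2,
                         pass$breakdown$l3)
    n_seen <- n_seen + w
  }
  means <- sums / n_seen
  list(bundle = bundle,
       losses = total_loss(means[["l1"]], means[["l2"]], means[["l3"]],
                           weights, n_cell_lines = n,
                           batch_size = config$batch_size),
       lr = lr, state = state)
}

# Held-out loss in evaluation mode (no dropout, deterministic).
validation_losses <- function(bundle, matrices, weights, normalization) {
  cycle_pass(bundle, matrices, weights, normalization,
             training = FALSE, with_grads = FALSE)$breakdown
}

#' Train a cyclic autoencoder bundle on an aligned multipanel
#'
#' Runs [epoch_pass()] until `max_epochs` or until the monitored held-out
#' value has not improved for `patience` consecutive epochs, and returns the
#' parameters of the best monitored epoch.  Shuffling, dropout and batching
#' are all driven by `config$seed`, so identical inputs yield identical
#' training runs.
#'
#' @param bundle A `cycle_bundle` whose cell lines match the multipanel.
#' @param multipanel A split `cetsa_multipanel` (see [split_dataset()]).
#' @param weights A [loss_weights()].
#' @param config A [train_config()].
#' @param verbose Print a progress line every 25 epochs.
#' @return A `cycle_fit` list: `bundle` (best checkpoint), `history` (tibble
#'   with per-epoch train components, held-out monitor and learning rate),
#'   `best_epoch`, `monitor`.
#' @export
train <- function(bundle, multipanel, weights = loss_weights(),
                  config = train_config(), verbose = FALSE) {
  stopifnot(inherits(bundle, "cycle_bundle"),
            inherits(multipanel, "cetsa_multipanel"))
  if (!setequal(bundle$cell_lines, multipanel$cell_lines)) {
    abort_cycletsa("Bundle and multipanel cell lines differ.",
                   "cycletsa_configuration_error")
  }
  train_acc <- split_accessions(multipanel, "train")
  if (length(train_acc) == 0L) {
    abort_cycletsa("The training split is empty.", "cycletsa_data_error")
  }
  test_acc <- split_accessions(multipanel, "test")
  train_m <- lapply(bundle$cell_lines, function(cl) {
    panel_matrix(multipanel, cl, train_acc)
  })
  val_m <- if (length(test_acc) > 0L) {
    lapply(bundle$cell_lines, function(cl) {
      panel_matrix(multipanel, cl, test_acc)
    })
  } else {
    train_m  # degenerate: monitor the training set
  }

  run <- withr::with_seed(config$seed, {
    state <- NULL
    best_val <- Inf
    best_bundle <- bundle
    best_epoch <- 0L
    since_best <- 0L
    hist <- vector("list", config$max_epochs)
    t0 <- Sys.time()
    n_epochs <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      ep <- epoch_pass(bundle, train_m, weights, config, state, epoch = epoch)
      bundle <- ep$bundle
      state <- ep$state
      val <- validation_losses(bundle, val_m, weights, config$normalization)
      monitored <- switch(config$monitor, total_loss = val$total, l1 = val$l1)
      improved <- monitored < best_val
      if (improved) {
        best_val <- monitored
        best_bundle <- bundle
        best_epoch <- epoch
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
      }
      hist[[epoch]] <- tibble::tibble(
        epoch = epoch, l1 = ep$losses$l1, l2 = ep$losses$l2,
        l3 = ep$losses$l3, total = ep$losses$total, lr = ep$lr,
        val = monitored, best = improved,
        elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
      n_epochs <- epoch
      if (verbose && epoch %% 25L == 0L) {
        message(sprintf("epoch %4d  train %.5g  val %.5g  lr %.4g", epoch,
                        ep$losses$total, monitored, ep$lr))
      }
      if (since_best >= config$patience) break
    }
    list(bundle = best_bundle, best_epoch = best_epoch,
         history = do.call(rbind, hist[seq_len(n_epochs)]))
  })

  structure(list(bundle = run$bundle, history = run$history,
                 best_epoch = run$best_epoch, monitor = config$monitor,
                 config = config, weights = weights),
            class = "cycle_fit")
}

#' @export
print.cycle_fit <- function(x, ...) {
  cat(sprintf(
    "<cycle_fit> %d epochs (best at %d, monitored %s = %.6g)\n",
    nrow(x$history), x$best_epoch, x$monitor,
    min(x$history$val)))
  invisible(x)
}

#' Predict one cell line's panel from another
#'
#' Applies the trained translation map to the source cell line's profiles
#' and returns the prediction as a panel in the target cell line's feature
#' space (not constrained to be non-negative, since the decoder output layer
#' is affine).
#'
#' @param bundle A `cycle_bundle`.
#' @param multipanel A `cetsa_multipanel` containing the source cell line.
#' @param source,target Cell-line names.
#' @param part Optional split part (`"train"`/`"test"`) to restrict the
#'   prediction to; default all common proteins.
#' @return A `cetsa_panel` of predicted profiles.
#' @export
translate_panel <- function(bundle, multipanel, source, target, part = NULL) {
  acc <- if (is.null(part)) multipanel$common_index
         else split_accessions(multipanel, part)
  X <- panel_matrix(multipanel, source, acc)
  pred <- translate(bundle, source, target, X)
  rownames(pred) <- acc
  cell_line_panel(paste0(target, ".predicted_from.", source), pred,
                  multipanel$grid, nonnegative = FALSE)
}
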