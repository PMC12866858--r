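# Single-pair fitting loop: Adam on the weighted total loss, a per-epoch
# trace of both loss components, best-checkpoint retention by minimal edge
# loss, and early stopping once the edge loss has exceeded its running
# minimum a fixed total number of times.

#' Training configuration
#'
#' @param lr Adam learning rate.
#' @param max_epochs upper limit on training epochs.
#' @param stop_patience early stopping halts after this many total epochs
#'   (cumulative, never reset) whose edge loss exceeds its running minimum.
#' @param weights a [loss_weights]; both zero is rejected for training.
#' @param seed integer seed (parameter init is seeded separately in
#'   [build_network()]; the loop itself is deterministic).
#' @param checkpoint_every save a checkpoint every this many epochs when
#'   `checkpoint_dir` is set.
#' @param checkpoint_dir optional directory for per-epoch checkpoints.
#' @return an object of class `train_config`.
#' @export
train_config <- function(lr = 3e-4, max_epochs = 2000L, stop_patience = 5L,
                         weights = loss_weights(1, 1), seed = 1L,
                         checkpoint_every = 1L, checkpoint_dir = NULL) {
  if (!is.numeric(lr) || lr <= 0) stopf("lr must be positive")
  if (!is_count(max_epochs)) stopf("max_epochs must be a positive integer")
  if (!is_count(stop_patience)) stopf("stop_patience must be >= 1")
  if (!is_count(checkpoint_every)) stopf("checkpoint_every must be >= 1")
  stopifnot(inherits(weights, "loss_weights"))
  structure(list(lr = lr, max_epochs = as.integer(max_epochs),
                 stop_patience = as.integer(stop_patience),
                 weights = weights, seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every),
                 checkpoint_dir = checkpoint_dir),
            class = "train_config")
}

#' Early-stopping counter state
#'
#' @param patience halt once the cumulative count of edge-loss increases
#'   (epochs not improving on the running minimum) reaches this value.
#' @return a state list with `counter`, `best`, `patience`, `halt`.
#' @export
early_stop_state <- function(patience = 5L) {
  if (!is_count(patience)) stopf("patience must be >= 1")
  list(counter = 0L, best = Inf, patience = as.integer(patience),
       halt = FALSE)
}

#' Advance the early-stopping counter by one epoch
#'
#' If `l_edge` improves on the running minimum the minimum is updated and
#' the counter is unchanged; otherwise the counter increments.  `halt`
#' becomes `TRUE` when the counter reaches the patience.  The count is
#' cumulative over the whole run — it is never reset.
#'
#' @param state state from [early_stop_state()] or a previous update.
#' @param l_edge this epoch's edge perceptual loss.
#' @return the updated state.
#' @export
early_stop_update <- function(state, l_edge) {
  if (l_edge < state$best) {
    state$best <- l_edge
  } else {
    state$counter <- state$counter + 1L
  }
  state$halt <- state$counter >= state$patience
  state
}

adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

# One Adam step with the standard defaults (0.9, 0.999, eps 1e-8).
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

train_hash <- function(net, K, cfg) {
  config_hash(list(
    network = unclass(net$spec),
    kernel = list(name = K$name, weights = as.vector(K$weights)),
    train = list(lr = cfg$lr, max_epochs = cfg$max_epochs,
                 stop_patience = cfg$stop_patience,
                 w_mse = cfg$weights$w_mse, w_edge = cfg$weights$w_edge,
                 seed = cfg$seed)))
}

#' Fit the fusion network to one registered pair
#'
#' Per epoch: forward pass, loss components recorded, total-loss gradient
#' backpropagated, Adam step.  The running minimum of the edge perceptual
#' loss selects the best checkpoint (restored into the returned fused
#' image), and each epoch whose edge loss does not improve on that minimum
#' increments the cumulative early-stopping counter.  When the edge weight
#' is zero, the edge loss is still computed and recorded every epoch but its
#' gradient is never evaluated.
#'
#' @param net a `fusion_net` from [build_network()] or
#'   [build_cnn_baseline()].
#' @param pair a `registered_pair` from [validate_registration()].
#' @param K an [edge_kernel].
#' @param cfg a [train_config].
#' @param resume optional checkpoint (path or object from
#'   [load_checkpoint()]) to continue an interrupted run.
#' @return an object of class `fusion_fit`: `fused` (the [fused_image] at
#'   the best epoch), `trace` (per-epoch `loss_trace` data frame),
#'   `net_best`, `net_final`, and `config_hash`.
#' @export
train_fusion <- function(net, pair, K = edge_kernel(),
                         cfg = train_config(), resume = NULL) {
  stopifnot(inherits(net, "fusion_net"), inherits(pair, "registered_pair"),
            inherits(K, "edge_kernel"), inherits(cfg, "train_config"))
  if (cfg$weights$w_mse == 0 && cfg$weights$w_edge == 0)
    stopf("both loss weights are zero; nothing to train")

  x <- pair$microscopy
  target <- pair$ion_interp
  lum <- to_luminance(x)
  edge_ref <- conv2d_same(lum, K)
  w1 <- cfg$weights$w_mse; w2 <- cfg$weights$w_edge
  hash <- train_hash(net, K, cfg)
  kw <- matrix(as.vector(K$weights), nrow = 1L)

  params <- net_params(net)
  opt <- adam_init(params)
  es <- early_stop_state(cfg$stop_patience)
  best <- list(epoch = NA_integer_, params = NULL)
  tr_epoch <- integer(0); tr_mse <- tr_edge <- tr_total <- numeric(0)
  tr_counter <- integer(0)
  start_epoch <- 1L

  if (!is.null(resume)) {
    ck <- if (is.character(resume)) load_checkpoint(resume) else resume
    if (!identical(ck$config_hash, hash))
      stopf("checkpoint config hash %s does not match this run (%s)",
            ck$config_hash, hash, class = "msifuse_hash_error")
    params <- ck$params; opt <- ck$opt; es <- ck$es; best <- ck$best
    tr_epoch <- ck$trace$epoch; tr_mse <- ck$trace$l_mse
    tr_edge <- ck$trace$l_edge; tr_total <- ck$trace$l_total
    tr_counter <- ck$trace$stop_counter
    start_epoch <- ck$epoch + 1L
  }

  stopped_at <- cfg$max_epochs
  if (start_epoch <= cfg$max_epochs) {
    for (epoch in start_epoch:cfg$max_epochs) {
      net <- net_set_params(net, params)
      fw <- net_forward_train(net, x)
      y <- fw$out
      l_mse <- mean((y - target)^2)
      e_out <- conv2d_same(y, K)
      l_edge <- mean((e_out - edge_ref)^2)
      l_total <- w1 * l_mse + w2 * l_edge
      if (!is.finite(l_total))
        stopf("non-finite loss at epoch %d (mse=%g, edge=%g)",
              epoch, l_mse, l_edge, class = "msifuse_numeric_error")

      if (l_edge < es$best) best <- list(epoch = epoch, params = params)
      es <- early_stop_update(es, l_edge)

      tr_epoch <- c(tr_epoch, epoch)
      tr_mse <- c(tr_mse, l_mse); tr_edge <- c(tr_edge, l_edge)
      tr_total <- c(tr_total, l_total)
      tr_counter <- c(tr_counter, es$counter)

      # checkpoints hold the state after completing an epoch (post-update),
      # so a resumed run continues exactly where the saved one left off
      save_ck <- function(epoch) {
        ck <- list(params = params, opt = opt, es = es, best = best,
                   epoch = epoch, config_hash = hash,
                   net_arch = net$arch, net_spec = net$spec,
                   trace = data.frame(epoch = tr_epoch, l_mse = tr_mse,
                                      l_edge = tr_edge, l_total = tr_total,
                                      stop_counter = tr_counter))
        save_checkpoint(ck, file.path(cfg$checkpoint_dir,
                                      sprintf("ckpt_%05d.rds", epoch)))
      }

      if (es$halt) {
        stopped_at <- epoch
        if (!is.null(cfg$checkpoint_dir)) save_ck(epoch)
        break
      }

      grad_y <- w1 * mse_loss_grad(y, target)
      if (w2 > 0) {
        d <- 2 * (e_out - edge_ref) / length(e_out)
        grad_y <- grad_y +
          w2 * cpp_conv_bwd(as_cube(y), kw, as_cube(d))$grad_input[, , 1]
      }
      grads <- net_backward(net, fw$caches, grad_y)
      st <- adam_step(params, grads, opt, cfg$lr)
      params <- st$params; opt <- st$state

      if (!is.null(cfg$checkpoint_dir) &&
          (epoch %% cfg$checkpoint_every == 0L || epoch == cfg$max_epochs))
        save_ck(epoch)
    }
  }

  trace <- data.frame(epoch = tr_epoch, l_mse = tr_mse, l_edge = tr_edge,
                      l_total = tr_total, stop_counter = tr_counter)
  trace$is_best <- trace$epoch == best$epoch
  attr(trace, "stopped_at") <- min(stopped_at, max(tr_epoch))
  attr(trace, "best_epoch") <- best$epoch
  class(trace) <- c("loss_trace", "data.frame")

  net_best <- net_set_params(net, best$params)
  net_final <- net_set_params(net, params)
  fused <- fused_image(net_forward(net_best, x), config_hash = hash,
                       epoch_of_best = best$epoch)
  structure(list(fused = fused, trace = trace, net_best = net_best,
                 net_final = net_final, config_hash = hash),
            class = "fusion_fit")
}

#' @export
print.fusion_fit <- function(x, ...) {
  cat(sprintf(
    "<fusion_fit> %d epochs (best %d), final mse %.3g, edge %.3g [%s]\n",
    attr(x$trace, "stopped_at"), attr(x$trace, "best_epoch"),
    x$trace$l_mse[nrow(x$trace)], x$trace$l_edge[nrow(x$trace)],
    x$config_hash))
  invisible(x)
}

#' Save a training checkpoint
#'
#' The payload (parameters, optimizer state, early-stopping state, trace) is
#' stored with an embedded content checksum and the run's config hash;
#' [load_checkpoint()] refuses tampered files or mismatched configurations.
#'
#' @param ckpt a checkpoint list produced by [train_fusion()].
#' @param path output path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(ckpt, path) {
  payload <- serialize(ckpt, NULL, version = 3L)
  saveRDS(list(checksum = cpp_fnv1a32(payload), payload = payload), path)
  invisible(path)
}

#' Load and verify a training checkpoint
#'
#' @param path path written by [save_checkpoint()].
#' @param expect_hash optional config hash that must match the checkpoint's.
#' @return the checkpoint list.
#' @export
load_checkpoint <- function(path, expect_hash = NULL) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stopf("cannot read checkpoint %s: %s", path, conditionMessage(e),
          class = "msifuse_checkpoint_error"))
  if (!is.list(obj) || !all(c("checksum", "payload") %in% names(obj)))
    stopf("%s is not a msifuse checkpoint", path,
          class = "msifuse_checkpoint_error")
  if (!identical(cpp_fnv1a32(obj$payload), obj$checksum))
    stopf("checkpoint %s failed its integrity checksum", path,
          class = "msifuse_checkpoint_error")
  ck <- unserialize(obj$payload)
  if (!is.null(expect_hash) && !identical(ck$config_hash, expect_hash))
    stopf("checkpoint config hash %s does not match expected %s",
          ck$config_hash, expect_hash, class = "msifuse_hash_error")
  ck
}

#' Export a loss trace as CSV
#'
#' @param trace a `loss_trace` from [train_fusion()].
#' @param path output CSV path.
#' @param hash optional config hash written as a constant column.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, hash = NULL) {
  df <- as.data.frame(trace)
  if (!is.null(hash)) df$config_hash <- hash
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
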