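test_that("early stopping counter follows the cumulative running-minimum rule", {
  # strictly improving sequence: counter never moves
  st <- early_stop_state(5L)
  for (v in c(3, 2, 1)) st <- early_stop_update(st, v)
  expect_equal(st$counter, 0L)
  expect_false(st$halt)

  # plateau counts as an increase (not strictly below the running minimum)
  st <- early_stop_state(5L)
  halted_at <- NA
  for (i in seq_along(c(1, 2, 2, 2, 2, 2))) {
    st <- early_stop_update(st, c(1, 2, 2, 2, 2, 2)[i])
    if (st$halt) { halted_at <- i; break }
  }
  expect_equal(halted_at, 6L)

  # boundary semantics: a repeat of the current best is not an improvement
  st <- early_stop_state(1L)
  st <- early_stop_update(st, 1)
  expect_false(st$halt)
  st <- early_stop_update(st, 1)
  expect_true(st$halt)

  # interleaved improvements and increases against the hand simulation
  seqv <- c(5, 4, 6, 3, 7, 2, 8, 1, 9, 0.5, 10, 11, 12)
  orc <- oracle_early_stop(seqv, 5L)
  st <- early_stop_state(5L)
  halted_at <- NA
  for (i in seq_along(seqv)) {
    st <- early_stop_update(st, seqv[i])
    if (st$halt) { halted_at <- i; break }
  }
  expect_equal(halted_at, orc$halt_at)
  expect_equal(st$best, orc$best)
  expect_equal(orc$best_index, 10L)  # the 0.5 entry
})

test_that("a one-epoch run returns a one-row trace", {
  s <- small_phantom_setup(seed = 1)
  fit <- train_fusion(s$net, s$pair, edge_kernel(),
                      train_config(max_epochs = 1L, seed = 1))
  expect_equal(nrow(fit$trace), 1L)
  expect_equal(attr(fit$trace, "stopped_at"), 1L)
  expect_equal(attr(fit$trace, "best_epoch"), 1L)
  expect_true(fit$trace$is_best[1])
})

test_that("training reduces the total loss and returns the best-edge state", {
  s <- small_phantom_setup(seed = 2)
  fit <- train_fusion(s$net, s$pair, edge_kernel(),
                      train_config(max_epochs = 60L, seed = 2))
  tr <- fit$trace
  expect_lt(tr$l_total[min(50, nrow(tr))], tr$l_total[1])

  # best epoch has the minimal recorded edge loss
  expect_equal(attr(tr, "best_epoch"), tr$epoch[which.min(tr$l_edge)])
  # the fused image is the best checkpoint's forward pass, not the last
  expect_identical(fit$fused$values,
                   net_forward(fit$net_best, s$pair$microscopy))
  expect_equal(fit$fused$epoch_of_best, attr(tr, "best_epoch"))
  # trace invariants
  expect_true(all(diff(tr$epoch) == 1))
  expect_true(all(diff(tr$stop_counter) >= 0))
})

test_that("with zero edge weight the trajectory ignores the edge gradient", {
  s <- small_phantom_setup(seed = 3)
  epochs <- 25L
  # patience large enough that the (unoptimized) edge loss cannot halt the
  # run, so both trajectories cover the same epochs
  cfgw <- function() train_config(max_epochs = epochs, stop_patience = 1000L,
                                  weights = loss_weights(1, 0), seed = 3)
  fit_a <- train_fusion(s$net, s$pair, edge_kernel("laplacian4"), cfgw())
  fit_b <- train_fusion(s$net, s$pair, edge_kernel("sobel_x"), cfgw())
  # the edge loss is recorded every epoch but never propagated: swapping the
  # kernel changes the recorded values, not the parameter trajectory
  expect_identical(msifuse:::net_params(fit_a$net_final),
                   msifuse:::net_params(fit_b$net_final))
  expect_identical(fit_a$trace$l_mse, fit_b$trace$l_mse)
  expect_false(identical(fit_a$trace$l_edge, fit_b$trace$l_edge))
  expect_true(all(fit_a$trace$l_edge > 0))

  # independent oracle: a plain MSE-only Adam loop over the same primitives
  # that never evaluates the edge term at all
  params <- msifuse:::net_params(s$net)
  opt <- msifuse:::adam_init(params)
  x <- s$pair$microscopy; target <- s$pair$ion_interp
  for (e in seq_len(epochs)) {
    n <- msifuse:::net_set_params(s$net, params)
    fw <- msifuse:::net_forward_train(n, x)
    g <- msifuse:::net_backward(n, fw$caches,
                                2 * (fw$out - target) / length(fw$out))
    st <- msifuse:::adam_step(params, g, opt, 3e-4)
    params <- st$params; opt <- st$state
  }
  expect_identical(msifuse:::net_params(fit_a$net_final), params)
})

test_that("training with both weights zero is rejected", {
  s <- small_phantom_setup(seed = 4)
  expect_error(train_fusion(s$net, s$pair, edge_kernel(),
                            train_config(weights = loss_weights(0, 0))),
               "nothing to train")
})

test_that("checkpoints round-trip, detect tampering, and support resume", {
  s <- small_phantom_setup(seed = 5)
  dir <- withr::local_tempdir()
  cfg <- train_config(max_epochs = 12L, seed = 5, checkpoint_every = 5L,
                      checkpoint_dir = dir)
  fit <- train_fusion(s$net, s$pair, edge_kernel(), cfg)
  files <- list.files(dir, pattern = "^ckpt_", full.names = TRUE)
  expect_true(length(files) >= 2)

  # save -> load -> forward equals the in-memory state
  ck <- load_checkpoint(files[length(files)])
  net2 <- msifuse:::net_set_params(s$net, ck$params)
  expect_identical(net_forward(net2, s$pair$microscopy),
                   net_forward(fit$net_final, s$pair$microscopy))

  # tampering is refused
  raw <- readRDS(files[1])
  raw$payload[100] <- as.raw(bitwXor(as.integer(raw$payload[100]), 255L))
  tampered <- file.path(dir, "tampered.rds")
  saveRDS(raw, tampered)
  expect_error(load_checkpoint(tampered),
               class = "msifuse_checkpoint_error")
  expect_error(load_checkpoint(files[1], expect_hash = "ffffffff"),
               class = "msifuse_hash_error")

  # resuming from epoch 5 reproduces the uninterrupted trace exactly
  cfg2 <- train_config(max_epochs = 12L, seed = 5, checkpoint_every = 5L,
                       checkpoint_dir = NULL)
  fit_resumed <- train_fusion(s$net, s$pair, edge_kernel(), cfg2,
                              resume = file.path(dir, "ckpt_00005.rds"))
  expect_equal(as.data.frame(fit_resumed$trace),
               as.data.frame(fit$trace), tolerance = 1e-14)
  expect_identical(msifuse:::net_params(fit_resumed$net_final),
                   msifuse:::net_params(fit$net_final))
})

test_that("fusion of a small phantom outperforms bilinear interpolation", {
  s <- small_phantom_setup(seed = 1, channels = c(12L, 8L, 1L))
  fit <- train_fusion(s$net, s$pair, edge_kernel(),
                      train_config(max_epochs = 120L, seed = 1))
  ssim_fused <- ssim(pmin(pmax(fit$fused$values, 0), 1), s$truth)
  ssim_interp <- ssim(s$pair$ion_interp, s$truth)
  expect_gt(ssim_fused, ssim_interp)
})
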