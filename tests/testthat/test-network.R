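test_that("forward pass preserves spatial shape for odd and even sizes", {
  net <- build_network(network_spec(block_channels = c(6L, 4L, 1L)),
                       seed = 1)
  for (hw in list(c(8, 8), c(37, 21), c(64, 11))) {
    x <- array(runif(prod(hw) * 3), c(hw, 3))
    y <- net_forward(net, x)
    expect_equal(dim(y), hw)
    expect_true(all(is.finite(y)))
  }
  base <- build_cnn_baseline(seed = 1, channels = c(6L, 4L, 1L))
  x <- array(runif(13 * 9 * 3), c(13, 9, 3))
  expect_equal(dim(net_forward(base, x)), c(13L, 9L))
})

test_that("parameter counts equal the closed-form sums over declared layers", {
  net <- build_network(network_spec(), seed = 1)
  expect_equal(count_parameters(net), oracle_residual_param_count())

  small <- build_network(network_spec(block_channels = c(6L, 4L, 1L)),
                         seed = 1)
  expect_equal(count_parameters(small),
               oracle_residual_param_count(c(3, 6, 4, 1)))

  base <- build_cnn_baseline(seed = 1)
  expect_equal(count_parameters(base), oracle_plain_param_count())
  # the baseline shares the 3 -> 64 -> 32 -> 1 main path but lacks each
  # block's second (width-preserving) convolution and its 1x1 skip
  extra <- (3 * 3 * 32 * 32 + 32) + (3 * 3 * 1 * 1 + 1) +  # convB layers
    (1 * 1 * 64 * 32 + 32) + (1 * 1 * 32 * 1 + 1)          # 1x1 skips
  expect_equal(count_parameters(net) - count_parameters(base), extra)
})

test_that("initialization is seeded and bit-reproducible", {
  a <- build_network(network_spec(block_channels = c(6L, 4L, 1L)), seed = 3)
  b <- build_network(network_spec(block_channels = c(6L, 4L, 1L)), seed = 3)
  c_ <- build_network(network_spec(block_channels = c(6L, 4L, 1L)), seed = 4)
  x <- array(runif(10 * 10 * 3), c(10, 10, 3))
  expect_identical(net_forward(a, x), net_forward(b, x))
  expect_false(identical(net_forward(a, x), net_forward(c_, x)))
  expect_identical(msifuse:::net_params(a), msifuse:::net_params(b))
})

test_that("a zeroed network outputs exactly zero", {
  net <- build_network(network_spec(block_channels = c(4L, 3L, 1L)),
                       seed = 1)
  p <- msifuse:::net_params(net)
  p <- lapply(p, function(q) q * 0)
  net0 <- msifuse:::net_set_params(net, p)
  x <- array(runif(6 * 6 * 3), c(6, 6, 3))
  expect_true(all(net_forward(net0, x) == 0))
})

test_that("hand-set pointwise weights reproduce a scalar convolution", {
  # single block, 1x1 main and skip kernels with known weights: the network
  # reduces to an affine map per pixel that we can compute by hand
  spec <- network_spec(block_channels = c(2L, 1L), kernel_size = 1L,
                       skip_kernel_size = 1L)
  net <- build_network(spec, seed = 1)
  p <- msifuse:::net_params(net)
  p[["init.W"]] <- matrix(c(1, 0, 0, 1, 0, 0), 2, 3)  # ch1 = R, ch2 = G
  p[["init.b"]] <- c(0, 0)
  p[["b1.convA.W"]] <- matrix(c(2, 0), 1, 2)  # 2 * relu(R)
  p[["b1.convA.b"]] <- 0
  p[["b1.convB.W"]] <- matrix(3, 1, 1)        # 3 * relu(2R)
  p[["b1.convB.b"]] <- 0.5
  p[["b1.skip.W"]] <- matrix(c(0, 1), 1, 2)   # + G
  p[["b1.skip.b"]] <- 0
  net <- msifuse:::net_set_params(net, p)
  x <- array(runif(2 * 2 * 3), c(2, 2, 3))
  expected <- 3 * (2 * x[, , 1]) + 0.5 + x[, , 2]  # all inputs positive
  expect_equal(net_forward(net, x), expected, tolerance = 1e-12)
})

test_that("residual block reduces to its skip path when conv weights vanish", {
  spec <- network_spec(block_channels = c(4L, 3L, 1L))
  net <- build_network(spec, seed = 2)
  p <- msifuse:::net_params(net)
  # zero both conv-path layers of block 2; keep a known 1x1 skip
  p[["b2.convA.W"]] <- p[["b2.convA.W"]] * 0
  p[["b2.convA.b"]] <- p[["b2.convA.b"]] * 0
  p[["b2.convB.W"]] <- p[["b2.convB.W"]] * 0
  p[["b2.convB.b"]] <- p[["b2.convB.b"]] * 0
  p[["b2.skip.W"]] <- matrix(c(1, 0, 0), 1, 3)
  p[["b2.skip.b"]] <- 0
  net <- msifuse:::net_set_params(net, p)
  x <- array(runif(7 * 5 * 3), c(7, 5, 3))
  # output must equal channel 1 of block 2's input (linear final head)
  fw <- msifuse:::net_forward_train(net, x)
  expect_equal(fw$out, fw$caches$blocks[[2]]$h_in[, , 1], tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences", {
  spec <- network_spec(block_channels = c(4L, 3L, 1L))
  net <- build_network(spec, seed = 7)
  set.seed(8)
  x <- array(runif(6 * 5 * 3), c(6, 5, 3))
  target <- matrix(runif(30), 6, 5)
  lossf <- function(pl) {
    n <- msifuse:::net_set_params(net, pl)
    mean((net_forward(n, x) - target)^2)
  }
  p <- msifuse:::net_params(net)
  fw <- msifuse:::net_forward_train(net, x)
  gr <- msifuse:::net_backward(net, fw$caches,
                               msifuse:::mse_loss_grad(fw$out, target))
  base <- lossf(p)
  for (nm in names(p)) {
    i <- sample(length(p[[nm]]), 1)
    eps <- 1e-6
    p2 <- p
    p2[[nm]][i] <- p2[[nm]][i] + eps
    num <- (lossf(p2) - base) / eps
    expect_equal(gr[[nm]][i], num, tolerance = 1e-3,
                 label = sprintf("gradient of %s", nm))
  }
})
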