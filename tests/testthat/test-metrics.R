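test_that("psnr follows its closed form and the infinity sentinel", {
  set.seed(1)
  a <- matrix(runif(144), 12, 12)
  expect_identical(psnr(a, a), Inf)

  # constant offset of 0.1 gives MSE 0.01, hence 20 dB at L = 1
  b <- matrix(0, 4, 4)
  expect_equal(psnr(b, b + 0.1), 20, tolerance = 1e-12)

  c_ <- matrix(runif(144), 12, 12)
  expect_equal(psnr(a, c_), 10 * log10(1 / oracle_mse(a, c_)),
               tolerance = 1e-10)
  expect_error(psnr(a, matrix(0, 2, 2)), "shape mismatch")
})

test_that("psnr decreases monotonically with growing MSE", {
  a <- matrix(0.5, 16, 16)
  offsets <- c(0.01, 0.05, 0.1, 0.2)
  vals <- vapply(offsets, function(d) psnr(a, a + d), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("ssim identities: self-similarity, symmetry, constant closed form", {
  set.seed(2)
  x <- matrix(runif(15 * 13), 15, 13)
  expect_equal(ssim(x, x), 1, tolerance = 1e-12)

  y <- matrix(runif(15 * 13), 15, 13)
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-12)
  expect_lte(ssim(x, y), 1)

  # two constant images: every window reduces to the same closed form
  p <- 0.3; q <- 0.7
  C1 <- 0.01^2; C2 <- 0.03^2
  closed <- ((2 * p * q + C1) * C2) / ((p^2 + q^2 + C1) * C2)
  expect_equal(ssim(matrix(p, 12, 12), matrix(q, 12, 12)), closed,
               tolerance = 1e-10)

  expect_error(ssim(matrix(0, 8, 20), matrix(0, 8, 20)), "at least")
})

test_that("feature hook metric consumes any extractor callable", {
  set.seed(3)
  a <- matrix(runif(36), 6, 6)
  b <- matrix(runif(36), 6, 6)
  expect_equal(feature_metric(a, b, identity), mean((a - b)^2))
  grad_extractor <- function(x) list(diff(x), t(diff(t(x))))
  expect_equal(feature_metric(a, a, grad_extractor), 0)
  expect_gt(feature_metric(a, b, grad_extractor), 0)
  expect_error(feature_metric(a, b, "not a function"), "function")
})

test_that("checkpoint evaluation matches direct metric calls and sorts by epoch", {
  s <- small_phantom_setup(seed = 6)
  dir <- withr::local_tempdir()
  fit <- train_fusion(s$net, s$pair, edge_kernel(),
                      train_config(max_epochs = 15L, seed = 6,
                                   checkpoint_every = 5L,
                                   checkpoint_dir = dir))
  files <- sort(list.files(dir, pattern = "^ckpt_", full.names = TRUE))
  res <- evaluate_checkpoints(files, s$pair, edge_kernel(), truth = s$truth)
  expect_equal(res$epoch, sort(res$epoch))
  expect_true(all(c("psnr_db", "ssim", "edge_loss", "psnr_truth",
                    "ssim_truth") %in% names(res)))

  # row-by-row compositional oracle
  lum <- to_luminance(s$pair$microscopy)
  for (i in seq_len(nrow(res))) {
    ck <- load_checkpoint(res$path[i])
    net <- msifuse:::net_set_params(s$net, ck$params)
    y <- pmin(pmax(net_forward(net, s$pair$microscopy), 0), 1)
    expect_equal(res$psnr_db[i], psnr(y, s$pair$ion_interp),
                 tolerance = 1e-12)
    expect_equal(res$ssim[i], ssim(y, s$pair$ion_interp),
                 tolerance = 1e-12)
    expect_equal(res$edge_loss[i],
                 edge_perceptual_loss(y, lum, edge_kernel()),
                 tolerance = 1e-12)
    expect_equal(res$ssim_truth[i], ssim(y, s$truth), tolerance = 1e-12)
  }

  # invariant to the order in which files are supplied
  res_rev <- evaluate_checkpoints(rev(files), s$pair, edge_kernel(),
                                  truth = s$truth)
  expect_equal(res_rev, res)

  # a missing checkpoint is reported as absent, the run continues
  res_na <- evaluate_checkpoints(c(files, file.path(dir, "ckpt_gone.rds")),
                                 s$pair, edge_kernel(), truth = s$truth)
  expect_equal(sum(is.na(res_na$epoch)), 1L)
  expect_equal(nrow(res_na), length(files) + 1L)

  # checkpoints from different configurations are refused together
  other <- train_fusion(s$net, s$pair, edge_kernel(),
                        train_config(max_epochs = 3L, seed = 6, lr = 1e-4,
                                     checkpoint_every = 1L,
                                     checkpoint_dir = dir))
  expect_error(evaluate_checkpoints(dir, s$pair, edge_kernel()),
               class = "msifuse_hash_error")

  expect_error(evaluate_checkpoints(character(0), s$pair),
               class = "msifuse_checkpoint_error")
})
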