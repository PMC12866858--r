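# Checkpoint and result evaluation: PSNR, SSIM, an evaluation-only wrapper
# of the edge perceptual loss, and a pluggable feature-extractor hook for
# perceptual-style metrics.

#' Peak signal-to-noise ratio
#'
#' `10 * log10(L^2 / MSE)` with data range `L = 1` after normalization.
#' Identical inputs return `Inf`.
#'
#' @param a,b numeric grids of identical shape with values in `[0, 1]`.
#' @param L data range.
#' @return PSNR in dB, or `Inf` for identical inputs.
#' @export
psnr <- function(a, b, L = 1) {
  if (!all(dim(as.matrix(a)) == dim(as.matrix(b))))
    stopf("psnr: shape mismatch")
  m <- mean((a - b)^2)
  if (m == 0) return(Inf)
  10 * log10(L^2 / m)
}

ssim_window <- function(size = 11L, sigma = 1.5) {
  half <- (size - 1L) / 2
  g <- dnorm(seq(-half, half), sd = sigma)
  w <- outer(g, g)
  w / sum(w)
}

# Weighted local moments via same-size convolution, cropped to the interior
# where the window fits entirely (valid convolution).
ssim_filter <- function(x, w) {
  half <- (nrow(w) - 1L) / 2
  f <- conv2d_same(x, w)
  f[(half + 1):(nrow(f) - half), (half + 1):(ncol(f) - half)]
}

#' Structural similarity index
#'
#' Mean local SSIM over an 11 x 11 Gaussian window (sigma 1.5) with the
#' canonical constants `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, `L = 1`.
#' Windows are evaluated where they fit entirely inside the image.
#'
#' @param a,b numeric grids of identical shape; each side must be at least
#'   the window size.
#' @param L data range.
#' @return scalar SSIM in `[-1, 1]`.
#' @export
ssim <- function(a, b, L = 1) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stopf("ssim: shape mismatch")
  win <- 11L
  if (min(dim(a)) < win)
    stopf("ssim needs images of at least %d x %d, got %d x %d",
          win, win, nrow(a), ncol(a))
  w <- ssim_window(win, 1.5)
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  mu_a <- ssim_filter(a, w); mu_b <- ssim_filter(b, w)
  s_aa <- ssim_filter(a * a, w) - mu_a^2
  s_bb <- ssim_filter(b * b, w) - mu_b^2
  s_ab <- ssim_filter(a * b, w) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + C1) * (2 * s_ab + C2)
  den <- (mu_a^2 + mu_b^2 + C1) * (s_aa + s_bb + C2)
  mean(num / den)
}

#' Perceptual-style metric through a pluggable feature extractor
#'
#' A hook for perceptual metrics computed from learned features: any
#' callable mapping an H x W grid to a numeric feature grid (or list of
#' grids) can be supplied; the metric is the mean squared difference of the
#' extracted features.  No pretrained weights ship with the package.
#'
#' @param a,b numeric grids of identical shape.
#' @param extractor function mapping a grid to features.
#' @return non-negative scalar.
#' @export
feature_metric <- function(a, b, extractor) {
  if (!is.function(extractor)) stopf("extractor must be a function")
  fa <- extractor(a); fb <- extractor(b)
  if (is.list(fa)) {
    mean(mapply(function(x, y) mean((x - y)^2), fa, fb))
  } else {
    mean((fa - fb)^2)
  }
}

#' Evaluate saved checkpoints with PSNR, SSIM and edge loss
#'
#' For each checkpoint the stored parameters are restored, the network is
#' run on the pair's microscopy channels, and the output is scored against
#' the interpolated ion target (PSNR, SSIM) and against the microscopy
#' luminance (edge perceptual loss).  With a ground-truth image (phantom
#' mode) truth-referenced PSNR/SSIM columns are added.  Missing or
#' unreadable checkpoints are listed with `NA` metrics and the run
#' continues.  Rows are ordered by epoch regardless of file order.
#'
#' @param checkpoints character vector of checkpoint paths, or a directory
#'   containing `ckpt_*.rds` files.
#' @param pair a `registered_pair`.
#' @param K an [edge_kernel].
#' @param truth optional H x W ground-truth grid in `[0, 1]`.
#' @return a data frame with one row per checkpoint.
#' @export
evaluate_checkpoints <- function(checkpoints, pair, K = edge_kernel(),
                                 truth = NULL) {
  stopifnot(inherits(pair, "registered_pair"))
  if (length(checkpoints) == 1L && dir.exists(checkpoints))
    checkpoints <- list.files(checkpoints, pattern = "^ckpt_.*\\.rds$",
                              full.names = TRUE)
  if (length(checkpoints) == 0L)
    stopf("no checkpoints to evaluate", class = "msifuse_checkpoint_error")
  lum <- to_luminance(pair$microscopy)
  hashes <- character(0)
  rows <- lapply(checkpoints, function(path) {
    ck <- tryCatch(suppressWarnings(load_checkpoint(path)),
                   error = function(e) NULL)
    if (is.null(ck)) {
      out <- data.frame(path = path, epoch = NA_integer_,
                        psnr_db = NA_real_, ssim = NA_real_,
                        edge_loss = NA_real_, config_hash = NA_character_)
      if (!is.null(truth)) {
        out$psnr_truth <- NA_real_
        out$ssim_truth <- NA_real_
      }
      return(out)
    }
    net <- if (ck$net_arch == "residual")
      build_network(ck$net_spec, seed = 0L)
    else
      build_cnn_baseline(seed = 0L, channels = ck$net_spec$block_channels)
    net <- net_set_params(net, ck$params)
    y <- clamp01(net_forward(net, pair$microscopy))
    out <- data.frame(path = path, epoch = ck$epoch,
                      psnr_db = psnr(y, pair$ion_interp),
                      ssim = ssim(y, pair$ion_interp),
                      edge_loss = edge_perceptual_loss(y, lum, K),
                      config_hash = ck$config_hash)
    if (!is.null(truth)) {
      out$psnr_truth <- psnr(y, truth)
      out$ssim_truth <- ssim(y, truth)
    }
    out
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$epoch, res$path), , drop = FALSE]
  rownames(res) <- NULL
  hashes <- unique(res$config_hash[!is.na(res$config_hash)])
  if (length(hashes) > 1L)
    stopf("checkpoints mix config hashes: %s",
          paste(hashes, collapse = ", "), class = "msifuse_hash_error")
  res
}
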