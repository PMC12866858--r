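# The fusion network: one initialization block (3x3 conv, 3 -> 64, ReLU)
# followed by two residual blocks.  Each residual block applies two 3x3
# convolutions (in -> out with ReLU, then out -> out) in parallel with a
# 1x1 convolution skip (in -> out); the two paths are summed.  The first
# block's sum passes through ReLU, the final block's sum is the linear
# output head (channels 3 -> 64 -> 32 -> 1).  All convolutions are
# same-spatial-size with replicate padding.  Forward and backward passes are
# explicit; there is no autodiff dependency.

#' Network architecture specification
#'
#' @param in_channels number of input channels; fixed at 3 (RGB microscopy).
#' @param block_channels channel widths at block boundaries; the first entry
#'   is the initialization-block output, subsequent entries the residual
#'   block outputs; the last must be 1 (single-channel fused image).
#' @param kernel_size odd spatial kernel size of the main convolutions.
#' @param skip_kernel_size odd kernel size of the residual skip (1 = the
#'   pointwise skip).
#' @param activation activation between convolutions (`"relu"`).
#' @param final_activation activation after the last block's sum (`"none"`
#'   or `"relu"`); the default linear head allows negative pre-clip values.
#' @return an object of class `network_spec`.
#' @export
network_spec <- function(in_channels = 3L,
                         block_channels = c(64L, 32L, 1L),
                         kernel_size = 3L,
                         skip_kernel_size = 1L,
                         activation = "relu",
                         final_activation = "none") {
  if (in_channels != 3L)
    stopf("in_channels is fixed at 3 (registered RGB microscopy)")
  block_channels <- as.integer(block_channels)
  if (length(block_channels) < 2L || any(block_channels < 1L))
    stopf("block_channels needs at least two positive widths")
  if (block_channels[length(block_channels)] != 1L)
    stopf("the final block width must be 1")
  if (kernel_size %% 2L != 1L || skip_kernel_size %% 2L != 1L)
    stopf("kernel sizes must be odd")
  if (!activation %in% c("relu", "none") ||
      !final_activation %in% c("relu", "none"))
    stopf("supported activations are 'relu' and 'none'")
  structure(list(in_channels = 3L, block_channels = block_channels,
                 kernel_size = as.integer(kernel_size),
                 skip_kernel_size = as.integer(skip_kernel_size),
                 activation = activation,
                 final_activation = final_activation),
            class = "network_spec")
}

# He-normal initialized conv layer; weight rows are (in_ch * k * k) long,
# ordered channel-major then kernel column then kernel row (row fastest),
# matching the C++ im2col layout.
conv_layer <- function(in_ch, out_ch, k) {
  fan_in <- in_ch * k * k
  list(k = as.integer(k), in_ch = as.integer(in_ch),
       out_ch = as.integer(out_ch),
       W = matrix(rnorm(out_ch * fan_in, 0, sqrt(2 / fan_in)),
                  out_ch, fan_in),
       b = numeric(out_ch))
}

#' Build the residual fusion network
#'
#' @param spec a [network_spec].
#' @param seed integer seed for parameter initialization (He-normal weights,
#'   zero biases); identical seeds give bit-identical parameters.
#' @return an object of class `fusion_net`.
#' @export
build_network <- function(spec = network_spec(), seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  with_seed(seed, {
    ch <- c(spec$in_channels, spec$block_channels)
    init <- conv_layer(ch[1], ch[2], spec$kernel_size)
    n_blocks <- length(spec$block_channels) - 1L
    blocks <- vector("list", n_blocks)
    for (i in seq_len(n_blocks)) {
      b_in <- ch[i + 1L]; b_out <- ch[i + 2L]
      blocks[[i]] <- list(
        convA = conv_layer(b_in, b_out, spec$kernel_size),
        convB = conv_layer(b_out, b_out, spec$kernel_size),
        skip = conv_layer(b_in, b_out, spec$skip_kernel_size),
        act_after = if (i < n_blocks) spec$activation else
          spec$final_activation
      )
    }
    structure(list(arch = "residual", spec = spec, init = init,
                   blocks = blocks, seed = as.integer(seed)),
              class = "fusion_net")
  })
}

#' Build the plain three-layer CNN baseline
#'
#' Three same-padded 3x3 convolutions (3 -> 64 -> 32 -> 1) with ReLU between
#' them and no skip connections — the minimal CNN comparison method.
#'
#' @param seed integer seed for initialization.
#' @param channels channel widths after each convolution.
#' @return an object of class `fusion_net`.
#' @export
build_cnn_baseline <- function(seed = 1L, channels = c(64L, 32L, 1L)) {
  channels <- as.integer(channels)
  if (channels[length(channels)] != 1L)
    stopf("the final width must be 1")
  with_seed(seed, {
    ch <- c(3L, channels)
    layers <- vector("list", length(channels))
    for (i in seq_along(channels)) {
      layers[[i]] <- list(conv = conv_layer(ch[i], ch[i + 1L], 3L),
                          act = if (i < length(channels)) "relu" else "none")
    }
    structure(list(arch = "plain",
                   spec = list(in_channels = 3L, block_channels = channels,
                               kernel_size = 3L),
                   layers = layers, seed = as.integer(seed)),
              class = "fusion_net")
  })
}

#' @export
print.fusion_net <- function(x, ...) {
  cat(sprintf("<fusion_net> %s architecture, channels 3 -> %s, %d parameters\n",
              x$arch, paste(x$spec$block_channels, collapse = " -> "),
              count_parameters(x)))
  invisible(x)
}

#' Total number of trainable parameters
#'
#' @param net a `fusion_net`.
#' @return integer parameter count (weights plus biases).
#' @export
count_parameters <- function(net) {
  sum(vapply(net_params(net), length, integer(1)))
}

relu_fwd <- function(x) {
  x[x < 0] <- 0
  x
}

apply_act <- function(x, act) if (act == "relu") relu_fwd(x) else x

act_mask <- function(pre, act) {
  if (act == "relu") (pre > 0) * 1 else array(1, dim = dim(pre))
}

# Flat named parameter list (matrices / vectors), and its inverse.  The
# naming is positional so the Adam state lines up across calls.
net_params <- function(net) {
  p <- list()
  if (net$arch == "residual") {
    p[["init.W"]] <- net$init$W; p[["init.b"]] <- net$init$b
    for (i in seq_along(net$blocks)) {
      for (part in c("convA", "convB", "skip")) {
        p[[sprintf("b%d.%s.W", i, part)]] <- net$blocks[[i]][[part]]$W
        p[[sprintf("b%d.%s.b", i, part)]] <- net$blocks[[i]][[part]]$b
      }
    }
  } else {
    for (i in seq_along(net$layers)) {
      p[[sprintf("l%d.W", i)]] <- net$layers[[i]]$conv$W
      p[[sprintf("l%d.b", i)]] <- net$layers[[i]]$conv$b
    }
  }
  p
}

net_set_params <- function(net, p) {
  if (net$arch == "residual") {
    net$init$W <- p[["init.W"]]; net$init$b <- p[["init.b"]]
    for (i in seq_along(net$blocks)) {
      for (part in c("convA", "convB", "skip")) {
        net$blocks[[i]][[part]]$W <- p[[sprintf("b%d.%s.W", i, part)]]
        net$blocks[[i]][[part]]$b <- p[[sprintf("b%d.%s.b", i, part)]]
      }
    }
  } else {
    for (i in seq_along(net$layers)) {
      net$layers[[i]]$conv$W <- p[[sprintf("l%d.W", i)]]
      net$layers[[i]]$conv$b <- p[[sprintf("l%d.b", i)]]
    }
  }
  net
}

# Forward pass keeping every intermediate needed by the backward pass.
net_forward_train <- function(net, x) {
  x <- as_cube(x)
  if (dim(x)[3] != 3L)
    stopf("network input must have 3 channels, got %d", dim(x)[3])
  if (net$arch == "residual") {
    act <- net$spec$activation
    c0_pre <- cpp_conv_fwd(x, net$init$W, net$init$b)
    h <- apply_act(c0_pre, act)
    bl_caches <- vector("list", length(net$blocks))
    for (i in seq_along(net$blocks)) {
      bl <- net$blocks[[i]]
      a_pre <- cpp_conv_fwd(h, bl$convA$W, bl$convA$b)
      a <- apply_act(a_pre, act)
      b_out <- cpp_conv_fwd(a, bl$convB$W, bl$convB$b)
      s <- cpp_conv_fwd(h, bl$skip$W, bl$skip$b)
      sum_pre <- b_out + s
      h_out <- apply_act(sum_pre, bl$act_after)
      bl_caches[[i]] <- list(h_in = h, a_pre = a_pre, a = a,
                             sum_pre = sum_pre)
      h <- h_out
    }
    list(out = h[, , 1], caches = list(x = x, c0_pre = c0_pre,
                                       blocks = bl_caches))
  } else {
    hs <- list(x)
    pres <- vector("list", length(net$layers))
    h <- x
    for (i in seq_along(net$layers)) {
      pre <- cpp_conv_fwd(h, net$layers[[i]]$conv$W, net$layers[[i]]$conv$b)
      pres[[i]] <- pre
      h <- apply_act(pre, net$layers[[i]]$act)
      hs[[i + 1L]] <- h
    }
    list(out = h[, , 1], caches = list(inputs = hs, pres = pres))
  }
}

# Backpropagate a gradient w.r.t. the (H x W) output through the network.
net_backward <- function(net, caches, grad_out) {
  g <- as_cube(grad_out)
  grads <- list()
  if (net$arch == "residual") {
    act <- net$spec$activation
    for (i in rev(seq_along(net$blocks))) {
      bl <- net$blocks[[i]]
      ca <- caches$blocks[[i]]
      g <- g * act_mask(ca$sum_pre, bl$act_after)
      bwdB <- cpp_conv_bwd(ca$a, bl$convB$W, g)
      ga <- bwdB$grad_input * act_mask(ca$a_pre, act)
      bwdA <- cpp_conv_bwd(ca$h_in, bl$convA$W, ga)
      bwdS <- cpp_conv_bwd(ca$h_in, bl$skip$W, g)
      grads[[sprintf("b%d.convB.W", i)]] <- bwdB$grad_w
      grads[[sprintf("b%d.convB.b", i)]] <- as.numeric(bwdB$grad_b)
      grads[[sprintf("b%d.convA.W", i)]] <- bwdA$grad_w
      grads[[sprintf("b%d.convA.b", i)]] <- as.numeric(bwdA$grad_b)
      grads[[sprintf("b%d.skip.W", i)]] <- bwdS$grad_w
      grads[[sprintf("b%d.skip.b", i)]] <- as.numeric(bwdS$grad_b)
      g <- bwdA$grad_input + bwdS$grad_input
    }
    g <- g * act_mask(caches$c0_pre, act)
    bwd0 <- cpp_conv_bwd(caches$x, net$init$W, g)
    grads[["init.W"]] <- bwd0$grad_w
    grads[["init.b"]] <- as.numeric(bwd0$grad_b)
  } else {
    for (i in rev(seq_along(net$layers))) {
      g <- g * act_mask(caches$pres[[i]], net$layers[[i]]$act)
      bwd <- cpp_conv_bwd(caches$inputs[[i]], net$layers[[i]]$conv$W, g)
      grads[[sprintf("l%d.W", i)]] <- bwd$grad_w
      grads[[sprintf("l%d.b", i)]] <- as.numeric(bwd$grad_b)
      g <- bwd$grad_input
    }
  }
  grads
}

#' Run the network on an input image
#'
#' Full-image forward pass (one sample, no patching).
#'
#' @param net a `fusion_net`.
#' @param x H x W x 3 array, or a `registered_pair` whose microscopy
#'   channels are used.
#' @return H x W numeric matrix (raw, unclipped output).
#' @export
net_forward <- function(net, x) {
  if (inherits(x, "registered_pair")) x <- x$microscopy
  net_forward_train(net, x)$out
}

#' Fuse a registered pair with a (trained) network
#'
#' @param net a `fusion_net`.
#' @param pair a `registered_pair` from [validate_registration()].
#' @param epoch_of_best epoch annotation carried into the output.
#' @return a [fused_image]; values are the raw network output, clipped to
#'   `[0, 1]` only on export by [write_fused()].
#' @export
fuse <- function(net, pair, epoch_of_best = NA_integer_) {
  stopifnot(inherits(pair, "registered_pair"))
  out <- net_forward(net, pair$microscopy)
  fused_image(out, config_hash = config_hash(unclass(net$spec)),
              epoch_of_best = epoch_of_best)
}

#' Fused single-channel output image
#'
#' @param values H x W numeric matrix (raw network output; clipped to
#'   `[0, 1]` on export).
#' @param config_hash provenance hash of the run configuration.
#' @param epoch_of_best epoch whose parameters produced these values.
#' @return an object of class `fused_image`.
#' @export
fused_image <- function(values, config_hash = "",
                        epoch_of_best = NA_integer_) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(!is.finite(values)))
    stopf("fused image contains non-finite values")
  structure(list(values = values, config_hash = config_hash,
                 epoch_of_best = as.integer(epoch_of_best)),
            class = "fused_image")
}

#' @export
print.fused_image <- function(x, ...) {
  cat(sprintf("<fused_image> %d x %d, best epoch %s, config %s\n",
              nrow(x$values), ncol(x$values),
              ifelse(is.na(x$epoch_of_best), "?", x$epoch_of_best),
              ifelse(nzchar(x$config_hash), x$config_hash, "?")))
  invisible(x)
}
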