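# Training losses: pixel MSE against the interpolated ion target and the
# edge perceptual loss — the MSE between edge-filtered versions of the
# network output and the microscopy luminance.  The edge filter is a single
# designated 3x3 kernel applied as written (no flip; irrelevant for the
# symmetric default), same-size with replicate padding so borders do not
# manufacture phantom edges.

edge_kernel_builtins <- list(
  laplacian4 = matrix(c(0, -1, 0, -1, 4, -1, 0, -1, 0), 3, 3),
  laplacian8 = matrix(c(-1, -1, -1, -1, 8, -1, -1, -1, -1), 3, 3),
  sobel_x = matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3),
  sobel_y = matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
)

#' Designated 3x3 edge-extraction kernel
#'
#' @param kernel a builtin name (`"laplacian4"` — the 4-neighbor Laplacian
#'   default — `"laplacian8"`, `"sobel_x"`, `"sobel_y"`) or a custom 3x3
#'   numeric matrix.  `sobel_x` responds to gradients across columns,
#'   `sobel_y` across rows.
#' @return an object of class `edge_kernel` with fields `weights` and `name`.
#' @export
edge_kernel <- function(kernel = "laplacian4") {
  if (is.character(kernel)) {
    if (!kernel %in% names(edge_kernel_builtins))
      stopf("unknown edge kernel '%s' (builtins: %s)", kernel,
            paste(names(edge_kernel_builtins), collapse = ", "))
    w <- edge_kernel_builtins[[kernel]]
    name <- kernel
  } else {
    w <- as.matrix(kernel)
    if (!all(dim(w) == c(3L, 3L)))
      stopf("a custom edge kernel must be exactly 3 x 3")
    name <- "custom"
  }
  storage.mode(w) <- "double"
  structure(list(weights = w, name = name), class = "edge_kernel")
}

# Same-size convolution of a single-channel grid with a 3x3 kernel,
# replicate padding.
conv2d_same <- function(grid, K) {
  w <- if (inherits(K, "edge_kernel")) K$weights else K
  cpp_conv_fwd(as_cube(as.matrix(grid)),
               matrix(as.vector(w), nrow = 1L), 0)[, , 1]
}

#' Mean squared error loss
#'
#' `1/N * sum((output - target)^2)` over all N pixels.
#'
#' @param output,target numeric grids of identical shape.
#' @return non-negative scalar.
#' @export
mse_loss <- function(output, target) {
  if (!all(dim(as.matrix(output)) == dim(as.matrix(target))))
    stopf("mse_loss: shape mismatch (%s vs %s)",
          paste(dim(as.matrix(output)), collapse = "x"),
          paste(dim(as.matrix(target)), collapse = "x"))
  mean((output - target)^2)
}

#' Edge perceptual loss
#'
#' Both grids are convolved with the designated 3x3 edge kernel (same-size,
#' replicate padding) and the mean squared difference of the edge maps is
#' returned — a morphology-preservation term comparing the network output
#' against the microscopy luminance.
#'
#' @param output H x W network output.
#' @param microscopy_lum H x W microscopy luminance (see [to_luminance()]).
#' @param K an [edge_kernel].
#' @return non-negative scalar.
#' @export
edge_perceptual_loss <- function(output, microscopy_lum,
                                 K = edge_kernel()) {
  if (!all(dim(as.matrix(output)) == dim(as.matrix(microscopy_lum))))
    stopf("edge_perceptual_loss: shape mismatch")
  e_out <- conv2d_same(output, K)
  e_ref <- conv2d_same(microscopy_lum, K)
  mean((e_out - e_ref)^2)
}

#' Loss weights for the additive total loss
#'
#' @param w_mse non-negative multiplier of the MSE term.
#' @param w_edge non-negative multiplier of the edge perceptual term.
#' @return an object of class `loss_weights`.
#' @export
loss_weights <- function(w_mse = 1, w_edge = 1) {
  if (w_mse < 0 || w_edge < 0) stopf("loss weights must be non-negative")
  structure(list(w_mse = as.numeric(w_mse), w_edge = as.numeric(w_edge)),
            class = "loss_weights")
}

#' Weighted total loss
#'
#' `w_mse * L_MSE + w_edge * L_edge`, with the two components reported
#' individually for the per-epoch trace.
#'
#' @param output H x W network output.
#' @param target H x W interpolated ion target.
#' @param microscopy_lum H x W microscopy luminance.
#' @param K an [edge_kernel].
#' @param w a [loss_weights].
#' @return list with elements `total`, `mse`, `edge`.
#' @export
total_loss <- function(output, target, microscopy_lum, K = edge_kernel(),
                       w = loss_weights()) {
  stopifnot(inherits(w, "loss_weights"))
  l_mse <- mse_loss(output, target)
  l_edge <- edge_perceptual_loss(output, microscopy_lum, K)
  list(total = w$w_mse * l_mse + w$w_edge * l_edge,
       mse = l_mse, edge = l_edge)
}

# Gradients of the two loss terms w.r.t. the network output (H x W).
mse_loss_grad <- function(output, target) {
  2 * (output - target) / length(output)
}

# d/dy mean((K*y - K*X)^2): the adjoint of the replicate-padded convolution
# applied to the residual edge map.
edge_loss_grad <- function(output, edge_ref, K) {
  w <- matrix(as.vector(K$weights), nrow = 1L)
  ycube <- as_cube(as.matrix(output))
  e_out <- cpp_conv_fwd(ycube, w, 0)[, , 1]
  d <- 2 * (e_out - edge_ref) / length(e_out)
  cpp_conv_bwd(ycube, w, as_cube(d))$grad_input[, , 1]
}
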