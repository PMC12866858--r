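# Deterministic plumbing between raw inputs and the training pair:
# min-max normalization, bilinear magnification of the ion image,
# registration-output validation, grayscale conversion.

#' Min-max normalize a grid to [0, 1]
#'
#' `(x - min) / (max - min)`; a constant grid maps to all zeros.  The input
#' extrema are recorded as attributes `range_min` / `range_max` so outputs
#' can be scaled back to native intensity units.
#'
#' @param grid finite numeric matrix or array.
#' @return same-shape grid in `[0, 1]`.
#' @export
minmax_normalize <- function(grid) {
  if (any(!is.finite(grid)))
    stopf("grid contains non-finite values", class = "msifuse_data_error")
  lo <- min(grid); hi <- max(grid)
  out <- if (hi == lo) grid * 0 else (grid - lo) / (hi - lo)
  attr(out, "range_min") <- lo
  attr(out, "range_max") <- hi
  out
}

#' Bilinearly upscale an ion image by an integer magnification
#'
#' Half-pixel-center alignment: output pixel `i` (0-based) samples source
#' coordinate `(i + 0.5) / magnification - 0.5`, clamped to the grid — the
#' convention of the common image-library linear resize.  The output pixel
#' pitch is the input pitch divided by the magnification.
#'
#' @param ion an [ion_image] or numeric matrix.
#' @param magnification integer >= 1.
#' @return numeric matrix of shape `dim * magnification`, with attribute
#'   `pixel_pitch_um` when the input was an [ion_image].
#' @export
upscale_bilinear <- function(ion, magnification) {
  if (!is_count(magnification))
    stopf("magnification must be a positive integer")
  m <- as.integer(magnification)
  v <- if (inherits(ion, "ion_image")) ion$values else as.matrix(ion)
  h <- nrow(v); w <- ncol(v)
  if (m == 1L) {
    out <- v
  } else {
    src_r <- pmin(pmax((seq_len(h * m) - 0.5) / m - 0.5, 0), h - 1)
    src_c <- pmin(pmax((seq_len(w * m) - 0.5) / m - 0.5, 0), w - 1)
    r0 <- floor(src_r); fr <- src_r - r0; r1 <- pmin(r0 + 1, h - 1)
    c0 <- floor(src_c); fc <- src_c - c0; c1 <- pmin(c0 + 1, w - 1)
    out <- v[r0 + 1, c0 + 1] * ((1 - fr) %o% (1 - fc)) +
           v[r1 + 1, c0 + 1] * (fr %o% (1 - fc)) +
           v[r0 + 1, c1 + 1] * ((1 - fr) %o% fc) +
           v[r1 + 1, c1 + 1] * (fr %o% fc)
  }
  if (inherits(ion, "ion_image"))
    attr(out, "pixel_pitch_um") <- ion$pixel_pitch_um / m
  out
}

#' Validate the registration contract and build the training pair
#'
#' Registration is performed externally (manual landmarks, e.g. BigWarp);
#' this function enforces its output contract — the microscopy grid must be
#' exactly `magnification` times the ion grid in both dimensions — and then
#' assembles the normalized pair: the microscopy channels and the bilinearly
#' magnified ion target, each min-max normalized to `[0, 1]` so the two loss
#' terms share a scale.
#'
#' @param microscopy a [microscopy_image].
#' @param ion an [ion_image].
#' @param magnification positive integer factor.
#' @return an object of class `registered_pair` with elements `microscopy`
#'   (H x W x 3 array), `ion_interp` (H x W matrix), `magnification`,
#'   `ion_native_shape`, and the recorded normalization ranges.
#' @export
validate_registration <- function(microscopy, ion, magnification) {
  stopifnot(inherits(microscopy, "microscopy_image"),
            inherits(ion, "ion_image"))
  if (!is_count(magnification))
    stopf("magnification must be a positive integer")
  m <- as.integer(magnification)
  mdim <- dim(microscopy$values)[1:2]
  idim <- dim(ion$values)
  if (!all(mdim == idim * m))
    stopf(paste0("registration contract violated: microscopy is %d x %d ",
                 "but ion %d x %d at magnification %d requires %d x %d"),
          mdim[1], mdim[2], idim[1], idim[2], m, idim[1] * m, idim[2] * m,
          class = "msifuse_registration_error")
  micro_norm <- minmax_normalize(microscopy$values)
  ion_up <- upscale_bilinear(ion, m)
  ion_norm <- minmax_normalize(ion_up)
  structure(list(microscopy = array(micro_norm, dim = dim(microscopy$values)),
                 ion_interp = matrix(ion_norm, mdim[1], mdim[2]),
                 magnification = m,
                 ion_native_shape = idim,
                 micro_range = c(attr(micro_norm, "range_min"),
                                 attr(micro_norm, "range_max")),
                 ion_range = c(attr(ion_norm, "range_min"),
                               attr(ion_norm, "range_max"))),
            class = "registered_pair")
}

#' @export
print.registered_pair <- function(x, ...) {
  cat(sprintf(
    "<registered_pair> microscopy %d x %d x 3, ion %d x %d at %dx\n",
    dim(x$microscopy)[1], dim(x$microscopy)[2],
    x$ion_native_shape[1], x$ion_native_shape[2], x$magnification))
  invisible(x)
}

#' Convert an RGB image to luminance
#'
#' Rec. 601 weights: `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param img a [microscopy_image] or H x W x 3 array.
#' @return H x W matrix in `[0, 1]`.
#' @export
to_luminance <- function(img) {
  v <- if (inherits(img, "microscopy_image")) img$values else img
  if (!is.array(v) || length(dim(v)) != 3L || dim(v)[3] != 3L)
    stopf("expected a 3-channel image")
  0.299 * v[, , 1] + 0.587 * v[, , 2] + 0.114 * v[, , 3]
}
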