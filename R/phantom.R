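# Seeded synthetic plant-tissue phantoms: a high-resolution "microscopy"
# image with dark cell-wall boundaries, a matching high-resolution ground
# truth ion abundance map, and its block-downsampled + noised low-resolution
# ion image.  Everything downstream of registration is testable against the
# generator's own ground truth.

#' Specification of a synthetic tissue phantom
#'
#' Cell geometry is a seeded Voronoi tessellation; cells are assigned to one
#' of three concentric tissue classes (outer epidermis-like rim, mid
#' mesophyll-like zone, central vascular-like core) and draw their mean ion
#' abundance from `abundance_profile` with a per-cell jitter.  Cell walls
#' (region boundaries, 1-2 px) are darkened in the microscopy channels and
#' attenuated in the ion truth by `wall_darkness`.
#'
#' @param hr_shape high-resolution grid `c(rows, cols)`; both divisible by
#'   `magnification`.
#' @param magnification integer downsampling factor to the low-resolution
#'   ion grid.
#' @param n_cells number of Voronoi cells (>= 2).
#' @param wall_darkness boundary darkening/attenuation fraction in `[0, 1]`.
#' @param abundance_profile named mean abundances per tissue class.
#' @param abundance_jitter fractional per-cell abundance variation: each
#'   cell's abundance is its class mean times a uniform draw from
#'   `[1 - abundance_jitter, 1 + abundance_jitter]`.
#' @param noise_sd Gaussian noise s.d. added to the downsampled ion image
#'   (intensities are on a 0-1 scale).
#' @param seed integer RNG seed; identical seeds give bit-identical phantoms.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(hr_shape = c(64L, 64L),
                         magnification = 8L,
                         n_cells = 25L,
                         wall_darkness = 0.6,
                         abundance_profile = c(epidermis = 0.25,
                                               mesophyll = 0.95,
                                               vascular = 0.5),
                         abundance_jitter = 0.2,
                         noise_sd = 0.02,
                         seed = 1L) {
  hr_shape <- as.integer(hr_shape)
  if (length(hr_shape) != 2L || any(hr_shape < 2L))
    stopf("hr_shape must be two integers >= 2")
  if (!is_count(magnification))
    stopf("magnification must be a positive integer")
  if (any(hr_shape %% magnification != 0L))
    stopf("hr_shape (%d x %d) must be divisible by magnification (%d)",
          hr_shape[1], hr_shape[2], magnification)
  if (!is_count(n_cells) || n_cells < 2)
    stopf("n_cells must be an integer >= 2")
  if (!is.numeric(wall_darkness) || wall_darkness < 0 || wall_darkness > 1)
    stopf("wall_darkness must lie in [0, 1]")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stopf("noise_sd must be non-negative")
  if (is.null(names(abundance_profile)) || any(abundance_profile < 0))
    stopf("abundance_profile must be a named non-negative vector")
  if (!is.numeric(abundance_jitter) || abundance_jitter < 0 ||
      abundance_jitter >= 1)
    stopf("abundance_jitter must lie in [0, 1)")
  structure(list(hr_shape = hr_shape,
                 magnification = as.integer(magnification),
                 n_cells = as.integer(n_cells),
                 wall_darkness = wall_darkness,
                 abundance_profile = abundance_profile,
                 abundance_jitter = abundance_jitter,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Assign each Voronoi site to a concentric tissue class by its normalized
# elliptical radius from the image center.
classify_sites <- function(sites_r, sites_c, hr_shape, classes) {
  rad <- sqrt(((sites_r - hr_shape[1] / 2) / (hr_shape[1] / 2))^2 +
              ((sites_c - hr_shape[2] / 2) / (hr_shape[2] / 2))^2)
  cls <- character(length(rad))
  k <- length(classes)
  if (k == 1L) return(rep(classes, length(rad)))
  # outermost class at rad > 0.75, innermost below 0.4; middle in between
  cut_hi <- 0.75; cut_lo <- 0.4
  cls[rad > cut_hi] <- classes[1L]
  cls[rad <= cut_lo] <- classes[k]
  mid <- classes[max(2L, k - 1L)]
  cls[cls == ""] <- mid
  cls
}

#' Generate a synthetic tissue phantom triplet
#'
#' @param spec a [phantom_spec].
#' @return an object of class `phantom_triplet` with elements `microscopy`
#'   ([microscopy_image]), `ion_truth_hr` (matrix), `ion_lr` ([ion_image]),
#'   plus the generator's `boundary_mask`, `region_id` and `spec` for
#'   ground-truth assertions.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$hr_shape[1]; W <- spec$hr_shape[2]
  classes <- names(spec$abundance_profile)

  with_seed(spec$seed, {
    sites_r <- runif(spec$n_cells, 0.5, H - 0.5)
    sites_c <- runif(spec$n_cells, 0.5, W - 0.5)

    # nearest-site (Voronoi) region id per pixel, pixel centers at i-0.5
    pr <- matrix(seq_len(H) - 0.5, H, W)
    pc <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)
    d2 <- matrix(Inf, H, W)
    region <- matrix(1L, H, W)
    for (s in seq_len(spec$n_cells)) {
      ds <- (pr - sites_r[s])^2 + (pc - sites_c[s])^2
      upd <- ds < d2
      region[upd] <- s
      d2[upd] <- ds[upd]
    }

    # boundary: any 4-neighbor in a different region (marks both sides)
    boundary <- matrix(FALSE, H, W)
    boundary[-H, ] <- boundary[-H, ] | (region[-H, ] != region[-1, ])
    boundary[-1, ] <- boundary[-1, ] | (region[-1, ] != region[-H, ])
    boundary[, -W] <- boundary[, -W] | (region[, -W] != region[, -1])
    boundary[, -1] <- boundary[, -1] | (region[, -1] != region[, -W])

    cls <- classify_sites(sites_r, sites_c, spec$hr_shape, classes)

    # per-cell abundance and color
    abu_cell <- spec$abundance_profile[cls] *
      runif(spec$n_cells, 1 - spec$abundance_jitter,
            1 + spec$abundance_jitter)
    base_colors <- rbind(epidermis = c(0.40, 0.55, 0.30),
                         mesophyll = c(0.60, 0.78, 0.45),
                         vascular  = c(0.78, 0.66, 0.45))
    col_cell <- matrix(0, spec$n_cells, 3L)
    for (s in seq_len(spec$n_cells)) {
      base <- if (cls[s] %in% rownames(base_colors)) base_colors[cls[s], ]
              else c(0.6, 0.6, 0.6)
      col_cell[s, ] <- clamp01(base + rnorm(3L, 0, 0.05))
    }

    micro <- array(0, dim = c(H, W, 3L))
    for (ch in 1:3) {
      plane <- matrix(col_cell[region, ch], H, W)
      plane <- plane + matrix(rnorm(H * W, 0, 0.01), H, W)
      plane[boundary] <- plane[boundary] * (1 - spec$wall_darkness)
      micro[, , ch] <- clamp01(plane)
    }

    truth <- matrix(abu_cell[region], H, W)
    truth[boundary] <- truth[boundary] * (1 - spec$wall_darkness)

    lr <- degrade(truth, spec$magnification, spec$noise_sd,
                  seed = spec$seed + 1000L)
    lr$pixel_pitch_um <- spec$magnification  # HR pitch is 1 um by convention

    structure(list(microscopy = microscopy_image(micro, "synthetic phantom"),
                   ion_truth_hr = truth,
                   ion_lr = lr,
                   boundary_mask = boundary,
                   region_id = region,
                   spec = spec),
              class = "phantom_triplet")
  })
}

#' Degrade a high-resolution ion map to a noisy low-resolution ion image
#'
#' Block-mean downsampling by `magnification` (the MSI pixel integrates
#' signal over its footprint), then seeded Gaussian noise clipped at 0.
#'
#' @param ion_truth_hr numeric matrix with dimensions divisible by
#'   `magnification`.
#' @param magnification positive integer block size.
#' @param noise_sd non-negative Gaussian noise s.d.
#' @param seed integer RNG seed for the noise.
#' @return an [ion_image] of shape `dim(ion_truth_hr) / magnification`.
#' @export
degrade <- function(ion_truth_hr, magnification, noise_sd = 0, seed = 1L) {
  v <- as.matrix(ion_truth_hr)
  if (!is_count(magnification))
    stopf("magnification must be a positive integer")
  m <- as.integer(magnification)
  if (any(dim(v) %% m != 0L))
    stopf("grid %d x %d is not divisible by magnification %d",
          nrow(v), ncol(v), m)
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  h <- nrow(v) %/% m; w <- ncol(v) %/% m
  arr <- array(v, dim = c(m, h, m, w))
  lr <- colMeans(aperm(arr, c(1L, 3L, 2L, 4L)), dims = 2L)
  if (noise_sd > 0) {
    lr <- with_seed(seed, lr + matrix(rnorm(h * w, 0, noise_sd), h, w))
    lr <- pmax(lr, 0)
  }
  ion_image(lr, pixel_pitch_um = m)
}
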