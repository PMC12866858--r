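# External representations: imzML/ibd MSI data, CSV ion-image grids,
# TIFF/PNG microscopy, and fused outputs.
#
# Internal conventions: coordinates are 0-based (row, col), origin top-left,
# row-major; imzML's 1-based pixel indices (x = column, y = row) are shifted
# on read.  Images are matrices / H x W x 3 arrays indexed [row, col(, ch)].

#' MSI dataset container
#'
#' A list of spectra on a rectangular pixel grid. Each spectrum is a list with
#' `coord` (0-based `c(row, col)`), `mz` (strictly increasing numeric) and
#' `intensity` (same length as `mz`).
#'
#' @param spectra list of spectra as described above.
#' @param grid_shape integer `c(n_rows, n_cols)`.
#' @param pixel_pitch_um positive pixel pitch in micrometers.
#' @return an object of class `msi_dataset`.
#' @export
msi_dataset <- function(spectra, grid_shape, pixel_pitch_um = 1) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 1L))
    stopf("grid_shape must be two positive integers")
  if (!is.numeric(pixel_pitch_um) || length(pixel_pitch_um) != 1L ||
      !is.finite(pixel_pitch_um) || pixel_pitch_um <= 0)
    stopf("pixel_pitch_um must be a positive real")
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    if (!all(c("coord", "mz", "intensity") %in% names(sp)))
      stopf("spectrum %d lacks coord/mz/intensity", i)
    co <- sp$coord
    if (length(co) != 2L || any(co < 0) || co[1] >= grid_shape[1] ||
        co[2] >= grid_shape[2])
      stopf("spectrum %d coordinate (%s) outside grid %d x %d",
            i, paste(co, collapse = ","), grid_shape[1], grid_shape[2],
            class = "msifuse_integrity_error")
    if (length(sp$mz) != length(sp$intensity))
      stopf("spectrum %d: m/z and intensity lengths differ", i)
    if (length(sp$mz) > 1L && any(diff(sp$mz) <= 0))
      stopf("spectrum %d: m/z values are not strictly increasing", i)
  }
  structure(list(spectra = spectra, grid_shape = grid_shape,
                 pixel_pitch_um = as.numeric(pixel_pitch_um)),
            class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("<msi_dataset> %d x %d grid, %d spectra, pitch %.3g um\n",
              x$grid_shape[1], x$grid_shape[2], length(x$spectra),
              x$pixel_pitch_um))
  invisible(x)
}

#' Single-ion intensity image
#'
#' @param values non-negative finite numeric matrix (rows = image rows,
#'   top row first).
#' @param pixel_pitch_um positive pixel pitch in micrometers.
#' @param mz_center,mz_tolerance_ppm optional provenance of the extraction
#'   window.
#' @return an object of class `ion_image`.
#' @export
ion_image <- function(values, pixel_pitch_um = 1, mz_center = NULL,
                      mz_tolerance_ppm = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(!is.finite(values)))
    stopf("ion image contains non-finite values")
  if (any(values < 0))
    stopf("ion image contains negative intensities")
  if (!is.numeric(pixel_pitch_um) || pixel_pitch_um <= 0)
    stopf("pixel_pitch_um must be a positive real")
  structure(list(values = values, pixel_pitch_um = as.numeric(pixel_pitch_um),
                 mz_center = mz_center, mz_tolerance_ppm = mz_tolerance_ppm),
            class = "ion_image")
}

#' @export
print.ion_image <- function(x, ...) {
  cat(sprintf("<ion_image> %d x %d, pitch %.3g um%s\n",
              nrow(x$values), ncol(x$values), x$pixel_pitch_um,
              if (!is.null(x$mz_center))
                sprintf(", m/z %.4f +/- %g ppm", x$mz_center,
                        x$mz_tolerance_ppm) else ""))
  invisible(x)
}

#' Registered high-resolution microscopy image
#'
#' @param values H x W x 3 array with values in `[0, 1]`.
#' @param provenance free-text origin (e.g. source file path).
#' @return an object of class `microscopy_image`.
#' @export
microscopy_image <- function(values, provenance = "") {
  if (!is.array(values) || length(dim(values)) != 3L || dim(values)[3] != 3L)
    stopf("microscopy image must be an H x W x 3 array")
  storage.mode(values) <- "double"
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1))
    stopf("microscopy values must be finite and within [0, 1]")
  structure(list(values = values, provenance = as.character(provenance)),
            class = "microscopy_image")
}

# ---------------------------------------------------------------------------
# imzML

imzml_ibd_path <- function(path) {
  sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
}

cv_value <- function(node, accession) {
  n <- xml2::xml_find_first(
    node, sprintf(".//cvParam[@accession='%s']", accession))
  if (inherits(n, "xml_missing")) NULL else xml2::xml_attr(n, "value")
}

has_cv <- function(node, accession) {
  !inherits(xml2::xml_find_first(
    node, sprintf(".//cvParam[@accession='%s']", accession)), "xml_missing")
}

#' Read an imzML/ibd pair into an MSI dataset
#'
#' Supports continuous and processed mode with uncompressed 32- or 64-bit
#' float binary arrays (the common export configuration).  imzML 1-based
#' pixel positions (`position x` = column, `position y` = row) become
#' 0-based `(row, col)` coordinates.
#'
#' @param path path to the `.imzML` file; the `.ibd` companion must sit next
#'   to it.
#' @return an [msi_dataset].
#' @export
read_imzml <- function(path) {
  if (!file.exists(path)) stopf("imzML file not found: %s", path)
  ibd <- imzml_ibd_path(path)
  if (!file.exists(ibd))
    stopf("missing .ibd companion for %s", path,
          class = "msifuse_format_error")
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  # dtype per referenceable param group id
  groups <- xml2::xml_find_all(doc, "//referenceableParamGroup")
  group_info <- list()
  for (g in groups) {
    id <- xml2::xml_attr(g, "id")
    group_info[[id]] <- list(
      is_mz = has_cv(g, "MS:1000514"),
      is_intensity = has_cv(g, "MS:1000515"),
      bytes = if (has_cv(g, "MS:1000521")) 4L else 8L
    )
  }

  max_x <- cv_value(doc, "IMS:1000042")
  max_y <- cv_value(doc, "IMS:1000043")
  pitch <- cv_value(doc, "IMS:1000046")
  pitch <- if (is.null(pitch)) 1 else as.numeric(pitch)

  con <- file(ibd, "rb")
  on.exit(close(con))

  read_array <- function(bda) {
    off <- as.numeric(cv_value(bda, "IMS:1000102"))
    n <- as.integer(cv_value(bda, "IMS:1000103"))
    ref <- xml2::xml_find_first(bda, ".//referenceableParamGroupRef")
    info <- NULL
    if (!inherits(ref, "xml_missing"))
      info <- group_info[[xml2::xml_attr(ref, "ref")]]
    is_mz <- if (!is.null(info)) info$is_mz else has_cv(bda, "MS:1000514")
    bytes <- if (!is.null(info)) info$bytes else
      if (has_cv(bda, "MS:1000521")) 4L else 8L
    if (is.na(off) || is.na(n))
      stopf("binary array lacks external offset/length",
            class = "msifuse_format_error")
    seek(con, where = off, origin = "start")
    vals <- readBin(con, "double", n = n, size = bytes, endian = "little")
    list(is_mz = is_mz, values = vals)
  }

  spec_nodes <- xml2::xml_find_all(doc, "//spectrum")
  spectra <- vector("list", length(spec_nodes))
  max_row <- -1L; max_col <- -1L
  for (i in seq_along(spec_nodes)) {
    sn <- spec_nodes[[i]]
    x <- as.integer(cv_value(sn, "IMS:1000050"))
    y <- as.integer(cv_value(sn, "IMS:1000051"))
    if (is.na(x) || is.na(y))
      stopf("spectrum %d lacks pixel position", i,
            class = "msifuse_format_error")
    if (!is.null(max_x) && (x > as.integer(max_x) || x < 1L))
      stopf("spectrum %d: position x=%d outside declared max count %s",
            i, x, max_x, class = "msifuse_integrity_error")
    if (!is.null(max_y) && (y > as.integer(max_y) || y < 1L))
      stopf("spectrum %d: position y=%d outside declared max count %s",
            i, y, max_y, class = "msifuse_integrity_error")
    bdas <- xml2::xml_find_all(sn, ".//binaryDataArray")
    mz <- NULL; inten <- NULL
    for (bda in bdas) {
      arr <- read_array(bda)
      if (arr$is_mz) mz <- arr$values else inten <- arr$values
    }
    if (is.null(mz) || is.null(inten))
      stopf("spectrum %d lacks m/z or intensity array", i,
            class = "msifuse_format_error")
    row <- y - 1L; col <- x - 1L
    max_row <- max(max_row, row); max_col <- max(max_col, col)
    spectra[[i]] <- list(coord = c(row, col), mz = mz, intensity = inten)
  }
  msi_dataset(spectra, grid_shape = c(max_row + 1L, max_col + 1L),
              pixel_pitch_um = pitch)
}

#' Write a minimal imzML/ibd pair (fixture writer)
#'
#' Processed-mode, uncompressed 64-bit float writer intended for tests and
#' round-trip checks, not production export.
#'
#' @param ds an [msi_dataset].
#' @param path output `.imzML` path; the `.ibd` is written alongside.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(ds, path) {
  stopifnot(inherits(ds, "msi_dataset"))
  ibd <- imzml_ibd_path(path)
  uuid <- paste(sprintf("%02x", 0:15), collapse = "")
  con <- file(ibd, "wb")
  writeBin(as.raw(0:15), con)  # 16-byte fixture UUID
  offset <- 16
  entries <- vector("list", length(ds$spectra))
  for (i in seq_along(ds$spectra)) {
    sp <- ds$spectra[[i]]
    n <- length(sp$mz)
    writeBin(as.double(sp$mz), con, size = 8, endian = "little")
    mz_off <- offset; offset <- offset + 8 * n
    writeBin(as.double(sp$intensity), con, size = 8, endian = "little")
    int_off <- offset; offset <- offset + 8 * n
    entries[[i]] <- list(n = n, mz_off = mz_off, int_off = int_off,
                         row = sp$coord[1], col = sp$coord[2])
  }
  close(con)

  bda <- function(ref, off, n) {
    paste0(
      '<binaryDataArray encodedLength="0">',
      sprintf('<referenceableParamGroupRef ref="%s"/>', ref),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>', off),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>', n),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>', 8L * n),
      '<binary/></binaryDataArray>')
  }
  spect <- vapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    paste0(
      sprintf('<spectrum id="spectrum=%d" index="%d" defaultArrayLength="%d">',
              i, i - 1L, e$n),
      '<scanList count="1"><scan>',
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>', e$col + 1L),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>', e$row + 1L),
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      bda("mzArray", e$mz_off, e$n),
      bda("intensityArray", e$int_off, e$n),
      '</binaryDataArrayList></spectrum>')
  }, character(1))

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="IMS" accession="IMS:1000031" name="processed" value=""/>',
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>', uuid),
    '</fileContent></fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    '<softwareList count="1"><software id="msifuse" version="0.1.0"/></softwareList>',
    '<scanSettingsList count="1"><scanSettings id="scanSettings1">',
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>', ds$grid_shape[2]),
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>', ds$grid_shape[1]),
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size (x)" value="%g"/>', ds$pixel_pitch_um),
    '</scanSettings></scanSettingsList>',
    '<instrumentConfigurationList count="1">',
    '<instrumentConfiguration id="IC1"/>',
    '</instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="DP1">',
    '<processingMethod order="1" softwareRef="msifuse"/>',
    '</dataProcessing></dataProcessingList>',
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">',
    '<spectrumList count="', length(entries),
    '" defaultDataProcessingRef="DP1">',
    paste(spect, collapse = ""),
    '</spectrumList></run></mzML>\n')
  writeLines(xml, path, sep = "")
  invisible(path)
}

#' Extract a single-ion image from an MSI dataset
#'
#' Per pixel, sums the intensities of all peaks within a ppm window around
#' `mz`; pixels with no spectrum (or no matching peak) are 0.
#'
#' @param ds an [msi_dataset].
#' @param mz positive target m/z.
#' @param tol_ppm positive ppm half-width of the extraction window.
#' @return an [ion_image].
#' @export
extract_ion_image <- function(ds, mz, tol_ppm = 5) {
  stopifnot(inherits(ds, "msi_dataset"))
  if (!is.numeric(mz) || length(mz) != 1L || !is.finite(mz) || mz <= 0)
    stopf("mz must be a positive real")
  if (!is.numeric(tol_ppm) || tol_ppm <= 0)
    stopf("tol_ppm must be a positive real")
  vals <- matrix(0, ds$grid_shape[1], ds$grid_shape[2])
  for (sp in ds$spectra) {
    sel <- abs(sp$mz - mz) / mz * 1e6 <= tol_ppm
    if (any(sel)) {
      r <- sp$coord[1] + 1L; c <- sp$coord[2] + 1L
      vals[r, c] <- vals[r, c] + sum(sp$intensity[sel])
    }
  }
  ion_image(vals, pixel_pitch_um = ds$pixel_pitch_um, mz_center = mz,
            mz_tolerance_ppm = tol_ppm)
}

# ---------------------------------------------------------------------------
# CSV grids

#' Read an ion image from a CSV intensity grid
#'
#' Comma-separated, period decimal, rows = image rows with the top row first.
#'
#' @param path CSV file path.
#' @param has_header if `TRUE` the first row is discarded.
#' @param pixel_pitch_um pixel pitch to attach (CSV carries none).
#' @return an [ion_image].
#' @export
read_ion_csv <- function(path, has_header = FALSE, pixel_pitch_um = 1) {
  ion_image(read_numeric_csv(path, has_header),
            pixel_pitch_um = pixel_pitch_um)
}

# Strict rectangular numeric CSV parser (internal); errors carry the first
# offending row/column.
read_numeric_csv <- function(path, has_header = FALSE) {
  if (!file.exists(path)) stopf("CSV file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (has_header) lines <- lines[-1L]
  if (length(lines) == 0L)
    stopf("CSV contains no data rows", class = "msifuse_format_error")
  cells <- strsplit(lines, ",", fixed = TRUE)
  ncols <- lengths(cells)
  if (length(unique(ncols)) != 1L)
    stopf("ragged CSV: row %d has %d cells, expected %d",
          which(ncols != ncols[1])[1], ncols[ncols != ncols[1]][1], ncols[1],
          class = "msifuse_format_error")
  vals <- suppressWarnings(
    vapply(cells, function(x) as.numeric(trimws(x)), numeric(ncols[1])))
  vals <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = 1L)
  if (any(is.na(vals))) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stopf("non-numeric cell at row %d, column %d", bad[1], bad[2],
          class = "msifuse_parse_error")
  }
  vals
}

#' Write an ion image (or plain matrix) as a CSV grid
#'
#' Full `%.17g` precision so that a read/write round trip is lossless at
#' double precision.
#'
#' @param img an [ion_image] or numeric matrix.
#' @param path output path.
#' @param header optional character vector of column names.
#' @return `path`, invisibly.
#' @export
write_ion_csv <- function(img, path, header = NULL) {
  vals <- if (inherits(img, "ion_image")) img$values else as.matrix(img)
  rows <- apply(vals, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  if (!is.null(header)) rows <- c(paste(header, collapse = ","), rows)
  writeLines(rows, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Microscopy and fused images

#' Read a registered microscopy image (TIFF or PNG)
#'
#' 8/16-bit values are rescaled to `[0, 1]` (the underlying readers divide by
#' the dtype maximum).  Grayscale input is replicated to 3 channels; an alpha
#' channel is dropped with a warning.
#'
#' @param path image path, extension `.tif`, `.tiff` or `.png`.
#' @return a [microscopy_image].
#' @export
read_microscopy <- function(path) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stopf("unsupported image extension '%s'", ext))
  if (is.matrix(vals)) vals <- array(vals, dim = c(dim(vals), 1L))
  nc <- dim(vals)[3]
  if (nc %in% c(2L, 4L)) {
    warning("dropping alpha channel from ", path)
    vals <- vals[, , -nc, drop = FALSE]
    nc <- dim(vals)[3]
  }
  if (nc == 1L) vals <- array(rep(vals, 3L), dim = c(dim(vals)[1:2], 3L))
  if (dim(vals)[3] != 3L)
    stopf("cannot coerce %d-channel image to RGB", nc)
  microscopy_image(clamp01(vals), provenance = path)
}

#' Write a fused image as 16-bit TIFF plus a lossless sidecar
#'
#' The TIFF holds values clipped to `[0, 1]` at 16-bit depth; the sidecar
#' (`<path>.values.csv`) keeps the raw floats, and `<path>.json` records
#' provenance (config hash, best epoch).
#'
#' @param img a [fused_image] (or numeric matrix).
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_fused <- function(img, path) {
  if (is.matrix(img)) img <- fused_image(img)
  stopifnot(inherits(img, "fused_image"))
  tiff::writeTIFF(clamp01(img$values), path, bits.per.sample = 16L)
  write_ion_csv(img$values, paste0(path, ".values.csv"))
  jsonlite::write_json(
    list(config_hash = img$config_hash,
         epoch_of_best = if (is.na(img$epoch_of_best)) NULL
                         else img$epoch_of_best,
         n_rows = nrow(img$values), n_cols = ncol(img$values)),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read back a fused image written by [write_fused()]
#'
#' @param path the TIFF path passed to [write_fused()].
#' @param sidecar if `TRUE` (default) and the float sidecar exists, the raw
#'   float values are used; otherwise the 16-bit TIFF is read.
#' @return a [fused_image].
#' @export
read_fused <- function(path, sidecar = TRUE) {
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  side <- paste0(path, ".values.csv")
  vals <- if (sidecar && file.exists(side)) {
    read_numeric_csv(side)
  } else {
    v <- tiff::readTIFF(path)
    if (!is.matrix(v)) v <- v[, , 1]
    v
  }
  fused_image(vals,
              config_hash = if (!is.null(meta$config_hash)) meta$config_hash
                            else "",
              epoch_of_best = if (!is.null(meta$epoch_of_best))
                meta$epoch_of_best else NA_integer_)
}
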