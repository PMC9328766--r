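## Volume and planar image I/O plus result serialization.
##
## Integer TIFFs are rescaled by the dtype maximum (255 for 8-bit, 65535
## for 16-bit), never by the per-image maximum, so that a probability
## threshold means the same thing across images. Voxel spacing is always
## supplied by the caller rather than parsed from TIFF tags.

#' Read a multi-page TIFF stack as a ProbabilityVolume
#'
#' Pages map to z in page order; each page must share one 2D shape.
#' 8/16-bit integer samples are rescaled so the dtype maximum maps to
#' 1.0; 32-bit float samples are taken as-is and clipped to \[0, 1\].
#'
#' @param path path to a grayscale multi-page TIFF.
#' @param spacing numeric(3), voxel size in micrometres (z, y, x).
#' @param name identifier stored on the volume (defaults to the file name).
#' @return A [ProbabilityVolume-class].
#' @seealso [writeVolume()], [thresholdVolume()]
#' @export
readVolume <- function(path, spacing, name = basename(path)) {
  if (!file.exists(path)) stop("cannot read volume: ", path)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (z, y, x)")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] == 1L) p <- p[, , 1L]
      else stop("only grayscale TIFFs are supported: ", path)
    }
    p
  })
  shp <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1))))
    stop("inconsistent page shapes in ", path)
  arr <- array(0, c(length(pages), shp))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
  arr[arr < 0] <- 0
  arr[arr > 1] <- 1
  ProbabilityVolume(arr, spacing = spacing, name = name)
}

#' Write a volume or mask as a multi-page TIFF stack
#'
#' @param x a [ProbabilityVolume-class] or [AxonMask-class].
#' @param path output path.
#' @param bitsPerSample 8, 16 or 32 (32 writes IEEE float).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(x, path, bitsPerSample = 16L) {
  arr <- volumeData(x)
  if (is.logical(arr)) {
    storage.mode(arr) <- "double"
  }
  pages <- lapply(seq_len(dim(arr)[1]), function(z) arr[z, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bitsPerSample))
  invisible(path)
}

#' Read a 2D grayscale image (TIFF or PNG)
#'
#' Multi-channel images are averaged to one luminance channel.
#'
#' @param path path to a TIFF or PNG file (chosen by extension).
#' @param pixelSize micrometres per pixel, `NA` if unknown.
#' @return A [PlanarImage-class].
#' @export
readPlanarImage <- function(path, pixelSize = NA_real_) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  PlanarImage(img, pixelSize = pixelSize)
}

#' Write a 2D grayscale image (TIFF or PNG)
#'
#' Intensities outside \[0, 1\] are rescaled by the image maximum before
#' writing (both formats store normalized samples).
#'
#' @param x a [PlanarImage-class] or numeric matrix.
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
writePlanarImage <- function(x, path) {
  m <- if (is(x, "PlanarImage")) volumeData(x) else as.matrix(x)
  if (max(m) > 1 || min(m) < 0) m <- (m - min(m)) / (max(m) - min(m))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(m, path, bits.per.sample = 16L),
    png = png::writePNG(m, path),
    stop("unsupported image format: .", ext))
  invisible(path)
}

record_to_row <- function(r) {
  if (is(r, "MorphometryResult") || is(r, "ExpansionEstimate"))
    return(as.data.frame(r))
  if (is.data.frame(r)) return(r)
  as.data.frame(as.list(r), stringsAsFactors = FALSE)
}

#' Write result records to CSV or JSON
#'
#' Numbers are serialized with 17 significant digits, so reading the
#' file back with [readResults()] reproduces every field to full double
#' precision.
#'
#' @param records a data.frame, or a list of records sharing one schema
#'   (data.frames, named lists, [MorphometryResult-class] or
#'   [ExpansionEstimate-class] objects).
#' @param path output path.
#' @param format `"csv"` (RFC-4180, header row) or `"json"`.
#' @return `path`, invisibly.
#' @seealso [readResults()]
#' @export
writeResults <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (is.data.frame(records)) {
    df <- records
  } else if (length(records) == 0L) {
    stop("cannot infer a schema from an empty record list; ",
         "pass a (possibly zero-row) data.frame instead")
  } else {
    rows <- lapply(records, record_to_row)
    nms <- lapply(rows, names)
    if (!all(vapply(nms, identical, logical(1), nms[[1]])))
      stop("records do not share one schema")
    df <- do.call(rbind, rows)
  }
  if (format == "csv") {
    out <- df
    for (j in seq_along(out))
      if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
    write.csv(out, path, row.names = FALSE, quote = TRUE)
  } else {
    jsonlite::write_json(df, path, digits = I(17), auto_unbox = FALSE,
                         dataframe = "rows")
  }
  invisible(path)
}

#' Read result records written by writeResults
#'
#' @param path file written by [writeResults()].
#' @param format `"csv"` or `"json"`; guessed from the extension if missing.
#' @return A `data.frame`.
#' @export
readResults <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
  df
}
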