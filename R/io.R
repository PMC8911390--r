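# Reading angiogram rasters and reading/writing measurement results.
# The physical scale is always supplied by the caller/config: device image
# metadata dialects are unreliable, so it is never parsed from the file.

pngBitDepth <- function(path) {
  # IHDR bit depth is byte 25 of a PNG stream (8 signature + 4 length +
  # 4 type + 8 width/height + 1 depth).
  hdr <- readBin(path, "raw", n = 25L)
  if (length(hdr) < 25L) stopInput("'%s' is not a valid PNG", path)
  as.integer(hdr[25L])
}

luminance <- function(arr) {
  # Rec. 601 luma weights for RGB-encoded grayscale exports.
  if (length(dim(arr)) == 2L) return(arr)
  ch <- dim(arr)[3]
  if (ch == 1L) return(arr[, , 1L])
  if (ch >= 3L)
    return(0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L])
  arr[, , 1L] # grayscale + alpha
}

#' Read a grayscale en-face angiogram from PNG or TIFF
#'
#' Intensities are returned on their native integer scale: an 8-bit file
#' gives values in 0..255, a 16-bit file values in 0..65535 (never rescaled
#' down to 8-bit). RGB files are converted to luminance with Rec. 601
#' weights. The pixel scale is supplied by the caller, not parsed from
#' file metadata.
#'
#' @param path PNG or TIFF file path.
#' @param mmPerPixel positive isotropic pixel scale, mm/pixel.
#' @param sourceId identifier for results; defaults to the file name.
#' @return an [AngiogramImage-class].
#' @export
readAngiogram <- function(path, mmPerPixel,
                          sourceId = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stopInput("file '%s' does not exist", path)
  if (!is.numeric(mmPerPixel) || length(mmPerPixel) != 1L || mmPerPixel <= 0)
    stopValidation("mmPerPixel must be a positive scalar")
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    arr <- tryCatch(png::readPNG(path),
                    error = function(e) stopInput("cannot read PNG '%s': %s",
                                                  path, conditionMessage(e)))
    depth <- pngBitDepth(path)
    vals <- round(luminance(arr) * (2^depth - 1))
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                    error = function(e) stopInput("cannot read TIFF '%s': %s",
                                                  path, conditionMessage(e)))
    if (is.list(arr)) arr <- arr[[1L]]
    vals <- luminance(arr)
    if (max(vals) <= 1 && !all(vals == round(vals)))
      vals <- round(vals * 255) # float-normalized export
    vals <- round(vals)
  } else {
    stopInput("unsupported image format '%s' (PNG or TIFF expected)", ext)
  }
  if (length(vals) == 0L || nrow(vals) == 0L)
    stopValidation("zero-area image '%s'", path)
  angiogramImage(vals, mmPerPixel = mmPerPixel, sourceId = sourceId)
}

#' Write an 8-bit grayscale image or binary mask to PNG/TIFF
#'
#' @param x an [AngiogramImage-class] (values clipped to 0..255) or a
#'   [BinaryMask-class] (written as 0/255).
#' @param path output path ending in .png, .tif or .tiff.
#' @return `invisible(path)`.
#' @export
writeImage <- function(x, path) {
  m <- if (is(x, "BinaryMask")) (pixels(x) * 1) else pmin(pmax(pixels(x), 0), 255)
  m <- if (is(x, "BinaryMask")) m else m / 255
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") png::writePNG(m, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(m, path, bits.per.sample = 8L)
  else stopInput("unsupported output format '%s'", ext)
  invisible(path)
}

measurementToList <- function(m) {
  num <- function(v) if (is.finite(v)) v else NULL
  list(source_id = m@sourceId,
       area_mm2 = num(m@areaMm2),
       vpd = num(m@vpd),
       fd = num(m@fd),
       fd_r2 = num(m@fdR2),
       lac = num(m@lac),
       n_foreground_px = m@nForegroundPx,
       flags = as.list(m@flags))
}

#' Serialize a lesion measurement to JSON
#'
#' Numeric fields are written at full precision; a degenerate (NaN) metric
#' is serialized as an explicit `null` and recorded in the `flags` array.
#'
#' @param measurement a [LesionMeasurement-class].
#' @param path output file path.
#' @return `invisible(path)`.
#' @export
writeMeasurement <- function(measurement, path) {
  jsonlite::write_json(measurementToList(measurement), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a lesion measurement from JSON
#'
#' @param path JSON file written by [writeMeasurement()].
#' @return a [LesionMeasurement-class].
#' @export
readMeasurement <- function(path) {
  if (!file.exists(path)) stopInput("file '%s' does not exist", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("source_id", "n_foreground_px")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stopInput("measurement JSON missing fields: %s", paste(missing, collapse = ", "))
  grab <- function(f) {
    v <- x[[f]]
    if (is.null(v)) NaN else as.numeric(v)
  }
  new("LesionMeasurement", sourceId = as.character(x$source_id),
      areaMm2 = grab("area_mm2"), vpd = grab("vpd"), fd = grab("fd"),
      fdR2 = grab("fd_r2"), lac = grab("lac"),
      nForegroundPx = as.integer(x$n_foreground_px),
      flags = as.character(unlist(x$flags)))
}

measurementColumns <- c("source_id", "area_mm2", "vpd", "fd", "fd_r2", "lac",
                        "n_foreground_px")

#' Convert measurements to a batch data frame
#'
#' @param measurements list of [LesionMeasurement-class] objects.
#' @return data.frame with the stable column order
#'   `source_id, area_mm2, vpd, fd, fd_r2, lac, n_foreground_px`.
#' @export
measurementTable <- function(measurements) {
  if (is(measurements, "LesionMeasurement")) measurements <- list(measurements)
  rows <- lapply(measurements, function(m)
    data.frame(source_id = m@sourceId, area_mm2 = m@areaMm2, vpd = m@vpd,
               fd = m@fd, fd_r2 = m@fdR2, lac = m@lac,
               n_foreground_px = m@nForegroundPx,
               stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Write a batch measurement table to CSV
#'
#' @param measurements list of [LesionMeasurement-class] objects or a
#'   data.frame from [measurementTable()].
#' @param path output CSV path.
#' @return `invisible(path)`.
#' @export
writeMeasurementTable <- function(measurements, path) {
  tab <- if (is.data.frame(measurements)) measurements
         else measurementTable(measurements)
  utils::write.csv(tab[, measurementColumns], path, row.names = FALSE)
  invisible(path)
}

#' Read a batch measurement table from CSV
#'
#' @param path CSV path written by [writeMeasurementTable()].
#' @return data.frame with the documented columns.
#' @export
readMeasurementTable <- function(path) {
  if (!file.exists(path)) stopInput("file '%s' does not exist", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(measurementColumns, names(tab))
  if (length(missing))
    stopInput("measurement CSV missing columns: %s",
              paste(missing, collapse = ", "))
  tab
}
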