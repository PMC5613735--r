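# Stack reading/writing: per-slice TIFF/JPEG images ordered by a
# tab-separated manifest (index, filename, damaged flag).

.read_image_8bit <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    # as.is returns integer sample values for 8-bit files
    if (max(img) <= 1 && is.double(img)) img <- round(img * 255)
  } else if (ext %in% c("jpg", "jpeg")) {
    img <- round(jpeg::readJPEG(path) * 255)
  } else {
    stop(sprintf("unsupported image format '%s' for '%s' (TIFF or JPEG expected)",
                 ext, path), call. = FALSE)
  }
  storage.mode(img) <- "integer"
  if (is.matrix(img)) {
    img <- array(img, dim = c(dim(img), 3))  # promote grayscale to RGB
  } else if (dim(img)[3] > 3) {
    img <- img[, , 1:3, drop = FALSE]        # drop alpha if present
  }
  img
}

.write_image_8bit <- function(pixels, path, quality = 0.95) {
  ext <- tolower(tools::file_ext(path))
  arr <- pixels / 255
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(arr, path, bits.per.sample = 8, compression = "none")
  } else if (ext %in% c("jpg", "jpeg")) {
    jpeg::writeJPEG(arr, path, quality = quality)
  } else {
    stop(sprintf("unsupported image format '%s'", ext), call. = FALSE)
  }
  invisible(path)
}

#' Read an ordered section-image stack via its manifest
#'
#' The manifest is tab-separated text with a header line and columns
#' `index` (0-based slice position), `filename` (relative to the
#' manifest's directory) and `damaged` (0/1). Sections are returned
#' sorted by slice index. Grayscale source images are promoted to three
#' channels by replication; all slices must share one frame size.
#'
#' @param manifest_path path to the manifest file.
#' @return List of [rgb_section()] objects in slice order.
#' @export
read_stack <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop(sprintf("manifest not found: '%s'", manifest_path), call. = FALSE)
  }
  man <- utils::read.delim(manifest_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  req <- c("index", "filename", "damaged")
  if (!all(req %in% names(man))) {
    stop(sprintf("manifest '%s' must have columns: %s", manifest_path,
                 paste(req, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(man$index)) {
    stop("manifest: duplicate slice indices", call. = FALSE)
  }
  man <- man[order(man$index), , drop = FALSE]
  base <- dirname(manifest_path)
  sections <- vector("list", nrow(man))
  frame <- NULL
  for (i in seq_len(nrow(man))) {
    path <- file.path(base, man$filename[i])
    if (!file.exists(path)) {
      stop(sprintf("slice %d: image file '%s' not found", man$index[i],
                   man$filename[i]), call. = FALSE)
    }
    px <- .read_image_8bit(path)
    if (is.null(frame)) {
      frame <- dim(px)[1:2]
    } else if (!identical(dim(px)[1:2], frame)) {
      stop(sprintf("slice %d ('%s'): image size %dx%d differs from stack frame %dx%d",
                   man$index[i], man$filename[i], dim(px)[2], dim(px)[1],
                   frame[2], frame[1]), call. = FALSE)
    }
    sections[[i]] <- rgb_section(px, slice_index = man$index[i],
                                 damaged = man$damaged[i] != 0,
                                 source_name = man$filename[i])
  }
  sections
}

#' Read per-slice landmark coordinates
#'
#' Landmarks are whitespace-separated two-column text: `x` (column) then
#' `y` (row), 0-based pixel coordinates, one landmark per line; pairing
#' across slices is by row order.
#'
#' @param path landmark file path.
#' @return Numeric matrix with columns `x`, `y`.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("landmark file not found: '%s'", path), call. = FALSE)
  }
  m <- as.matrix(utils::read.table(path, header = FALSE,
                                   col.names = c("x", "y")))
  if (ncol(m) != 2 || nrow(m) < 1) {
    stop(sprintf("landmark file '%s': expected two columns (x, y)", path),
         call. = FALSE)
  }
  storage.mode(m) <- "double"
  m
}
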