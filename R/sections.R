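#' One stitched 2D section image (RGB, 8-bit)
#'
#' @param pixels integer array `dim = c(height, width, 3)`, values in
#'   `[0, 255]`.
#' @param slice_index 0-based position in the stack.
#' @param damaged logical flag: TRUE when the tissue background of this
#'   section is too weak to classify and the slice is to be repaired by
#'   nearest-neighbour label interpolation downstream.
#' @param source_name originating filename (informational).
#' @return An object of class `rgb_section`.
#' @export
rgb_section <- function(pixels, slice_index, damaged = FALSE, source_name = "") {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    stop("rgb_section: 'pixels' must be a height x width x 3 array", call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("rgb_section: intensities must be in [0, 255]", call. = FALSE)
  }
  structure(list(pixels = pixels,
                 slice_index = as.integer(slice_index),
                 damaged = isTRUE(damaged),
                 source_name = as.character(source_name)[1]),
            class = "rgb_section")
}

#' Single-channel 8-bit working slice
#'
#' The grayscale working image of one section after marking and/or
#' smoothing, aligned or unaligned.
#'
#' @param pixels integer matrix `height x width`, values in `[0, 255]`.
#' @param slice_index 0-based position in the stack.
#' @param damaged logical damage flag, propagated from the source section.
#' @param marked logical: whether the positive-region intensity boost has
#'   been applied (guards against double marking).
#' @return An object of class `gray_slice`.
#' @export
gray_slice <- function(pixels, slice_index, damaged = FALSE, marked = FALSE) {
  if (!is.matrix(pixels)) {
    stop("gray_slice: 'pixels' must be a height x width matrix", call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("gray_slice: intensities must be in [0, 255]", call. = FALSE)
  }
  structure(list(pixels = pixels,
                 slice_index = as.integer(slice_index),
                 damaged = isTRUE(damaged),
                 marked = isTRUE(marked)),
            class = "gray_slice")
}

#' @export
print.rgb_section <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("rgb_section %d: %d x %d px%s%s\n", x$slice_index, d[2], d[1],
              if (x$damaged) " [damaged]" else "",
              if (nzchar(x$source_name)) paste0(" <", x$source_name, ">") else ""))
  invisible(x)
}

#' @export
print.gray_slice <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("gray_slice %d: %d x %d px%s%s\n", x$slice_index, d[2], d[1],
              if (x$damaged) " [damaged]" else "",
              if (x$marked) " [marked]" else ""))
  invisible(x)
}
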