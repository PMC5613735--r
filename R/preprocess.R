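# Per-slice preprocessing: contrast normalization, red-channel marking
# of positively stained regions with grayscale conversion, Gaussian
# smoothing and down-sampling.

.clip8 <- function(x) pmin(pmax(x, 0), 255)

# round half-up to match the documented luma rounding rule
.round_half_up <- function(x) floor(x + 0.5)

#' Linear auto-contrast stretch
#'
#' Per-image linear rescale mapping the saturation-clipped low tail to 0
#' and the high tail to 255. The three channels are rescaled jointly
#' (one transfer function per image) so that hue relations — in
#' particular the red-channel dominance of positively stained regions —
#' are preserved. Constant images are returned unchanged.
#'
#' With `n` pixel samples and saturation fraction `s`, the clip bounds
#' are the sorted sample values at ranks `floor(s*n) + 1` and
#' `ceiling((1-s)*n)` (i.e. at most a fraction `s` of samples saturates
#' at each tail).
#'
#' @param section an [rgb_section()].
#' @param saturation fraction of samples saturated at each tail, in
#'   `[0, 0.5)`; 0 gives a pure min–max stretch.
#' @return The contrast-adjusted [rgb_section()].
#' @export
auto_contrast <- function(section, saturation = 0) {
  stopifnot(inherits(section, "rgb_section"))
  if (!is.numeric(saturation) || length(saturation) != 1 ||
      saturation < 0 || saturation >= 0.5) {
    stop("auto_contrast: 'saturation' must be in [0, 0.5)", call. = FALSE)
  }
  v <- sort(as.vector(section$pixels))
  n <- length(v)
  lo <- v[floor(saturation * n) + 1]
  hi <- v[ceiling((1 - saturation) * n)]
  if (hi <= lo) return(section)  # constant (or degenerate-clip) image
  px <- .round_half_up(.clip8((section$pixels - lo) * 255 / (hi - lo)))
  storage.mode(px) <- "integer"
  rgb_section(px, section$slice_index, section$damaged, section$source_name)
}

#' Mark positively stained regions and convert to grayscale
#'
#' Converts an RGB section to 8-bit grayscale by the standard luma
#' combination `0.299 R + 0.587 G + 0.114 B` (rounded half-up), then
#' marks every pixel whose red channel is at or above `red_threshold` by
#' adding `mark_boost` to its grayscale intensity (clipped to 255). The
#' boost lifts positive regions far above the tissue intensity band so
#' that the downstream intensity classification separates them cleanly.
#'
#' Passing an already-marked [gray_slice()] is an error: the marked flag
#' exists to surface pipeline-wiring bugs that would boost twice.
#'
#' @param section an [rgb_section()].
#' @param red_threshold 8-bit red-channel threshold (inclusive);
#'   typical working range 20–30, default 25.
#' @param mark_boost additive intensity for marked pixels (default 100).
#' @return A marked [gray_slice()]; damage flag propagated.
#' @export
mark_and_grayscale <- function(section, red_threshold = 25, mark_boost = 100) {
  if (inherits(section, "gray_slice")) {
    stop("mark_and_grayscale: input is already a gray_slice (double marking is an error)",
         call. = FALSE)
  }
  stopifnot(inherits(section, "rgb_section"))
  if (red_threshold < 0 || red_threshold > 255) {
    stop("mark_and_grayscale: 'red_threshold' must be in [0, 255]", call. = FALSE)
  }
  if (mark_boost < 0) stop("mark_and_grayscale: 'mark_boost' must be >= 0",
                           call. = FALSE)
  px <- section$pixels
  gray <- .round_half_up(0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3])
  pos <- px[, , 1] >= red_threshold
  gray[pos] <- gray[pos] + mark_boost
  gray <- .clip8(gray)
  storage.mode(gray) <- "integer"
  gray_slice(gray, section$slice_index, damaged = section$damaged, marked = TRUE)
}

# 1D normalized Gaussian kernel; radius 3*sigma captures > 99.7% of mass
.gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- ceiling(3 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# reflect (half-sample symmetric) index fold into [1, n]
.reflect_index <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  # fold repeatedly for kernels wider than the image
  repeat {
    under <- i < 1
    over <- i > n
    if (!any(under) && !any(over)) return(i)
    i[under] <- 1L - i[under]
    i[over] <- 2L * n + 1L - i[over]
  }
}

# separable Gaussian blur on a numeric matrix, reflective boundary;
# returns doubles (no 8-bit rounding) — the quantization happens once,
# after decimation
.gaussian_blur <- function(mat, sigma) {
  k <- .gaussian_kernel(sigma)
  if (length(k) == 1) return(mat + 0)
  r <- (length(k) - 1) / 2
  n_row <- nrow(mat); n_col <- ncol(mat)
  out <- matrix(0, n_row, n_col)
  for (j in seq_along(k)) {        # rows
    idx <- .reflect_index(seq_len(n_row) + (j - r - 1), n_row)
    out <- out + k[j] * mat[idx, , drop = FALSE]
  }
  out2 <- matrix(0, n_row, n_col)
  for (j in seq_along(k)) {        # columns
    idx <- .reflect_index(seq_len(n_col) + (j - r - 1), n_col)
    out2 <- out2 + k[j] * out[, idx, drop = FALSE]
  }
  out2
}

#' Gaussian smoothing and down-sampling of a slice
#'
#' Convolves with a normalized Gaussian kernel (reflective boundary so
#' the mean intensity is preserved), then keeps every `factor`-th pixel
#' in each dimension starting at index 0. Output dimensions are
#' `ceiling(dim / factor)`. `factor = 1` with `sigma = 0` is the
#' identity.
#'
#' @param slice a [gray_slice()].
#' @param sigma Gaussian standard deviation in pixels (`>= 0`; 0 skips
#'   smoothing). For anti-aliasing before decimation, `factor / 2` is a
#'   reasonable choice.
#' @param factor integer decimation factor `>= 1`, applied to both
#'   dimensions.
#' @return The smoothed, decimated [gray_slice()]; flags propagated.
#' @export
gaussian_downsample <- function(slice, sigma = 0, factor = 1) {
  stopifnot(inherits(slice, "gray_slice"))
  if (sigma < 0) stop("gaussian_downsample: 'sigma' must be >= 0", call. = FALSE)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) {
    stop("gaussian_downsample: 'factor' must be an integer >= 1", call. = FALSE)
  }
  d <- dim(slice$pixels)
  if (factor > min(d)) {
    stop(sprintf("gaussian_downsample: factor %d exceeds image extent %dx%d",
                 factor, d[2], d[1]), call. = FALSE)
  }
  sm <- .gaussian_blur(slice$pixels, sigma)
  rows <- seq(1, d[1], by = factor)
  cols <- seq(1, d[2], by = factor)
  px <- .clip8(.round_half_up(sm[rows, cols, drop = FALSE]))
  storage.mode(px) <- "integer"
  gray_slice(px, slice$slice_index, damaged = slice$damaged, marked = slice$marked)
}
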