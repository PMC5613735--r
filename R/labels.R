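#' Voxel class labels
#'
#' Integer codes for the three voxel classes produced by
#' [classify_volume()]: non-tissue background, negatively stained tissue,
#' and positively stained tissue.
#'
#' @format Integer scalars: `LABEL_BACKGROUND = 0L`,
#'   `LABEL_NEGATIVE = 1L`, `LABEL_POSITIVE = 2L`.
#' @name labels
NULL

#' @rdname labels
#' @export
LABEL_BACKGROUND <- 0L

#' @rdname labels
#' @export
LABEL_NEGATIVE <- 1L

#' @rdname labels
#' @export
LABEL_POSITIVE <- 2L

.all_labels <- function() c(LABEL_BACKGROUND, LABEL_NEGATIVE, LABEL_POSITIVE)

#' Volume metadata
#'
#' Voxel-grid geometry carried with a [label_volume()]: voxel counts,
#' physical spacing per voxel, grid origin, and a free-text unit tag.
#' Spacing values are stored verbatim as metadata; no unit conversion is
#' ever applied.
#'
#' @param dims integer vector `(nx, ny, nz)` of voxel counts, all >= 1.
#' @param spacing numeric vector `(dx, dy, dz)` of physical units per
#'   voxel, all > 0.
#' @param origin numeric vector `(x0, y0, z0)`.
#' @param unit_label free-text unit tag carried into reports and
#'   documentation.
#' @return An object of class `volume_meta`.
#' @export
volume_meta <- function(dims, spacing = c(5.8, 8.9, 2.5),
                        origin = c(0, 0, 0),
                        unit_label = "as published (mm)") {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(dims) != 3 || any(is.na(dims)) || any(dims < 1)) {
    stop("volume_meta: 'dims' must be three integers >= 1", call. = FALSE)
  }
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("volume_meta: 'spacing' must be three positive numbers", call. = FALSE)
  }
  if (length(origin) != 3 || any(!is.finite(origin))) {
    stop("volume_meta: 'origin' must be three finite numbers", call. = FALSE)
  }
  structure(list(dims = dims, spacing = spacing, origin = origin,
                 unit_label = as.character(unit_label)[1]),
            class = "volume_meta")
}

#' Labelled voxel volume
#'
#' A 3D grid of voxel class labels plus geometry metadata. Labels are
#' stored as an `(ny, nx, nz)` integer array (image row-major layout,
#' one z-plane per section) with values in
#' `{LABEL_BACKGROUND, LABEL_NEGATIVE, LABEL_POSITIVE}`.
#'
#' @param labels integer array with `dim = c(ny, nx, nz)` and values in
#'   the three-label set.
#' @param meta a [volume_meta()]; defaults to unit origin and the
#'   published spacing with `dims` taken from `labels`. If supplied, its
#'   `dims` must equal `(ncol, nrow, nslice)` of `labels`.
#' @return An object of class `label_volume` with elements `labels` and
#'   `meta`.
#' @export
label_volume <- function(labels, meta = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3) {
    stop("label_volume: 'labels' must be a 3D array (ny, nx, nz)", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  if (!all(labels %in% .all_labels())) {
    stop("label_volume: labels must be in {LABEL_BACKGROUND, LABEL_NEGATIVE, LABEL_POSITIVE}",
         call. = FALSE)
  }
  d <- dim(labels)
  dims <- c(d[2], d[1], d[3])  # (nx, ny, nz)
  if (is.null(meta)) {
    meta <- volume_meta(dims)
  } else {
    if (!inherits(meta, "volume_meta")) {
      stop("label_volume: 'meta' must be a volume_meta object", call. = FALSE)
    }
    if (!identical(as.integer(meta$dims), as.integer(dims))) {
      stop(sprintf("label_volume: meta dims (%s) do not match label grid (%s)",
                   paste(meta$dims, collapse = "x"),
                   paste(dims, collapse = "x")), call. = FALSE)
    }
  }
  structure(list(labels = labels, meta = meta), class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- x$meta$dims
  counts <- label_counts(x)
  cat(sprintf("label_volume: %d x %d x %d voxels (x, y, z), spacing %s [%s]\n",
              d[1], d[2], d[3],
              paste(format(x$meta$spacing, trim = TRUE), collapse = " x "),
              x$meta$unit_label))
  cat(sprintf("  background %d | negative %d | positive %d\n",
              counts[["background"]], counts[["negative"]], counts[["positive"]]))
  invisible(x)
}

#' Count voxels per class
#'
#' @param volume a [label_volume()].
#' @return Named integer vector with elements `background`, `negative`,
#'   `positive`; the three always sum to the voxel total.
#' @export
label_counts <- function(volume) {
  stopifnot(inherits(volume, "label_volume"))
  c(background = sum(volume$labels == LABEL_BACKGROUND),
    negative = sum(volume$labels == LABEL_NEGATIVE),
    positive = sum(volume$labels == LABEL_POSITIVE))
}
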