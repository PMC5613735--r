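# Three-class intensity segmentation, damaged-slice repair, seeded 3D
# region growing, and majority-label volume down-sampling.

#' Classify an aligned slice stack into a label volume
#'
#' Pixel-wise three-class intensity segmentation: intensity strictly
#' above `positive_above` is positively stained, intensity from
#' `background_below` up to `positive_above` (inclusive) is negatively
#' stained tissue, and intensity strictly below `background_below` is
#' non-tissue background. With the defaults (80 / 3): over 80 positive,
#' 3–80 negative, below 3 background. Every voxel receives exactly one
#' label.
#'
#' @param slices list of aligned [gray_slice()] objects sharing one
#'   frame, in stack order (one z-plane each).
#' @param positive_above 8-bit threshold; intensity > this is positive.
#' @param background_below 8-bit threshold; intensity < this is
#'   background. Must satisfy `0 <= background_below <= positive_above
#'   <= 255`.
#' @param meta optional [volume_meta()] for the resulting volume;
#'   defaults to the published spacing with origin 0.
#' @return A [label_volume()].
#' @export
classify_volume <- function(slices, positive_above = 80, background_below = 3,
                            meta = NULL) {
  stopifnot(length(slices) >= 1, all(vapply(slices, inherits, logical(1), "gray_slice")))
  if (background_below < 0 || positive_above > 255 ||
      background_below > positive_above) {
    stop("thresholds must satisfy 0 <= background_below <= positive_above <= 255",
         call. = FALSE)
  }
  d <- dim(slices[[1]]$pixels)
  nz <- length(slices)
  for (s in slices) {
    if (!identical(dim(s$pixels), d)) {
      stop("classify_volume: slices are not in a uniform frame", call. = FALSE)
    }
  }
  labels <- array(LABEL_BACKGROUND, dim = c(d[1], d[2], nz))
  for (k in seq_len(nz)) {
    px <- slices[[k]]$pixels
    lab <- matrix(LABEL_BACKGROUND, d[1], d[2])
    lab[px >= background_below] <- LABEL_NEGATIVE
    lab[px > positive_above] <- LABEL_POSITIVE
    labels[, , k] <- lab
  }
  label_volume(labels, meta)
}

#' Repair damaged slices by nearest-neighbour label interpolation
#'
#' For slices whose tissue background was too weak to classify, every
#' voxel labelled background or negative is replaced by the label at the
#' same `(x, y)` position in the nearest non-damaged slice (ties broken
#' toward lower z). Positive voxels on damaged slices are preserved —
#' the positive signal remains distinguishable even when the tissue
#' background is not. Non-damaged slices are unchanged.
#'
#' @param volume a [label_volume()].
#' @param damaged 0-based z indices of damaged slices.
#' @return The repaired [label_volume()].
#' @export
interpolate_damaged_slices <- function(volume, damaged) {
  stopifnot(inherits(volume, "label_volume"))
  nz <- dim(volume$labels)[3]
  damaged <- unique(as.integer(damaged))
  if (length(damaged) == 0) return(volume)
  if (any(damaged < 0 | damaged >= nz)) {
    stop(sprintf("damaged slice index out of range [0, %d)", nz), call. = FALSE)
  }
  good <- setdiff(seq_len(nz) - 1L, damaged)
  if (length(good) == 0) {
    stop("all slices are damaged: no donor slice for interpolation", call. = FALSE)
  }
  labels <- volume$labels
  for (z in damaged) {
    dist <- abs(good - z)
    donor <- good[order(dist, good)][1]  # ties -> lower z
    cur <- labels[, , z + 1L]
    don <- labels[, , donor + 1L]
    keep <- cur == LABEL_POSITIVE
    cur[!keep] <- don[!keep]
    labels[, , z + 1L] <- cur
  }
  label_volume(labels, volume$meta)
}

.neighbor_offsets <- function(connectivity) {
  if (connectivity == 6) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else if (connectivity == 26) {
    g <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dz = -1:1))
    g <- g[, c("dx", "dy", "dz")]
    unname(g[rowSums(abs(g)) > 0, , drop = FALSE])
  } else {
    stop("connectivity must be 6 or 26", call. = FALSE)
  }
}

#' Remove extra-organ noise by seeded 3D region growing
#'
#' Grows from a seed voxel through tissue voxels (negative or positive)
#' under the given connectivity; tissue voxels not reached — isolated
#' speckle and other noise outside the organ — are relabelled
#' background. Voxels inside the grown region keep their labels (a
#' positive voxel is never downgraded).
#'
#' @param volume a [label_volume()] containing at least one tissue
#'   voxel.
#' @param connectivity 6 (face neighbours, the default — conservative
#'   against diagonal leakage across the anisotropic z spacing) or 26.
#' @param seed `"auto"` (default) to use the tissue voxel nearest the
#'   centroid of all tissue voxels, or a 0-based `(x, y, z)` voxel
#'   coordinate that must lie on tissue.
#' @return List with `volume` (the cleaned [label_volume()]) and
#'   `removed` (count of tissue voxels relabelled background).
#' @export
region_grow_cleanup <- function(volume, connectivity = 6, seed = "auto") {
  stopifnot(inherits(volume, "label_volume"))
  offs <- .neighbor_offsets(connectivity)
  labels <- volume$labels
  d <- dim(labels)                     # (ny, nx, nz)
  tissue <- labels != LABEL_BACKGROUND
  if (!any(tissue)) stop("region growing: volume has no tissue voxels", call. = FALSE)
  if (identical(seed, "auto")) {
    idx <- which(tissue, arr.ind = TRUE)       # (row=y+1, col=x+1, slice=z+1)
    cen <- colMeans(idx)
    dist2 <- (idx[, 1] - cen[1])^2 + (idx[, 2] - cen[2])^2 + (idx[, 3] - cen[3])^2
    s <- idx[which.min(dist2), ]               # first minimum in linear order
    seed_rcz <- as.integer(s)
  } else {
    seed <- as.integer(seed)
    if (length(seed) != 3 || anyNA(seed)) {
      stop("seed must be \"auto\" or a 0-based (x, y, z) triple", call. = FALSE)
    }
    seed_rcz <- c(seed[2] + 1L, seed[1] + 1L, seed[3] + 1L)
    if (any(seed_rcz < 1L) || any(seed_rcz > d)) {
      stop(sprintf("seed (%d, %d, %d) outside the volume", seed[1], seed[2], seed[3]),
           call. = FALSE)
    }
    if (!tissue[seed_rcz[1], seed_rcz[2], seed_rcz[3]]) {
      stop(sprintf("seed (%d, %d, %d) lies on a background voxel",
                   seed[1], seed[2], seed[3]), call. = FALSE)
    }
  }
  # breadth-first growth over coordinate frontiers (vectorized per layer)
  visited <- array(FALSE, d)
  visited[seed_rcz[1], seed_rcz[2], seed_rcz[3]] <- TRUE
  frontier <- matrix(seed_rcz, nrow = 1)
  n_off <- nrow(offs)
  while (nrow(frontier) > 0) {
    m <- nrow(frontier)
    cand <- frontier[rep(seq_len(m), times = n_off), , drop = FALSE] +
      offs[rep(seq_len(n_off), each = m), c(2, 1, 3), drop = FALSE]
    ok <- cand[, 1] >= 1L & cand[, 1] <= d[1] &
      cand[, 2] >= 1L & cand[, 2] <= d[2] &
      cand[, 3] >= 1L & cand[, 3] <= d[3]
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0) break
    lin <- cand[, 1] + d[1] * (cand[, 2] - 1L) + d[1] * d[2] * (cand[, 3] - 1L)
    keep <- !duplicated(lin)
    cand <- cand[keep, , drop = FALSE]
    lin <- lin[keep]
    grow <- tissue[lin] & !visited[lin]
    if (!any(grow)) break
    lin <- lin[grow]
    visited[lin] <- TRUE
    frontier <- cand[grow, , drop = FALSE]
  }
  out <- labels
  out[tissue & !visited] <- LABEL_BACKGROUND
  list(volume = label_volume(out, volume$meta),
       removed = sum(tissue & !visited))
}

#' Down-sample a label volume in X and Y by majority vote
#'
#' Each output voxel takes the majority label of its
#' `factor x factor x 1` block (Z is preserved: one voxel per section).
#' Ties are broken by precedence positive > negative > background, so
#' positive signal is never silently erased by a tie. Spacing in x and y
#' is multiplied by `factor`; dimensions become `ceiling(dim / factor)`.
#'
#' @param volume a [label_volume()].
#' @param factor integer down-sampling factor `>= 1`.
#' @return The down-sampled [label_volume()].
#' @export
volume_downsample <- function(volume, factor) {
  stopifnot(inherits(volume, "label_volume"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) {
    stop("volume_downsample: 'factor' must be an integer >= 1", call. = FALSE)
  }
  if (factor == 1) return(volume)
  labels <- volume$labels
  d <- dim(labels)                     # (ny, nx, nz)
  if (factor > d[1] || factor > d[2]) {
    stop(sprintf("volume_downsample: factor %d exceeds XY extent %dx%d",
                 factor, d[2], d[1]), call. = FALSE)
  }
  gy <- (seq_len(d[1]) - 1L) %/% factor
  gx <- (seq_len(d[2]) - 1L) %/% factor
  ny2 <- max(gy) + 1L; nx2 <- max(gx) + 1L
  counts <- array(0, dim = c(ny2, nx2, d[3], 3))
  for (z in seq_len(d[3])) {
    for (l in 0:2) {
      ind <- (labels[, , z] == l) + 0
      by_row <- rowsum(ind, gy, reorder = TRUE)
      counts[, , z, l + 1] <- t(rowsum(t(by_row), gx, reorder = TRUE))
    }
  }
  # majority with tie precedence positive > negative > background
  pos <- counts[, , , LABEL_POSITIVE + 1, drop = FALSE]
  neg <- counts[, , , LABEL_NEGATIVE + 1, drop = FALSE]
  bg <- counts[, , , LABEL_BACKGROUND + 1, drop = FALSE]
  out <- array(LABEL_BACKGROUND, dim = c(ny2, nx2, d[3]))
  out[neg >= bg] <- LABEL_NEGATIVE
  out[pos >= neg & pos >= bg] <- LABEL_POSITIVE
  meta <- volume$meta
  new_meta <- volume_meta(c(nx2, ny2, d[3]),
                          spacing = meta$spacing * c(factor, factor, 1),
                          origin = meta$origin,
                          unit_label = meta$unit_label)
  label_volume(out, new_meta)
}
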