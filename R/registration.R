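# Landmark-based rigid registration: least-squares rotation+translation
# fit (2D orthogonal Procrustes with the reflection excluded), and
# nearest-neighbour resampling of slices into a common reference frame.

.check_pairs <- function(moving, fixed) {
  if (is.null(dim(moving))) moving <- matrix(moving, ncol = 2)
  if (is.null(dim(fixed))) fixed <- matrix(fixed, ncol = 2)
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  storage.mode(moving) <- "double"; storage.mode(fixed) <- "double"
  if (ncol(moving) != 2 || ncol(fixed) != 2) {
    stop("landmarks must be n x 2 matrices of (x, y) coordinates", call. = FALSE)
  }
  if (nrow(moving) != nrow(fixed)) {
    stop(sprintf("landmark counts differ: %d moving vs %d fixed",
                 nrow(moving), nrow(fixed)), call. = FALSE)
  }
  if (nrow(moving) < 2) {
    stop("rigid fit needs at least 2 landmark pairs", call. = FALSE)
  }
  if (all(abs(sweep(moving, 2, moving[1, ], "-")) < 1e-12)) {
    stop("rigid fit is degenerate: all moving landmarks coincide", call. = FALSE)
  }
  list(moving = moving, fixed = fixed)
}

#' Least-squares rigid fit from matched landmarks
#'
#' Finds the rotation and translation minimizing the sum of squared
#' distances between transformed moving points and their fixed
#' counterparts, in closed form: subtract centroids, form the 2x2
#' cross-covariance, take the rotation from its polar decomposition with
#' the determinant forced to +1 (reflections are excluded — sections are
#' never flipped), and recover the translation from the centroids.
#'
#' @param moving,fixed n x 2 matrices of matched `(x, y)` coordinates
#'   (`moving` on the slice to align, `fixed` on the reference frame),
#'   paired by row; `n >= 2` with at least two distinct moving points.
#' @return List with `transform` (a [rigid_transform2d()] mapping moving
#'   into the fixed frame) and `rms_residual` (root-mean-square
#'   point-to-point distance after alignment, in pixels).
#' @export
estimate_rigid <- function(moving, fixed) {
  p <- .check_pairs(moving, fixed)
  moving <- p$moving; fixed <- p$fixed
  mc <- colMeans(moving); fc <- colMeans(fixed)
  M <- sweep(moving, 2, mc); F <- sweep(fixed, 2, fc)
  H <- t(M) %*% F                       # 2x2 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1                    # collinear degenerate: pick +1 branch
  R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
  theta <- atan2(R[2, 1], R[1, 1])
  t <- fc - as.numeric(R %*% mc)
  tf <- rigid_transform2d(theta, t[1], t[2])
  resid <- transform_apply(tf, moving) - fixed
  rms <- sqrt(mean(rowSums(resid^2)))
  list(transform = tf, rms_residual = rms)
}

# nearest-neighbour inverse warp of an integer matrix into an output
# frame: out(p) = img(T^{-1} p), out-of-frame samples -> 0
.warp_nn <- function(pixels, transform, out_h, out_w) {
  inv <- transform_invert(transform)
  Ri <- .rotation_matrix(inv$theta)
  xs <- rep(0:(out_w - 1), each = out_h)   # column-major over (row, col)
  ys <- rep(0:(out_h - 1), times = out_w)
  qx <- Ri[1, 1] * xs + Ri[1, 2] * ys + inv$t[1]
  qy <- Ri[2, 1] * xs + Ri[2, 2] * ys + inv$t[2]
  ci <- as.integer(round(qx)) + 1L
  ri <- as.integer(round(qy)) + 1L
  ok <- ci >= 1L & ci <= ncol(pixels) & ri >= 1L & ri <= nrow(pixels)
  out <- matrix(0L, out_h, out_w)
  out[cbind(ys[ok] + 1L, xs[ok] + 1L)] <- pixels[cbind(ri[ok], ci[ok])]
  out
}

#' Resample a slice through a rigid transform
#'
#' Inverse-warps the slice into the output frame with nearest-neighbour
#' sampling, so marked intensity plateaus and label-like values are
#' never blended by interpolation. Samples falling outside the source
#' frame become 0 (non-tissue background). The identity transform on a
#' matching frame returns a pixel-identical copy.
#'
#' @param slice a [gray_slice()].
#' @param transform a [rigid_transform2d()] mapping the slice's
#'   coordinates into the output frame.
#' @param out_dims output frame size `c(height, width)`; defaults to the
#'   slice's own frame.
#' @return The resampled [gray_slice()].
#' @export
apply_rigid <- function(slice, transform, out_dims = dim(slice$pixels)) {
  stopifnot(inherits(slice, "gray_slice"), inherits(transform, "rigid_transform2d"))
  px <- .warp_nn(slice$pixels, transform, out_dims[1], out_dims[2])
  gray_slice(px, slice$slice_index, damaged = slice$damaged, marked = slice$marked)
}

# like apply_rigid but for a h x w x 3 RGB array (used by the synthetic
# generator to render misaligned sections)
.warp_rgb_nn <- function(pixels, transform) {
  d <- dim(pixels)
  out <- array(0L, d)
  for (ch in 1:3) out[, , ch] <- .warp_nn(pixels[, , ch], transform, d[1], d[2])
  out
}

#' Align a stack of slices to a reference slice
#'
#' Estimates one rigid transform per slice from per-slice landmark sets
#' (points paired across slices by row order) and resamples every slice
#' into the reference slice's frame.
#'
#' In `"chain"` mode (the default, matching serial-section practice)
#' each slice is fitted to its nearest landmark-bearing neighbour toward
#' the reference and the pairwise fits are composed; this only requires
#' corresponding landmarks between neighbouring slices. In `"direct"`
#' mode every slice is fitted straight to the reference slice's
#' landmarks, which requires landmarks that span the whole stack.
#'
#' Slices without landmarks are an error unless flagged damaged;
#' damaged slices pass through with the identity transform and are
#' repaired later by [interpolate_damaged_slices()].
#'
#' @param slices list of [gray_slice()] objects in stack order.
#' @param landmark_sets list (same length) of n x 2 landmark matrices in
#'   each slice's own frame, or `NULL` entries for slices without
#'   landmarks.
#' @param reference_index 0-based index of the reference slice, or
#'   `"middle"` (default) for `floor(n/2)`.
#' @param mode `"chain"` or `"direct"` (see above).
#' @return List with `slices` (aligned), `transforms` (per-slice
#'   [rigid_transform2d()] into the reference frame) and `report`, a
#'   data frame with columns `slice`, `theta_deg`, `tx`, `ty`, `rms`.
#' @export
align_stack <- function(slices, landmark_sets, reference_index = "middle",
                        mode = c("chain", "direct")) {
  mode <- match.arg(mode)
  n <- length(slices)
  stopifnot(n >= 1, length(landmark_sets) == n)
  if (identical(reference_index, "middle")) reference_index <- n %/% 2
  reference_index <- as.integer(reference_index)
  if (is.na(reference_index) || reference_index < 0 || reference_index >= n) {
    stop(sprintf("reference_index %d out of range [0, %d)", reference_index, n),
         call. = FALSE)
  }
  ref <- reference_index + 1L  # 1-based
  has_lm <- !vapply(landmark_sets, is.null, logical(1))
  for (k in seq_len(n)) {
    if (!has_lm[k] && !slices[[k]]$damaged && k != ref) {
      stop(sprintf("slice %d has no landmarks and is not flagged damaged",
                   slices[[k]]$slice_index), call. = FALSE)
    }
  }
  transforms <- vector("list", n)
  rms <- numeric(n)
  transforms[[ref]] <- transform_identity()
  fit_to <- function(k, target) {
    est <- estimate_rigid(landmark_sets[[k]], landmark_sets[[target]])
    rms[k] <<- est$rms_residual
    est$transform
  }
  if (mode == "direct") {
    if (!has_lm[ref]) stop("direct mode: reference slice has no landmarks",
                           call. = FALSE)
    for (k in seq_len(n)) {
      if (k == ref) next
      transforms[[k]] <- if (has_lm[k]) fit_to(k, ref) else transform_identity()
    }
  } else {
    # chain mode: propagate pairwise fits outward from the reference
    for (side in c(-1L, 1L)) {
      anchor <- ref                 # nearest landmark-bearing slice toward ref
      k <- ref + side
      while (k >= 1L && k <= n) {
        if (!has_lm[k]) {
          transforms[[k]] <- transform_identity()  # damaged pass-through
        } else if (!has_lm[anchor]) {
          transforms[[k]] <- transform_identity()
          anchor <- k
        } else {
          transforms[[k]] <- transform_compose(transforms[[anchor]],
                                               fit_to(k, anchor))
          anchor <- k
        }
        k <- k + side
      }
    }
  }
  frame <- dim(slices[[ref]]$pixels)
  aligned <- vector("list", n)
  for (k in seq_len(n)) {
    aligned[[k]] <- apply_rigid(slices[[k]], transforms[[k]], frame)
  }
  report <- data.frame(
    slice = vapply(slices, function(s) s$slice_index, integer(1)),
    theta_deg = vapply(transforms, function(tf) tf$theta * 180 / pi, numeric(1)),
    tx = vapply(transforms, function(tf) unname(tf$t[1]), numeric(1)),
    ty = vapply(transforms, function(tf) unname(tf$t[2]), numeric(1)),
    rms = rms
  )
  list(slices = aligned, transforms = transforms, report = report)
}
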