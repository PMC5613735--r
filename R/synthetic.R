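# Synthetic serial-section stacks with full ground truth: per-slice
# applied rigid transforms, per-voxel true labels, and analytic landmark
# sets. The generator emulates misaligned coronal sections of a single
# organ silhouette carrying red-channel-bright positive cell clusters
# over a dimmer tissue background, plus extra-organ speckle noise.

.run_with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Specification of a synthetic serial-section stack
#'
#' Defines the geometry, staining, misalignment and noise of a synthetic
#' stack. Defaults produce a desk-scale stand-in for a full-resolution
#' reconstruction: a 256 x 256 x 24 stack of one smoothly varying
#' elliptical organ silhouette (a single connected 3D component, as
#' region growing assumes), with ellipsoidal positive cell clusters
#' whose red channel far exceeds the marking threshold, dim tissue
#' background in all channels with low red, and sparse extra-organ
#' speckle.
#'
#' @param n_slices number of sections (>= 1).
#' @param width,height frame size in pixels (>= 8).
#' @param organ list: `center = c(x, y)` mid-stack silhouette centre
#'   (default frame centre), `semi_axes = c(a, b)` mid-stack ellipse
#'   semi-axes in pixels, `min_scale` end-slice scale of the silhouette
#'   (elliptic profile along z), `center_drift` smooth sinusoidal x-drift
#'   of the centre across slices, in pixels.
#' @param tissue_intensity `c(mean, sd)` of the 8-bit tissue luminance;
#'   tissue red stays well below the marking threshold.
#' @param positive_clusters list: `n` clusters in total — the first is a
#'   transmural band running through every slice (the mapped population
#'   is present throughout the organ), the remaining `n - 1` are
#'   ellipsoidal satellites; `radius_range` in-plane radius bounds (px),
#'   `red_range` red-channel brightness bounds (8-bit),
#'   `z_radius_range` satellite out-of-plane radius bounds (slices).
#' @param misalignment list: `max_rot_deg`, `max_trans_px` — per-slice
#'   uniform misalignment bounds.
#' @param speckle list: `density` (expected blobs per pixel per slice),
#'   `radius_range` blob radius bounds (px).
#' @param damaged_slices 0-based slice indices rendered with near-zero
#'   tissue intensity (positive clusters retained).
#' @param damage_scale multiplier applied to tissue luminance on damaged
#'   slices.
#' @param seed integer RNG seed; identical specs give byte-identical
#'   stacks.
#' @param n_landmarks landmark points per slice (>= 2), placed
#'   analytically on the mid-stack organ boundary.
#' @return An object of class `stack_spec`.
#' @export
stack_spec <- function(n_slices = 24, width = 256, height = 256,
                       organ = list(),
                       tissue_intensity = c(mean = 40, sd = 6),
                       positive_clusters = list(),
                       misalignment = list(max_rot_deg = 3, max_trans_px = 8),
                       speckle = list(),
                       damaged_slices = integer(0),
                       damage_scale = 0.02,
                       seed = 1,
                       n_landmarks = 8) {
  err <- function(field, why) {
    stop(sprintf("stack_spec: invalid '%s': %s", field, why), call. = FALSE)
  }
  n_slices <- as.integer(n_slices)
  if (is.na(n_slices) || n_slices < 1) err("n_slices", "must be >= 1")
  width <- as.integer(width); height <- as.integer(height)
  if (is.na(width) || width < 8) err("width", "must be >= 8")
  if (is.na(height) || height < 8) err("height", "must be >= 8")
  organ <- utils::modifyList(list(center = c(width, height) / 2,
                                  semi_axes = c(0.32 * width, 0.38 * height),
                                  min_scale = 0.6,
                                  center_drift = 6), organ)
  if (any(organ$semi_axes <= 0)) err("organ$semi_axes", "must be positive")
  if (organ$min_scale <= 0 || organ$min_scale > 1) {
    err("organ$min_scale", "must be in (0, 1]")
  }
  tissue_intensity <- as.numeric(tissue_intensity)
  if (length(tissue_intensity) != 2 || any(tissue_intensity < 0) ||
      tissue_intensity[1] > 255) {
    err("tissue_intensity", "must be c(mean, sd) with mean in [0, 255], sd >= 0")
  }
  positive_clusters <- utils::modifyList(list(n = 12,
                                              radius_range = c(4, 10),
                                              red_range = c(180, 235),
                                              z_radius_range = c(1.5, 4)),
                                         positive_clusters)
  if (positive_clusters$n < 0) err("positive_clusters$n", "must be >= 0")
  if (any(positive_clusters$red_range < 0) || any(positive_clusters$red_range > 255)) {
    err("positive_clusters$red_range", "must be within [0, 255]")
  }
  misalignment <- utils::modifyList(list(max_rot_deg = 3, max_trans_px = 8),
                                    misalignment)
  if (misalignment$max_rot_deg < 0 || misalignment$max_trans_px < 0) {
    err("misalignment", "bounds must be >= 0")
  }
  speckle <- utils::modifyList(list(density = 5e-5, radius_range = c(1, 3)),
                               speckle)
  if (speckle$density < 0) err("speckle$density", "must be >= 0")
  damaged_slices <- unique(as.integer(damaged_slices))
  if (any(damaged_slices < 0 | damaged_slices >= n_slices)) {
    err("damaged_slices", sprintf("indices must lie in [0, %d)", n_slices))
  }
  if (damage_scale < 0 || damage_scale > 1) err("damage_scale", "must be in [0, 1]")
  n_landmarks <- as.integer(n_landmarks)
  if (is.na(n_landmarks) || n_landmarks < 2) {
    err("n_landmarks", "must be >= 2 (2D rigid fit needs >= 2 distinct points)")
  }
  structure(list(n_slices = n_slices, width = width, height = height,
                 organ = organ, tissue_intensity = tissue_intensity,
                 positive_clusters = positive_clusters,
                 misalignment = misalignment, speckle = speckle,
                 damaged_slices = damaged_slices, damage_scale = damage_scale,
                 seed = as.integer(seed), n_landmarks = n_landmarks),
            class = "stack_spec")
}

# per-slice silhouette geometry: elliptic z-profile plus smooth centre drift
.organ_geometry <- function(spec, k) {
  n <- spec$n_slices
  u <- if (n == 1) 0 else 2 * k / (n - 1) - 1
  s <- sqrt(1 - (1 - spec$organ$min_scale^2) * u^2)
  cx <- spec$organ$center[1] +
    spec$organ$center_drift * sin(pi * (if (n == 1) 0.5 else k / (n - 1)))
  list(cx = cx, cy = spec$organ$center[2],
       a = spec$organ$semi_axes[1] * s, b = spec$organ$semi_axes[2] * s)
}

.disk_mask <- function(h, w, cx, cy, rx, ry) {
  X <- matrix(rep(0:(w - 1), each = h), h, w)
  Y <- matrix(rep(0:(h - 1), times = w), h, w)
  ((X - cx) / rx)^2 + ((Y - cy) / ry)^2 <= 1
}

#' Generate a synthetic serial-section stack with ground truth
#'
#' Renders each canonical section (organ tissue near the configured
#' luminance in all channels but with low red, positive clusters with
#' red channel in the configured bright range, extra-organ speckle,
#' near-black elsewhere), then resamples slice `k` through a random
#' rigid misalignment. Damaged slices have their tissue luminance scaled
#' toward zero while positive clusters are retained. The returned truth
#' carries the applied transforms, the full-resolution canonical label
#' grid, the positive voxel fraction within the organ, and analytic
#' landmark sets in both the canonical and the misaligned frame.
#'
#' Identical specs (including the seed) give byte-identical output.
#'
#' @param spec a [stack_spec()].
#' @return List with `sections` (list of [rgb_section()]) and `truth`, a
#'   `synthetic_truth` list with elements `applied_transforms`,
#'   `true_labels` (`(height, width, n_slices)` integer array),
#'   `positive_fraction`, `landmarks_canonical` (n x 2 matrix) and
#'   `landmarks_moving` (per-slice n x 2 matrices).
#' @export
generate_stack <- function(spec) {
  stopifnot(inherits(spec, "stack_spec"))
  .run_with_seed(spec$seed, {
    n <- spec$n_slices; h <- spec$height; w <- spec$width
    # 1) per-slice misalignment (canonical -> misaligned frame)
    mis <- spec$misalignment
    thetas <- stats::runif(n, -mis$max_rot_deg, mis$max_rot_deg) * pi / 180
    txs <- stats::runif(n, -mis$max_trans_px, mis$max_trans_px)
    tys <- stats::runif(n, -mis$max_trans_px, mis$max_trans_px)
    transforms <- lapply(seq_len(n), function(k) {
      rigid_transform2d(thetas[k], txs[k], tys[k])
    })
    # 2) positive clusters: ellipsoids in canonical (x, y, z) space.
    # The first cluster is a transmural band running through the whole
    # stack — the mapped cell population is present in every section,
    # concentrated in one contiguous structure — and the rest are
    # satellite clusters scattered through the organ.
    pc <- spec$positive_clusters
    mid <- .organ_geometry(spec, (n - 1) / 2)
    clusters <- if (pc$n > 0) {
      phi <- stats::runif(pc$n, 0, 2 * pi)
      rad <- sqrt(stats::runif(pc$n)) * 0.7          # interior of the silhouette
      cl <- data.frame(
        cx = mid$cx + rad * cos(phi) * mid$a,
        cy = mid$cy + rad * sin(phi) * mid$b,
        cz = stats::runif(pc$n, 0, n - 1),
        rxy = stats::runif(pc$n, pc$radius_range[1], pc$radius_range[2]),
        rz = stats::runif(pc$n, pc$z_radius_range[1], pc$z_radius_range[2]),
        red = stats::runif(pc$n, pc$red_range[1], pc$red_range[2])
      )
      cl$cx[1] <- mid$cx + 0.25 * mid$a * cos(phi[1])
      cl$cy[1] <- mid$cy + 0.25 * mid$b * sin(phi[1])
      cl$cz[1] <- (n - 1) / 2
      cl$rz[1] <- n                     # spans every slice
      cl$rxy[1] <- max(0.12 * min(spec$organ$semi_axes), pc$radius_range[1])
      cl
    } else {
      data.frame()
    }
    # 3) landmarks: analytic points on the mid-stack organ boundary
    ang <- 2 * pi * (seq_len(spec$n_landmarks) - 1) / spec$n_landmarks
    lm_canon <- cbind(x = mid$cx + mid$a * cos(ang),
                      y = mid$cy + mid$b * sin(ang))
    lm_moving <- lapply(transforms, transform_apply, points = lm_canon)
    # 4) render canonical slices, then warp through the applied transforms
    true_labels <- array(LABEL_BACKGROUND, dim = c(h, w, n))
    sections <- vector("list", n)
    tm <- spec$tissue_intensity[1]; ts <- spec$tissue_intensity[2]
    for (k0 in seq_len(n) - 1L) {
      g <- .organ_geometry(spec, k0)
      organ <- .disk_mask(h, w, g$cx, g$cy, g$a, g$b)
      lab <- matrix(LABEL_BACKGROUND, h, w)
      lab[organ] <- LABEL_NEGATIVE
      red_img <- matrix(0, h, w)
      for (j in seq_len(nrow(clusters))) {
        cl <- clusters[j, ]
        dz <- (k0 - cl$cz) / cl$rz
        if (abs(dz) > 1) next
        r_k <- cl$rxy * sqrt(1 - dz^2)
        if (r_k < 0.5) next
        disk <- .disk_mask(h, w, cl$cx, cl$cy, r_k, r_k) & organ
        lab[disk] <- LABEL_POSITIVE
        red_img[disk] <- cl$red
      }
      true_labels[, , k0 + 1L] <- lab
      # tissue colouring: luminance ~ N(mean, sd), red kept low so that
      # only true positive clusters exceed the marking threshold
      damaged <- k0 %in% spec$damaged_slices
      scale <- if (damaged) spec$damage_scale else 1
      canvas <- array(0, dim = c(h, w, 3))
      tissue_idx <- which(lab != LABEL_BACKGROUND)
      if (length(tissue_idx) > 0) {
        L <- pmin(pmax(stats::rnorm(length(tissue_idx), tm, ts), 0), 255) * scale
        r_low <- pmin(pmax(stats::rnorm(length(tissue_idx), 6, 2.5), 0), 12) * scale
        gb <- pmin(pmax((L - 0.299 * r_low) / 0.701, 0), 255)
        ch <- canvas[, , 1]; ch[tissue_idx] <- r_low; canvas[, , 1] <- ch
        ch <- canvas[, , 2]; ch[tissue_idx] <- gb; canvas[, , 2] <- ch
        ch <- canvas[, , 3]; ch[tissue_idx] <- gb; canvas[, , 3] <- ch
      }
      # positive clusters: bright red, tissue-like green/blue; retained
      # at full red brightness on damaged slices
      pos_idx <- which(lab == LABEL_POSITIVE)
      if (length(pos_idx) > 0) {
        ch <- canvas[, , 1]; ch[pos_idx] <- red_img[pos_idx]; canvas[, , 1] <- ch
      }
      # extra-organ speckle blobs (noise removed later by region growing)
      n_spk <- stats::rpois(1, spec$speckle$density * h * w)
      if (n_spk > 0) {
        sx <- stats::runif(n_spk, 0, w - 1)
        sy <- stats::runif(n_spk, 0, h - 1)
        sr <- stats::runif(n_spk, spec$speckle$radius_range[1],
                           spec$speckle$radius_range[2])
        sv <- pmin(pmax(stats::rnorm(n_spk, tm, ts), 5), 255)
        for (j in seq_len(n_spk)) {
          blob <- .disk_mask(h, w, sx[j], sy[j], sr[j], sr[j]) & !organ
          if (!any(blob)) next
          for (ch_i in 2:3) {
            ch <- canvas[, , ch_i]; ch[blob] <- sv[j]; canvas[, , ch_i] <- ch
          }
          ch <- canvas[, , 1]; ch[blob] <- pmin(sv[j] * 0.2, 12); canvas[, , 1] <- ch
        }
      }
      canvas <- round(canvas)
      storage.mode(canvas) <- "integer"
      mis_px <- .warp_rgb_nn(canvas, transforms[[k0 + 1L]])
      sections[[k0 + 1L]] <- rgb_section(mis_px, slice_index = k0,
                                         damaged = damaged,
                                         source_name = sprintf("slice_%03d", k0))
    }
    organ_vox <- sum(true_labels != LABEL_BACKGROUND)
    pos_vox <- sum(true_labels == LABEL_POSITIVE)
    truth <- structure(list(
      applied_transforms = transforms,
      true_labels = true_labels,
      positive_fraction = if (organ_vox > 0) pos_vox / organ_vox else 0,
      landmarks_canonical = lm_canon,
      landmarks_moving = lm_moving
    ), class = "synthetic_truth")
    list(sections = sections, truth = truth)
  })
}

#' Write a synthetic stack as an on-disk fixture
#'
#' Writes one 8-bit image per slice (TIFF by default, for lossless
#' round trips; JPEG optionally), a tab-separated manifest
#' (`index`, `filename`, `damaged`), one two-column landmark file per
#' slice (misaligned-frame coordinates, `x y`, 0-based), and a
#' plain-text truth sidecar (applied transforms, positive fraction, and
#' the full-resolution label grid).
#'
#' @param stack result of [generate_stack()] (list with `sections` and
#'   `truth`).
#' @param dir output directory (created if needed).
#' @param format `"tiff"` (default, lossless) or `"jpeg"`.
#' @param quality JPEG quality in `(0, 1]` (ignored for TIFF).
#' @return The manifest path, invisibly.
#' @export
write_fixture <- function(stack, dir, format = c("tiff", "jpeg"), quality = 0.95) {
  format <- match.arg(format)
  ext <- if (format == "tiff") "tif" else "jpg"
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop(sprintf("cannot create directory '%s'", dir),
                             call. = FALSE)
  lm_dir <- file.path(dir, "landmarks")
  dir.create(lm_dir, showWarnings = FALSE)
  sections <- stack$sections
  truth <- stack$truth
  rows <- character(length(sections))
  for (i in seq_along(sections)) {
    s <- sections[[i]]
    fname <- sprintf("slice_%03d.%s", s$slice_index, ext)
    .write_image_8bit(s$pixels, file.path(dir, fname), quality = quality)
    rows[i] <- sprintf("%d\t%s\t%d", s$slice_index, fname, as.integer(s$damaged))
    lm <- truth$landmarks_moving[[i]]
    utils::write.table(lm, file.path(lm_dir, sprintf("landmarks_%03d.txt",
                                                     s$slice_index)),
                       row.names = FALSE, col.names = FALSE)
  }
  manifest <- file.path(dir, "manifest.tsv")
  writeLines(c("index\tfilename\tdamaged", rows), manifest)
  # truth sidecar: transforms table + summary + flattened label grid
  tf_rows <- vapply(seq_along(truth$applied_transforms), function(k) {
    tf <- truth$applied_transforms[[k]]
    sprintf("%d\t%.17g\t%.17g\t%.17g", k - 1L, tf$theta, tf$t[1], tf$t[2])
  }, character(1))
  writeLines(c("slice\ttheta\ttx\tty", tf_rows),
             file.path(dir, "truth_transforms.tsv"))
  d <- dim(truth$true_labels)
  con <- file(file.path(dir, "truth_labels.txt"), "wb")
  writeLines(c(paste(d, collapse = " "),
               paste(as.vector(truth$true_labels), collapse = " ")), con)
  close(con)
  yaml::write_yaml(list(positive_fraction = truth$positive_fraction,
                        n_slices = length(sections),
                        width = d[2], height = d[1]),
                   file.path(dir, "truth_summary.yaml"))
  invisible(manifest)
}
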