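make_volume <- function(values, nz = 1) {
  slices <- lapply(seq_len(nz), function(k) gray_slice(values, k - 1L))
  classify_volume(slices)
}

test_that("boundary intensities map to the documented classes", {
  m <- matrix(as.integer(c(2, 3, 80, 81)), 2, 2)
  vol <- make_volume(m)
  expect_equal(vol$labels[1, 1, 1], LABEL_BACKGROUND)  # 2  < 3
  expect_equal(vol$labels[2, 1, 1], LABEL_NEGATIVE)    # 3  in [3, 80]
  expect_equal(vol$labels[1, 2, 1], LABEL_NEGATIVE)    # 80 in [3, 80]
  expect_equal(vol$labels[2, 2, 1], LABEL_POSITIVE)    # 81 > 80
})

test_that("class counts always partition the voxel total", {
  set.seed(4)
  for (i in 1:5) {
    m <- matrix(sample(0:255, 20 * 20, replace = TRUE), 20, 20)
    vol <- make_volume(m, nz = 3)
    expect_equal(sum(label_counts(vol)), length(vol$labels))
  }
})

test_that("raising the positive threshold never increases the positive count", {
  set.seed(14)
  m <- matrix(sample(0:255, 30 * 30, replace = TRUE), 30, 30)
  slices <- list(gray_slice(m, 0))
  counts <- vapply(c(40, 80, 120, 200), function(th) {
    label_counts(classify_volume(slices, positive_above = th))[["positive"]]
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("damaged-slice repair copies the nearest donor and preserves positives", {
  lab <- array(LABEL_BACKGROUND, c(6, 6, 3))
  lab[2:5, 2:5, 1] <- LABEL_NEGATIVE
  lab[2:5, 2:5, 3] <- LABEL_NEGATIVE
  lab[3, 3, 2] <- LABEL_POSITIVE       # distinguishable signal on the damaged slice
  vol <- label_volume(lab)
  out <- interpolate_damaged_slices(vol, damaged = 1)
  # repaired slice equals its donor except the preserved positive voxel
  expected <- lab[, , 1]
  expected[3, 3] <- LABEL_POSITIVE
  expect_identical(out$labels[, , 2], expected)
  # non-damaged slices untouched
  expect_identical(out$labels[, , 1], lab[, , 1])
  expect_identical(out$labels[, , 3], lab[, , 3])
})

test_that("repair with no damaged slices is the identity; all-damaged errors", {
  vol <- random_label_volume(5, 5, 4)
  expect_identical(interpolate_damaged_slices(vol, integer(0))$labels, vol$labels)
  expect_error(interpolate_damaged_slices(vol, 0:3), "all slices")
  expect_error(interpolate_damaged_slices(vol, 7), "out of range")
})

test_that("nearest-donor ties break toward lower z", {
  lab <- array(LABEL_BACKGROUND, c(2, 2, 3))
  lab[, , 1] <- LABEL_NEGATIVE        # lower donor
  lab[, , 3] <- LABEL_POSITIVE        # upper donor, equidistant
  out <- interpolate_damaged_slices(label_volume(lab), damaged = 1)
  expect_true(all(out$labels[, , 2] == LABEL_NEGATIVE))
})

test_that("region growing keeps the seeded blob and removes disconnected speckle", {
  lab <- array(LABEL_BACKGROUND, c(12, 12, 5))
  lab[4:9, 4:9, 2:4] <- LABEL_NEGATIVE
  lab[6, 6, 3] <- LABEL_POSITIVE
  set.seed(6)
  speck <- 0
  while (speck < 10) {
    r <- sample(12, 1); c <- sample(12, 1); z <- sample(5, 1)
    if (r >= 3 && r <= 10 && c >= 3 && c <= 10) next  # keep clear of the blob
    if (lab[r, c, z] != LABEL_BACKGROUND) next
    lab[r, c, z] <- LABEL_NEGATIVE
    speck <- speck + 1
  }
  vol <- label_volume(lab)
  out <- region_grow_cleanup(vol, connectivity = 6, seed = "auto")
  expect_equal(out$removed, 10)
  blob <- array(FALSE, c(12, 12, 5)); blob[4:9, 4:9, 2:4] <- TRUE
  expect_true(all(out$volume$labels[!blob] == LABEL_BACKGROUND))
  expect_identical(out$volume$labels[blob], lab[blob])
  expect_equal(out$volume$labels[6, 6, 3], LABEL_POSITIVE)  # never downgraded
})

test_that("a fully connected tissue volume passes through unchanged", {
  lab <- array(LABEL_NEGATIVE, c(4, 4, 4))
  lab[2, 2, 2] <- LABEL_POSITIVE
  out <- region_grow_cleanup(label_volume(lab), 6, "auto")
  expect_identical(out$volume$labels, lab)
  expect_equal(out$removed, 0)
})

test_that("region growing matches the dilation flood-fill oracle on random volumes", {
  set.seed(77)
  for (i in 1:10) {
    vol <- random_label_volume(8, 9, 5, p = c(0.6, 0.3, 0.1))
    tissue <- vol$labels != LABEL_BACKGROUND
    if (!any(tissue)) next
    seed_rcz <- which(tissue, arr.ind = TRUE)[1, ]
    seed_xyz <- c(seed_rcz[2] - 1, seed_rcz[1] - 1, seed_rcz[3] - 1)
    for (conn in c(6, 26)) {
      out <- region_grow_cleanup(vol, conn, seed_xyz)
      reach <- flood_oracle(tissue, seed_rcz, conn)
      expect_identical(out$volume$labels != LABEL_BACKGROUND, reach)
      expect_equal(out$removed, sum(tissue & !reach))
    }
  }
})

test_that("bad region-growing seeds are rejected with the seed named", {
  lab <- array(LABEL_BACKGROUND, c(3, 3, 1)); lab[2, 2, 1] <- LABEL_NEGATIVE
  vol <- label_volume(lab)
  expect_error(region_grow_cleanup(vol, 6, c(0, 0, 0)), "\\(0, 0, 0\\)")
  expect_error(region_grow_cleanup(label_volume(array(LABEL_BACKGROUND, c(2, 2, 1))),
                                   6, "auto"), "no tissue")
})

test_that("majority down-sampling follows the stated tie-breaks and updates metadata", {
  lab <- array(LABEL_BACKGROUND, c(4, 4, 1))
  lab[1, 1, 1] <- LABEL_POSITIVE                    # 1 pos, 3 bg -> bg
  lab[1:2, 3, 1] <- LABEL_POSITIVE                  # 2 pos, 2 bg -> pos (tie)
  lab[3, 1:2, 1] <- LABEL_NEGATIVE                  # 2 neg, 2 bg -> neg (tie)
  lab[3:4, 3:4, 1] <- c(LABEL_POSITIVE, LABEL_POSITIVE,
                        LABEL_NEGATIVE, LABEL_NEGATIVE)  # 2v2 -> pos
  vol <- label_volume(lab, volume_meta(c(4, 4, 1), spacing = c(2, 3, 5)))
  out <- volume_downsample(vol, 2)
  expect_identical(out$meta$dims, c(2L, 2L, 1L))
  expect_equal(out$meta$spacing, c(4, 6, 5))
  expect_equal(out$labels[1, 1, 1], LABEL_BACKGROUND)
  expect_equal(out$labels[1, 2, 1], LABEL_POSITIVE)
  expect_equal(out$labels[2, 1, 1], LABEL_NEGATIVE)
  expect_equal(out$labels[2, 2, 1], LABEL_POSITIVE)
})

test_that("factor-1 down-sampling is the identity and oversize factors error", {
  vol <- random_label_volume(5, 6, 2)
  expect_identical(volume_downsample(vol, 1)$labels, vol$labels)
  expect_error(volume_downsample(vol, 10), "exceeds")
})

test_that("odd extents round up and edge blocks vote over their actual voxels", {
  lab <- array(LABEL_NEGATIVE, c(5, 5, 1))
  out <- volume_downsample(label_volume(lab), 2)
  expect_identical(out$meta$dims, c(3L, 3L, 1L))
  expect_true(all(out$labels == LABEL_NEGATIVE))
})
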