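test_that("read_stack errors name the missing slice file", {
  dir <- withr::local_tempdir()
  writeLines(c("index\tfilename\tdamaged", "0\tnope.tif\t0"),
             file.path(dir, "manifest.tsv"))
  expect_error(read_stack(file.path(dir, "manifest.tsv")), "nope.tif")
})

test_that("read_stack rejects inconsistent frame sizes", {
  dir <- withr::local_tempdir()
  tiff::writeTIFF(array(0.5, c(10, 10, 3)), file.path(dir, "a.tif"),
                  bits.per.sample = 8)
  tiff::writeTIFF(array(0.5, c(12, 10, 3)), file.path(dir, "b.tif"),
                  bits.per.sample = 8)
  writeLines(c("index\tfilename\tdamaged", "0\ta.tif\t0", "1\tb.tif\t0"),
             file.path(dir, "manifest.tsv"))
  expect_error(read_stack(file.path(dir, "manifest.tsv")), "differs")
})

test_that("grayscale sources are promoted to three replicated channels", {
  dir <- withr::local_tempdir()
  m <- matrix(seq(0, 1, length.out = 30), 5, 6)
  tiff::writeTIFF(m, file.path(dir, "g.tif"), bits.per.sample = 8)
  writeLines(c("index\tfilename\tdamaged", "0\tg.tif\t0"),
             file.path(dir, "manifest.tsv"))
  s <- read_stack(file.path(dir, "manifest.tsv"))[[1]]
  expect_identical(dim(s$pixels), c(5L, 6L, 3L))
  expect_identical(s$pixels[, , 1], s$pixels[, , 2])
  expect_identical(s$pixels[, , 1], s$pixels[, , 3])
})

test_that("VTK writer emits the legacy structured-points header", {
  vol <- label_volume(array(LABEL_BACKGROUND, c(2, 2, 1)))
  path <- withr::local_tempfile(fileext = ".vtk")
  write_vtk_structured_points(vol, path = path)
  lines <- readLines(path)
  expect_equal(lines[1], "# vtk DataFile Version 3.0")
  expect_equal(lines[3], "ASCII")
  expect_equal(lines[4], "DATASET STRUCTURED_POINTS")
  expect_true("DIMENSIONS 2 2 1" %in% lines)
  expect_true("POINT_DATA 4" %in% lines)
  # all-background volume with the default map -> every scalar is 0
  scal <- scan(text = paste(lines[-(1:10)], collapse = " "), quiet = TRUE)
  expect_identical(unique(scal), 0)
})

test_that("scalar ordering is x-fastest: a unique voxel lands at x + nx*(y + ny*z)", {
  labels <- array(LABEL_BACKGROUND, c(3, 4, 2))  # ny=3, nx=4, nz=2
  x <- 2; y <- 1; z <- 1                          # 0-based target voxel
  labels[y + 1, x + 1, z + 1] <- LABEL_POSITIVE
  path <- withr::local_tempfile(fileext = ".vtk")
  write_vtk_structured_points(label_volume(labels), path = path)
  lines <- readLines(path)
  scal <- scan(text = paste(lines[-(1:10)], collapse = " "), quiet = TRUE)
  flat <- x + 4 * (y + 3 * z)                     # x fastest, then y, then z
  expect_equal(which(scal == 200) - 1, flat)
})

test_that("VTK writer and reader are exact inverses on random label volumes", {
  set.seed(42)
  vm <- c(background = 0L, negative = 100L, positive = 200L)
  for (i in 1:10) {
    dims <- sample(1:6, 3, replace = TRUE)
    vol <- random_label_volume(dims[1], dims[2], dims[3])
    vol$meta$spacing <- runif(3, 0.5, 10)
    vol$meta$origin <- runif(3, -5, 5)
    path <- withr::local_tempfile(fileext = ".vtk")
    write_vtk_structured_points(vol, value_map = vm, path = path)
    back <- read_vtk_structured_points(path)
    expect_identical(back$meta$dims, vol$meta$dims)
    expect_equal(back$meta$spacing, vol$meta$spacing)
    expect_equal(back$meta$origin, vol$meta$origin)
    expect_identical(back$scalars, array(vm[vol$labels + 1L],
                                         dim = dim(vol$labels)))
  }
})

test_that("repeated writes of the same volume are byte-identical", {
  vol <- random_label_volume(4, 5, 3)
  p1 <- withr::local_tempfile(fileext = ".vtk")
  p2 <- withr::local_tempfile(fileext = ".vtk")
  write_vtk_structured_points(vol, path = p1)
  write_vtk_structured_points(vol, path = p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("the reader rejects malformed files citing the offending line", {
  path <- withr::local_tempfile(fileext = ".vtk")
  vol <- label_volume(array(LABEL_NEGATIVE, c(2, 2, 2)))
  write_vtk_structured_points(vol, path = path)
  lines <- readLines(path)

  broken <- lines
  broken[8] <- "POINT_DATA 9"  # != nx*ny*nz
  writeLines(broken, path)
  expect_error(read_vtk_structured_points(path), "POINT_DATA")

  broken <- lines
  broken[4] <- "DATASET POLYDATA"
  writeLines(broken, path)
  expect_error(read_vtk_structured_points(path), "STRUCTURED_POINTS")

  broken <- lines
  broken[9] <- "SCALARS labels float 1"
  writeLines(broken, path)
  expect_error(read_vtk_structured_points(path), "unsigned_char")
})

test_that("a hand-written minimal one-voxel file reads back its scalar", {
  path <- withr::local_tempfile(fileext = ".vtk")
  writeLines(c("# vtk DataFile Version 3.0", "tiny", "ASCII",
               "DATASET STRUCTURED_POINTS", "DIMENSIONS 1 1 1",
               "SPACING 1 1 1", "ORIGIN 0 0 0", "POINT_DATA 1",
               "SCALARS s unsigned_char 1", "LOOKUP_TABLE default", "7"),
             path)
  back <- read_vtk_structured_points(path)
  expect_identical(as.vector(back$scalars), 7L)
  expect_identical(back$meta$dims, c(1L, 1L, 1L))
})
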