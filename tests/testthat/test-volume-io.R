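# Volume and record I/O: lossless round trips, spacing metadata,
# 16-bit conversion, cropping.

test_that("TIFF volumes round-trip with values, shape and spacing intact", {
  set.seed(1)
  a <- array(sample(0:65535, 5 * 6 * 7, replace = TRUE), dim = c(5, 6, 7))
  v <- VoxelVolume(a, spacing = c(0.65, 0.65, 0.65))
  p <- file.path(withr::local_tempdir(), "v.tif")
  writeVolume(v, p)
  r <- readVolume(p)
  expect_identical(voxelData(r), voxelData(v))
  expect_equal(voxelSpacing(r), c(0.65, 0.65, 0.65))
  expect_identical(voxelKind(r), "grayscale")
})

test_that("single-page images are rejected as non-3D", {
  p <- file.path(withr::local_tempdir(), "flat.tif")
  tiff::writeTIFF(matrix(0.5, 4, 4), p)
  expect_error(readVolume(p, spacing = c(1, 1, 1)), "non-3D")
})

test_that("missing spacing is a distinct error; sidecar supplies it", {
  a <- array(0:23 * 1000, dim = c(2, 3, 4))
  v <- VoxelVolume(a, spacing = c(2, 1, 1))
  p <- file.path(withr::local_tempdir(), "v.tif")
  writeVolume(v, p)
  file.remove(paste0(p, ".json"))
  expect_error(readVolume(p), "missing spacing")
  expect_equal(voxelSpacing(readVolume(p, spacing = c(2, 1, 1))), c(2, 1, 1))
})

test_that("NRRD round trip populates spacing from the header alone", {
  a <- array(rnorm(2 * 3 * 4), dim = c(2, 3, 4))
  v <- VoxelVolume(a, spacing = c(0.45, 0.5, 0.65))
  p <- file.path(withr::local_tempdir(), "v.nrrd")
  writeVolume(v, p)
  r <- readVolume(p)                     # no sidecar, header only
  expect_equal(voxelData(r), voxelData(v))
  expect_equal(voxelSpacing(r), c(0.45, 0.5, 0.65))
})

test_that("16-bit conversion maps range endpoints and midpoint as specified", {
  a <- array(runif(4 * 4 * 4), dim = c(4, 4, 4))
  a[1] <- 0; a[2] <- 1; a[3] <- 0.5
  out <- voxelData(convertTo16bit(VoxelVolume(a)))
  expect_identical(out[1], 0)
  expect_identical(out[2], 65535)
  expect_identical(out[3], 32768)        # round-half-up at the midpoint
  cst <- convertTo16bit(VoxelVolume(array(7, dim = c(2, 2, 2))))
  expect_true(all(voxelData(cst) == 0))
  bad <- array(1, dim = c(2, 2, 2)); bad[1] <- NA
  expect_error(convertTo16bit(VoxelVolume(bad)), "non-finite")
})

test_that("cropping to foreground respects padding and clips to the grid", {
  a <- array(0L, dim = c(8, 9, 10))
  a[3, 4, 5] <- 1L
  v <- binVol(a)
  expect_equal(dim(cropToForeground(v, 0.5, 1)), c(3, 3, 3))
  expect_equal(dim(cropToForeground(v, 0.5, 0)), c(1, 1, 1))
  expect_error(cropToForeground(binVol(array(0L, c(2, 2, 2))), 0.5),
               "empty foreground")
})

test_that("volume measurement is invariant under cropping", {
  ph <- rodPhantomFixture(L = 30, r = 3)
  before <- sum(voxelData(ph$volume)) * prod(voxelSpacing(ph$volume))
  cr <- cropToForeground(ph$volume, 0.5, 2)
  after <- sum(voxelData(cr)) * prod(voxelSpacing(cr))
  expect_identical(after, before)
})

test_that("record CSVs round-trip and missing columns are named", {
  rec <- makeCohort(cohortSpec(n_per_group = 2, seed = 1),
                    render = FALSE)$truth[1:3, ]
  p <- file.path(withr::local_tempdir(), "rec.csv")
  writeRecords(rec, p)
  back <- readRecords(p)
  expect_equal(back, rec, tolerance = 1e-12)
  bad <- rec; bad$volume_um3 <- NULL
  expect_error(writeRecords(bad, p), "volume_um3")
  writeLines(paste(setdiff(names(rec), "volume_um3"), collapse = ","), p)
  expect_error(readRecords(p), "volume_um3")
  # empty table round-trips as a header-only file
  p2 <- file.path(withr::local_tempdir(), "empty.csv")
  writeRecords(rec[0, ], p2)
  expect_identical(nrow(readRecords(p2)), 0L)
})
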