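test_that("a 56-volume acquisition parses into 55 directions plus one b0", {
  td <- withr::local_tempdir()
  arr <- array(runif(3 * 3 * 3 * 56, 10, 100), c(3, 3, 3, 56))
  dwi <- dwiVolume(arr, imageGrid(c(3, 3, 3), 2.2), qbGtab)
  writeDWI(dwi, file.path(td, "d.nii.gz"), file.path(td, "bval"),
           file.path(td, "bvec"))
  rt <- readDWI(file.path(td, "d.nii.gz"), file.path(td, "bval"),
                file.path(td, "bvec"))
  expect_equal(sum(!b0Mask(rt@gtab)), 55L)
  expect_equal(sum(b0Mask(rt@gtab)), 1L)
  expect_equal(rt@data, arr, tolerance = 1e-6)
  expect_equal(rt@gtab@bvecs, dwi@gtab@bvecs, tolerance = 1e-9)
  expect_equal(rt@grid@voxelSize, c(2.2, 2.2, 2.2), tolerance = 1e-5)
})

test_that("a zero gradient direction with nonzero b is rejected", {
  expect_error(gradientTable(c(0, 2000), rbind(c(0, 0, 0), c(0, 0, 0))),
               "zero gradient")
})

test_that("volume/gradient length mismatch is a format error", {
  td <- withr::local_tempdir()
  arr <- array(runif(2 * 2 * 2 * 5, 1, 10), c(2, 2, 2, 5))
  g <- imageGrid(c(2, 2, 2), 2)
  RNifti::writeNifti(RNifti::asNifti(arr), file.path(td, "d.nii.gz"))
  writeLines(paste(c(0, 2000, 2000, 2000), collapse = " "),
             file.path(td, "bval"))
  m <- rbind(c(0, 0, 0), diag(3))
  write.table(t(m), file.path(td, "bvec"), row.names = FALSE,
              col.names = FALSE)
  expect_error(readDWI(file.path(td, "d.nii.gz"), file.path(td, "bval"),
                       file.path(td, "bvec")), "4 entries.*5 frames")
})

test_that("gradient rotation is norm-preserving, composes, and validates", {
  gt <- gradientTable(c(0, 2000), rbind(c(0, 0, 0), c(1, 0, 0)))
  # identity
  expect_equal(rotateGradientTable(gt, diag(3))@bvecs, gt@bvecs)
  # 90 degrees about z: x -> y
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  expect_equal(rotateGradientTable(gt, Rz)@bvecs[2, ], c(0, 1, 0),
               tolerance = 1e-12)
  # norms preserved and composition for arbitrary rotations
  set.seed(4)
  R1 <- randomRotation()
  R2 <- randomRotation()
  a <- rotateGradientTable(rotateGradientTable(qbGtab, R1), R2)
  b <- rotateGradientTable(qbGtab, R2 %*% R1)
  expect_equal(a@bvecs, b@bvecs, tolerance = 1e-6)
  nrm <- sqrt(rowSums(a@bvecs[!b0Mask(a), ]^2))
  expect_true(all(abs(nrm - 1) < 1e-9))
  # b-values untouched; improper matrix rejected
  expect_equal(a@bvals, qbGtab@bvals)
  expect_error(rotateGradientTable(gt, diag(c(1, 1, -1))), "proper")
})

test_that("TRK files round-trip streamlines on the acquisition grid", {
  grid <- imageGrid(c(10, 12, 8), 2.2)
  withr::local_seed(2)
  sl <- list(matrix(cumsum(rnorm(15, 0.5)) + 3, 5, 3),
             matrix(runif(6, 2, 14), 2, 3))
  tr <- tractogram(sl, grid)
  f <- withr::local_tempfile(fileext = ".trk")
  writeTractogram(tr, f)
  rt <- readTractogram(f)
  expect_equal(length(rt), 2L)
  for (i in 1:2)
    expect_lt(max(abs(rt@streamlines[[i]] - sl[[i]])), 1e-3)
  # header carries the 2.2 mm isotropic grid
  expect_equal(rt@grid@voxelSize, c(2.2, 2.2, 2.2), tolerance = 1e-5)
  expect_equal(rt@grid@dims, c(10L, 12L, 8L))
  # empty tractogram is a valid zero-track file
  writeTractogram(tractogram(list(), grid), f)
  expect_equal(length(readTractogram(f)), 0L)
  # grid mismatch on read is an error
  expect_error(readTractogram(f, grid = imageGrid(c(5, 5, 5), 2)),
               "does not match")
})

test_that("image grids validate invertibility and voxel-size consistency", {
  bad <- matrix(0, 4, 4)
  expect_error(imageGrid(c(2, 2, 2), 1, affine = bad), "invertible")
  aff <- diag(c(1, 1, 1, 1))
  expect_error(imageGrid(c(2, 2, 2), voxelSize = 2, affine = aff),
               "column norms")
  # scanner-style affine with offset round-trips world coordinates
  aff <- diag(c(2.2, 2.2, 2.2, 1))
  aff[1:3, 4] <- c(-20, -30, -10)
  g <- imageGrid(c(5, 5, 5), 2.2, affine = aff)
  p <- matrix(c(-15.6, -25.6, -5.6), 1)
  expect_equal(voxelToWorld(g, worldToVoxel(g, p)), p)
})

test_that("label volumes require every nonzero label in the lookup", {
  arr <- array(0L, c(2, 2, 2))
  arr[1, 1, 1] <- 3L
  g <- imageGrid(c(2, 2, 2), 1)
  expect_error(labelVolume(arr, c(`1` = "one"), g), "lookup")
  lv <- labelVolume(arr, c(`3` = "three"), g)
  expect_s4_class(lv, "LabelVolume")
  td <- withr::local_tempdir()
  writeLabelVolume(lv, file.path(td, "lab.nii.gz"), file.path(td, "lut.tsv"))
  rt <- readLabelVolume(file.path(td, "lab.nii.gz"), file.path(td, "lut.tsv"))
  expect_identical(rt@labels, arr)
  expect_identical(unname(rt@lookup["3"]), "three")
})
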