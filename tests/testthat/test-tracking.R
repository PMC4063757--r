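test_that("seed lattices have the right count, spacing and interiority", {
  g <- imageGrid(c(5, 5, 5), 2.2)
  # the protocol density: 11^3 seeds in one voxel
  s <- seedGrid(matrix(c(2, 2, 2), 1), g, 11L)
  expect_equal(nrow(s), 1331L)
  # n = 1 gives the voxel centre
  s1 <- seedGrid(matrix(c(2, 2, 2), 1), g, 1L)
  expect_equal(drop(s1), c(2, 2, 2) * 2.2)
  # 2 voxels at n = 2: 16 seeds, all strictly interior to their voxel
  roi <- rbind(c(1, 1, 1), c(3, 1, 1))
  s2 <- seedGrid(roi, g, 2L)
  expect_equal(nrow(s2), 16L)
  v <- worldToVoxel(g, s2)
  frac <- v - round(v)
  expect_true(all(abs(frac) > 0.01 & abs(frac) < 0.5))
  expect_error(seedGrid(roi, g, 0L), "seedsPerAxis")
  # pure function of ROI and n
  expect_identical(s2, seedGrid(roi, g, 2L))
})

test_that("direction selection follows the closest peak and terminates on
           empty sets", {
  pk <- peakSet(rbind(c(0, 0, 1), c(1, 0, 0)), c(1, 0.9))
  expect_equal(selectDirection(pk, c(0, 0, 1)), c(0, 0, 1))
  inc <- c(sin(10 * pi / 180), 0, cos(10 * pi / 180))
  expect_equal(selectDirection(pk, inc), c(0, 0, 1))
  # antipodal sign choice aligns with the incoming direction
  expect_equal(selectDirection(pk, c(0, 0, -1)), c(0, 0, -1))
  expect_null(selectDirection(peakSet(), c(0, 0, 1)))
  # at the seed every peak axis is returned
  expect_equal(nrow(selectDirection(pk)), 2L)
})

test_that("a homogeneous field tracks straight and stops at the FA
           boundary", {
  ph <- qbStraightPhantom
  cfg <- trackingConfig(seedsPerAxis = 2L)
  tr <- trackBundle(ph$dwi, ph$gate, cfg, masterSeed = 10L)
  expect_gt(length(tr), 0L)
  lg <- attr(tr, "log")
  expect_true(all(names(lg$terminationReasons) == "fa_threshold"))
  for (s in streamlines(tr)) {
    # spans most of the 44 mm bundle and stays on the tube axis
    expect_gt(max(s[, 2]) - min(s[, 2]), 35)
    expect_lt(max(abs(s[, 1] - 6 * 2.2)), 2.6)
    expect_lt(max(abs(s[, 3] - 4 * 2.2)), 2.6)
  }
})

test_that("a 70-degree bend in the direction field stops tracking at the
           bend plane", {
  d <- c(24, 24, 8)
  g <- imageGrid(d, 2.2)
  fa <- scalarVolume(array(0.8, d), g)
  bendY <- 12 * 2.2
  d1 <- c(0, 1, 0)
  d2 <- c(sin(70 * pi / 180), cos(70 * pi / 180), 0)
  provider <- function(voxel, id, step) {
    w <- voxelToWorld(g, voxel)
    if (w[2] < bendY) peakSet(matrix(d1, 1), 1)
    else peakSet(matrix(d2, 1), 1)
  }
  cfg <- trackingConfig(seedsPerAxis = 1L)
  sl <- propagate(c(12 * 2.2, 4 * 2.2, 4 * 2.2), provider, fa, cfg, g,
                  id = 0L)
  expect_equal(length(sl), 1L)
  s <- sl[[1]]
  # forward growth ends within one step of the bend plane
  expect_lt(max(s[, 2]), bendY + cfg@stepMm + 1e-6)
  expect_gt(max(s[, 2]), bendY - 2 * cfg@stepMm)
  expect_true(any(grepl("angle", attr(sl, "reasons"))))
})

test_that("streamlines obey step-length, angle and FA stopping rules as
           hard post-conditions", {
  ph <- qbStraightPhantom
  cfg <- trackingConfig(seedsPerAxis = 2L)
  tr <- trackBundle(ph$dwi, ph$gate, cfg, masterSeed = 4L)
  fa <- fitTensorFA(ph$dwi)
  for (s in streamlines(tr)) {
    seg <- s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE]
    len <- sqrt(rowSums(seg^2))
    expect_true(all(abs(len - cfg@stepMm) < 1e-3))
    if (nrow(seg) > 1) {
      u <- seg / len
      ct <- rowSums(u[-1, , drop = FALSE] * u[-nrow(u), , drop = FALSE])
      expect_true(all(acos(pmin(pmax(ct, -1), 1)) * 180 / pi <=
                        cfg@maxAngleDeg + 1e-6))
    }
    expect_true(all(interpolateScalar(fa, s) >= cfg@faThreshold))
  }
})

test_that("tracking is deterministic given the master seed, to the byte in
           TRK output", {
  ph <- qbStraightPhantom
  cfg <- trackingConfig(seedsPerAxis = 2L)
  t1 <- trackBundle(ph$dwi, ph$gate, cfg, masterSeed = 77L)
  t2 <- trackBundle(ph$dwi, ph$gate, cfg, masterSeed = 77L)
  expect_identical(streamlines(t1), streamlines(t2))
  f1 <- withr::local_tempfile(fileext = ".trk")
  f2 <- withr::local_tempfile(fileext = ".trk")
  writeTractogram(t1, f1)
  writeTractogram(t2, f2)
  expect_identical(readBin(f1, raw(), file.size(f1)),
                   readBin(f2, raw(), file.size(f2)))
  # with measurement noise, a different master seed changes the draws
  phn <- qbCrossingPhantom
  n1 <- trackBundle(phn$dwi, phn$gate, trackingConfig(seedsPerAxis = 1L),
                    masterSeed = 78L)
  n2 <- trackBundle(phn$dwi, phn$gate, trackingConfig(seedsPerAxis = 1L),
                    masterSeed = 79L)
  expect_false(identical(streamlines(n1), streamlines(n2)))
})

test_that("on the noiseless straight phantom nearly every seed connects the
           two end labels", {
  ph <- qbStraightPhantom
  cfg <- trackingConfig(seedsPerAxis = 3L)
  tr <- trackBundle(ph$dwi, ph$gate, cfg, masterSeed = 1L)
  lg <- attr(tr, "log")
  nm <- endpointLabelNames(tr, ph$labels)
  goodSeed <- logical(lg$nSeeds)
  for (i in seq_along(nm)) {
    if (setequal(nm[[i]], c("posterior_end", "anterior_end")) &&
        length(nm[[i]]) == 2L)
      goodSeed[lg$seedOf[i]] <- TRUE
  }
  expect_gte(mean(goodSeed), 0.95)
})
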