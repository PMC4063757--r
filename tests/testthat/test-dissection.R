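mkTract <- function(..., grid = imageGrid(c(20, 20, 10), 2.2)) {
  tractogram(list(...), grid)
}

test_that("plane filtering keeps traversing streamlines, touches included,
           and is idempotent", {
  pl <- planeSpec("y", 20)
  spans <- cbind(10, seq(10, 30, by = 2), 10)
  anterior <- cbind(10, seq(22, 30, by = 2), 10)
  touches <- cbind(10, c(16, 18, 20), 10)
  tr <- mkTract(spans, anterior, touches)
  kept <- filterByPlane(tr, pl)
  expect_equal(length(kept), 2L)
  expect_equal(streamlines(kept)[[1]], spans)
  expect_equal(streamlines(kept)[[2]], touches)
  expect_equal(streamlines(filterByPlane(kept, pl)), streamlines(kept))
  # side modes: only the entirely-anterior streamline lies fully above
  expect_equal(length(filterByPlane(tr, planeSpec("y", 20, "keep_above"))),
               1L)
  expect_equal(length(filterByPlane(tr, planeSpec("y", 20, "keep_below"))),
               1L)
})

test_that("loops and grey-matter-threading streamlines are excluded with a
           per-rule report", {
  g <- imageGrid(c(20, 20, 10), 2.2)
  straight <- cbind(10, seq(4, 40, by = 2), 10)
  th <- seq(0, 2.2 * pi, length.out = 80)
  circle <- cbind(20 + 6 * cos(th), 20 + 6 * sin(th), 10)
  lab <- array(0L, c(20, 20, 10))
  lab[6, 10, 5] <- 1L   # world x ~ 11-13
  lab[8, 10, 5] <- 2L
  lab[10, 10, 5] <- 3L
  labels <- labelVolume(lab, c(`1` = "a", `2` = "b", `3` = "c"), g)
  threading <- cbind(seq(8, 26, by = 1.1), 19.8, 8.8)
  tr <- tractogram(list(straight, circle, threading), g)
  out <- qcFilter(tr, labels)
  expect_equal(length(out), 1L)
  expect_equal(streamlines(out)[[1]], straight)
  expect_equal(attr(out, "exclusions"), c(loop = 1L, gm_traversal = 1L))
  # idempotent
  out2 <- qcFilter(out, labels)
  expect_equal(streamlines(out2), streamlines(out))
  expect_equal(attr(out2, "exclusions"), c(loop = 0L, gm_traversal = 0L))
})

test_that("label dilation respects depth, mask, nearest-label and tie
           rules", {
  g <- imageGrid(c(6, 6, 3), 2.2)
  lab <- array(0L, c(6, 6, 3))
  lab[2, , ] <- 1L
  lab[5, , ] <- 2L
  wm <- array(FALSE, c(6, 6, 3))
  wm[3:4, , ] <- TRUE
  lv <- labelVolume(lab, c(`1` = "left", `2` = "right"), g)
  # neighbouring voxel centres are 2.2 mm apart: no growth at 2.0 mm depth
  d0 <- dilateLabels(lv, wm, depthMm = 2.0)
  expect_identical(d0@labels, lab)
  # at 2.3 mm depth each label grows one shell into white matter
  d1 <- dilateLabels(lv, wm, depthMm = 2.3)
  expect_true(all(d1@labels[3, , ] == 1L))
  expect_true(all(d1@labels[4, , ] == 2L))
  # never shrinks, never grows outside mask or original support
  expect_true(all(d1@labels[lab > 0L] == lab[lab > 0L]))
  expect_true(all((d1@labels > 0L) <= (wm | lab > 0L)))
  # exact tie goes to the smaller label id
  labT <- array(0L, c(6, 6, 3))
  labT[2, , ] <- 2L
  labT[4, , ] <- 1L
  wmT <- array(FALSE, c(6, 6, 3))
  wmT[3, , ] <- TRUE
  dT <- dilateLabels(labelVolume(labT, c(`1` = "a", `2` = "b"), g), wmT,
                     depthMm = 2.3)
  expect_true(all(dT@labels[3, , ] == 1L))
  # overlapping growth from a single label never relabels it
  expect_error(dilateLabels(lv, NULL, 2), "mask")
})

test_that("termination classification tests endpoints only and is
           orientation-invariant", {
  g <- imageGrid(c(20, 20, 10), 2.2)
  lab <- array(0L, c(20, 20, 10))
  lab[10:12, 3, 5] <- 1L      # VOI A near y = 4.4
  lab[10:12, 17, 5] <- 2L     # VOI B near y = 35.2
  lab[10:12, 10, 5] <- 3L     # VOI C mid-course
  labels <- labelVolume(lab, c(`1` = "A", `2` = "B", `3` = "C"), g)
  s <- cbind(10 * 2.2, seq(2 * 2.2, 16 * 2.2, by = 1.1), 4 * 2.2)
  tr <- tractogram(list(s), g)
  row <- classifyTerminations(tr, labels, subject = "s1")
  expect_equal(row$count[row$name == "A"], 1L)
  expect_equal(row$count[row$name == "B"], 1L)
  # VOI C is crossed mid-course only: endpoints-only contract
  expect_equal(row$count[row$name == "C"], 0L)
  expect_equal(row$indicator, c(1L, 1L, 0L))
  rev <- tractogram(list(s[nrow(s):1, ]), g)
  expect_equal(classifyTerminations(rev, labels)$count, row$count)
})

test_that("a dissected phantom bundle sets exactly its two endpoint
           indicators", {
  ph <- qbStraightPhantom
  tr <- trackBundle(ph$dwi, ph$gate, trackingConfig(seedsPerAxis = 2L),
                    masterSeed = 3L)
  row <- classifyTerminations(tr, ph$labels, subject = "phantom")
  hit <- row$name[row$indicator == 1L]
  expect_setequal(hit, c("posterior_end", "anterior_end"))
})
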