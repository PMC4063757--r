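test_that("the default acquisition scheme is 55 well-spread directions plus
           one b0", {
  expect_equal(length(bValues(qbGtab)), 56L)
  expect_equal(sum(b0Mask(qbGtab)), 1L)
  expect_equal(unique(bValues(qbGtab)[!b0Mask(qbGtab)]), 2000)
  nrm <- sqrt(rowSums(qbDirs^2))
  expect_true(all(abs(nrm - 1) < 1e-9))
  expect_gte(minimumPairwiseAngle(qbGtab), 12)
  # deterministic given the seed
  expect_identical(bVectors(makeGradientTable(seed = 1)), bVectors(qbGtab))
})

test_that("the multi-tensor forward model matches hand evaluation", {
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0.6, 0.8, 0))
  dIso <- 0.7e-3
  sIso <- multiTensorSignal(dirs, 2000, 1, list(diag(dIso, 3)), S0 = 80)
  expect_equal(sIso, rep(80 * exp(-2000 * dIso), 3), tolerance = 1e-12)
  tens <- list(tensorFromAxis(c(1, 0, 0)), tensorFromAxis(c(0, 1, 0)))
  sFirst <- multiTensorSignal(dirs, 2000, c(1, 0), tens, S0 = 100)
  expect_equal(sFirst, multiTensorSignal(dirs, 2000, 1, tens[1], S0 = 100))
  # 50/50 perpendicular mixture at one direction, by hand:
  # q_i = l2 + (l1 - l2) (g . axis_i)^2, S = S0/2 (e^{-b q_1} + e^{-b q_2})
  g <- c(0.6, 0.8, 0)
  q1 <- 0.3e-3 + 1.4e-3 * 0.36
  q2 <- 0.3e-3 + 1.4e-3 * 0.64
  byHand <- 50 * (exp(-2000 * q1) + exp(-2000 * q2))
  s5050 <- multiTensorSignal(matrix(g, 1), 2000, c(0.5, 0.5), tens, S0 = 100)
  expect_equal(drop(s5050), byHand, tolerance = 1e-12)
  expect_error(multiTensorSignal(dirs, 2000, c(0.5, 0.4), tens), "sum to 1")
  # attenuation decreases monotonically in b
  bs <- seq(0, 3000, by = 500)
  sb <- multiTensorSignal(matrix(g, 1), bs[1], 1, tens[1])
  for (b in bs[-1]) {
    snew <- multiTensorSignal(matrix(g, 1), b, 1, tens[1])
    expect_lt(snew, sb)
    sb <- snew
  }
})

test_that("Rician noise has the expected moments and empirical SNR", {
  s <- rep(100, 1000)
  expect_identical(addRicianNoise(s, Inf), s)
  # pure-noise magnitude is Rayleigh: mean sigma*sqrt(pi/2), sd by formula
  sigma <- 5
  z <- addRicianNoise(numeric(1e5), snr = 100 / sigma, S0 = 100, seed = 2)
  expect_equal(mean(z), sigma * sqrt(pi / 2), tolerance = 0.02)
  expect_equal(sd(z), sigma * sqrt(2 - pi / 2), tolerance = 0.02)
  # requested SNR of 20 realised within 5% on a uniform b0 region
  b0 <- addRicianNoise(rep(100, 2e4), snr = 20, S0 = 100, seed = 3)
  expect_lt(abs(mean(b0) / sd(b0) - 20) / 20, 0.05)
  # deterministic given the seed
  expect_identical(addRicianNoise(s, 20, seed = 9),
                   addRicianNoise(s, 20, seed = 9))
})

test_that("phantoms are deterministic and their background FA sits below
           the tracking threshold", {
  p1 <- makePhantom(phantomPreset("crossing-90", snr = 30, seed = 5))
  p2 <- makePhantom(phantomPreset("crossing-90", snr = 30, seed = 5))
  expect_identical(p1$dwi@data, p2$dwi@data)
  expect_identical(p1$labels@labels, p2$labels@labels)
  ph <- qbStraightPhantom  # noiseless
  fa <- fitTensorFA(ph$dwi)
  bg <- !array(ph$truth$member[, 1], dim(fa@values))
  expect_lt(max(fa@values[bg]), 0.15)
  expect_gt(min(fa@values[!bg]), 0.15)
})

test_that("phantom specs validate geometry and eigenvalue ordering", {
  expect_error(phantomSpec(c(5, 5, 5), 2.2, list(list(
    points = rbind(c(1, 1, 1), c(9, 9, 9)), radius = 0.5,
    evals = c(1.7, 0.3, 0.3) * 1e-3, startLabel = "a", endLabel = "b")),
    gate = list(center = c(5, 5, 5), halfExtent = c(1, 1, 1))),
    "radius")
  expect_error(phantomSpec(c(5, 5, 5), 2.2, list(list(
    points = rbind(c(1, 1, 1), c(9, 9, 9)), radius = 2,
    evals = c(0.3, 1.7, 0.3) * 1e-3, startLabel = "a", endLabel = "b")),
    gate = list(center = c(5, 5, 5), halfExtent = c(1, 1, 1))),
    "descending")
  # bundle leaving the grid is refused at build time
  sp <- phantomSpec(c(5, 5, 5), 2.2, list(list(
    points = rbind(c(1, 1, 1), c(40, 40, 9)), radius = 2,
    evals = c(1.7, 0.3, 0.3) * 1e-3, startLabel = "a", endLabel = "b")),
    gate = list(center = c(5, 5, 5), halfExtent = c(1, 1, 1)))
  expect_error(makePhantom(sp), "leaves the grid")
})

test_that("packaged table fixtures load with verified structure and flags", {
  fx <- loadTableFixtures()
  expect_named(fx, c("left_frontal", "right_frontal", "left_posterior",
                     "right_posterior"))
  lp <- fx$left_posterior
  # 20 subjects x 8 columns (7 VOIs + the bundle-identified column)
  expect_equal(dim(indicators(lp)), c(20L, 8L))
  expect_equal(unname(summarizeTerminations(lp)["Y"]), 100)
  # flagged low-support entries match the transcription audit
  expect_equal(sum(fx$left_frontal@flags), 14L)
  expect_equal(sum(fx$right_frontal@flags), 19L)
  expect_equal(sum(fx$left_posterior@flags), 7L)
  expect_equal(sum(fx$right_posterior@flags), 5L)
  # flags only ever sit on indicator-1 entries
  for (t in fx) expect_true(all(indicators(t)[t@flags] == 1))
})

test_that("phantom output files round-trip through the standard formats", {
  td <- withr::local_tempdir()
  writePhantom(qbStraightPhantom, td)
  expect_true(all(file.exists(file.path(td, c(
    "dwi.nii.gz", "bvals", "bvecs", "labels.nii.gz", "lut.tsv",
    "truth.trk", "gate_roi.nii.gz")))))
  dwi <- readDWI(file.path(td, "dwi.nii.gz"), file.path(td, "bvals"),
                 file.path(td, "bvecs"))
  expect_equal(dwi@data, qbStraightPhantom$dwi@data, tolerance = 1e-6)
  lab <- readLabelVolume(file.path(td, "labels.nii.gz"),
                         file.path(td, "lut.tsv"))
  expect_identical(lab@labels, qbStraightPhantom$labels@labels)
})
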