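test_that("SH design matrix has the documented shape and basis identities", {
  B <- shDesignMatrix(qbGtab, 4L)
  expect_equal(dim(B), c(55L, 15L))
  # L = 0: the single constant column Y00 = 1/sqrt(4 pi)
  B0 <- shDesignMatrix(qbGtab, 0L)
  expect_equal(dim(B0), c(55L, 1L))
  expect_equal(unname(B0[, 1]), rep(1 / sqrt(4 * pi), 55), tolerance = 1e-12)
  # fitting a pure-Y20 input reproduces it exactly at the fit directions
  cTrue <- numeric(15)
  cTrue[4] <- 1   # (l, m) = (2, 0) in the fixed ordering
  y <- drop(B %*% cTrue)
  cHat <- drop(solve(crossprod(B), crossprod(B, y)))
  expect_equal(cHat, cTrue, tolerance = 1e-10)
  # underdetermined fit refused
  few <- gradientTable(c(0, rep(2000, 10)),
                       rbind(c(0, 0, 0), qbDirs[1:10, ]))
  expect_error(shDesignMatrix(few, 4L), "underdetermined")
})

test_that("isotropic attenuation fits with zero anisotropic coefficients", {
  sig <- c(100, rep(100 * exp(-2000 * 0.9e-3), 55))
  fit <- fitSignalSH(singleVoxelDwi(sig))
  expect_lt(max(abs(fit@coeffs[1, -1])), 1e-10)
})

test_that("the double-log signal fit reproduces the analytic transform at
           held-out directions", {
  D <- tensorFromAxis(c(0, 0, 1), c(1.7, 0.3, 0.3) * 1e-3)
  sig <- multiTensorSignal(qbDirs, 2000, 1, list(D), S0 = 100)
  withr::local_seed(31)
  held <- matrix(rnorm(300), 100, 3)
  held <- held / sqrt(rowSums(held^2))
  yTrue <- log(2000 * rowSums((held %*% D) * held))  # ln(-ln E), closed form
  rmse <- function(L) {
    fit <- fitSignalSH(singleVoxelDwi(c(100, sig)), L = L)
    yHat <- drop(realSphericalHarmonics(held, L) %*% fit@coeffs[1, ])
    sqrt(mean((yHat - yTrue)^2))
  }
  # order 4 carries the expected truncation error for this tensor;
  # enriching the basis drives the held-out error below 1e-2
  expect_lt(rmse(4L), 0.05)
  expect_lt(rmse(8L), 1e-2)
  expect_lt(rmse(8L), rmse(4L))
})

test_that("attenuation at the clamp boundary still yields a finite fit", {
  sig <- c(100, rep(50, 55))
  sig[2] <- 100   # E = 1 at one direction: clamped to 1 - epsilon
  fit <- fitSignalSH(singleVoxelDwi(sig))
  expect_true(all(is.finite(fit@coeffs)))
  expect_true(all(is.finite(fit@fitted)))
})

test_that("all-zero voxels are flagged invalid and excluded", {
  arr <- array(0, c(2, 1, 1, 56))
  arr[1, 1, 1, ] <- c(100, rep(40, 55))
  dwi <- dwiVolume(arr, imageGrid(c(2, 1, 1), 2.2), qbGtab)
  fit <- fitSignalSH(dwi)
  expect_equal(sum(fit@mask), 1L)
  expect_true(fit@mask[1, 1, 1])
})

test_that("CSA ODFs are normalised, isotropy-flat and antipodally even", {
  # isotropic voxel: ODF = 1/(4 pi) everywhere
  sig <- c(100, rep(100 * exp(-2000 * 0.9e-3), 55))
  odf <- csaOdf(fitSignalSH(singleVoxelDwi(sig)))
  vals <- odfValues(odf@coeffs[1, ], sphere = qbSphere)
  expect_lt(max(abs(vals - 1 / (4 * pi))), 1e-9)
  # unit integral and antipodal symmetry for random multi-tensor voxels
  withr::local_seed(8)
  for (i in 1:10) {
    k <- sample(1:3, 1)
    fr <- runif(k)
    fr <- fr / sum(fr)
    tens <- lapply(seq_len(k), function(j)
      tensorFromAxis(rnorm(3), sort(runif(3, 2e-4, 1.8e-3),
                                    decreasing = TRUE)))
    s <- multiTensorSignal(qbDirs, 2000, fr, tens, S0 = 100)
    o <- csaOdf(fitSignalSH(singleVoxelDwi(c(100, s))))
    expect_lt(abs(odfIntegral(o, sphere = qbSphere) - 1), 1e-3)
    v <- odfValues(o@coeffs[1, ], sphere = qbSphere)
    expect_lt(max(abs(v - v[qbSphere$antipode])), 1e-12)
  }
})

test_that("a single-tensor ODF peaks on the true axis within 3 degrees", {
  D <- tensorFromAxis(c(0, 0, 1))
  sig <- multiTensorSignal(qbDirs, 2000, 1, list(D), S0 = 100)
  odf <- csaOdf(fitSignalSH(singleVoxelDwi(c(100, sig))))
  vals <- odfValues(odf@coeffs[1, ], sphere = qbSphere)
  argmax <- qbSphere$vertices[which.max(vals), ]
  expect_lt(axisAngleDeg(argmax, c(0, 0, 1)), 3)
})

test_that("the ODF argmax is rotationally equivariant", {
  withr::local_seed(12)
  for (i in 1:5) {
    R <- randomRotation()
    ax <- c(0, 0, 1)
    # rotate scheme and tensor together; argmax must rotate along
    gtR <- rotateGradientTable(qbGtab, R)
    dirsR <- bVectors(gtR)[!b0Mask(gtR), ]
    DR <- R %*% tensorFromAxis(ax) %*% t(R)
    sig <- multiTensorSignal(dirsR, 2000, 1, list(DR), S0 = 100)
    odf <- csaOdf(fitSignalSH(singleVoxelDwi(c(100, sig), gtab = gtR)))
    argmax <- qbSphere$vertices[which.max(odfValues(odf@coeffs[1, ],
                                                    sphere = qbSphere)), ]
    expect_lt(axisAngleDeg(argmax, drop(R %*% ax)), 3)
  }
})

test_that("FA matches closed forms for isotropic, stick and cigar tensors", {
  iso <- c(100, rep(100 * exp(-2000 * 0.9e-3), 55))
  expect_lt(fitTensorFA(singleVoxelDwi(iso))@values[1, 1, 1], 1e-6)
  stick <- multiTensorSignal(qbDirs, 2000, 1,
                             list(tensorFromAxis(c(1, 0, 0),
                                                 c(1.2e-3, 0, 0) + 1e-12)),
                             S0 = 100)
  expect_equal(fitTensorFA(singleVoxelDwi(c(100, stick)))@values[1, 1, 1], 1,
               tolerance = 1e-6)
  ev <- c(1.7, 0.3, 0.3) * 1e-3
  cig <- multiTensorSignal(qbDirs, 2000, 1,
                           list(tensorFromAxis(c(0, 1, 0), ev)), S0 = 100)
  faTrue <- sqrt(1.5 * sum((ev - mean(ev))^2) / sum(ev^2))
  expect_equal(fitTensorFA(singleVoxelDwi(c(100, cig)))@values[1, 1, 1],
               faTrue, tolerance = 1e-6)
})
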