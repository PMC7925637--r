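test_that("diameter sampling: size, positivity, determinism, edge cases", {
  expect_identical(sampleDiameters(0, "uniform", list(min = 100, max = 300),
                                   seed = 1), numeric(0))
  d1 <- sampleDiameters(5, "shifted-exponential",
                        list(offset = 90, scale = 40), seed = 7)
  d2 <- sampleDiameters(5, "shifted-exponential",
                        list(offset = 90, scale = 40), seed = 7)
  expect_identical(d1, d2)
  expect_length(d1, 5L)
  expect_true(all(d1 > 0))
  d3 <- sampleDiameters(5, "lognormal", list(meanlog = 5, sdlog = 0.2),
                        seed = 7)
  expect_true(all(d3 > 0))
  expect_error(sampleDiameters(3, "weibull", list(), seed = 1))
  expect_error(sampleDiameters(3, "shifted-exponential",
                               list(offset = 90, scale = -1), seed = 1),
               "scale")
  expect_error(sampleDiameters(3, "uniform", list(min = 300, max = 100),
                               seed = 1))
})

test_that("shifted-exponential sample mean matches offset + scale", {
  # closed form: E[d] = offset + scale = 130 nm
  d <- sampleDiameters(1e5, "shifted-exponential",
                       list(offset = 90, scale = 40), seed = 3)
  expect_lt(abs(mean(d) - 130) / 130, 0.01)
})

test_that("sieve simulator renders membrane, pores and noise as specified", {
  # no pores, no bias, no noise: constant image at the membrane level
  tr0 <- sievePlateTruth(numeric(0), imageShape = c(32, 32),
                         biasFieldAmplitude = 0, noiseModel = "none",
                         membraneLevel = 200, seed = 1)
  img0 <- simulateSieveImage(tr0)$image
  expect_equal(dim(pixelValues(img0)), c(32L, 32L))
  expect_true(all(abs(pixelValues(img0) - 200) < 1e-6))

  # ground-truth completeness: one truth row per rendered pore
  sim <- makeCleanSieve(c(150, 200, 250), shape = c(160, 160))
  expect_identical(nrow(truthTable(sim$truth)), 3L)
  expect_identical(sim$truth, sim$truthRec)  # truth returned unchanged

  # seed determinism of the full render, noise included
  tr <- sievePlateTruth(c(180, 220), imageShape = c(96, 96), seed = 11)
  a <- simulateSieveImage(tr)$image
  b <- simulateSieveImage(tr)$image
  expect_identical(pixelValues(a), pixelValues(b))

  # a pore bigger than the image errors as out of bounds
  trBad <- sievePlateTruth(100, imageShape = c(64, 64), pixelSizeNm = 40,
                           centersNm = matrix(c(10, 10), 1), seed = 1)
  expect_error(simulateSieveImage(trBad), "bounds")
})

test_that("PSF blur lifts the pore floor above background (convolution oracle)", {
  # single pore with diameter == PSF FWHM == 100 nm: blur must keep the
  # pore minimum strictly above the nominal background level
  px <- 40
  tr <- sievePlateTruth(100, imageShape = c(32, 32), pixelSizeNm = px,
                        psfFwhmNm = 100, membraneLevel = 100,
                        backgroundLevel = 0, biasFieldAmplitude = 0,
                        noiseModel = "none",
                        centersNm = matrix(c(620, 620), 1), seed = 1)
  img <- pixelValues(simulateSieveImage(tr)$image)
  expect_gt(min(img), 0)

  # direct convolution oracle: rendering the same disk coverage and
  # blurring with an explicit kernel reproduces the simulator image
  sub <- 5; off <- (seq_len(sub) - (sub + 1) / 2) / sub
  ideal <- matrix(100, 32, 32)
  for (i in 1:32) for (j in 1:32) {
    cov <- 0
    for (oy in off) for (ox in off) {
      dy <- (i - 1 + oy) * px - 620; dx <- (j - 1 + ox) * px - 620
      if (dy^2 + dx^2 <= 50^2) cov <- cov + 1
    }
    ideal[i, j] <- 100 * (1 - cov / sub^2)
  }
  blurred <- oracleGaussBlur(ideal, 100 / (2 * sqrt(2 * log(2))) / px)
  expect_lt(max(abs(blurred - img)), 1e-3 * 100)
})

test_that("hyperspectral cube synthesis follows the two-peak model", {
  ax <- SpectralAxis()
  expect_length(wavenumbers(ax), 16L)  # (3020 - 2790)/15 + 1 samples

  z <- matrix(0, 4, 4)
  trZ <- new("HsiTruth", amp2845 = z, amp2920 = z, baseline = z,
             peakFwhmCm1 = 40, noiseSd = 0, seed = 1L)
  expect_true(all(pixelValues(simulateHsiCube(trZ)$cube) == 0))

  # pixel with (A2845, A2920) = (1, 0): the spectrum peaks at the 2845
  # sample when the axis contains it, and at the nearest sample (2850)
  # on the default 15 cm^-1 grid, where 2845 falls between samples
  a <- z; a[2, 2] <- 1
  trP <- new("HsiTruth", amp2845 = a, amp2920 = z, baseline = z,
             peakFwhmCm1 = 40, noiseSd = 0, seed = 1L)
  fine <- SpectralAxis(seq(2790, 3020, 5))
  spectrumFine <- pixelValues(simulateHsiCube(trP, fine)$cube)[2, 2, ]
  expect_identical(wavenumbers(fine)[which.max(spectrumFine)], 2845)
  spectrum <- pixelValues(simulateHsiCube(trP)$cube)[2, 2, ]
  expect_identical(wavenumbers(ax)[which.max(spectrum)], 2850)

  # shape mismatch between maps is rejected
  expect_error(new("HsiTruth", amp2845 = z, amp2920 = matrix(0, 3, 4),
                   baseline = z, peakFwhmCm1 = 40, noiseSd = 0, seed = 1L))

  # determinism under noise
  trN <- randomHsiTruth(16, 16, noiseSd = 0.1, seed = 9)
  expect_identical(pixelValues(simulateHsiCube(trN)$cube),
                   pixelValues(simulateHsiCube(trN)$cube))
})

test_that("forward projection conserves mass and respects disk symmetry", {
  # zero phantom: all-zero sinogram
  z <- PhantomImage(matrix(0, 24, 24))
  expect_true(all(sinogram(simulateOptProjections(z, 12, 10)) == 0))

  # centered disk: every projection identical within interpolation error
  # (the steep rim tolerates a few percent pointwise; RMS is much tighter)
  ph <- diskPhantom(64)
  ps <- simulateOptProjections(ph, 36, 10)
  S <- sinogram(ps)
  spread <- apply(S, 2, function(x) diff(range(x)))
  expect_lt(max(spread), 0.03 * max(S))
  expect_lt(sqrt(mean(sweep(S, 2, colMeans(S))^2)), 0.01 * max(S))

  # mass conservation: sum over detector bins equals phantom mass to 0.5%
  blob <- PhantomImage(oracleGaussBlur(diskPhantom(48, 12)@grid, 2))
  psB <- simulateOptProjections(blob, 20, 18)
  mass <- sum(pixelValues(blob))
  expect_true(all(abs(rowSums(sinogram(psB)) - mass) <= 0.005 * mass))

  # geometry guards
  expect_error(simulateOptProjections(PhantomImage(matrix(numeric(0), 0, 0))))
  expect_error(simulateOptProjections(ph, 700, 0.6), "360")

  # noise is seeded
  n1 <- simulateOptProjections(ph, 10, 36, noiseSd = 1, seed = 4)
  n2 <- simulateOptProjections(ph, 10, 36, noiseSd = 1, seed = 4)
  expect_identical(sinogram(n1), sinogram(n2))
})

test_that("pore placement honours the minimum separation", {
  d <- rep(200, 12)
  tr <- sievePlateTruth(d, imageShape = c(256, 256),
                        minSeparationFactor = 1.5, seed = 21)
  cc <- trueCenters(tr)
  dm <- as.matrix(dist(cc))
  diag(dm) <- Inf
  expect_true(all(dm >= 1.5 * 200 - 1e-9))
})
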