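test_that("injected odd/even phase errors are recovered from navigators", {
  p <- ciParams(nVolumes = 1)
  noise <- acqNoiseModel(theta0 = 0.15, theta1 = 0.002, seed = 4)
  sim <- simulateAcquisition(ciPhantom(), ciMaps(), p, ciReadout(), noise)
  pc <- estimatePhaseCorrection(sim$reference)
  expect_lt(abs(pc$theta0 - 0.15) / 0.15, 0.01)
  expect_lt(abs(pc$theta1 - 0.002) / 0.002, 0.01)

  # null case: estimates at the numerical noise floor
  pc0 <- estimatePhaseCorrection(ciSim()$reference)
  expect_lt(abs(pc0$theta0), 1e-10)
  expect_lt(abs(pc0$theta1), 1e-12)

  zero <- ciSim()$reference
  zero@data <- zero@data * 0
  expect_error(estimatePhaseCorrection(zero), "all-zero")
})

test_that("phase correction reduces the EPI ghost at least tenfold", {
  p <- ciParams(nVolumes = 2)
  noise <- acqNoiseModel(theta0 = pi / 20, seed = 4)
  sim <- simulateAcquisition(ciPhantom(), ciMaps(), p, ciReadout(), noise)
  tsRaw <- reconstructTimeseries(sim$sms, calibration = sim$reference,
                                 method = "slice_grappa",
                                 phaseCorrect = FALSE)
  tsFix <- reconstructTimeseries(sim$sms, calibration = sim$reference,
                                 method = "slice_grappa")
  gRaw <- ghostSignalRatio(tsRaw)
  gFix <- ghostSignalRatio(tsFix)
  expect_gt(gRaw, 0.05)
  expect_gt(gRaw / max(gFix, 1e-12), 10)
})

test_that("ramp regridding is exact for uniform and voxel-object data", {
  p <- sb1Params()
  ro <- sb1Sim()$ro        # flat-top-only sampling: samples on the grid
  nx <- p@matrixSize[1]
  k <- ro$kxSample
  # uniform flat-top samples pass through unchanged (identity)
  line <- complex(real = stats::rnorm(nx), imaginary = stats::rnorm(nx))
  out <- regridRampSamples(matrix(line, ncol = 1), k, +1, nx, p@fov[1])
  expect_lt(max(Mod(out - line)), 1e-12 * max(Mod(line)))

  # ramp-sampled single-voxel object matches the analytic DFT line
  p2 <- ciParams()
  ro2 <- ciReadout()
  x0 <- 3 * p2@fov[1] / p2@matrixSize[1]
  samp <- exp(-2i * pi * ro2$kxSample[, "even"] * x0)
  out2 <- regridRampSamples(matrix(samp, ncol = 1), ro2$kxSample, +1,
                            p2@matrixSize[1], p2@fov[1])
  kc <- ((seq_len(p2@matrixSize[1]) - 1) - p2@matrixSize[1] %/% 2) /
    p2@fov[1]
  expect_lt(max(Mod(out2 - exp(-2i * pi * kc * x0))), 1e-3)

  # energy preserved for band-limited content
  obj <- complex(real = stats::rnorm(p2@matrixSize[1]))
  sampBL <- vapply(ro2$kxSample[, "even"], function(kk)
    sum(obj * exp(-2i * pi * kk *
                    smsepi:::gridCoords(p2@matrixSize[1], p2@fov[1]))), 0i)
  outBL <- regridRampSamples(matrix(sampBL, ncol = 1), ro2$kxSample, +1,
                             p2@matrixSize[1], p2@fov[1])
  expect_lt(abs(sum(Mod(outBL)^2) - p2@matrixSize[1] * sum(Mod(obj)^2)) /
              (p2@matrixSize[1] * sum(Mod(obj)^2)), 0.01)

  # a grid wider than the sampled extent is refused
  expect_error(regridRampSamples(matrix(samp, ncol = 1),
                                 ro2$kxSample / 3, +1,
                                 p2@matrixSize[1], p2@fov[1]),
               "exceeds the sampled")
})

test_that("slice-GRAPPA calibration: delta kernel at SMS 1, tiny residual, deterministic", {
  fx <- sb1Sim()
  raw <- fx$sim$reference
  kern <- calibrateSliceGrappa(raw, matrix(0L, 1, 1),
                               array(0, c(length(raw@kyIndex), 1, 1)),
                               kernelSize = c(5, 5))
  expect_lt(kern$residual[1, 1], 1e-3)
  W <- kern$kernels[[1]][[1]]
  expect_equal(which.max(Mod(W[, 1])), 13L)    # center tap dominates

  sim <- ciSim()
  k1 <- calibrateSliceGrappa(sim$reference, sim$sms@bands,
                             sim$sms@caipiPhase)
  k2 <- calibrateSliceGrappa(sim$reference, sim$sms@bands,
                             sim$sms@caipiPhase)
  expect_identical(k1$kernels, k2$kernels)     # fully deterministic
  expect_lt(max(k1$residual), 1e-3)            # noiseless consistency
})

test_that("slice-GRAPPA unaliasing: accuracy, leakage and linearity", {
  p <- ciParams(nVolumes = 1)
  sim <- ciSim()
  ts <- reconstructTimeseries(sim$sms, calibration = sim$reference,
                              method = "slice_grappa")
  mask <- ciMask()
  expect_lt(inMaskNrmse(ts@data[, , , 1], ciPhantom()@data, mask), 0.05)

  # leakage: empty one band's slices, check signal recovered there
  ph2 <- ciPhantom()
  emptyBand <- sim$sms@bands[2, ] + 1L          # middle band of every shot
  ph2@data[, , emptyBand] <- 0
  sim2 <- simulateAcquisition(ph2, ciMaps(), p, ciReadout())
  ts2 <- reconstructTimeseries(sim2$sms, calibration = sim2$reference,
                               method = "slice_grappa")
  eEmpty <- sum(ts2@data[, , emptyBand, 1]^2)
  eSrc <- sum(ts2@data[, , -emptyBand, 1]^2)
  expect_lt(eEmpty / eSrc, 0.05^2 * length(emptyBand))

  # zero input maps to zero output
  kern <- calibrateSliceGrappa(sim$reference, sim$sms@bands,
                               sim$sms@caipiPhase)
  zero <- applySliceGrappa(array(0i, c(p@matrixSize[1],
                                       length(sim$sms@kyIndex), 6)),
                           kern, 1)
  expect_true(all(zero == 0))
})

test_that("SENSE unaliasing: identity case, exact recovery, g >= 1", {
  # SMS 1 with a single uniform coil returns the input
  img <- array(complex(real = stats::rnorm(64),
                       imaginary = stats::rnorm(64)), c(8, 8, 1))
  maps <- array(1 + 0i, c(8, 8, 1, 1))
  res <- senseUnalias(img, maps, matrix(0, 4, 1), 0:3, 1)
  expect_lt(max(Mod(res$images[, , 1] - img[, , 1])), 1e-10)

  sim <- ciSim()
  tss <- reconstructTimeseries(sim$sms, calibration = sim$reference,
                               method = "sense", maps = ciMaps())
  mask <- ciMask()
  expect_lt(inMaskNrmse(tss@data[, , , 1], ciPhantom()@data, mask), 1e-6)

  # g-factor bound on one shot's system
  p <- ciParams()
  sm <- ciMaps()@data[, , sim$sms@bands[, 1] + 1L, , drop = FALSE]
  sm <- aperm(sm, c(1, 2, 4, 3))
  collapsed <- array(0i, c(p@matrixSize[1], p@matrixSize[2], 6))
  g <- senseUnalias(collapsed, sm, sim$sms@caipiPhase[, , 1],
                    sim$sms@kyIndex, p@caipiShift)$g
  expect_gte(min(g), 1 - 1e-9)
})

test_that("partial-Fourier zero-fill: identity, grid size, PSF broadening", {
  ny <- 90
  ne <- 72
  kyIdx <- (ny - ne):(ny - 1)
  kd <- matrix(complex(real = stats::rnorm(12 * ny)), 12, ny)
  expect_identical(pfZerofill(kd, 0:(ny - 1), ny), kd)   # fraction 1.0
  out <- pfZerofill(kd[, 1:ne], kyIdx, ny)
  expect_identical(ncol(out), 90L)                       # full ky grid
  expect_true(all(out[, 1:(ny - ne)] == 0))

  # point-source PSF: main-lobe FWHM vs the analytic truncated-Fourier PSF
  psfFwhm <- function(kline) {
    up <- 64
    spec <- smsepi:::ifftshift1(kline)     # centered k-line -> FFT order
    padded <- c(spec[1:(ny / 2)], rep(0i, ny * (up - 1)),
                spec[(ny / 2 + 1):ny])
    prof <- Mod(stats::fft(padded, inverse = TRUE))
    prof <- prof / max(prof)
    r <- rle(prof >= 0.5)
    ends <- cumsum(r$lengths)
    starts <- c(1, head(ends, -1) + 1)
    pk <- which.max(prof)
    hit <- which(r$values & starts <= pk & ends >= pk)
    r$lengths[hit] / up
  }
  point <- rep(1 + 0i, ny)                         # flat spectrum source
  full <- point
  pf <- point; pf[1:(ny - ne)] <- 0
  ratio <- psfFwhm(pf) / psfFwhm(full)
  # analytic oracle: Dirichlet main lobes of widths ~ 1/ne vs 1/ny
  kfine <- seq(-3, 3, length.out = 20001)
  dirich <- function(n) {
    v <- abs(vapply(kfine, function(y)
      sum(exp(2i * pi * (1:n) * y / ny)), 0i))
    v <- v / max(v)
    d <- kfine[v >= 0.5]
    max(d) - min(d)
  }
  expect_lt(abs(ratio - dirich(ne) / dirich(ny)) / (dirich(ne) / dirich(ny)),
            0.05)
})

test_that("RSS coil combination matches the direct formula and its invariances", {
  arr <- array(complex(real = stats::rnorm(240),
                       imaginary = stats::rnorm(240)), c(6, 8, 5))
  rss <- coilCombineRss(arr)
  brute <- sqrt(apply(Mod(arr)^2, c(1, 2), sum))
  expect_lt(max(abs(rss - brute)), 1e-12)
  # invariant under per-coil global phase
  ph <- exp(1i * stats::runif(5, 0, 2 * pi))
  arr2 <- sweep(arr, 3, ph, `*`)
  expect_lt(max(abs(coilCombineRss(arr2) - rss)), 1e-12)
  one <- array(arr[, , 1], c(6, 8, 1))
  expect_equal(coilCombineRss(one), Mod(arr[, , 1]), tolerance = 1e-14)
})

test_that("full chain: cross-method agreement, determinism, error handling", {
  sim <- ciSim()
  tsg <- reconstructTimeseries(sim$sms, calibration = sim$reference,
                               method = "slice_grappa")
  tss <- reconstructTimeseries(sim$sms, calibration = sim$reference,
                               method = "sense", maps = ciMaps())
  mask <- ciMask()
  agree <- sqrt(sum((tsg@data[, , , 1][mask] - tss@data[, , , 1][mask])^2) /
                  sum(tss@data[, , , 1][mask]^2))
  expect_lt(agree, 0.05)

  tsg2 <- reconstructTimeseries(sim$sms, calibration = sim$reference,
                                method = "slice_grappa")
  expect_identical(tsg@data, tsg2@data)   # bit-identical determinism

  expect_error(reconstructTimeseries(sim$sms, method = "slice_grappa"),
               "requires single-band calibration")
  expect_error(reconstructTimeseries(sim$sms, method = "sense"),
               "requires coil maps or calibration")

  # degenerate single-band full-Fourier chain is exact
  fx <- sb1Sim()
  ts1 <- reconstructTimeseries(fx$sim$sms, calibration = fx$sim$reference,
                               method = "slice_grappa")
  expect_lt(smsepi:::nrmse(ts1@data[, , , 1], fx$phantom@data), 1e-3)
})

test_that("reconstructed SNR decreases with simulator noise", {
  p <- ciParams(nVolumes = 4)
  snrAt <- function(sigma) {
    sim <- simulateAcquisition(ciPhantom(), ciMaps(), p, ciReadout(),
                               acqNoiseModel(sigma = sigma, seed = 9))
    ts <- reconstructTimeseries(sim$sms, calibration = sim$reference,
                                method = "slice_grappa")
    computeSignalSfnrSnr(ts)$snr
  }
  snrs <- vapply(c(0.5, 1, 2), snrAt, 0)
  expect_true(all(diff(snrs) < 0))
})

test_that("NIfTI round trip preserves the time series and its geometry", {
  sim <- ciSim()
  ts <- reconstructTimeseries(sim$sms, calibration = sim$reference,
                              method = "slice_grappa")
  f <- tempfile(fileext = ".nii.gz")
  writeTimeSeriesNifti(ts, f)
  back <- readTimeSeriesNifti(f)
  expect_equal(back@data, ts@data, tolerance = 1e-6)
  expect_equal(back@voxelSize, ts@voxelSize, tolerance = 1e-6)
  expect_equal(back@tr, ts@tr, tolerance = 1e-6)
})
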