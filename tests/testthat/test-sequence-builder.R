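lim <- systemLimits()

test_that("the full-size readout matches the printed acquisition geometry", {
  p <- abcdParams()
  ro <- abcdReadout()
  # 72 echoes = ceil(0.8 * 90); late ky lines kept
  expect_identical(ro$nEchoes, 72L)
  expect_identical(range(ro$kyIndex), c(18L, 89L))
  # exact per-echo kx area: nx / fov
  expect_equal(ro$echoAmp * (ro$echoRise + ro$echoFlat),
               p@matrixSize[1] / p@fov[1], tolerance = 1e-9)
  # per-echo ky increment is 1/fov
  expect_equal(ro$dky, 1 / p@fov[2], tolerance = 1e-12)
  # readout slew was derated and the prediction respects the design bound
  expect_lte(ro$pns@peak, 100 * p@pnsDerate)
  expect_lt(ro$deratedSlew, lim@maxSlew)
})

test_that("fat-sat block carries the pulse plus a >= 4 pi spoiler", {
  p <- ciParams()
  blk <- buildFatsatBlock(p, lim)
  expect_false(is.null(blk@rf))
  expect_false(is.null(blk@gz))
  expect_null(blk@gx); expect_null(blk@adc)
  expect_lt(blk@rf@freqOffset, 0)                 # fat is downfield at 3 T
  area <- abs(smsepi:::trapArea(blk@gz))
  expect_gte(area * p@sliceThickness * 2 * pi, 4 * pi - 1e-9)
  # spoiler starts only after the RF (plus ringdown)
  expect_gte(blk@gz@delay, smsepi:::rfEnd(blk@rf))
})

test_that("the built protocol has the right shot structure and passes validation", {
  p <- ciParams()
  ro <- ciReadout()
  sq <- buildProtocol(p, lim, readout = ro)
  defs <- seqDefinitions(sq)
  nShots <- p@nSlices / p@smsFactor
  expect_identical(defs$SMSFactor, p@smsFactor)
  expect_identical(defs$NEchoes, ro$nEchoes)
  # reference segment: one shot per slice; SMS segment: nShots per volume
  perShot <- defs$ReferenceBlocks / p@nSlices
  expect_identical(perShot %% 1, 0)
  smsBlocks <- length(seqBlocks(sq)) - defs$ReferenceBlocks
  expect_equal(smsBlocks / perShot,
               nShots * (p@nDummies + p@nVolumes))
  expect_identical(nrow(validateSequence(sq)), 0L)

  # every volume lasts exactly one TR (block durations sum exactly)
  expect_equal(smsepi:::perVolumeDuration(sq, p), p@tr, tolerance = 1e-12)
  expect_equal(sequenceDuration(sq),
               p@nSlices * p@tr / nShots +
                 (p@nDummies + p@nVolumes) * p@tr, tolerance = 1e-12)
})

test_that("shot RF and ADC phases follow the RF-spoiling schedule", {
  p <- ciParams()
  sq <- buildProtocol(p, lim, readout = ciReadout())
  phases <- c()
  for (b in seqBlocks(sq)) {
    # slice-selective excitation: gradient under the pulse (delay 0),
    # unlike the fat-sat block whose spoiler starts after the RF
    if (!is.null(b@rf) && !is.null(b@gz) && b@gz@delay == 0)
      phases <- c(phases, b@rf@phaseOffset)
  }
  expected <- rfSpoilingPhase(seq_along(phases) - 1)
  expect_equal(phases, expected, tolerance = 1e-9)
  # navigator ADCs carry the same phase as their shot's excitation
  defs <- seqDefinitions(sq)
  perShot <- defs$ReferenceBlocks / p@nSlices
  shot1 <- seqBlocks(sq)[seq_len(perShot)]
  adcs <- Filter(function(b) !is.null(b@adc), shot1)
  expect_equal(adcs[[1]]@adc@phaseOffset, phases[1], tolerance = 1e-9)
})

test_that("one shot's trajectory covers the partial-Fourier ky range", {
  p <- ciParams(partialFourier = 0.8)
  ro <- designEpiReadout(p, lim)
  sq <- buildProtocol(p, lim, readout = ro)
  defs <- seqDefinitions(sq)
  perShot <- defs$ReferenceBlocks / p@nSlices
  i0 <- defs$ReferenceBlocks + 1L
  shotSeq <- new("PulseSequence",
                 blocks = seqBlocks(sq)[i0:(i0 + perShot - 1L)],
                 limits = lim, definitions = list())
  k <- computeKspace(shotSeq)
  adcBlocks <- unique(k$block)
  imgBlocks <- adcBlocks[-seq_len(ro$nNavigators)]
  ky <- vapply(imgBlocks, function(bl) k$ky[k$block == bl][1], 0)
  # distinct ky lines spaced 1/fov, covering the late partial_fourier band
  expect_identical(length(unique(round(ky * p@fov[2]))), ro$nEchoes)
  firstPol <- if (ro$nNavigators %% 2 == 0) 1 else -1
  expect_equal(diff(ky), rep(1 / p@fov[2], ro$nEchoes - 1),
               tolerance = 1e-6)
  expect_equal(ky[1], (ro$kyIndex[1] - p@matrixSize[2] / 2) / p@fov[2],
               tolerance = 1e-6)
  # navigators sit at ky = 0
  navKy <- vapply(adcBlocks[seq_len(ro$nNavigators)],
                  function(bl) k$ky[k$block == bl][1], 0)
  expect_equal(navKy, rep(0, ro$nNavigators), tolerance = 1e-6)
  # consecutive echoes alternate kx direction
  kx1 <- k$kx[k$block == imgBlocks[1]]
  kx2 <- k$kx[k$block == imgBlocks[2]]
  expect_gt(firstPol * (kx1[length(kx1)] - kx1[1]), 0)
  expect_lt(firstPol * (kx2[length(kx2)] - kx2[1]), 0)
})

test_that("CAIPI z-blips realize the simulator's encoding phases", {
  p <- ciParams()
  ro <- ciReadout()
  sq <- buildProtocol(p, lim, readout = ro)
  defs <- seqDefinitions(sq)
  perShot <- defs$ReferenceBlocks / p@nSlices
  i0 <- defs$ReferenceBlocks + 1L
  shotSeq <- new("PulseSequence",
                 blocks = seqBlocks(sq)[i0:(i0 + perShot - 1L)],
                 limits = lim, definitions = list())
  k <- computeKspace(shotSeq)
  adcBlocks <- unique(k$block)
  imgBlocks <- adcBlocks[-seq_len(ro$nNavigators)]
  kz <- vapply(imgBlocks, function(bl) k$kz[k$block == bl][1], 0)
  # blip increments are exact; the absolute offset (set by where the
  # multiband waveform peaks relative to the base-envelope isodelay) stays
  # below one blip step
  expect_equal(diff(kz), diff(ro$kzEcho), tolerance = 1e-6)
  expect_lt(abs(kz[1] - ro$kzEcho[1]), ro$dkz)
  # the simulator's per-band phase equals the blip-trajectory phase ramp
  sim <- ciSim()
  bands <- sim$sms@bands
  zb <- smsepi:::sliceZ(p, bands[, 1])
  for (b in seq_len(p@smsFactor)) {
    expected <- -2 * pi * ro$kzEcho * (zb[b] - zb[1])
    expect_equal(exp(1i * sim$sms@caipiPhase[, b, 1]),
                 exp(1i * expected), tolerance = 1e-9)
  }
})

test_that("TR fill holds across randomized feasible parameter sets", {
  combos <- list(
    list(m = 24, ns = 8, sms = 2, pf = 1, tr = 0.2, cs = 2),
    list(m = 32, ns = 8, sms = 4, pf = 0.75, tr = 0.3, cs = 3),
    list(m = 28, ns = 6, sms = 2, pf = 0.8, tr = 0.27, cs = 2))
  for (cb in combos) {
    p <- protocolParams(fov = c(0.2, 0.2, cb$ns * 0.007),
                        matrixSize = c(cb$m, cb$m), nSlices = cb$ns,
                        sliceThickness = 0.007, smsFactor = cb$sms,
                        tr = cb$tr, partialFourier = cb$pf, nVolumes = 1,
                        nDummies = 0, caipiShift = cb$cs)
    sq <- buildProtocol(p, lim)
    expect_equal(smsepi:::perVolumeDuration(sq, p), p@tr, tolerance = 1e-12)
    expect_identical(nrow(validateSequence(sq)), 0L)
  }
})

test_that("protocolReport recomputes its quantities from the events", {
  p <- ciParams()
  ro <- ciReadout()
  sq <- buildProtocol(p, lim, readout = ro)
  rep <- protocolReport(sq, p)
  expect_equal(rep$echoSpacing, ro$echoSpacing, tolerance = 1e-9)
  expect_equal(rep$readoutBandwidth, 1 / ro$dwell, tolerance = 1e-9)
  expect_equal(rep$totalDuration, sequenceDuration(sq))
  expect_equal(rep$volumeDuration, p@tr)
  expect_equal(rep$pnsPercent, ro$pns@peak, tolerance = 0.02 * ro$pns@peak)
  expect_gt(rep$te, 0)
  expect_gt(rep$relativeRfEnergy, 0)
})
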