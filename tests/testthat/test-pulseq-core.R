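lim <- systemLimits(maxGrad = mTmToHz(50), maxSlew = slewToHz(200))

smallSequence <- function() {
  sq <- pulseSequence(lim, definitions = list(Name = "unit",
                                              FOV = c(0.2, 0.2, 0.1)))
  rf <- rfEvent(complex(modulus = seq(0, 120, length.out = 64),
                        argument = seq(-1, 1, length.out = 64)),
                freqOffset = -440, phaseOffset = 0.3, limits = lim)
  sq <- addBlock(sq, rf, trapGradient("z", 4e5, 1e-4, 3e-4, limits = lim))
  sq <- addBlock(sq, trapGradient("x", -2e5, 5e-5, 1e-4, limits = lim),
                 adcEvent(64, 2e-6, delay = 2.5e-5, phaseOffset = 0.3))
  sq <- addBlock(sq, arbGradient("y", sin(seq(0, pi, length.out = 40)) * 1e5,
                                 first = 0, last = 0))
  addBlock(sq, duration = 1e-3)
}

test_that("a block holds at most one event per channel", {
  sq <- pulseSequence(lim)
  rf <- rfEvent(rep(100 + 0i, 10), limits = lim)
  expect_error(addBlock(sq, rf, rf), "multiple RF events")
  g1 <- trapGradient("x", 1e5, 1e-4, limits = lim)
  expect_error(addBlock(sq, g1, g1), "channel x")
  adc <- adcEvent(16, 1e-6, delay = 1e-4)
  expect_error(addBlock(sq, adc, adc), "multiple ADC events")
  sq2 <- addBlock(sq, rf)          # append to empty sequence
  expect_length(seqBlocks(sq2), 1L)
})

test_that("gradient continuity across block boundaries is enforced", {
  sq <- pulseSequence(lim)
  sq <- addBlock(sq, arbGradient("x", rep(1e4, 20), first = 0, last = 1e4))
  err <- tryCatch(addBlock(sq, trapGradient("x", 2e5, 1e-4, limits = lim)),
                  error = function(e) conditionMessage(e))
  expect_match(err, "discontinuity")
  expect_match(err, "1e\\+04|10000")   # previous boundary value named
  expect_match(err, "\\b0\\b")         # new boundary value named
  # continuing at the same amplitude is allowed
  sq2 <- addBlock(sq, arbGradient("x", rep(1e4, 10), first = 1e4, last = 0))
  expect_length(seqBlocks(sq2), 2L)
})

test_that("validateSequence reports limit and raster violations as data", {
  sqOk <- pulseSequence(systemLimits(maxGrad = mTmToHz(33),
                                     maxSlew = slewToHz(120)))
  sqOk <- addBlock(sqOk, trapGradient("x", mTmToHz(30), 3e-4, 2e-4,
                                      limits = seqLimits(sqOk)))
  # designed inside 33 mT/m, checked against a 50 mT/m profile: clean
  expect_identical(nrow(validateSequence(sqOk, lim)), 0L)

  # slew at 1.2x the limit
  bad <- new("TrapGradient", channel = "x", amplitude = 1.2e-4 * lim@maxSlew,
             riseTime = 1e-4, flatTime = 0, fallTime = 1e-4, delay = 0)
  sq <- pulseSequence(lim)
  sq@blocks <- list(sequenceBlock(bad, limits = lim))
  v <- validateSequence(sq)
  expect_true(any(v$rule == "slew" & v$block == 1))

  # ADC dwell at 1.5x the ADC raster time
  sq2 <- pulseSequence(lim)
  sq2 <- addBlock(sq2, rfEvent(rep(10 + 0i, 10), limits = lim))
  sq2 <- addBlock(sq2, adcEvent(8, 1.5 * lim@adcRasterTime, delay = 1e-4))
  v2 <- validateSequence(sq2)
  expect_true(any(v2$rule == "adc_dwell_raster"))
  expect_equal(v2$measured[v2$rule == "adc_dwell_raster"],
               1.5 * lim@adcRasterTime)
})

test_that("seq files round-trip the event model", {
  sq <- smallSequence()
  f1 <- tempfile(fileext = ".seq"); f2 <- tempfile(fileext = ".seq")
  writeSeq(sq, f1)
  writeSeq(sq, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))  # deterministic bytes
  sq2 <- readSeq(f1)
  expect_length(seqBlocks(sq2), length(seqBlocks(sq)))
  for (i in seq_along(seqBlocks(sq))) {
    b1 <- seqBlocks(sq)[[i]]; b2 <- seqBlocks(sq2)[[i]]
    expect_equal(b2@duration, b1@duration, tolerance = 1e-9)
    if (!is.null(b1@rf)) {
      expect_equal(max(Mod(b2@rf@signal - b1@rf@signal)), 0,
                   tolerance = 1e-6 * max(Mod(b1@rf@signal)))
      expect_equal(b2@rf@freqOffset, b1@rf@freqOffset, tolerance = 1e-6)
      expect_equal(b2@rf@phaseOffset, b1@rf@phaseOffset, tolerance = 1e-6)
    } else expect_null(b2@rf)
    for (ch in c("gx", "gy", "gz")) {
      g1 <- slot(b1, ch); g2 <- slot(b2, ch)
      if (is.null(g1)) { expect_null(g2); next }
      expect_identical(class(g2), class(g1))
      if (is(g1, "TrapGradient")) {
        expect_equal(g2@amplitude, g1@amplitude, tolerance = 1e-6)
        expect_equal(g2@riseTime, g1@riseTime, tolerance = 1e-9)
      } else {
        expect_equal(max(abs(g2@waveform - g1@waveform)), 0,
                     tolerance = 1e-6 * max(abs(g1@waveform)))
      }
    }
    if (!is.null(b1@adc)) {
      expect_equal(b2@adc@numSamples, b1@adc@numSamples)
      expect_equal(b2@adc@dwell, b1@adc@dwell, tolerance = 1e-9)
      expect_equal(b2@adc@phaseOffset, b1@adc@phaseOffset, tolerance = 1e-6)
    }
  }
  expect_equal(seqDefinitions(sq2)$FOV, c(0.2, 0.2, 0.1))
})

test_that("malformed seq files raise parse errors with line numbers", {
  sq <- smallSequence()
  f <- tempfile(fileext = ".seq")
  writeSeq(sq, f)
  lines <- readLines(f)

  # undefined shape reference
  bad <- sub("^1 (\\S+) (\\d+)", "1 \\1 99", lines[grep("^\\[RF\\]", lines) + 1])
  l2 <- lines; l2[grep("^\\[RF\\]", lines) + 1] <- bad
  fb <- tempfile(fileext = ".seq"); writeLines(l2, fb)
  expect_error(readSeq(fb), "undefined shape ID")

  # version mismatch
  l3 <- lines; l3[grep("^minor", l3)[1]] <- "minor 9"
  fb3 <- tempfile(fileext = ".seq"); writeLines(l3, fb3)
  expect_error(readSeq(fb3), "version mismatch")

  # malformed section header
  l4 <- lines; l4[grep("^\\[BLOCKS\\]", l4)] <- "[BLO CKS]"
  fb4 <- tempfile(fileext = ".seq"); writeLines(l4, fb4)
  expect_error(readSeq(fb4), "malformed section header")

  # unknown sections are reported and preserved, not dropped
  l5 <- c(lines, "[FOOBAR]", "1 2 3")
  fb5 <- tempfile(fileext = ".seq"); writeLines(l5, fb5)
  expect_message(sq5 <- readSeq(fb5), "FOOBAR")
  expect_true("FOOBAR" %in% names(seqDefinitions(sq5)$unknownSections))
})

test_that("computeKspace matches the brute-force integration oracle", {
  sq <- pulseSequence(lim)
  sq <- addBlock(sq, rfEvent(rep(50 + 0i, 100), limits = lim))
  sq <- addBlock(sq, trapGradient("x", 3e5, 1e-4, 2e-4, limits = lim),
                 trapGradient("y", -1e5, 2e-4, 1e-4, limits = lim))
  sq <- addBlock(sq, trapGradient("x", -1.5e5, 1e-4, 4e-4, limits = lim),
                 adcEvent(40, 7.3e-6, delay = 2.1e-5))
  k <- computeKspace(sq)
  ko <- oracleKspace(sq)
  expect_equal(k$kx, unname(ko[, "kx"]), tolerance = 1e-9)
  expect_equal(k$ky, unname(ko[, "ky"]), tolerance = 1e-9)
  expect_equal(k$kz, unname(ko[, "kz"]), tolerance = 1e-9)
})

test_that("computeKspace handles resets, zero gradients and ADC-before-RF", {
  # all-zero gradients: k stays at zero
  sq0 <- pulseSequence(lim)
  sq0 <- addBlock(sq0, rfEvent(rep(50 + 0i, 100), limits = lim))
  sq0 <- addBlock(sq0, adcEvent(16, 1e-6, delay = 1e-4))
  k0 <- computeKspace(sq0)
  expect_true(all(abs(c(k0$kx, k0$ky, k0$kz)) < 1e-12))

  # a trapezoid of area A before the ADC puts every sample at kx = A
  sq1 <- pulseSequence(lim)
  sq1 <- addBlock(sq1, rfEvent(rep(50 + 0i, 100), limits = lim))
  g <- trapGradient("x", 2.5e5, 1e-4, 3e-4, limits = lim)
  sq1 <- addBlock(sq1, g)
  sq1 <- addBlock(sq1, adcEvent(8, 1e-6, delay = 1e-4))
  k1 <- computeKspace(sq1)
  A <- g@amplitude * (g@flatTime + (g@riseTime + g@fallTime) / 2)
  expect_equal(k1$kx, rep(A, 8), tolerance = 1e-9)

  # ADC with no preceding excitation errors
  sqe <- pulseSequence(lim)
  sqe <- addBlock(sqe, adcEvent(8, 1e-6, delay = 1e-4))
  expect_error(computeKspace(sqe), "no preceding RF")
})

test_that("block durations are exact and sum to the sequence duration", {
  sq <- smallSequence()
  durs <- vapply(seqBlocks(sq), function(b) b@duration, 0)
  expect_identical(sequenceDuration(sq), sum(durs))
  expect_true(all(sapply(durs, smsepi:::onRaster,
                         raster = lim@blockDurationRaster)))
  # every accepted waveform sample is inside the limits
  v <- validateSequence(sq)
  expect_identical(nrow(v), 0L)
  gr <- lim@gradRasterTime
  for (b in seqBlocks(sq)) for (ch in c("x", "y", "z")) {
    w <- smsepi:::blockRasterWaveform(b, ch, gr)
    expect_true(all(abs(w) <= lim@maxGrad * (1 + 1e-9)))
    expect_true(all(abs(diff(w)) / gr <= lim@maxSlew * (1 + 1e-9)))
  }
})
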