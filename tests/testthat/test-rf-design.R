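lim <- systemLimits()

test_that("bloch simulator reproduces closed-form rotations and conserves |M|", {
  # zero RF leaves the magnetization untouched
  m0 <- blochSimulate(rep(0 + 0i, 50), 0, positions = c(-0.01, 0, 0.01),
                      raster = 1e-5)
  expect_equal(m0$mz, rep(1, 3))
  expect_equal(m0$mx, rep(0, 3))

  # on-resonance constant pulse of flip alpha: Mz = cos(alpha)
  for (deg in c(15, 45, 90, 130)) {
    amp <- (deg / 360) / 1e-3           # flip = 2 pi * amp * tau
    m <- blochSimulate(rep(amp + 0i, 200), 0, positions = 0, raster = 5e-6)
    expect_equal(m$mz, cos(deg * pi / 180), tolerance = 1e-6)
  }

  # |M| conserved through an off-resonance multi-position simulation
  des <- designSlrPulse(slrSpec(2e-3, 4, pi / 3), 3e-3, lim)
  m <- blochSimulate(des$pulse, des$grad@amplitude,
                     positions = seq(-5e-3, 5e-3, length.out = 101),
                     offResonance = 30)
  expect_lt(max(abs(sqrt(m$mx^2 + m$my^2 + m$mz^2) - 1)), 1e-9)

  expect_error(blochSimulate(rep(0i, 10), grad = numeric(5), raster = 1e-6),
               "mismatched lengths")
})

test_that("small-tip profile follows the Fourier transform of the envelope", {
  des <- designSlrPulse(slrSpec(3.2e-3, 4, 5 * pi / 180), 2.4e-3, lim)
  z <- seq(-6e-3, 6e-3, length.out = 201)
  m <- blochSimulate(des$pulse, des$grad@amplitude, positions = z)
  mxy <- abs(complex(real = m$mx, imaginary = m$my))
  # FT oracle: discrete transform of the envelope at the profile frequencies
  s <- des$pulse@samples
  tt <- (seq_along(s) - 0.5) * des$pulse@raster
  ft <- vapply(z, function(zz)
    abs(sum(s * exp(-2i * pi * des$grad@amplitude * zz * tt))), 0)
  expect_gt(stats::cor(mxy, ft), 0.99)
})

test_that("SLR excitation profile hits the requested slice width", {
  des <- designSlrPulse(slrSpec(3.2e-3, 4, pi / 2), 2.4e-3, lim)
  z <- seq(-6e-3, 6e-3, length.out = 401)
  m <- blochSimulate(des$pulse, des$grad@amplitude, positions = z)
  mxy <- complex(real = m$mx, imaginary = m$my)
  fw <- smsepi:::profileFwhm(z, mxy)
  expect_lt(abs(fw - 2.4e-3) / 2.4e-3, 0.05)
  # out-of-band excitation stays below a few ripple levels
  expect_lt(max(Mod(mxy)[abs(z) > 2.4e-3]), 0.05)
  # zero flip gives an all-zero waveform
  z0 <- designSlrPulse(slrSpec(3.2e-3, 4, 0), 2.4e-3, lim)
  expect_true(all(Mod(z0$pulse@samples) == 0))
  # infeasible gradient names the fix
  expect_error(designSlrPulse(slrSpec(0.2e-3, 8, pi / 2), 0.5e-3, lim),
               "longer|duration")
})

test_that("minimum-phase SLR matches the linear-phase magnitude profile with shorter isodelay", {
  z <- seq(-6e-3, 6e-3, length.out = 301)
  lin <- designSlrPulse(slrSpec(3.2e-3, 4, pi / 2), 2.4e-3, lim)
  mnp <- designSlrPulse(slrSpec(3.2e-3, 4, pi / 2,
                                filterType = "minimum_phase"), 2.4e-3, lim)
  pl <- blochSimulate(lin$pulse, lin$grad@amplitude, positions = z)
  pm <- blochSimulate(mnp$pulse, mnp$grad@amplitude, positions = z)
  al <- abs(complex(real = pl$mx, imaginary = pl$my))
  am <- abs(complex(real = pm$mx, imaginary = pm$my))
  expect_lt(mean(abs(al - am)), 0.05)        # same magnitude profile
  expect_lt(mnp$pulse@isodelay, lin$pulse@isodelay)
})

test_that("simulated on-resonance Mz decreases monotonically with flip", {
  flips <- c(10, 25, 40, 55, 70, 90) * pi / 180
  mz <- vapply(flips, function(fl) {
    des <- designSlrPulse(slrSpec(3.2e-3, 4, fl), 2.4e-3, lim)
    blochSimulate(des$pulse, des$grad@amplitude, positions = 0)$mz
  }, 0)
  expect_true(all(diff(mz) < 0))
})

test_that("fat saturation nulls fat and spares water", {
  fs <- makeFatsatPulse(fieldStrength = 3, limits = lim)
  off <- attr(fs, "freqOffset")
  # -3.45 ppm at 3 T: offset = ppm * gamma * B0 / 1e6
  expect_equal(off, -3.45 * 42.576e6 * 3 / 1e6, tolerance = 1e-6)
  mfat <- blochSimulate(fs, 0, positions = 0, offResonance = 0)
  mwat <- blochSimulate(fs, 0, positions = 0, offResonance = -off)
  expect_lt(abs(mfat$mz), 0.1)   # >= 90% saturation at the fat line
  expect_gt(mwat$mz, 0.95)       # water essentially untouched
  expect_error(makeFatsatPulse(fieldStrength = 0), "positive")
  expect_error(makeFatsatPulse(bwFraction = 2.5), "overlaps the water")
})

test_that("multiband synthesis places bands and reduces peak amplitude", {
  des <- designSlrPulse(slrSpec(3.2e-3, 4, pi / 2), 2.4e-3, lim)
  g <- des$grad@amplitude
  sms <- smsSpec(6, 24e-3, 2.4e-3)
  mb <- synthesizeSmsPulse(des$pulse, sms, g)
  mb0 <- synthesizeSmsPulse(des$pulse,
                            smsSpec(6, 24e-3, 2.4e-3,
                                    phaseOffsets = rep(0, 6)), g)
  expect_lt(max(Mod(mb@samples)), max(Mod(mb0@samples)))

  # single band: identity
  one <- synthesizeSmsPulse(des$pulse, smsSpec(1, 24e-3, 2.4e-3), g)
  expect_identical(one@samples, des$pulse@samples)

  # Bloch profile: six bands at the requested positions, right width
  z <- seq(-80e-3, 80e-3, length.out = 1601)
  m <- blochSimulate(mb, g, positions = z)
  mxy <- complex(real = m$mx, imaginary = m$my)
  expect_identical(smsepi:::countBands(z, mxy), 6L)
  mag <- Mod(mxy)
  r <- rle(mag >= max(mag) / 2)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)[r$values]; ends <- ends[r$values]
  centers <- vapply(seq_along(starts), function(k)
    mean(z[starts[k]:ends[k]]), 0)
  expect_equal(centers, (seq_len(6) - 3.5) * 24e-3, tolerance = 1.5e-3)
  for (k in seq_along(starts)) {
    seg <- max(1, starts[k] - 8):min(length(z), ends[k] + 8)
    expect_lt(abs(smsepi:::profileFwhm(z[seg], mxy[seg]) - 2.4e-3) / 2.4e-3,
              0.06)
  }

  # peak limit check names the remedy
  tight <- systemLimits(maxRf = 300)
  expect_error(synthesizeSmsPulse(des$pulse, sms, g, tight),
               "stretch the pulse duration")
})

test_that("multiband profile superposes single-band profiles at small tip", {
  des <- designSlrPulse(slrSpec(3.2e-3, 4, 5 * pi / 180), 2.4e-3, lim)
  g <- des$grad@amplitude
  mb <- synthesizeSmsPulse(des$pulse, smsSpec(3, 15e-3, 2.4e-3), g)
  z <- seq(-30e-3, 30e-3, length.out = 601)
  m <- blochSimulate(mb, g, positions = z)
  prof <- abs(complex(real = m$mx, imaginary = m$my))
  single <- blochSimulate(des$pulse, g, positions = z)
  sb <- abs(complex(real = single$mx, imaginary = single$my))
  super <- rep(0, length(z))
  for (zc in c(-15e-3, 0, 15e-3)) {
    sh <- blochSimulate(des$pulse, g, positions = z - zc)
    super <- super + abs(complex(real = sh$mx, imaginary = sh$my))
  }
  expect_gt(stats::cor(prof, super), 0.99)
})

test_that("RF spoiling follows the 117-degree quadratic schedule", {
  expect_identical(rfSpoilingPhase(0), 0)
  expect_equal(rfSpoilingPhase(2) * 180 / pi, 351)  # 117 * 3 mod 360
  ph <- rfSpoilingPhase(0:63) * 180 / pi
  d2 <- diff(diff(ph)) %% 360
  expect_true(all(abs(d2 - 117) < 1e-9))
  expect_error(rfSpoilingPhase(-1), "nonnegative")
})
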