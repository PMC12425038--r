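# Shared fixtures, memoized so expensive objects (readout designs,
# simulations, the full-size protocol) are built once per test run.

.fix <- new.env(parent = emptyenv())

memoFix <- function(name, fn) {
  if (is.null(.fix[[name]])) .fix[[name]] <- fn()
  .fix[[name]]
}

ciLimits <- function() systemLimits()

# reduced test geometry: 32 x 32, 12 slices, SMS 3, full ky, FOV/4 CAIPI
ciParams <- function(nVolumes = 2, nDummies = 0, partialFourier = 1,
                     caipiShift = 4) {
  protocolParams(fov = c(0.192, 0.192, 0.072), matrixSize = c(32, 32),
                 nSlices = 12, sliceThickness = 0.006, smsFactor = 3,
                 tr = 0.24, partialFourier = partialFourier,
                 flipAngle = 52 * pi / 180, nVolumes = nVolumes,
                 caipiShift = caipiShift, nDummies = nDummies)
}

ciReadout <- function() memoFix("ciReadout", function()
  designEpiReadout(ciParams(), ciLimits()))

ciPhantom <- function() memoFix("ciPhantom", function()
  makeBallPhantom(ciParams(), radius = 0.03))

ciMaps <- function() memoFix("ciMaps", function()
  makeCoilMaps(ciParams(), ncoils = 6, seed = 3))

ciSim <- function() memoFix("ciSim", function()
  simulateAcquisition(ciPhantom(), ciMaps(), ciParams(), ciReadout()))

ciMask <- function() ciPhantom()@data > 0.5 * max(ciPhantom()@data)

# degenerate geometry: single band, full Fourier, flat-top-only sampling
sb1Params <- function() {
  protocolParams(fov = c(0.216, 0.216, 0.072), matrixSize = c(32, 32),
                 nSlices = 4, sliceThickness = 0.018, smsFactor = 1,
                 tr = 0.4, partialFourier = 1, nVolumes = 1, nDummies = 0,
                 caipiShift = 1)
}

sb1Sim <- function() memoFix("sb1Sim", function() {
  p <- sb1Params()
  ro <- designEpiReadout(p, ciLimits(), rampSampling = FALSE)
  phan <- makeBallPhantom(p, radius = 0.03)
  maps <- makeCoilMaps(p, ncoils = 1, seed = 2)
  list(p = p, ro = ro, phantom = phan, maps = maps,
       sim = simulateAcquisition(phan, maps, p, ro))
})

# full ABCD-matched protocol objects (used by the acceptance suite)
abcdParams <- function(nVolumes = 5) protocolParams(nVolumes = nVolumes)

abcdReadout <- function() memoFix("abcdReadout", function()
  designEpiReadout(abcdParams(), systemLimits()))

abcdSequence <- function() memoFix("abcdSequence", function()
  buildProtocol(abcdParams(1), systemLimits(), readout = abcdReadout()))

inMaskNrmse <- function(vol, truth, mask) {
  sqrt(sum((vol[mask] - truth[mask])^2) / sum(truth[mask]^2))
}

# independent trapezoidal k-space integrator used as the trajectory oracle
oracleKspace <- function(seq) {
  gr <- seqLimits(seq)@gradRasterTime
  k <- c(0, 0, 0)
  t0 <- 0
  seenRf <- FALSE
  rows <- list()
  for (i in seq_along(seqBlocks(seq))) {
    b <- seqBlocks(seq)[[i]]
    n <- round(b@duration / gr)
    wf <- lapply(c("x", "y", "z"), function(ch)
      smsepi:::blockRasterWaveform(b, ch, gr))
    if (!is.null(b@rf)) seenRf <- TRUE
    if (!is.null(b@adc)) {
      stopifnot(seenRf)
      a <- b@adc
      for (m in seq_len(a@numSamples)) {
        ts <- a@delay + (m - 0.5) * a@dwell
        kk <- vapply(wf, function(w) {
          tt <- seq(0, n * gr, by = gr)
          idx <- tt <= ts
          extra <- 0
          j <- sum(idx)
          # trapezoid rule up to the last full raster edge, then partial
          base <- if (j >= 2)
            sum((w[1:(j - 1)] + w[2:j]) / 2 * gr) else 0
          if (j <= n)  # partial raster interval at trapezoid resolution
            extra <- (ts - tt[j]) * (w[j] + w[min(j + 1, n + 1)]) / 2
          base + extra
        }, 0)
        rows[[length(rows) + 1L]] <-
          c(block = i, sample = m, t = t0 + ts, kx = k[1] + kk[1],
            ky = k[2] + kk[2], kz = k[3] + kk[3])
      }
    }
    full <- vapply(wf, function(w) sum((w[-length(w)] + w[-1]) / 2 * gr), 0)
    k <- k + full
    if (!is.null(b@rf)) {
      tPk <- b@rf@delay +
        if (length(b@rf@signal) && max(Mod(b@rf@signal)) > 0)
          b@rf@t[which.max(Mod(b@rf@signal))]
        else smsepi:::rfEnd(b@rf) - b@rf@delay
      k <- vapply(seq_len(3), function(j) {
        w <- wf[[j]]
        tt <- seq(0, n * gr, by = gr)
        j0 <- min(max(sum(tt <= tPk), 1L), n)
        partial <- (tt[j0 + 1] - tPk) * (w[j0] + w[j0 + 1]) / 2
        if (j0 >= n) partial else
          partial + sum((w[(j0 + 1):n] + w[(j0 + 2):(n + 1)]) / 2 * gr)
      }, 0)
    }
    t0 <- t0 + b@duration
  }
  do.call(rbind, rows)
}
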