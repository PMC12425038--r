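# Assembly of the ABCD-matched SMS-EPI protocol: per shot, a fat-saturation
# block (minimum-phase SLR pulse + spoiler in one block), a multiband SLR
# excitation with its slice gradient, slice rephase + readout/phase-encode
# prewinders, phase-correction navigator echoes, a CAIPI-blipped
# ramp-sampled EPI train, an end-of-shot crusher and a TR-fill delay.  A
# single-band 2D reference segment (one excitation per slice, no CAIPI
# blips) precedes the SMS segment and supplies ghost-correction and
# unaliasing calibration data.
#
# The EPI readout slew rate is derated iteratively until the predicted PNS
# (impulse-response model, evaluated on the exact gradient waveforms of one
# shot) stays below the protocol's derate fraction of the stimulation
# limit.

# exact-area trapezoid on a given axis: triangle when possible, else
# amplitude-limited trapezoid; the requested area is met exactly
trapForArea <- function(channel, area, slew, limits) {
  gr <- limits@gradRasterTime
  a <- abs(area)
  if (a < 1e-12) return(NULL)
  gp <- sqrt(a * slew)
  if (gp <= limits@maxGrad) {
    rise <- max(ceilToRaster(gp / slew, gr), gr)
    flat <- 0
  } else {
    rise <- max(ceilToRaster(limits@maxGrad / slew, gr), gr)
    flat <- ceilToRaster(a / limits@maxGrad - rise, gr)
  }
  amp <- a / (rise + flat)  # trap area = amp * (flat + rise) for rise == fall
  new("TrapGradient", channel = channel, amplitude = sign(area) * amp,
      riseTime = rise, flatTime = flat, fallTime = rise, delay = 0)
}

trapDur <- function(tr) if (is.null(tr)) 0 else
  tr@riseTime + tr@flatTime + tr@fallTime

# slew used for non-readout "service" gradients (spoilers, crushers,
# rephasers, prewinders): kept moderate so their isolated PNS transients
# stay well below the limit
serviceSlew <- function(slew) min(slew, slewToHz(45))

# local kx(t) inside an EPI echo trapezoid/triangle starting from zero
# amplitude (vectorized in t)
kxLocal <- function(t, rise, flat, amp) {
  s <- amp / rise
  ifelse(t <= rise, s * t^2 / 2,
    ifelse(t <= rise + flat, amp * rise / 2 + amp * (t - rise),
      amp * rise / 2 + amp * flat +
        amp * (t - rise - flat) - s * (t - rise - flat)^2 / 2))
}

# geometry-only readout pieces for a candidate slew rate; NULL if infeasible
readoutPieces <- function(p, limits, slew, rampSampling, oversampling) {
  nx <- p@matrixSize[1]; ny <- p@matrixSize[2]
  ne <- ceiling(p@partialFourier * ny)
  gr <- limits@gradRasterTime
  A <- nx / p@fov[1]
  dky <- 1 / p@fov[2]
  nShots <- p@nSlices / p@smsFactor
  cs <- p@caipiShift
  dkz <- if (p@smsFactor > 1) 1 / (cs * nShots * p@sliceThickness) else 0
  if (rampSampling) {
    dt <- max(ceilToRaster(sqrt(A / slew), gr), 2 * gr)
    amp <- A / dt
    if (amp > limits@maxGrad) return(NULL)
    rise <- dt; flat <- 0
    nsamp <- 2 * ceiling(oversampling * nx / 2)
    win <- 2 * dt - 2 * limits@adcDeadTime
    dwell <- floor(win / nsamp / limits@adcRasterTime) * limits@adcRasterTime
    if (dwell <= 0) return(NULL)
  } else {
    nsamp <- nx
    dwell <- max(ceilToRaster(1 / (p@fov[1] * limits@maxGrad * 0.9),
                              limits@adcRasterTime), 1e-6)
    amp <- 1 / (p@fov[1] * dwell)
    rise <- max(ceilToRaster(amp / slew, gr), gr)
    flat <- ceilToRaster(nsamp * dwell + 2 * limits@adcDeadTime, gr)
  }
  echoDur <- 2 * rise + flat
  adcDelay <- (echoDur - nsamp * dwell) / 2
  # blips fill their block as shallow triangles; the block length is set by
  # the largest blip (the CAIPI rewind) at a moderate blip slew
  bslew <- min(slew, slewToHz(80))
  tb <- max(ceilToRaster(sqrt(dky / bslew), gr), gr)
  if (dkz > 0)
    tb <- max(tb, ceilToRaster(sqrt((cs - 1) * dkz / bslew), gr))
  blipDur <- 2 * tb
  tS <- adcDelay + (seq_len(nsamp) - 0.5) * dwell
  kxl <- kxLocal(tS, rise, flat, amp)
  areaEcho <- amp * (rise + flat)
  prewArea <- -nx / (2 * p@fov[1]) - kxl[1]
  list(nEchoes = as.integer(ne), nNavigators = p@nNavigators,
       echoRise = rise, echoFlat = flat, echoAmp = amp, echoDur = echoDur,
       blipDur = blipDur, echoSpacing = echoDur + blipDur,
       dky = dky, dkz = dkz,
       kyIndex = (ny - ne):(ny - 1),          # late lines kept
       kzEcho = dkz * ((seq_len(ne) - 1) %% cs),
       nSamples = nsamp, dwell = dwell, adcDelay = adcDelay,
       kxSample = cbind(even = prewArea + kxl,
                        odd = prewArea + areaEcho - kxl),
       prewArea = prewArea,
       yPrewArea = -(ny / 2 - (ny - ne)) * dky,
       deratedSlew = slew, rampSampling = rampSampling)
}

# per-shot pulse assets (independent of the readout slew)
protocolPulses <- function(p, limits, excDuration, excTimeBandwidth,
                           fieldStrength = 3, fatsat = TRUE) {
  exc <- designSlrPulse(
    slrSpec(excDuration, excTimeBandwidth, p@flipAngle),
    p@sliceThickness, limits)
  nShots <- p@nSlices / p@smsFactor
  mb <- if (p@smsFactor > 1)
    synthesizeSmsPulse(exc$pulse,
                       smsSpec(p@smsFactor, nShots * p@sliceThickness,
                               p@sliceThickness),
                       exc$grad@amplitude, limits)
  else exc$pulse
  fs <- if (fatsat) makeFatsatPulse(fieldStrength = fieldStrength,
                                    limits = limits) else NULL
  list(exc = exc, mb = mb, fatsat = fs, excDuration = excDuration,
       excTimeBandwidth = excTimeBandwidth)
}

# build the block list of one shot; with gradientsOnly = TRUE the RF and ADC
# events are omitted but every duration is identical (used for PNS derating)
shotBlockList <- function(p, limits, ro, pulses, excShape = NULL, freq = 0,
                          phase = 0, caipi = TRUE, gradientsOnly = FALSE,
                          fill = TRUE, recvZ = 0) {
  gr <- limits@gradRasterTime
  slew <- ro$deratedSlew
  shotDur <- p@tr / (p@nSlices / p@smsFactor)
  g <- pulses$exc$grad@amplitude
  out <- list()
  addB <- function(b) out[[length(out) + 1L]] <<- b

  sslew <- serviceSlew(slew)
  if (!is.null(pulses$fatsat)) {
    fsLen <- length(pulses$fatsat@samples) * pulses$fatsat@raster
    sp <- trapForArea("z", 2 / p@sliceThickness, sslew, limits)
    sp@delay <- ceilToRaster(limits@rfDeadTime + fsLen +
                               limits@rfRingdownTime, gr)
    if (gradientsOnly) addB(sequenceBlock(sp, limits = limits))
    else addB(sequenceBlock(
      rfEvent(pulses$fatsat@samples, delay = limits@rfDeadTime,
              freqOffset = attr(pulses$fatsat, "freqOffset"),
              phaseOffset = phase, limits = limits),
      sp, limits = limits))
  }
  # excitation: slice-select trapezoid with the RF on its flat top
  excG <- local({
    rise <- max(ceilToRaster(g / slew, gr), gr)
    pad <- ceilToRaster(max(0, limits@rfDeadTime - rise), gr)
    new("TrapGradient", channel = "z", amplitude = g, riseTime = rise,
        flatTime = pad + ceilToRaster(pulses$excDuration, gr),
        fallTime = rise, delay = 0)
  })
  rfDelay <- excG@riseTime + ceilToRaster(
    max(0, limits@rfDeadTime - excG@riseTime), gr)
  if (gradientsOnly) addB(sequenceBlock(excG, limits = limits))
  else addB(sequenceBlock(
    rfEvent(excShape@samples, delay = rfDelay, freqOffset = freq,
            phaseOffset = phase, limits = limits),
    excG, limits = limits))
  rephArea <- -(g * (pulses$exc$pulse@isodelay + excG@fallTime / 2))
  addB(sequenceBlock(trapForArea("z", rephArea, sslew, limits),
                     trapForArea("x", ro$prewArea, sslew, limits),
                     limits = limits))
  echoBlock <- function(sgn, kzNow = 0) {
    gx <- new("TrapGradient", channel = "x", amplitude = sgn * ro$echoAmp,
              riseTime = ro$echoRise, flatTime = ro$echoFlat,
              fallTime = ro$echoRise, delay = 0)
    if (gradientsOnly) return(sequenceBlock(gx, limits = limits))
    # receiver phase tracks the CAIPI blip phase at the group's first band,
    # so the residual inter-band phase is an exact FOV/caipiShift shift
    sequenceBlock(gx, adcEvent(ro$nSamples, ro$dwell, delay = ro$adcDelay,
                               phaseOffset = phase - 2 * pi * kzNow * recvZ),
                  limits = limits)
  }
  blipBlock <- function(yArea, zArea) {
    mk <- function(ch, area) {  # shallow triangle filling the blip block
      if (abs(area) < 1e-12) return(NULL)
      rise <- ro$blipDur / 2
      new("TrapGradient", channel = ch, amplitude = area / rise,
          riseTime = rise, flatTime = 0, fallTime = rise, delay = 0)
    }
    evs <- Filter(Negate(is.null), list(mk("y", yArea), mk("z", zArea)))
    do.call(sequenceBlock,
            c(evs, list(duration = ro$blipDur, limits = limits)))
  }
  sgn <- 1
  for (v in seq_len(ro$nNavigators)) { addB(echoBlock(sgn)); sgn <- -sgn }
  yp <- trapForArea("y", ro$yPrewArea, sslew, limits)
  if (!is.null(yp)) addB(sequenceBlock(yp, limits = limits))
  kz <- if (caipi) ro$kzEcho else numeric(ro$nEchoes)
  for (e in seq_len(ro$nEchoes)) {
    addB(echoBlock(sgn, kz[e])); sgn <- -sgn
    if (e < ro$nEchoes) addB(blipBlock(ro$dky, kz[e + 1] - kz[e]))
  }
  addB(sequenceBlock(trapForArea("z", 2 / p@sliceThickness, sslew, limits),
                     limits = limits))
  used <- sum(vapply(out, function(b) b@duration, 0))
  if (fill) {
    rem <- shotDur - used
    if (rem < -1e-9)
      stopf("shot needs %.2f ms but tr/nShots allows only %.2f ms",
            used * 1e3, shotDur * 1e3)
    if (rem > 1e-9)
      addB(sequenceBlock(duration = roundToRaster(rem,
             limits@blockDurationRaster), limits = limits))
  }
  out
}

#' Design the CAIPI-blipped (ramp-sampled) EPI readout
#'
#' Sizes the readout trapezoid so each echo spans the full kx extent (total
#' gradient area nx / fov_x, exactly), the phase-encode blips step ky by
#' 1 / fov_y per echo, and the slice-axis CAIPI blips cycle kz over
#' \code{caipiShift} values spaced 1 / (caipiShift * bandSeparation).  The
#' readout slew is reduced iteratively until the impulse-response PNS over
#' one shot's exact gradient waveforms (periodic wrap) stays below
#' \code{pnsDerate * 100} percent of the stimulation limit.
#'
#' @param p a \linkS4class{ProtocolParams}.
#' @param limits a \linkS4class{SystemLimits}.
#' @param pns \code{\link{pnsParams}} used for derating.
#' @param rampSampling if FALSE, sample only on the flat top at Cartesian
#'   kx positions (used by degenerate-geometry tests).
#' @param oversampling ADC samples per echo as a multiple of nx (ramp
#'   sampling only).
#' @param excDuration,excTimeBandwidth excitation pulse parameters (package
#'   defaults: 3.2 ms, TBW 4; the printed protocol does not pin them).
#' @param fieldStrength main field, T.
#' @param fatsat include fat saturation in the shot timing.
#' @return an object of class \code{EPIReadout}: a list holding the echo
#'   trapezoid, blip sizes, ADC timing, exact per-sample kx (even and odd
#'   polarity), ky line indices, kz per echo, echo spacing, prewinder
#'   areas, the derated slew rate and the achieved \linkS4class{PNSResult}.
#' @export
designEpiReadout <- function(p, limits = systemLimits(), pns = pnsParams(),
                             rampSampling = TRUE, oversampling = 1.4,
                             excDuration = 3.2e-3, excTimeBandwidth = 4,
                             fieldStrength = 3, fatsat = TRUE) {
  pulses <- protocolPulses(p, limits, excDuration, excTimeBandwidth,
                           fieldStrength, fatsat)
  gr <- limits@gradRasterTime
  shotDur <- p@tr / (p@nSlices / p@smsFactor)
  lastFit <- NULL
  for (alpha in seq(1, 0.1, by = -0.0125)) {
    ro <- readoutPieces(p, limits, alpha * limits@maxSlew, rampSampling,
                        oversampling)
    if (is.null(ro)) next
    blocks <- tryCatch(
      shotBlockList(p, limits, ro, pulses, gradientsOnly = TRUE),
      error = function(e) NULL)
    if (is.null(blocks)) {  # no longer fits the shot TR: derating failed
      if (!is.null(lastFit)) break
      stopf("infeasible echo spacing: shot exceeds tr/nShots at slew derate %.2f",
            alpha)
    }
    tmp <- new("PulseSequence", blocks = blocks, limits = limits,
               definitions = list())
    grads <- sequenceGradients(tmp)
    res <- pnsImpulseResponse(grads, pns, gr)
    lastFit <- alpha
    if (res@peak <= 100 * p@pnsDerate) {
      ro$pns <- res
      ro$pnsParams <- pns
      ro$pulses <- pulses
      ro$excDuration <- excDuration
      ro$excTimeBandwidth <- excTimeBandwidth
      class(ro) <- "EPIReadout"
      return(ro)
    }
  }
  stopf("infeasible echo spacing: PNS bound unreachable at minimum slew")
}

#' Build the fat-saturation block
#'
#' A minimum-phase spectrally selective SLR pulse at the fat resonance
#' followed, in the same block, by a slice-axis spoiler providing at least
#' 4 pi of dephasing across one slice thickness.
#'
#' @param p a \linkS4class{ProtocolParams}.
#' @param limits a \linkS4class{SystemLimits}.
#' @param slew spoiler slew rate, Hz/m/s.
#' @param fieldStrength main field, T.
#' @param phase RF phase offset, rad (the shot's spoiling phase).
#' @return a \linkS4class{SequenceBlock}.
#' @export
buildFatsatBlock <- function(p, limits = systemLimits(),
                             slew = 0.4 * limits@maxSlew, fieldStrength = 3,
                             phase = 0) {
  fs <- makeFatsatPulse(fieldStrength = fieldStrength, limits = limits)
  rf <- rfEvent(fs@samples, delay = limits@rfDeadTime,
                freqOffset = attr(fs, "freqOffset"), phaseOffset = phase,
                limits = limits)
  sp <- trapForArea("z", 2 / p@sliceThickness, slew, limits)
  sp@delay <- ceilToRaster(rfEnd(rf) + limits@rfRingdownTime,
                           limits@gradRasterTime)
  sequenceBlock(rf, sp, limits = limits)
}

# slice z position (m) of 0-based slice index j
sliceZ <- function(p, j) (j - (p@nSlices - 1) / 2) * p@sliceThickness

# interleaved acquisition order of 0-based indices: evens first, then odds
interleavedOrder <- function(n) {
  if (n == 1L) return(0L)
  c(seq(0L, n - 1L, by = 2L), seq(1L, n - 1L, by = 2L))
}

#' Build the full SMS-EPI protocol sequence
#'
#' Emits the single-band reference segment (one 2D EPI shot per slice,
#' interleaved order, no CAIPI blips) followed by
#' \code{nDummies + nVolumes} SMS volumes of \code{nSlices / smsFactor}
#' shots each.  Every shot carries the quadratic RF-spoiling phase on its
#' fat-saturation pulse, excitation and receiver; a delay block pads every
#' shot to exactly \code{tr / nShots}, so each volume lasts exactly one TR.
#'
#' @param p a \linkS4class{ProtocolParams}.
#' @param limits a \linkS4class{SystemLimits}.
#' @param readout optionally a precomputed \code{\link{designEpiReadout}};
#'   built with defaults otherwise.
#' @param fieldStrength main field, T (sets the fat-sat frequency offset).
#' @param fatsat include the fat-saturation block (default TRUE).
#' @return a \linkS4class{PulseSequence} whose definitions echo the
#'   protocol geometry; the readout design is attached as
#'   \code{attr(, "readout")}.
#' @export
buildProtocol <- function(p, limits = systemLimits(), readout = NULL,
                          fieldStrength = 3, fatsat = TRUE) {
  validObject(p)
  if (is.null(readout))
    readout <- designEpiReadout(p, limits, fieldStrength = fieldStrength,
                                fatsat = fatsat)
  pulses <- readout$pulses
  nShots <- p@nSlices / p@smsFactor
  if (!onRaster(p@tr / nShots, limits@blockDurationRaster))
    stopf("tr / nShots = %.6g s is not on the block-duration raster",
          p@tr / nShots)
  g <- pulses$exc$grad@amplitude

  blocks <- vector("list", 200L * (p@nSlices +
    nShots * (p@nDummies + p@nVolumes)))
  nb <- 0L
  push <- function(bl) for (b in bl) { nb <<- nb + 1L; blocks[[nb]] <<- b }
  shotCounter <- 0L
  for (j in interleavedOrder(p@nSlices)) {     # reference segment
    ph <- rfSpoilingPhase(shotCounter); shotCounter <- shotCounter + 1L
    push(shotBlockList(p, limits, readout, pulses,
                       excShape = pulses$exc$pulse, freq = g * sliceZ(p, j),
                       phase = ph, caipi = FALSE))
  }
  nRefBlocks <- nb
  shotOrder <- interleavedOrder(nShots)
  for (vol in seq_len(p@nDummies + p@nVolumes)) {
    for (s in shotOrder) {
      ph <- rfSpoilingPhase(shotCounter); shotCounter <- shotCounter + 1L
      zoff <- (s - (nShots - 1) / 2) * p@sliceThickness
      push(shotBlockList(p, limits, readout, pulses,
                         excShape = pulses$mb, freq = g * zoff, phase = ph,
                         caipi = TRUE, recvZ = sliceZ(p, s)))
    }
  }
  defs <- list(
    Name = "smsepi_abcd", FOV = p@fov, TR = p@tr,
    Nx = p@matrixSize[1], Ny = p@matrixSize[2], NSlices = p@nSlices,
    SMSFactor = p@smsFactor, PartialFourier = p@partialFourier,
    NVolumes = p@nVolumes, NDummies = p@nDummies,
    NNavigators = readout$nNavigators, NEchoes = readout$nEchoes,
    CaipiShift = p@caipiShift, SliceThickness = p@sliceThickness,
    FlipAngle = p@flipAngle, ReferenceBlocks = nRefBlocks,
    EchoSpacing = readout$echoSpacing, DeratedSlew = readout$deratedSlew)
  out <- new("PulseSequence", blocks = blocks[seq_len(nb)], limits = limits,
             definitions = defs)
  attr(out, "readout") <- readout
  out
}

#' Summarize a built protocol from its event data
#'
#' All quantities are recomputed from the assembled blocks, not taken from
#' the protocol parameters: echo spacing from consecutive ADC start times,
#' TE from the excitation peak to the ky = 0 echo center, readout bandwidth
#' from the ADC dwell, PNS by running the impulse-response model over one
#' shot's gradient waveforms, and RF energy integrated over the whole
#' sequence.  The flip angle is echoed as a nominal package default (the
#' printed protocol does not pin it).
#'
#' @param seq a sequence built by \code{\link{buildProtocol}}.
#' @param p the \linkS4class{ProtocolParams} used.
#' @param pns \code{\link{pnsParams}} for the PNS recomputation.
#' @return a list with \code{te}, \code{echoSpacing},
#'   \code{readoutBandwidth}, \code{totalDuration}, \code{volumeDuration},
#'   \code{pnsPercent}, \code{relativeRfEnergy}, \code{flipAngleNominal}.
#' @export
protocolReport <- function(seq, p, pns = pnsParams()) {
  defs <- seq@definitions
  nNav <- defs$NNavigators
  ne <- defs$NEchoes
  perShot <- defs$ReferenceBlocks / p@nSlices
  i0 <- defs$ReferenceBlocks + 1L   # first SMS shot
  shot <- seq@blocks[i0:(i0 + perShot - 1L)]
  tAcc <- 0
  rfPeakT <- NA_real_
  adcStarts <- adcCenters <- c()
  dwell <- NA_real_
  for (b in shot) {
    if (!is.null(b@rf) && !is.null(b@gz) && max(Mod(b@rf@signal)) > 0) {
      ip <- which.max(Mod(b@rf@signal))  # slice-selective excitation
      rfPeakT <- tAcc + b@rf@delay + b@rf@t[ip]
    }
    if (!is.null(b@adc)) {
      adcStarts <- c(adcStarts, tAcc + b@adc@delay)
      adcCenters <- c(adcCenters,
                      tAcc + b@adc@delay + b@adc@numSamples * b@adc@dwell / 2)
      dwell <- b@adc@dwell
    }
    tAcc <- tAcc + b@duration
  }
  imgCenters <- adcCenters[(nNav + 1):(nNav + ne)]
  eSp <- diff(adcStarts[(nNav + 1):(nNav + ne)])
  ky0Echo <- ne - p@matrixSize[2] / 2 + 1  # 1-based index of the ky = 0 echo
  grads <- sequenceGradients(seq, i0:(i0 + perShot - 1L))
  pr <- pnsImpulseResponse(grads, pns, seq@limits@gradRasterTime)
  energy <- rfEnergyReport(seq, tr = p@tr)
  list(te = imgCenters[ky0Echo] - rfPeakT,
       echoSpacing = stats::median(eSp),
       readoutBandwidth = 1 / dwell,
       totalDuration = sequenceDuration(seq),
       volumeDuration = perVolumeDuration(seq, p),
       pnsPercent = pr@peak, pnsModel = pns$model,
       pnsRheobase = pns$rheobase,
       relativeRfEnergy = energy$relativeEnergy,
       flipAngleNominal = p@flipAngle)
}

# duration of one SMS volume measured from block durations
perVolumeDuration <- function(seq, p) {
  i0 <- seq@definitions$ReferenceBlocks
  nv <- p@nDummies + p@nVolumes
  perVolBlocks <- (length(seq@blocks) - i0) / nv
  sum(vapply(seq@blocks[(i0 + 1):(i0 + perVolBlocks)],
             function(b) b@duration, 0))
}
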