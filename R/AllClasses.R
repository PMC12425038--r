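setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Scanner hardware limits
#'
#' Design-phase hardware capability profile.  Gradient quantities are
#' gamma-normalized (Hz/m, Hz/m/s); all times in seconds.  Every raster time
#' must be a positive integer multiple of 100 ns, the least common timing
#' grain of the targeted platforms.
#'
#' @slot maxRf peak RF amplitude, Hz
#' @slot rfDeadTime,rfRingdownTime,rfRasterTime RF subsystem timing, s
#' @slot maxGrad peak gradient, Hz/m
#' @slot maxSlew peak slew rate, Hz/m/s
#' @slot gradRasterTime gradient raster, s
#' @slot adcDeadTime,adcRasterTime ADC timing, s
#' @slot blockDurationRaster block duration raster, s
#' @export
setClass("SystemLimits", representation(
  maxRf = "numeric", rfDeadTime = "numeric", rfRingdownTime = "numeric",
  rfRasterTime = "numeric", maxGrad = "numeric", maxSlew = "numeric",
  gradRasterTime = "numeric", adcDeadTime = "numeric",
  adcRasterTime = "numeric", blockDurationRaster = "numeric"))

setValidity("SystemLimits", function(object) {
  v <- c(object@maxRf, object@rfDeadTime, object@rfRingdownTime,
         object@rfRasterTime, object@maxGrad, object@maxSlew,
         object@gradRasterTime, object@adcDeadTime, object@adcRasterTime,
         object@blockDurationRaster)
  if (length(v) != 10L || any(!is.finite(v)) || any(v <= 0))
    return("all limit fields must be single, finite, strictly positive values")
  rasters <- c(object@rfRasterTime, object@gradRasterTime,
               object@adcRasterTime, object@blockDurationRaster)
  if (!all(onRaster(rasters, 100e-9)))
    return("raster times must be integer multiples of 100 ns")
  TRUE
})

#' Construct a SystemLimits profile
#'
#' Defaults describe a contemporary 3 T whole-body system: 50 mT/m, 200 T/m/s,
#' 20 uT peak RF, with rasters of 1 us (RF), 10 us (gradient and block
#' duration) and 100 ns (ADC).
#'
#' @param maxRf peak RF amplitude in Hz (20 uT is ~851.5 Hz for protons).
#' @param rfDeadTime,rfRingdownTime RF amplifier switching times, s.
#' @param rfRasterTime,gradRasterTime,adcRasterTime,blockDurationRaster
#'   raster times, s.
#' @param maxGrad peak gradient, Hz/m.
#' @param maxSlew peak slew rate, Hz/m/s.
#' @param adcDeadTime minimum delay before an ADC window, s.
#' @return a \linkS4class{SystemLimits} object.
#' @examples
#' lims <- systemLimits(maxGrad = mTmToHz(33))
#' @export
systemLimits <- function(maxRf = 20e-6 * GAMMA_HZ_PER_T,
                         rfDeadTime = 100e-6, rfRingdownTime = 60e-6,
                         rfRasterTime = 1e-6,
                         maxGrad = mTmToHz(50), maxSlew = slewToHz(200),
                         gradRasterTime = 10e-6,
                         adcDeadTime = 20e-6, adcRasterTime = 100e-9,
                         blockDurationRaster = 10e-6) {
  new("SystemLimits", maxRf = maxRf, rfDeadTime = rfDeadTime,
      rfRingdownTime = rfRingdownTime, rfRasterTime = rfRasterTime,
      maxGrad = maxGrad, maxSlew = maxSlew, gradRasterTime = gradRasterTime,
      adcDeadTime = adcDeadTime, adcRasterTime = adcRasterTime,
      blockDurationRaster = blockDurationRaster)
}

#' RF event
#'
#' A complex RF waveform sampled at arbitrary (strictly increasing) time
#' points, with frequency/phase modulation offsets.  Amplitudes are in Hz
#' (gamma * B1).
#'
#' @slot delay start time relative to block start, s (must be >= dead time)
#' @slot signal complex amplitude samples, Hz
#' @slot t sample times relative to pulse start, s
#' @slot freqOffset frequency offset, Hz
#' @slot ppmOffset frequency offset in ppm of the main field
#' @slot phaseOffset phase offset, rad
#' @slot deadTime,ringdownTime system switching times bound at creation, s
#' @export
setClass("RFEvent", representation(
  delay = "numeric", signal = "complex", t = "numeric",
  freqOffset = "numeric", ppmOffset = "numeric", phaseOffset = "numeric",
  deadTime = "numeric", ringdownTime = "numeric"))

setValidity("RFEvent", function(object) {
  if (length(object@signal) != length(object@t))
    return("signal and t must have equal length")
  if (length(object@t) && (object@t[1] < -1e-12 ||
      any(diff(object@t) <= 0)))
    return("t must be strictly increasing and start at >= 0")
  if (object@delay < object@deadTime - 1e-12)
    return("RF delay must be >= dead time")
  TRUE
})

#' Create an RF event
#' @param signal complex waveform samples, Hz.
#' @param t sample times, s; defaults to the RF raster grid (sample centers).
#' @param delay start time in the block, s; defaults to the dead time.
#' @param freqOffset,ppmOffset,phaseOffset modulation offsets (Hz, ppm, rad).
#' @param limits a \linkS4class{SystemLimits} supplying dead/ringdown/raster
#'   times.
#' @return an \linkS4class{RFEvent}.
#' @export
rfEvent <- function(signal, t = NULL, delay = NULL, freqOffset = 0,
                    ppmOffset = 0, phaseOffset = 0, limits = systemLimits()) {
  if (is.null(t))
    t <- (seq_along(signal) - 0.5) * limits@rfRasterTime
  if (is.null(delay)) delay <- limits@rfDeadTime
  new("RFEvent", delay = delay, signal = as.complex(signal), t = t,
      freqOffset = freqOffset, ppmOffset = ppmOffset,
      phaseOffset = phaseOffset, deadTime = limits@rfDeadTime,
      ringdownTime = limits@rfRingdownTime)
}

#' Trapezoidal gradient event
#'
#' @slot channel one of "x", "y", "z"
#' @slot amplitude flat-top amplitude, Hz/m (signed)
#' @slot riseTime,flatTime,fallTime segment durations, s
#' @slot delay start time in block, s
#' @export
setClass("TrapGradient", representation(
  channel = "character", amplitude = "numeric", riseTime = "numeric",
  flatTime = "numeric", fallTime = "numeric", delay = "numeric"))

setValidity("TrapGradient", function(object) {
  if (!object@channel %in% c("x", "y", "z"))
    return("channel must be one of x, y, z")
  if (any(c(object@riseTime, object@flatTime, object@fallTime,
            object@delay) < -1e-12))
    return("rise/flat/fall/delay must be nonnegative")
  if (object@riseTime <= 0 && object@amplitude != 0)
    return("nonzero trapezoid needs riseTime > 0")
  TRUE
})

#' Create a trapezoidal gradient
#' @param channel "x", "y" or "z".
#' @param amplitude flat-top amplitude, Hz/m.
#' @param riseTime,flatTime,fallTime segment durations, s (rounded up to the
#'   gradient raster).
#' @param delay start time within the block, s.
#' @param limits \linkS4class{SystemLimits} used only for raster rounding.
#' @return a \linkS4class{TrapGradient}.
#' @export
trapGradient <- function(channel, amplitude, riseTime, flatTime = 0,
                         fallTime = riseTime, delay = 0,
                         limits = systemLimits()) {
  gr <- limits@gradRasterTime
  new("TrapGradient", channel = channel, amplitude = amplitude,
      riseTime = ceilToRaster(riseTime, gr), flatTime = ceilToRaster(flatTime, gr),
      fallTime = ceilToRaster(fallTime, gr), delay = ceilToRaster(delay, gr))
}

# trapezoid area in 1/m (Hz/m * s)
trapArea <- function(g) g@amplitude * (g@flatTime + (g@riseTime + g@fallTime) / 2)

#' Arbitrary-waveform gradient event
#'
#' Samples are on the gradient raster; first/last values are recorded so the
#' sequence container can enforce continuity across block boundaries.
#'
#' @slot channel axis
#' @slot waveform samples at the gradient raster, Hz/m
#' @slot delay start time in block, s
#' @slot first,last boundary values, Hz/m
#' @export
setClass("ArbGradient", representation(
  channel = "character", waveform = "numeric", delay = "numeric",
  first = "numeric", last = "numeric"))

setValidity("ArbGradient", function(object) {
  if (!object@channel %in% c("x", "y", "z"))
    return("channel must be one of x, y, z")
  if (!length(object@waveform)) return("waveform must be non-empty")
  TRUE
})

#' Create an arbitrary gradient
#' @param channel axis.
#' @param waveform samples at the gradient raster, Hz/m.
#' @param delay start time within the block, s.
#' @param first,last waveform boundary values; default to the first/last
#'   samples.
#' @return an \linkS4class{ArbGradient}.
#' @export
arbGradient <- function(channel, waveform, delay = 0,
                        first = waveform[1], last = waveform[length(waveform)]) {
  new("ArbGradient", channel = channel, waveform = waveform, delay = delay,
      first = first, last = last)
}

#' ADC readout window
#'
#' @slot numSamples number of samples
#' @slot dwell sample spacing, s
#' @slot delay start time in block, s
#' @slot freqOffset receiver frequency offset, Hz
#' @slot phaseOffset receiver phase, rad
#' @export
setClass("ADCEvent", representation(
  numSamples = "numeric", dwell = "numeric", delay = "numeric",
  freqOffset = "numeric", phaseOffset = "numeric"))

setValidity("ADCEvent", function(object) {
  if (object@numSamples < 1 || object@numSamples != round(object@numSamples))
    return("numSamples must be a positive integer")
  if (object@dwell <= 0) return("dwell must be positive")
  if (object@delay < -1e-12) return("delay must be nonnegative")
  TRUE
})

#' Create an ADC event
#' @param numSamples number of samples.
#' @param dwell dwell time, s (should be an integer multiple of the ADC
#'   raster).
#' @param delay start time within the block, s.
#' @param freqOffset,phaseOffset receiver demodulation offsets.
#' @return an \linkS4class{ADCEvent}.
#' @export
adcEvent <- function(numSamples, dwell, delay = 0, freqOffset = 0,
                     phaseOffset = 0) {
  new("ADCEvent", numSamples = numSamples, dwell = dwell, delay = delay,
      freqOffset = freqOffset, phaseOffset = phaseOffset)
}

#' Sequence block
#'
#' The atomic unit of the sequence: at most one RF pulse, one gradient per
#' axis and one ADC window, plus a total duration on the block-duration
#' raster.
#'
#' @slot rf an \linkS4class{RFEvent} or NULL
#' @slot gx,gy,gz a gradient event or NULL
#' @slot adc an \linkS4class{ADCEvent} or NULL
#' @slot duration block duration, s
#' @export
setClass("SequenceBlock", representation(
  rf = "ANY", gx = "ANY", gy = "ANY", gz = "ANY", adc = "ANY",
  duration = "numeric"))

#' Pulse sequence container
#'
#' An ordered list of \linkS4class{SequenceBlock}s executed back to back,
#' plus the hardware profile the sequence was designed against and a free
#' definitions map (name, FOV, rasters) which is serialized verbatim into
#' the .seq file.
#'
#' @slot blocks list of blocks, in execution order
#' @slot limits \linkS4class{SystemLimits}
#' @slot definitions named list
#' @export
setClass("PulseSequence", representation(
  blocks = "list", limits = "SystemLimits", definitions = "list"))

#' Create an empty pulse sequence
#' @param limits a \linkS4class{SystemLimits} profile.
#' @param definitions named list written to the file's definitions section.
#' @return a \linkS4class{PulseSequence} with no blocks.
#' @export
pulseSequence <- function(limits = systemLimits(), definitions = list()) {
  new("PulseSequence", blocks = list(), limits = limits,
      definitions = definitions)
}

#' @export
setMethod("length", "PulseSequence", function(x) length(x@blocks))

setMethod("show", "SystemLimits", function(object) {
  cat("SystemLimits:",
      sprintf("grad %.1f mT/m, slew %.0f T/m/s, RF %.0f Hz",
              hzToMTm(object@maxGrad), hzToSlew(object@maxSlew),
              object@maxRf), "\n")
})

setMethod("show", "PulseSequence", function(object) {
  cat(sprintf("PulseSequence with %d blocks, duration %.4f s\n",
              length(object@blocks), sequenceDuration(object)))
  if (length(object@definitions))
    cat("  definitions:", paste(names(object@definitions), collapse = ", "),
        "\n")
})

#' Acquisition protocol parameters
#'
#' The SMS-EPI protocol parameter set.  The defaults (set in
#' \code{\link{protocolParams}}) match the ABCD-style target protocol:
#' 2.4 mm isotropic voxels, 90 x 90 matrix, 60 slices, SMS factor 6,
#' TR 0.8 s, partial Fourier 0.8.
#'
#' @slot fov (x, y, z) field of view, m
#' @slot matrixSize (nx, ny)
#' @slot nSlices number of slices
#' @slot sliceThickness m
#' @slot smsFactor simultaneously excited slices per shot
#' @slot tr volume repetition time, s
#' @slot partialFourier acquired fraction of ky lines (late lines kept)
#' @slot flipAngle excitation flip angle, rad
#' @slot nVolumes time points in the output series (dummies excluded)
#' @slot caipiShift CAIPI FOV-shift denominator (interslice shift = FOV / this)
#' @slot pnsDerate design ceiling as a fraction of the stimulation limit
#' @slot nDummies steady-state volumes prepended and discarded
#' @slot nNavigators phase-correction navigator echoes per shot
#' @export
setClass("ProtocolParams", representation(
  fov = "numeric", matrixSize = "numeric", nSlices = "numeric",
  sliceThickness = "numeric", smsFactor = "numeric", tr = "numeric",
  partialFourier = "numeric", flipAngle = "numeric", nVolumes = "numeric",
  caipiShift = "numeric", pnsDerate = "numeric", nDummies = "numeric",
  nNavigators = "numeric"))

setValidity("ProtocolParams", function(object) {
  if (length(object@fov) != 3L || any(object@fov <= 0))
    return("fov must be three positive lengths (m)")
  if (length(object@matrixSize) != 2L || any(object@matrixSize < 4))
    return("matrixSize must be (nx, ny), both >= 4")
  if (object@nSlices %% object@smsFactor != 0)
    return("nSlices must be divisible by smsFactor")
  if (object@partialFourier <= 0.5 || object@partialFourier > 1)
    return("partialFourier must be in (0.5, 1]")
  if (abs(object@fov[3] - object@nSlices * object@sliceThickness) >
      1e-9 * object@fov[3])
    return("fov z must equal nSlices * sliceThickness (no gaps)")
  if (object@flipAngle <= 0 || object@flipAngle > pi)
    return("flipAngle must be in (0, pi]")
  TRUE
})

#' Construct protocol parameters
#'
#' With no arguments this returns the default ABCD-matched protocol
#' (2.4 mm isotropic, 90 x 90, 60 slices, SMS 6, TR 0.8 s, partial Fourier
#' 0.8, CAIPI FOV/3 shift).  The excitation flip angle defaults to 52 degrees
#' and is reported, not asserted, by \code{\link{protocolReport}}.
#'
#' @param fov (x, y, z) field of view in m.
#' @param matrixSize in-plane matrix (nx, ny).
#' @param nSlices slice count; must be a multiple of \code{smsFactor}.
#' @param sliceThickness slice thickness, m.
#' @param smsFactor multiband factor.
#' @param tr repetition time, s.
#' @param partialFourier acquired ky fraction in (0.5, 1].
#' @param flipAngle excitation flip, rad.
#' @param nVolumes output time points.
#' @param caipiShift CAIPI shift denominator (3 means FOV/3).
#' @param pnsDerate PNS design ceiling, fraction of the stimulation limit.
#' @param nDummies discarded steady-state volumes.
#' @param nNavigators navigator echoes per shot.
#' @return a \linkS4class{ProtocolParams}.
#' @examples
#' p <- protocolParams()            # full ABCD-matched protocol
#' ci <- protocolParams(matrixSize = c(32, 32), nSlices = 12, smsFactor = 3,
#'                      fov = c(0.216, 0.216, 12 * 0.006),
#'                      sliceThickness = 0.006, tr = 0.35, nVolumes = 2)
#' @export
protocolParams <- function(fov = c(0.216, 0.216, 0.144),
                           matrixSize = c(90, 90), nSlices = 60,
                           sliceThickness = 0.0024, smsFactor = 6,
                           tr = 0.8, partialFourier = 0.8,
                           flipAngle = 52 * pi / 180, nVolumes = 5,
                           caipiShift = 3, pnsDerate = 0.8,
                           nDummies = 2, nNavigators = 3) {
  new("ProtocolParams", fov = fov, matrixSize = matrixSize,
      nSlices = nSlices, sliceThickness = sliceThickness,
      smsFactor = smsFactor, tr = tr, partialFourier = partialFourier,
      flipAngle = flipAngle, nVolumes = nVolumes, caipiShift = caipiShift,
      pnsDerate = pnsDerate, nDummies = nDummies, nNavigators = nNavigators)
}

setMethod("show", "ProtocolParams", function(object) {
  cat(sprintf(
    "ProtocolParams: %dx%d matrix, %d slices, SMS %d, TR %.3g s, PF %.2f\n",
    object@matrixSize[1], object@matrixSize[2], object@nSlices,
    object@smsFactor, object@tr, object@partialFourier))
})

#' Multi-coil raw k-space container
#'
#' Output of \code{\link{simulateAcquisition}} and input to
#' \code{\link{reconstructTimeseries}}.  Data dimensions are
#' (sample, coil, echo, shot, volume); navigator echoes are included in the
#' echo dimension and flagged.  The sampled kx positions, per-echo ky line
#' indices, band membership per shot and CAIPI phase per (echo, band) fully
#' describe the encoding.
#'
#' @slot data complex 5-D array (sample, coil, echo, shot, volume)
#' @slot kxSample kx at each ADC sample (columns: even-, odd-polarity), 1/m
#' @slot kyIndex full-grid ky line index per imaging echo (0-based)
#' @slot navigator logical per echo: TRUE for navigator echoes (ky = 0)
#' @slot polarity +1/-1 readout polarity per echo
#' @slot bands matrix (smsFactor x nShots) of 0-based slice indices
#' @slot caipiPhase array (nEchoes x smsFactor x nShots): encoding phase, rad
#' @slot kzEcho kz at each imaging echo from the CAIPI blips, 1/m
#' @slot dwell ADC dwell, s
#' @slot params the generating \linkS4class{ProtocolParams}
#' @slot singleBand TRUE for single-band (calibration/reference) data, where
#'   shots map one-to-one onto slices
#' @export
setClass("RawKSpace", representation(
  data = "array", kxSample = "matrix", kyIndex = "numeric",
  navigator = "logical", polarity = "numeric", bands = "matrix",
  caipiPhase = "array", kzEcho = "numeric", dwell = "numeric",
  params = "ProtocolParams", singleBand = "logical"))

setValidity("RawKSpace", function(object) {
  d <- dim(object@data)
  if (length(d) != 5L) return("data must be 5-D (sample,coil,echo,shot,vol)")
  if (d[3] != length(object@navigator) || d[3] != length(object@polarity))
    return("echo annotations must match echo dimension")
  if (sum(!object@navigator) != length(object@kyIndex))
    return("kyIndex must annotate exactly the imaging echoes")
  if (any(!is.finite(object@data))) return("non-finite k-space samples")
  TRUE
})

setMethod("show", "RawKSpace", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "RawKSpace: %d samples x %d coils x %d echoes x %d shots x %d volumes%s\n",
    d[1], d[2], d[3], d[4], d[5],
    if (object@singleBand) " (single-band)" else ""))
})

#' Reconstructed 4-D image time series
#'
#' @slot data nonnegative 4-D magnitude array (nx, ny, nz, nt)
#' @slot voxelSize (dx, dy, dz), m
#' @slot tr volume TR, s
#' @export
setClass("ImageTimeSeries", representation(
  data = "array", voxelSize = "numeric", tr = "numeric"))

setValidity("ImageTimeSeries", function(object) {
  if (length(dim(object@data)) != 4L) return("data must be 4-D")
  if (any(object@data < 0)) return("magnitude data must be nonnegative")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be three positive lengths")
  TRUE
})

#' Create an image time series
#' @param data 4-D nonnegative array (nx, ny, nz, nt).
#' @param voxelSize voxel edge lengths (m).
#' @param tr repetition time (s).
#' @return an \linkS4class{ImageTimeSeries}.
#' @export
imageTimeSeries <- function(data, voxelSize, tr) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  new("ImageTimeSeries", data = data, voxelSize = voxelSize, tr = tr)
}

setMethod("show", "ImageTimeSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageTimeSeries: %d x %d x %d x %d, voxel %.2f mm, TR %.3g s\n",
              d[1], d[2], d[3], d[4], object@voxelSize[1] * 1e3, object@tr))
})

# ---- accessors ---------------------------------------------------------

#' Accessors for package containers
#'
#' \code{seqBlocks} returns the block list of a sequence; \code{seqLimits}
#' its hardware profile; \code{seqDefinitions} its definitions map;
#' \code{imageData} the underlying array of an image series or raw
#' container; \code{voxelSize} and \code{repetitionTime} the geometry of an
#' image series.
#'
#' @param x a package object.
#' @return the slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
seqBlocks <- function(x) x@blocks

#' @rdname accessors
#' @export
seqLimits <- function(x) x@limits

#' @rdname accessors
#' @export
seqDefinitions <- function(x) x@definitions

#' @rdname accessors
#' @export
imageData <- function(x) x@data

#' @rdname accessors
#' @export
voxelSize <- function(x) x@voxelSize

#' @rdname accessors
#' @export
repetitionTime <- function(x) x@tr
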