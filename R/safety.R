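# Design-phase safety estimation: peripheral nerve stimulation (PNS)
# prediction from the gradient slew history, via (a) a nerve impulse-response
# convolution model and (b) a SAFE-style cascade of first-order low-pass
# filters, plus a relative RF-energy report.
#
# The stimulation "limit" is parameterized by an effective gradient-coil
# rheobase in T/m/s: a sustained slew at the rheobase reads 100%.  The
# default rheobase (70 T/m/s, chronaxie 334 us) represents a modern
# whole-body gradient set; thresholds expressed in gradient units are
# strongly coil-dependent, so the value is configurable and every report
# states the parameters it used.

#' PNS model parameters
#'
#' @param model "impulse_response" (convolution with the normalized nerve
#'   impulse response c/(c+t)^2) or "safe" (weighted cascade of three
#'   first-order low-pass responses to the rectified slew).
#' @param rheobase effective slew threshold, T/m/s (100% at sustained slew).
#' @param chronaxie nerve chronaxie time, s.
#' @param safeTaus three low-pass time constants, s (safe model).
#' @param safeWeights three nonnegative weights summing to 1 (safe model).
#' @param safeRheobase threshold for the safe model, T/m/s; the default is
#'   calibrated so both models agree on EPI-like alternating trains, where
#'   rectification makes the safe cascade see a sustained slew while the
#'   signed convolution partially cancels.
#' @return an object of class \code{PNSParams}.
#' @export
pnsParams <- function(model = c("impulse_response", "safe"),
                      rheobase = 70, chronaxie = 334e-6,
                      safeTaus = c(0.2e-3, 1.5e-3, 10e-3),
                      safeWeights = c(1, 1, 1) / 3,
                      safeRheobase = rheobase / 0.57) {
  model <- match.arg(model)
  if (rheobase <= 0 || chronaxie <= 0)
    stopf("rheobase and chronaxie must be positive")
  if (any(safeWeights < 0)) stopf("SAFE weights must be nonnegative")
  structure(list(model = model, rheobase = rheobase, chronaxie = chronaxie,
                 safeTaus = safeTaus, safeWeights = safeWeights,
                 safeRheobase = safeRheobase), class = "PNSParams")
}

#' PNS prediction result
#'
#' @slot pnsPercent combined response per sample, % of the stimulation limit
#' @slot peak maximum of \code{pnsPercent}
#' @slot timeOfPeak s
#' @slot perAxis per-axis responses (nt x 3), % of limit
#' @slot raster sample spacing, s
#' @export
setClass("PNSResult", representation(
  pnsPercent = "numeric", peak = "numeric", timeOfPeak = "numeric",
  perAxis = "matrix", raster = "numeric"))

setMethod("show", "PNSResult", function(object) {
  cat(sprintf("PNSResult: peak %.1f%% of stimulation limit at t = %.4g s\n",
              object@peak, object@timeOfPeak))
})

pnsResultFrom <- function(perAxis, raster) {
  combined <- sqrt(rowSums(perAxis^2))
  ip <- which.max(combined)
  new("PNSResult", pnsPercent = combined, peak = combined[ip],
      timeOfPeak = (ip - 1) * raster, perAxis = perAxis, raster = raster)
}

# per-axis slew in T/m/s from a gamma-normalized gradient matrix (nt x 3)
slewTms <- function(grads, raster) {
  g <- rbind(grads[1, , drop = FALSE] * 0, grads)  # start from zero
  diff(g) / raster / GAMMA_HZ_PER_T
}

asGradMatrix <- function(grads) {
  if (is.list(grads)) grads <- do.call(cbind, grads)
  if (is.null(dim(grads))) grads <- matrix(grads, ncol = 1L)
  if (ncol(grads) < 3L)
    grads <- cbind(grads, matrix(0, nrow(grads), 3L - ncol(grads)))
  grads
}

#' PNS prediction by nerve impulse-response convolution
#'
#' Convolves each axis' slew rate (T/m/s) with the normalized nerve impulse
#' response \code{c/(c+t)^2}, combines axes by root-sum-of-squares and
#' expresses the result as percent of the rheobase-scaled limit.  The
#' convolution is circular (periodic wrap), matching evaluation of a
#' steady-state repeating gradient train over one TR.
#'
#' @param grads gradient waveforms, gamma-normalized Hz/m: an (nt x 3)
#'   matrix, a list of three vectors, or a single vector (x axis).
#' @param params a \code{\link{pnsParams}} (model "impulse_response").
#' @param raster sample spacing, s.
#' @return a \linkS4class{PNSResult}.
#' @export
pnsImpulseResponse <- function(grads, params = pnsParams(),
                               raster = 10e-6) {
  grads <- asGradMatrix(grads)
  nt <- nrow(grads)
  s <- slewTms(grads, raster)
  cc <- params$chronaxie
  h <- cc / (cc + (seq_len(nt) - 0.5) * raster)^2
  h <- h / sum(h * raster)  # unit DC gain: sustained slew reads 100% at r
  H <- fft(h)
  perAxis <- vapply(seq_len(3), function(a) {
    Re(fft(fft(s[, a]) * H, inverse = TRUE)) / nt * raster
  }, numeric(nt))
  pnsResultFrom(100 * perAxis / params$rheobase, raster)
}

#' PNS prediction with a SAFE-style filter cascade
#'
#' Each axis' rectified slew rate drives three first-order low-pass filters
#' whose weighted sum forms the axis response; axes combine by
#' root-sum-of-squares.  Filters are run to periodic steady state (the
#' waveform is treated as one period of a repeating train).
#'
#' @inheritParams pnsImpulseResponse
#' @param params a \code{\link{pnsParams}} (model "safe").
#' @return a \linkS4class{PNSResult}.
#' @export
pnsSafe <- function(grads, params = pnsParams("safe"), raster = 10e-6) {
  grads <- asGradMatrix(grads)
  nt <- nrow(grads)
  s <- abs(slewTms(grads, raster))
  perAxis <- matrix(0, nt, 3)
  for (a in seq_len(3)) {
    acc <- numeric(nt)
    for (k in seq_along(params$safeTaus)) {
      alpha <- raster / (params$safeTaus[k] + raster)
      y <- numeric(nt)
      # two passes wrap the filter state around the period boundary
      prev <- 0
      for (pass in 1:2) {
        for (i in seq_len(nt)) {
          prev <- prev + alpha * (s[i, a] - prev)
          y[i] <- prev
        }
      }
      acc <- acc + params$safeWeights[k] * y
    }
    perAxis[, a] <- acc
  }
  pnsResultFrom(100 * perAxis / params$safeRheobase, raster)
}

# concatenated gradient raster waveform of a block range, (nt x 3), sampled
# at raster intervals (left edges)
sequenceGradients <- function(seq, blocks = seq_along(seq@blocks)) {
  gr <- seq@limits@gradRasterTime
  chunks <- lapply(blocks, function(i) {
    b <- seq@blocks[[i]]
    n <- round(b@duration / gr)
    vapply(c("x", "y", "z"), function(ch)
      blockRasterWaveform(b, ch, gr)[seq_len(n)], numeric(n))
  })
  do.call(rbind, chunks)
}

#' Relative RF energy of a sequence
#'
#' Integrates \code{|b1|^2 dt} (Hz^2 s) over all RF events, and reports the
#' per-TR energy relative to a named reference: a 1 ms, 180-degree hard
#' pulse (500 Hz for 1 ms, i.e. 250 Hz^2 s) played once per TR.  This is a
#' design-phase comparison aid, not an absolute SAR estimate.
#'
#' @param seq a \linkS4class{PulseSequence} (>= 1 RF event).
#' @param tr repetition time used to normalize, s; defaults to the
#'   sequence's \code{TR} definition, else the total duration.
#' @return list with \code{totalEnergy} (Hz^2 s), \code{energyPerTR},
#'   \code{referenceEnergy} (250 Hz^2 s) and \code{relativeEnergy}
#'   (energy per TR / reference).
#' @export
rfEnergyReport <- function(seq, tr = NULL) {
  energies <- vapply(seq@blocks, function(b) {
    if (is.null(b@rf)) return(0)
    tt <- b@rf@t
    dt <- diff(c(0, tt))
    sum(Mod(b@rf@signal)^2 * dt)
  }, 0)
  if (!any(vapply(seq@blocks, function(b) !is.null(b@rf), TRUE)))
    stopf("sequence has no RF events")
  total <- sum(energies)
  dur <- sequenceDuration(seq)
  if (is.null(tr)) {
    tr <- seq@definitions$TR
    if (is.null(tr)) tr <- dur
  }
  ref <- (0.5 / 1e-3)^2 * 1e-3  # 1 ms 180-degree hard pulse
  perTR <- total / max(dur / tr, 1)
  list(totalEnergy = total, energyPerTR = perTR, referenceEnergy = ref,
       relativeEnergy = perTR / ref)
}
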