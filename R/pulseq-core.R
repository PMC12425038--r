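# Core sequence-assembly operations: the block/event data model enforces
# "at most one RF pulse, one gradient per axis, one ADC per block", gradient
# continuity across block boundaries, and hardware-limit conformance.

rfEnd <- function(rf) rf@delay + rf@t[length(rf@t)]
trapEnd <- function(g) g@delay + g@riseTime + g@flatTime + g@fallTime
arbEnd <- function(g, gradRaster) g@delay + length(g@waveform) * gradRaster
adcEnd <- function(a) a@delay + a@numSamples * a@dwell

gradEnd <- function(g, gradRaster) {
  if (is(g, "TrapGradient")) trapEnd(g) else arbEnd(g, gradRaster)
}

# gradient value at time t within its block (piecewise evaluation)
gradValueAt <- function(g, t, gradRaster) {
  if (is.null(g)) return(0)
  if (is(g, "TrapGradient")) {
    u <- t - g@delay
    if (u <= 0 || u >= g@riseTime + g@flatTime + g@fallTime) return(0)
    if (u < g@riseTime) return(g@amplitude * u / g@riseTime)
    if (u < g@riseTime + g@flatTime) return(g@amplitude)
    return(g@amplitude * (g@riseTime + g@flatTime + g@fallTime - u) / g@fallTime)
  }
  u <- t - g@delay
  n <- length(g@waveform)
  if (u <= 0) return(if (t <= 0) g@first else 0)
  if (u >= n * gradRaster) return(0)
  g@waveform[[min(n, floor(u / gradRaster) + 1L)]]
}

blockGradStart <- function(block, channel, gradRaster) {
  g <- slot(block, paste0("g", channel))
  if (is.null(g)) return(0)
  if (is(g, "ArbGradient") && g@delay <= 1e-12) return(g@first)
  gradValueAt(g, 0, gradRaster)
}

blockGradEnd <- function(block, channel, gradRaster) {
  g <- slot(block, paste0("g", channel))
  if (is.null(g)) return(0)
  if (is(g, "ArbGradient") &&
      arbEnd(g, gradRaster) >= block@duration - 1e-12) return(g@last)
  gradValueAt(g, block@duration, gradRaster)
}

# classify a set of events into block slots, rejecting duplicates
classifyEvents <- function(events) {
  out <- list(rf = NULL, gx = NULL, gy = NULL, gz = NULL, adc = NULL)
  for (ev in events) {
    if (is(ev, "RFEvent")) {
      if (!is.null(out$rf)) stopf("multiple RF events in one block")
      out$rf <- ev
    } else if (is(ev, "TrapGradient") || is(ev, "ArbGradient")) {
      slotn <- paste0("g", ev@channel)
      if (!is.null(out[[slotn]]))
        stopf("multiple gradient events on channel %s in one block", ev@channel)
      out[[slotn]] <- ev
    } else if (is(ev, "ADCEvent")) {
      if (!is.null(out$adc)) stopf("multiple ADC events in one block")
      out$adc <- ev
    } else if (!is.null(ev)) {
      stopf("unsupported event of class %s", class(ev)[1])
    }
  }
  out
}

# minimum feasible duration for the given events (before raster rounding)
eventsEnd <- function(ev, limits) {
  ends <- 0
  if (!is.null(ev$rf)) ends <- c(ends, rfEnd(ev$rf) + ev$rf@ringdownTime)
  for (ch in c("gx", "gy", "gz"))
    if (!is.null(ev[[ch]])) ends <- c(ends, gradEnd(ev[[ch]], limits@gradRasterTime))
  if (!is.null(ev$adc)) ends <- c(ends, adcEnd(ev$adc))
  max(ends)
}

#' Assemble a sequence block from events
#'
#' @param ... events: at most one \linkS4class{RFEvent}, one gradient per
#'   axis, one \linkS4class{ADCEvent}.  Pure delay blocks are created by
#'   passing only \code{duration}.
#' @param duration block duration, s; defaults to the latest event end
#'   (including RF ringdown), rounded up to the block-duration raster.
#' @param limits \linkS4class{SystemLimits} used for raster rounding.
#' @return a \linkS4class{SequenceBlock}.
#' @export
sequenceBlock <- function(..., duration = NULL, limits = systemLimits()) {
  ev <- classifyEvents(list(...))
  minDur <- eventsEnd(ev, limits)
  if (is.null(duration)) duration <- minDur
  duration <- ceilToRaster(duration, limits@blockDurationRaster)
  if (duration < minDur - 1e-9)
    stopf("block duration %.6g s shorter than latest event end %.6g s",
          duration, minDur)
  new("SequenceBlock", rf = ev$rf, gx = ev$gx, gy = ev$gy, gz = ev$gz,
      adc = ev$adc, duration = duration)
}

#' Append a block to a sequence
#'
#' Events are validated against the sequence's hardware profile rules that
#' must hold structurally (one event per channel) and the gradient
#' continuity invariant at the boundary with the previous block; full limit
#' checking is done by \code{\link{validateSequence}}.
#'
#' @param seq a \linkS4class{PulseSequence}.
#' @param ... events (see \code{\link{sequenceBlock}}), or a single
#'   pre-built \linkS4class{SequenceBlock}.
#' @param duration optional block duration, s.
#' @return the sequence with the block appended.
#' @examples
#' sq <- pulseSequence()
#' sq <- addBlock(sq, duration = 1e-3)     # pure delay block
#' length(sq)
#' @export
addBlock <- function(seq, ..., duration = NULL) {
  args <- list(...)
  if (length(args) == 1L && is(args[[1]], "SequenceBlock") && is.null(duration))
    blk <- args[[1]]
  else
    blk <- sequenceBlock(..., duration = duration, limits = seq@limits)
  checkContinuity(seq, blk)
  seq@blocks[[length(seq@blocks) + 1L]] <- blk
  seq
}

checkContinuity <- function(seq, blk) {
  n <- length(seq@blocks)
  gr <- seq@limits@gradRasterTime
  tol <- 1e-6 * seq@limits@maxGrad
  prevEnd <- if (n == 0L) c(x = 0, y = 0, z = 0) else {
    pb <- seq@blocks[[n]]
    c(x = blockGradEnd(pb, "x", gr), y = blockGradEnd(pb, "y", gr),
      z = blockGradEnd(pb, "z", gr))
  }
  for (ch in c("x", "y", "z")) {
    s <- blockGradStart(blk, ch, gr)
    if (abs(s - prevEnd[[ch]]) > tol)
      stopf(paste0("gradient discontinuity on channel %s at block boundary: ",
                   "previous block ends at %.6g Hz/m, new block starts at ",
                   "%.6g Hz/m"), ch, prevEnd[[ch]], s)
  }
  invisible(TRUE)
}

#' Total sequence duration
#'
#' The exact sum of block durations (blocks execute back to back without
#' gaps).
#'
#' @param seq a \linkS4class{PulseSequence}.
#' @return duration in seconds.
#' @export
sequenceDuration <- function(seq) {
  if (!length(seq@blocks)) return(0)
  sum(vapply(seq@blocks, function(b) b@duration, 0))
}

violationRow <- function(block, rule, measured, limit) {
  data.frame(block = block, rule = rule, measured = measured, limit = limit,
             stringsAsFactors = FALSE)
}

#' Validate a sequence against a hardware profile
#'
#' Checks every event of every block against amplitude, slew, raster and
#' timing rules, plus block-duration raster and gradient continuity across
#' boundaries.  Violations are returned as data, not raised as errors: the
#' report is empty if and only if the sequence is compatible with the
#' profile.
#'
#' @param seq a \linkS4class{PulseSequence}.
#' @param limits the \linkS4class{SystemLimits} to check against; defaults
#'   to the profile the sequence was designed with.
#' @return a data.frame with columns block, rule, measured, limit (zero rows
#'   when the sequence passes).
#' @export
validateSequence <- function(seq, limits = seq@limits) {
  out <- list()
  gr <- limits@gradRasterTime
  prevEnd <- c(x = 0, y = 0, z = 0)
  ctol <- 1e-6 * limits@maxGrad
  for (i in seq_along(seq@blocks)) {
    b <- seq@blocks[[i]]
    add <- function(rule, measured, limit)
      out[[length(out) + 1L]] <<- violationRow(i, rule, measured, limit)
    if (!onRaster(b@duration, limits@blockDurationRaster))
      add("block_duration_raster", b@duration, limits@blockDurationRaster)
    if (!is.null(b@rf)) {
      rf <- b@rf
      if (max(Mod(rf@signal)) > limits@maxRf * (1 + 1e-9))
        add("rf_amplitude", max(Mod(rf@signal)), limits@maxRf)
      if (rf@delay < limits@rfDeadTime - 1e-12)
        add("rf_dead_time", rf@delay, limits@rfDeadTime)
      if (rfEnd(rf) + limits@rfRingdownTime > b@duration + 1e-12)
        add("rf_ringdown", rfEnd(rf) + limits@rfRingdownTime, b@duration)
    }
    for (ch in c("gx", "gy", "gz")) {
      g <- slot(b, ch)
      if (is.null(g)) next
      if (is(g, "TrapGradient")) {
        if (abs(g@amplitude) > limits@maxGrad * (1 + 1e-9))
          add("grad_amplitude", abs(g@amplitude), limits@maxGrad)
        for (seg in c("riseTime", "flatTime", "fallTime"))
          if (!onRaster(slot(g, seg), gr))
            add("grad_raster", slot(g, seg), gr)
        if (g@riseTime > 0 && abs(g@amplitude) / g@riseTime >
            limits@maxSlew * (1 + 1e-9))
          add("slew", abs(g@amplitude) / g@riseTime, limits@maxSlew)
        if (g@fallTime > 0 && abs(g@amplitude) / g@fallTime >
            limits@maxSlew * (1 + 1e-9))
          add("slew", abs(g@amplitude) / g@fallTime, limits@maxSlew)
      } else {
        if (max(abs(g@waveform)) > limits@maxGrad * (1 + 1e-9))
          add("grad_amplitude", max(abs(g@waveform)), limits@maxGrad)
        sl <- max(abs(diff(c(g@first, g@waveform, g@last)))) / gr
        if (sl > limits@maxSlew * (1 + 1e-9)) add("slew", sl, limits@maxSlew)
      }
      if (gradEnd(g, gr) > b@duration + 1e-12)
        add("grad_duration", gradEnd(g, gr), b@duration)
    }
    if (!is.null(b@adc)) {
      a <- b@adc
      if (!onRaster(a@dwell, limits@adcRasterTime))
        add("adc_dwell_raster", a@dwell, limits@adcRasterTime)
      if (a@delay < limits@adcDeadTime - 1e-12)
        add("adc_dead_time", a@delay, limits@adcDeadTime)
      if (adcEnd(a) > b@duration + 1e-12)
        add("adc_duration", adcEnd(a), b@duration)
    }
    for (ch in c("x", "y", "z")) {
      s <- blockGradStart(b, ch, gr)
      if (abs(s - prevEnd[[ch]]) > ctol)
        add(paste0("continuity_", ch), s, prevEnd[[ch]])
      prevEnd[[ch]] <- blockGradEnd(b, ch, gr)
    }
  }
  if (!length(out))
    return(data.frame(block = integer(), rule = character(),
                      measured = numeric(), limit = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# evaluate one channel of a block on the gradient raster *edges*
# (length nRaster + 1), so trapezoidal integration is exact for trapezoids
blockRasterWaveform <- function(b, channel, gradRaster) {
  n <- round(b@duration / gradRaster)
  tt <- seq(0, by = gradRaster, length.out = n + 1L)
  g <- slot(b, paste0("g", channel))
  if (is.null(g)) return(numeric(n + 1L))
  if (is(g, "TrapGradient")) {
    brk <- g@delay + cumsum(c(0, g@riseTime, g@flatTime, g@fallTime))
    vapply(tt, function(t) {
      if (t <= brk[1] || t >= brk[4]) return(0)
      if (t <= brk[2]) return(g@amplitude * (t - brk[1]) / max(g@riseTime, 1e-12))
      if (t <= brk[3]) return(g@amplitude)
      g@amplitude * (brk[4] - t) / max(g@fallTime, 1e-12)
    }, 0)
  } else {
    w <- numeric(n + 1L)
    i0 <- round(g@delay / gradRaster)
    m <- length(g@waveform)
    # arbitrary waveforms are sample values on raster intervals; edges take
    # the midpoint between neighbours so integration matches sample sums
    edges <- c(g@first, (g@waveform[-m] + g@waveform[-1]) / 2, g@last)
    w[(i0 + 1L):(i0 + m + 1L)] <- edges
    w
  }
}

# k-vector right after an RF reset: area from the RF peak sample (the
# effective excitation point) to the block end
kAfterRfReset <- function(b, cums, n, gr) {
  tPk <- b@rf@delay + if (length(b@rf@signal) && max(Mod(b@rf@signal)) > 0)
    b@rf@t[which.max(Mod(b@rf@signal))] else rfEnd(b@rf) - b@rf@delay
  idx <- min(max(tPk / gr, 0), n)
  lo <- min(floor(idx), n - 1L)
  fr <- idx - lo
  vapply(seq_len(3), function(j) {
    cj <- cums[[j]]
    cums[[j]][n + 1L] - (cj[lo + 1L] * (1 - fr) + cj[lo + 2L] * fr)
  }, 0)
}

#' Compute the k-space trajectory at every ADC sample
#'
#' Integrates the gamma-normalized gradient waveforms (trapezoidal rule at
#' gradient-raster resolution) across the whole sequence, resetting k to
#' zero at the peak of every RF event, and reports the k-vector at each
#' ADC sample time (sample centers, linear interpolation within a raster
#' interval).
#'
#' @param seq a \linkS4class{PulseSequence} containing at least one ADC.
#' @return a data.frame with columns \code{block}, \code{sample}, \code{t}
#'   (s, from sequence start), \code{kx}, \code{ky}, \code{kz} (1/m).
#' @export
computeKspace <- function(seq) {
  gr <- seq@limits@gradRasterTime
  k <- c(x = 0, y = 0, z = 0)
  t0 <- 0
  seenRf <- FALSE
  rows <- list()
  for (i in seq_along(seq@blocks)) {
    b <- seq@blocks[[i]]
    n <- round(b@duration / gr)
    wf <- lapply(c("x", "y", "z"), function(ch)
      blockRasterWaveform(b, ch, gr))
    # cumulative integral at raster edges within the block
    cums <- lapply(wf, function(w)
      c(0, cumsum((w[-length(w)] + w[-1]) / 2 * gr)))
    if (!is.null(b@rf)) seenRf <- TRUE
    if (!is.null(b@adc)) {
      if (!seenRf)
        stopf("ADC in block %d has no preceding RF excitation", i)
      a <- b@adc
      ts <- a@delay + (seq_len(a@numSamples) - 0.5) * a@dwell
      idx <- pmin(pmax(ts / gr, 0), n)
      lo <- pmin(floor(idx), n - 1L)
      fr <- idx - lo
      kat <- lapply(seq_len(3), function(j) {
        cj <- cums[[j]]
        k[[j]] + cj[lo + 1L] * (1 - fr) + cj[lo + 2L] * fr
      })
      rows[[length(rows) + 1L]] <- data.frame(
        block = i, sample = seq_len(a@numSamples), t = t0 + ts,
        kx = kat[[1]], ky = kat[[2]], kz = kat[[3]])
    }
    for (j in seq_len(3)) k[[j]] <- k[[j]] + cums[[j]][n + 1L]
    if (!is.null(b@rf)) {
      # excitation resets the k-space origin at the RF peak (the effective
      # excitation point); gradient area played after it still contributes
      k <- kAfterRfReset(b, cums, n, gr)
    }
    t0 <- t0 + b@duration
  }
  if (!length(rows)) stopf("sequence contains no ADC events")
  do.call(rbind, rows)
}
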