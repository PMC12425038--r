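# fBIRN/ABCD-style phantom QA battery on 4-D time series: SNR and SFNR
# (signal-fluctuation-to-noise), RMS residual after quadratic detrending,
# the Weisskoff radius of decorrelation, per-axis spatial FWHM from lag-1
# autocorrelation of the detrended residuals, and the EPI ghost-to-signal
# ratio.  Conventions (ROI sizes, detrend order, background corners) follow
# the fBIRN defaults and are echoed in the report so numbers are not
# conflated across pipelines.

#' Region-of-interest conventions for the QA battery
#'
#' @param signalWidth signal ROI edge length, voxels; default 21 for
#'   matrices of 64 and larger, else about a quarter of the matrix (odd).
#' @param weisskoffWidths ROI widths for the Weisskoff plot (default 1 up
#'   to 21, clipped to the matrix).
#' @param bgWidth corner background ROI edge length, voxels.
#' @param slice 1-based slice index (default: center slice).
#' @param center c(x, y) ROI center voxel (default: center of mass).
#' @param peAxis phase-encode axis for the ghost ROI (2 = y).
#' @return an object of class \code{ROISpec}.
#' @export
roiSpec <- function(signalWidth = NULL, weisskoffWidths = NULL,
                    bgWidth = NULL, slice = NULL, center = NULL,
                    peAxis = 2L) {
  structure(list(signalWidth = signalWidth,
                 weisskoffWidths = weisskoffWidths, bgWidth = bgWidth,
                 slice = slice, center = center, peAxis = peAxis),
            class = "ROISpec")
}

# fill in data-dependent ROI defaults for an (nx, ny) slice
resolveRoi <- function(roi, meanSlice) {
  nx <- nrow(meanSlice); ny <- ncol(meanSlice)
  out <- roi
  if (is.null(out$signalWidth))
    out$signalWidth <- if (min(nx, ny) >= 64) 21L else
      max(5L, 2L * floor(min(nx, ny) / 8) + 1L)
  if (is.null(out$weisskoffWidths))
    out$weisskoffWidths <- seq_len(min(21L, floor(min(nx, ny) / 2)))
  if (is.null(out$bgWidth)) out$bgWidth <- max(2L, floor(min(nx, ny) / 8))
  if (is.null(out$center)) {
    tot <- sum(meanSlice)
    out$center <- if (tot > 0)
      c(round(sum(row(meanSlice) * meanSlice) / tot),
        round(sum(col(meanSlice) * meanSlice) / tot))
    else c(floor(nx / 2) + 1L, floor(ny / 2) + 1L)
  }
  out
}

roiIndices <- function(center, width, nx, ny) {
  h <- floor(width / 2)
  xs <- (center[1] - h):(center[1] - h + width - 1L)
  ys <- (center[2] - h):(center[2] - h + width - 1L)
  if (min(xs) < 1 || max(xs) > nx || min(ys) < 1 || max(ys) > ny)
    stopf("ROI of width %d at (%d, %d) leaves the image", width,
          center[1], center[2])
  list(x = xs, y = ys)
}

# residual maker for 2nd-order polynomial detrending over time
detrendResiduals <- function(Y) {  # Y: nvox x nt
  nt <- ncol(Y)
  X <- cbind(1, stats::poly(seq_len(nt), degree = 2))
  Y - Y %*% X %*% solve(crossprod(X), t(X))
}

centerSliceSeries <- function(ts, roi) {
  d <- ts@data
  sl <- roi$slice
  if (is.null(sl)) sl <- floor(dim(d)[3] / 2) + 1L
  list(series = d[, , sl, , drop = TRUE], slice = sl)
}

#' Signal, SFNR and SNR of a phantom time series
#'
#' fBIRN conventions on the center slice: the signal image is the temporal
#' mean; the fluctuation noise is the temporal SD of residuals after
#' 2nd-order polynomial detrending per voxel; SFNR is the ROI mean of
#' mean/SD.  SNR uses the odd/even volume-sum difference image: the spatial
#' SD of that image in the ROI divided by sqrt(nt) estimates the thermal
#' noise.
#'
#' @param ts an \linkS4class{ImageTimeSeries} with nt >= 4, even.
#' @param roi an \code{\link{roiSpec}}.
#' @return list: \code{meanSignal}, \code{sfnr}, \code{snr},
#'   \code{rmsResidualPercent}, \code{driftPercent}, \code{flags}.
#' @export
computeSignalSfnrSnr <- function(ts, roi = roiSpec()) {
  nt <- dim(ts@data)[4]
  if (nt < 4 || nt %% 2 != 0) stopf("need nt >= 4 and even (got %d)", nt)
  cs <- centerSliceSeries(ts, roi)
  s <- cs$series                      # nx x ny x nt
  nx <- dim(s)[1]; ny <- dim(s)[2]
  meanImg <- apply(s, 1:2, mean)
  roi <- resolveRoi(roi, meanImg)
  idx <- roiIndices(roi$center, roi$signalWidth, nx, ny)
  Y <- matrix(s, nx * ny, nt)
  res <- detrendResiduals(Y)
  sdImg <- matrix(sqrt(rowSums(res^2) / (nt - 3)), nx, ny)
  # clamp pure numerical residue of an exactly constant series to zero
  tiny <- 1e-12 * max(abs(meanImg), .Machine$double.eps)
  sdImg[sdImg < tiny] <- 0
  flags <- character(0)
  sfnrImg <- meanImg / pmax(sdImg, .Machine$double.eps)
  cap <- 1e6
  if (any(sdImg[idx$x, idx$y] == 0)) {
    flags <- c(flags, "constant_series_sfnr_capped")
    sfnrImg <- pmin(sfnrImg, cap)
  }
  odd <- seq(1, nt, by = 2); even <- seq(2, nt, by = 2)
  D <- apply(s[, , odd, drop = FALSE], 1:2, sum) -
    apply(s[, , even, drop = FALSE], 1:2, sum)
  noiseSd <- stats::sd(D[idx$x, idx$y]) / sqrt(nt)
  meanSignal <- mean(meanImg[idx$x, idx$y])
  snr <- if (noiseSd > 0) meanSignal / noiseSd else {
    flags <- c(flags, "zero_noise_snr_capped"); cap
  }
  rmsImg <- matrix(sqrt(rowMeans(res^2)), nx, ny)
  rmsImg[rmsImg < tiny] <- 0
  rmsPct <- 100 * mean(rmsImg[idx$x, idx$y]) / max(meanSignal,
                                                   .Machine$double.eps)
  tc <- apply(s[idx$x, idx$y, , drop = FALSE], 3, mean)
  fit <- stats::fitted(stats::lm(tc ~ stats::poly(seq_len(nt), 2)))
  driftPct <- 100 * (max(fit) - min(fit)) / max(mean(tc),
                                                .Machine$double.eps)
  list(meanSignal = meanSignal, sfnr = min(mean(sfnrImg[idx$x, idx$y]), cap),
       snr = snr, rmsResidualPercent = rmsPct, driftPercent = driftPct,
       flags = flags)
}

#' Weisskoff plot and radius of decorrelation
#'
#' F(N) is the temporal coefficient of variation of the mean signal over an
#' N x N ROI (after quadratic detrending); for spatially independent noise
#' F(N) = F(1)/N, so the radius of decorrelation RDC = F(1)/F(Nmax) reaches
#' the largest width, while perfectly correlated noise gives RDC = 1.  The
#' returned RDC is clipped to [1, Nmax] and flagged at the bounds.
#'
#' @param ts an \linkS4class{ImageTimeSeries}.
#' @param roi an \code{\link{roiSpec}} (>= 2 widths).
#' @return list: \code{rdc}, \code{widths}, \code{F}, \code{flags}.
#' @export
weisskoffRdc <- function(ts, roi = roiSpec()) {
  cs <- centerSliceSeries(ts, roi)
  s <- cs$series
  nt <- dim(s)[3]
  meanImg <- apply(s, 1:2, mean)
  roi <- resolveRoi(roi, meanImg)
  widths <- roi$weisskoffWidths
  if (length(widths) < 2) stopf("need >= 2 Weisskoff widths")
  Fv <- vapply(widths, function(w) {
    idx <- roiIndices(roi$center, w, dim(s)[1], dim(s)[2])
    tc <- apply(s[idx$x, idx$y, , drop = FALSE], 3, mean)
    r <- detrendResiduals(matrix(tc, 1L, nt))
    stats::sd(r) / max(mean(tc), .Machine$double.eps)
  }, 0)
  flags <- character(0)
  rdc <- Fv[1] / max(Fv[length(Fv)], .Machine$double.eps)
  nmax <- widths[length(widths)]
  if (rdc < 1) { rdc <- 1; flags <- c(flags, "rdc_clipped_low") }
  if (rdc > nmax) { rdc <- nmax; flags <- c(flags, "rdc_clipped_high") }
  list(rdc = rdc, widths = widths, F = Fv, flags = flags)
}

#' Per-axis spatial FWHM from lag-1 autocorrelation
#'
#' Gaussian-equivalent smoothness of the detrended residuals:
#' \code{FWHM = dx * sqrt(-2 ln 2 / ln r1)} for lag-1 autocorrelation
#' \code{0 < r1 < 1}; nonpositive r1 is reported as a sub-voxel floor
#' (half a voxel) with a flag.  With a single volume the demeaned image
#' itself is analyzed.
#'
#' @param ts an \linkS4class{ImageTimeSeries} (or single volume in one).
#' @param mask optional logical 3-D mask; defaults to voxels above 20
#'   percent of the maximum mean intensity (all voxels if that region is
#'   tiny, as for pure-noise input).
#' @return list: \code{fwhm} (per-axis, m), \code{fwhmVoxels}, \code{r1},
#'   \code{flags}.
#' @export
spatialFwhm <- function(ts, mask = NULL) {
  d <- ts@data
  nt <- dim(d)[4]
  meanImg <- apply(d, 1:3, mean)
  if (is.null(mask)) {
    mask <- meanImg > 0.2 * max(meanImg)
    if (sum(mask) < 0.05 * length(mask)) mask <- array(TRUE, dim(meanImg))
  }
  res <- if (nt >= 4) {
    Y <- matrix(d, prod(dim(d)[1:3]), nt)
    array(detrendResiduals(Y), dim(d))
  } else {
    array(d[, , , 1] - mean(d[, , , 1][mask]), c(dim(d)[1:3], 1L))
  }
  flags <- character(0)
  r1 <- numeric(3)
  for (ax in 1:3) {
    num <- 0; den1 <- 0; den2 <- 0
    n <- dim(res)[ax]
    if (n < 8) {  # too few voxels along this axis for a stable estimate
      r1[ax] <- NA_real_
      flags <- c(flags, sprintf("axis%d_too_small", ax))
      next
    }
    for (t0 in seq_len(dim(res)[4])) {
      v <- array(res[, , , t0], dim(res)[1:3])
      a <- switch(ax, v[-n, , ], v[, -n, ], v[, , -n])
      b <- switch(ax, v[-1, , ], v[, -1, ], v[, , -1])
      ma <- switch(ax, mask[-n, , ] & mask[-1, , ],
                   mask[, -n, ] & mask[, -1, ],
                   mask[, , -n] & mask[, , -1])
      num <- num + sum(a[ma] * b[ma])
      den1 <- den1 + sum(a[ma]^2); den2 <- den2 + sum(b[ma]^2)
    }
    r1[ax] <- num / max(sqrt(den1 * den2), .Machine$double.eps)
  }
  fwhmVox <- vapply(r1, function(r) {
    if (is.na(r)) return(NA_real_)
    if (r <= 0) return(0.5)
    if (r >= 1) return(Inf)
    sqrt(-2 * log(2) / log(r))
  }, 0)
  if (any(!is.na(r1) & r1 <= 0)) flags <- c(flags, "subvoxel_floor")
  if (any(!is.na(r1) & r1 >= 1)) flags <- c(flags, "perfectly_smooth")
  list(fwhm = fwhmVox * ts@voxelSize, fwhmVoxels = fwhmVox, r1 = r1,
       flags = flags)
}

#' EPI ghost-to-signal ratio
#'
#' \code{GSR = (mean ghost ROI - mean background ROI) / mean signal ROI},
#' where the ghost ROI is the signal ROI translated by FOV/2 along the
#' phase-encode axis (circularly) and the background is the average of the
#' four corner ROIs.  The object must occupy less than half the FOV along
#' the phase-encode direction.
#'
#' @param ts an \linkS4class{ImageTimeSeries} (first volume and center
#'   slice are analyzed) .
#' @param roi an \code{\link{roiSpec}}; \code{peAxis} selects the
#'   phase-encode axis.
#' @return the dimensionless ratio.
#' @export
ghostSignalRatio <- function(ts, roi = roiSpec()) {
  cs <- centerSliceSeries(ts, roi)
  img <- if (length(dim(cs$series)) == 3L) cs$series[, , 1] else cs$series
  nx <- nrow(img); ny <- ncol(img)
  roi <- resolveRoi(roi, img)
  # the ghost ROI construction assumes the object spans < half the FOV
  # along the phase-encode axis
  prof <- if (roi$peAxis == 2L) colSums(img) else rowSums(img)
  occ <- which(prof > 0.1 * max(prof))
  if (length(occ) && (max(occ) - min(occ) + 1L) > length(prof) / 2)
    stopf("signal and ghost ROIs overlap: object exceeds half the FOV")
  idx <- roiIndices(roi$center, roi$signalWidth, nx, ny)
  half <- if (roi$peAxis == 2L) ny %/% 2L else nx %/% 2L
  gx <- idx$x; gy <- idx$y
  if (roi$peAxis == 2L) gy <- ((gy - 1L + half) %% ny) + 1L
  else gx <- ((gx - 1L + half) %% nx) + 1L
  if (length(intersect(if (roi$peAxis == 2L) gy else gx,
                       if (roi$peAxis == 2L) idx$y else idx$x)))
    stopf("ghost and signal ROIs overlap: object exceeds half the FOV")
  b <- roi$bgWidth
  corners <- list(c(1L, 1L), c(nx - b + 1L, 1L), c(1L, ny - b + 1L),
                  c(nx - b + 1L, ny - b + 1L))
  bg <- mean(vapply(corners, function(cn)
    mean(img[cn[1]:(cn[1] + b - 1L), cn[2]:(cn[2] + b - 1L)]), 0))
  sig <- mean(img[idx$x, idx$y])
  ghost <- mean(img[gx, gy])
  (ghost - bg) / max(sig, .Machine$double.eps)
}

#' Run the full QA battery
#'
#' Aggregates all metrics into a \code{QAReport} (a named list with a JSON
#' serialization) including a protocol echo (TR, matrix, voxel size) and
#' the package version.  Identical input yields identical reports.
#'
#' @param ts an \linkS4class{ImageTimeSeries}.
#' @param roi an \code{\link{roiSpec}}.
#' @return an object of class \code{QAReport}.
#' @export
runQa <- function(ts, roi = roiSpec()) {
  base <- computeSignalSfnrSnr(ts, roi)
  wk <- weisskoffRdc(ts, roi)
  fw <- spatialFwhm(ts)
  gsr <- tryCatch(ghostSignalRatio(ts, roi), error = function(e) NA_real_)
  gflag <- if (is.na(gsr)) "ghost_roi_invalid" else character(0)
  d <- dim(ts@data)
  rep <- list(
    snr = base$snr, sfnr = base$sfnr, meanSignal = base$meanSignal,
    rmsResidualPercent = base$rmsResidualPercent,
    driftPercent = base$driftPercent,
    rdc = wk$rdc, weisskoffWidths = wk$widths, weisskoffF = wk$F,
    fwhmMm = as.numeric(fw$fwhm) * 1e3, fwhmVoxels = fw$fwhmVoxels,
    ghostToSignal = gsr,
    flags = unique(c(base$flags, wk$flags, fw$flags, gflag)),
    protocol = list(tr = ts@tr, matrix = d[1:2], nSlices = d[3],
                    nVolumes = d[4], voxelSizeMm = ts@voxelSize * 1e3),
    conventions = "fBIRN: 2nd-order polynomial detrend, center slice, CoM-centered square ROIs, 4-corner background",
    version = as.character(utils::packageVersion("smsepi")))
  class(rep) <- "QAReport"
  rep
}

#' @export
print.QAReport <- function(x, ...) {
  cat("QA report (fBIRN/ABCD conventions)\n")
  cat(sprintf("  SNR  %.1f   SFNR %.1f   mean signal %.1f\n",
              x$snr, x$sfnr, x$meanSignal))
  cat(sprintf("  RMS residual %.3f%%   drift %.3f%%\n",
              x$rmsResidualPercent, x$driftPercent))
  cat(sprintf("  RDC %.1f   FWHM [%s] mm   ghost/signal %.4f\n", x$rdc,
              paste(sprintf("%.2f", x$fwhmMm), collapse = ", "),
              x$ghostToSignal))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Write a QA report as JSON
#'
#' @param report a \code{QAReport}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeQaReport <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
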