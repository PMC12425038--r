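# Harmonized image reconstruction: EPI odd/even phase correction estimated
# from navigator echoes, least-squares regridding of ramp samples onto the
# Cartesian kx grid, SMS unaliasing by slice GRAPPA (k-space kernels) or
# SENSE (image-domain joint coset solve, i.e. 3D SENSE over the CAIPI
# shifts), zero-filled partial Fourier, unitary inverse FFT and
# root-sum-of-squares coil combination.  The chain is deterministic:
# identical raw input yields bit-identical output.

#' EPI odd/even phase correction parameters
#'
#' @param theta0 constant phase of odd-polarity echoes, rad.
#' @param theta1 linear phase, rad per kx sample (about the readout center).
#' @return an object of class \code{PhaseCorrection}.
#' @export
phaseCorrection <- function(theta0 = 0, theta1 = 0) {
  if (!is.finite(theta0) || !is.finite(theta1) || abs(theta1) >= pi / 2)
    stopf("phase correction must be finite with |theta1| < pi/2 per sample")
  structure(list(theta0 = theta0, theta1 = theta1),
            class = "PhaseCorrection")
}

#' Estimate the odd/even phase error from navigator echoes
#'
#' Opposite-polarity navigator echoes sample mirrored kx positions, so the
#' sample-wise product of an odd-polarity navigator with the index-reversed
#' even-polarity navigator isolates the inter-polarity phase
#' \code{theta0 + theta1 (s - center)}; a magnitude-weighted linear fit of
#' its phase (accumulated over shots, coils and navigator pairs) yields the
#' correction.
#'
#' @param raw a \linkS4class{RawKSpace} with >= 2 navigator echoes of
#'   opposite polarity (typically the single-band reference segment).
#' @return a \code{\link{phaseCorrection}}.
#' @export
estimatePhaseCorrection <- function(raw) {
  nav <- which(raw@navigator)
  if (length(nav) < 2) stopf("need >= 2 navigator echoes")
  pol <- raw@polarity[nav]
  if (length(unique(pol)) < 2)
    stopf("need navigator echoes of opposite polarity")
  d <- raw@data
  nsamp <- dim(d)[1]
  acc <- complex(nsamp)
  for (i in seq_len(length(nav) - 1L)) {
    e1 <- nav[i]; e2 <- nav[i + 1L]
    if (raw@polarity[e1] == raw@polarity[e2]) next
    odd <- if (raw@polarity[e1] < 0) e1 else e2
    evn <- if (raw@polarity[e1] < 0) e2 else e1
    o <- d[, , odd, , 1, drop = FALSE]
    e <- d[, , evn, , 1, drop = FALSE][nsamp:1, , , , , drop = FALSE]
    acc <- acc + rowSums(o * Conj(e), dims = 1)
  }
  if (max(Mod(acc)) == 0) stopf("all-zero navigators")
  s <- seq_len(nsamp) - (nsamp + 1) / 2
  ph <- Arg(acc)
  w <- Mod(acc)
  fit <- stats::lm(ph ~ s, weights = w)
  phaseCorrection(coef(fit)[[1]], coef(fit)[[2]])
}

# multiply odd-polarity echoes of (nsamp x ncoil x nechoes [x ...]) data by
# the inverse of the estimated phase error
applyPhaseCorrection <- function(d, polarity, pc) {
  if (pc$theta0 == 0 && pc$theta1 == 0) return(d)
  nsamp <- dim(d)[1]
  corr <- exp(-1i * (pc$theta0 +
                       pc$theta1 * (seq_len(nsamp) - (nsamp + 1) / 2)))
  odd <- which(polarity < 0)
  dims <- dim(d)
  idx <- slice.index(d, 3) %in% odd
  d[idx] <- d[idx] * rep(corr, length.out = sum(idx))  # recycled per column
  d
}

# complex Moore-Penrose pseudoinverse via SVD
cpinv <- function(B, tol = 1e-10) {
  s <- svd(B)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*%
    (Conj(t(s$u[, keep, drop = FALSE])) / s$d[keep])
}

# least-squares regridding operators for even/odd readout polarity
makeRegridOperators <- function(kxSample, nx, fov) {
  xg <- gridCoords(nx, fov)
  kc <- kGrid(nx, fov)
  if (max(abs(kc)) > max(abs(kxSample)) + 0.5 / fov)
    stopf("target grid bandwidth exceeds the sampled kx extent")
  C <- exp(-2i * pi * outer(kc, xg))
  list(even = C %*% cpinv(exp(-2i * pi * outer(kxSample[, "even"], xg))),
       odd = C %*% cpinv(exp(-2i * pi * outer(kxSample[, "odd"], xg))))
}

#' Regrid ramp-sampled echoes onto the Cartesian kx grid
#'
#' Least-squares interpolation: the non-uniform samples of each echo are
#' explained by an nx-voxel object and re-evaluated at the uniform kx
#' points, which is exact for noiseless support-limited data; echoes of
#' reversed polarity are regridded with their own mirrored operator so all
#' output lines share one orientation.
#'
#' @param samples complex array (nsamp x nEchoes) or
#'   (nsamp x nEchoes x ncoil).
#' @param kxSample two-column matrix of per-sample kx (even, odd), 1/m.
#' @param polarity +1/-1 per echo.
#' @param nx target grid size.
#' @param fov readout field of view, m.
#' @return array (nx x nEchoes [x ncoil]).
#' @export
regridRampSamples <- function(samples, kxSample, polarity, nx, fov) {
  ops <- makeRegridOperators(kxSample, nx, fov)
  d3 <- length(dim(samples)) == 3L
  if (!d3) samples <- array(samples, c(dim(samples), 1L))
  ne <- dim(samples)[2]; nc <- dim(samples)[3]
  out <- array(0i, c(nx, ne, nc))
  ev <- which(polarity > 0); od <- which(polarity < 0)
  for (c0 in seq_len(nc)) {
    if (length(ev))
      out[, ev, c0] <- ops$even %*% samples[, ev, c0]
    if (length(od))
      out[, od, c0] <- ops$odd %*% samples[, od, c0]
  }
  if (d3) out else out[, , 1]
}

#' Zero-filled partial Fourier expansion
#'
#' Places the acquired late ky lines at their grid positions and leaves the
#' early lines zero (no phase estimation, deliberately plain zero-filling).
#'
#' @param kdata array (nx x nAcquired [x ncoil]).
#' @param kyIndex 0-based full-grid ky line index per acquired line.
#' @param ny full phase-encode matrix size.
#' @return array (nx x ny [x ncoil]).
#' @export
pfZerofill <- function(kdata, kyIndex, ny) {
  d3 <- length(dim(kdata)) == 3L
  if (!d3) kdata <- array(kdata, c(dim(kdata), 1L))
  out <- array(0i, c(dim(kdata)[1], ny, dim(kdata)[3]))
  out[, kyIndex + 1L, ] <- kdata
  if (d3) out else out[, , 1]
}

#' Root-sum-of-squares coil combination
#'
#' @param imgs complex or numeric array with coils in the last dimension.
#' @return nonnegative array with the coil dimension dropped.
#' @export
coilCombineRss <- function(imgs) {
  d <- dim(imgs)
  n <- length(d)
  sqrt(apply(abs(imgs)^2, seq_len(n - 1L), sum))
}

#' Calibrate slice-GRAPPA kernels from single-band reference data
#'
#' For every SMS shot group, the single-band slices are given their CAIPI
#' encoding phases and summed into a synthetic collapsed data set; per band
#' and target coil, a k-space kernel is fit by regularized least squares to
#' map the collapsed neighborhood onto that band's (phased) k-space.
#'
#' @param calibration single-band \linkS4class{RawKSpace}.
#' @param bands matrix (smsFactor x nShots) of 0-based slice indices per
#'   SMS shot.
#' @param caipiPhase array (nEchoes x smsFactor x nShots) of encoding
#'   phases, rad.
#' @param kernelSize c(kx, ky) kernel taps (odd).
#' @param pc a \code{\link{phaseCorrection}} applied to the calibration
#'   data first (estimated from its navigators when NULL).
#' @param lambda Tikhonov factor relative to the mean source energy.
#' @return an object of class \code{SliceGrappaKernels}: per-group,
#'   per-band kernel matrices plus relative calibration residuals.
#' @export
calibrateSliceGrappa <- function(calibration, bands, caipiPhase,
                                 kernelSize = c(5, 5), pc = NULL,
                                 lambda = 1e-8) {
  if (!calibration@singleBand)
    stopf("calibration must be single-band data")
  if (any(kernelSize %% 2 != 1)) stopf("kernel dims must be odd")
  p <- calibration@params
  nx <- p@matrixSize[1]
  ne <- length(calibration@kyIndex)
  ncoil <- dim(calibration@data)[2]
  if (is.null(pc)) pc <- estimatePhaseCorrection(calibration)
  calGrid <- calibrationGrids(calibration, pc)   # list per slice: nx*ne*nc
  kh <- (kernelSize[1] - 1) / 2; eh <- (kernelSize[2] - 1) / 2
  if (nx < kernelSize[1] + 2 || ne < kernelSize[2] + 2)
    stopf("calibration region too small for a %dx%d kernel (underdetermined)",
          kernelSize[1], kernelSize[2])
  nShots <- ncol(bands)
  nb <- nrow(bands)
  kernels <- vector("list", nShots)
  resid <- matrix(0, nShots, nb)
  rows <- (1 + kh):(nx - kh)
  cols <- (1 + eh):(ne - eh)
  for (s in seq_len(nShots)) {
    phased <- lapply(seq_len(nb), function(b) {
      ph <- exp(1i * caipiPhase[, b, s])
      calGrid[[bands[b, s] + 1L]] *
        array(rep(ph, each = nx), c(nx, ne, ncoil))
    })
    collapsed <- Reduce(`+`, phased)
    A <- sourceMatrix(collapsed, rows, cols, kh, eh)
    AhA <- crossprod(Conj(A), A)
    reg <- lambda * Re(mean(diag(AhA)))
    AhAr <- AhA + diag(reg, nrow(AhA))
    kernels[[s]] <- vector("list", nb)
    for (b in seq_len(nb)) {
      B <- matrix(phased[[b]][rows, cols, ], ncol = ncoil)
      W <- solve(AhAr, crossprod(Conj(A), B))
      kernels[[s]][[b]] <- W
      resid[s, b] <- sqrt(sum(Mod(A %*% W - B)^2) / max(sum(Mod(B)^2),
                                                        .Machine$double.eps))
    }
  }
  structure(list(kernels = kernels, residual = resid,
                 kernelSize = kernelSize, nCoils = ncoil, bands = bands,
                 caipiPhase = caipiPhase),
            class = "SliceGrappaKernels")
}

# phase-corrected, regridded per-slice calibration k-space
calibrationGrids <- function(calibration, pc) {
  p <- calibration@params
  nx <- p@matrixSize[1]
  img <- which(!calibration@navigator)
  pol <- calibration@polarity[img]
  lapply(seq_len(dim(calibration@data)[4]), function(sh) {
    d <- applyPhaseCorrection(
      array(calibration@data[, , , sh, 1], dim(calibration@data)[1:3]),
      calibration@polarity, pc)
    d <- aperm(d[, , img, drop = FALSE], c(1, 3, 2))  # nsamp x ne x ncoil
    regridRampSamples(d, calibration@kxSample, pol, nx, p@fov[1])
  })
}

# im2col-style source matrix: rows = target points, cols = taps x coils
sourceMatrix <- function(collapsed, rows, cols, kh, eh) {
  nx <- dim(collapsed)[1]; ne <- dim(collapsed)[2]
  ncoil <- dim(collapsed)[3]
  pad <- array(0i, c(nx + 2 * kh, ne + 2 * eh, ncoil))
  pad[(1 + kh):(nx + kh), (1 + eh):(ne + eh), ] <- collapsed
  npts <- length(rows) * length(cols)
  out <- matrix(0i, npts, (2 * kh + 1) * (2 * eh + 1) * ncoil)
  col <- 0L
  for (c0 in seq_len(ncoil)) {
    for (dy in -eh:eh) {
      for (dx in -kh:kh) {
        col <- col + 1L
        out[, col] <- pad[rows + kh + dx, cols + eh + dy, c0]
      }
    }
  }
  out
}

#' Apply slice-GRAPPA kernels to one collapsed SMS shot
#'
#' @param shotData regridded collapsed k-space of one shot
#'   (nx x nEchoes x ncoil).
#' @param kernels a \code{SliceGrappaKernels}.
#' @param shot 1-based SMS shot (group) index selecting the kernel set.
#' @return array (nx x nEchoes x ncoil x smsFactor) of per-band k-space
#'   with the CAIPI phases removed.
#' @export
applySliceGrappa <- function(shotData, kernels, shot) {
  ks <- kernels$kernelSize
  kh <- (ks[1] - 1) / 2; eh <- (ks[2] - 1) / 2
  nx <- dim(shotData)[1]; ne <- dim(shotData)[2]
  ncoil <- dim(shotData)[3]
  if (ncoil != kernels$nCoils) stopf("coil count mismatch with kernels")
  if (shot > ncol(kernels$bands)) stopf("no kernels for shot %d", shot)
  nb <- nrow(kernels$bands)
  A <- sourceMatrix(shotData, seq_len(nx), seq_len(ne), kh, eh)
  out <- array(0i, c(nx, ne, ncoil, nb))
  for (b in seq_len(nb)) {
    est <- A %*% kernels$kernels[[shot]][[b]]
    est <- array(est, c(nx, ne, ncoil))
    ph <- exp(-1i * kernels$caipiPhase[, b, shot])
    out[, , , b] <- est * array(rep(ph, each = nx), c(nx, ne, ncoil))
  }
  out
}

# coset mixing weights: multiplying acquired line iy by F(iy mod cs) is, in
# image space, a sum of copies shifted by j*ny/cs with weights w_j
cosetWeights <- function(caipiPhaseShot, kyIndex, cs) {
  nb <- ncol(caipiPhaseShot)
  Fb <- matrix(0i, cs, nb)
  for (m in 0:(cs - 1)) {
    e <- which(kyIndex %% cs == m)[1]
    Fb[m + 1L, ] <- exp(1i * caipiPhaseShot[e, ])
  }
  w <- matrix(0i, cs, nb)
  for (j in 0:(cs - 1))
    w[j + 1L, ] <- colMeans(Fb * exp(-2i * pi * (0:(cs - 1)) * j / cs))
  w
}

#' SENSE unaliasing of one collapsed SMS shot (image domain)
#'
#' Solves, per readout position and phase-encode coset, the joint linear
#' system over simultaneous bands and CAIPI-shifted in-plane positions
#' (equivalent to 3D SENSE for blipped-CAIPI sampling), using the coil
#' sensitivity maps of the excited slices.  Rank-deficient voxels are
#' zero-filled and flagged; the SENSE g-factor map is returned.
#'
#' @param images collapsed per-coil images (nx x ny x ncoil), i.e. the
#'   unitary inverse FFT of the (zero-filled) collapsed k-space.
#' @param maps complex coil maps for the shot's bands
#'   (nx x ny x ncoil x smsFactor).
#' @param caipiPhaseShot matrix (nEchoes x smsFactor) of encoding phases.
#' @param kyIndex acquired 0-based ky line indices.
#' @param caipiShift CAIPI shift denominator.
#' @return list with \code{images} (complex, nx x ny x smsFactor),
#'   \code{g} (g-factor, same dims) and \code{flagged} (logical).
#' @export
senseUnalias <- function(images, maps, caipiPhaseShot, kyIndex,
                         caipiShift) {
  nx <- dim(images)[1]; ny <- dim(images)[2]; ncoil <- dim(images)[3]
  nb <- dim(maps)[4]
  cs <- if (nb > 1) caipiShift else 1L
  if (ny %% cs != 0) stopf("ny must be divisible by the CAIPI shift")
  dY <- ny / cs
  w <- if (nb > 1) cosetWeights(caipiPhaseShot, kyIndex, cs) else
    matrix(1 + 0i, 1, 1)
  out <- array(0i, c(nx, ny, nb))
  g <- array(0, c(nx, ny, nb))
  flagged <- array(FALSE, c(nx, ny, nb))
  nun <- nb * cs
  neq <- ncoil * cs
  # centering factor from the centered-FFT convention: shifting by j*ny/cs
  # carries the phase exp(2 pi i (ny/2) j / cs)
  eps <- exp(2i * pi * floor(ny / 2) * (0:(cs - 1)) / cs)
  for (x in seq_len(nx)) {
    for (y0 in seq_len(dY)) {
      ys <- y0 + (0:(cs - 1)) * dY
      M <- matrix(0i, neq, nun)
      for (jp in 0:(cs - 1)) {
        for (m in 0:(cs - 1)) {
          j <- (m - jp) %% cs
          for (b in seq_len(nb)) {
            M[jp * ncoil + seq_len(ncoil), (m * nb) + b] <-
              w[j + 1L, b] * eps[j + 1L] * maps[x, ys[m + 1L], , b]
          }
        }
      }
      sv <- svd(M)
      ok <- sv$d > 1e-6 * sv$d[1]
      if (!all(ok)) flagged[x, ys, ] <- TRUE
      P <- sv$v[, ok, drop = FALSE] %*%
        (Conj(t(sv$u[, ok, drop = FALSE])) / sv$d[ok])
      yv <- as.vector(t(matrix(images[x, ys, ], cs, ncoil)))
      u <- P %*% yv
      MhM <- crossprod(Conj(M), M)
      Pi <- P %*% Conj(t(P))     # (M^H M)^-1 for the kept subspace
      gv <- sqrt(pmax(Re(diag(Pi)) * Re(diag(MhM)), 0))
      for (m in 0:(cs - 1)) {
        out[x, ys[m + 1L], ] <- u[m * nb + seq_len(nb)]
        g[x, ys[m + 1L], ] <- gv[m * nb + seq_len(nb)]
      }
    }
  }
  list(images = out, g = g, flagged = flagged)
}

#' Estimate coil sensitivity maps from the single-band reference
#'
#' Direct ratio maps: each coil's zero-filled reference image divided by
#' the root-sum-of-squares combination.
#'
#' @param calibration single-band \linkS4class{RawKSpace}.
#' @param pc optional \code{\link{phaseCorrection}}.
#' @return a \linkS4class{CoilMaps}.
#' @export
estimateCoilMaps <- function(calibration, pc = NULL) {
  p <- calibration@params
  if (is.null(pc)) pc <- estimatePhaseCorrection(calibration)
  nx <- p@matrixSize[1]; ny <- p@matrixSize[2]
  ncoil <- dim(calibration@data)[2]
  grids <- calibrationGrids(calibration, pc)
  maps <- array(0i, c(nx, ny, p@nSlices, ncoil))
  for (sh in seq_along(grids)) {
    j <- calibration@bands[1, sh] + 1L
    full <- pfZerofill(grids[[sh]], calibration@kyIndex, ny)
    imgs <- array(0i, c(nx, ny, ncoil))
    for (c0 in seq_len(ncoil)) imgs[, , c0] <- iftc2(full[, , c0])
    rss <- coilCombineRss(imgs)
    floorv <- 0.05 * max(rss)
    maps[, , j, ] <- imgs / pmax(rss, floorv)
  }
  new("CoilMaps", data = maps)
}

#' Reconstruct the image time series from raw SMS-EPI k-space
#'
#' Fixed deterministic chain: odd/even phase correction (estimated once
#' from the reference segment's navigators), least-squares ramp regridding,
#' SMS unaliasing by slice GRAPPA or SENSE, zero-filled partial Fourier,
#' unitary inverse FFT, root-sum-of-squares coil combination.  Dummy
#' (steady-state) volumes are dropped from the output.
#'
#' @param raw SMS \linkS4class{RawKSpace} (or single-band data, which is
#'   reconstructed directly).
#' @param calibration single-band \linkS4class{RawKSpace}; required for
#'   slice GRAPPA and for SENSE when \code{maps} is NULL.
#' @param method "slice_grappa" or "sense".
#' @param maps optional \linkS4class{CoilMaps} for SENSE (defaults to
#'   ratio maps estimated from the calibration).
#' @param phaseCorrect apply the odd/even correction (default TRUE).
#' @param kernelSize slice-GRAPPA kernel taps.
#' @param outNifti optional path: write the result as NIfTI-1.
#' @return an \linkS4class{ImageTimeSeries}.
#' @export
reconstructTimeseries <- function(raw, calibration = NULL,
                                  method = c("slice_grappa", "sense"),
                                  maps = NULL, phaseCorrect = TRUE,
                                  kernelSize = c(5, 5), outNifti = NULL) {
  method <- match.arg(method)
  p <- raw@params
  nx <- p@matrixSize[1]; ny <- p@matrixSize[2]
  ncoil <- dim(raw@data)[2]
  nShots <- dim(raw@data)[4]
  nVol <- dim(raw@data)[5]
  sms <- nrow(raw@bands)
  if (sms > 1 && method == "slice_grappa" && is.null(calibration))
    stopf("slice_grappa reconstruction requires single-band calibration data")
  if (sms > 1 && method == "sense" && is.null(maps)) {
    if (is.null(calibration))
      stopf("sense reconstruction requires coil maps or calibration data")
    maps <- estimateCoilMaps(calibration)
  }
  pc <- if (!phaseCorrect) phaseCorrection(0, 0) else
    estimatePhaseCorrection(if (!is.null(calibration)) calibration else raw)
  img <- which(!raw@navigator)
  pol <- raw@polarity[img]
  ops <- makeRegridOperators(raw@kxSample, nx, p@fov[1])
  kern <- NULL
  if (sms > 1 && method == "slice_grappa")
    kern <- calibrateSliceGrappa(calibration, raw@bands, raw@caipiPhase,
                                 kernelSize, pc)
  scale <- 1 / sqrt(nx * ny)
  vols <- array(0, c(nx, ny, p@nSlices, nVol))
  ev <- which(pol > 0); od <- which(pol < 0)
  for (v in seq_len(nVol)) {
    for (sh in seq_len(nShots)) {
      d <- applyPhaseCorrection(array(raw@data[, , , sh, v],
                                      dim(raw@data)[1:3]),
                                raw@polarity, pc)
      d <- aperm(d[, , img, drop = FALSE], c(1, 3, 2))  # nsamp x ne x nc
      K <- array(0i, c(nx, length(img), ncoil))
      for (c0 in seq_len(ncoil)) {
        if (length(ev)) K[, ev, c0] <- ops$even %*% d[, ev, c0]
        if (length(od)) K[, od, c0] <- ops$odd %*% d[, od, c0]
      }
      if (sms == 1) {
        full <- pfZerofill(K, raw@kyIndex, ny)
        imgs <- array(0i, c(nx, ny, ncoil))
        for (c0 in seq_len(ncoil)) imgs[, , c0] <- iftc2(full[, , c0])
        vols[, , raw@bands[1, sh] + 1L, v] <- coilCombineRss(imgs) * scale
      } else if (method == "slice_grappa") {
        perBand <- applySliceGrappa(K, kern, sh)
        for (b in seq_len(sms)) {
          full <- pfZerofill(perBand[, , , b], raw@kyIndex, ny)
          imgs <- array(0i, c(nx, ny, ncoil))
          for (c0 in seq_len(ncoil)) imgs[, , c0] <- iftc2(full[, , c0])
          vols[, , raw@bands[b, sh] + 1L, v] <-
            coilCombineRss(imgs) * scale
        }
      } else {
        full <- pfZerofill(K, raw@kyIndex, ny)
        imgs <- array(0i, c(nx, ny, ncoil))
        for (c0 in seq_len(ncoil)) imgs[, , c0] <- iftc2(full[, , c0])
        sm <- maps@data[, , raw@bands[, sh] + 1L, , drop = FALSE]
        sm <- aperm(sm, c(1, 2, 4, 3))   # nx x ny x ncoil x bands
        res <- senseUnalias(imgs, sm, raw@caipiPhase[, , sh],
                            raw@kyIndex, p@caipiShift)
        for (b in seq_len(sms))
          vols[, , raw@bands[b, sh] + 1L, v] <-
            Mod(res$images[, , b]) * scale
      }
    }
  }
  keep <- if (raw@singleBand || nVol <= p@nDummies) seq_len(nVol) else
    (p@nDummies + 1L):nVol
  ts <- imageTimeSeries(vols[, , , keep, drop = FALSE],
                        c(p@fov[1] / nx, p@fov[2] / ny, p@sliceThickness),
                        p@tr)
  if (!is.null(outNifti)) writeTimeSeriesNifti(ts, outNifti)
  ts
}

#' Write / read an image time series as NIfTI-1
#'
#' @param ts an \linkS4class{ImageTimeSeries}.
#' @param path file path (.nii or .nii.gz).
#' @return the path (write) or an \linkS4class{ImageTimeSeries} (read).
#' @export
writeTimeSeriesNifti <- function(ts, path) {
  im <- RNifti::asNifti(ts@data)
  RNifti::pixdim(im) <- c(ts@voxelSize * 1000, ts@tr)
  RNifti::pixunits(im) <- c("mm", "s")
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' @rdname writeTimeSeriesNifti
#' @export
readTimeSeriesNifti <- function(path) {
  im <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(im)
  a <- array(as.numeric(im), dim(im))
  if (length(dim(a)) == 3L) dim(a) <- c(dim(a), 1L)
  imageTimeSeries(a, pd[1:3] / 1000, if (length(pd) >= 4) pd[4] else 1)
}
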