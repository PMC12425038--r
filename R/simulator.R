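# Synthetic-data generation: digital ball phantoms, smooth ring-array coil
# sensitivity maps, and forward simulation of the SMS-EPI acquisition.  The
# forward model is a discrete-voxel DFT evaluated at the exact (possibly
# ramp-sampled) trajectory points, so that noiseless data admit an exact
# linear reconstruction oracle.  Slices are treated as thin planes at the
# excited slice centers; odd-polarity echoes can carry an injected
# constant/linear phase error (the EPI ghost mechanism), and a
# multiplicative per-volume drift and seeded complex Gaussian noise model
# the slow instabilities the QA battery is designed to detect.

#' Digital phantom
#'
#' @slot data nonnegative 3-D intensity grid (nx, ny, nz)
#' @slot voxelSize (dx, dy, dz), m
#' @export
setClass("DigitalPhantom", representation(
  data = "array", voxelSize = "numeric"))

setValidity("DigitalPhantom", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be 3-D")
  if (any(object@data < 0)) return("intensities must be nonnegative")
  TRUE
})

#' Complex coil sensitivity maps
#'
#' Root-sum-of-squares over coils is 1 at every voxel.
#'
#' @slot data complex array (nx, ny, nz, ncoils)
#' @export
setClass("CoilMaps", representation(data = "array"))

setMethod("show", "CoilMaps", function(object) {
  d <- dim(object@data)
  cat(sprintf("CoilMaps: %d coils on a %d x %d x %d grid\n",
              d[4], d[1], d[2], d[3]))
})

#' Acquisition noise / instability model
#'
#' @param sigma complex Gaussian noise level: standard deviation of the
#'   real and imaginary parts of every k-space sample, per coil.
#' @param theta0 constant phase error on odd-polarity echoes, rad.
#' @param theta1 linear phase error on odd-polarity echoes, rad per kx
#'   sample (about the readout center).
#' @param drift multiplicative signal drift across the run (fraction;
#'   volume v is scaled by 1 + drift * (v - 1) / (nvol - 1)).
#' @param seed RNG seed; fixes all randomness of the simulation.
#' @return an object of class \code{AcqNoiseModel}.
#' @export
acqNoiseModel <- function(sigma = 0, theta0 = 0, theta1 = 0, drift = 0,
                          seed = 1L) {
  if (sigma < 0) stopf("sigma must be nonnegative")
  structure(list(sigma = sigma, theta0 = theta0, theta1 = theta1,
                 drift = drift, seed = as.integer(seed)),
            class = "AcqNoiseModel")
}

# slice-center z coordinates of all slices (matches the sequence's
# excitation frequency offsets)
sliceZAll <- function(p) sliceZ(p, seq_len(p@nSlices) - 1)

#' Make a uniform ball phantom
#'
#' A uniform sphere with a linearly anti-aliased boundary, emulating the
#' uniform QA ball phantom, on the protocol's voxel grid.
#'
#' @param p a \linkS4class{ProtocolParams} (defines grid and voxel size).
#' @param radius sphere radius, m; must be < half the smallest FOV extent.
#' @param intensity interior intensity.
#' @return a \linkS4class{DigitalPhantom}.
#' @export
makeBallPhantom <- function(p, radius = 0.35 * min(p@fov),
                            intensity = 100) {
  if (radius >= min(p@fov) / 2)
    stopf("radius %.3g m too large for FOV (max %.3g m)", radius,
          min(p@fov) / 2)
  nx <- p@matrixSize[1]; ny <- p@matrixSize[2]; nz <- p@nSlices
  x <- gridCoords(nx, p@fov[1]); y <- gridCoords(ny, p@fov[2])
  z <- sliceZAll(p)
  vx <- c(p@fov[1] / nx, p@fov[2] / ny, p@sliceThickness)
  dd <- sqrt(outer(outer(x^2, y^2, `+`), z^2, `+`))
  frac <- (dd <= radius) * 1
  # supersample the boundary shell for an accurately anti-aliased surface
  shell <- which(abs(dd - radius) <= sqrt(sum(vx^2)), arr.ind = TRUE)
  if (nrow(shell) && radius > 0) {
    ss <- (seq_len(4) - 2.5) / 4
    off <- as.matrix(expand.grid(ss * vx[1], ss * vx[2], ss * vx[3]))
    for (i in seq_len(nrow(shell))) {
      ctr <- c(x[shell[i, 1]], y[shell[i, 2]], z[shell[i, 3]])
      pts <- sweep(off, 2, ctr, `+`)
      frac[shell[i, 1], shell[i, 2], shell[i, 3]] <-
        mean(rowSums(pts^2) <= radius^2)
    }
  }
  new("DigitalPhantom", data = intensity * frac, voxelSize = vx)
}

#' Make smooth ring-array coil sensitivity maps
#'
#' Coils are Gaussian lobes centered on a ring around the FOV with mild
#' random low-order polynomial modulation and smooth phase; maps are
#' normalized to unit root-sum-of-squares at every voxel.
#'
#' @param p a \linkS4class{ProtocolParams}.
#' @param ncoils number of coils (>= 1).
#' @param seed RNG seed (same seed, same maps).
#' @return a \linkS4class{CoilMaps}.
#' @export
makeCoilMaps <- function(p, ncoils = 8L, seed = 1L) {
  if (ncoils < 1) stopf("ncoils must be >= 1")
  nx <- p@matrixSize[1]; ny <- p@matrixSize[2]; nz <- p@nSlices
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  x <- gridCoords(nx, p@fov[1]) / p@fov[1]
  y <- gridCoords(ny, p@fov[2]) / p@fov[2]
  z <- sliceZAll(p) / max(p@fov[3], p@sliceThickness)
  maps <- array(0i, c(nx, ny, nz, ncoils))
  X <- array(rep(x, times = ny * nz), c(nx, ny, nz))
  Y <- array(rep(rep(y, each = nx), times = nz), c(nx, ny, nz))
  Z <- array(rep(z, each = nx * ny), c(nx, ny, nz))
  for (c0 in seq_len(ncoils)) {
    ang <- 2 * pi * (c0 - 1) / ncoils
    cx <- 0.55 * cos(ang); cy <- 0.55 * sin(ang)
    sig <- 0.45 + 0.05 * stats::runif(1)
    mag <- exp(-((X - cx)^2 + (Y - cy)^2 + 0.3 * Z^2) / (2 * sig^2)) *
      (1 + 0.15 * stats::runif(1, -1, 1) * X +
         0.15 * stats::runif(1, -1, 1) * Y)
    ph <- ang + pi * (stats::runif(1, -1, 1) * X +
                        stats::runif(1, -1, 1) * Y +
                        0.3 * stats::runif(1, -1, 1) * Z)
    maps[, , , c0] <- mag * exp(1i * ph)
  }
  rss <- sqrt(apply(abs(maps)^2, 1:3, sum))
  for (c0 in seq_len(ncoils)) maps[, , , c0] <- maps[, , , c0] / rss
  new("CoilMaps", data = maps)
}

# encoding phase e^{i phi(e,b)} = exp(-2 pi i kz(e) z_b) for a shot's bands
caipiPhaseFor <- function(kzEcho, zBands) {
  outer(kzEcho, zBands, function(kz, z) -2 * pi * kz * z)
}

#' Simulate the SMS-EPI acquisition
#'
#' Evaluates the discrete-voxel DFT of phantom x coil maps at the exact
#' readout trajectory (per-sample kx including ramps, per-echo ky, CAIPI
#' kz phases per band), for the SMS segment and the matching single-band
#' reference segment.  Odd-polarity echoes are multiplied by the noise
#' model's constant/linear phase error; each volume is scaled by the drift
#' factor; seeded complex Gaussian noise is added per sample and coil.
#'
#' @param phantom a \linkS4class{DigitalPhantom}.
#' @param maps a \linkS4class{CoilMaps}.
#' @param p a \linkS4class{ProtocolParams}.
#' @param readout an \code{EPIReadout} from \code{\link{designEpiReadout}}.
#' @param noise an \code{\link{acqNoiseModel}}.
#' @return list with elements \code{sms} (volumes including dummies) and
#'   \code{reference} (single-band calibration segment), both
#'   \linkS4class{RawKSpace}.
#' @export
simulateAcquisition <- function(phantom, maps, p, readout,
                                noise = acqNoiseModel()) {
  nx <- p@matrixSize[1]; ny <- p@matrixSize[2]
  if (!all(dim(phantom@data) == c(nx, ny, p@nSlices)))
    stopf("phantom grid %s does not match protocol %dx%dx%d",
          paste(dim(phantom@data), collapse = "x"), nx, ny, p@nSlices)
  if (!all(dim(maps@data)[1:3] == dim(phantom@data)))
    stopf("coil map grid does not match the phantom")
  ncoil <- dim(maps@data)[4]
  ro <- readout
  ne <- ro$nEchoes; nNav <- ro$nNavigators; netot <- nNav + ne
  nsamp <- ro$nSamples
  nShots <- p@nSlices / p@smsFactor
  nVolTot <- p@nDummies + p@nVolumes

  xg <- gridCoords(nx, p@fov[1])
  yg <- gridCoords(ny, p@fov[2])
  kyE <- c(rep(0, nNav), (ro$kyIndex - ny / 2) / p@fov[2])
  polarity <- rep_len(c(1, -1), netot)
  kzImg <- ro$kzEcho
  Ey <- exp(-2i * pi * outer(yg, kyE))              # ny x netot
  AxE <- exp(-2i * pi * outer(ro$kxSample[, "even"], xg))  # nsamp x nx
  AxO <- exp(-2i * pi * outer(ro$kxSample[, "odd"], xg))
  oddIdx <- which(polarity < 0)

  # per (slice, coil) echo signals, nsamp x netot
  sig <- array(0i, c(nsamp, netot, ncoil, p@nSlices))
  for (j in seq_len(p@nSlices)) {
    for (c0 in seq_len(ncoil)) {
      W <- phantom@data[, , j] * maps@data[, , j, c0]
      G <- W %*% Ey
      Se <- AxE %*% G
      if (length(oddIdx)) {
        So <- AxO %*% G[, oddIdx, drop = FALSE]
        Se[, oddIdx] <- So
      }
      sig[, , c0, j] <- Se
    }
  }
  # odd-echo phase error (ghost mechanism)
  if (noise$theta0 != 0 || noise$theta1 != 0) {
    ph <- exp(1i * (noise$theta0 +
                      noise$theta1 * (seq_len(nsamp) - (nsamp + 1) / 2)))
    sig[, oddIdx, , ] <- sig[, oddIdx, , , drop = FALSE] *
      array(ph, c(nsamp, length(oddIdx), ncoil, p@nSlices))
  }

  zAll <- sliceZAll(p)
  bands <- vapply(seq_len(nShots) - 1L,
                  function(s) as.integer(s + (seq_len(p@smsFactor) - 1L) *
                                           nShots),
                  integer(p@smsFactor))
  bands <- matrix(bands, nrow = p@smsFactor)
  # CAIPI phase referenced to each group's first band (the receiver tracks
  # the blip phase at that slice), so the remaining inter-band phase is an
  # exactly linear ky ramp: band b is shifted by (b-1) * FOV / caipiShift
  caipi <- array(0, c(ne, p@smsFactor, nShots))
  for (s in seq_len(nShots))
    caipi[, , s] <- caipiPhaseFor(kzImg, zAll[bands[, s] + 1L] -
                                    zAll[bands[1L, s] + 1L])

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(noise$seed)
  cnoise <- function(n) complex(real = stats::rnorm(n, 0, noise$sigma),
                                imaginary = stats::rnorm(n, 0, noise$sigma))

  # single-band reference segment (one "volume")
  refData <- array(0i, c(nsamp, ncoil, netot, p@nSlices, 1L))
  for (j in seq_len(p@nSlices))
    refData[, , , j, 1] <- aperm(array(sig[, , , j],
                                       c(nsamp, netot, ncoil)), c(1, 3, 2))
  if (noise$sigma > 0)
    refData <- refData + array(cnoise(length(refData)), dim(refData))

  # SMS segment: per-shot band sums with CAIPI phases, then volumes
  shotSig <- array(0i, c(nsamp, ncoil, netot, nShots))
  for (s in seq_len(nShots)) {
    acc <- array(0i, c(nsamp, netot, ncoil))
    for (b in seq_len(p@smsFactor)) {
      w <- c(rep(1 + 0i, nNav), exp(1i * caipi[, b, s]))
      acc <- acc + array(sig[, , , bands[b, s] + 1L],
                         c(nsamp, netot, ncoil)) *
        array(rep(w, each = nsamp), c(nsamp, netot, ncoil))
    }
    shotSig[, , , s] <- aperm(acc, c(1, 3, 2))
  }
  smsData <- array(0i, c(nsamp, ncoil, netot, nShots, nVolTot))
  for (v in seq_len(nVolTot)) {
    f <- if (nVolTot > 1) 1 + noise$drift * (v - 1) / (nVolTot - 1) else 1
    smsData[, , , , v] <- f * shotSig
  }
  if (noise$sigma > 0)
    smsData <- smsData + array(cnoise(length(smsData)), dim(smsData))

  navFlag <- c(rep(TRUE, nNav), rep(FALSE, ne))
  mk <- function(data, bandsM, caipiA, single) {
    new("RawKSpace", data = data, kxSample = ro$kxSample,
        kyIndex = ro$kyIndex, navigator = navFlag, polarity = polarity,
        bands = bandsM, caipiPhase = caipiA, kzEcho = kzImg,
        dwell = ro$dwell, params = p, singleBand = single)
  }
  list(
    sms = mk(smsData, bands, caipi, FALSE),
    reference = mk(refData,
                   matrix(seq_len(p@nSlices) - 1L, nrow = 1L),
                   array(0, c(ne, 1L, p@nSlices)), TRUE))
}
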