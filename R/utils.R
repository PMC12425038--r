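#' @import methods
#' @importFrom stats rnorm sd lm coef fft mvfft nextn sd quantile setNames
#' @importFrom utils head tail packageVersion modifyList
NULL

# Proton gyromagnetic ratio, Hz/T. All gradient amplitudes in this package are
# gamma-normalized (Hz/m); use these helpers at the user-facing boundary only.
GAMMA_HZ_PER_T <- 42.576e6

#' Convert gradient amplitudes between mT/m and gamma-normalized Hz/m
#'
#' Internally all gradients are stored gamma-normalized (Hz/m), following the
#' public Pulseq convention; these helpers convert to and from physical
#' units assuming the proton gyromagnetic ratio (42.576 MHz/T).
#'
#' @param g_mT_m gradient amplitude(s) in mT/m (or slew in T/m/s for
#'   \code{slewToHz}).
#' @return numeric vector in Hz/m (or Hz/m/s).
#' @examples
#' mTmToHz(33)           # ~1.405e6 Hz/m
#' hzToMTm(mTmToHz(33))  # 33
#' @export
mTmToHz <- function(g_mT_m) g_mT_m * 1e-3 * GAMMA_HZ_PER_T

#' @rdname mTmToHz
#' @param g_Hz_m gradient amplitude(s) in Hz/m.
#' @export
hzToMTm <- function(g_Hz_m) g_Hz_m / GAMMA_HZ_PER_T * 1e3

#' @rdname mTmToHz
#' @param s_T_m_s slew rate(s) in T/m/s.
#' @export
slewToHz <- function(s_T_m_s) s_T_m_s * GAMMA_HZ_PER_T

#' @rdname mTmToHz
#' @param s_Hz_m_s slew rate(s) in Hz/m/s.
#' @export
hzToSlew <- function(s_Hz_m_s) s_Hz_m_s / GAMMA_HZ_PER_T

# round `x` seconds up to an integer multiple of `raster` seconds
ceilToRaster <- function(x, raster) {
  n <- ceiling(x / raster - 1e-9)
  n * raster
}

roundToRaster <- function(x, raster) round(x / raster) * raster

# TRUE if x is an integer multiple of raster (to relative tolerance)
onRaster <- function(x, raster, tol = 1e-6) {
  abs(x / raster - round(x / raster)) < tol
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Centered unitary FFT helpers.  ky = 0 / x = 0 sit at index floor(n/2) + 1
# (0-based index n/2), matching the simulator's voxel/frequency grids.
fftshift1 <- function(x) {
  n <- length(x)
  x[c((floor(n / 2) + 1L):n, seq_len(floor(n / 2)))]
}

ifftshift1 <- function(x) {
  n <- length(x)
  x[c((ceiling(n / 2) + 1L):n, seq_len(ceiling(n / 2)))]
}

# centered unitary 1D FFT along columns of a matrix (or of a vector)
ftc1 <- function(x) {
  v <- is.null(dim(x))
  if (v) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  sh <- function(m, idx) m[idx, , drop = FALSE]
  i1 <- c((ceiling(n / 2) + 1L):n, seq_len(ceiling(n / 2)))  # ifftshift
  i2 <- c((floor(n / 2) + 1L):n, seq_len(floor(n / 2)))      # fftshift
  out <- sh(mvfft(sh(x, i1)), i2) / sqrt(n)
  if (v) drop(out) else out
}

iftc1 <- function(x) {
  v <- is.null(dim(x))
  if (v) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  i1 <- c((ceiling(n / 2) + 1L):n, seq_len(ceiling(n / 2)))
  i2 <- c((floor(n / 2) + 1L):n, seq_len(floor(n / 2)))
  out <- x[i1, , drop = FALSE]
  out <- mvfft(out, inverse = TRUE) / sqrt(n)
  out <- out[i2, , drop = FALSE]
  if (v) drop(out) else out
}

# centered unitary 2D FFT of a matrix
ftc2 <- function(x) t(ftc1(t(ftc1(x))))
iftc2 <- function(x) t(iftc1(t(iftc1(x))))

# voxel center coordinates (m) for n voxels of size d, x = 0 at index n/2
# (0-based), consistent with the centered FFT convention above
gridCoords <- function(n, fov) ((seq_len(n) - 1L) - floor(n / 2)) * (fov / n)

# frequency grid (1/m): k = (idx - n/2)/fov
kGrid <- function(n, fov) ((seq_len(n) - 1L) - floor(n / 2)) / fov

nrmse <- function(x, ref) {
  sqrt(sum(abs(x - ref)^2) / max(sum(abs(ref)^2), .Machine$double.eps))
}
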