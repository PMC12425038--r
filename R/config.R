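# Plain-text configuration: a minimal flat-TOML reader (sections, scalar /
# string / boolean / array values) for the hardware-limits and protocol
# profiles.  Hardware profiles are written in SI units (T/m, T/m/s, s) and
# converted to the gamma-normalized internal units on read.

#' Read a flat TOML configuration file
#'
#' Supports \code{[section]} headers, \code{key = value} pairs with
#' numeric, boolean, quoted-string and flat-array values, and comments.
#'
#' @param path file path.
#' @return a named list; sectioned keys are nested one level.
#' @export
readToml <- function(path) {
  lines <- readLines(path)
  out <- list()
  section <- NULL
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[[A-Za-z0-9_.]+\\]$", ln)) {
      section <- gsub("[\\[\\]]", "", ln, perl = TRUE)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3)
      stopf("cannot parse line %d of %s: '%s'", i, path, lines[i])
    key <- m[2]; val <- trimws(m[3])
    parseScalar <- function(v) {
      v <- trimws(v)
      if (grepl('^".*"$', v)) return(gsub('^"|"$', "", v))
      if (v %in% c("true", "false")) return(v == "true")
      n <- suppressWarnings(as.numeric(v))
      if (is.na(n)) stopf("cannot parse value '%s' in %s", v, path)
      n
    }
    value <- if (grepl("^\\[.*\\]$", val)) {
      parts <- strsplit(gsub("^\\[|\\]$", "", val), ",")[[1]]
      vv <- lapply(parts, parseScalar)
      if (all(vapply(vv, is.numeric, TRUE))) unlist(vv) else vv
    } else parseScalar(val)
    if (is.null(section)) out[[key]] <- value
    else out[[section]][[key]] <- value
  }
  out
}

#' Read a hardware-limits profile
#'
#' The profile is a TOML file with the limit fields in SI units:
#' \code{max_rf} (T), \code{max_gradient} (T/m), \code{max_slew} (T/m/s),
#' and the dead/ringdown/raster times in seconds.  Values are converted to
#' the gamma-normalized internal units.
#'
#' @param path TOML file path.
#' @return a \linkS4class{SystemLimits}.
#' @export
readSystemLimits <- function(path) {
  cfg <- readToml(path)
  if (!is.null(cfg$limits)) cfg <- cfg$limits
  g <- function(key, default) if (is.null(cfg[[key]])) default else cfg[[key]]
  systemLimits(
    maxRf = g("max_rf", 20e-6) * GAMMA_HZ_PER_T,
    rfDeadTime = g("rf_dead_time", 100e-6),
    rfRingdownTime = g("rf_ringdown_time", 60e-6),
    rfRasterTime = g("rf_raster_time", 1e-6),
    maxGrad = g("max_gradient", 50e-3) * GAMMA_HZ_PER_T,
    maxSlew = g("max_slew", 200) * GAMMA_HZ_PER_T,
    gradRasterTime = g("grad_raster_time", 10e-6),
    adcDeadTime = g("adc_dead_time", 20e-6),
    adcRasterTime = g("adc_raster_time", 100e-9),
    blockDurationRaster = g("block_duration_raster", 10e-6))
}

#' Read a protocol-parameter profile
#'
#' TOML keys mirror \code{\link{protocolParams}} arguments in snake_case
#' (\code{fov} in m, \code{flip_angle_deg} in degrees); missing keys take
#' the ABCD-matched defaults.
#'
#' @param path TOML file path.
#' @return a \linkS4class{ProtocolParams}.
#' @export
readProtocolParams <- function(path) {
  cfg <- readToml(path)
  if (!is.null(cfg$protocol)) cfg <- cfg$protocol
  d <- protocolParams()
  g <- function(key, default) if (is.null(cfg[[key]])) default else cfg[[key]]
  protocolParams(
    fov = g("fov", d@fov),
    matrixSize = g("matrix", d@matrixSize),
    nSlices = g("n_slices", d@nSlices),
    sliceThickness = g("slice_thickness", d@sliceThickness),
    smsFactor = g("sms_factor", d@smsFactor),
    tr = g("tr", d@tr),
    partialFourier = g("partial_fourier", d@partialFourier),
    flipAngle = g("flip_angle_deg", d@flipAngle * 180 / pi) * pi / 180,
    nVolumes = g("n_volumes", d@nVolumes),
    caipiShift = g("caipi_shift", d@caipiShift),
    pnsDerate = g("pns_derate", d@pnsDerate),
    nDummies = g("n_dummies", d@nDummies),
    nNavigators = g("n_navigators", d@nNavigators))
}
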