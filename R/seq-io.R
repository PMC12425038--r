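# Pulseq-style .seq text serialization (v1.4-compatible dialect).
# Sections: [VERSION], [DEFINITIONS], [BLOCKS], [RF], [GRADIENTS], [TRAP],
# [ADC], [SHAPES].  Arbitrary-gradient entries carry explicit first/last
# boundary samples (as in newer dialect revisions) because the in-memory
# model uses them for the continuity invariant.  Event entries are
# deduplicated by content, so repeated waveforms share one library entry.

fnum <- function(x) sprintf("%.10g", x)

# run-length compression of a shape's derivative (public Pulseq scheme):
# runs of equal derivative values are encoded as value, value, extra-count.
compressShape <- function(w) {
  d <- c(w[1], diff(w))
  ds <- fnum(d)  # run detection on the serialized representation, so the
  n <- length(d) # decoder's exact-equality pair rule always agrees
  out <- numeric(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && ds[j + 1L] == ds[i]) j <- j + 1L
    len <- j - i + 1L
    if (len == 1L) out <- c(out, d[i])
    else out <- c(out, d[i], d[i], len - 2L)  # pair + extra-repeat count
    i <- j + 1L
  }
  if (length(out) >= length(w)) w else out  # store raw if compression loses
}

# decompression: samples were stored either raw (length == numSamples) or as
# RLE-compressed derivative triples
expandShape <- function(vals, numSamples) {
  if (length(vals) == numSamples) return(vals)
  d <- numeric(numSamples)
  m <- 0L
  i <- 1L
  n <- length(vals)
  while (i <= n) {
    v <- vals[i]
    if (i < n && vals[i + 1L] == v) {  # a pair announces a repeat count next
      if (i + 2L > n) stop("shape decompression: truncated repeat count")
      cnt <- 2L + as.integer(round(vals[i + 2L]))
      if (m + cnt > numSamples)
        stop("shape decompression overruns declared sample count")
      d[(m + 1L):(m + cnt)] <- v
      m <- m + cnt
      i <- i + 3L
    } else {
      m <- m + 1L
      if (m > numSamples)
        stop("shape decompression overruns declared sample count")
      d[m] <- v
      i <- i + 1L
    }
  }
  if (m != numSamples)
    stop("shape decompression yields wrong sample count")
  cumsum(d)
}

# simple content-addressed library: signature string -> integer id.
# Long signatures (full waveforms) are bucketed by a cheap checksum; the
# full signature is compared inside the bucket, so collisions are safe.
newLibrary <- function() {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  env$entries <- list()
  env$buckets <- new.env(parent = emptyenv())
  env
}

sigKey <- function(sig) {
  b <- utf8ToInt(sig)
  sprintf("k%.0f_%.0f_%d", sum(b) %% 1e9,
          sum(b * (seq_along(b) %% 8191)) %% 1e9, length(b))
}

libId <- function(lib, signature, payload) {
  key <- sigKey(signature)
  bucket <- lib$buckets[[key]]
  if (!is.null(bucket))
    for (ent in bucket) if (ent$sig == signature) return(ent$id)
  lib$n <- lib$n + 1L
  lib$buckets[[key]] <- c(bucket, list(list(sig = signature, id = lib$n)))
  lib$entries[[lib$n]] <- payload
  lib$n
}

#' Write a sequence to a Pulseq-style .seq text file
#'
#' Serialization is deterministic: writing the same sequence twice produces
#' byte-identical files.  Identical waveforms are stored once in the shape
#' library.
#'
#' @param seq a \linkS4class{PulseSequence}.
#' @param path output file path.
#' @return the path, invisibly.
#' @seealso \code{\link{readSeq}}
#' @export
writeSeq <- function(seq, path) {
  lim <- seq@limits
  shapes <- newLibrary()
  rfs <- newLibrary(); traps <- newLibrary(); grads <- newLibrary()
  adcs <- newLibrary()

  shapeId <- function(w) {
    libId(shapes, paste(fnum(w), collapse = ","), w)
  }

  blockRows <- character(length(seq@blocks))
  for (i in seq_along(seq@blocks)) {
    b <- seq@blocks[[i]]
    rfId <- gxId <- gyId <- gzId <- adcId <- 0L
    if (!is.null(b@rf)) {
      rf <- b@rf
      amp <- max(Mod(rf@signal))
      mag <- if (amp > 0) Mod(rf@signal) / amp else Mod(rf@signal)
      ph <- (Arg(rf@signal) / (2 * pi)) %% 1
      mid <- shapeId(mag)
      pid <- shapeId(ph)
      defaultT <- (seq_along(rf@t) - 0.5) * lim@rfRasterTime
      tid <- if (max(abs(rf@t - defaultT)) < 1e-12) 0L else
        shapeId(rf@t / lim@rfRasterTime)
      sig <- paste(fnum(c(amp, mid, pid, tid, rf@delay, rf@freqOffset,
                          rf@ppmOffset, rf@phaseOffset)), collapse = " ")
      rfId <- libId(rfs, sig, sig)
    }
    for (ch in c("x", "y", "z")) {
      g <- slot(b, paste0("g", ch))
      if (is.null(g)) next
      if (is(g, "TrapGradient")) {
        sig <- paste(fnum(c(g@amplitude, g@riseTime * 1e6, g@flatTime * 1e6,
                            g@fallTime * 1e6, g@delay * 1e6)), collapse = " ")
        id <- -libId(traps, sig, sig)  # negative marks trapezoid entries
      } else {
        amp <- max(abs(g@waveform), abs(g@first), abs(g@last))
        sc <- if (amp > 0) amp else 1
        sid <- shapeId(g@waveform / sc)
        sig <- paste(fnum(c(amp, g@first / sc, g@last / sc, sid,
                            g@delay * 1e6)), collapse = " ")
        id <- libId(grads, sig, sig)
      }
      if (ch == "x") gxId <- id else if (ch == "y") gyId <- id else gzId <- id
    }
    if (!is.null(b@adc)) {
      a <- b@adc
      sig <- paste(fnum(c(a@numSamples, a@dwell * 1e9, a@delay * 1e6,
                          a@freqOffset, a@phaseOffset)), collapse = " ")
      adcId <- libId(adcs, sig, sig)
    }
    blockRows[i] <- sprintf("%d %d %d %d %d %d %d 0", i,
                            round(b@duration / lim@blockDurationRaster),
                            rfId, gxId, gyId, gzId, adcId)
  }

  defs <- seq@definitions
  defs$TotalDuration <- sequenceDuration(seq)
  limDefs <- list(
    GradientRasterTime = lim@gradRasterTime,
    RadiofrequencyRasterTime = lim@rfRasterTime,
    AdcRasterTime = lim@adcRasterTime,
    BlockDurationRaster = lim@blockDurationRaster,
    MaxGrad = lim@maxGrad, MaxSlew = lim@maxSlew, MaxRF = lim@maxRf,
    RFDeadTime = lim@rfDeadTime, RFRingdownTime = lim@rfRingdownTime,
    AdcDeadTime = lim@adcDeadTime)
  defs <- defs[setdiff(names(defs), c(names(limDefs), "unknownSections"))]
  defs <- c(limDefs, defs)
  defLines <- vapply(names(defs), function(k) {
    v <- defs[[k]]
    paste(k, if (is.character(v)) v else paste(fnum(v), collapse = " "))
  }, "")

  lines <- c(
    "# Pulseq sequence file",
    "# Written by smsepi",
    "",
    "[VERSION]", "major 1", "minor 4", "revision 1", "",
    "[DEFINITIONS]", unname(defLines), "",
    "[BLOCKS]", blockRows, "")
  if (rfs$n) lines <- c(lines, "[RF]",
    vapply(seq_len(rfs$n), function(i) paste(i, rfs$entries[[i]]), ""), "")
  if (grads$n) lines <- c(lines, "[GRADIENTS]",
    vapply(seq_len(grads$n), function(i) paste(i, grads$entries[[i]]), ""), "")
  if (traps$n) lines <- c(lines, "[TRAP]",
    vapply(seq_len(traps$n), function(i) paste(i, traps$entries[[i]]), ""), "")
  if (adcs$n) lines <- c(lines, "[ADC]",
    vapply(seq_len(adcs$n), function(i) paste(i, adcs$entries[[i]]), ""), "")
  if (shapes$n) {
    sh <- unlist(lapply(seq_len(shapes$n), function(i) {
      w <- shapes$entries[[i]]
      c(sprintf("shape_id %d", i), sprintf("num_samples %d", length(w)),
        fnum(compressShape(w)), "")
    }))
    lines <- c(lines, "[SHAPES]", sh)
  }
  con <- file(path, "wb")  # binary mode: LF endings on every platform
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

parseNums <- function(line, lineNo) {
  v <- suppressWarnings(as.numeric(strsplit(trimws(line), "\\s+")[[1]]))
  if (any(is.na(v)))
    stopf("parse error at line %d: expected numeric fields in '%s'",
          lineNo, line)
  v
}

#' Read a Pulseq-style .seq file
#'
#' Reconstructs the full block/event model.  Unknown sections are not
#' silently dropped: their raw lines are kept under
#' \code{seqDefinitions(seq)$unknownSections} and reported with a message.
#' Malformed headers, undefined shape/event references and unsupported
#' versions raise parse errors naming the offending line.
#'
#' @param path path to a .seq file.
#' @return a \linkS4class{PulseSequence}.
#' @export
readSeq <- function(path) {
  lines <- readLines(path)
  stripped <- sub("#.*$", "", lines)
  isHeader <- grepl("^\\s*\\[", stripped)
  badHeader <- isHeader & !grepl("^\\s*\\[[A-Za-z0-9_]+\\]\\s*$", stripped)
  if (any(badHeader))
    stopf("parse error at line %d: malformed section header '%s'",
          which(badHeader)[1], lines[which(badHeader)[1]])
  headerIdx <- which(isHeader)
  if (!length(headerIdx)) stopf("parse error: no sections found")
  sections <- list()
  secName <- toupper(gsub("[\\[\\]\\s]", "", stripped[headerIdx], perl = TRUE))
  for (i in seq_along(headerIdx)) {
    from <- headerIdx[i] + 1L
    to <- if (i < length(headerIdx)) headerIdx[i + 1L] - 1L else length(lines)
    body <- seq(from, length.out = max(0, to - from + 1L))
    body <- body[nzchar(trimws(stripped[body]))]
    sections[[secName[i]]] <- list(lines = stripped[body], lineNo = body)
  }
  known <- c("VERSION", "DEFINITIONS", "BLOCKS", "RF", "GRADIENTS", "TRAP",
             "ADC", "SHAPES", "SIGNATURE", "EXTENSIONS")
  unknown <- setdiff(names(sections), known)

  ver <- sections$VERSION
  if (is.null(ver)) stopf("parse error: missing [VERSION] section")
  getv <- function(key) {
    ln <- grep(paste0("^\\s*", key, "\\b"), ver$lines, value = TRUE)
    if (!length(ln)) return(NA_real_)
    as.numeric(strsplit(trimws(ln[1]), "\\s+")[[1]][2])
  }
  if (!identical(getv("major"), 1) || !identical(getv("minor"), 4))
    stopf("version mismatch at line %d: this reader supports v1.4 (found %s.%s)",
          ver$lineNo[1], getv("major"), getv("minor"))

  defs <- list()
  for (j in seq_along(sections$DEFINITIONS$lines)) {
    ln <- trimws(sections$DEFINITIONS$lines[j])
    parts <- strsplit(ln, "\\s+")[[1]]
    key <- parts[1]
    vals <- suppressWarnings(as.numeric(parts[-1]))
    defs[[key]] <- if (any(is.na(vals))) paste(parts[-1], collapse = " ") else vals
  }
  getdef <- function(key, default) {
    v <- defs[[key]]
    if (is.null(v)) default else v
  }
  lim <- systemLimits(
    maxRf = getdef("MaxRF", 20e-6 * GAMMA_HZ_PER_T),
    rfDeadTime = getdef("RFDeadTime", 100e-6),
    rfRingdownTime = getdef("RFRingdownTime", 60e-6),
    rfRasterTime = getdef("RadiofrequencyRasterTime", 1e-6),
    maxGrad = getdef("MaxGrad", mTmToHz(50)),
    maxSlew = getdef("MaxSlew", slewToHz(200)),
    gradRasterTime = getdef("GradientRasterTime", 10e-6),
    adcDeadTime = getdef("AdcDeadTime", 20e-6),
    adcRasterTime = getdef("AdcRasterTime", 100e-9),
    blockDurationRaster = getdef("BlockDurationRaster", 10e-6))
  userDefs <- defs[setdiff(names(defs),
    c("MaxRF", "RFDeadTime", "RFRingdownTime", "RadiofrequencyRasterTime",
      "MaxGrad", "MaxSlew", "GradientRasterTime", "AdcDeadTime",
      "AdcRasterTime", "BlockDurationRaster"))]

  # shape library
  shapes <- list()
  sl <- sections$SHAPES
  if (!is.null(sl)) {
    j <- 1L
    n <- length(sl$lines)
    while (j <= n) {
      ln <- trimws(sl$lines[j])
      if (!grepl("^shape_id", ln))
        stopf("parse error at line %d: expected shape_id, got '%s'",
              sl$lineNo[j], ln)
      id <- as.integer(strsplit(ln, "\\s+")[[1]][2])
      ns <- strsplit(trimws(sl$lines[j + 1L]), "\\s+")[[1]]
      if (ns[1] != "num_samples")
        stopf("parse error at line %d: expected num_samples", sl$lineNo[j + 1L])
      numSamples <- as.integer(ns[2])
      j <- j + 2L
      vals <- numeric(0)
      while (j <= n && !grepl("^shape_id", trimws(sl$lines[j]))) {
        vals <- c(vals, parseNums(sl$lines[j], sl$lineNo[j]))
        j <- j + 1L
      }
      shapes[[id]] <- expandShape(vals, numSamples)
    }
  }
  getShape <- function(id, lineNo) {
    if (id < 1 || id > length(shapes) || is.null(shapes[[id]]))
      stopf("parse error at line %d: reference to undefined shape ID %d",
            lineNo, id)
    shapes[[id]]
  }

  parseTable <- function(name) {
    sec <- sections[[name]]
    if (is.null(sec)) return(list())
    out <- list()
    for (j in seq_along(sec$lines)) {
      v <- parseNums(sec$lines[j], sec$lineNo[j])
      out[[as.integer(v[1])]] <- list(vals = v[-1], lineNo = sec$lineNo[j])
    }
    out
  }
  rfTab <- parseTable("RF")
  gradTab <- parseTable("GRADIENTS")
  trapTab <- parseTable("TRAP")
  adcTab <- parseTable("ADC")

  need <- function(tab, id, what, lineNo) {
    if (id < 1 || id > length(tab) || is.null(tab[[id]]))
      stopf("parse error at line %d: reference to undefined %s ID %d",
            lineNo, what, id)
    tab[[id]]
  }

  blocks <- list()
  bl <- sections$BLOCKS
  if (is.null(bl)) stopf("parse error: missing [BLOCKS] section")
  for (j in seq_along(bl$lines)) {
    v <- parseNums(bl$lines[j], bl$lineNo[j])
    if (length(v) < 7)
      stopf("parse error at line %d: block row needs >= 7 fields", bl$lineNo[j])
    dur <- v[2] * lim@blockDurationRaster
    rf <- NULL
    if (v[3] != 0) {
      e <- need(rfTab, as.integer(v[3]), "RF event", bl$lineNo[j])
      w <- e$vals
      mag <- getShape(as.integer(w[2]), e$lineNo)
      ph <- getShape(as.integer(w[3]), e$lineNo)
      tt <- if (w[4] == 0) (seq_along(mag) - 0.5) * lim@rfRasterTime else
        getShape(as.integer(w[4]), e$lineNo) * lim@rfRasterTime
      rf <- new("RFEvent", delay = w[5], signal = as.complex(
                  w[1] * mag * exp(2i * pi * ph)), t = tt,
                freqOffset = w[6], ppmOffset = w[7], phaseOffset = w[8],
                deadTime = lim@rfDeadTime, ringdownTime = lim@rfRingdownTime)
    }
    mkGrad <- function(id, channel) {
      if (id == 0) return(NULL)
      if (id < 0) {
        e <- need(trapTab, -as.integer(id), "trapezoid", bl$lineNo[j])
        w <- e$vals
        new("TrapGradient", channel = channel, amplitude = w[1],
            riseTime = w[2] * 1e-6, flatTime = w[3] * 1e-6,
            fallTime = w[4] * 1e-6, delay = w[5] * 1e-6)
      } else {
        e <- need(gradTab, as.integer(id), "gradient", bl$lineNo[j])
        w <- e$vals
        sh <- getShape(as.integer(w[4]), e$lineNo)
        new("ArbGradient", channel = channel, waveform = w[1] * sh,
            delay = w[5] * 1e-6, first = w[1] * w[2], last = w[1] * w[3])
      }
    }
    adc <- NULL
    if (v[7] != 0) {
      e <- need(adcTab, as.integer(v[7]), "ADC event", bl$lineNo[j])
      w <- e$vals
      adc <- new("ADCEvent", numSamples = w[1], dwell = w[2] * 1e-9,
                 delay = w[3] * 1e-6, freqOffset = w[4], phaseOffset = w[5])
    }
    blocks[[as.integer(v[1])]] <- new("SequenceBlock", rf = rf,
      gx = mkGrad(v[4], "x"), gy = mkGrad(v[5], "y"), gz = mkGrad(v[6], "z"),
      adc = adc, duration = dur)
  }

  if (length(unknown)) {
    message("readSeq: preserving unknown section(s): ",
            paste(unknown, collapse = ", "))
    userDefs$unknownSections <- lapply(sections[unknown], `[[`, "lines")
  }
  new("PulseSequence", blocks = blocks, limits = lim, definitions = userDefs)
}
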