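## Minimal EDF (European Data Format) support: continuous recordings with a
## uniform sampling rate across signals. ASCII header fields are fixed-width;
## sample data are little-endian 16-bit integers scaled between the digital
## and physical ranges declared per signal. Physical dimension must be uV
## (passed through) or mV (converted); anything else is rejected so that the
## in-memory unit is always microvolts.

.edfField <- function(raw, off, len) {
  trimws(rawToChar(raw[(off + 1):(off + len)]))
}

readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 256)
  nRecords <- as.integer(.edfField(hdr, 236, 8))
  recDur <- as.numeric(.edfField(hdr, 244, 8))
  ns <- as.integer(.edfField(hdr, 252, 4))
  if (is.na(ns) || ns < 1) stop("EDF header: invalid signal count")
  sig <- readBin(con, "raw", ns * 256)
  fld <- function(off, len, i) .edfField(sig, ns * off + (i - 1) * len, len)
  labels <- vapply(seq_len(ns), function(i) fld(0, 16, i), "")
  dims <- vapply(seq_len(ns), function(i) fld(96, 8, i), "")
  physMin <- as.numeric(vapply(seq_len(ns), function(i) fld(104, 8, i), ""))
  physMax <- as.numeric(vapply(seq_len(ns), function(i) fld(112, 8, i), ""))
  digMin <- as.numeric(vapply(seq_len(ns), function(i) fld(120, 8, i), ""))
  digMax <- as.numeric(vapply(seq_len(ns), function(i) fld(128, 8, i), ""))
  nSamp <- as.integer(vapply(seq_len(ns), function(i) fld(216, 8, i), ""))
  if (length(unique(nSamp)) != 1)
    stop("EDF: differing per-signal sampling rates are not supported")
  scale <- vapply(dims, function(d) {
    d <- tolower(gsub("µ", "u", d))
    if (d %in% c("uv", "")) 1
    else if (d == "mv") 1000
    else stop("EDF physical dimension '", d,
              "' not supported; expected uV or mV")
  }, 0)
  nPerRec <- nSamp[1]
  data <- matrix(0, nrow = ns, ncol = nRecords * nPerRec)
  for (r in seq_len(nRecords)) {
    block <- readBin(con, "integer", n = ns * nPerRec, size = 2,
                     signed = TRUE, endian = "little")
    block <- matrix(block, nrow = nPerRec, ncol = ns)
    cols <- (r - 1) * nPerRec + seq_len(nPerRec)
    data[, cols] <- t(block)
  }
  gainPhys <- (physMax - physMin) / (digMax - digMin)
  data <- (data - digMin) * gainPhys + physMin
  data <- data * scale
  rownames(data) <- labels
  list(data = data, samplingRate = nPerRec / recDur)
}

.edfPad <- function(x, len) {
  x <- substr(as.character(x), 1, len)
  formatC(x, width = len, flag = "-")
}

writeEDF <- function(data, samplingRate, path) {
  ns <- nrow(data)
  nSamples <- ncol(data)
  ## one-second records when the sample count allows, else a single record
  if (samplingRate == round(samplingRate) && nSamples %% samplingRate == 0) {
    nPerRec <- as.integer(samplingRate); recDur <- 1
  } else {
    nPerRec <- nSamples; recDur <- nSamples / samplingRate
  }
  nRecords <- nSamples %/% nPerRec
  physMax <- max(1e-6, max(abs(data)))
  physMin <- -physMax
  digMax <- 32767; digMin <- -32768
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, len) writeBin(charToRaw(.edfPad(x, len)), con)
  wr("0", 8); wr("synthetic", 80); wr("microstates", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 * (ns + 1), 8); wr("", 44)
  wr(nRecords, 8); wr(format(recDur, digits = 8), 8); wr(ns, 4)
  nm <- rownames(data); if (is.null(nm)) nm <- paste0("E", seq_len(ns))
  for (x in nm) wr(x, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(format(physMin, digits = 7), 8)
  for (i in seq_len(ns)) wr(format(physMax, digits = 7), 8)
  for (i in seq_len(ns)) wr(digMin, 8)
  for (i in seq_len(ns)) wr(digMax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(nPerRec, 8)
  for (i in seq_len(ns)) wr("", 32)
  dig <- round((data - physMin) / (physMax - physMin) * (digMax - digMin) +
               digMin)
  dig[] <- pmin(pmax(dig, digMin), digMax)
  for (r in seq_len(nRecords)) {
    cols <- (r - 1) * nPerRec + seq_len(nPerRec)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}
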