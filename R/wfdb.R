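#' @include AllClasses.R
NULL

# unit strings accepted in WFDB headers, with scale factor to mV
.WFDB_UNITS <- c(mV = 1, mv = 1, uV = 1e-3, uv = 1e-3, V = 1e3, v = 1e3,
                 millivolts = 1, microvolts = 1e-3)

#' Read a WFDB record (header + format-16 signal file)
#'
#' Minimal reader for the PhysioNet WFDB format as used by 12-lead ECG
#' corpora: a \code{.hea} text header plus a single \code{.dat} signal
#' file in format 16 (16-bit little-endian two's complement, samples
#' interleaved across channels). Amplitudes are converted to mV via each
#' signal's ADC gain, baseline and unit.
#'
#' @param path record path, with or without the \code{.hea} extension.
#' @param label optional class label to attach.
#' @return A \linkS4class{MultichannelRecord} in mV.
#' @export
readWfdb <- function(path, label = NA_character_) {
  base <- sub("\\.hea$", "", path)
  hea <- paste0(base, ".hea")
  if (!file.exists(hea)) .stopIO(sprintf("WFDB header not found: %s", hea))
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) .stopFormat(sprintf("empty WFDB header: %s", hea))
  rec <- strsplit(trimws(lines[[1]]), "[[:space:]]+")[[1]]
  if (length(rec) < 4)
    .stopFormat(sprintf("malformed WFDB record line in %s", hea))
  nsig <- as.integer(rec[[2]])
  fs <- as.numeric(sub("/.*", "", rec[[3]]))
  nsamp <- as.integer(rec[[4]])
  sigLines <- lines[-1]
  if (length(sigLines) < nsig)
    .stopFormat(sprintf("%s declares %d signals but lists %d",
                        hea, nsig, length(sigLines)))
  sigLines <- sigLines[seq_len(nsig)]
  parse1 <- function(l) {
    f <- strsplit(trimws(l), "[[:space:]]+")[[1]]
    if (length(f) < 3)
      .stopFormat(sprintf("malformed signal line in %s: '%s'", hea, l))
    fmt <- sub("x.*", "", f[[2]])
    gainField <- f[[3]]
    unit <- "mV"
    if (grepl("/", gainField, fixed = TRUE)) {
      unit <- sub(".*/", "", gainField)
      gainField <- sub("/.*", "", gainField)
    }
    baseline <- 0
    if (grepl("\\(", gainField)) {
      baseline <- as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gainField))
      gainField <- sub("\\(.*", "", gainField)
    }
    gain <- as.numeric(gainField)
    if (is.na(gain) || gain == 0) gain <- 200  # WFDB default adu per unit
    adczero <- if (length(f) >= 5) as.numeric(f[[5]]) else 0
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else NA
    list(file = f[[1]], format = fmt, gain = gain, baseline = baseline,
         adczero = adczero, unit = unit, desc = desc)
  }
  sigs <- lapply(sigLines, parse1)
  fmts <- unique(vapply(sigs, `[[`, character(1), "format"))
  if (!identical(fmts, "16"))
    .stopFormat(sprintf("unsupported WFDB signal format(s) %s in %s (only 16)",
                        paste(fmts, collapse = ","), hea))
  datFiles <- unique(vapply(sigs, `[[`, character(1), "file"))
  if (length(datFiles) != 1)
    .stopFormat(sprintf("multi-file WFDB records not supported (%s)", hea))
  dat <- file.path(dirname(hea), datFiles)
  if (!file.exists(dat)) .stopIO(sprintf("WFDB signal file not found: %s", dat))
  raw <- readBin(dat, "integer", n = file.size(dat) / 2, size = 2,
                 signed = TRUE, endian = "little")
  if (length(raw) != nsig * nsamp)
    .stopFormat(sprintf(
      "%s holds %d samples; header %s declares %d signals x %d samples",
      dat, length(raw), hea, nsig, nsamp))
  adc <- matrix(raw, nrow = nsamp, ncol = nsig, byrow = TRUE)
  data <- matrix(0, nsamp, nsig)
  names <- character(nsig)
  for (j in seq_len(nsig)) {
    s <- sigs[[j]]
    if (!s$unit %in% names(.WFDB_UNITS))
      .stopFormat(sprintf("unit '%s' in %s is not convertible to mV",
                          s$unit, hea))
    # physical value = (adc - baseline) / gain, then unit scale to mV
    data[, j] <- (adc[, j] - s$baseline) / s$gain * .WFDB_UNITS[[s$unit]]
    names[j] <- if (!is.na(s$desc) && nzchar(s$desc)) s$desc
                else paste0("ch", j)
  }
  MultichannelRecord(data, channelNames = names, samplingRate = fs,
                     label = label)
}

#' Write a record as a WFDB header + format-16 signal pair
#'
#' Counterpart of \code{\link{readWfdb}}; amplitudes are quantized at the
#' given ADC gain (default 1000 ADC units per mV, i.e. 1 uV resolution).
#'
#' @param record a \linkS4class{MultichannelRecord} (mV).
#' @param path record path without extension.
#' @param gain ADC units per mV.
#' @return the header path, invisibly.
#' @export
writeWfdb <- function(record, path, gain = 1000) {
  stopifnot(is(record, "MultichannelRecord"))
  base <- sub("\\.hea$", "", path)
  recName <- basename(base)
  n <- nrow(record@data)
  k <- ncol(record@data)
  adc <- round(record@data * gain)
  if (any(abs(adc) > 32767))
    .stopContract("amplitudes overflow 16-bit range at this gain")
  hea <- c(sprintf("%s %d %g %d", recName, k, record@samplingRate, n),
           sprintf("%s.dat 16 %g(0)/mV 16 0 0 0 0 %s",
                   recName, gain, record@channelNames))
  writeLines(hea, paste0(base, ".hea"))
  inter <- as.integer(t(adc))  # interleave samples across channels
  writeBin(inter, paste0(base, ".dat"), size = 2, endian = "little")
  invisible(paste0(base, ".hea"))
}
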