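#' @include AllClasses.R
NULL

#' Read a multichannel record from a delimited text file
#'
#' Reads a rectangular numeric table (samples x channels) in CSV/TSV or
#' whitespace-delimited form. Amplitudes are taken to be in mV.
#'
#' @param path file path.
#' @param nameRow \code{TRUE} if the first row holds channel names,
#'   \code{FALSE} if not, or \code{"auto"} (default) to detect: a first row
#'   with any non-numeric token is treated as a header.
#' @param samplingRate sampling rate in Hz to attach (default 500).
#' @param sep field separator; \code{NULL} (default) auto-detects comma,
#'   tab, or whitespace.
#' @param label optional class label to attach.
#' @return A \linkS4class{MultichannelRecord}. Without a header row,
#'   channels are named \code{ch1..chN}.
#' @export
readDelimited <- function(path, nameRow = "auto", samplingRate = 500,
                          sep = NULL, label = NA_character_) {
  if (!file.exists(path)) .stopIO(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) .stopFormat(sprintf("empty file: %s", path))
  if (is.null(sep)) {
    sep <- if (grepl(",", lines[[1]], fixed = TRUE)) ","
           else if (grepl("\t", lines[[1]], fixed = TRUE)) "\t"
           else "[[:space:]]+"
  }
  tok <- function(l) {
    parts <- strsplit(trimws(l), sep)[[1]]
    parts[nzchar(parts)]
  }
  first <- tok(lines[[1]])
  hasHeader <- if (identical(nameRow, "auto")) {
    suppressWarnings(anyNA(as.numeric(first)))
  } else isTRUE(nameRow)
  if (hasHeader) {
    names <- first
    body <- lines[-1]
    if (!length(body)) .stopFormat(sprintf("no data rows in %s", path))
  } else {
    names <- NULL
    body <- lines
  }
  ncolExp <- if (hasHeader) length(first) else length(tok(body[[1]]))
  mat <- matrix(NA_real_, length(body), ncolExp)
  for (i in seq_along(body)) {
    parts <- tok(body[[i]])
    if (length(parts) != ncolExp)
      .stopFormat(sprintf("row %d of %s has %d fields, expected %d",
                          i + hasHeader, path, length(parts), ncolExp))
    vals <- suppressWarnings(as.numeric(parts))
    if (anyNA(vals))
      .stopFormat(sprintf("non-numeric value in row %d of %s", i + hasHeader, path))
    mat[i, ] <- vals
  }
  if (is.null(names)) names <- paste0("ch", seq_len(ncolExp))
  MultichannelRecord(mat, channelNames = names, samplingRate = samplingRate,
                     label = label)
}

#' Write a record as delimited text
#'
#' Writes samples x channels values with a channel-name header row;
#' round-trips through \code{\link{readDelimited}} to at least 6
#' significant digits.
#'
#' @param record a \linkS4class{MultichannelRecord}.
#' @param path output path.
#' @param sep field separator (default comma).
#' @return \code{path}, invisibly.
#' @export
writeDelimited <- function(record, path, sep = ",") {
  stopifnot(is(record, "MultichannelRecord"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(record@channelNames, collapse = sep), con)
  body <- apply(record@data, 1L,
                function(r) paste(sprintf("%.10g", r), collapse = sep))
  writeLines(body, con)
  invisible(path)
}

#' Concatenate a collection into one long record
#'
#' Stacks the member records sample-wise in collection order, preserving
#' channel order. Concatenating records increases the sample count behind
#' each bin-probability estimate, which is how corpus-level entropies are
#' stabilized. Labels are dropped (a concatenated corpus has no single
#' class).
#'
#' @param collection a \linkS4class{RecordCollection} (a plain list of
#'   records is accepted and validated).
#' @return A single \linkS4class{MultichannelRecord} whose sample count is
#'   the sum of the members'.
#' @export
concatenateRecords <- function(collection) {
  if (is.list(collection)) collection <- RecordCollection(collection)
  stopifnot(is(collection, "RecordCollection"))
  recs <- collection@records
  ref <- recs[[1]]
  data <- do.call(rbind, lapply(recs, function(r) r@data))
  MultichannelRecord(data, channelNames = ref@channelNames,
                     samplingRate = ref@samplingRate)
}
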