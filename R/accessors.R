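#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @aliases channelNames,MultichannelRecord-method
setMethod("channelNames", "MultichannelRecord", function(x) x@channelNames)

#' @rdname accessors
#' @aliases channelNames,BinnedChannels-method
setMethod("channelNames", "BinnedChannels", function(x) x@channelNames)

#' @rdname accessors
#' @aliases channelNames,RecordCollection-method
setMethod("channelNames", "RecordCollection",
          function(x) x@records[[1]]@channelNames)

#' @rdname accessors
#' @aliases channelNames,RedundancyReport-method
setMethod("channelNames", "RedundancyReport", function(x) x@channelNames)

#' @rdname accessors
#' @aliases signalData,MultichannelRecord-method
setMethod("signalData", "MultichannelRecord", function(x) x@data)

#' @rdname accessors
#' @aliases samplingRate,MultichannelRecord-method
setMethod("samplingRate", "MultichannelRecord", function(x) x@samplingRate)

#' @rdname accessors
#' @aliases samplingRate,RecordCollection-method
setMethod("samplingRate", "RecordCollection",
          function(x) x@records[[1]]@samplingRate)

#' @rdname accessors
#' @aliases recordLabel,MultichannelRecord-method
setMethod("recordLabel", "MultichannelRecord", function(x) x@label)

#' @rdname accessors
#' @aliases nChannels,MultichannelRecord-method
setMethod("nChannels", "MultichannelRecord", function(x) ncol(x@data))

#' @rdname accessors
#' @aliases nChannels,BinnedChannels-method
setMethod("nChannels", "BinnedChannels", function(x) ncol(x@bins))

#' @rdname accessors
#' @aliases nSamples,MultichannelRecord-method
setMethod("nSamples", "MultichannelRecord", function(x) nrow(x@data))

#' @rdname accessors
#' @aliases nSamples,BinnedChannels-method
setMethod("nSamples", "BinnedChannels", function(x) nrow(x@bins))

#' @rdname accessors
#' @aliases binIndices,BinnedChannels-method
setMethod("binIndices", "BinnedChannels", function(x) x@bins)

#' @rdname accessors
#' @aliases binningConfig,BinnedChannels-method
setMethod("binningConfig", "BinnedChannels", function(x) x@config)

#' @rdname accessors
#' @aliases binningConfig,RedundancyReport-method
setMethod("binningConfig", "RedundancyReport", function(x) x@config)

#' @rdname accessors
#' @aliases records,RecordCollection-method
setMethod("records", "RecordCollection", function(x) x@records)

#' Number of records in a collection
#' @param x a RecordCollection.
#' @export
setMethod("length", "RecordCollection", function(x) length(x@records))

#' Extract a record from a collection
#' @param x a RecordCollection.
#' @param i record index.
#' @export
setMethod("[[", "RecordCollection", function(x, i) x@records[[i]])

#' Subset the channels of a record
#'
#' @param x a \linkS4class{MultichannelRecord}.
#' @param channels channel names or column indices, in the desired output
#'   order.
#' @return A MultichannelRecord with only the requested channels.
#' @export
selectChannels <- function(x, channels) {
  stopifnot(is(x, "MultichannelRecord"))
  if (is.character(channels)) {
    missing <- setdiff(channels, x@channelNames)
    if (length(missing))
      .stopContract(sprintf("channel(s) not present: %s",
                            paste(missing, collapse = ", ")))
    idx <- match(channels, x@channelNames)
  } else {
    idx <- as.integer(channels)
    if (any(idx < 1 | idx > ncol(x@data)))
      .stopContract("channel index out of range")
  }
  MultichannelRecord(x@data[, idx, drop = FALSE],
                     channelNames = x@channelNames[idx],
                     samplingRate = x@samplingRate, label = x@label)
}

#' Per-channel redundancy values from a report
#' @param x a \linkS4class{RedundancyReport}.
#' @param percent report on the 0-100 scale.
#' @return named numeric vector.
#' @export
perChannelRedundancy <- function(x, percent = FALSE) {
  stopifnot(is(x, "RedundancyReport"))
  v <- x@perChannel
  names(v) <- x@channelNames
  if (percent) v * 100 else v
}

#' Set redundancy value from a report
#' @inheritParams perChannelRedundancy
#' @export
setRedundancyValue <- function(x, percent = FALSE) {
  stopifnot(is(x, "RedundancyReport"))
  if (percent) x@setR * 100 else x@setR
}

#' Explained variance fractions of a PCA model
#' @param x a \linkS4class{PcaModel}.
#' @export
explainedVariance <- function(x) {
  stopifnot(is(x, "PcaModel"))
  x@varianceFraction
}

#' Component rows of a PCA model
#' @param x a \linkS4class{PcaModel}.
#' @export
pcaRotation <- function(x) {
  stopifnot(is(x, "PcaModel"))
  x@rotation
}

#' Channel means of a PCA model
#' @param x a \linkS4class{PcaModel}.
#' @export
pcaCenter <- function(x) {
  stopifnot(is(x, "PcaModel"))
  x@center
}
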