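#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Standard accessors for the package's containers. Use these rather than
#' reaching into slots.
#'
#' @param x an ecgredund object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("signalData", function(x) standardGeneric("signalData"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("recordLabel", function(x) standardGeneric("recordLabel"))

#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("binIndices", function(x) standardGeneric("binIndices"))

#' @rdname accessors
#' @export
setGeneric("binningConfig", function(x) standardGeneric("binningConfig"))

#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' Quantize a record into amplitude bins
#' @param record a \linkS4class{MultichannelRecord} (or an object coercible
#'   to one).
#' @param config a \linkS4class{BinningConfig}.
#' @export
setGeneric("binRecord", function(record, config = BinningConfig())
  standardGeneric("binRecord"))

#' Entropy-family generics
#'
#' These dispatch on either \linkS4class{BinnedChannels} (computed as-is)
#' or \linkS4class{MultichannelRecord} (binned first with \code{config}).
#'
#' @param x a BinnedChannels or MultichannelRecord.
#' @param ... passed through; for record inputs a \code{config} argument
#'   (default \code{BinningConfig()}) selects the binning.
#' @name infotheory-generics
NULL

#' @rdname infotheory-generics
#' @export
setGeneric("channelEntropy", function(x, ...) standardGeneric("channelEntropy"))

#' @rdname infotheory-generics
#' @export
setGeneric("jointEntropy", function(x, ...) standardGeneric("jointEntropy"))

#' @rdname infotheory-generics
#' @export
setGeneric("mutualInformation", function(x, ...) standardGeneric("mutualInformation"))

#' @rdname infotheory-generics
#' @export
setGeneric("nmi", function(x, ...) standardGeneric("nmi"))

#' @rdname infotheory-generics
#' @export
setGeneric("nmiMatrix", function(x, ...) standardGeneric("nmiMatrix"))

#' @rdname infotheory-generics
#' @export
setGeneric("channelRedundancy", function(x, ...) standardGeneric("channelRedundancy"))

#' @rdname infotheory-generics
#' @export
setGeneric("setRedundancy", function(x, ...) standardGeneric("setRedundancy"))

#' @rdname infotheory-generics
#' @export
setGeneric("redundancyReport", function(x, ...) standardGeneric("redundancyReport"))
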