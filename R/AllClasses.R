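#' @import methods
#' @import data.table
NULL

#' Classed error helpers
#'
#' Internal condition constructors so callers and tests can distinguish
#' contract violations (bad arguments), format problems in input files,
#' I/O failures, and mathematically undefined values (e.g. NMI of two
#' constant channels).
#' @noRd
.stopWith <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(class, "ecgrError", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}
.stopContract  <- function(msg) .stopWith("ecgrContractError", msg)
.stopFormat    <- function(msg) .stopWith("ecgrFormatError", msg)
.stopIO        <- function(msg) .stopWith("ecgrIOError", msg)
.stopUndefined <- function(msg) .stopWith("ecgrUndefinedError", msg)

#' MultichannelRecord: a synchronized set of named signal channels
#'
#' The central container of the package: a samples x channels real matrix
#' of amplitudes in millivolts, recorded at a fixed sampling rate, with an
#' optional diagnostic class label (one of NORM, MI, STTC, CD, HYP).
#' Standard 12-lead ECGs are the motivating case but any channel set is
#' accepted.
#'
#' @slot data numeric matrix, samples x channels, amplitudes in mV.
#' @slot channelNames character vector of distinct channel (lead) labels,
#'   one per column of \code{data}.
#' @slot samplingRate positive sampling rate in Hz.
#' @slot label optional diagnostic class tag (\code{NA_character_} if absent).
#' @exportClass MultichannelRecord
setClass("MultichannelRecord",
  representation(
    data         = "matrix",
    channelNames = "character",
    samplingRate = "numeric",
    label        = "character"
  ),
  prototype(
    data         = matrix(numeric(0), 0, 0),
    channelNames = character(0),
    samplingRate = 500,
    label        = NA_character_
  )
)

.CLASS_LABELS <- c("NORM", "MI", "STTC", "CD", "HYP")

setValidity("MultichannelRecord", function(object) {
  msgs <- character(0)
  if (!is.numeric(object@data))
    msgs <- c(msgs, "signal data must be a numeric matrix")
  if (ncol(object@data) != length(object@channelNames))
    msgs <- c(msgs, sprintf(
      "number of data columns (%d) must equal number of channel names (%d)",
      ncol(object@data), length(object@channelNames)))
  if (anyDuplicated(object@channelNames))
    msgs <- c(msgs, "channel names must be distinct")
  if (length(object@samplingRate) != 1 || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msgs <- c(msgs, "samplingRate must be a single positive number")
  if (nrow(object@data) < 2)
    msgs <- c(msgs, "a record needs at least 2 samples")
  if (length(object@label) != 1 ||
      (!is.na(object@label) && !object@label %in% .CLASS_LABELS))
    msgs <- c(msgs, sprintf("label must be NA or one of %s",
                            paste(.CLASS_LABELS, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct a MultichannelRecord
#'
#' @param data samples x channels numeric matrix (mV). A plain vector is
#'   treated as a single channel.
#' @param channelNames channel labels; defaults to the matrix column names
#'   or \code{ch1..chN}.
#' @param samplingRate sampling rate in Hz (default 500, the rate the
#'   redundancy analyses in this package assume for ECG work).
#' @param label optional diagnostic class (NORM, MI, STTC, CD, HYP).
#' @return A \linkS4class{MultichannelRecord}.
#' @examples
#' rec <- MultichannelRecord(cbind(I = rnorm(100), II = rnorm(100)))
#' nChannels(rec)
#' @export
MultichannelRecord <- function(data, channelNames = NULL, samplingRate = 500,
                               label = NA_character_) {
  if (is.null(dim(data))) data <- matrix(as.numeric(data), ncol = 1)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channelNames)) {
    channelNames <- if (!is.null(colnames(data))) colnames(data)
                    else paste0("ch", seq_len(ncol(data)))
  }
  colnames(data) <- channelNames
  new("MultichannelRecord", data = data,
      channelNames = as.character(channelNames),
      samplingRate = as.numeric(samplingRate),
      label = as.character(label))
}

#' RecordCollection: records sharing channels and sampling rate
#'
#' A homogeneous set of \linkS4class{MultichannelRecord}s: identical channel
#' name order and sampling rate across members, so they can be concatenated
#' sample-wise into a single long record for corpus-level entropy estimation.
#'
#' @slot records list of MultichannelRecord objects.
#' @exportClass RecordCollection
setClass("RecordCollection", representation(records = "list"))

setValidity("RecordCollection", function(object) {
  recs <- object@records
  if (!length(recs)) return("collection must contain at least one record")
  if (!all(vapply(recs, is, logical(1), "MultichannelRecord")))
    return("all members must be MultichannelRecord objects")
  ref <- recs[[1]]
  for (i in seq_along(recs)) {
    if (!identical(recs[[i]]@channelNames, ref@channelNames))
      return(sprintf("record %d has a different channel name order", i))
    if (!identical(recs[[i]]@samplingRate, ref@samplingRate))
      return(sprintf("record %d has a different sampling rate", i))
  }
  TRUE
})

#' Construct a RecordCollection
#' @param records list of \linkS4class{MultichannelRecord} objects with
#'   identical channel order and sampling rate.
#' @return A \linkS4class{RecordCollection}.
#' @export
RecordCollection <- function(records) {
  if (is(records, "MultichannelRecord")) records <- list(records)
  new("RecordCollection", records = records)
}

#' BinningConfig: fixed-width amplitude quantization settings
#'
#' Entropy in this package is the plug-in estimate over fixed-width
#' amplitude bins. The default width of 0.5 mV is the empirically chosen
#' value for 12-lead ECG at 500 Hz; bin edges are half-open intervals
#' \code{[k*w, (k+1)*w)} anchored at 0 mV.
#'
#' @slot binWidth bin width in mV (> 0, default 0.5).
#' @slot anchor bin-edge anchor in mV (default 0).
#' @slot logBase logarithm base for entropies (default 2, i.e. bits). All
#'   normalized quantities (NMI, redundancy) are base-invariant.
#' @exportClass BinningConfig
setClass("BinningConfig",
  representation(binWidth = "numeric", anchor = "numeric", logBase = "numeric"),
  prototype(binWidth = 0.5, anchor = 0, logBase = 2)
)

setValidity("BinningConfig", function(object) {
  msgs <- character(0)
  if (length(object@binWidth) != 1 || !is.finite(object@binWidth) ||
      object@binWidth <= 0)
    msgs <- c(msgs, "binWidth must be a single positive number")
  if (length(object@anchor) != 1 || !is.finite(object@anchor))
    msgs <- c(msgs, "anchor must be a single finite number")
  if (length(object@logBase) != 1 || !is.finite(object@logBase) ||
      object@logBase <= 1)
    msgs <- c(msgs, "logBase must be > 1")
  if (length(msgs)) msgs else TRUE
})

#' @rdname BinningConfig-class
#' @param binWidth bin width in mV.
#' @param anchor bin-edge anchor in mV.
#' @param logBase entropy logarithm base.
#' @return A \linkS4class{BinningConfig}.
#' @export
BinningConfig <- function(binWidth = 0.5, anchor = 0, logBase = 2) {
  new("BinningConfig", binWidth = as.numeric(binWidth),
      anchor = as.numeric(anchor), logBase = as.numeric(logBase))
}

#' BinnedChannels: integer bin indices per sample and channel
#'
#' Result of quantizing a \linkS4class{MultichannelRecord}; the substrate
#' for every entropy-based computation.
#'
#' @slot bins integer matrix, samples x channels, bin index
#'   \code{floor((value - anchor)/binWidth)}.
#' @slot channelNames channel labels.
#' @slot config the \linkS4class{BinningConfig} that produced the bins.
#' @exportClass BinnedChannels
setClass("BinnedChannels",
  representation(bins = "matrix", channelNames = "character",
                 config = "BinningConfig"))

setValidity("BinnedChannels", function(object) {
  msgs <- character(0)
  if (!is.integer(object@bins))
    msgs <- c(msgs, "bins must be an integer matrix")
  if (anyNA(object@bins))
    msgs <- c(msgs, "bins must be finite integers")
  if (ncol(object@bins) != length(object@channelNames))
    msgs <- c(msgs, "bin columns must match channel names")
  if (anyDuplicated(object@channelNames))
    msgs <- c(msgs, "channel names must be distinct")
  if (length(msgs)) msgs else TRUE
})

#' RedundancyReport: per-channel and set-level redundancy
#'
#' Per-channel redundancy is the fraction of a channel's entropy
#' recoverable from the remaining channels; set redundancy is the fraction
#' of the joint entropy shared by at least two channels. Both live in
#' [0, 1] (use \code{percent = TRUE} in \code{\link{redundancyReport}} to
#' display on the 0-100 scale).
#'
#' @slot channelNames channel labels.
#' @slot perChannel numeric vector in [0,1], one value per channel
#'   (NA where a channel's redundancy is undefined, e.g. a single-channel
#'   input).
#' @slot setR set redundancy in [0,1].
#' @slot config the binning configuration used.
#' @slot nSamples number of samples the estimate is based on.
#' @exportClass RedundancyReport
setClass("RedundancyReport",
  representation(channelNames = "character", perChannel = "numeric",
                 setR = "numeric", config = "BinningConfig",
                 nSamples = "integer"))

setValidity("RedundancyReport", function(object) {
  tol <- 1e-9
  msgs <- character(0)
  if (length(object@perChannel) != length(object@channelNames))
    msgs <- c(msgs, "one perChannel value per channel required")
  vals <- c(object@perChannel[!is.na(object@perChannel)], object@setR)
  if (any(vals < -tol | vals > 1 + tol))
    msgs <- c(msgs, "redundancy values must lie in [0,1]")
  if (length(msgs)) msgs else TRUE
})

#' PcaModel: corpus-level principal component transform
#'
#' A single linear transform fitted on the concatenated corpus (never per
#' record): channel means, orthonormal component rows ordered by
#' non-increasing explained variance, and the variance fractions.
#'
#' @slot center per-channel mean offsets (mV).
#' @slot rotation components x channels matrix with orthonormal rows; the
#'   sign of each row is fixed so its largest-magnitude entry is positive.
#' @slot varianceFraction explained variance fractions, non-increasing,
#'   summing to 1.
#' @slot channelNames input channel labels.
#' @exportClass PcaModel
setClass("PcaModel",
  representation(center = "numeric", rotation = "matrix",
                 varianceFraction = "numeric", channelNames = "character"))

setValidity("PcaModel", function(object) {
  msgs <- character(0)
  k <- nrow(object@rotation)
  if (length(object@center) != ncol(object@rotation))
    msgs <- c(msgs, "center length must match rotation columns")
  if (length(object@varianceFraction) != k)
    msgs <- c(msgs, "one variance fraction per component required")
  g <- object@rotation %*% t(object@rotation)
  if (max(abs(g - diag(k))) > 1e-8)
    msgs <- c(msgs, "component rows must be orthonormal")
  vf <- object@varianceFraction
  if (any(vf < -1e-12 | vf > 1 + 1e-12) || is.unsorted(rev(vf), strictly = FALSE))
    msgs <- c(msgs, "variance fractions must be in [0,1] and non-increasing")
  if (abs(sum(vf) - 1) > 1e-8)
    msgs <- c(msgs, "variance fractions must sum to 1")
  if (length(msgs)) msgs else TRUE
})

#' TransformSpec: a named linear map between channel sets
#'
#' Wraps a fixed outputs x inputs matrix together with its channel labels;
#' used for the forward Dower projection and the inverse Dower transform.
#'
#' @slot name transform label.
#' @slot inputChannels labels of the expected input channels, in matrix
#'   column order.
#' @slot outputChannels labels of the produced channels, in matrix row order.
#' @slot matrix outputs x inputs numeric matrix.
#' @exportClass TransformSpec
setClass("TransformSpec",
  representation(name = "character", inputChannels = "character",
                 outputChannels = "character", matrix = "matrix"))

setValidity("TransformSpec", function(object) {
  msgs <- character(0)
  if (nrow(object@matrix) != length(object@outputChannels) ||
      ncol(object@matrix) != length(object@inputChannels))
    msgs <- c(msgs, "matrix dimensions must match channel lists")
  if (!all(is.finite(object@matrix)))
    msgs <- c(msgs, "matrix entries must be finite")
  if (length(msgs)) msgs else TRUE
})

#' DipoleParams: settings for the synthetic dipole ECG generator
#'
#' The generator models the cardiac dipole as three orthogonal axis signals
#' (X, Y, Z), each a sum of Gaussian bumps in beat phase (P, QRS and T
#' waves), with beats placed at RR intervals of 60/heart rate perturbed by
#' a jitter fraction. Leads are fixed-angle plane projections of the
#' dipole, optionally with per-record electrode-angle jitter and additive
#' white noise.
#'
#' @slot rateHz sampling rate (default 500 Hz).
#' @slot durationS record duration in seconds (default 10).
#' @slot heartRateBpm mean heart rate (default 70 bpm).
#' @slot rrJitterFrac RR-interval jitter as a fraction of the mean RR
#'   (default 0.05).
#' @slot waveComponents named list with elements \code{x}, \code{y},
#'   \code{z}; each a data.frame with columns \code{center} (beat phase,
#'   rad, R peak at 0), \code{width} (rad, > 0) and \code{amplitude} (mV).
#' @slot beatRotSd SD (degrees) of the per-beat frontal axis wobble
#'   (respiratory modulation); stays within the 3-D dipole space.
#' @slot beatScaleSd SD of the per-beat log-normal amplitude modulation.
#' @slot restOffsetMv constant resting dipole offset per axis (mV); keeps
#'   lead baselines away from the 0 mV bin edge, as real isoelectric
#'   baselines sit at small nonzero offsets.
#' @slot noiseSdMv additive white noise standard deviation per lead (mV).
#' @slot electrodeJitterDeg SD of the per-record, per-lead angular
#'   perturbation (degrees); constant within a record.
#' @slot seed integer RNG seed; all generator randomness derives from it.
#' @exportClass DipoleParams
setClass("DipoleParams",
  representation(rateHz = "numeric", durationS = "numeric",
                 heartRateBpm = "numeric", rrJitterFrac = "numeric",
                 waveComponents = "list", beatRotSd = "numeric",
                 beatScaleSd = "numeric", restOffsetMv = "numeric",
                 noiseSdMv = "numeric",
                 electrodeJitterDeg = "numeric", seed = "integer"))

setValidity("DipoleParams", function(object) {
  msgs <- character(0)
  if (object@rateHz <= 0 || object@durationS <= 0)
    msgs <- c(msgs, "rateHz and durationS must be positive")
  n <- object@rateHz * object@durationS
  if (abs(n - round(n)) > 1e-9)
    msgs <- c(msgs, "rateHz * durationS must be an integer sample count")
  if (object@heartRateBpm <= 0)
    msgs <- c(msgs, "heartRateBpm must be positive")
  if (object@rrJitterFrac < 0 || object@noiseSdMv < 0 ||
      object@electrodeJitterDeg < 0 || object@beatRotSd < 0 ||
      object@beatScaleSd < 0)
    msgs <- c(msgs, "jitter, wobble and noise parameters must be >= 0")
  if (length(object@restOffsetMv) != 3 || !all(is.finite(object@restOffsetMv)))
    msgs <- c(msgs, "restOffsetMv must be 3 finite values (X, Y, Z)")
  if (!all(c("x", "y", "z") %in% names(object@waveComponents)))
    msgs <- c(msgs, "waveComponents must have elements x, y, z")
  for (ax in intersect(c("x", "y", "z"), names(object@waveComponents))) {
    wc <- object@waveComponents[[ax]]
    if (!is.data.frame(wc) ||
        !all(c("center", "width", "amplitude") %in% names(wc)))
      msgs <- c(msgs, sprintf("waveComponents$%s needs center/width/amplitude", ax))
    else {
      if (any(wc$width <= 0)) msgs <- c(msgs, sprintf("%s widths must be > 0", ax))
      if (!all(is.finite(wc$amplitude)))
        msgs <- c(msgs, sprintf("%s amplitudes must be finite", ax))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' show methods
#' @param object the object to display.
#' @name show-methods
#' @aliases show,MultichannelRecord-method show,RecordCollection-method
#'   show,BinnedChannels-method show,RedundancyReport-method
#'   show,PcaModel-method show,TransformSpec-method
NULL

#' @rdname show-methods
setMethod("show", "MultichannelRecord", function(object) {
  cat(sprintf("MultichannelRecord: %d samples x %d channels @ %g Hz (%g s)\n",
              nrow(object@data), ncol(object@data), object@samplingRate,
              nrow(object@data) / object@samplingRate))
  cat("  channels:", paste(object@channelNames, collapse = ", "), "\n")
  if (!is.na(object@label)) cat("  label:", object@label, "\n")
})

#' @rdname show-methods
setMethod("show", "RecordCollection", function(object) {
  ref <- object@records[[1]]
  cat(sprintf("RecordCollection: %d records, %d channels @ %g Hz\n",
              length(object@records), length(ref@channelNames),
              ref@samplingRate))
  labs <- vapply(object@records, function(r) r@label, character(1))
  if (any(!is.na(labs))) {
    tab <- table(labs, useNA = "ifany")
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
})

#' @rdname show-methods
setMethod("show", "BinnedChannels", function(object) {
  cat(sprintf("BinnedChannels: %d samples x %d channels, bin width %g mV (anchor %g)\n",
              nrow(object@bins), ncol(object@bins), object@config@binWidth,
              object@config@anchor))
})

#' @rdname show-methods
setMethod("show", "RedundancyReport", function(object) {
  cat(sprintf("RedundancyReport (bin width %g mV, n = %d samples)\n",
              object@config@binWidth, object@nSamples))
  cat(sprintf("  set redundancy: %.4f (%.2f%%)\n", object@setR, 100 * object@setR))
  pc <- format(round(object@perChannel, 4))
  cat("  per channel:\n")
  for (i in seq_along(object@channelNames))
    cat(sprintf("    %-4s %s\n", object@channelNames[i], pc[i]))
})

#' @rdname show-methods
setMethod("show", "PcaModel", function(object) {
  cat(sprintf("PcaModel: %d components over %d channels\n",
              nrow(object@rotation), ncol(object@rotation)))
  cat("  explained variance fractions:",
      paste(sprintf("%.4f", object@varianceFraction), collapse = " "), "\n")
})

#' @rdname show-methods
setMethod("show", "TransformSpec", function(object) {
  cat(sprintf("TransformSpec '%s': %s -> %s\n", object@name,
              paste(object@inputChannels, collapse = ","),
              paste(object@outputChannels, collapse = ",")))
})
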