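#' @include AllGenerics.R
NULL

# ---- sparse joint-histogram primitive ------------------------------------
# Every entropy-family quantity in the package reduces to the entropy of
# the empirical distribution over observed bin tuples. Tuples are counted
# sparsely (grouping observed rows), never via a dense n-dimensional
# histogram, so high channel counts stay tractable.

.tupleCounts <- function(bins) {
  if (ncol(bins) == 1L) {
    dt <- data.table::data.table(v = bins[, 1L])
    return(dt[, .N, by = "v"][["N"]])
  }
  dt <- data.table::as.data.table(bins)
  dt[, .N, by = names(dt)][["N"]]
}

.entropyFromCounts <- function(counts, base) {
  n <- sum(counts)
  p <- counts / n
  # 0 log 0 := 0 is automatic: zero-count tuples are never materialized
  -sum(p * log(p)) / log(base)
}

.binsEntropy <- function(bins, cols, base) {
  .entropyFromCounts(.tupleCounts(bins[, cols, drop = FALSE]), base)
}

# resolve channel names/indices against a BinnedChannels or record
.resolveChannels <- function(names, spec, what = "channel") {
  if (is.null(spec)) return(seq_along(names))
  if (is.character(spec)) {
    idx <- match(spec, names)
    if (anyNA(idx))
      .stopContract(sprintf("unknown %s(s): %s", what,
                            paste(spec[is.na(idx)], collapse = ", ")))
  } else {
    idx <- as.integer(spec)
    if (any(idx < 1L | idx > length(names)))
      .stopContract(sprintf("%s index out of range (1..%d)", what,
                            length(names)))
  }
  idx
}

.asBinned <- function(x, config) {
  if (is(x, "BinnedChannels")) x else binRecord(x, config)
}

# ---- binning -------------------------------------------------------------

#' @describeIn binRecord Quantize each channel with
#'   \code{floor((value - anchor)/binWidth)}; deterministic, no clipping.
#' @export
setMethod("binRecord", "MultichannelRecord", function(record, config) {
  stopifnot(is(config, "BinningConfig"))
  bad <- which(!is.finite(record@data), arr.ind = TRUE)
  if (nrow(bad))
    .stopContract(sprintf(
      "non-finite amplitude at sample %d, channel '%s'",
      bad[1, 1], record@channelNames[bad[1, 2]]))
  bins <- floor((record@data - config@anchor) / config@binWidth)
  storage.mode(bins) <- "integer"
  new("BinnedChannels", bins = bins, channelNames = record@channelNames,
      config = config)
})

# ---- entropies -----------------------------------------------------------

#' @describeIn infotheory-generics Plug-in entropy of one channel (or all
#'   channels when \code{channel} is NULL), in units of the config's log
#'   base.
#' @param channel channel name or index (NULL = all channels).
#' @export
setMethod("channelEntropy", "BinnedChannels", function(x, channel = NULL, ...) {
  if (nrow(x@bins) < 1L) .stopContract("empty input")
  idx <- .resolveChannels(x@channelNames, channel)
  base <- x@config@logBase
  h <- vapply(idx, function(j) .binsEntropy(x@bins, j, base), numeric(1))
  names(h) <- x@channelNames[idx]
  if (length(idx) == 1L && !is.null(channel)) unname(h) else h
})

#' @describeIn infotheory-generics Joint entropy of a channel subset via a
#'   sparse map from observed bin tuple to count.
#' @param subset channel names or indices (NULL = all channels).
#' @export
setMethod("jointEntropy", "BinnedChannels", function(x, subset = NULL, ...) {
  idx <- .resolveChannels(x@channelNames, subset)
  if (!length(idx)) .stopContract("subset must be non-empty")
  if (anyDuplicated(idx)) .stopContract("duplicate channels in subset")
  .binsEntropy(x@bins, idx, x@config@logBase)
})

#' @describeIn infotheory-generics Mutual information
#'   I(X;Y) = H(X) + H(Y) - H(X,Y) between two channels; tiny negative
#'   values from floating arithmetic (> -1e-12) are clamped to 0.
#' @param i,j channel names or indices.
#' @export
setMethod("mutualInformation", "BinnedChannels", function(x, i, j, ...) {
  ii <- .resolveChannels(x@channelNames, i)
  jj <- .resolveChannels(x@channelNames, j)
  if (length(ii) != 1L || length(jj) != 1L)
    .stopContract("i and j must each name a single channel")
  base <- x@config@logBase
  hi <- .binsEntropy(x@bins, ii, base)
  if (ii == jj) return(hi)
  hj <- .binsEntropy(x@bins, jj, base)
  hij <- .binsEntropy(x@bins, c(ii, jj), base)
  mi <- hi + hj - hij
  if (mi < 0) {
    if (mi < -1e-12)
      .stopWith("ecgrInternalError",
                sprintf("mutual information %.3g below numerical tolerance", mi))
    mi <- 0
  }
  mi
})

#' @describeIn infotheory-generics Normalized mutual information
#'   NMI(X;Y) = I(X;Y)/H(X,Y), in [0,1]: 0 for independent, 1 for
#'   identical channels. Undefined when both channels are constant.
#' @export
setMethod("nmi", "BinnedChannels", function(x, i, j, ...) {
  ii <- .resolveChannels(x@channelNames, i)
  jj <- .resolveChannels(x@channelNames, j)
  if (length(ii) != 1L || length(jj) != 1L)
    .stopContract("i and j must each name a single channel")
  base <- x@config@logBase
  hij <- if (ii == jj) .binsEntropy(x@bins, ii, base)
         else .binsEntropy(x@bins, c(ii, jj), base)
  if (hij <= 0)
    .stopUndefined(sprintf(
      "NMI(%s, %s) undefined: joint entropy is zero (both channels constant)",
      x@channelNames[ii], x@channelNames[jj]))
  mi <- mutualInformation(x, ii, jj)
  mi / hij
})

#' @describeIn infotheory-generics Symmetric matrix of pairwise NMI values
#'   with unit diagonal (for non-constant channels).
#' @export
setMethod("nmiMatrix", "BinnedChannels", function(x, ...) {
  k <- ncol(x@bins)
  m <- diag(1, k)
  dimnames(m) <- list(x@channelNames, x@channelNames)
  for (a in seq_len(k)) {
    ha <- .binsEntropy(x@bins, a, x@config@logBase)
    if (ha <= 0)
      .stopUndefined(sprintf("channel '%s' is constant; its NMI is undefined",
                             x@channelNames[a]))
    for (b in seq_len(k)) if (b > a) {
      m[a, b] <- m[b, a] <- nmi(x, a, b)
    }
  }
  m
})

# ---- redundancy ----------------------------------------------------------

#' @describeIn infotheory-generics Per-channel redundancy
#'   R(Xi) = (H(Xi) - H(Xi | rest)) / H(Xi): the fraction of channel i's
#'   entropy recoverable from the remaining channels. The conditional term
#'   is computed by the chain rule as H(all) - H(all except i). Requires at
#'   least two channels and a non-constant channel i.
#' @export
setMethod("channelRedundancy", "BinnedChannels", function(x, channel = NULL, ...) {
  if (ncol(x@bins) < 2L)
    .stopContract("channel redundancy needs at least 2 channels to condition on")
  idx <- .resolveChannels(x@channelNames, channel)
  base <- x@config@logBase
  all <- seq_len(ncol(x@bins))
  hAll <- .binsEntropy(x@bins, all, base)
  r <- vapply(idx, function(i) {
    hi <- .binsEntropy(x@bins, i, base)
    if (hi <= 0)
      .stopUndefined(sprintf("channel '%s' is constant; its redundancy is undefined",
                             x@channelNames[i]))
    hRest <- .binsEntropy(x@bins, setdiff(all, i), base)
    .clampUnit((hi - (hAll - hRest)) / hi, 1e-9, "channel redundancy")
  }, numeric(1))
  names(r) <- x@channelNames[idx]
  if (length(idx) == 1L && !is.null(channel)) unname(r) else r
})

.clampUnit <- function(v, tol, what) {
  if (v < -tol || v > 1 + tol)
    .stopWith("ecgrInternalError",
              sprintf("%s = %.6g outside [0,1] beyond tolerance", what, v))
  min(max(v, 0), 1)
}

#' @describeIn infotheory-generics Set redundancy
#'   R(X1..Xn) = (H(X1..Xn) - sum_i H(Xi | rest)) / H(X1..Xn): the
#'   fraction of the joint entropy shared by at least two channels. Each
#'   conditional term is H(joint) - H(joint without that channel). A
#'   single-channel set has redundancy 0 by construction.
#' @param percent report on the 0-100 scale.
#' @export
setMethod("setRedundancy", "BinnedChannels",
          function(x, subset = NULL, percent = FALSE, ...) {
  idx <- .resolveChannels(x@channelNames, subset)
  if (!length(idx)) .stopContract("subset must be non-empty")
  if (anyDuplicated(idx)) .stopContract("duplicate channels in subset")
  base <- x@config@logBase
  hJoint <- .binsEntropy(x@bins, idx, base)
  if (hJoint <= 0)
    .stopUndefined("set redundancy undefined: all channels constant")
  r <- if (length(idx) == 1L) 0 else {
    # numerator: H - sum_i (H - H_{-i}) = (1-n) H + sum_i H_{-i}
    hMinus <- vapply(seq_along(idx), function(k)
      .binsEntropy(x@bins, idx[-k], base), numeric(1))
    .clampUnit(((1 - length(idx)) * hJoint + sum(hMinus)) / hJoint,
               1e-9, "set redundancy")
  }
  if (percent) r * 100 else r
})

#' @describeIn infotheory-generics Full redundancy report: per-channel and
#'   set redundancy plus the binning configuration that produced them.
#' @export
setMethod("redundancyReport", "BinnedChannels", function(x, ...) {
  k <- ncol(x@bins)
  perCh <- if (k >= 2L) channelRedundancy(x) else rep(NA_real_, k)
  new("RedundancyReport", channelNames = x@channelNames,
      perChannel = as.numeric(perCh), setR = setRedundancy(x),
      config = x@config, nSamples = nrow(x@bins))
})

# ---- record-level convenience methods ------------------------------------

.recordMethod <- function(generic) {
  force(generic)
  function(x, ..., config = BinningConfig()) {
    do.call(generic, c(list(binRecord(x, config)), list(...)))
  }
}

#' @rdname infotheory-generics
#' @param config binning configuration used when the input is an unbinned
#'   record.
#' @export
setMethod("channelEntropy", "MultichannelRecord", .recordMethod(channelEntropy))

#' @rdname infotheory-generics
#' @export
setMethod("jointEntropy", "MultichannelRecord", .recordMethod(jointEntropy))

#' @rdname infotheory-generics
#' @export
setMethod("mutualInformation", "MultichannelRecord", .recordMethod(mutualInformation))

#' @rdname infotheory-generics
#' @export
setMethod("nmi", "MultichannelRecord", .recordMethod(nmi))

#' @rdname infotheory-generics
#' @export
setMethod("nmiMatrix", "MultichannelRecord", .recordMethod(nmiMatrix))

#' @rdname infotheory-generics
#' @export
setMethod("channelRedundancy", "MultichannelRecord", .recordMethod(channelRedundancy))

#' @rdname infotheory-generics
#' @export
setMethod("setRedundancy", "MultichannelRecord", .recordMethod(setRedundancy))

#' @rdname infotheory-generics
#' @export
setMethod("redundancyReport", "MultichannelRecord", .recordMethod(redundancyReport))

# ---- morphology correlation ----------------------------------------------

#' Pearson correlation between two raw channels
#'
#' Morphology similarity between leads is quantified on the raw (unbinned)
#' amplitudes with the sample Pearson correlation coefficient.
#'
#' @param record a \linkS4class{MultichannelRecord}.
#' @param i,j channel names or indices.
#' @return correlation in [-1, 1].
#' @export
pcc <- function(record, i, j) {
  stopifnot(is(record, "MultichannelRecord"))
  ii <- .resolveChannels(record@channelNames, i)
  jj <- .resolveChannels(record@channelNames, j)
  if (length(ii) != 1L || length(jj) != 1L)
    .stopContract("i and j must each name a single channel")
  a <- record@data[, ii]
  b <- record@data[, jj]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    .stopUndefined("Pearson correlation undefined for a zero-variance channel")
  stats::cor(a, b)
}
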