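#' @include records-io.R
NULL

# leads the Dower matrices operate on, in matrix row order
.DOWER_LEADS <- c("V1", "V2", "V3", "V4", "V5", "V6", "I", "II")

.dowerForwardMatrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "dower_forward.csv",
                          package = "ecgredund", mustWork = TRUE)
      tab <- utils::read.csv(path, comment.char = "#",
                             stringsAsFactors = FALSE)
      m <- as.matrix(tab[, c("X", "Y", "Z")])
      rownames(m) <- tab$lead
      cache <<- m[.DOWER_LEADS, , drop = FALSE]
    }
    cache
  }
})

#' Dower transform specifications
#'
#' \code{dowerForwardSpec} is the published 8x3 forward Dower projection
#' that synthesizes the 8 independent ECG leads (V1-V6, I, II) from the
#' vectorcardiogram axes X, Y, Z. \code{inverseDowerSpec} is its
#' Moore-Penrose pseudoinverse (3x8), the inverse Dower transform (IDT),
#' computed from the forward matrix so that IDT composed with the forward
#' projection is the exact identity on 3-channel signals.
#'
#' @return A \linkS4class{TransformSpec}.
#' @export
dowerForwardSpec <- function() {
  D <- .dowerForwardMatrix()
  new("TransformSpec", name = "dower_forward",
      inputChannels = c("X", "Y", "Z"), outputChannels = .DOWER_LEADS,
      matrix = unname(D))
}

#' @rdname dowerForwardSpec
#' @export
inverseDowerSpec <- function() {
  D <- .dowerForwardMatrix()
  idt <- solve(crossprod(D), t(D))  # pseudoinverse of the full-rank forward map
  new("TransformSpec", name = "inverse_dower",
      inputChannels = .DOWER_LEADS, outputChannels = c("X", "Y", "Z"),
      matrix = unname(idt))
}

#' Apply a linear channel transform
#'
#' Selects the spec's input channels from the record (by name) and applies
#' the spec's matrix per sample.
#'
#' @param spec a \linkS4class{TransformSpec}.
#' @param record a \linkS4class{MultichannelRecord}.
#' @return A \linkS4class{MultichannelRecord} with the spec's output
#'   channels.
#' @export
applyTransform <- function(spec, record) {
  stopifnot(is(spec, "TransformSpec"), is(record, "MultichannelRecord"))
  missing <- setdiff(spec@inputChannels, record@channelNames)
  if (length(missing))
    .stopContract(sprintf("transform '%s' requires missing lead(s): %s",
                          spec@name, paste(missing, collapse = ", ")))
  inp <- record@data[, match(spec@inputChannels, record@channelNames),
                     drop = FALSE]
  out <- inp %*% t(spec@matrix)
  MultichannelRecord(out, channelNames = spec@outputChannels,
                     samplingRate = record@samplingRate,
                     label = record@label)
}

#' Derive the four dependent limb leads from I and II
#'
#' Applies the Einthoven and Goldberger identities: III = II - I,
#' aVR = -(I + II)/2, aVL = I - II/2, aVF = II - I/2. Only two of the six
#' limb leads are linearly independent; this reconstructs the full frontal
#' set.
#'
#' @param record a record containing channels I and II (mV).
#' @return A record with channels I, II, III, aVR, aVL, aVF.
#' @export
deriveLimbLeads <- function(record) {
  stopifnot(is(record, "MultichannelRecord"))
  missing <- setdiff(c("I", "II"), record@channelNames)
  if (length(missing))
    .stopContract(sprintf("limb-lead derivation requires lead(s): %s",
                          paste(missing, collapse = ", ")))
  I <- record@data[, match("I", record@channelNames)]
  II <- record@data[, match("II", record@channelNames)]
  out <- cbind(I = I, II = II, III = II - I, aVR = -(I + II) / 2,
               aVL = I - II / 2, aVF = II - I / 2)
  MultichannelRecord(out, samplingRate = record@samplingRate,
                     label = record@label)
}

#' Forward Dower projection of a vectorcardiogram
#'
#' @param record a 3-channel record with channels X, Y, Z (mV).
#' @return An 8-channel record with the independent leads V1-V6, I, II.
#' @export
dowerForward <- function(record) {
  stopifnot(is(record, "MultichannelRecord"))
  if (nChannels(record) != 3L)
    .stopContract(sprintf("forward Dower projection needs 3 channels, got %d",
                          nChannels(record)))
  applyTransform(dowerForwardSpec(), record)
}

#' Inverse Dower transform to an estimated vectorcardiogram
#'
#' Linearly converts the 8 independent leads (I, II, V1-V6) of a 12-lead
#' ECG into the 3-channel X/Y/Z vectorcardiogram estimate.
#'
#' @param record a record containing I, II and V1-V6 (mV).
#' @return A 3-channel record X, Y, Z.
#' @export
inverseDower <- function(record) {
  stopifnot(is(record, "MultichannelRecord"))
  applyTransform(inverseDowerSpec(), record)
}

#' Augment a 12-lead record to 15 channels
#'
#' Appends the inverse-Dower vectorcardiogram estimate (X, Y, Z) to the
#' original 12 leads. The appended channels are linear combinations of
#' channels already present, so all added information is redundant: the
#' set redundancy of the 15-channel record is at least that of the
#' original 12 leads.
#'
#' @param record a 12-lead record.
#' @return A 15-channel record: the original 12 leads followed by X, Y, Z.
#' @export
augment15 <- function(record) {
  stopifnot(is(record, "MultichannelRecord"))
  vcg <- inverseDower(record)
  MultichannelRecord(cbind(record@data, vcg@data),
                     channelNames = c(record@channelNames, c("X", "Y", "Z")),
                     samplingRate = record@samplingRate,
                     label = record@label)
}

#' Fit a corpus-level PCA transform
#'
#' Fits one principal component transform to the concatenated corpus
#' (channel covariance of all samples pooled across records); per-record
#' fits are deliberately not offered — a single linear map must apply to
#' every record so that transformed corpora remain comparable. Component
#' rows are orthonormal, ordered by non-increasing explained variance,
#' with the sign of each row fixed so its largest-magnitude entry is
#' positive.
#'
#' @param collection a \linkS4class{RecordCollection} (or single record /
#'   plain list of records).
#' @return A \linkS4class{PcaModel}.
#' @export
pcaFit <- function(collection) {
  if (is(collection, "MultichannelRecord"))
    collection <- RecordCollection(list(collection))
  corpus <- concatenateRecords(collection)
  x <- corpus@data
  if (nrow(x) <= ncol(x))
    .stopContract("PCA needs more pooled samples than channels")
  if (all(abs(sweep(x, 2, colMeans(x))) < .Machine$double.eps * 10))
    .stopUndefined("PCA undefined on a zero-variance corpus")
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rot <- t(pr$rotation)                      # components x channels
  for (r in seq_len(nrow(rot)))
    if (rot[r, which.max(abs(rot[r, ]))] < 0) rot[r, ] <- -rot[r, ]
  ev <- pr$sdev^2
  new("PcaModel", center = unname(pr$center), rotation = unname(rot),
      varianceFraction = ev / sum(ev), channelNames = corpus@channelNames)
}

#' Project a record onto leading principal components
#'
#' @param record a record with the model's input channels.
#' @param model a \linkS4class{PcaModel} from \code{\link{pcaFit}}.
#' @param q number of leading components to keep (1..component count).
#' @return A q-channel record with channels PC1..PCq.
#' @export
pcaTransform <- function(record, model, q = nrow(model@rotation)) {
  stopifnot(is(record, "MultichannelRecord"), is(model, "PcaModel"))
  if (q < 1 || q > nrow(model@rotation))
    .stopContract(sprintf("q must be in 1..%d", nrow(model@rotation)))
  missing <- setdiff(model@channelNames, record@channelNames)
  if (length(missing))
    .stopContract(sprintf("record lacks fitted channel(s): %s",
                          paste(missing, collapse = ", ")))
  x <- record@data[, match(model@channelNames, record@channelNames),
                   drop = FALSE]
  scores <- sweep(x, 2, model@center) %*% t(model@rotation[seq_len(q), ,
                                                           drop = FALSE])
  MultichannelRecord(scores, channelNames = paste0("PC", seq_len(q)),
                     samplingRate = record@samplingRate,
                     label = record@label)
}
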