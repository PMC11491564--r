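#' @include infotheory.R
NULL

#' Projection geometry of the standard 12-lead system
#'
#' Conventional hexaxial frontal-plane angles for the limb leads and
#' textbook transverse-plane angles for the precordial leads. Shipped as a
#' replaceable table: every geometry-dependent operation takes it as an
#' argument. Angles are in degrees in (-180, 180]; each lead is a unit
#' projection direction in its plane.
#'
#' @return data.frame with columns \code{lead}, \code{plane}
#'   (\code{frontal}/\code{transverse}) and \code{angle}.
#' @examples
#' leadGeometry()
#' @export
leadGeometry <- function() {
  data.frame(
    lead  = c("I", "II", "III", "aVR", "aVL", "aVF",
              "V1", "V2", "V3", "V4", "V5", "V6"),
    plane = c(rep("frontal", 6), rep("transverse", 6)),
    angle = c(0, 60, 120, -150, -30, 90,
              115, 95, 75, 60, 30, 0),
    stringsAsFactors = FALSE
  )
}

.STANDARD_LEADS <- leadGeometry()$lead

#' Absolute angle between two lead directions
#'
#' The smallest angle in absolute value between the two projection
#' directions, treating a direction and its reversal as equivalent; the
#' result is folded into [0, 90] degrees. Only within-plane comparisons
#' are meaningful.
#'
#' @param leadA,leadB lead labels.
#' @param geometry geometry table (default \code{\link{leadGeometry}()}).
#' @return angle in degrees in [0, 90].
#' @examples
#' absoluteAngle("I", "aVF")   # 90
#' absoluteAngle("II", "aVF")  # 30
#' @export
absoluteAngle <- function(leadA, leadB, geometry = leadGeometry()) {
  ga <- geometry[geometry$lead == leadA, ]
  gb <- geometry[geometry$lead == leadB, ]
  if (nrow(ga) != 1 || nrow(gb) != 1)
    .stopContract(sprintf("unknown lead(s): %s",
                          paste(setdiff(c(leadA, leadB), geometry$lead),
                                collapse = ", ")))
  if (ga$plane != gb$plane)
    .stopContract(sprintf(
      "leads %s (%s) and %s (%s) are in different planes; absolute angle is defined within a plane",
      leadA, ga$plane, leadB, gb$plane))
  d <- abs(ga$angle - gb$angle) %% 180
  min(d, 180 - d)
}

#' Fixed reduced lead subsets
#'
#' The shipped 8-, 6-, 3- and 1-lead subsets for the standard 12-lead
#' system. These are constants chosen from corpus-level redundancy
#' analysis of a large healthy 12-lead population, not recomputed per
#' call: the eight-lead set drops the four algebraically derivable limb
#' leads; the six-lead set keeps the lowest-redundancy orthogonal frontal
#' pair (II, aVL) plus V1, V3, V5, V6; the three-lead set maximizes
#' orthogonality (aVR, III, V2); the single lead is the most
#' representative one (V6). Use \code{\link{searchMinRedundancySubset}} to
#' re-derive subsets on any corpus.
#'
#' @param name one of \code{"eight"}, \code{"six"}, \code{"three"},
#'   \code{"one"}.
#' @return character vector of lead labels.
#' @export
fixedSubset <- function(name = c("eight", "six", "three", "one")) {
  if (length(name) != 1 || !name %in% c("eight", "six", "three", "one"))
    .stopContract("name must be one of eight, six, three, one")
  switch(name,
    eight = c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6"),
    six   = c("II", "aVL", "V1", "V3", "V5", "V6"),
    three = c("aVR", "III", "V2"),
    one   = "V6")
}

#' Rank lead pairs by set redundancy
#'
#' Evaluates the two-channel set redundancy of each candidate pair and
#' returns them sorted ascending (lowest redundancy = most complementary
#' pair first). Ties keep input order.
#'
#' @param x a \linkS4class{BinnedChannels} or
#'   \linkS4class{MultichannelRecord}.
#' @param pairs list of length-2 character vectors of lead labels.
#' @param config binning configuration for record input.
#' @return data.frame with columns \code{leads} (collapsed "A-B" label),
#'   \code{setR}, sorted ascending by \code{setR}.
#' @export
rankOrthogonalPairs <- function(x, pairs, config = BinningConfig()) {
  binned <- .asBinned(x, config)
  if (!length(pairs)) .stopContract("pairs must be non-empty")
  scores <- vapply(pairs, function(p) {
    if (length(p) != 2) .stopContract("each pair must have exactly 2 leads")
    setRedundancy(binned, subset = p)
  }, numeric(1))
  labels <- vapply(pairs, paste, character(1), collapse = "-")
  ord <- order(scores)  # stable: ties keep input order
  data.frame(leads = labels[ord], setR = scores[ord],
             stringsAsFactors = FALSE)
}

#' Most representative lead
#'
#' The channel with the highest per-channel redundancy, i.e. the lead
#' whose information is best recoverable from the remaining leads — the
#' natural single-lead choice. Ties break by channel order.
#'
#' @inheritParams rankOrthogonalPairs
#' @return lead label.
#' @export
mostRepresentativeLead <- function(x, config = BinningConfig()) {
  binned <- .asBinned(x, config)
  r <- channelRedundancy(binned)
  channelNames(binned)[which.max(r)]
}

#' Search for a minimum-redundancy lead subset
#'
#' Finds a size-k channel subset with low set redundancy. Exhaustive mode
#' scans all C(n,k) subsets (capped at 5000 candidate subsets; beyond
#' that, use greedy) and returns the minimum, ties resolved to the first
#' subset in lexicographic channel order. Greedy mode seeds with the
#' minimum-redundancy pair and grows by adding the channel that minimizes
#' the redundancy of the extended set.
#'
#' @inheritParams rankOrthogonalPairs
#' @param k subset size, 1..n channels.
#' @param mode \code{"exhaustive"} or \code{"greedy"}.
#' @return list with \code{leads} (character vector), \code{setR}, and
#'   \code{mode}.
#' @export
searchMinRedundancySubset <- function(x, k, mode = c("exhaustive", "greedy"),
                                      config = BinningConfig()) {
  binned <- .asBinned(x, config)
  mode <- match.arg(mode)
  n <- nChannels(binned)
  if (k < 1 || k > n)
    .stopContract(sprintf("k must be in 1..%d", n))
  nm <- channelNames(binned)
  if (k == 1) {
    # every single channel has set redundancy 0; lexicographic tie-break
    # picks the first channel
    return(list(leads = nm[1L], setR = 0, mode = mode))
  }
  if (mode == "exhaustive") {
    if (choose(n, k) > 5000)
      .stopContract(sprintf(
        "exhaustive search over C(%d,%d) = %g subsets exceeds the 5000 cap; use greedy mode",
        n, k, choose(n, k)))
    combos <- utils::combn(n, k)
    scores <- apply(combos, 2L, function(idx)
      setRedundancy(binned, subset = idx))
    best <- which.min(scores)  # first minimum = lexicographically first
    list(leads = nm[combos[, best]], setR = scores[best], mode = "exhaustive")
  } else {
    pairs <- utils::combn(n, 2)
    pairScores <- apply(pairs, 2L, function(idx)
      setRedundancy(binned, subset = idx))
    current <- pairs[, which.min(pairScores)]
    score <- min(pairScores)
    while (length(current) < k) {
      cand <- setdiff(seq_len(n), current)
      candScores <- vapply(cand, function(c)
        setRedundancy(binned, subset = c(current, c)), numeric(1))
      current <- c(current, cand[which.min(candScores)])
      score <- min(candScores)
    }
    list(leads = nm[current], setR = score, mode = "greedy")
  }
}
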