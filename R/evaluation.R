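#' @include AllClasses.R
NULL

#' Class-imbalance loss weights
#'
#' Inverse-frequency weights with a spread exponent:
#' \code{w_c = (sum_i n_i / n_c)^lambda}. Weights decrease strictly with
#' class count, so minority classes are up-weighted; \code{lambda > 1}
#' widens the relative spread between minority and majority weights,
#' \code{lambda < 1} flattens it. Weights are not normalized (loss
#' frameworks rescale freely).
#'
#' @param counts named positive integer vector of per-class sample counts
#'   (at least 2 classes).
#' @param lambda spread exponent, > 0.
#' @return named numeric vector of weights.
#' @examples
#' classWeights(c(NORM = 300, MI = 100), lambda = 1)   # 4/3 and 4
#' @export
classWeights <- function(counts, lambda = 1) {
  if (length(counts) < 2) .stopContract("at least 2 classes required")
  if (any(counts < 1)) .stopContract("class counts must be >= 1")
  if (length(lambda) != 1 || !is.finite(lambda) || lambda <= 0)
    .stopContract("lambda must be a single positive number")
  (sum(counts) / counts)^lambda
}

#' Confusion-matrix metrics for one positive class
#'
#' One-vs-rest sensitivity (recall), specificity, precision and F1 from
#' hard label predictions. A 0/0 ratio (e.g. precision with no positive
#' predictions) is returned as \code{NA}, the undefined marker excluded
#' from macro averaging.
#'
#' @param truth true labels.
#' @param predicted predicted labels (same length).
#' @param positive the class treated as positive.
#' @return named list: \code{SN}, \code{SP}, \code{Prec}, \code{F1}.
#' @export
confusionMetrics <- function(truth, predicted, positive) {
  if (length(truth) != length(predicted))
    .stopContract("truth and predicted must have the same length")
  if (!positive %in% c(truth, predicted))
    .stopContract(sprintf("positive class '%s' absent from labels", positive))
  tp <- sum(truth == positive & predicted == positive)
  fn <- sum(truth == positive & predicted != positive)
  fp <- sum(truth != positive & predicted == positive)
  tn <- sum(truth != positive & predicted != positive)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sn <- ratio(tp, tp + fn)
  sp <- ratio(tn, tn + fp)
  prec <- ratio(tp, tp + fp)
  f1 <- if (is.na(prec) || is.na(sn) || prec + sn == 0) NA_real_
        else 2 * prec * sn / (prec + sn)
  list(SN = sn, SP = sp, Prec = prec, F1 = f1)
}

#' Ranking metrics for one positive class
#'
#' AUC of the ROC curve via the rank statistic (equivalent to trapezoidal
#' integration with tie-averaging: the probability a random positive
#' outscores a random negative, ties counting half), and the area under
#' the precision-recall curve by step-wise integration over distinct
#' score thresholds.
#'
#' @param truth true labels.
#' @param scores numeric scores, higher = more positive.
#' @param positive the class treated as positive.
#' @return named list: \code{AUPRC}, \code{AUC}.
#' @export
curveMetrics <- function(truth, scores, positive) {
  if (length(truth) != length(scores))
    .stopContract("truth and scores must have the same length")
  pos <- truth == positive
  nPos <- sum(pos)
  nNeg <- sum(!pos)
  if (nPos == 0 || nNeg == 0)
    .stopUndefined("curve metrics undefined with single-class truth")
  r <- rank(scores)
  auc <- (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  # PR curve over decreasing score thresholds; ties handled by grouping
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  cumTp <- cumsum(p)
  cumFp <- cumsum(!p)
  last <- which(s != c(s[-1], NA))  # last index of each distinct score block
  tp <- cumTp[last]
  prec <- tp / (tp + cumFp[last])
  rec <- tp / nPos
  dRec <- diff(c(0, rec))
  auprc <- sum(dRec * prec)
  list(AUPRC = auprc, AUC = auc)
}

#' Macro average over per-class metric values
#'
#' Unweighted mean across classes, skipping undefined (\code{NA}) values.
#'
#' @param values numeric vector of one metric across classes.
#' @return mean of the defined values.
#' @export
macroAverage <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) .stopUndefined("no class has a defined value")
  mean(v)
}

#' Score multiclass predictions
#'
#' One-vs-rest confusion and (when scores are supplied) curve metrics per
#' class, plus their macro averages.
#'
#' @param truth true labels.
#' @param predicted predicted labels.
#' @param scores optional numeric matrix of per-class scores with one
#'   column per class (column names = class labels).
#' @param classes classes to evaluate (default: sorted unique truth
#'   labels).
#' @return data.frame with one row per class plus a \code{"macro"} row;
#'   columns SN, SP, Prec, F1 and, with scores, AUPRC and AUC.
#' @export
evaluatePredictions <- function(truth, predicted, scores = NULL,
                                classes = sort(unique(truth))) {
  rows <- lapply(classes, function(cl) {
    cm <- confusionMetrics(truth, predicted, cl)
    if (!is.null(scores)) {
      if (!cl %in% colnames(scores))
        .stopContract(sprintf("scores lack a column for class '%s'", cl))
      cm <- c(cm, curveMetrics(truth, scores[, cl], cl))
    }
    as.data.frame(cm)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- classes
  macro <- vapply(out, macroAverage, numeric(1))
  out <- rbind(out, macro = macro)
  out
}
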