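# Fixture builders and independent brute-force oracles used across tests.
# Oracles deliberately avoid the package's sparse-histogram/chain-rule code
# paths: they materialize explicit joint tuple distributions.

makeRecord <- function(..., rate = 500, label = NA_character_) {
  cols <- list(...)
  MultichannelRecord(do.call(cbind, cols), channelNames = names(cols),
                     samplingRate = rate, label = label)
}

randomRecord <- function(n, channels, seed, sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * channels, sd = sd), n, channels)
  MultichannelRecord(m, channelNames = paste0("ch", seq_len(channels)))
}

# explicit joint tuple distribution over selected columns of a bin matrix
bruteJointProbs <- function(bins, cols) {
  keys <- apply(bins[, cols, drop = FALSE], 1L, paste, collapse = "|")
  tab <- table(keys)
  as.numeric(tab) / sum(tab)
}

bruteEntropy <- function(bins, cols, base = 2) {
  p <- bruteJointProbs(bins, cols)
  -sum(p * log(p)) / log(base)
}

# conditional entropy H(A | B) by direct conditioning (never the chain rule)
bruteConditionalEntropy <- function(bins, aCols, bCols, base = 2) {
  bKeys <- apply(bins[, bCols, drop = FALSE], 1L, paste, collapse = "|")
  total <- 0
  for (bv in unique(bKeys)) {
    idx <- bKeys == bv
    pb <- mean(idx)
    aKeys <- apply(bins[idx, aCols, drop = FALSE], 1L, paste, collapse = "|")
    pa <- as.numeric(table(aKeys)) / sum(idx)
    total <- total + pb * (-sum(pa * log(pa)) / log(base))
  }
  total
}

bruteChannelRedundancy <- function(bins, i, base = 2) {
  hi <- bruteEntropy(bins, i, base)
  rest <- setdiff(seq_len(ncol(bins)), i)
  (hi - bruteConditionalEntropy(bins, i, rest, base)) / hi
}

bruteSetRedundancy <- function(bins, cols, base = 2) {
  if (length(cols) == 1L) return(0)
  hj <- bruteEntropy(bins, cols, base)
  condSum <- sum(vapply(seq_along(cols), function(k)
    bruteConditionalEntropy(bins, cols[k], cols[-k], base), numeric(1)))
  (hj - condSum) / hj
}

# AUC as the fraction of correctly ordered positive-negative score pairs
# (ties count one half)
bruteAuc <- function(truth, scores, positive) {
  pos <- scores[truth == positive]
  neg <- scores[truth != positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# small binned fixture with mixed dependence for oracle comparisons
oracleBinned <- function() {
  rec <- makeRecord(
    a = c(0.1, 0.6, 1.2, 0.1, 0.6, 1.7, 0.1, 0.6),
    b = c(0.1, 0.6, 0.6, 0.1, 1.2, 0.6, 0.6, 0.1),
    c = c(1.2, 0.1, 0.6, 1.2, 0.1, 0.1, 0.6, 0.6))
  binRecord(rec)
}

# a small labelled synthetic corpus shared by selection/transform tests;
# computed once per test run
sharedCorpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateCorpus(12, c(NORM = 1), dipoleParams(seed = 2024L))
    cache
  }
})
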