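## Confusion-matrix mutual information with shuffle bias correction.
## Probabilities are plug-in (counts / total, no smoothing); the 0 log 0
## convention applies. Finite-sampling bias is estimated by permuting the
## tilt labels, re-running the leave-one-out classification against the
## permuted labels, and averaging the resulting information.

.miCounts <- function(m) {
  total <- sum(m)
  if (total <= 0) stop("confusion matrix has no counts")
  p <- m / total
  pr <- rowSums(p)
  ps <- colSums(p)
  e <- outer(pr, ps)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / e[nz]))
}

#' Mutual information of a confusion matrix
#'
#' Plug-in estimate \eqn{I(r;s) = \sum_{r,s} P(r,s) \log_2 \frac{P(r,s)}
#' {P(r)P(s)}} in bits, with probabilities taken as counts / total and the
#' convention \eqn{0 \log 0 = 0}. For a 4x4 matrix the value lies in
#' [0, 2] bits.
#'
#' @param cm a [ConfusionMatrix-class] or a non-negative count matrix.
#' @return Mutual information in bits.
#' @export
#' @examples
#' mutualInformation(confusionMatrix(diag(100, 4)))  # 2 bits
#' mutualInformation(confusionMatrix(matrix(25, 4, 4)))  # 0 bits
mutualInformation <- function(cm) {
  m <- if (is(cm, "ConfusionMatrix")) confusionCounts(cm) else as.matrix(cm)
  if (any(m < 0)) stop("counts must be non-negative")
  .miCounts(m)
}

## draw label permutations once so paired analyses (ensemble vs singles)
## can reuse identical shuffles
.drawPermutations <- function(n, nShuffles, seed) {
  withSeed(seed, replicate(nShuffles, sample.int(n), simplify = FALSE))
}

#' Shuffle-bias-corrected mutual information
#'
#' Computes the raw information of the leave-one-out template-classifier
#' confusion matrix, then estimates the finite-sampling bias as the mean
#' information over \code{nShuffles} random permutations of the tilt-label
#' vector (classification re-run against the shuffled labels, which
#' eliminates the response-stimulus association). Corrected information is
#' \code{raw - bias}; estimates with corrected information not above 0 are
#' flagged excluded from population analyses.
#'
#' @param responses numeric matrix, trials x features (binned spike
#'   counts).
#' @param labels integer tilt types (1-4), one per trial; every represented
#'   type needs at least 2 trials.
#' @param nShuffles number of label permutations (>= 1; 50 gives a stable
#'   bias estimate).
#' @param seed integer seed for the permutations.
#' @param mode estimate label: \code{"timing"}, \code{"count"} or
#'   \code{"ensemble"}.
#' @param permutations optional pre-drawn list of permutation vectors
#'   (overrides \code{nShuffles}/\code{seed}); used to pair ensemble and
#'   single-neuron bias estimates on identical shuffles.
#' @return An [InfoEstimate-class].
#' @export
biasCorrectedInformation <- function(responses, labels, nShuffles = 50,
                                     seed = NULL, mode = "timing",
                                     permutations = NULL) {
  X <- as.matrix(responses)
  y <- as.integer(labels)
  if (nrow(X) != length(y)) stop("responses and labels differ in length")
  if (any(tabulate(y, 4L)[unique(y)] < 2))
    stop("every represented tilt type needs >= 2 trials")
  if (is.null(permutations)) {
    if (nShuffles < 1) stop("nShuffles must be >= 1")
    permutations <- .drawPermutations(length(y), nShuffles, seed)
  }
  pred <- .looPredict(X, y)
  raw <- .miCounts(confusionCounts(confusionMatrix(y, pred)))
  shuffled <- vapply(permutations, function(p) {
    ys <- y[p]
    ps <- .looPredict(X, ys)
    .miCounts(confusionCounts(confusionMatrix(ys, ps)))
  }, numeric(1))
  bias <- mean(shuffled)
  corrected <- raw - bias
  new("InfoEstimate", raw = raw, bias = bias, corrected = corrected,
      nShuffles = length(permutations), mode = mode,
      included = corrected > 0)
}

## per-trial response features for information analyses (post-tilt window)
.infoFeatures <- function(session, neuronIds, binWidth,
                          window = c(0, 200)) {
  tr <- trialTable(session)
  edges <- .binEdgesFor(window, binWidth)
  list(X = .trialFeatureMatrix(session, neuronIds, tr$trial_id, edges),
       y = tr$tilt_type)
}

#' Spike-timing and spike-count information for one neuron
#'
#' Both measures use the 200 ms window from tilt start: timing information
#' bins it into ten 20 ms bins, count information into one 200 ms bin.
#' Each is bias-corrected with [biasCorrectedInformation()] on the same
#' label permutations, and their difference (timing - count) is the
#' temporal information gained from spike timing beyond spike count.
#'
#' @param session a [SessionRecording-class].
#' @param neuronId single neuron id.
#' @param firstN leading-trials filter (default 300).
#' @param nShuffles label permutations for the bias estimate.
#' @param seed integer seed.
#' @return List with \code{timing} and \code{count}
#'   ([InfoEstimate-class]) and \code{temporal} (bits,
#'   \code{correctedInfo(timing) - correctedInfo(count)}).
#' @export
timingAndCountInformation <- function(session, neuronId, firstN = 300,
                                      nShuffles = 50, seed = NULL) {
  sess <- filterFirstN(session, firstN)
  perms <- .drawPermutations(nrow(trialTable(sess)), nShuffles, seed)
  ft <- .infoFeatures(sess, neuronId, binWidth = 20)
  fc <- .infoFeatures(sess, neuronId, binWidth = 200)
  timing <- biasCorrectedInformation(ft$X, ft$y, mode = "timing",
                                     permutations = perms)
  count <- biasCorrectedInformation(fc$X, fc$y, mode = "count",
                                    permutations = perms)
  list(timing = timing, count = count,
       temporal = correctedInfo(timing) - correctedInfo(count))
}

#' Ensemble redundancy for one hemisphere
#'
#' Computes \code{P = I_ensemble - sum(I_neuron)} where \code{I_ensemble}
#' is the bias-corrected information of the leave-one-out classifier run
#' on all recorded neurons of the hemisphere jointly (concatenated 20 ms
#' binned responses over the 0-200 ms window) and the sum runs over single
#' neurons with corrected information above 0. The reported
#' \code{redundancy} is \code{-P}, so larger values mean more overlapping
#' information. Ensemble and single-neuron bias estimates share the same
#' label permutations, so a single-neuron hemisphere gives \code{P = 0}
#' exactly.
#'
#' @param session a [SessionRecording-class].
#' @param hemisphere \code{"direct"} or \code{"indirect"}.
#' @param firstN leading-trials filter (default 300).
#' @param nShuffles label permutations.
#' @param seed integer seed.
#' @param neurons optional explicit neuron subset (overrides
#'   \code{hemisphere}).
#' @return A [RedundancyResult-class].
#' @export
ensembleRedundancy <- function(session, hemisphere = c("direct",
                                                       "indirect"),
                               firstN = 300, nShuffles = 50, seed = NULL,
                               neurons = NULL) {
  sess <- filterFirstN(session, firstN)
  if (is.null(neurons)) {
    hemisphere <- match.arg(hemisphere)
    nr <- neuronRoster(sess)
    neurons <- nr$neuron_id[nr$hemisphere == hemisphere]
  }
  if (length(neurons) == 0) stop("no neurons in the requested hemisphere")
  perms <- .drawPermutations(nrow(trialTable(sess)), nShuffles, seed)
  single <- vapply(neurons, function(id) {
    f <- .infoFeatures(sess, id, binWidth = 20)
    correctedInfo(biasCorrectedInformation(f$X, f$y, mode = "timing",
                                           permutations = perms))
  }, numeric(1))
  included <- single > 0
  if (!any(included))
    stop("no neuron with bias-corrected information above 0")
  fe <- .infoFeatures(sess, neurons, binWidth = 20)
  ens <- biasCorrectedInformation(fe$X, fe$y, mode = "ensemble",
                                  permutations = perms)
  ensInfo <- correctedInfo(ens)
  sumSingle <- sum(single[included])
  P <- ensInfo - sumSingle
  new("RedundancyResult", ensembleInfo = ensInfo,
      sumSingleInfo = sumSingle, P = P, redundancy = -P,
      singleInfo = single, nIncluded = sum(included))
}

#' Pearson correlation between mean information and redundancy z-score
#'
#' Correlates the per-day average corrected mutual information across a
#' hemisphere's neurons with the per-day redundancy z-score (z-scored per
#' animal across its training days).
#'
#' @param meanInfo numeric per-day mean corrected information (bits).
#' @param redundancyZ numeric per-day redundancy z-scores (same length).
#' @return Pearson r, or \code{NA} with a warning if either series has
#'   zero variance.
#' @export
#' @examples
#' infoRedundancyCorrelation(1:5, (1:5) * 2 - 3)  # 1
infoRedundancyCorrelation <- function(meanInfo, redundancyZ) {
  if (length(meanInfo) != length(redundancyZ))
    stop("series lengths differ")
  if (length(meanInfo) < 3) stop("need >= 3 days")
  if (stats::sd(meanInfo) == 0 || stats::sd(redundancyZ) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(meanInfo, redundancyZ)
}
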