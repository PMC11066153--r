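## PSTH construction. Bins are half-open [left, right): a spike at exactly
## the right edge of the last bin is excluded. Decoding templates use
## 20 ms bins over the full -200..200 ms window; responsiveness uses 2 ms
## bins; information analyses use the 0..200 ms post-tilt half.

.binEdgesFor <- function(window, binWidth) {
  if (length(window) != 2L || window[2] <= window[1])
    stop("window must be c(left, right) with left < right")
  span <- window[2] - window[1]
  nb <- span / binWidth
  if (abs(nb - round(nb)) > 1e-9)
    stop("window bounds must be a multiple of the bin width")
  seq(window[1], window[2], by = binWidth)
}

## Per-trial binned spike counts as a trials x (neurons * bins) matrix,
## columns ordered neuron-major (all bins of roster[1], then roster[2], ...).
## Neurons absent from the spike table contribute zero counts.
.trialFeatureMatrix <- function(session, roster, trialIds, edges) {
  sp <- spikeTable(session)
  nT <- length(trialIds)
  nB <- length(edges) - 1L
  nN <- length(roster)
  keep <- sp$neuron_id %in% roster & sp$trial_id %in% trialIds &
    sp$time_ms >= edges[1] & sp$time_ms < edges[nB + 1L]
  sp <- sp[keep, , drop = FALSE]
  X <- matrix(0, nT, nN * nB)
  if (nrow(sp)) {
    ti <- match(sp$trial_id, trialIds)
    ni <- match(sp$neuron_id, roster)
    bi <- floor((sp$time_ms - edges[1]) / (edges[2] - edges[1])) + 1L
    bi[bi > nB] <- nB # guard exact arithmetic at the right edge of inner bins
    col <- (ni - 1L) * nB + bi
    counts <- tabulate((col - 1L) * nT + ti, nbins = nT * nN * nB)
    X[] <- matrix(counts, nT, nN * nB)
  }
  X
}

.psthFromFeatures <- function(X, roster, edges, tilts) {
  nB <- length(edges) - 1L
  vals <- matrix(colMeans(X), length(roster), nB, byrow = TRUE)
  rownames(vals) <- roster
  new("PsthMatrix", values = vals, binEdges = edges,
      tiltTypes = as.integer(sort(unique(tilts))),
      nTrials = nrow(X))
}

#' Build per-tilt-type PSTHs for a session
#'
#' Computes, for each of the four tilt types, the mean binned response of
#' every neuron across the included trials (spikes in bin / number of
#' trials), on half-open uniform bins.
#'
#' @param session a [SessionRecording-class].
#' @param neurons character vector of neuron ids (default: full roster,
#'   optionally restricted by \code{hemisphere}).
#' @param binWidth bin width in ms (20 for decoding templates).
#' @param window \code{c(left, right)} ms window; bounds must be multiples
#'   of \code{binWidth}.
#' @param trials integer vector of trial ids to include (default: all).
#' @param hemisphere optionally restrict to \code{"direct"} or
#'   \code{"indirect"} neurons.
#' @return Named list of four [PsthMatrix-class] objects (\code{"1"} to
#'   \code{"4"}).
#' @export
#' @examples
#' ns <- neuronSpec("n1", "direct", 5, c(40, 0, 0, 0), rep(60, 4), 0, 15)
#' s <- simulateSession(ns, 0, 40, seed = 1)
#' p <- buildPsth(s)
#' p[["1"]]
buildPsth <- function(session, neurons = NULL, binWidth = 20,
                      window = tiltWindow(), trials = NULL,
                      hemisphere = NULL) {
  edges <- .binEdgesFor(window, binWidth)
  roster <- .resolveRoster(session, neurons, hemisphere)
  tr <- trialTable(session)
  if (!is.null(trials)) tr <- tr[tr$trial_id %in% trials, , drop = FALSE]
  out <- vector("list", 4L)
  names(out) <- as.character(1:4)
  for (tt in 1:4) {
    ids <- tr$trial_id[tr$tilt_type == tt]
    if (length(ids) == 0)
      stop("no trials of tilt type ", tt, " in the requested subset")
    X <- .trialFeatureMatrix(session, roster, ids, edges)
    out[[tt]] <- .psthFromFeatures(X, roster, edges, tt)
  }
  out
}

#' Pooled PSTH over an arbitrary set of tilt types
#'
#' Pools the trials of several tilt types into one PSTH, as used by the
#' grouped tilt contrasts (e.g. all right tilts, fast and slow pooled).
#'
#' @inheritParams buildPsth
#' @param tilts integer vector of tilt types to pool (subset of 1:4).
#' @return A [PsthMatrix-class].
#' @export
psthPooled <- function(session, tilts, neurons = NULL, binWidth = 20,
                       window = tiltWindow(), trials = NULL,
                       hemisphere = NULL) {
  if (!length(tilts) || !all(tilts %in% 1:4))
    stop("tilts must be a non-empty subset of 1:4")
  edges <- .binEdgesFor(window, binWidth)
  roster <- .resolveRoster(session, neurons, hemisphere)
  tr <- trialTable(session)
  if (!is.null(trials)) tr <- tr[tr$trial_id %in% trials, , drop = FALSE]
  ids <- tr$trial_id[tr$tilt_type %in% tilts]
  if (length(ids) == 0) stop("no trials of the requested tilt types")
  X <- .trialFeatureMatrix(session, roster, ids, edges)
  .psthFromFeatures(X, roster, edges, tilts)
}

#' Build a day's decoder template set
#'
#' Wraps [buildPsth()] into a [TemplateSet-class]: the four per-tilt-type
#' templates on a fixed neuron roster, carrying the session day.
#'
#' @inheritParams buildPsth
#' @return A [TemplateSet-class].
#' @export
buildTemplates <- function(session, neurons = NULL, binWidth = 20,
                           window = tiltWindow(), trials = NULL,
                           hemisphere = NULL) {
  psths <- buildPsth(session, neurons = neurons, binWidth = binWidth,
                     window = window, trials = trials,
                     hemisphere = hemisphere)
  roster <- rownames(psthValues(psths[[1]]))
  new("TemplateSet", day = sessionDay(session), roster = roster,
      binEdges = binEdges(psths[[1]]), templates = psths)
}

.resolveRoster <- function(session, neurons, hemisphere) {
  nr <- neuronRoster(session)
  roster <- if (is.null(neurons)) nr$neuron_id else as.character(neurons)
  if (!is.null(hemisphere)) {
    hemisphere <- match.arg(hemisphere, c("direct", "indirect"))
    roster <- roster[roster %in% nr$neuron_id[nr$hemisphere == hemisphere]]
  }
  bad <- setdiff(roster, nr$neuron_id)
  if (length(bad))
    stop("neurons not in the session roster: ", paste(bad, collapse = ", "))
  if (length(roster) == 0) stop("empty neuron roster")
  roster
}
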