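## Minimum-Euclidean-distance template decoding. A single trial is binned
## with the template bin edges and roster (neuron-major concatenation) and
## assigned to the tilt type whose template vector is nearest; ties break
## to the lowest tilt index.

## template matrix: 4 x features, rows = tilt types, neuron-major columns
.templateMatrix <- function(ts) {
  t(vapply(templates(ts),
           function(p) as.numeric(t(psthValues(p))),
           numeric(length(decodingRoster(ts)) *
                     (length(binEdges(ts)) - 1L))))
}

## nearest template by Euclidean distance; ties -> lowest row index
.nearestTemplate <- function(x, Tmat) {
  d2 <- unname(colSums((t(Tmat) - x)^2))
  list(predicted = which.min(d2), distances = sqrt(d2))
}

#' Classify one trial against a template set
#'
#' Bins the trial's spikes with the template bin edges and neuron roster
#' (neurons missing from the trial contribute zero counts) and predicts the
#' tilt type with the smallest Euclidean distance between the concatenated
#' single-trial count vector and the concatenated template vector. Equal
#' distances break to the lowest tilt-type index.
#'
#' @param session a [SessionRecording-class] containing the trial.
#' @param trialId trial id to classify.
#' @param templateSet a [TemplateSet-class].
#' @return List with \code{predicted} (integer tilt type) and
#'   \code{distances} (named numeric length 4).
#' @export
classifyTrial <- function(session, trialId, templateSet) {
  roster <- decodingRoster(templateSet)
  known <- neuronRoster(session)$neuron_id
  if (!all(roster %in% known))
    stop("template roster contains neurons unknown to the session")
  if (!trialId %in% trialTable(session)$trial_id)
    stop("trial ", trialId, " not in session")
  x <- .trialFeatureMatrix(session, roster, trialId,
                           binEdges(templateSet))[1, ]
  res <- .nearestTemplate(x, .templateMatrix(templateSet))
  names(res$distances) <- 1:4
  res
}

## Leave-one-out nearest-class-mean prediction. X: trials x features,
## y: integer labels 1..4. For trial i the class-y_i template is rebuilt
## without trial i; other templates are plain class means.
.looPredict <- function(X, y) {
  n <- nrow(X)
  counts <- tabulate(y, nbins = 4L)
  if (any(counts > 0 & counts < 2))
    stop("leave-one-out needs >= 2 trials per represented tilt type")
  S <- matrix(0, 4L, ncol(X))
  present <- rowsum(X, group = factor(y, levels = 1:4))
  S[as.integer(rownames(present)), ] <- present
  Tbase <- S / pmax(counts, 1L)
  ## distances to unadjusted class means
  D2 <- matrix(rowSums(X^2), n, 4L) -
    2 * X %*% t(Tbase) +
    matrix(rowSums(Tbase^2), n, 4L, byrow = TRUE)
  ## own-class template excludes the held-out trial
  Tadj <- (S[y, , drop = FALSE] - X) / (counts[y] - 1L)
  D2[cbind(seq_len(n), y)] <- rowSums((X - Tadj)^2)
  D2[D2 < 0] <- 0 # numerical guard
  max.col(-D2, ties.method = "first")
}

#' Offline (leave-one-out) decoding of a session
#'
#' For every retained trial, templates are rebuilt from all other retained
#' trials and the trial is classified; accuracy is the fraction of correct
#' predictions. Only the first \code{firstN} trials of the session are
#' analysed (fatigue filter).
#'
#' @param session a [SessionRecording-class].
#' @param hemisphere \code{"direct"}, \code{"indirect"} or \code{"both"}.
#' @param firstN number of leading trials to analyse (default 300); use
#'   \code{Inf} for all.
#' @param binWidth template bin width, ms.
#' @param window decoding window, ms.
#' @param neurons optional explicit neuron subset.
#' @return List with \code{confusion} ([ConfusionMatrix-class]),
#'   \code{accuracy}, and \code{predictions} (data.frame of trial_id,
#'   actual, predicted, correct).
#' @export
#' @examples
#' ns <- defaultNeurons(2, seed = 1)
#' s <- simulateSession(ns, 0, 80, seed = 2)
#' decodeOffline(s, firstN = Inf)$accuracy
decodeOffline <- function(session, hemisphere = c("both", "direct",
                                                  "indirect"),
                          firstN = 300, binWidth = 20,
                          window = tiltWindow(), neurons = NULL) {
  hemisphere <- match.arg(hemisphere)
  hemi <- if (hemisphere == "both") NULL else hemisphere
  sess <- filterFirstN(session, firstN)
  roster <- .resolveRoster(sess, neurons, hemi)
  tr <- trialTable(sess)
  if (any(tabulate(tr$tilt_type, 4L) < 2))
    stop("need >= 2 trials per tilt type after the first-N filter")
  edges <- .binEdgesFor(window, binWidth)
  X <- .trialFeatureMatrix(sess, roster, tr$trial_id, edges)
  pred <- .looPredict(X, tr$tilt_type)
  cm <- confusionMatrix(tr$tilt_type, pred)
  list(confusion = cm,
       accuracy = decodingAccuracy(cm),
       predictions = data.frame(trial_id = tr$trial_id,
                                actual = tr$tilt_type,
                                predicted = pred,
                                correct = pred == tr$tilt_type))
}

#' Online decoding with the previous day's templates
#'
#' Reconciles the neuron rosters of the two days (only neurons firing on
#' both days are used), builds fixed templates from yesterday's session,
#' classifies every trial of today's session, and writes the
#' correct/incorrect outcomes back into today's trial table.
#'
#' @param today,yesterday [SessionRecording-class] objects for consecutive
#'   days (day 1 uses the day-0 baseline as \code{yesterday}).
#' @param hemisphere hemisphere used by the decoder (default
#'   \code{"direct"}).
#' @param binWidth,window template binning (20 ms bins over the full
#'   peri-tilt window).
#' @return List with \code{session} (today with outcomes filled in),
#'   \code{confusion}, \code{accuracy}, \code{roster} and
#'   \code{predictions}.
#' @export
decodeOnline <- function(today, yesterday,
                         hemisphere = c("direct", "indirect", "both"),
                         binWidth = 20, window = tiltWindow()) {
  hemisphere <- match.arg(hemisphere)
  hemi <- if (hemisphere == "both") NULL else hemisphere
  roster <- reconcileRoster(yesterday, today, hemisphere = hemi)
  if (length(roster) == 0)
    stop("empty reconciled roster: no neuron fired on both days")
  ts <- buildTemplates(yesterday, neurons = roster, binWidth = binWidth,
                       window = window)
  tr <- trialTable(today)
  edges <- binEdges(ts)
  X <- .trialFeatureMatrix(today, roster, tr$trial_id, edges)
  Tmat <- .templateMatrix(ts)
  D2 <- matrix(rowSums(X^2), nrow(X), 4L) -
    2 * X %*% t(Tmat) +
    matrix(rowSums(Tmat^2), nrow(X), 4L, byrow = TRUE)
  pred <- max.col(-D2, ties.method = "first")
  correct <- pred == tr$tilt_type
  tr$outcome <- ifelse(correct, "correct", "incorrect")
  out <- sessionRecording(animalId(today), sessionDay(today), tr,
                          spikeTable(today), neuronRoster(today))
  cm <- confusionMatrix(trialTable(today)$tilt_type, pred)
  list(session = out, confusion = cm,
       accuracy = decodingAccuracy(cm), roster = roster,
       predictions = data.frame(trial_id = tr$trial_id,
                                actual = trialTable(today)$tilt_type,
                                predicted = pred, correct = correct))
}

#' Reconcile decoder rosters across consecutive days
#'
#' The decoder only uses neurons present (firing at least one spike) on
#' both the template day and the decoding day: units that stopped firing
#' are dropped, and newly appearing units are recorded but not decoded
#' until they have been present for a full previous day.
#'
#' @param yesterday,today [SessionRecording-class] objects.
#' @param hemisphere optionally restrict to one hemisphere.
#' @return Character vector of neuron ids usable for decoding today.
#' @export
#' @examples
#' ## a neuron silent yesterday is excluded today
reconcileRoster <- function(yesterday, today, hemisphere = NULL) {
  firing <- function(s) {
    ids <- unique(spikeTable(s)$neuron_id)
    nr <- neuronRoster(s)
    ids <- intersect(nr$neuron_id, ids)
    if (!is.null(hemisphere))
      ids <- ids[ids %in% nr$neuron_id[nr$hemisphere == hemisphere]]
    ids
  }
  y <- firing(yesterday)
  t <- firing(today)
  y[y %in% t]
}
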