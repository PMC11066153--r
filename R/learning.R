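## Session- and experiment-level learning measures: performance
## normalisation, learner/nonlearner classification, early/late phases,
## naive-vs-expert PSTH distances on grouped tilts, and the intertrial
## cumulative-sum analysis.

#' Keep only the first n trials of a session
#'
#' Retains the leading \code{n} trials in session order (fatigue filter;
#' 300 by convention) and drops the spikes of excluded trials. Shorter
#' sessions pass through unchanged.
#'
#' @param session a [SessionRecording-class].
#' @param n number of leading trials to keep (\code{Inf} for all).
#' @return A [SessionRecording-class] subset.
#' @export
filterFirstN <- function(session, n = 300) {
  tr <- trialTable(session)
  if (!is.finite(n) || nrow(tr) <= n) return(session)
  tr <- tr[seq_len(n), , drop = FALSE]
  sp <- spikeTable(session)
  sp <- sp[sp$trial_id %in% tr$trial_id, , drop = FALSE]
  rownames(sp) <- NULL
  sessionRecording(animalId(session), sessionDay(session), tr, sp,
                   neuronRoster(session))
}

#' Normalize a daily performance series to a reference day
#'
#' Expresses each day's decoding accuracy as the change from a reference
#' day: online series are referenced to the day-0 baseline, offline
#' (leave-one-out) series to the first training day.
#'
#' @param series data.frame with columns \code{day} and \code{accuracy}
#'   (fractions in [0, 1]).
#' @param referenceDay day whose accuracy anchors the series (must be
#'   present).
#' @return The series with an added \code{normalized} column
#'   (\code{accuracy - accuracy[reference]}; 0 at the reference day).
#' @export
#' @examples
#' normalizePerformance(data.frame(day = 1:3,
#'                                 accuracy = c(.3, .4, .5)), 1)
normalizePerformance <- function(series, referenceDay) {
  if (!all(c("day", "accuracy") %in% names(series)))
    stop("series needs columns day and accuracy")
  ref <- series$accuracy[series$day == referenceDay]
  if (length(ref) != 1L)
    stop("reference day ", referenceDay, " not present exactly once")
  series$normalized <- series$accuracy - ref
  series
}

#' Classify an animal as learner or nonlearner
#'
#' An animal is a learner when its training performance shows at least
#' \code{minRun} consecutive days each strictly above the first training
#' day's performance; otherwise it is a nonlearner. Control animals are
#' assigned by design, not by this rule.
#'
#' @param series data.frame with columns \code{day} and \code{accuracy}
#'   for the training days (>= 5 rows), in day order.
#' @param minRun run length required (5 by the study rule).
#' @param strict compare with \code{>} (TRUE, default) or \code{>=}.
#' @return \code{"learner"} or \code{"nonlearner"}.
#' @export
#' @examples
#' acc <- c(.3, .4, .41, .42, .43, .44, .35)
#' classifyLearner(data.frame(day = 1:7, accuracy = acc))
classifyLearner <- function(series, minRun = 5, strict = TRUE) {
  if (!all(c("day", "accuracy") %in% names(series)))
    stop("series needs columns day and accuracy")
  series <- series[order(series$day), , drop = FALSE]
  if (nrow(series) < minRun)
    stop("need at least ", minRun, " training days")
  ref <- series$accuracy[1]
  above <- if (strict) series$accuracy > ref else series$accuracy >= ref
  if (maxRunLength(above) >= minRun) "learner" else "nonlearner"
}

#' Split training days into early and late phases
#'
#' @param days integer vector of training days (>= 10 distinct days).
#' @return List with \code{early} (first 5 days) and \code{late} (last 5
#'   days).
#' @export
#' @examples
#' splitPhases(1:25)
splitPhases <- function(days) {
  days <- sort(unique(as.integer(days)))
  if (length(days) < 10)
    stop("need >= 10 training days to define early and late phases")
  list(early = days[1:5], late = days[(length(days) - 4):length(days)])
}

#' Population Euclidean distance between two PSTHs
#'
#' Lines the two PSTHs up bin-wise, takes each neuron's Euclidean distance
#' over the bins, and averages across neurons:
#' \eqn{d = \frac{1}{N}\sum_n \sqrt{\sum_b (T1_{nb} - T2_{nb})^2}}.
#'
#' @param psthA,psthB [PsthMatrix-class] objects on the same neuron set
#'   and bin edges.
#' @param perNeuron return the per-neuron distances instead of their mean.
#' @return Population distance (or named per-neuron vector).
#' @export
tiltPairDistance <- function(psthA, psthB, perNeuron = FALSE) {
  A <- psthValues(psthA)
  B <- psthValues(psthB)
  if (!identical(rownames(A), rownames(B)))
    stop("neuron sets differ between the two PSTHs")
  if (!isTRUE(all.equal(binEdges(psthA), binEdges(psthB))))
    stop("bin edges differ between the two PSTHs")
  d <- sqrt(rowSums((A - B)^2))
  if (perNeuron) d else mean(d)
}

#' Grouped tilt contrasts
#'
#' Tilt types are coded 1 = fast right, 2 = slow right, 3 = fast left,
#' 4 = slow left. Pooling fast and slow within a side gives the RFS and
#' LFS groups; pooling sides within a speed gives FRL and SRL. The two
#' orthogonal contrasts compare right vs left (RFS vs LFS) and fast vs
#' slow (FRL vs SRL).
#'
#' @return Named list of integer tilt-type sets.
#' @export
tiltGroupings <- function() {
  list(RFS = c(1L, 2L), LFS = c(3L, 4L), FRL = c(1L, 3L), SRL = c(2L, 4L))
}

#' Naive vs expert grouped-PSTH distances
#'
#' For the naive (day 0) and expert sessions, pools trials into the
#' grouped tilt PSTHs (20 ms bins over the full peri-tilt window) on the
#' common set of neurons firing in both sessions, and computes the
#' population Euclidean distance for the side contrast (RFS vs LFS) and
#' the speed contrast (FRL vs SRL). Learners are expected to sit above the
#' identity line (expert > naive) for direct neurons.
#'
#' @param naive,expert [SessionRecording-class] objects (day 0 and the
#'   best-performance training day).
#' @param hemisphere hemisphere whose neurons are compared.
#' @param firstN leading-trials filter applied to both sessions.
#' @return data.frame with columns \code{contrast}, \code{naive},
#'   \code{expert}.
#' @export
naiveExpertDistances <- function(naive, expert,
                                 hemisphere = c("direct", "indirect"),
                                 firstN = 300) {
  hemisphere <- match.arg(hemisphere)
  naive <- filterFirstN(naive, firstN)
  expert <- filterFirstN(expert, firstN)
  roster <- reconcileRoster(naive, expert, hemisphere = hemisphere)
  if (length(roster) == 0) stop("no common firing neurons")
  g <- tiltGroupings()
  distFor <- function(sess, a, b)
    tiltPairDistance(psthPooled(sess, g[[a]], neurons = roster),
                     psthPooled(sess, g[[b]], neurons = roster))
  data.frame(
    contrast = c("RFS-LFS", "FRL-SRL"),
    naive = c(distFor(naive, "RFS", "LFS"),
              distFor(naive, "FRL", "SRL")),
    expert = c(distFor(expert, "RFS", "LFS"),
               distFor(expert, "FRL", "SRL"))
  )
}

#' Expert day of a performance series
#'
#' @param series data.frame with columns \code{day} and \code{accuracy}.
#' @return The training day with maximum accuracy; ties go to the latest
#'   such day.
#' @export
expertDay <- function(series) {
  best <- series$day[series$accuracy == max(series$accuracy)]
  max(best)
}

#' Intertrial cumulative-sum analysis
#'
#' Builds the cumulative sum of trial outcomes (+1 correct, +0 incorrect)
#' over the session and fits an ordinary least-squares line against trial
#' index. A uniform distribution of incorrect trials over the session
#' gives a near-perfect linear fit, with slope equal to the session
#' accuracy.
#'
#' @param outcomes logical/0-1 vector, or character
#'   (\code{"correct"}/\code{"incorrect"}); >= 10 trials.
#' @return List with \code{slope}, \code{intercept}, \code{r_squared} and
#'   \code{cumsum}. The r-squared of an all-flat cumulative sum (all
#'   incorrect) is defined as 0.
#' @export
#' @examples
#' intertrialCumsum(rep(c(TRUE, FALSE), 50))
intertrialCumsum <- function(outcomes) {
  if (is.character(outcomes)) {
    if (!all(outcomes %in% c("correct", "incorrect")))
      stop("outcomes must be 'correct'/'incorrect' or binary")
    outcomes <- outcomes == "correct"
  }
  x <- as.numeric(outcomes)
  if (length(x) < 10) stop("need >= 10 trials")
  if (!all(x %in% c(0, 1))) stop("outcomes must be binary")
  cs <- cumsum(x)
  idx <- seq_along(cs)
  ## closed-form simple OLS (equivalent to lm(cs ~ idx))
  vx <- stats::var(idx)
  vy <- stats::var(cs)
  slope <- stats::cov(idx, cs) / vx
  intercept <- mean(cs) - slope * mean(idx)
  r2 <- if (vy == 0) 0 else stats::cor(idx, cs)^2
  list(slope = slope, intercept = intercept, r_squared = r2, cumsum = cs)
}
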