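## Single-neuron response characterisation: responsiveness on a 2 ms PSTH,
## peak response (PR) and peak latency (PL), trial-to-trial normalized
## variance of the pre-tilt spike count, and baseline z-scoring.

## per-trial counts of one neuron in one window, rows = trials of tiltType
.neuronTrialCounts <- function(session, neuronId, tiltType, window,
                               binWidth = diff(window)) {
  tr <- trialTable(session)
  ids <- tr$trial_id[tr$tilt_type %in% tiltType]
  edges <- .binEdgesFor(window, binWidth)
  list(X = .trialFeatureMatrix(session, neuronId, ids, edges),
       edges = edges, trialIds = ids)
}

#' Responsiveness of a neuron to one tilt type
#'
#' A neuron is responsive to a tilt type when its 2 ms PSTH shows at least
#' \code{minRun} consecutive post-tilt bins above threshold (background
#' mean + \code{threshSd} standard deviations of the pre-tilt 2 ms bin
#' values) and the per-trial activity in the detected response window
#' exceeds the per-trial background activity by a one-sided paired t-test
#' at \code{alpha}. The background is estimated from the pre-tilt window
#' (-200 to 0 ms) of the same trials.
#'
#' @param session a [SessionRecording-class].
#' @param neuronId single neuron id.
#' @param tiltType tilt type (1-4).
#' @param binWidth PSTH resolution, ms (2 by convention here).
#' @param threshSd threshold in background SDs above the background mean.
#' @param minRun minimum number of consecutive supra-threshold bins.
#' @param alpha significance level of the paired test.
#' @param firstN optional leading-trials filter.
#' @return List with \code{responsive} (logical), \code{window}
#'   (\code{c(start, end)} ms of the detected supra-threshold run, or
#'   \code{NULL}), \code{threshold} (spikes/trial/bin) and \code{pValue}.
#' @export
detectResponsive <- function(session, neuronId, tiltType, binWidth = 2,
                             threshSd = 2, minRun = 5, alpha = 0.001,
                             firstN = NULL) {
  if (!is.null(firstN)) session <- filterFirstN(session, firstN)
  w <- tiltWindow()
  if (diff(w) < 10) stop("analysis window shorter than 10 ms")
  bg <- .neuronTrialCounts(session, neuronId, tiltType, c(w[1], 0),
                           binWidth)
  rs <- .neuronTrialCounts(session, neuronId, tiltType, c(0, w[2]),
                           binWidth)
  bgBins <- colMeans(bg$X) # spikes / trial / bin
  thr <- mean(bgBins) + threshSd * stats::sd(bgBins)
  above <- colMeans(rs$X) > thr
  run <- longestRun(above)
  if (is.null(run) || run["length"] < minRun)
    return(list(responsive = FALSE, window = NULL, threshold = thr,
                pValue = NA_real_))
  b0 <- run["start"]
  b1 <- b0 + run["length"] - 1L
  winMs <- c(rs$edges[b0], rs$edges[b1 + 1L])
  ## per-trial mean activity (spikes per bin) in the response window vs
  ## the background window, paired across trials
  respTrial <- rowMeans(rs$X[, b0:b1, drop = FALSE])
  bgTrial <- rowMeans(bg$X)
  p <- tryCatch(
    stats::t.test(respTrial, bgTrial, paired = TRUE,
                  alternative = "greater")$p.value,
    error = function(e) NA_real_)
  list(responsive = isTRUE(p < alpha), window = unname(winMs),
       threshold = thr, pValue = p)
}

#' Peak response and peak latency of a responsive neuron
#'
#' PR is the post-tilt PSTH bin with the maximum spike count divided by
#' the number of trials, after subtracting the background firing rate
#' (expressed as spikes per trial per bin, estimated from the pre-tilt
#' window of the same trials). PL is the centre time of that bin relative
#' to tilt start (first bin on ties).
#'
#' @inheritParams detectResponsive
#' @param check verify responsiveness first and error on a non-responsive
#'   input (default TRUE).
#' @return List with \code{PR} (spikes/trial) and \code{PL} (ms).
#' @export
peakResponseLatency <- function(session, neuronId, tiltType, binWidth = 2,
                                firstN = NULL, check = TRUE, threshSd = 2,
                                minRun = 5, alpha = 0.001) {
  if (!is.null(firstN)) session <- filterFirstN(session, firstN)
  if (check) {
    det <- detectResponsive(session, neuronId, tiltType,
                            binWidth = binWidth, threshSd = threshSd,
                            minRun = minRun, alpha = alpha)
    if (!det$responsive)
      stop("neuron ", neuronId, " is not responsive to tilt ", tiltType)
  }
  w <- tiltWindow()
  bg <- .neuronTrialCounts(session, neuronId, tiltType, c(w[1], 0),
                           binWidth)
  rs <- .neuronTrialCounts(session, neuronId, tiltType, c(0, w[2]),
                           binWidth)
  perTrialBin <- colMeans(rs$X)
  bgPerBin <- mean(colMeans(bg$X))
  b <- which.max(perTrialBin)
  list(PR = unname(perTrialBin[b] - bgPerBin),
       PL = unname((rs$edges[b] + rs$edges[b + 1L]) / 2))
}

#' Response profiles for all neurons of a session
#'
#' Applies the responsiveness criterion to every neuron and tilt type and,
#' for responsive neurons, keeps the most responsive case (maximum PR), so
#' each neuron contributes at most one observation per day.
#'
#' @inheritParams detectResponsive
#' @param hemisphere optionally restrict to one hemisphere.
#' @return data.frame with one row per neuron: \code{neuron_id},
#'   \code{hemisphere}, \code{responsive}, \code{tilt_type}, \code{PR},
#'   \code{PL} (NA for non-responsive neurons).
#' @export
responseProfiles <- function(session, hemisphere = NULL, binWidth = 2,
                             threshSd = 2, minRun = 5, alpha = 0.001,
                             firstN = NULL) {
  if (!is.null(firstN)) session <- filterFirstN(session, firstN)
  nr <- neuronRoster(session)
  if (!is.null(hemisphere)) nr <- nr[nr$hemisphere == hemisphere, ]
  rows <- lapply(seq_len(nrow(nr)), function(i) {
    id <- nr$neuron_id[i]
    best <- NULL
    for (tt in 1:4) {
      det <- detectResponsive(session, id, tt, binWidth = binWidth,
                              threshSd = threshSd, minRun = minRun,
                              alpha = alpha)
      if (!det$responsive) next
      pk <- peakResponseLatency(session, id, tt, binWidth = binWidth,
                                check = FALSE)
      if (is.null(best) || pk$PR > best$PR)
        best <- list(tilt = tt, PR = pk$PR, PL = pk$PL)
    }
    if (is.null(best))
      data.frame(neuron_id = id, hemisphere = nr$hemisphere[i],
                 responsive = FALSE, tilt_type = NA_integer_,
                 PR = NA_real_, PL = NA_real_)
    else
      data.frame(neuron_id = id, hemisphere = nr$hemisphere[i],
                 responsive = TRUE, tilt_type = best$tilt,
                 PR = best$PR, PL = best$PL)
  })
  do.call(rbind, rows)
}

#' Normalized variance of the pre-tilt spike count
#'
#' Fano-factor-style preparedness measure: spikes of the neuron are
#' counted in the single 200 ms pre-tilt bin of each trial of the tilt
#' type, and NV = var(counts) / (mean(counts) + \code{epsilon}) with
#' \code{epsilon = 0.01} stabilising near-silent neurons. The 200 ms
#' window constant converts counts to firing rates (spikes/s) for the
#' reported mean rate; the variance ratio itself is taken on counts, for
#' which a Poisson train gives NV near 1.
#'
#' @param session a [SessionRecording-class].
#' @param neuronId single neuron id.
#' @param tiltType tilt type (1-4); at least 10 trials required.
#' @param firstN leading-trials filter (default 300).
#' @param epsilon offset added to the mean count in the divisor.
#' @param window pre-tilt counting window, ms.
#' @return List with \code{nv}, \code{meanCount}, \code{varCount},
#'   \code{meanRate} (spikes/s) and \code{nTrials}.
#' @export
normalizedVariance <- function(session, neuronId, tiltType, firstN = 300,
                               epsilon = 0.01, window = c(-200, 0)) {
  sess <- filterFirstN(session, firstN)
  cc <- .neuronTrialCounts(sess, neuronId, tiltType, window)
  counts <- cc$X[, 1]
  if (length(counts) < 10)
    stop("need >= 10 trials of tilt type ", tiltType)
  m <- mean(counts)
  v <- stats::var(counts)
  list(nv = v / (m + epsilon), meanCount = m, varCount = v,
       meanRate = m / (diff(window) / 1000), nTrials = length(counts))
}

#' Per-day hemisphere normalized variance
#'
#' Computes, for each tilt type, the mean normalized variance across the
#' hemisphere's neurons, z-scores each tilt's series against the baseline
#' (day 0) value distribution across neurons, and averages the four
#' per-tilt z-scores to one value per hemisphere per day.
#'
#' @param sessions named list of [SessionRecording-class] objects keyed by
#'   day (\code{"0"} = baseline, which must be present).
#' @param hemisphere \code{"direct"} or \code{"indirect"}.
#' @param firstN leading-trials filter.
#' @param epsilon divisor offset, see [normalizedVariance()].
#' @return data.frame with one row per (day, tilt) carrying \code{nv} and
#'   \code{z}, plus attribute-free per-day means in column \code{day_mean}
#'   repeated within day.
#' @export
varianceByDay <- function(sessions, hemisphere = c("direct", "indirect"),
                          firstN = 300, epsilon = 0.01) {
  hemisphere <- match.arg(hemisphere)
  if (!"0" %in% names(sessions)) stop("baseline session '0' required")
  perNeuronNv <- function(sess, tt) {
    nr <- neuronRoster(sess)
    ids <- nr$neuron_id[nr$hemisphere == hemisphere]
    vapply(ids, function(id)
      normalizedVariance(sess, id, tt, firstN = firstN,
                         epsilon = epsilon)$nv, numeric(1))
  }
  base <- lapply(1:4, function(tt) perNeuronNv(sessions[["0"]], tt))
  rows <- lapply(names(sessions), function(d) {
    sess <- sessions[[d]]
    do.call(rbind, lapply(1:4, function(tt) {
      nv <- mean(perNeuronNv(sess, tt))
      z <- zscoreToBaseline(nv, base[[tt]])
      data.frame(day = as.integer(d), tilt_type = tt, nv = nv, z = z)
    }))
  })
  out <- do.call(rbind, rows)
  dm <- stats::ave(out$z, out$day, FUN = mean)
  out$day_mean <- dm
  out
}

#' Z-score values against a baseline distribution
#'
#' @param values numeric values to normalise.
#' @param baseline numeric baseline observations (>= 2 with nonzero
#'   spread).
#' @return \code{(values - mean(baseline)) / sd(baseline)}; \code{NA} with
#'   a warning when the baseline SD is zero.
#' @export
#' @examples
#' zscoreToBaseline(c(5, 7), c(1, 3, 5))  # 1 and 2
zscoreToBaseline <- function(values, baseline) {
  if (length(baseline) < 2) stop("baseline needs >= 2 observations")
  s <- stats::sd(baseline)
  if (s == 0) {
    warning("zero baseline SD: z-scores undefined")
    return(rep(NA_real_, length(values)))
  }
  (values - mean(baseline)) / s
}
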