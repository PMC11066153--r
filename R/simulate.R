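## Inhomogeneous-Poisson spike-train simulator. The rate function per trial
## is background + amp * exp(-(t - centre)^2 / (2 width^2)) with the bump
## centre jittered per trial; sampling uses the exact superposition of a
## homogeneous background process and a Poisson number of bump spikes with
## truncated-normal times, which is distributionally identical to thinning
## for this rate function.

#' Simulate one recording session
#'
#' Generates a [SessionRecording-class] for one animal-day: a balanced,
#' randomly ordered trial sequence over the four tilt types, and for every
#' neuron an inhomogeneous Poisson spike train per trial (constant
#' background over the peri-tilt window plus a Gaussian-profile rate bump
#' for the trial's tilt type, truncated at the window edges). If a
#' trajectory is supplied, the neuron specification is first adjusted for
#' the requested day with [dayAdjustedNeurons()].
#'
#' @param neurons neuron specification data.frame (see [neuronSpec()]).
#' @param day non-negative integer day index (0 = baseline).
#' @param nTrials number of trials, divisible by 4 (balanced design).
#' @param trajectory optional trajectory data.frame from [trajectorySpec()].
#' @param animalId animal identifier stored in the session.
#' @param seed integer seed; the same seed reproduces the session exactly.
#' @return A [SessionRecording-class]; outcomes are \code{"n/a"} until
#'   decoding assigns them.
#' @export
#' @examples
#' ns <- neuronSpec("n1", "direct", 10, c(50, 0, 0, 0), rep(60, 4), 0, 15)
#' s <- simulateSession(ns, day = 0, nTrials = 40, seed = 1)
#' s
simulateSession <- function(neurons, day, nTrials, trajectory = NULL,
                            animalId = "sim", seed = NULL) {
  validateNeuronSpec(neurons)
  stopifnotScalarCount(nTrials, "nTrials")
  if (nTrials %% 4 != 0)
    stop("nTrials must be divisible by 4 for a balanced tilt design")
  if (!is.null(trajectory))
    neurons <- dayAdjustedNeurons(neurons, trajectory, day)
  w <- tiltWindow()
  winLen <- (w[2] - w[1]) / 1000 # seconds
  withSeed(seed, {
    tilt <- sample(rep.int(1:4, nTrials / 4L))
    trials <- data.frame(trial_id = seq_len(nTrials), tilt_type = tilt,
                         outcome = "n/a", stringsAsFactors = FALSE)
    parts <- vector("list", nrow(neurons))
    for (i in seq_len(nrow(neurons))) {
      ni <- neurons[i, ]
      ## homogeneous background over the whole window
      nBg <- stats::rpois(nTrials, ni$background_rate * winLen)
      bgTrial <- rep.int(seq_len(nTrials), nBg)
      bgTimes <- stats::runif(sum(nBg), w[1], w[2])
      ## tuned bump: Poisson count with the truncated-Gaussian integral,
      ## times drawn from the truncated normal
      amp <- as.numeric(ni[paste0("amp", tilt)])
      lat <- as.numeric(ni[paste0("lat", tilt)])
      centre <- lat + stats::rnorm(nTrials, 0, ni$jitter_sd)
      width <- ni$response_width
      lo <- stats::pnorm((w[1] - centre) / width)
      hi <- stats::pnorm((w[2] - centre) / width)
      lambda <- amp / 1000 * width * sqrt(2 * pi) * (hi - lo)
      nBump <- stats::rpois(nTrials, lambda)
      bumpTrial <- rep.int(seq_len(nTrials), nBump)
      u <- stats::runif(sum(nBump), rep.int(lo, nBump), rep.int(hi, nBump))
      bumpTimes <- stats::qnorm(u) * width + rep.int(centre, nBump)
      parts[[i]] <- data.frame(
        neuron_id = ni$neuron_id,
        trial_id = c(bgTrial, bumpTrial),
        time_ms = c(bgTimes, bumpTimes),
        stringsAsFactors = FALSE
      )
    }
    spikes <- do.call(rbind, parts)
    if (is.null(spikes))
      spikes <- data.frame(neuron_id = character(), trial_id = integer(),
                           time_ms = numeric())
    ## guard against floating-point spill just outside the window
    spikes$time_ms <- pmin(pmax(spikes$time_ms, w[1]), w[2])
    spikes <- spikes[order(spikes$neuron_id, spikes$trial_id,
                           spikes$time_ms), , drop = FALSE]
    rownames(spikes) <- NULL
    sessionRecording(animalId, day, trials, spikes,
                     neurons[, c("neuron_id", "hemisphere")])
  })
}

#' Simulate a full multi-animal experiment
#'
#' For each animal, generates one baseline session (day 0, identity
#' multipliers) followed by \code{nDays} training sessions along the
#' animal's group trajectory, together with a ground-truth ledger of every
#' day-adjusted neuron specification for parameter-recovery tests.
#'
#' @param cohort cohort settings from [cohortSpec()].
#' @param seed integer seed controlling neuron draws and all sessions.
#' @return List with elements \code{sessions} (nested list,
#'   \code{sessions[[animal]][[as.character(day)]]}), \code{animals}
#'   (data.frame of animal_id and group) and \code{groundTruth} (nested list
#'   of day-adjusted neuron specification tables).
#' @export
#' @examples
#' ex <- simulateExperiment(cohortSpec(1, 1, 0, 3, nDays = 2, nTrials = 40),
#'                          seed = 1)
#' names(ex$sessions)
simulateExperiment <- function(cohort = cohortSpec(), seed = 1) {
  groups <- rep(c("learner", "nonlearner", "control"),
                c(cohort$nLearners, cohort$nNonlearners, cohort$nControls))
  if (length(groups) == 0) stop("empty cohort")
  if (cohort$nDays < 1) stop("nDays must be >= 1")
  animals <- data.frame(
    animal_id = sprintf("%s%d", substr(groups, 1, 1),
                        stats::ave(seq_along(groups), groups,
                                   FUN = seq_along)),
    group = groups, stringsAsFactors = FALSE
  )
  nA <- nrow(animals)
  seeds <- matrix(childSeeds(seed, nA * (cohort$nDays + 2L)),
                  nrow = nA)
  sessions <- vector("list", nA)
  groundTruth <- vector("list", nA)
  names(sessions) <- names(groundTruth) <- animals$animal_id
  for (a in seq_len(nA)) {
    grp <- animals$group[a]
    traj <- trajectorySpec(grp, nDays = cohort$nDays)
    neurons <- defaultNeurons(cohort$neuronsPerHemisphere,
                              seed = seeds[a, 1],
                              prefix = paste0(animals$animal_id[a], "_n"))
    days <- 0:cohort$nDays
    sess <- vector("list", length(days))
    gt <- vector("list", length(days))
    names(sess) <- names(gt) <- as.character(days)
    for (d in days) {
      nTr <- if (d == 0) cohort$baselineTrials else cohort$nTrials
      gt[[as.character(d)]] <- dayAdjustedNeurons(neurons, traj, d)
      sess[[as.character(d)]] <- simulateSession(
        neurons, day = d, nTrials = nTr, trajectory = traj,
        animalId = animals$animal_id[a], seed = seeds[a, d + 2L])
    }
    sessions[[a]] <- sess
    groundTruth[[a]] <- gt
  }
  list(sessions = sessions, animals = animals, groundTruth = groundTruth)
}
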