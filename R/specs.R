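## Ground-truth parameter tables for the simulator: per-neuron tuning
## (NeuronSpec rows) and day-by-day learning trajectories (TrajectorySpec
## rows). Both are validated data.frames rather than S4 objects because
## they are flat parameter tables that users may want to edit directly.

#' Per-neuron tuning specification
#'
#' Builds one row of a neuron specification table. Each neuron fires as an
#' inhomogeneous Poisson process: a constant background rate over the
#' peri-tilt window plus, on trials of tilt type t, a Gaussian-profile rate
#' bump of amplitude \code{amplitude[t]} (spikes/s) centred at
#' \code{latency[t]} ms (jittered per trial by \code{N(0, jitterSd)}) with
#' standard-deviation width \code{responseWidth} ms.
#'
#' @param neuronId character id.
#' @param hemisphere \code{"direct"} (used by the decoder) or
#'   \code{"indirect"} (recorded only).
#' @param backgroundRate background firing rate, spikes/s, >= 0.
#' @param amplitude numeric length-4, bump amplitude per tilt type,
#'   spikes/s, >= 0.
#' @param latency numeric length-4, bump centre per tilt type, ms in
#'   [0, 200].
#' @param jitterSd per-trial SD of the bump centre, ms, >= 0.
#' @param responseWidth Gaussian bump SD, ms, > 0.
#' @return One-row data.frame with columns \code{neuron_id},
#'   \code{hemisphere}, \code{background_rate}, \code{amp1..amp4},
#'   \code{lat1..lat4}, \code{jitter_sd}, \code{response_width}.
#' @export
#' @examples
#' neuronSpec("n1", "direct", 5, c(40, 0, 0, 0), c(50, 50, 50, 50), 5, 15)
neuronSpec <- function(neuronId, hemisphere, backgroundRate,
                       amplitude, latency, jitterSd, responseWidth) {
  spec <- data.frame(
    neuron_id = as.character(neuronId),
    hemisphere = as.character(hemisphere),
    background_rate = as.numeric(backgroundRate),
    amp1 = amplitude[1], amp2 = amplitude[2],
    amp3 = amplitude[3], amp4 = amplitude[4],
    lat1 = latency[1], lat2 = latency[2],
    lat3 = latency[3], lat4 = latency[4],
    jitter_sd = as.numeric(jitterSd),
    response_width = as.numeric(responseWidth),
    stringsAsFactors = FALSE
  )
  validateNeuronSpec(spec)
  spec
}

#' Validate a neuron specification table
#'
#' @param spec data.frame of neuron specifications (rows as produced by
#'   [neuronSpec()]).
#' @return Invisibly \code{TRUE}; stops with a parameter error otherwise.
#' @export
validateNeuronSpec <- function(spec) {
  need <- c("neuron_id", "hemisphere", "background_rate",
            paste0("amp", 1:4), paste0("lat", 1:4),
            "jitter_sd", "response_width")
  if (!is.data.frame(spec) || !all(need %in% names(spec)))
    stop("invalid NeuronSpec: missing columns ",
         paste(setdiff(need, names(spec)), collapse = ", "))
  if (anyDuplicated(spec$neuron_id)) stop("invalid NeuronSpec: duplicated ids")
  if (!all(spec$hemisphere %in% c("direct", "indirect")))
    stop("invalid NeuronSpec: hemisphere must be 'direct' or 'indirect'")
  amps <- as.matrix(spec[paste0("amp", 1:4)])
  lats <- as.matrix(spec[paste0("lat", 1:4)])
  if (any(spec$background_rate < 0) || any(amps < 0))
    stop("invalid NeuronSpec: rates and amplitudes must be >= 0")
  if (any(lats < 0) || any(lats > 200))
    stop("invalid NeuronSpec: latencies must lie in [0, 200] ms")
  if (any(spec$jitter_sd < 0))
    stop("invalid NeuronSpec: jitter_sd must be >= 0")
  if (any(spec$response_width <= 0))
    stop("invalid NeuronSpec: response_width must be > 0")
  invisible(TRUE)
}

#' Draw a random neuron roster for one animal
#'
#' Samples tuning parameters typical of hindlimb sensorimotor units
#' responding to platform tilts: moderate background rates, one preferred
#' tilt type with a stronger bump, and post-tilt latencies.
#'
#' @param nPerHemisphere neurons per hemisphere.
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @param prefix id prefix.
#' @return Neuron specification data.frame (both hemispheres).
#' @export
defaultNeurons <- function(nPerHemisphere = 10, seed = NULL, prefix = "n") {
  withSeed(seed, {
    n <- 2L * nPerHemisphere
    pref <- sample(1:4, n, replace = TRUE)
    amps <- matrix(runif(n * 4, 0, 8), n, 4)
    amps[cbind(seq_len(n), pref)] <- runif(n, 15, 30)
    lats <- matrix(runif(n * 4, 30, 120), n, 4)
    spec <- data.frame(
      neuron_id = sprintf("%s%02d", prefix, seq_len(n)),
      hemisphere = rep(c("direct", "indirect"), each = nPerHemisphere),
      background_rate = runif(n, 2, 10),
      amp1 = amps[, 1], amp2 = amps[, 2], amp3 = amps[, 3], amp4 = amps[, 4],
      lat1 = lats[, 1], lat2 = lats[, 2], lat3 = lats[, 3], lat4 = lats[, 4],
      jitter_sd = runif(n, 5, 15),
      response_width = runif(n, 10, 25),
      stringsAsFactors = FALSE
    )
    validateNeuronSpec(spec)
    spec
  })
}

#' Day-by-day learning trajectory
#'
#' Per-day multipliers applied to the neuron specification before
#' simulating each training day. Day 0 (baseline) is always identity.
#' Learner trajectories increase the tilt-type separation of direct-neuron
#' amplitudes monotonically across days, with a fast early rise and a
#' saturating late phase, and sharpen direct-neuron timing late (jitter
#' multiplier < 1); indirect neurons show an early, transient latency
#' increase. Nonlearner trajectories drift gently downwards in amplitude
#' separation (no improvement, slight late decline); control trajectories
#' stay at identity.
#'
#' @param group \code{"learner"}, \code{"nonlearner"} or \code{"control"}.
#' @param nDays number of training days (>= 1).
#' @param sepGain asymptotic extra amplitude separation for learners'
#'   direct neurons (multiplier reaches \code{1 + sepGain}).
#' @param sepTau e-folding time of the separation rise, days.
#' @param jitterDrop fractional late-phase reduction in direct-neuron
#'   jitter for learners.
#' @param latBump peak fractional increase of indirect-neuron latency in
#'   the early phase for learners.
#' @param nonlearnerDecline total fractional loss of amplitude separation
#'   across training for nonlearners (mild monotone performance decline,
#'   as nonlearner performance curves drift slightly below their initial
#'   level; 0 gives an exactly flat trajectory).
#' @return data.frame with one row per (day, role): columns \code{day},
#'   \code{role}, \code{amp_sep}, \code{lat_mult}, \code{jitter_mult},
#'   \code{bg_mult}, plus a \code{group} column.
#' @export
#' @examples
#' tr <- trajectorySpec("learner", nDays = 25)
#' subset(tr, role == "direct" & day %in% c(0, 1, 25))
trajectorySpec <- function(group = c("learner", "nonlearner", "control"),
                           nDays = 25, sepGain = 2, sepTau = 6,
                           jitterDrop = 0.5, latBump = 0.3,
                           nonlearnerDecline = 0.15) {
  group <- match.arg(group)
  stopifnotScalarCount(nDays, "nDays")
  days <- 0:nDays
  grid <- expand.grid(day = days, role = c("direct", "indirect"),
                      stringsAsFactors = FALSE)
  grid$amp_sep <- 1
  grid$lat_mult <- 1
  grid$jitter_mult <- 1
  grid$bg_mult <- 1
  if (group == "learner") {
    d <- grid$day
    dir <- grid$role == "direct"
    ## monotone, saturating separation growth for direct neurons
    grid$amp_sep[dir] <- 1 + sepGain * (1 - exp(-d[dir] / sepTau))
    ## late-phase temporal sharpening (jitter reduction) for direct neurons
    grid$jitter_mult[dir] <- 1 - jitterDrop * (d[dir] / nDays)^2
    ## transient early latency increase for indirect neurons,
    ## peaking around day 3 and relaxing in the late phase
    bump <- (d / 3) * exp(1 - d / 3)
    grid$lat_mult[!dir] <- 1 + latBump * bump[!dir]
  }
  if (group == "nonlearner" && nonlearnerDecline > 0) {
    ## nonlearner performance drifts slightly below its first-day level:
    ## the initial natural responsiveness degrades over the first week of
    ## unsuccessful training and stays slightly depressed thereafter
    d <- pmax(grid$day - 1, 0)
    grid$amp_sep <- 1 - nonlearnerDecline * (1 - exp(-d / 4))
  }
  grid$group <- group
  validateTrajectorySpec(grid)
  grid
}

#' Validate a trajectory specification table
#'
#' @param trajectory data.frame as produced by [trajectorySpec()].
#' @return Invisibly \code{TRUE}; stops otherwise.
#' @export
validateTrajectorySpec <- function(trajectory) {
  need <- c("day", "role", "amp_sep", "lat_mult", "jitter_mult", "bg_mult")
  if (!is.data.frame(trajectory) || !all(need %in% names(trajectory)))
    stop("invalid TrajectorySpec: missing columns ",
         paste(setdiff(need, names(trajectory)), collapse = ", "))
  d0 <- trajectory[trajectory$day == 0,
                   c("amp_sep", "lat_mult", "jitter_mult", "bg_mult")]
  if (nrow(d0) == 0 || any(abs(as.matrix(d0) - 1) > 1e-9))
    stop("invalid TrajectorySpec: day-0 multipliers must be identity")
  if (any(trajectory$jitter_mult < 0) || any(trajectory$amp_sep < 0))
    stop("invalid TrajectorySpec: multipliers must be >= 0")
  invisible(TRUE)
}

#' Apply a trajectory to a neuron roster for one day
#'
#' Amplitudes are separated about their per-neuron mean
#' (\code{mean + amp_sep * (amp - mean)}, clamped at 0), latencies scaled by
#' \code{lat_mult} (clamped to [0, 200] ms), jitter scaled by
#' \code{jitter_mult} and background rate by \code{bg_mult}.
#'
#' @param neurons neuron specification data.frame.
#' @param trajectory trajectory data.frame from [trajectorySpec()].
#' @param day day index present in the trajectory.
#' @return Day-adjusted neuron specification data.frame.
#' @export
dayAdjustedNeurons <- function(neurons, trajectory, day) {
  validateNeuronSpec(neurons)
  validateTrajectorySpec(trajectory)
  out <- neurons
  for (role in c("direct", "indirect")) {
    row <- trajectory[trajectory$day == day & trajectory$role == role, ]
    if (nrow(row) != 1L)
      stop("trajectory has no unique entry for day ", day, " role ", role)
    sel <- out$hemisphere == role
    if (!any(sel)) next
    amps <- as.matrix(out[sel, paste0("amp", 1:4)])
    m <- rowMeans(amps)
    amps <- m + row$amp_sep * (amps - m)
    amps[amps < 0] <- 0
    out[sel, paste0("amp", 1:4)] <- amps
    lats <- as.matrix(out[sel, paste0("lat", 1:4)]) * row$lat_mult
    lats[lats < 0] <- 0
    lats[lats > 200] <- 200
    out[sel, paste0("lat", 1:4)] <- lats
    out$jitter_sd[sel] <- out$jitter_sd[sel] * row$jitter_mult
    out$background_rate[sel] <- out$background_rate[sel] * row$bg_mult
  }
  validateNeuronSpec(out)
  out
}

#' Cohort specification for a simulated experiment
#'
#' Defaults mirror the rat tilt-BMI study conditions: 4 learners, 4
#' nonlearners and 4 control animals; a day-0 baseline session of 400
#' trials (100 per tilt type) followed by 25 consecutive training days.
#'
#' @param nLearners,nNonlearners,nControls animals per group.
#' @param neuronsPerHemisphere units recorded per hemisphere.
#' @param nDays training days.
#' @param nTrials trials per training session (divisible by 4).
#' @param baselineTrials trials in the day-0 baseline session.
#' @return A list of class-free cohort settings consumed by
#'   [simulateExperiment()].
#' @export
cohortSpec <- function(nLearners = 4, nNonlearners = 4, nControls = 4,
                       neuronsPerHemisphere = 10, nDays = 25,
                       nTrials = 400, baselineTrials = 400) {
  if (nTrials %% 4 != 0 || baselineTrials %% 4 != 0)
    stop("trial counts must be divisible by 4")
  list(nLearners = as.integer(nLearners),
       nNonlearners = as.integer(nNonlearners),
       nControls = as.integer(nControls),
       neuronsPerHemisphere = as.integer(neuronsPerHemisphere),
       nDays = as.integer(nDays),
       nTrials = as.integer(nTrials),
       baselineTrials = as.integer(baselineTrials))
}
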