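## Central containers for the tilt-BMI pipeline. Spike events are ragged
## (variable spikes per neuron per trial), so sessions hold long-format
## event tables rather than an assay matrix.

#' Analysis window relative to tilt onset, in ms
#'
#' All spike times are stored relative to tilt onset and restricted to the
#' peri-tilt window of -200 to +200 ms. Decoding templates span the full
#' window; information analyses use the post-tilt half (0 to 200 ms).
#'
#' @return Numeric length-2 vector, \code{c(-200, 200)}.
#' @export
#' @examples
#' tiltWindow()
tiltWindow <- function() c(-200, 200)

.TILT_TYPES <- 1:4
.OUTCOMES <- c("correct", "incorrect", "n/a")

## ---------------------------------------------------------------------------
## SessionRecording
## ---------------------------------------------------------------------------

#' SessionRecording: spike events and trial metadata for one animal-day
#'
#' Holds everything recorded in one session: the ordered trial table (tilt
#' type and outcome per trial), the spike-event table (times in ms relative
#' to tilt onset, within \code{tiltWindow()}), and the neuron roster with
#' hemisphere labels (\code{"direct"} neurons drive the decoder,
#' \code{"indirect"} neurons are recorded only).
#'
#' @slot animalId single character animal identifier.
#' @slot day integer day index; 0 is the baseline session recorded before
#'   BMI training starts.
#' @slot trials data.frame with columns \code{trial_id} (integer),
#'   \code{tilt_type} (integer 1-4) and \code{outcome}
#'   (\code{"correct"}, \code{"incorrect"} or \code{"n/a"}), in session order.
#' @slot spikes data.frame with columns \code{neuron_id} (character),
#'   \code{trial_id} (integer) and \code{time_ms} (numeric).
#' @slot neurons data.frame with columns \code{neuron_id} (character) and
#'   \code{hemisphere} (\code{"direct"} or \code{"indirect"}).
#'
#' @seealso [sessionRecording()], [simulateSession()], [filterFirstN()]
#' @name SessionRecording-class
#' @rdname SessionRecording-class
#' @exportClass SessionRecording
setClass("SessionRecording",
  representation(
    animalId = "character",
    day = "integer",
    trials = "data.frame",
    spikes = "data.frame",
    neurons = "data.frame"
  )
)

setValidity("SessionRecording", function(object) {
  msg <- character()
  if (length(object@animalId) != 1L) msg <- c(msg, "animalId must be length 1")
  if (length(object@day) != 1L || is.na(object@day) || object@day < 0L)
    msg <- c(msg, "day must be a single non-negative integer")
  tr <- object@trials
  need <- c("trial_id", "tilt_type", "outcome")
  if (!all(need %in% names(tr)))
    msg <- c(msg, "trials must have columns trial_id, tilt_type, outcome")
  else {
    if (anyDuplicated(tr$trial_id)) msg <- c(msg, "duplicated trial_id")
    if (!all(tr$tilt_type %in% .TILT_TYPES))
      msg <- c(msg, "tilt_type values must be in 1:4")
    if (!all(tr$outcome %in% .OUTCOMES))
      msg <- c(msg, "outcome must be 'correct', 'incorrect' or 'n/a'")
  }
  nr <- object@neurons
  if (!all(c("neuron_id", "hemisphere") %in% names(nr)))
    msg <- c(msg, "neurons must have columns neuron_id, hemisphere")
  else {
    if (anyDuplicated(nr$neuron_id)) msg <- c(msg, "duplicated neuron_id")
    if (!all(nr$hemisphere %in% c("direct", "indirect")))
      msg <- c(msg, "hemisphere must be 'direct' or 'indirect'")
  }
  sp <- object@spikes
  if (!all(c("neuron_id", "trial_id", "time_ms") %in% names(sp)))
    msg <- c(msg, "spikes must have columns neuron_id, trial_id, time_ms")
  else if (nrow(sp) > 0) {
    w <- tiltWindow()
    if (!all(sp$time_ms >= w[1] & sp$time_ms <= w[2]))
      msg <- c(msg, "spike times must lie within the peri-tilt window")
    if (all(need %in% names(tr)) && !all(sp$trial_id %in% tr$trial_id))
      msg <- c(msg, "spikes reference unknown trials")
    if (all(c("neuron_id", "hemisphere") %in% names(nr)) &&
        !all(sp$neuron_id %in% nr$neuron_id))
      msg <- c(msg, "spikes reference unknown neurons")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SessionRecording
#'
#' @param animalId single character animal identifier.
#' @param day non-negative integer day index (0 = baseline).
#' @param trials data.frame with \code{trial_id}, \code{tilt_type},
#'   \code{outcome} columns; rows in session order.
#' @param spikes data.frame with \code{neuron_id}, \code{trial_id},
#'   \code{time_ms} columns.
#' @param neurons data.frame with \code{neuron_id}, \code{hemisphere} columns.
#' @return A validated [SessionRecording-class] object.
#' @export
#' @examples
#' trials <- data.frame(trial_id = 1:4, tilt_type = 1:4, outcome = "n/a")
#' spikes <- data.frame(neuron_id = "n1", trial_id = 1L, time_ms = 10)
#' neurons <- data.frame(neuron_id = "n1", hemisphere = "direct")
#' sessionRecording("rat1", 0, trials, spikes, neurons)
sessionRecording <- function(animalId, day, trials, spikes, neurons) {
  trials$trial_id <- as.integer(trials$trial_id)
  trials$tilt_type <- as.integer(trials$tilt_type)
  trials$outcome <- as.character(trials$outcome)
  spikes$neuron_id <- as.character(spikes$neuron_id)
  spikes$trial_id <- as.integer(spikes$trial_id)
  spikes$time_ms <- as.numeric(spikes$time_ms)
  neurons$neuron_id <- as.character(neurons$neuron_id)
  neurons$hemisphere <- as.character(neurons$hemisphere)
  new("SessionRecording",
      animalId = as.character(animalId), day = as.integer(day),
      trials = trials, spikes = spikes, neurons = neurons)
}

#' @rdname tiltBMI-accessors
#' @export
setMethod("animalId", "SessionRecording", function(object) object@animalId)

#' @rdname tiltBMI-accessors
#' @export
setMethod("sessionDay", "SessionRecording", function(object) object@day)

#' @rdname tiltBMI-accessors
#' @export
setMethod("trialTable", "SessionRecording", function(object) object@trials)

#' @rdname tiltBMI-accessors
#' @export
setMethod("spikeTable", "SessionRecording", function(object) object@spikes)

#' @rdname tiltBMI-accessors
#' @export
setMethod("neuronRoster", "SessionRecording", function(object) object@neurons)

setMethod("show", "SessionRecording", function(object) {
  cat("SessionRecording: animal", object@animalId,
      "day", object@day, "\n")
  cat("  ", nrow(object@trials), "trials,",
      nrow(object@spikes), "spikes,",
      nrow(object@neurons), "neurons (",
      sum(object@neurons$hemisphere == "direct"), "direct /",
      sum(object@neurons$hemisphere == "indirect"), "indirect )\n")
})

## ---------------------------------------------------------------------------
## PsthMatrix
## ---------------------------------------------------------------------------

#' PsthMatrix: binned mean response per neuron
#'
#' Per-neuron peri-stimulus time histogram for one tilt type (or a pooled
#' set of tilt types): mean spikes per trial per bin, on uniform half-open
#' bins \code{[left, right)}.
#'
#' @slot values numeric matrix, neurons x bins, row names are neuron ids;
#'   entry = total spikes in the bin across included trials / number of trials.
#' @slot binEdges numeric vector of uniform bin edges in ms.
#' @slot tiltTypes integer vector of the tilt type(s) the included trials
#'   belong to.
#' @slot nTrials integer number of trials averaged.
#'
#' @seealso [buildPsth()], [psthPooled()]
#' @name PsthMatrix-class
#' @rdname PsthMatrix-class
#' @exportClass PsthMatrix
setClass("PsthMatrix",
  representation(
    values = "matrix",
    binEdges = "numeric",
    tiltTypes = "integer",
    nTrials = "integer"
  )
)

setValidity("PsthMatrix", function(object) {
  msg <- character()
  e <- object@binEdges
  if (length(e) < 2L || is.unsorted(e, strictly = TRUE))
    msg <- c(msg, "binEdges must be strictly increasing, length >= 2")
  w <- diff(e)
  if (length(w) && max(abs(w - w[1])) > 1e-9)
    msg <- c(msg, "bins must have uniform width")
  if (ncol(object@values) != length(e) - 1L)
    msg <- c(msg, "ncol(values) must equal length(binEdges) - 1")
  if (any(object@values < 0)) msg <- c(msg, "PSTH values must be >= 0")
  if (is.null(rownames(object@values)))
    msg <- c(msg, "values must carry neuron ids as row names")
  if (!all(object@tiltTypes %in% .TILT_TYPES))
    msg <- c(msg, "tiltTypes must be in 1:4")
  if (object@nTrials < 1L) msg <- c(msg, "nTrials must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname tiltBMI-accessors
#' @export
setMethod("psthValues", "PsthMatrix", function(object) object@values)

#' @rdname tiltBMI-accessors
#' @export
setMethod("binEdges", "PsthMatrix", function(object) object@binEdges)

#' @rdname tiltBMI-accessors
#' @export
setMethod("tiltTypes", "PsthMatrix", function(object) object@tiltTypes)

setMethod("show", "PsthMatrix", function(object) {
  cat("PsthMatrix:", nrow(object@values), "neurons x",
      ncol(object@values), "bins of",
      diff(object@binEdges[1:2]), "ms; tilt type(s)",
      paste(object@tiltTypes, collapse = ","),
      "over", object@nTrials, "trials\n")
})

## ---------------------------------------------------------------------------
## TemplateSet
## ---------------------------------------------------------------------------

#' TemplateSet: one day's decoder templates
#'
#' Four [PsthMatrix-class] templates (one per tilt type) on a common neuron
#' roster and common bin edges, as used by the minimum-Euclidean-distance
#' template classifier.
#'
#' @slot day integer day the templates were built from.
#' @slot roster ordered character vector of neuron ids used for decoding.
#' @slot binEdges numeric bin edges shared by all four templates.
#' @slot templates list of four PsthMatrix objects named "1".."4".
#'
#' @seealso [buildTemplates()], [classifyTrial()]
#' @name TemplateSet-class
#' @rdname TemplateSet-class
#' @exportClass TemplateSet
setClass("TemplateSet",
  representation(
    day = "integer",
    roster = "character",
    binEdges = "numeric",
    templates = "list"
  )
)

setValidity("TemplateSet", function(object) {
  msg <- character()
  if (!identical(names(object@templates), as.character(1:4)))
    msg <- c(msg, "templates must be a list named '1'..'4'")
  else {
    for (tt in 1:4) {
      tm <- object@templates[[tt]]
      if (!is(tm, "PsthMatrix")) {
        msg <- c(msg, "templates must contain PsthMatrix objects")
        break
      }
      if (!identical(rownames(tm@values), object@roster))
        msg <- c(msg, sprintf("template %d roster mismatch", tt))
      if (!isTRUE(all.equal(tm@binEdges, object@binEdges)))
        msg <- c(msg, sprintf("template %d bin-edge mismatch", tt))
    }
  }
  if (length(object@roster) < 1L) msg <- c(msg, "empty decoding roster")
  if (length(msg)) msg else TRUE
})

#' @rdname tiltBMI-accessors
#' @export
setMethod("sessionDay", "TemplateSet", function(object) object@day)

#' @rdname tiltBMI-accessors
#' @export
setMethod("decodingRoster", "TemplateSet", function(object) object@roster)

#' @rdname tiltBMI-accessors
#' @export
setMethod("binEdges", "TemplateSet", function(object) object@binEdges)

#' @rdname tiltBMI-accessors
#' @export
setMethod("templates", "TemplateSet", function(object) object@templates)

setMethod("show", "TemplateSet", function(object) {
  cat("TemplateSet: day", object@day, "-",
      length(object@roster), "neurons,",
      length(object@binEdges) - 1L, "bins of",
      diff(object@binEdges[1:2]), "ms\n")
})

## ---------------------------------------------------------------------------
## ConfusionMatrix
## ---------------------------------------------------------------------------

#' ConfusionMatrix: actual x predicted tilt counts
#'
#' 4x4 matrix of trial counts with rows = actual tilt type and columns =
#' predicted tilt type. Decoding accuracy and mutual information derive
#' from this object.
#'
#' @slot counts integer 4x4 matrix; row sums equal the number of trials per
#'   actual tilt type.
#'
#' @seealso [confusionMatrix()], [mutualInformation()], [decodeOffline()]
#' @name ConfusionMatrix-class
#' @rdname ConfusionMatrix-class
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix", representation(counts = "matrix"))

setValidity("ConfusionMatrix", function(object) {
  m <- object@counts
  msg <- character()
  if (!all(dim(m) == c(4L, 4L))) msg <- c(msg, "counts must be 4x4")
  if (any(m < 0) || any(m != round(m)))
    msg <- c(msg, "counts must be non-negative integers")
  if (length(msg)) msg else TRUE
})

#' Construct a ConfusionMatrix from actual/predicted labels or counts
#'
#' @param actual integer vector of actual tilt types (1-4), or a 4x4 count
#'   matrix if \code{predicted} is missing.
#' @param predicted integer vector of predicted tilt types (1-4).
#' @return A [ConfusionMatrix-class] object.
#' @export
#' @examples
#' confusionMatrix(c(1, 2, 3, 4), c(1, 2, 3, 3))
confusionMatrix <- function(actual, predicted) {
  if (missing(predicted)) {
    m <- as.matrix(actual)
  } else {
    m <- unname(table(factor(actual, levels = 1:4),
                      factor(predicted, levels = 1:4)))
    m <- matrix(as.integer(m), 4L, 4L)
  }
  storage.mode(m) <- "integer"
  dimnames(m) <- list(actual = 1:4, predicted = 1:4)
  new("ConfusionMatrix", counts = m)
}

#' @rdname tiltBMI-accessors
#' @export
setMethod("confusionCounts", "ConfusionMatrix", function(object) object@counts)

#' Decoding accuracy from a confusion matrix
#'
#' @param cm a [ConfusionMatrix-class].
#' @return Fraction of correctly classified trials (diagonal / total).
#' @export
decodingAccuracy <- function(cm) {
  m <- confusionCounts(cm)
  sum(diag(m)) / sum(m)
}

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (rows actual, cols predicted),",
      sum(object@counts), "trials, accuracy",
      sprintf("%.3f", decodingAccuracy(object)), "\n")
  print(object@counts)
})

## ---------------------------------------------------------------------------
## InfoEstimate
## ---------------------------------------------------------------------------

#' InfoEstimate: shuffle-bias-corrected mutual information
#'
#' Mutual information between tilt type and decoded class, in bits, with
#' the finite-sampling bias estimated by re-running classification after
#' randomly permuting the tilt labels. Only estimates with corrected
#' information above 0 bits are marked included for population analyses.
#'
#' @slot raw plug-in mutual information of the confusion matrix, bits.
#' @slot bias mean information over label-shuffled reruns, bits.
#' @slot corrected \code{raw - bias}, bits.
#' @slot nShuffles number of label permutations used.
#' @slot mode one of \code{"timing"}, \code{"count"}, \code{"ensemble"}.
#' @slot included logical, \code{corrected > 0}.
#'
#' @seealso [biasCorrectedInformation()], [timingAndCountInformation()]
#' @name InfoEstimate-class
#' @rdname InfoEstimate-class
#' @exportClass InfoEstimate
setClass("InfoEstimate",
  representation(
    raw = "numeric", bias = "numeric", corrected = "numeric",
    nShuffles = "integer", mode = "character", included = "logical"
  )
)

setValidity("InfoEstimate", function(object) {
  msg <- character()
  if (object@raw < -1e-12 || object@raw > 2 + 1e-9)
    msg <- c(msg, "raw information must lie in [0, 2] bits for 4 classes")
  if (abs(object@corrected - (object@raw - object@bias)) > 1e-9)
    msg <- c(msg, "corrected must equal raw - bias")
  if (!object@mode %in% c("timing", "count", "ensemble"))
    msg <- c(msg, "mode must be 'timing', 'count' or 'ensemble'")
  if (length(msg)) msg else TRUE
})

#' @rdname tiltBMI-accessors
#' @export
setMethod("rawInfo", "InfoEstimate", function(object) object@raw)

#' @rdname tiltBMI-accessors
#' @export
setMethod("infoBias", "InfoEstimate", function(object) object@bias)

#' @rdname tiltBMI-accessors
#' @export
setMethod("correctedInfo", "InfoEstimate", function(object) object@corrected)

#' @rdname tiltBMI-accessors
#' @export
setMethod("isIncluded", "InfoEstimate", function(object) object@included)

#' @rdname tiltBMI-accessors
#' @export
setMethod("infoMode", "InfoEstimate", function(object) object@mode)

setMethod("show", "InfoEstimate", function(object) {
  cat(sprintf(
    "InfoEstimate (%s): raw %.4f - bias %.4f = %.4f bits (%d shuffles)%s\n",
    object@mode, object@raw, object@bias, object@corrected,
    object@nShuffles, if (object@included) "" else " [excluded]"))
})

## ---------------------------------------------------------------------------
## RedundancyResult
## ---------------------------------------------------------------------------

#' RedundancyResult: ensemble information vs summed single-neuron information
#'
#' Holds \code{P = I_ensemble - sum(I_neuron)} for one hemisphere, and the
#' sign-inverted value \code{redundancy = -P} so that larger values mean more
#' overlapping (redundant) information across neurons.
#'
#' @slot ensembleInfo bias-corrected ensemble information, bits.
#' @slot sumSingleInfo sum of included single-neuron corrected information,
#'   bits.
#' @slot P \code{ensembleInfo - sumSingleInfo}, bits.
#' @slot redundancy \code{-P}, bits.
#' @slot singleInfo named numeric vector of per-neuron corrected information.
#' @slot nIncluded number of neurons with corrected information above 0.
#'
#' @seealso [ensembleRedundancy()]
#' @name RedundancyResult-class
#' @rdname RedundancyResult-class
#' @exportClass RedundancyResult
setClass("RedundancyResult",
  representation(
    ensembleInfo = "numeric", sumSingleInfo = "numeric",
    P = "numeric", redundancy = "numeric",
    singleInfo = "numeric", nIncluded = "integer"
  )
)

setValidity("RedundancyResult", function(object) {
  msg <- character()
  if (abs(object@P - (object@ensembleInfo - object@sumSingleInfo)) > 1e-9)
    msg <- c(msg, "P must equal ensembleInfo - sumSingleInfo")
  if (abs(object@redundancy + object@P) > 1e-9)
    msg <- c(msg, "redundancy must equal -P")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RedundancyResult", function(object) {
  cat(sprintf(
    "RedundancyResult: I_ensemble %.4f, sum I_neuron %.4f (n=%d included), P %.4f, redundancy %.4f bits\n",
    object@ensembleInfo, object@sumSingleInfo, object@nIncluded,
    object@P, object@redundancy))
})
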