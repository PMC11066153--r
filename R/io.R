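## Plain-text I/O: sessions as three CSV tables (trials, spikes, neurons),
## templates and ground-truth ledgers as JSON. UTF-8, header rows, "."
## decimal separator, times in ms as floats, tilt types as integers 1-4.

#' Write a session to CSV files
#'
#' Writes \code{trials.csv} (trial_id, tilt_type, outcome, day, animal_id),
#' \code{spikes.csv} (neuron_id, trial_id, time_ms) and \code{neurons.csv}
#' (neuron_id, hemisphere) into \code{dir}.
#'
#' @param session a [SessionRecording-class].
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
writeSession <- function(session, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tr <- trialTable(session)
  tr$day <- sessionDay(session)
  tr$animal_id <- animalId(session)
  paths <- file.path(dir, c("trials.csv", "spikes.csv", "neurons.csv"))
  utils::write.csv(tr, paths[1], row.names = FALSE)
  utils::write.csv(spikeTable(session), paths[2], row.names = FALSE)
  utils::write.csv(neuronRoster(session), paths[3], row.names = FALSE)
  invisible(paths)
}

#' Read a session from CSV files
#'
#' Inverse of [writeSession()].
#'
#' @param dir directory holding \code{trials.csv}, \code{spikes.csv} and
#'   \code{neurons.csv}.
#' @return A [SessionRecording-class].
#' @export
readSession <- function(dir) {
  tr <- utils::read.csv(file.path(dir, "trials.csv"),
                        stringsAsFactors = FALSE)
  sp <- utils::read.csv(file.path(dir, "spikes.csv"),
                        stringsAsFactors = FALSE)
  nr <- utils::read.csv(file.path(dir, "neurons.csv"),
                        stringsAsFactors = FALSE)
  if (nrow(sp) == 0)
    sp <- data.frame(neuron_id = character(), trial_id = integer(),
                     time_ms = numeric())
  sessionRecording(tr$animal_id[1], tr$day[1],
                   tr[c("trial_id", "tilt_type", "outcome")], sp, nr)
}

#' Serialize a template set to JSON
#'
#' Stores day, roster, bin edges and the per-tilt-type template matrices.
#'
#' @param templateSet a [TemplateSet-class].
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeTemplates <- function(templateSet, path) {
  tl <- lapply(templates(templateSet), function(p) {
    list(values = unname(psthValues(p)), nTrials = p@nTrials,
         tiltTypes = tiltTypes(p))
  })
  obj <- list(day = sessionDay(templateSet),
              roster = decodingRoster(templateSet),
              binEdges = binEdges(templateSet),
              templates = tl)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a template set from JSON
#'
#' @param path file written by [writeTemplates()].
#' @return A [TemplateSet-class].
#' @export
readTemplates <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  roster <- as.character(obj$roster)
  edges <- as.numeric(obj$binEdges)
  tl <- lapply(obj$templates, function(t) {
    v <- matrix(unlist(t$values), nrow = length(roster))
    rownames(v) <- roster
    new("PsthMatrix", values = v, binEdges = edges,
        tiltTypes = as.integer(t$tiltTypes),
        nTrials = as.integer(t$nTrials))
  })
  names(tl) <- as.character(1:4)
  new("TemplateSet", day = as.integer(obj$day), roster = roster,
      binEdges = edges, templates = tl)
}

#' Write the ground-truth ledger of a simulated experiment
#'
#' @param groundTruth the \code{groundTruth} element of
#'   [simulateExperiment()]'s result.
#' @param path output JSON file.
#' @return Invisibly, \code{path}.
#' @export
writeGroundTruth <- function(groundTruth, path) {
  jsonlite::write_json(groundTruth, path, dataframe = "columns",
                       digits = NA)
  invisible(path)
}
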