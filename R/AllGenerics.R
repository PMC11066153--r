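#' @import methods
NULL

#' Accessor generics for tiltBMI classes
#'
#' Small accessor generics used across the package's S4 classes. Prefer these
#' over direct slot access.
#'
#' @param object an object of one of the tiltBMI S4 classes.
#' @return The accessed component; see the class documentation for details.
#' @name tiltBMI-accessors
#' @rdname tiltBMI-accessors
NULL

#' @rdname tiltBMI-accessors
#' @export
setGeneric("animalId", function(object) standardGeneric("animalId"))

#' @rdname tiltBMI-accessors
#' @export
setGeneric("sessionDay", function(object) standardGeneric("sessionDay"))

#' @rdname tiltBMI-accessors
#' @export
setGeneric("trialTable", function(object) standardGeneric("trialTable"))

#' @rdname tiltBMI-accessors
#' @export
setGeneric("spikeTable", function(object) standardGeneric("spikeTable"))

#' @rdname tiltBMI-accessors
#' @export
setGeneric("neuronRoster", function(object) standardGeneric("neuronRoster"))

#' @rdname tiltBMI-accessors
#' @export
setGeneric("psthValues", function(object) standardGeneric("psthValues"))

#' @rdname tiltBMI-accessors
#' @export
setGeneric("binEdges", function(object) standardGeneric("binEdges"))

#' @rdname tiltBMI-accessors
#' @export
setGeneric("tiltTypes", function(object) standardGeneric("tiltTypes"))

#' @rdname tiltBMI-accessors
#' @export
setGeneric("templates", function(object) standardGeneric("templates"))

#' @rdname tiltBMI-accessors
#' @export
setGeneric("decodingRoster", function(object) standardGeneric("decodingRoster"))

#' @rdname tiltBMI-accessors
#' @export
setGeneric("confusionCounts", function(object) standardGeneric("confusionCounts"))

#' @rdname tiltBMI-accessors
#' @export
setGeneric("rawInfo", function(object) standardGeneric("rawInfo"))

#' @rdname tiltBMI-accessors
#' @export
setGeneric("infoBias", function(object) standardGeneric("infoBias"))

#' @rdname tiltBMI-accessors
#' @export
setGeneric("correctedInfo", function(object) standardGeneric("correctedInfo"))

#' @rdname tiltBMI-accessors
#' @export
setGeneric("isIncluded", function(object) standardGeneric("isIncluded"))

#' @rdname tiltBMI-accessors
#' @export
setGeneric("infoMode", function(object) standardGeneric("infoMode"))
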