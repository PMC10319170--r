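#' @import methods
NULL

#' Event intensity matrix of an EventTable
#'
#' @param object an \linkS4class{EventTable}.
#' @return numeric matrix, events in rows, channels in columns.
#' @export
setGeneric("exprs", function(object) standardGeneric("exprs"))

#' Channel names of an EventTable
#' @param object an \linkS4class{EventTable}.
#' @return character vector of channel names.
#' @export
setGeneric("channels", function(object) standardGeneric("channels"))

#' Number of events
#' @param object an \linkS4class{EventTable}.
#' @return integer event count.
#' @export
setGeneric("nEvents", function(object) standardGeneric("nEvents"))

#' Sample identifier
#' @param object an \linkS4class{EventTable}.
#' @return character scalar.
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' Tube identifier
#' @param object an \linkS4class{EventTable}.
#' @return character scalar.
#' @export
setGeneric("tubeId", function(object) standardGeneric("tubeId"))

#' Acquisition keywords
#' @param object an \linkS4class{EventTable}.
#' @return named list of keyword values.
#' @export
setGeneric("keywords", function(object) standardGeneric("keywords"))

#' Apply a gate to events
#'
#' @param gate a \linkS4class{Gate}.
#' @param events an \linkS4class{EventTable} or numeric matrix with channel
#'   column names.
#' @return logical vector of gate membership, one element per event.
#' @export
setGeneric("applyGate", function(gate, events) standardGeneric("applyGate"))
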