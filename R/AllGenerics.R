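# Generics for accessors and cross-class operations.

#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @export
setGeneric("modelID", function(x) standardGeneric("modelID"))

#' @export
setGeneric("models", function(x) standardGeneric("models"))

#' @export
setGeneric("energies", function(x) standardGeneric("energies"))

#' @export
setGeneric("coreResidues", function(x) standardGeneric("coreResidues"))

#' @export
setGeneric("shiftEntries", function(x) standardGeneric("shiftEntries"))

#' @export
setGeneric("numberingScheme", function(x) standardGeneric("numberingScheme"))

#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' @export
setGeneric("peakTruth", function(x) standardGeneric("peakTruth"))

#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @export
setGeneric("restraints", function(x) standardGeneric("restraints"))

#' @export
setGeneric("rdcRecords", function(x) standardGeneric("rdcRecords"))

#' @export
setGeneric("saupeMatrix", function(x) standardGeneric("saupeMatrix"))

#' @export
setGeneric("tensorDa", function(x) standardGeneric("tensorDa"))

#' @export
setGeneric("tensorRhombicity", function(x) standardGeneric("tensorRhombicity"))

#' @export
setGeneric("disorderTable", function(x) standardGeneric("disorderTable"))

#' @export
setGeneric("distanceClasses", function(x) standardGeneric("distanceClasses"))

#' @export
setGeneric("calibrationConstant",
           function(x) standardGeneric("calibrationConstant"))

#' @export
setGeneric("fitReportTable", function(x) standardGeneric("fitReportTable"))

#' @export
setGeneric("fitQ", function(x) standardGeneric("fitQ"))

#' Translate residue numbering between schemes
#'
#' @param x object carrying residue numbers.
#' @param map a numbering map built with \code{\link{numberingMap}}.
#' @param ... unused.
#' @return the same class of object, renumbered.
#' @export
setGeneric("mapNumbering", function(x, map, ...) standardGeneric("mapNumbering"))
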