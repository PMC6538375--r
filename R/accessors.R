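# Accessors and show methods.

#' @describeIn StructureModel-class atom table accessor
#' @param x a StructureModel
#' @aliases atoms
#' @export
setMethod("atoms", "StructureModel", function(x) x@atoms)

#' @describeIn StructureModel-class model identifier
#' @export
setMethod("modelID", "StructureModel", function(x) x@model_id)

#' @describeIn Ensemble-class list of member models
#' @param x an Ensemble
#' @export
setMethod("models", "Ensemble", function(x) x@models)

#' @describeIn Ensemble-class per-model scores (lower is better)
#' @export
setMethod("energies", "Ensemble", function(x) x@energies)

#' @describeIn Ensemble-class core residue numbers
#' @export
setMethod("coreResidues", "Ensemble", function(x) x@core_residues)

#' @describeIn ChemicalShiftTable-class entry table accessor
#' @param x a ChemicalShiftTable
#' @export
setMethod("shiftEntries", "ChemicalShiftTable", function(x) x@entries)

#' @describeIn ChemicalShiftTable-class numbering-scheme label
#' @export
setMethod("numberingScheme", "ChemicalShiftTable", function(x) x@scheme)

#' @describeIn NOEPeakTable-class peak table accessor
#' @param x an NOEPeakTable
#' @export
setMethod("peaks", "NOEPeakTable", function(x) x@peaks)

#' @describeIn NOEPeakTable-class ground-truth distances (simulated data)
#' @export
setMethod("peakTruth", "NOEPeakTable", function(x) x@truth)

#' @describeIn NOEPeakTable-class TRUE after diagonal normalization
#' @export
setMethod("isNormalized", "NOEPeakTable", function(x) x@normalized)

#' @describeIn RestraintList-class restraint table accessor
#' @param x a RestraintList
#' @export
setMethod("restraints", "RestraintList", function(x) x@restraints)

#' @describeIn RDCTable-class record table accessor
#' @param x an RDCTable
#' @export
setMethod("rdcRecords", "RDCTable", function(x) x@records)

#' @describeIn AlignmentTensor-class 3x3 Saupe matrix
#' @param x an AlignmentTensor
#' @export
setMethod("saupeMatrix", "AlignmentTensor", function(x) x@saupe)

#' @describeIn AlignmentTensor-class axial magnitude Da (Hz)
#' @export
setMethod("tensorDa", "AlignmentTensor", function(x) x@Da)

#' @describeIn AlignmentTensor-class rhombicity R
#' @export
setMethod("tensorRhombicity", "AlignmentTensor", function(x) x@rhombicity)

#' @describeIn DisorderProfile-class per-residue profile table
#' @param x a DisorderProfile
#' @export
setMethod("disorderTable", "DisorderProfile", function(x) x@profile)

#' @describeIn SheetDistanceStats-class characteristic class centers (A)
#' @param x a SheetDistanceStats
#' @export
setMethod("distanceClasses", "SheetDistanceStats", function(x) x@classes)

#' @describeIn CalibrationResult-class proportionality constant c
#' @param x a CalibrationResult
#' @export
setMethod("calibrationConstant", "CalibrationResult", function(x) x@c)

#' @describeIn RDCFitReport-class per-record observed/back-calculated table
#' @param x an RDCFitReport
#' @export
setMethod("fitReportTable", "RDCFitReport", function(x) x@records)

#' @describeIn RDCFitReport-class Q-factor of the fit
#' @export
setMethod("fitQ", "RDCFitReport", function(x) x@q)

setMethod("show", "StructureModel", function(object) {
  at <- object@atoms
  cat(sprintf("StructureModel #%d: %d atoms, %d residues\n",
              object@model_id, nrow(at),
              length(unique(paste(at$chain, at$resno)))))
})

setMethod("show", "Ensemble", function(object) {
  cat(sprintf("Ensemble: %d models, %d core residues%s\n",
              length(object@models), length(object@core_residues),
              if (length(object@energies)) ", scored" else ""))
})

setMethod("show", "ChemicalShiftTable", function(object) {
  e <- object@entries
  cat(sprintf("ChemicalShiftTable (%s numbering): %d shifts, %d residues\n",
              object@scheme, nrow(e), length(unique(e$resno))))
})

setMethod("show", "NOEPeakTable", function(object) {
  p <- object@peaks
  cat(sprintf("NOEPeakTable: %d peaks (%s)%s\n", nrow(p),
              paste(sprintf("%s: %d", names(table(p$class)), table(p$class)),
                    collapse = ", "),
              if (object@normalized) ", normalized" else ""))
})

setMethod("show", "RestraintList", function(object) {
  r <- object@restraints
  cat(sprintf("RestraintList: %d restraints, bounds %.1f-%.1f A\n",
              nrow(r),
              if (nrow(r)) min(r$upper) else NA, if (nrow(r)) max(r$upper) else NA))
})

setMethod("show", "RDCTable", function(object) {
  r <- object@records
  cat(sprintf("RDCTable: %d records (%s)\n", nrow(r),
              paste(sprintf("%s: %d", names(table(r$type)), table(r$type)),
                    collapse = ", ")))
})

setMethod("show", "AlignmentTensor", function(object) {
  cat(sprintf("AlignmentTensor: Da = %.3f Hz, R = %.3f\n",
              object@Da, object@rhombicity))
})

setMethod("show", "RDCFitReport", function(object) {
  cat(sprintf("RDCFitReport: %d/%d records used, Q = %.4f, rms = %.3f Hz\n",
              sum(object@records$used), nrow(object@records), object@q,
              object@rms))
})

setMethod("show", "DisorderProfile", function(object) {
  p <- object@profile
  cat(sprintf("DisorderProfile: %d residues, %d with coverage\n",
              nrow(p), sum(p$coverage)))
})

setMethod("show", "SheetDistanceStats", function(object) {
  cat(sprintf("SheetDistanceStats (%s): classes %s A (n = %d)\n",
              object@topology,
              paste(sprintf("%.2f", object@classes), collapse = ", "),
              object@n_distances))
})

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf(
    "CalibrationResult: c = %.4g, reference peak %d at %.2f A, pad %.2f A\n",
    object@c, object@ref_peak, object@ref_distance, object@pad))
})
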