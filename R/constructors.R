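# User-facing constructors. These are thin validity-checked wrappers around
# new(); most objects are normally produced by the readers or simulators.

#' Construct a StructureModel
#'
#' @param atoms data.frame with columns chain, resno, resname, atom, element,
#'   x, y, z.
#' @param model_id integer model identifier.
#' @param linker logical flags for linker residues (optional).
#' @return a \linkS4class{StructureModel}.
#' @export
StructureModel <- function(atoms, model_id = 1L, linker = logical()) {
  atoms <- as.data.frame(atoms)
  rownames(atoms) <- NULL
  new("StructureModel", model_id = as.integer(model_id), atoms = atoms,
      linker = linker)
}

#' Construct an Ensemble
#'
#' @param models list of \linkS4class{StructureModel}.
#' @param energies numeric per-model score, lower is better (optional).
#' @param core_residues integer residue numbers of the structured core
#'   (optional).
#' @return an \linkS4class{Ensemble}.
#' @export
Ensemble <- function(models, energies = numeric(),
                     core_residues = integer()) {
  new("Ensemble", models = models, energies = as.numeric(energies),
      core_residues = as.integer(core_residues))
}

#' Construct a ChemicalShiftTable
#'
#' @param entries data.frame with columns resno, resname, atom, shift,
#'   ambiguity (ambiguity defaults to 1 when missing).
#' @param scheme numbering-scheme label.
#' @return a \linkS4class{ChemicalShiftTable}.
#' @export
ChemicalShiftTable <- function(entries, scheme = "unspecified") {
  entries <- as.data.frame(entries)
  if (is.null(entries$ambiguity)) entries$ambiguity <- 1L
  entries$resno <- as.integer(entries$resno)
  rownames(entries) <- NULL
  new("ChemicalShiftTable", entries = entries, scheme = scheme)
}

#' Construct an NOEPeakTable
#'
#' @param peaks data.frame with columns group_a, group_b, cross and
#'   optionally diag_a, diag_b, class, peak_id. Missing diagonals are NA;
#'   a missing class is inferred from the group specs.
#' @param normalized logical, TRUE when intensities are already
#'   diagonal-normalized.
#' @param truth optional data.frame (peak_id, r_true) of ground-truth
#'   effective distances.
#' @return an \linkS4class{NOEPeakTable}.
#' @export
NOEPeakTable <- function(peaks, normalized = FALSE, truth = NULL) {
  peaks <- as.data.frame(peaks)
  if (is.null(peaks$peak_id)) peaks$peak_id <- seq_len(nrow(peaks))
  if (is.null(peaks$diag_a)) peaks$diag_a <- NA_real_
  if (is.null(peaks$diag_b)) peaks$diag_b <- NA_real_
  if (is.null(peaks$class))
    peaks$class <- vapply(seq_len(nrow(peaks)), function(i)
      inferPeakClass(peaks$group_a[i], peaks$group_b[i]), character(1L))
  if (is.null(peaks$flagged))
    peaks$flagged <- is.na(peaks$diag_a) & is.na(peaks$diag_b)
  peaks <- peaks[c("peak_id", "group_a", "group_b", "cross", "diag_a",
                   "diag_b", "class", "flagged")]
  rownames(peaks) <- NULL
  if (is.null(truth))
    truth <- data.frame(peak_id = integer(), r_true = numeric())
  new("NOEPeakTable", peaks = peaks, normalized = normalized,
      truth = as.data.frame(truth))
}

#' Construct a RestraintList
#'
#' @param restraints data.frame with columns group_a, group_b, upper and
#'   optionally class (inferred from the group specs when missing).
#' @param allow_loose logical; permit upper bounds above 7.0 A.
#' @return a \linkS4class{RestraintList}.
#' @export
RestraintList <- function(restraints, allow_loose = FALSE) {
  restraints <- as.data.frame(restraints)
  if (nrow(restraints) && is.null(restraints$class))
    restraints$class <- vapply(seq_len(nrow(restraints)), function(i)
      inferPeakClass(restraints$group_a[i], restraints$group_b[i]),
      character(1L))
  if (!nrow(restraints))
    restraints <- data.frame(group_a = character(), group_b = character(),
                             upper = numeric(), class = character())
  restraints <- restraints[c("group_a", "group_b", "upper", "class")]
  rownames(restraints) <- NULL
  new("RestraintList", restraints = restraints, allow_loose = allow_loose)
}

#' Construct an RDCTable
#'
#' @param records data.frame with columns resno, type ("NH"/"NC"), D and
#'   optionally sigma.
#' @return an \linkS4class{RDCTable}.
#' @export
RDCTable <- function(records) {
  records <- as.data.frame(records)
  if (is.null(records$sigma)) records$sigma <- NA_real_
  records$resno <- as.integer(records$resno)
  records <- records[c("resno", "type", "D", "sigma")]
  rownames(records) <- NULL
  new("RDCTable", records = records)
}

#' Construct an AlignmentTensor from Da, rhombicity and orientation
#'
#' Builds the laboratory-frame tensor \eqn{A = V \Lambda V^T} with principal
#' values \eqn{(2D_a, -D_a(1+3R/2), -D_a(1-3R/2))} on (z, y, x) and the
#' principal frame given by z-y-z Euler angles.
#'
#' @param Da axial magnitude in Hz (NH-equivalent units).
#' @param rhombicity rhombicity R in [0, 2/3].
#' @param euler numeric(3) z-y-z Euler angles in degrees.
#' @return an \linkS4class{AlignmentTensor}.
#' @export
AlignmentTensor <- function(Da, rhombicity = 0, euler = c(0, 0, 0)) {
  stopifnot(rhombicity >= 0, rhombicity <= 2 / 3)
  V <- .eulerZYZ(euler[1L], euler[2L], euler[3L])
  lam <- diag(c(-Da * (1 - 1.5 * rhombicity),   # x
                -Da * (1 + 1.5 * rhombicity),   # y
                2 * Da))                        # z
  A <- V %*% lam %*% t(V)
  A <- (A + t(A)) / 2
  A <- A - diag(rep(sum(diag(A)) / 3, 3L))  # numerically clean trace
  new("AlignmentTensor", saupe = A, Da = Da, rhombicity = rhombicity,
      euler = as.numeric(euler))
}
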