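# S4 classes for the core data containers. Tabular payloads are stored as
# plain data.frames inside validity-checked S4 wrappers, following the
# Bioconductor convention of accessor-mediated slot access.

.BACKBONE_REQUIRED <- c("N", "CA", "C")

#' StructureModel: atomic coordinates of one model
#'
#' Holds one set of atomic coordinates (one MODEL of a PDB file, or one
#' generated structure). The \code{atoms} slot is a data.frame with columns
#' \code{chain}, \code{resno}, \code{resname} (3-letter code), \code{atom}
#' (PDB v3 atom name), \code{element}, and Cartesian \code{x}, \code{y},
#' \code{z} in Angstrom.
#'
#' Validity requires finite coordinates, residue numbers strictly increasing
#' within each chain, and backbone N/CA/C present in every residue.
#'
#' @slot model_id integer model identifier.
#' @slot atoms data.frame of atom records (see Description).
#' @slot linker logical vector flagging linker residues (parallel to the
#'   unique residues of \code{atoms}); may be length zero when unused.
#' @export
setClass("StructureModel",
  representation(model_id = "integer", atoms = "data.frame",
                 linker = "logical"),
  prototype(model_id = 1L,
            atoms = data.frame(chain = character(), resno = integer(),
                               resname = character(), atom = character(),
                               element = character(), x = numeric(),
                               y = numeric(), z = numeric()),
            linker = logical())
)

setValidity("StructureModel", function(object) {
  at <- object@atoms
  need <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  if (!all(need %in% names(at)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(at) == 0L) return(TRUE)
  if (!all(is.finite(at$x)) || !all(is.finite(at$y)) || !all(is.finite(at$z)))
    return("non-finite coordinates")
  for (ch in unique(at$chain)) {
    r <- at$resno[at$chain == ch]
    ur <- unique(r)
    if (is.unsorted(ur, strictly = TRUE))
      return(sprintf("residue numbers not strictly increasing in chain %s", ch))
  }
  key <- paste(at$chain, at$resno)
  for (k in unique(key)) {
    nm <- at$atom[key == k]
    miss <- setdiff(.BACKBONE_REQUIRED, nm)
    if (length(miss))
      return(sprintf("residue %s lacks backbone atom(s) %s",
                     k, paste(miss, collapse = ",")))
  }
  TRUE
})

#' Ensemble: a pool of structure models with scores
#'
#' @slot models list of \linkS4class{StructureModel}.
#' @slot energies numeric per-model score (opaque units, lower is better).
#' @slot core_residues integer residue numbers defining the structured core.
#' @export
setClass("Ensemble",
  representation(models = "list", energies = "numeric",
                 core_residues = "integer"),
  prototype(models = list(), energies = numeric(), core_residues = integer())
)

setValidity("Ensemble", function(object) {
  if (!all(vapply(object@models, is, logical(1L), "StructureModel")))
    return("models must all be StructureModel objects")
  if (length(object@energies) &&
      length(object@energies) != length(object@models))
    return("energies must be empty or match the number of models")
  if (length(object@energies) && !all(is.finite(object@energies)))
    return("energies must be finite")
  TRUE
})

#' ChemicalShiftTable: assigned chemical shifts
#'
#' @slot entries data.frame with columns \code{resno}, \code{resname},
#'   \code{atom}, \code{shift} (ppm), \code{ambiguity}.
#' @slot scheme character label of the residue-numbering scheme
#'   (e.g. "human", "zebrafish").
#' @export
setClass("ChemicalShiftTable",
  representation(entries = "data.frame", scheme = "character"),
  prototype(entries = data.frame(resno = integer(), resname = character(),
                                 atom = character(), shift = numeric(),
                                 ambiguity = integer()),
            scheme = "unspecified")
)

.shiftWindow <- function(atom) {
  el <- substr(atom, 1L, 1L)
  switch(el,
         H = c(-2, 13),
         C = c(0, 220),
         N = c(90, 140),
         c(-Inf, Inf))
}

setValidity("ChemicalShiftTable", function(object) {
  e <- object@entries
  need <- c("resno", "resname", "atom", "shift", "ambiguity")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  key <- paste(e$resno, e$atom)
  if (anyDuplicated(key))
    return(paste("duplicate (residue, atom) entries:",
                 paste(unique(key[duplicated(key)]), collapse = "; ")))
  for (i in seq_len(nrow(e))) {
    w <- .shiftWindow(e$atom[i])
    if (e$shift[i] < w[1L] || e$shift[i] > w[2L])
      return(sprintf("shift %.2f ppm for %d.%s outside physical window [%g, %g]",
                     e$shift[i], e$resno[i], e$atom[i], w[1L], w[2L]))
  }
  TRUE
})

#' NOEPeakTable: NOE cross-peaks with intensities
#'
#' @slot peaks data.frame with columns \code{peak_id}, \code{group_a},
#'   \code{group_b}, \code{cross}, \code{diag_a}, \code{diag_b} (NA when
#'   absent), \code{class} (amide-amide, amide-methyl or methyl-methyl) and
#'   \code{flagged} (no diagonal available for normalization).
#' @slot normalized logical scalar: have intensities been divided by the
#'   diagonal geometric mean?
#' @slot truth data.frame of ground-truth effective distances (columns
#'   \code{peak_id}, \code{r_true}); populated by simulators, empty for
#'   experimental data.
#' @export
setClass("NOEPeakTable",
  representation(peaks = "data.frame", normalized = "logical",
                 truth = "data.frame"),
  prototype(peaks = data.frame(peak_id = integer(), group_a = character(),
                               group_b = character(), cross = numeric(),
                               diag_a = numeric(), diag_b = numeric(),
                               class = character(), flagged = logical()),
            normalized = FALSE,
            truth = data.frame(peak_id = integer(), r_true = numeric()))
)

.NOE_CLASSES <- c("amide-amide", "amide-methyl", "methyl-methyl")

setValidity("NOEPeakTable", function(object) {
  p <- object@peaks
  need <- c("peak_id", "group_a", "group_b", "cross", "diag_a", "diag_b",
            "class", "flagged")
  if (!all(need %in% names(p)))
    return(paste("peaks must have columns:", paste(need, collapse = ", ")))
  if (nrow(p) && any(p$cross <= 0))
    return("cross intensities must be positive")
  if (nrow(p) && !all(p$class %in% .NOE_CLASSES))
    return(paste("class must be one of:", paste(.NOE_CLASSES, collapse = ", ")))
  bad <- c(p$diag_a[!is.na(p$diag_a)], p$diag_b[!is.na(p$diag_b)])
  if (length(bad) && any(bad <= 0))
    return("diagonal intensities must be positive when present")
  TRUE
})

#' RestraintList: upper-bound distance restraints
#'
#' @slot restraints data.frame with columns \code{group_a}, \code{group_b},
#'   \code{upper} (Angstrom) and \code{class}.
#' @slot allow_loose logical; when TRUE the 7 A upper cap is not enforced.
#' @export
setClass("RestraintList",
  representation(restraints = "data.frame", allow_loose = "logical"),
  prototype(restraints = data.frame(group_a = character(),
                                    group_b = character(), upper = numeric(),
                                    class = character()),
            allow_loose = FALSE)
)

setValidity("RestraintList", function(object) {
  r <- object@restraints
  need <- c("group_a", "group_b", "upper", "class")
  if (!all(need %in% names(r)))
    return(paste("restraints must have columns:", paste(need, collapse = ", ")))
  if (nrow(r)) {
    if (any(r$upper < 1.8))
      return("upper bounds below the 1.8 A van der Waals floor")
    if (!object@allow_loose && any(r$upper > 7.0))
      return("upper bounds above the 7.0 A cap (set allow_loose to permit)")
  }
  TRUE
})

#' RDCTable: observed residual dipolar couplings
#'
#' @slot records data.frame with columns \code{resno}, \code{type}
#'   ("NH" or "NC"), \code{D} (Hz) and \code{sigma} (Hz uncertainty, NA when
#'   not reported).
#' @export
setClass("RDCTable",
  representation(records = "data.frame"),
  prototype(records = data.frame(resno = integer(), type = character(),
                                 D = numeric(), sigma = numeric()))
)

setValidity("RDCTable", function(object) {
  r <- object@records
  need <- c("resno", "type", "D", "sigma")
  if (!all(need %in% names(r)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (nrow(r)) {
    key <- paste(r$resno, r$type)
    if (anyDuplicated(key))
      return(paste("duplicate (residue, type) records:",
                   paste(unique(key[duplicated(key)]), collapse = "; ")))
    if (!all(r$type %in% c("NH", "NC")))
      return("type must be NH or NC")
    nh <- r$D[r$type == "NH"]
    if (length(nh) && any(abs(nh) > 60))
      return("NH couplings outside +/-60 Hz; screen outliers before building")
  }
  TRUE
})

#' AlignmentTensor: Saupe order matrix of a weak-alignment medium
#'
#' The tensor is the symmetric traceless matrix \eqn{A} such that a bond
#' unit vector u experiences \eqn{D = u^T A u}; its eigenvalues are
#' \eqn{(2D_a, -D_a(1 + 3R/2), -D_a(1 - 3R/2))} with magnitude \eqn{D_a}
#' (Hz, in NH-equivalent units) and rhombicity \eqn{R \in [0, 2/3]}.
#'
#' @slot saupe 3x3 symmetric traceless matrix (Hz).
#' @slot Da numeric axial magnitude (Hz).
#' @slot rhombicity numeric in [0, 2/3].
#' @slot euler numeric z-y-z Euler angles (degrees) of the principal frame.
#' @export
setClass("AlignmentTensor",
  representation(saupe = "matrix", Da = "numeric", rhombicity = "numeric",
                 euler = "numeric"),
  prototype(saupe = matrix(0, 3L, 3L), Da = 0, rhombicity = 0,
            euler = c(0, 0, 0))
)

setValidity("AlignmentTensor", function(object) {
  s <- object@saupe
  if (!all(dim(s) == c(3L, 3L))) return("saupe must be 3x3")
  if (max(abs(s - t(s))) > 1e-9) return("saupe must be symmetric")
  if (abs(sum(diag(s))) > 1e-9 * max(1, max(abs(s))))
    return("saupe must be traceless")
  if (object@rhombicity < -1e-9 || object@rhombicity > 2 / 3 + 1e-9)
    return("rhombicity must lie in [0, 2/3]")
  TRUE
})

#' RDCFitReport: result of an alignment-tensor fit
#'
#' @slot records data.frame with per-record \code{resno}, \code{type},
#'   \code{D_obs}, \code{D_calc}, \code{used} and \code{reason} (why a record
#'   was excluded; "" for used records).
#' @slot tensor fitted \linkS4class{AlignmentTensor}.
#' @slot q numeric Q-factor over the fitted records.
#' @slot q_validation numeric Q-factor over excluded validation-type records
#'   (NA when none).
#' @slot rms numeric rms deviation (Hz) over fitted records.
#' @slot condition numeric condition number of the design matrix.
#' @export
setClass("RDCFitReport",
  representation(records = "data.frame", tensor = "AlignmentTensor",
                 q = "numeric", q_validation = "numeric", rms = "numeric",
                 condition = "numeric")
)

#' DisorderProfile: per-residue SSI and RCI order parameters
#'
#' @slot profile data.frame with columns \code{resno}, \code{ssi} in [-1, 1]
#'   (+1 strand-like, -1 helix-like), \code{rci_s2} in [0, 1] and
#'   \code{coverage} (TRUE when enough shifts were available to score).
#' @export
setClass("DisorderProfile",
  representation(profile = "data.frame"),
  prototype(profile = data.frame(resno = integer(), ssi = numeric(),
                                 rci_s2 = numeric(), coverage = logical()))
)

setValidity("DisorderProfile", function(object) {
  p <- object@profile
  need <- c("resno", "ssi", "rci_s2", "coverage")
  if (!all(need %in% names(p)))
    return(paste("profile must have columns:", paste(need, collapse = ", ")))
  ok <- p$coverage & !is.na(p$ssi)
  if (any(abs(p$ssi[ok]) > 1 + 1e-9)) return("SSI outside [-1, 1]")
  ok2 <- p$coverage & !is.na(p$rci_s2)
  if (any(p$rci_s2[ok2] < -1e-9 | p$rci_s2[ok2] > 1 + 1e-9))
    return("RCI-S2 outside [0, 1]")
  TRUE
})

#' SheetDistanceStats: characteristic beta-sheet amide-proton distances
#'
#' @slot topology "antiparallel" or "parallel".
#' @slot classes numeric centers (Angstrom) of the characteristic HN-HN
#'   distance classes, sorted ascending.
#' @slot dispersion numeric per-class standard deviation (Angstrom).
#' @slot n_distances integer number of distances clustered.
#' @export
setClass("SheetDistanceStats",
  representation(topology = "character", classes = "numeric",
                 dispersion = "numeric", n_distances = "integer"),
  prototype(topology = "antiparallel", classes = numeric(),
            dispersion = numeric(), n_distances = 0L)
)

setValidity("SheetDistanceStats", function(object) {
  if (!object@topology %in% c("antiparallel", "parallel"))
    return("topology must be antiparallel or parallel")
  cl <- object@classes
  if (length(cl)) {
    if (is.unsorted(cl)) return("classes must be sorted ascending")
    if (any(cl < 2 | cl > 6)) return("classes must lie within [2, 6] A")
  }
  TRUE
})

#' CalibrationResult: NOE proportionality-constant calibration
#'
#' @slot c numeric proportionality constant (intensity x A^6).
#' @slot ref_peak integer peak_id of the reference (strongest) peak.
#' @slot ref_distance numeric reference distance (Angstrom).
#' @slot pad numeric padding added to bounds downstream (Angstrom),
#'   recorded for provenance.
#' @export
setClass("CalibrationResult",
  representation(c = "numeric", ref_peak = "integer", ref_distance = "numeric",
                 pad = "numeric"),
  prototype(c = NA_real_, ref_peak = NA_integer_, ref_distance = NA_real_,
            pad = 0)
)

setValidity("CalibrationResult", function(object) {
  if (!is.na(object@c) && object@c <= 0) return("c must be positive")
  TRUE
})
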