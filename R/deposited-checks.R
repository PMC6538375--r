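# Optional checks against deposited data. These functions operate on files
# the user has downloaded locally (PDB coordinate/restraint files, BMRB
# NMR-STAR files); the package performs no network access. They are kept
# separate from the core test suite, which runs entirely on synthetic data.

#' Summarize a deposited multi-model ensemble
#'
#' @param pdb_path local path to a deposited multi-MODEL PDB file.
#' @param core_residues residue numbers of the structured core used for the
#'   convergence statistic.
#' @return list with \code{n_models}, \code{mean_pairwise_rmsd} and
#'   \code{rmsd_to_mean} (both core heavy atoms, Angstrom).
#' @export
checkDepositedEnsemble <- function(pdb_path, core_residues) {
  mods <- readPDBModels(pdb_path)
  ens <- Ensemble(mods, core_residues = as.integer(core_residues))
  pw <- ensembleRMSD(ens, selection = "core_heavy", mode = "pairwise")
  tm <- ensembleRMSD(ens, selection = "core_heavy", mode = "to-mean")
  list(n_models = length(mods), mean_pairwise_rmsd = pw$mean_rmsd,
       rmsd_to_mean = tm$mean_rmsd)
}

#' Summarize a deposited restraint list
#'
#' @param path local path to a restraint list (TSV or CYANA .upl dialect).
#' @param allow_loose permit bounds above 7 A.
#' @return list with \code{n_restraints} and per-class counts.
#' @export
checkDepositedRestraints <- function(path, allow_loose = TRUE) {
  rl <- readRestraints(path, allow_loose = allow_loose)
  r <- restraints(rl)
  counts <- table(r$class)
  list(n_restraints = nrow(r), by_class = as.list(counts))
}

#' Summarize deposited chemical-shift assignments
#'
#' Counts residues carrying backbone amide assignments (both N and H of the
#' same residue) and non-proline residues, the standard completeness
#' statistic for backbone assignment work.
#'
#' @param star_path local path to a BMRB NMR-STAR v3 file.
#' @return list with \code{n_residues_assigned_amide},
#'   \code{n_nonpro_residues} and \code{n_shifts}.
#' @export
checkDepositedShifts <- function(star_path) {
  tab <- readNmrStarShifts(star_path)
  e <- shiftEntries(tab)
  byres <- split(e$atom, e$resno)
  amide <- vapply(byres, function(a) all(c("N", "H") %in% a), logical(1L))
  nonpro <- vapply(split(e$resname, e$resno),
                   function(r) r[1L] != "PRO", logical(1L))
  list(n_residues_assigned_amide = sum(amide),
       n_nonpro_residues = sum(nonpro),
       n_shifts = nrow(e))
}
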