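# Ensemble analysis: Kabsch superposition, pairwise convergence statistics
# and the energy / RDC-fit / convergence model-selection funnel.

.selectAtoms <- function(model, selection = c("core_heavy", "core_backbone",
                                              "all"),
                         core_residues = NULL) {
  selection <- match.arg(selection)
  at <- atoms(model)
  if (selection != "all") {
    if (is.null(core_residues) || !length(core_residues))
      stop("core selection requested but no core residues given")
    at <- at[at$resno %in% core_residues, , drop = FALSE]
  }
  if (selection == "core_backbone")
    at <- at[at$atom %in% c("N", "CA", "C", "O"), , drop = FALSE]
  else
    at <- at[at$element != "H", , drop = FALSE]
  if (nrow(at) == 0L) stop("empty atom selection")
  at
}

# match two atom tables on (resno, atom); returns paired coordinate matrices
.pairCoords <- function(a, b) {
  ka <- paste(a$resno, a$atom)
  kb <- paste(b$resno, b$atom)
  common <- intersect(ka, kb)
  if (length(common) < 3L) stop("fewer than 3 shared atoms in selection")
  ia <- match(common, ka)
  ib <- match(common, kb)
  list(a = as.matrix(a[ia, c("x", "y", "z")]),
       b = as.matrix(b[ib, c("x", "y", "z")]))
}

#' Kabsch superposition of two models
#'
#' Finds the proper rotation (determinant +1) and translation minimizing
#' the RMSD of the paired selection, via SVD of the covariance matrix.
#'
#' @param mobile,reference \linkS4class{StructureModel}s.
#' @param selection "core_heavy", "core_backbone" or "all".
#' @param core_residues residue numbers for core selections.
#' @return list with \code{rotation} (3x3), \code{translation} (length 3;
#'   the superposed coordinates are \code{x \%*\% rotation + translation}),
#'   \code{rmsd} (Angstrom) and \code{n_atoms}.
#' @export
kabschSuperpose <- function(mobile, reference, selection = "all",
                            core_residues = NULL) {
  pa <- .selectAtoms(mobile, selection, core_residues)
  pb <- .selectAtoms(reference, selection, core_residues)
  pc <- .pairCoords(pa, pb)
  k <- .kabschCore(pc$a, pc$b)
  k$n_atoms <- nrow(pc$a)
  k
}

#' Ensemble convergence statistics
#'
#' Mean pairwise RMSD over all unordered model pairs, each pair superposed
#' independently on the selection ("pairwise" mode), or mean RMSD to the
#' iteratively computed mean structure ("to-mean" mode). The pairwise matrix
#' is symmetric with a zero diagonal; superposition RMSD does not satisfy
#' the triangle inequality and none is assumed.
#'
#' @param ensemble an \linkS4class{Ensemble} (>= 2 models).
#' @param selection "core_heavy", "core_backbone" or "all".
#' @param core_residues residue numbers for core selections (default: the
#'   ensemble's own core set).
#' @param mode "pairwise" or "to-mean".
#' @return list with \code{mean_rmsd} (Angstrom) and \code{matrix}
#'   (pairwise mode) or per-model \code{rmsd_to_mean} (to-mean mode).
#' @export
ensembleRMSD <- function(ensemble, selection = "core_heavy",
                         core_residues = NULL,
                         mode = c("pairwise", "to-mean")) {
  mode <- match.arg(mode)
  mods <- models(ensemble)
  if (length(mods) < 2L) stop("need at least two models")
  if (is.null(core_residues)) core_residues <- coreResidues(ensemble)
  sel <- lapply(mods, .selectAtoms, selection = selection,
                core_residues = core_residues)
  n <- length(mods)
  if (mode == "pairwise") {
    m <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        pc <- .pairCoords(sel[[i]], sel[[j]])
        m[i, j] <- m[j, i] <- .kabschCore(pc$a, pc$b)$rmsd
      }
    }
    list(mean_rmsd = mean(m[upper.tri(m)]), matrix = m)
  } else {
    # iterative superposition onto the evolving mean structure
    key1 <- paste(sel[[1L]]$resno, sel[[1L]]$atom)
    common <- Reduce(intersect,
                     lapply(sel, function(s) paste(s$resno, s$atom)))
    mats <- lapply(sel, function(s) {
      as.matrix(s[match(common, paste(s$resno, s$atom)), c("x", "y", "z")])
    })
    ref <- mats[[1L]]
    for (iter in 1:3) {
      fitted <- lapply(mats, function(x) {
        k <- .kabschCore(x, ref)
        sweep(x %*% k$rotation, 2L, k$translation, "+")
      })
      ref <- Reduce(`+`, fitted) / length(fitted)
    }
    rmsds <- vapply(mats, function(x) .kabschCore(x, ref)$rmsd, numeric(1L))
    list(mean_rmsd = mean(rmsds), rmsd_to_mean = rmsds)
  }
}

#' Model-selection funnel: energy, then RDC fit and mutual convergence
#'
#' Reproduces the staged selection used for NMR ensemble curation: from the
#' full pool keep the \code{n_energy} lowest-energy models; within those,
#' rank by per-model RDC Q-factor and by mean RMSD to the pool medoid, and
#' keep the \code{n_final} models with the best combined (summed) rank.
#' All tie-breaks are deterministic by model index.
#'
#' @param pool an \linkS4class{Ensemble} with energies.
#' @param rdcs an \linkS4class{RDCTable} (NULL skips the RDC stage).
#' @param n_energy models retained by the energy cut (default 30).
#' @param n_final models in the final ensemble (default 10).
#' @param selection atom selection for the convergence metric.
#' @return an \linkS4class{Ensemble} of the selected models (energies and
#'   core residues carried over), with a \code{selection} attribute
#'   recording the retained pool indices.
#' @export
selectModels <- function(pool, rdcs = NULL, n_energy = 30L, n_final = 10L,
                         selection = "core_heavy") {
  mods <- models(pool)
  en <- energies(pool)
  if (length(mods) < n_final) stop("pool smaller than n_final")
  if (!length(en)) stop("pool carries no energies")
  keep <- order(en, seq_along(en))[seq_len(min(n_energy, length(mods)))]
  sub <- Ensemble(mods[keep], energies = en[keep],
                  core_residues = coreResidues(pool))
  nsub <- length(keep)
  # RDC rank
  if (!is.null(rdcs)) {
    qtab <- scoreModels(sub, rdcs)
    qrank <- rank(qtab$q[order(qtab$model)], ties.method = "first",
                  na.last = "keep")
    qrank[is.na(qrank)] <- nsub
  } else qrank <- rep(1, nsub)
  # convergence rank: mean RMSD to the medoid model
  pm <- ensembleRMSD(sub, selection = selection)$matrix
  medoid <- which.min(rowMeans(pm))
  conv <- pm[, medoid]
  crank <- rank(conv, ties.method = "first")
  total <- qrank + crank
  final <- order(total, seq_len(nsub))[seq_len(n_final)]
  out <- Ensemble(models(sub)[final], energies = energies(sub)[final],
                  core_residues = coreResidues(pool))
  attr(out, "selection") <- keep[final]
  out
}
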