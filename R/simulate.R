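# Forward simulators with known ground truth: NOE intensities obeying
# I = c * r^-6 with multiplicative lognormal noise, RDCs from a known
# alignment tensor with additive Gaussian noise, chemical shifts as
# random-coil values plus secondary-structure offsets, and ensembles as a
# reference model plus seeded Gaussian coordinate perturbations. All
# generators are pure functions of (arguments, seed).

#' Simulate NOE cross-peaks from a structure model
#'
#' Enumerates proton-group pairs (amide protons and methyl groups by
#' default), computes effective distances by r^-6 summation, and emits cross
#' intensities \eqn{I = c\,r_{eff}^{-6}} with multiplicative lognormal noise
#' of unit mean and coefficient of variation \code{noise_cv}. Diagonal
#' intensities are drawn around a common scale. Ground-truth effective
#' distances are stored in the table's \code{truth} slot.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param c proportionality constant (intensity x Angstrom^6).
#' @param max_r only group pairs with effective distance <= max_r (Angstrom)
#'   produce a peak.
#' @param noise_cv coefficient of variation of the multiplicative intensity
#'   noise (0 = noiseless).
#' @param seed integer random seed.
#' @param groups optional character vector of group specs to consider
#'   (default: all amide protons and all methyl groups in the model).
#' @param diag_scale common diagonal intensity scale.
#' @return an \linkS4class{NOEPeakTable} (not normalized).
#' @export
simulateNOEPeaks <- function(model, c = 729, max_r = 5.5, noise_cv = 0,
                             seed = 1L, groups = NULL, diag_scale = 1) {
  stopifnot(c > 0, noise_cv >= 0)
  if (is.null(groups)) groups <- listProtonGroups(model)
  if (length(groups) < 2L) stop("need at least two proton groups")
  coords <- lapply(groups, resolveGroup, model = model)
  n <- length(groups)
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  lnoise <- function(k) if (noise_cv == 0) rep(1, k)
                        else exp(rnorm(k, -sdlog^2 / 2, sdlog))
  rows <- truth <- list()
  diagn <- setNames(diag_scale * lnoise(n), groups)
  id <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip intra-residue / sequential-irrelevant? keep all pairs <= max_r
      reff <- .reffFromCoords(coords[[i]], coords[[j]])
      if (reff > max_r) next
      id <- id + 1L
      rows[[id]] <- data.frame(
        peak_id = id, group_a = groups[i], group_b = groups[j],
        cross = c * reff^(-6) * lnoise(1L),
        diag_a = diagn[[groups[i]]], diag_b = diagn[[groups[j]]],
        class = inferPeakClass(groups[i], groups[j]), flagged = FALSE)
      truth[[id]] <- data.frame(peak_id = id, r_true = reff)
    }
  }
  if (id == 0L) stop("no group pair within max_r")
  NOEPeakTable(do.call(rbind, rows), normalized = FALSE,
               truth = do.call(rbind, truth))
}

#' List the NOE-active proton groups of a model
#'
#' @param model a \linkS4class{StructureModel}.
#' @return character vector of group specs: one amide group per residue with
#'   an amide proton and one group per complete methyl.
#' @export
listProtonGroups <- function(model) {
  at <- atoms(model)
  out <- character()
  for (r in unique(at$resno)) {
    sub <- at[at$resno == r, , drop = FALSE]
    if ("H" %in% sub$atom) out <- c(out, sprintf("%d.HN", r))
    resname <- sub$resname[1L]
    for (cn in .METHYL_CARBONS[[resname]]) {
      if (all(.methylProtonNames(cn) %in% sub$atom))
        out <- c(out, sprintf("%d.%s", r, cn))
    }
  }
  out
}

# gyromagnetic-ratio and bond-length scaling of the one-bond N-C' dipolar
# interaction relative to N-H: (gammaC/gammaH) * (rNH/rNC)^3
.NC_SCALE <- (10.7084 / 42.5775) * (1.02 / 1.329)^3

#' Simulate residual dipolar couplings from a model and alignment tensor
#'
#' Couplings follow \eqn{D = u^T A u} for the bond unit vector u in the
#' laboratory frame, equivalently
#' \eqn{D = D_a (3\cos^2\theta - 1 + \frac{3}{2} R \sin^2\theta \cos 2\phi)}
#' in the tensor principal frame. N-C' couplings are scaled by the standard
#' dipolar prefactor ratio relative to N-H. Gaussian noise of standard
#' deviation \code{noise_sd} Hz is added.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param tensor an \linkS4class{AlignmentTensor}.
#' @param types coupling types to generate ("NH", "NC").
#' @param noise_sd Gaussian noise sd in Hz.
#' @param seed integer random seed.
#' @return an \linkS4class{RDCTable}.
#' @export
simulateRDCs <- function(model, tensor, types = "NH", noise_sd = 0,
                         seed = 1L) {
  stopifnot(noise_sd >= 0)
  vec <- bondVectors(model, types)
  if (nrow(vec) == 0L) stop("no requested bond vectors found in model")
  A <- saupeMatrix(tensor)
  u <- as.matrix(vec[c("ux", "uy", "uz")])
  D <- rowSums((u %*% A) * u)
  D[vec$type == "NC"] <- D[vec$type == "NC"] * .NC_SCALE
  set.seed(seed)
  if (noise_sd > 0) D <- D + rnorm(length(D), 0, noise_sd)
  RDCTable(data.frame(resno = vec$resno, type = vec$type, D = D,
                      sigma = if (noise_sd > 0) noise_sd else NA_real_))
}

#' Extract bond unit vectors from a model
#'
#' NH vectors run N to amide H (built from heavy atoms when absent); NC
#' vectors run N(i) to C'(i-1), the peptide-bond N-C' direction.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param types "NH", "NC" or both.
#' @return data.frame with resno, type and unit-vector components ux, uy,
#'   uz. Residues lacking the partner atom are skipped with a message.
#' @export
bondVectors <- function(model, types = c("NH", "NC")) {
  at <- atoms(model)
  res <- unique(at$resno)
  rows <- list()
  get <- function(r, a) {
    x <- at[at$resno == r & at$atom == a, c("x", "y", "z")]
    if (nrow(x) == 1L) as.numeric(x) else NULL
  }
  for (r in res) {
    n <- get(r, "N")
    if ("NH" %in% types) {
      h <- get(r, "H")
      if (is.null(h)) {
        hb <- .buildAmideH(at, r)
        h <- if (is.null(hb)) NULL else as.numeric(hb)
      }
      if (!is.null(h) && !is.null(n)) {
        u <- .vunit(h - n)
        rows[[length(rows) + 1L]] <-
          data.frame(resno = r, type = "NH", ux = u[1L], uy = u[2L],
                     uz = u[3L])
      } else {
        message(sprintf("bondVectors: residue %d skipped for NH (no amide proton)", r))
      }
    }
    if ("NC" %in% types) {
      cp <- get(r - 1L, "C")
      if (!is.null(cp) && !is.null(n)) {
        u <- .vunit(cp - n)
        rows[[length(rows) + 1L]] <-
          data.frame(resno = r, type = "NC", ux = u[1L], uy = u[2L],
                     uz = u[3L])
      }
    }
  }
  if (!length(rows))
    return(data.frame(resno = integer(), type = character(), ux = numeric(),
                      uy = numeric(), uz = numeric()))
  do.call(rbind, rows)
}

#' Simulate chemical shifts from a sequence and secondary structure
#'
#' Per residue, shift = random-coil reference (per residue type) +
#' secondary-structure offset (helix: positive CA, negative CB; strand:
#' negative CA, positive CB; coil: zero) + Gaussian noise. Atoms CA, CB
#' (except Gly), C, N and H (except Pro) are emitted.
#'
#' @param sequence one-letter amino-acid string.
#' @param ss_string per-residue secondary structure in {H, E, C}.
#' @param noise_sd Gaussian noise sd in ppm, applied to every shift.
#' @param seed integer random seed.
#' @param start_resno first residue number.
#' @param scheme numbering-scheme label.
#' @return a \linkS4class{ChemicalShiftTable}.
#' @export
simulateShifts <- function(sequence, ss_string, noise_sd = 0, seed = 1L,
                           start_resno = 1L, scheme = "synthetic") {
  seq1 <- strsplit(sequence, "")[[1L]]
  ss <- strsplit(ss_string, "")[[1L]]
  if (length(seq1) != length(ss))
    stop("sequence and ss_string lengths differ")
  if (!all(seq1 %in% names(.AA3)))
    stop(sprintf("unknown residue letter(s): %s",
                 paste(setdiff(seq1, names(.AA3)), collapse = ", ")))
  if (!all(ss %in% c("H", "E", "C")))
    stop("secondary structure codes must be H, E or C")
  set.seed(seed)
  rows <- list()
  for (i in seq_along(seq1)) {
    aa <- seq1[i]
    res3 <- .AA3[[aa]]
    rc <- .RANDOM_COIL[[aa]]
    for (atom in names(rc)) {
      if (atom == "CB" && aa == "G") next
      if (atom == "H" && aa == "P") next
      if (atom == "N" && aa == "P") next
      off <- .SS_OFFSET[[ss[i]]][[atom]]
      rows[[length(rows) + 1L]] <- data.frame(
        resno = start_resno + i - 1L, resname = res3, atom = atom,
        shift = rc[[atom]] + off + (if (noise_sd > 0) rnorm(1L, 0, noise_sd)
                                    else 0),
        ambiguity = 1L)
    }
  }
  ChemicalShiftTable(do.call(rbind, rows), scheme = scheme)
}

#' Perturb a reference model into a synthetic ensemble
#'
#' Each of \code{n_models} copies receives independent isotropic Gaussian
#' per-atom displacements whose 3D root-mean-square magnitude is
#' \code{core_sd} on atoms of \code{core_residues} and \code{tail_sd}
#' elsewhere (per-coordinate sd = sd/sqrt(3)). With this convention the
#' expected pairwise per-atom displacement between two models is
#' \code{sqrt(2) * sd}, which is the closed form the convergence statistics
#' are checked against. A synthetic per-model energy equal to the total
#' squared displacement is assigned, so less-perturbed models score better.
#'
#' @param model reference \linkS4class{StructureModel}.
#' @param n_models number of models (>= 2).
#' @param core_sd rms atomic displacement (Angstrom) for core atoms.
#' @param tail_sd rms displacement for non-core atoms; >= core_sd.
#' @param core_residues integer residue numbers forming the core (default:
#'   all residues).
#' @param seed integer random seed.
#' @return an \linkS4class{Ensemble} with energies and core residues set.
#' @export
perturbEnsemble <- function(model, n_models, core_sd, tail_sd = core_sd,
                            core_residues = NULL, seed = 1L) {
  if (n_models < 2L) stop("n_models must be >= 2")
  if (core_sd > tail_sd) stop("core_sd must be <= tail_sd")
  at <- atoms(model)
  if (is.null(core_residues)) core_residues <- unique(at$resno)
  sds <- ifelse(at$resno %in% core_residues, core_sd, tail_sd) / sqrt(3)
  set.seed(seed)
  mods <- vector("list", n_models)
  en <- numeric(n_models)
  for (m in seq_len(n_models)) {
    d <- matrix(rnorm(3L * nrow(at)), ncol = 3L) * sds
    a2 <- at
    a2$x <- at$x + d[, 1L]
    a2$y <- at$y + d[, 2L]
    a2$z <- at$z + d[, 3L]
    mods[[m]] <- StructureModel(a2, model_id = m)
    en[m] <- sum(d^2)
  }
  Ensemble(mods, energies = en,
           core_residues = as.integer(core_residues))
}
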