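# Chemical-shift analysis: secondary shifts against a random-coil
# reference, a consensus secondary-structure index (SSI), random-coil-index
# order parameters (RCI-S2) and flexible-end trimming.

# Random-coil chemical shifts (ppm) for backbone nuclei, after the
# commonly used peptide random-coil reference tables (Wishart-type values).
# Tests assert signs and orderings of derived quantities, not these
# constants themselves.
.RANDOM_COIL <- list(
  A = c(CA = 52.5, CB = 19.1, C = 177.8, N = 123.8, H = 8.24),
  R = c(CA = 56.0, CB = 30.9, C = 176.3, N = 120.5, H = 8.23),
  N = c(CA = 53.1, CB = 38.9, C = 175.2, N = 118.7, H = 8.40),
  D = c(CA = 54.2, CB = 41.1, C = 176.3, N = 120.4, H = 8.34),
  C = c(CA = 58.2, CB = 28.0, C = 174.6, N = 118.8, H = 8.32),
  Q = c(CA = 55.7, CB = 29.4, C = 176.0, N = 119.8, H = 8.32),
  E = c(CA = 56.6, CB = 29.9, C = 176.6, N = 120.2, H = 8.42),
  G = c(CA = 45.1, C = 174.9, N = 108.8, H = 8.33),
  H = c(CA = 55.0, CB = 29.0, C = 174.1, N = 118.2, H = 8.42),
  I = c(CA = 61.1, CB = 38.8, C = 176.4, N = 119.9, H = 8.00),
  L = c(CA = 55.1, CB = 42.4, C = 177.6, N = 121.8, H = 8.16),
  K = c(CA = 56.2, CB = 33.1, C = 176.6, N = 120.4, H = 8.29),
  M = c(CA = 55.4, CB = 32.9, C = 176.3, N = 119.6, H = 8.28),
  F = c(CA = 57.7, CB = 39.6, C = 175.8, N = 120.3, H = 8.30),
  P = c(CA = 63.3, CB = 32.1, C = 177.3),
  S = c(CA = 58.3, CB = 63.8, C = 174.6, N = 115.7, H = 8.31),
  T = c(CA = 61.8, CB = 69.8, C = 174.7, N = 113.6, H = 8.15),
  W = c(CA = 57.5, CB = 29.6, C = 176.1, N = 121.3, H = 8.25),
  Y = c(CA = 57.9, CB = 38.8, C = 175.9, N = 120.3, H = 8.12),
  V = c(CA = 62.2, CB = 32.9, C = 176.3, N = 119.2, H = 8.03)
)

# Mean secondary-structure shift offsets (ppm): helix raises CA/C' and
# lowers CB/N/HN; strand does the opposite.
.SS_OFFSET <- list(
  H = c(CA = 2.6, CB = -0.4, C = 1.8, N = -1.0, H = -0.25),
  E = c(CA = -1.4, CB = 2.2, C = -1.4, N = 1.5, H = 0.30),
  C = c(CA = 0, CB = 0, C = 0, N = 0, H = 0)
)

# per-nucleus normalization scales (ppm) used by SSI/RCI weighting:
# a typical full secondary-structure perturbation for that nucleus
.RCI_SCALE <- c(CA = 2.5, CB = 2.5, C = 2.0, N = 4.0, H = 0.6)
.RCI_GAIN <- 40
.RCI_MAX <- 1

# significance deadband (ppm) on the strand-vs-helix score: smaller
# combined CA/CB secondary shifts count as coil, the usual consensus-CSI
# convention for suppressing referencing and measurement noise
.SSI_DEADBAND <- 1.0

#' Secondary chemical shifts
#'
#' Observed minus random-coil reference for the same residue type, per atom.
#' Missing atoms are absent from the result rather than zero.
#'
#' @param table a \linkS4class{ChemicalShiftTable} whose entries carry
#'   residue names.
#' @return data.frame with columns resno, resname, atom, delta (ppm).
#' @export
secondaryShifts <- function(table) {
  e <- shiftEntries(table)
  rows <- list()
  for (i in seq_len(nrow(e))) {
    res3 <- e$resname[i]
    aa <- .AA1[res3]
    if (is.na(aa))
      stop(sprintf("residue type '%s' absent from random-coil reference", res3))
    rc <- .RANDOM_COIL[[aa]]
    atom <- e$atom[i]
    if (atom %in% c("HN")) atom <- "H"
    if (!atom %in% names(rc)) next
    rows[[length(rows) + 1L]] <- data.frame(
      resno = e$resno[i], resname = res3, atom = atom,
      delta = e$shift[i] - rc[[atom]])
  }
  if (!length(rows))
    return(data.frame(resno = integer(), resname = character(),
                      atom = character(), delta = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$resno), , drop = FALSE]
}

# per-residue strand-vs-helix evidence: positive = strand-like
.strandScore <- function(deltas) {
  res <- sort(unique(deltas$resno))
  vapply(res, function(r) {
    d <- deltas[deltas$resno == r, , drop = FALSE]
    ca <- d$delta[d$atom == "CA"]
    cb <- d$delta[d$atom == "CB"]
    if (length(ca) && length(cb)) cb[1L] - ca[1L]
    else if (length(ca)) -ca[1L]
    else if (length(cb)) cb[1L]
    else NA_real_
  }, numeric(1L))
}

#' Secondary-structure index from secondary shifts
#'
#' A consensus index over a sliding window of the per-residue sign of
#' (delta-CB - delta-CA): +1 is fully strand-like, -1 fully helix-like, and
#' the magnitude is the fraction of in-window residues agreeing in sign.
#' Scores within a significance deadband (1 ppm) count as coil (sign 0), the
#' usual consensus convention that keeps random-coil data near zero.
#'
#' @param deltas secondary shifts from \code{\link{secondaryShifts}}.
#' @param window odd integer window width (default 3).
#' @return a \linkS4class{DisorderProfile} with the \code{ssi} column set
#'   (\code{rci_s2} is NA; combine with \code{\link{computeRCIS2}} via
#'   \code{\link{disorderProfile}}).
#' @export
computeSSI <- function(deltas, window = 3L) {
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  res <- sort(unique(deltas$resno))
  x <- .strandScore(deltas)
  half <- (window - 1L) %/% 2L
  ssi <- rep(NA_real_, length(res))
  for (k in seq_along(res)) {
    idx <- which(res >= res[k] - half & res <= res[k] + half)
    s <- sign(x[idx]) * (abs(x[idx]) >= .SSI_DEADBAND)
    s <- s[!is.na(s)]
    ssi[k] <- if (length(s)) mean(s) else NA_real_
  }
  new("DisorderProfile",
      profile = data.frame(resno = res, ssi = ssi, rci_s2 = NA_real_,
                           coverage = !is.na(x)))
}

#' Random-coil-index order parameters from secondary shifts
#'
#' The per-residue random-coil index is the inverse of a smoothed, weighted
#' mean of absolute normalized secondary shifts; it is mapped monotonically
#' to an order parameter \eqn{S^2 \in [0, 1]} through
#' \eqn{S^2 = 1 - 0.4\,\ln(1 + 17.7\,\mathrm{RCI})} (clamped at 0), so
#' larger secondary shifts always give larger S2.
#'
#' @param deltas secondary shifts from \code{\link{secondaryShifts}}.
#' @param window odd smoothing window (default 3).
#' @param min_atoms minimum shift types per residue for coverage.
#' @return a \linkS4class{DisorderProfile} with the \code{rci_s2} column set.
#' @export
computeRCIS2 <- function(deltas, window = 3L, min_atoms = 2L) {
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  res <- sort(unique(deltas$resno))
  a <- nat <- rep(NA_real_, length(res))
  for (k in seq_along(res)) {
    d <- deltas[deltas$resno == res[k] & deltas$atom %in% names(.RCI_SCALE), ,
                drop = FALSE]
    nat[k] <- nrow(d)
    if (nrow(d))
      a[k] <- mean(abs(d$delta) / .RCI_SCALE[d$atom])
  }
  covered <- !is.na(a) & nat >= min_atoms
  if (mean(covered) < 0.5)
    warning("fewer than half of the residues have enough shifts for RCI")
  half <- (window - 1L) %/% 2L
  s2 <- rep(NA_real_, length(res))
  for (k in seq_along(res)) {
    idx <- which(res >= res[k] - half & res <= res[k] + half)
    v <- a[idx]
    v <- v[!is.na(v)]
    if (!length(v) || !covered[k]) next
    rci <- min(.RCI_MAX, 1 / (1 + .RCI_GAIN * mean(v)))
    s2[k] <- max(0, min(1, 1 - 0.4 * log(1 + 17.7 * rci)))
  }
  new("DisorderProfile",
      profile = data.frame(resno = res, ssi = NA_real_, rci_s2 = s2,
                           coverage = covered))
}

#' Combine SSI and RCI-S2 profiles
#'
#' @param ssi a \linkS4class{DisorderProfile} from \code{\link{computeSSI}}.
#' @param rci a \linkS4class{DisorderProfile} from
#'   \code{\link{computeRCIS2}}.
#' @return a merged \linkS4class{DisorderProfile}; coverage is the AND of
#'   the two inputs.
#' @export
disorderProfile <- function(ssi, rci) {
  a <- disorderTable(ssi)
  b <- disorderTable(rci)
  m <- merge(a[c("resno", "ssi", "coverage")],
             b[c("resno", "rci_s2", "coverage")],
             by = "resno", all = TRUE, suffixes = c("_ssi", "_rci"))
  new("DisorderProfile",
      profile = data.frame(resno = m$resno, ssi = m$ssi, rci_s2 = m$rci_s2,
                           coverage = m$coverage_ssi & m$coverage_rci))
}

#' Trim flexible chain ends by order parameter
#'
#' Removes the longest terminal runs of residues with \eqn{S^2} below the
#' threshold (residues without coverage count as flexible); interior
#' residues are never removed.
#'
#' @param profile a \linkS4class{DisorderProfile} covering the termini.
#' @param s2_threshold order-parameter threshold (default 0.5).
#' @param min_run only trim a terminal run of at least this many flexible
#'   residues (default 3).
#' @return data.frame with columns start, end: the retained inclusive core
#'   interval. Zero rows (with a warning) when everything is flexible.
#' @export
trimFlexibleEnds <- function(profile, s2_threshold = 0.5, min_run = 3L) {
  p <- disorderTable(profile)
  p <- p[order(p$resno), , drop = FALSE]
  flex <- is.na(p$rci_s2) | p$rci_s2 < s2_threshold
  n <- nrow(p)
  lead <- 0L
  while (lead < n && flex[lead + 1L]) lead <- lead + 1L
  trail <- 0L
  while (trail < n - lead && flex[n - trail]) trail <- trail + 1L
  if (lead + trail >= n) {
    warning("all residues below the order-parameter threshold; empty core")
    return(data.frame(start = integer(), end = integer()))
  }
  if (lead < min_run) lead <- 0L
  if (trail < min_run) trail <- 0L
  data.frame(start = p$resno[lead + 1L], end = p$resno[n - trail])
}
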