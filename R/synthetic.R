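# Synthetic structure generators: ideal backbones from phi/psi internal
# coordinates (NeRF chain extension), idealized methyl-bearing sidechains for
# ILV/Ala/Thr, and paired beta-sheets with canonical hydrogen-bond registry
# obtained by rigid-body least squares on N-H...O=C geometry.


#' Build an ideal backbone from a sequence and secondary-structure string
#'
#' Constructs backbone atoms (N, H, CA, C, O and CB except glycine) from
#' standard bond lengths and angles with canonical dihedrals: phi/psi of
#' (-57, -47) degrees for helix (H), (-139, 135) for antiparallel strand (E;
#' (-119, 113) with \code{parallel = TRUE}) and (-120, 120) for coil (C).
#' The amide proton is placed in the peptide plane anti to the carbonyl
#' oxygen. Methyl-bearing sidechains (Ala, Val, Leu, Ile, Thr) are completed
#' with idealized tetrahedral methyl groups when \code{methyls = TRUE} so
#' that NOE group specs can be resolved against generated models.
#'
#' @param sequence one-letter amino-acid string.
#' @param ss_string per-residue secondary structure, letters in {H, E, C};
#'   same length as \code{sequence}.
#' @param parallel logical: use the parallel-sheet strand dihedrals for E.
#' @param methyls logical: build idealized methyl groups.
#' @param start_resno first residue number.
#' @param chain chain identifier.
#' @param model_id model identifier.
#' @return a \linkS4class{StructureModel}.
#' @examples
#' helix <- makeIdealBackbone(strrep("A", 10), strrep("H", 10))
#' @export
makeIdealBackbone <- function(sequence, ss_string, parallel = FALSE,
                              methyls = TRUE, start_resno = 1L,
                              chain = "A", model_id = 1L) {
  seq1 <- strsplit(sequence, "")[[1L]]
  ss <- strsplit(ss_string, "")[[1L]]
  if (length(ss) == 0L) stop("empty ss_string")
  if (length(seq1) != length(ss))
    stop("sequence and ss_string lengths differ")
  if (!all(ss %in% c("H", "E", "C")))
    stop(sprintf("unknown secondary-structure code(s): %s",
                 paste(setdiff(ss, c("H", "E", "C")), collapse = ", ")))
  if (!all(seq1 %in% names(.AA3)))
    stop(sprintf("unknown residue letter(s): %s",
                 paste(setdiff(seq1, names(.AA3)), collapse = ", ")))
  nres <- length(seq1)
  pp <- t(vapply(ss, function(s) {
    key <- if (s == "E" && parallel) "Ep" else s
    .PHIPSI[[key]]
  }, numeric(2L)))
  g <- .BB
  N <- CA <- C <- O <- H <- vector("list", nres)
  N[[1L]] <- c(0, 0, 0)
  CA[[1L]] <- c(g$b_NCA, 0, 0)
  th <- .deg2rad(180 - g$a_NCAC)
  C[[1L]] <- CA[[1L]] + g$b_CAC * c(cos(th), sin(th), 0)
  for (i in seq_len(nres)) {
    if (i > 1L) {
      N[[i]] <- .placeAtom(N[[i - 1L]], CA[[i - 1L]], C[[i - 1L]],
                           g$b_CN, g$a_CACN, pp[i - 1L, 2L])
      CA[[i]] <- .placeAtom(CA[[i - 1L]], C[[i - 1L]], N[[i]],
                            g$b_NCA, g$a_CNCA, 180)
      C[[i]] <- .placeAtom(C[[i - 1L]], N[[i]], CA[[i]],
                           g$b_CAC, g$a_NCAC, pp[i, 1L])
      H[[i]] <- .placeAtom(O[[i - 1L]], C[[i - 1L]], N[[i]],
                           g$b_NH, g$a_CNH, 180)
    }
    O[[i]] <- .placeAtom(N[[i]], CA[[i]], C[[i]],
                         g$b_CO, g$a_CACO, pp[i, 2L] + 180)
  }
  # residue 1 has no preceding carbonyl; place H with the periodic
  # convention dihedral(C, CA, N, H) = phi + 180 observed for i > 1
  H[[1L]] <- .placeAtom(C[[1L]], CA[[1L]], N[[1L]], g$b_NH, 118.2,
                        pp[1L, 1L] + 180)
  rows <- list()
  for (i in seq_len(nres)) {
    resno <- start_resno + i - 1L
    resname <- .AA3[[seq1[i]]]
    add <- function(name, el, xyz)
      data.frame(chain = chain, resno = resno, resname = resname,
                 atom = name, element = el,
                 x = xyz[1L], y = xyz[2L], z = xyz[3L])
    r <- rbind(add("N", "N", N[[i]]),
               if (resname != "PRO") add("H", "H", H[[i]]),
               add("CA", "C", CA[[i]]),
               add("C", "C", C[[i]]),
               add("O", "O", O[[i]]))
    if (resname != "GLY") {
      cb <- .placeAtom(N[[i]], C[[i]], CA[[i]], g$b_CACB, g$a_CCACB, g$impCB)
      r <- rbind(r, add("CB", "C", cb))
      if (methyls && resname %in% names(.METHYL_CARBONS))
        r <- rbind(r, .buildMethylSidechain(resname, N[[i]], CA[[i]], C[[i]],
                                            cb, chain, resno))
    }
    rows[[i]] <- r
  }
  StructureModel(do.call(rbind, rows), model_id = model_id)
}

# Idealized ILV/Ala/Thr sidechains: chi angles fixed at common rotamers,
# tetrahedral methyl protons staggered about the methyl axis.
.buildMethylSidechain <- function(resname, n, ca, c, cb, chain, resno) {
  g <- .BB
  add <- function(name, el, xyz)
    data.frame(chain = chain, resno = resno, resname = resname, atom = name,
               element = el, x = xyz[1L], y = xyz[2L], z = xyz[3L])
  methyl <- function(carbon_name, ref1, ref2, cpos) {
    hn <- .methylProtonNames(carbon_name)
    out <- NULL
    for (k in 1:3)
      out <- rbind(out, add(hn[k], "H",
                            .placeAtom(ref1, ref2, cpos, g$b_CH, g$a_tet,
                                       60 + 120 * (k - 1L))))
    out
  }
  out <- NULL
  if (resname == "ALA") {
    out <- methyl("CB", n, ca, cb)
  } else if (resname == "VAL") {
    cg1 <- .placeAtom(n, ca, cb, g$b_CC, g$a_CCC, 175)
    cg2 <- .placeAtom(n, ca, cb, g$b_CC, g$a_CCC, 175 - 122)
    out <- rbind(add("CG1", "C", cg1), methyl("CG1", ca, cb, cg1),
                 add("CG2", "C", cg2), methyl("CG2", ca, cb, cg2))
  } else if (resname == "THR") {
    cg2 <- .placeAtom(n, ca, cb, g$b_CC, g$a_CCC, -60)
    og1 <- .placeAtom(n, ca, cb, 1.43, g$a_CCC, -60 + 122)
    out <- rbind(add("CG2", "C", cg2), methyl("CG2", ca, cb, cg2),
                 add("OG1", "O", og1))
  } else if (resname == "LEU") {
    cg <- .placeAtom(n, ca, cb, g$b_CC, g$a_CCC, -60)
    cd1 <- .placeAtom(ca, cb, cg, g$b_CC, g$a_CCC, 175)
    cd2 <- .placeAtom(ca, cb, cg, g$b_CC, g$a_CCC, 175 - 122)
    out <- rbind(add("CG", "C", cg),
                 add("CD1", "C", cd1), methyl("CD1", cb, cg, cd1),
                 add("CD2", "C", cd2), methyl("CD2", cb, cg, cd2))
  } else if (resname == "ILE") {
    cg1 <- .placeAtom(n, ca, cb, g$b_CC, g$a_CCC, -60)
    cg2 <- .placeAtom(n, ca, cb, g$b_CC, g$a_CCC, -60 + 122)
    cd1 <- .placeAtom(ca, cb, cg1, g$b_CC, g$a_CCC, 180)
    out <- rbind(add("CG1", "C", cg1),
                 add("CG2", "C", cg2), methyl("CG2", ca, cb, cg2),
                 add("CD1", "C", cd1), methyl("CD1", cb, cg1, cd1))
  }
  out
}

.applyRigid <- function(at, R, t) {
  xyz <- as.matrix(at[c("x", "y", "z")]) %*% R
  at$x <- xyz[, 1L] + t[1L]
  at$y <- xyz[, 2L] + t[2L]
  at$z <- xyz[, 3L] + t[3L]
  at
}

.rigidFromPar <- function(par) {
  R <- .eulerZYZ(par[1L], par[2L], par[3L])
  list(R = R, t = par[4:6])
}

#' Build an ideal two-or-more-strand beta-sheet with known registry
#'
#' Strands are ideal extended chains (strand dihedrals as in
#' \code{\link{makeIdealBackbone}}); each successive strand is positioned by
#' rigid-body least squares so that the canonical inter-strand
#' N-H...O=C hydrogen bonds of the requested topology reach ideal geometry
#' (H...O 1.95 A, N...O 2.95 A). The pairing table (residue partners,
#' orientation, hydrogen-bonded "narrow" pairs for antiparallel sheets) is
#' returned alongside the model for use as a geometric oracle.
#'
#' @param n_strands number of strands (>= 2).
#' @param strand_len residues per strand (>= 3).
#' @param topology "antiparallel" or "parallel".
#' @param sequence optional one-letter sequence per strand (defaults to
#'   poly-Ala, whose compact methyls keep ideal flat strands clash-free
#'   while still exercising methyl NOE machinery).
#' @param gap numbering gap between consecutive strands.
#' @return list with elements \code{model} (a
#'   \linkS4class{StructureModel}), \code{pairing} (data.frame with columns
#'   \code{resno_a}, \code{resno_b}, \code{strand_a}, \code{strand_b},
#'   \code{topology}, \code{hbonded}), and \code{strands} (data.frame of
#'   strand start/end residue numbers).
#' @examples
#' sh <- makeSheet(2, 6, "antiparallel")
#' @export
makeSheet <- function(n_strands, strand_len,
                      topology = c("antiparallel", "parallel"),
                      sequence = NULL, gap = 5L) {
  topology <- match.arg(topology)
  if (n_strands < 2L) stop("n_strands must be >= 2")
  if (strand_len < 3L) stop("strand_len must be >= 3")
  if (is.null(sequence)) sequence <- strrep("A", strand_len)
  if (nchar(sequence) != strand_len)
    stop("sequence length must equal strand_len")
  parallel <- topology == "parallel"
  ss <- strrep("E", strand_len)
  starts <- 1L + (seq_len(n_strands) - 1L) * (strand_len + gap)
  strandModels <- lapply(seq_len(n_strands), function(k)
    makeIdealBackbone(sequence, ss, parallel = parallel,
                      start_resno = starts[k], model_id = 1L))
  placed <- list(atoms(strandModels[[1L]]))
  pairing <- NULL
  # a residue's N-H points to one neighbour strand only, so the
  # hydrogen-bonded parity of successive antiparallel strand pairs depends
  # on the strand length: the donors toward strand k+1 must be the residues
  # not already bonded toward strand k-1
  phase <- 0L
  for (k in 2L:n_strands) {
    prev <- placed[[k - 1L]]
    cur <- atoms(strandModels[[k]])
    reg <- .sheetRegistry(starts[k - 1L], starts[k], strand_len, topology,
                          phase = phase)
    phase <- (strand_len - phase) %% 2L
    others <- if (k > 2L) do.call(rbind, placed[seq_len(k - 2L)]) else NULL
    fit <- .placeStrand(prev, cur, reg$hbonds, topology, others)
    placed[[k]] <- fit
    pairing <- rbind(pairing,
                     data.frame(resno_a = reg$pairs$a, resno_b = reg$pairs$b,
                                strand_a = k - 1L, strand_b = k,
                                topology = topology,
                                hbonded = reg$pairs$hbonded))
  }
  at <- do.call(rbind, placed)
  rownames(at) <- NULL
  list(model = StructureModel(at, model_id = 1L),
       pairing = pairing,
       strands = data.frame(strand = seq_len(n_strands), start = starts,
                            end = starts + strand_len - 1L))
}

# Canonical registry between strand A (residues sa..sa+len-1) and strand B
# (sb..sb+len-1). Antiparallel: residue sa+i pairs sb+(len-1-i); alternating
# pairs are doubly hydrogen bonded ("narrow"). Parallel: sa+i pairs sb+i with
# H-bonds N-H(b_i) -> O(a_{i-1}) and N-H(a_{i+1}) -> O(b_i).
.sheetRegistry <- function(sa, sb, len, topology, phase = 0L) {
  ia <- seq_len(len) - 1L
  if (topology == "antiparallel") {
    a <- sa + ia
    b <- sb + (len - 1L - ia)
    hb <- (ia %% 2L) == phase
    hbonds <- NULL
    for (j in which(hb)) {
      hbonds <- rbind(hbonds,
                      data.frame(donor = b[j], acceptor = a[j]),
                      data.frame(donor = a[j], acceptor = b[j]))
    }
    list(pairs = data.frame(a = a, b = b, hbonded = hb), hbonds = hbonds)
  } else {
    # parallel: only alternate residues face a given neighbour strand; the
    # facing pairs (i, j) form rings N-H(j) -> O(i-1) and N-H(i+1) -> O(j)
    a <- sa + ia
    b <- sb + ia
    ring <- (ia %% 2L) == 1L  # interior alternate positions
    hbonds <- NULL
    for (j in which(ring)) {
      if (j > 1L)
        hbonds <- rbind(hbonds, data.frame(donor = b[j], acceptor = a[j - 1L]))
      if (j < len)
        hbonds <- rbind(hbonds, data.frame(donor = a[j + 1L], acceptor = b[j]))
    }
    list(pairs = data.frame(a = a, b = b, hbonded = ring), hbonds = hbonds)
  }
}

# Rigid-body placement of a strand against an already-placed partner:
# minimize squared deviations of H...O (1.95 A) and N...O (2.95 A) over the
# canonical hydrogen bonds. Several deterministic starting placements are
# tried; the best optimum is kept.
.placeStrand <- function(prev, cur, hbonds, topology, others = NULL) {
  getxyz <- function(at, resno, name) {
    r <- at[at$resno == resno & at$atom == name, c("x", "y", "z")]
    if (nrow(r) != 1L) stop(sprintf("atom %d.%s missing", resno, name))
    as.numeric(r)
  }
  inCur <- function(resno) resno %in% cur$resno
  src <- function(resno) if (inCur(resno)) cur else prev
  nh <- nrow(hbonds)
  H <- N <- O <- CC <- matrix(0, nh, 3L)
  hCur <- nCur <- oCur <- logical(nh)
  for (i in seq_len(nh)) {
    H[i, ] <- getxyz(src(hbonds$donor[i]), hbonds$donor[i], "H")
    N[i, ] <- getxyz(src(hbonds$donor[i]), hbonds$donor[i], "N")
    O[i, ] <- getxyz(src(hbonds$acceptor[i]), hbonds$acceptor[i], "O")
    CC[i, ] <- getxyz(src(hbonds$acceptor[i]), hbonds$acceptor[i], "C")
    hCur[i] <- nCur[i] <- inCur(hbonds$donor[i])
    oCur[i] <- inCur(hbonds$acceptor[i])
  }
  caPonly <- as.matrix(prev[prev$atom == "CA", c("x", "y", "z")])
  caP <- caPonly
  if (!is.null(others))
    caP <- rbind(caP, as.matrix(others[others$atom == "CA",
                                       c("x", "y", "z")]))
  caC <- as.matrix(cur[cur$atom == "CA", c("x", "y", "z")])
  objective <- function(par) {
    tr <- .rigidFromPar(par)
    mv <- function(M, flag) {
      out <- M
      if (any(flag))
        out[flag, ] <- sweep(M[flag, , drop = FALSE] %*% tr$R, 2L, tr$t, "+")
      out
    }
    Ht <- mv(H, hCur); Nt <- mv(N, nCur); Ot <- mv(O, oCur)
    Ct <- mv(CC, oCur)
    dHO <- sqrt(rowSums((Ht - Ot)^2))
    dNO <- sqrt(rowSums((Nt - Ot)^2))
    s <- sum((dHO - 1.95)^2) + sum((dNO - 2.95)^2)
    # acceptor directionality: H approaches within ~30 degrees of the C=O
    # axis (hinge penalty; exact collinearity is not the sheet geometry)
    co <- Ot - Ct
    oh <- Ht - Ot
    cosca <- rowSums(co * oh) /
      (sqrt(rowSums(co^2)) * pmax(sqrt(rowSums(oh^2)), 1e-6))
    s <- s + sum(pmax(0, 0.866 - cosca)^2)
    # soft steric guard: CA atoms of distinct strands at >= 4 A
    caCt <- sweep(caC %*% tr$R, 2L, tr$t, "+")
    d2 <- outer(rowSums(caP^2), rowSums(caCt^2), "+") - 2 * caP %*% t(caCt)
    dmin <- sqrt(pmax(d2, 0))
    s + sum(pmax(0, 4 - dmin)^2)
  }
  caPrev <- colMeans(prev[prev$atom == "CA", c("x", "y", "z")])
  caCur <- colMeans(cur[cur$atom == "CA", c("x", "y", "z")])
  # deterministic starting placements: strands lie roughly along x with
  # NH/CO along +/-y, so the partner strand is reached by a C2 about the
  # sheet normal (antiparallel) or a pure translation (parallel), offset
  # ~4.4 A laterally with a small axial shift for hydrogen-bond registry.
  # Analytic start: ideal target positions for the mobile strand's
  # hydrogen-bonding atoms, extrapolated along the fixed strand's N-H and
  # C=O axes, then a Kabsch fit of the mobile atoms onto those targets.
  mob <- ref <- NULL
  for (i in seq_len(nh)) {
    don <- hbonds$donor[i]; acc <- hbonds$acceptor[i]
    if (inCur(don) && !inCur(acc)) {
      o <- getxyz(prev, acc, "O"); cc <- getxyz(prev, acc, "C")
      u <- .vunit(o - cc)
      mob <- rbind(mob, getxyz(cur, don, "H"), getxyz(cur, don, "N"))
      ref <- rbind(ref, o + 1.95 * u, o + 2.96 * u)
    } else if (inCur(acc) && !inCur(don)) {
      hh <- getxyz(prev, don, "H"); nn <- getxyz(prev, don, "N")
      u <- .vunit(hh - nn)
      mob <- rbind(mob, getxyz(cur, acc, "O"), getxyz(cur, acc, "C"))
      ref <- rbind(ref, nn + (1.01 + 1.95) * u, nn + (1.01 + 1.95 + 1.23) * u)
    }
  }
  starts <- list()
  if (!is.null(mob) && nrow(mob) >= 3L) {
    kb <- try(.kabschCore(mob, ref), silent = TRUE)
    if (!inherits(kb, "try-error")) {
      # recover zyz Euler angles of kb$rotation for the parameter vector
      R <- kb$rotation
      beta <- acos(max(-1, min(1, R[3L, 3L])))
      if (abs(sin(beta)) > 1e-8) {
        alpha <- atan2(R[2L, 3L], R[1L, 3L])
        gamma <- atan2(R[3L, 2L], -R[3L, 1L])
      } else {
        alpha <- atan2(R[2L, 1L], R[1L, 1L]); gamma <- 0
      }
      starts[[1L]] <- c(.rad2deg(alpha), .rad2deg(beta), .rad2deg(gamma),
                        kb$translation)
    }
  }
  rot0 <- if (topology == "antiparallel") c(180, 0, 0) else c(0, 0, 0)
  axis <- .vunit(caPonly[nrow(caPonly), ] - caPonly[1L, ])
  lat <- c(0, 1, 0)
  if (!is.null(others)) {
    away <- caPrev - colMeans(as.matrix(others[others$atom == "CA",
                                               c("x", "y", "z")]))
    away <- away - sum(away * axis) * axis
    if (.vnorm(away) > 1e-6) lat <- .vunit(away)
  }
  lat <- lat - sum(lat * axis) * axis
  lat <- .vunit(lat)
  sgns <- if (is.null(others)) c(1, -1) else 1
  for (sgn in sgns) {
    for (ax in c(-2.4, 0, 2.4)) {
      R0 <- .eulerZYZ(rot0[1L], rot0[2L], rot0[3L])
      t0 <- caPrev + sgn * 4.4 * lat + ax * axis -
        as.numeric(caCur %*% R0)
      starts[[length(starts) + 1L]] <- c(rot0, t0)
    }
  }
  # When the analytic lattice fit already realizes the hydrogen-bond
  # geometry (it does for commensurate registries), accept it outright: it
  # is symmetric and deterministic. Otherwise refine from all starts.
  best <- NULL
  good <- 0.02 * nh
  for (p0 in starts) {
    v0 <- objective(p0)
    if (v0 < good) { best <- list(par = p0, value = v0); break }
    fit <- optim(p0, objective, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
    if (best$value < good) break
  }
  if (best$value >= good) {
    for (p0 in starts) {
      fit <- optim(p0, objective, method = "Nelder-Mead",
                   control = list(maxit = 4000, reltol = 1e-12))
      fit <- optim(fit$par, objective, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14))
      if (fit$value < best$value) best <- fit
    }
  }
  tr <- .rigidFromPar(best$par)
  .applyRigid(cur, tr$R, tr$t)
}
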