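# Atom-group specs. An NOE connects proton groups rather than single atoms:
# an amide proton ("12.HN" or "12.H") or a methyl group named by its carbon
# ("45.CD1", expanding to the three methyl protons). Isopropyl groups without
# stereo assignment are written as a union, e.g. "45.CD1|45.CD2".

#' Parse an atom-group spec
#'
#' @param spec character scalar, e.g. "12.HN", "45.CD1" or "45.CD1|45.CD2".
#' @return data.frame with one row per union member: resno, atom, kind
#'   ("amide" or "methyl").
#' @export
parseGroupSpec <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1L, nzchar(spec))
  parts <- strsplit(spec, "|", fixed = TRUE)[[1L]]
  out <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^([0-9]+)\\.([A-Za-z][A-Za-z0-9]*)$", p))[[1L]]
    if (length(m) != 3L)
      stop(sprintf("malformed group spec '%s' (expected RESNO.ATOM)", p))
    atom <- toupper(m[3L])
    kind <- if (atom %in% c("H", "HN")) "amide"
            else if (substr(atom, 1L, 1L) == "C") "methyl"
            else stop(sprintf("group atom '%s' is neither an amide proton nor a methyl carbon", atom))
    data.frame(resno = as.integer(m[2L]),
               atom = if (atom == "HN") "H" else atom,
               kind = kind)
  })
  do.call(rbind, out)
}

#' Infer the NOE class of a peak from its two group specs
#'
#' @param spec_a,spec_b atom-group specs.
#' @return "amide-amide", "amide-methyl" or "methyl-methyl".
#' @export
inferPeakClass <- function(spec_a, spec_b) {
  ka <- unique(parseGroupSpec(spec_a)$kind)
  kb <- unique(parseGroupSpec(spec_b)$kind)
  if (length(ka) != 1L || length(kb) != 1L)
    stop("mixed amide/methyl unions are not supported in one group")
  k <- sort(c(ka, kb))
  if (all(k == "amide")) "amide-amide"
  else if (all(k == "methyl")) "methyl-methyl"
  else "amide-methyl"
}

# Methyl proton names for a methyl carbon, e.g. CD1 -> HD11 HD12 HD13,
# CB -> HB1 HB2 HB3.
.methylProtonNames <- function(carbon) {
  stem <- sub("^C", "H", carbon)
  paste0(stem, 1:3)
}

#' Resolve a group spec to proton coordinates in a model
#'
#' Amide groups resolve to the backbone amide proton (built from heavy atoms
#' if absent); methyl groups resolve to the three methyl protons, and unions
#' to the protons of all members.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param spec an atom-group spec string.
#' @return matrix (n x 3) of proton coordinates.
#' @export
resolveGroup <- function(model, spec) {
  g <- parseGroupSpec(spec)
  at <- atoms(model)
  coords <- NULL
  for (i in seq_len(nrow(g))) {
    sel <- at$resno == g$resno[i]
    if (!any(sel))
      stop(sprintf("group '%s': residue %d absent from model", spec, g$resno[i]))
    if (g$kind[i] == "amide") {
      row <- at[sel & at$atom == "H", , drop = FALSE]
      if (nrow(row) == 0L) {
        h <- .buildAmideH(at, g$resno[i])
        if (is.null(h))
          stop(sprintf("group '%s': no amide proton buildable for residue %d",
                       spec, g$resno[i]))
        coords <- rbind(coords, h)
      } else {
        coords <- rbind(coords, as.matrix(row[1L, c("x", "y", "z")]))
      }
    } else {
      hn <- .methylProtonNames(g$atom[i])
      rows <- at[sel & at$atom %in% hn, , drop = FALSE]
      if (nrow(rows) != 3L)
        stop(sprintf("group '%s': methyl protons %s not all present for residue %d",
                     spec, paste(hn, collapse = "/"), g$resno[i]))
      coords <- rbind(coords, as.matrix(rows[c("x", "y", "z")]))
    }
  }
  dimnames(coords) <- NULL
  coords
}

# Build an amide proton position from C(i-1), N(i), CA(i): H on the bisector
# of the two in-plane directions away from the heavy neighbours, 1.01 A from
# N. Returns NULL for residue 1 without a preceding carbonyl or for proline.
.buildAmideH <- function(at, resno) {
  if (any(at$resno == resno & at$resname == "PRO")) return(NULL)
  n <- at[at$resno == resno & at$atom == "N", c("x", "y", "z")]
  ca <- at[at$resno == resno & at$atom == "CA", c("x", "y", "z")]
  cp <- at[at$resno == resno - 1L & at$atom == "C", c("x", "y", "z")]
  if (nrow(n) != 1L || nrow(ca) != 1L || nrow(cp) != 1L) return(NULL)
  n <- as.numeric(n); ca <- as.numeric(ca); cp <- as.numeric(cp)
  u <- .vunit(.vunit(n - cp) + .vunit(n - ca))
  matrix(n + 1.01 * u, 1L, 3L)
}

#' Effective distance between two proton groups
#'
#' NOE intensity sums over all inter-group proton pairs, so the effective
#' distance is \eqn{r_{eff} = (\sum_{ij} r_{ij}^{-6})^{-1/6}}. For two single
#' protons this is the plain distance; for groups it is shorter than the
#' closest pair-center distance.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param spec_a,spec_b atom-group specs.
#' @return effective distance in Angstrom.
#' @export
effectiveDistance <- function(model, spec_a, spec_b) {
  pa <- resolveGroup(model, spec_a)
  pb <- resolveGroup(model, spec_b)
  .reffFromCoords(pa, pb)
}

.reffFromCoords <- function(pa, pb) {
  s <- 0
  for (i in seq_len(nrow(pa))) {
    d2 <- (pb[, 1L] - pa[i, 1L])^2 + (pb[, 2L] - pa[i, 2L])^2 +
      (pb[, 3L] - pa[i, 3L])^2
    s <- s + sum(d2^(-3))
  }
  s^(-1 / 6)
}
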