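# Hydrogen-bond based secondary-structure assignment (three states H/E/C)
# using the Kabsch-Sander electrostatic energy, plus beta-sheet topology
# extraction from bridge partners.

.KS_CUTOFF <- -0.5  # kcal/mol

# Kabsch-Sander hydrogen-bond energy between donor (N-H of residue d) and
# acceptor (C=O of residue a):
# E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)
.hbondEnergies <- function(model) {
  at <- atoms(model)
  res <- sort(unique(at$resno))
  get <- function(r, a) {
    x <- at[at$resno == r & at$atom == a, c("x", "y", "z")]
    if (nrow(x) == 1L) as.numeric(x) else NULL
  }
  pos <- list()
  for (r in res) {
    h <- get(r, "H")
    if (is.null(h)) {
      hb <- .buildAmideH(at, r)
      h <- if (is.null(hb)) NULL else as.numeric(hb)
    }
    pos[[as.character(r)]] <- list(N = get(r, "N"), H = h, C = get(r, "C"),
                                   O = get(r, "O"))
  }
  # chain breaks: consecutive residues with C-N distance > 2.5 A
  breaks <- logical(length(res))
  for (k in seq_along(res)[-1L]) {
    c0 <- pos[[as.character(res[k - 1L])]]$C
    n1 <- pos[[as.character(res[k])]]$N
    breaks[k] <- is.null(c0) || is.null(n1) ||
      res[k] != res[k - 1L] + 1L || .vnorm(n1 - c0) > 2.5
  }
  hb <- matrix(FALSE, length(res), length(res),
               dimnames = list(res, res))
  for (di in seq_along(res)) {
    d <- pos[[di]]
    if (is.null(d$H) || is.null(d$N)) next
    for (ai in seq_along(res)) {
      if (abs(res[di] - res[ai]) < 2L) next
      a <- pos[[ai]]
      if (is.null(a$O) || is.null(a$C)) next
      rON <- .vnorm(a$O - d$N)
      if (rON > 5.2) next
      rCH <- .vnorm(a$C - d$H)
      rOH <- .vnorm(a$O - d$H)
      rCN <- .vnorm(a$C - d$N)
      E <- 0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      hb[di, ai] <- E < .KS_CUTOFF
    }
  }
  list(res = res, hb = hb, breaks = breaks)
}

# bridge detection per Kabsch-Sander: returns data.frame (i, j, type)
.findBridges <- function(hbinfo) {
  res <- hbinfo$res
  hb <- hbinfo$hb
  idx <- function(r) match(r, res)
  H <- function(d, a) {
    di <- idx(d); ai <- idx(a)
    !is.na(di) && !is.na(ai) && hb[di, ai]
  }
  rows <- list()
  for (i in res) for (j in res) {
    if (j - i < 3L) next
    par <- (H(i, j - 1L) && H(j + 1L, i)) || (H(j, i - 1L) && H(i + 1L, j))
    anti <- (H(i, j) && H(j, i)) ||
      (H(i - 1L, j + 1L) && H(j - 1L, i + 1L))
    if (par) rows[[length(rows) + 1L]] <-
        data.frame(i = i, j = j, type = "parallel")
    if (anti) rows[[length(rows) + 1L]] <-
        data.frame(i = i, j = j, type = "antiparallel")
  }
  if (!length(rows))
    return(data.frame(i = integer(), j = integer(), type = character()))
  do.call(rbind, rows)
}

#' Assign three-state secondary structure from backbone hydrogen bonds
#'
#' Backbone H-bonds are detected with the Kabsch-Sander electrostatic
#' energy (cutoff -0.5 kcal/mol; amide protons built from heavy atoms when
#' absent). Helix (H) is assigned to residues covered by consecutive
#' i -> i+4 hydrogen-bond turns, strand (E) to residues in parallel or
#' antiparallel bridge ladders, and coil (C) otherwise. A single extended
#' strand without a bridge partner stays coil. Chain breaks restart the
#' patterns.
#'
#' @param model a \linkS4class{StructureModel} with backbone N, CA, C, O.
#' @return character string of per-residue codes in {H, E, C}, named by
#'   residue number.
#' @export
assignSecondaryStructure <- function(model) {
  at <- atoms(model)
  for (r in unique(at$resno))
    if (!"O" %in% at$atom[at$resno == r])
      stop(sprintf("residue %d lacks a carbonyl O", r))
  info <- .hbondEnergies(model)
  res <- info$res
  hb <- info$hb
  n <- length(res)
  idx <- function(r) match(r, res)
  turn4 <- logical(n)
  for (k in seq_len(n)) {
    k4 <- k + 4L
    if (k4 <= n && res[k4] == res[k] + 4L &&
        !any(info$breaks[(k + 1L):k4]) && hb[k4, k])
      turn4[k] <- TRUE
  }
  ss <- rep("C", n)
  # helix: two consecutive 4-turns make residues i+1..i+4 helical
  for (k in seq_len(n - 1L)) {
    if (turn4[k] && turn4[k + 1L]) {
      span <- idx(res[k] + 1L):idx(res[k] + 4L)
      ss[span] <- "H"
    }
  }
  bridges <- .findBridges(info)
  for (b in seq_len(nrow(bridges))) {
    for (r in c(bridges$i[b], bridges$j[b])) {
      k <- idx(r)
      if (ss[k] == "C") ss[k] <- "E"
    }
  }
  setNames(ss, res)
}

#' Beta-sheet topology from bridge partners
#'
#' Strands are maximal runs of strand-assigned residues; pairings come from
#' bridge partners with orientation and register. For an ensemble, the
#' per-model topologies are reduced by majority consensus.
#'
#' @param x a \linkS4class{StructureModel} or \linkS4class{Ensemble}.
#' @return list with \code{strands} (data.frame: strand, start, end),
#'   \code{pairs} (data.frame: strand_a, strand_b, topology, register) and
#'   \code{pairing} (data.frame of residue-level partners: resno_a,
#'   resno_b, topology).
#' @export
sheetTopology <- function(x) {
  if (is(x, "Ensemble")) {
    per <- lapply(models(x), sheetTopology)
    # consensus: keep residue pairings present in a majority of models
    allp <- do.call(rbind, lapply(per, `[[`, "pairing"))
    if (is.null(allp) || nrow(allp) == 0L)
      return(list(strands = per[[1L]]$strands,
                  pairs = per[[1L]]$pairs[0L, ],
                  pairing = data.frame(resno_a = integer(),
                                       resno_b = integer(),
                                       topology = character())))
    key <- paste(allp$resno_a, allp$resno_b, allp$topology)
    tab <- table(key)
    keep <- names(tab)[tab > length(per) / 2]
    cons <- allp[!duplicated(key) & key %in% keep, , drop = FALSE]
    rownames(cons) <- NULL
    strands <- .strandRuns(sort(unique(c(cons$resno_a, cons$resno_b))))
    return(list(strands = strands, pairs = .strandPairs(strands, cons),
                pairing = cons))
  }
  ss <- assignSecondaryStructure(x)
  res <- as.integer(names(ss))
  erun <- res[ss == "E"]
  strands <- .strandRuns(erun)
  info <- .hbondEnergies(x)
  bridges <- .findBridges(info)
  bridges <- bridges[bridges$i %in% erun & bridges$j %in% erun, ,
                     drop = FALSE]
  pairing <- data.frame(resno_a = bridges$i, resno_b = bridges$j,
                        topology = bridges$type)
  list(strands = strands, pairs = .strandPairs(strands, pairing),
       pairing = pairing)
}

.strandRuns <- function(resnos) {
  if (!length(resnos))
    return(data.frame(strand = integer(), start = integer(),
                      end = integer()))
  resnos <- sort(unique(resnos))
  brk <- c(0L, which(diff(resnos) > 1L), length(resnos))
  rows <- lapply(seq_len(length(brk) - 1L), function(k) {
    data.frame(strand = k, start = resnos[brk[k] + 1L],
               end = resnos[brk[k + 1L]])
  })
  do.call(rbind, rows)
}

.strandPairs <- function(strands, pairing) {
  if (nrow(pairing) == 0L || nrow(strands) == 0L)
    return(data.frame(strand_a = integer(), strand_b = integer(),
                      topology = character(), register = integer()))
  strandOf <- function(r) {
    hit <- which(strands$start <= r & strands$end >= r)
    if (length(hit)) hit[1L] else NA_integer_
  }
  pairing$sa <- vapply(pairing$resno_a, strandOf, integer(1L))
  pairing$sb <- vapply(pairing$resno_b, strandOf, integer(1L))
  pairing <- pairing[!is.na(pairing$sa) & !is.na(pairing$sb) &
                       pairing$sa != pairing$sb, , drop = FALSE]
  if (nrow(pairing) == 0L)
    return(data.frame(strand_a = integer(), strand_b = integer(),
                      topology = character(), register = integer()))
  key <- paste(pairing$sa, pairing$sb, pairing$topology)
  rows <- lapply(unique(key), function(k) {
    sub <- pairing[key == k, , drop = FALSE]
    reg <- if (sub$topology[1L] == "parallel")
      median(sub$resno_b - sub$resno_a)
    else median(sub$resno_b + sub$resno_a)
    data.frame(strand_a = sub$sa[1L], strand_b = sub$sb[1L],
               topology = sub$topology[1L], register = as.integer(reg))
  })
  out <- do.call(rbind, rows)
  out[order(out$strand_a, out$strand_b), , drop = FALSE]
}
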