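# NOE calibration: diagonal normalization, beta-sheet distance statistics,
# proportionality-constant estimation from the strongest amide-amide peak,
# intensity-to-bound inversion, model-bootstrapped recalibration for methyl
# classes, and restraint validation against an ensemble.

#' Normalize NOE cross intensities by their diagonals
#'
#' Each cross intensity is divided by the geometric mean of the available
#' diagonal intensities of its two spins (symmetric in the two spins and
#' invariant to a global intensity rescaling). Peaks lacking both diagonals
#' are flagged and passed through unchanged.
#'
#' @param x an \linkS4class{NOEPeakTable}.
#' @return the table with normalized intensities.
#' @export
normalizeIntensities <- function(x) {
  if (isNormalized(x)) return(x)
  p <- peaks(x)
  for (i in seq_len(nrow(p))) {
    d <- c(p$diag_a[i], p$diag_b[i])
    d <- d[!is.na(d)]
    if (!length(d)) {
      p$flagged[i] <- TRUE
      next
    }
    if (any(d <= 0))
      stop(sprintf("non-positive diagonal intensity for peak %d (%s / %s)",
                   p$peak_id[i], p$group_a[i], p$group_b[i]))
    p$cross[i] <- p$cross[i] / exp(mean(log(d)))
  }
  new("NOEPeakTable", peaks = p, normalized = TRUE, truth = x@truth)
}

#' Characteristic beta-sheet amide-proton distance statistics
#'
#' Collects HN-HN distances from paired beta-strands and clusters them into
#' characteristic classes. For antiparallel sheets all inter-strand amide
#' pairs of each paired strand duo within the NOE-observable range enter
#' (the doubly hydrogen-bonded "narrow" pairs and the next-nearest diagonal
#' pairs form the two classes). For parallel sheets the register-diagonal
#' pairs (i with j+1/j-1 of the partner strand, the cross-strand amide
#' contacts within NOE range in parallel geometry, where the registered
#' facing pairs lie at ~5 A) and the sequential intra-strand pairs enter.
#'
#' @param models a \linkS4class{StructureModel} or list of them (classes are
#'   pooled over models).
#' @param pairing data.frame with columns resno_a, resno_b (registered
#'   strand pairs), e.g. from \code{\link{makeSheet}}; when NULL, pairing is
#'   detected via \code{\link{sheetTopology}}.
#' @param topology "antiparallel" or "parallel".
#' @param max_r NOE observability cutoff in Angstrom.
#' @param k number of distance classes.
#' @return a \linkS4class{SheetDistanceStats}.
#' @export
sheetDistanceStats <- function(models, pairing = NULL,
                               topology = c("antiparallel", "parallel"),
                               max_r = 5.5, k = 2L) {
  topology <- match.arg(topology)
  if (is(models, "StructureModel")) models <- list(models)
  dists <- numeric()
  for (model in models) {
    if (is.null(pairing)) {
      topo <- sheetTopology(model)
      if (nrow(topo$pairing) == 0L)
        stop("no paired beta-strands found in model")
      pr <- topo$pairing
    } else pr <- pairing
    at <- atoms(model)
    hpos <- function(r) {
      h <- at[at$resno == r & at$atom == "H", c("x", "y", "z")]
      if (nrow(h) == 1L) as.numeric(h) else {
        hb <- .buildAmideH(at, r)
        if (is.null(hb)) NULL else as.numeric(hb)
      }
    }
    # group residue pairings by strand duo so that multi-strand sheets do
    # not mix residues of non-adjacent strands (or a strand with itself)
    strands <- .strandRuns(sort(unique(c(pr$resno_a, pr$resno_b))))
    strandOf <- function(r) {
      hit <- which(strands$start <= r & strands$end >= r)
      if (length(hit)) hit[1L] else NA_integer_
    }
    duo <- paste(vapply(pr$resno_a, strandOf, integer(1L)),
                 vapply(pr$resno_b, strandOf, integer(1L)))
    for (grp in split(pr, duo)) {
      ra <- sort(unique(grp$resno_a))
      rb <- sort(unique(grp$resno_b))
      if (topology == "antiparallel") {
        # all inter-strand amide pairs of the duo
        for (i in ra) for (j in rb) {
          hi <- hpos(i); hj <- hpos(j)
          if (is.null(hi) || is.null(hj)) next
          d <- .vnorm(hi - hj)
          if (d > 0.1 && d <= max_r) dists <- c(dists, d)
        }
      } else {
        # register-diagonal pairs (i, j +/- 1)
        for (q in seq_len(nrow(grp))) {
          hi <- hpos(grp$resno_a[q])
          if (is.null(hi)) next
          for (j in grp$resno_b[q] + c(-1L, 1L)) {
            if (!j %in% rb) next
            hj <- hpos(j)
            if (is.null(hj)) next
            d <- .vnorm(hi - hj)
            if (d > 0.1 && d <= max_r) dists <- c(dists, d)
          }
        }
        # sequential intra-strand pairs
        for (span in list(ra, rb)) {
          for (i in span[-length(span)]) {
            if (!(i + 1L) %in% span) next
            hi <- hpos(i); hj <- hpos(i + 1L)
            if (is.null(hi) || is.null(hj)) next
            d <- .vnorm(hi - hj)
            if (d <= max_r) dists <- c(dists, d)
          }
        }
      }
    }
  }
  if (length(dists) < k)
    stop("too few amide-amide distances to form classes (isolated strand?)")
  cl <- .cluster1d(dists, k)
  new("SheetDistanceStats", topology = topology, classes = cl$centers,
      dispersion = cl$sds, n_distances = length(dists))
}

# deterministic 1-d k-means: initial centers at the quantile extremes
.cluster1d <- function(x, k) {
  init <- seq(min(x), max(x), length.out = k)
  if (length(unique(x)) <= k) {
    u <- sort(unique(x))
    centers <- u
    sds <- vapply(u, function(c0) {
      v <- x[x == c0]
      if (length(v) > 1L) sd(v) else 0
    }, numeric(1L))
    return(list(centers = centers, sds = sds))
  }
  km <- kmeans(x, centers = matrix(init, ncol = 1L))
  ord <- order(km$centers[, 1L])
  centers <- as.numeric(km$centers[ord, 1L])
  sds <- vapply(ord, function(o) {
    v <- x[km$cluster == o]
    if (length(v) > 1L) sd(v) else 0
  }, numeric(1L))
  list(centers = centers, sds = sds)
}

#' Calibrate the NOE proportionality constant
#'
#' Implements the strongest-peak anchor: \eqn{c = I_{max} r_{ref}^6}, where
#' \eqn{I_{max}} is the strongest normalized amide-amide intensity and
#' \eqn{r_{ref}} the shortest characteristic amide-proton distance class of
#' the beta-sheet statistics. Ties on intensity break by peak id.
#'
#' @param x a normalized \linkS4class{NOEPeakTable} containing amide-amide
#'   peaks.
#' @param stats a \linkS4class{SheetDistanceStats}, or a bare numeric
#'   reference distance in Angstrom.
#' @param pad bound padding recorded for provenance (Angstrom).
#' @return a \linkS4class{CalibrationResult}.
#' @export
calibrateConstant <- function(x, stats, pad = 0.5) {
  p <- peaks(x)
  p <- p[p$class == "amide-amide", , drop = FALSE]
  if (nrow(p) == 0L) stop("no amide-amide peaks to calibrate from")
  r_ref <- if (is.numeric(stats)) stats[1L] else min(distanceClasses(stats))
  ord <- order(-p$cross, p$peak_id)
  top <- p[ord[1L], , drop = FALSE]
  new("CalibrationResult", c = top$cross * r_ref^6,
      ref_peak = as.integer(top$peak_id), ref_distance = r_ref, pad = pad)
}

#' Upper distance bounds from normalized intensities
#'
#' Inverts \eqn{I = c\,r^{-6}} per peak and pads:
#' \eqn{b = \mathrm{clamp}((c/I)^{1/6} + pad,\ floor,\ cap)}. The transform
#' is antitone in intensity: a stronger peak never gets a larger bound.
#'
#' @param x a normalized \linkS4class{NOEPeakTable}.
#' @param calibration a \linkS4class{CalibrationResult} (or positive numeric
#'   c).
#' @param pad padding in Angstrom added to each bound (default: the
#'   calibration's pad).
#' @param floor,cap clamp limits in Angstrom.
#' @param classes restrict to these NOE classes (default: all).
#' @return a \linkS4class{RestraintList}.
#' @export
boundsFromIntensities <- function(x, calibration, pad = NULL, floor = 1.8,
                                  cap = 7.0, classes = .NOE_CLASSES) {
  cc <- if (is.numeric(calibration)) calibration[1L]
        else calibrationConstant(calibration)
  if (is.null(pad))
    pad <- if (is.numeric(calibration)) 0.5 else calibration@pad
  stopifnot(cc > 0)
  p <- peaks(x)
  p <- p[p$class %in% classes, , drop = FALSE]
  if (any(p$cross <= 0)) stop("non-positive intensity")
  upper <- pmin(cap, pmax(floor, (cc / p$cross)^(1 / 6) + pad))
  RestraintList(data.frame(group_a = p$group_a, group_b = p$group_b,
                           upper = upper, class = p$class))
}

#' Recalibrate methyl-class bounds from preliminary models
#'
#' For amide-methyl and methyl-methyl peaks, the bound is taken from the
#' spread of effective distances across a preliminary ensemble (models
#' computed under uniform loose bounds):
#' \eqn{b = \mathrm{mean}(r_{eff}) + k_{sd}\,\mathrm{sd}(r_{eff})}, clamped
#' to [floor, cap]. Effective distances use full r^-6 summation over group
#' protons.
#'
#' @param x an \linkS4class{NOEPeakTable}; only amide-methyl and
#'   methyl-methyl peaks are used.
#' @param preliminary an \linkS4class{Ensemble} with >= 3 models.
#' @param k_sd number of standard deviations added to the mean (default 1).
#' @param floor,cap clamp limits in Angstrom.
#' @return a \linkS4class{RestraintList}.
#' @export
recalibrateFromModels <- function(x, preliminary, k_sd = 1, floor = 1.8,
                                  cap = 7.0) {
  mods <- models(preliminary)
  if (length(mods) < 3L) stop("preliminary ensemble must have >= 3 models")
  p <- peaks(x)
  p <- p[p$class %in% c("amide-methyl", "methyl-methyl"), , drop = FALSE]
  if (nrow(p) == 0L) stop("no methyl-class peaks to recalibrate")
  rows <- list()
  for (i in seq_len(nrow(p))) {
    reff <- vapply(mods, effectiveDistance, numeric(1L),
                   spec_a = p$group_a[i], spec_b = p$group_b[i])
    b <- mean(reff) + k_sd * sd(reff)
    rows[[i]] <- data.frame(group_a = p$group_a[i], group_b = p$group_b[i],
                            upper = min(cap, max(floor, b)),
                            class = p$class[i])
  }
  RestraintList(do.call(rbind, rows))
}

#' Validate distance restraints against an ensemble
#'
#' Per restraint and model, computes the effective distance and the
#' violation \eqn{\max(0, r_{eff} - b)}; reports per-restraint maxima
#' (sorted descending) and per-model totals.
#'
#' @param ensemble an \linkS4class{Ensemble} (or single model).
#' @param rl a \linkS4class{RestraintList}.
#' @return list with \code{by_restraint} (group_a, group_b, upper, mean_r,
#'   max_violation), \code{by_model} (model, n_violated, sum_violation) and
#'   \code{unresolvable} (restraints whose groups could not be resolved).
#' @export
validateRestraints <- function(ensemble, rl) {
  if (is(ensemble, "StructureModel")) ensemble <- Ensemble(list(ensemble))
  mods <- models(ensemble)
  r <- restraints(rl)
  nr <- nrow(r)
  nm <- length(mods)
  viol <- matrix(NA_real_, nr, nm)
  reff <- matrix(NA_real_, nr, nm)
  bad <- logical(nr)
  for (i in seq_len(nr)) {
    for (m in seq_len(nm)) {
      d <- try(effectiveDistance(mods[[m]], r$group_a[i], r$group_b[i]),
               silent = TRUE)
      if (inherits(d, "try-error")) { bad[i] <- TRUE; break }
      reff[i, m] <- d
      viol[i, m] <- max(0, d - r$upper[i])
    }
  }
  ok <- which(!bad)
  by_restraint <- data.frame(
    group_a = r$group_a[ok], group_b = r$group_b[ok], upper = r$upper[ok],
    mean_r = rowMeans(reff[ok, , drop = FALSE]),
    max_violation = apply(viol[ok, , drop = FALSE], 1L, max))
  by_restraint <- by_restraint[order(-by_restraint$max_violation), ,
                               drop = FALSE]
  rownames(by_restraint) <- NULL
  by_model <- data.frame(
    model = seq_len(nm),
    n_violated = colSums(viol[ok, , drop = FALSE] > 1e-9),
    sum_violation = colSums(viol[ok, , drop = FALSE]))
  list(by_restraint = by_restraint, by_model = by_model,
       unresolvable = r[bad, , drop = FALSE])
}
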