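# Residue-numbering translation between schemes (e.g. zebrafish construct
# numbering to human isoform numbering). A map is a set of inclusive source
# segments, each with an additive offset; segments must not overlap after
# mapping so that the inverse map exists.

#' Build a residue-numbering map
#'
#' @param from_start,from_end integer vectors, inclusive source segment
#'   bounds.
#' @param offset integer vector of additive offsets per segment.
#' @param from,to labels of the source and target numbering schemes.
#' @return an object of class "numberingMap".
#' @examples
#' # zebrafish TAD 571-623 corresponds to human 696-748
#' m <- numberingMap(571, 623, +125, from = "zebrafish", to = "human")
#' @export
numberingMap <- function(from_start, from_end, offset,
                         from = "source", to = "target") {
  stopifnot(length(from_start) == length(from_end),
            length(offset) == length(from_start),
            all(from_end >= from_start))
  seg <- data.frame(from_start = as.integer(from_start),
                    from_end = as.integer(from_end),
                    offset = as.integer(offset))
  seg <- seg[order(seg$from_start), , drop = FALSE]
  if (nrow(seg) > 1L) {
    if (any(seg$from_start[-1L] <= seg$from_end[-nrow(seg)]))
      stop("source segments overlap")
    ts <- seg$from_start + seg$offset
    te <- seg$from_end + seg$offset
    o <- order(ts)
    if (any(ts[o][-1L] <= te[o][-nrow(seg)]))
      stop("segments overlap after mapping")
  }
  structure(list(segments = seg, from = from, to = to),
            class = "numberingMap")
}

#' Invert a numbering map
#'
#' @param map a \code{\link{numberingMap}}.
#' @return the inverse map; composing the two is the identity.
#' @export
invertNumberingMap <- function(map) {
  s <- map$segments
  numberingMap(s$from_start + s$offset, s$from_end + s$offset, -s$offset,
               from = map$to, to = map$from)
}

.mapResno <- function(resno, map) {
  s <- map$segments
  out <- rep(NA_integer_, length(resno))
  for (i in seq_len(nrow(s))) {
    hit <- resno >= s$from_start[i] & resno <= s$from_end[i]
    out[hit] <- resno[hit] + s$offset[i]
  }
  if (anyNA(out))
    stop(sprintf("residue(s) outside all map segments: %s",
                 paste(unique(resno[is.na(out)]), collapse = ", ")))
  out
}

.mapSpec <- function(spec, map) {
  g <- parseGroupSpec(spec)
  newres <- .mapResno(g$resno, map)
  atom <- ifelse(g$atom == "H", "HN", g$atom)
  paste(sprintf("%d.%s", newres, atom), collapse = "|")
}

#' @describeIn mapNumbering renumber a chemical-shift table
#' @export
setMethod("mapNumbering", "ChemicalShiftTable", function(x, map, ...) {
  e <- shiftEntries(x)
  e$resno <- .mapResno(e$resno, map)
  ChemicalShiftTable(e, scheme = map$to)
})

#' @describeIn mapNumbering renumber a restraint list
#' @export
setMethod("mapNumbering", "RestraintList", function(x, map, ...) {
  r <- restraints(x)
  r$group_a <- vapply(r$group_a, .mapSpec, character(1L), map = map)
  r$group_b <- vapply(r$group_b, .mapSpec, character(1L), map = map)
  RestraintList(r, allow_loose = x@allow_loose)
})

#' @describeIn mapNumbering renumber an RDC table
#' @export
setMethod("mapNumbering", "RDCTable", function(x, map, ...) {
  r <- rdcRecords(x)
  r$resno <- .mapResno(r$resno, map)
  RDCTable(r)
})

#' @describeIn mapNumbering renumber an NOE peak table
#' @export
setMethod("mapNumbering", "NOEPeakTable", function(x, map, ...) {
  p <- peaks(x)
  p$group_a <- vapply(p$group_a, .mapSpec, character(1L), map = map)
  p$group_b <- vapply(p$group_b, .mapSpec, character(1L), map = map)
  NOEPeakTable(p, normalized = x@normalized, truth = x@truth)
})

#' @describeIn mapNumbering renumber a structure model
#' @export
setMethod("mapNumbering", "StructureModel", function(x, map, ...) {
  at <- atoms(x)
  at$resno <- .mapResno(at$resno, map)
  StructureModel(at, model_id = modelID(x), linker = x@linker)
})
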