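# Tabular I/O: distance restraints (TSV dialect and CYANA-style .upl upper
# limit lines, with autodetection), NOE peak tables and RDC tables. All TSV
# dialects carry a documented header line; reads and writes round-trip.

.CYANA_PSEUDO <- c(QB = "CB", QG1 = "CG1", QG2 = "CG2", QD1 = "CD1",
                   QD2 = "CD2", QE = "CE")

.upToSpec <- function(resno, atom) {
  atom <- toupper(atom)
  if (atom %in% c("H", "HN")) return(sprintf("%d.HN", resno))
  if (atom == "QQD") return(sprintf("%d.CD1|%d.CD2", resno, resno))
  if (atom == "QQG") return(sprintf("%d.CG1|%d.CG2", resno, resno))
  if (atom %in% names(.CYANA_PSEUDO))
    return(sprintf("%d.%s", resno, .CYANA_PSEUDO[[atom]]))
  if (substr(atom, 1L, 1L) == "C") return(sprintf("%d.%s", resno, atom))
  stop(sprintf("unsupported CYANA atom name '%s'", atom))
}

.specToUpl <- function(spec) {
  g <- parseGroupSpec(spec)
  if (nrow(g) == 2L) {
    stems <- sub("[12]$", "", g$atom)
    if (length(unique(g$resno)) == 1L && length(unique(stems)) == 1L) {
      nm <- switch(stems[1L], CD = "QQD", CG = "QQG",
                   stop(sprintf("cannot write union '%s' as a CYANA pseudoatom", spec)))
      return(list(resno = g$resno[1L], atom = nm))
    }
    stop(sprintf("cannot write union '%s' as a CYANA pseudoatom", spec))
  }
  if (g$kind[1L] == "amide") return(list(resno = g$resno[1L], atom = "HN"))
  rev <- names(.CYANA_PSEUDO)[match(g$atom[1L], .CYANA_PSEUDO)]
  list(resno = g$resno[1L], atom = if (is.na(rev)) g$atom[1L] else rev)
}

#' Read a distance-restraint list
#'
#' Supports a TSV dialect (header columns \code{group_a}, \code{group_b},
#' \code{upper_A}, \code{class}) and CYANA-style .upl upper-limit lines
#' (\code{resno resname atom resno resname atom upper}); the dialect is
#' autodetected unless given.
#'
#' @param path input file.
#' @param dialect "auto", "tsv" or "cyana-upl".
#' @param allow_loose permit upper bounds above the 7.0 A cap.
#' @return a \linkS4class{RestraintList}.
#' @export
readRestraints <- function(path, dialect = c("auto", "tsv", "cyana-upl"),
                           allow_loose = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  content <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(content) == 0L)
    return(RestraintList(data.frame(group_a = character(),
                                    group_b = character(),
                                    upper = numeric(), class = character()),
                         allow_loose = allow_loose))
  if (dialect == "auto")
    dialect <- if (grepl("group_a", content[1L])) "tsv" else "cyana-upl"
  if (dialect == "tsv") {
    df <- read.table(text = content, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    need <- c("group_a", "group_b", "upper_A")
    if (!all(need %in% names(df)))
      stop("TSV restraint file must have columns group_a, group_b, upper_A")
    out <- data.frame(group_a = df$group_a, group_b = df$group_b,
                      upper = as.numeric(df$upper_A))
    if ("class" %in% names(df)) out$class <- df$class
  } else {
    rows <- lapply(seq_along(content), function(i) {
      tok <- strsplit(trimws(content[i]), "\\s+")[[1L]]
      if (length(tok) < 7L)
        stop(sprintf("unparseable .upl line %d: '%s'", i, content[i]))
      data.frame(group_a = .upToSpec(as.integer(tok[1L]), tok[3L]),
                 group_b = .upToSpec(as.integer(tok[4L]), tok[6L]),
                 upper = as.numeric(tok[7L]))
    })
    out <- do.call(rbind, rows)
  }
  if (any(out$upper < 1.8))
    stop("restraint bound(s) below the 1.8 A floor")
  if (!allow_loose && any(out$upper > 7.0))
    stop("restraint bound(s) above the 7.0 A cap (use allow_loose)")
  RestraintList(out, allow_loose = allow_loose)
}

#' Write a distance-restraint list
#'
#' @param x a \linkS4class{RestraintList}.
#' @param path output file.
#' @param dialect "tsv" or "cyana-upl".
#' @param resnames optional named vector mapping residue numbers to 3-letter
#'   codes for .upl output (UNK when missing).
#' @param header optional character vector of provenance lines written as
#'   leading comments.
#' @return invisibly, the path.
#' @export
writeRestraints <- function(x, path, dialect = c("tsv", "cyana-upl"),
                            resnames = NULL, header = NULL) {
  dialect <- match.arg(dialect)
  r <- restraints(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  if (dialect == "tsv") {
    writeLines("group_a\tgroup_b\tupper_A\tclass", con)
    if (nrow(r))
      writeLines(sprintf("%s\t%s\t%.3f\t%s", r$group_a, r$group_b, r$upper,
                         r$class), con)
  } else {
    rn <- function(resno) {
      if (!is.null(resnames) && as.character(resno) %in% names(resnames))
        resnames[[as.character(resno)]] else "UNK"
    }
    for (i in seq_len(nrow(r))) {
      a <- .specToUpl(r$group_a[i])
      b <- .specToUpl(r$group_b[i])
      writeLines(sprintf("%4d %-4s %-5s %4d %-4s %-5s %6.2f",
                         a$resno, rn(a$resno), a$atom,
                         b$resno, rn(b$resno), b$atom, r$upper[i]), con)
    }
  }
  invisible(path)
}

#' Read an NOE peak table (TSV)
#'
#' Header columns: \code{peak_id}, \code{group_a}, \code{group_b},
#' \code{cross}, \code{diag_a}, \code{diag_b}, \code{class}. Absent
#' diagonals are NA.
#'
#' @param path input file.
#' @return an \linkS4class{NOEPeakTable}.
#' @export
readNOEPeaks <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("NA", "."))
  NOEPeakTable(df)
}

#' Write an NOE peak table (TSV)
#'
#' @param x an \linkS4class{NOEPeakTable}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeNOEPeaks <- function(x, path) {
  p <- peaks(x)
  write.table(p[c("peak_id", "group_a", "group_b", "cross", "diag_a",
                  "diag_b", "class")],
              path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read an RDC table (TSV)
#'
#' Header columns: \code{resno}, \code{type} (NH or NC), \code{D_Hz},
#' optional \code{sigma_Hz}.
#'
#' @param path input file.
#' @return an \linkS4class{RDCTable}.
#' @export
readRDCTable <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("NA", "."))
  need <- c("resno", "type", "D_Hz")
  if (!all(need %in% names(df)))
    stop("RDC TSV must have columns resno, type, D_Hz")
  RDCTable(data.frame(resno = df$resno, type = df$type, D = df$D_Hz,
                      sigma = if ("sigma_Hz" %in% names(df)) df$sigma_Hz
                              else NA_real_))
}

#' Write an RDC table (TSV)
#'
#' @param x an \linkS4class{RDCTable}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeRDCTable <- function(x, path) {
  r <- rdcRecords(x)
  out <- data.frame(resno = r$resno, type = r$type, D_Hz = r$D,
                    sigma_Hz = r$sigma)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Write a chemical-shift table (TSV)
#'
#' @param x a \linkS4class{ChemicalShiftTable}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeShiftTSV <- function(x, path) {
  e <- shiftEntries(x)
  write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a chemical-shift table (TSV)
#'
#' @param path input file with header columns resno, resname, atom, shift,
#'   ambiguity.
#' @param scheme numbering-scheme label.
#' @return a \linkS4class{ChemicalShiftTable}.
#' @export
readShiftTSV <- function(path, scheme = "unspecified") {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  ChemicalShiftTable(df, scheme = scheme)
}
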