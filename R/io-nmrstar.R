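# Minimal NMR-STAR v3 reader for assigned chemical-shift loops. Only the
# _Atom_chem_shift loop is consumed; tags are matched by name so column
# order in the file is free. Values 'missing' per STAR convention (".", "?")
# become NA and are dropped.

#' Read assigned chemical shifts from an NMR-STAR v3 file
#'
#' Parses the \code{_Atom_chem_shift} loop of an NMR-STAR v3.x file (the
#' format used by the BMRB). Residue numbering is taken verbatim from
#' \code{Comp_index_ID} (falling back to \code{Seq_ID}).
#'
#' @param path path to an NMR-STAR file.
#' @param scheme numbering-scheme label to record on the table.
#' @return a \linkS4class{ChemicalShiftTable}.
#' @export
readNmrStarShifts <- function(path, scheme = "unspecified") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  i <- 1L
  n <- length(lines)
  found <- NULL
  while (i <= n) {
    if (grepl("^\\s*loop_\\s*$", lines[i])) {
      j <- i + 1L
      tags <- character()
      while (j <= n && grepl("^\\s*_", lines[j])) {
        tags <- c(tags, trimws(lines[j]))
        j <- j + 1L
      }
      if (length(tags) && all(startsWith(tags, "_Atom_chem_shift."))) {
        vals <- character()
        while (j <= n && !grepl("^\\s*(stop_|loop_)\\s*$", lines[j])) {
          vals <- c(vals, .starTokens(lines[j]))
          j <- j + 1L
        }
        found <- list(tags = sub("^_Atom_chem_shift\\.", "", tags),
                      vals = vals)
        break
      }
      i <- j
    } else i <- i + 1L
  }
  if (is.null(found))
    stop("no _Atom_chem_shift loop found in NMR-STAR file")
  k <- length(found$tags)
  if (length(found$vals) %% k != 0L)
    stop("malformed _Atom_chem_shift loop: value count not a multiple of tag count")
  m <- matrix(found$vals, ncol = k, byrow = TRUE)
  colnames(m) <- found$tags
  col <- function(...) {
    for (nm in c(...)) if (nm %in% colnames(m)) return(m[, nm])
    NULL
  }
  resno <- col("Comp_index_ID", "Seq_ID")
  resname <- col("Comp_ID")
  atom <- col("Atom_ID")
  val <- col("Val")
  amb <- col("Ambiguity_code")
  if (is.null(resno) || is.null(atom) || is.null(val))
    stop("_Atom_chem_shift loop lacks Comp_index_ID/Atom_ID/Val tags")
  miss <- val %in% c(".", "?")
  e <- data.frame(resno = as.integer(resno),
                  resname = if (is.null(resname)) NA_character_ else resname,
                  atom = atom,
                  shift = suppressWarnings(as.numeric(val)),
                  ambiguity = if (is.null(amb)) 1L
                              else suppressWarnings(as.integer(amb)))
  e <- e[!miss & !is.na(e$shift), , drop = FALSE]
  e$ambiguity[is.na(e$ambiguity)] <- 1L
  key <- paste(e$resno, e$atom)
  if (anyDuplicated(key))
    stop(paste("duplicate (residue, atom) assignments:",
               paste(unique(key[duplicated(key)]), collapse = "; ")))
  ChemicalShiftTable(e, scheme = scheme)
}

.starTokens <- function(line) {
  line <- trimws(line)
  if (!nzchar(line)) return(character())
  out <- character()
  while (nzchar(line)) {
    if (substr(line, 1L, 1L) %in% c("'", '"')) {
      q <- substr(line, 1L, 1L)
      rest <- substring(line, 2L)
      pos <- regexpr(q, rest, fixed = TRUE)
      if (pos < 0L) stop("unterminated quoted STAR value")
      out <- c(out, substr(rest, 1L, pos - 1L))
      line <- trimws(substring(rest, pos + 1L))
    } else {
      pos <- regexpr("\\s", line)
      if (pos < 0L) {
        out <- c(out, line)
        line <- ""
      } else {
        out <- c(out, substr(line, 1L, pos - 1L))
        line <- trimws(substring(line, pos + 1L))
      }
    }
  }
  out
}

#' Write a ChemicalShiftTable as a minimal NMR-STAR v3 shift loop
#'
#' @param table a \linkS4class{ChemicalShiftTable}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeNmrStarShifts <- function(table, path) {
  e <- shiftEntries(table)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("data_shifts", "", "save_assigned_chemical_shifts",
               "   loop_",
               "      _Atom_chem_shift.ID",
               "      _Atom_chem_shift.Comp_index_ID",
               "      _Atom_chem_shift.Comp_ID",
               "      _Atom_chem_shift.Atom_ID",
               "      _Atom_chem_shift.Val",
               "      _Atom_chem_shift.Ambiguity_code"), con)
  if (nrow(e))
    writeLines(sprintf("      %d %d %s %s %.2f %d", seq_len(nrow(e)),
                       e$resno, e$resname, e$atom, e$shift, e$ambiguity), con)
  writeLines(c("   stop_", "save_"), con)
  invisible(path)
}
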