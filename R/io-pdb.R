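# PDB multi-MODEL I/O. Reading is delegated to bio3d's parser; writing uses
# a fixed-width v3 ATOM record formatter so that write -> read round-trips
# coordinates at the format's native 3 decimals.

#' Read a (possibly multi-MODEL) PDB file
#'
#' @param path path to a PDB-format file.
#' @param validate logical, check backbone completeness (N, CA, C per
#'   residue) and strictly increasing residue numbering.
#' @return list of \linkS4class{StructureModel}, one per MODEL record
#'   (length 1 for single-model files).
#' @examples
#' mod <- makeIdealBackbone("AGAGA", "CCCCC")
#' f <- tempfile(fileext = ".pdb")
#' writePDBModels(list(mod), f)
#' length(readPDBModels(f))
#' @export
readPDBModels <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  .scanPDBLines(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- pdb$atom
  keep <- a$type == "ATOM"
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0L) stop(sprintf("no ATOM records in %s", path))
  chain <- ifelse(is.na(a$chain) | a$chain == "", "A", a$chain)
  element <- a$elesy
  element[is.na(element) | element == ""] <-
    substr(gsub("[^A-Za-z].*", "", a$elety[is.na(element) | element == ""]), 1L, 1L)
  nmodel <- max(1L, nrow(pdb$xyz))
  idx <- which(keep)
  out <- vector("list", nmodel)
  for (m in seq_len(nmodel)) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE)[idx, , drop = FALSE]
    at <- data.frame(chain = chain, resno = as.integer(a$resno),
                     resname = a$resid, atom = a$elety, element = element,
                     x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L])
    out[[m]] <- if (validate) StructureModel(at, model_id = m)
                else new("StructureModel", model_id = m, atoms = at,
                         linker = logical())
  }
  out
}

# Pre-scan for unparseable ATOM/HETATM coordinate fields so that malformed
# files fail with a line number rather than inside the parser.
.scanPDBLines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop(sprintf("unparseable ATOM record at line %d: too short", i))
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop(sprintf("unparseable coordinates at line %d", i))
  }
  invisible(TRUE)
}

.formatAtomName <- function(name, element) {
  # PDB v3: single-letter elements start in column 14
  if (nchar(name) >= 4L) return(substr(name, 1L, 4L))
  if (nchar(element) == 1L) sprintf(" %-3s", name) else sprintf("%-4s", name)
}

#' Write models as a multi-MODEL PDB file
#'
#' @param mods list of \linkS4class{StructureModel} (or a single model, or an
#'   \linkS4class{Ensemble}).
#' @param path output path.
#' @return invisibly, the path.
#' @export
writePDBModels <- function(mods, path) {
  if (is(mods, "Ensemble")) mods <- models(mods)
  if (is(mods, "StructureModel")) mods <- list(mods)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(mods) > 1L
  for (m in seq_along(mods)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    at <- atoms(mods[[m]])
    serial <- seq_len(nrow(at))
    lines <- sprintf(
      "ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial,
      vapply(seq_len(nrow(at)),
             function(i) .formatAtomName(at$atom[i], at$element[i]),
             character(1L)),
      at$resname, at$chain, at$resno, at$x, at$y, at$z, 1, 0,
      toupper(at$element))
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
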