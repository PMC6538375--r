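# Shared fixtures. Sheet construction involves a rigid-body fit, so the
# standard sheets are built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

sheetFixture <- function(topology = "antiparallel", n_strands = 2L,
                         strand_len = 6L) {
  key <- paste(topology, n_strands, strand_len, sep = "_")
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- makeSheet(n_strands, strand_len, topology)
  .fixtures[[key]]
}

# a tiny hand-built model: two alanine methyls with CB carbons exactly
# `sep` apart along x, each with idealized tetrahedral protons; backbone
# atoms present to satisfy validity
twoMethylModel <- function(sep = 5) {
  mod <- makeIdealBackbone("AA", "CC")
  at <- atoms(mod)
  # move residue 2 so its CB sits exactly `sep` from residue 1's CB
  cb1 <- as.numeric(at[at$resno == 1 & at$atom == "CB", c("x", "y", "z")])
  cb2 <- as.numeric(at[at$resno == 2 & at$atom == "CB", c("x", "y", "z")])
  shift <- (cb1 + c(sep, 0, 0)) - cb2
  sel <- at$resno == 2
  at$x[sel] <- at$x[sel] + shift[1]
  at$y[sel] <- at$y[sel] + shift[2]
  at$z[sel] <- at$z[sel] + shift[3]
  StructureModel(at)
}

# brute-force r^-6 effective distance oracle over explicit coordinates
bruteReff <- function(pa, pb) {
  s <- 0
  for (i in seq_len(nrow(pa)))
    for (j in seq_len(nrow(pb)))
      s <- s + sum((pa[i, ] - pb[j, ])^2)^(-3)
  s^(-1 / 6)
}

# random unit vectors (fixed seed handled by caller)
randomUnitVectors <- function(n) {
  m <- matrix(rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

methylProtonCoords <- function(model, resno, carbon) {
  at <- atoms(model)
  hn <- paste0(sub("^C", "H", carbon), 1:3)
  as.matrix(at[at$resno == resno & at$atom %in% hn, c("x", "y", "z")])
}
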