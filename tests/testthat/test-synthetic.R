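# Generators: ideal backbone geometry, sheets with hydrogen-bond registry,
# and the NOE/RDC/shift/ensemble simulators with known ground truth.

coords <- function(model, resno, atom) {
  at <- atoms(model)
  as.numeric(at[at$resno == resno & at$atom == atom, c("x", "y", "z")])
}
dist3 <- function(p, q) sqrt(sum((p - q)^2))

test_that("ideal helix geometry places i -> i+4 hydrogen bonds", {
  h <- makeIdealBackbone(strrep("A", 10), strrep("H", 10))
  for (i in 1:6)
    expect_lt(dist3(coords(h, i, "O"), coords(h, i + 4, "H")), 2.5)
})

test_that("ideal strand has trans-peptide CA-CA spacing of 3.8 A", {
  e <- makeIdealBackbone(strrep("V", 6), strrep("E", 6))
  for (i in 1:5)
    expect_equal(dist3(coords(e, i, "CA"), coords(e, i + 1, "CA")), 3.8,
                 tolerance = 0.1 / 3.8)
})

test_that("backbone generator rejects bad input", {
  expect_error(makeIdealBackbone("AAA", ""), "empty|length")
  expect_error(makeIdealBackbone("AAA", "HXH"), "unknown secondary")
  expect_error(makeIdealBackbone("AZB", "HHH"), "unknown residue")
  expect_error(makeIdealBackbone("AAAA", "HH"), "length")
})

test_that("generated residues are L-amino acids with correct dihedrals", {
  m <- makeIdealBackbone("VVVVV", "EEEEE")
  at <- atoms(m)
  g <- function(r, a) as.numeric(at[at$resno == r & at$atom == a,
                                    c("x", "y", "z")])
  # improper N-C-CA-CB near -122.6 for every residue
  for (r in 2:4) {
    b1 <- g(r, "C") - g(r, "N"); b2 <- g(r, "CA") - g(r, "C")
    # compute via kabschSuperpose-free dihedral through atan2
    p1 <- g(r, "N"); p2 <- g(r, "C"); p3 <- g(r, "CA"); p4 <- g(r, "CB")
    u1 <- p2 - p1; u2 <- p3 - p2; u3 <- p4 - p3
    n1 <- c(u1[2]*u2[3]-u1[3]*u2[2], u1[3]*u2[1]-u1[1]*u2[3],
            u1[1]*u2[2]-u1[2]*u2[1])
    n2 <- c(u2[2]*u3[3]-u2[3]*u3[2], u2[3]*u3[1]-u2[1]*u3[3],
            u2[1]*u3[2]-u2[2]*u3[1])
    m1 <- c(n1[2]*u2[3]-n1[3]*u2[2], n1[3]*u2[1]-n1[1]*u2[3],
            n1[1]*u2[2]-n1[2]*u2[1]) / sqrt(sum(u2^2))
    ang <- atan2(sum(m1*n2), sum(n1*n2)) * 180 / pi
    expect_equal(ang, -122.6, tolerance = 0.01)
  }
})

test_that("antiparallel sheets have cross-strand N-H...O=C pairs at every other residue", {
  sh <- sheetFixture("antiparallel")
  model <- sh$model
  pr <- sh$pairing
  narrow <- pr[pr$hbonded, ]
  expect_gte(nrow(narrow), 3L)
  for (k in seq_len(nrow(narrow))) {
    dHO1 <- dist3(coords(model, narrow$resno_a[k], "H"),
                  coords(model, narrow$resno_b[k], "O"))
    dHO2 <- dist3(coords(model, narrow$resno_b[k], "H"),
                  coords(model, narrow$resno_a[k], "O"))
    expect_lt(dHO1, 2.3)
    expect_lt(dHO2, 2.3)
  }
  # alternating pattern
  expect_equal(narrow$resno_a, seq(min(pr$resno_a), max(pr$resno_a), by = 2))
})

test_that("parallel sheets pair with constant register offset", {
  sh <- sheetFixture("parallel")
  pr <- sh$pairing
  expect_equal(length(unique(pr$resno_b - pr$resno_a)), 1L)
})

test_that("middle strand of a 3-strand sheet has partners on both sides", {
  sh <- sheetFixture("antiparallel", n_strands = 3L, strand_len = 5L)
  pr <- sh$pairing
  expect_setequal(unique(paste(pr$strand_a, pr$strand_b)), c("1 2", "2 3"))
  # strand 2 residues appear in both pairings
  mid <- sh$strands$start[2]:sh$strands$end[2]
  expect_true(any(pr$resno_b %in% mid & pr$strand_b == 2))
  expect_true(any(pr$resno_a %in% mid & pr$strand_a == 2))
})

test_that("sheet generator rejects degenerate sizes", {
  expect_error(makeSheet(1, 6), "n_strands")
  expect_error(makeSheet(2, 2), "strand_len")
})

test_that("noiseless NOE intensities obey I = c r^-6 exactly", {
  m <- twoMethylModel(5)
  # use the two amide protons as a two-spin system at known distance
  at <- atoms(m)
  rHH <- dist3(coords(m, 1, "H"), coords(m, 2, "H"))
  pk <- simulateNOEPeaks(m, c = 729, max_r = 20, noise_cv = 0, seed = 1,
                         groups = c("1.HN", "2.HN"))
  expect_equal(peaks(pk)$cross, 729 * rHH^(-6), tolerance = 1e-12)
  # halving the distance multiplies intensity by 64: check the scaling law
  # directly on truth-annotated peaks
  expect_equal(peakTruth(pk)$r_true, rHH, tolerance = 1e-12)
})

test_that("NOE simulation is deterministic in the seed", {
  sh <- sheetFixture("antiparallel")
  a <- simulateNOEPeaks(sh$model, noise_cv = 0.2, seed = 42)
  b <- simulateNOEPeaks(sh$model, noise_cv = 0.2, seed = 42)
  expect_identical(peaks(a), peaks(b))
  c_ <- simulateNOEPeaks(sh$model, noise_cv = 0.2, seed = 43)
  expect_false(identical(peaks(a)$cross, peaks(c_)$cross))
})

test_that("RDC forward model honors the tensor principal values", {
  # bond vector along z with R = 0 gives 2 Da; in the xy-plane gives -Da
  A <- saupeMatrix(AlignmentTensor(10, 0))
  z <- c(0, 0, 1)
  expect_equal(as.numeric(z %*% A %*% z), 20, tolerance = 1e-9)
  x <- c(1, 0, 0)
  expect_equal(as.numeric(x %*% A %*% x), -10, tolerance = 1e-9)
  # isotropic average over many orientations vanishes
  set.seed(99)
  u <- randomUnitVectors(20000)
  D <- rowSums((u %*% A) * u)
  expect_lt(abs(mean(D)), 0.3)
})

test_that("simulated RDC tables are reproducible and typed", {
  sh <- sheetFixture("antiparallel")
  ten <- AlignmentTensor(8, 0.2, c(10, 30, 50))
  a <- simulateRDCs(sh$model, ten, types = c("NH", "NC"), noise_sd = 1,
                    seed = 5)
  b <- simulateRDCs(sh$model, ten, types = c("NH", "NC"), noise_sd = 1,
                    seed = 5)
  expect_identical(rdcRecords(a), rdcRecords(b))
  expect_setequal(unique(rdcRecords(a)$type), c("NH", "NC"))
})

test_that("coil shifts reproduce the random-coil table exactly at zero noise", {
  st <- simulateShifts("AVLI", "CCCC", noise_sd = 0, seed = 1)
  d <- secondaryShifts(st)
  expect_true(all(abs(d$delta) < 1e-12))
})

test_that("helix and strand secondary shifts differ in CA sign everywhere", {
  h <- secondaryShifts(simulateShifts(strrep("A", 8), strrep("H", 8), 0, 1))
  e <- secondaryShifts(simulateShifts(strrep("A", 8), strrep("E", 8), 0, 1))
  expect_true(all(h$delta[h$atom == "CA"] > 0))
  expect_true(all(e$delta[e$atom == "CA"] < 0))
  expect_error(simulateShifts("AXB", "CCC"), "unknown residue")
})

test_that("perturbEnsemble: zero core sd leaves core RMSD at zero", {
  base <- makeIdealBackbone("AVLIAV", "CCCCCC")
  ens <- perturbEnsemble(base, 3, core_sd = 0, tail_sd = 1,
                         core_residues = 2:4, seed = 3)
  r <- ensembleRMSD(ens, selection = "core_heavy", core_residues = 2:4)
  expect_lt(r$mean_rmsd, 1e-9)
  expect_error(perturbEnsemble(base, 1, 0.1), "n_models")
  expect_error(perturbEnsemble(base, 3, 1, 0.5), "core_sd")
})

test_that("pairwise displacement follows the sqrt(2) * sd Gaussian form", {
  base <- sheetFixture("antiparallel", 3L, 6L)$model
  s <- 0.4
  ens <- perturbEnsemble(base, 6, core_sd = s, seed = 21)
  r <- ensembleRMSD(ens, selection = "all")
  expect_equal(r$mean_rmsd, sqrt(2) * s, tolerance = 0.08)
  # determinism
  ens2 <- perturbEnsemble(base, 6, core_sd = s, seed = 21)
  expect_identical(atoms(models(ens)[[3]]), atoms(models(ens2)[[3]]))
})
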