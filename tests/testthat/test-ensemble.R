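# Superposition, convergence statistics, the model-selection funnel,
# secondary-structure assignment and sheet topology.

test_that("Kabsch superposition handles identity, translation and a known rotation", {
  m <- makeIdealBackbone("AVLI", "CCCC")
  k <- kabschSuperpose(m, m)
  expect_lt(k$rmsd, 1e-12)
  expect_equal(k$rotation, diag(3), tolerance = 1e-9)
  # translated copy
  at <- atoms(m)
  at$x <- at$x + 12.3; at$y <- at$y - 4.5
  k2 <- kabschSuperpose(StructureModel(at), m)
  expect_lt(k2$rmsd, 1e-12)
  # known 90-degree rotation about z on an asymmetric 4-atom set
  R90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  at3 <- atoms(m)
  xyz <- as.matrix(at3[c("x", "y", "z")]) %*% t(R90)
  at3$x <- xyz[, 1]; at3$y <- xyz[, 2]; at3$z <- xyz[, 3]
  k3 <- kabschSuperpose(StructureModel(at3), m)
  expect_lt(k3$rmsd, 1e-9)
  expect_equal(k3$rotation %*% t(R90), diag(3), tolerance = 1e-9)
  expect_equal(det(k3$rotation), 1, tolerance = 1e-9)
})

test_that("Kabsch rejects degenerate selections and matches bio3d", {
  # collinear points
  at <- data.frame(chain = "A", resno = 1:3, resname = "GLY",
                   atom = rep(c("N", "CA", "C"), 1),
                   element = "X", x = 0, y = 0, z = 0)
  expect_error(nmrkit:::.kabschCore(matrix(1:9, 3, 3) * 0,
                                    matrix(1:9, 3, 3) * 0), "degenerate")
  # independent cross-check against bio3d's least-squares fit
  set.seed(8)
  a <- matrix(rnorm(30), ncol = 3)
  R <- nmrkit:::.axisRotation(c(1, 2, 3), 61)
  b <- a %*% t(R) + matrix(rep(c(3, -1, 2), each = 10), ncol = 3)
  k <- nmrkit:::.kabschCore(b, a)
  bb <- bio3d::rmsd(as.numeric(t(a)), as.numeric(t(b)), fit = TRUE)
  expect_equal(k$rmsd, bb, tolerance = 1e-4)
})

test_that("ensemble RMSD: zero for duplicates, symmetric matrix, rigid-motion invariant", {
  base <- sheetFixture("antiparallel")$model
  ens <- Ensemble(list(base, base, base), core_residues = atoms(base)$resno)
  r <- ensembleRMSD(ens, "all")
  expect_equal(r$mean_rmsd, 0, tolerance = 1e-12)
  ens2 <- perturbEnsemble(base, 4, 0.4, seed = 2)
  r2 <- ensembleRMSD(ens2, "all")
  expect_equal(r2$matrix, t(r2$matrix))
  expect_true(all(diag(r2$matrix) == 0))
  # rigid-body transform of one model leaves all statistics unchanged
  mods <- models(ens2)
  at <- atoms(mods[[2]])
  R <- nmrkit:::.axisRotation(c(0.3, -1, 0.5), 133)
  xyz <- as.matrix(at[c("x", "y", "z")]) %*% t(R)
  at$x <- xyz[, 1] + 5; at$y <- xyz[, 2] - 8; at$z <- xyz[, 3] + 1
  mods[[2]] <- StructureModel(at, model_id = 2L)
  r3 <- ensembleRMSD(Ensemble(mods, core_residues = coreResidues(ens2)),
                     "all")
  expect_equal(r3$matrix, r2$matrix, tolerance = 1e-6)
  # both convergence modes exist and broadly agree for tight ensembles
  rt <- ensembleRMSD(ens2, "all", mode = "to-mean")
  expect_lt(abs(rt$mean_rmsd - r2$mean_rmsd / sqrt(2)), 0.2)
})

test_that("selection funnel keeps the planted good models", {
  base <- sheetFixture("antiparallel")$model
  truth <- AlignmentTensor(10, 0.2, c(15, 35, 55))
  rd <- simulateRDCs(base, truth, noise_sd = 0.2, seed = 30)
  for (seed in 1:3) {
    good <- models(perturbEnsemble(base, 10, 0.02, seed = seed))
    bad <- models(perturbEnsemble(base, 30, 2.0, seed = 100 + seed))
    pool <- c(good, bad)
    energies <- c(rnorm(10, 10, 1), rnorm(30, 50, 5))
    set.seed(seed)
    perm <- sample(40)
    ens <- Ensemble(pool[perm], energies = energies[perm],
                    core_residues = unique(atoms(base)$resno))
    sel <- selectModels(ens, rd, n_energy = 15, n_final = 10)
    expect_length(models(sel), 10L)
    expect_setequal(attr(sel, "selection"), which(perm <= 10))
  }
})

test_that("selection funnel agrees with plain energy ranking when orders agree", {
  base <- makeIdealBackbone("AVLIAVLI", "CCCCCCCC")
  ens <- perturbEnsemble(base, 12, 0.3, seed = 4)
  # energies increasing with model index; no RDCs: convergence plus energy
  en <- seq_len(12)
  ens2 <- Ensemble(models(ens), energies = en,
                   core_residues = coreResidues(ens))
  sel <- selectModels(ens2, NULL, n_energy = 6, n_final = 6)
  expect_setequal(attr(sel, "selection"), 1:6)
  expect_error(selectModels(ens2, NULL, n_final = 40), "smaller")
})

test_that("secondary-structure assignment matches ideal-geometry oracles", {
  h <- makeIdealBackbone(strrep("A", 14), strrep("H", 14))
  ssh <- assignSecondaryStructure(h)
  expect_true(all(ssh[3:12] == "H"))
  sh <- sheetFixture("antiparallel")
  sse <- assignSecondaryStructure(sh$model)
  pr <- sh$pairing
  interior <- c(2:5, 14:17)
  expect_true(all(sse[as.character(interior)] == "E"))
  # a lone extended strand has no bridge partner, hence coil
  lone <- makeIdealBackbone(strrep("V", 8), strrep("E", 8))
  expect_true(all(assignSecondaryStructure(lone) == "C"))
})

test_that("secondary-structure assignment is invariant to rigid motion", {
  sh <- sheetFixture("antiparallel")
  at <- atoms(sh$model)
  R <- nmrkit:::.axisRotation(c(1, 1, 1), 77)
  xyz <- as.matrix(at[c("x", "y", "z")]) %*% t(R)
  at$x <- xyz[, 1] + 3; at$y <- xyz[, 2] + 4; at$z <- xyz[, 3] - 9
  expect_identical(assignSecondaryStructure(StructureModel(at)),
                   assignSecondaryStructure(sh$model))
})

test_that("sheet topology reports strands and pairings in construction order", {
  sh5 <- sheetFixture("antiparallel", 5L, 5L)
  topo <- sheetTopology(sh5$model)
  expect_equal(nrow(topo$pairs), 4L)
  expect_true(all(topo$pairs$topology == "antiparallel"))
  expect_equal(topo$pairs$strand_a, 1:4)
  expect_equal(topo$pairs$strand_b, 2:5)
  # all-helix model has empty topology, not an error
  h <- makeIdealBackbone(strrep("A", 12), strrep("H", 12))
  topoh <- sheetTopology(h)
  expect_equal(nrow(topoh$pairs), 0L)
  expect_equal(nrow(topoh$strands), 0L)
})

test_that("parallel sheets are labelled parallel in the pairing table", {
  shp <- sheetFixture("parallel")
  topo <- sheetTopology(shp$model)
  expect_gte(nrow(topo$pairing), 1L)
  expect_true(all(topo$pairing$topology == "parallel"))
})

test_that("ensemble topology consensus survives a noisy member", {
  sh <- sheetFixture("antiparallel", 2L, 8L)
  tight <- models(perturbEnsemble(sh$model, 4, 0.2, seed = 6))
  wrecked <- models(perturbEnsemble(sh$model, 2, 3.0, seed = 7))[2]
  ens <- Ensemble(c(tight, wrecked))
  topo <- sheetTopology(ens)
  expect_gte(nrow(topo$pairing), 2L)
  expect_true(all(topo$pairing$topology == "antiparallel"))
})
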