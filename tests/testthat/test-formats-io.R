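# External-format readers/writers: PDB multi-MODEL, NMR-STAR shift loops,
# restraint dialects, peak/RDC TSVs and numbering maps.

test_that("PDB write -> read round-trips coordinates at 3 decimals", {
  set.seed(11)
  base <- makeIdealBackbone("AVLIG", "CCCCC")
  mods <- models(perturbEnsemble(base, 3, 0.5, seed = 7))
  f <- tempfile(fileext = ".pdb")
  writePDBModels(mods, f)
  back <- readPDBModels(f)
  expect_length(back, 3L)
  for (m in 1:3) {
    a <- atoms(mods[[m]])
    b <- atoms(back[[m]])
    expect_equal(nrow(a), nrow(b))
    expect_equal(b$atom, a$atom)
    expect_equal(b$resname, a$resname)
    expect_equal(b$x, round(a$x, 3), tolerance = 1e-9)
    expect_equal(b$z, round(a$z, 3), tolerance = 1e-9)
  }
})

test_that("single-model PDB files read as one model", {
  f <- tempfile(fileext = ".pdb")
  writePDBModels(makeIdealBackbone("AGA", "CCC"), f)
  mods <- readPDBModels(f)
  expect_length(mods, 1L)
  expect_equal(length(unique(atoms(mods[[1]])$resno)), 3L)
})

test_that("malformed and incomplete PDB files give structured errors", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  N   ALA A   1      bad.xyz   0.000   0.000",
               "END"), f)
  expect_error(readPDBModels(f), "line 1")
  # residue missing CA
  g <- tempfile(fileext = ".pdb")
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  C   ALA A   1       1.500   0.000   0.000  1.00  0.00           C",
    "END")
  writeLines(lines, g)
  expect_error(readPDBModels(g), "lacks backbone")
})

test_that("NMR-STAR shift loops parse, with duplicates rejected", {
  f <- tempfile(fileext = ".str")
  writeLines(c(
    "data_test", "save_shifts", "   loop_",
    "      _Atom_chem_shift.ID",
    "      _Atom_chem_shift.Comp_index_ID",
    "      _Atom_chem_shift.Comp_ID",
    "      _Atom_chem_shift.Atom_ID",
    "      _Atom_chem_shift.Val",
    "      _Atom_chem_shift.Ambiguity_code",
    "      1 1 ALA N 123.4 1",
    "      2 1 ALA H 8.21 1",
    "      3 1 ALA CA 52.6 1",
    "      4 1 ALA CB 19.2 1",
    "      5 2 LEU N 121.0 1",
    "      6 2 LEU H 8.05 1",
    "      7 2 LEU CA 55.3 1",
    "      8 2 LEU CB 42.1 1",
    "   stop_", "save_"), f)
  tab <- readNmrStarShifts(f, scheme = "test")
  expect_s4_class(tab, "ChemicalShiftTable")
  expect_equal(nrow(shiftEntries(tab)), 8L)
  expect_equal(numberingScheme(tab), "test")
  # round-trip through the writer
  g <- tempfile(fileext = ".str")
  writeNmrStarShifts(tab, g)
  back <- readNmrStarShifts(g, scheme = "test")
  expect_equal(shiftEntries(back)$shift, shiftEntries(tab)$shift,
               tolerance = 0.005)
  # duplicate entry
  h <- tempfile(fileext = ".str")
  writeLines(c(
    "data_t", "   loop_",
    "      _Atom_chem_shift.Comp_index_ID",
    "      _Atom_chem_shift.Comp_ID",
    "      _Atom_chem_shift.Atom_ID",
    "      _Atom_chem_shift.Val",
    "      1 ALA CA 52.6", "      1 ALA CA 52.7",
    "   stop_"), h)
  expect_error(readNmrStarShifts(h), "duplicate")
  # no shift loop at all
  k <- tempfile(fileext = ".str")
  writeLines(c("data_empty", "save_x", "save_"), k)
  expect_error(readNmrStarShifts(k), "no _Atom_chem_shift loop")
})

test_that("proline-only entries carry CA but no amide proton", {
  f <- tempfile(fileext = ".str")
  writeLines(c(
    "data_t", "   loop_",
    "      _Atom_chem_shift.Comp_index_ID",
    "      _Atom_chem_shift.Comp_ID",
    "      _Atom_chem_shift.Atom_ID",
    "      _Atom_chem_shift.Val",
    "      1 PRO CA 63.2", "      1 PRO CB 32.0", "      2 PRO CA 63.4",
    "   stop_"), f)
  tab <- readNmrStarShifts(f)
  e <- shiftEntries(tab)
  expect_equal(sum(e$atom == "H"), 0L)
  expect_equal(sum(e$atom == "CA"), 2L)
})

test_that("restraint lists round-trip in both dialects with autodetection", {
  rl <- RestraintList(data.frame(
    group_a = c("3.HN", "5.CD1|5.CD2", "2.CB"),
    group_b = c("15.HN", "12.CG2", "12.CD1"),
    upper = c(3.4, 5.5, 6.2)))
  for (dialect in c("tsv", "cyana-upl")) {
    f <- tempfile()
    writeRestraints(rl, f, dialect = dialect)
    back <- readRestraints(f)  # autodetect
    expect_equal(restraints(back)$upper, restraints(rl)$upper,
                 tolerance = 0.01)
    expect_equal(restraints(back)$group_a, restraints(rl)$group_a)
    expect_equal(restraints(back)$class, restraints(rl)$class)
  }
})

test_that("empty restraint files give empty lists; bad bounds error", {
  f <- tempfile()
  writeLines(c("# just a comment"), f)
  expect_equal(nrow(restraints(readRestraints(f))), 0L)
  g <- tempfile()
  writeLines("group_a\tgroup_b\tupper_A\n1.HN\t5.HN\t9.0", g)
  expect_error(readRestraints(g), "cap")
  expect_equal(nrow(restraints(readRestraints(g, allow_loose = TRUE))), 1L)
  h <- tempfile()
  writeLines("group_a\tgroup_b\tupper_A\n1.HN\t5.HN\t1.0", h)
  expect_error(readRestraints(h), "floor")
})

test_that("NOE peak and RDC TSVs round-trip including NA diagonals", {
  pk <- NOEPeakTable(data.frame(
    group_a = c("1.HN", "2.HN"), group_b = c("5.HN", "6.CD1"),
    cross = c(0.5, 0.1), diag_a = c(1.2, NA), diag_b = c(0.9, NA)))
  f <- tempfile()
  writeNOEPeaks(pk, f)
  back <- readNOEPeaks(f)
  expect_equal(peaks(back)$cross, peaks(pk)$cross)
  expect_equal(peaks(back)$flagged, c(FALSE, TRUE))
  expect_equal(peaks(back)$class, c("amide-amide", "amide-methyl"))

  rd <- RDCTable(data.frame(resno = 1:5, type = "NH",
                            D = c(-3.2, 8.1, 12.0, -7.7, 0.3)))
  g <- tempfile()
  writeRDCTable(rd, g)
  expect_equal(rdcRecords(readRDCTable(g))$D, rdcRecords(rd)$D)
})

test_that("numbering maps translate, compose to identity, and reject gaps", {
  m <- numberingMap(571, 623, +125, from = "zebrafish", to = "human")
  tab <- ChemicalShiftTable(data.frame(
    resno = c(571, 600, 623), resname = "ALA",
    atom = "CA", shift = c(52, 53, 54)), scheme = "zebrafish")
  expect_error(validObject(tab), NA)
  mapped <- mapNumbering(tab, m)
  expect_equal(shiftEntries(mapped)$resno, c(696, 725, 748))
  expect_equal(numberingScheme(mapped), "human")
  back <- mapNumbering(mapped, invertNumberingMap(m))
  expect_equal(shiftEntries(back)$resno, shiftEntries(tab)$resno)
  # identity map leaves everything unchanged
  idm <- numberingMap(571, 623, 0)
  expect_equal(shiftEntries(mapNumbering(tab, idm))$resno,
               shiftEntries(tab)$resno)
  # residue outside all segments
  bad <- ChemicalShiftTable(data.frame(resno = 100, resname = "ALA",
                                       atom = "CA", shift = 52))
  expect_error(mapNumbering(bad, m), "100")
  # restraint lists translate group specs
  rl <- RestraintList(data.frame(group_a = "571.HN", group_b = "600.CD1",
                                 upper = 5))
  rl2 <- mapNumbering(rl, m)
  expect_equal(restraints(rl2)$group_a, "696.HN")
  expect_equal(restraints(rl2)$group_b, "725.CD1")
})

test_that("shift tables enforce physical windows and uniqueness", {
  expect_error(ChemicalShiftTable(data.frame(
    resno = 1, resname = "ALA", atom = "CA", shift = 300)), "window")
  expect_error(ChemicalShiftTable(data.frame(
    resno = c(1, 1), resname = "ALA", atom = c("CA", "CA"),
    shift = c(52, 53))), "duplicate")
})
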