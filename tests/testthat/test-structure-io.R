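test_that("a minimal PDB reads back its atoms and coordinates exactly", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeMiniPdb(f, c(
    pdbAtomLine(1, "N", "ALA", "A", 1, 1.234, 2.345, 3.456),
    pdbAtomLine(2, "CA", "ALA", "A", 1, 4.000, 5.000, 6.000),
    pdbAtomLine(3, "C", "ALA", "A", 1, -7.125, 8.250, -9.375)
  ))
  s <- readStructure(f)
  expect_equal(nrow(atomData(s)), 3L)
  expect_equal(nModels(s), 1L)
  expect_identical(modelCoords(s)[2, ], c(4, 5, 6))
  expect_identical(modelCoords(s)[3, ], c(-7.125, 8.25, -9.375))
  expect_equal(atomData(s)$elety, c("N", "CA", "C"))
})

test_that("multi-model files expose every model with atom counts preserved", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    pdbAtomLine(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdbAtomLine(2, "CA", "ALA", "A", 2, 3.8, 0, 0),
    "ENDMDL",
    "MODEL        2",
    pdbAtomLine(1, "CA", "ALA", "A", 1, 1, 1, 1),
    pdbAtomLine(2, "CA", "ALA", "A", 2, 4.8, 1, 1),
    "ENDMDL", "END"), f)
  s <- readStructure(f)
  expect_equal(nModels(s), 2L)
  expect_equal(nrow(modelCoords(s, 1)), 2L)
  expect_equal(modelCoords(s, 2)[1, ], c(1, 1, 1))
  expect_error(readStructure(f, modelIndex = 3), "3")
  s1 <- readStructure(f, modelIndex = 2)
  expect_equal(nModels(s1), 1L)
})

test_that("a non-numeric coordinate field raises a parse error citing the line", {
  f <- withr::local_tempfile(fileext = ".pdb")
  good <- pdbAtomLine(1, "CA", "ALA", "A", 1, 0, 0, 0)
  bad <- sub("3.800", "3.8xy", pdbAtomLine(2, "CA", "ALA", "A", 2, 3.8, 0, 0))
  writeMiniPdb(f, c(good, bad))
  expect_error(readStructure(f), "line 2")
})

test_that("round-trip write/read preserves Calpha coordinates to PDB precision", {
  toy <- makeToyTransporter()
  f <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(toy$structure, f)
  s2 <- readStructure(f)
  ca1 <- regionCa(toy$structure, toy$annotation, c("TH4", "ICD1", "S9_1"))
  ca2 <- regionCa(s2, toy$annotation, c("TH4", "ICD1", "S9_1"))
  expect_lt(max(abs(ca1 - ca2)), 1e-3)
  # HETATM DUMMY records survive the round trip
  expect_equal(nrow(dumAtoms(s2)), nrow(dumAtoms(toy$structure)))
})

test_that("OPM membrane parsing recovers symmetric and offset DUMMY layers", {
  mk <- function(zs) {
    rows <- list(); i <- 0L
    for (z in zs) for (x in c(-10, 0, 10)) for (y in c(-10, 0, 10)) {
      i <- i + 1L
      rows[[i]] <- pdbAtomLine(i, "DUM", "DUM", "M", 900 + i, x, y, z, "HETATM")
    }
    unlist(rows)
  }
  f <- withr::local_tempfile(fileext = ".pdb")
  writeMiniPdb(f, mk(c(15, -15)))
  m <- parseOpmMembrane(readStructure(f))
  expect_equal(membraneCenter(m)[3], 0)
  expect_equal(membraneNormal(m), c(0, 0, 1))
  expect_equal(membraneThickness(m), 30)

  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeMiniPdb(f2, mk(c(20, -10)))
  m2 <- parseOpmMembrane(readStructure(f2))
  expect_equal(membraneCenter(m2)[3], 5)
  expect_equal(membraneThickness(m2), 30)

  # no DUM residues at all
  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeMiniPdb(f3, pdbAtomLine(1, "CA", "ALA", "A", 1, 0, 0, 0))
  expect_error(parseOpmMembrane(readStructure(f3)), "no membrane annotation")
})

test_that("membrane parsing recovers a generator membrane to 1e-6", {
  for (nrm in list(c(0, 0, 1), c(0.2, -0.1, 1))) {
    ms <- makeOpmMembraneStructure(center = c(3, -2, 5), normal = nrm,
                                   thickness = 28)
    m <- parseOpmMembrane(ms)
    expect_lt(max(abs(membraneCenter(m) - c(3, -2, 5))), 1e-6)
    u <- nrm / sqrt(sum(nrm^2))
    expect_lt(max(abs(membraneNormal(m) - u)), 1e-6)
    expect_lt(abs(membraneThickness(m) - 28), 1e-6)
  }
})

test_that("annotation TSV loading validates schema, ranges and duplicates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("region_name\tchain\tstart\tend", "TH4\tA\t219\t243"), f)
  ann <- loadAnnotation(f)
  e <- regions(ann)
  expect_identical(e$region, "TH4")
  expect_identical(e$start, 219L)
  expect_identical(e$end, 243L)

  writeLines(c("region_name\tchain\tstart\tend", "TH4\tA\t243\t219"), f)
  expect_error(loadAnnotation(f), "start")

  writeLines(c("region_name\tchain\tstart\tend",
               "TH4\tA\t219\t243", "TH4\tA\t300\t310"), f)
  expect_error(loadAnnotation(f), "duplicate")

  writeLines(c("region_name\tchain\tstart\tend\tcolor",
               "TH4\tA\t219\t243\tred"), f)
  expect_error(loadAnnotation(f), "unknown")
})

test_that("annotation validation reports missing regions before computation", {
  toy <- makeToyTransporter()
  partial <- regionAnnotation(regions(toy$annotation)[1:3, ])
  expect_error(
    computeConftor(toy$structure, partial, "NBDX1", toy$membrane),
    "NBDX1.*CH1|CH1.*NBDX1")
})

test_that("a missing range-end Calpha is substituted inward with a warning", {
  toy <- makeToyTransporter()
  s <- toy$structure
  keep <- !(s@atoms$resno == 175 & s@atoms$chain == "A") # first residue of TH4
  s2 <- proteinStructure("pruned", s@atoms[keep, ],
                         lapply(s@coords, function(m) m[keep, , drop = FALSE]))
  w <- capture_warnings(cf <- computeConftor(s2, toy$annotation, "THV1", toy$membrane))
  expect_true(any(grepl("substituted", w)))
  expect_s4_class(cf, "Conftor")
  # more than 2 positions missing is an error
  keep3 <- !(s@atoms$resno %in% 175:177 & s@atoms$chain == "A")
  s3 <- proteinStructure("pruned3", s@atoms[keep3, ],
                         lapply(s@coords, function(m) m[keep3, , drop = FALSE]))
  expect_error(suppressWarnings(
    computeConftor(s3, toy$annotation, "THV1", toy$membrane)), "within 2")
})
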