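test_that("PDB ingestion flags terminals, lipids, waters and handles empty input", {
  s <- readStructure(tripeptidePDB(c("ALA", "SER", "ALA")))
  r <- residueTable(s)
  expect_equal(nrow(r), 3L)
  expect_equal(r$is_terminal, c(TRUE, FALSE, TRUE))
  expect_true(all(r$usable))

  lip <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    pdbLine(4, "C22", "DPPC", "L", 1, 4, 0, 0, het = TRUE),
    pdbLine(5, "O", "HOH", "W", 1, 8, 0, 0, het = TRUE))
  s2 <- readStructure(lip)
  a <- atomTable(s2)
  expect_true(a$is_lipid[a$resname == "DPPC"])
  expect_true(a$is_water[a$resname == "HOH"])
  expect_false(any(a$is_lipid & a$is_water))

  s3 <- readStructure("")
  expect_equal(nrow(atomTable(s3)), 0L)
  expect_equal(nrow(residueTable(s3)), 0L)
})

test_that("malformed records raise parse errors with a line number", {
  bad <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      bogus!")
  expect_error(readStructure(bad), "line 2")
})

test_that("residues missing backbone atoms are unusable, not fatal", {
  txt <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  N   GLY A   2       3.300   1.500   0.500  1.00  0.00           N",
    "ATOM      5  CA  GLY A   2       4.500   2.000   1.000  1.00  0.00           C")
  s <- readStructure(txt)
  r <- residueTable(s)
  expect_true(r$usable[1L])
  expect_false(r$usable[2L])
  expect_match(r$reason[2L], "missing backbone")
})

test_that("alternate locations keep the highest-occupancy conformer, ties to A", {
  txt <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BALA A   1       1.500   0.100   0.000  0.60  0.00           C",
    "ATOM      4  C  AALA A   1       2.000   1.400   0.000  0.50  0.00           C",
    "ATOM      5  C  BALA A   1       2.100   1.500   0.000  0.50  0.00           C")
  s <- readStructure(txt)
  a <- atomTable(s)
  expect_equal(sum(a$name == "CA"), 1L)
  expect_equal(a$x[a$name == "CA"], 1.500)  # occupancy 0.6 wins
  expect_equal(sum(a$name == "C"), 1L)
  expect_equal(a$x[a$name == "C"], 2.000)   # tie -> altloc A
})

test_that("lipid trimming is inclusive at the cutoff and monotone", {
  ## protein atoms along +y so the lipid's minimum distance is exactly d
  mk <- function(d) c(
    pdbLine(1, "N", "ALA", "A", 1, 0, 0, 0),
    pdbLine(2, "CA", "ALA", "A", 1, 0, 1.458, 0, element = "C"),
    pdbLine(3, "C", "ALA", "A", 1, 0, 2.9, 0),
    pdbLine(4, "C22", "DPPC", "L", 1, d, 0, 0, het = TRUE))
  for (case in list(c(7.0, 0L), c(5.0, 1L), c(6.0, 1L))) {
    s <- trimLipids(readStructure(mk(case[1L])), cutoff = 6)
    expect_equal(sum(atomTable(s)$is_lipid), as.integer(case[2L]),
                 info = sprintf("lipid at %.1f A", case[1L]))
  }
  ## monotone: retained at 5 is a subset of retained at 6
  fx <- smallBundle()
  k5 <- unique(atomTable(trimLipids(fx$structure, 5))$residue_key)
  k6 <- unique(atomTable(trimLipids(fx$structure, 6))$residue_key)
  expect_true(all(k5 %in% k6))
})

test_that("hydrogen placement matches valence counts and is idempotent", {
  s <- readStructure(tripeptidePDB(c("GLY", "ALA", "GLY")))
  sh <- addHydrogens(s)
  a <- atomTable(sh)
  ala <- a[a$resname == "ALA", ]
  expect_equal(sum(ala$name %in% c("HB1", "HB2", "HB3")), 3L)
  expect_true("HA" %in% ala$name)
  expect_true("H" %in% ala$name)
  gly <- a[a$residue_key == "A:1", ]
  expect_equal(sum(gly$name %in% c("HA2", "HA3")), 2L)
  ## idempotent
  sh2 <- addHydrogens(sh)
  expect_equal(nrow(atomTable(sh2)), nrow(atomTable(sh)))
  ## bond lengths sane (all H within 1.6 A of a heavy atom)
  hh <- a[a$element == "H", ]
  heavy <- a[a$element != "H", ]
  mind <- vapply(seq_len(nrow(hh)), function(i)
    min(sqrt((heavy$x - hh$x[i])^2 + (heavy$y - hh$y[i])^2 +
               (heavy$z - hh$z[i])^2)), numeric(1))
  expect_true(all(mind < 1.6))
})

test_that("membrane classification follows the backbone-between-planes rule", {
  mk <- function(zs, resno, s0) {
    vapply(1:3, function(i)
      pdbLine(s0 + i, c("N", "CA", "C")[i], "ALA", "A", resno,
              c(0, 1.4, 2.0)[i], c(0, 0, 1.4)[i], zs[i],
              element = c("N", "C", "C")[i]), character(1))
  }
  s <- readStructure(c(mk(c(-5, 0, 5), 1L, 0L), mk(c(18, 20, 22), 2L, 3L)))
  ann <- new("MembraneAnnotation", z_upper = 15, z_lower = -15,
             pore_flags = c("A:2" = FALSE))
  env <- classifyEnvironment(s, ann)
  expect_equal(unname(env["A:1"]), "mL")
  expect_equal(unname(env["A:2"]), "mS")
  ann2 <- new("MembraneAnnotation", z_upper = 15, z_lower = -15,
              pore_flags = c("A:1" = TRUE))
  expect_equal(unname(classifyEnvironment(s, ann2)["A:1"]), "mC")
  ## soluble mode
  expect_true(all(classifyEnvironment(s) == "soluble"))
})

test_that("environment tags partition the usable residues of a bundle", {
  fx <- smallBundle()
  ann <- readMembraneAnnotation(fx$planes, fx$pore_csv)
  env <- classifyEnvironment(fx$structure, ann)
  usable <- residueTable(fx$structure)
  usable <- usable$key[usable$usable]
  tags <- env[names(env) %in% usable]
  expect_true(all(tags %in% c("mS", "mC", "mL")))
  expect_false(anyNA(tags))
})

test_that("the distortions reader recovers the leaflet planes", {
  fx <- smallBundle()
  ann <- readMembraneAnnotation(fx$distortions, fx$pore_csv)
  expect_equal(ann@z_lower, -15)
  expect_equal(ann@z_upper, 15)
  ann2 <- readMembraneAnnotation(fx$planes, fx$pore_csv)
  expect_equal(ann2@z_lower, ann@z_lower)
  expect_equal(ann2@z_upper, ann@z_upper)
  expect_true(any(ann@pore_flags))
  expect_true(!all(ann@pore_flags))
})

test_that("disulfide-bridged cysteines are renamed CYX", {
  mkcys <- function(s0, resno, chain, sgx) c(
    pdbLine(s0 + 1, "N", "CYS", chain, resno, sgx - 2.8, 0, 0),
    pdbLine(s0 + 2, "CA", "CYS", chain, resno, sgx - 2.0, 1.0, 0,
            element = "C"),
    pdbLine(s0 + 3, "C", "CYS", chain, resno, sgx - 1.0, 2.0, 0),
    pdbLine(s0 + 4, "CB", "CYS", chain, resno, sgx - 1.2, 0, 0,
            element = "C"),
    pdbLine(s0 + 5, "SG", "CYS", chain, resno, sgx, 0, 0, element = "S"))
  ## SG atoms 2.04 A apart -> bridged; a third CYS far away stays CYS
  txt <- c(mkcys(0, 1, "A", 0), mkcys(5, 1, "B", 2.04),
           mkcys(10, 1, "C", 30))
  s <- readStructure(txt)
  r <- residueTable(s)
  expect_equal(r$type[r$chain == "A"], "CYX")
  expect_equal(r$type[r$chain == "B"], "CYX")
  expect_equal(r$type[r$chain == "C"], "CYS")
})
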