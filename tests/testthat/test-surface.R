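test_that("an isolated sidechain atom has the closed-form sphere area", {
  one <- "ATOM      1  CB  ALA A   1       0.000   0.000   0.000  1.00  0.00           C"
  s <- atomAccessibility(readStructure(one))
  want <- 4 * pi * (1.70 + 1.4)^2
  expect_equal(residueSasa(s, "A:1"), want, tolerance = 1e-9)
})

test_that("caged residues have near-zero area and distant residues are additive", {
  pts <- hydromaps:::spherePoints(30L) * 2.2
  cage <- c("ATOM      1  CB  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
            sprintf("HETATM%5d  O   HOH W%4d    %8.3f%8.3f%8.3f  1.00  0.00           O",
                    2:31, 2:31, pts[, 1], pts[, 2], pts[, 3]))
  s <- atomAccessibility(readStructure(cage))
  expect_lt(residueSasa(s, "A:1"),
            0.02 * 4 * pi * (1.7 + 1.4)^2)

  two <- c("ATOM      1  CB  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
           "ATOM      2  CB  ALA B   1      50.000   0.000   0.000  1.00  0.00           C")
  s2 <- atomAccessibility(readStructure(two))
  want <- 4 * pi * (1.70 + 1.4)^2
  expect_equal(residueSasa(s2, "A:1"), want, tolerance = 1e-9)
  expect_equal(residueSasa(s2, "B:1"), want, tolerance = 1e-9)
})

test_that("sidechain SASA agrees with a random-point sphere oracle within 2%", {
  ## oracle: uniform Monte-Carlo points per atom, full pairwise occlusion
  oracleSasa <- function(atoms, idx, probe = 1.4, n = 20000L) {
    set.seed(7)
    radii <- hydromaps:::.bondiRadius(atoms$element) + probe
    xyz <- atomCoords(atoms)
    tot <- 0
    for (i in idx) {
      z <- stats::runif(n, -1, 1)
      th <- stats::runif(n, 0, 2 * pi)
      rxy <- sqrt(1 - z^2)
      pts <- cbind(rxy * cos(th), rxy * sin(th), z) * radii[i]
      pts <- sweep(pts, 2L, xyz[i, ], `+`)
      ok <- rep(TRUE, n)
      for (j in seq_len(nrow(atoms))) {
        if (j == i) next
        d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
          (pts[, 3] - xyz[j, 3])^2
        ok <- ok & d2 >= radii[j]^2
      }
      tot <- tot + mean(ok) * 4 * pi * radii[i]^2
    }
    tot
  }
  for (seed in 1:10) {
    set.seed(seed)
    types <- sample(c("LEU", "SER", "VAL", "THR", "ILE", "PHE"), 2L)
    s <- annotatedPair(types, separation = runif(1, 6, 9), seed = seed,
                       n_points = 960L)
    a <- atomTable(s)
    idx <- hydromaps:::.sidechainIdx(a, "A:1", types[1L])
    got <- residueSasa(s, "A:1")
    want <- oracleSasa(a, idx)
    expect_equal(got, want, tolerance = 0.02,
                 info = sprintf("seed %d (%s/%s)", seed, types[1], types[2]))
  }
})

test_that("the SASA/LASA partition uses the strict 0.1 rule", {
  expect_equal(partitionAsa("A:1", 40, 0.2)$label, "LASA")
  expect_equal(partitionAsa("A:1", 40, 0.05)$label, "SASA")
  expect_equal(partitionAsa("A:1", 40, 0.1)$label, "SASA")  # strict >
  expect_error(partitionAsa("A:1", -1, 0.5))
})

test_that("interaction characters are conserved sums and linear", {
  g <- residueGridSpec("THR")
  fr <- identityFrame()
  z <- interactionCharacter(computeMapSet("x", hydromaps:::.emptyPairs(),
                                          g, fr))
  expect_equal(unname(z), c(0, 0, 0, 0))
  p <- data.frame(value = 5, class = "polPlus", r = 1, mx = 0, my = 0,
                  mz = 1, partner_is_lipid = FALSE)
  ch <- interactionCharacter(computeMapSet("x", p, g, fr))
  expect_equal(ch[["polPlus"]], 5, tolerance = 1e-6)
  ## character(mL) - character(mN) = character(mL - mN)
  pp <- randomPairs(200, "THR", seed = 21)
  mL <- computeMapSet("x", pp, g, fr, mode = "mL")
  mN <- computeMapSet("x", pp[!pp$partner_is_lipid, ], g, fr, mode = "mN")
  expect_equal(interactionCharacter(mL) - interactionCharacter(mN),
               interactionCharacter(differenceMap(mL, mN)),
               tolerance = 1e-9)
})

test_that("random-coil normalization matches the published reference areas", {
  rc <- randomCoilSasa()
  expect_equal(unname(rc["CYX"]), 153.5)          # printed value
  expect_equal(unname(rc["CYX"]), 1.5 * unname(rc["CYS"]), tolerance = 1e-3)
  expect_equal(unname(rc["GLY"]), 87.2)           # full-residue value
  expect_equal(unname(rc[c("ALA", "VAL", "TRP")]), c(64.9, 122.3, 224.6))
  v <- c(hydMinus = -30, hydPlus = 10, polMinus = -5, polPlus = 20)
  nv <- normalizeCharacter(v, "ALA")
  expect_equal(unname(nv), unname(v) * 100 / 64.9)
  expect_equal(normalizeCharacter(2 * v, "ALA"), 2 * nv)
  expect_equal(unname(normalizeCharacter(v * 0, "TYR")), c(0, 0, 0, 0))
  expect_error(normalizeCharacter(v, "XXX"))
})

test_that("catalog summaries reproduce subset-fraction arithmetic", {
  ## the published membrane ALA counts: 16,566 / 1,942 / 15,480
  rd <- data.frame(
    key = sprintf("r%d", 1:33988),
    type = "ALA",
    env = rep(c("mS", "mC", "mL"), times = c(16566, 1942, 15480)),
    sasa = 1, lasa = 0, hydMinus = -1, hydPlus = 1, polMinus = 0,
    polPlus = 0, stringsAsFactors = FALSE)
  out <- summarizeCatalog(NULL, rd)
  expect_equal(out$fractions$mS, 0.487, tolerance = 1e-3)
  expect_equal(out$fractions$mS + out$fractions$mC + out$fractions$mL, 1,
               tolerance = 1e-9)

  ## single-member cluster reports sd = 0
  cat1 <- data.frame(bin = "c3", cluster = "1", count = 1L, exemplar = "r1",
                     members = "r1", stringsAsFactors = FALSE)
  out2 <- summarizeCatalog(cat1, rd[1L, ])
  expect_equal(out2$per_cluster$sasa_sd, 0)
  expect_equal(out2$per_cluster$count, 1L)
})
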