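test_that("atom constants follow the sign conventions", {
  s <- annotatedPair(c("LEU", "ASP"))
  a <- atomTable(s)
  cd1 <- a[a$resname == "LEU" & a$name == "CD1", ]
  expect_gt(cd1$a, 0)
  expect_equal(cd1$polar_class, "hydrophobic")
  od1 <- a[a$resname == "ASP" & a$name == "OD1", ]
  expect_lt(od1$a, 0)
  expect_equal(od1$polar_class, "base")
  amideH <- a[a$name == "H" & a$element == "H", ]
  expect_true(all(amideH$a < 0))
  expect_true(all(amideH$polar_class == "acid"))
})

test_that("unknown atoms raise a configuration error listing names", {
  txt <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  XX  ALA A   1       3.000   1.400   0.000  1.00  0.00           X")
  expect_error(assignAtomConstants(readStructure(txt)), "ALA XX")
})

test_that("accessibility is 1 for isolated atoms and ~0 for caged atoms", {
  one <- "ATOM      1  CB  ALA A   1       0.000   0.000   0.000  1.00  0.00           C"
  s1 <- atomAccessibility(readStructure(one))
  expect_equal(atomTable(s1)$S, 1)

  ## cage: central atom surrounded by a tight icosahedral-ish shell
  pts <- hydromaps:::spherePoints(30L) * 2.2
  cage <- c("ATOM      1  CB  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
            sprintf("ATOM  %5d  CB  ALA B%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                    2:31, 2:31, pts[, 1], pts[, 2], pts[, 3]))
  s2 <- atomAccessibility(readStructure(cage))
  expect_lt(atomTable(s2)$S[1L], 0.02)
})

test_that("two-atom occlusion matches a Monte-Carlo sphere oracle within 1%", {
  ## independent oracle: uniform random sphere points, occlusion test
  mcFraction <- function(p1, p2, r1, r2, probe, n = 60000L) {
    set.seed(99)
    z <- stats::runif(n, -1, 1)
    th <- stats::runif(n, 0, 2 * pi)
    rxy <- sqrt(1 - z^2)
    pts <- cbind(rxy * cos(th), rxy * sin(th), z) * (r1 + probe)
    pts <- sweep(pts, 2L, p1, `+`)
    d2 <- (pts[, 1] - p2[1])^2 + (pts[, 2] - p2[2])^2 + (pts[, 3] - p2[3])^2
    mean(d2 >= (r2 + probe)^2)
  }
  for (d in c(2.0, 2.8, 3.4)) {
    txt <- c(
      "ATOM      1  CB  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
      sprintf("ATOM      2  O   HOH W   1    %8.3f   0.000   0.000  1.00  0.00           O", d))
    s <- atomAccessibility(readStructure(txt))
    rC <- 1.70; rO <- 1.52
    want <- mcFraction(c(0, 0, 0), c(d, 0, 0), rC, rO, 1.4)
    expect_equal(atomTable(s)$S[1L], want, tolerance = 0.01,
                 info = sprintf("separation %.1f", d))
  }
})

test_that("pair scoring honours the stated sign and attenuation contract", {
  mk <- function(a, S, cls, x = 0) list(x = x, y = 0, z = 0, a = a, S = S,
                                        polar_class = cls, is_lipid = FALSE)
  ## two hydrophobic atoms at r = 0 -> +1, Hyd+
  p <- pairScore(mk(1, 1, "hydrophobic"), mk(1, 1, "hydrophobic"))
  expect_equal(p$value, 1.0)
  expect_equal(p$interaction_class, "hydPlus")
  ## acid with base at r = 0 -> +1, Pol+
  p <- pairScore(mk(-1, 1, "acid"), mk(-1, 1, "base"))
  expect_equal(p$value, 1.0)
  expect_equal(p$interaction_class, "polPlus")
  ## acid-acid -> negative, Pol-
  p <- pairScore(mk(-1, 1, "acid"), mk(-1, 1, "acid"))
  expect_equal(p$value, -1.0)
  expect_equal(p$interaction_class, "polMinus")
  ## hydrophobic x polar forced negative, Hyd-
  p <- pairScore(mk(1, 1, "hydrophobic"), mk(-1, 1, "base"))
  expect_lt(p$value, 0)
  expect_equal(p$interaction_class, "hydMinus")
  ## exp(-r) attenuation: value halves at r = ln 2
  p2 <- pairScore(mk(1, 1, "hydrophobic"),
                  mk(1, 1, "hydrophobic", x = log(2)))
  expect_equal(p2$value, 0.5, tolerance = 1e-12)
  ## symmetry and midpoint
  pa <- mk(0.7, 0.8, "hydrophobic"); pb <- mk(0.9, 0.4, "hydrophobic", x = 3)
  expect_equal(pairScore(pa, pb)$value, pairScore(pb, pa)$value)
  expect_equal(pairScore(pa, pb)$midpoint, c(1.5, 0, 0))
  ## monotone decay in r
  rs <- seq(0.5, 8, by = 0.5)
  vals <- vapply(rs, function(r)
    abs(pairScore(mk(1, 1, "hydrophobic"),
                  mk(-1, 1, "acid", x = r))$value), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("every polar-class combination maps to exactly one interaction class", {
  classes <- c("hydrophobic", "acid", "base", "amphoteric")
  want <- function(c1, c2) {
    if (c1 == "hydrophobic" && c2 == "hydrophobic") "hydPlus"
    else if (xor(c1 == "hydrophobic", c2 == "hydrophobic")) "hydMinus"
    else if ((c1 == "acid" && c2 == "acid") ||
             (c1 == "base" && c2 == "base")) "polMinus"
    else "polPlus"
  }
  for (c1 in classes) for (c2 in classes) {
    a1 <- if (c1 == "hydrophobic") 1 else -1
    a2 <- if (c2 == "hydrophobic") 1 else -1
    p <- pairScore(list(x = 0, y = 0, z = 0, a = a1, S = 1, polar_class = c1),
                   list(x = 1, y = 0, z = 0, a = a2, S = 1, polar_class = c2))
    expect_equal(p$interaction_class, want(c1, c2),
                 info = paste(c1, c2))
    sgn <- if (p$interaction_class %in% c("hydPlus", "polPlus")) 1 else -1
    expect_equal(sign(p$value), sgn, info = paste(c1, c2))
  }
})

test_that("partner pairs respect the mode contract and omit intra-residue pairs", {
  ## isolated residue has no partners
  far <- annotatedPair(c("LEU", "LEU"), separation = 50)
  expect_equal(nrow(residuePartnerPairs("A:1", far, mode = "soluble")), 0L)

  ## bundle residue: mL and mN differ exactly by the lipid-partner pairs
  fx <- smallBundle()
  s <- trimLipids(fx$structure)
  s <- addHydrogens(s)
  s <- assignAtomConstants(s)
  s <- atomAccessibility(s, n_points = 240L)
  ann <- readMembraneAnnotation(fx$planes, fx$pore_csv)
  env <- classifyEnvironment(s, ann)
  key <- names(env)[which(env == "mL")][5L]
  pL <- residuePartnerPairs(key, s, mode = "mL")
  pN <- residuePartnerPairs(key, s, mode = "mN")
  expect_true(any(pL$partner_is_lipid))
  expect_false(any(pN$partner_is_lipid))
  expect_equal(pL[!pL$partner_is_lipid, ], pN, ignore_attr = TRUE)
  ## r never zero (a zero distance would be an intra-residue self pair)
  expect_true(all(pL$r > 0.5))
})

test_that("the lipid score ratio is the absolute-score share of lipid pairs", {
  p0 <- data.frame(value = c(1, -2), partner_is_lipid = c(FALSE, FALSE))
  expect_equal(lipidScoreRatio(p0), 0)
  p1 <- data.frame(value = c(1, -2), partner_is_lipid = c(TRUE, TRUE))
  expect_equal(lipidScoreRatio(p1), 1)
  p2 <- data.frame(value = c(1, -1, 0.5, -1.5),
                   partner_is_lipid = c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(lipidScoreRatio(p2), 0.25)
  expect_equal(lipidScoreRatio(data.frame(value = numeric(0),
                                          partner_is_lipid = logical(0))), 0)
})

test_that("pH50 constants match the published values", {
  sol <- ionizationModel("soluble")
  expect_identical(unname(sol$pH50[c("ASP", "CYS", "GLU", "HIS")]),
                   c(3.3449, 9.5814, 4.2240, 5.1743))
  mem <- ionizationModel("membrane")
  expect_identical(unname(mem$pH50[c("ASP", "CYS", "GLU", "HIS")]),
                   c(3.9331, 9.4506, 4.2021, 5.4206))
})

test_that("ionization selection follows the pH penalty when raw scores tie", {
  ## an isolated ASP: every variant scores ~0 raw, so the pH term decides
  s <- annotatedPair(c("ASP", "LEU"), separation = 50)
  model <- ionizationModel("soluble")
  hi <- selectIonizationState(s, "A:1", pH = 12, model = model)
  expect_equal(hi$state, "deprotonated")
  lo <- selectIonizationState(s, "A:1", pH = 1, model = model)
  expect_equal(lo$state, "protonated")
  ## the protonated variant carries the scanned -XH proton
  expect_true("HD2" %in% lo$atoms$name)
  expect_false("HD2" %in% hi$atoms$name)
  ## non-ionizable types are rejected
  expect_error(selectIonizationState(s, "B:1", pH = 7, model = model),
               "ASP, CYS, GLU, HIS")
})

test_that("HIS enumerates tautomer/cation variants in both ring geometries", {
  s <- annotatedPair(c("HIS", "SER"), separation = 9)
  sel <- selectIonizationState(s, "A:1", pH = 7,
                               model = ionizationModel("soluble"))
  expect_equal(nrow(sel$scores), 6L)
  expect_setequal(unique(sel$scores$state), c("protonated", "deprotonated"))
  expect_true(any(grepl("flipped", sel$scores$variant)))
})
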