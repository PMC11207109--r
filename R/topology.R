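## Residue topology: idealized sidechain internal coordinates, intra-residue
## bond lists, and hydrogen-placement specifications for the 20 amino acids
## plus disulfide-bridged cysteine (CYX). Bond lengths/angles are standard
## ideal values; sidechain torsions are parameterized by chi1..chi4 so the
## fixture generator can emit arbitrary rotamers.

.AA_TYPES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "CYX", "GLN", "GLU", "GLY",
               "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR",
               "TRP", "TYR", "VAL")

## types parsed by chi1 only / chi1+chi2 / proline / unparsed
.PARSE1_TYPES <- c("ASN", "ASP", "CYS", "CYX", "HIS", "ILE", "LEU", "MET",
                   "PHE", "SER", "THR", "TRP", "TYR")
.PARSE2_TYPES <- c("ARG", "GLN", "GLU", "LYS")
.NOPARSE_TYPES <- c("ALA", "GLY", "VAL")

zm <- function(name, dref, aref, tref, r, theta, dih) {
  data.frame(name = name, dref = dref, aref = aref, tref = tref,
             r = r, theta = theta, dih = dih, stringsAsFactors = FALSE)
}

## Sidechain z-matrix per residue type (heavy atoms beyond CB). Dihedral
## entries are expressions in x1..x4 (degrees) or plain numbers.
.SIDECHAIN_ZMAT <- list(
  ALA = NULL,
  ARG = rbind(
    zm("CG", "CB", "CA", "N", 1.52, 114.1, "x1"),
    zm("CD", "CG", "CB", "CA", 1.52, 111.3, "x2"),
    zm("NE", "CD", "CG", "CB", 1.46, 112.0, "x3"),
    zm("CZ", "NE", "CD", "CG", 1.33, 124.2, "x4"),
    zm("NH1", "CZ", "NE", "CD", 1.33, 120.0, "0"),
    zm("NH2", "CZ", "NE", "CD", 1.33, 120.0, "180")),
  ASN = rbind(
    zm("CG", "CB", "CA", "N", 1.52, 112.6, "x1"),
    zm("OD1", "CG", "CB", "CA", 1.23, 120.8, "x2"),
    zm("ND2", "CG", "CB", "CA", 1.33, 116.4, "x2+180")),
  ASP = rbind(
    zm("CG", "CB", "CA", "N", 1.52, 112.6, "x1"),
    zm("OD1", "CG", "CB", "CA", 1.25, 118.5, "x2"),
    zm("OD2", "CG", "CB", "CA", 1.25, 118.5, "x2+180")),
  CYS = zm("SG", "CB", "CA", "N", 1.81, 114.0, "x1"),
  CYX = zm("SG", "CB", "CA", "N", 1.81, 114.0, "x1"),
  GLN = rbind(
    zm("CG", "CB", "CA", "N", 1.52, 114.1, "x1"),
    zm("CD", "CG", "CB", "CA", 1.52, 112.6, "x2"),
    zm("OE1", "CD", "CG", "CB", 1.23, 120.8, "x3"),
    zm("NE2", "CD", "CG", "CB", 1.33, 116.4, "x3+180")),
  GLU = rbind(
    zm("CG", "CB", "CA", "N", 1.52, 114.1, "x1"),
    zm("CD", "CG", "CB", "CA", 1.52, 112.6, "x2"),
    zm("OE1", "CD", "CG", "CB", 1.25, 118.5, "x3"),
    zm("OE2", "CD", "CG", "CB", 1.25, 118.5, "x3+180")),
  GLY = NULL,
  HIS = rbind(
    zm("CG", "CB", "CA", "N", 1.50, 113.8, "x1"),
    zm("ND1", "CG", "CB", "CA", 1.38, 122.7, "x2"),
    zm("CD2", "CG", "CB", "CA", 1.36, 129.1, "x2+180"),
    zm("CE1", "ND1", "CG", "CB", 1.32, 109.3, "180"),
    zm("NE2", "CE1", "ND1", "CG", 1.32, 111.0, "0")),
  ILE = rbind(
    zm("CG1", "CB", "CA", "N", 1.53, 110.4, "x1"),
    zm("CG2", "CB", "CA", "N", 1.53, 110.5, "x1-122"),
    zm("CD1", "CG1", "CB", "CA", 1.52, 113.8, "180")),
  LEU = rbind(
    zm("CG", "CB", "CA", "N", 1.53, 116.3, "x1"),
    zm("CD1", "CG", "CB", "CA", 1.52, 110.7, "x2"),
    zm("CD2", "CG", "CB", "CA", 1.52, 110.7, "x2+122")),
  LYS = rbind(
    zm("CG", "CB", "CA", "N", 1.52, 114.1, "x1"),
    zm("CD", "CG", "CB", "CA", 1.52, 111.3, "x2"),
    zm("CE", "CD", "CG", "CB", 1.52, 111.3, "180"),
    zm("NZ", "CE", "CD", "CG", 1.47, 111.0, "180")),
  MET = rbind(
    zm("CG", "CB", "CA", "N", 1.52, 114.1, "x1"),
    zm("SD", "CG", "CB", "CA", 1.81, 112.7, "x2"),
    zm("CE", "SD", "CG", "CB", 1.79, 100.2, "180")),
  PHE = rbind(
    zm("CG", "CB", "CA", "N", 1.51, 113.8, "x1"),
    zm("CD1", "CG", "CB", "CA", 1.39, 120.8, "x2"),
    zm("CD2", "CG", "CB", "CA", 1.39, 120.8, "x2+180"),
    zm("CE1", "CD1", "CG", "CB", 1.39, 120.0, "180"),
    zm("CE2", "CD2", "CG", "CB", 1.39, 120.0, "180"),
    zm("CZ", "CE1", "CD1", "CG", 1.39, 120.0, "0")),
  PRO = rbind(
    zm("CG", "CB", "CA", "N", 1.50, 104.5, "x1"),
    zm("CD", "CG", "CB", "CA", 1.51, 105.5, "x2")),
  SER = zm("OG", "CB", "CA", "N", 1.42, 110.8, "x1"),
  THR = rbind(
    zm("OG1", "CB", "CA", "N", 1.43, 109.3, "x1"),
    zm("CG2", "CB", "CA", "N", 1.53, 110.5, "x1-120")),
  TRP = rbind(
    zm("CG", "CB", "CA", "N", 1.50, 113.8, "x1"),
    zm("CD1", "CG", "CB", "CA", 1.37, 126.9, "x2"),
    zm("CD2", "CG", "CB", "CA", 1.43, 126.6, "x2+180"),
    zm("NE1", "CD1", "CG", "CB", 1.38, 110.2, "180"),
    zm("CE2", "NE1", "CD1", "CG", 1.37, 108.9, "0"),
    zm("CZ2", "CE2", "NE1", "CD1", 1.40, 130.1, "180"),
    zm("CE3", "CD2", "CG", "CB", 1.40, 133.9, "0"),
    zm("CZ3", "CE3", "CD2", "CG", 1.39, 118.6, "180"),
    zm("CH2", "CZ2", "CE2", "CD2", 1.37, 117.5, "180")),
  TYR = rbind(
    zm("CG", "CB", "CA", "N", 1.51, 113.8, "x1"),
    zm("CD1", "CG", "CB", "CA", 1.39, 120.8, "x2"),
    zm("CD2", "CG", "CB", "CA", 1.39, 120.8, "x2+180"),
    zm("CE1", "CD1", "CG", "CB", 1.39, 120.0, "180"),
    zm("CE2", "CD2", "CG", "CB", 1.39, 120.0, "180"),
    zm("CZ", "CE1", "CD1", "CG", 1.39, 120.0, "0"),
    zm("OH", "CZ", "CE1", "CD1", 1.38, 120.0, "180")),
  VAL = rbind(
    zm("CG1", "CB", "CA", "N", 1.53, 110.5, "x1"),
    zm("CG2", "CB", "CA", "N", 1.53, 110.5, "x1+122"))
)

## ring-closure bonds not captured by the z-matrix parent links
.RING_CLOSURES <- list(
  HIS = rbind(c("NE2", "CD2")),
  PHE = rbind(c("CZ", "CE2")),
  TYR = rbind(c("CZ", "CE2")),
  TRP = rbind(c("CE2", "CD2"), c("CH2", "CZ3")),
  PRO = rbind(c("CD", "N"))
)

## default chi angles (degrees) for the canonical conformer of each type
.DEFAULT_CHI <- list(
  ALA = numeric(0), GLY = numeric(0),
  ARG = c(x1 = 300, x2 = 180, x3 = 180, x4 = 180),
  ASN = c(x1 = 300, x2 = 0), ASP = c(x1 = 300, x2 = 0),
  CYS = c(x1 = 300), CYX = c(x1 = 300),
  GLN = c(x1 = 300, x2 = 180, x3 = 0), GLU = c(x1 = 300, x2 = 180, x3 = 0),
  HIS = c(x1 = 300, x2 = 90), ILE = c(x1 = 300), LEU = c(x1 = 300, x2 = 180),
  LYS = c(x1 = 300, x2 = 180), MET = c(x1 = 300, x2 = 180),
  PHE = c(x1 = 300, x2 = 90), PRO = c(x1 = 30, x2 = 325),
  SER = c(x1 = 300), THR = c(x1 = 300),
  TRP = c(x1 = 300, x2 = 90), TYR = c(x1 = 300, x2 = 90),
  VAL = c(x1 = 180)
)

## chi angle atom definitions (chi1 = N-CA-CB-G, etc.)
.CHI_ATOMS <- list(
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD")),
  ASN = list(c("N", "CA", "CB", "CG")),
  ASP = list(c("N", "CA", "CB", "CG")),
  CYS = list(c("N", "CA", "CB", "SG")),
  CYX = list(c("N", "CA", "CB", "SG")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD")),
  HIS = list(c("N", "CA", "CB", "CG")),
  ILE = list(c("N", "CA", "CB", "CG1")),
  LEU = list(c("N", "CA", "CB", "CG")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD")),
  MET = list(c("N", "CA", "CB", "CG")),
  PHE = list(c("N", "CA", "CB", "CG")),
  PRO = list(c("N", "CA", "CB", "CG")),
  SER = list(c("N", "CA", "CB", "OG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  TRP = list(c("N", "CA", "CB", "CG")),
  TYR = list(c("N", "CA", "CB", "CG")),
  VAL = list(c("N", "CA", "CB", "CG1"))
)

hp <- function(heavy, mode, hnames, r = 1.09) {
  data.frame(heavy = heavy, mode = mode,
             hnames = paste(hnames, collapse = ","), r = r,
             stringsAsFactors = FALSE)
}

## Sidechain hydrogen placement specs. Modes:
##  complete  - 1 H completing the valence against >=2 heavy neighbors
##              (tetrahedral CH or planar ring/amide H)
##  methylene - 2 H on sp3 C with 2 heavy neighbors
##  methyl    - 3 H, staggered about the single heavy bond (also NH3+)
##  nh2       - 2 planar H on sp2 N with one heavy neighbor
##  polar_rot - 1 rotatable H on O/S, placed anti to the parent dihedral
.SIDECHAIN_H <- list(
  ALA = hp("CB", "methyl", c("HB1", "HB2", "HB3")),
  ARG = rbind(hp("CB", "methylene", c("HB2", "HB3")),
              hp("CG", "methylene", c("HG2", "HG3")),
              hp("CD", "methylene", c("HD2", "HD3")),
              hp("NE", "complete", "HE", 1.01),
              hp("NH1", "nh2", c("HH11", "HH12"), 1.01),
              hp("NH2", "nh2", c("HH21", "HH22"), 1.01)),
  ASN = rbind(hp("CB", "methylene", c("HB2", "HB3")),
              hp("ND2", "nh2", c("HD21", "HD22"), 1.01)),
  ASP = hp("CB", "methylene", c("HB2", "HB3")),
  CYS = rbind(hp("CB", "methylene", c("HB2", "HB3")),
              hp("SG", "polar_rot", "HG", 1.34)),
  CYX = hp("CB", "methylene", c("HB2", "HB3")),
  GLN = rbind(hp("CB", "methylene", c("HB2", "HB3")),
              hp("CG", "methylene", c("HG2", "HG3")),
              hp("NE2", "nh2", c("HE21", "HE22"), 1.01)),
  GLU = rbind(hp("CB", "methylene", c("HB2", "HB3")),
              hp("CG", "methylene", c("HG2", "HG3"))),
  GLY = NULL,
  HIS = rbind(hp("CB", "methylene", c("HB2", "HB3")),
              hp("CD2", "complete", "HD2"),
              hp("CE1", "complete", "HE1"),
              hp("NE2", "complete", "HE2", 1.01)),
  ILE = rbind(hp("CB", "complete", "HB"),
              hp("CG1", "methylene", c("HG12", "HG13")),
              hp("CG2", "methyl", c("HG21", "HG22", "HG23")),
              hp("CD1", "methyl", c("HD11", "HD12", "HD13"))),
  LEU = rbind(hp("CB", "methylene", c("HB2", "HB3")),
              hp("CG", "complete", "HG"),
              hp("CD1", "methyl", c("HD11", "HD12", "HD13")),
              hp("CD2", "methyl", c("HD21", "HD22", "HD23"))),
  LYS = rbind(hp("CB", "methylene", c("HB2", "HB3")),
              hp("CG", "methylene", c("HG2", "HG3")),
              hp("CD", "methylene", c("HD2", "HD3")),
              hp("CE", "methylene", c("HE2", "HE3")),
              hp("NZ", "methyl", c("HZ1", "HZ2", "HZ3"), 1.01)),
  MET = rbind(hp("CB", "methylene", c("HB2", "HB3")),
              hp("CG", "methylene", c("HG2", "HG3")),
              hp("CE", "methyl", c("HE1", "HE2", "HE3"))),
  PHE = rbind(hp("CB", "methylene", c("HB2", "HB3")),
              hp("CD1", "complete", "HD1"), hp("CD2", "complete", "HD2"),
              hp("CE1", "complete", "HE1"), hp("CE2", "complete", "HE2"),
              hp("CZ", "complete", "HZ")),
  PRO = rbind(hp("CB", "methylene", c("HB2", "HB3")),
              hp("CG", "methylene", c("HG2", "HG3")),
              hp("CD", "methylene", c("HD2", "HD3"))),
  SER = rbind(hp("CB", "methylene", c("HB2", "HB3")),
              hp("OG", "polar_rot", "HG", 0.96)),
  THR = rbind(hp("CB", "complete", "HB"),
              hp("OG1", "polar_rot", "HG1", 0.96),
              hp("CG2", "methyl", c("HG21", "HG22", "HG23"))),
  TRP = rbind(hp("CB", "methylene", c("HB2", "HB3")),
              hp("CD1", "complete", "HD1"),
              hp("NE1", "complete", "HE1", 1.01),
              hp("CE3", "complete", "HE3"), hp("CZ2", "complete", "HZ2"),
              hp("CZ3", "complete", "HZ3"), hp("CH2", "complete", "HH2")),
  TYR = rbind(hp("CB", "methylene", c("HB2", "HB3")),
              hp("CD1", "complete", "HD1"), hp("CD2", "complete", "HD2"),
              hp("CE1", "complete", "HE1"), hp("CE2", "complete", "HE2"),
              hp("OH", "polar_rot", "HH", 0.96)),
  VAL = rbind(hp("CB", "complete", "HB"),
              hp("CG1", "methyl", c("HG11", "HG12", "HG13")),
              hp("CG2", "methyl", c("HG21", "HG22", "HG23")))
)

## evaluate a z-matrix dihedral expression against chi values
evalDih <- function(expr, chi) {
  env <- as.list(chi)
  as.numeric(eval(parse(text = expr), envir = env))
}

#' Intra-residue heavy-atom bond list for a residue type
#'
#' Derived from the internal-coordinate template (each atom bonds its
#' distance reference) plus backbone bonds and ring closures.
#'
#' @param type three-letter residue type.
#' @return 2-column character matrix of bonded atom-name pairs.
#' @export
residueBonds <- function(type) {
  b <- rbind(c("N", "CA"), c("CA", "C"), c("C", "O"))
  if (!type %in% c("GLY")) b <- rbind(b, c("CA", "CB"))
  z <- .SIDECHAIN_ZMAT[[type]]
  if (!is.null(z)) b <- rbind(b, cbind(z$name, z$dref))
  rc <- .RING_CLOSURES[[type]]
  if (!is.null(rc)) b <- rbind(b, rc)
  b
}

## Build one residue's ideal heavy-atom coordinates given backbone stubs.
## Returns a named list of length-3 coordinate vectors including the inputs.
buildSidechain <- function(type, N, CA, C, chi = NULL) {
  if (!type %in% .AA_TYPES) stop("unknown residue type: ", type)
  pos <- list(N = N, CA = CA, C = C)
  if (type != "GLY") {
    ## CB placed to give L-chirality: det(N-CA, C-CA, CB-CA) > 0
    cb <- placeAtom(CA, N, C, 1.53, 110.4, 122.5)
    dtm <- det(rbind(N - CA, C - CA, cb - CA))
    if (dtm < 0) cb <- placeAtom(CA, N, C, 1.53, 110.4, -122.5)
    pos$CB <- cb
  }
  zmx <- .SIDECHAIN_ZMAT[[type]]
  if (!is.null(zmx)) {
    ch <- .DEFAULT_CHI[[type]]
    if (!is.null(chi) && length(chi)) ch[names(chi)] <- chi
    for (i in seq_len(nrow(zmx))) {
      row <- zmx[i, ]
      pos[[row$name]] <- placeAtom(pos[[row$dref]], pos[[row$aref]],
                                   pos[[row$tref]], row$r, row$theta,
                                   evalDih(row$dih, ch))
    }
  }
  pos
}

## Max heavy-atom distance from CA for the fully extended conformer; cached.
.extentCache <- new.env(parent = emptyenv())

residueExtent <- function(type) {
  if (!is.null(.extentCache[[type]])) return(.extentCache[[type]])
  ## canonical backbone stub (ideal geometry, arbitrary placement)
  N <- c(-0.525, 1.363, 0); CA <- c(0, 0, 0); C <- c(1.526, 0, 0)
  ch <- .DEFAULT_CHI[[type]]
  if (length(ch)) ch[] <- 180  # extended sidechain = maximal reach
  pos <- buildSidechain(type, N, CA, C, chi = ch)
  d <- max(vapply(pos, function(p) vnorm(p - CA), numeric(1)))
  ext <- d + 1.5  # margin for bond-angle variation and hydrogens
  .extentCache[[type]] <- ext
  ext
}
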