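## hint_engine: hydropathic atom constants, solvent accessibility scaling,
## pairwise scoring into the four interaction classes, and ionization-state
## selection.

.POLAR_CLASSES <- c("hydrophobic", "acid", "base", "amphoteric")

## Bondi van der Waals radii (Angstrom) by element
.BONDI <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

.bondiRadius <- function(element) {
  r <- .BONDI[toupper(substr(element, 1L, 1L))]
  r[is.na(r)] <- 1.70
  unname(r)
}

## hydrogen constants derived from the parent heavy element
.H_CONSTANTS <- list(C = c(a = 0.20, class = "hydrophobic"),
                     N = c(a = -0.50, class = "acid"),
                     O = c(a = -0.60, class = "acid"),
                     S = c(a = -0.30, class = "acid"))

#' Load the hydropathic atom-constant table
#'
#' The shipped table follows Hansch-Leo sign conventions: aliphatic/aromatic
#' carbons positive (hydrophobic), N/O/S and formal-charge-bearing atoms
#' negative (polar), with magnitudes acting as calibration constants. The
#' wildcard residue type \code{*} supplies backbone entries for all amino
#' acids. Hydrogen constants are derived at assignment time from the parent
#' heavy atom's element and are not tabulated.
#'
#' @param path optional path to an alternative TSV
#'   (columns res_type, atom_name, a, polar_class).
#' @return data.frame of atom constants.
#' @export
hintParameters <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hint_atom_constants.tsv",
                        package = "hydromaps", mustWork = TRUE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("res_type", "atom_name", "a", "polar_class") %in% names(d)))
  bad <- setdiff(unique(d$polar_class), .POLAR_CLASSES)
  if (length(bad)) stop("unknown polar classes in table: ",
                        paste(bad, collapse = ", "))
  d
}

#' Annotate atoms with hydropathic constants and polar classes
#'
#' Every scored atom receives the hydrophobic atom constant \code{a}
#' (sign-carrying, atom-level logP) and a polar class. Heavy atoms are looked
#' up in the parameter table (residue-specific entries first, then the
#' backbone wildcard); hydrogens inherit from the bonded heavy atom's
#' element. Atoms with no entry raise an error listing their names.
#'
#' @param structure a \linkS4class{HydroStructure}.
#' @param params parameter table from \code{\link{hintParameters}}.
#' @return the structure with atom columns \code{a} and \code{polar_class}.
#' @export
assignAtomConstants <- function(structure, params = hintParameters()) {
  atoms <- structure@atoms
  n <- nrow(atoms)
  a <- rep(NA_real_, n)
  cls <- rep(NA_character_, n)
  isH <- atoms$element == "H"

  keyed <- paste(params$res_type, params$atom_name)
  idx <- match(paste(atoms$resname, atoms$name), keyed)
  wib <- match(paste("*", atoms$name), keyed)
  use_wild <- is.na(idx) & !is.na(wib) & atoms$resname %in% .AA_TYPES
  idx[use_wild] <- wib[use_wild]
  ok <- !is.na(idx) & !isH
  a[ok] <- params$a[idx[ok]]
  cls[ok] <- params$polar_class[idx[ok]]

  ## hydrogens: nearest heavy atom in the same residue is the parent
  if (any(isH)) {
    xyz <- atomCoords(atoms)
    for (i in which(isH)) {
      same <- which(atoms$residue_key == atoms$residue_key[i] & !isH)
      if (!length(same)) next
      d2 <- (xyz[same, 1L] - xyz[i, 1L])^2 + (xyz[same, 2L] - xyz[i, 2L])^2 +
        (xyz[same, 3L] - xyz[i, 3L])^2
      parent <- same[which.min(d2)]
      hc <- .H_CONSTANTS[[toupper(substr(atoms$element[parent], 1L, 1L))]]
      if (is.null(hc)) hc <- .H_CONSTANTS$C
      a[i] <- as.numeric(hc["a"])
      cls[i] <- as.character(hc["class"])
    }
  }
  miss <- is.na(a)
  if (any(miss))
    stop("no atom-constant entry for: ",
         paste(unique(paste(atoms$resname[miss], atoms$name[miss])),
               collapse = ", "))
  atoms$a <- a
  atoms$polar_class <- cls
  newHydroStructure(atoms, structure@residues)
}

## Shrake-Rupley exposed-fraction core. coords: n x 3; radii: length n.
.shrakeRupley <- function(coords, radii, probe = 1.4, n_points = 960L) {
  n <- nrow(coords)
  if (!n) return(numeric(0))
  pts <- spherePoints(n_points)
  rs <- radii + probe
  maxr <- max(rs)
  ## cell list for neighbor search
  cell <- ceiling(2 * maxr + 0.01)
  ci <- floor(coords / cell)
  ckey <- paste(ci[, 1L], ci[, 2L], ci[, 3L])
  cmap <- split(seq_len(n), ckey)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  S <- numeric(n)
  for (i in seq_len(n)) {
    keys <- paste(ci[i, 1L] + offs[, 1L], ci[i, 2L] + offs[, 2L],
                  ci[i, 3L] + offs[, 3L])
    cand <- unlist(cmap[keys], use.names = FALSE)
    cand <- cand[cand != i]
    if (length(cand)) {
      dx <- coords[cand, 1L] - coords[i, 1L]
      dy <- coords[cand, 2L] - coords[i, 2L]
      dz <- coords[cand, 3L] - coords[i, 3L]
      d2 <- dx * dx + dy * dy + dz * dz
      nb <- cand[d2 < (rs[i] + rs[cand])^2]
    } else nb <- integer(0)
    if (!length(nb)) { S[i] <- 1; next }
    sp <- pts * rs[i]
    sp <- sweep(sp, 2L, coords[i, ], `+`)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      e <- which(exposed)
      dd <- (sp[e, 1L] - coords[j, 1L])^2 + (sp[e, 2L] - coords[j, 2L])^2 +
        (sp[e, 3L] - coords[j, 3L])^2
      exposed[e[dd < rs[j]^2]] <- FALSE
    }
    S[i] <- sum(exposed) / n_points
  }
  S
}

#' Per-atom solvent accessibility scale factors
#'
#' Shrake-Rupley fraction of each atom's solvent-accessible sphere (Bondi
#' radius + probe) not occluded by neighbors; the HINT \code{S_i} factor.
#'
#' @param structure a \linkS4class{HydroStructure} (hydrogens placed).
#' @param probe probe radius (Angstrom), default 1.4.
#' @param n_points number of deterministic sphere sample points.
#' @return the structure with an atom column \code{S} in [0, 1].
#' @export
atomAccessibility <- function(structure, probe = 1.4, n_points = 960L) {
  atoms <- structure@atoms
  S <- .shrakeRupley(atomCoords(atoms), .bondiRadius(atoms$element),
                     probe = probe, n_points = n_points)
  atoms$S <- S
  newHydroStructure(atoms, structure@residues)
}

## Vectorized four-class pair scoring. Returns list(value, class).
## b = a1 S1 a2 S2 T exp(-r); T = -1 for like polar classes (acid-acid,
## base-base), +1 otherwise; hydrophobic x polar is forced negative (Hyd-).
.scorePairsVec <- function(a1, S1, c1, a2, S2, c2, r) {
  base <- a1 * S1 * a2 * S2 * exp(-r)
  h1 <- c1 == "hydrophobic"
  h2 <- c2 == "hydrophobic"
  cls <- character(length(base))
  val <- numeric(length(base))
  bb <- h1 & h2
  cls[bb] <- "hydPlus"; val[bb] <- abs(base[bb])
  mx <- xor(h1, h2)
  cls[mx] <- "hydMinus"; val[mx] <- -abs(base[mx])
  pp <- !h1 & !h2
  like <- pp & ((c1 == "acid" & c2 == "acid") | (c1 == "base" & c2 == "base"))
  unlike <- pp & !like
  cls[like] <- "polMinus"; val[like] <- -abs(base[like])
  cls[unlike] <- "polPlus"; val[unlike] <- abs(base[unlike])
  list(value = val, class = cls)
}

#' Score one atom pair
#'
#' @param atom_i,atom_j one-row data.frames (or named lists) with x, y, z,
#'   a, S, polar_class (and optionally is_lipid).
#' @return list: value, interaction_class, r, midpoint, partner_is_lipid.
#' @export
pairScore <- function(atom_i, atom_j) {
  gi <- function(a, f) if (is.data.frame(a)) a[[f]][1L] else a[[f]]
  p1 <- c(gi(atom_i, "x"), gi(atom_i, "y"), gi(atom_i, "z"))
  p2 <- c(gi(atom_j, "x"), gi(atom_j, "y"), gi(atom_j, "z"))
  r <- vnorm(p1 - p2)
  sc <- .scorePairsVec(gi(atom_i, "a"), gi(atom_i, "S"),
                       gi(atom_i, "polar_class"),
                       gi(atom_j, "a"), gi(atom_j, "S"),
                       gi(atom_j, "polar_class"), r)
  lip <- isTRUE(gi(atom_i, "is_lipid")) || isTRUE(gi(atom_j, "is_lipid"))
  list(value = sc$value, interaction_class = sc$class, r = r,
       midpoint = (p1 + p2) / 2, partner_is_lipid = lip)
}

.BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT", "H", "H1", "H2", "H3",
                     "HA", "HA2", "HA3")

## indices of the atoms of `key` that act as the mapped moiety
.sidechainIdx <- function(atoms, key, type) {
  own <- atoms$residue_key == key
  if (identical(type, "GLY")) which(own)
  else which(own & !(atoms$name %in% .BACKBONE_NAMES))
}

#' All scored partner pairs of one residue
#'
#' Pairs the residue's sidechain atoms (whole residue for GLY) against all
#' atoms of other residues, including waters; lipid atoms participate in
#' every mode except \code{mN} (lipid interactions switched off). Pairs
#' beyond the distance cutoff are omitted; intra-residue pairs never appear.
#'
#' @param residue_key residue key.
#' @param structure annotated structure (a, polar_class, S columns present).
#' @param mode one of soluble, mS, mC, mL, mN.
#' @param cutoff interatomic distance cutoff (Angstrom), default 8.
#' @return data.frame: value, class, r, mx, my, mz, partner_is_lipid.
#' @export
residuePartnerPairs <- function(residue_key, structure,
                                mode = c("soluble", "mS", "mC", "mL", "mN"),
                                cutoff = 8.0) {
  mode <- match.arg(mode)
  atoms <- structure@atoms
  if (is.null(atoms$a) || is.null(atoms$S))
    stop("structure must be annotated (assignAtomConstants, atomAccessibility)")
  type <- structure@residues$type[match(residue_key, structure@residues$key)]
  si <- .sidechainIdx(atoms, residue_key, type)
  pj <- which(atoms$residue_key != residue_key)
  if (mode == "mN") pj <- pj[!atoms$is_lipid[pj]]
  if (!length(si) || !length(pj)) return(.emptyPairs())
  xyz <- atomCoords(atoms)
  out <- vector("list", length(si))
  for (k in seq_along(si)) {
    i <- si[k]
    dx <- xyz[pj, 1L] - xyz[i, 1L]
    dy <- xyz[pj, 2L] - xyz[i, 2L]
    dz <- xyz[pj, 3L] - xyz[i, 3L]
    d2 <- dx * dx + dy * dy + dz * dz
    sel <- which(d2 <= cutoff^2)
    if (!length(sel)) next
    j <- pj[sel]
    r <- sqrt(d2[sel])
    sc <- .scorePairsVec(atoms$a[i], atoms$S[i], atoms$polar_class[i],
                         atoms$a[j], atoms$S[j], atoms$polar_class[j], r)
    out[[k]] <- data.frame(
      value = sc$value, class = sc$class, r = r,
      mx = (xyz[i, 1L] + xyz[j, 1L]) / 2,
      my = (xyz[i, 2L] + xyz[j, 2L]) / 2,
      mz = (xyz[i, 3L] + xyz[j, 3L]) / 2,
      partner_is_lipid = atoms$is_lipid[j], stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(.emptyPairs())
  do.call(rbind, out)
}

.emptyPairs <- function() {
  data.frame(value = numeric(0), class = character(0), r = numeric(0),
             mx = numeric(0), my = numeric(0), mz = numeric(0),
             partner_is_lipid = logical(0), stringsAsFactors = FALSE)
}

#' Lipid share of a residue's interaction score
#'
#' Ratio of the absolute score sum over lipid-partner pairs to the absolute
#' score sum over all pairs (0 when there are no pairs). Ratios above 0.1
#' mark a residue's accessible surface as lipid-accessible (LASA).
#'
#' @param pair_scores data.frame from \code{\link{residuePartnerPairs}}.
#' @return ratio in [0, 1].
#' @export
lipidScoreRatio <- function(pair_scores) {
  tot <- sum(abs(pair_scores$value))
  if (tot == 0) return(0)
  sum(abs(pair_scores$value[pair_scores$partner_is_lipid])) / tot
}

#' Ionization model constants
#'
#' pH50 values (the pH splitting each ionizable residue population evenly)
#' for the soluble and membrane datasets, nominal model-compound pKa values,
#' and the score-per-kcal conversion.
#'
#' @param dataset "soluble" or "membrane" (selects the pH50 set).
#' @return list: pH50 (named vector), pKa (named vector), kcal_to_score,
#'   temperature.
#' @export
ionizationModel <- function(dataset = c("soluble", "membrane")) {
  dataset <- match.arg(dataset)
  pH50 <- if (dataset == "soluble") {
    c(ASP = 3.3449, CYS = 9.5814, GLU = 4.2240, HIS = 5.1743)
  } else {
    c(ASP = 3.9331, CYS = 9.4506, GLU = 4.2021, HIS = 5.4206)
  }
  list(pH50 = pH50,
       pKa = c(ASP = 3.71, GLU = 4.15, CYS = 8.55, HIS = 6.04),
       kcal_to_score = 515, temperature = 298.15)
}

## gas constant, kcal / (mol K)
.RGAS <- 1.98720425864083e-3

## raw interaction score of a (possibly modified) residue atom table against
## the rest of the structure
.variantRawScore <- function(vatoms, structure, residue_key, type,
                             include_lipids = TRUE, cutoff = 8.0) {
  atoms <- structure@atoms
  pj <- which(atoms$residue_key != residue_key)
  if (!include_lipids) pj <- pj[!atoms$is_lipid[pj]]
  if (!nrow(vatoms) || !length(pj)) return(0)
  keep <- if (identical(type, "GLY")) rep(TRUE, nrow(vatoms))
          else !(vatoms$name %in% .BACKBONE_NAMES)
  va <- vatoms[keep, , drop = FALSE]
  tot <- 0
  for (i in seq_len(nrow(va))) {
    dx <- atoms$x[pj] - va$x[i]; dy <- atoms$y[pj] - va$y[i]
    dz <- atoms$z[pj] - va$z[i]
    d2 <- dx * dx + dy * dy + dz * dz
    sel <- which(d2 <= cutoff^2)
    if (!length(sel)) next
    j <- pj[sel]
    sc <- .scorePairsVec(va$a[i], va$S[i], va$polar_class[i],
                         atoms$a[j], atoms$S[j], atoms$polar_class[j],
                         sqrt(d2[sel]))
    tot <- tot + sum(sc$value)
  }
  tot
}

## helpers used by the variant builders -------------------------------------

.vset <- function(atoms, name, a = NULL, cls = NULL) {
  i <- match(name, atoms$name)
  if (!is.na(i)) {
    if (!is.null(a)) atoms$a[i] <- a
    if (!is.null(cls)) atoms$polar_class[i] <- cls
  }
  atoms
}

.vdrop <- function(atoms, name) atoms[!(atoms$name %in% name), , drop = FALSE]

.vaddH <- function(atoms, hname, at, par, gp, r, theta, dih, a, cls) {
  pos <- function(nm) { i <- match(nm, atoms$name)
    if (is.na(i)) return(NULL); c(atoms$x[i], atoms$y[i], atoms$z[i]) }
  p <- pos(at); q <- pos(par); g <- pos(gp)
  if (is.null(p) || is.null(q) || is.null(g)) return(atoms)
  h <- placeAtom(p, q, g, r, theta, dih)
  i <- match(at, atoms$name)
  row <- atoms[i, , drop = FALSE]
  row$name <- hname; row$element <- "H"
  row$x <- h[1L]; row$y <- h[2L]; row$z <- h[3L]
  row$a <- a; row$polar_class <- cls
  row$serial <- max(atoms$serial, na.rm = TRUE) + 1L
  rbind(atoms, row)
}

## rotate named atoms 180 degrees about the axis through `pivot` along
## (pivot - base); used for the HIS ring flip
.vflip <- function(atoms, names, pivot, base) {
  ip <- match(pivot, atoms$name); ib <- match(base, atoms$name)
  if (is.na(ip) || is.na(ib)) return(atoms)
  p0 <- c(atoms$x[ip], atoms$y[ip], atoms$z[ip])
  ax <- c(atoms$x[ip] - atoms$x[ib], atoms$y[ip] - atoms$y[ib],
          atoms$z[ip] - atoms$z[ib])
  R <- axisRotation(ax, 180)
  for (nm in names) {
    i <- match(nm, atoms$name)
    if (is.na(i)) next
    v <- c(atoms$x[i], atoms$y[i], atoms$z[i]) - p0
    v <- as.numeric(R %*% v) + p0
    atoms$x[i] <- v[1L]; atoms$y[i] <- v[2L]; atoms$z[i] <- v[3L]
  }
  atoms
}

## enumerate ionization variants for one residue; each entry:
## list(name, state ("protonated"/"deprotonated"), atoms, scan (logical))
.ionizationVariants <- function(type, ra, xh_step = 30) {
  sAvg <- function(nm) { i <- match(nm, ra$name)
    if (is.na(i) || is.null(ra$S)) 0.5 else ra$S[i] }
  scan <- seq(0, 360 - xh_step, by = xh_step)
  vars <- list()
  if (type %in% c("ASP", "GLU")) {
    o1 <- if (type == "ASP") "OD1" else "OE1"
    o2 <- if (type == "ASP") "OD2" else "OE2"
    cc <- if (type == "ASP") "CG" else "CD"
    cp <- if (type == "ASP") "CB" else "CG"
    hn <- if (type == "ASP") "HD2" else "HE2"
    dep <- .vdrop(ra, hn)
    dep <- .vset(dep, o1, a = -1.8, cls = "base")
    dep <- .vset(dep, o2, a = -1.8, cls = "base")
    vars[[length(vars) + 1L]] <- list(name = "deprotonated",
                                      state = "deprotonated", atoms = dep)
    for (d in scan) {
      pr <- .vdrop(ra, hn)
      pr <- .vset(pr, o1, a = -1.0, cls = "base")
      pr <- .vset(pr, o2, a = -0.8, cls = "amphoteric")
      pr <- .vaddH(pr, hn, o2, cc, cp, 0.96, 108.5, d, -0.6, "acid")
      i <- match(hn, pr$name)
      if (!is.na(i) && !is.null(pr$S)) pr$S[i] <- sAvg(o2)
      vars[[length(vars) + 1L]] <- list(name = sprintf("protonated.%d", d),
                                        state = "protonated", atoms = pr)
    }
  } else if (type == "CYS") {
    dep <- .vdrop(ra, "HG")
    dep <- .vset(dep, "SG", a = -1.5, cls = "base")
    vars[[length(vars) + 1L]] <- list(name = "deprotonated",
                                      state = "deprotonated", atoms = dep)
    for (d in scan) {
      pr <- .vdrop(ra, "HG")
      pr <- .vset(pr, "SG", a = -0.4, cls = "amphoteric")
      pr <- .vaddH(pr, "HG", "SG", "CB", "CA", 1.34, 96, d, -0.3, "acid")
      i <- match("HG", pr$name)
      if (!is.na(i) && !is.null(pr$S)) pr$S[i] <- sAvg("SG")
      vars[[length(vars) + 1L]] <- list(name = sprintf("protonated.%d", d),
                                        state = "protonated", atoms = pr)
    }
  } else if (type == "HIS") {
    ring <- c("ND1", "CD2", "CE1", "NE2", "HD1", "HD2", "HE1", "HE2")
    geoms <- list(asbuilt = ra, flipped = .vflip(ra, ring, "CG", "CB"))
    for (g in names(geoms)) {
      base <- geoms[[g]]
      ## N-epsilon tautomer (neutral, HE2 present; treated deprotonated
      ## relative to the cation)
      eps <- .vdrop(base, "HD1")
      eps <- .vset(eps, "ND1", a = -1.2, cls = "base")
      eps <- .vset(eps, "NE2", a = -1.0, cls = "acid")
      eps <- .ensureRingH(eps, "HE2", "NE2")
      vars[[length(vars) + 1L]] <- list(name = paste0("tautNE2.", g),
                                        state = "deprotonated", atoms = eps)
      del <- .vdrop(base, "HE2")
      del <- .vset(del, "ND1", a = -1.0, cls = "acid")
      del <- .vset(del, "NE2", a = -1.2, cls = "base")
      del <- .ensureRingH(del, "HD1", "ND1")
      vars[[length(vars) + 1L]] <- list(name = paste0("tautND1.", g),
                                        state = "deprotonated", atoms = del)
      cat_ <- .vset(base, "ND1", a = -1.5, cls = "acid")
      cat_ <- .vset(cat_, "NE2", a = -1.5, cls = "acid")
      cat_ <- .ensureRingH(cat_, "HD1", "ND1")
      cat_ <- .ensureRingH(cat_, "HE2", "NE2")
      vars[[length(vars) + 1L]] <- list(name = paste0("cation.", g),
                                        state = "protonated", atoms = cat_)
    }
  } else {
    stop("ionization variants defined only for ASP, CYS, GLU, HIS")
  }
  vars
}

## add a ring N-H completing the two ring neighbors, if missing
.ensureRingH <- function(atoms, hname, nname) {
  if (hname %in% atoms$name) return(atoms)
  nbs <- list(ND1 = c("CG", "CE1"), NE2 = c("CE1", "CD2"))[[nname]]
  pos <- function(nm) { i <- match(nm, atoms$name)
    if (is.na(i)) return(NULL); c(atoms$x[i], atoms$y[i], atoms$z[i]) }
  p <- pos(nname); n1 <- pos(nbs[1L]); n2 <- pos(nbs[2L])
  if (is.null(p) || is.null(n1) || is.null(n2)) return(atoms)
  u <- unitv(unitv(n1 - p) + unitv(n2 - p))
  h <- p - 1.01 * u
  i <- match(nname, atoms$name)
  row <- atoms[i, , drop = FALSE]
  row$name <- hname; row$element <- "H"
  row$x <- h[1L]; row$y <- h[2L]; row$z <- h[3L]
  row$a <- -0.5; row$polar_class <- "acid"
  row$serial <- max(atoms$serial, na.rm = TRUE) + 1L
  rbind(atoms, row)
}

#' Select the most likely ionization state of a residue at a given pH
#'
#' Enumerates protonation variants (protonated -XH hydrogens scanned in
#' 30-degree steps for the best raw score; HIS as two neutral tautomers and
#' the cation, each with the ring as built and flipped 180 degrees), scores
#' each against the environment, applies the energetic pH correction
#' \code{raw - k * 2.303 * R * T * max(0, sigma * (pH - pKa))} (sigma = +1
#' protonated, -1 deprotonated) and returns the argmax; ties go to the
#' deprotonated state.
#'
#' @param structure annotated \linkS4class{HydroStructure}.
#' @param residue_key key of an ASP, CYS, GLU or HIS residue.
#' @param pH the evaluation pH (e.g. the dataset's pH50).
#' @param model constants from \code{\link{ionizationModel}}.
#' @param include_lipids include lipid partners in the raw score.
#' @param cutoff pair cutoff (Angstrom).
#' @return list: state ("protonated"/"deprotonated"), variant (name),
#'   corrected (best corrected score), scores (per-variant data.frame),
#'   atoms (the chosen variant's residue atom table).
#' @export
selectIonizationState <- function(structure, residue_key, pH,
                                  model = ionizationModel("soluble"),
                                  include_lipids = TRUE, cutoff = 8.0) {
  res <- structure@residues
  type <- res$type[match(residue_key, res$key)]
  if (!type %in% c("ASP", "CYS", "GLU", "HIS"))
    stop("ionization-state selection applies to ASP, CYS, GLU, HIS only")
  ra <- structure@atoms[structure@atoms$residue_key == residue_key, ,
                        drop = FALSE]
  vars <- .ionizationVariants(type, ra)
  pKa <- model$pKa[type]
  kRT <- model$kcal_to_score * 2.303 * .RGAS * model$temperature
  raw <- vapply(vars, function(v)
    .variantRawScore(v$atoms, structure, residue_key, type,
                     include_lipids = include_lipids, cutoff = cutoff),
    numeric(1))
  sigma <- ifelse(vapply(vars, `[[`, character(1), "state") == "protonated",
                  1, -1)
  corrected <- raw - kRT * pmax(0, sigma * (pH - pKa))
  ## best -XH scan per state family is implied by taking the overall argmax;
  ## ties resolved toward deprotonated
  ord <- order(-corrected, sigma)  # sigma -1 (deprotonated) first on ties
  best <- ord[1L]
  list(state = vars[[best]]$state, variant = vars[[best]]$name,
       corrected = corrected[best],
       scores = data.frame(
         variant = vapply(vars, `[[`, character(1), "name"),
         state = vapply(vars, `[[`, character(1), "state"),
         raw = raw, corrected = corrected, stringsAsFactors = FALSE),
       atoms = vars[[best]]$atoms)
}

#' Apply ionization-state selection across a structure
#'
#' Runs \code{\link{selectIonizationState}} for every usable ASP, CYS, GLU
#' and HIS residue (CYX excluded) at the model's per-type pH50 and splices
#' the chosen variant's atoms into the structure.
#'
#' @param structure annotated \linkS4class{HydroStructure}.
#' @param model from \code{\link{ionizationModel}}; its pH50 values are the
#'   evaluation pH per type.
#' @param include_lipids include lipid partners in the raw scores.
#' @return list: structure (modified), states (data.frame key, type, state,
#'   variant).
#' @export
applyIonizationStates <- function(structure,
                                  model = ionizationModel("soluble"),
                                  include_lipids = TRUE) {
  res <- structure@residues
  targets <- res$key[res$type %in% c("ASP", "CYS", "GLU", "HIS") & res$usable]
  states <- NULL
  atoms <- structure@atoms
  for (key in targets) {
    type <- res$type[match(key, res$key)]
    sel <- selectIonizationState(structure, key, pH = model$pH50[type],
                                 model = model,
                                 include_lipids = include_lipids)
    ## splice variant atoms in place of the residue's atoms
    first <- match(key, atoms$residue_key)
    before <- atoms[seq_len(first - 1L), , drop = FALSE]
    after <- atoms[atoms$residue_key != key &
                     seq_len(nrow(atoms)) >= first, , drop = FALSE]
    atoms <- rbind(before, sel$atoms, after)
    structure <- newHydroStructure(atoms, res)
    states <- rbind(states, data.frame(key = key, type = type,
                                       state = sel$state,
                                       variant = sel$variant,
                                       stringsAsFactors = FALSE))
  }
  list(structure = structure, states = states)
}
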