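## structure_model: PDB ingestion, hydrogen placement, lipid trimming and
## membrane-environment classification.

.WATER_NAMES <- c("HOH", "WAT", "TIP3", "SOL", "H2O")
.DEFAULT_LIPID_NAMES <- "DPPC"

#' Read a structure from PDB text or a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), resolves alternate locations by
#' keeping the highest-occupancy conformer (ties broken in favour of altloc
#' "A"), flags lipid and water records, identifies disulfide-bridged
#' cysteines (renamed CYX), and flags terminal and unusable residues.
#' Residues missing any of N, CA, C are kept but marked unusable.
#'
#' @param pdb path to a PDB file, or a character vector of PDB text lines
#'   (anything containing a newline or not naming an existing file is treated
#'   as text).
#' @param lipid_names residue names treated as membrane lipids.
#' @param ss_cutoff S-S bond distance cutoff (Angstrom) for CYX detection.
#' @return A \linkS4class{HydroStructure}.
#' @export
readStructure <- function(pdb, lipid_names = .DEFAULT_LIPID_NAMES,
                          ss_cutoff = 2.5) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    lines <- readLines(pdb, warn = FALSE)
  } else {
    lines <- unlist(strsplit(pdb, "\n", fixed = TRUE), use.names = FALSE)
  }
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) {
    return(newHydroStructure(.emptyAtoms(), .emptyResidues()))
  }
  bad <- which(rec & nchar(lines) < 54)
  if (length(bad))
    stop(sprintf("malformed PDB record at line %d: '%s'", bad[1L],
                 substr(lines[bad[1L]], 1, 30)))
  for (i in which(rec)) {
    coords <- substring(lines[i], c(31, 39, 47), c(38, 46, 54))
    if (anyNA(suppressWarnings(as.numeric(coords))))
      stop(sprintf("malformed PDB coordinates at line %d", i))
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  invisible(utils::capture.output(
    p <- bio3d::read.pdb(tf, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)))
  a <- p$atom
  a$chain[is.na(a$chain)] <- " "
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  a$o[is.na(a$o)] <- 1
  a$b[is.na(a$b)] <- 0
  a$elesy[is.na(a$elesy) | !nzchar(a$elesy)] <-
    substr(gsub("[^A-Za-z].*", "", gsub("^[0-9]", "", a$elety[is.na(a$elesy) | !nzchar(a$elesy)])), 1, 1)
  key <- paste0(a$chain, ":", a$resno, a$insert)

  ## altloc resolution: per residue+atom-name keep highest occupancy,
  ## ties -> altloc "A" (then first record)
  if (any(nzchar(a$alt))) {
    id <- paste(key, a$elety)
    ord <- order(id, -a$o, a$alt != "A", seq_len(nrow(a)))
    a <- a[ord, , drop = FALSE]
    key <- key[ord]
    keep <- !duplicated(paste(key, a$elety))
    a <- a[keep, , drop = FALSE]
    key <- key[keep]
    ord2 <- order(a$eleno)
    a <- a[ord2, , drop = FALSE]
    key <- key[ord2]
  }

  atoms <- data.frame(
    serial = a$eleno, name = a$elety, element = toupper(a$elesy),
    resname = a$resid, chain = a$chain, resno = a$resno, insert = a$insert,
    x = a$x, y = a$y, z = a$z, o = a$o, b = a$b,
    is_lipid = a$resid %in% lipid_names,
    is_water = a$resid %in% .WATER_NAMES,
    residue_key = key, stringsAsFactors = FALSE)

  .finalizeStructure(atoms, ss_cutoff = ss_cutoff)
}

.emptyAtoms <- function() {
  data.frame(serial = integer(0), name = character(0), element = character(0),
             resname = character(0), chain = character(0), resno = integer(0),
             insert = character(0), x = numeric(0), y = numeric(0),
             z = numeric(0), o = numeric(0), b = numeric(0),
             is_lipid = logical(0), is_water = logical(0),
             residue_key = character(0), stringsAsFactors = FALSE)
}

.emptyResidues <- function() {
  data.frame(key = character(0), chain = character(0), resno = integer(0),
             insert = character(0), type = character(0),
             is_terminal = logical(0), usable = logical(0),
             reason = character(0), stringsAsFactors = FALSE)
}

## Build the residue table (type, terminal/usable flags) and detect CYX.
.finalizeStructure <- function(atoms, ss_cutoff = 2.5) {
  ukey <- unique(atoms$residue_key)
  first <- match(ukey, atoms$residue_key)
  residues <- data.frame(
    key = ukey, chain = atoms$chain[first], resno = atoms$resno[first],
    insert = atoms$insert[first], type = atoms$resname[first],
    is_terminal = FALSE, usable = TRUE, reason = "",
    stringsAsFactors = FALSE)

  ## CYX: CYS whose SG is within ss_cutoff of another CYS SG
  sg <- atoms[atoms$resname %in% c("CYS", "CYX") & atoms$name == "SG", ,
              drop = FALSE]
  if (nrow(sg) >= 2L) {
    xyz <- atomCoords(sg)
    d <- as.matrix(stats::dist(xyz))
    diag(d) <- Inf
    bridged <- sg$residue_key[apply(d <= ss_cutoff, 1L, any)]
    residues$type[residues$key %in% bridged] <- "CYX"
    atoms$resname[atoms$residue_key %in% bridged] <- "CYX"
  }

  isaa <- residues$type %in% .AA_TYPES
  ## terminal flags: first and last amino-acid residue of each chain
  for (ch in unique(residues$chain[isaa])) {
    idx <- which(isaa & residues$chain == ch)
    residues$is_terminal[idx[c(1L, length(idx))]] <- TRUE
  }
  ## usability: amino acids need a complete backbone
  for (i in which(isaa)) {
    nm <- atoms$name[atoms$residue_key == residues$key[i]]
    miss <- setdiff(c("N", "CA", "C"), nm)
    if (length(miss)) {
      residues$usable[i] <- FALSE
      residues$reason[i] <- paste("missing backbone atom(s):",
                                  paste(miss, collapse = ","))
    }
  }
  residues$usable[!isaa] <- FALSE
  residues$reason[!isaa] <- ifelse(residues$type[!isaa] %in% .WATER_NAMES,
                                   "water", "non-amino-acid")
  newHydroStructure(atoms, residues)
}

#' Remove lipids distant from the protein
#'
#' A lipid residue is retained iff the minimum distance from any of its atoms
#' to any protein (amino-acid) atom is at most \code{cutoff}; the boundary is
#' inclusive.
#'
#' @param structure a \linkS4class{HydroStructure}.
#' @param cutoff distance cutoff (Angstrom), default 6.
#' @return the trimmed structure.
#' @export
trimLipids <- function(structure, cutoff = 6.0) {
  stopifnot(cutoff > 0)
  atoms <- structure@atoms
  res <- structure@residues
  lipkeys <- unique(atoms$residue_key[atoms$is_lipid])
  if (!length(lipkeys)) return(structure)
  prot <- atomCoords(atoms[atoms$resname %in% .AA_TYPES, , drop = FALSE])
  if (!nrow(prot)) return(structure)
  keep <- vapply(lipkeys, function(k) {
    lx <- atomCoords(atoms[atoms$residue_key == k, , drop = FALSE])
    ## min atom-atom distance, done blockwise
    d2min <- Inf
    for (i in seq_len(nrow(lx))) {
      dd <- (prot[, 1L] - lx[i, 1L])^2 + (prot[, 2L] - lx[i, 2L])^2 +
        (prot[, 3L] - lx[i, 3L])^2
      d2min <- min(d2min, min(dd))
      if (d2min <= cutoff^2) return(TRUE)
    }
    sqrt(d2min) <= cutoff
  }, logical(1))
  drop <- lipkeys[!keep]
  if (length(drop)) {
    atoms <- atoms[!atoms$residue_key %in% drop, , drop = FALSE]
    res <- res[!res$key %in% drop, , drop = FALSE]
  }
  newHydroStructure(atoms, res)
}

#' Place missing hydrogens by ideal geometry
#'
#' Adds polar and aliphatic hydrogens to amino-acid residues using sp2/sp3
#' geometric templates (C-H 1.09, N-H 1.01, O-H 0.96, S-H 1.34 Angstrom).
#' Rotatable hydroxyl/thiol hydrogens are placed anti to the preceding
#' heavy-atom dihedral. Existing hydrogens are preserved (the operation is
#' idempotent); no minimization is performed. Lipid and water records are
#' left untouched (lipids are treated united-atom throughout the package).
#'
#' @param structure a \linkS4class{HydroStructure}.
#' @return structure with hydrogens added.
#' @export
addHydrogens <- function(structure) {
  atoms <- structure@atoms
  res <- structure@residues
  if (!nrow(atoms)) return(structure)
  newH <- vector("list", nrow(res))
  aares <- res[res$type %in% .AA_TYPES, , drop = FALSE]
  for (i in seq_len(nrow(aares))) {
    key <- aares$key[i]
    type <- aares$type[i]
    ra <- atoms[atoms$residue_key == key, , drop = FALSE]
    pos <- setNames(lapply(seq_len(nrow(ra)),
                           function(j) c(ra$x[j], ra$y[j], ra$z[j])), ra$name)
    ## previous residue's C (for the amide H)
    prevC <- NULL
    ridx <- which(res$key == key)
    if (ridx > 1L && res$chain[ridx - 1L] == aares$chain[i] &&
        res$type[ridx - 1L] %in% .AA_TYPES) {
      pa <- atoms[atoms$residue_key == res$key[ridx - 1L] &
                    atoms$name == "C", , drop = FALSE]
      if (nrow(pa)) prevC <- c(pa$x[1L], pa$y[1L], pa$z[1L])
    }
    hs <- .placeResidueH(type, pos, prevC)
    if (length(hs)) {
      newH[[match(key, res$key)]] <- data.frame(
        serial = NA_integer_, name = names(hs), element = "H",
        resname = type, chain = aares$chain[i], resno = aares$resno[i],
        insert = aares$insert[i],
        x = vapply(hs, `[`, numeric(1), 1L),
        y = vapply(hs, `[`, numeric(1), 2L),
        z = vapply(hs, `[`, numeric(1), 3L),
        o = 1, b = 0, is_lipid = FALSE, is_water = FALSE,
        residue_key = key, stringsAsFactors = FALSE)
    }
  }
  add <- do.call(rbind, newH[!vapply(newH, is.null, logical(1))])
  if (is.null(add) || !nrow(add)) return(structure)
  ## keep residues contiguous: interleave by residue order
  pieces <- lapply(res$key, function(k) {
    rbind(atoms[atoms$residue_key == k, , drop = FALSE],
          add[add$residue_key == k, , drop = FALSE])
  })
  atoms2 <- do.call(rbind, pieces)
  atoms2$serial <- seq_len(nrow(atoms2))
  newHydroStructure(atoms2, res)
}

## hydrogens for one residue; returns named list of coordinates (missing only)
.placeResidueH <- function(type, pos, prevC = NULL) {
  if (!type %in% .AA_TYPES) return(list())
  bonds <- residueBonds(type)
  neighborsOf <- function(at) {
    nb <- c(bonds[bonds[, 1L] == at, 2L], bonds[bonds[, 2L] == at, 1L])
    nb[nb %in% names(pos)]
  }
  out <- list()
  have <- function(nm) nm %in% names(pos) || nm %in% names(out)
  get <- function(nm) if (nm %in% names(out)) out[[nm]] else pos[[nm]]

  completeH <- function(at, r) {
    nbs <- neighborsOf(at)
    if (length(nbs) < 2L) return(NULL)
    u <- Reduce(`+`, lapply(nbs, function(n) unitv(get(n) - get(at))))
    if (vnorm(u) < 1e-6) return(NULL)
    get(at) - r * unitv(u)  # H opposite the neighbor sum
  }
  methyleneH <- function(at, r) {
    nbs <- neighborsOf(at)
    if (length(nbs) < 2L) return(NULL)
    u1 <- unitv(get(nbs[1L]) - get(at))
    u2 <- unitv(get(nbs[2L]) - get(at))
    b <- -unitv(u1 + u2)
    n <- unitv(cross3(u1, u2))
    th <- 0.5 * 109.5 * pi / 180
    list(get(at) + r * unitv(b * cos(th) + n * sin(th)),
         get(at) + r * unitv(b * cos(th) - n * sin(th)))
  }
  methylH <- function(at, r, dihs = c(180, 60, -60)) {
    nbs <- neighborsOf(at)
    if (length(nbs) < 1L) return(NULL)
    par <- nbs[1L]
    gps <- setdiff(neighborsOf(par), at)
    if (!length(gps)) return(NULL)
    lapply(dihs, function(d)
      placeAtom(get(at), get(par), get(gps[1L]), r, 109.5, d))
  }
  nh2H <- function(at, r) {
    nbs <- neighborsOf(at)
    if (length(nbs) < 1L) return(NULL)
    par <- nbs[1L]
    gps <- setdiff(neighborsOf(par), at)
    if (!length(gps)) return(NULL)
    lapply(c(0, 180), function(d)
      placeAtom(get(at), get(par), get(gps[1L]), r, 120, d))
  }
  polarRotH <- function(at, r) {
    nbs <- neighborsOf(at)
    if (length(nbs) < 1L) return(NULL)
    par <- nbs[1L]
    gps <- setdiff(neighborsOf(par), at)
    if (!length(gps)) return(NULL)
    placeAtom(get(at), get(par), get(gps[1L]), r, 108.5, 180)
  }

  ## backbone amide H (not PRO, needs previous C for the sp2 plane)
  if (type != "PRO" && !have("H") && all(c("N", "CA") %in% names(pos))) {
    if (!is.null(prevC)) {
      u <- unitv(unitv(get("CA") - get("N")) + unitv(prevC - get("N")))
      out$H <- get("N") - 1.01 * u
    } else if ("C" %in% names(pos)) {
      out$H <- placeAtom(get("N"), get("CA"), get("C"), 1.01, 119, 180)
    }
  }
  ## HA (GLY: HA2/HA3)
  if (type == "GLY") {
    if (!have("HA2") || !have("HA3")) {
      hh <- methyleneH("CA", 1.09)
      if (!is.null(hh)) {
        if (!have("HA2")) out$HA2 <- hh[[1L]]
        if (!have("HA3")) out$HA3 <- hh[[2L]]
      }
    }
  } else if (!have("HA")) {
    h <- completeH("CA", 1.09)
    if (!is.null(h)) out$HA <- h
  }

  spec <- .SIDECHAIN_H[[type]]
  if (!is.null(spec)) {
    for (i in seq_len(nrow(spec))) {
      heavy <- spec$heavy[i]
      if (!heavy %in% names(pos)) next
      hn <- strsplit(spec$hnames[i], ",", fixed = TRUE)[[1L]]
      missing <- hn[!vapply(hn, have, logical(1))]
      if (!length(missing)) next
      r <- spec$r[i]
      placed <- switch(spec$mode[i],
        complete = { h <- completeH(heavy, r); if (is.null(h)) NULL else list(h) },
        methylene = methyleneH(heavy, r),
        methyl = methylH(heavy, r),
        nh2 = nh2H(heavy, r),
        polar_rot = { h <- polarRotH(heavy, r); if (is.null(h)) NULL else list(h) })
      if (is.null(placed)) next
      names(placed) <- hn[seq_along(placed)]
      for (nm in names(placed)) if (nm %in% missing) out[[nm]] <- placed[[nm]]
    }
  }
  out
}

#' Read a membrane annotation from sidecar files
#'
#' @param planes path to a JSON file \code{{"z_lower": ..., "z_upper": ...}}
#'   or to an average-phosphate-surface ("distortions") PDB, in which case
#'   the per-leaflet mean z of the phosphate records defines the planes.
#' @param pore_csv path to a CSV with header \code{residue_id,pore} where
#'   residue_id is chain-qualified (\code{A:123}) and pore is 0/1 or
#'   TRUE/FALSE.
#' @return A \linkS4class{MembraneAnnotation}.
#' @export
readMembraneAnnotation <- function(planes, pore_csv = NULL) {
  if (grepl("\\.json$", planes, ignore.case = TRUE)) {
    j <- jsonlite::fromJSON(planes)
    zl <- as.numeric(j$z_lower); zu <- as.numeric(j$z_upper)
  } else {
    s <- readStructure(planes)
    a <- s@atoms
    p <- a[a$element == "P" | a$name == "P", , drop = FALSE]
    if (!nrow(p)) p <- a
    mid <- mean(p$z)
    zl <- mean(p$z[p$z < mid]); zu <- mean(p$z[p$z >= mid])
  }
  flags <- logical(0)
  if (!is.null(pore_csv)) {
    d <- utils::read.csv(pore_csv, stringsAsFactors = FALSE)
    if (!all(c("residue_id", "pore") %in% names(d)))
      stop("pore CSV must have header residue_id,pore")
    flags <- setNames(as.logical(as.integer(as.logical(d$pore)) |
                                   d$pore %in% c("1", "TRUE", "true")),
                      d$residue_id)
  }
  new("MembraneAnnotation", z_upper = zu, z_lower = zl, pore_flags = flags)
}

#' Classify each residue's membrane environment
#'
#' A residue with all three backbone atoms (N, CA, C) strictly between the
#' bilayer planes is in the membrane region: pore-lining residues are tagged
#' core-facing (\code{mC}), the rest lipid-facing (\code{mL}). Residues
#' outside the planes are in the soluble domain (\code{mS}). Without an
#' annotation every residue is tagged \code{soluble}. Residues missing
#' backbone atoms get \code{NA} (unusable).
#'
#' @param structure a \linkS4class{HydroStructure}.
#' @param annotation a \linkS4class{MembraneAnnotation}, or NULL for
#'   soluble-mode classification.
#' @return named character vector, residue key -> tag.
#' @export
classifyEnvironment <- function(structure, annotation = NULL) {
  res <- structure@residues
  aa <- res$type %in% .AA_TYPES
  out <- setNames(rep(NA_character_, nrow(res)), res$key)
  if (is.null(annotation)) {
    out[aa & res$usable] <- "soluble"
    return(out[aa])
  }
  atoms <- structure@atoms
  for (i in which(aa)) {
    if (!res$usable[i]) next
    bz <- atoms$z[atoms$residue_key == res$key[i] &
                    atoms$name %in% c("N", "CA", "C")]
    if (length(bz) < 3L) next
    inside <- all(bz > annotation@z_lower & bz < annotation@z_upper)
    if (inside) {
      pore <- isTRUE(annotation@pore_flags[res$key[i]])
      out[i] <- if (pore) "mC" else "mL"
    } else {
      out[i] <- "mS"
    }
  }
  out[aa]
}
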