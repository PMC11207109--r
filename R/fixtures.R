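## fixtures_cli: synthetic structure and membrane-annotation generator.
## The default spec is the package's reference study condition: a
## seven-helix bundle (~200 residues) spanning a 30 Angstrom bilayer with
## ~40 surrounding lipid-like DPPC chains.

#' Synthetic membrane fixture specification
#'
#' @param n_helices number of ideal alpha helices in the bundle.
#' @param helix_length residues per helix.
#' @param sequences optional character vector (one string of three-letter
#'   codes separated by "-" per helix); NULL selects residue types by
#'   orientation (lipid-facing positions hydrophobic, pore-facing polar).
#' @param half_thickness membrane half-thickness t (Angstrom): the
#'   phosphate planes sit at z = -t and +t.
#' @param n_lipids number of DPPC-like lipid chains packed around the
#'   bundle (split between the two leaflets).
#' @param seed integer seed; the same spec and seed yield byte-identical
#'   outputs.
#' @return list of class "fixtureSpec".
#' @export
fixtureSpec <- function(n_helices = 7L, helix_length = 28L, sequences = NULL,
                        half_thickness = 15, n_lipids = 40L, seed = 1L) {
  structure(list(n_helices = as.integer(n_helices),
                 helix_length = as.integer(helix_length),
                 sequences = sequences,
                 half_thickness = half_thickness,
                 n_lipids = as.integer(n_lipids),
                 seed = as.integer(seed)),
            class = "fixtureSpec")
}

.HYDRO_SET <- c("LEU", "ILE", "VAL", "PHE", "ALA")
.POLAR_SET <- c("SER", "THR", "GLY", "ASP", "ALA")

## ideal helix backbone (phi -57, psi -47, omega 180) with seeded jitter;
## returns list of per-residue lists (N, CA, C, O) plus the angles used
.buildHelixBackbone <- function(n, jitter = 4) {
  ## ideal alpha-helical torsions, kept clear of the 45-degree bin edges so
  ## one helix populates a single chess square
  phi <- -57 + stats::runif(n, -jitter, jitter)
  psi <- -50 + stats::runif(n, -jitter, jitter)
  res <- vector("list", n)
  N <- c(0, 0, 0)
  CA <- c(1.458, 0, 0)
  C <- placeAtom(CA, N, c(0, 1, 0), 1.525, 111.0, 60)
  for (i in seq_len(n)) {
    res[[i]] <- list(N = N, CA = CA, C = C)
    if (i < n) {
      Nn <- placeAtom(C, CA, N, 1.329, 116.6, psi[i])
      CAn <- placeAtom(Nn, C, CA, 1.458, 121.7, 180)
      Cn <- placeAtom(CAn, Nn, C, 1.525, 111.0, phi[i + 1L])
      N <- Nn; CA <- CAn; C <- Cn
    }
  }
  for (i in seq_len(n))
    res[[i]]$O <- placeAtom(res[[i]]$C, res[[i]]$CA, res[[i]]$N,
                            1.231, 120.8, psi[i] + 180)
  list(residues = res, phi = phi, psi = psi)
}

## rigid transform aligning the CA principal axis with +z, centred at the
## origin
.axisAlign <- function(backbone) {
  ca <- do.call(rbind, lapply(backbone$residues, `[[`, "CA"))
  ctr <- colMeans(ca)
  cc <- sweep(ca, 2L, ctr)
  ax <- svd(cc)$v[, 1L]
  if (sum(ax * (ca[nrow(ca), ] - ca[1L, ])) < 0) ax <- -ax
  z <- c(0, 0, 1)
  v <- cross3(ax, z)
  s <- vnorm(v)
  if (s < 1e-9) {
    R <- diag(3)
  } else {
    K <- matrix(c(0, -v[3L], v[2L], v[3L], 0, -v[1L], -v[2L], v[1L], 0),
                3L, 3L, byrow = TRUE)
    cth <- sum(ax * z)
    R <- diag(3) + K + K %*% K * (1 / (1 + cth))
  }
  for (i in seq_along(backbone$residues)) {
    backbone$residues[[i]] <- lapply(backbone$residues[[i]], function(p)
      as.numeric(R %*% (p - ctr)))
  }
  backbone
}

## simplified DPPC template in local coordinates: head group at the top
## (z = 0 at the phosphate), two tails hanging along -z
.lipidTemplate <- function() {
  tail <- function(x0, zs) {
    out <- list()
    for (i in seq_along(zs))
      out[[i]] <- c(x0 + 0.25 * (i %% 2), 0.4 * (i %% 2), zs[i])
    out
  }
  zsA <- seq(-2.6, -11.4, by = -1.25)[1:8]
  zsB <- seq(-2.9, -11.7, by = -1.25)[1:8]
  pos <- list(
    N = c(0.3, 0.6, 3.6), C13 = c(1.4, 1.2, 4.2), C14 = c(-0.8, 1.3, 4.1),
    C15 = c(0.5, -0.7, 4.4), C12 = c(0.2, 0.8, 2.1), C11 = c(0.7, -0.3, 1.3),
    P = c(0, 0, 0), O11 = c(1.2, 0.6, -0.4), O12 = c(-1.2, 0.7, -0.3),
    O13 = c(0.2, -1.4, 0.4), O14 = c(-0.2, 0.2, 1.4),
    C1 = c(0.4, 0.3, -1.4), C2 = c(-0.3, -0.4, -2.2), C3 = c(1.5, -0.4, -1.7),
    O21 = c(-1.2, 0.2, -2.8), C21 = c(-1.6, -0.4, -3.7),
    O22 = c(-1.1, -1.4, -4.1),
    O31 = c(2.2, 0.5, -2.5), C31 = c(3.0, -0.1, -3.1),
    O32 = c(3.3, -1.2, -2.8))
  tA <- tail(-0.6, zsA); names(tA) <- paste0("C2", 2:9)
  tB <- tail(2.6, zsB); names(tB) <- paste0("C3", 2:9)
  c(pos, tA, tB)
}

#' Generate a synthetic membrane protein fixture with sidecars
#'
#' Builds an ideal alpha-helical bundle spanning the two bilayer planes,
#' packs lipid-like DPPC chains (polar head group plus hydrophobic tails)
#' around it in two leaflets, and writes the coordinate file plus the
#' membrane-annotation sidecars: an average-phosphate-surface PDB
#' (\code{<name>_default_dppc-distortions.pdb}), a per-residue pore-flag CSV
#' (\code{<name>_default_dppc-by-resid.csv}) and a planes JSON. Pore flags
#' mark in-membrane residues whose sidechains point toward the bundle axis.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param dir output directory (created if needed).
#' @param name basename for the files (default "synthbundle").
#' @return list: pdb, distortions, pore_csv, planes (paths), spec, and the
#'   generated \linkS4class{HydroStructure}.
#' @export
makeMembraneFixture <- function(spec = fixtureSpec(), dir = tempfile("fix"),
                                name = "synthbundle") {
  stopifnot(inherits(spec, "fixtureSpec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(spec$seed)
  t <- spec$half_thickness
  nh <- spec$n_helices
  nres <- spec$helix_length
  Rb <- if (nh > 1L) 10 / (2 * sin(pi / nh)) else 0

  atoms <- list()
  pore <- list()
  serial <- 0L
  for (h in seq_len(nh)) {
    bb <- .axisAlign(.buildHelixBackbone(nres))
    ang <- 2 * pi * (h - 1) / nh
    off <- c(Rb * cos(ang), Rb * sin(ang), 0)
    flip <- h %% 2L == 0L  # antiparallel packing
    seqh <- if (!is.null(spec$sequences))
      strsplit(spec$sequences[[h]], "-", fixed = TRUE)[[1L]] else NULL
    for (i in seq_len(nres)) {
      r <- lapply(bb$residues[[i]], function(p) {
        if (flip) p <- c(p[1L], -p[2L], -p[3L])
        p + off
      })
      ## outward = away from the bundle axis, in the xy plane
      caxy <- r$CA[1:2]
      outward <- if (vnorm(caxy - off[1:2]) > 1e-6 || Rb == 0) {
        u <- r$CA[1:2]
        if (vnorm(u) < 1e-6) c(1, 0) else u / vnorm(u)
      } else c(cos(ang), sin(ang))
      cb0 <- buildSidechain("ALA", r$N, r$CA, r$C)$CB
      cbdir <- (cb0 - r$CA)[1:2]
      facing_out <- sum(cbdir * outward) > 0
      type <- if (!is.null(seqh)) seqh[i]
        else if (facing_out) sample(.HYDRO_SET, 1L)
        else sample(.POLAR_SET, 1L)
      chi <- .DEFAULT_CHI[[type]]
      if (length(chi)) chi <- chi + stats::runif(length(chi), -8, 8)
      pos <- buildSidechain(type, r$N, r$CA, r$C, chi = chi)
      pos$O <- r$O
      jit <- matrix(stats::runif(3 * length(pos), -0.03, 0.03),
                    ncol = 3L)
      nms <- names(pos)
      for (j in seq_along(pos)) pos[[j]] <- pos[[j]] + jit[j, ]
      in_mem <- all(vapply(c("N", "CA", "C"),
                           function(a) abs(pos[[a]][3L]) < t, logical(1)))
      key <- paste0(LETTERS[h], ":", i)
      pore[[key]] <- in_mem && !facing_out
      for (j in seq_along(pos)) {
        serial <- serial + 1L
        atoms[[length(atoms) + 1L]] <- data.frame(
          type = "ATOM", serial = serial, name = nms[j],
          resname = type, chain = LETTERS[h], resno = i,
          x = pos[[j]][1L], y = pos[[j]][2L], z = pos[[j]][3L],
          element = substr(nms[j], 1L, 1L), stringsAsFactors = FALSE)
      }
    }
  }

  ## lipids: two leaflets packed around the bundle
  tmpl <- .lipidTemplate()
  nlip <- spec$n_lipids
  lres <- 0L
  for (li in seq_len(nlip)) {
    leaf <- if (li %% 2L == 0L) 1 else -1
    ang <- 2 * pi * (ceiling(li / 2) - 1) / ceiling(nlip / 2) +
      stats::runif(1, -0.08, 0.08)
    rad <- Rb + 7.0 + stats::runif(1, -0.5, 0.5)
    ctr <- c(rad * cos(ang), rad * sin(ang), leaf * t)
    spin <- axisRotation(c(0, 0, 1), stats::runif(1, 0, 360))
    lres <- lres + 1L
    for (nm in names(tmpl)) {
      p <- as.numeric(spin %*% tmpl[[nm]])
      if (leaf < 0) p <- c(p[1L], p[2L], -p[3L])  # mirror for lower leaflet
      p <- p + ctr + stats::runif(3, -0.15, 0.15)
      serial <- serial + 1L
      atoms[[length(atoms) + 1L]] <- data.frame(
        type = "HETATM", serial = serial, name = nm, resname = "DPPC",
        chain = "L", resno = lres, x = p[1L], y = p[2L], z = p[3L],
        element = substr(nm, 1L, 1L), stringsAsFactors = FALSE)
    }
  }
  at <- do.call(rbind, atoms)

  pdb_path <- file.path(dir, paste0(name, ".pdb"))
  .writeFixturePDB(at, pdb_path)

  ## distortions sidecar: grid of phosphate markers on each plane
  gp <- expand.grid(x = seq(-20, 20, by = 10), y = seq(-20, 20, by = 10))
  dist_at <- do.call(rbind, lapply(c(-1, 1), function(s) {
    data.frame(type = "HETATM", serial = seq_len(nrow(gp)),
               name = "P", resname = "DPPC", chain = "M",
               resno = seq_len(nrow(gp)), x = gp$x, y = gp$y, z = s * t,
               element = "P", stringsAsFactors = FALSE)
  }))
  dist_at$serial <- seq_len(nrow(dist_at))
  dist_path <- file.path(dir, paste0(name, "_default_dppc-distortions.pdb"))
  .writeFixturePDB(dist_at, dist_path)

  pore_path <- file.path(dir, paste0(name, "_default_dppc-by-resid.csv"))
  keys <- names(pore)
  utils::write.csv(data.frame(residue_id = keys,
                              pore = as.integer(unlist(pore))),
                   pore_path, row.names = FALSE, quote = FALSE)

  planes_path <- file.path(dir, paste0(name, "_planes.json"))
  jsonlite::write_json(list(z_lower = -t, z_upper = t), planes_path,
                       auto_unbox = TRUE, digits = NA)

  list(pdb = pdb_path, distortions = dist_path, pore_csv = pore_path,
       planes = planes_path, spec = spec,
       structure = readStructure(pdb_path))
}

## minimal deterministic PDB writer (fixed-width ATOM/HETATM records)
.writeFixturePDB <- function(at, path) {
  fmtName <- function(n) {
    ifelse(nchar(n) < 4L, sprintf(" %-3s", n), sprintf("%-4s", n))
  }
  lines <- sprintf("%-6s%5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   at$type, at$serial %% 100000L, fmtName(at$name),
                   at$resname, at$chain, at$resno, at$x, at$y, at$z,
                   1, 0, at$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Build a two-residue toy fixture
#'
#' Two residues on backbone stubs facing each other along z: the first
#' sidechain points up (+z), the second down, with the given CA-CA
#' separation. Used for pair-score and map unit tests.
#'
#' @param types character vector of two residue types.
#' @param separation CA-CA distance (Angstrom).
#' @param seed seed for the small chi jitter.
#' @param chi optional list of two named chi vectors.
#' @return PDB text (character vector of lines).
#' @export
makeToyPair <- function(types, separation = 9, seed = 1L, chi = NULL) {
  stopifnot(length(types) == 2L)
  set.seed(seed)
  mk <- function(type, up, zoff, chiv) {
    N <- c(-0.525, 1.363, 0); CA <- c(0, 0, 0); C <- c(1.526, 0, 0)
    pos <- buildSidechain(type, N, CA, C, chi = chiv)
    pos$O <- placeAtom(C, CA, N, 1.231, 120.8, -45)
    ## orient the CA->CB direction along +z (or -z), via the canonical axis
    ref <- if (type == "GLY") {
      ideal <- placeAtom(CA, N, C, 1.53, 110.4, 122.5)
      if (det(rbind(N - CA, C - CA, ideal - CA)) < 0)
        ideal <- placeAtom(CA, N, C, 1.53, 110.4, -122.5)
      ideal
    } else pos$CB
    zax <- unitv(ref - CA)
    v <- cross3(zax, c(0, 0, 1))
    s <- vnorm(v)
    R <- if (s < 1e-9) diag(3) else {
      K <- matrix(c(0, -v[3L], v[2L], v[3L], 0, -v[1L], -v[2L], v[1L], 0),
                  3L, 3L, byrow = TRUE)
      diag(3) + K + K %*% K * ((1 - sum(zax * c(0, 0, 1))) / s^2)
    }
    pos <- lapply(pos, function(p) as.numeric(R %*% (p - CA)))
    if (!up) pos <- lapply(pos, function(p) c(p[1L], -p[2L], -p[3L]))
    lapply(pos, function(p) p + c(0, 0, zoff))
  }
  chi1 <- if (!is.null(chi)) chi[[1L]] else NULL
  chi2 <- if (!is.null(chi)) chi[[2L]] else NULL
  p1 <- mk(types[1L], up = TRUE, zoff = 0, chiv = chi1)
  p2 <- mk(types[2L], up = FALSE, zoff = separation, chiv = chi2)
  rows <- list()
  serial <- 0L
  emit <- function(pos, chain, resno, type) {
    for (nm in names(pos)) {
      serial <<- serial + 1L
      rows[[length(rows) + 1L]] <<- data.frame(
        type = "ATOM", serial = serial, name = nm, resname = type,
        chain = chain, resno = resno, x = pos[[nm]][1L], y = pos[[nm]][2L],
        z = pos[[nm]][3L], element = substr(nm, 1L, 1L),
        stringsAsFactors = FALSE)
    }
  }
  emit(p1, "A", 1L, types[1L])
  emit(p2, "B", 1L, types[2L])
  at <- do.call(rbind, rows)
  tf <- tempfile(fileext = ".pdb")
  .writeFixturePDB(at, tf)
  on.exit(unlink(tf))
  readLines(tf)
}
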