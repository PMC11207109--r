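## Shared in-code fixtures. Everything is generated at test time; the
## heavier objects are memoized per session.

.cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.cache[[name]])) .cache[[name]] <- force(expr)
  .cache[[name]]
}

## one correctly formatted ATOM/HETATM line (handles 4-char residue names)
pdbLine <- function(serial, name, resname, chain, resno, x, y, z,
                    het = FALSE, element = substr(name, 1, 1)) {
  at <- data.frame(type = if (het) "HETATM" else "ATOM", serial = serial,
                   name = name, resname = resname, chain = chain,
                   resno = resno, x = x, y = y, z = z, element = element,
                   stringsAsFactors = FALSE)
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  hydromaps:::.writeFixturePDB(at, tf)
  readLines(tf)[1L]
}

## minimal PDB text for a tripeptide of the given types on an ideal
## extended-ish backbone (built with the package's own geometry engine)
tripeptidePDB <- function(types = c("ALA", "ALA", "ALA"),
                          phi = -57, psi = -50) {
  bb <- hydromaps:::.buildHelixBackbone(length(types), jitter = 0)
  rows <- list()
  serial <- 0L
  for (i in seq_along(types)) {
    r <- bb$residues[[i]]
    pos <- hydromaps:::buildSidechain(types[i], r$N, r$CA, r$C)
    pos$O <- r$O
    for (nm in names(pos)) {
      serial <- serial + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        type = "ATOM", serial = serial, name = nm, resname = types[i],
        chain = "A", resno = i, x = pos[[nm]][1], y = pos[[nm]][2],
        z = pos[[nm]][3], element = substr(nm, 1, 1),
        stringsAsFactors = FALSE)
    }
  }
  tf <- tempfile(fileext = ".pdb")
  hydromaps:::.writeFixturePDB(do.call(rbind, rows), tf)
  on.exit(unlink(tf))
  readLines(tf)
}

## fully annotated toy-pair structure (hydrogens, constants, accessibility)
annotatedPair <- function(types, separation = 9, seed = 1L,
                          n_points = 240L) {
  s <- readStructure(makeToyPair(types, separation, seed = seed))
  s <- addHydrogens(s)
  s <- assignAtomConstants(s)
  atomAccessibility(s, n_points = n_points)
}

## small membrane bundle, annotated sidecars included
smallBundle <- function() memo("smallBundle", {
  makeMembraneFixture(fixtureSpec(n_helices = 3L, helix_length = 18L,
                                  n_lipids = 12L, seed = 7L))
})

## random synthetic MapSet populations with `k` planted groups: each group
## deposits at its own set of nodes on a common small grid
plantedMaps <- function(k, per_group = 8L, seed = 1L, noise = 0.05) {
  set.seed(seed)
  g <- new("GridSpec", origin = c(-2, -2, -2), shape = c(9L, 9L, 9L),
           spacing = 0.5)
  centers <- lapply(seq_len(k), function(i) {
    n <- prod(g@shape)
    idx <- ((i - 1L) * floor(n / k)) + seq_len(10L)
    list(idx = idx, val = stats::runif(10L, 0.5, 1.5))
  })
  maps <- list()
  for (i in seq_len(k)) {
    for (j in seq_len(per_group)) {
      f <- hydromaps:::zeroField(g)
      f[centers[[i]]$idx] <- centers[[i]]$val +
        stats::rnorm(10L, sd = noise)
      f <- abs(f)
      ms <- emptyMapSet(g, list(residue_key = sprintf("g%d.%d", i, j),
                                bin = "t", mode = "t"))
      ms@fields$hydPlus <- f
      maps[[length(maps) + 1L]] <- ms
      names(maps)[length(maps)] <- sprintf("g%d.%d", i, j)
    }
  }
  list(maps = maps, truth = rep(seq_len(k), each = per_group), grid = g)
}

## random pair-score table for deposition tests: midpoints well inside the
## type's grid box
randomPairs <- function(n, type = "LEU", seed = 1L) {
  set.seed(seed)
  ext <- hydromaps:::residueExtent(type)
  classes <- c("hydPlus", "hydMinus", "polPlus", "polMinus")
  cls <- sample(classes, n, replace = TRUE)
  sgn <- ifelse(cls %in% c("hydPlus", "polPlus"), 1, -1)
  data.frame(
    value = sgn * stats::runif(n, 0.1, 2),
    class = cls, r = stats::runif(n, 1, 7),
    mx = stats::runif(n, -ext, ext), my = stats::runif(n, -ext, ext),
    mz = stats::runif(n, -ext, ext),
    partner_is_lipid = sample(c(TRUE, FALSE), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

## negate a MapSet (test helper; flagged as difference to bypass the sign
## validity of ordinary maps)
negateMapSet <- function(ms) {
  f <- lapply(ms@fields, function(x) -x)
  new("MapSet", grid = ms@grid, fields = f,
      provenance = c(ms@provenance[setdiff(names(ms@provenance), "difference")],
                     list(difference = TRUE)),
      clipped = list(n = 0L, score = 0))
}

## identity frame transform
identityFrame <- function() {
  new("FrameTransform", rotation = diag(3), translation = c(0, 0, 0))
}

## frame from rotation/translation
frameOf <- function(R, t) new("FrameTransform", rotation = R,
                              translation = as.numeric(t))
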