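#' @import methods
NULL

#' Annotated molecular structure
#'
#' Container for a parsed coordinate set: a per-atom table and a per-residue
#' table. Amino-acid residues carry backbone-completeness and terminal flags;
#' lipid (DPPC by default) and water records are flagged at the atom level.
#' Residues are identified throughout the package by a chain-qualified key
#' \code{"<chain>:<resno><insert>"}.
#'
#' @slot atoms data.frame with columns serial, name, element, resname, chain,
#'   resno, insert, x, y, z, o, b, is_lipid, is_water, residue_key.
#' @slot residues data.frame with columns key, chain, resno, insert, type,
#'   is_terminal, usable, reason.
#' @export
setClass("HydroStructure",
  representation(atoms = "data.frame", residues = "data.frame"))

setValidity("HydroStructure", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "element", "resname", "chain", "resno",
            "insert", "x", "y", "z", "o", "b", "is_lipid", "is_water",
            "residue_key")
  if (!all(need %in% names(a)))
    return(paste("atoms table missing columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a)) {
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
      return("non-finite atom coordinates")
    if (any(!nzchar(a$element)))
      return("empty element symbols")
    if (any(a$is_lipid & a$is_water))
      return("atoms flagged both lipid and water")
  }
  r <- object@residues
  needr <- c("key", "chain", "resno", "insert", "type", "is_terminal",
             "usable", "reason")
  if (!all(needr %in% names(r)))
    return(paste("residues table missing columns:",
                 paste(setdiff(needr, names(r)), collapse = ", ")))
  TRUE
})

#' Rigid-body transform into the canonical residue frame
#'
#' Represents \code{y = R x + t} with \code{det(R) = +1} (pure rotation).
#'
#' @slot rotation 3x3 orthonormal matrix.
#' @slot translation numeric length-3 (Angstrom).
#' @export
setClass("FrameTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("FrameTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3L))) > 1e-6) return("rotation not orthonormal")
  if (abs(det(R) - 1) > 1e-6) return("rotation must be proper (det = +1)")
  if (length(object@translation) != 3L) return("translation must be length 3")
  TRUE
})

#' Regular 3D grid specification
#'
#' Axis-aligned grid with a common spacing (default 0.5 Angstrom in this
#' package). Node \code{(i,j,k)} (1-based) sits at
#' \code{origin + (i-1, j-1, k-1) * spacing}.
#'
#' @slot origin numeric length-3, position of the first node (Angstrom).
#' @slot shape integer length-3, number of nodes per axis.
#' @slot spacing numeric scalar, node separation (Angstrom).
#' @export
setClass("GridSpec",
  representation(origin = "numeric", shape = "integer", spacing = "numeric"))

setValidity("GridSpec", function(object) {
  if (length(object@origin) != 3L) return("origin must be length 3")
  if (length(object@shape) != 3L) return("shape must be length 3")
  if (any(object@shape < 2L)) return("shape must be >= 2 per axis")
  if (length(object@spacing) != 1L || object@spacing <= 0)
    return("spacing must be a positive scalar")
  TRUE
})

#' Four-class 3D hydropathic interaction map set
#'
#' Four co-registered scalar fields over one \linkS4class{GridSpec}:
#' favorable hydrophobic (\code{hydPlus}, >= 0), unfavorable hydrophobic
#' (\code{hydMinus}, <= 0), favorable polar (\code{polPlus}, >= 0) and
#' unfavorable polar (\code{polMinus}, <= 0).
#'
#' @slot grid a \linkS4class{GridSpec}.
#' @slot fields named list of four 3D arrays (hydPlus, hydMinus, polPlus,
#'   polMinus) with dim equal to \code{grid@shape}.
#' @slot provenance list: residue_key, bin, mode plus free-form entries.
#' @slot clipped list: n (pairs clipped off-grid) and score (total |value|
#'   clipped).
#' @export
setClass("MapSet",
  representation(grid = "GridSpec", fields = "list", provenance = "list",
                 clipped = "list"))

.MAP_CLASSES <- c("hydPlus", "hydMinus", "polPlus", "polMinus")

setValidity("MapSet", function(object) {
  if (!identical(names(object@fields), .MAP_CLASSES))
    return("fields must be hydPlus, hydMinus, polPlus, polMinus (in order)")
  shp <- object@grid@shape
  for (nm in .MAP_CLASSES) {
    f <- object@fields[[nm]]
    if (!is.array(f) || !identical(dim(f), as.integer(shp)))
      return(sprintf("field %s does not match grid shape", nm))
  }
  if (!isTRUE(object@provenance$difference)) {
    tol <- 1e-9 * max(1, max(abs(unlist(lapply(object@fields, range)))))
    if (min(object@fields$hydPlus) < -tol) return("hydPlus must be >= 0")
    if (min(object@fields$polPlus) < -tol) return("polPlus must be >= 0")
    if (max(object@fields$hydMinus) > tol) return("hydMinus must be <= 0")
    if (max(object@fields$polMinus) > tol) return("polMinus must be <= 0")
  }
  TRUE
})

#' Membrane annotation (bilayer planes and pore flags)
#'
#' @slot z_upper,z_lower average phosphate-plane z of the two leaflets
#'   (Angstrom), \code{z_lower < z_upper}.
#' @slot pore_flags named logical vector, residue_key -> pore-lining flag.
#' @export
setClass("MembraneAnnotation",
  representation(z_upper = "numeric", z_lower = "numeric",
                 pore_flags = "logical"))

setValidity("MembraneAnnotation", function(object) {
  if (!(object@z_lower < object@z_upper))
    return("z_lower must be below z_upper")
  TRUE
})

#' One clustered interaction motif
#'
#' @slot name cluster name: the exemplar's ordinal within its bin, as text.
#' @slot members residue keys belonging to the cluster.
#' @slot exemplar the member closest to the cluster centroid.
#' @slot averageMap Gaussian-weighted average \linkS4class{MapSet}.
#' @slot weights named numeric, member -> normalized Gaussian weight.
#' @export
setClass("ClusterEntry",
  representation(name = "character", members = "character",
                 exemplar = "character", averageMap = "MapSet",
                 weights = "numeric"))

setValidity("ClusterEntry", function(object) {
  if (!length(object@members)) return("cluster must be non-empty")
  if (!(object@exemplar %in% object@members))
    return("exemplar must be a member")
  if (abs(sum(object@weights) - 1) > 1e-9)
    return("weights must sum to 1")
  if (!identical(sort(names(object@weights)), sort(object@members)))
    return("weights must be named by the members")
  TRUE
})

setMethod("show", "HydroStructure", function(object) {
  r <- object@residues
  cat(sprintf("HydroStructure: %d atoms, %d residues (%d usable)\n",
              nrow(object@atoms), nrow(r), sum(r$usable)))
  nl <- sum(object@atoms$is_lipid)
  nw <- sum(object@atoms$is_water)
  if (nl) cat(sprintf("  lipid atoms: %d\n", nl))
  if (nw) cat(sprintf("  water atoms: %d\n", nw))
  invisible(object)
})

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d x %d nodes, spacing %.3g A, origin (%.2f, %.2f, %.2f)\n",
              object@shape[1L], object@shape[2L], object@shape[3L],
              object@spacing, object@origin[1L], object@origin[2L],
              object@origin[3L]))
  invisible(object)
})

setMethod("show", "MapSet", function(object) {
  s <- vapply(object@fields, sum, numeric(1))
  p <- object@provenance
  cat(sprintf("MapSet [%s %s %s]  sums: Hyd+ %.3g  Hyd- %.3g  Pol+ %.3g  Pol- %.3g\n",
              p$residue_key %||% "?", p$bin %||% "?", p$mode %||% "?",
              s["hydPlus"], s["hydMinus"], s["polPlus"], s["polMinus"]))
  invisible(object)
})

setMethod("show", "ClusterEntry", function(object) {
  cat(sprintf("ClusterEntry %s: %d members, exemplar %s\n",
              object@name, length(object@members), object@exemplar))
  invisible(object)
})

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- small accessor surface (avoid slot access in user code) ----

#' @describeIn HydroStructure-accessors atom table of a structure
#' @export
atomTable <- function(x) x@atoms

#' Accessors for HydroStructure
#'
#' @param x a \linkS4class{HydroStructure}.
#' @param key residue key.
#' @name HydroStructure-accessors
NULL

#' @describeIn HydroStructure-accessors residue table
#' @export
residueTable <- function(x) x@residues

#' @describeIn HydroStructure-accessors residue keys
#' @export
residueKeys <- function(x) x@residues$key

#' @describeIn HydroStructure-accessors atoms of one residue
#' @export
residueAtoms <- function(x, key) x@atoms[x@atoms$residue_key == key, , drop = FALSE]

#' @describeIn HydroStructure-accessors n x 3 coordinate matrix
#' @export
atomCoords <- function(x) {
  a <- if (is(x, "HydroStructure")) x@atoms else x
  cbind(x = a$x, y = a$y, z = a$z)
}

## internal constructor keeping the two tables consistent
newHydroStructure <- function(atoms, residues) {
  rownames(atoms) <- NULL
  rownames(residues) <- NULL
  new("HydroStructure", atoms = atoms, residues = residues)
}

#' Grid node coordinates along each axis
#'
#' @param grid a \linkS4class{GridSpec}.
#' @return list of three numeric vectors (node positions per axis, Angstrom).
#' @export
gridAxes <- function(grid) {
  lapply(1:3, function(d)
    grid@origin[d] + (seq_len(grid@shape[d]) - 1) * grid@spacing)
}

## total number of nodes
gridSize <- function(grid) prod(grid@shape)

## empty field array for a grid
zeroField <- function(grid) array(0, dim = grid@shape)

#' Construct an all-zero MapSet over a grid
#'
#' @param grid a \linkS4class{GridSpec}.
#' @param provenance list with residue_key, bin, mode.
#' @export
emptyMapSet <- function(grid, provenance = list()) {
  f <- setNames(lapply(.MAP_CLASSES, function(i) zeroField(grid)), .MAP_CLASSES)
  new("MapSet", grid = grid, fields = f, provenance = provenance,
      clipped = list(n = 0L, score = 0))
}

#' Apply / invert a canonical frame transform
#'
#' \code{applyFrame} maps lab-frame coordinates into the residue frame;
#' \code{invertFrame} returns the inverse transform.
#'
#' @param frame a \linkS4class{FrameTransform}.
#' @param xyz n x 3 matrix or length-3 vector.
#' @return transformed coordinates with the input's shape.
#' @export
applyFrame <- function(frame, xyz) {
  v <- !is.matrix(xyz)
  if (v) xyz <- matrix(xyz, nrow = 1L)
  out <- xyz %*% t(frame@rotation) +
    matrix(frame@translation, nrow(xyz), 3L, byrow = TRUE)
  if (v) out[1L, ] else out
}

#' @rdname applyFrame
#' @export
invertFrame <- function(frame) {
  Rt <- t(frame@rotation)
  new("FrameTransform", rotation = Rt,
      translation = as.numeric(-Rt %*% frame@translation))
}
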