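## maps3d: four-class 3D hydropathic interaction maps in the canonical
## residue frame, difference maps, and OpenDX text I/O.

.GRID_SPACING <- 0.5
.GRID_PAD <- 5.0

#' Standard residue-frame grid for a residue type
#'
#' Cubic box, centred on the canonical-frame origin (CA), sized to contain
#' the residue type in all expected conformations (extended-conformer reach)
#' with 5 Angstrom added per dimension, at 0.5 Angstrom spacing.
#' Deterministic per type.
#'
#' @param residue_type three-letter type.
#' @param spacing grid spacing (Angstrom), default 0.5.
#' @param pad padding added per dimension (Angstrom), default 5.
#' @return A \linkS4class{GridSpec}.
#' @export
residueGridSpec <- function(residue_type, spacing = .GRID_SPACING,
                            pad = .GRID_PAD) {
  h <- residueExtent(residue_type) + pad
  n <- 2L * as.integer(ceiling(h / spacing)) + 1L
  half <- (n - 1L) / 2 * spacing
  new("GridSpec", origin = rep(-half, 3L), shape = rep(n, 3L),
      spacing = spacing)
}

## deposition kernel: isotropic Gaussian, sigma in Angstrom, truncated at
## trunc*sigma; offsets are precomputed relative node displacements
.kernelOffsets <- function(spacing, sigma = 0.5, trunc = 2) {
  rad <- as.integer(ceiling(trunc * sigma / spacing))
  g <- expand.grid(dx = -rad:rad, dy = -rad:rad, dz = -rad:rad)
  as.matrix(g)
}

#' Compute a residue's four-class interaction map set
#'
#' Each scored pair deposits its value into the field of its interaction
#' class as a truncated Gaussian (sigma 0.5 Angstrom, cut at 2 sigma)
#' centred at the frame-transformed pair midpoint and normalized so that the
#' deposited grid sum equals the pair value exactly (in-box nodes only).
#' Pairs whose kernel has no in-box node are counted as clipped.
#'
#' @param residue_key residue key (provenance only).
#' @param pair_scores data.frame from \code{\link{residuePartnerPairs}}.
#' @param grid_spec the residue type's \linkS4class{GridSpec}.
#' @param frame the residue's canonical \linkS4class{FrameTransform}.
#' @param bin,mode provenance labels (chess square + parse; dataset mode).
#' @param sigma,trunc kernel width (Angstrom) and truncation (in sigmas).
#' @return A \linkS4class{MapSet}.
#' @export
computeMapSet <- function(residue_key, pair_scores, grid_spec, frame,
                          bin = "", mode = "", sigma = 0.5, trunc = 2) {
  prov <- list(residue_key = residue_key, bin = bin, mode = mode)
  ms <- emptyMapSet(grid_spec, prov)
  if (!nrow(pair_scores)) return(ms)
  mid <- applyFrame(frame, cbind(pair_scores$mx, pair_scores$my,
                                 pair_scores$mz))
  sp <- grid_spec@spacing
  org <- grid_spec@origin
  shp <- grid_spec@shape
  offs <- .kernelOffsets(sp, sigma, trunc)
  noff <- nrow(offs)
  rmax2 <- (trunc * sigma)^2
  ## fractional node position of each midpoint
  fx <- (mid[, 1L] - org[1L]) / sp
  fy <- (mid[, 2L] - org[2L]) / sp
  fz <- (mid[, 3L] - org[3L]) / sp
  i0 <- round(fx); j0 <- round(fy); k0 <- round(fz)
  npair <- nrow(pair_scores)
  fields <- ms@fields
  nclip <- 0L
  sclip <- 0
  cls <- pair_scores$class
  val <- pair_scores$value
  for (cl in .MAP_CLASSES) {
    rows <- which(cls == cl)
    if (!length(rows)) next
    f <- fields[[cl]]
    ## node indices and weights for all pairs of this class at once
    ii <- outer(rep(1, length(rows)), offs[, 1L]) + i0[rows]
    jj <- outer(rep(1, length(rows)), offs[, 2L]) + j0[rows]
    kk <- outer(rep(1, length(rows)), offs[, 3L]) + k0[rows]
    dxx <- ii - fx[rows]; dyy <- jj - fy[rows]; dzz <- kk - fz[rows]
    d2 <- (dxx * dxx + dyy * dyy + dzz * dzz) * sp * sp
    w <- exp(-d2 / (2 * sigma^2))
    w[d2 > rmax2] <- 0
    inbox <- ii >= 0 & ii < shp[1L] & jj >= 0 & jj < shp[2L] &
      kk >= 0 & kk < shp[3L]
    w[!inbox] <- 0
    wsum <- rowSums(w)
    clipped <- wsum <= 0
    if (any(clipped)) {
      nclip <- nclip + sum(clipped)
      sclip <- sclip + sum(abs(val[rows[clipped]]))
    }
    ok <- which(!clipped)
    if (!length(ok)) { fields[[cl]] <- f; next }
    w <- w[ok, , drop = FALSE] / wsum[ok]
    contrib <- w * val[rows[ok]]
    lin <- 1 + ii[ok, , drop = FALSE] + jj[ok, , drop = FALSE] * shp[1L] +
      kk[ok, , drop = FALSE] * shp[1L] * shp[2L]
    keep <- contrib != 0
    add <- rowsum(as.numeric(contrib[keep]), group = as.integer(lin[keep]))
    idx <- as.integer(rownames(add))
    f[idx] <- f[idx] + add[, 1L]
    fields[[cl]] <- f
  }
  tot <- sum(abs(val))
  if (tot > 0 && sclip / tot > 0.01)
    warning(sprintf("%.1f%% of |score| clipped outside the %s grid",
                    100 * sclip / tot, residue_key))
  new("MapSet", grid = grid_spec, fields = fields, provenance = prov,
      clipped = list(n = nclip, score = sclip))
}

#' Field-wise difference of two map sets
#'
#' Computes a - b per class field. For the lipid-facing calculation modes
#' this represents the lipid-only interactions: map(mL) - map(mN) equals the
#' map deposited from lipid-partner pairs alone (linearity of deposition).
#' Difference maps are flagged in their provenance and exempt from the
#' per-class sign constraints of ordinary map sets.
#'
#' @param mapset_a,mapset_b \linkS4class{MapSet}s on the same grid.
#' @return A \linkS4class{MapSet} with provenance mode "a-b".
#' @export
differenceMap <- function(mapset_a, mapset_b) {
  if (!identical(mapset_a@grid@shape, mapset_b@grid@shape) ||
      max(abs(mapset_a@grid@origin - mapset_b@grid@origin)) > 1e-9 ||
      abs(mapset_a@grid@spacing - mapset_b@grid@spacing) > 1e-12)
    stop("difference map requires identical grids")
  f <- setNames(lapply(.MAP_CLASSES, function(cl)
    mapset_a@fields[[cl]] - mapset_b@fields[[cl]]), .MAP_CLASSES)
  pa <- mapset_a@provenance
  pb <- mapset_b@provenance
  new("MapSet", grid = mapset_a@grid, fields = f,
      provenance = list(residue_key = pa$residue_key %||% "?",
                        bin = pa$bin %||% "",
                        mode = paste0(pa$mode %||% "a", "-", pb$mode %||% "b"),
                        difference = TRUE),
      clipped = list(n = 0L, score = 0))
}

## default display contour levels recorded in the sidecar: opaque/translucent
## for the polar and unfavorable-hydrophobic classes, halved for Hyd+
.CONTOUR_DEFAULTS <- list(
  hydPlus = c(opaque = 12, translucent = 3),
  hydMinus = c(opaque = -24, translucent = -6),
  polPlus = c(opaque = 24, translucent = 6),
  polMinus = c(opaque = -24, translucent = -6))

#' Write / read a map set as OpenDX text plus a JSON sidecar
#'
#' One OpenDX general-array scalar file per class
#' (\code{<prefix>.<class>.dx}) and \code{<prefix>.json} holding grid
#' metadata, provenance and default contour levels. The round trip is
#' lossless to float-text precision.
#'
#' @param mapset a \linkS4class{MapSet}.
#' @param prefix output path prefix (directory must exist).
#' @return \code{writeMapSet}: invisibly, the sidecar path.
#' @export
writeMapSet <- function(mapset, prefix) {
  g <- mapset@grid
  for (cl in .MAP_CLASSES) {
    .writeDX(mapset@fields[[cl]], g, paste0(prefix, ".", cl, ".dx"),
             comment = sprintf("hydromaps %s map", cl))
  }
  meta <- list(origin = g@origin, shape = g@shape, spacing = g@spacing,
               provenance = mapset@provenance,
               clipped = mapset@clipped,
               contours = .CONTOUR_DEFAULTS,
               classes = .MAP_CLASSES)
  path <- paste0(prefix, ".json")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMapSet
#' @export
readMapSet <- function(prefix) {
  path <- paste0(prefix, ".json")
  if (!file.exists(path)) stop("missing map sidecar: ", path)
  meta <- jsonlite::fromJSON(path)
  g <- new("GridSpec", origin = as.numeric(meta$origin),
           shape = as.integer(meta$shape), spacing = as.numeric(meta$spacing))
  fields <- list()
  for (cl in .MAP_CLASSES) {
    f <- paste0(prefix, ".", cl, ".dx")
    if (!file.exists(f)) stop("missing map field file: ", f)
    fields[[cl]] <- .readDX(f, g)
  }
  clipped <- meta$clipped
  new("MapSet", grid = g, fields = fields,
      provenance = as.list(meta$provenance),
      clipped = list(n = as.integer(clipped$n), score = as.numeric(clipped$score)))
}

## OpenDX general array, x fastest in our arrays but DX expects z fastest;
## permute on write/read.
.writeDX <- function(field, grid, path, comment = "") {
  shp <- grid@shape
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("#", comment),
    sprintf("object 1 class gridpositions counts %d %d %d",
            shp[1L], shp[2L], shp[3L]),
    sprintf("origin %.6f %.6f %.6f", grid@origin[1L], grid@origin[2L],
            grid@origin[3L]),
    sprintf("delta %.6f 0 0", grid@spacing),
    sprintf("delta 0 %.6f 0", grid@spacing),
    sprintf("delta 0 0 %.6f", grid@spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            shp[1L], shp[2L], shp[3L]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(shp))), con)
  v <- as.numeric(aperm(field, c(3L, 2L, 1L)))  # z fastest -> last index fastest
  n <- length(v)
  pad <- (3 - n %% 3) %% 3
  if (pad) v <- c(v, rep(NA_real_, pad))
  m <- matrix(v, ncol = 3L, byrow = TRUE)
  lines <- apply(m, 1L, function(r)
    paste(formatC(r[!is.na(r)], format = "e", digits = 9), collapse = " "))
  writeLines(lines, con)
  writeLines(c("attribute \"dep\" string \"positions\"",
               "object \"density\" class field",
               "component \"positions\" value 1",
               "component \"connections\" value 2",
               "component \"data\" value 3"), con)
  invisible(path)
}

.readDX <- function(path, grid) {
  lines <- readLines(path, warn = FALSE)
  start <- grep("data follows", lines)
  if (!length(start)) stop("corrupt OpenDX file (no data section): ", path)
  end <- grep("^attribute", lines)
  end <- if (length(end)) min(end[end > start[1L]]) - 1L else length(lines)
  vals <- as.numeric(unlist(strsplit(trimws(
    lines[(start[1L] + 1L):end]), "\\s+")))
  vals <- vals[!is.na(vals)]
  shp <- grid@shape
  if (length(vals) != prod(shp))
    stop("corrupt OpenDX file (wrong item count): ", path)
  aperm(array(vals, dim = rev(shp)), c(3L, 2L, 1L))
}
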