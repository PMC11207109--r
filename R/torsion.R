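## torsion_frames: backbone/sidechain dihedrals, chess-square and chi-parse
## assignment, and the canonical residue alignment frame.

#' Backbone dihedrals of a residue
#'
#' phi = C(i-1)-N-CA-C, psi = N-CA-C-N(i+1); both in [-180, 180). Terminal
#' residues (no flanking residue) have undefined angles and are excluded
#' from mapping.
#'
#' @param prev_residue,residue,next_residue named lists/atom tables giving
#'   coordinates for C (previous), N/CA/C, and N (next). Each may be a
#'   residue atom data.frame (columns name, x, y, z) or a named list of
#'   length-3 vectors.
#' @return c(phi, psi) in degrees.
#' @export
backboneDihedrals <- function(prev_residue, residue, next_residue) {
  gp <- .atomPos
  Cp <- gp(prev_residue, "C")
  N <- gp(residue, "N"); CA <- gp(residue, "CA"); C <- gp(residue, "C")
  Nn <- gp(next_residue, "N")
  if (is.null(Cp) || is.null(Nn) || is.null(N) || is.null(CA) || is.null(C))
    stop("backbone dihedrals undefined: flanking/backbone atoms missing")
  c(phi = torsionAngle(Cp, N, CA, C), psi = torsionAngle(N, CA, C, Nn))
}

.atomPos <- function(res, name) {
  if (is.null(res)) return(NULL)
  if (is.data.frame(res)) {
    i <- match(name, res$name)
    if (is.na(i)) return(NULL)
    return(c(res$x[i], res$y[i], res$z[i]))
  }
  res[[name]]
}

#' Ramachandran chess square of a (phi, psi) pair
#'
#' The Ramachandran plane is divided into sixty-four 45 x 45 degree bins
#' named a1..h8 from lower left to upper right: the column letter bins phi,
#' the row digit bins psi, both ascending from -180. Registration offsets
#' (degrees, added to the angles before binning) allow remapping the board.
#'
#' @param phi,psi backbone angles in degrees (wrapped internally).
#' @param phi_offset,psi_offset registration offsets in degrees (default 0).
#' @return square name, e.g. "c5".
#' @export
chessSquare <- function(phi, psi, phi_offset = 0, psi_offset = 0) {
  f <- wrapAngle(phi + phi_offset)
  s <- wrapAngle(psi + psi_offset)
  col <- pmin(7L, pmax(0L, floor((f + 180) / 45)))
  row <- pmin(7L, pmax(0L, floor((s + 180) / 45)))
  paste0(letters[col + 1L], row + 1L)
}

#' Chi-parse label of a residue conformation
#'
#' chi1 is binned into ".60" [0,120), ".180" [120,240) and ".300" [240,360)
#' (angles reduced mod 360). ARG/GLN/GLU/LYS are additionally parsed by chi2
#' (".60.180" etc., nine two-angle parses). PRO parses to ".30p" for chi1 in
#' [0,180) and ".30m" otherwise. ALA/GLY/VAL are not parsed ("").
#'
#' @param residue_type three-letter type.
#' @param chi1,chi2 sidechain torsions in degrees (chi2 needed only for the
#'   two-angle types).
#' @return parse label.
#' @export
chiParse <- function(residue_type, chi1 = NULL, chi2 = NULL) {
  if (residue_type %in% .NOPARSE_TYPES) return("")
  if (is.null(chi1) || is.na(chi1))
    stop("chi1 required for residue type ", residue_type)
  if (residue_type == "PRO") {
    c1 <- wrapAngle360(chi1)
    return(if (c1 < 180) ".30p" else ".30m")
  }
  bin1 <- .chiBin(chi1)
  if (residue_type %in% .PARSE2_TYPES) {
    if (is.null(chi2) || is.na(chi2))
      stop("chi2 required for residue type ", residue_type)
    return(paste0(bin1, .chiBin(chi2)))
  }
  bin1
}

.chiBin <- function(chi) {
  c1 <- wrapAngle360(chi)
  if (c1 < 120) ".60" else if (c1 < 240) ".180" else ".300"
}

#' Sidechain chi angles of a residue
#'
#' @param residue atom table of one residue (columns name, x, y, z).
#' @param type three-letter residue type.
#' @return named numeric vector (chi1, chi2, ...) in degrees; length 0 for
#'   unparsed types. NA entries indicate missing sidechain atoms.
#' @export
chiAngles <- function(residue, type) {
  defs <- .CHI_ATOMS[[type]]
  if (is.null(defs)) return(numeric(0))
  out <- vapply(seq_along(defs), function(i) {
    ps <- lapply(defs[[i]], .atomPos, res = residue)
    if (any(vapply(ps, is.null, logical(1)))) return(NA_real_)
    torsionAngle(ps[[1L]], ps[[2L]], ps[[3L]], ps[[4L]])
  }, numeric(1))
  names(out) <- paste0("chi", seq_along(out))
  out
}

#' Canonical residue alignment frame
#'
#' Rigid transform placing CA at the origin, the CA-CB bond on the +z axis,
#' and the CA-HA bond in the yz-plane with positive y component. For GLY the
#' pro-S alpha hydrogen stands in for CB (the remaining one plays HA).
#'
#' @param residue atom table of one residue (columns name, x, y, z), with
#'   hydrogens placed.
#' @param type residue three-letter type (GLY handled specially).
#' @return A \linkS4class{FrameTransform} mapping lab to canonical frame.
#' @export
canonicalFrame <- function(residue, type = NULL) {
  if (is.null(type) && is.data.frame(residue) && "resname" %in% names(residue))
    type <- residue$resname[1L]
  CA <- .atomPos(residue, "CA")
  if (is.null(CA)) stop("canonical frame requires CA")
  if (identical(type, "GLY")) {
    pseudo <- .glyPseudoCB(residue)
    CB <- pseudo$cb; HA <- pseudo$ha
  } else {
    CB <- .atomPos(residue, "CB")
    HA <- .atomPos(residue, "HA")
  }
  if (is.null(CB)) stop("canonical frame requires CB (or GLY surrogate)")
  if (is.null(HA)) stop("canonical frame requires HA")
  zax <- CB - CA
  if (vnorm(zax) < 1e-6) stop("degenerate geometry: CA and CB coincide")
  zax <- unitv(zax)
  ha <- HA - CA
  yax <- ha - sum(ha * zax) * zax
  if (vnorm(yax) < 1e-6) stop("degenerate geometry: HA collinear with CA-CB")
  yax <- unitv(yax)
  xax <- cross3(yax, zax)
  R <- rbind(xax, yax, zax)
  dimnames(R) <- NULL
  new("FrameTransform", rotation = R, translation = as.numeric(-R %*% CA))
}

## GLY: pick the pro-S HA as pseudo-CB (the hydrogen closest to where an
## L-residue's CB would sit), the other as HA.
.glyPseudoCB <- function(residue) {
  N <- .atomPos(residue, "N"); CA <- .atomPos(residue, "CA")
  C <- .atomPos(residue, "C")
  h2 <- .atomPos(residue, "HA2"); h3 <- .atomPos(residue, "HA3")
  if (is.null(h2) || is.null(h3))
    stop("GLY canonical frame requires HA2 and HA3")
  if (is.null(N) || is.null(C)) stop("GLY canonical frame requires N and C")
  idealCB <- placeAtom(CA, N, C, 1.53, 110.4, 122.5)
  if (det(rbind(N - CA, C - CA, idealCB - CA)) < 0)
    idealCB <- placeAtom(CA, N, C, 1.53, 110.4, -122.5)
  if (vnorm(h2 - idealCB) <= vnorm(h3 - idealCB)) {
    list(cb = h2, ha = h3)
  } else {
    list(cb = h3, ha = h2)
  }
}

#' Backbone-bin (chess square + parse) assignment for all usable residues
#'
#' Convenience wrapper computing phi/psi, chi angles, square and parse for
#' every usable, non-terminal residue of a structure.
#'
#' @param structure a \linkS4class{HydroStructure} (hydrogens placed if GLY
#'   frames are needed downstream).
#' @param phi_offset,psi_offset chessboard registration offsets (degrees).
#' @return data.frame: key, type, phi, psi, chi1, chi2, square, parse, bin.
#' @export
assignBins <- function(structure, phi_offset = 0, psi_offset = 0) {
  res <- structure@residues
  atoms <- structure@atoms
  aa <- which(res$type %in% .AA_TYPES & res$usable & !res$is_terminal)
  rows <- lapply(aa, function(i) {
    key <- res$key[i]
    ridx <- i
    prev_ok <- ridx > 1L && res$chain[ridx - 1L] == res$chain[ridx] &&
      res$type[ridx - 1L] %in% .AA_TYPES
    next_ok <- ridx < nrow(res) && res$chain[ridx + 1L] == res$chain[ridx] &&
      res$type[ridx + 1L] %in% .AA_TYPES
    if (!prev_ok || !next_ok) return(NULL)
    ra <- atoms[atoms$residue_key == key, , drop = FALSE]
    pa <- atoms[atoms$residue_key == res$key[ridx - 1L], , drop = FALSE]
    na <- atoms[atoms$residue_key == res$key[ridx + 1L], , drop = FALSE]
    ang <- tryCatch(backboneDihedrals(pa, ra, na), error = function(e) NULL)
    if (is.null(ang)) return(NULL)
    chi <- chiAngles(ra, res$type[i])
    parse <- tryCatch(
      chiParse(res$type[i], chi["chi1"], if (length(chi) > 1L) chi["chi2"] else NULL),
      error = function(e) NA_character_)
    if (is.na(parse) || (length(chi) && anyNA(chi[1:min(2, length(chi))]) &&
                         !res$type[i] %in% .NOPARSE_TYPES)) {
      if (!res$type[i] %in% .NOPARSE_TYPES && anyNA(chi)) {
        warning("residue ", key, " excluded: missing sidechain atoms for chi")
        return(NULL)
      }
    }
    sq <- chessSquare(ang["phi"], ang["psi"], phi_offset, psi_offset)
    data.frame(key = key, type = res$type[i],
               phi = unname(ang["phi"]), psi = unname(ang["psi"]),
               chi1 = if (length(chi)) unname(chi[1L]) else NA_real_,
               chi2 = if (length(chi) > 1L) unname(chi[2L]) else NA_real_,
               square = sq, parse = parse,
               bin = paste0(sq, parse), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(data.frame(key = character(0), type = character(0),
    phi = numeric(0), psi = numeric(0), chi1 = numeric(0), chi2 = numeric(0),
    square = character(0), parse = character(0), bin = character(0)))
  do.call(rbind, rows)
}
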