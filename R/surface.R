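## surface_character: sidechain SASA, the SASA/LASA partition, interaction
## character vectors with random-coil normalization, and summary tables.

#' Random-coil reference SASA per residue type
#'
#' Fully exposed sidechain surface areas (Gly-X-Gly tripeptides, Angstrom^2)
#' used as normalization constants. GLY carries the full-residue value
#' (87.2, it has no sidechain); CYX is set to 150 percent of the CYS value
#' (153.5).
#'
#' @return named numeric vector.
#' @export
randomCoilSasa <- function() {
  c(ALA = 64.9, ARG = 195.5, ASN = 114.3, ASP = 113.0, CYS = 102.3,
    CYX = 153.5, GLN = 143.7, GLU = 141.2, GLY = 87.2, HIS = 154.6,
    ILE = 147.3, LEU = 146.2, LYS = 164.5, MET = 158.3, PHE = 180.1,
    PRO = 105.2, SER = 77.4, THR = 106.2, TRP = 224.6, TYR = 193.1,
    VAL = 122.3)
}

#' Sidechain solvent-accessible surface area of a residue
#'
#' Shrake-Rupley area (probe 1.4 Angstrom, Bondi radii) summed over the
#' residue's sidechain atoms, computed in the context of the whole
#' structure. GLY reports its full-residue area.
#'
#' @param structure a \linkS4class{HydroStructure} with hydrogens placed.
#' @param residue_key residue key.
#' @param probe probe radius (Angstrom).
#' @param n_points Shrake-Rupley sphere points.
#' @return area in Angstrom^2.
#' @export
residueSasa <- function(structure, residue_key, probe = 1.4,
                        n_points = 960L) {
  atoms <- structure@atoms
  if (is.null(atoms$S))
    structure <- atomAccessibility(structure, probe = probe,
                                   n_points = n_points)
  .residueSasaFromS(structure, residue_key, probe = probe)
}

## sidechain area from precomputed per-atom S factors
.residueSasaFromS <- function(structure, residue_key, probe = 1.4) {
  atoms <- structure@atoms
  type <- structure@residues$type[match(residue_key,
                                        structure@residues$key)]
  idx <- .sidechainIdx(atoms, residue_key, type)
  if (!length(idx)) return(0)
  r <- .bondiRadius(atoms$element[idx]) + probe
  sum(atoms$S[idx] * 4 * pi * r^2)
}

#' Partition a residue's accessible area into SASA or LASA
#'
#' The whole accessible area is labeled lipid-accessible (LASA) when the
#' lipid share of the residue's interaction-score sum exceeds 0.1 (strict
#' inequality), solvent-accessible (SASA) otherwise.
#'
#' @param residue_key residue key.
#' @param asa sidechain accessible surface area (Angstrom^2).
#' @param lipid_ratio from \code{\link{lipidScoreRatio}}, in [0, 1].
#' @param threshold classification threshold (default 0.1).
#' @return data.frame (one row): residue_key, sidechain_ASA, label,
#'   lipid_ratio.
#' @export
partitionAsa <- function(residue_key, asa, lipid_ratio, threshold = 0.1) {
  stopifnot(asa >= 0, lipid_ratio >= 0, lipid_ratio <= 1)
  data.frame(residue_key = residue_key, sidechain_ASA = asa,
             label = if (lipid_ratio > threshold) "LASA" else "SASA",
             lipid_ratio = lipid_ratio, stringsAsFactors = FALSE)
}

#' Interaction character of a map set
#'
#' Per-class sums of the grid values: (Hyd-, Hyd+, Pol-, Pol+) in score
#' units. By kernel conservation these equal the per-class pair-score sums.
#'
#' @param mapset a \linkS4class{MapSet}.
#' @return named numeric vector hydMinus, hydPlus, polMinus, polPlus.
#' @export
interactionCharacter <- function(mapset) {
  c(hydMinus = sum(mapset@fields$hydMinus),
    hydPlus = sum(mapset@fields$hydPlus),
    polMinus = sum(mapset@fields$polMinus),
    polPlus = sum(mapset@fields$polPlus))
}

#' Normalize a character vector by the random-coil SASA
#'
#' Each component is scaled by 100 / (random-coil SASA of the residue type),
#' making magnitudes comparable across residue sizes.
#'
#' @param character_vector from \code{\link{interactionCharacter}}.
#' @param residue_type three-letter type.
#' @param table reference areas (default \code{\link{randomCoilSasa}}).
#' @param scale numerator of the normalization factor (default 100).
#' @return normalized named numeric vector.
#' @export
normalizeCharacter <- function(character_vector, residue_type,
                               table = randomCoilSasa(), scale = 100) {
  rc <- table[residue_type]
  if (is.na(rc)) stop("no random-coil SASA for type ", residue_type)
  character_vector * scale / as.numeric(rc)
}

#' Summaries over a cluster catalog
#'
#' Produces per-cluster and per-type tables in the layout of the published
#' summaries: member counts, SASA/LASA mean +/- sd, the four character
#' columns, and per-type membrane-subset occurrence fractions
#' count_subset / (count_mS + count_mC + count_mL).
#'
#' @param catalog data.frame from \code{\link{clusterCatalog}} with an added
#'   \code{type} column, or NULL to skip the per-cluster table.
#' @param residue_data data.frame with one row per residue: key, type, env,
#'   sasa, lasa, hydMinus, hydPlus, polMinus, polPlus.
#' @return list: per_cluster (data.frame or NULL), per_type (data.frame),
#'   fractions (data.frame type, mS, mC, mL).
#' @export
summarizeCatalog <- function(catalog, residue_data) {
  msd <- function(x) {
    if (!length(x)) return(c(mean = 0, sd = 0))
    c(mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else 0)
  }
  per_cluster <- NULL
  if (!is.null(catalog) && nrow(catalog)) {
    rows <- lapply(seq_len(nrow(catalog)), function(i) {
      mem <- strsplit(catalog$members[i], ";", fixed = TRUE)[[1L]]
      rd <- residue_data[residue_data$key %in% mem, , drop = FALSE]
      s <- msd(rd$sasa); l <- msd(rd$lasa)
      data.frame(bin = catalog$bin[i], cluster = catalog$cluster[i],
                 count = length(mem),
                 sasa_mean = s["mean"], sasa_sd = s["sd"],
                 lasa_mean = l["mean"], lasa_sd = l["sd"],
                 hydMinus = mean(rd$hydMinus), hydPlus = mean(rd$hydPlus),
                 polMinus = mean(rd$polMinus), polPlus = mean(rd$polPlus),
                 stringsAsFactors = FALSE)
    })
    per_cluster <- do.call(rbind, rows)
    rownames(per_cluster) <- NULL
  }
  types <- sort(unique(residue_data$type))
  per_type <- do.call(rbind, lapply(types, function(tp) {
    rd <- residue_data[residue_data$type == tp, , drop = FALSE]
    s <- msd(rd$sasa); l <- msd(rd$lasa)
    data.frame(type = tp, count = nrow(rd),
               sasa_mean = s["mean"], sasa_sd = s["sd"],
               lasa_mean = l["mean"], lasa_sd = l["sd"],
               hydMinus = mean(rd$hydMinus), hydPlus = mean(rd$hydPlus),
               polMinus = mean(rd$polMinus), polPlus = mean(rd$polPlus),
               stringsAsFactors = FALSE)
  }))
  rownames(per_type) <- NULL
  fractions <- do.call(rbind, lapply(types, function(tp) {
    rd <- residue_data[residue_data$type == tp, , drop = FALSE]
    nm <- c(mS = sum(rd$env == "mS"), mC = sum(rd$env == "mC"),
            mL = sum(rd$env == "mL"))
    tot <- sum(nm)
    fr <- if (tot > 0) nm / tot else nm * NA_real_
    data.frame(type = tp, n_mS = nm["mS"], n_mC = nm["mC"], n_mL = nm["mL"],
               mS = fr["mS"], mC = fr["mC"], mL = fr["mL"],
               stringsAsFactors = FALSE)
  }))
  rownames(fractions) <- NULL
  list(per_cluster = per_cluster, per_type = per_type, fractions = fractions)
}
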