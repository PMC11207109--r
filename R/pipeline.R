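## End-to-end orchestration: classify -> bin -> score -> maps -> cluster ->
## surfaces -> character -> composite, with a single config carrying every
## threshold at its published default.

#' Pipeline configuration
#'
#' All tunable thresholds in one place, at their standard values: 6 Angstrom
#' lipid trim, 0.1 LASA ratio, 0.5 Angstrom grid spacing, 5 Angstrom grid
#' padding, 8 Angstrom pair cutoff, 1.4 Angstrom probe, and the
#' dataset-specific pH50 set.
#'
#' @param dataset "membrane" or "soluble" (selects the pH50 constants).
#' @param seed integer seed used for clustering.
#' @param ... overrides for individual entries.
#' @return named list.
#' @export
hydroConfig <- function(dataset = c("membrane", "soluble"), seed = 1L, ...) {
  dataset <- match.arg(dataset)
  cfg <- list(
    dataset = dataset, seed = as.integer(seed),
    trim_cutoff = 6.0, lasa_threshold = 0.1,
    spacing = 0.5, pad = 5.0, pair_cutoff = 8.0,
    probe = 1.4, sasa_points = 960L,
    kernel_sigma = 0.5, kernel_trunc = 2,
    phi_offset = 0, psi_offset = 0,
    min_members = 5L, gap_B = 50L,
    score_mode = "additive")
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

#' Run the full residue-deconstruction pipeline
#'
#' Reads (or accepts) a structure, trims distant lipids, places hydrogens,
#' classifies membrane environments, selects ionization states at the
#' dataset pH50s, computes per-atom accessibilities, assigns
#' backbone-conformation bins and canonical frames, scores partner pairs
#' and deposits the four-class maps (both mL and mN for lipid-facing
#' residues), computes SASA/LASA and interaction characters, clusters each
#' dataset's bins, and (optionally) accumulates protein-frame composite
#' maps and the additive score grid.
#'
#' @param pdb path/text accepted by \code{\link{readStructure}}, or a
#'   \linkS4class{HydroStructure}.
#' @param planes,pore_csv membrane-annotation sidecars (NULL for soluble
#'   mode); see \code{\link{readMembraneAnnotation}}.
#' @param config from \code{\link{hydroConfig}}.
#' @param cluster run the clustering stage.
#' @param composite accumulate composite maps and the score grid (membrane
#'   mode: mN composite, mL-mN composite).
#' @param ionize run ionization-state selection (ASP/CYS/GLU/HIS).
#' @return list: structure, env, bins, residue_data, maps, clusters,
#'   catalog, summary, composites, score, states, provenance.
#' @export
runPipeline <- function(pdb, planes = NULL, pore_csv = NULL,
                        config = hydroConfig(), cluster = TRUE,
                        composite = TRUE, ionize = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  s <- if (is(pdb, "HydroStructure")) pdb else readStructure(pdb)
  annotation <- if (!is.null(planes))
    readMembraneAnnotation(planes, pore_csv) else NULL

  s <- trimLipids(s, cutoff = config$trim_cutoff)
  s <- addHydrogens(s)
  env <- classifyEnvironment(s, annotation)
  s <- assignAtomConstants(s)
  s <- atomAccessibility(s, probe = config$probe,
                         n_points = config$sasa_points)

  states <- NULL
  if (ionize) {
    model <- ionizationModel(if (is.null(annotation)) "soluble" else "membrane")
    ion <- applyIonizationStates(s, model = model,
                                 include_lipids = !is.null(annotation))
    s <- ion$structure
    states <- ion$states
    s <- atomAccessibility(s, probe = config$probe,
                           n_points = config$sasa_points)
  }

  bins <- assignBins(s, phi_offset = config$phi_offset,
                     psi_offset = config$psi_offset)
  res <- s@residues

  maps <- list()
  rows <- list()
  frames <- list()
  for (i in seq_len(nrow(bins))) {
    key <- bins$key[i]
    tag <- env[key]
    if (is.na(tag)) next
    ra <- residueAtoms(s, key)
    fr <- tryCatch(canonicalFrame(ra, type = bins$type[i]),
                   error = function(e) NULL)
    if (is.null(fr)) next
    frames[[key]] <- fr
    gs <- residueGridSpec(bins$type[i], spacing = config$spacing,
                          pad = config$pad)
    modes <- if (tag == "mL") c("mL", "mN") else tag
    pp <- residuePartnerPairs(key, s, mode = modes[1L],
                              cutoff = config$pair_cutoff)
    mset <- list()
    mset[[modes[1L]]] <- computeMapSet(key, pp, gs, fr,
                                       bin = bins$bin[i], mode = modes[1L],
                                       sigma = config$kernel_sigma,
                                       trunc = config$kernel_trunc)
    if (length(modes) > 1L) {
      ppn <- pp[!pp$partner_is_lipid, , drop = FALSE]
      mset$mN <- computeMapSet(key, ppn, gs, fr, bin = bins$bin[i],
                               mode = "mN", sigma = config$kernel_sigma,
                               trunc = config$kernel_trunc)
    }
    maps[[key]] <- mset
    ratio <- lipidScoreRatio(pp)
    asa <- .residueSasaFromS(s, key, probe = config$probe)
    part <- partitionAsa(key, asa, ratio, threshold = config$lasa_threshold)
    ch <- interactionCharacter(mset[[modes[1L]]])
    rows[[length(rows) + 1L]] <- data.frame(
      key = key, type = bins$type[i], env = tag, square = bins$square[i],
      parse = bins$parse[i], bin = bins$bin[i],
      asa = asa, label = part$label, lipid_ratio = ratio,
      sasa = if (part$label == "SASA") asa else 0,
      lasa = if (part$label == "LASA") asa else 0,
      hydMinus = ch[["hydMinus"]], hydPlus = ch[["hydPlus"]],
      polMinus = ch[["polMinus"]], polPlus = ch[["polPlus"]],
      stringsAsFactors = FALSE)
  }
  residue_data <- if (length(rows)) do.call(rbind, rows) else NULL

  clusters <- list()
  if (cluster && !is.null(residue_data)) {
    kmax <- clusterKMax()
    for (tag in unique(residue_data$env)) {
      rd <- residue_data[residue_data$env == tag, , drop = FALSE]
      mode1 <- if (tag == "mL") "mL" else tag
      for (b in unique(paste(rd$type, rd$bin))) {
        sel <- rd[paste(rd$type, rd$bin) == b, , drop = FALSE]
        tp <- sel$type[1L]
        ms <- setNames(lapply(sel$key, function(k) maps[[k]][[mode1]]),
                       sel$key)
        entries <- clusterBin(ms, k_max = kmax[tp],
                              min_members = config$min_members,
                              seed = config$seed, B = config$gap_B)
        label <- paste0(tag, ".", tp, ".", sel$bin[1L])
        clusters[[label]] <- entries
        if (tag == "mL") {
          ## mN cluster averages reuse the mL membership and weights
          clusters[[paste0("mN.", tp, ".", sel$bin[1L])]] <-
            lapply(entries, function(e) {
              mn <- lapply(e@members, function(k) maps[[k]]$mN)
              avg <- averageMap(mn, as.numeric(e@weights[e@members]))
              new("ClusterEntry", name = e@name, members = e@members,
                  exemplar = e@exemplar, averageMap = avg,
                  weights = e@weights)
            })
        }
      }
    }
  }
  catalog <- clusterCatalog(clusters)
  summary <- if (!is.null(residue_data))
    summarizeCatalog(catalog, residue_data) else NULL

  composites <- NULL
  score <- NULL
  if (composite && !is.null(residue_data) && length(clusters)) {
    memb_keys <- residue_data$key[residue_data$env == "mL"]
    use_keys <- if (length(memb_keys)) memb_keys else residue_data$key
    mode1 <- if (length(memb_keys)) "mL" else
      residue_data$env[match(use_keys[1L], residue_data$key)]
    pg <- proteinGrid(atomCoords(s@atoms[s@atoms$residue_key %in% use_keys, ,
                                         drop = FALSE]),
                      spacing = config$spacing, pad = config$pad)
    ## each residue carries its cluster's average map
    clusterOf <- function(key, prefix) {
      rdrow <- residue_data[residue_data$key == key, ]
      label <- paste0(prefix, ".", rdrow$type, ".", rdrow$bin)
      ent <- clusters[[label]]
      if (is.null(ent)) return(NULL)
      for (e in ent) if (key %in% e@members) return(e@averageMap)
      NULL
    }
    rules <- list()
    assignA <- list()
    assignB <- list()
    for (key in use_keys) {
      rdrow <- residue_data[residue_data$key == key, ]
      gs <- residueGridSpec(rdrow$type, spacing = config$spacing,
                            pad = config$pad)
      rules[[key]] <- interpolationRules(frames[[key]], gs, pg)
      mA <- clusterOf(key, if (length(memb_keys)) "mL" else rdrow$env)
      if (!is.null(mA)) assignA[[key]] <- mA
      if (length(memb_keys)) {
        mB <- clusterOf(key, "mN")
        if (!is.null(mB)) assignB[[key]] <- mB
      }
    }
    compA <- accumulateComposite(assignA, rules, pg)
    composites <- list(grid = pg, primary = compA)
    if (length(assignB)) {
      compB <- accumulateComposite(assignB, rules, pg)
      composites$mN <- compB
      composites$lipid_only <- setNames(lapply(.MAP_CLASSES, function(cl)
        compA[[cl]] - compB[[cl]]), .MAP_CLASSES)
    }
    score <- scoreModel(assignA, rules, pg, mode = config$score_mode)
    score$s_field <- NULL  # keep the run report light
  }

  prov <- list(
    seed = config$seed,
    config = config[order(names(config))],
    counts = list(
      atoms = nrow(s@atoms), residues = nrow(s@residues),
      usable = sum(s@residues$usable),
      binned = nrow(bins),
      mapped = if (is.null(residue_data)) 0L else nrow(residue_data),
      clusters = if (is.null(catalog)) 0L else nrow(catalog)),
    env_counts = as.list(table(env, useNA = "no")),
    elapsed_s = proc.time()[["elapsed"]] - t0)

  list(structure = s, env = env, bins = bins, residue_data = residue_data,
       maps = maps, frames = frames, clusters = clusters, catalog = catalog,
       summary = summary, composites = composites, score = score,
       states = states, provenance = prov)
}

#' Write a provenance report for a pipeline run
#'
#' @param result from \code{\link{runPipeline}}.
#' @param path output JSON path.
#' @return invisibly, the path.
#' @export
writeProvenance <- function(result, path) {
  jsonlite::write_json(result$provenance, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
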