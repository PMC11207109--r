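## composite_score: protein-frame grids, frame-shift interpolation rules,
## composite map accumulation, and score-grid model evaluation/optimisation.

#' Protein-frame grid enclosing a selection
#'
#' Bounding box of the selected atoms, maxima increased and minima decreased
#' by 5 Angstrom, at 0.5 Angstrom spacing.
#'
#' @param coords n x 3 coordinate matrix (or an atom data.frame).
#' @param spacing grid spacing (Angstrom).
#' @param pad padding (Angstrom).
#' @return A \linkS4class{GridSpec}.
#' @export
proteinGrid <- function(coords, spacing = .GRID_SPACING, pad = .GRID_PAD) {
  if (is.data.frame(coords)) coords <- atomCoords(coords)
  stopifnot(nrow(coords) >= 1L)
  lo <- apply(coords, 2L, min) - pad
  hi <- apply(coords, 2L, max) + pad
  shape <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  shape <- pmax(shape, 2L)
  new("GridSpec", origin = as.numeric(lo), shape = shape, spacing = spacing)
}

#' Frame-shift interpolation rules for one residue
#'
#' The residue's canonical alignment is "unapplied": every protein-grid
#' point is carried into the residue frame, and points falling inside the
#' residue's standard grid box receive the eight enclosing residue-map node
#' indices and trilinear weights (sub-cube volumes normalized by the
#' spacing-cubed cell volume, 0.5^3 = 0.125). Points outside are irrelevant.
#'
#' @param frame the residue's canonical \linkS4class{FrameTransform}
#'   (lab -> residue frame).
#' @param residue_grid_spec the residue type's \linkS4class{GridSpec}.
#' @param protein_grid the protein-frame \linkS4class{GridSpec}.
#' @return list: points (protein-grid linear indices, 1-based), indices
#'   (n x 8 residue-grid linear indices), weights (n x 8, rows sum to 1).
#' @export
interpolationRules <- function(frame, residue_grid_spec, protein_grid) {
  rg <- residue_grid_spec
  pg <- protein_grid
  sp <- rg@spacing
  ## lab-frame bounding box of the residue box limits the candidate nodes
  ext <- rg@origin + (rg@shape - 1L) * sp
  corners <- as.matrix(expand.grid(c(rg@origin[1L], ext[1L]),
                                   c(rg@origin[2L], ext[2L]),
                                   c(rg@origin[3L], ext[3L])))
  inv <- invertFrame(frame)
  lab <- applyFrame(inv, corners)
  lo <- apply(lab, 2L, min)
  hi <- apply(lab, 2L, max)
  i1 <- pmax(1L, as.integer(floor((lo - pg@origin) / pg@spacing)) + 1L)
  i2 <- pmin(pg@shape, as.integer(ceiling((hi - pg@origin) / pg@spacing)) + 1L)
  if (any(i1 > i2))
    return(list(points = integer(0),
                indices = matrix(integer(0), 0L, 8L),
                weights = matrix(numeric(0), 0L, 8L)))
  ax <- gridAxes(pg)
  gx <- ax[[1L]][i1[1L]:i2[1L]]
  gy <- ax[[2L]][i1[2L]:i2[2L]]
  gz <- ax[[3L]][i1[3L]:i2[3L]]
  cand <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  q <- applyFrame(frame, cand)
  f <- sweep(q, 2L, rg@origin, `-`) / sp
  eps <- 1e-9
  inside <- f[, 1L] >= -eps & f[, 1L] <= rg@shape[1L] - 1 + eps &
    f[, 2L] >= -eps & f[, 2L] <= rg@shape[2L] - 1 + eps &
    f[, 3L] >= -eps & f[, 3L] <= rg@shape[3L] - 1 + eps
  if (!any(inside))
    return(list(points = integer(0),
                indices = matrix(integer(0), 0L, 8L),
                weights = matrix(numeric(0), 0L, 8L)))
  f <- f[inside, , drop = FALSE]
  ## protein-grid linear indices of the candidates (1-based, x fastest)
  ci <- as.matrix(expand.grid(i1[1L]:i2[1L], i1[2L]:i2[2L], i1[3L]:i2[3L]))
  ci <- ci[inside, , drop = FALSE]
  plin <- ci[, 1L] + (ci[, 2L] - 1L) * pg@shape[1L] +
    (ci[, 3L] - 1L) * pg@shape[1L] * pg@shape[2L]
  i0 <- pmin(pmax(floor(f[, 1L]), 0), rg@shape[1L] - 2L)
  j0 <- pmin(pmax(floor(f[, 2L]), 0), rg@shape[2L] - 2L)
  k0 <- pmin(pmax(floor(f[, 3L]), 0), rg@shape[3L] - 2L)
  fx <- pmin(pmax(f[, 1L] - i0, 0), 1)
  fy <- pmin(pmax(f[, 2L] - j0, 0), 1)
  fz <- pmin(pmax(f[, 3L] - k0, 0), 1)
  nx <- rg@shape[1L]; nxy <- nx * rg@shape[2L]
  base <- 1L + i0 + j0 * nx + k0 * nxy
  idx <- cbind(base, base + 1L, base + nx, base + nx + 1L,
               base + nxy, base + nxy + 1L, base + nxy + nx,
               base + nxy + nx + 1L)
  w <- cbind((1 - fx) * (1 - fy) * (1 - fz), fx * (1 - fy) * (1 - fz),
             (1 - fx) * fy * (1 - fz), fx * fy * (1 - fz),
             (1 - fx) * (1 - fy) * fz, fx * (1 - fy) * fz,
             (1 - fx) * fy * fz, fx * fy * fz)
  list(points = as.integer(plin), indices = idx, weights = w)
}

## interpolate one residue-frame field onto the protein grid (sparse):
## returns values aligned with rules$points
.interpField <- function(field, rules) {
  if (!length(rules$points)) return(numeric(0))
  v <- field[rules$indices]
  dim(v) <- dim(rules$indices)
  rowSums(rules$weights * v)
}

#' Accumulate residue maps into protein-frame composite fields
#'
#' @param assignment named list residue_key -> \linkS4class{MapSet} (on the
#'   residue's standard grid).
#' @param rules named list residue_key -> interpolation rules.
#' @param protein_grid the protein-frame \linkS4class{GridSpec}.
#' @return named list of four 3D arrays (hydPlus, hydMinus, polPlus,
#'   polMinus) over the protein grid.
#' @export
accumulateComposite <- function(assignment, rules, protein_grid) {
  comp <- setNames(lapply(.MAP_CLASSES, function(cl) zeroField(protein_grid)),
                   .MAP_CLASSES)
  for (key in names(assignment)) {
    ru <- rules[[key]]
    if (is.null(ru)) stop("no interpolation rules for residue ", key)
    ms <- assignment[[key]]
    if (!identical(as.integer(dim(ms@fields[[1L]])),
                   as.integer(residueGridShapeOf(ms))))
      stop("assigned map does not match its grid")
    if (!length(ru$points)) next
    for (cl in .MAP_CLASSES) {
      v <- .interpField(ms@fields[[cl]], ru)
      comp[[cl]][ru$points] <- comp[[cl]][ru$points] + v
    }
  }
  comp
}

## dim of a MapSet's grid (helper kept terse)
residueGridShapeOf <- function(ms) ms@grid@shape

#' Number of candidate models
#'
#' Product of the per-residue candidate-map counts (an empty selection has
#' one trivial model).
#'
#' @param candidate_counts integer vector of per-residue map counts.
#' @return number of unique models.
#' @export
countModels <- function(candidate_counts) {
  if (!length(candidate_counts)) return(1)
  stopifnot(all(candidate_counts >= 1))
  prod(as.numeric(candidate_counts))
}

#' Score a complete sidechain-map assignment on the protein grid
#'
#' Additive mode (the literal score grid): each grid point holds the sum of
#' all interpolated map values and \code{S_model} is the grand total.
#' Overlap mode additionally rewards same-class co-location between
#' different residues' maps: with net fields \code{h_i = Hyd+ + Hyd-} and
#' \code{p_i = Pol+ + Pol-}, the reward is
#' \code{sum_points sum_{i<j} (h_i h_j + p_i p_j)} (same-sign co-location
#' adds, opposing-sign co-location subtracts).
#'
#' @param assignment named list residue_key -> \linkS4class{MapSet}.
#' @param rules named list residue_key -> interpolation rules.
#' @param protein_grid \linkS4class{GridSpec}.
#' @param mode "additive" (default) or "overlap".
#' @return list: S_model (scalar), s_field (3D array over the protein
#'   grid), mode.
#' @export
scoreModel <- function(assignment, rules, protein_grid,
                       mode = c("additive", "overlap")) {
  mode <- match.arg(mode)
  missing_rules <- setdiff(names(assignment), names(rules))
  if (length(missing_rules))
    stop("incomplete rules for: ", paste(missing_rules, collapse = ", "))
  s <- zeroField(protein_grid)
  sumH <- NULL; sumP <- NULL; sumH2 <- NULL; sumP2 <- NULL
  if (mode == "overlap") {
    sumH <- zeroField(protein_grid); sumP <- zeroField(protein_grid)
    sumH2 <- zeroField(protein_grid); sumP2 <- zeroField(protein_grid)
  }
  for (key in names(assignment)) {
    ru <- rules[[key]]
    if (!length(ru$points)) next
    ms <- assignment[[key]]
    h <- .interpField(ms@fields$hydPlus, ru) +
      .interpField(ms@fields$hydMinus, ru)
    p <- .interpField(ms@fields$polPlus, ru) +
      .interpField(ms@fields$polMinus, ru)
    s[ru$points] <- s[ru$points] + h + p
    if (mode == "overlap") {
      sumH[ru$points] <- sumH[ru$points] + h
      sumP[ru$points] <- sumP[ru$points] + p
      sumH2[ru$points] <- sumH2[ru$points] + h * h
      sumP2[ru$points] <- sumP2[ru$points] + p * p
    }
  }
  S <- sum(s)
  if (mode == "overlap") {
    reward <- 0.5 * (sum(sumH * sumH) - sum(sumH2)) +
      0.5 * (sum(sumP * sumP) - sum(sumP2))
    s <- s + 0.5 * (sumH * sumH - sumH2) + 0.5 * (sumP * sumP - sumP2)
    S <- S + reward
  }
  list(S_model = S, s_field = s, mode = mode)
}

#' Optimize the map assignment over candidate sets
#'
#' Exhaustive enumeration when \code{countModels} does not exceed
#' \code{exhaustive_limit}; otherwise seeded steepest-ascent coordinate
#' search with random restarts within the evaluation budget. In additive
#' mode the problem is separable and the optimum is the per-residue argmax.
#'
#' @param candidates named list residue_key -> list of \linkS4class{MapSet}
#'   candidates.
#' @param rules named list residue_key -> interpolation rules.
#' @param protein_grid \linkS4class{GridSpec}.
#' @param mode "additive" or "overlap".
#' @param budget maximum model evaluations for the stochastic search.
#' @param seed integer seed for restarts.
#' @param exhaustive_limit switch point between enumeration and search.
#' @return list: assignment (named integer vector of chosen candidate
#'   indices), S_model, mode, n_models, method.
#' @export
optimizeAssignment <- function(candidates, rules, protein_grid,
                               mode = c("additive", "overlap"),
                               budget = 2000L, seed = 1L,
                               exhaustive_limit = 1e6) {
  mode <- match.arg(mode)
  stopifnot(all(vapply(candidates, length, integer(1)) >= 1L))
  keys <- names(candidates)
  counts <- vapply(candidates, length, integer(1))
  nmod <- countModels(counts)

  ## per-candidate interpolated net fields (sparse over each rule support)
  cache <- lapply(keys, function(k) {
    ru <- rules[[k]]
    lapply(candidates[[k]], function(ms) {
      h <- .interpField(ms@fields$hydPlus, ru) +
        .interpField(ms@fields$hydMinus, ru)
      p <- .interpField(ms@fields$polPlus, ru) +
        .interpField(ms@fields$polMinus, ru)
      list(h = h, p = p, add = sum(h) + sum(p))
    })
  })
  names(cache) <- keys

  if (mode == "additive") {
    ## separable: optimum is the independent per-residue argmax
    pick <- vapply(keys, function(k)
      which.max(vapply(cache[[k]], `[[`, numeric(1), "add")), integer(1))
    S <- sum(vapply(keys, function(k) cache[[k]][[pick[k]]]$add, numeric(1)))
    return(list(assignment = pick, S_model = S, mode = mode,
                n_models = nmod, method = "separable"))
  }

  evalAssign <- function(pick) {
    sumH <- zeroField(protein_grid); sumP <- zeroField(protein_grid)
    S2h <- 0; S2p <- 0; Sadd <- 0
    for (k in keys) {
      ru <- rules[[k]]
      if (!length(ru$points)) next
      cv <- cache[[k]][[pick[k]]]
      sumH[ru$points] <- sumH[ru$points] + cv$h
      sumP[ru$points] <- sumP[ru$points] + cv$p
      S2h <- S2h + sum(cv$h^2)
      S2p <- S2p + sum(cv$p^2)
      Sadd <- Sadd + cv$add
    }
    Sadd + 0.5 * (sum(sumH^2) - S2h) + 0.5 * (sum(sumP^2) - S2p)
  }

  if (nmod <= exhaustive_limit) {
    pick <- setNames(rep(1L, length(keys)), keys)
    best <- pick
    bestS <- evalAssign(pick)
    repeat {
      ## odometer increment over candidate indices
      i <- 1L
      while (i <= length(keys)) {
        if (pick[i] < counts[i]) { pick[i] <- pick[i] + 1L; break }
        pick[i] <- 1L
        i <- i + 1L
      }
      if (i > length(keys)) break
      S <- evalAssign(pick)
      if (S > bestS) { bestS <- S; best <- pick }
    }
    return(list(assignment = best, S_model = bestS, mode = mode,
                n_models = nmod, method = "exhaustive"))
  }

  ## steepest-ascent coordinate search with random restarts
  set.seed(seed)
  evals <- 0L
  bestS <- -Inf
  best <- NULL
  while (evals < budget) {
    pick <- setNames(vapply(counts, function(n) sample.int(n, 1L),
                            integer(1)), keys)
    S <- evalAssign(pick); evals <- evals + 1L
    improved <- TRUE
    while (improved && evals < budget) {
      improved <- FALSE
      for (k in keys) {
        for (ci in seq_len(counts[k])) {
          if (ci == pick[k]) next
          trial <- pick
          trial[k] <- ci
          St <- evalAssign(trial); evals <- evals + 1L
          if (St > S) { S <- St; pick <- trial; improved <- TRUE }
          if (evals >= budget) break
        }
        if (evals >= budget) break
      }
    }
    if (S > bestS) { bestS <- S; best <- pick }
  }
  list(assignment = best, S_model = bestS, mode = mode,
       n_models = nmod, method = "hillclimb")
}
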