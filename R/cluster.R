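## clustering: map-map similarity, per-bin k-means with gap-statistic k
## selection, singleton backfill, exemplars and Gaussian-weighted averages.

#' Maximum cluster count per residue type
#'
#' Manually set caps reflecting each type's structural complexity.
#'
#' @return named integer vector over the 21 residue types.
#' @export
clusterKMax <- function() {
  c(ALA = 4L, ARG = 18L, ASN = 12L, ASP = 12L, CYS = 6L, CYX = 12L,
    GLN = 12L, GLU = 12L, GLY = 9L, HIS = 12L, ILE = 9L, LEU = 9L,
    LYS = 18L, MET = 18L, PHE = 12L, PRO = 6L, SER = 6L, THR = 6L,
    TRP = 12L, TYR = 12L, VAL = 9L)
}

#' Similarity between two map sets
#'
#' Per-class Hodgkin index \code{H_c = 2 sum(f_a f_b) / (sum(f_a^2) +
#' sum(f_b^2))} over the four fields, combined as the mean weighted by each
#' class's joint norm \code{sum(f_a^2) + sum(f_b^2)}. Bounded in [-1, 1];
#' 1 for identical non-empty maps, -1 for a map and its negation, 0 for
#' disjoint support or when both maps are empty.
#'
#' @param mapset_a,mapset_b \linkS4class{MapSet}s on identical grids.
#' @return similarity in [-1, 1].
#' @export
mapSimilarity <- function(mapset_a, mapset_b) {
  if (!identical(mapset_a@grid@shape, mapset_b@grid@shape) ||
      max(abs(mapset_a@grid@origin - mapset_b@grid@origin)) > 1e-9)
    stop("map similarity requires identical grids")
  num <- 0
  den <- 0
  for (cl in .MAP_CLASSES) {
    fa <- mapset_a@fields[[cl]]
    fb <- mapset_b@fields[[cl]]
    n2 <- sum(fa * fa) + sum(fb * fb)
    if (n2 <= 0) next
    h <- 2 * sum(fa * fb) / n2
    num <- num + n2 * h
    den <- den + n2
  }
  if (den <= 0) return(0)
  num / den
}

#' Pairwise similarity matrix for a bin of map sets
#'
#' @param mapsets named list of \linkS4class{MapSet}s (one bin).
#' @return symmetric matrix with unit diagonal, dimnames = member keys.
#' @export
similarityMatrix <- function(mapsets) {
  n <- length(mapsets)
  stopifnot(n >= 1L)
  keys <- names(mapsets)
  if (is.null(keys)) keys <- as.character(seq_len(n))
  m <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        s <- mapSimilarity(mapsets[[i]], mapsets[[j]])
        m[i, j] <- s
        m[j, i] <- s
      }
    }
  }
  dimnames(m) <- list(keys, keys)
  m
}

.kmeansFun <- function(x, k) {
  if (k == 1L) return(list(cluster = rep(1L, nrow(x))))
  stats::kmeans(x, centers = k, nstart = 25L, iter.max = 100L)
}

#' Choose the number of clusters by the gap statistic
#'
#' Tibshirani gap statistic (uniform reference sets over the feature box, B
#' bootstrap sets) on the similarity-matrix rows, over
#' k = 1..min(k_max, n-1). The chosen k is the one with the dominant gap
#' increase (largest jump of the gap curve), guarded by a 1-SE significance
#' check against the k = 1 gap; structureless bins return 1, as do
#' degenerate bins with all members identical. The jump criterion is
#' preferred over the original smallest-k 1-SE stopping rule because with
#' tight, well-separated map clusters the gap curve keeps creeping upward
#' past the true k by more than its (very small) simulation error.
#'
#' @param matrix similarity matrix from \code{\link{similarityMatrix}}.
#' @param k_max cap on k for this residue type.
#' @param seed integer seed (gap reference sets and k-means starts).
#' @param B number of reference sets (default 50).
#' @return chosen k (integer).
#' @export
chooseK <- function(matrix, k_max, seed = 1L, B = 50L) {
  x <- unname(matrix)
  n <- nrow(x)
  kmax <- min(as.integer(k_max), n - 1L)
  if (kmax < 2L) return(1L)
  if (max(stats::dist(x)) < 1e-9) return(1L)
  set.seed(seed)
  gap <- cluster::clusGap(x, FUNcluster = .kmeansFun, K.max = kmax,
                          B = as.integer(B), spaceH0 = "original",
                          verbose = FALSE)
  g <- gap$Tab[, "gap"]
  se <- gap$Tab[, "SE.sim"]
  jumps <- diff(g)
  kbest <- which.max(jumps) + 1L
  if (g[kbest] <= g[1L] + se[1L]) return(1L)
  min(as.integer(kbest), as.integer(k_max))
}

#' Gaussian-weighted average of member maps
#'
#' @param mapsets list of \linkS4class{MapSet}s on one grid.
#' @param weights numeric weights summing to 1 (e.g. Gaussian in the
#'   centroid distance).
#' @return A \linkS4class{MapSet}.
#' @export
averageMap <- function(mapsets, weights) {
  stopifnot(length(mapsets) == length(weights),
            abs(sum(weights) - 1) < 1e-9)
  g <- mapsets[[1L]]@grid
  f <- setNames(lapply(.MAP_CLASSES, function(cl) {
    acc <- zeroField(g)
    for (i in seq_along(mapsets)) acc <- acc + weights[i] * mapsets[[i]]@fields[[cl]]
    acc
  }), .MAP_CLASSES)
  p <- mapsets[[1L]]@provenance
  new("MapSet", grid = g, fields = f,
      provenance = list(residue_key = "average", bin = p$bin %||% "",
                        mode = p$mode %||% ""),
      clipped = list(n = 0L, score = 0))
}

## Gaussian weights from centroid distances: w_i = exp(-d_i^2 / (2 s^2)),
## s = median distance (epsilon if all zero), normalized to sum 1.
.gaussianWeights <- function(d) {
  s <- stats::median(d)
  if (s < 1e-12) s <- 1e-12
  w <- exp(-d^2 / (2 * s^2))
  w / sum(w)
}

#' Cluster one bin of residue maps
#'
#' Bins with fewer than \code{min_members} maps are averaged into a single
#' pseudo-cluster. Larger bins are k-means clustered (similarity-matrix rows
#' as feature vectors, gap-statistic k, fixed seed); members whose distance
#' to their assigned centroid exceeds mean + 3 sd of all within-cluster
#' distances are split out as singleton clusters (backfill). Each cluster is
#' named by its exemplar's ordinal in the bin's member list; the exemplar is
#' the member most similar to the cluster's Gaussian-weighted average map.
#'
#' @param mapsets named list of \linkS4class{MapSet}s (ordinal order).
#' @param k_max cap on k (per residue type; see \code{\link{clusterKMax}}).
#' @param min_members minimum bin size for clustering proper (default 5).
#' @param seed integer seed.
#' @param B gap-statistic reference sets.
#' @return list of \linkS4class{ClusterEntry}.
#' @export
clusterBin <- function(mapsets, k_max, min_members = 5L, seed = 1L, B = 50L) {
  n <- length(mapsets)
  stopifnot(n >= 1L)
  keys <- names(mapsets)
  if (is.null(keys)) {
    keys <- as.character(seq_len(n))
    names(mapsets) <- keys
  }
  if (n < min_members) {
    w <- rep(1 / n, n)
    avg <- averageMap(mapsets, w)
    sims <- vapply(mapsets, mapSimilarity, numeric(1), mapset_b = avg)
    ex <- which.max(sims)
    return(list(new("ClusterEntry", name = as.character(ex),
                    members = keys, exemplar = keys[ex], averageMap = avg,
                    weights = setNames(w, keys))))
  }
  sm <- similarityMatrix(mapsets)
  feats <- unname(sm)
  k <- chooseK(sm, k_max = k_max, seed = seed, B = B)
  set.seed(seed)
  assign <- .kmeansFun(feats, k)$cluster
  ## singleton backfill on pooled within-cluster distances
  cent <- function(rows) colMeans(feats[rows, , drop = FALSE])
  d <- numeric(n)
  for (cl in unique(assign)) {
    rows <- which(assign == cl)
    cc <- cent(rows)
    d[rows] <- sqrt(colSums((t(feats[rows, , drop = FALSE]) - cc)^2))
  }
  sdd <- stats::sd(d)
  if (is.finite(sdd) && sdd > 0) {
    thr <- mean(d) + 3 * sdd
    out <- which(d > thr)
    if (length(out)) {
      nxt <- max(assign) + 1L
      for (i in out) {
        if (sum(assign == assign[i]) > 1L) {
          assign[i] <- nxt
          nxt <- nxt + 1L
        }
      }
    }
  }
  entries <- list()
  for (cl in sort(unique(assign))) {
    rows <- which(assign == cl)
    cc <- cent(rows)
    dd <- sqrt(colSums((t(feats[rows, , drop = FALSE]) - cc)^2))
    w <- .gaussianWeights(dd)
    avg <- averageMap(mapsets[rows], w)
    sims <- vapply(mapsets[rows], mapSimilarity, numeric(1), mapset_b = avg)
    ex <- rows[which.max(sims)]
    entries[[length(entries) + 1L]] <-
      new("ClusterEntry", name = as.character(ex), members = keys[rows],
          exemplar = keys[ex], averageMap = avg,
          weights = setNames(w, keys[rows]))
  }
  entries
}

#' Cluster catalog table
#'
#' Flattens cluster entries (across bins) into the catalog layout: bin,
#' cluster name, member count, exemplar, member list.
#'
#' @param bins named list: bin label -> list of \linkS4class{ClusterEntry}.
#' @return data.frame.
#' @export
clusterCatalog <- function(bins) {
  rows <- list()
  for (b in names(bins)) {
    for (e in bins[[b]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        bin = b, cluster = e@name, count = length(e@members),
        exemplar = e@exemplar,
        members = paste(e@members, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(bin = character(0), cluster = character(0),
                      count = integer(0), exemplar = character(0),
                      members = character(0)))
  do.call(rbind, rows)
}
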