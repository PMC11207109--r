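test_that("protein grids pad the bounding box by 5 A at 0.5 A spacing", {
  g <- proteinGrid(matrix(c(0, 0, 0), 1L))
  expect_equal(g@origin, c(-5, -5, -5))
  expect_equal(g@spacing, 0.5)
  ax <- gridAxes(g)
  expect_true(all(vapply(ax, max, numeric(1)) >= 5))
  ## adding a distant atom enlarges the box monotonically
  g2 <- proteinGrid(rbind(c(0, 0, 0), c(10, 3, -4)))
  expect_true(all(g2@shape >= g@shape))
  expect_true(all(g2@origin <= g@origin))
})

test_that("interpolation rules are trilinear with unit weight sums", {
  rg <- new("GridSpec", origin = c(-2, -2, -2), shape = c(9L, 9L, 9L),
            spacing = 0.5)
  pg <- new("GridSpec", origin = c(-2, -2, -2), shape = c(9L, 9L, 9L),
            spacing = 0.5)
  ## identity frame, coincident grids: every relevant point hits one node
  ru <- interpolationRules(identityFrame(), rg, pg)
  expect_equal(length(ru$points), prod(pg@shape))
  expect_equal(max(abs(rowSums(ru$weights) - 1)), 0, tolerance = 1e-9)
  expect_true(all(apply(ru$weights, 1L, max) > 1 - 1e-9))
  ## half-spacing shift: cube centres, eight weights of 0.125
  fr <- frameOf(diag(3), c(0.25, 0.25, 0.25))
  ru2 <- interpolationRules(fr, rg, pg)
  inner <- which(apply(ru2$weights, 1L, min) > 0)
  expect_true(length(inner) > 0)
  expect_true(all(abs(ru2$weights[inner, ] - 0.125) < 1e-9))
  expect_equal(max(abs(rowSums(ru2$weights) - 1)), 0, tolerance = 1e-9)
  ## rotated frames keep the unit weight sum at every relevant point
  set.seed(31)
  for (i in 1:5) {
    fr3 <- frameOf(hydromaps:::randomRotation(), runif(3, -0.6, 0.6))
    ru3 <- interpolationRules(fr3, rg, pg)
    if (length(ru3$points))
      expect_equal(max(abs(rowSums(ru3$weights) - 1)), 0, tolerance = 1e-9)
  }
})

test_that("composite accumulation is exact for coincident grids and linear", {
  rg <- new("GridSpec", origin = c(-2, -2, -2), shape = c(9L, 9L, 9L),
            spacing = 0.5)
  pg <- new("GridSpec", origin = c(-4, -4, -4), shape = c(17L, 17L, 17L),
            spacing = 0.5)
  mkMap <- function(seed) {
    set.seed(seed)
    ms <- emptyMapSet(rg)
    f <- hydromaps:::zeroField(rg)
    f[sample(prod(rg@shape), 40L)] <- runif(40L, 0.2, 2)
    ms@fields$hydPlus <- f
    f2 <- hydromaps:::zeroField(rg)
    f2[sample(prod(rg@shape), 40L)] <- -runif(40L, 0.2, 2)
    ms@fields$polMinus <- f2
    ms
  }
  a <- mkMap(1); b <- mkMap(2)
  rules <- list(r1 = interpolationRules(identityFrame(), rg, pg))
  compA <- accumulateComposite(list(r1 = a), rules, pg)
  ## identity frame, commensurate grids: composite equals the residue map
  ## on the overlap
  expect_equal(sum(compA$hydPlus), sum(a@fields$hydPlus), tolerance = 1e-9)
  expect_equal(sort(compA$hydPlus[compA$hydPlus != 0]),
               sort(a@fields$hydPlus[a@fields$hydPlus != 0]),
               tolerance = 1e-9)
  ## all-zero assignment -> zero composite
  z <- accumulateComposite(list(r1 = emptyMapSet(rg)), rules, pg)
  expect_true(all(z$hydPlus == 0))
  ## linearity: accumulate(a) + accumulate(b) = accumulate(a+b)
  ab <- emptyMapSet(rg)
  for (cl in names(ab@fields))
    ab@fields[[cl]] <- a@fields[[cl]] + b@fields[[cl]]
  compB <- accumulateComposite(list(r1 = b), rules, pg)
  compAB <- accumulateComposite(list(r1 = ab), rules, pg)
  expect_equal(compAB$hydPlus, compA$hydPlus + compB$hydPlus,
               tolerance = 1e-9)
  expect_equal(compAB$polMinus, compA$polMinus + compB$polMinus,
               tolerance = 1e-9)
})

test_that("translated frames conserve composite map mass", {
  rg <- new("GridSpec", origin = c(-2, -2, -2), shape = c(9L, 9L, 9L),
            spacing = 0.5)
  pg <- new("GridSpec", origin = c(-6, -6, -6), shape = c(25L, 25L, 25L),
            spacing = 0.5)
  set.seed(5)
  ms <- emptyMapSet(rg)
  f <- hydromaps:::zeroField(rg)
  ## deposits live in the padded interior of the residue box (as real maps
  ## do); boundary nodes have no complete dual interpolation cell
  interior <- as.matrix(expand.grid(2:8, 2:8, 2:8))
  lin <- interior[, 1] + (interior[, 2] - 1) * 9 + (interior[, 3] - 1) * 81
  f[sample(lin, 60L)] <- runif(60L, 0.2, 2)
  ms@fields$hydPlus <- f
  for (i in 1:5) {
    fr <- frameOf(diag(3), runif(3, -0.45, 0.45))
    ru <- interpolationRules(fr, rg, pg)
    comp <- accumulateComposite(list(r = ms), list(r = ru), pg)
    expect_equal(sum(comp$hydPlus), sum(ms@fields$hydPlus),
                 tolerance = 1e-5)
  }
})

test_that("model counting is the product of candidate counts", {
  expect_equal(countModels(c(6, 12, 12, 12, 4)), 41472)
  expect_equal(countModels(integer(0)), 1)
  expect_equal(countModels(1), 1)
  expect_equal(countModels(c(2, 3)), 6)
  expect_error(countModels(c(2, 0)))
})

## shared toy candidate problem for the score/optimizer tests
toyProblem <- function(n_res = 3L, n_cand = 3L, seed = 1L) {
  rg <- new("GridSpec", origin = c(-1, -1, -1), shape = c(5L, 5L, 5L),
            spacing = 0.5)
  pg <- new("GridSpec", origin = c(-3, -3, -3), shape = c(13L, 13L, 13L),
            spacing = 0.5)
  set.seed(seed)
  cands <- list()
  rules <- list()
  for (r in seq_len(n_res)) {
    key <- paste0("r", r)
    fr <- frameOf(diag(3), runif(3, -1, 1))
    rules[[key]] <- interpolationRules(fr, rg, pg)
    cands[[key]] <- lapply(seq_len(n_cand), function(ci) {
      ms <- emptyMapSet(rg)
      f <- hydromaps:::zeroField(rg)
      f[sample(prod(rg@shape), 15L)] <- runif(15L, 0, 1.5)
      ms@fields$hydPlus <- f
      g <- hydromaps:::zeroField(rg)
      g[sample(prod(rg@shape), 10L)] <- -runif(10L, 0, 1)
      ms@fields$hydMinus <- g
      ms
    })
  }
  list(cands = cands, rules = rules, pg = pg)
}

test_that("the additive score grid is the literal sum of interpolated maps", {
  tp <- toyProblem()
  one <- list(r1 = tp$cands$r1[[1L]])
  sc <- scoreModel(one, tp$rules, tp$pg, mode = "additive")
  ru <- tp$rules$r1
  manual <- sum(hydromaps:::.interpField(one$r1@fields$hydPlus, ru)) +
    sum(hydromaps:::.interpField(one$r1@fields$hydMinus, ru))
  expect_equal(sc$S_model, manual, tolerance = 1e-9)
  ## all-zero maps -> 0
  rg <- one$r1@grid
  z <- scoreModel(list(r1 = emptyMapSet(rg)), tp$rules, tp$pg)
  expect_equal(z$S_model, 0)
  ## additivity across residues
  full <- list(r1 = tp$cands$r1[[1]], r2 = tp$cands$r2[[2]],
               r3 = tp$cands$r3[[3]])
  parts <- vapply(names(full), function(k) {
    scoreModel(full[k], tp$rules, tp$pg)$S_model
  }, numeric(1))
  expect_equal(scoreModel(full, tp$rules, tp$pg)$S_model, sum(parts),
               tolerance = 1e-9)
  ## incomplete rules error
  expect_error(scoreModel(list(zz = tp$cands$r1[[1]]), tp$rules, tp$pg),
               "incomplete")
})

test_that("the optimizer returns trivial and separable optima exactly", {
  tp <- toyProblem()
  ## single candidate per residue -> that assignment
  single <- lapply(tp$cands, `[`, 1L)
  opt <- optimizeAssignment(single, tp$rules, tp$pg, mode = "additive")
  expect_true(all(opt$assignment == 1L))
  ## additive exhaustive optimum equals the per-residue argmax
  opt2 <- optimizeAssignment(tp$cands, tp$rules, tp$pg, mode = "additive")
  manual <- vapply(names(tp$cands), function(k) {
    which.max(vapply(tp$cands[[k]], function(ms)
      scoreModel(setNames(list(ms), k), tp$rules, tp$pg)$S_model,
      numeric(1)))
  }, integer(1))
  expect_equal(opt2$assignment, manual)
})

test_that("exhaustive search recovers a planted overlap optimum", {
  rg <- new("GridSpec", origin = c(-1, -1, -1), shape = c(5L, 5L, 5L),
            spacing = 0.5)
  pg <- new("GridSpec", origin = c(-2, -2, -2), shape = c(9L, 9L, 9L),
            spacing = 0.5)
  ## two residues, same support: one candidate pair co-locates (reward),
  ## the others are disjoint
  target <- sample(1:3, 2L)
  mk <- function(nodes, val) {
    ms <- emptyMapSet(rg)
    f <- hydromaps:::zeroField(rg)
    f[nodes] <- val
    ms@fields$hydPlus <- f
    ms
  }
  shared <- 40:50
  cands <- list(
    r1 = list(mk(1:10, 0.2), mk(shared, 1), mk(60:70, 0.2)),
    r2 = list(mk(80:90, 0.2), mk(shared, 1), mk(100:110, 0.2)))
  rules <- list(r1 = interpolationRules(identityFrame(), rg, pg),
                r2 = interpolationRules(identityFrame(), rg, pg))
  opt <- optimizeAssignment(cands, rules, pg, mode = "overlap")
  expect_equal(opt$method, "exhaustive")
  expect_equal(unname(opt$assignment), c(2L, 2L))
  ## sanity: the overlap score beats 100 random assignments
  set.seed(2)
  for (i in 1:100) {
    pick <- setNames(sample(1:3, 2L, replace = TRUE), c("r1", "r2"))
    asn <- list(r1 = cands$r1[[pick[1]]], r2 = cands$r2[[pick[2]]])
    expect_lte(scoreModel(asn, rules, pg, mode = "overlap")$S_model,
               opt$S_model + 1e-9)
  }
})
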