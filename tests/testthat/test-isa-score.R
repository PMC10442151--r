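solidGrid <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      rec <- shellReceptor(radius = 10, thickness = 9.99, nAtoms = 1500,
                           solid = TRUE, seed = 41)
      cache <<- list(rec = rec$structure,
                     grid = buildScoringGrid(rec$structure, binWidth = 1))
    }
    cache
  }
})

test_that("score classification follows the published cutoffs", {
  expect_equal(classifyScore(8.4), "fitting")
  expect_equal(classifyScore(406.2), "non_fitting")
  expect_equal(classifyScore(100), "marginal")   # "lower than 100" fits
  expect_equal(classifyScore(150), "non_fitting")  # "150 and above"
  expect_equal(classifyScore(c(0, 99.999, 149.999)),
               c("fitting", "fitting", "marginal"))
  expect_error(classifyScore(-1), "negative")
  expect_equal(classifyScore(120, cutoffs = c(130, 200)), "fitting")
})

test_that("poses with no intersection score exactly zero", {
  sg <- solidGrid()
  lig <- toyLigand(nH1 = 5, nUb = 6, clashDepth = 0, receptor = sg$rec)
  sc <- scorePose(sg$grid, lig$structure)
  expect_equal(sc$score, 0)
  expect_equal(sc$classification, "fitting")
  # fully outside the box as well
  far <- atomCoords(lig$structure) + 500
  sc2 <- scorePose(sg$grid, lig$structure, poseCoords = far)
  expect_equal(sc2$score, 0)
  expect_equal(sc2$nAtomsInBox, 0L)
})

test_that("an empty scored subunit scores zero", {
  sg <- solidGrid()
  lig <- toyLigand(nH1 = 5, nUb = 0, clashDepth = 0, receptor = sg$rec)
  sc <- scorePose(sg$grid, lig$structure)
  expect_equal(sc$score, 0)
  expect_equal(sc$nAtomsInBox, 0L)
  expect_error(scorePose(sg$grid, lig$structure, scoredSubunit = "XX"),
               "not defined")
})

test_that("pose scores are exactly additive over atoms", {
  sg <- solidGrid()
  set.seed(42)
  pts <- matrix(runif(9, -8, 8), 3)
  total <- scoreCoordsPublic <- scorePose(sg$grid, poseCoords = pts,
                                          scoredSubunit = NULL)$score
  singles <- vapply(1:3, function(i)
    scorePose(sg$grid, poseCoords = pts[i, , drop = FALSE],
              scoredSubunit = NULL)$score, numeric(1))
  expect_identical(total, sum(singles))
})

test_that("hand-built grid values are summed per atom bin", {
  geo <- new("GridGeometry", origin = c(0, 0, 0), binWidth = 1,
             nBins = c(2L, 2L, 2L))
  vals <- array(seq(0, 1, length.out = 8), c(2, 2, 2))
  vals <- (vals - min(vals)) / (max(vals) - min(vals))
  g <- new("ScoringGrid", geometry = geo, values = vals,
           receptorLabel = "hand", nReceptorAtoms = 8L, rawMax = 7)
  pts <- rbind(c(0.5, 0.5, 0.5), c(1.5, 0.5, 0.5), c(1.5, 1.5, 1.5))
  sc <- scorePose(g, poseCoords = pts, scoredSubunit = NULL)
  expect_equal(sc$score, vals[1, 1, 1] + vals[2, 1, 1] + vals[2, 2, 2])
  expect_equal(sc$nAtomsInBox, 3L)
})

test_that("deeper interpenetration scores strictly higher", {
  sg <- solidGrid()
  depths <- c(0, 2, 5, 8, 12)
  scores <- vapply(depths, function(d)
    scorePose(sg$grid, toyLigand(nH1 = 4, nUb = 6, clashDepth = d,
                                 receptor = sg$rec)$structure)$score,
    numeric(1))
  expect_equal(scores[1], 0)
  expect_true(all(diff(scores) > 0))
})

test_that("monotone burial holds along a radius of the solid ball", {
  sg <- solidGrid()
  radii <- seq(14, 0, by = -2)
  scores <- vapply(radii, function(r)
    scorePose(sg$grid, poseCoords = matrix(c(r, 0, 0), 1),
              scoredSubunit = NULL)$score, numeric(1))
  expect_true(all(diff(scores) >= 0))
  expect_equal(scores[1], 0)
  expect_equal(scores[length(scores)], 1)  # centre bin carries the max
})

test_that("halving the bin width keeps out-of-box poses at zero", {
  rec <- solidGrid()$rec
  g1 <- buildScoringGrid(rec, binWidth = 1)
  g2 <- buildScoringGrid(rec, binWidth = 0.5)
  pose <- matrix(c(30, 0, 0, 0, 35, 0), 2, byrow = TRUE)
  s1 <- scorePose(g1, poseCoords = pose, scoredSubunit = NULL)$score
  s2 <- scorePose(g2, poseCoords = pose, scoredSubunit = NULL)$score
  expect_identical(s1, 0)
  expect_identical(s2, 0)
})

test_that("ensemble scoring superposes, scores and is chunk-invariant", {
  sg <- solidGrid()
  lig <- toyLigand(nH1 = 8, nUb = 6, clashDepth = 4, receptor = sg$rec)
  s <- lig$structure
  set.seed(43)
  frames <- replicate(10, {
    R <- randomRotation()
    sweep(atomCoords(s) %*% t(R), 2, runif(3, -20, 20), "+")
  }, simplify = FALSE)
  t <- Trajectory(s, frames)
  refH1 <- subsetStructure(s, selectAtoms(s, subunit = "H1"))
  sc1 <- scoreEnsemble(sg$grid, t, refH1)
  expect_equal(nrow(sc1), 10L)
  # superposition undoes the rigid motion: every frame equals the pose
  direct <- scorePose(sg$grid, s)$score
  expect_equal(sc1$score, rep(direct, 10), tolerance = 1e-9)
  # chunking never changes results
  for (ch in c(2L, 3L, 10L))
    expect_equal(scoreEnsemble(sg$grid, t, refH1, chunks = ch), sc1)
  # sequence-alignment fallback when C-alpha counts differ
  refLong <- testCaStructure(
    rbind(atomCoords(refH1), c(999, 999, 999)),
    resnames = c(atomData(refH1)$resname, "GLY"), chain = "L")
  sc2 <- scoreEnsemble(sg$grid, t, refLong)
  expect_equal(sc2$score, sc1$score, tolerance = 1e-9)
})

test_that("ensemble scores increase with generator clash depth", {
  sg <- solidGrid()
  scores <- vapply(c(0, 3, 7), function(d) {
    lig <- toyLigand(nH1 = 6, nUb = 6, clashDepth = d, receptor = sg$rec)
    t <- Trajectory(lig$structure, list(atomCoords(lig$structure)))
    refH1 <- subsetStructure(lig$structure,
                             selectAtoms(lig$structure, subunit = "H1"))
    scoreEnsemble(sg$grid, t, refH1)$score
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
  expect_equal(scores[1], 0)
})
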