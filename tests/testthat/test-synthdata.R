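test_that("ring fixture matches its declared geometry", {
  r <- ringPoints()
  expect_equal(nrow(r$points), 500L)
  expect_equal(r$manifest$radius, 3)
  radii <- sqrt(rowSums(r$points^2))
  se <- 0.2 / sqrt(500)
  expect_lt(abs(mean(radii) - 3), 4 * se)
  # sigma = 0 collapses onto the exact circle
  r0 <- ringPoints(n = 50, sigma = 0, seed = 2)
  expect_equal(sqrt(rowSums(r0$points^2)), rep(3, 50), tolerance = 1e-12)
  expect_error(ringPoints(sigma = -1), "sigma")
  expect_error(ringPoints(n = 0), "n must")
})

test_that("generators are bit-identical under a fixed seed", {
  expect_identical(ringPoints(seed = 9)$points, ringPoints(seed = 9)$points)
  expect_identical(shellReceptor(seed = 9)$structure@coords,
                   shellReceptor(seed = 9)$structure@coords)
  a <- toyTrajectory(kClusters = 2, framesPerCluster = 20, seed = 9)
  b <- toyTrajectory(kClusters = 2, framesPerCluster = 20, seed = 9)
  expect_identical(a$trajectory@coords, b$trajectory@coords)
  expect_identical(projectionPoints(a$projection),
                   projectionPoints(b$projection))
  # and different seeds differ
  c <- toyTrajectory(kClusters = 2, framesPerCluster = 20, seed = 10)
  expect_false(identical(a$trajectory@coords, c$trajectory@coords))
})

test_that("shell manifest classifies probes analytically", {
  sh <- shellReceptor(radius = 8, thickness = 2, nAtoms = 300, seed = 3)
  expect_equal(sh$manifest$classify(c(0, 0, 0)), "cavity")
  expect_equal(sh$manifest$classify(c(7, 0, 0)), "inside")
  expect_equal(sh$manifest$classify(c(9, 0, 0)), "outside")
  radii <- sqrt(rowSums(atomCoords(sh$structure)^2))
  expect_true(all(radii >= 6 - 1e-9 & radii <= 8 + 1e-9))
  solid <- shellReceptor(radius = 8, thickness = 2, nAtoms = 300,
                         solid = TRUE, seed = 3)
  expect_equal(solid$manifest$classify(c(0, 0, 0)), "inside")
  expect_error(shellReceptor(radius = 1, thickness = 2), "radius")
})

test_that("the merged grid fills the shell interior (core penalty)", {
  # the min-merged cumulative construction deliberately fills enclosed
  # cavities: an atom reaching into the core of a closed shell must be
  # penalized even though no receptor atom occupies the centre bin
  sh <- shellReceptor(radius = 9, thickness = 1.5, nAtoms = 3000,
                      seed = 4)
  g <- buildScoringGrid(sh$structure, binWidth = 1.5)
  at <- function(x, y, z) scorePose(g, poseCoords = matrix(c(x, y, z), 1),
                                    scoredSubunit = NULL)$score
  expect_gt(at(0, 0, 0), 0.5)         # interior strongly penalized
  expect_gt(at(0, 0, 0), at(8.2, 0, 0))  # more than the wall sliver
  expect_identical(at(30, 0, 0), 0)   # outside stays free
})

test_that("toy ligands declare their pose and partition", {
  rec <- shellReceptor(solid = TRUE, nAtoms = 400, seed = 5)$structure
  lig <- toyLigand(nH1 = 7, nUb = 5, clashDepth = 2.5, receptor = rec)
  expect_equal(lengths(subunits(lig$structure))[c("H1", "Ub")],
               c(H1 = 7L, Ub = 5L))
  expect_equal(lig$manifest$clashDepth, 2.5)
  # innermost Ub atom sits margin - depth outside the surface
  ub <- atomCoords(lig$structure)[subunits(lig$structure)$Ub, ]
  expect_equal(min(sqrt(rowSums(ub^2))),
               lig$manifest$receptorRadius + 2 - 2.5, tolerance = 1e-9)
  # H1 stays clear of the receptor
  h1 <- atomCoords(lig$structure)[subunits(lig$structure)$H1, ]
  expect_gt(min(sqrt(rowSums(h1^2))), lig$manifest$receptorRadius)
  expect_error(toyLigand(clashDepth = -1, receptor = rec), ">= 0")
})

test_that("trajectory templates honour the declared separation", {
  tt <- toyTrajectory(kClusters = 3, framesPerCluster = 10,
                      interShift = 10, seed = 6)
  expect_gte(tt$manifest$minTemplateRmsd, 10)
  expect_equal(length(tt$manifest$trueLabels), 30L)
  # cross-cluster RMSD far exceeds within-cluster RMSD
  m <- pairwiseRmsdMatrix(tt$trajectory)
  lab <- tt$manifest$trueLabels
  within <- m[lab == 1, lab == 1]
  across <- m[lab == 1, lab == 2]
  expect_gt(min(across), 5 * max(within))
})

test_that("merged-blob mode plants the refinement scenario", {
  tt <- toyTrajectory(kClusters = 2, framesPerCluster = 50,
                      mergedBlob = TRUE, seed = 7)
  expect_equal(tt$manifest$nGroups, 3L)
  expect_equal(tt$manifest$groupSizes, c(50L, 50L, 100L))
  ctr <- tt$manifest$centres
  # sub-blobs 1 and 2 are adjacent; group 3 is far away
  expect_lt(sqrt(sum((ctr[1, ] - ctr[2, ])^2)), 5)
  expect_gt(sqrt(sum((ctr[1, ] - ctr[3, ])^2)), 10)
})

test_that("generated structures round-trip through the PDB writer", {
  tt <- toyTrajectory(kClusters = 1, framesPerCluster = 2, seed = 8)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(tt$trajectory, f)
  back <- readTrajectory(f)
  expect_equal(nFrames(back), 2L)
  expect_lt(max(abs(back@coords - tt$trajectory@coords)), 1e-3)
  expect_identical(atomData(back)$resname,
                   atomData(tt$trajectory)$resname)
})
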