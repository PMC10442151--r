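# trajectory of identical frames with chosen 2D projection distances
projTraj <- function(d2d, nAtoms = 5) {
  n <- length(d2d) + 1L
  base <- matrix(rnorm(nAtoms * 3), nAtoms)
  t <- Trajectory(testCaStructure(base), replicate(n, base,
                                                   simplify = FALSE))
  pts <- rbind(c(0, 0), cbind(d2d, 0))
  list(t = t, p = Projection2D(pts))
}

test_that("diagnostics on identical structures give zero RMSD", {
  set.seed(81)
  pt <- projTraj(abs(rnorm(30)))
  d <- clusterDiagnostics(seq_len(31), pt$p, pt$t, atomIndices = 1:5,
                          seed = 1)
  expect_equal(d$meanRmsdToCentroid, 0, tolerance = 1e-10)
  expect_equal(d$centroidFrame, 1L)  # tie broken by lowest frame index
  expect_false(d$multimodal)
})

test_that("2D-distance skewness matches the half-normal closed form", {
  set.seed(82)
  d2d <- abs(rnorm(1000))
  pt <- projTraj(d2d)
  d <- clusterDiagnostics(seq_len(1001), pt$p, pt$t, atomIndices = 1:5,
                          seed = 2)
  hn <- sqrt(2) * (4 - pi) / (pi - 2)^1.5  # half-normal g1 ~ 0.995
  expect_lt(abs(d$skewness2d - hn), 0.25)  # sampling tolerance at n=1000
  # two well-separated 2D modes are flagged multimodal
  d2 <- clusterDiagnostics(seq_len(601),
                           projTraj(c(rnorm(300, 1, .05),
                                      rnorm(300, 5, .05)))$p,
                           projTraj(rep(1, 600))$t,
                           atomIndices = 1:5, seed = 3)
  expect_true(d2$multimodal)
})

test_that("variant composition is tallied from frame metadata", {
  set.seed(83)
  pt <- projTraj(abs(rnorm(9)))
  fm <- frameMeta(pt$t)
  fm$variant <- rep(c("K30Ub", "K63Ub"), c(6, 4))
  frameMeta(pt$t) <- fm
  d <- clusterDiagnostics(1:10, pt$p, pt$t, atomIndices = 1:5, seed = 4)
  comp <- d$variantComposition[[1]]
  expect_equal(unname(comp[c("K30Ub", "K63Ub")]), c(0.6, 0.4))
  expect_equal(sum(comp), 1, tolerance = 1e-9)
  expect_error(clusterDiagnostics(1L, pt$p, pt$t), "at least 2")
})

test_that("refinement gating follows the strict-inequality convention", {
  mk <- function(rmsd, skew, multi)
    data.frame(meanRmsdToCentroid = rmsd, skewness2d = skew,
               multimodal = multi)
  sch <- PassSchedule()
  expect_true(passesRefinement(mk(0, 0, FALSE), sch)$accepted)
  # values exactly at the thresholds pass ("greater than" rejects)
  expect_true(passesRefinement(mk(6, 0.5, FALSE), sch)$accepted)
  g1 <- passesRefinement(mk(6.0001, 0, FALSE), sch)
  expect_false(g1$accepted)
  expect_equal(g1$reasons, "rmsd")
  g2 <- passesRefinement(mk(7, 0, FALSE), sch)
  expect_equal(g2$reasons, "rmsd")
  g3 <- passesRefinement(mk(0, 0.6, FALSE), sch)
  expect_false(g3$accepted)
  expect_equal(g3$reasons, "skewness")
  g4 <- passesRefinement(mk(0, 0, TRUE), sch)
  expect_equal(g4$reasons, "multimodal")
  g5 <- passesRefinement(mk(9, 0.9, TRUE), sch)
  expect_setequal(g5$reasons, c("rmsd", "skewness", "multimodal"))
})

test_that("schedule validity matches the published protocol shape", {
  sch <- PassSchedule()
  expect_equal(sch@artifactPassSize, 1000L)
  expect_equal(sch@refinementSizes, c(750L, 500L, 250L, 125L, 75L, 50L,
                                      25L))
  expect_error(PassSchedule(refinementSizes = c(100L, 100L)),
               "strictly decreasing")
})

test_that("dense high-RMSD-variance patches are excluded as artifacts", {
  ta <- toyTrajectory(kClusters = 1, framesPerCluster = 320,
                      nArtifact = 320, nNoise = 40, seed = 84)
  sch <- PassSchedule(artifactPassSize = 300L,
                      refinementSizes = c(150L, 75L))
  ex <- excludeArtifacts(ta$projection, ta$trajectory, sch, seed = 5)
  truth <- ta$manifest$trueLabels
  expect_true(all(which(truth == 0) %in% which(ex$mask)))
  expect_false(any(which(truth == 1) %in% which(ex$mask)))
  expect_gt(nrow(ex$report), 0)
  # a clean projection yields an empty mask
  tc <- toyTrajectory(kClusters = 2, framesPerCluster = 200, seed = 85)
  ex2 <- excludeArtifacts(tc$projection, tc$trajectory,
                          PassSchedule(artifactPassSize = 150L),
                          seed = 6)
  expect_equal(sum(ex2$mask), 0L)
  # fewer points than the pass size: warning, nothing excluded
  expect_warning(
    ex3 <- excludeArtifacts(tc$projection, tc$trajectory,
                            PassSchedule(), seed = 7),
    "fewer points")
  expect_equal(sum(ex3$mask), 0L)
})

test_that("iterative refinement recovers planted clusters exactly", {
  tt <- toyTrajectory(kClusters = 2, framesPerCluster = 150, nNoise = 50,
                      seed = 86)
  sch <- PassSchedule(artifactPassSize = 1000L,
                      refinementSizes = c(100L, 50L, 25L))
  ct <- iterativeCluster(tt$projection, tt$trajectory, sch, seed = 8)
  expect_equal(nrow(ct@diagnostics), 2L)
  expect_equal(mclust::adjustedRandIndex(clusterLabels(ct),
                                         tt$manifest$trueLabels), 1)
  expect_true(all(clusterLabels(ct)[tt$manifest$trueLabels == -1] == -1L))
  # determinism
  ct2 <- iterativeCluster(tt$projection, tt$trajectory, sch, seed = 8)
  expect_identical(clusterLabels(ct), clusterLabels(ct2))
  # post-hoc: accepted clusters meet size and criteria
  for (r in seq_len(nrow(ct@diagnostics))) {
    d <- ct@diagnostics[r, ]
    expect_gte(d$size, sch@refinementSizes[d$pass - 1L])
    expect_true(passesRefinement(d, sch)$accepted)
  }
  # empty projection
  e <- iterativeCluster(Projection2D(matrix(0, 0, 2)),
                        tt$trajectory, sch, seed = 1)
  expect_length(clusterLabels(e), 0L)
})

test_that("a merged heterogeneous blob is rejected then resolved", {
  tt <- toyTrajectory(kClusters = 2, framesPerCluster = 100,
                      nNoise = 60, mergedBlob = TRUE, seed = 87)
  # groups: two structural groups of 100 sharing a double disk + clean 200
  sch <- PassSchedule(artifactPassSize = 1000L,
                      refinementSizes = c(150L, 75L))
  # at the large pass the merged blob must appear and fail a criterion
  cl <- hdbscanClusters(projectionPoints(tt$projection), 150L)
  sizes <- vapply(seq_len(cl$nClusters), function(k) sum(cl$labels == k),
                  integer(1))
  merged <- which(sizes >= 190)[1]
  expect_false(is.na(merged))
  d <- clusterDiagnostics(which(cl$labels == merged), tt$projection,
                          tt$trajectory, seed = 9)
  gate <- passesRefinement(d)
  expect_false(gate$accepted)
  expect_gt(length(gate$reasons), 0)
  # the full refinement resolves it into the two structural groups
  ct <- iterativeCluster(tt$projection, tt$trajectory, sch, seed = 9)
  lab <- clusterLabels(ct)
  truth <- tt$manifest$trueLabels
  expect_gte(nrow(ct@diagnostics), 3L)
  expect_gt(mclust::adjustedRandIndex(lab, truth), 0.95)
  # sub-groups 1 and 2 were accepted at a later (smaller) pass
  g1pass <- ct@acceptedPass[lab[which(truth == 1)[1]]]
  g3pass <- ct@acceptedPass[lab[which(truth == 3)[1]]]
  expect_gt(g1pass, g3pass)
})

test_that("cluster tables export per-frame and per-cluster CSVs", {
  tt <- toyTrajectory(kClusters = 2, framesPerCluster = 60, seed = 88)
  ct <- iterativeCluster(tt$projection, tt$trajectory,
                         PassSchedule(artifactPassSize = 1000L,
                                      refinementSizes = c(50L, 25L)),
                         seed = 10)
  f <- withr::local_tempfile(fileext = ".csv")
  writeClusterTable(ct, f)
  frames <- read.csv(f)
  expect_equal(nrow(frames), 120L)
  expect_setequal(names(frames), c("frame", "label", "accepted_pass"))
  clusters <- read.csv(paste0(f, ".clusters.csv"))
  expect_equal(nrow(clusters), nrow(ct@diagnostics))
})
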