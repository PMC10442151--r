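test_that("1D corner cumulatives reduce to ascending/descending sums", {
  h <- c(1, 0, 2, 0, 1)
  expect_equal(cornerCumulative(h, FALSE), c(1, 1, 3, 3, 4))
  expect_equal(cornerCumulative(h, TRUE), c(4, 3, 3, 1, 1))
  mn <- mergeAndNormalize(list(cornerCumulative(h, FALSE),
                               cornerCumulative(h, TRUE)))
  expect_equal(mn$merged, c(1, 1, 3, 1, 1))
  expect_equal(mn$values, (c(1, 1, 3, 1, 1) - 1) / 2)  # min-max over {1,3}
})

test_that("the starting corner bin holds its own count", {
  set.seed(31)
  h <- array(sample(0:4, 27, TRUE), c(3, 3, 3))
  for (corner in 1:8) {
    cc <- cornerCumulative(h, corner)
    rv <- as.logical(bitwAnd(corner - 1L, 2L^(0:2)) > 0L)
    ix <- ifelse(rv, dim(h), 1L)
    expect_equal(cc[ix[1], ix[2], ix[3]], h[ix[1], ix[2], ix[3]])
  }
})

test_that("corner cumulatives equal brute-force box counting", {
  set.seed(32)
  for (rep in 1:3) {
    h <- array(sample(0:3, 64, TRUE), c(4, 4, 4))
    for (corner in 1:8)
      expect_equal(cornerCumulative(h, corner) + 0,
                   bruteCornerCumulative(h, corner) + 0)
  }
})

test_that("occupancy histograms bin every in-box atom exactly once", {
  # 8 atoms at the corners of a cube, 2x2x2 bins: one count per bin
  corners <- as.matrix(expand.grid(c(0.5, 1.5), c(0.5, 1.5), c(0.5, 1.5)))
  geo <- new("GridGeometry", origin = c(0, 0, 0), binWidth = 1,
             nBins = c(2L, 2L, 2L))
  h <- buildOccupancyHistogram(corners, geometry = geo)
  expect_true(all(h == 1L))
  expect_equal(sum(h), 8L)
  # empty receptor with explicit geometry: all zeros
  h0 <- buildOccupancyHistogram(matrix(0, 0, 3), geometry = geo)
  expect_true(all(h0 == 0L))
  # random atoms match the per-atom loop
  set.seed(33)
  coords <- matrix(runif(3000, -5, 5), ncol = 3)
  h1 <- buildOccupancyHistogram(coords, binWidth = 1.3)
  oracle <- bruteBinCounts(coords, attr(h1, "geometry"))
  expect_equal(h1 + 0L, oracle + 0L, ignore_attr = TRUE)
  expect_equal(sum(h1), 1000L)
})

test_that("atoms outside a user-supplied box follow the drop policy", {
  geo <- new("GridGeometry", origin = c(0, 0, 0), binWidth = 1,
             nBins = c(2L, 2L, 2L))
  coords <- rbind(c(0.5, 0.5, 0.5), c(10, 10, 10))
  expect_warning(h <- buildOccupancyHistogram(coords, geometry = geo),
                 "dropped")
  expect_equal(sum(h), 1L)
  expect_equal(attr(h, "nDropped"), 1L)
  expect_error(buildOccupancyHistogram(coords, geometry = geo,
                                       outside = "error"), "outside")
})

test_that("boundary atoms go to the higher-index bin (half-open bins)", {
  geo <- new("GridGeometry", origin = c(0, 0, 0), binWidth = 1,
             nBins = c(3L, 3L, 3L))
  h <- buildOccupancyHistogram(matrix(c(1, 1, 1), 1), geometry = geo)
  expect_equal(h[2, 2, 2], 1L)
  expect_equal(sum(h), 1L)
})

test_that("merge takes the per-bin minimum and normalizes to [0, 1]", {
  set.seed(34)
  h <- array(sample(0:3, 125, TRUE), c(5, 5, 5))
  cums <- lapply(1:8, function(k) cornerCumulative(h, k))
  mn <- mergeAndNormalize(cums)
  brute <- array(0, dim(h))
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    brute[i, j, k] <- min(vapply(1:8, function(c)
      bruteCornerCumulative(h, c)[i, j, k], numeric(1)))
  expect_equal(mn$merged + 0, brute + 0)
  expect_equal(min(mn$values), 0)
  expect_equal(max(mn$values), 1)
  # all-zero input: no division error, all-zero output
  z <- array(0, c(2, 2, 2))
  expect_true(all(mergeAndNormalize(lapply(1:8, function(k)
    cornerCumulative(z, k)))$values == 0))
  expect_error(mergeAndNormalize(list(array(0, c(2, 2, 2)),
                                      array(0, c(3, 2, 2)))), "shapes")
})

test_that("a single atom marks exactly its inward bins before scaling", {
  # one atom at the box centre: merged count is 1 at the atom's bin and
  # 0 at any bin separated from it along some axis
  geo <- new("GridGeometry", origin = c(0, 0, 0), binWidth = 1,
             nBins = c(3L, 3L, 3L))
  h <- buildOccupancyHistogram(matrix(c(1.5, 1.5, 1.5), 1),
                               geometry = geo)
  merged <- mergeAndNormalize(lapply(1:8, function(k)
    cornerCumulative(h, k)))$merged
  expect_equal(merged[2, 2, 2], 1)
  expect_equal(sum(merged), 1)  # everything else is 0
})

test_that("grids from random receptors satisfy the normalization contract", {
  set.seed(35)
  for (rep in 1:3) {
    coords <- matrix(rnorm(300 * 3, sd = 4), ncol = 3)
    g <- buildScoringGrid(coords, binWidth = 1.5)
    expect_equal(min(gridValues(g)), 0)
    expect_equal(max(gridValues(g)), 1)
    expect_equal(g@nReceptorAtoms, 300L)
    expect_gt(g@rawMax, 0)
  }
})

test_that("grid and scores are invariant under atom order permutation", {
  set.seed(36)
  coords <- matrix(rnorm(600, sd = 5), ncol = 3)
  geo <- autoGridGeometry(coords, 1)
  g1 <- buildScoringGrid(coords, geometry = geo)
  g2 <- buildScoringGrid(coords[sample(nrow(coords)), ], geometry = geo)
  expect_identical(gridValues(g1), gridValues(g2))
})

test_that("scoring grids round-trip exactly through the text container", {
  g <- buildScoringGrid(matrix(rnorm(150, sd = 3), ncol = 3),
                        binWidth = 0.9, label = "rt")
  f <- withr::local_tempfile(fileext = ".isa")
  writeScoringGrid(g, f)
  g2 <- readScoringGrid(f)
  expect_identical(gridValues(g2), gridValues(g))
  expect_identical(g2@geometry@origin, g@geometry@origin)
  expect_identical(g2@geometry@nBins, g@geometry@nBins)
  expect_identical(g2@nReceptorAtoms, g@nReceptorAtoms)
  expect_identical(g2@rawMax, g@rawMax)
  expect_identical(g2@receptorLabel, g@receptorLabel)
})
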