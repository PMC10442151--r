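#' Construct a Projection2D
#'
#' @param points numeric n x 2 matrix.
#' @param frameMeta optional per-point provenance data.frame.
#' @return a [Projection2D-class].
#' @export
Projection2D <- function(points, frameMeta = NULL) {
  points <- as.matrix(points)
  if (is.null(frameMeta)) {
    n <- nrow(points)
    frameMeta <- data.frame(variant = rep(NA_character_, n),
                            source = rep(NA_character_, n),
                            frame = seq_len(n),
                            stringsAsFactors = FALSE)
  }
  new("Projection2D", points = points, frameMeta = frameMeta)
}

#' Read a 2D projection from a two-column numeric table
#'
#' Whitespace- or comma-separated; extra columns are ignored.
#'
#' @param path file path.
#' @return a [Projection2D-class].
#' @export
readProjection <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "",
                          comment.char = "#",
                          blank.lines.skip = TRUE)
  if (ncol(df) == 1L)
    df <- utils::read.csv(path, header = FALSE)
  if (ncol(df) < 2L) stop("projection table needs two numeric columns")
  Projection2D(as.matrix(df[, 1:2]))
}

#' Pass schedule constructor (published defaults)
#'
#' @param artifactPassSize minimal cluster size of the artifact-exclusion
#'   pass (default 1000).
#' @param refinementSizes decreasing minimal cluster sizes of the
#'   refinement passes (default 750, 500, 250, 125, 75, 50, 25; together
#'   with the artifact pass this is 8 clustering passes).
#' @param rmsdMeanMax rejection threshold on the mean RMSD to the cluster
#'   centroid, Angstrom (default 6).
#' @param skewnessMax rejection threshold on the Fisher-Pearson skewness
#'   of the 2D distance distribution (default 0.5).
#' @param multimodalityAlpha dip-test significance level (default 0.05).
#' @return a [PassSchedule-class].
#' @export
PassSchedule <- function(artifactPassSize = 1000L,
                         refinementSizes = c(750L, 500L, 250L, 125L, 75L,
                                             50L, 25L),
                         rmsdMeanMax = 6, skewnessMax = 0.5,
                         multimodalityAlpha = 0.05) {
  new("PassSchedule", artifactPassSize = as.integer(artifactPassSize),
      refinementSizes = as.integer(refinementSizes),
      rmsdMeanMax = rmsdMeanMax, skewnessMax = skewnessMax,
      multimodalityAlpha = multimodalityAlpha)
}

#' Diagnostics of one candidate cluster
#'
#' The cluster's RMSD centroid is the member frame minimizing the row sum
#' of the pairwise minimized-RMSD matrix (ties broken by the lowest frame
#' index). Reported are the mean and standard deviation of the RMSD from
#' the centroid to the other members, the Fisher-Pearson skewness
#' (g1 = m3 / m2^(3/2)) of the 2D projection distances from the
#' centroid's point to the other members' points, a Monte-Carlo dip test
#' of multimodality of those distances (the same distribution that is
#' tested for skewness; the dip p-value of the RMSD distribution is also
#' recorded but does not gate acceptance), and the per-variant
#' composition.
#'
#' @param members integer point/frame indices of the cluster (size >= 2).
#' @param p a [Projection2D-class].
#' @param t the co-indexed [Trajectory-class].
#' @param atomIndices atoms for the RMSD computations (default C-alpha).
#' @param schedule a [PassSchedule-class] (for the dip alpha).
#' @param seed seed for the dip-test null sampling.
#' @param dipB Monte-Carlo replicates for the dip test.
#' @return one-row data.frame of diagnostics.
#' @export
clusterDiagnostics <- function(members, p, t,
                               atomIndices = selectAtoms(t, name = "CA"),
                               schedule = PassSchedule(), seed = 1L,
                               dipB = 199L) {
  members <- as.integer(members)
  if (length(members) < 2L) stop("cluster must have at least 2 members")
  rm <- pairwiseRmsdMatrix(t, atomIndices, frames = members)
  ctrLocal <- which.min(rowSums(rm))  # which.min takes the first = lowest
  centroid <- members[ctrLocal]
  rmsds <- rm[ctrLocal, -ctrLocal]
  pts <- projectionPoints(p)[members, , drop = FALSE]
  d2d <- sqrt((pts[, 1] - pts[ctrLocal, 1])^2 +
              (pts[, 2] - pts[ctrLocal, 2])^2)[-ctrLocal]
  skew <- if (sd(d2d) > 0) e1071::skewness(d2d, type = 1) else 0
  dip2d <- dipTest(d2d, B = dipB, seed = seed)
  dipRmsd <- dipTest(rmsds, B = dipB, seed = seed + 1L)
  variants <- frameMeta(t)$variant[members]
  comp <- table(variants, useNA = "ifany") / length(members)
  data.frame(size = length(members), centroidFrame = centroid,
             meanRmsdToCentroid = mean(rmsds), rmsdSd = sd(rmsds),
             skewness2d = skew, dipP2d = dip2d$pValue,
             dipPRmsd = dipRmsd$pValue,
             multimodal = dip2d$pValue < schedule@multimodalityAlpha,
             variantComposition = I(list(setNames(as.numeric(comp),
                                                  names(comp)))),
             stringsAsFactors = FALSE)
}

#' Structure-homogeneity gate for a candidate cluster
#'
#' A cluster is rejected if ANY of the three criteria fires: mean RMSD to
#' the centroid strictly greater than `rmsdMeanMax` (6 Angstrom by
#' default), Fisher-Pearson skewness of the 2D distance distribution
#' strictly greater than `skewnessMax` (0.5), or multimodality of that
#' distribution (dip-test p below `multimodalityAlpha`). Values exactly
#' at a threshold therefore pass.
#'
#' @param d one-row diagnostics data.frame from [clusterDiagnostics()].
#' @param schedule a [PassSchedule-class].
#' @return list: `accepted` (logical), `reasons` (character vector of
#'   violated criteria, empty when accepted).
#' @export
passesRefinement <- function(d, schedule = PassSchedule()) {
  reasons <- character()
  if (d$meanRmsdToCentroid > schedule@rmsdMeanMax)
    reasons <- c(reasons, "rmsd")
  if (d$skewness2d > schedule@skewnessMax)
    reasons <- c(reasons, "skewness")
  if (isTRUE(d$multimodal))
    reasons <- c(reasons, "multimodal")
  list(accepted = !length(reasons), reasons = reasons)
}

#' Artifact-exclusion pass
#'
#' One HDBSCAN pass at the artifact minimal cluster size (1000 by
#' default); clusters whose 2D density is high but whose structures are
#' heterogeneous (mean RMSD to the centroid above the schedule threshold)
#' are projection artifacts - many dissimilar structures collapsed onto
#' one dense patch - and are removed from further analysis.
#'
#' @param p a [Projection2D-class].
#' @param t the co-indexed [Trajectory-class].
#' @param schedule a [PassSchedule-class].
#' @param atomIndices atoms for the RMSD computation (default C-alpha).
#' @param seed seed for diagnostics.
#' @return list: `mask` (logical, TRUE = removed), `report` (data.frame
#'   of flagged clusters with diagnostics).
#' @export
excludeArtifacts <- function(p, t, schedule = PassSchedule(),
                             atomIndices = selectAtoms(t, name = "CA"),
                             seed = 1L) {
  pts <- projectionPoints(p)
  n <- nrow(pts)
  mask <- rep(FALSE, n)
  report <- NULL
  if (n < schedule@artifactPassSize) {
    warning("fewer points (", n, ") than the artifact pass size (",
            schedule@artifactPassSize, "); nothing excluded")
    return(list(mask = mask, report = data.frame()))
  }
  cl <- hdbscanClusters(pts, schedule@artifactPassSize)
  for (k in seq_len(cl$nClusters)) {
    members <- which(cl$labels == k)
    d <- clusterDiagnostics(members, p, t, atomIndices, schedule,
                            seed = seed)
    if (d$meanRmsdToCentroid > schedule@rmsdMeanMax) {
      mask[members] <- TRUE
      report <- rbind(report, cbind(cluster = k, d))
    }
  }
  list(mask = mask, report = if (is.null(report)) data.frame() else report)
}

#' Iterative density-based cluster refinement
#'
#' Identifies characteristic conformational states: after (optional)
#' artifact exclusion, HDBSCAN is run repeatedly on the pool of
#' unassigned points with a decreasing minimal-cluster-size schedule.
#' Clusters passing the three homogeneity criteria are accepted and
#' frozen; rejected clusters return their points to the pool so that a
#' smaller pass may resolve them into homogeneous sub-states. Points
#' never accepted are labelled -1. Deterministic for fixed seed and
#' inputs.
#'
#' @param p a [Projection2D-class].
#' @param t the co-indexed [Trajectory-class].
#' @param schedule a [PassSchedule-class].
#' @param seed integer seed (drives the Monte-Carlo dip tests).
#' @param excludeArtifactsFirst run [excludeArtifacts()] first (default
#'   TRUE).
#' @param atomIndices atoms for RMSD diagnostics (default C-alpha).
#' @param minSamples HDBSCAN core-distance neighbourhood size.
#' @return a [ClusterTable-class].
#' @export
iterativeCluster <- function(p, t, schedule = PassSchedule(), seed = 1L,
                             excludeArtifactsFirst = TRUE,
                             atomIndices = selectAtoms(t, name = "CA"),
                             minSamples = 5L) {
  pts <- projectionPoints(p)
  n <- nrow(pts)
  labels <- rep(-1L, n)
  excluded <- integer()
  if (n == 0L)
    return(new("ClusterTable", labels = labels,
               acceptedPass = integer(), diagnostics = data.frame(),
               excluded = excluded))
  if (excludeArtifactsFirst && n >= schedule@artifactPassSize) {
    ex <- excludeArtifacts(p, t, schedule, atomIndices, seed = seed)
    excluded <- which(ex$mask)
  }
  nextId <- 0L
  acceptedPass <- integer()
  diagnostics <- NULL
  passIndex <- 1L  # pass 1 is the artifact pass
  for (size in schedule@refinementSizes) {
    passIndex <- passIndex + 1L
    pool <- setdiff(which(labels == -1L), excluded)
    if (length(pool) < size) next
    cl <- hdbscanClusters(pts[pool, , drop = FALSE], size,
                          minSamples = minSamples)
    for (k in seq_len(cl$nClusters)) {
      members <- pool[cl$labels == k]
      d <- clusterDiagnostics(members, p, t, atomIndices, schedule,
                              seed = seed + passIndex)
      gate <- passesRefinement(d, schedule)
      if (gate$accepted) {
        nextId <- nextId + 1L
        labels[members] <- nextId
        acceptedPass[nextId] <- passIndex
        diagnostics <- rbind(diagnostics,
                             cbind(cluster = nextId, pass = passIndex, d))
      }
      # rejected: members simply remain in the pool
    }
  }
  names(acceptedPass) <- seq_len(nextId)
  new("ClusterTable", labels = labels, acceptedPass = acceptedPass,
      diagnostics = if (is.null(diagnostics)) data.frame() else
        diagnostics,
      excluded = excluded)
}

#' Export cluster assignments and diagnostics as CSV
#'
#' Writes `<path>` with per-frame rows (frame, label, accepted_pass) and
#' `<path>.clusters.csv` with per-cluster diagnostics (size, variant
#' composition, internal RMSD mean/sd, skewness, dip p-values).
#'
#' @param ct a [ClusterTable-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeClusterTable <- function(ct, path) {
  stopifnot(is(ct, "ClusterTable"))
  lab <- clusterLabels(ct)
  pass <- rep(NA_integer_, length(lab))
  ok <- lab > 0L
  pass[ok] <- ct@acceptedPass[lab[ok]]
  write.csv(data.frame(frame = seq_along(lab), label = lab,
                       accepted_pass = pass),
            path, row.names = FALSE)
  d <- ct@diagnostics
  if (nrow(d)) {
    d$variantComposition <- vapply(d$variantComposition, function(v)
      paste(sprintf("%s:%.4f", names(v), v), collapse = ";"),
      character(1))
  }
  write.csv(d, paste0(path, ".clusters.csv"), row.names = FALSE)
  invisible(path)
}
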