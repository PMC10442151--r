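#' Sampling-campaign bookkeeping
#'
#' An expansion-scheme campaign runs `nStarting` short simulations per
#' variant, then `nExpansions` rounds in which each variant continues
#' with `nContinuing` simulations, plus optional long exploratory
#' simulations. `totalSimulationTime()` returns the aggregated simulated
#' time in microseconds:
#' `nVariants * nStarting * tStarting + nExpansions * (nVariants *
#' nContinuing * tExpansion) + tLong`.
#'
#' @param nVariants number of ligand variants simulated.
#' @param nStarting starting simulations per variant.
#' @param tStartingNs length of each starting simulation, nanoseconds.
#' @param nExpansions number of expansion rounds.
#' @param nContinuing continuing simulations per variant per round.
#' @param tExpansionNs length of each continuation, nanoseconds.
#' @param tLongUs additional long-simulation time, microseconds.
#' @return `expansionPlan()`: a validated plan (list);
#'   `totalSimulationTime()`: total time in microseconds.
#' @export
expansionPlan <- function(nVariants = 6L, nStarting = 18L,
                          tStartingNs = 20, nExpansions = 9L,
                          nContinuing = 20L, tExpansionNs = 20,
                          tLongUs = 12) {
  plan <- list(nVariants = nVariants, nStarting = nStarting,
               tStartingNs = tStartingNs, nExpansions = nExpansions,
               nContinuing = nContinuing, tExpansionNs = tExpansionNs,
               tLongUs = tLongUs)
  if (any(unlist(plan) < 0)) stop("plan counts and times must be >= 0")
  plan
}

#' @rdname expansionPlan
#' @param plan a plan from [expansionPlan()].
#' @export
totalSimulationTime <- function(plan) {
  ns <- plan$nVariants * plan$nStarting * plan$tStartingNs +
    plan$nExpansions * (plan$nVariants * plan$nContinuing *
                          plan$tExpansionNs)
  ns / 1000 + plan$tLongUs
}

#' Select restart frames from sparsely populated projection bins
#'
#' The projection is binned on a regular 2D grid over its bounding box;
#' non-empty bins are ranked by ascending occupancy (ties broken by a
#' seeded shuffle) and one frame (seeded uniform choice within the bin)
#' is taken per bin in rank order until `nSelect` frames are chosen,
#' cycling over the sparse bins with repetition (never repeating a
#' frame) if the single round is exhausted. Deterministic for a fixed
#' seed.
#'
#' @param p a [Projection2D-class] (or n x 2 matrix).
#' @param nSelect number of restart frames (the published campaigns used
#'   20 per expansion step).
#' @param gridDim bins per axis (default c(30, 30)).
#' @param seed integer seed.
#' @return data.frame: `frame`, `binX`, `binY`, `occupancy`, ordered by
#'   selection; frames are distinct.
#' @export
selectRestarts <- function(p, nSelect = 20L, gridDim = c(30L, 30L),
                           seed = 1L) {
  pts <- if (is(p, "Projection2D")) projectionPoints(p) else as.matrix(p)
  n <- nrow(pts)
  if (!n) stop("empty projection")
  if (nSelect < 1L) stop("nSelect must be >= 1")
  if (nSelect > n)
    stop("cannot select ", nSelect, " distinct frames from ", n, " points")
  gridDim <- rep(as.integer(gridDim), length.out = 2L)
  bin1 <- function(v, nb) {
    lo <- min(v)
    w <- (max(v) - lo) / nb
    if (w == 0) return(rep(1L, length(v)))
    pmin(nb, as.integer(floor((v - lo) / w)) + 1L)
  }
  bx <- bin1(pts[, 1], gridDim[1])
  by <- bin1(pts[, 2], gridDim[2])
  binId <- (by - 1L) * gridDim[1] + bx
  occ <- table(binId)
  withr::with_seed(seed, {
    ids <- as.integer(names(occ))
    rank <- order(as.integer(occ), runif(length(occ)))
    ids <- ids[rank]
    members <- lapply(ids, function(b) {
      m <- which(binId == b)
      m[sample.int(length(m))]  # pre-shuffled draw order within the bin
    })
    sel <- integer(0)
    round <- 1L
    while (length(sel) < nSelect) {
      added <- FALSE
      for (j in seq_along(ids)) {
        if (length(members[[j]]) >= round) {
          sel <- c(sel, members[[j]][round])
          added <- TRUE
          if (length(sel) == nSelect) break
        }
      }
      if (!added) break
      round <- round + 1L
    }
  })
  data.frame(frame = sel, binX = bx[sel], binY = by[sel],
             occupancy = as.integer(occ[as.character(binId[sel])]))
}
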