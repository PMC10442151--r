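#' Grid geometry covering a set of coordinates
#'
#' The bounding box of the coordinates is padded by `pad` bins on each
#' side, so the corner bins of the resulting grid are guaranteed empty
#' (the corner-anchored cumulative histograms then start from zero
#' occupancy).
#'
#' @param coords numeric n x 3 matrix, Angstrom.
#' @param binWidth bin width, Angstrom (length 1 or 3). Default 1.
#' @param pad number of empty bins added on every side (default 1).
#' @return a [GridGeometry-class].
#' @export
autoGridGeometry <- function(coords, binWidth = 1, pad = 1L) {
  coords <- as.matrix(coords)
  if (!nrow(coords)) stop("cannot derive a grid from zero atoms")
  w <- rep(binWidth, length.out = 3)
  lo <- apply(coords, 2, min)
  hi <- apply(coords, 2, max)
  origin <- lo - pad * w
  nb <- as.integer(floor((hi - origin) / w)) + 1L + pad
  new("GridGeometry", origin = origin, binWidth = w, nBins = nb)
}

# 1-based bin indices per axis; bins are half-open [low, high): an atom
# exactly on a boundary is assigned to the higher-index bin.
coordsToBins <- function(geometry, coords) {
  w <- rep(geometry@binWidth, length.out = 3)
  idx <- floor(sweep(sweep(as.matrix(coords), 2, geometry@origin), 2, w,
                     "/")) + 1
  storage.mode(idx) <- "integer"
  idx
}

#' Bin receptor atom positions into a 3D occupancy histogram
#'
#' @param coords numeric n x 3 matrix of receptor atom positions, or a
#'   [Structure-class].
#' @param geometry a [GridGeometry-class], or NULL to derive one with
#'   [autoGridGeometry()] (all atoms then fall inside the box).
#' @param binWidth used when `geometry` is NULL.
#' @param outside policy for atoms outside a user-supplied box:
#'   `"drop"` (default; the dropped count is attached as attribute
#'   `nDropped` and warned about) or `"error"`.
#' @return integer 3D array of per-bin atom counts with attributes
#'   `geometry` and `nDropped`. The sum over bins equals the number of
#'   atoms inside the box.
#' @export
buildOccupancyHistogram <- function(coords, geometry = NULL, binWidth = 1,
                                    outside = c("drop", "error")) {
  outside <- match.arg(outside)
  if (is(coords, "Structure")) coords <- atomCoords(coords)
  coords <- as.matrix(coords)
  if (is.null(geometry)) geometry <- autoGridGeometry(coords, binWidth)
  nb <- geometry@nBins
  if (nrow(coords)) {
    idx <- coordsToBins(geometry, coords)
    inside <- idx[, 1] >= 1L & idx[, 1] <= nb[1] &
              idx[, 2] >= 1L & idx[, 2] <= nb[2] &
              idx[, 3] >= 1L & idx[, 3] <= nb[3]
    nDropped <- sum(!inside)
    if (nDropped && outside == "error")
      stop(nDropped, " atom(s) outside the supplied grid box")
    if (nDropped)
      warning(nDropped, " atom(s) outside the grid box were dropped")
    idx <- idx[inside, , drop = FALSE]
    lin <- idx[, 1] + (idx[, 2] - 1L) * nb[1] +
           (idx[, 3] - 1L) * nb[1] * nb[2]
    counts <- tabulate(lin, nbins = prod(nb))
  } else {
    counts <- integer(prod(nb))
    nDropped <- 0L
  }
  h <- array(as.integer(counts), dim = nb)
  attr(h, "geometry") <- geometry
  attr(h, "nDropped") <- nDropped
  h
}

# Directional cumulative sum along one axis of an array (any rank).
dirCumsum <- function(a, axis, reverse = FALSE) {
  d <- dim(a)
  if (is.null(d)) {
    if (reverse) rev(cumsum(rev(a))) else cumsum(a)
  } else {
    perm <- c(axis, setdiff(seq_along(d), axis))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = d[axis])
    if (reverse) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    m <- apply(m, 2, cumsum)
    if (!is.matrix(m)) m <- matrix(m, nrow = d[axis])
    if (reverse) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    aperm(array(m, d[perm]), order(perm))
  }
}

#' Corner-anchored cumulative occupancy histogram
#'
#' Each bin of the result holds the total atom count inside the
#' axis-aligned sub-box spanned between the chosen bounding-box corner
#' and that bin, inclusive (an inclusion-exclusion prefix sum, with axes
#' reversed according to the corner). In 1D this reduces exactly to the
#' ascending/descending cumulative sums of the textbook construction.
#'
#' @param hist numeric/integer array of any rank d (a 3D occupancy
#'   histogram in normal use; 1D/2D inputs are supported for the reduced
#'   constructions).
#' @param corner either an integer in `1:2^d` or a logical vector of
#'   length d; `TRUE`/set bit means the cumulation runs backwards along
#'   that axis (corner at the high end). Corner 1 is the all-low corner.
#' @return array of the same shape.
#' @export
cornerCumulative <- function(hist, corner) {
  d <- if (is.null(dim(hist))) 1L else length(dim(hist))
  if (is.logical(corner)) {
    if (length(corner) != d) stop("corner flags must match array rank")
    rev_axes <- corner
  } else {
    corner <- as.integer(corner)
    if (corner < 1L || corner > 2^d) stop("corner id must be in 1..2^d")
    rev_axes <- as.logical(bitwAnd(corner - 1L, 2L^(seq_len(d) - 1L)) > 0L)
  }
  out <- hist
  for (ax in seq_len(d)) out <- dirCumsum(out, ax, rev_axes[ax])
  out
}

#' Min-merge corner cumulative histograms and min-max normalize
#'
#' Every bin is assigned the lowest value over the corner cumulative
#' histograms (8 in 3D), and the merged array is min-max normalized onto
#' [0, 1]. An all-constant merged array (e.g. empty receptor) yields an
#' all-zero grid rather than a division error.
#'
#' @param hists list of equally shaped cumulative arrays (one per
#'   corner).
#' @return list with `values` (normalized array), `merged` (pre-
#'   normalization min-merge), `rawMax` and `rawMin`.
#' @export
mergeAndNormalize <- function(hists) {
  if (!length(hists)) stop("need at least one histogram")
  dims <- lapply(hists, function(h) dim(h) %||% length(h))
  if (length(unique(dims)) != 1L) stop("histogram shapes differ")
  merged <- Reduce(pmin, hists)
  rawMax <- max(merged)
  rawMin <- min(merged)
  values <- if (rawMax > rawMin) (merged - rawMin) / (rawMax - rawMin)
            else merged * 0
  list(values = values, merged = merged, rawMax = rawMax, rawMin = rawMin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the ISA scoring grid from a receptor
#'
#' Bins the receptor atoms, builds the eight corner-anchored cumulative
#' histograms, merges them by the per-bin minimum and min-max normalizes
#' onto [0, 1].
#'
#' @param receptor a [Structure-class] or numeric n x 3 coordinate
#'   matrix.
#' @param binWidth bin width in Angstrom (default 1).
#' @param geometry optional explicit [GridGeometry-class].
#' @param label receptor label stored in the grid.
#' @return a [ScoringGrid-class].
#' @export
buildScoringGrid <- function(receptor, binWidth = 1, geometry = NULL,
                             label = NULL) {
  if (is(receptor, "Structure")) {
    if (is.null(label)) label <- receptor@label
    coords <- atomCoords(receptor)
  } else {
    coords <- as.matrix(receptor)
    if (is.null(label)) label <- "receptor"
  }
  if (!nrow(coords) && is.null(geometry))
    stop("empty receptor requires an explicit geometry")
  h <- buildOccupancyHistogram(coords, geometry = geometry,
                               binWidth = binWidth)
  geometry <- attr(h, "geometry")
  cums <- lapply(1:8, function(k) cornerCumulative(h, k))
  mn <- mergeAndNormalize(cums)
  new("ScoringGrid", geometry = geometry,
      values = array(mn$values, dim = geometry@nBins),
      receptorLabel = label, nReceptorAtoms = sum(h),
      rawMax = as.numeric(mn$rawMax))
}

#' Classify an ISA score
#'
#' Scores strictly below the first cutoff are `"fitting"`; scores at or
#' above the first and strictly below the second are `"marginal"`
#' (typically intersecting the DNA linkers); scores at or above the
#' second are `"non_fitting"`. Defaults (100, 150) follow the published
#' calibration and are configurable because the score scale depends on
#' the receptor and bin width.
#'
#' @param score numeric vector of non-negative ISA scores.
#' @param cutoffs numeric length-2 vector `(fitting, non_fitting)`.
#' @return character vector in `{"fitting","marginal","non_fitting"}`.
#' @export
classifyScore <- function(score, cutoffs = c(100, 150)) {
  if (any(score < 0)) stop("ISA scores cannot be negative")
  if (length(cutoffs) != 2L || diff(cutoffs) <= 0)
    stop("cutoffs must be increasing, length 2")
  ifelse(score < cutoffs[1], "fitting",
         ifelse(score < cutoffs[2], "marginal", "non_fitting"))
}

#' Score one superposed ligand pose against a scoring grid
#'
#' Every atom of the scored subunit contributes the value of the grid
#' bin it intersects; the score is the sum of those per-atom values.
#' Atoms outside the grid box contribute 0, so a pose with no
#' intersection scores exactly 0.
#'
#' @param grid a [ScoringGrid-class].
#' @param ligand optional [Structure-class] providing the subunit map.
#' @param poseCoords pose coordinates in the grid frame (already
#'   superposed); defaults to `atomCoords(ligand)`.
#' @param scoredSubunit subunit whose atoms are scored (default `"Ub"`);
#'   `NULL` scores every atom of the pose.
#' @param cutoffs passed to [classifyScore()].
#' @return one-row data.frame: `score`, `nAtomsInBox`, `classification`.
#' @export
scorePose <- function(grid, ligand = NULL, poseCoords = NULL,
                      scoredSubunit = "Ub", cutoffs = c(100, 150)) {
  stopifnot(is(grid, "ScoringGrid"))
  if (is.null(poseCoords)) {
    if (is.null(ligand)) stop("either ligand or poseCoords is required")
    poseCoords <- atomCoords(ligand)
  }
  poseCoords <- as.matrix(poseCoords)
  if (!is.null(scoredSubunit)) {
    if (is.null(ligand)) stop("scoredSubunit requires a ligand")
    su <- subunits(ligand)
    if (!scoredSubunit %in% names(su))
      stop("subunit '", scoredSubunit, "' is not defined in the ligand")
    poseCoords <- poseCoords[su[[scoredSubunit]], , drop = FALSE]
  }
  sc <- scoreCoords(grid, poseCoords)
  data.frame(score = sc$score, nAtomsInBox = sc$nInBox,
             classification = classifyScore(sc$score, cutoffs),
             stringsAsFactors = FALSE)
}

scoreCoords <- function(grid, coords) {
  nb <- grid@geometry@nBins
  if (!nrow(coords)) return(list(score = 0, nInBox = 0L))
  idx <- coordsToBins(grid@geometry, coords)
  inside <- idx[, 1] >= 1L & idx[, 1] <= nb[1] &
            idx[, 2] >= 1L & idx[, 2] <= nb[2] &
            idx[, 3] >= 1L & idx[, 3] <= nb[3]
  idx <- idx[inside, , drop = FALSE]
  lin <- idx[, 1] + (idx[, 2] - 1L) * nb[1] + (idx[, 3] - 1L) * nb[1] * nb[2]
  list(score = sum(grid@values[lin]), nInBox = sum(inside))
}

#' Score every frame of a ligand ensemble against a receptor grid
#'
#' Per frame, the ligand histone-subunit C-alpha atoms are superposed
#' (Kabsch) onto the matched C-alpha atoms of the reference linker
#' histone, the transform is applied to the whole ligand, and the scored
#' subunit is evaluated with [scorePose()]. When the C-alpha counts of
#' ligand and reference differ, matching falls back to a global sequence
#' alignment. Frames are independent: results are identical for any
#' chunking of the frame list.
#'
#' @param grid a [ScoringGrid-class].
#' @param t ligand [Trajectory-class] with subunits `ligandSubunit`
#'   (and `scoredSubunit` unless NULL).
#' @param referenceHistone [Structure-class]: the linker histone in the
#'   receptor (grid) frame.
#' @param ligandSubunit subunit anchoring the superposition (default
#'   `"H1"`).
#' @param scoredSubunit subunit to score (default `"Ub"`); NULL scores
#'   the whole ligand.
#' @param alignment optional [AlignmentMap-class] overriding the
#'   automatic matching.
#' @param cutoffs passed to [classifyScore()].
#' @param chunks number of evaluation chunks (wall-time knob only;
#'   results never depend on it).
#' @param returnTransforms attach the per-frame [RigidTransform-class]
#'   list as attribute `"transforms"`.
#' @return data.frame with one row per frame: `frame`, `score`,
#'   `nAtomsInBox`, `classification`, `variant`.
#' @export
scoreEnsemble <- function(grid, t, referenceHistone, ligandSubunit = "H1",
                          scoredSubunit = "Ub", alignment = NULL,
                          cutoffs = c(100, 150), chunks = 1L,
                          returnTransforms = FALSE) {
  stopifnot(is(grid, "ScoringGrid"), is(t, "Trajectory"),
            is(referenceHistone, "Structure"))
  lca <- selectAtoms(t, name = "CA", subunit = ligandSubunit)
  rca <- selectAtoms(referenceHistone, name = "CA")
  if (!length(lca) || !length(rca))
    stop("no mappable C-alpha pairs between ligand and reference")
  if (is.null(alignment) && length(lca) != length(rca))
    alignment <- alignSequences(structureSequence(t, lca),
                                structureSequence(referenceHistone, rca))
  if (is.null(alignment)) {
    mi <- lca
    ti <- rca
  } else {
    stopifnot(is(alignment, "AlignmentMap"))
    if (!nrow(alignment@pairs))
      stop("no mappable C-alpha pairs between ligand and reference")
    mi <- lca[alignment@pairs[, 1]]
    ti <- rca[alignment@pairs[, 2]]
  }
  target <- atomCoords(referenceHistone)[ti, , drop = FALSE]
  sIdx <- if (is.null(scoredSubunit)) seq_len(nAtoms(t)) else {
    su <- subunits(t)
    if (!scoredSubunit %in% names(su))
      stop("subunit '", scoredSubunit, "' is not defined in the ligand")
    su[[scoredSubunit]]
  }
  nf <- nFrames(t)
  chunkId <- if (nf) sort(rep_len(seq_len(max(1L, chunks)), nf)) else integer()
  doFrame <- function(f) {
    m <- t@coords[, , f]
    tr <- kabschFit(m[mi, , drop = FALSE], target)
    pose <- applyTransform(tr, m[sIdx, , drop = FALSE])
    sc <- scoreCoords(grid, pose)
    list(score = sc$score, nInBox = sc$nInBox, transform = tr)
  }
  res <- unlist(lapply(split(seq_len(nf), chunkId),
                       function(ix) lapply(ix, doFrame)),
                recursive = FALSE, use.names = FALSE)
  scores <- vapply(res, `[[`, numeric(1), "score")
  out <- data.frame(frame = seq_len(nf), score = scores,
                    nAtomsInBox = vapply(res, `[[`, integer(1), "nInBox"),
                    classification = classifyScore(scores, cutoffs),
                    variant = frameMeta(t)$variant,
                    stringsAsFactors = FALSE)
  if (returnTransforms)
    attr(out, "transforms") <- lapply(res, `[[`, "transform")
  out
}

#' Split a chromatosome into receptor and reference linker histone
#'
#' The receptor keeps DNA, core histones and polymeric heteroatoms;
#' waters and monoatomic (ion) HETATM residues are excluded by default.
#' The removed linker-histone chain is returned separately as the
#' superposition reference.
#'
#' @param chromatosome a [Structure-class].
#' @param linkerChain chain id of the linker histone.
#' @param dropWaters,dropIons exclusion switches (defaults TRUE).
#' @return list with elements `receptor` and `referenceHistone`, both
#'   [Structure-class].
#' @export
prepareReceptor <- function(chromatosome, linkerChain, dropWaters = TRUE,
                            dropIons = TRUE) {
  a <- atomData(chromatosome)
  if (!linkerChain %in% a$chain)
    stop("linker chain '", linkerChain, "' not present")
  isLinker <- a$chain == linkerChain
  isWater <- a$resname %in% c("HOH", "WAT", "SOL", "H2O", "DOD",
                              "TIP", "TIP3", "TIP4")
  drop <- rep(FALSE, nrow(a))
  if (dropWaters) drop <- drop | isWater
  if (dropIons) {
    key <- paste(a$chain, a$resno, a$resname)
    sizes <- table(key)
    drop <- drop | (a$het & !isWater & sizes[key] == 1L)
  }
  list(receptor = subsetStructure(chromatosome, which(!isLinker & !drop)),
       referenceHistone = subsetStructure(chromatosome, which(isLinker)))
}

#' Place a reference linker histone into a nucleosome array
#'
#' For each mapped core-histone chain pair the sequences are globally
#' aligned, the longest uninterrupted run of matched columns is
#' extracted, and the C-alpha pairs of all usable chains are pooled into
#' one Kabsch fit of the reference cores onto the array cores. The
#' resulting transform is applied to the reference linker histone.
#'
#' @param array nucleosome-array [Structure-class] (no linker histone).
#' @param referenceChromatosome [Structure-class] containing core
#'   histones and the linker histone.
#' @param coreChains named character vector mapping reference chain ids
#'   (names) to array chain ids (values), typically 8 core histones.
#' @param linkerChain linker-histone chain id in the reference.
#' @param minRun minimal usable run length (default 5); chains with no
#'   run at least this long are excluded, and an error is raised only if
#'   every chain is excluded.
#' @return list: `placed` ([Structure-class] in the array frame),
#'   `transform` ([RigidTransform-class]), `chainsUsed`, `nPairs`.
#' @export
placeReferenceHistone <- function(array, referenceChromatosome, coreChains,
                                  linkerChain, minRun = 5L) {
  stopifnot(is(array, "Structure"), is(referenceChromatosome, "Structure"))
  mobile <- NULL
  target <- NULL
  used <- character()
  for (rc in names(coreChains)) {
    ac <- coreChains[[rc]]
    rIdx <- selectAtoms(referenceChromatosome, name = "CA", chain = rc)
    aIdx <- selectAtoms(array, name = "CA", chain = ac)
    if (!length(rIdx) || !length(aIdx)) next
    sa <- structureSequence(referenceChromatosome, rIdx)
    sb <- structureSequence(array, aIdx)
    al <- alignSequences(sa, sb)
    run <- longestMatchedRun(al@pairs, sa, sb)
    if (nrow(run) < minRun) next
    mobile <- rbind(mobile,
                    atomCoords(referenceChromatosome)[rIdx[run[, 1]], ,
                                                      drop = FALSE])
    target <- rbind(target, atomCoords(array)[aIdx[run[, 2]], ,
                                              drop = FALSE])
    used <- c(used, rc)
  }
  if (is.null(mobile) || nrow(mobile) < minRun)
    stop("no core-histone chain produced a matched run of at least ",
         minRun, " residues")
  tr <- kabschFit(mobile, target)
  lh <- subsetStructure(referenceChromatosome,
                        selectAtoms(referenceChromatosome,
                                    chain = linkerChain))
  if (!nAtoms(lh)) stop("linker chain '", linkerChain, "' not present")
  lh@coords <- applyTransform(tr, lh@coords)
  list(placed = lh, transform = tr, chainsUsed = used,
       nPairs = nrow(mobile))
}

# Longest uninterrupted run of matched alignment columns: consecutive in
# both sequences and identical at every column (so unrelated/scrambled
# chains cannot contribute a spurious gap-free correspondence).
longestMatchedRun <- function(pairs, seqA, seqB) {
  if (!nrow(pairs)) return(pairs)
  ca <- strsplit(seqA, "")[[1]][pairs[, 1]]
  cb <- strsplit(seqB, "")[[1]][pairs[, 2]]
  ident <- ca == cb
  pairs <- pairs[ident, , drop = FALSE]
  if (!nrow(pairs)) return(pairs)
  brk <- c(TRUE, diff(pairs[, 1]) != 1L | diff(pairs[, 2]) != 1L)
  grp <- cumsum(brk)
  best <- names(which.max(table(grp)))
  pairs[grp == as.integer(best), , drop = FALSE]
}

#' Average per-residue minimal distance from a ligand subunit to target
#' atoms
#'
#' For each residue of the subunit: per frame, the minimum distance from
#' any of its atoms (after applying that frame's pose transform) to any
#' target atom; averaged over frames. Used for per-residue
#' ligand-to-DNA distance profiles.
#'
#' @param t ligand [Trajectory-class].
#' @param receptor receptor [Structure-class] providing target
#'   coordinates.
#' @param targetAtoms non-empty integer indices into the receptor (e.g.
#'   the DNA atoms).
#' @param transforms optional list of per-frame [RigidTransform-class]
#'   (e.g. from [scoreEnsemble()] with `returnTransforms = TRUE`); NULL
#'   uses the raw frame coordinates.
#' @param subunit ligand subunit (default `"Ub"`).
#' @return data.frame: `resid`, `resno`, `resname`, `meanMinDist`
#'   (Angstrom).
#' @export
perResidueMinDistance <- function(t, receptor, targetAtoms,
                                  transforms = NULL, subunit = "Ub") {
  stopifnot(is(t, "Trajectory"), is(receptor, "Structure"))
  if (!length(targetAtoms)) stop("targetAtoms must be non-empty")
  sIdx <- selectAtoms(t, subunit = subunit)
  if (!length(sIdx)) stop("subunit '", subunit, "' has no atoms")
  a <- atomData(t)[sIdx, , drop = FALSE]
  resKey <- paste(a$resid, a$resname)
  resF <- factor(resKey, levels = unique(resKey))
  tgt <- atomCoords(receptor)[targetAtoms, , drop = FALSE]
  nf <- nFrames(t)
  acc <- matrix(0, nlevels(resF), nf)
  for (f in seq_len(nf)) {
    m <- t@coords[sIdx, , f, drop = FALSE]
    dim(m) <- dim(m)[1:2]
    if (!is.null(transforms)) m <- applyTransform(transforms[[f]], m)
    dmin <- apply(crossDist(m, tgt), 1, min)
    acc[, f] <- tapply(dmin, resF, min)
  }
  first <- !duplicated(resF)
  data.frame(resid = a$resid[first], resno = a$resno[first],
             resname = a$resname[first], meanMinDist = rowMeans(acc),
             stringsAsFactors = FALSE)
}

#' Write / read a scoring grid container
#'
#' Self-describing text format: a single JSON header line (format
#' version, origin, bin width, bin counts, receptor atom count, raw
#' maximum, label) followed by the grid values in flat layout with the x
#' index fastest. Round-trips exactly.
#'
#' @param grid a [ScoringGrid-class].
#' @param path output path.
#' @return `path` invisibly (writer); a [ScoringGrid-class] (reader).
#' @export
writeScoringGrid <- function(grid, path) {
  stopifnot(is(grid, "ScoringGrid"))
  g <- grid@geometry
  num <- function(v) paste(sprintf("%.17g", v), collapse = ",")
  # header numerals formatted at full precision for an exact round-trip
  header <- sprintf(
    paste0('{"format":"isa-grid-1","origin":[%s],"bin_width":[%s],',
           '"n_bins":[%s],"n_receptor_atoms":%d,"raw_max":%s,',
           '"receptor_label":%s}'),
    num(g@origin), num(rep(g@binWidth, length.out = 3)),
    paste(g@nBins, collapse = ","), grid@nReceptorAtoms,
    sprintf("%.17g", grid@rawMax),
    jsonlite::toJSON(grid@receptorLabel, auto_unbox = TRUE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(sprintf("%.17g", as.vector(grid@values)), con)
  invisible(path)
}

#' @rdname writeScoringGrid
#' @export
readScoringGrid <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  header <- jsonlite::fromJSON(readLines(con, n = 1))
  if (!identical(header$format, "isa-grid-1"))
    stop("not an isa-grid-1 file: ", path)
  vals <- scan(con, what = double(), quiet = TRUE)
  nb <- as.integer(header$n_bins)
  if (length(vals) != prod(nb)) stop("grid value count mismatch in ", path)
  new("ScoringGrid",
      geometry = new("GridGeometry", origin = as.numeric(header$origin),
                     binWidth = as.numeric(header$bin_width), nBins = nb),
      values = array(vals, dim = nb),
      receptorLabel = as.character(header$receptor_label),
      nReceptorAtoms = as.integer(header$n_receptor_atoms),
      rawMax = as.numeric(header$raw_max))
}
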