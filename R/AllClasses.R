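#' @import methods
#' @importFrom stats dist sd rnorm runif setNames quantile
#' @importFrom utils head tail write.csv read.csv
#' @useDynLib isafit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Molecular structure with atom metadata and subunit bookkeeping
#'
#' An ordered collection of atoms with PDB-style metadata, Cartesian
#' coordinates in Angstrom, and an optional partition of atoms into named
#' subunits (for two-domain ligands these are conventionally `"H1"`, the
#' histone subunit, and `"Ub"`, the ubiquitin subunit).
#'
#' The `atoms` data frame carries one row per atom with columns
#' `serial`, `name`, `elem`, `resid` (0-based contiguous internal residue
#' index), `resno` (original PDB residue number, 1-based biological
#' numbering such as K30), `resname`, `chain`, and `het` (logical,
#' HETATM record).
#'
#' @slot atoms data.frame of per-atom metadata (see Details).
#' @slot coords numeric matrix, n_atoms x 3, Angstrom.
#' @slot subunits named list of integer atom-index vectors; may be empty.
#'   Subunits must not overlap.
#' @slot label character scalar identifying the structure.
#' @export
setClass("Structure",
  representation(atoms = "data.frame", coords = "matrix",
                 subunits = "list", label = "character"))

setValidity("Structure", function(object) {
  msg <- character()
  if (!is.numeric(object@coords) || ncol(object@coords) != 3L)
    msg <- c(msg, "coords must be an n x 3 numeric matrix")
  if (nrow(object@coords) != nrow(object@atoms))
    msg <- c(msg, "coords and atoms must have the same number of rows")
  if (nrow(object@coords) && !all(is.finite(object@coords)))
    msg <- c(msg, "coords must be finite")
  need <- c("serial", "name", "elem", "resid", "resno", "resname",
            "chain", "het")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, paste("atoms must have columns:",
                        paste(need, collapse = ", ")))
  if ("resid" %in% names(object@atoms) && nrow(object@atoms) &&
      any(object@atoms$resid < 0L))
    msg <- c(msg, "residue indices must be non-negative")
  if (length(object@subunits)) {
    idx <- unlist(object@subunits, use.names = FALSE)
    if (length(idx) && (any(idx < 1L) || any(idx > nrow(object@atoms))))
      msg <- c(msg, "subunit indices out of range")
    if (anyDuplicated(idx))
      msg <- c(msg, "subunits must not overlap")
    if (is.null(names(object@subunits)) || any(names(object@subunits) == ""))
      msg <- c(msg, "subunits must be named")
  }
  if (length(msg)) msg else TRUE
})

#' Conformational ensemble sharing one topology
#'
#' Ordered frames of coordinates over a fixed [Structure] topology, with
#' per-frame provenance (ubiquitylation-variant label such as `"K30Ub"`,
#' source simulation id, original frame index).
#'
#' @slot topology a [Structure].
#' @slot coords numeric array, n_atoms x 3 x n_frames, Angstrom.
#' @slot frameMeta data.frame with one row per frame; columns `variant`,
#'   `source`, `frame`.
#' @export
setClass("Trajectory",
  representation(topology = "Structure", coords = "array",
                 frameMeta = "data.frame"))

setValidity("Trajectory", function(object) {
  msg <- character()
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    msg <- c(msg, "coords must be an n_atoms x 3 x n_frames array")
  else {
    if (d[1] != nrow(object@topology@atoms))
      msg <- c(msg, "every frame must have exactly n_atoms rows")
    if (nrow(object@frameMeta) != d[3])
      msg <- c(msg, "frameMeta must have one row per frame")
  }
  if (length(msg)) msg else TRUE
})

#' Axis-aligned grid geometry for occupancy histograms
#'
#' @slot origin numeric 3-vector, Angstrom: minimum corner of the (padded)
#'   bounding box.
#' @slot binWidth numeric, length 1 (isotropic) or 3, Angstrom.
#' @slot nBins integer 3-vector, bins per axis.
#' @export
setClass("GridGeometry",
  representation(origin = "numeric", binWidth = "numeric",
                 nBins = "integer"))

setValidity("GridGeometry", function(object) {
  msg <- character()
  if (length(object@origin) != 3L) msg <- c(msg, "origin must be length 3")
  if (!length(object@binWidth) %in% c(1L, 3L) || any(object@binWidth <= 0))
    msg <- c(msg, "binWidth must be positive, length 1 or 3")
  if (length(object@nBins) != 3L || any(object@nBins < 1L))
    msg <- c(msg, "nBins must be three integers >= 1")
  if (length(msg)) msg else TRUE
})

#' Normalized min-merged cumulative occupancy grid (ISA receptor)
#'
#' The receptor representation used by the interpenetration and scoring
#' algorithm: eight corner-anchored cumulative occupancy histograms of the
#' receptor atoms, merged by the per-bin minimum and min-max normalized
#' onto [0, 1].
#'
#' @slot geometry a [GridGeometry].
#' @slot values numeric 3D array in [0, 1].
#' @slot receptorLabel character scalar.
#' @slot nReceptorAtoms integer, atoms binned into the grid.
#' @slot rawMax numeric, the pre-normalization maximum (provenance).
#' @export
setClass("ScoringGrid",
  representation(geometry = "GridGeometry", values = "array",
                 receptorLabel = "character", nReceptorAtoms = "integer",
                 rawMax = "numeric"))

setValidity("ScoringGrid", function(object) {
  msg <- character()
  if (!identical(dim(object@values), as.integer(object@geometry@nBins)))
    msg <- c(msg, "values dimensions must match geometry nBins")
  if (any(object@values < 0))
    msg <- c(msg, "grid values must be non-negative")
  if (max(object@values) > 1 + 1e-12)
    msg <- c(msg, "grid values must lie in [0, 1]")
  if (object@nReceptorAtoms > 0L && object@rawMax > 0) {
    if (abs(max(object@values) - 1) > 1e-12)
      msg <- c(msg, "non-empty receptor grid must attain max 1")
    if (min(object@values) != 0)
      msg <- c(msg, "grid minimum must be 0")
  }
  if (length(msg)) msg else TRUE
})

#' Frames-by-collective-variable matrix
#'
#' Per-frame collective variables describing inter-subunit geometry:
#' either the flattened matrix of distances between surface-exposed
#' C-alpha atoms of the two subunits (`"sasa_cv"`) or the residue-wise
#' minimal C-alpha distance from histone to ubiquitin (`"rmd_cv"`).
#' Distances are in Angstrom.
#'
#' @slot values numeric matrix, n_frames x n_cv.
#' @slot cvKind `"sasa_cv"` or `"rmd_cv"`.
#' @slot cvLabels character, one label per column (residue or residue-pair).
#' @slot frameMeta data.frame inherited from the source [Trajectory].
#' @export
setClass("CVMatrix",
  representation(values = "matrix", cvKind = "character",
                 cvLabels = "character", frameMeta = "data.frame"))

setValidity("CVMatrix", function(object) {
  msg <- character()
  if (!object@cvKind %in% c("sasa_cv", "rmd_cv"))
    msg <- c(msg, "cvKind must be 'sasa_cv' or 'rmd_cv'")
  if (nrow(object@values) && any(object@values < 0))
    msg <- c(msg, "CV values must be non-negative")
  if (length(object@cvLabels) != ncol(object@values))
    msg <- c(msg, "one cvLabel per column required")
  if (nrow(object@frameMeta) && nrow(object@frameMeta) != nrow(object@values))
    msg <- c(msg, "frameMeta rows must match frames")
  if (length(msg)) msg else TRUE
})

#' Selection of surface-exposed C-alpha atoms for SASA-CVs
#'
#' @slot h1Indices integer atom indices of exposed histone C-alpha atoms.
#' @slot ubIndices integer atom indices of exposed ubiquitin C-alpha atoms.
#' @slot threshold numeric SASA threshold used for the selection.
#' @slot unit `"A2"` or `"nm2"`.
#' @slot sourceLabel character.
#' @export
setClass("SasaSelection",
  representation(h1Indices = "integer", ubIndices = "integer",
                 threshold = "numeric", unit = "character",
                 sourceLabel = "character"))

#' Rigid-body transform from Kabsch superposition
#'
#' @slot rotation 3 x 3 proper rotation matrix (det = +1).
#' @slot translation numeric 3-vector, Angstrom.
#' @slot rmsdAfter numeric, RMSD after applying the transform, Angstrom.
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric",
                 rmsdAfter = "numeric"))

setValidity("RigidTransform", function(object) {
  msg <- character()
  if (!identical(dim(object@rotation), c(3L, 3L)))
    msg <- c(msg, "rotation must be 3 x 3")
  else {
    if (abs(det(object@rotation) - 1) > 1e-8)
      msg <- c(msg, "rotation must be proper (det = +1)")
    if (max(abs(crossprod(object@rotation) - diag(3))) > 1e-8)
      msg <- c(msg, "rotation must be orthonormal")
  }
  if (length(object@translation) != 3L)
    msg <- c(msg, "translation must be length 3")
  if (length(msg)) msg else TRUE
})

#' Global pairwise sequence alignment map
#'
#' Matched (non-gap) columns of a Needleman-Wunsch global alignment, as
#' 1-based residue positions in both sequences.
#'
#' @slot pairs integer matrix with columns `a`, `b`; strictly increasing
#'   in both (no crossings).
#' @slot score numeric alignment score.
#' @slot identity numeric in [0, 1], fraction of matched columns that are
#'   identical.
#' @export
setClass("AlignmentMap",
  representation(pairs = "matrix", score = "numeric",
                 identity = "numeric"))

setValidity("AlignmentMap", function(object) {
  msg <- character()
  p <- object@pairs
  if (ncol(p) != 2L) msg <- c(msg, "pairs must have two columns")
  else if (nrow(p) > 1L &&
           (any(diff(p[, 1]) <= 0) || any(diff(p[, 2]) <= 0)))
    msg <- c(msg, "pairs must be strictly increasing in both coordinates")
  if (length(msg)) msg else TRUE
})

#' Two-dimensional projection of an ensemble
#'
#' Externally computed low-dimensional (e.g. sketch-map) projection:
#' one 2D point per frame, with per-point provenance.
#'
#' @slot points numeric matrix, n x 2 (arbitrary units).
#' @slot frameMeta data.frame with one row per point.
#' @export
setClass("Projection2D",
  representation(points = "matrix", frameMeta = "data.frame"))

setValidity("Projection2D", function(object) {
  msg <- character()
  if (ncol(object@points) != 2L)
    msg <- c(msg, "points must be an n x 2 matrix")
  if (nrow(object@points) && !all(is.finite(object@points)))
    msg <- c(msg, "projection points must be finite")
  if (nrow(object@frameMeta) && nrow(object@frameMeta) != nrow(object@points))
    msg <- c(msg, "frameMeta rows must match points")
  if (length(msg)) msg else TRUE
})

#' Pass schedule for iterative density-based cluster refinement
#'
#' Defaults follow the published protocol: one artifact-exclusion pass at
#' minimal cluster size 1000, then refinement passes at sizes 750, 500,
#' 250, 125, 75, 50, 25 (8 passes total), gated by three rejection
#' criteria: mean RMSD to the cluster centroid > 6 Angstrom, Fisher-Pearson
#' skewness of the 2D distance distribution > 0.5, or multimodality of
#' that distribution (dip test at alpha = 0.05).
#'
#' @slot artifactPassSize integer.
#' @slot refinementSizes strictly decreasing integer vector, all >= 2.
#' @slot rmsdMeanMax numeric, Angstrom.
#' @slot skewnessMax numeric.
#' @slot multimodalityAlpha numeric in (0, 1).
#' @export
setClass("PassSchedule",
  representation(artifactPassSize = "integer", refinementSizes = "integer",
                 rmsdMeanMax = "numeric", skewnessMax = "numeric",
                 multimodalityAlpha = "numeric"))

setValidity("PassSchedule", function(object) {
  msg <- character()
  s <- object@refinementSizes
  if (length(s) && (any(diff(s) >= 0) || any(s < 2L)))
    msg <- c(msg, "refinementSizes must be strictly decreasing, all >= 2")
  if (object@artifactPassSize < 2L)
    msg <- c(msg, "artifactPassSize must be >= 2")
  if (object@multimodalityAlpha <= 0 || object@multimodalityAlpha >= 1)
    msg <- c(msg, "multimodalityAlpha must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Per-frame cluster assignments with per-cluster diagnostics
#'
#' @slot labels integer per-point cluster label; -1 marks unassigned
#'   (noise or never accepted) points.
#' @slot acceptedPass integer per-cluster pass index (1 = artifact pass,
#'   2..8 = refinement passes), named by cluster id.
#' @slot diagnostics data.frame of per-cluster diagnostics (one row per
#'   accepted cluster: size, centroid frame, RMSD mean/sd, 2D skewness,
#'   dip p-value, multimodality flag, variant composition).
#' @slot excluded integer indices of points removed by the
#'   artifact-exclusion pass.
#' @export
setClass("ClusterTable",
  representation(labels = "integer", acceptedPass = "integer",
                 diagnostics = "data.frame", excluded = "integer"))
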