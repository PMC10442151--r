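#' @rdname Structure-class
#' @param object,x an object.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname Trajectory-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Coordinates of a structure or trajectory frame
#' @param x a `Structure` or `Trajectory`.
#' @param ... for `Trajectory`, `frame =` selects a frame (default all,
#'   returned as an n_atoms x 3 x n_frames array).
#' @return numeric matrix (or array), Angstrom.
#' @export
setGeneric("atomCoords", function(x, ...) standardGeneric("atomCoords"))

#' Per-atom metadata table
#' @param x a `Structure` or `Trajectory`.
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' Named subunit partition of a structure
#' @param x a `Structure` or `Trajectory`.
#' @export
setGeneric("subunits", function(x) standardGeneric("subunits"))

#' @rdname subunits
#' @param value named list of integer atom-index vectors.
#' @export
setGeneric("subunits<-", function(x, value) standardGeneric("subunits<-"))

#' Per-frame provenance of a trajectory or projection
#' @param x a `Trajectory`, `Projection2D` or `CVMatrix`.
#' @export
setGeneric("frameMeta", function(x) standardGeneric("frameMeta"))

#' @rdname frameMeta
#' @param value data.frame with one row per frame.
#' @export
setGeneric("frameMeta<-", function(x, value) standardGeneric("frameMeta<-"))

# ---- methods -------------------------------------------------------------

#' @export
setMethod("nAtoms", "Structure", function(x) nrow(x@atoms))
#' @export
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[1])
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])

#' @export
setMethod("atomCoords", "Structure", function(x, ...) x@coords)
#' @export
setMethod("atomCoords", "Trajectory", function(x, ..., frame = NULL) {
  if (is.null(frame)) return(x@coords)
  stopifnot(frame >= 1, frame <= nFrames(x))
  x@coords[, , frame, drop = FALSE][, , 1]
})

#' @export
setMethod("atomData", "Structure", function(x) x@atoms)
#' @export
setMethod("atomData", "Trajectory", function(x) x@topology@atoms)

#' @export
setMethod("subunits", "Structure", function(x) x@subunits)
#' @export
setMethod("subunits", "Trajectory", function(x) x@topology@subunits)
#' @export
setReplaceMethod("subunits", "Structure", function(x, value) {
  x@subunits <- value
  validObject(x)
  x
})
#' @export
setReplaceMethod("subunits", "Trajectory", function(x, value) {
  subunits(x@topology) <- value
  x
})

#' @export
setMethod("frameMeta", "Trajectory", function(x) x@frameMeta)
#' @export
setMethod("frameMeta", "Projection2D", function(x) x@frameMeta)
#' @export
setMethod("frameMeta", "CVMatrix", function(x) x@frameMeta)
#' @export
setReplaceMethod("frameMeta", "Trajectory", function(x, value) {
  x@frameMeta <- value
  validObject(x)
  x
})

#' Topology of a trajectory
#' @param x a `Trajectory`.
#' @export
topology <- function(x) {
  stopifnot(is(x, "Trajectory"))
  x@topology
}

#' Projection points accessor
#' @param x a `Projection2D`.
#' @export
projectionPoints <- function(x) {
  stopifnot(is(x, "Projection2D"))
  x@points
}

#' Grid values and geometry accessors
#' @param x a `ScoringGrid`.
#' @export
gridValues <- function(x) {
  stopifnot(is(x, "ScoringGrid"))
  x@values
}

#' @rdname gridValues
#' @export
gridGeometry <- function(x) {
  stopifnot(is(x, "ScoringGrid"))
  x@geometry
}

#' CV values accessor
#' @param x a `CVMatrix`.
#' @export
cvValues <- function(x) {
  stopifnot(is(x, "CVMatrix"))
  x@values
}

#' Cluster labels accessor
#' @param x a `ClusterTable`.
#' @export
clusterLabels <- function(x) {
  stopifnot(is(x, "ClusterTable"))
  x@labels
}

#' @rdname clusterLabels
#' @export
clusterDiagnosticsTable <- function(x) {
  stopifnot(is(x, "ClusterTable"))
  x@diagnostics
}

setMethod("show", "Structure", function(object) {
  cat("Structure '", object@label, "': ", nAtoms(object), " atoms, ",
      length(unique(object@atoms$chain)), " chain(s)", sep = "")
  if (length(object@subunits))
    cat("; subunits: ",
        paste(sprintf("%s (%d)", names(object@subunits),
                      lengths(object@subunits)), collapse = ", "),
        sep = "")
  cat("\n")
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory: ", nFrames(object), " frames x ", nAtoms(object),
      " atoms ('", object@topology@label, "')\n", sep = "")
})

setMethod("show", "ScoringGrid", function(object) {
  g <- object@geometry
  cat("ScoringGrid '", object@receptorLabel, "': ",
      paste(g@nBins, collapse = " x "), " bins, width ",
      paste(format(g@binWidth), collapse = "/"), " A, ",
      object@nReceptorAtoms, " receptor atoms (raw max ",
      format(object@rawMax), ")\n", sep = "")
})

setMethod("show", "CVMatrix", function(object) {
  cat("CVMatrix (", object@cvKind, "): ", nrow(object@values),
      " frames x ", ncol(object@values), " CVs\n", sep = "")
})

setMethod("show", "ClusterTable", function(object) {
  k <- sum(object@labels != -1L)
  cat("ClusterTable: ", length(object@labels), " points, ",
      nrow(object@diagnostics), " accepted cluster(s), ", k,
      " assigned, ", length(object@excluded), " excluded as artifacts\n",
      sep = "")
})
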