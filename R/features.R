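#' Select surface-exposed C-alpha atoms of both subunits
#'
#' C-alpha atoms whose own solvent-accessible surface area is strictly
#' greater than `threshold` are selected per subunit, in residue order.
#' The SASA is computed on the full structure (reference conformation),
#' so the selection cardinality depends on the threshold unit: both
#' Angstrom^2 and nm^2 modes are supported and recorded in the result.
#'
#' @param s a [Structure-class] with subunits `h1` and `ub` defined.
#' @param threshold SASA threshold (default 1, in `unit`).
#' @param unit `"A2"` (default) or `"nm2"`.
#' @param h1,ub subunit names (defaults `"H1"`, `"Ub"`).
#' @param ... passed to [computeAtomSasa()].
#' @return a [SasaSelection-class].
#' @export
selectSasaCalphas <- function(s, threshold = 1, unit = c("A2", "nm2"),
                              h1 = "H1", ub = "Ub", ...) {
  unit <- match.arg(unit)
  su <- subunits(s)
  if (!all(c(h1, ub) %in% names(su)))
    stop("structure must define subunits '", h1, "' and '", ub, "'")
  sasa <- computeAtomSasa(s, unit = unit, ...)
  pick <- function(sub) {
    ca <- selectAtoms(s, name = "CA", subunit = sub)
    ca[sasa[ca] > threshold]
  }
  h1i <- pick(h1)
  ubi <- pick(ub)
  if (!length(h1i) || !length(ubi))
    stop("empty exposed C-alpha selection (threshold ", threshold, " ",
         unit, "): SASA-CVs are undefined")
  new("SasaSelection", h1Indices = as.integer(h1i),
      ubIndices = as.integer(ubi), threshold = threshold, unit = unit,
      sourceLabel = s@label)
}

#' Surface-exposed C-alpha distance collective variables (SASA-CVs)
#'
#' Per frame, the matrix of Euclidean distances between every selected
#' histone C-alpha and every selected ubiquitin C-alpha, flattened
#' row-major (histone outer, ubiquitin inner). For the reference
#' crystal-structure selection of 16 histone and 19 ubiquitin atoms this
#' yields a 304-dimensional descriptor per frame.
#'
#' @param t a [Trajectory-class].
#' @param sel a [SasaSelection-class] (indices valid for the topology).
#' @return a [CVMatrix-class] with `cvKind = "sasa_cv"`.
#' @export
computeSasaCVs <- function(t, sel) {
  stopifnot(is(t, "Trajectory"), is(sel, "SasaSelection"))
  h1i <- sel@h1Indices
  ubi <- sel@ubIndices
  na <- nAtoms(t)
  if (any(c(h1i, ubi) < 1L) || any(c(h1i, ubi) > na))
    stop("selection index out of range for trajectory topology")
  nf <- nFrames(t)
  vals <- matrix(0, nf, length(h1i) * length(ubi))
  for (f in seq_len(nf)) {
    m <- t@coords[, , f]
    d <- crossDist(m[h1i, , drop = FALSE], m[ubi, , drop = FALSE])
    vals[f, ] <- as.vector(t(d))  # row-major: H1 outer, Ub inner
  }
  a <- atomData(t)
  labels <- as.vector(t(outer(a$resno[h1i], a$resno[ubi], paste,
                              sep = "-")))
  new("CVMatrix", values = vals, cvKind = "sasa_cv", cvLabels = labels,
      frameMeta = frameMeta(t))
}

#' Residue-wise minimal distance collective variables (RMD-CVs)
#'
#' Per frame, for each histone C-alpha atom the minimum distance to any
#' ubiquitin C-alpha atom (row-wise minimum of the cross-subunit pairwise
#' distance matrix). For a 75-residue histone subunit this yields a
#' 75-dimensional descriptor regardless of the ubiquitin size.
#'
#' @param t a [Trajectory-class] whose topology defines subunits `h1`
#'   and `ub`, each with at least one C-alpha atom.
#' @param h1,ub subunit names (defaults `"H1"`, `"Ub"`).
#' @return a [CVMatrix-class] with `cvKind = "rmd_cv"`.
#' @export
computeRmdCVs <- function(t, h1 = "H1", ub = "Ub") {
  stopifnot(is(t, "Trajectory"))
  su <- subunits(t)
  if (!all(c(h1, ub) %in% names(su)))
    stop("topology must define subunits '", h1, "' and '", ub, "'")
  h1i <- selectAtoms(t, name = "CA", subunit = h1)
  ubi <- selectAtoms(t, name = "CA", subunit = ub)
  if (!length(h1i) || !length(ubi))
    stop("both subunits need at least one C-alpha atom")
  nf <- nFrames(t)
  vals <- matrix(0, nf, length(h1i))
  for (f in seq_len(nf)) {
    m <- t@coords[, , f]
    d <- crossDist(m[h1i, , drop = FALSE], m[ubi, , drop = FALSE])
    vals[f, ] <- apply(d, 1, min)
  }
  a <- atomData(t)
  new("CVMatrix", values = vals, cvKind = "rmd_cv",
      cvLabels = as.character(a$resno[h1i]), frameMeta = frameMeta(t))
}

# All pairwise Euclidean distances between row sets a (n1 x 3), b (n2 x 3).
crossDist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Write a CV matrix as CSV (with frame metadata sidecar)
#'
#' The main file has a header row of CV labels and one row per frame;
#' `<path>.meta.csv` holds the frame metadata.
#'
#' @param cv a [CVMatrix-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeCVMatrix <- function(cv, path) {
  stopifnot(is(cv, "CVMatrix"))
  df <- as.data.frame(cv@values)
  names(df) <- cv@cvLabels
  write.csv(df, path, row.names = FALSE)
  write.csv(cv@frameMeta, paste0(path, ".meta.csv"), row.names = FALSE)
  invisible(path)
}
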