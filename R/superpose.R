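#' Global pairwise sequence alignment (Needleman-Wunsch)
#'
#' Global alignment with BLOSUM62 and affine gap penalties (open 10,
#' extend 0.5 by default), returning the matched (non-gap) columns as
#' 1-based residue position pairs. Used to map ligand C-alpha atoms onto
#' a reference linker histone when the residue counts differ, and core
#' histones onto nucleosome-array cores.
#'
#' @param seqA,seqB amino-acid sequences (one-letter codes).
#' @param substitutionMatrix name of a substitution matrix available to
#'   Biostrings (default `"BLOSUM62"`).
#' @param gapOpening,gapExtension gap penalties (positive).
#' @return an [AlignmentMap-class].
#' @export
alignSequences <- function(seqA, seqB, substitutionMatrix = "BLOSUM62",
                           gapOpening = 10, gapExtension = 0.5) {
  if (!nzchar(seqA) || !nzchar(seqB)) stop("sequences must be non-empty")
  ok <- "^[ACDEFGHIKLMNPQRSTVWYX]+$"
  if (!grepl(ok, seqA) || !grepl(ok, seqB))
    stop("sequences must use the standard one-letter amino-acid alphabet")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seqA), Biostrings::AAString(seqB),
    type = "global", substitutionMatrix = substitutionMatrix,
    gapOpening = gapOpening, gapExtension = gapExtension)
  sa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ia <- cumsum(sa != "-")
  ib <- cumsum(sb != "-")
  both <- sa != "-" & sb != "-"
  pairs <- cbind(a = ia[both], b = ib[both])
  idf <- if (nrow(pairs)) mean(sa[both] == sb[both]) else 0
  new("AlignmentMap", pairs = pairs, score = Biostrings::score(pa),
      identity = idf)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares proper rotation + translation mapping `mobile` onto
#' `target`; reflections are forbidden (determinant-corrected SVD).
#'
#' @param mobile,target numeric n x 3 coordinate matrices (same n >= 3,
#'   not collinear).
#' @return a [RigidTransform-class] whose `rmsdAfter` is the global
#'   minimum over proper rigid transforms.
#' @export
kabschFit <- function(mobile, target) {
  mobile <- as.matrix(mobile)
  target <- as.matrix(target)
  if (!identical(dim(mobile), dim(target)))
    stop("mobile and target must have the same dimensions")
  n <- nrow(mobile)
  if (n < 3L) stop("at least 3 points are required")
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(target, 2, ct)
  svP <- svd(P)$d
  svQ <- svd(Q)$d
  if (svP[2] <= 1e-8 * max(svP[1], 1) || svQ[2] <= 1e-8 * max(svQ[1], 1))
    stop("degenerate (collinear) input: superposition is not unique")
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- ct - as.vector(R %*% cm)
  fitted <- tcrossprod(P, R)
  rmsd <- sqrt(sum((sweep(fitted, 2, ct, "+") - target)^2) / n)
  new("RigidTransform", rotation = R, translation = tr, rmsdAfter = rmsd)
}

#' Apply a rigid transform to coordinates
#'
#' @param transform a [RigidTransform-class].
#' @param coords numeric n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
applyTransform <- function(transform, coords) {
  stopifnot(is(transform, "RigidTransform"))
  sweep(tcrossprod(as.matrix(coords), transform@rotation), 2,
        transform@translation, "+")
}

#' Pairwise minimized-RMSD matrix over trajectory frames
#'
#' Each entry is the Kabsch-minimized RMSD between two frames on the
#' given atom subset. The diagonal is zero and the matrix symmetric;
#' minimized RMSD is not a metric and triangle-inequality violations are
#' possible.
#'
#' @param t a [Trajectory-class] with at least 2 frames.
#' @param atomIndices atom indices used for the superposition (default:
#'   all C-alpha atoms).
#' @param frames optional frame subset (default all).
#' @return symmetric numeric matrix, Angstrom.
#' @export
pairwiseRmsdMatrix <- function(t, atomIndices = selectAtoms(t, name = "CA"),
                               frames = NULL) {
  stopifnot(is(t, "Trajectory"))
  if (is.null(frames)) frames <- seq_len(nFrames(t))
  if (length(frames) < 2L) stop("at least 2 frames are required")
  if (!length(atomIndices)) stop("empty atom selection")
  cpp_pairwise_rmsd(t@coords[atomIndices, , frames, drop = FALSE])
}
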