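#' Construct a Structure from atom metadata and coordinates
#'
#' @param atoms data.frame with columns `serial`, `name`, `elem`, `resno`,
#'   `resname`, `chain`; optional `het` (default FALSE) and `resid`
#'   (recomputed 0-based, contiguous per chain, when absent).
#' @param coords numeric n x 3 matrix, Angstrom.
#' @param subunits named list of integer atom-index vectors.
#' @param label character scalar.
#' @return a [Structure-class] object.
#' @export
Structure <- function(atoms, coords, subunits = list(), label = "structure") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (is.null(atoms$het)) atoms$het <- FALSE
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$elem)) atoms$elem <- guessElement(atoms$name)
  if (is.null(atoms$resid))
    atoms$resid <- internalResidueIndex(atoms$chain, atoms$resno)
  atoms$serial <- as.integer(atoms$serial)
  atoms$resno <- as.integer(atoms$resno)
  atoms$resid <- as.integer(atoms$resid)
  rownames(atoms) <- NULL
  new("Structure", atoms = atoms, coords = unname(coords),
      subunits = subunits, label = label)
}

#' Construct a Trajectory
#'
#' @param topology a [Structure-class].
#' @param coords either an n_atoms x 3 x n_frames array or a list of
#'   n_atoms x 3 matrices.
#' @param frameMeta optional data.frame (`variant`, `source`, `frame`);
#'   defaults are filled in.
#' @return a [Trajectory-class] object.
#' @export
Trajectory <- function(topology, coords, frameMeta = NULL) {
  if (is.list(coords)) {
    nf <- length(coords)
    arr <- array(0, c(nAtoms(topology), 3L, nf))
    for (i in seq_len(nf)) arr[, , i] <- as.matrix(coords[[i]])
    coords <- arr
  }
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  nf <- dim(coords)[3]
  if (is.null(frameMeta))
    frameMeta <- data.frame(variant = rep(NA_character_, nf),
                            source = rep(topology@label, nf),
                            frame = seq_len(nf),
                            stringsAsFactors = FALSE)
  new("Trajectory", topology = topology, coords = coords,
      frameMeta = frameMeta)
}

# 0-based internal residue index, contiguous per chain; a new residue
# starts whenever chain or original residue number changes.
internalResidueIndex <- function(chain, resno) {
  if (!length(chain)) return(integer())
  key <- paste(chain, resno, sep = "\r")
  newres <- c(TRUE, key[-1] != key[-length(key)])
  newchain <- c(TRUE, chain[-1] != chain[-length(chain)])
  idx <- integer(length(chain))
  cur <- -1L
  for (i in seq_along(chain)) {
    if (newchain[i]) cur <- -1L
    if (newres[i]) cur <- cur + 1L
    idx[i] <- cur
  }
  idx
}

guessElement <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substr(nm, 1, 2)
  one <- substr(nm, 1, 1)
  ifelse(two %in% c("CL", "BR", "MG", "ZN", "MN", "FE", "SE", "NA"),
         two, one)
}

#' Read a molecular structure from a PDB file
#'
#' All ATOM/HETATM records of the first model are represented; chain and
#' residue metadata are preserved and coordinates are in Angstrom.
#' Alternate locations other than blank or 'A' are dropped. Hydrogens are
#' kept as present in the file.
#'
#' @param path PDB file path.
#' @param format currently only `"pdb"`.
#' @param label structure label (defaults to the file name).
#' @return a [Structure-class].
#' @export
readStructure <- function(path, format = c("pdb"), label = basename(path)) {
  format <- match.arg(format)
  pdb <- parsePdbChecked(path)
  buildStructureFromBio3d(pdb, model = 1L, label = label)
}

#' Read a multi-model PDB file as a Trajectory
#'
#' Each MODEL block becomes one frame; the first model provides the
#' topology.
#'
#' @inheritParams readStructure
#' @return a [Trajectory-class].
#' @export
readTrajectory <- function(path, format = c("pdb"), label = basename(path)) {
  format <- match.arg(format)
  pdb <- parsePdbChecked(path, multi = TRUE)
  topo <- buildStructureFromBio3d(pdb, model = 1L, label = label)
  keep <- attr(topo, "keepIdx")
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  arr <- array(0, c(nAtoms(topo), 3L, nf))
  for (f in seq_len(nf)) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    arr[, , f] <- m[keep, , drop = FALSE]
  }
  Trajectory(topo, arr,
             data.frame(variant = NA_character_, source = label,
                        frame = seq_len(nf), stringsAsFactors = FALSE))
}

parsePdbChecked <- function(path, multi = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records in ", path)
  # validate fixed-width coordinate fields before handing to the parser
  bad <- which(rec)[vapply(which(rec), function(i) {
    ln <- lines[i]
    any(is.na(suppressWarnings(as.numeric(
      c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))))))
  }, logical(1))]
  if (length(bad))
    stop("malformed ATOM/HETATM record at line ", bad[1], " of ", path)
  bio3d::read.pdb(path, multi = multi, verbose = FALSE)
}

buildStructureFromBio3d <- function(pdb, model = 1L, label = "structure") {
  a <- pdb$atom
  keep <- which(is.na(a$alt) | a$alt %in% c("", "A"))
  a <- a[keep, , drop = FALSE]
  chain <- a$chain
  chain[is.na(chain)] <- " "
  elem <- a$elesy
  miss <- is.na(elem) | elem == ""
  if (any(miss)) elem[miss] <- guessElement(a$elety[miss])
  atoms <- data.frame(serial = a$eleno, name = a$elety, elem = elem,
                      resno = a$resno, resname = a$resid, chain = chain,
                      het = a$type == "HETATM", stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (!is.null(dim(xyz))) xyz <- xyz[model, ]
  m <- matrix(xyz, ncol = 3, byrow = TRUE)[keep, , drop = FALSE]
  s <- Structure(atoms, m, label = label)
  attr(s, "keepIdx") <- keep
  s
}

#' Write a structure (or trajectory) to a PDB file
#'
#' Round-trips atom count, names, chains, and coordinates to PDB precision
#' (3 decimals). Atom serial numbers above 99999 are written wrapped
#' modulo 100000 (the documented convention; internal serials are
#' unaffected).
#'
#' @param s a [Structure-class] or [Trajectory-class] (multi-model output).
#' @param path output file path.
#' @param format currently only `"pdb"`.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(s, path, format = c("pdb")) {
  format <- match.arg(format)
  if (is(s, "Trajectory")) {
    topo <- topology(s)
    xyz <- t(apply(s@coords, 3, function(m) as.vector(t(m))))
  } else {
    topo <- s
    xyz <- matrix(as.vector(t(s@coords)), nrow = 1)
  }
  if (nAtoms(topo) == 0L) stop("refusing to write an empty structure")
  a <- topo@atoms
  serial <- ((a$serial - 1L) %% 100000L) + 1L
  con <- file(path, "w")
  on.exit(close(con))
  multi <- nrow(xyz) > 1L
  for (f in seq_len(nrow(xyz))) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    writeLines(pdbAtomLines(a, m, serial), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# Fixed-width ATOM/HETATM records (PDB v3.3 layout).
pdbAtomLines <- function(a, coords, serial) {
  name4 <- vapply(a$name, function(n) {
    if (nchar(n) >= 4L) substr(n, 1, 4)
    else sprintf(" %-3s", n)
  }, character(1))
  sprintf("%-6s%5d %4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          ifelse(a$het, "HETATM", "ATOM"), serial, name4,
          substr(a$resname, 1, 4), substr(a$chain, 1, 1), a$resno %% 10000L,
          coords[, 1], coords[, 2], coords[, 3], 1, 0,
          substr(a$elem, 1, 2))
}

#' Select atoms by metadata predicates
#'
#' Criteria are combined with AND; each accepts a vector of allowed
#' values. Returns a strictly increasing index vector. Selection is
#' idempotent and order-stable, and complementary predicates partition
#' the atom set.
#'
#' @param s a [Structure-class] or [Trajectory-class].
#' @param name,elem,chain,resno,resid,resname,subunit allowed values
#'   (NULL = no constraint). `resid` is the 0-based internal index,
#'   `resno` the original PDB residue number. `subunit` names an entry of
#'   `subunits(s)`.
#' @param ... unused; supplying an unknown field is an error.
#' @return integer vector of atom indices, strictly increasing.
#' @export
selectAtoms <- function(s, name = NULL, elem = NULL, chain = NULL,
                        resno = NULL, resid = NULL, resname = NULL,
                        subunit = NULL, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown selection field(s): ",
         paste(names(extra), collapse = ", "))
  a <- atomData(s)
  keep <- rep(TRUE, nrow(a))
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(elem)) keep <- keep & a$elem %in% elem
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(subunit)) {
    su <- subunits(s)
    if (!all(subunit %in% names(su)))
      stop("unknown subunit(s): ",
           paste(setdiff(subunit, names(su)), collapse = ", "))
    inset <- rep(FALSE, nrow(a))
    inset[unlist(su[subunit], use.names = FALSE)] <- TRUE
    keep <- keep & inset
  }
  which(keep)
}

#' Extract a sub-structure by atom indices
#'
#' Subunit maps are re-indexed to the retained atoms.
#'
#' @param s a [Structure-class].
#' @param indices integer atom indices (increasing order enforced).
#' @return a [Structure-class].
#' @export
subsetStructure <- function(s, indices) {
  indices <- sort(unique(as.integer(indices)))
  su <- lapply(s@subunits, function(ix) {
    match(intersect(ix, indices), indices)
  })
  su <- su[lengths(su) > 0]
  new("Structure", atoms = s@atoms[indices, , drop = FALSE] |>
        (\(d) { rownames(d) <- NULL; d })(),
      coords = s@coords[indices, , drop = FALSE],
      subunits = su, label = s@label)
}

#' One-letter amino-acid sequence of selected C-alpha atoms
#'
#' @param s a [Structure-class] or [Trajectory-class].
#' @param indices atom indices of C-alpha atoms (defaults to all atoms
#'   named CA).
#' @return character scalar (one-letter codes; unknown residues map to X).
#' @export
structureSequence <- function(s, indices = selectAtoms(s, name = "CA")) {
  a <- atomData(s)
  paste(bio3d::aa321(a$resname[indices]), collapse = "")
}
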