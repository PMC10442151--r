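#' Ring point set (cumulative-histogram demonstration fixture)
#'
#' `n` points on a noisy ring: angles uniform on [0, 2pi), radii
#' `radius + N(0, sigma)`. The defaults (500 points, r = 3, sigma = 0.2)
#' reproduce the classical 2D demonstration of the merged cumulative
#' histogram.
#'
#' @param n number of points.
#' @param radius ring radius.
#' @param sigma radial Gaussian noise sd (>= 0).
#' @param seed integer seed.
#' @return list: `points` (n x 2 matrix), `manifest`.
#' @export
ringPoints <- function(n = 500L, radius = 3, sigma = 0.2, seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  if (sigma < 0) stop("sigma must be >= 0")
  pts <- withr::with_seed(seed, {
    ang <- runif(n, 0, 2 * pi)
    r <- radius + rnorm(n, 0, sigma)
    cbind(x = r * cos(ang), y = r * sin(ang))
  })
  list(points = pts,
       manifest = list(generator = "ringPoints", n = n, radius = radius,
                       sigma = sigma, seed = seed))
}

# standard 20 amino acids, cycled for toy chains
aaCycle <- function(n, offset = 0L) {
  aas <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")
  aas[((seq_len(n) - 1L + offset) %% 20L) + 1L]
}

# C-alpha-only Structure from coordinates
caStructure <- function(coords, chain = "A", resnames = NULL,
                        label = "toy", subunits = list(), het = FALSE,
                        resnoStart = 1L) {
  n <- nrow(coords)
  if (is.null(resnames)) resnames <- aaCycle(n)
  Structure(data.frame(serial = seq_len(n), name = "CA", elem = "C",
                       resno = seq_len(n) + resnoStart - 1L,
                       resname = resnames, chain = chain, het = het,
                       stringsAsFactors = FALSE),
            coords, subunits = subunits, label = label)
}

#' Spherical shell / solid ball toy receptor
#'
#' Atoms uniform on a spherical shell of the given radius and thickness
#' (or in the solid ball when `solid = TRUE`), centred at the origin.
#' The manifest classifies any probe point analytically (inside the
#' occupied region, in the interior cavity, or outside).
#'
#' @param radius outer radius, Angstrom.
#' @param thickness shell thickness, Angstrom (`radius > thickness`).
#' @param nAtoms number of atoms (>= 1).
#' @param solid fill the whole ball instead of a shell.
#' @param seed integer seed.
#' @return list: `structure` ([Structure-class]), `manifest` (with a
#'   `classify(point)` function).
#' @export
shellReceptor <- function(radius = 10, thickness = 2, nAtoms = 1000L,
                          solid = FALSE, seed = 1L) {
  if (nAtoms < 1L) stop("nAtoms must be >= 1")
  if (radius <= thickness || thickness < 0)
    stop("need radius > thickness >= 0")
  coords <- withr::with_seed(seed, {
    u <- matrix(rnorm(3L * nAtoms), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    r <- if (solid) radius * runif(nAtoms)^(1 / 3)
         else radius - thickness * runif(nAtoms)
    u * r
  })
  rInner <- if (solid) 0 else radius - thickness
  s <- Structure(data.frame(serial = seq_len(nAtoms), name = "C",
                            elem = "C", resno = seq_len(nAtoms),
                            resname = "DUM", chain = "A", het = FALSE,
                            stringsAsFactors = FALSE),
                 coords, label = if (solid) "solid-ball" else "shell")
  classify <- function(pt) {
    d <- sqrt(sum(pt^2))
    if (d > radius) "outside"
    else if (d < rInner) "cavity"
    else "inside"
  }
  list(structure = s,
       manifest = list(generator = "shellReceptor", radius = radius,
                       thickness = thickness, nAtoms = nAtoms,
                       solid = solid, seed = seed, rInner = rInner,
                       classify = classify))
}

#' Two-subunit toy ligand with controlled interpenetration
#'
#' A C-alpha-only two-domain ligand: the histone (`H1`) subunit sits at
#' a declared reference pose outside the receptor, while the ubiquitin
#' (`Ub`) subunit is a chain running outward along `axis` whose
#' innermost atom is translated `clashDepth` Angstrom into the receptor
#' surface. With `clashDepth = 0` the whole ligand clears the receptor
#' (score 0); deeper values bury the leading Ub atoms further.
#'
#' @param nH1,nUb residues per subunit (`nUb = 0` gives an empty scored
#'   subunit).
#' @param clashDepth penetration depth, Angstrom (>= 0).
#' @param receptor receptor [Structure-class] (assumed centred near the
#'   origin, e.g. from [shellReceptor()]).
#' @param axis approach direction (default +x), normalized internally.
#' @param margin clearance of the innermost atom at depth 0 (default 2).
#' @param spacing C-alpha spacing, Angstrom (default 3.8).
#' @return list: `structure` with subunits `H1`, `Ub`; `manifest`.
#' @export
toyLigand <- function(nH1 = 10L, nUb = 8L, clashDepth = 0,
                      receptor, axis = c(1, 0, 0), margin = 2,
                      spacing = 3.8) {
  if (clashDepth < 0) stop("clashDepth must be >= 0")
  u <- axis / sqrt(sum(axis^2))
  R <- max(sqrt(rowSums(atomCoords(receptor)^2)))
  ubStart <- R + margin - clashDepth
  ubPos <- if (nUb > 0)
    outer(ubStart + spacing * (seq_len(nUb) - 1L), u) else
    matrix(0, 0, 3)
  # helical (non-collinear) anchor subunit, fully clear of the receptor
  h1Start <- R + margin + spacing * max(nUb, 1L) + 10
  helix <- helixTemplate(max(nH1, 1L), 1.7)
  helix <- sweep(helix, 2, colMeans(helix))
  h1Pos <- sweep(helix, 2, h1Start * u, "+")[seq_len(nH1), , drop = FALSE]
  coords <- rbind(h1Pos, ubPos)
  s <- caStructure(coords, chain = "A",
                   resnames = aaCycle(nH1 + nUb), label = "toy-ligand",
                   subunits = list(H1 = seq_len(nH1),
                                   Ub = as.integer(nH1) + seq_len(nUb)))
  list(structure = s,
       manifest = list(generator = "toyLigand", nH1 = nH1, nUb = nUb,
                       clashDepth = clashDepth, axis = u, margin = margin,
                       receptorRadius = R, spacing = spacing))
}

# helical C-alpha template; turn angle per residue controls the shape
helixTemplate <- function(nRes, turn, rise = 1.5, spacing = 3.8) {
  r <- sqrt(spacing^2 - rise^2) / (2 * sin(turn / 2))
  i <- seq_len(nRes) - 1L
  cbind(r * cos(turn * i), r * sin(turn * i), rise * i)
}

# (turn, rise) ladder with large pairwise minimized RMSD between the
# resulting 40-residue templates (max-min spaced over helix geometries)
templateParams <- function(k) {
  ladder <- cbind(turn = c(0.3, 1.1, 0.5, 0.3, 0.7, 0.5, 0.3, 0.5),
                  rise = c(0.6, 3.3, 1.5, 2.4, 0.6, 2.4, 1.5, 0.6))
  if (k > nrow(ladder))
    stop("at most ", nrow(ladder), " distinct templates are supported")
  ladder[seq_len(k), , drop = FALSE]
}

#' Toy trajectory with planted conformational clusters and 2D projection
#'
#' Generates `kClusters` structural templates (helical C-alpha chains
#' with well-separated turn angles, so templates differ by large
#' minimized RMSD), `framesPerCluster` noisy copies of each, and
#' `nNoise` scattered frames with their own random templates. The
#' accompanying 2D projection places each cluster as a uniform disk and
#' the noise uniformly over the bounding square - emulating dense,
#' structurally homogeneous basins over a sparse background.
#'
#' In `mergedBlob` mode (the refinement scenario) two structurally
#' distinct groups share one double-disk 2D blob (centres
#' `mergedSeparation` apart) next to one well-behaved blob: a large
#' minimal-cluster-size pass sees a single heterogeneous cluster (high
#' mean RMSD to the centroid) that only a smaller pass resolves.
#'
#' @param kClusters planted clusters (>= 1).
#' @param framesPerCluster frames per cluster.
#' @param intraNoise isotropic coordinate noise sd within a cluster,
#'   Angstrom (default 0.3).
#' @param interShift minimal pairwise minimized RMSD between templates,
#'   Angstrom (default 10; checked, not just declared).
#' @param nNoise scattered background frames (transition-state stand-ins,
#'   placed at the fringes of the map as the projection method does).
#' @param nArtifact frames of a projection artifact: one dense central
#'   patch whose member structures are mutually dissimilar (each frame
#'   its own random template).
#' @param nResidues chain length (default 40).
#' @param blobRadius 2D disk radius (default 1.5).
#' @param clusterSpread radius of the circle on which cluster centres
#'   sit (default 6).
#' @param noiseRange radial annulus of the 2D background noise (default
#'   c(20, 35), well outside the cluster constellation).
#' @param mergedBlob generate the merged-blob refinement scenario.
#' @param mergedSeparation 2D distance between the merged sub-blob
#'   centres (default 4.5, leaving a resolvable density gap between the
#'   two disks).
#' @param seed integer seed.
#' @return list: `trajectory` ([Trajectory-class]), `projection`
#'   ([Projection2D-class]), `manifest` (with `trueLabels`: clusters
#'   1..k, noise -1, artifact 0).
#' @export
toyTrajectory <- function(kClusters = 2L, framesPerCluster = 100L,
                          intraNoise = 0.3, interShift = 10,
                          nNoise = 0L, nArtifact = 0L, nResidues = 40L,
                          blobRadius = 1.5, clusterSpread = 6,
                          noiseRange = c(20, 35), mergedBlob = FALSE,
                          mergedSeparation = 4.5, seed = 1L) {
  if (kClusters < 1L) stop("kClusters must be >= 1")
  variants <- paste0("K", c(30, 41, 47, 51, 56, 63), "Ub")
  out <- withr::with_seed(seed, {
    nGroups <- if (mergedBlob) kClusters + 1L else kClusters
    prm <- templateParams(nGroups)
    templates <- lapply(seq_len(nGroups), function(j)
      helixTemplate(nResidues, prm[j, "turn"], prm[j, "rise"]))
    # verify declared structural separation between templates
    if (nGroups > 1L) {
      tArr <- array(0, c(nResidues, 3L, nGroups))
      for (j in seq_len(nGroups)) tArr[, , j] <- templates[[j]]
      sep <- cpp_pairwise_rmsd(tArr)
      minSep <- min(sep[upper.tri(sep)])
      if (minSep < interShift)
        stop("template separation ", round(minSep, 2),
             " below requested interShift ", interShift)
    } else minSep <- Inf
    if (mergedBlob) {
      # sub-blobs 1 and 2 share one double-disk region; group 3 is clean
      centres <- rbind(
        c(-clusterSpread - mergedSeparation / 2, 0),
        c(-clusterSpread + mergedSeparation / 2, 0),
        c(clusterSpread, 0))[seq_len(nGroups), , drop = FALSE]
    } else {
      ang <- 2 * pi * (seq_len(nGroups) - 1L) / max(nGroups, 1L)
      centres <- if (nGroups == 1L) cbind(0, 0)
                 else clusterSpread * cbind(cos(ang), sin(ang))
    }
    frames <- list()
    pts <- NULL
    labels <- integer(0)
    # in merged mode the clean group is twice as populous, so that the
    # first (largest) pass performs a true split into the merged pair
    # and the clean cluster
    groupSizes <- rep(framesPerCluster, nGroups)
    if (mergedBlob && nGroups >= 3L)
      groupSizes[nGroups] <- 2L * framesPerCluster
    for (j in seq_len(nGroups)) {
      gs <- groupSizes[j]
      for (f in seq_len(gs)) {
        frames[[length(frames) + 1L]] <- templates[[j]] +
          matrix(rnorm(3L * nResidues, 0, intraNoise), ncol = 3)
      }
      rr <- blobRadius * sqrt(runif(gs))
      aa <- runif(gs, 0, 2 * pi)
      pts <- rbind(pts, cbind(centres[j, 1] + rr * cos(aa),
                              centres[j, 2] + rr * sin(aa)))
      labels <- c(labels, rep(j, gs))
    }
    if (nArtifact > 0L) {
      # dense patch opposite the clusters; structurally heterogeneous
      ac <- c(0, -2.5 * clusterSpread)
      for (f in seq_len(nArtifact)) {
        tpl <- helixTemplate(nResidues, runif(1, 0.3, 2.5),
                             runif(1, 0.6, 3.3))
        frames[[length(frames) + 1L]] <- tpl +
          matrix(rnorm(3L * nResidues, 0, intraNoise), ncol = 3)
      }
      rr <- blobRadius * sqrt(runif(nArtifact))
      aa <- runif(nArtifact, 0, 2 * pi)
      pts <- rbind(pts, cbind(ac[1] + rr * cos(aa),
                              ac[2] + rr * sin(aa)))
      labels <- c(labels, rep(0L, nArtifact))
    }
    if (nNoise > 0L) {
      for (f in seq_len(nNoise)) {
        tpl <- helixTemplate(nResidues, runif(1, 0.3, 2.5),
                             runif(1, 0.6, 3.3))
        frames[[length(frames) + 1L]] <- tpl +
          matrix(rnorm(3L * nResidues, 0, intraNoise), ncol = 3)
      }
      rr <- sqrt(runif(nNoise, noiseRange[1]^2, noiseRange[2]^2))
      aa <- runif(nNoise, 0, 2 * pi)
      pts <- rbind(pts, cbind(rr * cos(aa), rr * sin(aa)))
      labels <- c(labels, rep(-1L, nNoise))
    }
    list(frames = frames, pts = pts, labels = labels, minSep = minSep,
         groupSizes = groupSizes,
         prm = prm,
         centres = centres, nGroups = nGroups)
  })
  nf <- length(out$frames)
  half <- nResidues %/% 2L
  topo <- caStructure(out$frames[[1]], chain = "A",
                      label = "toy-trajectory",
                      subunits = list(H1 = seq_len(half),
                                      Ub = (half + 1L):nResidues))
  meta <- data.frame(
    variant = ifelse(out$labels > 0L,
                     variants[((out$labels - 1L) %% 6L) + 1L],
                     variants[(seq_len(nf) %% 6L) + 1L]),
    source = "toyTrajectory", frame = seq_len(nf),
    stringsAsFactors = FALSE)
  traj <- Trajectory(topo, out$frames, meta)
  proj <- Projection2D(out$pts, meta)
  list(trajectory = traj, projection = proj,
       manifest = list(generator = "toyTrajectory", seed = seed,
                       kClusters = kClusters, nGroups = out$nGroups,
                       framesPerCluster = framesPerCluster,
                       intraNoise = intraNoise, interShift = interShift,
                       minTemplateRmsd = out$minSep, nNoise = nNoise,
                       nResidues = nResidues, templateParams = out$prm,
                       groupSizes = out$groupSizes,
                       centres = out$centres, mergedBlob = mergedBlob,
                       trueLabels = out$labels))
}

#' Synthetic chromatosome fixture
#'
#' A small chromatosome-like structure assembled from code: eight
#' core-histone C-alpha chains (A-H) with distinct random sequences, two
#' DNA-like phosphorus-backbone chains (I, J), one linker-histone chain
#' (L), plus waters and monoatomic ions (HETATM). Used to exercise
#' receptor preparation and core-histone-guided placement without any
#' external structure.
#'
#' @param nPerCore residues per core-histone chain (default 30).
#' @param nLinker residues of the linker histone (default 25).
#' @param nDna nucleotides per DNA chain (default 40).
#' @param nWaters,nIons HETATM decorations (defaults 20, 5).
#' @param seed integer seed.
#' @return list: `structure`, `manifest` (chain ids, per-chain sequences,
#'   atom counts).
#' @export
syntheticChromatosome <- function(nPerCore = 30L, nLinker = 25L,
                                  nDna = 40L, nWaters = 20L, nIons = 5L,
                                  seed = 1L) {
  aas <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")
  withr::with_seed(seed, {
    rows <- NULL
    xyz <- NULL
    sequences <- list()
    addChain <- function(chain, coords, name, elem, resnames, het) {
      n <- nrow(coords)
      rows <<- rbind(rows, data.frame(
        serial = 0L, name = name, elem = elem, resno = seq_len(n),
        resname = resnames, chain = chain, het = het,
        stringsAsFactors = FALSE))
      xyz <<- rbind(xyz, coords)
    }
    coreChains <- LETTERS[1:8]
    for (i in seq_along(coreChains)) {
      ctr <- 18 * c(cos(2 * pi * i / 8), sin(2 * pi * i / 8), 0)
      tpl <- helixTemplate(nPerCore, 1.7) +
        matrix(ctr, nPerCore, 3, byrow = TRUE)
      sq <- sample(aas, nPerCore, replace = TRUE)
      sequences[[coreChains[i]]] <- paste(bio3d::aa321(sq), collapse = "")
      addChain(coreChains[i], tpl, "CA", "C", sq, FALSE)
    }
    for (ch in c("I", "J")) {
      z <- if (ch == "I") 8 else -8
      ang <- seq(0, 3 * pi, length.out = nDna)
      dna <- cbind(30 * cos(ang), 30 * sin(ang), z + seq_len(nDna) / 10)
      addChain(ch, dna, "P", "P",
               sample(c("DA", "DT", "DG", "DC"), nDna, TRUE), FALSE)
    }
    lh <- helixTemplate(nLinker, 1.2) +
      matrix(c(0, 0, 20), nLinker, 3, byrow = TRUE)
    lseq <- sample(aas, nLinker, replace = TRUE)
    sequences[["L"]] <- paste(bio3d::aa321(lseq), collapse = "")
    addChain("L", lh, "CA", "C", lseq, FALSE)
    if (nWaters > 0L)
      addChain("W", matrix(runif(3L * nWaters, -35, 35), ncol = 3),
               "O", "O", rep("HOH", nWaters), TRUE)
    if (nIons > 0L)
      addChain("X", matrix(runif(3L * nIons, -35, 35), ncol = 3),
               "NA", "NA", rep("NA", nIons), TRUE)
    rows$serial <- seq_len(nrow(rows))
    s <- Structure(rows, xyz, label = "synthetic-chromatosome")
    list(structure = s,
         manifest = list(generator = "syntheticChromatosome", seed = seed,
                         coreChains = coreChains, linkerChain = "L",
                         dnaChains = c("I", "J"), sequences = sequences,
                         nPerCore = nPerCore, nLinker = nLinker,
                         nDna = nDna, nWaters = nWaters, nIons = nIons))
  })
}
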