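#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Sphere-sampling SASA: each atom's van der Waals sphere is inflated by
#' the probe radius and sampled with a deterministic Fibonacci lattice of
#' `nSpherePoints` points; the accessible fraction is the fraction of
#' sample points outside all neighbouring inflated spheres. With 960
#' points the quadrature error for an isolated sphere is well below 1%.
#'
#' @param s a [Structure-class].
#' @param probeRadius probe radius in Angstrom (default 1.4, water).
#' @param nSpherePoints number of lattice points per atom (default 960).
#' @param unit `"A2"` (Angstrom^2, default) or `"nm2"`.
#' @param radii named numeric vector of van der Waals radii per element,
#'   Angstrom; merged over the built-in table.
#' @return numeric vector of per-atom areas (>= 0) in `unit`.
#' @export
computeAtomSasa <- function(s, probeRadius = 1.4, nSpherePoints = 960L,
                            unit = c("A2", "nm2"), radii = NULL) {
  unit <- match.arg(unit)
  if (nAtoms(s) < 1L) stop("structure has no atoms")
  rtab <- vdwRadii()
  if (!is.null(radii)) rtab[names(radii)] <- radii
  elem <- toupper(atomData(s)$elem)
  unknown <- setdiff(unique(elem), names(rtab))
  if (length(unknown))
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  r <- unname(rtab[elem]) + probeRadius
  xyz <- atomCoords(s)
  pts <- fibonacciSphere(nSpherePoints)
  n <- nrow(xyz)
  area <- numeric(n)
  maxr <- max(r)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
          (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (r[i] + maxr)^2 & d2 > 0)
    nb <- nb[d2[nb] < (r[i] + r[nb])^2]
    p <- pts * r[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    acc <- rep(TRUE, nSpherePoints)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
             (p[, 3] - xyz[j, 3])^2
      acc <- acc & (dj2 >= r[j]^2)
    }
    area[i] <- 4 * pi * r[i]^2 * sum(acc) / nSpherePoints
  }
  if (unit == "nm2") area <- area * 0.01
  area
}

# Bondi-type van der Waals radii, Angstrom.
vdwRadii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)
}

# Deterministic, nearly uniform unit-sphere point set (golden-angle
# Fibonacci lattice).
fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}
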