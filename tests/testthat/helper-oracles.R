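# Independent oracles used across the suite. Each re-derives the target
# quantity by a different route than the implementation under test.

# Quaternion characteristic-polynomial RMSD: the minimal RMSD over proper
# rotations equals sqrt((Ga + Gb - 2*lmax)/n), lmax the largest eigenvalue
# of the 4x4 key matrix of the cross-covariance.
quaternionRmsd <- function(mobile, target) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(target, 2, colMeans(target))
  S <- crossprod(P, Q)
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2], S[3,1]-S[1,3], S[1,2]-S[2,1],
    S[2,3]-S[3,2], S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1], S[3,1]+S[1,3],
    S[3,1]-S[1,3], S[1,2]+S[2,1], -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1], S[3,1]+S[1,3], S[2,3]+S[3,2], -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lmax) / nrow(P)
  sqrt(max(msd, 0))
}

# Brute-force axis-aligned box counting for corner cumulative histograms.
bruteCornerCumulative <- function(h, corner) {
  d <- dim(h)
  if (is.null(d)) {
    n <- length(h)
    rv <- corner
    out <- numeric(n)
    for (i in seq_len(n)) out[i] <- if (rv) sum(h[i:n]) else sum(h[1:i])
    return(out)
  }
  rv <- as.logical(bitwAnd(as.integer(corner) - 1L,
                           2L^(seq_along(d) - 1L)) > 0L)
  out <- array(0, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    rx <- if (rv[1]) i:d[1] else 1:i
    ry <- if (rv[2]) j:d[2] else 1:j
    rz <- if (rv[3]) k:d[3] else 1:k
    out[i, j, k] <- sum(h[rx, ry, rz])
  }
  out
}

# Per-atom binning loop (oracle for the vectorized histogram).
bruteBinCounts <- function(coords, geometry) {
  nb <- geometry@nBins
  w <- rep(geometry@binWidth, length.out = 3)
  out <- array(0L, nb)
  drop <- 0L
  for (r in seq_len(nrow(coords))) {
    ix <- floor((coords[r, ] - geometry@origin) / w) + 1
    if (all(ix >= 1) && all(ix <= nb))
      out[ix[1], ix[2], ix[3]] <- out[ix[1], ix[2], ix[3]] + 1L
    else drop <- drop + 1L
  }
  attr(out, "nDropped") <- drop
  out
}

# Feasibility LP for the split-fit dip definition (quadprog), independent
# of the hull implementation.
bruteSplitDip <- function(x) {
  x <- sort(x)
  v <- unique(x)
  m <- length(v)
  n <- length(x)
  if (m == 1) return(0)
  cnt <- tabulate(match(x, v))
  b <- cumsum(cnt) / n
  a <- c(0, b[-m])
  sideEps <- function(idx, kind, anchor = NULL) {
    k <- length(idx)
    if (k == 0) return(0)
    nv <- k + 1L
    A <- NULL; bv <- NULL
    addGe <- function(row, rhs) { A <<- rbind(A, row); bv <<- c(bv, rhs) }
    unit <- function(i, c = 1) { r <- numeric(nv); r[i] <- c; r }
    for (q in 1:k) {
      t <- idx[q]
      addGe(unit(q) + unit(nv), b[t])
      up <- if (!is.null(anchor) && t == anchor) b[t] else a[t]
      addGe(-unit(q) + unit(nv), -up)
    }
    if (k >= 2) for (q in 1:(k - 1)) addGe(unit(q + 1) - unit(q), 0)
    if (k >= 3) for (q in 2:(k - 1)) {
      dx1 <- v[idx[q]] - v[idx[q - 1]]
      dx2 <- v[idx[q + 1]] - v[idx[q]]
      r <- numeric(nv)
      if (kind == "cvx") {
        r[q + 1] <- 1 / dx2; r[q] <- -1 / dx2 - 1 / dx1; r[q - 1] <- 1 / dx1
      } else {
        r[q + 1] <- -1 / dx2; r[q] <- 1 / dx2 + 1 / dx1; r[q - 1] <- -1 / dx1
      }
      addGe(r, 0)
    }
    addGe(unit(nv), 0)
    D <- diag(rep(1e-10, nv))
    dvec <- c(rep(0, k), -1)
    sol <- tryCatch(quadprog::solve.QP(D, dvec, t(A), bv),
                    error = function(e) NULL)
    if (is.null(sol)) Inf else sol$solution[nv]
  }
  best <- Inf
  for (j in 1:m)
    best <- min(best, max(sideEps(seq_len(j - 1), "cvx"),
                          sideEps(j:m, "ccv", anchor = j)))
  best
}

# Exhaustive global affine-gap alignment score (oracle for short pairs).
enumAlignScore <- function(a, b, open = 10, ext = 0.5) {
  sm <- getBlosum62()
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, state, sc) {
    if (i > length(A) && j > length(B)) {
      best <<- max(best, sc)
      return()
    }
    if (i <= length(A) && j <= length(B))
      rec(i + 1, j + 1, "m", sc + sm[A[i], B[j]])
    if (i <= length(A))
      rec(i + 1, j, "d", sc - ext - if (state == "d") 0 else open)
    if (j <= length(B))
      rec(i, j + 1, "i", sc - ext - if (state == "i") 0 else open)
  }
  rec(1, 1, "start", 0)
  best
}

getBlosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# Small C-alpha structure builder for tests.
testCaStructure <- function(coords, ...) isafit:::caStructure(coords, ...)

# One-atom structure with a given element at a position.
atomAt <- function(x, y, z, elem = "C", name = "C") {
  Structure(data.frame(serial = 1L, name = name, elem = elem, resno = 1L,
                       resname = "DUM", chain = "A", het = FALSE),
            matrix(c(x, y, z), 1), label = "atom")
}

randomRotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a*a+b*b-c*c-d*d, 2*(b*c-a*d), 2*(b*d+a*c),
           2*(b*c+a*d), a*a-b*b+c*c-d*d, 2*(c*d-a*b),
           2*(b*d-a*c), 2*(c*d+a*b), a*a-b*b-c*c+d*d), 3, byrow = TRUE)
}
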