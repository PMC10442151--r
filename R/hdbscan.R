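#' Hierarchical density-based clustering (HDBSCAN)
#'
#' Density-based clustering of a point set: distances are transformed to
#' mutual reachability (each pairwise distance floored by both points'
#' core distances, which pushes sparse points away from dense regions),
#' a minimum spanning tree of the mutual-reachability graph is condensed
#' into a cluster tree at the given minimal cluster size, and flat
#' clusters are selected by excess-of-mass stability. Points not in any
#' selected cluster are labelled noise (-1). Deterministic: no random
#' element.
#'
#' @param x numeric n x d matrix (2D projections in normal use).
#' @param minClusterSize smallest cluster size to report.
#' @param minSamples neighbourhood size k for the core distance (distance
#'   to the k-th nearest neighbour, excluding the point itself);
#'   default 5.
#' @param allowSingleCluster whether the root of the cluster tree may be
#'   selected (default FALSE).
#' @return list: `labels` (integer, -1 = noise, clusters numbered 1..k
#'   by decreasing size), `nClusters`, `clusterSizes`.
#' @export
hdbscanClusters <- function(x, minClusterSize, minSamples = 5L,
                            allowSingleCluster = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x)
  minClusterSize <- as.integer(minClusterSize)
  if (minClusterSize < 2L) stop("minClusterSize must be >= 2")
  if (n < 2L || n < minClusterSize)
    return(list(labels = rep(-1L, max(n, 0L)), nClusters = 0L,
                clusterSizes = integer()))
  k <- min(minSamples, n - 1L)
  core <- coreDistances(x, k)
  mst <- mstMutualReachability(x, core)
  sl <- singleLinkageTree(mst, n)
  cond <- condenseTree(sl, n, minClusterSize)
  selected <- selectClustersEOM(cond, allowSingleCluster)
  labelsFromCondensed(cond, selected, n)
}

# distance to the k-th nearest neighbour (self excluded), per point
coreDistances <- function(x, k) {
  n <- nrow(x)
  core <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(x, 2, x[i, ])^2)
    core[i] <- sqrt(sort.int(d2, partial = k + 1L)[k + 1L])
  }
  core
}

# Prim's MST over the complete mutual-reachability graph, O(n^2) without
# materializing the distance matrix.
mstMutualReachability <- function(x, core) {
  n <- nrow(x)
  inTree <- rep(FALSE, n)
  best <- rep(Inf, n)
  from <- integer(n)
  edges <- matrix(0, n - 1L, 3L)
  cur <- 1L
  inTree[1L] <- TRUE
  for (e in seq_len(n - 1L)) {
    d <- sqrt(rowSums(sweep(x, 2, x[cur, ])^2))
    mr <- pmax(d, core, core[cur])
    upd <- !inTree & mr < best
    best[upd] <- mr[upd]
    from[upd] <- cur
    cand <- which(!inTree)
    nxt <- cand[which.min(best[cand])]
    edges[e, ] <- c(from[nxt], nxt, best[nxt])
    inTree[nxt] <- TRUE
    cur <- nxt
  }
  edges[order(edges[, 3]), , drop = FALSE]
}

# Single-linkage dendrogram from sorted MST edges (union-find).
# Returns merges (m x 2 node ids; leaves 1..n, internal n+1..2n-1),
# heights, sizes.
singleLinkageTree <- function(edges, n) {
  parent <- seq_len(2L * n - 1L)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  sizes <- c(rep(1L, n), integer(n - 1L))
  merges <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1L])
    b <- find(edges[e, 2L])
    node <- n + e
    merges[e, ] <- c(a, b)
    heights[e] <- edges[e, 3L]
    sizes[node] <- sizes[a] + sizes[b]
    parent[a] <- node
    parent[b] <- node
  }
  list(merges = merges, heights = heights, sizes = sizes)
}

# Condense the dendrogram at minClusterSize. Clusters are numbered from
# 1 (root). Returns per-cluster birth lambda, parent, children, and
# per-point (cluster, lambda-at-fallout).
condenseTree <- function(sl, n, minClusterSize) {
  nNodes <- 2L * n - 1L
  root <- nNodes
  clParent <- integer(0)
  clBirth <- numeric(0)
  newCluster <- function(parent, birth) {
    clParent[length(clParent) + 1L] <<- parent
    clBirth[length(clBirth) + 1L] <<- birth
    length(clParent)
  }
  ptCluster <- integer(n)
  ptLambda <- numeric(n)
  clStability <- numeric(0)
  rootId <- newCluster(0L, 0)
  clStability[1] <- 0
  # stack entries: dendrogram node, owning cluster id
  stack <- list(c(root, rootId))
  leavesUnder <- function(node) {
    out <- integer(0)
    st <- node
    while (length(st)) {
      nd <- st[[length(st)]]
      st <- st[-length(st)]
      if (nd <= n) out <- c(out, nd)
      else st <- c(st, sl$merges[nd - n, ])
    }
    out
  }
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top[1]
    cl <- top[2]
    if (node <= n) {  # singleton reached: falls out at infinite density
      ptCluster[node] <- cl
      ptLambda[node] <- Inf
      next
    }
    ch <- sl$merges[node - n, ]
    h <- sl$heights[node - n]
    lam <- if (h > 0) 1 / h else Inf
    szs <- sl$sizes[ch]
    big <- szs >= minClusterSize
    if (all(big)) {  # true split: two new clusters born at lam
      ends <- min(lam, 1e12)
      clStability[cl] <- clStability[cl] +
        sum(szs) * (ends - clBirth[cl])
      for (c2 in ch) {
        id <- newCluster(cl, ends)
        clStability[id] <- 0
        stack[[length(stack) + 1L]] <- c(c2, id)
      }
    } else {
      # children below size fall out of cl at lam; big child continues
      for (j in 1:2) {
        if (big[j]) {
          stack[[length(stack) + 1L]] <- c(ch[j], cl)
        } else {
          lv <- leavesUnder(ch[j])
          ptCluster[lv] <- cl
          ptLambda[lv] <- lam
          clStability[cl] <- clStability[cl] +
            length(lv) * (min(lam, 1e12) - clBirth[cl])
        }
      }
    }
  }
  list(parent = clParent, birth = clBirth, stability = clStability,
       ptCluster = ptCluster, ptLambda = ptLambda, root = rootId)
}

# Excess-of-mass cluster selection on the condensed tree.
selectClustersEOM <- function(cond, allowSingleCluster) {
  k <- length(cond$parent)
  children <- vector("list", k)
  for (i in seq_len(k)) {
    p <- cond$parent[i]
    if (p > 0L) children[[p]] <- c(children[[p]], i)
  }
  selected <- rep(FALSE, k)
  subtreeStab <- numeric(k)
  # children always have larger ids than parents: reverse id order is a
  # valid bottom-up order
  for (i in rev(seq_len(k))) {
    ch <- children[[i]]
    if (!length(ch)) {
      selected[i] <- TRUE
      subtreeStab[i] <- cond$stability[i]
    } else {
      cs <- sum(subtreeStab[ch])
      if (cond$stability[i] > cs && (i != cond$root || allowSingleCluster)) {
        selected[i] <- TRUE
        deselectDescendants(i, children, environment())
        subtreeStab[i] <- cond$stability[i]
      } else {
        subtreeStab[i] <- max(cs, cond$stability[i])
        if (i == cond$root && !allowSingleCluster) subtreeStab[i] <- cs
      }
    }
  }
  if (!allowSingleCluster) selected[cond$root] <- FALSE
  selected
}

deselectDescendants <- function(i, children, env) {
  st <- children[[i]]
  while (length(st)) {
    j <- st[[length(st)]]
    st <- st[-length(st)]
    env$selected[j] <- FALSE
    st <- c(st, children[[j]])
  }
}

labelsFromCondensed <- function(cond, selected, n) {
  k <- length(cond$parent)
  # deepest selected ancestor (inclusive) per cluster
  anc <- integer(k)
  for (i in seq_len(k)) {
    j <- i
    anc[i] <- 0L
    while (j > 0L) {
      if (selected[j]) {
        anc[i] <- j
        break
      }
      j <- cond$parent[j]
    }
  }
  lab <- ifelse(cond$ptCluster > 0L, anc[cond$ptCluster], 0L)
  ids <- sort(unique(lab[lab > 0L]))
  out <- rep(-1L, n)
  if (length(ids)) {
    sizes <- vapply(ids, function(id) sum(lab == id), integer(1))
    ord <- ids[order(-sizes)]
    for (j in seq_along(ord)) out[lab == ord[j]] <- j
  }
  list(labels = out, nClusters = length(ids),
       clusterSizes = if (length(ids)) sort(tabulate(out[out > 0L]),
                                            decreasing = TRUE)
                      else integer())
}
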