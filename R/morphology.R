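# shift a matrix by (dr, dc) with zero fill (used by the thinning kernel)
shiftZero <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  okR <- rs >= 1 & rs <= nr; okC <- cs >= 1 & cs <= nc
  out[okR, okC] <- m[rs[okR], cs[okC]]
  out
}

# Zhang-Suen topological thinning of a logical mask to a 1-px skeleton.
thinMask <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- as.integer(mask)
  nbrs <- function(m) {
    # P2..P9 clockwise from north; out[r,c] holds the neighbour's value
    list(P2 = shiftZero(m, -1, 0), P3 = shiftZero(m, -1, 1),
         P4 = shiftZero(m, 0, 1),  P5 = shiftZero(m, 1, 1),
         P6 = shiftZero(m, 1, 0),  P7 = shiftZero(m, 1, -1),
         P8 = shiftZero(m, 0, -1), P9 = shiftZero(m, -1, -1))
  }
  repeat {
    changedAny <- FALSE
    for (sub in 1:2) {
      p <- nbrs(m)
      B <- p$P2 + p$P3 + p$P4 + p$P5 + p$P6 + p$P7 + p$P8 + p$P9
      seqs <- list(p$P2, p$P3, p$P4, p$P5, p$P6, p$P7, p$P8, p$P9, p$P2)
      A <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) A <- A + (seqs[[i]] == 0L & seqs[[i + 1]] == 1L)
      if (sub == 1) {
        c1 <- p$P2 * p$P4 * p$P6 == 0L; c2 <- p$P4 * p$P6 * p$P8 == 0L
      } else {
        c1 <- p$P2 * p$P4 * p$P8 == 0L; c2 <- p$P2 * p$P6 * p$P8 == 0L
      }
      del <- m == 1L & B >= 2 & B <= 6 & A == 1L & c1 & c2
      if (any(del)) { m[del] <- 0L; changedAny <- TRUE }
    }
    if (!changedAny) break
  }
  # sequential cleanup: the parallel passes can leave 2-px-wide diagonal
  # staircases; delete 8-simple points (foreground neighbourhood forms one
  # 8-connected component) one at a time, which preserves both connectivity
  # and endpoints, until the skeleton is unit width
  nbDr <- c(-1, -1, 0, 1, 1, 1, 0, -1); nbDc <- c(0, 1, 1, 1, 0, -1, -1, -1)
  nbAdj <- outer(seq_len(8), seq_len(8), function(i, j)
    pmax(abs(nbDr[i] - nbDr[j]), abs(nbDc[i] - nbDc[j])) == 1)
  repeat {
    pts <- which(m == 1L, arr.ind = TRUE)
    changed <- FALSE
    for (i in seq_len(nrow(pts))) {
      r <- pts[i, 1]; c <- pts[i, 2]
      if (m[r, c] == 0L) next
      on <- which(m[cbind(r + nbDr, c + nbDc)] == 1L)
      B <- length(on)
      if (B < 2 || B > 6) next
      # count components of the on-neighbours under 8-adjacency
      seen <- logical(B); stack <- 1L; seen[1] <- TRUE
      while (length(stack)) {
        k <- stack[1]; stack <- stack[-1]
        nxt <- which(!seen & nbAdj[on[k], on])
        seen[nxt] <- TRUE
        stack <- c(stack, nxt)
      }
      if (all(seen)) { m[r, c] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  out <- m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] == 1L
  out
}

# 8-neighbour offsets
nbrOffsets <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                    dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

#' Skeletonize an aggregate and build its skeleton graph
#'
#' The region mask is thinned to a 1-px skeleton (Zhang-Suen), which is then
#' condensed into a graph: nodes at endpoints (one skeleton neighbour) and
#' junctions (three or more; 8-adjacent junction pixels merge into one node),
#' edges as the junction-free pixel paths between them. Path lengths count 1
#' px per axial and sqrt(2) px per diagonal step, times the pixel size.
#' A closed skeleton with no endpoints is flagged as a ring, its longest
#' chain being the cycle circumference. Branch points are nodes of degree
#' >= 3.
#'
#' @param region an \code{\link{AggregateRegion}}.
#' @param dims dimensions (rows, cols) of the source image.
#' @return a \code{\link{SkeletonGraph}}.
#' @examples
#' m <- matrix(0, 9, 25); m[5, 3:23] <- 100
#' r <- segmentAggregates(MicroImage(m, pixelSize = 1))[[1]]
#' skeletonizeRegion(r, dim(m))
#' @export
skeletonizeRegion <- function(region, dims) {
  stopifnot(is(region, "AggregateRegion"))
  if (region@area == 0) stop("region mask is empty")
  px <- region@pixelSize
  mask <- regionMask(region, dims)
  skel <- thinMask(mask)
  pts <- which(skel, arr.ind = TRUE)
  n <- nrow(pts)
  emptyGraph <- function(tl, lc, path, ring, nbp, nodes, edges, paths)
    new("SkeletonGraph", nodes = nodes, edges = edges, paths = paths,
        totalLength = tl, longestChainLength = lc, longestChainPath = path,
        nBranchPoints = nbp, ringFlag = ring, pixelSize = px)
  key <- function(r, c) paste(r, c)
  idx <- setNames(seq_len(n), key(pts[, 1], pts[, 2]))
  nbrList <- lapply(seq_len(n), function(i) {
    cand <- key(pts[i, 1] + nbrOffsets[, 1], pts[i, 2] + nbrOffsets[, 2])
    unname(idx[cand[cand %in% names(idx)]])
  })
  deg <- lengths(nbrList)
  if (n == 1)   # skeleton collapsed to one pixel: one-pixel chain convention
    return(emptyGraph(px, px, pts,
                      FALSE, 0L,
                      data.frame(row = pts[1, 1], col = pts[1, 2], degree = 0L),
                      data.frame(from = integer(0), to = integer(0),
                                 length = numeric(0)), list()))
  nodePix <- which(deg != 2)
  if (!length(nodePix)) {
    # pure cycle: traverse it once
    order <- integer(n); order[1] <- 1L
    prev <- 0L; cur <- 1L
    for (k in 2:n) {
      nxt <- setdiff(nbrList[[cur]], prev)[1]
      order[k] <- nxt; prev <- cur; cur <- nxt
    }
    path <- pts[c(order, order[1]), , drop = FALSE]
    len <- pathStepLength(path) * px
    return(emptyGraph(len, len, pts[order, , drop = FALSE], TRUE, 0L,
                      data.frame(row = pts[order[1], 1], col = pts[order[1], 2],
                                 degree = 2L),
                      data.frame(from = 1L, to = 1L, length = len),
                      list(path)))
  }
  # merge 8-adjacent junction pixels (degree >= 3) into single nodes
  nodeId <- rep(NA_integer_, n)
  junc <- nodePix[deg[nodePix] >= 3]
  ends <- nodePix[deg[nodePix] < 3]   # endpoints and isolated pixels
  nextId <- 0L
  if (length(junc)) {
    sub <- igraph::graph_from_data_frame(d = data.frame(
      from = character(0), to = character(0)),
      vertices = data.frame(name = as.character(junc)), directed = FALSE)
    pairs <- NULL
    for (j in junc) {
      adjJ <- intersect(nbrList[[j]], junc)
      if (length(adjJ))
        pairs <- rbind(pairs, cbind(as.character(j), as.character(adjJ)))
    }
    if (!is.null(pairs))
      sub <- igraph::add_edges(sub, t(pairs))
    comp <- igraph::components(sub)$membership
    nodeId[junc] <- comp[as.character(junc)]
    nextId <- max(nodeId, na.rm = TRUE)
  }
  for (e in ends) { nextId <- nextId + 1L; nodeId[e] <- nextId }
  nNodes <- nextId
  # node table: representative pixel = centroid-nearest member
  nodes <- data.frame(row = numeric(nNodes), col = numeric(nNodes),
                      degree = 0L)
  for (v in seq_len(nNodes)) {
    mem <- which(nodeId == v)
    nodes$row[v] <- round(mean(pts[mem, 1]))
    nodes$col[v] <- round(mean(pts[mem, 2]))
  }
  # trace edges from every node pixel through degree-2 corridors
  edges <- data.frame(from = integer(0), to = integer(0), length = numeric(0))
  paths <- list()
  usedStep <- new.env(hash = TRUE)
  stepKey <- function(a, b) paste(a, b)
  for (start in which(!is.na(nodeId))) {
    for (nb in nbrList[[start]]) {
      if (!is.na(nodeId[nb]) && nodeId[nb] == nodeId[start]) next  # intra-node
      if (exists(stepKey(start, nb), envir = usedStep)) next
      path <- c(start, nb)
      prev <- start; cur <- nb
      while (is.na(nodeId[cur])) {
        nxt <- setdiff(nbrList[[cur]], prev)
        # at a corridor pixel degree is 2, so exactly one continuation
        nxt <- nxt[1]
        path <- c(path, nxt)
        prev <- cur; cur <- nxt
      }
      assign(stepKey(start, nb), TRUE, envir = usedStep)
      assign(stepKey(cur, prev), TRUE, envir = usedStep)
      pmat <- pts[path, , drop = FALSE]
      edges <- rbind(edges, data.frame(from = nodeId[start], to = nodeId[cur],
                                       length = pathStepLength(pmat) * px))
      paths[[length(paths) + 1L]] <- pmat
    }
  }
  for (v in seq_len(nNodes))
    nodes$degree[v] <- sum(edges$from == v) + sum(edges$to == v)
  total <- sum(edges$length)
  g <- emptyGraph(total, 0, matrix(numeric(0), 0, 2), FALSE,
                  as.integer(sum(nodes$degree >= 3)), nodes, edges, paths)
  lc <- longestChain(g)
  g@longestChainLength <- lc$length
  g@longestChainPath <- lc$path
  validObject(g)
  g
}

#' Longest chain of a skeleton graph
#'
#' Exhaustive search for the maximum-length simple path between endpoint
#' (degree-1) nodes, with edge path lengths as weights; skeleton graphs are
#' small, so enumeration is exact. If the graph has fewer than two endpoints
#' (e.g. a loop with one tail) the search runs over all node pairs. For a
#' pure cycle the cycle circumference is returned and the ring flag is set on
#' the graph.
#'
#' @param graph a \code{\link{SkeletonGraph}}.
#' @return list with \code{length} (physical units) and \code{path}
#'   (pixel matrix).
#' @export
longestChain <- function(graph) {
  stopifnot(is(graph, "SkeletonGraph"))
  if (graph@ringFlag)
    return(list(length = graph@totalLength,
                path = if (length(graph@paths)) graph@paths[[1]]
                       else graph@longestChainPath))
  edges <- graph@edges
  if (!nrow(edges)) {
    if (nrow(graph@nodes) == 1)  # single-pixel skeleton: one-pixel chain
      return(list(length = graph@pixelSize,
                  path = as.matrix(graph@nodes[1, c("row", "col")])))
    stop("empty skeleton graph")
  }
  nNodes <- nrow(graph@nodes)
  inc <- lapply(seq_len(nNodes), function(v)
    which(edges$from == v | edges$to == v))
  endpoints <- which(graph@nodes$degree == 1)
  targets <- if (length(endpoints) >= 2) endpoints else seq_len(nNodes)
  starts <- targets
  best <- list(length = -1, edgeSeq = integer(0))
  visited <- rep(FALSE, nNodes)
  dfs <- function(v, len, edgeSeq) {
    if (v %in% targets && len > best$length && length(edgeSeq))
      best <<- list(length = len, edgeSeq = edgeSeq)
    for (e in inc[[v]]) {
      if (e %in% edgeSeq) next
      w <- if (edges$from[e] == v) edges$to[e] else edges$from[e]
      if (w == v) next            # self loops cannot extend a simple path
      if (visited[w]) next
      visited[w] <<- TRUE
      dfs(w, len + edges$length[e], c(edgeSeq, e))
      visited[w] <<- FALSE
    }
  }
  for (s in starts) {
    visited[s] <- TRUE
    dfs(s, 0, integer(0))
    visited[s] <- FALSE
  }
  # stitch the pixel path together, orienting each edge path as traversed
  if (!length(best$edgeSeq))
    return(list(length = graph@pixelSize,
                path = as.matrix(graph@nodes[1, c("row", "col")])))
  # recover traversal orientation by walking the edge sequence
  path <- NULL
  # find starting node of the sequence
  e1 <- best$edgeSeq[1]
  v <- if (length(best$edgeSeq) > 1) {
    e2 <- best$edgeSeq[2]
    shared <- intersect(c(edges$from[e1], edges$to[e1]),
                        c(edges$from[e2], edges$to[e2]))
    setdiff(c(edges$from[e1], edges$to[e1]), shared)[1]
  } else edges$from[e1]
  for (e in best$edgeSeq) {
    p <- graph@paths[[e]]
    if (edges$from[e] == v) { v <- edges$to[e] }
    else { p <- p[rev(seq_len(nrow(p))), , drop = FALSE]; v <- edges$from[e] }
    path <- if (is.null(path)) p else rbind(path, p[-1, , drop = FALSE])
  }
  list(length = best$length, path = path)
}

#' Mean width of an aggregate along its longest chain
#'
#' The local width at a chain pixel is twice the Euclidean distance transform
#' of the region mask minus one pixel (so a 1-px line has width 1 px: the
#' half-pixel convention); the mean is taken over all chain pixels and
#' converted to physical units.
#'
#' @param region an \code{\link{AggregateRegion}}.
#' @param chainPath pixel matrix (row, col) from \code{\link{longestChain}}.
#' @param dims image dimensions.
#' @return mean width in the image's physical unit.
#' @export
meanWidthAlongChain <- function(region, chainPath, dims) {
  stopifnot(is(region, "AggregateRegion"))
  mask <- regionMask(region, dims)
  if (any(!mask[chainPath[, , drop = FALSE]]))
    stop("chain path leaves the region mask")
  dt <- EBImage::distmap(mask)
  w <- 2 * dt[chainPath[, , drop = FALSE]] - 1
  mean(pmax(w, 1)) * region@pixelSize
}

#' Count fluorescence intensity peaks (puncta) in an aggregate
#'
#' Multi-scale Laplacian-of-Gaussian blob detection restricted to the region's
#' bounding box. A blob is a strict local maximum of the scale-normalized LoG
#' response in space and scale whose center lies inside the region, whose
#' response exceeds \code{relThreshold} times the maximum response over the
#' region, and whose smoothed-intensity Hessian is round
#' (|lambda_min/lambda_max| >= \code{roundnessMin}) -- the roundness test
#' rejects ridge responses from fibril backbones, which are not puncta.
#'
#' @param img the intensity \code{\link{MicroImage}}.
#' @param region an \code{\link{AggregateRegion}}.
#' @param sigmaRange blob scale range as Gaussian sigmas in physical units;
#'   the default covers punctum radii 0.15-0.5 um (sigma = radius/sqrt(2)).
#' @param nScales number of logarithmically spaced scales.
#' @param relThreshold response threshold relative to the region maximum.
#' @param roundnessMin minimum Hessian eigenvalue ratio for a blob.
#' @return blob count (integer).
#' @export
countIntensityPeaks <- function(img, region,
                                sigmaRange = c(0.15, 0.5) / sqrt(2),
                                nScales = 5, relThreshold = 0.3,
                                roundnessMin = 0.33) {
  stopifnot(is(img, "MicroImage"), is(region, "AggregateRegion"))
  if (length(sigmaRange) != 2 || any(sigmaRange <= 0) ||
      sigmaRange[2] < sigmaRange[1])
    stop("sigmaRange must be a positive increasing pair")
  px <- pixelSize(img)
  sigmasPx <- exp(seq(log(sigmaRange[1] / px), log(sigmaRange[2] / px),
                      length.out = nScales))
  mat <- pixels(img)
  marg <- ceiling(4 * max(sigmasPx)) + 1
  r0 <- max(1, region@bbox[1] - marg); r1 <- min(nrow(mat), region@bbox[3] - 1 + marg)
  c0 <- max(1, region@bbox[2] - marg); c1 <- min(ncol(mat), region@bbox[4] - 1 + marg)
  crop <- mat[r0:r1, c0:c1, drop = FALSE]
  inRegion <- regionMask(region, dim(mat))[r0:r1, c0:c1, drop = FALSE]
  resp <- lapply(sigmasPx, function(s) convolve2d(crop, logKernel(s)))
  maxResp <- max(vapply(resp, function(m) max(m[inRegion]), numeric(1)))
  if (maxResp <= 0) return(0L)
  count <- 0L
  nr <- nrow(crop); nc <- ncol(crop)
  smooth <- lapply(sigmasPx, function(s) convolve2d(crop, gaussianKernel(s)))
  for (k in seq_along(sigmasPx)) {
    m <- resp[[k]]
    sm <- smooth[[k]]
    lower <- if (k > 1) resp[[k - 1]] else NULL
    upper <- if (k < length(sigmasPx)) resp[[k + 1]] else NULL
    cand <- which(m >= relThreshold * maxResp & inRegion, arr.ind = TRUE)
    for (i in seq_len(nrow(cand))) {
      r <- cand[i, 1]; c <- cand[i, 2]
      if (r < 2 || c < 2 || r > nr - 1 || c > nc - 1) next
      v <- m[r, c]
      nb <- m[(r - 1):(r + 1), (c - 1):(c + 1)]
      if (sum(nb >= v) > 1) next              # strict spatial maximum
      if (!is.null(lower) && any(lower[(r - 1):(r + 1), (c - 1):(c + 1)] >= v)) next
      if (!is.null(upper) && any(upper[(r - 1):(r + 1), (c - 1):(c + 1)] > v)) next
      # Hessian roundness of the smoothed image at this scale
      hrr <- sm[r - 1, c] - 2 * sm[r, c] + sm[r + 1, c]
      hcc <- sm[r, c - 1] - 2 * sm[r, c] + sm[r, c + 1]
      hrc <- (sm[r + 1, c + 1] - sm[r + 1, c - 1] -
              sm[r - 1, c + 1] + sm[r - 1, c - 1]) / 4
      ev <- eigen(matrix(c(hrr, hrc, hrc, hcc), 2, 2),
                  symmetric = TRUE, only.values = TRUE)$values
      ratio <- if (max(abs(ev)) == 0) 0 else min(abs(ev)) / max(abs(ev))
      if (ratio < roundnessMin) next
      count <- count + 1L
    }
  }
  count
}

#' Extract the per-aggregate shape feature vector
#'
#' Composes the skeleton, width and blob analyses into the seven shape
#' descriptors used for classification: \code{f1} longest chain length (um),
#' \code{f2} mean width along the chain (um), \code{f3} mean width per longest
#' chain (f2/f1), \code{f4} total fluorescence intensity (a.u.), \code{f5}
#' branch points per longest chain (1/um), \code{f6} intensity peaks per
#' longest chain (1/um), and \code{f7} longest chain as a percentage of total
#' skeleton length. \code{includeTotalLength} adds total skeleton length as an
#' optional eighth column (off by default).
#'
#' Topological thinning erodes the skeleton tips by roughly the local
#' half-width, biasing chain lengths low for thick or compact aggregates;
#' with \code{tipCorrection} (default) the distance-transform value at each
#' chain end (minus the half-pixel convention) is added back, so the chain
#' spans the full mask extent. \code{f7} is computed from the uncorrected
#' skeleton lengths so it never exceeds 100.
#'
#' @param img the background-subtracted \code{\link{MicroImage}}.
#' @param region an \code{\link{AggregateRegion}}.
#' @param includeTotalLength add \code{f8} = total skeleton length (um).
#' @param tipCorrection extend the longest chain to the mask boundary at its
#'   two ends (ignored for rings).
#' @param ... passed to \code{\link{countIntensityPeaks}}.
#' @return one-row data.frame with the features plus \code{id},
#'   \code{ringFlag}, \code{edgeFlag}, \code{nBranchPoints}, \code{nPeaks}.
#' @export
extractFeatures <- function(img, region, includeTotalLength = FALSE,
                            tipCorrection = TRUE, ...) {
  dims <- dim(pixels(img))
  sk <- skeletonizeRegion(region, dims)
  f1 <- sk@longestChainLength
  if (tipCorrection && !sk@ringFlag && nrow(sk@longestChainPath) >= 1) {
    mask <- regionMask(region, dims)
    dt <- EBImage::distmap(mask)
    path <- sk@longestChainPath
    np <- nrow(path)
    maskPx <- region@pixelCoords
    extend <- function(tipIdx, innerIdx) {
      tip <- path[tipIdx, ]
      if (np < 2) return(max(dt[matrix(tip, 1)] - 0.5, 0))
      u <- tip - path[innerIdx, ]
      u <- u / sqrt(sum(u^2))
      rel <- sweep(maskPx, 2, tip)
      proj <- rel[, 1] * u[1] + rel[, 2] * u[2]
      perp <- abs(rel[, 1] * u[2] - rel[, 2] * u[1])
      # follow the mask straight out from the tip, ignoring side structure
      ok <- perp <= dt[matrix(tip, 1)] + 1
      max(c(proj[ok], 0))
    }
    f1 <- f1 + (extend(1, min(np, 6)) + extend(np, max(1, np - 5))) *
      region@pixelSize
  }
  f2 <- meanWidthAlongChain(region, sk@longestChainPath, dims)
  nPeaks <- countIntensityPeaks(img, region, ...)
  out <- data.frame(id = region@id,
    f1 = f1, f2 = f2, f3 = f2 / f1, f4 = region@totalIntensity,
    f5 = sk@nBranchPoints / f1, f6 = nPeaks / f1,
    f7 = 100 * sk@longestChainLength / max(sk@totalLength, sk@longestChainLength),
    nBranchPoints = sk@nBranchPoints, nPeaks = nPeaks,
    ringFlag = sk@ringFlag, edgeFlag = region@edgeFlag)
  if (includeTotalLength) out$f8 <- sk@totalLength
  out
}

#' Feature table for a list of regions
#'
#' @param img a \code{\link{MicroImage}}.
#' @param regions list of \code{\link{AggregateRegion}}.
#' @param ... passed to \code{\link{extractFeatures}}.
#' @return data.frame, one row per region.
#' @export
extractFeatureTable <- function(img, regions, ...) {
  do.call(rbind, lapply(regions, function(r) extractFeatures(img, r, ...)))
}
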