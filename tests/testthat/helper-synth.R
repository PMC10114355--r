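# Shared builders and independent oracles for the test suite.

# straight horizontal chain of n tangent puncta, centered at the origin (um)
chainEntry <- function(n, d = 0.5) {
  cen <- cbind(d * (seq_len(n) - (n + 1) / 2), 0)
  list(classLabel = "linear_fractal", centers = cen, backbone = NULL,
       trueLongestChain = n * d, trueBranchPoints = 0L, trueWidth = d)
}

# independent brute-force adjacency analysis of a punctum cluster:
# pairwise-distance tangency graph, degree-based branch count, and the
# longest simple path found by plain recursive DFS over adjacency lists
bruteClusterStats <- function(centers, d, tol = 0.01) {
  n <- nrow(centers)
  adj <- vector("list", n)
  deg <- integer(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dij <- sqrt(sum((centers[i, ] - centers[j, ])^2))
    if (dij <= d * (1 + tol)) { adj[[i]] <- c(adj[[i]], j); deg[i] <- deg[i] + 1L }
  }
  best <- 1L
  visited <- rep(FALSE, n)
  dfs <- function(v, len) {
    if (len > best) best <<- len
    for (w in adj[[v]]) if (!visited[w]) {
      visited[w] <<- TRUE
      dfs(w, len + 1L)
      visited[w] <<- FALSE
    }
  }
  for (s in seq_len(n)) { visited[s] <- TRUE; dfs(s, 1L); visited[s] <- FALSE }
  list(branchPoints = sum(deg >= 3), chainPuncta = best,
       connected = {
         seen <- logical(n); stack <- 1L; seen[1] <- TRUE
         while (length(stack)) {
           v <- stack[1]; stack <- stack[-1]
           nw <- adj[[v]][!seen[adj[[v]]]]
           seen[nw] <- TRUE; stack <- c(stack, nw)
         }
         all(seen)
       })
}

# exhaustive longest path over the pixel adjacency graph of a skeleton mask
# (independent of the package's condensed-graph search); lengths count 1 px
# per axial and sqrt(2) per diagonal step
brutePixelLongestPath <- function(skel) {
  pts <- which(skel, arr.ind = TRUE)
  n <- nrow(pts)
  if (n == 1) return(1)   # one-pixel-chain convention, as in the package
  adj <- vector("list", n)
  wts <- vector("list", n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dr <- abs(pts[i, 1] - pts[j, 1]); dc <- abs(pts[i, 2] - pts[j, 2])
    if (dr <= 1 && dc <= 1) {
      adj[[i]] <- c(adj[[i]], j)
      wts[[i]] <- c(wts[[i]], if (dr + dc == 2) sqrt(2) else 1)
    }
  }
  best <- 0
  visited <- rep(FALSE, n)
  dfs <- function(v, len) {
    if (len > best) best <<- len
    for (k in seq_along(adj[[v]])) {
      w <- adj[[v]][k]
      if (!visited[w]) {
        visited[w] <<- TRUE
        dfs(w, len + wts[[v]][k])
        visited[w] <<- FALSE
      }
    }
  }
  for (s in seq_len(n)) { visited[s] <- TRUE; dfs(s, 0); visited[s] <- FALSE }
  best
}

# render a single ground-truth entry on its own field, optionally noiseless
renderSingle <- function(entry, seed, fieldSize = 128, noise = TRUE, ...) {
  renderScene(GroundTruth(list(entry)),
              simParams(rngSeed = seed, noise = noise, ...),
              fieldSize = fieldSize)
}

# segment the single aggregate of a rendered scene (background threshold only;
# the constant camera offset sits far below the detection threshold)
segmentSingle <- function(scene, ...) {
  regs <- segmentAggregates(scene$mCherry, ...)
  expect_true(length(regs) >= 1)
  regs[[1]]
}
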