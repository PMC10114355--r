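#' SimParams: parameters of the synthetic-scene simulator
#'
#' Holds every knob of the scene generator: the punctum-docking growth model
#' (diffusion-limited cluster-cluster aggregation by 2-D random-walk approach
#' with stick-on-first-contact), worm-like-chain fibrils, the Gaussian PSF and
#' the Poisson-Gaussian camera model. Lengths are micrometres, intensities on
#' the 16-bit camera scale.
#'
#' @slot nPuncta number of puncta in a fractal cluster.
#' @slot punctumDiameter punctum diameter, um (default 0.5).
#' @slot dockingStages growth stage: 1 chain, 2 branched, 3 larger branched.
#' @slot fibrilLength,fibrilWidth fibril backbone arc length and width, um.
#' @slot persistenceLength worm-like-chain persistence length, um; \code{Inf}
#'   gives a straight fibril.
#' @slot embeddedPuncta number of puncta placed on a fibril backbone.
#' @slot psfSigma Gaussian PSF sigma, um.
#' @slot backgroundLevel camera offset, a.u. (0 <= level < 65535).
#' @slot noiseReadSigma Gaussian read-noise sigma, a.u.
#' @slot photonGain a.u. per photon for the Poisson shot-noise stage.
#' @slot noise logical master switch for both noise sources.
#' @slot chromaticShift length-2 (dx, dy) px translation injected into the
#'   second channel.
#' @slot pixelSize um per px (default 0.1625, a 6.5-um camera pixel at 40x).
#' @slot punctumAmplitude integrated intensity of one punctum, a.u.
#' @slot fibrilDensity fibril backbone line density, a.u. per um.
#' @slot rngSeed integer seed; identical params reproduce identical scenes.
#' @export
setClass("SimParams",
  representation(nPuncta = "numeric", punctumDiameter = "numeric",
    dockingStages = "numeric", fibrilLength = "numeric",
    fibrilWidth = "numeric", persistenceLength = "numeric",
    embeddedPuncta = "numeric", psfSigma = "numeric",
    backgroundLevel = "numeric", noiseReadSigma = "numeric",
    photonGain = "numeric", noise = "logical", chromaticShift = "numeric",
    pixelSize = "numeric", punctumAmplitude = "numeric",
    fibrilDensity = "numeric", rngSeed = "numeric"),
  prototype(nPuncta = 3, punctumDiameter = 0.5, dockingStages = 1,
    fibrilLength = 27, fibrilWidth = 0.15, persistenceLength = 200,
    embeddedPuncta = 2, psfSigma = 0.15, backgroundLevel = 20,
    noiseReadSigma = 3, photonGain = 2, noise = TRUE,
    chromaticShift = c(0, 0), pixelSize = 0.1625, punctumAmplitude = 1300,
    fibrilDensity = 3500, rngSeed = 1))

setValidity("SimParams", function(object) {
  pos <- c(punctumDiameter = object@punctumDiameter,
           fibrilLength = object@fibrilLength,
           fibrilWidth = object@fibrilWidth,
           persistenceLength = object@persistenceLength,
           psfSigma = object@psfSigma, pixelSize = object@pixelSize,
           photonGain = object@photonGain)
  bad <- names(pos)[!is.na(pos) & pos <= 0]
  if (length(bad)) return(paste("must be strictly positive:",
                                paste(bad, collapse = ", ")))
  if (object@nPuncta < 1) return("nPuncta must be >= 1")
  if (object@backgroundLevel < 0 || object@backgroundLevel >= 65535)
    return("backgroundLevel must be in [0, 65535)")
  if (length(object@chromaticShift) != 2) return("chromaticShift must be (dx, dy)")
  if (object@noiseReadSigma < 0) return("noiseReadSigma must be >= 0")
  TRUE
})

#' @rdname SimParams-class
#' @param ... slot values overriding the defaults (see slots).
#' @return a validated \code{SimParams} object.
#' @examples
#' p <- simParams(nPuncta = 7, dockingStages = 2, rngSeed = 11)
#' @export
simParams <- function(...) new("SimParams", ...)

# --- ground truth ------------------------------------------------------------

#' GroundTruth: labelled description of a simulated scene
#'
#' One entry per aggregate: the morphological class, punctum centers and/or
#' fibril backbone polyline in micrometre coordinates, and the true longest
#' chain length, branch-point count and width derived from the construction.
#'
#' @slot aggregates list of entries, each a list with elements
#'   \code{classLabel} (\code{"linear_fractal"}, \code{"branched_fractal"} or
#'   \code{"fibril"}), \code{centers} (n x 2 matrix, um), \code{backbone}
#'   (m x 2 matrix, um, or NULL), \code{trueLongestChain} (um),
#'   \code{trueBranchPoints} (count), \code{trueWidth} (um).
#' @export
setClass("GroundTruth", representation(aggregates = "list"))

setValidity("GroundTruth", function(object) {
  for (a in object@aggregates) {
    hasBB <- !is.null(a$backbone) && nrow(a$backbone) > 0
    if ((a$classLabel == "fibril") != hasBB)
      return("classLabel 'fibril' must coincide with a non-empty backbone")
    if (a$classLabel == "linear_fractal" && a$trueBranchPoints != 0)
      return("linear_fractal entries must have 0 branch points")
  }
  TRUE
})

#' @rdname GroundTruth-class
#' @param aggregates list of ground-truth entries.
#' @export
GroundTruth <- function(aggregates = list())
  new("GroundTruth", aggregates = aggregates)

# punctum adjacency under the tangency relation (1% tolerance on diameter)
punctumAdjacency <- function(centers, d, tol = 0.01) {
  n <- nrow(centers)
  if (n == 1) return(matrix(FALSE, 1, 1))
  dm <- as.matrix(stats::dist(centers))
  adj <- dm <= d * (1 + tol) & dm > 0
  adj
}

# Longest simple path (node count) and branch points of a punctum cluster,
# from its tangency adjacency graph.
clusterGraphTruth <- function(centers, d) {
  n <- nrow(centers)
  if (n == 1) return(list(chainPuncta = 1L, branchPoints = 0L))
  adj <- punctumAdjacency(centers, d)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  deg <- igraph::degree(g)
  best <- 1L
  for (v in seq_len(n)) {
    sp <- igraph::all_simple_paths(g, from = v)
    if (length(sp)) best <- max(best, max(vapply(sp, length, integer(1))))
  }
  list(chainPuncta = as.integer(best),
       branchPoints = as.integer(sum(deg >= 3)))
}

# Grow a linear chain of n tangent puncta with bounded angular jitter.
buildChain <- function(n, d, jitterSd = 0.35) {
  centers <- matrix(0, n, 2)
  if (n == 1) return(centers)
  theta <- runif(1, 0, 2 * pi)
  for (i in 2:n) {
    for (try in 1:50) {
      th <- theta + rnorm(1, 0, jitterSd)
      cand <- centers[i - 1, ] + d * c(cos(th), sin(th))
      dd <- sqrt(rowSums((centers[seq_len(i - 1), , drop = FALSE] -
                          matrix(cand, i - 1, 2, byrow = TRUE))^2))
      if (all(dd >= d * 0.999)) { centers[i, ] <- cand; theta <- th; break }
      if (try == 50) stop("chain construction failed to avoid overlap")
    }
  }
  centers
}

# Random-walk approach of rigid cluster B toward cluster A with
# stick-on-first-contact docking; returns B translated to tangency.
# With `nearIndex` the walker is launched just outside punctum A[nearIndex, ]
# (uniform accessibility over the cluster surface); otherwise it starts on a
# circle enclosing both clusters.
dockClusters <- function(A, B, d, maxSteps = 50000, nearIndex = NULL) {
  cA <- colMeans(A); cB0 <- colMeans(B)
  rA <- if (nrow(A) > 1) max(sqrt(rowSums(sweep(A, 2, cA)^2))) else 0
  rB <- if (nrow(B) > 1) max(sqrt(rowSums(sweep(B, 2, cB0)^2))) else 0
  anchor <- if (is.null(nearIndex)) cA else A[nearIndex, ]
  R0 <- if (is.null(nearIndex)) rA + rB + 3 * d else rB + 2.2 * d
  leash <- if (is.null(nearIndex)) 2 * R0 else rB + 6 * d
  phi <- runif(1, 0, 2 * pi)
  offset <- anchor + R0 * c(cos(phi), sin(phi)) - cB0
  Bc <- sweep(B, 2, offset, "+")
  h <- d / 3
  minD <- function(M) min(sqrt(outer(rowSums(A^2), rep(1, nrow(M))) +
                               outer(rep(1, nrow(A)), rowSums(M^2)) -
                               2 * A %*% t(M)))
  for (step in seq_len(maxSteps)) {
    ang <- runif(1, 0, 2 * pi)
    s <- h * c(cos(ang), sin(ang))
    Bn <- sweep(Bc, 2, s, "+")
    if (minD(Bn) < d) {
      # solve the first-contact fraction t in [0,1] along the step
      tBest <- 1
      for (i in seq_len(nrow(A))) for (j in seq_len(nrow(Bc))) {
        q <- Bc[j, ] - A[i, ]
        aa <- sum(s^2); bb <- 2 * sum(s * q); cc <- sum(q^2) - d^2
        disc <- bb^2 - 4 * aa * cc
        if (disc >= 0) {
          tt <- (-bb - sqrt(disc)) / (2 * aa)
          if (tt >= 0 && tt < tBest) tBest <- tt
        }
      }
      return(sweep(Bc, 2, tBest * s, "+"))
    }
    Bc <- Bn
    # keep the walker inside a generous arena so contact always happens
    cB <- colMeans(Bc)
    if (sqrt(sum((cB - anchor)^2)) > leash) {
      dirv <- (cB - anchor) / sqrt(sum((cB - anchor)^2))
      Bc <- sweep(Bc, 2, (anchor + R0 * dirv) - cB, "+")
    }
  }
  stop("docking failed to converge within the step budget; ",
       "check punctum diameter and cluster sizes")
}

# Attach a k-punctum arm at cluster punctum `attachAt`. An arriving chain
# sticks at its first contact and, being screened by the cluster, ends up
# pointing into open space: the arm direction is chosen as the angle with
# maximal clearance from the existing puncta (with a random dither), then
# grows outward with angular jitter. Overlapping placements are rejected.
attachArm <- function(acc, k, d, attachAt, jitterSd = 0.3) {
  base <- acc[attachAt, ]
  angs <- seq(0, 2 * pi, length.out = 17)[-17] + runif(1, 0, 0.4)
  clear <- vapply(angs, function(a) {
    p <- base + d * c(cos(a), sin(a))
    min(sqrt(rowSums((acc - matrix(p, nrow(acc), 2, byrow = TRUE))^2))[-attachAt])
  }, numeric(1))
  for (th in angs[order(clear, decreasing = TRUE)][1:4]) {
    arm <- matrix(0, k, 2)
    prev <- base
    ok <- TRUE
    thk <- th
    for (j in seq_len(k)) {
      if (j > 1) thk <- thk + rnorm(1, 0, jitterSd)
      cand <- prev + d * c(cos(thk), sin(thk))
      dd <- sqrt(rowSums((rbind(acc, arm[seq_len(j - 1), , drop = FALSE]) -
                          matrix(cand, nrow(acc) + j - 1, 2, byrow = TRUE))^2))
      ddOK <- if (j == 1) all(dd[-attachAt] >= d * 0.999) else all(dd >= d * 0.999)
      if (!ddOK) { ok <- FALSE; break }
      arm[j, ] <- cand
      prev <- cand
    }
    if (ok) return(rbind(acc, arm))
  }
  acc   # arm could not be placed without overlap; cluster stays as is
}

#' Simulate a fractal-shaped aggregate by hierarchical punctum docking
#'
#' Growth model: stage 1 docks single puncta into a linear chain; stage 2
#' docks several chains onto each other by an off-lattice 2-D random walk with
#' stick-on-first-contact; stage 3 docks stage-2 clusters. Ground-truth
#' longest chain and branch points are computed from the punctum tangency
#' adjacency graph (tangency tolerance 1% of the diameter): the longest chain
#' is (path punctum count) x diameter, branch points are graph nodes of degree
#' >= 3.
#'
#' @param params a \code{\link{SimParams}}; \code{nPuncta} and
#'   \code{punctumDiameter} are used, randomness from \code{rngSeed}.
#' @param stage 1 (linear), 2 (branched) or 3 (larger branched); defaults to
#'   \code{dockingStages}.
#' @return a ground-truth entry (list; see \code{\link{GroundTruth}}).
#' @examples
#' e <- simulateFractalAggregate(simParams(nPuncta = 7, rngSeed = 1), stage = 2)
#' e$trueBranchPoints
#' @export
simulateFractalAggregate <- function(params, stage = params@dockingStages) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  if (!stage %in% 1:3) stop("stage must be 1, 2 or 3")
  n <- as.integer(params@nPuncta)
  if (n < 1) stop("nPuncta must be >= 1")
  d <- params@punctumDiameter
  set.seed(deriveSeed(params@rngSeed, 101 + stage))
  buildCluster <- function(n, stage) {
    if (stage == 1 || n <= 2) return(buildChain(n, d))
    if (stage == 2) {
      # a core chain decorated by short outward-pointing arms attached at
      # interior puncta: the open chain-plus-side-branch morphology of the
      # intermediate growth stage (arriving chains stick at first contact,
      # so arms point away from the cluster rather than hugging it)
      core <- max(4, min(n - 2, round(0.33 * n)))
      acc <- buildChain(core, d)
      left <- n - core
      while (left > 0) {
        k <- min(left, 2L)
        grown <- attachArm(acc, k, d,
                           attachAt = sample(2:max(2, nrow(acc) - 1), 1))
        if (nrow(grown) == nrow(acc))   # crowded: fall back to free docking
          grown <- rbind(acc, dockClusters(acc, buildChain(k, d), d))
        acc <- grown
        left <- left - k
      }
      return(acc)
    }
    # stage 3: dock two or three stage-2 clusters onto each other
    nSub <- if (n >= 15) sample(2:3, 1) else 2
    sizes <- rep(n %/% nSub, nSub)
    sizes[1] <- sizes[1] + n %% nSub
    subs <- lapply(sizes, function(k) buildCluster(k, 2))
    acc <- subs[[1]]
    for (i in 2:length(subs)) acc <- rbind(acc, dockClusters(acc, subs[[i]], d))
    acc
  }
  centers <- buildCluster(n, stage)
  centers <- sweep(centers, 2, colMeans(centers))
  tr <- clusterGraphTruth(centers, d)
  label <- if (stage == 1 || tr$branchPoints == 0) "linear_fractal"
           else "branched_fractal"
  list(classLabel = label, centers = centers, backbone = NULL,
       trueLongestChain = tr$chainPuncta * d,
       trueBranchPoints = if (label == "linear_fractal") 0L else tr$branchPoints,
       trueWidth = d)
}

#' Simulate a fibril-shaped aggregate as a worm-like chain
#'
#' The backbone is a tangent-angle random walk: angle increments are
#' i.i.d. Gaussian with variance (step / persistence length), giving the 2-D
#' worm-like chain. The polyline arc length equals the requested fibril
#' length exactly by construction. \code{embeddedPuncta} punctum centers are
#' placed at uniform random arc positions on the backbone.
#'
#' @param params a \code{\link{SimParams}}; uses \code{fibrilLength},
#'   \code{fibrilWidth}, \code{persistenceLength}, \code{embeddedPuncta}.
#' @return a ground-truth entry with class \code{"fibril"}.
#' @examples
#' e <- simulateFibril(simParams(fibrilLength = 27, rngSeed = 3))
#' @export
simulateFibril <- function(params) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  L <- params@fibrilLength
  Lp <- params@persistenceLength
  if (!is.infinite(Lp) && Lp <= 0) stop("persistenceLength must be > 0")
  if (L < params@pixelSize) stop("fibrilLength must be >= pixelSize")
  set.seed(deriveSeed(params@rngSeed, 201))
  ds <- min(0.05, L / 20)
  nFull <- floor(L / ds)
  steps <- c(rep(ds, nFull), L - nFull * ds)
  steps <- steps[steps > 1e-12]
  theta0 <- runif(1, 0, 2 * pi)
  dth <- if (is.infinite(Lp)) rep(0, length(steps))
         else rnorm(length(steps), 0, sqrt(steps / Lp))
  theta <- theta0 + cumsum(dth) - dth[1]   # first step along theta0
  pts <- rbind(c(0, 0),
               cbind(cumsum(steps * cos(theta)), cumsum(steps * sin(theta))))
  arc <- c(0, cumsum(steps))
  nP <- as.integer(params@embeddedPuncta)
  centers <- matrix(numeric(0), 0, 2)
  if (nP > 0) {
    sPos <- sort(runif(nP, 0.05 * L, 0.95 * L))
    centers <- t(vapply(sPos, function(s) {
      i <- findInterval(s, arc, rightmost.closed = TRUE)
      f <- (s - arc[i]) / (arc[i + 1] - arc[i])
      pts[i, ] + f * (pts[i + 1, ] - pts[i, ])
    }, numeric(2)))
  }
  ctr <- colMeans(pts)
  pts <- sweep(pts, 2, ctr)
  if (nrow(centers)) centers <- sweep(centers, 2, ctr)
  list(classLabel = "fibril", centers = centers, backbone = pts,
       trueLongestChain = L, trueBranchPoints = 0L,
       trueWidth = params@fibrilWidth)
}

# arc length of a polyline (matrix of points)
polylineLength <- function(p) sum(sqrt(rowSums(diff(p)^2)))

# --- rendering ---------------------------------------------------------------

# Splat one ground-truth entry (um coords, plus an offset in um) onto a canvas.
splatAggregate <- function(entry, offsetUm, nr, nc, params) {
  px <- params@pixelSize
  toRC <- function(xy) cbind(row = (xy[, 2] + offsetUm[2]) / px + 1,
                             col = (xy[, 1] + offsetUm[1]) / px + 1)
  acc <- matrix(0, nr, nc)
  if (!is.null(entry$backbone) && nrow(entry$backbone) > 1) {
    # resample backbone at 0.25-px steps; each sample carries density * ds
    bb <- entry$backbone
    seg <- sqrt(rowSums(diff(bb)^2))
    arc <- c(0, cumsum(seg))
    sGrid <- seq(0, arc[length(arc)], by = 0.25 * px)
    i <- findInterval(sGrid, arc, rightmost.closed = TRUE)
    i <- pmin(i, nrow(bb) - 1)
    f <- (sGrid - arc[i]) / pmax(seg[i], 1e-12)
    smp <- bb[i, , drop = FALSE] + f * (bb[i + 1, , drop = FALSE] - bb[i, , drop = FALSE])
    ds <- c(diff(sGrid), 0.25 * px)
    rc <- toRC(smp)
    acc <- acc + splatPoints(nr, nc, rc[, 1], rc[, 2], params@fibrilDensity * ds)
  }
  if (nrow(entry$centers)) {
    rc <- toRC(entry$centers)
    acc <- acc + splatPoints(nr, nc, rc[, 1], rc[, 2],
                             rep(params@punctumAmplitude, nrow(rc)))
  }
  acc
}

applyCameraNoise <- function(field, params) {
  if (!params@noise) return(field)
  g <- params@photonGain
  noisy <- rpois(length(field), field / g) * g
  noisy <- noisy + rnorm(length(field), 0, params@noiseReadSigma)
  out <- matrix(noisy, nrow(field), ncol(field))
  pmin(pmax(out, 0), 65535)
}

#' Render a two-channel fluorescence scene from ground truth
#'
#' Puncta are deposited as point masses and fibril backbones as line densities,
#' convolved with the Gaussian PSF and placed on the camera offset. The second
#' (ThT-like) channel is the first channel's noiseless field translated by
#' \code{chromaticShift} before noise; both channels then receive independent
#' Poisson shot noise and Gaussian read noise. The label mask records the
#' ground-truth aggregate id per pixel (0 = background).
#'
#' Aggregates are placed on a jittered grid so that distinct aggregates do not
#' overlap; the returned ground truth carries the absolute coordinates.
#'
#' @param truth a \code{\link{GroundTruth}}.
#' @param params a \code{\link{SimParams}}.
#' @param fieldSize canvas side, px.
#' @param labelThreshold noiseless intensity (a.u.) above which a pixel is
#'   assigned to an aggregate in the label mask.
#' @return list with \code{mCherry} and \code{tht} (\code{\link{MicroImage}}),
#'   \code{labels} (integer matrix), \code{truth} (absolute coordinates) and
#'   \code{noiseless} (matrix, channel-1 field before noise).
#' @examples
#' tr <- GroundTruth(list(simulateFractalAggregate(simParams(rngSeed = 2), 1)))
#' sc <- renderScene(tr, simParams(rngSeed = 2), fieldSize = 128)
#' @export
renderScene <- function(truth, params, fieldSize = 256, labelThreshold = 30) {
  stopifnot(is(truth, "GroundTruth"), is(params, "SimParams"))
  validObject(truth); validObject(params)
  set.seed(deriveSeed(params@rngSeed, 301))
  nr <- nc <- as.integer(fieldSize)
  px <- params@pixelSize
  aggs <- truth@aggregates
  nA <- length(aggs)
  fields <- vector("list", nA)
  placed <- aggs
  if (nA > 0) {
    # jittered grid placement, one cell per aggregate
    gside <- ceiling(sqrt(nA))
    cells <- sample(gside^2, nA)
    cw <- nr / gside * px
    for (i in seq_len(nA)) {
      cellR <- (cells[i] - 1) %/% gside
      cellC <- (cells[i] - 1) %% gside
      ext <- rbind(aggs[[i]]$centers, aggs[[i]]$backbone)
      half <- max(abs(ext)) + 2 * params@punctumDiameter
      lo <- half; hi <- cw - half
      jit <- if (hi > lo) runif(2, lo, hi) else rep(cw / 2, 2)
      off <- c(cellC * cw + jit[1], cellR * cw + jit[2])
      placed[[i]]$centers <- if (nrow(aggs[[i]]$centers))
        sweep(aggs[[i]]$centers, 2, off, "+") else aggs[[i]]$centers
      if (!is.null(aggs[[i]]$backbone))
        placed[[i]]$backbone <- sweep(aggs[[i]]$backbone, 2, off, "+")
      fields[[i]] <- splatAggregate(aggs[[i]], off, nr, nc, params)
    }
  }
  kern <- gaussianKernel(params@psfSigma / px)
  # clamp FFT ringing so noiseless fields are exactly non-negative
  smooth <- lapply(fields, function(f) pmax(convolve2d(f, kern), 0))
  fieldSum <- Reduce(`+`, smooth, matrix(0, nr, nc))
  peak <- max(fieldSum) + params@backgroundLevel
  if (peak > 65535)
    stop(sprintf("rendered field reaches %.0f a.u. (> 65535); reduce gain",
                 peak))
  labels <- matrix(0L, nr, nc)
  if (nA > 0) {
    stackMax <- smooth[[1]]
    arg <- matrix(1L, nr, nc)
    if (nA > 1) for (i in 2:nA) {
      sel <- smooth[[i]] > stackMax
      stackMax[sel] <- smooth[[i]][sel]
      arg[sel] <- i
    }
    labels[stackMax > labelThreshold] <- arg[stackMax > labelThreshold]
  }
  noiseless <- fieldSum + params@backgroundLevel
  ch1 <- applyCameraNoise(noiseless, params)
  sh <- params@chromaticShift
  shifted <- if (all(sh == 0)) noiseless else {
    m <- translateImage(noiseless, sh[1], sh[2], fill = params@backgroundLevel)
    m
  }
  ch2 <- applyCameraNoise(shifted, params)
  list(mCherry = MicroImage(ch1, pixelSize = px, channel = "mCherry"),
       tht = MicroImage(ch2, pixelSize = px, channel = "ThT"),
       labels = labels,
       truth = GroundTruth(placed),
       noiseless = noiseless)
}

#' KineticsParams: parameters of the simulated ThT aggregation time course
#'
#' The aggregate-bound signal is a logistic
#' \code{baseline + amplitude / (1 + exp(-growthRate (t - tMid)))} with
#' \code{tMid = lagTime + 2/growthRate}, so that the maximum-slope tangent
#' intercepts the baseline exactly at \code{lagTime} -- the same convention the
#' estimator uses. An optional decaying component
#' \code{initialMonomerPeak exp(-t / monomerTau)} reproduces the early
#' non-aggregate ThT signal seen immediately after mixing dye with monomer.
#'
#' @slot amplitude,baseline a.u.
#' @slot lagTime min (tangent-intercept convention).
#' @slot growthRate 1/min.
#' @slot initialMonomerPeak a.u. (0 disables the early component).
#' @slot monomerTau min, decay constant of the early component.
#' @slot seeded logical flag carried into the trace condition.
#' @slot samplingInterval min (default 10).
#' @slot duration min (default 1440, i.e. 24 h).
#' @slot replicateNoiseSigma a.u.
#' @slot rngSeed integer.
#' @export
setClass("KineticsParams",
  representation(amplitude = "numeric", lagTime = "numeric",
    growthRate = "numeric", baseline = "numeric",
    initialMonomerPeak = "numeric", monomerTau = "numeric",
    seeded = "logical", samplingInterval = "numeric", duration = "numeric",
    replicateNoiseSigma = "numeric", rngSeed = "numeric"),
  prototype(amplitude = 3e5, lagTime = 300, growthRate = 0.01,
    baseline = 1000, initialMonomerPeak = 0, monomerTau = 120,
    seeded = FALSE, samplingInterval = 10, duration = 1440,
    replicateNoiseSigma = 0, rngSeed = 1))

setValidity("KineticsParams", function(object) {
  if (object@amplitude < 0) return("amplitude must be >= 0")
  if (object@lagTime < 0) return("lagTime must be >= 0")
  if (object@growthRate <= 0) return("growthRate must be > 0")
  if (object@duration < object@samplingInterval)
    return("duration must be >= samplingInterval")
  TRUE
})

#' @rdname KineticsParams-class
#' @param ... slot values overriding the defaults.
#' @export
kineticsParams <- function(...) new("KineticsParams", ...)

#' Simulate a ThT aggregation kinetics trace
#'
#' @param params a \code{\link{KineticsParams}}.
#' @param replicateId integer replicate label (also perturbs the noise seed).
#' @return a \code{\link{KineticsTrace}} on the uniform sampling grid.
#' @examples
#' tr <- simulateKinetics(kineticsParams(lagTime = 300, rngSeed = 7))
#' @export
simulateKinetics <- function(params, replicateId = 1L) {
  stopifnot(is(params, "KineticsParams"))
  validObject(params)
  if (params@amplitude < 0) stop("amplitude must be >= 0")
  t <- seq(0, params@duration, by = params@samplingInterval)
  tMid <- params@lagTime + 2 / params@growthRate
  y <- params@baseline +
    params@amplitude / (1 + exp(-params@growthRate * (t - tMid)))
  if (params@initialMonomerPeak > 0)
    y <- y + params@initialMonomerPeak * exp(-t / params@monomerTau)
  if (params@replicateNoiseSigma > 0) {
    set.seed(deriveSeed(params@rngSeed, 400 + replicateId))
    y <- y + rnorm(length(t), 0, params@replicateNoiseSigma)
  }
  KineticsTrace(t, y, condition = if (params@seeded) "seeded" else "unseeded",
                replicateId = replicateId)
}

#' Render a negative-stain TEM image of a fibril ribbon
#'
#' Negative stain accumulates at the particle rim, so a fibril appears as a
#' ribbon whose perpendicular intensity profile has two maxima exactly at the
#' ribbon edges. The profile is
#' \code{exp(-(|u| - w(s)/2)^2 / (2 edgeSigma^2))} for signed perpendicular
#' offset \code{u}; the peak-to-peak distance therefore equals the local width
#' \code{w(s)}. An optional sinusoidal twist modulates the width along the
#' axis.
#'
#' @param widthNm ribbon width, nm.
#' @param lengthNm ribbon length, nm.
#' @param nmPerPx calibration, nm per pixel.
#' @param edgeSigmaPx Gaussian sharpness of the rim peaks, px.
#' @param twistAmplitude relative width modulation (0 = constant width).
#' @param twistPeriodNm modulation period, nm.
#' @param amplitude peak intensity above background, a.u.
#' @param backgroundLevel,noiseSigma camera offset and Gaussian noise (a.u.).
#' @param margin border margin, px.
#' @param rngSeed seed for the noise.
#' @return a \code{\link{MicroImage}} with channel \code{"TEM"} and nm
#'   calibration; the fibril axis runs horizontally through the image center.
#' @examples
#' img <- renderTemFibril(150, 2000, nmPerPx = 1, noiseSigma = 0)
#' @export
renderTemFibril <- function(widthNm, lengthNm, nmPerPx = 1, edgeSigmaPx = 4,
                            twistAmplitude = 0, twistPeriodNm = lengthNm / 3,
                            amplitude = 20000, backgroundLevel = 500,
                            noiseSigma = 0, margin = 20, rngSeed = 1) {
  if (widthNm < 3 * nmPerPx)
    stop("width below 3 pixels is unresolvable at this calibration")
  wPx <- widthNm / nmPerPx
  lPx <- lengthNm / nmPerPx
  nc <- ceiling(lPx) + 2 * margin
  nr <- ceiling(wPx * (1 + abs(twistAmplitude))) + 2 * margin +
    8 * ceiling(edgeSigmaPx)
  rowAxis <- (nr + 1) / 2
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  row <- matrix(seq_len(nr), nr, nc)
  sNm <- (col - margin) * nmPerPx
  wLoc <- wPx * (1 + twistAmplitude * sin(2 * pi * sNm / twistPeriodNm))
  u <- abs(row - rowAxis)
  inAxis <- col >= margin & col <= nc - margin
  field <- amplitude * exp(-(u - wLoc / 2)^2 / (2 * edgeSigmaPx^2))
  field[!inAxis] <- 0
  img <- field + backgroundLevel
  if (noiseSigma > 0) {
    set.seed(deriveSeed(rngSeed, 501))
    img <- pmax(img + matrix(rnorm(nr * nc, 0, noiseSigma), nr, nc), 0)
  }
  MicroImage(pmin(img, 65535), pixelSize = nmPerPx, sizeUnit = "nm",
             channel = "TEM")
}
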