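# Class-conditioned scene sets: the study conditions for the three
# morphological classes, used by the round-trip validation and examples.

# Draw one ground-truth aggregate of a requested class at the study scales:
# linear chains of 2-4 puncta (~1.4 um), branched clusters of 14-18 puncta
# with >= 3 branch points (~3.3 um longest chain, ~4 branches), fibrils with
# log-normal length of median 27 um.
sampleClassTruth <- function(classLabel, seed, baseParams = simParams()) {
  set.seed(deriveSeed(seed, 601))
  if (classLabel == "linear_fractal") {
    n <- sample(2:4, 1)
    e <- simulateFractalAggregate(
      simParams(nPuncta = n, rngSeed = deriveSeed(seed, 602)), stage = 1)
  } else if (classLabel == "branched_fractal") {
    # resample until the docking produced a genuinely branched cluster
    for (try in 1:40) {
      n <- sample(10:14, 1)
      e <- simulateFractalAggregate(
        simParams(nPuncta = n, rngSeed = deriveSeed(seed, 603 + try)),
        stage = 2)
      if (e$trueBranchPoints >= 3) break
    }
    if (e$trueBranchPoints < 3)
      stop("failed to draw a branched cluster; check docking parameters")
  } else if (classLabel == "fibril") {
    len <- min(55, max(12, stats::rlnorm(1, log(27), 0.5)))
    e <- simulateFibril(simParams(fibrilLength = len,
                                  embeddedPuncta = sample(0:3, 1),
                                  rngSeed = deriveSeed(seed, 604)))
  } else stop("unknown class label: ", classLabel)
  e
}

#' Simulate a labelled set of single-aggregate scenes
#'
#' Draws aggregate classes at the given proportions (default: the observed
#' 56 / 32 / 12 percent split of linear-fractal, branched-fractal and fibril
#' aggregates), builds one ground-truth aggregate per scene at the study
#' scales -- linear chains of 2-4 half-micron puncta, branched clusters with
#' at least 3 branch points and ~3 um longest chains, fibrils with log-normal
#' lengths around a 27-um median -- and renders each on its own field (small
#' fields for fractal classes, a large field for fibrils).
#'
#' @param nScenes number of scenes.
#' @param seed master seed; all per-scene seeds derive from it.
#' @param classProbs named numeric (linear_fractal, branched_fractal, fibril)
#'   summing to 1.
#' @param noise render with camera noise.
#' @return list of records, each with \code{classLabel}, \code{scene}
#'   (from \code{\link{renderScene}}) and \code{fieldSize}.
#' @export
simulateSceneSet <- function(nScenes, seed = 1,
                             classProbs = c(linear_fractal = 0.56,
                                            branched_fractal = 0.32,
                                            fibril = 0.12),
                             noise = TRUE) {
  stopifnot(abs(sum(classProbs) - 1) < 1e-6)
  set.seed(deriveSeed(seed, 600))
  # deterministic class counts at the requested proportions, shuffled
  counts <- round(classProbs * nScenes)
  while (sum(counts) > nScenes) counts[which.max(counts)] <- counts[which.max(counts)] - 1
  while (sum(counts) < nScenes) counts[which.min(counts)] <- counts[which.min(counts)] + 1
  classes <- sample(rep(names(classProbs), counts))
  lapply(seq_len(nScenes), function(i) {
    e <- sampleClassTruth(classes[i], deriveSeed(seed, 7000 + i))
    fs <- if (classes[i] == "fibril") 512L else 128L
    sc <- renderScene(GroundTruth(list(e)),
                      simParams(rngSeed = deriveSeed(seed, 8000 + i),
                                noise = noise), fieldSize = fs)
    list(classLabel = classes[i], scene = sc, fieldSize = fs)
  })
}

#' Match detected regions to ground-truth aggregates via the label mask
#'
#' Each region is assigned the majority ground-truth label over its pixels
#' (0 when the majority of pixels are background).
#'
#' @param regions list of \code{\link{AggregateRegion}}.
#' @param labels integer label matrix from \code{\link{renderScene}}.
#' @return integer vector of ground-truth ids (0 = unmatched).
#' @export
matchRegionsToTruth <- function(regions, labels) {
  vapply(regions, function(r) {
    v <- labels[r@pixelCoords]
    tv <- table(v)
    as.integer(names(tv)[which.max(tv)])
  }, integer(1))
}

#' Segment and featurize a scene set
#'
#' Runs background subtraction (ball radius capped below the field size),
#' detection and feature extraction on every scene, keeping the largest
#' truth-matched region per scene, and pools the features with their
#' ground-truth class labels.
#'
#' @param set result of \code{\link{simulateSceneSet}}.
#' @param intensityThreshold detection threshold, a.u.
#' @return data.frame: pooled features plus \code{trueClass} and
#'   \code{sceneIndex}; scenes whose aggregate went undetected are dropped.
#' @export
analyzeSceneSet <- function(set, intensityThreshold = 60) {
  out <- lapply(seq_along(set), function(i) {
    rec <- set[[i]]
    img <- rec$scene$mCherry
    radius <- min(200, floor(min(dim(pixels(img))) / 2))
    bs <- subtractBackground(img, radius = radius)
    regs <- segmentAggregates(bs, intensityThreshold = intensityThreshold)
    if (!length(regs)) return(NULL)
    ids <- matchRegionsToTruth(regs, rec$scene$labels)
    keep <- which(ids > 0)
    if (!length(keep)) return(NULL)
    r <- regs[[keep[1]]]   # regions are area-sorted; take the largest match
    ft <- extractFeatures(bs, r)
    ft$trueClass <- rec$classLabel
    ft$sceneIndex <- i
    ft
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Classification round trip on a labelled scene set
#'
#' Classifies the pooled feature table and scores the agreement with the
#' ground-truth classes.
#'
#' @param features output of \code{\link{analyzeSceneSet}}.
#' @param seed k-means seed.
#' @return list with \code{classes}, \code{accuracy} (fraction agreeing with
#'   \code{trueClass}), \code{confusion} (table) and \code{summary}.
#' @export
evaluateClassification <- function(features, seed = 1) {
  res <- classifyAggregates(features, seed = seed)
  acc <- mean(res$classes == features$trueClass)
  list(classes = res$classes, accuracy = acc,
       confusion = table(truth = features$trueClass, predicted = res$classes),
       summary = res$summary)
}
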