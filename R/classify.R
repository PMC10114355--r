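#' PcaModel: standardized principal components of the shape features
#'
#' @slot center,scale per-feature means and standard deviations used for
#'   z-scoring.
#' @slot loadings feature x 2 matrix of PC1/PC2 loading vectors, sign-fixed so
#'   each vector's largest-magnitude entry is positive.
#' @slot explainedVariance variance fractions for all components.
#' @slot scores n x 2 matrix of per-aggregate (PC1, PC2) scores.
#' @export
setClass("PcaModel",
  representation(center = "numeric", scale = "numeric", loadings = "matrix",
                 explainedVariance = "numeric", scores = "matrix"))

setValidity("PcaModel", function(object) {
  L <- object@loadings
  if (ncol(L) >= 2) {
    g <- crossprod(L)
    if (max(abs(g - diag(ncol(L)))) > 1e-8)
      return("loading vectors must be orthonormal")
  }
  ev <- object@explainedVariance
  if (length(ev) >= 2 && ev[1] < ev[2] - 1e-12)
    return("explained variance must be non-increasing")
  TRUE
})

setMethod("show", "PcaModel", function(object) {
  cat(sprintf("PcaModel: %d features, PC1 %.1f%% / PC2 %.1f%% variance, n = %d\n",
              nrow(object@loadings), 100 * object@explainedVariance[1],
              100 * object@explainedVariance[2], nrow(object@scores)))
})

featureColumns <- function(features) {
  cols <- grep("^f[0-9]$", names(features), value = TRUE)
  if (!length(cols)) stop("no feature columns (f1..f8) found")
  cols
}

#' Fit a PCA on the aggregate shape features
#'
#' Feature columns (f1..f7, optionally f8) are z-score standardized -- they
#' carry incompatible units -- and decomposed by \code{\link[stats]{prcomp}};
#' per-aggregate scores on the two leading components are returned. The sign
#' of each loading vector is fixed so that its largest-magnitude entry is
#' positive, making results reproducible across platforms.
#'
#' @param features data.frame from \code{\link{extractFeatureTable}}.
#' @return a \code{\link{PcaModel}}.
#' @export
fitPca <- function(features) {
  cols <- featureColumns(features)
  X <- as.matrix(features[, cols])
  if (nrow(X) < 3) stop("PCA needs at least 3 aggregates")
  if (any(!is.finite(X))) stop("features contain missing values")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("zero-variance feature column(s): ",
         paste(cols[sds == 0], collapse = ", "))
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  # sign convention
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  new("PcaModel", center = pc$center, scale = pc$scale,
      loadings = pc$rotation[, 1:2, drop = FALSE],
      explainedVariance = ev,
      scores = pc$x[, 1:2, drop = FALSE])
}

#' k-means clustering of the PC scores
#'
#' k is fixed at 4, matching the shape-classification procedure (the fourth,
#' singleton cluster is merged downstream by \code{\link{resolveClasses}}).
#' Multiple seeded restarts keep the best inertia; results are deterministic
#' for a fixed seed.
#'
#' @param scores n x 2 matrix of (PC1, PC2) scores (or a \code{PcaModel}).
#' @param k number of clusters (default 4).
#' @param seed integer seed.
#' @param nstart random restarts.
#' @return integer cluster ids (1..k).
#' @export
clusterKmeans <- function(scores, k = 4, seed = 1, nstart = 50) {
  if (is(scores, "PcaModel")) scores <- scores@scores
  if (nrow(scores) < k)
    stop("need at least k aggregates to form k clusters")
  if (nrow(unique(as.data.frame(scores))) < k)
    stop("degenerate scores: fewer distinct points than clusters")
  set.seed(as.integer(seed))
  km <- kmeans(scores, centers = k, nstart = nstart, iter.max = 100)
  as.integer(km$cluster)
}

#' Resolve k-means clusters into named morphological classes
#'
#' Two steps. (i) Outlier merge: any singleton cluster whose member is either
#' ring-flagged or PC-outlying (both |PC| scores beyond 3 standardized sd) is
#' assigned to the fibril class -- a ring is a closed fibril, and a lone
#' extreme point is not a class of its own. (ii) The remaining clusters are
#' named by feature heuristics: greatest median longest-chain length (f1)
#' becomes fibril; of the rest, the greater median branch count becomes
#' branched_fractal; the remainder are linear_fractal.
#'
#' @param clusters integer cluster ids from \code{\link{clusterKmeans}}.
#' @param features the feature table (needs f1, nBranchPoints, ringFlag).
#' @param scores the (PC1, PC2) score matrix.
#' @return character vector of class labels, one per aggregate.
#' @export
resolveClasses <- function(clusters, features, scores) {
  if (is(scores, "PcaModel")) scores <- scores@scores
  n <- length(clusters)
  stopifnot(nrow(features) == n, nrow(scores) == n)
  labels <- rep(NA_character_, n)
  sds <- apply(scores, 2, sd)
  tab <- table(clusters)
  mergedFibril <- rep(FALSE, n)
  active <- sort(unique(clusters))
  for (cl in names(tab)[tab == 1]) {
    i <- which(clusters == as.integer(cl))
    outlying <- all(abs(scores[i, ]) > 3 * sds)
    if (isTRUE(features$ringFlag[i]) || outlying) {
      mergedFibril[i] <- TRUE
      active <- setdiff(active, as.integer(cl))
    }
  }
  if (length(active) < 1) stop("no clusters left after outlier merge")
  medF1 <- vapply(active, function(cl)
    median(features$f1[clusters == cl & !mergedFibril]), numeric(1))
  # fibril: the longest-chain cluster, together with any cluster on the same
  # length scale (k-means regularly splits the decade-wide fibril lengths
  # over two clusters). Clusters sorted by median chain length; the largest
  # log-scale gap separates the fibril group from the fractal classes.
  ord <- order(medF1, decreasing = TRUE)
  fibCl <- active[ord[1]]
  if (length(active) > 2) {
    gaps <- diff(log(pmax(medF1[ord], 1e-9)))      # negative values
    cut <- which.min(gaps)                          # most negative = largest
    fibCl <- active[ord[seq_len(min(cut, length(active) - 2))]]
  }
  rest <- setdiff(active, fibCl)
  if (length(rest) >= 2) {
    medBr <- vapply(rest, function(cl)
      median(features$nBranchPoints[clusters == cl & !mergedFibril]),
      numeric(1))
    branchedCl <- rest[medBr >= 1]
    if (!length(branchedCl)) {
      restF1 <- medF1[match(rest, active)]
      ord <- rest[order(medBr, restF1, decreasing = TRUE)]
      branchedCl <- ord[1]
    }
    linearCl <- setdiff(rest, branchedCl)
    if (!length(linearCl)) {
      # everything branched: hand the least-branched cluster to linear
      medBr2 <- medBr[match(branchedCl, rest)]
      linearCl <- branchedCl[which.min(medBr2)]
      branchedCl <- setdiff(branchedCl, linearCl)
    }
  } else { branchedCl <- integer(0); linearCl <- rest }
  labels[clusters %in% fibCl & !mergedFibril] <- "fibril"
  labels[clusters %in% branchedCl & !mergedFibril] <- "branched_fractal"
  labels[clusters %in% linearCl & !mergedFibril] <- "linear_fractal"
  labels[mergedFibril] <- "fibril"
  if (anyNA(labels)) stop("class resolution left unlabeled aggregates")
  labels
}

#' Per-class proportions and median [quartile] summaries
#'
#' Proportions are percentages of all aggregates (summing to 100 within
#' rounding); medians and quartiles interpolate the order statistics linearly
#' at plotting positions (n+1)p (\code{\link[stats]{quantile}} type 6), so
#' e.g. branch counts {3,4,4,5,6} give quartiles 3.5 and 5.5. Requested
#' feature columns are summarized per class; empty classes report n = 0.
#'
#' @param classes character vector of class labels.
#' @param features the feature table.
#' @param summarize columns to summarize (default f1 and branch points).
#' @return data.frame: class, n, percent, then median/q1/q3 per column.
#' @export
classSummary <- function(classes, features,
                         summarize = c("f1", "nBranchPoints")) {
  lv <- c("linear_fractal", "branched_fractal", "fibril")
  out <- do.call(rbind, lapply(lv, function(cl) {
    sel <- classes == cl
    row <- data.frame(class = cl, n = sum(sel),
                      percent = 100 * sum(sel) / length(classes))
    for (col in summarize) {
      v <- features[[col]][sel]
      row[[paste0(col, "_median")]] <- if (length(v)) median(v) else NA_real_
      row[[paste0(col, "_q1")]] <- if (length(v))
        unname(quantile(v, 0.25, type = 6)) else NA_real_
      row[[paste0(col, "_q3")]] <- if (length(v))
        unname(quantile(v, 0.75, type = 6)) else NA_real_
    }
    row
  }))
  out
}

#' Classify a feature table end to end
#'
#' Convenience wrapper: PCA, k-means (k = 4), outlier/ring merge and class
#' naming.
#'
#' @param features feature table from \code{\link{extractFeatureTable}}.
#' @param seed k-means seed.
#' @return list with \code{pca}, \code{clusters}, \code{classes},
#'   \code{summary}.
#' @export
classifyAggregates <- function(features, seed = 1) {
  pca <- fitPca(features)
  clusters <- clusterKmeans(pca@scores, k = 4, seed = seed)
  classes <- resolveClasses(clusters, features, pca@scores)
  list(pca = pca, clusters = clusters, classes = classes,
       summary = classSummary(classes, features))
}
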