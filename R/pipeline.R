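#' Default run configuration
#'
#' Every analysis constant in one list, serializable to YAML: detection
#' thresholds (60 a.u. for morphometry, 250 a.u. for kinetics imaging, both
#' out of 65535), the strict 9-px minimum area, the 200-px rolling-ball
#' radius, 8-connectivity, k = 4 for k-means, the 10-min sampling interval,
#' pixel calibrations and the master seed.
#'
#' @return named list of configuration values.
#' @export
defaultRunConfig <- function() {
  list(pixel_size_um = 0.1625,
       intensity_threshold = 60,
       kinetics_threshold = 250,
       min_area_px = 9,
       rolling_ball_radius = 200,
       connectivity = 8,
       kmeans_k = 4,
       kmeans_restarts = 50,
       sampling_interval_min = 10,
       log_sigma_min_um = 0.15 / sqrt(2),
       log_sigma_max_um = 0.5 / sqrt(2),
       seed = 1)
}

#' Read and write run configurations (YAML)
#'
#' @param config named list.
#' @param path YAML file.
#' @return \code{readRunConfig}: the list; \code{writeRunConfig}: the path.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path, precision = 12)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validateRunConfig(cfg)
  cfg
}

validateRunConfig <- function(cfg) {
  num <- function(key, lo, hi) {
    v <- cfg[[key]]
    if (is.null(v) || !is.numeric(v) || v < lo || v > hi)
      stop(sprintf("config key '%s' must be a number in [%g, %g]", key, lo, hi))
  }
  num("intensity_threshold", 0, 65535)
  num("kinetics_threshold", 0, 65535)
  num("min_area_px", 0, Inf)
  num("rolling_ball_radius", 1, Inf)
  num("pixel_size_um", 1e-6, Inf)
  num("kmeans_k", 2, Inf)
  if (!cfg$connectivity %in% c(4, 8))
    stop("config key 'connectivity' must be 4 or 8")
  invisible(TRUE)
}

#' Read a TIFF image as a MicroImage
#'
#' 16-bit values are preserved exactly. 8-bit input is accepted and
#' up-converted to the 16-bit scale (x 257) with a message, so the standard
#' thresholds remain applicable.
#'
#' @param path TIFF file.
#' @param pixelSize,sizeUnit,channel calibration and tag for the result.
#' @param page page index for multi-page files.
#' @return a \code{\link{MicroImage}}.
#' @export
readImageTiff <- function(path, pixelSize = 0.1625, sizeUnit = "um",
                          channel = "mCherry", page = 1) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (page > length(pages)) stop("page index beyond the number of TIFF pages")
  m <- pages[[page]]
  bits <- attr(m, "bits.per.sample", exact = TRUE)
  if (length(dim(m)) == 3) m <- m[, , 1]
  if (!is.null(bits) && bits == 8) {
    message("8-bit input up-converted to the 16-bit scale (x 257)")
    m <- m * 257
  }
  attributes(m) <- list(dim = dim(m))
  MicroImage(m * 1.0, pixelSize = pixelSize, sizeUnit = sizeUnit,
             channel = channel)
}

#' Write MicroImages (or matrices) as 16-bit TIFF
#'
#' @param img a \code{\link{MicroImage}}, matrix, or list of either
#'   (multi-page output).
#' @param path output TIFF file.
#' @return the path, invisibly.
#' @export
writeImageTiff <- function(img, path) {
  asMat <- function(x) {
    m <- if (is(x, "MicroImage")) pixels(x) else x
    if (any(m < 0 | m > 65535)) stop("intensities outside the 16-bit range")
    round(m) / 65535
  }
  mats <- if (is.list(img)) lapply(img, asMat) else list(asMat(img))
  tiff::writeTIFF(mats, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a rendered scene bundle to disk
#'
#' Two-channel 16-bit TIFF (page 1 mCherry, page 2 ThT), a 16-bit label mask,
#' the ground truth as CSV (one row per aggregate) and a YAML metadata
#' sidecar (pixel size, seed, field size).
#'
#' @param scene result of \code{\link{renderScene}}.
#' @param params the \code{\link{SimParams}} used.
#' @param dir output directory (created).
#' @param name file name stem.
#' @return the directory, invisibly.
#' @export
writeScene <- function(scene, params, dir, name = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeImageTiff(list(scene$mCherry, scene$tht),
                 file.path(dir, paste0(name, ".tif")))
  writeImageTiff(matrix(as.numeric(scene$labels), nrow(scene$labels)),
                 file.path(dir, paste0(name, "_labels.tif")))
  truthDf <- do.call(rbind, lapply(seq_along(scene$truth@aggregates),
    function(i) {
      a <- scene$truth@aggregates[[i]]
      data.frame(id = i, class_label = a$classLabel,
                 n_puncta = nrow(a$centers),
                 true_longest_chain_um = a$trueLongestChain,
                 true_branch_points = a$trueBranchPoints,
                 true_width_um = a$trueWidth)
    }))
  write.csv(truthDf, file.path(dir, paste0(name, "_truth.csv")),
            row.names = FALSE)
  yaml::write_yaml(list(pixel_size_um = params@pixelSize,
                        seed = params@rngSeed,
                        psf_sigma_um = params@psfSigma,
                        background_level = params@backgroundLevel,
                        field_px = nrow(pixels(scene$mCherry))),
                   file.path(dir, paste0(name, "_meta.yaml")))
  invisible(dir)
}

#' Run the morphometry pipeline on one image
#'
#' Executes background subtraction, aggregate detection, feature extraction
#' and (when enough aggregates are present) PCA + k-means classification, and
#' writes the feature table, score/class table, class summary, resolved
#' configuration and a run log into \code{outDir}. Rerunning with the same
#' configuration and input reproduces identical tables.
#'
#' @param img a \code{\link{MicroImage}} or a TIFF path.
#' @param outDir output directory.
#' @param config configuration list (see \code{\link{defaultRunConfig}}).
#' @return list with \code{features}, \code{classes} (NULL if too few
#'   aggregates), \code{summary}, and \code{outDir}.
#' @export
runPipeline <- function(img, outDir, config = defaultRunConfig()) {
  validateRunConfig(config)
  if (is.character(img)) {
    if (!file.exists(img)) stop("input image not found: ", img)
    img <- readImageTiff(img, pixelSize = config$pixel_size_um)
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  bs <- subtractBackground(img, radius = config$rolling_ball_radius)
  regs <- segmentAggregates(bs, intensityThreshold = config$intensity_threshold,
                            minAreaExclusive = config$min_area_px,
                            connectivity = config$connectivity)
  feats <- if (length(regs)) extractFeatureTable(bs, regs,
    sigmaRange = c(config$log_sigma_min_um, config$log_sigma_max_um)) else NULL
  cls <- NULL; summ <- NULL
  if (!is.null(feats) && nrow(feats) >= config$kmeans_k + 1) {
    res <- tryCatch(classifyAggregates(feats, seed = config$seed),
                    error = function(e) NULL)
    if (!is.null(res)) {
      cls <- res$classes
      summ <- res$summary
      scoreDf <- data.frame(id = feats$id, PC1 = res$pca@scores[, 1],
                            PC2 = res$pca@scores[, 2],
                            cluster = res$clusters, class = cls)
      write.csv(scoreDf, file.path(outDir, "scores.csv"), row.names = FALSE)
      write.csv(summ, file.path(outDir, "class_summary.csv"),
                row.names = FALSE)
    }
  }
  if (!is.null(feats))
    write.csv(feats, file.path(outDir, "features.csv"), row.names = FALSE)
  cfgPath <- file.path(outDir, "run_config.yaml")
  writeRunConfig(config, cfgPath)
  log <- c(sprintf("aggremorph run %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           sprintf("seed: %d", config$seed),
           sprintf("config md5: %s", unname(tools::md5sum(cfgPath))),
           sprintf("aggregates detected: %d", length(regs)))
  writeLines(log, file.path(outDir, "run.log"))
  list(features = feats, classes = cls, summary = summ, outDir = outDir)
}
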