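regionFromMask <- function(m, value = 100) {
  img <- MicroImage(m * value, pixelSize = 1)
  segmentAggregates(img, intensityThreshold = 60, minAreaExclusive = 0)[[1]]
}

test_that("a straight line skeletonizes to two endpoints and one edge", {
  m <- matrix(0, 9, 25); m[5, 3:23] <- 1
  g <- skeletonizeRegion(regionFromMask(m), dim(m))
  expect_equal(nrow(g@nodes), 2)
  expect_equal(nrow(g@edges), 1)
  expect_equal(totalLength(g), 20)
  expect_equal(longestChainLength(g), 20)
  expect_equal(nBranchPoints(g), 0L)
  expect_false(ringFlag(g))
})

test_that("a plus-sign mask yields a single junction (one branch point)", {
  m <- matrix(0, 21, 21)
  m[11, 4:18] <- 1; m[4:18, 11] <- 1
  g <- skeletonizeRegion(regionFromMask(m), dim(m))
  expect_equal(nBranchPoints(g), 1L)
  expect_equal(sum(g@nodes$degree >= 3), 1)
  # longest chain spans two opposite arms
  expect_equal(longestChainLength(g), 14, tolerance = 0.15)
})

test_that("skeleton totals and longest chains match the exhaustive pixel-graph oracle", {
  set.seed(12)
  checked <- 0
  for (seed in 1:20) {
    set.seed(seed)
    # small random blob: dilated random walk, <= 30 px
    m <- matrix(0, 24, 24)
    r <- 12; c <- 12
    for (s in 1:9) {
      m[r, c] <- 1
      st <- sample(4, 1)
      r <- min(22, max(3, r + c(-1, 1, 0, 0)[st]))
      c <- min(22, max(3, c + c(0, 0, -1, 1)[st]))
    }
    m <- 1 * (EBImage::dilate(m, EBImage::makeBrush(3, "box")) > 0)
    if (sum(m) > 30) next
    reg <- regionFromMask(m)
    g <- skeletonizeRegion(reg, dim(m))
    skel <- matrix(FALSE, 24, 24)
    skel[aggremorph:::thinMask(m > 0)] <- TRUE
    expect_lte(longestChainLength(g), totalLength(g) + 1e-9)
    if (all(g@nodes$degree <= 2) && !ringFlag(g)) {
      # junction-free: condensed graph and pixel graph agree exactly
      expect_equal(longestChainLength(g), brutePixelLongestPath(skel),
                   tolerance = 1e-9)
      expect_equal(totalLength(g), brutePixelLongestPath(skel),
                   tolerance = 1e-9)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 10)
})

test_that("longest chain on a Y graph picks the two longest arms", {
  # constructed condensed graph: arms of 5, 7 and 9 px meeting at one node;
  # all 3 endpoint pairs enumerated by hand give 7 + 9 = 16
  mkPath <- function(len, col0) cbind(rep(1, len + 1), col0 + 0:len)
  g <- new("SkeletonGraph",
    nodes = data.frame(row = c(1, 1, 1, 1), col = c(0, 20, 40, 10),
                       degree = c(1L, 1L, 1L, 3L)),
    edges = data.frame(from = c(1L, 2L, 3L), to = c(4L, 4L, 4L),
                       length = c(5, 7, 9)),
    paths = list(mkPath(5, 0), mkPath(7, 20), mkPath(9, 40)),
    totalLength = 21, longestChainLength = 16,
    longestChainPath = matrix(0, 0, 2), nBranchPoints = 1L,
    ringFlag = FALSE, pixelSize = 1)
  lc <- longestChain(g)
  expect_equal(lc$length, 16)

  # the same topology drawn as a mask (junction merging costs at most ~1 px)
  m <- matrix(0, 32, 32)
  m[16, 6:16] <- 1          # west arm, 10 steps
  m[16:24, 16] <- 1         # south arm, 8 steps
  m[10:16, 16] <- 1         # north arm, 6 steps
  gm <- skeletonizeRegion(regionFromMask(m), dim(m))
  expect_equal(nBranchPoints(gm), 1L)
  expect_equal(longestChainLength(gm), 18, tolerance = 1)   # 10 + 8
})

test_that("a closed ring is flagged and measured by its circumference", {
  m <- matrix(0, 32, 32)
  th <- seq(0, 2 * pi, length.out = 200)
  for (t in th) m[round(16 + 9 * sin(t)), round(16 + 9 * cos(t))] <- 1
  g <- skeletonizeRegion(regionFromMask(m), dim(m))
  expect_true(ringFlag(g))
  expect_equal(longestChainLength(g), totalLength(g))
  expect_equal(longestChainLength(g), 2 * pi * 9, tolerance = 0.15 * 2 * pi * 9)
})

test_that("mean width follows the distance-transform convention", {
  # 5-px-wide bar
  m <- matrix(0, 16, 40); m[6:10, 5:35] <- 1
  reg <- regionFromMask(m)
  chain <- cbind(rep(8, 25), 8:32)
  expect_equal(meanWidthAlongChain(reg, chain, dim(m)), 5, tolerance = 1)
  # 1-px line: thinnest convention = 1 px
  m1 <- matrix(0, 9, 30); m1[5, 3:27] <- 1
  reg1 <- regionFromMask(m1)
  expect_equal(meanWidthAlongChain(reg1, cbind(rep(5, 25), 3:27), dim(m1)), 1)
  # disc of radius 8: central width ~ diameter
  md <- matrix(0, 41, 41)
  for (r in 1:41) for (c in 1:41) if ((r - 21)^2 + (c - 21)^2 <= 64) md[r, c] <- 1
  regd <- regionFromMask(md)
  expect_equal(meanWidthAlongChain(regd, cbind(21, 21), dim(md)), 16,
               tolerance = 1.5)
  expect_error(meanWidthAlongChain(reg1, cbind(1, 1), dim(m1)), "leaves")
})

test_that("LoG blob counting sees puncta but not bare fibril ridges", {
  e1 <- list(classLabel = "linear_fractal", centers = matrix(c(0, 0), 1),
             backbone = NULL, trueLongestChain = 0.5, trueBranchPoints = 0L,
             trueWidth = 0.5)
  sc1 <- renderSingle(e1, seed = 2, fieldSize = 64, noise = FALSE)
  r1 <- segmentAggregates(sc1$mCherry, minAreaExclusive = 5)[[1]]
  expect_equal(countIntensityPeaks(sc1$mCherry, r1), 1L)

  # two puncta 4 PSF sigmas apart resolve as two blobs
  cen <- rbind(c(0, 0), c(0.6, 0))
  e2 <- list(classLabel = "linear_fractal", centers = cen, backbone = NULL,
             trueLongestChain = 1, trueBranchPoints = 0L, trueWidth = 0.5)
  sc2 <- renderSingle(e2, seed = 3, fieldSize = 64, noise = FALSE)
  r2 <- segmentAggregates(sc2$mCherry, minAreaExclusive = 5)[[1]]
  expect_equal(countIntensityPeaks(sc2$mCherry, r2), 2L)

  # fibril without embedded puncta: an extended ridge, no blobs
  ef <- simulateFibril(simParams(fibrilLength = 20, embeddedPuncta = 0,
                                 rngSeed = 2))
  scf <- renderSingle(ef, seed = 2, fieldSize = 256, noise = FALSE)
  rf <- segmentAggregates(scf$mCherry)[[1]]
  expect_equal(countIntensityPeaks(scf$mCherry, rf), 0L)

  expect_error(countIntensityPeaks(sc1$mCherry, r1, sigmaRange = c(0.2, 0.1)),
               "sigmaRange")
})

test_that("the feature vector satisfies its definitional identities", {
  # straight thin fibril drawn directly: chain is the whole skeleton
  m <- matrix(0, 16, 64); m[8, 5:60] <- 100
  img <- MicroImage(m, pixelSize = 0.1625)
  reg <- segmentAggregates(img)[[1]]
  ft <- extractFeatures(img, reg)
  expect_equal(ft$f7, 100)
  expect_equal(ft$f5, 0)
  expect_equal(ft$f3 * ft$f1, ft$f2, tolerance = 1e-9)

  # two-punctum chain: f6 x f1 recovers the punctum count
  sc <- renderSingle(chainEntry(2), seed = 4, fieldSize = 64, noise = FALSE)
  r <- segmentAggregates(sc$mCherry)[[1]]
  ft2 <- extractFeatures(sc$mCherry, r)
  expect_equal(round(ft2$f6 * ft2$f1), 2)
  expect_equal(ft2$nPeaks, 2L)

  # optional eighth feature stays off by default
  expect_false("f8" %in% names(ft2))
  ft3 <- extractFeatures(sc$mCherry, r, includeTotalLength = TRUE)
  expect_true("f8" %in% names(ft3))
})

test_that("intensity scaling moves only the total-intensity feature", {
  sc <- renderSingle(chainEntry(3), seed = 9, fieldSize = 64, noise = FALSE)
  base <- pixels(sc$mCherry) - 20
  imgA <- MicroImage(base, pixelSize = 0.1625)
  imgB <- MicroImage(base * 3, pixelSize = 0.1625)
  # segment imgA and reuse its threshold-scaled counterpart for B
  rA <- segmentAggregates(imgA)[[1]]
  rB <- segmentAggregates(imgB, intensityThreshold = 180)[[1]]
  fA <- extractFeatures(imgA, rA)
  fB <- extractFeatures(imgB, rB)
  expect_equal(fB$f4, 3 * fA$f4, tolerance = 1e-9)
  for (col in c("f1", "f2", "f3", "f5", "f6", "f7"))
    expect_equal(fB[[col]], fA[[col]], tolerance = 1e-9)
})

test_that("ground-truth recovery: chains within 15 percent, branches within one", {
  rels <- c(); brOk <- c()
  for (seed in 1:25) {
    n <- 6 + seed %% 5
    e <- simulateFractalAggregate(simParams(nPuncta = n, rngSeed = seed), 2)
    sc <- renderSingle(e, seed = seed + 300, fieldSize = 128)
    bs <- subtractBackground(sc$mCherry, 60)
    regs <- segmentAggregates(bs)
    if (!length(regs)) next
    ft <- extractFeatures(bs, regs[[1]])
    rels <- c(rels, abs(ft$f1 / e$trueLongestChain - 1))
    brOk <- c(brOk, abs(ft$nBranchPoints - e$trueBranchPoints) <= 1)
  }
  expect_gte(length(rels), 20)
  expect_lte(median(rels), 0.15)
  expect_gte(mean(brOk), 0.9)
})
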