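test_that("degenerate and tangent clusters have the expected geometry", {
  e1 <- simulateFractalAggregate(simParams(nPuncta = 1, rngSeed = 1), stage = 1)
  expect_equal(nrow(e1$centers), 1)
  expect_equal(e1$trueLongestChain, 0.5)
  expect_equal(e1$trueBranchPoints, 0L)

  e2 <- simulateFractalAggregate(simParams(nPuncta = 2, rngSeed = 1), stage = 1)
  sep <- sqrt(sum((e2$centers[1, ] - e2$centers[2, ])^2))
  expect_equal(sep, 0.5, tolerance = 1e-9)
  expect_equal(e2$trueBranchPoints, 0L)
})

test_that("fractal growth conserves puncta and matches the brute-force adjacency oracle", {
  for (seed in 1:8) {
    n <- 5 + seed
    e <- simulateFractalAggregate(simParams(nPuncta = n, rngSeed = seed),
                                  stage = 2)
    expect_equal(nrow(e$centers), n)
    oracle <- bruteClusterStats(e$centers, 0.5)
    expect_true(oracle$connected)
    if (e$classLabel == "branched_fractal")
      expect_equal(e$trueBranchPoints, oracle$branchPoints)
    expect_equal(e$trueLongestChain, oracle$chainPuncta * 0.5)
    # no overlap beyond the tangency tolerance
    dm <- as.matrix(dist(e$centers))
    expect_true(min(dm[dm > 0]) >= 0.5 * 0.999)
  }
})

test_that("stage-1 chains have longest chain n x diameter and no branches", {
  for (seed in 1:5) {
    n <- 2 + seed
    e <- simulateFractalAggregate(simParams(nPuncta = n, rngSeed = seed),
                                  stage = 1)
    expect_equal(e$trueLongestChain, n * 0.5, tolerance = 1e-9)
    expect_equal(e$trueBranchPoints, 0L)
    expect_true(bruteClusterStats(e$centers, 0.5)$connected)
  }
})

test_that("fibril backbones have the requested arc length and stiffness limit", {
  e <- simulateFibril(simParams(fibrilLength = 27, rngSeed = 3))
  arc <- sum(sqrt(rowSums(diff(e$backbone)^2)))
  expect_equal(arc, 27, tolerance = 27 * 0.005)

  es <- simulateFibril(simParams(fibrilLength = 27,
                                 persistenceLength = Inf, rngSeed = 3))
  # infinite stiffness: all points collinear
  v <- diff(es$backbone)
  cross <- v[-1, 1] * v[1, 2] - v[-1, 2] * v[1, 1]
  expect_lt(max(abs(cross)), 1e-9)
  expect_equal(sum(sqrt(rowSums(v^2))), 27, tolerance = 1e-9)

  expect_error(simulateFibril(simParams(persistenceLength = -1)),
               "persistenceLength|positive")
})

test_that("embedded puncta sit on the fibril backbone", {
  e <- simulateFibril(simParams(fibrilLength = 20, embeddedPuncta = 2,
                                rngSeed = 5))
  expect_equal(nrow(e$centers), 2)
  # point-to-polyline distance oracle
  segDist <- function(p, a, b) {
    ab <- b - a; t <- sum((p - a) * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    sqrt(sum((a + t * ab - p)^2))
  }
  for (k in 1:2) {
    dmin <- min(vapply(seq_len(nrow(e$backbone) - 1), function(i)
      segDist(e$centers[k, ], e$backbone[i, ], e$backbone[i + 1, ]),
      numeric(1)))
    expect_lt(dmin, 0.25)
  }
})

test_that("rendering: empty truth, no-shift identity, centroid accuracy", {
  p <- simParams(rngSeed = 7, noise = FALSE)
  sc0 <- renderScene(GroundTruth(list()), p, fieldSize = 64)
  expect_equal(unique(as.vector(pixels(sc0$mCherry))), p@backgroundLevel)
  expect_true(all(sc0$labels == 0))

  e <- chainEntry(3)
  sc <- renderSingle(e, seed = 7, fieldSize = 64, noise = FALSE)
  expect_identical(pixels(sc$mCherry), pixels(sc$tht))

  e1 <- list(classLabel = "linear_fractal",
             centers = matrix(c(0, 0), 1), backbone = NULL,
             trueLongestChain = 0.5, trueBranchPoints = 0L, trueWidth = 0.5)
  sc1 <- renderSingle(e1, seed = 5, fieldSize = 64, noise = FALSE)
  m <- pixels(sc1$mCherry) - 20
  ii <- which(m > 0, arr.ind = TRUE)
  w <- m[m > 0] / sum(m[m > 0])
  cen <- c(sum(ii[, 1] * w), sum(ii[, 2] * w))
  truthC <- sc1$truth@aggregates[[1]]$centers
  expect_lt(abs(cen[1] - (truthC[2] / 0.1625 + 1)), 0.05)
  expect_lt(abs(cen[2] - (truthC[1] / 0.1625 + 1)), 0.05)
})

test_that("the injected chromatic shift is an exact translation before noise", {
  e <- chainEntry(3)
  scA <- renderSingle(e, seed = 11, fieldSize = 64, noise = FALSE)
  scB <- renderSingle(e, seed = 11, fieldSize = 64, noise = FALSE,
                      chromaticShift = c(3, -2))
  a <- pixels(scA$mCherry); b <- pixels(scB$tht)
  # b(r, c) = a(r + 2, c - 3) on the valid interior
  expect_equal(b[1:60, 4:64], a[3:62, 1:61], tolerance = 1e-9)
})

test_that("scenes are bit-identical for identical SimParams", {
  p <- simParams(rngSeed = 42, nPuncta = 6)
  e1 <- simulateFractalAggregate(p, 2)
  e2 <- simulateFractalAggregate(p, 2)
  expect_identical(e1, e2)
  s1 <- renderScene(GroundTruth(list(e1)), p, fieldSize = 96)
  s2 <- renderScene(GroundTruth(list(e2)), p, fieldSize = 96)
  expect_identical(pixels(s1$mCherry), pixels(s2$mCherry))
  expect_identical(pixels(s1$tht), pixels(s2$tht))
})

test_that("rendering errors on 16-bit overflow and rejects empty clusters", {
  e <- chainEntry(2)
  expect_error(renderSingle(e, seed = 1, fieldSize = 64,
                            punctumAmplitude = 1e9), "65535")
  expect_error(simParams(nPuncta = 0), "nPuncta")
})

test_that("simulated kinetics match the logistic and its lag convention", {
  flat <- simulateKinetics(kineticsParams(amplitude = 0, baseline = 500))
  expect_true(all(traceIntensity(flat) == 500))

  kp <- kineticsParams(lagTime = 300, growthRate = 0.01, amplitude = 1e5,
                       baseline = 1000)
  tr <- simulateKinetics(kp)
  tMid <- 300 + 2 / 0.01
  yMid <- approx(traceTimes(tr), traceIntensity(tr), xout = tMid)$y
  expect_equal(yMid, 1000 + 1e5 / 2, tolerance = 1e5 * 1e-3)

  seeded <- simulateKinetics(kineticsParams(lagTime = 80, seeded = TRUE))
  unseeded <- simulateKinetics(kineticsParams(lagTime = 300))
  half <- function(x) traceTimes(x)[min(which(traceIntensity(x) >=
    min(traceIntensity(x)) + diff(range(traceIntensity(x))) / 2))]
  expect_lt(half(seeded), half(unseeded))
  expect_identical(condition(seeded), "seeded")

  expect_error(kineticsParams(amplitude = -1), "amplitude")
})

test_that("TEM ribbon edge peaks sit exactly one width apart", {
  for (w in c(150, 1200)) {
    nmpp <- if (w > 400) 10 else 1
    img <- renderTemFibril(w, 1500, nmPerPx = nmpp, noiseSigma = 0)
    mat <- pixels(img)
    col <- mat[, ncol(mat) %/% 2]
    pk <- which(diff(sign(diff(col))) < 0) + 1
    pk <- pk[order(col[pk], decreasing = TRUE)][1:2]
    expect_equal(abs(diff(pk)) * nmpp, w, tolerance = w * 0.02)
  }
  # zero twist amplitude: width constant along the whole axis
  img <- renderTemFibril(100, 800, nmPerPx = 1, twistAmplitude = 0)
  tr <- straightenFibril(img, data.frame(x = c(25, 800), y = rep((nrow(pixels(img)) + 1) / 2, 2)),
                         halfWindow = 70)
  wp <- profileWidth(tr)
  expect_lt(diff(range(fibrilWidths(wp)[is.finite(fibrilWidths(wp))])), 2)
  expect_error(renderTemFibril(2, 100, nmPerPx = 1), "unresolvable|3 pixels")
})
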