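test_that("straightening a straight horizontal trace reproduces the band", {
  set.seed(1)
  m <- aggremorph:::convolve2d(matrix(runif(80 * 200, 0, 1000), 80, 200),
                               aggremorph:::gaussianKernel(1))
  img <- MicroImage(m, pixelSize = 2, sizeUnit = "nm", channel = "TEM")
  tr <- straightenFibril(img, data.frame(x = c(20, 180), y = c(40, 40)),
                         halfWindow = 20)
  expect_equal(dim(tr@straightened), c(41, 161))
  # rows are offsets -20..20 about y = 40; compare to the direct crop
  expect_equal(tr@straightened, m[20:60, 20:180], tolerance = 1e-9)
  expect_error(straightenFibril(img,
    data.frame(x = c(50, 50), y = c(40, 40)), 10), "coincide")
  expect_error(straightenFibril(img,
    data.frame(x = c(20, 180), y = c(40, 40)), 60), "frame")
})

test_that("a curved trace over a constant-width ribbon straightens to constant extent", {
  # ribbon of constant width 30 px around a quarter circle of radius 120
  n <- 200
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  rad <- sqrt((rows - 10)^2 + (cols - 10)^2)
  img <- MicroImage(1000 * exp(-(abs(rad - 120) - 15)^2 / 8),
                    pixelSize = 1, sizeUnit = "nm", channel = "TEM")
  th <- seq(0.15, pi / 2 - 0.15, length.out = 60)
  poly <- data.frame(x = 10 + 120 * cos(th), y = 10 + 120 * sin(th))
  tr <- straightenFibril(img, poly, halfWindow = 30)
  wp <- profileWidth(tr)
  w <- fibrilWidths(wp)
  expect_gt(wp@nColumns, 100)
  expect_lt(diff(range(w[is.finite(w)])), 2)
  expect_equal(wp@median, 30, tolerance = 1)
})

test_that("two delta rows give the exact peak separation in every column", {
  m <- matrix(0, 60, 50)
  m[10, ] <- 500; m[50, ] <- 500
  img <- MicroImage(m, pixelSize = 3, sizeUnit = "nm", channel = "TEM")
  tr <- straightenFibril(img, data.frame(x = c(2, 48), y = c(30, 30)),
                         halfWindow = 25)
  wp <- profileWidth(tr)
  w <- fibrilWidths(wp)
  expect_true(all(abs(w[is.finite(w)] - 40 * 3) < 1e-6))
  expect_equal(wp@q1, wp@median)
  expect_equal(wp@q3, wp@median)
})

test_that("synthetic TEM ribbons are measured at their nominal widths", {
  for (w in c(150, 1200)) {
    nmpp <- if (w > 400) 10 else 1
    img <- renderTemFibril(w, 1500, nmPerPx = nmpp, noiseSigma = 200,
                           rngSeed = 4)
    nr <- nrow(pixels(img)); nc <- ncol(pixels(img))
    tr <- straightenFibril(img, data.frame(x = c(25, nc - 25),
                                           y = rep((nr + 1) / 2, 2)),
                           halfWindow = floor(nr / 2) - 2)
    wp <- profileWidth(tr)
    expect_equal(wp@median, w, tolerance = 0.05 * w)
    expect_true(wp@q1 <= wp@median && wp@median <= wp@q3)
  }
})

test_that("per-column widths track a twist modulation", {
  img <- renderTemFibril(150, 2000, nmPerPx = 1, twistAmplitude = 0.3,
                         twistPeriodNm = 600, noiseSigma = 0)
  nr <- nrow(pixels(img)); nc <- ncol(pixels(img))
  tr <- straightenFibril(img, data.frame(x = c(25, nc - 25),
                                         y = rep((nr + 1) / 2, 2)),
                         halfWindow = floor(nr / 2) - 2)
  w <- fibrilWidths(profileWidth(tr))
  s <- (seq_along(w) - 1)   # nm along the axis (1 nm/px), axis starts at x=25
  expected <- 150 * (1 + 0.3 * sin(2 * pi * (s + 5) / 600))
  ok <- is.finite(w)
  relErr <- abs(w[ok] - expected[ok]) / expected[ok]
  expect_lt(median(relErr), 0.05)
})

test_that("width estimates are invariant to intensity scale and offset", {
  img <- renderTemFibril(200, 800, nmPerPx = 2, noiseSigma = 0)
  nr <- nrow(pixels(img)); nc <- ncol(pixels(img))
  poly <- data.frame(x = c(25, nc - 25), y = rep((nr + 1) / 2, 2))
  hw <- floor(nr / 2) - 2
  w1 <- profileWidth(straightenFibril(img, poly, hw))@median
  img2 <- MicroImage(pixels(img) * 4 + 1000, pixelSize = 2, sizeUnit = "nm",
                     channel = "TEM")
  w2 <- profileWidth(straightenFibril(img2, poly, hw))@median
  expect_equal(w1, w2, tolerance = 1e-9)
})
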