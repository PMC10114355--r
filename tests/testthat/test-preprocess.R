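# a textured test field with structure in every quadrant
texturedImage <- function(seed = 1, n = 64) {
  set.seed(seed)
  base <- matrix(runif(n * n, 0, 100), n, n)
  MicroImage(aggremorph:::convolve2d(base, aggremorph:::gaussianKernel(1.5)))
}

roisFor <- function(n = 64) data.frame(row = c(20, 20, n - 20, n - 20),
                                       col = c(20, n - 20, 20, n - 20))

test_that("translation estimation recovers identity, integer and subpixel shifts", {
  ref <- texturedImage(1)
  est0 <- estimateTranslation(ref, ref, roisFor())
  expect_equal(c(est0@dx, est0@dy), c(0, 0), tolerance = 1e-6)

  movI <- MicroImage(aggremorph:::translateImage(pixels(ref), 3, -2))
  estI <- estimateTranslation(ref, movI, roisFor())
  expect_equal(c(estI@dx, estI@dy), c(3, -2), tolerance = 1e-6)

  movS <- MicroImage(aggremorph:::translateImage(pixels(ref), 0.5, 0.25))
  estS <- estimateTranslation(ref, movS, roisFor())
  expect_lt(abs(estS@dx - 0.5), 0.25)
  expect_lt(abs(estS@dy - 0.25), 0.25)
})

test_that("stack averaging and ROI validation work", {
  ref <- texturedImage(2)
  stack <- list(ref, ref, ref)
  est <- estimateTranslation(stack, stack, roisFor())
  expect_equal(c(est@dx, est@dy), c(0, 0), tolerance = 1e-6)

  flat <- MicroImage(matrix(50, 64, 64))
  expect_error(estimateTranslation(flat, flat, roisFor()), "variance")
  expect_error(estimateTranslation(ref, ref,
                                   data.frame(row = 1, col = 1)), "ROI")
})

test_that("applying a shift inverts it; integer round trips are exact", {
  ref <- texturedImage(3)
  expect_identical(pixels(applyTranslation(ref, shiftParams(0, 0))),
                   pixels(ref))

  fwd <- MicroImage(aggremorph:::translateImage(pixels(ref), 2, 1))
  back <- applyTranslation(fwd, shiftParams(2, 1))
  inner <- 4:60
  expect_equal(pixels(back)[inner, inner], pixels(ref)[inner, inner],
               tolerance = 1e-12)
  expect_false(all(validMask(back)))   # border marked invalid

  expect_error(applyTranslation(ref, shiftParams(99, 0)), "radius")
})

test_that("registration residual stays below 0.25 px across random shifts", {
  set.seed(20)
  ref <- texturedImage(4)
  for (i in 1:20) {
    sh <- runif(2, -3, 3)
    mov <- MicroImage(aggremorph:::translateImage(pixels(ref), sh[1], sh[2]))
    est <- estimateTranslation(ref, mov, roisFor())
    corr <- applyTranslation(mov, est)
    res <- estimateTranslation(ref, corr, roisFor())
    expect_lt(max(abs(c(res@dx, res@dy))), 0.25)
  }
})

test_that("rolling-ball subtraction flattens backgrounds and keeps puncta", {
  flat <- MicroImage(matrix(123.4, 96, 96))
  out <- subtractBackground(flat, radius = 30)
  expect_lt(max(abs(pixels(out))), 1e-6)

  # punctum far narrower than the ball survives nearly unchanged
  g <- aggremorph:::gaussianKernel(1.2)
  spot <- matrix(0, 128, 128); spot[64, 64] <- 1000
  spotF <- aggremorph:::convolve2d(spot, g)
  img <- MicroImage(matrix(100, 128, 128) + spotF)
  sub <- subtractBackground(img, radius = 60)
  expect_equal(max(pixels(sub)), max(spotF), tolerance = 0.05 * max(spotF))

  # gentle linear ramp is removed away from the border
  ramp <- MicroImage(matrix(rep(seq(100, 160, length.out = 256), each = 256),
                            256, byrow = FALSE))
  res <- pixels(subtractBackground(ramp, radius = 32))
  expect_lt(max(res[49:208, 49:208]), 0.02 * 60)

  expect_error(subtractBackground(flat, radius = 0), "radius")
  expect_error(subtractBackground(flat, radius = 96), "radius")
})

test_that("background subtraction is idempotent and preserves geometry", {
  # realistic field: sparse aggregates on an offset with a gentle gradient
  e <- chainEntry(3)
  sc <- renderSingle(e, seed = 13, fieldSize = 256, noise = FALSE)
  grad <- matrix(rep(seq(0, 20, length.out = 256), each = 256), 256,
                 byrow = FALSE)
  img <- MicroImage(pixels(sc$mCherry) + grad, pixelSize = 0.1625)
  b1 <- subtractBackground(img, radius = 32)
  b2 <- subtractBackground(b1, radius = 32)
  inner <- 49:208
  expect_lt(max(abs(pixels(b2) - pixels(b1))[inner, inner]),
            0.02 * diff(range(pixels(img))))
  expect_identical(dim(pixels(b1)), dim(pixels(img)))
  expect_identical(pixelSize(b1), 0.1625)
})
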