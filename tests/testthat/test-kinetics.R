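blockFrame <- function(value, rows = 15:16, cols = 10:15, n = 32, bg = 0) {
  m <- matrix(bg, n, n)
  m[rows, cols] <- value
  MicroImage(m, channel = "ThT")
}

test_that("trace extraction sums intensity over detected aggregates", {
  blankStack <- replicate(5, MicroImage(matrix(0, 32, 32), channel = "ThT"))
  tr <- extractTrace(blankStack)
  expect_true(all(traceIntensity(tr) == 0))
  expect_equal(traceTimes(tr), seq(0, 40, by = 10))

  # one static 2 x 6 block of 300 a.u.: 3600 a.u. per frame
  stack <- replicate(4, blockFrame(300), simplify = FALSE)
  tr2 <- extractTrace(stack)
  expect_true(all(traceIntensity(tr2) == 3600))

  expect_error(extractTrace(stack, times = c(0, 10, 15, 40)), "uniform")
})

test_that("trace extraction is additive over disjoint aggregates", {
  mk <- function(both) {
    m <- matrix(0, 48, 48)
    m[5:6, 5:10] <- 300
    if (both) m[30:31, 30:35] <- 400
    MicroImage(m, channel = "ThT")
  }
  one <- extractTrace(replicate(3, mk(FALSE), simplify = FALSE))
  two <- extractTrace(replicate(3, mk(TRUE), simplify = FALSE))
  expect_equal(traceIntensity(two) - traceIntensity(one), rep(4800, 3))
})

test_that("blank subtraction behaves like pointwise difference", {
  t <- seq(0, 100, by = 10)
  a <- KineticsTrace(t, 100 + t)
  b <- KineticsTrace(t, rep(100, 11), condition = "blank")
  expect_equal(traceIntensity(blankSubtract(a, a)), rep(0, 11))
  z <- KineticsTrace(t, rep(0, 11), condition = "blank")
  expect_equal(traceIntensity(blankSubtract(a, z)), traceIntensity(a))
  expect_equal(traceIntensity(blankSubtract(a, b)), as.numeric(t))
  expect_error(blankSubtract(a, KineticsTrace(t + 1, rep(0, 11))), "grid")
})

test_that("sigmoid fits recover the tangent-intercept lag convention", {
  tr <- simulateKinetics(kineticsParams(lagTime = 300, growthRate = 0.01,
                                        amplitude = 3e5, baseline = 1000))
  fit <- fitSigmoid(tr)
  expect_lt(abs(lagTime(fit) - 300), 10)
  expect_equal(fit@plateauTime, fit@tMid + log(19) / fit@growthRate)
  expect_lt(fit@rmse, 1)

  flat <- fitSigmoid(KineticsTrace(seq(0, 200, 10), rep(50, 21)))
  expect_false(flat@lagDefined)
  expect_equal(flat@amplitude, 0)
  expect_true(is.na(lagTime(flat)))

  expect_error(fitSigmoid(KineticsTrace(c(0, 10), c(1, 2))), "10 time points")
})

test_that("seeded traces fit with a shorter lag than unseeded ones", {
  su <- fitSigmoid(simulateKinetics(kineticsParams(lagTime = 300,
    replicateNoiseSigma = 5e3, rngSeed = 2)))
  ss <- fitSigmoid(simulateKinetics(kineticsParams(lagTime = 80, seeded = TRUE,
    replicateNoiseSigma = 5e3, rngSeed = 3)))
  expect_lt(lagTime(ss), lagTime(su))
  expect_lt(lagTime(ss), 100)
})

test_that("lag recovery across noisy replicates is essentially unbiased", {
  lags <- vapply(1:60, function(i) {
    tr <- simulateKinetics(kineticsParams(lagTime = 300, growthRate = 0.01,
      amplitude = 3e5, baseline = 1000, replicateNoiseSigma = 0.05 * 3e5,
      rngSeed = i), replicateId = i)
    lagTime(fitSigmoid(tr))
  }, numeric(1))
  expect_lt(abs(mean(lags) - 300) / 300, 0.05)           # bias < 5 %
  expect_lt(sqrt(mean((lags - 300)^2)) / 300, 0.10)      # rmse < 10 %
})

test_that("condition summaries aggregate replicates correctly", {
  mkFit <- function(lag, cond, id) {
    tr <- simulateKinetics(kineticsParams(lagTime = lag,
      seeded = cond == "seeded"), replicateId = id)
    fitSigmoid(tr)
  }
  same <- list(mkFit(300, "unseeded", 1), mkFit(300, "unseeded", 2))
  cmpS <- compareConditions(same)
  expect_equal(cmpS$table$lag_sd[1], 0, tolerance = 1e-6)

  fits <- list(mkFit(290, "unseeded", 1), mkFit(300, "unseeded", 2),
               mkFit(310, "unseeded", 3), mkFit(80, "seeded", 1))
  cmp <- compareConditions(fits)
  un <- cmp$table[cmp$table$condition == "unseeded", ]
  expect_equal(un$lag_mean, 300, tolerance = 1)
  expect_equal(un$lag_sd, 10, tolerance = 1)
  expect_gt(cmp$lagReduction, 0)
  se <- cmp$table[cmp$table$condition == "seeded", ]
  expect_true(is.na(se$lag_sd))
})

test_that("kinetics CSV round-trips in wide and long formats", {
  t <- seq(0, 100, by = 10)
  traces <- list(KineticsTrace(t, t + 1, replicateId = 1L),
                 KineticsTrace(t, t * 2, replicateId = 2L))
  f <- tempfile(fileext = ".csv")
  writeKineticsCsv(traces, f)
  back <- readKineticsCsv(f, format = "long")
  expect_length(back, 2)
  expect_equal(traceIntensity(back[[2]]), t * 2)

  wide <- data.frame(time_min = t, r1 = t + 1, r2 = t * 2)
  fw <- tempfile(fileext = ".csv")
  write.csv(wide, fw, row.names = FALSE)
  backW <- readKineticsCsv(fw, format = "wide", condition = "seeded")
  expect_length(backW, 2)
  expect_identical(condition(backW[[1]]), "seeded")
  expect_equal(traceIntensity(backW[[1]]), t + 1)
})
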