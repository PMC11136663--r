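flatTrace <- function(n = 40, value = 100, dt = 30)
  CaTrace((seq_len(n) - 1) * dt, rep(value, n))

test_that("stable-baseline search matches a brute-force window scan", {
  expect_equal(findStableBaseline(flatTrace()), c(1L, 10L))
  # initial transient pushes the window later
  v <- c(500, 450, 400, 300, 200, rep(100, 35))
  tr <- CaTrace((0:39) * 30, v)
  got <- findStableBaseline(tr)
  expect_equal(got, bruteBaseline(v))
  expect_gte(got[1], 6L)
  # randomized traces agree with the oracle
  set.seed(71)
  for (i in 1:20) {
    v <- 100 + stats::rnorm(60, sd = sample(c(1, 4, 8), 1))
    v[sample(60, 5)] <- v[sample(60, 5)] + 50
    b <- bruteBaseline(v)
    if (is.null(b))
      expect_error(findStableBaseline(v),
                   class = "pco_error_no_stable_baseline")
    else expect_equal(unname(findStableBaseline(v)), b)
  }
  # everywhere-noisy trace has no stable run
  set.seed(5)
  noisy <- 100 + stats::rnorm(40, sd = 30)
  expect_error(findStableBaseline(pmax(noisy, 1)),
               class = "pco_error_no_stable_baseline")
})

test_that("dF/F0 follows (F - F0)/F0", {
  tr <- CaTrace((0:29) * 30, c(rep(100, 10), rep(300, 10), rep(500, 10)))
  dff <- computeDff(tr, baseline = c(1L, 10L))
  expect_equal(baselineF0(dff), 100)
  expect_equal(dffValues(dff)[1:10], rep(0, 10))
  expect_equal(dffValues(dff)[11], 2)   # 3x baseline
  expect_equal(dffValues(dff)[21], 4)   # 5x baseline: the CaOscL criterion
  # invariant to multiplicative rescaling of the raw trace
  tr2 <- CaTrace(traceTimes(tr), 7.3 * traceValues(tr))
  expect_equal(dffValues(computeDff(tr2, c(1L, 10L))), dffValues(dff))
  expect_error(computeDff(tr, baseline = c(1L, 100L)),
               class = "pco_error_invalid_baseline")
})

test_that("bleach correction inverts a pure exponential decay", {
  t <- (0:99) * 30
  tr <- CaTrace(t, 200 * exp(-5e-5 * t))
  corr <- correctBleaching(tr)
  v <- traceValues(corr)
  expect_lt(max(abs(v / mean(v) - 1)), 1e-6)   # constant after inversion
  expect_equal(traceMeta(corr)$bleach$rate, 5e-5, tolerance = 1e-4)
  # a constant trace passes through unchanged
  ct <- flatTrace(60)
  expect_equal(traceValues(correctBleaching(ct)), traceValues(ct),
               tolerance = 1e-9)
})

test_that("bleach rate is recovered within 5% on event-laden traces", {
  out <- generateTrace(osmolarityToParams(535, "WT", seed = 12))
  # with the ground-truth event mask
  mask <- truthEventMask(out$trace, out$truth)
  corr <- correctBleaching(out$trace, eventMask = mask)
  expect_equal(traceMeta(corr)$bleach$model, "exponential")
  expect_lt(abs(traceMeta(corr)$bleach$rate - 2e-5) / 2e-5, 0.05)
  # and with the internal fit -> detect -> refit scheme
  corr2 <- correctBleaching(out$trace)
  expect_lt(abs(traceMeta(corr2)$bleach$rate - 2e-5) / 2e-5, 0.05)
})

test_that("corrected dF/F0 recovers true event peaks on noise-free traces", {
  out <- generateTrace(osmolarityToParams(420, "WT", noiseSd = 0,
                                          seed = 21))
  dff <- preprocessTrace(out$trace)
  ev <- detectSpikes(dff, detectionConfig())
  truth <- out$truth$events
  expect_equal(nrow(ev), nrow(truth))
  relErr <- abs(ev$peak_dff - truth$peakDff) / truth$peakDff
  expect_lt(max(relErr), 0.02)
})

test_that("ratiometric traces behave like raw traces", {
  t <- (0:29) * 2
  num <- CaTrace(t, rep(300, 30), roiId = "r_ch1")
  den <- CaTrace(t, rep(150, 30), roiId = "r_ch2")
  expect_equal(unique(traceValues(ratiometricTrace(num, den))), 2)
  expect_equal(unique(traceValues(ratiometricTrace(num, num))), 1)
  off <- CaTrace(t + 1, rep(150, 30))
  expect_error(ratiometricTrace(num, off), class = "pco_error_alignment")
  # zero denominator values are rejected by the trace container upstream;
  # a tiny positive denominator is the legal edge
  tiny <- CaTrace(t, rep(1e-6, 30))
  expect_equal(unique(traceValues(ratiometricTrace(num, tiny))), 3e8)
})

test_that("a constant time offset only shifts time stamps", {
  out <- generateTrace(osmolarityToParams(535, "WT", noiseSd = 0,
                                          seed = 31))
  tr <- out$trace
  shifted <- CaTrace(traceTimes(tr) + 1234, traceValues(tr),
                     meta = traceMeta(tr))
  a <- preprocessTrace(tr)
  b <- preprocessTrace(shifted)
  expect_equal(dffValues(b), dffValues(a), tolerance = 1e-8)
  expect_equal(baselineF0(b), baselineF0(a), tolerance = 1e-8)
})
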