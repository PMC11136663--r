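test_that("a flat trace yields no events", {
  dff <- DffTrace((0:59) * 30, rep(0, 60))
  expect_equal(nrow(detectSpikes(dff)), 0L)
})

test_that("two bumps of known height are found with their peaks and classes", {
  dff <- bumpDff(c(200, 300), c(1.5, 4.5))
  ev <- detectSpikes(dff, detectionConfig())
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$peak_time_s, c(200, 300))
  expect_equal(ev$peak_dff, c(1.5, 4.5), tolerance = 1e-6)
  expect_equal(ev$class, c("small", "large"))
  expect_true(all(ev$onset_s < ev$peak_time_s))
  expect_true(all(ev$offset_s > ev$peak_time_s))
  expect_equal(ev$duration_s, ev$offset_s - ev$onset_s)
  # agrees with the exhaustive frame scan
  br <- bruteDetect(dff)
  expect_equal(ev$peak_time_s, br$peak_time_s)
  expect_equal(ev$class, br$class)
})

test_that("classification uses the five-times-baseline boundary", {
  cfg <- detectionConfig()
  expect_equal(classifySpikes(c(1.5, 4.0, 3.999), cfg),
               c("small", "large", "small"))
  # threshold-monotone: raising the boundary never turns small into large
  set.seed(9)
  peaks <- stats::runif(200, 1, 7)
  base <- classifySpikes(peaks, cfg)
  higher <- classifySpikes(peaks, detectionConfig(largeMinDff = 5))
  expect_true(all(!(base == "small" & higher == "large")))
})

test_that("noise-free generator events are recovered exactly", {
  for (s in c(3, 14)) {
    out <- generateTrace(osmolarityToParams(535, "WT", noiseSd = 0,
                                            seed = s))
    res <- analyzeTrace(out$trace)
    truth <- out$truth$events
    expect_equal(nrow(res$events), nrow(truth))
    expect_true(all(abs(res$events$peak_time_s - truth$peakTimeS) <= 30))
    expect_identical(res$events$class, truth$class)
  }
})

test_that("spike metrics summarize counts, periods and frequencies", {
  m0 <- spikeMetrics(detectSpikes(DffTrace((0:29) * 30, rep(0, 30))), 870)
  expect_equal(m0$count, c(0L, 0L))
  expect_true(all(is.na(m0$amp_mean)))
  expect_equal(m0$freq_per_min, c(0, 0))
  ev <- data.frame(roi_id = "r", peak_time_s = c(0, 300, 600),
                   peak_dff = c(5, 5.5, 6), trough_dff = 0,
                   onset_s = c(0, 290, 590), offset_s = c(60, 360, 660),
                   duration_s = 60, class = "large",
                   stringsAsFactors = FALSE)
  m <- spikeMetrics(ev, 900)
  lg <- m[m$class == "large", ]
  expect_equal(lg$count, 3L)
  expect_equal(lg$period_mean, 300)
  expect_equal(lg$freq_per_min, 0.2)
  expect_equal(lg$amp_mean, 5.5)
  expect_equal(lg$amp_pt_mean, 5.5)
  expect_equal(lg$first_event_s, 0)
})

test_that("recovered periods match generator truth on noise-free traces", {
  for (s in c(2, 8)) {
    out <- generateTrace(osmolarityToParams(420, "WT", noiseSd = 0,
                                            seed = s))
    res <- analyzeTrace(out$trace)
    for (cl in c("small", "large")) {
      tp <- out$truth$events$peakTimeS[out$truth$events$class == cl]
      truePeriod <- mean(diff(tp))
      got <- res$metrics$period_mean[res$metrics$class == cl]
      expect_lt(abs(got - truePeriod), 30)   # one frame interval
    }
  }
})

test_that("detection is equivariant to time shifts", {
  dff <- bumpDff(c(150, 320, 450), c(2, 6, 1.4))
  a <- detectSpikes(dff)
  b <- detectSpikes(DffTrace(traceTimes(dff) + 500, dffValues(dff)))
  expect_equal(b$peak_time_s, a$peak_time_s + 500)
  expect_equal(b$peak_dff, a$peak_dff)
  expect_equal(b$class, a$class)
})

test_that("detector agrees with the exhaustive frame scan on varied traces", {
  cfgG <- detectionConfig()
  cfgS <- detectionConfig(mode = "shock")
  checkOne <- function(dff, cfg) {
    ev <- detectSpikes(dff, cfg)
    br <- bruteDetect(dff, cfg)
    expect_equal(ev$peak_time_s, br$peak_time_s)
    expect_equal(ev$peak_dff, br$peak_dff)
    expect_equal(ev$class, br$class)
  }
  for (s in 1:4) {
    out <- generateTrace(osmolarityToParams(c(350, 535, 680, 420)[s],
                                            "WT", seed = s,
                                            noiseSd = c(0, 2, 5, 2)[s]))
    checkOne(preprocessTrace(out$trace), cfgG)
  }
  ps <- osmolarityToParams(600, "WT", mode = "shock", nShocks = 2,
                           desensitizationFactor = 0.7, seed = 5)
  checkOne(preprocessTrace(generateShockTrace(ps)$trace, mode = "shock"),
           cfgS)
  checkOne(bumpDff(c(100, 200, 260), c(1.2, 7, 4.1)), cfgG)
})
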