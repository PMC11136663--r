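mkEvents <- function(peaks, classes, halfWidth = 30) {
  data.frame(roi_id = "r", peak_time_s = peaks, peak_dff = ifelse(
    classes == "large", 5.5, 1.5), trough_dff = 0,
    onset_s = peaks - halfWidth, offset_s = peaks + halfWidth,
    duration_s = 2 * halfWidth, class = classes, stringsAsFactors = FALSE)
}

test_that("an all-quiet trace is a single first resting phase", {
  segs <- segmentPhases(detectSpikes(DffTrace((0:99) * 30, rep(0, 100))),
                        c(0, 2970))
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$label, "RePh1")
  expect_equal(c(segs$start_s, segs$end_s), c(0, 2970))
})

test_that("the canonical five-phase anatomy is labelled in order", {
  ev <- mkEvents(c(3000, 3300, 3600, 4200, 4500, 9000, 9400, 9800, 10200),
                 c(rep("small", 5), rep("large", 4)))
  segs <- segmentPhases(ev, c(0, 18000))
  expect_equal(segs$label, c("RePh1", "CaOscS", "RePh2", "CaOscL", "RePh3"))
  expect_equal(segs$class, c("rest", "small", "rest", "large", "rest"))
  # tiling without overlap
  expect_equal(segs$start_s[-1], segs$end_s[-nrow(segs)])
  expect_equal(segs$start_s[1], 0)
  expect_equal(segs$end_s[nrow(segs)], 18000)
  # event counts live in the oscillation segments
  expect_equal(segs$n_events, c(0L, 5L, 0L, 4L, 0L))
  expect_equal(countModules(segs), 1L)
})

test_that("a large event inside a small run splits the run at its onset", {
  ev <- mkEvents(c(1000, 1300, 1600, 1900, 2200),
                 c("small", "small", "large", "small", "large"))
  segs <- segmentPhases(ev, c(0, 6000))
  oscs <- segs[segs$class != "rest", ]
  expect_equal(oscs$class, c("small", "large"))
  expect_equal(oscs$end_s[1], 1600 - 30)     # first large event's onset
  expect_equal(oscs$start_s[2], 1600 - 30)
  expect_equal(oscs$n_events, c(2L, 3L))     # remainder promoted to CaOscL
  expect_equal(countModules(segs), 1L)
})

test_that("module counting requires a small train followed by a large train", {
  onlySmall <- segmentPhases(mkEvents(c(1000, 1200), c("small", "small")),
                             c(0, 4000))
  expect_equal(countModules(onlySmall), 0L)
  onlyLarge <- segmentPhases(mkEvents(c(1000, 1200), c("large", "large")),
                             c(0, 4000))
  expect_equal(countModules(onlyLarge), 0L)
  two <- mkEvents(c(1000, 1200, 2400, 2600, 4000, 4200, 5400, 5600),
                  rep(c("small", "small", "large", "large"), 2))
  expect_equal(countModules(segmentPhases(two, c(0, 7000))), 2L)
})

test_that("segmentation recovers generator phase structure", {
  for (r in 1:3) {
    p <- osmolarityToParams(535, "WT", noiseSd = 0, moduleRepeats = r,
                            seed = 40 + r)
    out <- generateTrace(p)
    res <- analyzeTrace(out$trace)
    expect_equal(res$nModules, r)
    truth <- out$truth$phases
    osc <- truth[truth$class != "none" & truth$nEvents > 0, ]
    for (i in seq_len(nrow(osc))) {
      seg <- res$segments[res$segments$label == osc$label[i], ]
      expect_equal(nrow(seg), 1L)
      expect_lt(abs(seg$start_s - osc$realizedStartS[i]), 300)
      expect_lt(abs(seg$end_s - osc$realizedEndS[i]), 300)
    }
  }
})

test_that("segmentation depends only on the event list", {
  ev <- mkEvents(c(2000, 2300, 5000, 5300), c("small", "small", "large",
                                              "large"))
  a <- segmentPhases(ev, c(0, 9000))
  b <- segmentPhases(ev[sample(nrow(ev)), ], c(0, 9000))
  expect_equal(a, b)
})

test_that("RePh1 shortens as medium osmolarity drops (wild-type presets)", {
  reph1At <- function(x) {
    out <- generateTrace(osmolarityToParams(x, "WT", noiseSd = 0,
                                            seed = 77))
    analyzeTrace(out$trace)$rePh1S
  }
  d <- vapply(c(350, 535, 680), reph1At, numeric(1))
  expect_true(all(diff(d) > 0))
})
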