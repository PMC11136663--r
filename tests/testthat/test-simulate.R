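test_that("generation is deterministic for identical parameters and seed", {
  p <- osmolarityToParams(535, "WT", seed = 9)
  a <- generateTrace(p)
  b <- generateTrace(p)
  expect_identical(traceValues(a$trace), traceValues(b$trace))
  expect_identical(a$truth$events, b$truth$events)
  # parameter maps are deterministic too
  expect_identical(osmolarityToParams(420, "osca2.1/2.2", seed = 3),
                   osmolarityToParams(420, "osca2.1/2.2", seed = 3))
})

test_that("noise-free, event-free traces are the pure bleaching curve", {
  p <- generativeParams(nFrames = 60L, bleachRate = 1e-4, noiseSd = 0)
  out <- generateTrace(p)
  t <- traceTimes(out$trace)
  expect_equal(traceValues(out$trace), 100 * exp(-1e-4 * t))
  expect_equal(nrow(out$truth$events), 0L)
  # no bleaching either: exactly constant
  p2 <- generativeParams(nFrames = 40L, bleachRate = 0, noiseSd = 0)
  expect_equal(unique(traceValues(generateTrace(p2)$trace)), 100)
})

test_that("a single known event is recovered at its true dF/F0 peak", {
  plan <- singlePhasePlan("large", durationS = 460, periodS = 400,
                          ampLo = 5.5, ampHi = 5.5, leadS = 600,
                          tailS = 900)
  p <- generativeParams(nFrames = 80L, noiseSd = 0, bleachRate = 2e-5,
                        phasePlan = plan, seed = 4)
  out <- generateTrace(p)
  expect_equal(nrow(out$truth$events), 1L)
  dff <- preprocessTrace(out$trace)
  expect_equal(max(dffValues(dff)), 4.5, tolerance = 0.02)
})

test_that("mean event count agrees with the plan's rate within renewal edge effects", {
  plan <- singlePhasePlan("small", durationS = 3600, periodS = 360)
  counts <- vapply(1:100, function(s) {
    p <- generativeParams(nFrames = 200L, noiseSd = 0, phasePlan = plan,
                          seed = s)
    nrow(generateTrace(p)$truth$events)
  }, numeric(1))
  expected <- 3600 / 360
  se <- stats::sd(counts) / sqrt(length(counts))
  # a renewal process can differ from duration/period by at most ~1 event
  expect_lt(abs(mean(counts) - expected), 1 + 3 * se)
})

test_that("generated amplitudes respect class bands and avoid the 3-5x gap", {
  for (s in 1:5) {
    out <- generateTrace(osmolarityToParams(350, "WT", noiseSd = 0,
                                            seed = s))
    ev <- out$truth$events
    sm <- ev$ampFF0[ev$class == "small"]
    lg <- ev$ampFF0[ev$class == "large"]
    expect_true(all(sm >= 2 & sm <= 3))
    expect_true(all(lg >= 5 & lg <= 8))
  }
})

test_that("parameter maps are strictly monotone in osmolarity", {
  osms <- seq(150, 950, by = 100)
  for (g in c("WT", "osca2.1/2.2")) {
    ps <- lapply(osms, osmolarityToParams, genotype = g)
    pick <- function(label, col) vapply(ps, function(p) {
      r <- p@phasePlan[p@phasePlan$label == label, ]
      if (nrow(r)) r[[col]][1] else NA_real_
    }, numeric(1))
    reph1 <- pick("RePh1", "durationS")
    perS <- pick("CaOscS", "periodS")
    ampS <- (pick("CaOscS", "ampLo") + pick("CaOscS", "ampHi")) / 2
    rateS <- pick("CaOscS", "durationS") / perS
    expect_true(all(diff(reph1) > 0))   # RePh1 grows with osmolarity
    expect_true(all(diff(perS) > 0))    # periods lengthen
    expect_true(all(diff(ampS) < 0))    # amplitudes shrink
    expect_true(all(diff(rateS) < 0))   # event counts fall
  }
  expect_error(osmolarityToParams(50), class = "pco_error_invalid_input")
  expect_error(osmolarityToParams(1200), class = "pco_error_invalid_input")
})

test_that("the mutant preset is hypo-responsive relative to wild type", {
  for (x in c(350, 535, 680)) {
    wt <- osmolarityToParams(x, "WT")
    mu <- osmolarityToParams(x, "osca2.1/2.2")
    g <- function(p, label, col) {
      r <- p@phasePlan[p@phasePlan$label == label, ]
      if (nrow(r)) r[[col]][1] else NA_real_
    }
    expect_gt(g(mu, "RePh1", "durationS"), g(wt, "RePh1", "durationS"))
    expect_gt(g(mu, "CaOscS", "periodS"), g(wt, "CaOscS", "periodS"))
    expect_lt(g(mu, "CaOscS", "ampHi"), g(wt, "CaOscS", "ampHi"))
    # RePh2 abolished in the mutant plan
    expect_false("RePh2" %in% mu@phasePlan$label)
    expect_true("RePh2" %in% wt@phasePlan$label)
    # expected event totals lower
    tot <- function(p) {
      pp <- p@phasePlan[p@phasePlan$class != "none", ]
      sum(pp$durationS / pp$periodS)
    }
    expect_lt(tot(mu), tot(wt))
  }
  # mutant large events nearly absent at high osmolarity
  nL <- vapply(1:6, function(s) {
    out <- generateTrace(osmolarityToParams(680, "osca2.1/2.2",
                                            noiseSd = 0, seed = s))
    sum(out$truth$events$class == "large")
  }, numeric(1))
  expect_lt(mean(nL), 1.5)
})

test_that("shock traces follow the rise/decay/desensitization construction", {
  # equal peaks without desensitization
  p <- osmolarityToParams(500, "WT", mode = "shock", nShocks = 2,
                          noiseSd = 0)
  out <- generateShockTrace(p)
  expect_equal(out$truth$shocks$peakDff[1], out$truth$shocks$peakDff[2])
  # factor 0.5 halves successive true peaks
  p2 <- osmolarityToParams(500, "WT", mode = "shock", nShocks = 3,
                           desensitizationFactor = 0.5, noiseSd = 0)
  tr2 <- generateShockTrace(p2)$truth$shocks
  expect_equal(tr2$peakDff / tr2$peakDff[1], c(1, 0.5, 0.25))
  # flat before the shock, exact peak at the snapped rise end
  v <- traceValues(out$trace)
  t <- traceTimes(out$trace)
  expect_true(all(v[t < 30] == 100))
  # first peak is exact; the second rides on the first one's residual tail
  expect_equal(max(v[t < 330]) / 100 - 1, out$truth$shocks$peakDff[1],
               tolerance = 1e-9)
  # peak dF/F0 increases with pre-incubation osmolarity
  peaks <- vapply(c(300, 500, 700), function(x)
    osmolarityToParams(x, "WT", mode = "shock")@shock$peakDff, numeric(1))
  expect_true(all(diff(peaks) > 0))
  # shock generation requires a shock protocol
  expect_error(generateShockTrace(osmolarityToParams(500, "WT")),
               class = "pco_error_invalid_input")
})

test_that("cohorts are reproducible and follow the osmolarity design", {
  a <- generateCohort("WT", c(350, 680), 3, seed = 1, noiseSd = 0)
  b <- generateCohort("WT", c(350, 680), 3, seed = 1, noiseSd = 0)
  expect_identical(lapply(a, function(e) traceValues(e$trace)),
                   lapply(b, function(e) traceValues(e$trace)))
  totalAt <- function(cohort, osm) sum(vapply(cohort, function(e)
    if (e$osmolarityMosm == osm) nrow(e$truth$events) else 0L, numeric(1)))
  expect_gt(totalAt(a, 350), totalAt(a, 680))
})
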