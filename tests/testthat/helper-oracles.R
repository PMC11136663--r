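# Independent oracles and small fixture builders, written as plain loops so
# they share no code path with the package implementation.

# Exhaustive frame-scan spike detector: same definition as detectSpikes
# (smoothed local maxima, raw-peak refinement and threshold, greedy
# acceptance by height with a minimal gap) implemented with explicit loops.
bruteDetect <- function(dff, cfg = detectionConfig()) {
  x <- dffValues(dff)
  t <- traceTimes(dff)
  n <- length(x)
  dt <- stats::median(diff(t))
  minGap <- if (is.null(cfg$minGapS)) 2 * dt else cfg$minGapS
  h <- cfg$smoothFrames %/% 2
  s <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    acc <- 0
    for (j in lo:hi) acc <- acc + x[j]
    s[i] <- acc / (hi - lo + 1)
  }
  cand <- integer()
  for (i in 2:(n - 1))
    if (s[i] > s[i - 1] && s[i] >= s[i + 1]) cand <- c(cand, i)
  ref <- integer()
  for (i in cand) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    best <- lo
    for (j in lo:hi) if (x[j] > x[best]) best <- j
    ref <- c(ref, min(max(best, 2), n - 1))
  }
  ref <- unique(ref)
  ref <- ref[x[ref] >= cfg$detectMinDff]
  if (!length(ref)) return(data.frame(peak_time_s = numeric(),
                                      peak_dff = numeric(),
                                      class = character()))
  ord <- ref[order(-x[ref], t[ref])]
  acc <- integer()
  for (i in ord) {
    okAll <- TRUE
    for (a in acc) if (abs(t[i] - t[a]) < minGap) okAll <- FALSE
    if (okAll) acc <- c(acc, i)
  }
  acc <- sort(acc)
  data.frame(peak_time_s = t[acc], peak_dff = x[acc],
             class = ifelse(x[acc] >= cfg$largeMinDff, "large", "small"),
             stringsAsFactors = FALSE)
}

# Brute-force scan over every window for the earliest stable baseline.
bruteBaseline <- function(values, window = 10, cvMax = 0.05) {
  n <- length(values)
  for (s in seq_len(n - window + 1)) {
    w <- values[s:(s + window - 1)]
    m <- mean(w)
    if (m > 0 && stats::sd(w) / m <= cvMax) return(c(s, s + window - 1))
  }
  NULL
}

# dF/F0 trace made of Gaussian bumps on a flat baseline.
bumpDff <- function(peakTimes, peakHeights, dt = 5, spanS = 600, sd = 15) {
  times <- seq(0, spanS, by = dt)
  x <- numeric(length(times))
  for (k in seq_along(peakTimes))
    x <- x + peakHeights[k] * exp(-(times - peakTimes[k])^2 / (2 * sd^2))
  DffTrace(times, x)
}

# Ground-truth event mask for bleach fitting (frames within an event).
truthEventMask <- function(trace, truth, padBeforeS = 40, padAfterS = 240) {
  t <- traceTimes(trace)
  mask <- rep(FALSE, length(t))
  for (pk in truth$events$peakTimeS)
    mask <- mask | (t >= pk - padBeforeS & t <= pk + padAfterS)
  mask
}

# Greedy matching of detected to true events within a time tolerance;
# returns tp/fp/fn and class-mismatch counts.
matchEvents <- function(truthEv, detected, tolS = 60) {
  used <- rep(FALSE, nrow(detected))
  tp <- fn <- bad <- 0
  for (i in seq_len(nrow(truthEv))) {
    d <- abs(detected$peak_time_s - truthEv$peakTimeS[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tolS) {
      used[j] <- TRUE
      tp <- tp + 1
      if (detected$class[j] != truthEv$class[i]) bad <- bad + 1
    } else fn <- fn + 1
  }
  list(tp = tp, fp = sum(!used), fn = fn, badClass = bad)
}

# One oscillation phase flanked by rests, for compact generator fixtures.
singlePhasePlan <- function(class = "small", durationS = 3600,
                            periodS = 360, ampLo = 2, ampHi = 3,
                            leadS = 600, tailS = 1800) {
  data.frame(
    label = c("RePh1", if (class == "small") "CaOscS" else "CaOscL",
              "RePh3"),
    class = c("none", class, "none"),
    durationS = c(leadS, durationS, tailS),
    periodS = c(NA, periodS, NA),
    ampLo = c(NA, ampLo, NA), ampHi = c(NA, ampHi, NA),
    stringsAsFactors = FALSE)
}
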