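## Synthetic pollen-grain calcium recordings with ground truth.
##
## The generative model is multiplicative: a baseline fluorescence F0 decays
## mono-exponentially with photobleaching, calcium spikes scale it as
## (1 + sum of spike contributions in dF/F0 units), and Gaussian read noise
## is added on the raw intensity. Spike trains inside oscillation phases are
## a refractory renewal process: intervals are (refractory gap) +
## Gamma-distributed jitter, capped below the resting-gap criterion so a
## within-train gap can never mimic a resting phase. Small-class events have
## true peaks of 2-3x baseline (F/F0), large-class events 5-8x; the (3,5)x
## band is never generated by default so class recovery is unambiguous.

## Inter-spike intervals are hard-capped below the 600 s resting-gap default.
INTER_SPIKE_CAP_S <- 560
## Gamma shape of the interval jitter: CV of the jitter is 1/sqrt(shape).
INTERVAL_GAMMA_SHAPE <- 16

#' Map medium osmolarity and genotype to generative parameters
#'
#' Encodes the qualitative signatures of germinating pollen as monotone
#' parameter maps. For \code{mode = "germination"} and decreasing medium
#' osmolarity the presets give a shorter first resting phase (RePh1),
#' shorter CaOscS/CaOscL periods (hence higher spike rates), longer
#' oscillation trains and larger amplitudes, all strictly monotone over the
#' 100-1000 mOsm domain. The \code{osca2.1/2.2} preset has, at every
#' osmolarity, a longer RePh1 (x2.5), a shortened CaOscS train, no RePh2
#' (the resting phase between trains is abolished), a strongly diminished
#' CaOscL train, longer periods (+150 s) and smaller amplitudes than
#' wild type. For \code{mode = "shock"} the preset maps pre-incubation
#' osmolarity to the peak dF/F0 of the hypo-osmotic shock transient
#' (increasing with osmolarity; mutant peaks scaled to one quarter).
#'
#' @param osmolarityMosm medium (germination) or pre-incubation (shock)
#'   osmolarity, mOsm, in \[100, 1000\].
#' @param genotype "WT" or "osca2.1/2.2".
#' @param mode "germination" (30 s frames, 600 frames = 300 min) or
#'   "shock" (1 s frames, 350 frames for a single challenge).
#' @param moduleRepeats number of CaOscS -> RePh2 -> CaOscL -> RePh3
#'   modules; frames are extended as needed for repeats > 1.
#' @param nShocks number of successive hypo-osmotic challenges (shock mode).
#' @param interShockS spacing between challenges, s.
#' @param desensitizationFactor per-challenge peak scaling in (0, 1\].
#' @param noiseSd additive noise s.d. in a.u.; default \code{baselineF0/50}
#'   (SNR 50); pass 0 for noise-free traces.
#' @param seed integer seed stored in the parameter set.
#' @return A \linkS4class{GenerativeParams}.
#' @examples
#' p <- osmolarityToParams(535, "WT", seed = 7)
#' p@phasePlan[, c("label", "durationS", "periodS")]
#' @export
osmolarityToParams <- function(osmolarityMosm,
                               genotype = c("WT", "osca2.1/2.2"),
                               mode = c("germination", "shock"),
                               moduleRepeats = 1L, nShocks = 1L,
                               interShockS = 300,
                               desensitizationFactor = 1,
                               noiseSd = NULL, seed = 1L) {
  genotype <- match.arg(genotype)
  mode <- match.arg(mode)
  if (!is.finite(osmolarityMosm) || osmolarityMosm < 100 ||
      osmolarityMosm > 1000)
    pcoStop("invalid_input",
            "osmolarity must lie in [100, 1000] mOsm for the presets")
  f0 <- 100
  if (is.null(noiseSd)) noiseSd <- f0 / 50
  u <- (1000 - osmolarityMosm) / 900   # 0 at 1000 mOsm, 1 at 100 mOsm

  if (mode == "shock") {
    peak <- 0.4 + 3.0 * (osmolarityMosm - 100) / 900
    if (genotype == "osca2.1/2.2") peak <- 0.25 * peak
    shocks <- 30 + (seq_len(nShocks) - 1) * interShockS
    nFrames <- max(350L, as.integer(ceiling(max(shocks) + 300 + 20)))
    return(generativeParams(
      mode = "shock", genotype = genotype,
      osmolarityMosm = osmolarityMosm, frameIntervalS = 1, nFrames = nFrames,
      baselineF0 = f0, bleachRate = 0, noiseSd = noiseSd,
      phasePlan = emptyPhasePlan(),
      shock = list(shockTimesS = shocks, peakDff = peak, decayTauS = 40,
                   riseTimeS = 5,
                   desensitizationFactor = desensitizationFactor),
      seed = seed))
  }

  ## germination presets (all monotone in osmolarity)
  d1 <- 4800 - 3000 * u                       # RePh1 duration, s
  dS <- 2400 + 1800 * u                       # CaOscS train duration
  pS <- 440 - 200 * u                         # CaOscS inter-spike period
  aS <- c(2 + 0.5 * u, 2.5 + 0.5 * u)         # small amps, F/F0
  d2 <- 1500                                  # RePh2 duration
  dL <- 2100 + 1500 * u                       # CaOscL train duration
  pL <- 500 - 200 * u                         # CaOscL period
  aL <- c(5 + 1.5 * u, 6.5 + 1.5 * u)         # large amps, F/F0
  if (genotype == "osca2.1/2.2") {
    d1 <- 2.5 * d1
    dS <- 0.6 * dS
    d2 <- 0                                   # RePh2 abolished
    dL <- 0.4 * u * dL                        # CaOscL strongly diminished
    pS <- pS + 150
    pL <- pL + 150
    aS <- c(2 + 0.25 * u, 2.25 + 0.25 * u)
    aL <- c(5 + 0.75 * u, 5.5 + 0.75 * u)
  }

  interRest <- 1500
  r <- as.integer(moduleRepeats)
  if (r < 1L) pcoStop("invalid_input", "moduleRepeats must be >= 1")
  rows <- list(data.frame(label = "RePh1", class = "none", durationS = d1,
                          periodS = NA_real_, ampLo = NA_real_,
                          ampHi = NA_real_, stringsAsFactors = FALSE))
  for (k in seq_len(r)) {
    sfx <- if (k == 1L) "" else paste0("_r", k)
    rows <- c(rows, list(
      data.frame(label = paste0("CaOscS", sfx), class = "small",
                 durationS = dS, periodS = pS, ampLo = aS[1], ampHi = aS[2],
                 stringsAsFactors = FALSE)))
    if (d2 > 0)
      rows <- c(rows, list(
        data.frame(label = paste0("RePh2", sfx), class = "none",
                   durationS = d2, periodS = NA_real_, ampLo = NA_real_,
                   ampHi = NA_real_, stringsAsFactors = FALSE)))
    if (dL > 0)
      rows <- c(rows, list(
        data.frame(label = paste0("CaOscL", sfx), class = "large",
                   durationS = dL, periodS = pL, ampLo = aL[1],
                   ampHi = aL[2], stringsAsFactors = FALSE)))
    if (k < r)
      rows <- c(rows, list(
        data.frame(label = paste0("RePh3", sfx), class = "none",
                   durationS = interRest, periodS = NA_real_,
                   ampLo = NA_real_, ampHi = NA_real_,
                   stringsAsFactors = FALSE)))
  }
  plan <- do.call(rbind, rows)
  dt <- 30
  nFrames <- max(600L, as.integer(ceiling((sum(plan$durationS) + 1500) / dt)))
  span <- nFrames * dt
  tailSfx <- if (r == 1L) "" else paste0("_r", r)
  plan <- rbind(plan, data.frame(
    label = paste0("RePh3", tailSfx), class = "none",
    durationS = span - sum(plan$durationS), periodS = NA_real_,
    ampLo = NA_real_, ampHi = NA_real_, stringsAsFactors = FALSE))

  generativeParams(mode = "germination", genotype = genotype,
                   osmolarityMosm = osmolarityMosm, frameIntervalS = dt,
                   nFrames = nFrames, baselineF0 = f0, bleachRate = 2e-5,
                   noiseSd = noiseSd, phasePlan = plan, seed = seed)
}

## Spike contribution in dF/F0 units: linear rise over riseS to (amp - 1),
## then exponential decay with tauS. amp is the true peak as an F/F0 ratio.
spikeContrib <- function(times, peakT, amp, riseS, tauS) {
  s <- numeric(length(times))
  rel <- times - peakT
  up <- rel > -riseS & rel <= 0
  s[up] <- (amp - 1) * (1 + rel[up] / riseS)
  dn <- rel > 0
  s[dn] <- (amp - 1) * exp(-rel[dn] / tauS)
  s
}

## Draw event peak times in [t0, t1) for one oscillation phase.
## Refractory renewal: intervals = gap + Gamma jitter with mean
## (period - gap), capped at INTER_SPIKE_CAP_S. Peaks snap to the frame
## grid so a noise-free trace attains the true peak exactly.
drawPhaseEvents <- function(t0, t1, periodS, gapS, dt) {
  jm <- max(periodS - gapS, 5)
  t <- t0 + stats::runif(1, gapS / 3, max(gapS / 3 + dt, periodS))
  peaks <- numeric()
  while (t <= t1 - 2 * dt) {
    peaks <- c(peaks, round(t / dt) * dt)
    iv <- gapS + stats::rgamma(1, shape = INTERVAL_GAMMA_SHAPE,
                               scale = jm / INTERVAL_GAMMA_SHAPE)
    t <- t + min(iv, INTER_SPIKE_CAP_S)
  }
  peaks
}

#' Generate a synthetic germination-mode recording with ground truth
#'
#' Draws spike trains phase by phase from the parameter set's phase plan and
#' renders the raw fluorescence
#' \eqn{F(t) = F_0 e^{-\lambda t}(1 + \sum_k s_k(t)) + \epsilon(t)} with
#' additive Gaussian noise. All randomness is governed by \code{params@seed};
#' identical parameters give bit-identical output.
#'
#' @param params a \linkS4class{GenerativeParams} (germination mode).
#' @param roiId label for the generated trace.
#' @return \code{list(trace, truth)} where \code{trace} is a
#'   \linkS4class{CaTrace} and \code{truth} a list with \code{events}
#'   (peak time, class, true F/F0 amplitude, true peak dF/F0),
#'   \code{phases} (planned and realized boundaries, event counts) and
#'   \code{germinationTimeS} (end of the first CaOscL train with >= 3
#'   large events, or NA).
#' @examples
#' out <- generateTrace(osmolarityToParams(535, "WT", noiseSd = 0, seed = 1))
#' nrow(out$truth$events)
#' @export
generateTrace <- function(params, roiId = "roi1") {
  stopifnot(is(params, "GenerativeParams"))
  validObject(params)
  dt <- params@frameIntervalS
  n <- params@nFrames
  times <- (seq_len(n) - 1) * dt
  span <- n * dt
  plan <- params@phasePlan

  out <- withr::with_seed(params@seed, {
    ev <- list()
    ph <- list()
    t0 <- 0
    for (i in seq_len(nrow(plan))) {
      row <- plan[i, ]
      t1 <- min(t0 + row$durationS, span)
      if (row$class != "none" && t1 > t0) {
        shape <- params@spikeShapes[[row$class]]
        gap <- shape$riseS + 4 * shape$tauS
        peaks <- drawPhaseEvents(t0, t1, row$periodS, gap, dt)
        amps <- if (row$class == "small")
          stats::runif(length(peaks), row$ampLo, row$ampHi)
        else
          exp(stats::runif(length(peaks), log(row$ampLo), log(row$ampHi)))
        if (length(peaks))
          ev[[length(ev) + 1L]] <- data.frame(
            peakTimeS = peaks, class = row$class, ampFF0 = amps,
            peakDff = amps - 1, phase = i, stringsAsFactors = FALSE)
        realized <- if (length(peaks))
          c(min(peaks) - 0.8 * shape$riseS,
            max(peaks) + log(5) * shape$tauS)
        else c(NA_real_, NA_real_)
      } else realized <- c(NA_real_, NA_real_)
      ph[[i]] <- data.frame(
        label = row$label, class = row$class, plannedStartS = t0,
        plannedEndS = t1, realizedStartS = realized[1],
        realizedEndS = realized[2],
        nEvents = if (row$class != "none" && length(ev) &&
                      ev[[length(ev)]]$phase[1] == i)
          nrow(ev[[length(ev)]]) else 0L,
        stringsAsFactors = FALSE)
      t0 <- t1
    }
    events <- if (length(ev)) do.call(rbind, ev) else
      data.frame(peakTimeS = numeric(), class = character(),
                 ampFF0 = numeric(), peakDff = numeric(), phase = integer(),
                 stringsAsFactors = FALSE)
    phases <- do.call(rbind, ph)
    sig <- numeric(n)
    for (j in seq_len(nrow(events))) {
      shape <- params@spikeShapes[[events$class[j]]]
      sig <- sig + spikeContrib(times, events$peakTimeS[j],
                                events$ampFF0[j], shape$riseS, shape$tauS)
    }
    values <- params@baselineF0 * exp(-params@bleachRate * times) * (1 + sig)
    if (params@noiseSd > 0)
      values <- values + stats::rnorm(n, 0, params@noiseSd)
    list(events = events, phases = phases, values = pmax(values, 0))
  })

  lg <- out$phases$class == "large" & out$phases$nEvents >= 3
  germT <- if (any(lg)) out$phases$realizedEndS[which(lg)[1]] else NA_real_
  trace <- CaTrace(times, out$values, roiId = roiId,
                   meta = list(genotype = params@genotype,
                               osmolarityMosm = params@osmolarityMosm,
                               frameIntervalS = dt))
  list(trace = trace,
       truth = list(events = out$events, phases = out$phases,
                    germinationTimeS = germT, params = params))
}

#' Generate a hypo-osmotic shock recording with ground truth
#'
#' Renders a flat baseline before the first challenge, then for each shock a
#' linear rise over \code{riseTimeS} to the peak followed by mono-exponential
#' decay with \code{decayTauS}; the k-th successive challenge is scaled by
#' \code{desensitizationFactor^(k-1)}.
#'
#' @inheritParams generateTrace
#' @return \code{list(trace, truth)}; \code{truth$shocks} lists per
#'   challenge the shock time, true peak dF/F0, true peak time and decay
#'   constant.
#' @examples
#' p <- osmolarityToParams(500, "WT", mode = "shock", noiseSd = 0)
#' out <- generateShockTrace(p)
#' out$truth$shocks
#' @export
generateShockTrace <- function(params, roiId = "roi1") {
  stopifnot(is(params, "GenerativeParams"))
  validObject(params)
  if (!length(params@shock))
    pcoStop("invalid_input", "params has no shock protocol")
  s <- params@shock
  dt <- params@frameIntervalS
  n <- params@nFrames
  times <- (seq_len(n) - 1) * dt

  k <- seq_along(s$shockTimesS)
  peaks <- s$peakDff * s$desensitizationFactor^(k - 1)
  peakT <- round((s$shockTimesS + s$riseTimeS) / dt) * dt
  dffTrue <- numeric(n)
  for (i in k)
    dffTrue <- dffTrue + spikeContrib(times, peakT[i], 1 + peaks[i],
                                      s$riseTimeS, s$decayTauS)
  values <- params@baselineF0 * exp(-params@bleachRate * times) *
    (1 + dffTrue)
  values <- withr::with_seed(params@seed, {
    if (params@noiseSd > 0)
      values <- values + stats::rnorm(n, 0, params@noiseSd)
    pmax(values, 0)
  })
  trace <- CaTrace(times, values, roiId = roiId,
                   meta = list(genotype = params@genotype,
                               osmolarityMosm = params@osmolarityMosm,
                               frameIntervalS = dt,
                               shockTimeS = s$shockTimesS[1]))
  list(trace = trace,
       truth = list(shocks = data.frame(
         shockTimeS = s$shockTimesS, peakDff = peaks,
         truePeakTimeS = peakT, decayTauS = s$decayTauS),
         params = params))
}

#' Generate a reproducible cohort of synthetic recordings
#'
#' Builds a dataset keyed by (genotype, osmolarity, replicate). Per-replicate
#' seeds are derived deterministically from \code{seed}, so the same call
#' always yields byte-identical output.
#'
#' @param genotypes character vector of genotype labels.
#' @param osmolarities numeric vector of osmolarities, mOsm.
#' @param nPerCondition replicates per (genotype, osmolarity) cell (>= 1).
#' @param seed master seed.
#' @param mode "germination" or "shock".
#' @param ... further arguments passed to \code{\link{osmolarityToParams}}
#'   (e.g. \code{noiseSd}, \code{moduleRepeats}).
#' @return List of entries, each
#'   \code{list(genotype, osmolarityMosm, replicate, trace, truth)}.
#' @export
generateCohort <- function(genotypes, osmolarities, nPerCondition,
                           seed = 1L, mode = "germination", ...) {
  if (nPerCondition < 1) pcoStop("invalid_input", "nPerCondition must be >= 1")
  grid <- expand.grid(replicate = seq_len(nPerCondition),
                      osmolarityMosm = osmolarities, genotype = genotypes,
                      stringsAsFactors = FALSE)
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(.Machine$integer.max - 1L, nrow(grid)))
  lapply(seq_len(nrow(grid)), function(i) {
    g <- grid$genotype[i]
    x <- grid$osmolarityMosm[i]
    id <- sprintf("%s_%g_r%02d", gsub("[^A-Za-z0-9.]", "", g), x,
                  grid$replicate[i])
    p <- osmolarityToParams(x, genotype = g, mode = mode,
                            seed = seeds[i], ...)
    out <- if (mode == "shock") generateShockTrace(p, roiId = id)
           else generateTrace(p, roiId = id)
    c(list(genotype = g, osmolarityMosm = x,
           replicate = grid$replicate[i]), out)
  })
}
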