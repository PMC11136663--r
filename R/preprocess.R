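## Raw-trace normalization: stable-baseline search, photobleaching
## correction, dF/F0 construction, and ratiometric channel handling.

#' Find the earliest stable baseline window
#'
#' Scans consecutive windows of \code{window} frames and returns the
#' earliest whose coefficient of variation (sd/mean) is at most
#' \code{cvMax}. This operationalizes "the first ten stable frames": F0 is
#' taken from the first run of frames that is quiet enough, skipping any
#' initial transient.
#'
#' @param trace a \linkS4class{CaTrace} (or numeric vector of intensities).
#' @param window window length in frames (default 10).
#' @param cvMax maximal coefficient of variation regarded as stable
#'   (default 0.05).
#' @return Integer length-2: first and last frame of the window (1-based).
#' @examples
#' findStableBaseline(CaTrace(seq(0, 570, 30), rep(100, 20)))
#' @export
findStableBaseline <- function(trace, window = 10L, cvMax = 0.05) {
  v <- if (is.numeric(trace)) trace else traceValues(trace)
  n <- length(v)
  if (n < window)
    pcoStop("invalid_input", "trace shorter than the baseline window")
  cs <- cumsum(c(0, v))
  cs2 <- cumsum(c(0, v^2))
  starts <- seq_len(n - window + 1L)
  m <- (cs[starts + window] - cs[starts]) / window
  ss <- cs2[starts + window] - cs2[starts]
  sd <- sqrt(pmax((ss - window * m^2) / (window - 1), 0))
  cv <- ifelse(m > 0, sd / m, Inf)
  i <- which(cv <= cvMax)[1]
  if (is.na(i))
    pcoStop("no_stable_baseline",
            sprintf("no run of %d frames with CV <= %g", window, cvMax))
  c(i, i + as.integer(window) - 1L)
}

#' Compute the dF/F0 trace
#'
#' F0 is the mean raw intensity over the baseline window and
#' dF/F0 = (F - F0)/F0 frame-wise. Note that an event reaching k times the
#' baseline intensity (F/F0 = k) has dF/F0 = k - 1.
#'
#' @param trace a \linkS4class{CaTrace} (bleach-correct first for long
#'   recordings, see \code{\link{correctBleaching}}).
#' @param baseline integer length-2 frame range for F0; when NULL the first
#'   stable window is searched, falling back to the first \code{window}
#'   frames with a warning.
#' @param window,cvMax passed to \code{\link{findStableBaseline}}.
#' @return A \linkS4class{DffTrace}.
#' @examples
#' tr <- CaTrace(seq(0, 570, 30), c(rep(100, 10), rep(300, 10)))
#' max(dffValues(computeDff(tr)))   # 2: three times baseline
#' @export
computeDff <- function(trace, baseline = NULL, window = 10L, cvMax = 0.05) {
  v <- traceValues(trace)
  if (is.null(baseline)) {
    baseline <- tryCatch(
      findStableBaseline(trace, window, cvMax),
      pco_error_no_stable_baseline = function(e) {
        warning("no stable baseline found; using the first ", window,
                " frames", call. = FALSE)
        c(1L, as.integer(window))
      })
  }
  baseline <- as.integer(baseline)
  if (baseline[1] < 1L || baseline[2] > length(v) ||
      baseline[2] < baseline[1])
    pcoStop("invalid_baseline", "baseline window outside the trace")
  f0 <- mean(v[baseline[1]:baseline[2]])
  if (!is.finite(f0) || f0 <= 0)
    pcoStop("invalid_baseline", "baseline mean must be positive")
  bleach <- traceMeta(trace)$bleach %||%
    list(model = "none", rate = NA_real_, fitFrames = integer())
  DffTrace(traceTimes(trace), (v - f0) / f0, f0 = f0,
           baselineFrames = baseline, bleachModel = bleach,
           roiId = roiLabel(trace), meta = traceMeta(trace))
}

## Mono-exponential fit B * exp(-l * t) on selected frames; log-linear
## start values, Levenberg-Marquardt refinement.
fitExpDecay <- function(t, v, use) {
  ok <- use & v > 0 & is.finite(v)
  if (sum(ok) < 20)
    pcoStop("bleach_fit", "need >= 20 non-event frames to fit bleaching")
  ll <- stats::lm(log(v[ok]) ~ t[ok])
  B0 <- exp(stats::coef(ll)[[1]])
  l0 <- max(-stats::coef(ll)[[2]], 0)
  df <- data.frame(tv = t[ok], Fv = v[ok])
  fit <- tryCatch(
    minpack.lm::nlsLM(Fv ~ B * exp(-l * tv), data = df,
                      start = list(B = B0, l = l0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  if (cf[["l"]] < -1e-7 || cf[["B"]] <= 0) return(NULL)
  list(model = "exponential", B = cf[["B"]], rate = cf[["l"]],
       curve = function(tt) cf[["B"]] * exp(-cf[["l"]] * tt))
}

fitLinearDecay <- function(t, v, use) {
  ok <- use & is.finite(v)
  if (sum(ok) < 20)
    pcoStop("bleach_fit", "need >= 20 non-event frames to fit bleaching")
  lf <- stats::lm(v[ok] ~ t[ok])
  a <- stats::coef(lf)[[1]]
  b <- stats::coef(lf)[[2]]
  curve <- function(tt) a + b * tt
  if (any(curve(range(t)) <= 0))
    pcoStop("bleach_fit", "linear bleach model crosses zero over the trace")
  list(model = "linear", B = a, rate = b, curve = curve)
}

#' Correct multiplicative photobleaching
#'
#' Fits a mono-exponential decay \eqn{B e^{-\lambda t}} to resting
#' (non-event) frames, divides the trace by the fitted curve and rescales so
#' the mean over the baseline window is preserved. When no event mask is
#' supplied, an iterative scheme is used: a trimmed provisional fit (the
#' 60 percent of frames with the lowest log-residuals, which excludes spike
#' frames), spike detection on the provisional dF/F0, and one refit on the
#' frames outside detected events. If the exponential fit fails or the
#' fitted rate is negative beyond tolerance, a linear model is used; if that
#' also fails a bleach-fit error is raised.
#'
#' @param trace a \linkS4class{CaTrace}.
#' @param eventMask optional logical vector (TRUE = event frame, excluded
#'   from the fit), e.g. built from known ground truth.
#' @param detectCfg \code{\link{detectionConfig}} for the provisional
#'   detection pass (defaults to germination-mode settings).
#' @param window,cvMax baseline-window search parameters used for the
#'   rescaling reference.
#' @return A \linkS4class{CaTrace} with corrected values; the fitted model
#'   is recorded in \code{traceMeta(x)$bleach} (\code{model}, \code{rate},
#'   \code{fitFrames}).
#' @export
correctBleaching <- function(trace, eventMask = NULL, detectCfg = NULL,
                             window = 10L, cvMax = 0.05) {
  t <- traceTimes(trace)
  v <- traceValues(trace)
  n <- length(v)
  baseWin <- tryCatch(findStableBaseline(trace, window, cvMax),
                      pco_error_no_stable_baseline = function(e)
                        c(1L, as.integer(window)))
  if (is.null(eventMask)) {
    ## provisional trimmed fit -> detect -> mask
    ll <- stats::lm(log(pmax(v, .Machine$double.eps)) ~ t)
    res <- stats::residuals(ll)
    trim <- res <= stats::quantile(res, 0.6)
    prov <- fitExpDecay(t, v, trim)
    if (is.null(prov)) prov <- fitLinearDecay(t, v, trim)
    corr0 <- v / prov$curve(t)
    f00 <- mean(corr0[baseWin[1]:baseWin[2]])
    dff0 <- DffTrace(t, corr0 / f00 - 1, f0 = f00, baselineFrames = baseWin,
                     roiId = roiLabel(trace), meta = traceMeta(trace))
    cfg <- detectCfg %||% detectionConfig()
    evs <- detectSpikes(dff0, cfg)
    eventMask <- rep(FALSE, n)
    dt <- stats::median(diff(t))
    for (k in seq_len(nrow(evs)))
      eventMask <- eventMask |
        (t >= evs$onset_s[k] - dt & t <= evs$offset_s[k] + dt)
  }
  if (length(eventMask) != n)
    pcoStop("invalid_input", "eventMask must have one entry per frame")
  fit <- fitExpDecay(t, v, !eventMask)
  if (is.null(fit)) fit <- fitLinearDecay(t, v, !eventMask)
  corrected <- v / fit$curve(t)
  corrected <- corrected *
    mean(v[baseWin[1]:baseWin[2]]) /
    mean(corrected[baseWin[1]:baseWin[2]])
  meta <- traceMeta(trace)
  meta$bleach <- list(model = fit$model, rate = fit$rate,
                      fitFrames = which(!eventMask))
  CaTrace(t, pmax(corrected, 0), roiId = roiLabel(trace), meta = meta)
}

#' Form a ratiometric trace from two channels
#'
#' Builds the frame-wise ratio (e.g. F340/F380 for Fura-2) and returns it as
#' an ordinary \linkS4class{CaTrace}; all downstream analysis treats the
#' ratio exactly like a raw single-channel trace.
#'
#' @param chNum numerator-channel \linkS4class{CaTrace}.
#' @param chDen denominator-channel \linkS4class{CaTrace} on the same grid,
#'   with strictly positive values.
#' @return A \linkS4class{CaTrace} of ratios, metadata taken from the
#'   numerator channel.
#' @export
ratiometricTrace <- function(chNum, chDen) {
  tn <- traceTimes(chNum)
  td <- traceTimes(chDen)
  if (length(tn) != length(td) ||
      max(abs(tn - td)) > 1e-6 * stats::median(diff(tn)))
    pcoStop("alignment", "channel time grids do not match")
  dv <- traceValues(chDen)
  if (any(dv <= 0))
    pcoStop("invalid_input", "denominator channel must be strictly positive")
  CaTrace(tn, traceValues(chNum) / dv,
          roiId = sub("_ch[0-9]+$", "", roiLabel(chNum)),
          meta = traceMeta(chNum))
}

#' Raw trace to bleach-corrected dF/F0 in one step
#'
#' Convenience pipeline: optional photobleaching correction (default on for
#' germination-mode recordings, off for short shock recordings), stable
#' baseline search with fallback to the first \code{window} frames, and
#' dF/F0 computation.
#'
#' @param trace a \linkS4class{CaTrace}.
#' @param mode "germination" or "shock".
#' @param bleachCorrect override the per-mode default.
#' @param window,cvMax baseline-window parameters.
#' @param detectCfg detection settings for the bleach-fit event masking.
#' @return A \linkS4class{DffTrace}.
#' @export
preprocessTrace <- function(trace, mode = c("germination", "shock"),
                            bleachCorrect = NULL, window = 10L,
                            cvMax = 0.05, detectCfg = NULL) {
  mode <- match.arg(mode)
  if (is.null(bleachCorrect)) bleachCorrect <- mode == "germination"
  if (is.null(detectCfg)) detectCfg <- detectionConfig(mode = mode)
  if (bleachCorrect)
    trace <- correctBleaching(trace, detectCfg = detectCfg,
                              window = window, cvMax = cvMax)
  computeDff(trace, baseline = NULL, window = window, cvMax = cvMax)
}
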