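#' @import methods
NULL

## Shared helpers -------------------------------------------------------------

#' Raise a classed error
#'
#' All package errors carry a condition class of the form
#' \code{"pco_error_<kind>"} so callers can branch on the failure mode.
#' @noRd
pcoStop <- function(kind, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(paste0("pco_error_", kind), "pco_error"),
                      call = call))
}

#' Check a numeric vector for a uniform, strictly increasing time grid
#' @noRd
isUniformGrid <- function(times, relTol = 1e-4) {
  d <- diff(times)
  if (any(d <= 0)) return(FALSE)
  m <- stats::median(d)
  all(abs(d - m) <= relTol * m)
}

defaultMeta <- function(meta, frameInterval) {
  base <- list(genotype = NA_character_, osmolarityMosm = NA_real_,
               frameIntervalS = frameInterval, shockTimeS = NA_real_)
  base[names(meta)] <- meta
  base
}

## CaTrace ---------------------------------------------------------------------

#' Raw fluorescence trace for one region of interest
#'
#' A \code{CaTrace} holds the time-stamped raw fluorescence of a single
#' region of interest (one pollen grain), in arbitrary intensity units, on a
#' uniform acquisition grid, together with acquisition metadata (genotype,
#' medium osmolarity in mOsm, frame interval, shock time if any). Ratiometric
#' (Fura-2 style) inputs are carried in the same container after the 340/380
#' ratio has been formed with \code{\link{ratiometricTrace}}.
#'
#' @slot times numeric, acquisition times in seconds (uniform, increasing).
#' @slot values numeric, raw fluorescence in arbitrary units (finite, >= 0).
#' @slot roiId character scalar labelling the region of interest.
#' @slot meta named list: \code{genotype}, \code{osmolarityMosm},
#'   \code{frameIntervalS}, \code{shockTimeS}, plus free-form entries
#'   (e.g. the recorded photobleaching fit).
#' @export
setClass("CaTrace",
         representation(times = "numeric", values = "numeric",
                        roiId = "character", meta = "list"))

setValidity("CaTrace", function(object) {
  msgs <- character()
  if (length(object@times) != length(object@values))
    msgs <- c(msgs, "times and values must have equal length")
  if (length(object@times) < 20)
    msgs <- c(msgs, "a trace needs at least 20 frames")
  else if (!isUniformGrid(object@times))
    msgs <- c(msgs, "times must be strictly increasing on a uniform grid")
  if (any(!is.finite(object@values)) || any(object@values < 0))
    msgs <- c(msgs, "values must be finite and non-negative")
  if (length(object@roiId) != 1L || is.na(object@roiId))
    msgs <- c(msgs, "roiId must be a single non-missing label")
  if (length(msgs)) msgs else TRUE
})

#' Construct a CaTrace
#'
#' @param times acquisition times in seconds (uniform grid, >= 20 frames).
#' @param values raw fluorescence, arbitrary units, finite and non-negative.
#' @param roiId region-of-interest label.
#' @param meta named list of acquisition metadata; missing standard fields
#'   (\code{genotype}, \code{osmolarityMosm}, \code{frameIntervalS},
#'   \code{shockTimeS}) are filled with defaults.
#' @return A validated \linkS4class{CaTrace}.
#' @examples
#' tr <- CaTrace(times = seq(0, 570, by = 30), values = rep(100, 20))
#' traceValues(tr)[1:3]
#' @export
CaTrace <- function(times, values, roiId = "roi1", meta = list()) {
  dt <- if (length(times) > 1) stats::median(diff(times)) else NA_real_
  new("CaTrace", times = as.numeric(times), values = as.numeric(values),
      roiId = as.character(roiId), meta = defaultMeta(meta, dt))
}

setMethod("show", "CaTrace", function(object) {
  cat(sprintf("CaTrace '%s': %d frames, dt = %gs, span = %gs\n",
              object@roiId, length(object@times),
              object@meta$frameIntervalS,
              utils::tail(object@times, 1) - object@times[1]))
  cat(sprintf("  genotype: %s  osmolarity: %s mOsm\n",
              object@meta$genotype, format(object@meta$osmolarityMosm)))
})

## DffTrace --------------------------------------------------------------------

#' Normalized dF/F0 trace
#'
#' Holds the dF/F0 = (F - F0)/F0 series of one region of interest together
#' with the baseline F0 (the mean over the first stable baseline window),
#' the frame range used for F0, and the photobleaching model that was
#' divided out before normalization.
#'
#' @slot times numeric, seconds.
#' @slot dff numeric, dimensionless dF/F0 (finite, >= -1).
#' @slot f0 numeric scalar, baseline fluorescence in a.u. (> 0).
#' @slot baselineFrames integer length-2, first and last frame (1-based)
#'   averaged for F0.
#' @slot bleachModel list with elements \code{model} (one of "none",
#'   "exponential", "linear"), \code{rate} (fitted decay rate, 1/s, or the
#'   linear slope), and \code{fitFrames} (indices used in the fit).
#' @slot roiId character scalar.
#' @slot meta named list, propagated from the raw trace.
#' @export
setClass("DffTrace",
         representation(times = "numeric", dff = "numeric", f0 = "numeric",
                        baselineFrames = "integer", bleachModel = "list",
                        roiId = "character", meta = "list"))

setValidity("DffTrace", function(object) {
  msgs <- character()
  if (length(object@times) != length(object@dff))
    msgs <- c(msgs, "times and dff must have equal length")
  if (any(!is.finite(object@dff)) || any(object@dff < -1 - 1e-9))
    msgs <- c(msgs, "dff must be finite and >= -1")
  if (length(object@f0) != 1L || !is.finite(object@f0) || object@f0 <= 0)
    msgs <- c(msgs, "f0 must be a single positive number")
  if (length(object@baselineFrames) != 2L ||
      object@baselineFrames[1] < 1L ||
      object@baselineFrames[2] < object@baselineFrames[1])
    msgs <- c(msgs, "baselineFrames must be a valid 1-based frame range")
  if (!is.character(object@bleachModel$model %||% NA_character_) ||
      !(object@bleachModel$model %||% "none") %in%
        c("none", "exponential", "linear"))
    msgs <- c(msgs, "bleachModel$model must be none/exponential/linear")
  if (length(msgs)) msgs else TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a DffTrace
#'
#' Mostly used internally by \code{\link{computeDff}}; exported so tests and
#' users can build dF/F0 series directly (e.g. idealized bump traces).
#'
#' @param times seconds.
#' @param dff dimensionless dF/F0 values.
#' @param f0 baseline fluorescence (a.u.).
#' @param baselineFrames 1-based frame range averaged for F0.
#' @param bleachModel list describing the bleaching correction applied.
#' @param roiId,meta as for \code{\link{CaTrace}}.
#' @return A validated \linkS4class{DffTrace}.
#' @export
DffTrace <- function(times, dff, f0 = 1, baselineFrames = c(1L, 10L),
                     bleachModel = list(model = "none", rate = NA_real_,
                                        fitFrames = integer()),
                     roiId = "roi1", meta = list()) {
  dt <- if (length(times) > 1) stats::median(diff(times)) else NA_real_
  new("DffTrace", times = as.numeric(times), dff = as.numeric(dff),
      f0 = as.numeric(f0), baselineFrames = as.integer(baselineFrames),
      bleachModel = bleachModel, roiId = as.character(roiId),
      meta = defaultMeta(meta, dt))
}

setMethod("show", "DffTrace", function(object) {
  cat(sprintf(
    "DffTrace '%s': %d frames, F0 = %.4g (frames %d-%d), bleach = %s\n",
    object@roiId, length(object@times), object@f0,
    object@baselineFrames[1], object@baselineFrames[2],
    object@bleachModel$model))
  cat(sprintf("  dF/F0 range: [%.3g, %.3g]\n",
              min(object@dff), max(object@dff)))
})

## GenerativeParams ------------------------------------------------------------

#' Full specification of the synthetic trace model
#'
#' Encodes everything needed to generate one synthetic pollen recording:
#' acquisition grid, baseline fluorescence, multiplicative photobleaching
#' rate, additive Gaussian noise, the ordered phase plan (resting and
#' oscillation phases with per-phase period and amplitude ranges), spike
#' kinetics per amplitude class, an optional hypo-osmotic shock protocol,
#' and the seed. Usually built by \code{\link{osmolarityToParams}}.
#'
#' @slot mode "germination" or "shock".
#' @slot genotype label, "WT" or "osca2.1/2.2".
#' @slot osmolarityMosm medium (or pre-incubation) osmolarity in mOsm.
#' @slot frameIntervalS acquisition interval in seconds.
#' @slot nFrames number of frames (>= 20 so the baseline rule applies).
#' @slot baselineF0 baseline fluorescence, a.u.
#' @slot bleachRate mono-exponential photobleaching rate, 1/s (>= 0).
#' @slot noiseSd additive Gaussian noise s.d. on raw intensity, a.u. (>= 0).
#' @slot phasePlan data.frame with columns \code{label}, \code{class}
#'   ("none", "small", "large"), \code{durationS}, \code{periodS},
#'   \code{ampLo}, \code{ampHi} (amplitudes as F/F0 ratios).
#' @slot spikeShapes list with \code{small} and \code{large} elements, each
#'   \code{list(riseS, tauS)}: linear rise time and exponential decay
#'   constant in seconds.
#' @slot shock list; empty for germination mode, otherwise
#'   \code{shockTimesS}, \code{peakDff}, \code{decayTauS}, \code{riseTimeS},
#'   \code{desensitizationFactor} (in (0, 1]).
#' @slot seed integer seed for all randomness in generation.
#' @export
setClass("GenerativeParams",
         representation(mode = "character", genotype = "character",
                        osmolarityMosm = "numeric",
                        frameIntervalS = "numeric", nFrames = "integer",
                        baselineF0 = "numeric", bleachRate = "numeric",
                        noiseSd = "numeric", phasePlan = "data.frame",
                        spikeShapes = "list", shock = "list",
                        seed = "integer"))

planCols <- c("label", "class", "durationS", "periodS", "ampLo", "ampHi")

setValidity("GenerativeParams", function(object) {
  msgs <- character()
  if (!(object@mode %in% c("germination", "shock")))
    msgs <- c(msgs, "mode must be 'germination' or 'shock'")
  if (object@nFrames < 20L)
    msgs <- c(msgs, "nFrames must be >= 20 (baseline needs 10 stable frames)")
  if (object@frameIntervalS <= 0) msgs <- c(msgs, "frameIntervalS must be > 0")
  if (object@baselineF0 <= 0) msgs <- c(msgs, "baselineF0 must be > 0")
  if (object@bleachRate < 0) msgs <- c(msgs, "bleachRate must be >= 0")
  if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be >= 0")
  pp <- object@phasePlan
  if (nrow(pp)) {
    if (!all(planCols %in% names(pp)))
      msgs <- c(msgs, paste("phasePlan needs columns:",
                            paste(planCols, collapse = ", ")))
    else {
      if (!all(pp$class %in% c("none", "small", "large")))
        msgs <- c(msgs, "phasePlan$class must be none/small/large")
      osc <- pp$class != "none"
      if (any(osc & (!is.finite(pp$periodS) | pp$periodS <= 0)))
        msgs <- c(msgs, "oscillation phases need a positive periodS")
      if (any(osc & (pp$ampLo < 1 | pp$ampHi < pp$ampLo)))
        msgs <- c(msgs, "amplitude ranges must satisfy 1 <= ampLo <= ampHi")
      if (any(pp$durationS < 0)) msgs <- c(msgs, "durations must be >= 0")
    }
  }
  if (length(object@shock)) {
    s <- object@shock
    need <- c("shockTimesS", "peakDff", "decayTauS", "riseTimeS",
              "desensitizationFactor")
    if (!all(need %in% names(s)))
      msgs <- c(msgs, paste("shock needs:", paste(need, collapse = ", ")))
    else if (s$desensitizationFactor <= 0 || s$desensitizationFactor > 1)
      msgs <- c(msgs, "desensitizationFactor must be in (0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct GenerativeParams
#'
#' Low-level constructor; \code{\link{osmolarityToParams}} builds the
#' presets that mirror wild-type and mutant pollen behaviour.
#'
#' @param mode "germination" or "shock".
#' @param genotype genotype label.
#' @param osmolarityMosm medium osmolarity, mOsm.
#' @param frameIntervalS frame interval, s.
#' @param nFrames frame count.
#' @param baselineF0 baseline fluorescence, a.u.
#' @param bleachRate photobleaching rate, 1/s.
#' @param noiseSd additive noise s.d., a.u.
#' @param phasePlan phase plan data.frame (see class docs).
#' @param spikeShapes per-class spike kinetics.
#' @param shock shock protocol list or \code{list()}.
#' @param seed integer seed.
#' @return A validated \linkS4class{GenerativeParams}.
#' @export
generativeParams <- function(mode = "germination", genotype = "WT",
                             osmolarityMosm = 535, frameIntervalS = 30,
                             nFrames = 600L, baselineF0 = 100,
                             bleachRate = 2e-5, noiseSd = 2,
                             phasePlan = emptyPhasePlan(),
                             spikeShapes = defaultSpikeShapes(),
                             shock = list(), seed = 1L) {
  new("GenerativeParams", mode = mode, genotype = genotype,
      osmolarityMosm = as.numeric(osmolarityMosm),
      frameIntervalS = as.numeric(frameIntervalS),
      nFrames = as.integer(nFrames), baselineF0 = as.numeric(baselineF0),
      bleachRate = as.numeric(bleachRate), noiseSd = as.numeric(noiseSd),
      phasePlan = phasePlan, spikeShapes = spikeShapes, shock = shock,
      seed = as.integer(seed))
}

#' @rdname generativeParams
#' @export
emptyPhasePlan <- function() {
  data.frame(label = character(), class = character(), durationS = numeric(),
             periodS = numeric(), ampLo = numeric(), ampHi = numeric(),
             stringsAsFactors = FALSE)
}

#' @rdname generativeParams
#' @export
defaultSpikeShapes <- function() {
  list(small = list(riseS = 30, tauS = 45),
       large = list(riseS = 30, tauS = 60))
}

setMethod("show", "GenerativeParams", function(object) {
  cat(sprintf("GenerativeParams [%s] %s @ %g mOsm, seed %d\n", object@mode,
              object@genotype, object@osmolarityMosm, object@seed))
  cat(sprintf("  %d frames x %gs, F0 = %g, bleach = %g/s, noise sd = %g\n",
              object@nFrames, object@frameIntervalS, object@baselineF0,
              object@bleachRate, object@noiseSd))
  if (nrow(object@phasePlan))
    cat("  plan:", paste(object@phasePlan$label, collapse = " -> "), "\n")
  if (length(object@shock))
    cat(sprintf("  shocks at %s s, peak dF/F0 = %g, tau = %gs\n",
                paste(object@shock$shockTimesS, collapse = ", "),
                object@shock$peakDff, object@shock$decayTauS))
})

## Accessors -------------------------------------------------------------------

#' Accessors for trace objects
#'
#' @param x a \linkS4class{CaTrace} or \linkS4class{DffTrace}.
#' @return \code{traceTimes}: numeric seconds; \code{traceValues}: raw
#'   fluorescence (CaTrace only); \code{dffValues}: dF/F0 (DffTrace only);
#'   \code{traceMeta}: metadata list; \code{roiLabel}: ROI label;
#'   \code{baselineF0}, \code{baselineFrames}, \code{bleachModel}: the F0
#'   bookkeeping of a DffTrace.
#' @name trace-accessors
NULL

#' @rdname trace-accessors
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))
#' @rdname trace-accessors
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))
#' @rdname trace-accessors
#' @export
setGeneric("dffValues", function(x) standardGeneric("dffValues"))
#' @rdname trace-accessors
#' @export
setGeneric("traceMeta", function(x) standardGeneric("traceMeta"))
#' @rdname trace-accessors
#' @export
setGeneric("roiLabel", function(x) standardGeneric("roiLabel"))
#' @rdname trace-accessors
#' @export
setGeneric("baselineF0", function(x) standardGeneric("baselineF0"))
#' @rdname trace-accessors
#' @export
setGeneric("baselineFrames", function(x) standardGeneric("baselineFrames"))
#' @rdname trace-accessors
#' @export
setGeneric("bleachModel", function(x) standardGeneric("bleachModel"))

#' @rdname trace-accessors
setMethod("traceTimes", "CaTrace", function(x) x@times)
#' @rdname trace-accessors
setMethod("traceTimes", "DffTrace", function(x) x@times)
#' @rdname trace-accessors
setMethod("traceValues", "CaTrace", function(x) x@values)
#' @rdname trace-accessors
setMethod("dffValues", "DffTrace", function(x) x@dff)
#' @rdname trace-accessors
setMethod("traceMeta", "CaTrace", function(x) x@meta)
#' @rdname trace-accessors
setMethod("traceMeta", "DffTrace", function(x) x@meta)
#' @rdname trace-accessors
setMethod("roiLabel", "CaTrace", function(x) x@roiId)
#' @rdname trace-accessors
setMethod("roiLabel", "DffTrace", function(x) x@roiId)
#' @rdname trace-accessors
setMethod("baselineF0", "DffTrace", function(x) x@f0)
#' @rdname trace-accessors
setMethod("baselineFrames", "DffTrace", function(x) x@baselineFrames)
#' @rdname trace-accessors
setMethod("bleachModel", "DffTrace", function(x) x@bleachModel)
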