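## Spike detection and amplitude classification on dF/F0 traces.
##
## Events are local maxima of the (optionally smoothed) dF/F0 trace whose
## raw peak exceeds a detection floor; the small/large class boundary is the
## five-times-baseline-or-more criterion, i.e. dF/F0 >= 4. Small events
## correspond to the 2-3x baseline flashes (dF/F0 of 1-2).

#' Detection settings
#'
#' @param detectMinDff detection floor on raw peak dF/F0 (default 1.0, the
#'   lower edge of the small-event range, F/F0 = 2).
#' @param largeMinDff small/large class boundary on peak dF/F0 (default
#'   4.0, i.e. F/F0 = 5; five times baseline or more is large).
#' @param onsetFraction onset/offset are the crossings of this fraction of
#'   the peak (default 0.2).
#' @param minGapS minimal peak separation in seconds; default two frame
#'   intervals, resolved at detection time.
#' @param smoothFrames centered moving-average width (odd); 3 for
#'   germination-mode traces, 1 (none) for shock mode. The threshold and
#'   the reported peak are always taken on the unsmoothed trace.
#' @param mode convenience preset: "germination" (smoothing 3) or "shock"
#'   (no smoothing).
#' @return A list of class \code{DetectionConfig}.
#' @export
detectionConfig <- function(detectMinDff = 1, largeMinDff = 4,
                            onsetFraction = 0.2, minGapS = NULL,
                            smoothFrames = NULL,
                            mode = c("germination", "shock")) {
  mode <- match.arg(mode)
  if (is.null(smoothFrames))
    smoothFrames <- if (mode == "shock") 1L else 3L
  if (!(detectMinDff > 0 && largeMinDff > detectMinDff))
    pcoStop("invalid_input", "need 0 < detectMinDff < largeMinDff")
  if (!(onsetFraction > 0 && onsetFraction < 1))
    pcoStop("invalid_input", "onsetFraction must be in (0, 1)")
  if (smoothFrames < 1 || smoothFrames %% 2 == 0)
    pcoStop("invalid_input", "smoothFrames must be odd and >= 1")
  structure(list(detectMinDff = detectMinDff, largeMinDff = largeMinDff,
                 onsetFraction = onsetFraction, minGapS = minGapS,
                 smoothFrames = as.integer(smoothFrames), mode = mode),
            class = "DetectionConfig")
}

## Centered moving average with shrinking windows at the edges.
movingAverage <- function(x, w) {
  if (w <= 1) return(x)
  h <- w %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

emptyEvents <- function() {
  data.frame(roi_id = character(), peak_time_s = numeric(),
             peak_dff = numeric(), trough_dff = numeric(),
             onset_s = numeric(), offset_s = numeric(),
             duration_s = numeric(), class = character(),
             stringsAsFactors = FALSE)
}

#' Detect calcium spikes on a dF/F0 trace
#'
#' Candidate peaks are local maxima of the smoothed trace (plateaus count
#' once, at their first frame), refined to the raw-trace maximum within the
#' smoothing half-width. Candidates whose raw peak is below
#' \code{detectMinDff} are dropped; the remainder are accepted greedily by
#' decreasing height (ties to the earlier peak) subject to a minimal peak
#' separation of \code{minGapS}. Onset and offset are the crossings of
#' \code{onsetFraction * peak} before and after the peak, the offset capped
#' at the next event's onset so events never overlap. The trough is the
#' minimal dF/F0 between a peak and the following one (or the trace end).
#'
#' @param dff a \linkS4class{DffTrace}.
#' @param cfg a \code{\link{detectionConfig}}.
#' @return data.frame with one row per event: \code{roi_id},
#'   \code{peak_time_s}, \code{peak_dff}, \code{trough_dff}, \code{onset_s},
#'   \code{offset_s}, \code{duration_s}, \code{class} ("small"/"large"),
#'   sorted by peak time. Zero rows when nothing is detected.
#' @seealso [classifySpikes()], [spikeMetrics()]
#' @export
detectSpikes <- function(dff, cfg = detectionConfig()) {
  x <- dffValues(dff)
  t <- traceTimes(dff)
  n <- length(x)
  dt <- stats::median(diff(t))
  minGap <- cfg$minGapS %||% (2 * dt)
  s <- movingAverage(x, cfg$smoothFrames)

  cand <- which(s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n]) + 1L
  if (!length(cand)) return(emptyEvents())
  h <- cfg$smoothFrames %/% 2L
  ref <- vapply(cand, function(i) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  ref <- unique(pmin(pmax(ref, 2L), n - 1L))
  ref <- ref[x[ref] >= cfg$detectMinDff]
  if (!length(ref)) return(emptyEvents())

  ord <- ref[order(-x[ref], t[ref])]
  acc <- integer()
  for (i in ord)
    if (!length(acc) || all(abs(t[i] - t[acc]) >= minGap))
      acc <- c(acc, i)
  acc <- sort(acc)

  k <- length(acc)
  onset <- offset <- trough <- numeric(k)
  for (j in seq_len(k)) {
    p <- acc[j]
    thr <- cfg$onsetFraction * x[p]
    below <- which(x[seq_len(p - 1L)] <= thr)
    onset[j] <- if (length(below)) t[max(below)] else t[1]
    after <- which(x[(p + 1L):n] <= thr)
    offset[j] <- if (length(after)) t[p + after[1]] else t[n]
    nxt <- if (j < k) acc[j + 1L] else n
    trough[j] <- if (p < nxt) min(x[(p + 1L):nxt]) else x[p]
  }
  for (j in seq_len(k - 1L))
    offset[j] <- max(min(offset[j], onset[j + 1L]), t[acc[j] + 1L])

  data.frame(roi_id = roiLabel(dff), peak_time_s = t[acc],
             peak_dff = x[acc], trough_dff = trough, onset_s = onset,
             offset_s = offset, duration_s = offset - onset,
             class = classifySpikes(x[acc], cfg), stringsAsFactors = FALSE)
}

#' Classify spike amplitudes as small or large
#'
#' An event is large iff its peak dF/F0 is at least \code{largeMinDff}
#' (default 4, i.e. F/F0 >= 5: five times baseline or more); everything
#' else, including the 3-5x band, is small.
#'
#' @param peakDff numeric vector of peak dF/F0 values.
#' @param cfg a \code{\link{detectionConfig}}.
#' @return Character vector, "small" or "large".
#' @examples
#' classifySpikes(c(1.5, 3.999, 4.0))   # small, small, large
#' @export
classifySpikes <- function(peakDff, cfg = detectionConfig()) {
  ifelse(peakDff >= cfg$largeMinDff, "large", "small")
}

#' Per-class oscillation metrics
#'
#' Summarizes a detected event list per amplitude class: counts, amplitude
#' (both the peak dF/F0 and peak-minus-trough), duration, period (mean of
#' successive same-class peak-to-peak intervals, defined for >= 2 events)
#' and frequency in events/min over the class's active span,
#' \code{(count - 1)/(last - first peak)}.
#'
#' @param events event data.frame from \code{\link{detectSpikes}}.
#' @param spanS recorded span in seconds (kept for bookkeeping; frequencies
#'   use the class's own active span).
#' @return data.frame with one row per class ("small", "large"):
#'   \code{count}, \code{amp_mean}, \code{amp_sd}, \code{amp_pt_mean},
#'   \code{amp_pt_sd}, \code{dur_mean}, \code{dur_sd}, \code{period_mean},
#'   \code{period_sd}, \code{freq_per_min}, \code{first_event_s}. Undefined
#'   statistics are NA; counts and frequencies are 0 when empty.
#' @examples
#' ev <- data.frame(roi_id = "r", peak_time_s = c(0, 300, 600),
#'                  peak_dff = 5, trough_dff = 0, onset_s = c(0, 290, 590),
#'                  offset_s = c(60, 360, 600), duration_s = 60,
#'                  class = "large")
#' spikeMetrics(ev, 600)[2, c("period_mean", "freq_per_min")]  # 300, 0.2
#' @export
spikeMetrics <- function(events, spanS) {
  perClass <- lapply(c("small", "large"), function(cl) {
    e <- events[events$class == cl, , drop = FALSE]
    cnt <- nrow(e)
    periods <- if (cnt >= 2) diff(e$peak_time_s) else numeric()
    freq <- if (cnt >= 2)
      60 * (cnt - 1) / (max(e$peak_time_s) - min(e$peak_time_s)) else 0
    data.frame(
      class = cl, count = cnt,
      amp_mean = if (cnt) mean(e$peak_dff) else NA_real_,
      amp_sd = if (cnt > 1) stats::sd(e$peak_dff) else NA_real_,
      amp_pt_mean = if (cnt) mean(e$peak_dff - e$trough_dff) else NA_real_,
      amp_pt_sd = if (cnt > 1) stats::sd(e$peak_dff - e$trough_dff)
                  else NA_real_,
      dur_mean = if (cnt) mean(e$duration_s) else NA_real_,
      dur_sd = if (cnt > 1) stats::sd(e$duration_s) else NA_real_,
      period_mean = if (length(periods)) mean(periods) else NA_real_,
      period_sd = if (length(periods) > 1) stats::sd(periods) else NA_real_,
      freq_per_min = freq,
      first_event_s = if (cnt) min(e$peak_time_s) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, perClass)
  attr(out, "spanS") <- spanS
  out
}
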