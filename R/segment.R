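## Phase segmentation: the resting/oscillation grammar of germinating
## pollen. A recording decomposes into a first resting phase (RePh1), a
## train of small-amplitude oscillations (CaOscS), a second resting phase
## (RePh2), a train of large-amplitude oscillations (CaOscL) and a final
## resting phase (RePh3); the CaOscS -> RePh2 -> CaOscL -> RePh3 module may
## recur, in which case repeats carry an _r<k> suffix.

#' Segmentation settings
#'
#' @param restMinGapS minimal event-free interval, in seconds, that opens a
#'   resting segment (default 600 s = 20 frames at 30 s): resting phases
#'   span tens of minutes whereas within-train gaps are a few minutes.
#' @return A list of class \code{SegmentationConfig}.
#' @export
segmentationConfig <- function(restMinGapS = 600) {
  if (!is.finite(restMinGapS) || restMinGapS <= 0)
    pcoStop("invalid_input", "restMinGapS must be > 0")
  structure(list(restMinGapS = restMinGapS), class = "SegmentationConfig")
}

restRow <- function(label, start, end)
  data.frame(label = label, class = "rest", start_s = start, end_s = end,
             n_events = 0L, stringsAsFactors = FALSE)

oscRow <- function(label, cls, start, end, nEv)
  data.frame(label = label, class = cls, start_s = start, end_s = end,
             n_events = nEv, stringsAsFactors = FALSE)

#' Segment a trace into resting and oscillation phases
#'
#' Greedy left-to-right labelling of a classified, sorted event list.
#' Events separated by quiet intervals shorter than \code{restMinGapS} form
#' one oscillation run; longer quiet intervals become resting segments. A
#' run that contains a large event is split at the first large event's
#' onset: the preceding small events form a CaOscS segment and the
#' remainder is promoted to CaOscL. A leading quiet interval of at least
#' \code{restMinGapS} is RePh1 (an all-quiet trace is one RePh1 spanning
#' the recording); the rest after a CaOscS run is RePh2, after a CaOscL run
#' RePh3. Later modules repeat these labels with an \code{_r<k>} suffix.
#' Segments tile the span exactly.
#'
#' @param events event data.frame from \code{\link{detectSpikes}}.
#' @param span recorded interval: \code{c(start, end)} in seconds, or a
#'   scalar end (start 0).
#' @param cfg a \code{\link{segmentationConfig}}.
#' @return data.frame with columns \code{label}, \code{class}
#'   ("rest"/"small"/"large"), \code{start_s}, \code{end_s},
#'   \code{n_events}.
#' @seealso [countModules()]
#' @export
segmentPhases <- function(events, span, cfg = segmentationConfig()) {
  if (length(span) == 1) span <- c(0, span)
  gap <- cfg$restMinGapS
  if (!nrow(events))
    return(restRow("RePh1", span[1], span[2]))
  ev <- events[order(events$peak_time_s), , drop = FALSE]
  quiet <- if (nrow(ev) > 1)
    ev$onset_s[-1] - ev$offset_s[-nrow(ev)] else numeric()
  runId <- cumsum(c(1L, as.integer(quiet >= gap)))

  ## decompose runs into (class, event-index) pieces, splitting mixed runs
  ## at the first large event's onset
  pieces <- list()
  for (r in unique(runId)) {
    idx <- which(runId == r)
    firstLarge <- idx[which(ev$class[idx] == "large")[1]]
    if (is.na(firstLarge) || firstLarge == idx[1]) {
      cls <- if (is.na(firstLarge)) "small" else "large"
      pieces[[length(pieces) + 1L]] <- list(class = cls, idx = idx,
                                            endAt = NA_real_,
                                            startAt = NA_real_)
    } else {
      splitAt <- ev$onset_s[firstLarge]
      pieces[[length(pieces) + 1L]] <-
        list(class = "small", idx = idx[idx < firstLarge], endAt = splitAt,
             startAt = NA_real_)
      pieces[[length(pieces) + 1L]] <-
        list(class = "large", idx = idx[idx >= firstLarge],
             endAt = NA_real_, startAt = splitAt)
    }
  }

  segs <- list()
  cursor <- span[1]
  m <- 0L
  lastOsc <- NA_character_
  for (k in seq_along(pieces)) {
    pc <- pieces[[k]]
    runStart <- if (is.na(pc$startAt)) ev$onset_s[pc$idx[1]] else pc$startAt
    runEnd <- if (is.na(pc$endAt))
      min(ev$offset_s[pc$idx[length(pc$idx)]], span[2]) else pc$endAt
    if (runStart - cursor >= gap) {
      restLabel <- if (is.na(lastOsc)) "RePh1"
      else if (lastOsc == "small") paste0("RePh2", moduleSuffix(m))
      else paste0("RePh3", moduleSuffix(m))
      segs[[length(segs) + 1L]] <- restRow(restLabel, cursor, runStart)
      segStart <- runStart
    } else segStart <- cursor
    if (pc$class == "small") {
      if (is.na(lastOsc) || lastOsc == "large") m <- m + 1L
      label <- paste0("CaOscS", moduleSuffix(m))
    } else {
      if (m == 0L) m <- 1L
      label <- paste0("CaOscL", moduleSuffix(m))
    }
    segs[[length(segs) + 1L]] <-
      oscRow(label, pc$class, segStart, runEnd, length(pc$idx))
    lastOsc <- pc$class
    cursor <- runEnd
  }
  if (span[2] - cursor >= gap) {
    label <- if (lastOsc == "small") paste0("RePh2", moduleSuffix(m))
             else paste0("RePh3", moduleSuffix(m))
    segs[[length(segs) + 1L]] <- restRow(label, cursor, span[2])
  } else if (span[2] > cursor) {
    segs[[length(segs)]]$end_s <- span[2]
  }
  do.call(rbind, segs)
}

moduleSuffix <- function(m) if (m <= 1L) "" else paste0("_r", m)

#' Count completed oscillation modules
#'
#' A module is a CaOscS train followed (resting segments in between are
#' optional) by a CaOscL train. Counts the maximal number of such
#' non-overlapping subsequences in segment order; an isolated CaOscS or a
#' CaOscL with no preceding CaOscS does not complete a module.
#'
#' @param segments segmentation data.frame from \code{\link{segmentPhases}}.
#' @return Integer module count.
#' @examples
#' segs <- data.frame(label = c("RePh1", "CaOscS", "RePh2", "CaOscL"),
#'                    class = c("rest", "small", "rest", "large"),
#'                    start_s = c(0, 100, 200, 300),
#'                    end_s = c(100, 200, 300, 400),
#'                    n_events = c(0L, 3L, 0L, 2L))
#' countModules(segs)   # 1
#' @export
countModules <- function(segments) {
  osc <- segments$class[segments$class %in% c("small", "large")]
  pending <- FALSE
  count <- 0L
  for (cl in osc) {
    if (cl == "small") pending <- TRUE
    else if (pending) {
      count <- count + 1L
      pending <- FALSE
    }
  }
  count
}
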