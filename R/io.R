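## Trace-table input/output.
##
## The canonical on-disk dialect is a long CSV (time_s, roi_id, F), with a
## two-channel variant (time_s, roi_id, F_ch1, F_ch2) for ratiometric
## recordings; wide tables (time_s plus one column per ROI) are accepted on
## read. Acquisition metadata travels in a JSON sidecar named
## <table>.meta.json, keyed by ROI.

sidecarPath <- function(path)
  paste0(tools::file_path_sans_ext(path), ".meta.json")

#' Write traces to a long CSV table plus a JSON metadata sidecar
#'
#' @param traces a \linkS4class{CaTrace} or list of them.
#' @param path output CSV path; metadata goes to
#'   \code{<path sans ext>.meta.json}.
#' @param sidecar write the metadata sidecar?
#' @return The CSV path, invisibly.
#' @seealso [readTraces()]
#' @export
writeTraces <- function(traces, path, sidecar = TRUE) {
  if (is(traces, "CaTrace")) traces <- list(traces)
  tab <- do.call(rbind, lapply(traces, function(tr)
    data.frame(time_s = traceTimes(tr), roi_id = roiLabel(tr),
               F = traceValues(tr), stringsAsFactors = FALSE)))
  utils::write.csv(tab, path, row.names = FALSE)
  if (sidecar) {
    meta <- lapply(traces, traceMeta)
    names(meta) <- vapply(traces, roiLabel, character(1))
    jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null")
  }
  invisible(path)
}

#' Read traces from a delimited table
#'
#' Accepts the long dialect (\code{time_s, roi_id, F}), the two-channel
#' dialect (\code{time_s, roi_id, F_ch1, F_ch2}; each channel becomes a
#' trace with suffix \code{_ch1}/\code{_ch2}, ready for
#' \code{\link{ratiometricTrace}}), or a wide table (\code{time_s} plus one
#' numeric column per ROI). Rows are sorted by time; duplicate (time, roi)
#' rows and non-uniform time grids are format errors. A
#' \code{<path>.meta.json} sidecar, if present, attaches per-ROI metadata.
#'
#' @param path CSV path.
#' @param format "auto" (default), "long", "two_channel" or "wide".
#' @param meta extra metadata merged into every trace.
#' @return A named list of \linkS4class{CaTrace}.
#' @export
readTraces <- function(path, format = c("auto", "long", "two_channel",
                                        "wide"), meta = list()) {
  format <- match.arg(format)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time_s" %in% names(tab))
    pcoStop("format", "trace table must have a 'time_s' column")
  if (format == "auto") {
    format <- if (all(c("roi_id", "F") %in% names(tab))) "long"
    else if (all(c("roi_id", "F_ch1", "F_ch2") %in% names(tab))) "two_channel"
    else "wide"
  }
  sc <- sidecarPath(path)
  sideMeta <- if (file.exists(sc)) jsonlite::read_json(sc) else list()

  buildOne <- function(times, values, id) {
    ord <- order(times)
    times <- times[ord]; values <- values[ord]
    if (anyDuplicated(times))
      pcoStop("format", sprintf("duplicated (time, roi) rows for '%s'", id))
    if (!isUniformGrid(times))
      pcoStop("format",
              sprintf("non-uniform time grid for '%s'", id))
    m <- meta
    side <- sideMeta[[sub("_ch[0-9]+$", "", id)]] %||% sideMeta[[id]]
    if (!is.null(side)) m <- utils::modifyList(lapply(side, unlist), m)
    tryCatch(CaTrace(times, values, roiId = id, meta = m),
             error = function(e) pcoStop("format", conditionMessage(e)))
  }

  if (format == "wide") {
    ids <- setdiff(names(tab), "time_s")
    out <- lapply(ids, function(id) buildOne(tab$time_s, tab[[id]], id))
    names(out) <- ids
    return(out)
  }
  if (!"roi_id" %in% names(tab))
    pcoStop("format", "long trace tables need a 'roi_id' column")
  ids <- unique(tab$roi_id)
  cols <- if (format == "two_channel") c("F_ch1", "F_ch2") else "F"
  if (!all(cols %in% names(tab)))
    pcoStop("format", paste("missing value column(s):",
                            paste(setdiff(cols, names(tab)), collapse = ", ")))
  out <- list()
  for (id in ids) {
    sub <- tab[tab$roi_id == id, , drop = FALSE]
    if (format == "two_channel") {
      out[[paste0(id, "_ch1")]] <- buildOne(sub$time_s, sub$F_ch1,
                                            paste0(id, "_ch1"))
      out[[paste0(id, "_ch2")]] <- buildOne(sub$time_s, sub$F_ch2,
                                            paste0(id, "_ch2"))
    } else {
      out[[id]] <- buildOne(sub$time_s, sub$F, id)
    }
  }
  out
}

#' Read and write ROI definition tables
#'
#' Plain CSV with columns \code{roi_id, x, y, radius_px}; coordinates are
#' 0-based pixels, x to the right, y down.
#'
#' @param rois data.frame of ROI definitions.
#' @param path CSV path.
#' @return \code{readRoiTable}: the data.frame; \code{writeRoiTable}: the
#'   path, invisibly.
#' @export
writeRoiTable <- function(rois, path) {
  utils::write.csv(rois[, c("roi_id", "x", "y", "radius_px")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname writeRoiTable
#' @export
readRoiTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "x", "y", "radius_px")
  if (!all(need %in% names(tab)))
    pcoStop("format", paste("ROI table needs columns:",
                            paste(need, collapse = ", ")))
  tab
}
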