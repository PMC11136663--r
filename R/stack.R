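## Synthetic image stacks and ROI trace extraction.
##
## Stacks are arrays [rows (y), cols (x), frames] of intensities in a.u.
## Pixel coordinates are 0-based with x to the right and y down; a pixel
## belongs to a circular ROI when its centre distance is <= radius. ROIs are
## fixed over time: fluorescence-area growth is deliberately not tracked.

roiMask <- function(nrow, ncol, x, y, radius) {
  px <- matrix(rep(seq_len(ncol) - 1, each = nrow), nrow = nrow)
  py <- matrix(rep(seq_len(nrow) - 1, times = ncol), nrow = nrow)
  (px - x)^2 + (py - y)^2 <= radius^2
}

checkRoiBounds <- function(roi, nrow, ncol) {
  roi$x - roi$radius >= 0 && roi$x + roi$radius <= ncol - 1 &&
    roi$y - roi$radius >= 0 && roi$y + roi$radius <= nrow - 1 &&
    roi$radius > 0
}

#' Render synthetic grains into an image stack
#'
#' Each grain is a disc whose pixels all take the grain's generated trace
#' value frame by frame, over a constant background, so the disc mean
#' recovers the trace exactly in the noise-free case.
#'
#' @param params a \linkS4class{GenerativeParams} or a list of one per
#'   grain; with a single parameter set, per-grain seeds are derived from
#'   \code{params@seed} so grains differ.
#' @param layout data.frame with columns \code{roi_id}, \code{x}, \code{y},
#'   \code{radius_px} (0-based pixel coordinates); zero rows give a
#'   background-only stack.
#' @param imageSize c(rows, cols) of each frame.
#' @param background background intensity, a.u.
#' @return \code{list(stack, rois, traces, truths)}: the stack array, the
#'   layout echoed back, and per-grain \linkS4class{CaTrace}s with their
#'   ground truths.
#' @export
generateImageStack <- function(params, layout,
                               imageSize = c(64L, 64L), background = 10) {
  if (is(params, "GenerativeParams")) {
    base <- params
    params <- lapply(seq_len(max(nrow(layout), 1L)), function(i) {
      p <- base
      p@seed <- as.integer((base@seed + i * 7919L) %% .Machine$integer.max)
      p
    })
  }
  nr <- imageSize[1]; nc <- imageSize[2]
  if (nrow(layout)) {
    if (length(params) < nrow(layout))
      pcoStop("invalid_input", "need one parameter set per grain")
    for (i in seq_len(nrow(layout)))
      if (!checkRoiBounds(list(x = layout$x[i], y = layout$y[i],
                               radius = layout$radius_px[i]), nr, nc))
        pcoStop("invalid_layout", sprintf("grain '%s' is outside the frame",
                                          layout$roi_id[i]))
    if (nrow(layout) > 1) {
      for (i in seq_len(nrow(layout) - 1)) for (j in (i + 1):nrow(layout)) {
        d <- sqrt((layout$x[i] - layout$x[j])^2 +
                  (layout$y[i] - layout$y[j])^2)
        if (d < layout$radius_px[i] + layout$radius_px[j])
          pcoStop("invalid_layout", sprintf("grains '%s' and '%s' overlap",
                                            layout$roi_id[i],
                                            layout$roi_id[j]))
      }
    }
  }
  outs <- lapply(seq_len(nrow(layout)), function(i) {
    p <- params[[i]]
    if (length(p@shock)) generateShockTrace(p, roiId = layout$roi_id[i])
    else generateTrace(p, roiId = layout$roi_id[i])
  })
  nF <- if (length(outs)) length(traceTimes(outs[[1]]$trace))
        else if (length(params)) params[[1]]@nFrames else 20L
  stack <- array(background, dim = c(nr, nc, nF))
  for (i in seq_along(outs)) {
    m <- roiMask(nr, nc, layout$x[i], layout$y[i], layout$radius_px[i])
    v <- traceValues(outs[[i]]$trace)
    for (f in seq_len(nF)) {
      fr <- stack[, , f]
      fr[m] <- v[f]
      stack[, , f] <- fr
    }
  }
  list(stack = stack, rois = layout,
       traces = lapply(outs, `[[`, "trace"),
       truths = lapply(outs, `[[`, "truth"))
}

#' Extract per-ROI mean-intensity traces from an image stack
#'
#' @param stack array \[rows, cols, frames\].
#' @param rois data.frame with \code{roi_id}, \code{x}, \code{y},
#'   \code{radius_px} (0-based coordinates).
#' @param frameIntervalS acquisition interval, s.
#' @param meta metadata attached to every extracted trace.
#' @return List of \linkS4class{CaTrace}, one per ROI (empty list for an
#'   empty ROI table).
#' @export
extractRoiTraces <- function(stack, rois, frameIntervalS = 30,
                             meta = list()) {
  d <- dim(stack)
  if (length(d) != 3) pcoStop("invalid_input", "stack must be a 3-d array")
  lapply(seq_len(nrow(rois)), function(i) {
    if (!checkRoiBounds(list(x = rois$x[i], y = rois$y[i],
                             radius = rois$radius_px[i]), d[1], d[2]))
      pcoStop("invalid_roi", sprintf("ROI '%s' lies outside the stack",
                                     rois$roi_id[i]))
    m <- roiMask(d[1], d[2], rois$x[i], rois$y[i], rois$radius_px[i])
    vals <- vapply(seq_len(d[3]), function(f) mean(stack[, , f][m]),
                   numeric(1))
    CaTrace((seq_len(d[3]) - 1) * frameIntervalS, vals,
            roiId = as.character(rois$roi_id[i]),
            meta = c(meta, list(frameIntervalS = frameIntervalS)))
  })
}

#' Read and write grayscale multi-page TIFF stacks
#'
#' Intensities are stored as 16-bit samples; in-memory stacks are in a.u.
#' on \[0, 65535\] and are scaled on write, so a round trip quantizes values
#' to the nearest integer step at most.
#'
#' @param stack array \[rows, cols, frames\] with values in \[0, 65535\].
#' @param path file path.
#' @return \code{readStack}: the stack array; \code{writeStack}: the path,
#'   invisibly.
#' @export
writeStack <- function(stack, path) {
  pages <- lapply(seq_len(dim(stack)[3]),
                  function(f) pmin(pmax(stack[, , f] / 65535, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname writeStack
#' @export
readStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2],
                          length(pages)))
  for (f in seq_along(pages)) arr[, , f] <- pages[[f]] * 65535
  arr
}
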