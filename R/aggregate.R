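## Cohort-level aggregation: per-trace pipeline, grouped summaries over
## (genotype, osmolarity), germination rates, and relative growth-rate
## normalization for expression screens. Hypothesis testing is deliberately
## left to external tools; this module emits tidy summary tables.

#' Run the full single-trace analysis pipeline
#'
#' Raw trace to bleach-corrected dF/F0 (\code{\link{preprocessTrace}}),
#' spike detection and classification (\code{\link{detectSpikes}}),
#' per-class metrics (\code{\link{spikeMetrics}}) and, for germination-mode
#' recordings, phase segmentation and module counting.
#'
#' @param trace a \linkS4class{CaTrace}.
#' @param mode "germination" or "shock".
#' @param detectCfg a \code{\link{detectionConfig}}; defaults to the
#'   per-mode preset.
#' @param segCfg a \code{\link{segmentationConfig}}.
#' @param germinated optional logical ground-truth label carried into
#'   cohort summaries.
#' @return List with \code{roiId}, \code{meta}, \code{dff}, \code{events},
#'   \code{metrics}, \code{segments}, \code{nModules}, \code{rePh1S} (first
#'   resting-phase duration, 0 when absent), \code{germinated} and
#'   \code{config}.
#' @export
analyzeTrace <- function(trace, mode = c("germination", "shock"),
                         detectCfg = NULL, segCfg = segmentationConfig(),
                         germinated = NA) {
  mode <- match.arg(mode)
  if (is.null(detectCfg)) detectCfg <- detectionConfig(mode = mode)
  dff <- preprocessTrace(trace, mode = mode, detectCfg = detectCfg)
  events <- detectSpikes(dff, detectCfg)
  t <- traceTimes(dff)
  metrics <- spikeMetrics(events, spanS = t[length(t)] - t[1])
  segments <- nModules <- rePh1 <- NULL
  if (mode == "germination") {
    segments <- segmentPhases(events, c(t[1], t[length(t)]), segCfg)
    nModules <- countModules(segments)
    rePh1 <- if (segments$label[1] == "RePh1")
      segments$end_s[1] - segments$start_s[1] else 0
  }
  list(roiId = roiLabel(trace), meta = traceMeta(trace), dff = dff,
       events = events, metrics = metrics, segments = segments,
       nModules = nModules, rePh1S = rePh1, germinated = germinated,
       config = list(mode = mode, detect = unclass(detectCfg),
                     segment = unclass(segCfg)))
}

metricOf <- function(res, cl, col) {
  m <- res$metrics
  m[m$class == cl, col][1]
}

#' Summarize a cohort of analyzed traces by genotype and osmolarity
#'
#' Groups per-trace results by (genotype, osmolarity) and reports trace
#' counts, summed spike counts per class, across-trace means with both s.d.
#' and s.e.m. for amplitude and period per class, first-resting-phase
#' duration, module counts and (when ground-truth labels are present) the
#' germination fraction. All member traces must have been analyzed with
#' identical configurations. A trend table (sign of the rank correlation
#' between osmolarity and total spikes / CaOscL period / CaOscL amplitude
#' per genotype) is attached as attribute \code{"trends"}.
#'
#' @param results list of results from \code{\link{analyzeTrace}}; each
#'   must carry \code{genotype} and \code{osmolarityMosm} in its meta.
#' @return data.frame with one row per (genotype, osmolarity) key.
#' @export
summarizeCohort <- function(results) {
  if (!length(results)) pcoStop("invalid_input", "no results given")
  cfgs <- lapply(results, `[[`, "config")
  if (!all(vapply(cfgs[-1], identical, logical(1), y = cfgs[[1]])))
    pcoStop("config_mismatch",
            "member traces were analyzed with different configurations")
  keyOf <- function(r) paste(r$meta$genotype, r$meta$osmolarityMosm,
                             sep = "\r")
  keys <- vapply(results, keyOf, character(1))
  rows <- lapply(split(seq_along(results), keys), function(ii) {
    rs <- results[ii]
    n <- length(rs)
    counts <- function(cl)
      vapply(rs, function(r) sum(r$events$class == cl), numeric(1))
    colMean <- function(cl, col) {
      v <- vapply(rs, metricOf, numeric(1), cl = cl, col = col)
      v[is.nan(v)] <- NA
      v
    }
    disp <- function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) c(NA_real_, NA_real_)
      else c(stats::sd(v), stats::sd(v) / sqrt(length(v)))
    }
    nS <- counts("small"); nL <- counts("large")
    ampS <- colMean("small", "amp_mean"); ampL <- colMean("large", "amp_mean")
    perS <- colMean("small", "period_mean")
    perL <- colMean("large", "period_mean")
    germ <- vapply(rs, function(r) as.logical(r$germinated), logical(1))
    re1 <- vapply(rs, function(r) r$rePh1S %||% NA_real_, numeric(1))
    mods <- vapply(rs, function(r) r$nModules %||% NA_real_, numeric(1))
    data.frame(
      genotype = rs[[1]]$meta$genotype,
      osmolarity_mosm = rs[[1]]$meta$osmolarityMosm,
      n_traces = n,
      n_small = sum(nS), n_large = sum(nL), n_total = sum(nS + nL),
      amp_small_mean = mean(ampS, na.rm = TRUE),
      amp_small_sd = disp(ampS)[1], amp_small_sem = disp(ampS)[2],
      amp_large_mean = mean(ampL, na.rm = TRUE),
      amp_large_sd = disp(ampL)[1], amp_large_sem = disp(ampL)[2],
      period_small_mean = mean(perS, na.rm = TRUE),
      period_small_sd = disp(perS)[1],
      period_large_mean = mean(perL, na.rm = TRUE),
      period_large_sd = disp(perL)[1],
      reph1_mean_s = mean(re1, na.rm = TRUE),
      modules_mean = mean(mods, na.rm = TRUE),
      germination_fraction = if (all(is.na(germ))) NA_real_
                             else mean(germ, na.rm = TRUE),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$genotype, out$osmolarity_mosm), ]
  rownames(out) <- NULL
  trendSign <- function(df, col) {
    ok <- is.finite(df[[col]])
    if (sum(ok) < 2) return(NA_real_)
    sign(stats::cor(df$osmolarity_mosm[ok], df[[col]][ok],
                    method = "spearman"))
  }
  trends <- do.call(rbind, lapply(split(out, out$genotype), function(df)
    data.frame(genotype = df$genotype[1],
               total_spikes = trendSign(df, "n_total"),
               period_large = trendSign(df, "period_large_mean"),
               amp_large = trendSign(df, "amp_large_mean"),
               stringsAsFactors = FALSE)))
  rownames(trends) <- NULL
  attr(out, "trends") <- trends
  out
}

#' Germination rate in percent
#'
#' @param nGerminated number of germinated grains (0 <= n <= total).
#' @param nTotal total grains scored (> 0).
#' @return Percentage, \code{100 * nGerminated / nTotal}.
#' @examples
#' germinationRate(27, 60)   # 45
#' @export
germinationRate <- function(nGerminated, nTotal) {
  if (any(!is.finite(c(nGerminated, nTotal))) || any(nTotal <= 0))
    pcoStop("invalid_input", "nTotal must be positive")
  if (any(nGerminated < 0) || any(nGerminated > nTotal))
    pcoStop("invalid_input", "need 0 <= nGerminated <= nTotal")
  100 * nGerminated / nTotal
}

#' Normalize growth measurements to the matched uninduced control
#'
#' For each construct, the relative growth rate is the raw measure divided
#' by that construct's control-condition raw measure, so the control maps
#' to exactly 1 (controls without induction are set to 1 by convention).
#' Idempotent on already-normalized records.
#'
#' @param records data.frame with columns \code{construct},
#'   \code{condition} and \code{raw}.
#' @param controlCondition the condition label of the matched control
#'   (default "control").
#' @return The records with a \code{relative} column appended.
#' @examples
#' rec <- data.frame(construct = "osca2.1",
#'                   condition = c("control", "IPTG"), raw = c(4, 2))
#' normalizeGrowth(rec)$relative   # 1.0 0.5
#' @export
normalizeGrowth <- function(records, controlCondition = "control") {
  need <- c("construct", "condition", "raw")
  if (!all(need %in% names(records)))
    pcoStop("invalid_input", paste("records need columns:",
                                   paste(need, collapse = ", ")))
  out <- records
  out$relative <- NA_real_
  for (cs in unique(records$construct)) {
    ii <- records$construct == cs
    ctrl <- records$raw[ii & records$condition == controlCondition]
    if (!length(ctrl) || !all(is.finite(ctrl)) || mean(ctrl) <= 0)
      pcoStop("normalization",
              sprintf("construct '%s' has no positive control record", cs))
    out$relative[ii] <- records$raw[ii] / mean(ctrl)
  }
  out
}
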