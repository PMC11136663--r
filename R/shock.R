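## Hypo-osmotic shock (HOSCA) quantification: peak response, kinetics,
## mono-exponential decay, desensitization across repeated challenges, and
## dose-response versus pre-incubation osmolarity.

#' Quantify one hypo-osmotic shock transient
#'
#' The peak is the maximal dF/F0 within \code{windowS} seconds of the shock
#' (ties broken toward the earlier time); the decay constant comes from a
#' least-squares mono-exponential fit with a floating plateau,
#' \eqn{A e^{-(t - t_p)/\tau} + C}, on the frames from the peak to the end
#' of the window (traces need not return to zero).
#'
#' @param dff a \linkS4class{DffTrace} (shock recordings are typically not
#'   bleach-corrected; see \code{\link{preprocessTrace}} with
#'   \code{mode = "shock"}).
#' @param shockTimeS stimulus time, s; must lie within the trace with at
#'   least 30 frames after it.
#' @param windowS response window after the shock, s (default 300, matching
#'   1 s acquisition for 300 s).
#' @return One-row data.frame: \code{shock_time_s}, \code{peak_dff},
#'   \code{time_to_peak_s}, \code{decay_tau_s}, \code{fit_r2},
#'   \code{decay_ok}. When the decay fit fails (e.g. a flat trace) the tau
#'   is NA and \code{decay_ok} is FALSE.
#' @export
quantifyShock <- function(dff, shockTimeS, windowS = 300) {
  t <- traceTimes(dff)
  x <- dffValues(dff)
  if (shockTimeS < t[1] || shockTimeS > t[length(t)])
    pcoStop("invalid_input", "shock time lies outside the trace")
  after <- which(t >= shockTimeS)
  if (length(after) < 30)
    pcoStop("invalid_input", "need at least 30 frames after the shock")
  win <- after[t[after] <= shockTimeS + windowS]
  pk <- win[which.max(x[win])]          # which.max: earliest tie wins
  peak <- x[pk]
  fitIdx <- win[win >= pk]
  tau <- NA_real_
  r2 <- NA_real_
  ok <- FALSE
  if (peak > 0 && length(fitIdx) >= 5) {
    td <- t[fitIdx] - t[pk]
    y <- x[fitIdx]
    c0 <- min(y)
    a0 <- max(peak - c0, .Machine$double.eps)
    t0 <- max(td[length(td)] / 3, 1e-6)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-td / tau) + C,
                        start = list(A = a0, tau = t0, C = c0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && stats::coef(fit)[["tau"]] > 0) {
      tau <- stats::coef(fit)[["tau"]]
      ss <- sum(stats::residuals(fit)^2)
      tot <- sum((y - mean(y))^2)
      r2 <- if (tot > 0) 1 - ss / tot else 1
      ok <- TRUE
    }
  }
  data.frame(shock_time_s = shockTimeS, peak_dff = peak,
             time_to_peak_s = t[pk] - shockTimeS, decay_tau_s = tau,
             fit_r2 = r2, decay_ok = ok)
}

#' Quantify a train of successive shocks
#'
#' Applies \code{\link{quantifyShock}} to each challenge, capping each
#' response window at the next shock.
#'
#' @inheritParams quantifyShock
#' @param shockTimesS increasing vector of stimulus times, s.
#' @return data.frame with one row per challenge.
#' @export
analyzeShockTrain <- function(dff, shockTimesS, windowS = 300) {
  shockTimesS <- sort(shockTimesS)
  do.call(rbind, lapply(seq_along(shockTimesS), function(k) {
    w <- windowS
    if (k < length(shockTimesS))
      w <- min(w, shockTimesS[k + 1] - shockTimesS[k])
    quantifyShock(dff, shockTimesS[k], w)
  }))
}

#' Desensitization index across repeated challenges
#'
#' Ratios of each peak to the first peak; a monotone decline indicates a
#' desensitizing response but is not enforced.
#'
#' @param responses data.frame of shock responses ordered by
#'   \code{shock_time_s} (>= 2 rows, first peak > 0).
#' @return Numeric vector of peak ratios, first element 1.
#' @examples
#' r <- data.frame(shock_time_s = c(0, 300), peak_dff = c(2, 1))
#' desensitizationIndex(r)   # 1.0 0.5
#' @export
desensitizationIndex <- function(responses) {
  responses <- responses[order(responses$shock_time_s), , drop = FALSE]
  if (nrow(responses) < 2)
    pcoStop("invalid_input", "need at least two responses")
  if (responses$peak_dff[1] <= 0)
    pcoStop("undefined_index", "first peak must be positive")
  responses$peak_dff / responses$peak_dff[1]
}

#' Dose-response of shock peaks versus pre-incubation osmolarity
#'
#' Groups responses by pre-incubation osmolarity and summarizes the peak
#' dF/F0 per group; also reports the rank correlation between osmolarity
#' and mean peak as a monotone-trend summary.
#'
#' @param responses data.frame with columns \code{pre_osmolarity_mosm} and
#'   \code{peak_dff} (one row per recording).
#' @return data.frame sorted by osmolarity with \code{pre_osmolarity_mosm},
#'   \code{mean_peak_dff}, \code{sd_peak_dff} (0 when n = 1), \code{sem},
#'   \code{n}; the Spearman rank correlation is attached as attribute
#'   \code{"trend_rank_correlation"}.
#' @export
doseResponse <- function(responses) {
  if (!nrow(responses)) pcoStop("invalid_input", "no responses given")
  groups <- split(responses$peak_dff, responses$pre_osmolarity_mosm)
  out <- data.frame(
    pre_osmolarity_mosm = as.numeric(names(groups)),
    mean_peak_dff = vapply(groups, mean, numeric(1)),
    sd_peak_dff = vapply(groups, function(g)
      if (length(g) > 1) stats::sd(g) else 0, numeric(1)),
    n = lengths(groups), row.names = NULL)
  out$sem <- out$sd_peak_dff / sqrt(out$n)
  out <- out[order(out$pre_osmolarity_mosm), ]
  rho <- if (nrow(out) > 1)
    stats::cor(out$pre_osmolarity_mosm, out$mean_peak_dff,
               method = "spearman") else NA_real_
  attr(out, "trend_rank_correlation") <- rho
  out
}
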