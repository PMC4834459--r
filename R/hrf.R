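#' Canonical double-gamma hemodynamic response function
#'
#' The de facto standard impulse response: a gamma density peaking at 6 s
#' minus one sixth of a gamma density peaking at 16 s, over a 32 s kernel.
#'
#' @param peakDelayS,undershootDelayS gamma shape parameters (s).
#' @param peakDispersion,undershootDispersion gamma dispersions.
#' @param ratio undershoot-to-peak amplitude ratio.
#' @param lengthS kernel length (s), at least 16.
#' @param dtS fine-grid sampling step (s).
#' @return an \linkS4class{HRFSpec}.
#' @export
hrfSpec <- function(peakDelayS = 6, undershootDelayS = 16,
                    peakDispersion = 1, undershootDispersion = 1,
                    ratio = 1 / 6, lengthS = 32, dtS = 0.1) {
  new("HRFSpec", peakDelayS = peakDelayS, undershootDelayS = undershootDelayS,
      peakDispersion = peakDispersion,
      undershootDispersion = undershootDispersion,
      ratio = ratio, lengthS = lengthS, dtS = dtS)
}

#' Sample an HRF kernel on its fine time grid
#'
#' @param hrf an \linkS4class{HRFSpec}.
#' @return numeric vector of kernel values at \code{seq(0, lengthS, dtS)},
#'   scaled to unit peak.
#' @export
hrfKernel <- function(hrf = hrfSpec()) {
  t <- seq(0, hrf@lengthS, by = hrf@dtS)
  h <- stats::dgamma(t, shape = hrf@peakDelayS / hrf@peakDispersion,
                     rate = 1 / hrf@peakDispersion) -
    hrf@ratio * stats::dgamma(t, shape = hrf@undershootDelayS / hrf@undershootDispersion,
                              rate = 1 / hrf@undershootDispersion)
  h / max(h)
}

setMethod("show", "HRFSpec", function(object) {
  cat(sprintf("HRFSpec: double-gamma, peak %g s, undershoot %g s (ratio %.3g), %g s kernel\n",
              object@peakDelayS, object@undershootDelayS, object@ratio,
              object@lengthS))
})

#' Build a condition-weighted, HRF-convolved psychological regressor
#'
#' A boxcar is formed on a fine (0.1 s) grid, weighted per condition
#' (default: guilt +1, indignation -1, baseline 0 — the guilt-vs-indignation
#' contrast), convolved with the HRF, sampled at the volume acquisition
#' times and mean-centered.
#'
#' @param events an \linkS4class{EventSchedule}.
#' @param weights named condition weights.
#' @param hrf an \linkS4class{HRFSpec}.
#' @param nVolumes number of volumes in the run.
#' @param trS repetition time (s).
#' @return numeric vector of length \code{nVolumes}, mean-centered.
#' @export
buildPsychRegressor <- function(events,
                                weights = c(guilt = 1, indignation = -1,
                                            baseline = 0),
                                hrf = hrfSpec(), nVolumes, trS) {
  present <- unique(events@conditions)
  missing_w <- setdiff(present, names(weights))
  if (length(missing_w))
    stop(paste("no weight defined for condition(s):",
               paste(missing_w, collapse = ", ")))
  dt <- hrf@dtS
  runLen <- nVolumes * trS
  nFine <- ceiling(runLen / dt) + length(hrfKernel(hrf))
  box <- numeric(nFine)
  for (i in seq_along(events@onsetsS)) {
    w <- weights[[events@conditions[i]]]
    if (w == 0) next
    a <- floor(events@onsetsS[i] / dt) + 1L
    b <- min(nFine, ceiling((events@onsetsS[i] + events@durationsS[i]) / dt))
    box[a:b] <- box[a:b] + w
  }
  k <- hrfKernel(hrf)
  conv <- stats::convolve(box, rev(k), type = "open")[seq_len(nFine)]
  # sample at acquisition times t = (v - 1) * TR
  volIdx <- pmin(nFine, floor(((seq_len(nVolumes) - 1) * trS) / dt) + 1L)
  reg <- conv[volIdx]
  reg - mean(reg)
}
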