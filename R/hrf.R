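#' Canonical double-gamma hemodynamic response function
#'
#' Evaluates the standard double-gamma HRF: a gamma density (shape 6,
#' scale 1 s) modelling the positive response minus 1/6 of a gamma density
#' (shape 16, scale 1 s) modelling the post-stimulus undershoot, on a regular
#' grid over \[0, 32\] s. The kernel is scaled so its peak value is 1; the
#' peak falls near 5 s and the negative undershoot lobe after ~12 s.
#'
#' @param dt_s Sampling interval in seconds, in (0, 3\].
#' @return An object of class `hrf_kernel`: a list with `dt_s`, `times`
#'   (seconds) and `samples` (kernel values, peak 1).
#' @examples
#' h <- canonical_hrf(0.1)
#' h$times[which.max(h$samples)] # ~5 s
#' @export
canonical_hrf <- function(dt_s) {
  if (!is.numeric(dt_s) || length(dt_s) != 1 || !is.finite(dt_s) ||
      dt_s <= 0 || dt_s > 3)
    stop("dt_s must be a single value in (0, 3]")
  times <- seq(0, 32, by = dt_s)
  h <- stats::dgamma(times, shape = 6, scale = 1) -
    stats::dgamma(times, shape = 16, scale = 1) / 6
  h <- h / max(h)
  structure(list(dt_s = dt_s, times = times, samples = h),
            class = "hrf_kernel")
}
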