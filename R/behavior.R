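#' Per-load median response time
#'
#' Median RT over correct, responded trials at one memory load; incorrect
#' and timeout trials are excluded before taking the median.
#'
#' @param events Event table from [make_events()].
#' @param load Memory load (1, 3 or 6).
#' @return Median RT in seconds, or `NA` if no qualifying trial exists.
#' @export
median_rt <- function(events, load) {
  keep <- events$load == load & events$correct & !events$timeout &
    !is.na(events$rt_s)
  if (!any(keep)) return(NA_real_)
  median(events$rt_s[keep])
}

#' Set-size slope of response time (sRT)
#'
#' Ordinary least-squares slope of the per-load median RTs against the raw
#' load values (1, 3, 6 letters): seconds of additional response time per
#' letter held in memory.
#'
#' @param medians Numeric vector of three median RTs at loads 1, 3, 6.
#' @param loads Load values; default `c(1, 3, 6)`.
#' @return Slope in seconds per letter, `NA` if any median is missing.
#' @export
srt_slope <- function(medians, loads = c(1, 3, 6)) {
  if (length(medians) != length(loads)) stop("one median per load required")
  if (anyNA(medians)) return(NA_real_)
  x <- loads - mean(loads)
  sum(x * (medians - mean(medians))) / sum(x^2)
}

#' Logistic discrimination index d_L
#'
#' Response-bias-free accuracy for yes/no recognition: the log odds-ratio of
#' the hit and false-alarm rates,
#' `d_L = ln[H (1 - FA) / ((1 - H) FA)]`, with the log-linear correction
#' `H = (hits + 0.5) / (hits + misses + 1)` (and analogously for FA) so the
#' index stays finite at perfect performance.
#'
#' @param hits,misses Counts on match (target-present) trials.
#' @param false_alarms,correct_rejections Counts on non-match trials.
#' @return The discrimination index (dimensionless; 0 = chance).
#' @export
d_l <- function(hits, misses, false_alarms, correct_rejections) {
  if (hits + misses < 1 || false_alarms + correct_rejections < 1)
    stop("at least one match and one non-match trial required")
  H <- (hits + 0.5) / (hits + misses + 1)
  FA <- (false_alarms + 0.5) / (false_alarms + correct_rejections + 1)
  log(H * (1 - FA) / ((1 - H) * FA))
}

#' Normalized whole brain volume
#'
#' The fraction of intracranial volume occupied by brain tissue:
#' `(GM + WM) / (GM + WM + CSF)`. A global proxy for age-related atrophy.
#'
#' @param gm,wm,csf Gray matter, white matter and cerebrospinal fluid
#'   volumes (same units, all positive).
#' @return Dimensionless fraction in (0, 1).
#' @export
nwbv <- function(gm, wm, csf) {
  if (any(c(gm, wm, csf) <= 0)) stop("tissue volumes must be positive")
  (gm + wm) / (gm + wm + csf)
}

#' Behavioral summary for one subject
#'
#' Per-load median RTs, the set-size slope sRT, and (when the event table
#' carries a `match` column) per-load hit/false-alarm counts and d_L.
#'
#' @param events Event table from [make_events()] covering all runs of one
#'   subject.
#' @return A list with `median_rt` (named by load), `srt`, and per-load
#'   `d_l`, `hits`, `misses`, `false_alarms`, `correct_rejections` (NA/empty
#'   when match status is unavailable).
#' @export
behavior_summary <- function(events) {
  loads <- c(1, 3, 6)
  med <- vapply(loads, function(l) median_rt(events, l), numeric(1))
  names(med) <- paste0("load", loads)
  out <- list(median_rt = med, srt = srt_slope(med))
  if (!all(is.na(events$match))) {
    dl <- counts <- NULL
    dtab <- lapply(loads, function(l) {
      ev <- events[events$load == l & !events$timeout, , drop = FALSE]
      hits <- sum(ev$match & ev$correct)
      misses <- sum(ev$match & !ev$correct)
      fa <- sum(!ev$match & !ev$correct)
      cr <- sum(!ev$match & ev$correct)
      c(hits = hits, misses = misses, false_alarms = fa,
        correct_rejections = cr,
        d_l = d_l(hits, misses, fa, cr))
    })
    dtab <- do.call(rbind, dtab)
    rownames(dtab) <- paste0("load", loads)
    out$d_l <- dtab[, "d_l"]
    out$counts <- dtab[, 1:4]
  } else {
    out$d_l <- rep(NA_real_, 3)
  }
  out
}
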