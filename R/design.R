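#' Trial event tables for the delayed item recognition task
#'
#' Each trial of the task presents a letter set (stimulus, 3 s), a retention
#' delay (7 s) and a probe letter; the probe phase ends at the trial response
#' (the RT) within a 3 s response window. Memory load is the set size
#' (1, 3 or 6 letters).
#'
#' `make_events()` validates and normalizes a trial table;
#' `read_events()`/`write_events()` round-trip the delimited-text interface
#' (one row per trial; columns `onset_s`, `load`, `rt_s`, `correct`,
#' `timeout`, `run`, and optionally `match`).
#'
#' @param onset_s Trial (stimulus) onsets in seconds from run start.
#' @param load Memory load per trial; each must be 1, 3 or 6.
#' @param rt_s Response time in seconds, `NA` for timeouts; must lie in
#'   (0, 3\] when present.
#' @param correct Logical, correct response.
#' @param timeout Logical, no response within the 3 s window.
#' @param run Run index per trial.
#' @param match Optional logical, probe was in the study set (used for the
#'   discrimination index).
#' @param stim_dur_s,retention_dur_s Phase durations in seconds.
#' @return A `data.frame` of validated trial events with a `probe_onset_s`
#'   column.
#' @export
make_events <- function(onset_s, load, rt_s, correct, timeout,
                        run = 1L, match = NA,
                        stim_dur_s = 3.0, retention_dur_s = 7.0) {
  n <- length(onset_s)
  ev <- data.frame(onset_s = as.numeric(onset_s),
                   load = as.integer(load),
                   rt_s = as.numeric(rt_s),
                   correct = as.logical(correct),
                   timeout = as.logical(timeout),
                   run = rep_len(as.integer(run), n),
                   match = rep_len(match, n),
                   stim_dur_s = rep_len(stim_dur_s, n),
                   retention_dur_s = rep_len(retention_dur_s, n))
  if (any(ev$onset_s < 0)) stop("onsets must be non-negative")
  if (!all(ev$load %in% c(1L, 3L, 6L)))
    stop("invalid load: loads must be 1, 3 or 6")
  bad_rt <- !is.na(ev$rt_s) & (ev$rt_s <= 0 | ev$rt_s > 3)
  if (any(bad_rt)) stop("rt_s must lie in (0, 3] when present")
  if (any(ev$timeout & !is.na(ev$rt_s)))
    stop("timeout trials cannot carry an RT")
  if (any(!ev$timeout & is.na(ev$rt_s)))
    stop("non-timeout trials must carry an RT")
  ev$probe_onset_s <- ev$onset_s + ev$stim_dur_s + ev$retention_dur_s
  ev
}

#' @rdname make_events
#' @param path File path for the delimited (tab-separated) event table.
#' @export
read_events <- function(path) {
  d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("onset_s", "load", "rt_s", "correct", "timeout", "run")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("event table missing columns: ",
                         paste(miss, collapse = ", "))
  make_events(d$onset_s, d$load, d$rt_s, d$correct, d$timeout, d$run,
              match = if ("match" %in% names(d)) d$match else NA,
              stim_dur_s = if ("stim_dur_s" %in% names(d)) d$stim_dur_s else 3,
              retention_dur_s =
                if ("retention_dur_s" %in% names(d)) d$retention_dur_s else 7)
}

#' @rdname make_events
#' @param events A validated event table.
#' @export
write_events <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

task_phases <- c("stim", "ret", "probe")
task_loads <- c(1L, 3L, 6L)

task_regressor_names <- function() {
  as.vector(t(outer(task_phases, task_loads,
                    function(p, l) paste0(p, "_load", l))))
}

#' Convolved design matrix for the load-by-phase task model
#'
#' Crosses memory load (1, 3, 6) with task phase (stimulus, retention,
#' probe) into nine regressors of interest. Phase boxcars (stimulus 3 s,
#' retention 7 s, probe lasting until the trial RT) are built on a microtime
#' grid of `TR_s / microtime` seconds, convolved with the double-gamma HRF
#' and sampled at scan times. Correct trials contribute only to their
#' load-by-phase regressors; incorrect and timeout trials contribute all
#' three of their phases to a single nuisance error regressor (timeout probe
#' epochs span the full 3 s response window). Task columns are mean-centered
#' within run; one intercept column per run absorbs baselines.
#'
#' @param events Event table from [make_events()]; may span several runs.
#' @param n_scans Scans per run (all runs equal length).
#' @param TR_s Repetition time in seconds.
#' @param hrf HRF kernel from [canonical_hrf()] sampled at `TR_s/microtime`;
#'   built automatically when `NULL`.
#' @param microtime Microtime bins per TR.
#' @param runs Run indices to include; defaults to the runs present in
#'   `events` (or run 1 for an empty table).
#' @return An object of class `design_matrix`: list with `matrix`
#'   (scans x regressors), `regressor_names`, `task_cols`, `TR_s`, `runs`,
#'   and `contrasts` (see [contrasts_of_interest()]).
#' @export
build_design_matrix <- function(events, n_scans, TR_s = 3.0, hrf = NULL,
                                microtime = 16L, runs = NULL) {
  if (microtime < 1) stop("microtime must be >= 1")
  dt <- TR_s / microtime
  if (is.null(hrf)) hrf <- canonical_hrf(dt)
  if (!inherits(hrf, "hrf_kernel") || abs(hrf$dt_s - dt) > 1e-12)
    stop("hrf must be sampled at TR_s/microtime seconds")
  if (is.null(runs))
    runs <- if (nrow(events)) sort(unique(events$run)) else 1L
  n_runs <- length(runs)
  run_dur <- n_scans * TR_s
  reg_names <- task_regressor_names()
  n_task <- length(reg_names)
  n_bins <- n_scans * microtime
  scan_bins <- (seq_len(n_scans) - 1L) * microtime + 1L
  hk <- hrf$samples

  blocks <- vector("list", n_runs)
  err_blocks <- vector("list", n_runs)
  for (ri in seq_len(n_runs)) {
    ev <- events[nrow(events) > 0 & events$run == runs[ri], , drop = FALSE]
    box <- matrix(0, n_bins, n_task, dimnames = list(NULL, reg_names))
    err <- numeric(n_bins)
    add_epoch <- function(vec, onset, dur) {
      i0 <- floor(onset / dt) + 1L
      i1 <- min(ceiling((onset + dur) / dt), n_bins)
      vec[i0:i1] <- vec[i0:i1] + 1
      vec
    }
    for (k in seq_len(nrow(ev))) {
      tr <- ev[k, ]
      probe_dur <- if (tr$timeout || is.na(tr$rt_s)) 3.0 else tr$rt_s
      if (tr$onset_s + tr$stim_dur_s + tr$retention_dur_s + probe_dur >
          run_dur)
        stop("event outside run: trial at onset ", tr$onset_s,
             " extends past ", run_dur, " s")
      ons <- c(tr$onset_s, tr$onset_s + tr$stim_dur_s, tr$probe_onset_s)
      dur <- c(tr$stim_dur_s, tr$retention_dur_s, probe_dur)
      if (tr$correct && !tr$timeout) {
        for (ph in 1:3) {
          cn <- paste0(task_phases[ph], "_load", tr$load)
          box[, cn] <- add_epoch(box[, cn], ons[ph], dur[ph])
        }
      } else {
        for (ph in 1:3) err <- add_epoch(err, ons[ph], dur[ph])
      }
    }
    conv_col <- function(x) {
      if (all(x == 0)) return(numeric(n_scans))
      y <- stats::convolve(x, rev(hk), type = "open")[seq_len(n_bins)] * dt
      y[scan_bins]
    }
    X <- apply(box, 2, conv_col)
    blocks[[ri]] <- scale(X, center = TRUE, scale = FALSE)
    err_blocks[[ri]] <- conv_col(err)
  }

  task_mat <- do.call(rbind, blocks)
  err_col <- unlist(err_blocks)
  intercepts <- matrix(0, n_scans * n_runs, n_runs)
  for (ri in seq_len(n_runs))
    intercepts[(ri - 1L) * n_scans + seq_len(n_scans), ri] <- 1
  M <- cbind(task_mat, error = err_col, intercepts)
  colnames(M) <- c(reg_names, "error", paste0("run", runs))
  structure(list(matrix = M,
                 regressor_names = colnames(M),
                 task_cols = seq_len(n_task),
                 TR_s = TR_s, runs = runs, n_scans = n_scans,
                 contrasts = contrasts_of_interest(pad_to = ncol(M))),
            class = "design_matrix")
}

#' Load-dependent and load-independent contrasts of interest
#'
#' Six contrasts over the nine load-by-phase regressors: within each task
#' phase, a load-dependent contrast with weights proportional to the
#' centered loads (-7/3, -1/3, 8/3 for loads 1, 3, 6; scaled to unit
#' Euclidean norm, summing to zero) and a load-independent contrast
#' averaging the three loads (weights 1/3). Weight vectors carry zero weight
#' on nuisance columns when padded to a full design width.
#'
#' @param pad_to Total design width; weights beyond the nine task columns
#'   are zero. Default 9 (task columns only).
#' @return Named list of six weight vectors, ordered load-dependent
#'   stimulus/retention/probe then load-independent stimulus/retention/probe.
#' @export
contrasts_of_interest <- function(pad_to = 9L) {
  loads <- as.numeric(task_loads)
  w_dep <- loads - mean(loads)
  w_dep <- w_dep / sqrt(sum(w_dep^2))
  w_ind <- rep(1 / 3, 3)
  out <- list()
  for (kind in c("loaddep", "loadindep")) {
    w <- if (kind == "loaddep") w_dep else w_ind
    for (ph in task_phases) {
      v <- numeric(pad_to)
      # regressors are phase-major: stim 1/3/6, ret 1/3/6, probe 1/3/6
      base <- (match(ph, task_phases) - 1L) * 3L
      v[base + 1:3] <- w
      out[[paste0(kind, "_", ph)]] <- v
    }
  }
  out
}
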