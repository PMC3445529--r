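#' Mask and demean one 4D run
#'
#' Converts a 4D array (x, y, z, scans) or a scans x voxels matrix into the
#' masked, per-voxel demeaned matrix the reduction stage expects.
#'
#' @param data 4D numeric array or scans x voxels matrix.
#' @param mask Logical/0-1 3D array selecting brain voxels (ignored for
#'   matrix input).
#' @param subject_id,run_id Identifiers carried through the model.
#' @return List of class `run_data`: `matrix` (scans x voxels, demeaned),
#'   `subject_id`, `run_id`, `n_scans`, `mask_index` (linear voxel indices).
#' @export
prepare_run <- function(data, mask = NULL, subject_id = "sub-001",
                        run_id = 1L) {
  if (length(dim(data)) == 4) {
    if (is.null(mask)) stop("a mask is required for 4D input")
    mask_index <- which(as.logical(mask))
    n_scans <- dim(data)[4]
    m <- t(apply(data, 4, function(v) v[mask_index]))
    if (n_scans == 1) m <- matrix(m, nrow = 1)
  } else {
    m <- as.matrix(data)
    mask_index <- seq_len(ncol(m))
    n_scans <- nrow(m)
  }
  m <- scale(m, center = TRUE, scale = FALSE)
  attr(m, "scaled:center") <- NULL
  structure(list(matrix = m, subject_id = subject_id, run_id = run_id,
                 n_scans = n_scans, mask_index = mask_index),
            class = "run_data")
}

#' Group spatial ICA with two-stage reduction and ICASSO
#'
#' The full group decomposition: temporal PCA within each run
#' ([reduce_run()], 30 components per run by convention), a second PCA
#' across the row-stacked reduced data of all subjects and runs
#' ([reduce_group()]), and infomax ICA on the whitened group data with
#' ICASSO stability selection ([icasso()]).
#'
#' @param runs List of `run_data` objects (all sharing one mask), ordered or
#'   orderable subject-major, run-minor.
#' @param n_ic Number of independent components (model order).
#' @param retained_run Principal components kept per run.
#' @param n_reps ICASSO repetitions.
#' @param seed Master seed.
#' @param ... Passed to [infomax_ica()].
#' @return Object of class `group_ica_model`: `sources` (n_ic x voxels
#'   aggregate maps, unit variance, sign-normalized), `unmixing`, `mixing`,
#'   `stability_iq`, `group_reduction`, `run_info` (per subject-run
#'   reduction + stacked-row offsets), `mask_index`, `n_ic`, `converged_all`.
#' @export
group_ica <- function(runs, n_ic, retained_run = 30L, n_reps = 20L,
                      seed = 1L, ...) {
  ord <- order(vapply(runs, `[[`, character(1), "subject_id"),
               vapply(runs, function(r) as.integer(r$run_id), integer(1)))
  runs <- runs[ord]
  red <- lapply(runs, function(r) reduce_run(r$matrix, retained_run))
  stacked <- do.call(rbind, lapply(red, `[[`, "reduced"))
  grp <- reduce_group(stacked, n_ic)
  ic <- icasso(grp$reduced, n_reps = n_reps, seed = seed, ...)
  offsets <- (seq_along(runs) - 1L) * retained_run
  run_info <- lapply(seq_along(runs), function(i) {
    list(subject_id = runs[[i]]$subject_id, run_id = runs[[i]]$run_id,
         reduction = red[[i]]$reduction, row_offset = offsets[i],
         n_scans = runs[[i]]$n_scans)
  })
  names(run_info) <- vapply(runs, function(r)
    paste0(r$subject_id, ".", r$run_id), character(1))
  structure(list(sources = ic$sources, unmixing = ic$unmixing,
                 mixing = solve(ic$unmixing),
                 stability_iq = ic$stability_iq,
                 group_reduction = grp$reduction,
                 retained_run = retained_run,
                 run_info = run_info,
                 mask_index = runs[[1]]$mask_index,
                 n_ic = n_ic, converged_all = ic$converged_all),
            class = "group_ica_model")
}

#' Back-reconstruct subject component time courses and maps
#'
#' GICA back-reconstruction: the subject-run time courses are the
#' composition of the run dewhitening operator, the subject-run partition of
#' the group dewhitening operator, and the ICA mixing matrix; the
#' subject-run spatial maps are the pseudo-inverse of that composed mixing
#' applied to the run's reduced data. With `flavor = "dual_regression"` the
#' time courses are instead the least-squares regression of the aggregate
#' maps onto the run data.
#'
#' @param model A [group_ica()] model.
#' @param run A `run_data` object whose subject/run pair is in the model.
#' @param flavor `"gica"` (default) or `"dual_regression"`.
#' @return List with `timecourses` (scans x n_ic) and `spatial_maps`
#'   (n_ic x voxels).
#' @export
back_reconstruct <- function(model, run, flavor = c("gica",
                                                    "dual_regression")) {
  flavor <- match.arg(flavor)
  key <- paste0(run$subject_id, ".", run$run_id)
  info <- model$run_info[[key]]
  if (is.null(info))
    stop("missing reduction: no stored operators for ", key)
  if (flavor == "dual_regression") {
    S <- model$sources
    tc <- run$matrix %*% t(S) %*% solve(tcrossprod(S))
    maps <- t(pinv(tc) %*% run$matrix)
    return(list(timecourses = tc, spatial_maps = t(maps)))
  }
  rows <- info$row_offset + seq_len(model$retained_run)
  H_i <- model$group_reduction$debasis[rows, , drop = FALSE]
  mix_i <- H_i %*% model$mixing                    # retained_run x n_ic
  tc <- info$reduction$debasis %*% mix_i           # scans x n_ic
  reduced <- info$reduction$basis %*% run$matrix
  maps <- pinv(mix_i) %*% reduced                  # n_ic x voxels
  list(timecourses = tc, spatial_maps = maps)
}

#' Concatenated back-reconstruction for one subject
#'
#' @param model A [group_ica()] model.
#' @param runs List of the subject's `run_data` objects in acquisition
#'   order.
#' @param ... Passed to [back_reconstruct()].
#' @return List of class `subject_components`: `timecourses`
#'   (total scans x n_ic, runs stacked), `spatial_maps` (n_ic x voxels,
#'   averaged over runs), `run_index` (run label per row).
#' @export
subject_components <- function(model, runs, ...) {
  br <- lapply(runs, function(r) back_reconstruct(model, r, ...))
  tc <- do.call(rbind, lapply(br, `[[`, "timecourses"))
  maps <- Reduce(`+`, lapply(br, `[[`, "spatial_maps")) / length(br)
  run_index <- unlist(lapply(runs, function(r) rep(r$run_id, r$n_scans)))
  structure(list(timecourses = tc, spatial_maps = maps,
                 run_index = run_index),
            class = "subject_components")
}

# 6-neighborhood erosion of a logical 3D mask, `steps` times.
erode_mask <- function(mask, steps = 1L) {
  m <- array(as.logical(mask), dim(mask))
  for (s in seq_len(steps)) {
    d <- dim(m)
    keep <- m
    shift <- function(a, ax, by) {
      out <- array(FALSE, dim(a))
      idx_from <- lapply(dim(a), seq_len)
      idx_to <- idx_from
      idx_from[[ax]] <- idx_from[[ax]] - by
      ok <- idx_from[[ax]] >= 1 & idx_from[[ax]] <= dim(a)[ax]
      idx_to[[ax]] <- idx_to[[ax]][ok]
      idx_from[[ax]] <- idx_from[[ax]][ok]
      out[idx_to[[1]], idx_to[[2]], idx_to[[3]]] <-
        a[idx_from[[1]], idx_from[[2]], idx_from[[3]]]
      out
    }
    for (ax in 1:3) for (by in c(-1L, 1L))
      keep <- keep & shift(m, ax, by)
    m <- keep
  }
  m
}

#' Rule-based artifact component flagging
#'
#' Replaces visual artifact identification with two rules: a component is
#' flagged when the voxel of its largest absolute weight falls outside the
#' eroded interior of the brain mask (edge/motion/pulsation signatures), or
#' when the average fraction of its subject time-course spectral power above
#' `freq_cutoff` exceeds `power_frac` (physiological noise faster than any
#' hemodynamic task response). The flagged list can be overridden manually.
#'
#' @param model A [group_ica()] model.
#' @param mask 3D brain mask the model was built in.
#' @param timecourses Optional list of per-subject time-course matrices used
#'   for the spectral rule; skipped when `NULL`.
#' @param TR_s Repetition time (needed for the spectral rule).
#' @param erode Erosion steps defining the mask interior.
#' @param freq_cutoff High-frequency boundary in Hz.
#' @param power_frac Maximum tolerated high-frequency power fraction.
#' @param override Integer vector replacing the rule-based list entirely.
#' @return Integer vector of flagged component indices.
#' @export
flag_artifacts <- function(model, mask, timecourses = NULL, TR_s = 3.0,
                           erode = 1L, freq_cutoff = 0.1, power_frac = 0.5,
                           override = NULL) {
  if (!is.null(override)) return(sort(unique(as.integer(override))))
  interior <- erode_mask(mask, erode)
  interior_idx <- which(as.logical(interior))
  peak_vox <- model$mask_index[apply(abs(model$sources), 1, which.max)]
  flagged <- !(peak_vox %in% interior_idx)
  if (!is.null(timecourses)) {
    hi_frac <- rep(0, model$n_ic)
    for (tc in timecourses) {
      n <- nrow(tc)
      freqs <- (seq_len(n) - 1) / (n * TR_s)
      nyq <- freqs <= 1 / (2 * TR_s)
      pw <- abs(stats::mvfft(scale(tc, scale = FALSE)))^2
      hi <- freqs > freq_cutoff & nyq
      lo <- freqs > 0 & nyq
      hi_frac <- hi_frac + colSums(pw[hi, , drop = FALSE]) /
        colSums(pw[lo, , drop = FALSE])
    }
    hi_frac <- hi_frac / length(timecourses)
    flagged <- flagged | hi_frac > power_frac
  }
  which(flagged)
}
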