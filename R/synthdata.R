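#' Configuration of a synthetic verbal working-memory fMRI study
#'
#' Defaults emulate the study design: 75 young and 37 old subjects, 3 runs
#' of 69 scans at TR = 3 s, spatially compact sources whose residual time
#' courses carry group-specific between-network correlations, a planted
#' connectivity edge (1-2) whose strength partially transmits the age
#' difference in the RT set-size slope, a second planted edge (3-4) with a
#' group difference only, and an age difference in normalized brain volume
#' that is conditionally independent of connectivity given age group.
#' Young per-load median RTs target 0.88/1.01/1.18 s; the planted edge-1-2
#' Fisher-z group means target 0.514 (young) and 0.059 (old); path defaults
#' give a = -0.455, b = -0.15, direct effect 0.042 (total ~0.11 s/letter).
#' Each run holds 4 trials per load (12 trials of ~13 s plus jittered ITIs
#' fill the 207 s run).
#'
#' @param ... Named overrides of any default listed below.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(...) {
  base_r <- 0.10
  mk_fnc <- function(e12, e34, k = 6) {
    R <- matrix(base_r, k, k)
    diag(R) <- 1
    R[1, 2] <- R[2, 1] <- e12
    R[3, 4] <- R[4, 3] <- e34
    R
  }
  # one row per source over the 9 task regressors (phase-major order);
  # loadings keep each source's task-signal variance a small share of the
  # residual variance so the planted residual correlations survive into the
  # raw time-course FNC
  betas <- rbind(
    c(0.22, 0.22, 0.22, 0, 0, 0, 0, 0, 0),        # stimulus responder
    c(0, 0, 0, 0.08, 0.11, 0.14, 0, 0, 0),        # load-graded retention
    c(0, 0, 0, 0, 0, 0, 0.45, 0.45, 0.45),        # probe responder
    c(0.18, 0.18, 0.18, 0, 0, 0, 0.3, 0.3, 0.3),
    c(0, 0, 0, -0.08, -0.11, -0.14, 0, 0, 0),     # task-induced deactivation
    c(0, 0, 0, 0, 0, 0, 0, 0, 0)                  # task-unrelated network
  )
  cfg <- list(
    n_young = 75L, n_old = 37L,
    runs = 3L, scans_per_run = 69L, TR_s = 3.0,
    trials_per_load_per_run = 4L,
    grid = c(12L, 12L, 12L), mask = NULL,
    n_sources = 6L, blob_sigma = 1.5, max_source_cor = 0.2,
    fnc_young = mk_fnc(0.514, 0.448),
    fnc_old = mk_fnc(0.059, 0.113),
    subject_z_sd = 0.15,
    task_betas = betas,
    resid_sd = 1.0, noise_sd = 1.0,
    rt_model = list(intercept = c(young = 0.83, old = 0.81),
                    slope_young = 0.0596, slope_old_extra = 0.042,
                    kappa = -0.15, slope_sd = 0.01, trial_sd = 0.25,
                    hit_rate = 0.80, fa_rate = 0.25, timeout_rate = 0.02),
    volume_model = list(
      young = c(gm = 700e3, wm = 500e3, csf = 210e3),
      old = c(gm = 640e3, wm = 470e3, csf = 455e3),
      sdlog = 0.05),
    prop_male = c(young = 50 / 75, old = 15 / 37),
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (is.null(cfg$mask)) cfg$mask <- array(TRUE, cfg$grid)
  k <- cfg$n_sources
  for (f in c("fnc_young", "fnc_old")) {
    R <- cfg[[f]]
    if (!isTRUE(all.equal(R, t(R))) || any(diag(R) != 1) ||
        any(eigen(R, symmetric = TRUE, only.values = TRUE)$values <= 0))
      stop(f, " must be a symmetric positive-definite correlation matrix")
    if (nrow(R) != k) stop(f, " dimension must match n_sources")
  }
  if (cfg$n_young < 3 || cfg$n_old < 3) stop("group sizes must be >= 3")
  structure(cfg, class = "synth_config")
}

# unit-variance Laplace noise: super-Gaussian innovations keep the infomax
# separation well-posed
rlaplace_unit <- function(n) {
  stats::rexp(n, rate = sqrt(2)) * sample(c(-1, 1), n, replace = TRUE)
}

#' Plant spatially compact source maps
#'
#' Smooth Gaussian blobs at well-separated centers inside the mask; unit
#' variance per source, pairwise spatial correlation below
#' `cfg$max_source_cor` by construction (placement is retried until the
#' constraint holds).
#'
#' @param cfg A [synth_config()].
#' @return Matrix n_sources x masked voxels; attribute `centers`.
#' @export
make_sources <- function(cfg) {
  mask_index <- which(as.logical(cfg$mask))
  V <- length(mask_index)
  if (cfg$n_sources > V / 20)
    stop("infeasible packing: too many sources for the mask")
  dims <- cfg$grid
  coords <- arrayInd(mask_index, dims)
  margin <- ceiling(cfg$blob_sigma)
  interior <- which(apply(coords, 1, function(p)
    all(p > margin & p <= dims - margin)))
  if (length(interior) < cfg$n_sources)
    stop("infeasible packing: mask interior too small")
  # two Gaussian blobs of width sigma correlate below the bound when their
  # centers sit at least this far apart
  min_dist <- 2 * cfg$blob_sigma * sqrt(log(1 / cfg$max_source_cor))
  for (attempt in 1:500) {
    cand <- sample(interior)
    picked <- integer(0)
    for (i in cand) {
      if (!length(picked)) {
        picked <- i
      } else {
        d <- sqrt(rowSums((coords[picked, , drop = FALSE] -
                           matrix(coords[i, ], length(picked), 3,
                                  byrow = TRUE))^2))
        if (all(d >= min_dist)) picked <- c(picked, i)
      }
      if (length(picked) == cfg$n_sources) break
    }
    if (length(picked) < cfg$n_sources) next
    centers <- coords[picked, , drop = FALSE]
    S <- t(apply(centers, 1, function(ct) {
      d2 <- rowSums((coords - matrix(ct, V, 3, byrow = TRUE))^2)
      exp(-d2 / (2 * cfg$blob_sigma^2))
    }))
    S <- S / apply(S, 1, sd)
    cc <- abs(cor(t(S)))
    diag(cc) <- 0
    if (max(cc) < cfg$max_source_cor)
      return(structure(S, centers = centers))
  }
  stop("infeasible packing: could not satisfy the overlap constraint")
}

# per-subject correlation matrix: group base with the planted edges moved to
# this subject's true values; jittered toward the base if not PD
subject_fnc_target <- function(base, z12, z34) {
  R <- base
  R[1, 2] <- R[2, 1] <- tanh(z12)
  if (nrow(R) >= 4) R[3, 4] <- R[4, 3] <- tanh(z34)
  w <- 1
  repeat {
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 1e-8) return(R)
    w <- w * 0.8
    R <- w * R + (1 - w) * base
  }
}

#' Sample source time courses with planted connectivity
#'
#' Per-source time courses are the convolved task regressors weighted by
#' `cfg$task_betas` plus correlated residual noise: unit-variance Laplace
#' innovations mixed through the Cholesky factor of the target correlation
#' matrix and scaled by `cfg$resid_sd`. Empirical residual correlations
#' converge to the target as scans grow.
#'
#' @param cfg A [synth_config()].
#' @param design A [build_design_matrix()] object spanning the subject's
#'   runs.
#' @param group `"young"` or `"old"`.
#' @param edge_z Optional `c(z12, z34)` subject-specific Fisher-z values for
#'   the two planted edges; group means are used when `NULL`.
#' @return Matrix total scans x n_sources of true source time courses.
#' @export
sample_timecourses <- function(cfg, design, group, edge_z = NULL) {
  base <- if (group == "young") cfg$fnc_young else cfg$fnc_old
  if (is.null(edge_z))
    edge_z <- c(fisher_z(base[1, 2]),
                if (nrow(base) >= 4) fisher_z(base[3, 4]) else 0)
  R <- subject_fnc_target(base, edge_z[1], edge_z[2])
  Tt <- nrow(design$matrix)
  k <- cfg$n_sources
  E <- matrix(rlaplace_unit(Tt * k), Tt, k) %*% chol(R)
  task <- design$matrix[, design$task_cols, drop = FALSE]
  task %*% t(cfg$task_betas) + cfg$resid_sd * E
}

#' Mix sources into voxel data and add scanner noise
#'
#' @param sources Matrix n_sources x voxels.
#' @param tcs Matrix scans x n_sources of time courses for one run.
#' @param noise_sd Gaussian voxel noise standard deviation.
#' @return Matrix scans x voxels.
#' @export
mix_and_noise <- function(sources, tcs, noise_sd) {
  Y <- tcs %*% sources
  if (noise_sd > 0)
    Y <- Y + matrix(rnorm(length(Y), sd = noise_sd), nrow(Y), ncol(Y))
  Y
}

#' Simulate one subject's trial events and behavior
#'
#' Trials follow the delayed item recognition schedule (3 s stimulus, 7 s
#' retention, probe within a 3 s window; jittered inter-trial intervals).
#' Per-trial RT is `intercept_group + slope_subject * load` plus Gaussian
#' trial noise, truncated to (0, 3\]; the subject's slope is the group slope
#' plus `kappa * (planted edge z - young group mean z)` plus subject noise,
#' so weaker connectivity steepens the load cost and the age effect on the
#' slope is partially transmitted through the planted edge. Accuracy is
#' Bernoulli with hit/false-alarm rates chosen so d_L lands near 2.3-2.5;
#' timeouts occur at a small fixed rate.
#'
#' @param cfg A [synth_config()].
#' @param group `"young"` or `"old"`.
#' @param edge_z12 The subject's planted edge-(1,2) Fisher-z value.
#' @return List with `events` (all runs), `slope_subject`, and the
#'   [behavior_summary()].
#' @export
simulate_behavior <- function(cfg, group, edge_z12) {
  rt <- cfg$rt_model
  z_ref <- fisher_z(cfg$fnc_young[1, 2])
  slope_group <- rt$slope_young +
    if (group == "old") rt$slope_old_extra else 0
  slope_subject <- slope_group + rt$kappa * (edge_z12 - z_ref) +
    rnorm(1, 0, rt$slope_sd)
  intercept <- rt$intercept[[group]]
  n_per <- cfg$trials_per_load_per_run
  ev_runs <- lapply(seq_len(cfg$runs), function(run) {
    loads <- sample(rep(c(1L, 3L, 6L), n_per))
    n_tr <- length(loads)
    match <- logical(n_tr)
    for (l in c(1L, 3L, 6L)) {
      i <- which(loads == l)
      match[i] <- sample(rep(c(TRUE, FALSE), length.out = length(i)))
    }
    iti <- runif(n_tr, 1, 3)
    onset <- 2 + cumsum(c(0, (13 + iti)[-n_tr]))
    timeout <- runif(n_tr) < rt$timeout_rate
    p_correct <- ifelse(match, rt$hit_rate, 1 - rt$fa_rate)
    correct <- runif(n_tr) < p_correct
    correct[timeout] <- FALSE
    rt_s <- intercept + slope_subject * loads + rnorm(n_tr, 0, rt$trial_sd)
    bad <- !timeout & (rt_s <= 0 | rt_s > 3)
    while (any(bad)) {
      rt_s[bad] <- intercept + slope_subject * loads[bad] +
        rnorm(sum(bad), 0, rt$trial_sd)
      bad <- !timeout & (rt_s <= 0 | rt_s > 3)
    }
    rt_s[timeout] <- NA_real_
    make_events(onset, loads, rt_s, correct, timeout, run = run,
                match = match)
  })
  events <- do.call(rbind, ev_runs)
  list(events = events, slope_subject = slope_subject,
       summary = behavior_summary(events))
}

#' Simulate tissue volumes for one subject
#'
#' Lognormal GM/WM/CSF volumes with group-specific means: the old group's
#' larger CSF and smaller tissue means shift its normalized whole brain
#' volume down, while volumes stay independent of the planted connectivity
#' within group (the volume path is deliberately a non-mediator).
#'
#' @param cfg A [synth_config()].
#' @param group `"young"` or `"old"`.
#' @return List with `gm_mm3`, `wm_mm3`, `csf_mm3`, `nwbv`.
#' @export
simulate_volumes <- function(cfg, group) {
  vm <- cfg$volume_model
  mu <- vm[[group]]
  v <- stats::rlnorm(3, meanlog = log(mu), sdlog = vm$sdlog)
  list(gm_mm3 = v[1], wm_mm3 = v[2], csf_mm3 = v[3],
       nwbv = nwbv(v[1], v[2], v[3]))
}

#' Simulate a complete study in memory
#'
#' Draws the source maps, all subjects' planted edge strengths, time
#' courses, voxel data, events, volumes and demographics from one seed, and
#' returns everything together with the ground truth needed to score
#' recovery of every pipeline output.
#'
#' @param cfg A [synth_config()].
#' @return List of class `synth_study`: `cfg`, `sources`, `mask`,
#'   `subjects` (data.frame: subject_id, group, gender, volumes, true edge
#'   z-values, true RT slope), `events` (per subject), `bold` (per subject:
#'   list of scans x voxels run matrices), `design` (per subject),
#'   `true_tcs` (per subject), `truth` (paths and group targets).
#' @export
simulate_study <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  sources <- make_sources(cfg)
  n <- cfg$n_young + cfg$n_old
  group <- rep(c("young", "old"), c(cfg$n_young, cfg$n_old))
  gender <- unlist(lapply(c("young", "old"), function(g) {
    ng <- if (g == "young") cfg$n_young else cfg$n_old
    nm <- round(cfg$prop_male[[g]] * ng)
    sample(rep(c("M", "F"), c(nm, ng - nm)))
  }))
  ids <- sprintf("sub-%03d", seq_len(n))
  z12_mean <- c(young = fisher_z(cfg$fnc_young[1, 2]),
                old = fisher_z(cfg$fnc_old[1, 2]))
  z34_mean <- if (cfg$n_sources >= 4)
    c(young = fisher_z(cfg$fnc_young[3, 4]),
      old = fisher_z(cfg$fnc_old[3, 4]))
  else c(young = 0, old = 0)
  events <- bold <- designs <- true_tcs <- vector("list", n)
  sub_rows <- vector("list", n)
  for (s in seq_len(n)) {
    g <- group[s]
    z12 <- rnorm(1, z12_mean[[g]], cfg$subject_z_sd)
    z34 <- rnorm(1, z34_mean[[g]], cfg$subject_z_sd)
    beh <- simulate_behavior(cfg, g, z12)
    des <- build_design_matrix(beh$events, cfg$scans_per_run, cfg$TR_s,
                               runs = seq_len(cfg$runs))
    tcs <- sample_timecourses(cfg, des, g, edge_z = c(z12, z34))
    runs <- lapply(seq_len(cfg$runs), function(r) {
      rows <- (r - 1L) * cfg$scans_per_run + seq_len(cfg$scans_per_run)
      mix_and_noise(sources, tcs[rows, , drop = FALSE], cfg$noise_sd)
    })
    vol <- simulate_volumes(cfg, g)
    events[[s]] <- beh$events
    bold[[s]] <- runs
    designs[[s]] <- des
    true_tcs[[s]] <- tcs
    sub_rows[[s]] <- data.frame(
      subject_id = ids[s], group = g, gender = gender[s],
      gm_mm3 = vol$gm_mm3, wm_mm3 = vol$wm_mm3, csf_mm3 = vol$csf_mm3,
      nwbv = vol$nwbv, true_z12 = z12, true_z34 = z34,
      true_slope = beh$slope_subject,
      srt = beh$summary$srt,
      median_rt1 = beh$summary$median_rt[1],
      median_rt3 = beh$summary$median_rt[2],
      median_rt6 = beh$summary$median_rt[3],
      d_l1 = beh$summary$d_l[1], d_l3 = beh$summary$d_l[2],
      d_l6 = beh$summary$d_l[3])
  }
  subjects <- do.call(rbind, sub_rows)
  names(events) <- names(bold) <- names(designs) <- names(true_tcs) <- ids
  rt <- cfg$rt_model
  truth <- list(
    a_fnc = z12_mean[["old"]] - z12_mean[["young"]],
    b_fnc = rt$kappa,
    c_prime_fnc = rt$slope_old_extra,
    indirect_fnc = (z12_mean[["old"]] - z12_mean[["young"]]) * rt$kappa,
    z12_mean = z12_mean, z34_mean = z34_mean,
    nwbv_young = nwbv(cfg$volume_model$young[1], cfg$volume_model$young[2],
                      cfg$volume_model$young[3]),
    nwbv_old = nwbv(cfg$volume_model$old[1], cfg$volume_model$old[2],
                    cfg$volume_model$old[3]))
  structure(list(cfg = cfg, sources = sources, mask = cfg$mask,
                 mask_index = which(as.logical(cfg$mask)),
                 subjects = subjects, events = events, bold = bold,
                 design = designs, true_tcs = true_tcs, truth = truth),
            class = "synth_study")
}

#' Write a simulated study to disk
#'
#' Generates (or takes) a [simulate_study()] result and writes the standard
#' file tree: `mask.nii.gz`, per subject `sub-XXX/run-X_bold.nii.gz` 4D
#' images and `sub-XXX_events.tsv`, plus `participants.tsv`, `volumes.tsv`
#' and a `ground_truth.rds` archive. Fully reproducible from the config
#' seed.
#'
#' @param cfg A [synth_config()].
#' @param dir Output study root.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @param study Optional pre-simulated `synth_study` to write out.
#' @return The study root, invisibly; attribute `study` carries the
#'   in-memory object.
#' @export
generate_study <- function(cfg = synth_config(), dir, overwrite = FALSE,
                           study = NULL) {
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite)
    stop("output directory exists and is not empty; use overwrite = TRUE")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(study)) study <- simulate_study(cfg)
  cfg <- study$cfg
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(cfg$mask), cfg$grid),
                                     pixdim = c(2, 2, 2)),
                     file.path(dir, "mask.nii.gz"))
  mask_index <- study$mask_index
  for (s in seq_len(nrow(study$subjects))) {
    id <- study$subjects$subject_id[s]
    sdir <- file.path(dir, id)
    dir.create(sdir, showWarnings = FALSE)
    for (r in seq_len(cfg$runs)) {
      Y <- study$bold[[id]][[r]]
      arr <- array(0, c(cfg$grid, cfg$scans_per_run))
      flat <- matrix(0, prod(cfg$grid), cfg$scans_per_run)
      flat[mask_index, ] <- t(Y)
      arr[] <- flat
      RNifti::writeNifti(
        RNifti::asNifti(arr, pixdim = c(2, 2, 2, cfg$TR_s)),
        file.path(sdir, sprintf("run-%d_bold.nii.gz", r)))
    }
    write_events(study$events[[id]],
                 file.path(dir, paste0(id, "_events.tsv")))
  }
  write.table(study$subjects[, c("subject_id", "group", "gender")],
              file.path(dir, "participants.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(study$subjects[, c("subject_id", "gm_mm3", "wm_mm3",
                                 "csf_mm3", "nwbv")],
              file.path(dir, "volumes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  saveRDS(list(cfg = cfg, sources = study$sources,
               subjects = study$subjects, truth = study$truth),
          file.path(dir, "ground_truth.rds"))
  invisible(structure(dir, study = study))
}
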