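#' Pipeline configuration
#'
#' Reads (or takes) a YAML configuration with blocks `paths` (study_root,
#' out_root), `synth` (any [synth_config()] field), `ica` (n_ic,
#' retained_run, n_reps, seed, flavor), `glm` (alpha, family_size), `fnc`
#' (alpha), and `mediation` (n_boot, ci_level, seed), fills defaults, and
#' validates it before any stage runs.
#'
#' @param config Path to a YAML file, or a list with the same structure.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- list(
    paths = list(study_root = "study", out_root = "out"),
    synth = list(),
    ica = list(n_ic = 6L, retained_run = 30L, n_reps = 20L, seed = 1L,
               flavor = "gica", artifact_override = NULL),
    glm = list(alpha = 0.05, family_size = NULL),
    fnc = list(alpha = 0.05),
    mediation = list(n_boot = 10000L, ci_level = 0.95, seed = 1L))
  for (blk in names(def)) {
    if (!is.null(config[[blk]])) def[[blk]][names(config[[blk]])] <-
        config[[blk]]
  }
  stopifnot(def$ica$n_ic >= 2, def$ica$n_reps >= 2,
            def$glm$alpha > 0, def$glm$alpha < 1,
            def$mediation$n_boot >= 1)
  structure(def, class = "pipeline_config")
}

stage_digest <- function(obj, files = character()) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tmp)
  unname(c(tools::md5sum(tmp),
           tools::md5sum(files[file.exists(files)])))
}

stage_current <- function(out_root, stage, digest) {
  f <- file.path(out_root, paste0(stage, ".done.json"))
  file.exists(f) &&
    identical(unlist(jsonlite::read_json(f)$digest), unname(digest))
}

stage_mark <- function(out_root, stage, digest) {
  jsonlite::write_json(list(stage = stage, digest = digest,
                            time = format(Sys.time())),
                       file.path(out_root, paste0(stage, ".done.json")),
                       auto_unbox = TRUE)
}

read_participants <- function(study_root) {
  f <- file.path(study_root, "participants.tsv")
  if (!file.exists(f)) stop("missing participants.tsv in ", study_root,
                            "; run the synth stage first")
  read.delim(f, stringsAsFactors = FALSE)
}

#' Run pipeline stages
#'
#' Executes one stage (or `"all"`) of the analysis chain
#' synth -> design -> ica -> glm -> fnc -> behavior -> mediate. Each stage
#' reads only its predecessors' serialized outputs from disk, writes its
#' artifacts under `paths$out_root`, and records an input digest so
#' rerunning a completed stage with unchanged inputs is a no-op.
#'
#' @param subcommand One of `"synth"`, `"design"`, `"ica"`, `"glm"`,
#'   `"fnc"`, `"behavior"`, `"mediate"`, `"all"`.
#' @param config A [pipeline_config()], a list, or a YAML path.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the output root.
#' @export
run_pipeline <- function(subcommand, config, quiet = FALSE) {
  stages <- c("synth", "design", "ica", "glm", "fnc", "behavior", "mediate")
  subcommand <- match.arg(subcommand, c(stages, "all"))
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  todo <- if (subcommand == "all") stages else subcommand
  out_root <- cfg$paths$out_root
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[taskfnc] ", ...)
  for (st in todo) {
    fn <- get(paste0("stage_", st), mode = "function")
    fn(cfg, say)
  }
  invisible(out_root)
}

stage_synth <- function(cfg, say) {
  sc <- do.call(synth_config, cfg$synth)
  dg <- stage_digest(unclass(sc)[setdiff(names(sc), "mask")])
  if (stage_current(cfg$paths$out_root, "synth", dg)) {
    say("synth: up to date"); return(invisible())
  }
  say("synth: generating study at ", cfg$paths$study_root)
  generate_study(sc, cfg$paths$study_root, overwrite = TRUE)
  stage_mark(cfg$paths$out_root, "synth", dg)
}

pipeline_designs <- function(cfg) {
  sc <- do.call(synth_config, cfg$synth)
  parts <- read_participants(cfg$paths$study_root)
  designs <- lapply(parts$subject_id, function(id) {
    ev <- read_events(file.path(cfg$paths$study_root,
                                paste0(id, "_events.tsv")))
    build_design_matrix(ev, sc$scans_per_run, sc$TR_s,
                        runs = seq_len(sc$runs))
  })
  names(designs) <- parts$subject_id
  designs
}

stage_design <- function(cfg, say) {
  parts <- read_participants(cfg$paths$study_root)
  ev_files <- file.path(cfg$paths$study_root,
                        paste0(parts$subject_id, "_events.tsv"))
  dg <- stage_digest(cfg$synth, ev_files)
  if (stage_current(cfg$paths$out_root, "design", dg)) {
    say("design: up to date"); return(invisible())
  }
  say("design: building design matrices")
  ddir <- file.path(cfg$paths$out_root, "design")
  dir.create(ddir, showWarnings = FALSE)
  designs <- pipeline_designs(cfg)
  for (id in names(designs)) {
    M <- designs[[id]]$matrix
    write.table(data.frame(M, check.names = FALSE),
                file.path(ddir, paste0(id, "_design.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  stage_mark(cfg$paths$out_root, "design", dg)
}

pipeline_load_runs <- function(cfg) {
  sc <- do.call(synth_config, cfg$synth)
  study_root <- cfg$paths$study_root
  maskf <- file.path(study_root, "mask.nii.gz")
  if (!file.exists(maskf)) stop("missing mask at ", maskf,
                                "; run the synth stage first")
  mask <- as.array(RNifti::readNifti(maskf)) > 0
  parts <- read_participants(study_root)
  runs <- list()
  for (id in parts$subject_id) for (r in seq_len(sc$runs)) {
    f <- file.path(study_root, id, sprintf("run-%d_bold.nii.gz", r))
    if (!file.exists(f)) stop("missing run image ", f,
                              "; run the synth stage first")
    arr <- as.array(RNifti::readNifti(f))
    if (length(dim(arr)) != 4) stop("corrupt NIfTI input (not 4D): ", f)
    runs[[paste0(id, ".", r)]] <- prepare_run(arr, mask, id, r)
  }
  list(runs = runs, mask = mask, parts = parts, sc = sc)
}

stage_ica <- function(cfg, say) {
  parts <- read_participants(cfg$paths$study_root)
  dg <- stage_digest(list(cfg$synth, cfg$ica),
                     file.path(cfg$paths$study_root, "mask.nii.gz"))
  if (stage_current(cfg$paths$out_root, "ica", dg)) {
    say("ica: up to date"); return(invisible())
  }
  say("ica: two-stage reduction + infomax/ICASSO")
  ld <- pipeline_load_runs(cfg)
  retained <- min(cfg$ica$retained_run, ld$sc$scans_per_run)
  model <- group_ica(ld$runs, n_ic = cfg$ica$n_ic,
                     retained_run = retained,
                     n_reps = cfg$ica$n_reps, seed = cfg$ica$seed)
  idir <- file.path(cfg$paths$out_root, "ica")
  dir.create(idir, showWarnings = FALSE)
  tcl <- list()
  for (id in ld$parts$subject_id) {
    subj_runs <- ld$runs[paste0(id, ".", seq_len(ld$sc$runs))]
    comp <- subject_components(model, subj_runs, flavor = cfg$ica$flavor)
    tc <- comp$timecourses
    colnames(tc) <- paste0("IC", seq_len(ncol(tc)))
    write.table(data.frame(run = comp$run_index, tc, check.names = FALSE),
                file.path(idir, paste0(id, "_timecourses.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    tcl[[id]] <- comp$timecourses
  }
  grid <- dim(ld$mask)
  maps <- array(0, c(grid, model$n_ic))
  flat <- matrix(0, prod(grid), model$n_ic)
  flat[model$mask_index, ] <- t(model$sources)
  maps[] <- flat
  RNifti::writeNifti(RNifti::asNifti(maps),
                     file.path(idir, "aggregate_maps.nii.gz"))
  artifacts <- flag_artifacts(model, ld$mask, timecourses = tcl,
                              TR_s = ld$sc$TR_s,
                              override = cfg$ica$artifact_override)
  saveRDS(list(model = model, artifacts = artifacts,
               stability_iq = model$stability_iq),
          file.path(idir, "model.rds"))
  write.table(data.frame(component = seq_len(model$n_ic),
                         stability_iq = model$stability_iq,
                         artifact = seq_len(model$n_ic) %in% artifacts),
              file.path(idir, "components.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  stage_mark(cfg$paths$out_root, "ica", dg)
}

read_timecourses <- function(out_root, id) {
  f <- file.path(out_root, "ica", paste0(id, "_timecourses.tsv"))
  if (!file.exists(f)) stop("missing time courses for ", id,
                            "; run the ica stage first")
  d <- read.delim(f)
  list(tc = as.matrix(d[, -1, drop = FALSE]), runs = d$run)
}

stage_glm <- function(cfg, say) {
  out_root <- cfg$paths$out_root
  modelf <- file.path(out_root, "ica", "model.rds")
  if (!file.exists(modelf)) stop("missing ICA model; run the ica stage first")
  dg <- stage_digest(cfg$glm, modelf)
  if (stage_current(out_root, "glm", dg)) {
    say("glm: up to date"); return(invisible())
  }
  say("glm: component time-course GLMs + task-relatedness")
  parts <- read_participants(cfg$paths$study_root)
  designs <- pipeline_designs(cfg)
  ica <- readRDS(modelf)
  keep <- setdiff(seq_len(ica$model$n_ic), ica$artifacts)
  n_sub <- nrow(parts)
  vals <- array(NA_real_, c(n_sub, length(keep), 6))
  for (s in seq_len(n_sub)) {
    id <- parts$subject_id[s]
    tcd <- read_timecourses(out_root, id)
    des <- designs[[id]]
    for (ci in seq_along(keep)) {
      fit <- fit_component_glm(tcd$tc[, keep[ci]], des)
      vals[s, ci, ] <- contrast_values(fit$betas, des)
    }
  }
  dimnames(vals)[[3]] <- names(designs[[1]]$contrasts)
  fam <- cfg$glm$family_size
  tab <- task_relatedness_table(vals, parts$group, parts$gender,
                                alpha = cfg$glm$alpha,
                                family_size = fam)
  cls <- classify_task_related(tab)
  gdir <- file.path(out_root, "glm")
  dir.create(gdir, showWarnings = FALSE)
  flat <- do.call(rbind, lapply(seq_along(keep), function(ci) {
    data.frame(component = keep[ci],
               contrast = dimnames(vals)[[3]],
               t_young = tab$t_within[1, ci, ],
               t_old = tab$t_within[2, ci, ],
               t_between = tab$t_between[ci, ],
               p_young = tab$p_within[1, ci, ],
               p_old = tab$p_within[2, ci, ])
  }))
  write.table(flat, file.path(gdir, "task_relatedness.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  saveRDS(list(values = vals, components = keep, table = tab,
               task_related = keep[cls$retained],
               family_size = cls$family_size),
          file.path(gdir, "glm.rds"))
  stage_mark(out_root, "glm", dg)
}

stage_fnc <- function(cfg, say) {
  out_root <- cfg$paths$out_root
  glmf <- file.path(out_root, "glm", "glm.rds")
  if (!file.exists(glmf)) stop("missing GLM results; run the glm stage first")
  dg <- stage_digest(cfg$fnc, glmf)
  if (stage_current(out_root, "fnc", dg)) {
    say("fnc: up to date"); return(invisible())
  }
  say("fnc: per-subject connectivity + edge tests")
  parts <- read_participants(cfg$paths$study_root)
  glm_res <- readRDS(glmf)
  comps <- glm_res$task_related
  if (length(comps) < 2) stop("fewer than 2 task-related components")
  fdir <- file.path(out_root, "fnc")
  dir.create(fdir, showWarnings = FALSE)
  fncs <- lapply(parts$subject_id, function(id) {
    tcd <- read_timecourses(out_root, id)
    z <- compute_fnc(tcd$tc[, comps, drop = FALSE], runs = tcd$runs)
    write.table(round(z, 6), file.path(fdir, paste0(id, "_fnc.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    z
  })
  tab <- edge_group_tests(fncs, parts$group, parts$gender,
                          alpha = cfg$fnc$alpha)
  pruned <- prune_unconnected(tab)
  tab$comp_i <- comps[tab$i]
  tab$comp_j <- comps[tab$j]
  write.table(tab, file.path(fdir, "edge_tests.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  saveRDS(list(fncs = fncs, table = tab, components = comps,
               retained = comps[pruned$retained],
               dropped = comps[pruned$dropped]),
          file.path(fdir, "fnc.rds"))
  stage_mark(out_root, "fnc", dg)
}

stage_behavior <- function(cfg, say) {
  study_root <- cfg$paths$study_root
  parts <- read_participants(study_root)
  ev_files <- file.path(study_root, paste0(parts$subject_id, "_events.tsv"))
  volf <- file.path(study_root, "volumes.tsv")
  dg <- stage_digest(list(), c(ev_files, volf))
  if (stage_current(cfg$paths$out_root, "behavior", dg)) {
    say("behavior: up to date"); return(invisible())
  }
  say("behavior: covariate table")
  vols <- read.delim(volf, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(parts)), function(s) {
    ev <- read_events(ev_files[s])
    bs <- behavior_summary(ev)
    data.frame(subject_id = parts$subject_id[s], group = parts$group[s],
               gender = parts$gender[s],
               median_rt1 = bs$median_rt[1], median_rt3 = bs$median_rt[2],
               median_rt6 = bs$median_rt[3], srt = bs$srt,
               d_l1 = bs$d_l[1], d_l3 = bs$d_l[2], d_l6 = bs$d_l[3])
  })
  cov <- merge(do.call(rbind, rows), vols, by = "subject_id", sort = FALSE)
  write.table(cov, file.path(cfg$paths$out_root, "covariates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  stage_mark(cfg$paths$out_root, "behavior", dg)
}

stage_mediate <- function(cfg, say) {
  out_root <- cfg$paths$out_root
  fncf <- file.path(out_root, "fnc", "fnc.rds")
  covf <- file.path(out_root, "covariates.tsv")
  if (!file.exists(fncf)) stop("missing FNC results; run the fnc stage first")
  if (!file.exists(covf)) stop("missing covariates; run the behavior stage",
                               " first")
  dg <- stage_digest(cfg$mediation, c(fncf, covf))
  if (stage_current(out_root, "mediate", dg)) {
    say("mediate: up to date"); return(invisible())
  }
  say("mediate: performance edges + bootstrap mediation")
  cov <- read.delim(covf, stringsAsFactors = FALSE)
  fnc_res <- readRDS(fncf)
  tab <- fnc_res$table
  sig <- tab[tab$significant, , drop = FALSE]
  x <- as.numeric(cov$group == "old")
  gcov <- gender_covariate(cov$gender)
  perf <- do.call(rbind, lapply(seq_len(nrow(sig)), function(e) {
    z <- vapply(fnc_res$fncs, function(f) f[sig$i[e], sig$j[e]], numeric(1))
    pr <- edge_performance_regression(z, cov$srt, cov$gender,
                                      family = nrow(sig))
    data.frame(comp_i = sig$comp_i[e], comp_j = sig$comp_j[e],
               slope = pr$slope, t = pr$t, p = pr$p,
               significant = pr$significant)
  }))
  mdir <- file.path(out_root, "mediation")
  dir.create(mdir, showWarnings = FALSE)
  if (!is.null(perf))
    write.table(perf, file.path(mdir, "performance_edges.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  med_edges <- if (!is.null(perf) && any(perf$significant))
    perf[perf$significant, c("comp_i", "comp_j")] else NULL
  res <- list()
  if (!is.null(med_edges)) for (e in seq_len(nrow(med_edges))) {
    i <- which(fnc_res$components == med_edges$comp_i[e])
    j <- which(fnc_res$components == med_edges$comp_j[e])
    z <- vapply(fnc_res$fncs, function(f) f[i, j], numeric(1))
    lab <- sprintf("r(%d,%d)", med_edges$comp_i[e], med_edges$comp_j[e])
    m1 <- mediation_test(x, z, cov$srt, covariates = gcov,
                         n_boot = cfg$mediation$n_boot,
                         ci_level = cfg$mediation$ci_level,
                         seed = cfg$mediation$seed)
    m2 <- mediation_test(x, cov$nwbv, z, covariates = gcov,
                         n_boot = cfg$mediation$n_boot,
                         ci_level = cfg$mediation$ci_level,
                         seed = cfg$mediation$seed + 1L)
    res[[lab]] <- list(fnc_mediates_performance = m1,
                       volume_mediates_fnc = m2)
  }
  rows <- do.call(rbind, lapply(names(res), function(lab) {
    do.call(rbind, lapply(c("fnc_mediates_performance",
                            "volume_mediates_fnc"), function(kind) {
      m <- res[[lab]][[kind]]
      data.frame(edge = lab, model = kind, c = m$c, a = m$a, b = m$b,
                 c_prime = m$c_prime, indirect = m$indirect,
                 ci_low = m$ci_low, ci_high = m$ci_high,
                 significant = m$significant)
    }))
  }))
  if (!is.null(rows))
    write.table(rows, file.path(mdir, "mediation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  saveRDS(res, file.path(mdir, "mediation.rds"))
  stage_mark(out_root, "mediate", dg)
}
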