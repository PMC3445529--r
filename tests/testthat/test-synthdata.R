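test_that("planted sources are compact, separated and reproducible", {
  cfg <- synth_config(grid = c(10L, 10L, 10L), seed = 70)
  set.seed(cfg$seed)
  S1 <- make_sources(cfg)
  set.seed(cfg$seed)
  S2 <- make_sources(cfg)
  expect_identical(S1, S2)
  cc <- abs(cor(t(S1)))
  diag(cc) <- 0
  expect_lt(max(cc), cfg$max_source_cor)
  expect_equal(unname(apply(S1, 1, sd)), rep(1, cfg$n_sources))
  centers <- attr(S1, "centers")
  expect_equal(nrow(unique(centers)), cfg$n_sources)
  # infeasible packings are refused
  tiny <- synth_config(grid = c(5L, 5L, 5L), n_sources = 6L,
                       fnc_young = diag(6), fnc_old = diag(6))
  set.seed(1)
  expect_error(make_sources(tiny), "packing")
})

test_that("config invariants are enforced", {
  bad <- matrix(0.9, 6, 6); diag(bad) <- 1
  bad[1, 2] <- bad[2, 1] <- -0.9   # not positive definite
  expect_error(synth_config(fnc_young = bad), "positive-definite")
  expect_error(synth_config(n_old = 2L), "group sizes")
  expect_error(synth_config(nonsense = 1), "unknown config")
})

test_that("identity-correlation residuals decorrelate at long scan counts",
          {
  set.seed(71)
  cfg <- synth_config(fnc_young = diag(6), fnc_old = diag(6),
                      task_betas = matrix(0, 6, 9), scans_per_run = 690L)
  beh <- simulate_behavior(cfg, "young", 0)
  des <- build_design_matrix(beh$events, 690, 3, runs = 1:3)
  tc <- sample_timecourses(cfg, des, "young")
  r <- cor(tc)
  expect_lt(mean(abs(r[upper.tri(r)])), 0.05)
})

test_that("zero task loadings leave contrasts centered at zero", {
  set.seed(72)
  cfg <- synth_config(task_betas = matrix(0, 6, 9))
  beh <- simulate_behavior(cfg, "young", 0.5)
  des <- build_design_matrix(beh$events, cfg$scans_per_run, cfg$TR_s,
                             runs = 1:3)
  cvals <- replicate(60, {
    tc <- sample_timecourses(cfg, des, "young")
    fit <- fit_component_glm(tc[, 1], des)
    contrast_values(fit$betas, des)[["loadindep_stim"]]
  })
  expect_lt(abs(mean(cvals)), 3 * sd(cvals) / sqrt(length(cvals)))
})

test_that("planted edge connectivity calibrates to the configured group
           means", {
  set.seed(73)
  cfg <- synth_config()
  beh <- simulate_behavior(cfg, "young", fisher_z(cfg$fnc_young[1, 2]))
  des <- build_design_matrix(beh$events, cfg$scans_per_run, cfg$TR_s,
                             runs = 1:3)
  zs <- replicate(150, {
    tc <- sample_timecourses(cfg, des, "young")
    compute_fnc(tc, runs = rep(1:3, each = cfg$scans_per_run))[1, 2]
  })
  expect_lt(abs(mean(zs) - fisher_z(0.514)), 0.05)
})

test_that("behavior generator respects the response window and targets", {
  set.seed(74)
  cfg <- synth_config()
  z_ref <- fisher_z(cfg$fnc_young[1, 2])
  meds <- replicate(150, {
    b <- simulate_behavior(cfg, "young", z_ref + rnorm(1, 0, 0.15))
    expect_true(all(is.na(b$events$rt_s) | (b$events$rt_s > 0 &
                                            b$events$rt_s <= 3)))
    b$summary$median_rt
  })
  target <- c(0.88, 1.01, 1.18)
  expect_true(all(abs(rowMeans(meds) - target) < 0.05))
  # discrimination lands in the configured range
  set.seed(75)
  dls <- replicate(100, mean(simulate_behavior(cfg, "young",
                                               z_ref)$summary$d_l))
  expect_gt(mean(dls), 2.1)
  expect_lt(mean(dls), 2.8)
})

test_that("no edge coupling and equal slopes yield a null group
           difference", {
  set.seed(76)
  cfg <- synth_config()
  cfg$rt_model$kappa <- 0
  cfg$rt_model$slope_old_extra <- 0
  diffs <- replicate(80, {
    sy <- simulate_behavior(cfg, "young",
                            fisher_z(cfg$fnc_young[1, 2]))$slope_subject
    so <- simulate_behavior(cfg, "old",
                            fisher_z(cfg$fnc_old[1, 2]))$slope_subject
    so - sy
  })
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)))
})

test_that("volumes order by group, stay positive and ignore connectivity", {
  set.seed(77)
  cfg <- synth_config()
  vy <- replicate(150, simulate_volumes(cfg, "young")$nwbv)
  vo <- replicate(150, simulate_volumes(cfg, "old")$nwbv)
  expect_gt(mean(vy), mean(vo))
  expect_true(all(vy > 0 & vy < 1))
  st <- tiny_study()
  young <- st$subjects[st$subjects$group == "young", ]
  expect_lt(abs(cor(young$nwbv, young$true_z12)), 0.6)  # small n, null cor
})

test_that("the study writer produces the documented tree reproducibly", {
  cfg <- synth_config(n_young = 3L, n_old = 3L, grid = c(8L, 8L, 8L),
                      n_sources = 3L,
                      fnc_young = diag(3) + 0.1 - diag(0.1, 3),
                      fnc_old = diag(3) + 0.05 - diag(0.05, 3),
                      task_betas = matrix(0.2, 3, 9), seed = 78)
  d1 <- tempfile("study1"); d2 <- tempfile("study2")
  generate_study(cfg, d1)
  generate_study(cfg, d2)
  expect_true(file.exists(file.path(d1, "mask.nii.gz")))
  expect_true(file.exists(file.path(d1, "participants.tsv")))
  expect_true(file.exists(file.path(d1, "volumes.tsv")))
  expect_true(file.exists(file.path(d1, "ground_truth.rds")))
  expect_true(file.exists(file.path(d1, "sub-001", "run-3_bold.nii.gz")))
  img <- RNifti::readNifti(file.path(d1, "sub-001", "run-1_bold.nii.gz"))
  expect_equal(dim(img), c(8, 8, 8, 69))
  # same seed, byte-identical event tables
  e1 <- readLines(file.path(d1, "sub-002_events.tsv"))
  e2 <- readLines(file.path(d2, "sub-002_events.tsv"))
  expect_identical(e1, e2)
  # refuses to clobber without the flag
  expect_error(generate_study(cfg, d1), "overwrite")
  unlink(c(d1, d2), recursive = TRUE)
})
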