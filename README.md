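# taskfnc

Group spatial ICA, functional network connectivity and bootstrap mediation
for task fMRI, with a synthetic-study generator for end-to-end validation.

## The problem

Aging changes brain structure, the coordination of activity between brain
networks, and cognitive performance — but these changes are usually studied
separately. `taskfnc` implements the analysis chain that ties them together
for a verbal delayed item recognition (DIR) task: subjects encode 1, 3 or 6
letters (stimulus, 3 s), hold them (retention, 7 s), and judge a probe
letter within a 3 s window. The pipeline asks, in order:

1. Which spatial networks are engaged by the task? Group spatial ICA
   (infomax with ICASSO stability selection over two PCA reduction stages)
   extracts independent components; each component's back-reconstructed
   time course is fit with a GLM whose nine regressors cross memory load
   (1/3/6) with task phase (stimulus/retention/probe), convolved with the
   canonical double-gamma HRF.
2. Does age change the coupling *between* networks? Functional network
   connectivity (FNC) is the Pearson correlation between component time
   courses within subject, Fisher z-transformed
   (`z = atanh(r)`), compared between age groups with gender-adjusted
   t-tests under Bonferroni correction.
3. Does connectivity carry the age effect on performance? Single-mediator
   models with stratified bootstrap (resampling preserves each group's n)
   and bias-corrected percentile confidence intervals test the indirect
   effect `a*b` in `age -> FNC -> sRT` (sRT = slope of median RT against
   set size) and `age -> nWBV -> FNC`
   (nWBV = (GM+WM)/(GM+WM+CSF), a global atrophy proxy). For OLS paths with
   shared covariates the decomposition `c = c' + a*b` is exact.

Because no public dataset accompanies this design, the package ships a
first-class synthetic-study generator (`synth_config()`,
`simulate_study()`, `generate_study()`) that plants known spatial sources,
group-specific between-network correlations, a connectivity-coupled RT
slope and group-shifted tissue volumes — so every stage of the pipeline is
checked by parameter recovery.

## Worked example

A reduced synthetic study (12 + 12 subjects, 10^3 voxel grid, 6 sources,
3 runs x 69 scans at TR = 3 s), decomposed and analysed end to end:

```r
library(taskfnc)

cfg <- synth_config(n_young = 12, n_old = 12, grid = c(10L, 10L, 10L),
                    seed = 11)
study <- simulate_study(cfg)

runs <- list()
for (id in study$subjects$subject_id)
  for (r in 1:cfg$runs)
    runs[[paste0(id, ".", r)]] <-
      prepare_run(study$bold[[id]][[r]], subject_id = id, run_id = r)

model <- group_ica(runs, n_ic = 6, retained_run = 30, n_reps = 10, seed = 5)
round(model$stability_iq, 2)
#> 0.96 0.96 0.96 0.95 0.95 0.95
apply(abs(cor(t(model$sources), t(study$sources))), 2, max)
#> 0.997 0.998 0.998 0.997 0.998 0.998   # planted maps recovered
```

Every planted source is recovered with spatial |r| > 0.99 and high ICASSO
stability (Iq near 1 means the component reappears across repetitions).
Connectivity edge tests then find exactly the two planted group
differences:

```r
# match component order (and sign) to the planted sources for readability
cc <- cor(t(model$sources), t(study$sources))
perm <- apply(abs(cc), 2, which.max)
sgn <- sign(cc[cbind(perm, 1:6)])
fncs <- lapply(study$subjects$subject_id, function(id) {
  comp <- subject_components(model, runs[paste0(id, ".", 1:3)])
  compute_fnc(comp$timecourses[, perm] %*% diag(sgn), runs = comp$run_index)
})
tab <- edge_group_tests(fncs, study$subjects$group, study$subjects$gender)
tab[tab$significant, c("i", "j", "t", "p", "mean_young", "mean_old")]
#>  i j    t        p mean_young mean_old
#>  1 2 6.63 1.47e-06      0.436  -0.0313
#>  3 4 4.67 1.33e-04      0.530   0.2381
```

(Here components are matched to the planted source order; the young group's
connectivity is stronger on both planted edges, and the t values are
positive by the young-minus-old sign convention.) Finally, the mediation
model tests whether that edge transmits the age effect on the RT set-size
slope:

```r
z12 <- sapply(fncs, function(f) f[1, 2])
x <- as.numeric(study$subjects$group == "old")
gender <- scale(as.numeric(factor(study$subjects$gender)), scale = FALSE)[, 1]
mediation_test(x, z12, study$subjects$srt, covariates = gender,
               n_boot = 10000, seed = 1)
#> Mediation (single mediator, stratified bootstrap BC CI)
#>   c = 0.1269  a = -0.4878  b = -0.1338  c' = 0.0616
#>   indirect a*b = 0.0652, 95% CI [0.0288, 0.1162] (B = 10000) *
```

Old age lowers edge connectivity (`a < 0`), and lower connectivity steepens
the RT-per-letter slope (`b < 0`), so the indirect effect is positive and
its 95% interval excludes zero: connectivity partially mediates the age
effect on speeded performance. The planted values behind these estimates
are `a = -0.455`, `b = -0.15`, direct effect `0.042`.

A file-based pipeline (`run_pipeline("all", config)` or
`Rscript inst/cli/taskfnc.R all --config config.yaml`) orchestrates the
same stages over a study directory of NIfTI runs and TSV tables, with
digest-based stage skipping.

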