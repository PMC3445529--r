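# Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# Reduced synthetic study: 12 + 12 subjects on a 10^3 grid, 6 sources,
# 3 x 69 scans (the full-size temporal structure at a small spatial size).
tiny_study <- function() {
  fixture("tiny_study", function() {
    simulate_study(synth_config(n_young = 12L, n_old = 12L,
                                grid = c(10L, 10L, 10L), seed = 11L))
  })
}

tiny_runs <- function() {
  fixture("tiny_runs", function() {
    st <- tiny_study()
    runs <- list()
    for (id in st$subjects$subject_id) for (r in seq_len(st$cfg$runs))
      runs[[paste0(id, ".", r)]] <-
        prepare_run(st$bold[[id]][[r]], subject_id = id, run_id = r)
    runs
  })
}

tiny_model <- function() {
  fixture("tiny_model", function() {
    group_ica(tiny_runs(), n_ic = 6L, retained_run = 30L, n_reps = 10L,
              seed = 5L)
  })
}

# Reduced-subject study at the generator's default 12^3 grid, for the
# connectivity-recovery property (more voxels = less map-estimation leakage).
grid_study <- function() {
  fixture("grid_study", function() {
    st <- simulate_study(synth_config(n_young = 12L, n_old = 12L,
                                      seed = 11L))
    runs <- list()
    for (id in st$subjects$subject_id) for (r in seq_len(st$cfg$runs))
      runs[[paste0(id, ".", r)]] <-
        prepare_run(st$bold[[id]][[r]], subject_id = id, run_id = r)
    model <- group_ica(runs, n_ic = 6L, retained_run = 30L, n_reps = 5L,
                       seed = 5L)
    list(st = st, runs = runs, model = model)
  })
}

# Three planted super-Gaussian sources on disjoint voxel blobs, mixed by
# random time courses; whitened for the ICA tests.
planted_white <- function() {
  fixture("planted_white", function() {
    set.seed(42)
    V <- 2000L; n <- 3L; Tt <- 100L
    S <- matrix(0, n, V)
    S[1, 1:100] <- rexp(100)
    S[2, 500:650] <- rexp(151)
    S[3, 1200:1420] <- rexp(221)
    S <- S / apply(S, 1, sd)
    TC <- matrix(rnorm(Tt * n), Tt, n)
    X <- TC %*% S + matrix(rnorm(Tt * V, sd = 0.05), Tt, V)
    X <- scale(X, center = TRUE, scale = FALSE)
    list(white = reduce_run(X, n, check_demeaned = FALSE)$reduced,
         sources = S)
  })
}

# Amari index between two unmixing matrices (0 = same up to permutation
# and scale); the standard ICA identifiability diagnostic.
amari_index <- function(W1, W2) {
  P <- abs(W1 %*% solve(W2))
  n <- nrow(P)
  (sum(P / apply(P, 1, max)) + sum(t(P) / apply(P, 2, max)) - 2 * n) /
    (2 * n * (n - 1))
}

# Best |correlation| match of each planted source among recovered ones.
match_sources <- function(recovered, planted) {
  cc <- abs(cor(t(recovered), t(planted)))
  apply(cc, 2, max)
}

balanced_gender <- function(n) rep(c("M", "F"), length.out = n)
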