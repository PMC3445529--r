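test_that("Fisher z round-trips and matches the closed form", {
  r <- seq(-0.999999, 0.999999, length.out = 41)
  expect_equal(fisher_z_inv(fisher_z(r)), r, tolerance = 1e-12)
  # constructed pair with r = 0.5 exactly
  x <- c(-1, 0, 1, 0, -1, 1)
  y <- x * 0.5 + sqrt(1 - 0.25) * c(0.5, -1, 0.5, 1, -0.5, -0.5)
  # simpler: direct atanh check
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(round(fisher_z(0.5), 4), 0.5493)
  # perfect correlation is clipped, not infinite
  expect_equal(fisher_z(1), atanh(1 - 1e-12))
  expect_true(is.finite(fisher_z(-1)))
})

test_that("identical time courses hit the clipped maximum", {
  set.seed(40)
  tc <- cbind(a = rnorm(50), b = rnorm(50))
  tc <- cbind(tc, c = tc[, 1])
  z <- compute_fnc(tc)
  expect_equal(z[1, 3], atanh(1 - 1e-12))
  expect_equal(z[1, 2], z[2, 1])
  expect_true(all(is.na(diag(z))))
})

test_that("Fisher variance approximation holds for white noise", {
  set.seed(41)
  Tt <- 207
  zs <- replicate(1000, {
    compute_fnc(matrix(rnorm(Tt * 2), Tt, 2))[1, 2]
  })
  expect_equal(sd(zs), 1 / sqrt(Tt - 3), tolerance = 0.1)
})

test_that("connectivity ignores per-run offsets and component scaling", {
  set.seed(42)
  tc <- matrix(rnorm(60 * 3), 60, 3)
  runs <- rep(1:2, each = 30)
  z0 <- compute_fnc(tc, runs)
  # adding run-specific offsets changes nothing
  tc_off <- tc + outer(ifelse(runs == 1, 5, -3), c(1, 2, 3))
  expect_equal(compute_fnc(tc_off, runs), z0, tolerance = 1e-12)
  # scaling and sign flips preserve |z| and flip its sign consistently
  tc_fs <- tc %*% diag(c(2, -0.5, 1))
  z_fs <- compute_fnc(tc_fs, runs)
  expect_equal(abs(z_fs), abs(z0), tolerance = 1e-12)
  expect_equal(z_fs[1, 2], -z0[1, 2], tolerance = 1e-12)
})

test_that("constant time courses are masked with a warning", {
  set.seed(43)
  tc <- cbind(rnorm(30), rnorm(30), 1)
  expect_warning(z <- compute_fnc(tc), "constant")
  expect_true(is.na(z[1, 3]) && is.na(z[2, 3]))
  expect_false(is.na(z[1, 2]))
})

simulate_fncs <- function(n_young, n_old, k, delta = NULL, sd_z = 0.2,
                          edge = c(1, 2)) {
  n <- n_young + n_old
  group <- rep(c("young", "old"), c(n_young, n_old))
  lapply(seq_len(n), function(s) {
    z <- matrix(rnorm(k * k, 0, sd_z), k, k)
    z[lower.tri(z)] <- t(z)[lower.tri(z)]
    diag(z) <- NA
    if (!is.null(delta) && group[s] == "young") {
      z[edge[1], edge[2]] <- z[edge[1], edge[2]] + delta
      z[edge[2], edge[1]] <- z[edge[1], edge[2]]
    }
    structure(z, class = c("fnc_matrix", "matrix"))
  })
}

test_that("edge family size is the number of unordered pairs", {
  set.seed(44)
  fncs <- simulate_fncs(8, 6, 18)
  group <- rep(c("young", "old"), c(8, 6))
  tab <- edge_group_tests(fncs, group, balanced_gender(14))
  expect_equal(attr(tab, "family_size"), choose(18, 2))
  expect_equal(attr(tab, "family_size"), 153)
  expect_equal(nrow(tab), 153)
})

test_that("null edge tests keep the family-wise error controlled", {
  set.seed(45)
  group <- rep(c("young", "old"), c(20, 12))
  any_sig <- replicate(120, {
    fncs <- simulate_fncs(20, 12, 8)
    tab <- edge_group_tests(fncs, group, balanced_gender(32))
    any(tab$significant)
  })
  # Bonferroni at alpha 0.05: binomial(120, 0.05) stays below ~12
  expect_lt(sum(any_sig), 13)
})

test_that("a planted group difference is detected with the right sign", {
  set.seed(46)
  group <- rep(c("young", "old"), c(75, 37))
  hits <- replicate(60, {
    fncs <- simulate_fncs(75, 37, 6, delta = 0.4)
    tab <- edge_group_tests(fncs, group, balanced_gender(112))
    row <- tab[tab$i == 1 & tab$j == 2, ]
    row$significant && row$t > 0
  })
  expect_gt(mean(hits), 0.95)
})

test_that("masked edges are excluded pairwise and counted", {
  set.seed(47)
  fncs <- simulate_fncs(6, 6, 4)
  fncs[[1]][1, 2] <- fncs[[1]][2, 1] <- NA
  group <- rep(c("young", "old"), each = 6)
  tab <- edge_group_tests(fncs, group, balanced_gender(12))
  expect_equal(tab$n_excluded[tab$i == 1 & tab$j == 2], 1)
  expect_true(all(tab$n_excluded[!(tab$i == 1 & tab$j == 2)] == 0))
})

test_that("pruning drops components with no significant edges", {
  mk_tab <- function(k, sig_pairs) {
    pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
    d <- data.frame(i = pairs[, 1], j = pairs[, 2], significant = FALSE)
    for (p in sig_pairs)
      d$significant[d$i == p[1] & d$j == p[2]] <- TRUE
    attr(d, "n_components") <- k
    d
  }
  # nothing significant: everything dropped
  expect_length(prune_unconnected(mk_tab(5, list()))$retained, 0)
  # the study configuration: 18 components, 3 of them (10, 16, 18 here)
  # unconnected leaves 15
  sig <- list(c(1, 2), c(3, 4), c(5, 6), c(7, 8), c(9, 11), c(12, 13),
              c(14, 15), c(15, 17), c(2, 3), c(4, 5))
  pr <- prune_unconnected(mk_tab(18, sig))
  expect_length(pr$retained, 15)
  expect_equal(pr$dropped, c(10L, 16L, 18L))
  # full significance retains everything
  all_pairs <- apply(which(upper.tri(matrix(0, 4, 4)), arr.ind = TRUE), 1,
                     identity, simplify = FALSE)
  expect_length(prune_unconnected(mk_tab(4, all_pairs))$dropped, 0)
})

test_that("edge-performance regression recovers a planted slope", {
  set.seed(48)
  n <- 112
  gender <- balanced_gender(n)
  covered <- replicate(200, {
    z <- rnorm(n, 0.3, 0.25)
    srt <- 0.1 - 0.15 * z + rnorm(n, 0, 0.01)
    f <- edge_performance_regression(z, srt, gender)
    se <- f$slope / f$t
    (f$slope - 2 * se) <= -0.15 && -0.15 <= (f$slope + 2 * se)
  })
  expect_gt(mean(covered), 0.9)
  # duplicating every subject leaves the point estimate unchanged
  z <- rnorm(20); srt <- -0.15 * z + rnorm(20, 0, 0.02)
  g20 <- balanced_gender(20)
  f1 <- edge_performance_regression(z, srt, g20)
  f2 <- edge_performance_regression(rep(z, 2), rep(srt, 2), rep(g20, 2))
  expect_equal(f1$slope, f2$slope, tolerance = 1e-12)
})
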