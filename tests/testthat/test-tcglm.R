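glm_design <- function(n_scans = 40) {
  # one incorrect trial keeps the error regressor (and the design) full rank
  ev <- make_events(c(2, 30, 60, 90), c(1, 3, 6, 3), c(0.8, 1.0, 1.2, 0.7),
                    c(TRUE, TRUE, TRUE, FALSE), rep(FALSE, 4))
  build_design_matrix(ev, n_scans)
}

test_that("noiseless GLM recovers the generating betas exactly", {
  d <- glm_design()
  beta <- seq(0.1, 1.1, length.out = ncol(d$matrix))
  tc <- d$matrix %*% beta
  fit <- fit_component_glm(tc, d)
  expect_equal(unname(fit$betas), beta, tolerance = 1e-8)
  # contrast values follow from the weights
  cv <- contrast_values(fit$betas, d)
  expect_equal(unname(cv["loadindep_stim"]), mean(beta[1:3]),
               tolerance = 1e-8)
})

test_that("adding a constant changes only the intercept betas", {
  d <- glm_design()
  set.seed(30)
  tc <- rnorm(40)
  f1 <- fit_component_glm(tc, d)
  f2 <- fit_component_glm(tc + 10, d)
  expect_equal(f1$betas[1:10], f2$betas[1:10], tolerance = 1e-8)
  expect_equal(unname(f2$betas["run1"] - f1$betas["run1"]), 10,
               tolerance = 1e-8)
})

test_that("aliased design columns are dropped with a warning", {
  d <- glm_design()
  d$matrix <- cbind(d$matrix, dup = d$matrix[, 1])
  d$regressor_names <- c(d$regressor_names, "dup")
  expect_warning(fit_component_glm(rnorm(40), d), "rank deficient")
})

test_that("null time courses give Student-t contrast statistics", {
  ev <- make_events(c(2, 40, 80, 120, 160), c(1, 3, 6, 1, 6),
                    c(0.8, 1.0, 1.2, 0.9, 1.1),
                    c(TRUE, TRUE, TRUE, TRUE, FALSE), rep(FALSE, 5))
  d <- build_design_matrix(ev, 60)
  X <- d$matrix
  w <- d$contrasts$loadindep_stim
  XtXi <- solve(crossprod(X))
  se_scale <- sqrt(drop(t(w) %*% XtXi %*% w))
  df <- nrow(X) - ncol(X)
  set.seed(31)
  tvals <- replicate(500, {
    f <- taskfnc:::ols_t(X, rnorm(nrow(X)))
    sum(w * f$coef) / (sqrt(sum(f$residuals^2) / df) * se_scale)
  })
  expect_gt(ks.test(tvals, pt, df = df)$p.value, 0.01)
})

test_that("within-group test controls for gender as documented", {
  g <- rep(c("M", "F"), 8)
  w <- within_group_test(rep(5, 16), g)
  expect_lt(w$p, 1e-12)
  # antisymmetric values across balanced genders: intercept t is zero
  vals <- ifelse(g == "M", 2, -2)
  w2 <- within_group_test(vals, g)
  expect_equal(w2$t, 0, tolerance = 1e-10)
  expect_equal(w2$df, 14)
  expect_warning(within_group_test(rnorm(8), rep("M", 8)), "single-gender")
})

test_that("within-group intercept is unbiased for the group mean", {
  set.seed(32)
  g <- rep(c("M", "F"), c(10, 6))
  mu <- 0.3
  est <- replicate(500, {
    v <- mu + 0.5 * (g == "M") - 0.5 * mean(g == "M") + rnorm(16, 0, 0.4)
    within_group_test(v, g)$estimate
  })
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - mu), 2 * mc_se + 1e-3)
})

test_that("between-group test matches the closed-form covariate oracle", {
  set.seed(33)
  n <- 30
  group <- rep(c("young", "old"), c(18, 12))
  gender <- sample(c("M", "F"), n, replace = TRUE)
  v <- rnorm(n) + 0.8 * (group == "young")
  bt <- between_group_test(v, group, gender)
  # independent oracle: normal-equations OLS with explicit inverse
  X <- cbind(1, as.numeric(group == "young"),
             scale(as.numeric(factor(gender)), scale = FALSE)[, 1])
  XtXi <- solve(t(X) %*% X)
  bhat <- XtXi %*% t(X) %*% v
  s2 <- sum((v - X %*% bhat)^2) / (n - 3)
  t_oracle <- bhat[2] / sqrt(s2 * XtXi[2, 2])
  expect_equal(bt$t, drop(t_oracle), tolerance = 1e-10)
  expect_equal(bt$df, n - 3)
  # positive t means young exceeds old
  expect_gt(bt$t, 0)
})

test_that("between-group t is invariant to affine group coding", {
  set.seed(34)
  v <- rnorm(20)
  gender <- rep(c("M", "F"), 10)
  t1 <- between_group_test(v, rep(c(0, 1), 10), gender,
                           positive_level = "1")$t
  t2 <- between_group_test(v, rep(c(1, 2), 10), gender,
                           positive_level = "2")$t
  expect_equal(t1, t2, tolerance = 1e-12)
})

test_that("task-relatedness classification applies the Bonferroni rule", {
  mk_table <- function(p_arr) {
    structure(list(p_within = p_arr, alpha = 0.05,
                   family_size = dim(p_arr)[2] * dim(p_arr)[3] * 2),
              class = "task_relatedness_table")
  }
  p_all1 <- array(1, c(2, 4, 6))
  expect_length(classify_task_related(mk_table(p_all1))$retained, 0)
  p_one <- p_all1
  p_one[1, 2, 3] <- 1e-12
  cls <- classify_task_related(mk_table(p_one))
  expect_equal(cls$retained, 2L)
  expect_equal(cls$excluded, c(1L, 3L, 4L))
  # the study's configuration: 36 components, 11 artifacts leave 25 in the
  # family (25 x 6 x 2 = 300 comparisons); 7 non-task leave 18 retained
  p_paper <- array(0.5, c(2, 25, 6))
  task_comps <- 1:18
  p_paper[1, task_comps, 1] <- 1e-8
  cls_p <- classify_task_related(mk_table(p_paper))
  expect_equal(cls_p$family_size, 300)
  expect_length(cls_p$retained, 18)
})

test_that("full relatedness table has the documented shape and signs", {
  set.seed(35)
  n <- 24
  group <- rep(c("young", "old"), each = 12)
  gender <- balanced_gender(n)
  vals <- array(rnorm(n * 3 * 6), c(n, 3, 6))
  vals[group == "young", 2, ] <- vals[group == "young", 2, ] + 3
  tab <- task_relatedness_table(vals, group, gender)
  expect_equal(dim(tab$t_within), c(2, 3, 6))
  expect_equal(tab$family_size, 36)
  # young > old on component 2 gives positive between-group t
  expect_true(all(tab$t_between[2, ] > 0))
})
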