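#' Fit the task design to a component time course
#'
#' Ordinary least squares of one back-reconstructed component time course on
#' the run-blocked convolved design matrix. Aliased (rank-deficient) columns
#' are dropped with a warning and return `NA` coefficients.
#'
#' @param tc Numeric vector, concatenated-run component time course; length
#'   must match the design rows.
#' @param design A [build_design_matrix()] object covering the same runs.
#' @return A list with `betas` (named, one per regressor), `residuals`,
#'   `df`, and `sigma2`.
#' @export
fit_component_glm <- function(tc, design) {
  X <- design$matrix
  if (length(tc) != nrow(X))
    stop("time course length (", length(tc),
         ") does not match design rows (", nrow(X), ")")
  f <- ols_t(X, as.numeric(tc))
  if (f$rank < ncol(X))
    warning("design is rank deficient; ", ncol(X) - f$rank,
            " aliased column(s) dropped")
  betas <- f$coef
  names(betas) <- design$regressor_names
  list(betas = betas, residuals = f$residuals, df = f$df,
       sigma2 = sum(f$residuals^2) / f$df)
}

#' Contrast values from a fitted component GLM
#'
#' @param betas Named coefficient vector from [fit_component_glm()].
#' @param design The design the betas come from.
#' @return Named numeric vector of the six contrast-weighted beta values.
#' @export
contrast_values <- function(betas, design) {
  b <- betas
  b[is.na(b)] <- 0
  vapply(design$contrasts, function(w) sum(w * b), numeric(1))
}

#' One-sample within-group test controlling for gender
#'
#' Regression of the contrast values on an intercept plus a centered gender
#' indicator; the intercept t tests whether the group mean differs from
#' zero, with n - 2 residual degrees of freedom. A single-gender group falls
#' back to a plain one-sample t-test with a warning.
#'
#' @param values Per-subject contrast (or connectivity) values for one group.
#' @param gender Per-subject gender labels.
#' @return List with `estimate`, `t`, `p` (two-sided), `df`.
#' @export
within_group_test <- function(values, gender) {
  g <- gender_covariate(gender)
  if (is.null(g)) {
    warning("single-gender group: plain one-sample t-test")
    X <- matrix(1, length(values), 1)
  } else {
    X <- cbind(1, g)
  }
  f <- ols_t(X, values)
  list(estimate = f$coef[1], t = f$t[1], p = f$p[1], df = f$df)
}

#' Between-group test controlling for gender
#'
#' Regression of values on an intercept, a group indicator and a centered
#' gender covariate. The indicator is oriented so a positive t means the
#' `positive_level` group (young, by default) exceeds the other.
#'
#' @param values Per-subject values across both groups.
#' @param group Per-subject group labels (two levels).
#' @param gender Per-subject gender labels.
#' @param positive_level Group whose excess yields positive t; defaults to
#'   `"young"` when present, otherwise the first level.
#' @return List with `estimate` (group difference), `t`, `p`, `df`, and the
#'   two group means.
#' @export
between_group_test <- function(values, group, gender,
                               positive_level = NULL) {
  lev <- unique(as.character(group))
  if (length(lev) != 2) stop("both groups must be present")
  if (is.null(positive_level))
    positive_level <- if ("young" %in% lev) "young" else lev[1]
  ind <- as.numeric(group == positive_level)
  g <- gender_covariate(gender)
  X <- if (is.null(g)) cbind(1, ind) else cbind(1, ind, g)
  f <- ols_t(X, values)
  list(estimate = f$coef[2], t = f$t[2], p = f$p[2], df = f$df,
       mean_positive = mean(values[ind == 1]),
       mean_other = mean(values[ind == 0]))
}

#' Task-relatedness tests for all components
#'
#' Within-group (one-sample, gender-adjusted) and between-group t-tests for
#' every component and each of the six contrasts of interest.
#'
#' @param values 3-d array subjects x components x contrasts of
#'   contrast-weighted beta values.
#' @param group,gender Per-subject labels.
#' @param alpha Significance level before correction.
#' @param family_size Bonferroni family; defaults to
#'   components x contrasts x 2 groups.
#' @return A list of class `task_relatedness_table` with `t_within`,
#'   `p_within` (group x component x contrast), `t_between`, `p_between`,
#'   `family_size`, `alpha`.
#' @export
task_relatedness_table <- function(values, group, gender, alpha = 0.05,
                                   family_size = NULL) {
  stopifnot(length(dim(values)) == 3)
  n_comp <- dim(values)[2]
  n_con <- dim(values)[3]
  groups <- unique(as.character(group))
  if (length(groups) != 2) stop("exactly two groups required")
  if ("young" %in% groups) groups <- c("young", setdiff(groups, "young"))
  if (is.null(family_size)) family_size <- n_comp * n_con * 2L
  t_w <- p_w <- array(NA_real_, c(2, n_comp, n_con),
                      dimnames = list(groups, NULL, dimnames(values)[[3]]))
  t_b <- p_b <- matrix(NA_real_, n_comp, n_con,
                       dimnames = list(NULL, dimnames(values)[[3]]))
  for (ci in seq_len(n_comp)) for (ki in seq_len(n_con)) {
    for (gi in 1:2) {
      sel <- group == groups[gi]
      w <- within_group_test(values[sel, ci, ki], gender[sel])
      t_w[gi, ci, ki] <- w$t
      p_w[gi, ci, ki] <- w$p
    }
    b <- between_group_test(values[, ci, ki], group, gender,
                            positive_level = groups[1])
    t_b[ci, ki] <- b$t
    p_b[ci, ki] <- b$p
  }
  structure(list(t_within = t_w, p_within = p_w, t_between = t_b,
                 p_between = p_b, groups = groups,
                 family_size = family_size, alpha = alpha),
            class = "task_relatedness_table")
}

#' Classify components as task-related
#'
#' A component is task-related if any of its within-group contrast tests is
#' significant in at least one age group at `alpha`, Bonferroni corrected
#' for the recorded family size.
#'
#' @param table A [task_relatedness_table()] result.
#' @param alpha,family_size Override the table's stored values.
#' @return List with `retained` (sorted component indices), `excluded`,
#'   `threshold` and `family_size`.
#' @export
classify_task_related <- function(table, alpha = NULL, family_size = NULL) {
  alpha <- if (is.null(alpha)) table$alpha else alpha
  family_size <- if (is.null(family_size)) table$family_size else family_size
  thr <- alpha / family_size
  sig <- apply(table$p_within < thr, 2, any)
  comp <- seq_len(dim(table$p_within)[2])
  list(retained = comp[sig], excluded = comp[!sig],
       threshold = thr, family_size = family_size)
}
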