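#' Fisher z transform and its inverse
#'
#' `fisher_z()` clips correlations to `|r| <= 1 - 1e-12` before `atanh` so
#' degenerate (perfect) correlations stay finite; `fisher_z_inv()` is `tanh`.
#'
#' @param r Correlation values.
#' @param z Fisher-z values.
#' @param clip Clipping bound applied to `|r|`.
#' @return Transformed values.
#' @export
fisher_z <- function(r, clip = 1 - 1e-12) atanh(pmin(pmax(r, -clip), clip))

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Functional network connectivity matrix for one subject
#'
#' Pearson correlation between every pair of component time courses, Fisher
#' z-transformed. Runs are demeaned individually and concatenated before
#' correlating, so inter-run offsets do not inflate connectivity. Constant
#' time courses yield masked (NA) edges with a warning.
#'
#' @param tcs Matrix, total scans x components (runs stacked in acquisition
#'   order).
#' @param runs Run index per row; a single run when `NULL`.
#' @return An object of class `fnc_matrix`: symmetric components x
#'   components Fisher-z matrix with `NA` diagonal.
#' @export
compute_fnc <- function(tcs, runs = NULL) {
  tcs <- as.matrix(tcs)
  if (ncol(tcs) < 2) stop("at least 2 components required")
  if (nrow(tcs) < 3) stop("at least 3 time points required")
  if (is.null(runs)) runs <- rep(1L, nrow(tcs))
  for (r in unique(runs)) {
    i <- runs == r
    tcs[i, ] <- scale(tcs[i, , drop = FALSE], center = TRUE, scale = FALSE)
  }
  const <- apply(tcs, 2, function(x) sd(x) == 0 || !all(is.finite(x)))
  if (any(const))
    warning(sum(const), " constant time course(s); their edges are masked")
  R <- suppressWarnings(cor(tcs))
  R[const, ] <- NA
  R[, const] <- NA
  Z <- fisher_z(R)
  diag(Z) <- NA
  structure(Z, class = c("fnc_matrix", "matrix"))
}

#' Between-group tests on every connectivity edge
#'
#' For each unordered component pair, the gender-adjusted between-group
#' t-test ([between_group_test()]) on the subjects' Fisher-z values, with
#' Bonferroni correction over the number of pairs. Subjects with a masked
#' edge are excluded pairwise and counted.
#'
#' @param fncs List of per-subject `fnc_matrix` objects (same dimension).
#' @param group,gender Per-subject labels.
#' @param alpha Significance level; corrected threshold is
#'   `alpha / n_pairs`.
#' @return A `data.frame` of class `edge_test_table`: columns `i`, `j`, `t`,
#'   `p`, `mean_young`, `se_young`, `mean_old`, `se_old`, `n_excluded`,
#'   `significant`; attributes `family_size`, `alpha`, `n_components`.
#' @export
edge_group_tests <- function(fncs, group, gender, alpha = 0.05) {
  k <- nrow(fncs[[1]])
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  family <- nrow(pairs)
  lev <- unique(as.character(group))
  pos <- if ("young" %in% lev) "young" else lev[1]
  res <- lapply(seq_len(family), function(e) {
    i <- pairs[e, 1]; j <- pairs[e, 2]
    z <- vapply(fncs, function(f) f[i, j], numeric(1))
    ok <- is.finite(z)
    bt <- between_group_test(z[ok], group[ok], gender[ok],
                             positive_level = pos)
    zp <- z[ok][group[ok] == pos]
    zo <- z[ok][group[ok] != pos]
    data.frame(i = i, j = j, t = bt$t, p = bt$p,
               mean_young = mean(zp), se_young = sd(zp) / sqrt(length(zp)),
               mean_old = mean(zo), se_old = sd(zo) / sqrt(length(zo)),
               n_excluded = sum(!ok))
  })
  out <- do.call(rbind, res)
  out$significant <- out$p < alpha / family
  attr(out, "family_size") <- family
  attr(out, "alpha") <- alpha
  attr(out, "n_components") <- k
  class(out) <- c("edge_test_table", "data.frame")
  out
}

#' Drop components with no significant connectivity differences
#'
#' Components incident to zero significant edges in the between-group edge
#' table are removed from further analyses.
#'
#' @param table An [edge_group_tests()] result.
#' @return List with `retained` and `dropped` component indices.
#' @export
prune_unconnected <- function(table) {
  k <- attr(table, "n_components")
  sig <- table[table$significant, , drop = FALSE]
  connected <- sort(unique(c(sig$i, sig$j)))
  list(retained = connected, dropped = setdiff(seq_len(k), connected))
}

#' Regression of task performance on connectivity strength
#'
#' OLS of the speeded-performance measure (sRT) on one edge's Fisher-z
#' values plus a centered gender covariate, Bonferroni corrected over the
#' supplied family of edges tested.
#'
#' @param z_edge Per-subject Fisher-z values of one edge.
#' @param srt Per-subject set-size RT slopes.
#' @param gender Per-subject labels.
#' @param family Number of edges in the tested family.
#' @param alpha Significance level before correction.
#' @return List with `slope`, `t`, `p`, `df`, `significant`.
#' @export
edge_performance_regression <- function(z_edge, srt, gender, family = 1L,
                                        alpha = 0.05) {
  stopifnot(length(z_edge) == length(srt), length(srt) == length(gender))
  g <- gender_covariate(gender)
  X <- if (is.null(g)) cbind(1, z_edge) else cbind(1, z_edge, g)
  f <- ols_t(X, srt)
  list(slope = f$coef[2], t = f$t[2], p = f$p[2], df = f$df,
       significant = f$p[2] < alpha / family)
}
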