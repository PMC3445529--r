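#' Covariate-adjusted mediation path coefficients
#'
#' Three OLS regressions with the same covariates throughout:
#' total effect `c` from `y ~ x + cov`, path `a` from `m ~ x + cov`,
#' and `b` with direct effect `c'` from `y ~ x + m + cov`. With identical
#' covariate sets the decomposition `c = c' + a*b` holds exactly.
#'
#' @param x Binary exposure (e.g. age group, old = 1, young = 0).
#' @param m Mediator values.
#' @param y Outcome values.
#' @param covariates Optional numeric matrix/vector of covariates (e.g. a
#'   centered gender indicator), entered in all three regressions.
#' @return List with `a`, `b`, `c`, `c_prime`, `indirect` (= a*b) and the
#'   per-path `t` and `p` values.
#' @export
fit_paths <- function(x, m, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(m) == n, length(y) == n)
  if (anyNA(c(x, m, y))) stop("missing values are not supported")
  cv <- if (is.null(covariates)) NULL else as.matrix(covariates)
  if (!is.null(cv)) {
    keep <- apply(cv, 2, function(col) sd(col) > 0)
    if (!all(keep)) {
      warning("constant covariate(s) dropped")
      cv <- cv[, keep, drop = FALSE]
      if (ncol(cv) == 0) cv <- NULL
    }
  }
  X0 <- cbind(1, x, cv)
  X1 <- cbind(1, x, m, cv)
  fc <- ols_t(X0, y)
  fa <- ols_t(X0, m)
  fb <- ols_t(X1, y)
  list(a = fa$coef[2], b = fb$coef[3], c = fc$coef[2], c_prime = fb$coef[2],
       indirect = fa$coef[2] * fb$coef[3],
       t = c(a = fa$t[2], b = fb$t[3], c = fc$t[2], c_prime = fb$t[2]),
       p = c(a = fa$p[2], b = fb$p[3], c = fc$p[2], c_prime = fb$p[2]))
}

# Fast indirect effect (a*b) used inside the bootstrap loop.
indirect_ab <- function(X0, X1, m, y) {
  a <- stats::.lm.fit(X0, m)$coefficients[2]
  b <- stats::.lm.fit(X1, y)$coefficients[3]
  a * b
}

#' Stratified bootstrap of the indirect effect
#'
#' Resamples subjects with replacement within each exposure stratum,
#' preserving the two group sizes exactly in every replicate (the exposure
#' is categorical and the groups are unbalanced), and recomputes the
#' indirect effect a*b per replicate. Replicates where the mediator or
#' outcome has zero variance are redrawn and counted.
#'
#' @inheritParams fit_paths
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed; the draw is reproducible.
#' @param return_indices Also return the resampled subject indices (one row
#'   per replicate), for auditing the stratification.
#' @return Numeric vector of `n_boot` indirect effects; attribute
#'   `n_redrawn` counts redrawn degenerate replicates; attribute `indices`
#'   when requested.
#' @export
stratified_bootstrap <- function(x, m, y, covariates = NULL,
                                 n_boot = 10000L, seed = 1L,
                                 return_indices = FALSE) {
  i1 <- which(x == 1)
  i0 <- which(x == 0)
  if (!length(i1) || !length(i0)) stop("both strata must be non-empty")
  cv <- if (is.null(covariates)) NULL else as.matrix(covariates)
  set.seed(seed)
  out <- numeric(n_boot)
  idx_mat <- if (return_indices) matrix(NA_integer_, n_boot, length(x))
  redrawn <- 0L
  for (bi in seq_len(n_boot)) {
    repeat {
      idx <- c(sample(i1, length(i1), replace = TRUE),
               sample(i0, length(i0), replace = TRUE))
      mb <- m[idx]; yb <- y[idx]
      if (var(mb) > 0 && var(yb) > 0) break
      redrawn <- redrawn + 1L
    }
    xb <- x[idx]
    cvb <- if (is.null(cv)) NULL else cv[idx, , drop = FALSE]
    X0 <- cbind(1, xb, cvb)
    out[bi] <- indirect_ab(X0, cbind(X0[, 1:2], mb, cvb), mb, yb)
    if (return_indices) idx_mat[bi, ] <- idx
  }
  attr(out, "n_redrawn") <- redrawn
  if (return_indices) attr(out, "indices") <- idx_mat
  out
}

#' Bias-corrected percentile confidence interval
#'
#' The BC (not BCa: no acceleration term) bootstrap interval. The bias
#' correction `z0` is the normal quantile of the fraction of bootstrap
#' values below the point estimate (ties counted half; degenerate fractions
#' clamped to `1/B` from the boundary), and the interval endpoints are the
#' bootstrap order statistics at adjusted percentiles
#' `pnorm(2 z0 + qnorm(alpha/2))` and `pnorm(2 z0 + qnorm(1 - alpha/2))`,
#' using the (B+1)p order-statistic convention (quantile type 6).
#'
#' @param boot Bootstrap sample of the statistic (length >= 100 advised).
#' @param point Point estimate on the original data.
#' @param level Confidence level.
#' @return Numeric `c(low, high)`; attribute `z0`.
#' @export
bc_percentile_ci <- function(boot, point, level = 0.95) {
  B <- length(boot)
  if (B < 2) stop("bootstrap sample too small")
  if (all(boot == boot[1])) {
    warning("degenerate bootstrap distribution")
    return(structure(c(point, point), z0 = 0))
  }
  frac <- (sum(boot < point) + 0.5 * sum(boot == point)) / B
  frac <- min(max(frac, 1 / B), 1 - 1 / B)
  z0 <- qnorm(frac)
  alpha <- 1 - level
  plo <- pnorm(2 * z0 + qnorm(alpha / 2))
  phi <- pnorm(2 * z0 + qnorm(1 - alpha / 2))
  ci <- unname(quantile(boot, c(plo, phi), type = 6, names = FALSE))
  structure(ci, z0 = z0)
}

#' Single-mediator test with stratified bootstrap BC interval
#'
#' Assembles the covariate-adjusted paths, the stratified bootstrap of the
#' indirect effect, and the bias-corrected percentile interval; the indirect
#' effect is significant when the interval excludes zero.
#'
#' @inheritParams stratified_bootstrap
#' @param ci_level Confidence level for the indirect-effect interval.
#' @return Object of class `mediation_result`: paths `a`, `b`, `c`,
#'   `c_prime`, `indirect`, `ci_low`, `ci_high`, `significant`, `n_boot`,
#'   bootstrap summary statistics and the path t/p values.
#' @export
mediation_test <- function(x, m, y, covariates = NULL, n_boot = 10000L,
                           ci_level = 0.95, seed = 1L) {
  paths <- fit_paths(x, m, y, covariates)
  boot <- stratified_bootstrap(x, m, y, covariates, n_boot = n_boot,
                               seed = seed)
  ci <- bc_percentile_ci(boot, paths$indirect, level = ci_level)
  structure(c(paths,
              list(ci_low = ci[1], ci_high = ci[2],
                   significant = ci[1] > 0 || ci[2] < 0,
                   ci_level = ci_level, n_boot = n_boot,
                   boot_mean = mean(boot), boot_sd = sd(boot),
                   n_redrawn = attr(boot, "n_redrawn"))),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Mediation (single mediator, stratified bootstrap BC CI)\n")
  cat(sprintf("  c = %.4f  a = %.4f  b = %.4f  c' = %.4f\n",
              x$c, x$a, x$b, x$c_prime))
  cat(sprintf("  indirect a*b = %.4f, %d%% CI [%.4f, %.4f] (B = %d)%s\n",
              x$indirect, round(100 * x$ci_level), x$ci_low, x$ci_high,
              x$n_boot, if (x$significant) " *" else ""))
  invisible(x)
}
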