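#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef cor lm median pnorm pt qnorm quantile rbinom rnorm
#'   runif sd var
#' @importFrom utils read.delim write.table
NULL

# Fast OLS with t-statistics. X must include the intercept column explicitly.
# Aliased (rank-deficient) columns get NA coefficients. Returns coefficients,
# standard errors, t and two-sided p, residual df.
ols_t <- function(X, y) {
  X <- as.matrix(X)
  fit <- stats::lm.fit(X, y)
  r <- fit$rank
  df <- length(y) - r
  if (df <= 0) stop("no residual degrees of freedom")
  sigma2 <- sum(fit$residuals^2) / df
  R <- qr.R(fit$qr)[seq_len(r), seq_len(r), drop = FALSE]
  Rinv <- backsolve(R, diag(r))
  se <- rep(NA_real_, ncol(X))
  se[fit$qr$pivot[seq_len(r)]] <- sqrt(rowSums(Rinv^2) * sigma2)
  cf <- unname(fit$coefficients)
  tval <- cf / se
  pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  list(coef = cf, se = se, t = tval, p = pval, df = df,
       residuals = fit$residuals, rank = r)
}

# Moore-Penrose pseudo-inverse via SVD.
pinv <- function(A, tol = NULL) {
  s <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * max(s$d) * .Machine$double.eps
  pos <- s$d > tol
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# Derive a stream of child seeds from one master seed, kept inside 32-bit
# integer range so set.seed() accepts them.
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 1000L * seq_len(n)) %% .Machine$integer.max
}

center <- function(x) x - mean(x)

# Map gender labels to a centered numeric covariate.
gender_covariate <- function(gender) {
  g <- as.integer(factor(gender))
  if (length(unique(g)) < 2) return(NULL)
  center(as.numeric(g))
}
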