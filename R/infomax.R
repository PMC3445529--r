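#' Infomax independent components analysis
#'
#' Natural-gradient infomax (Bell-Sejnowski) with the logistic nonlinearity
#' on whitened data: each pass visits random-permutation mini-batches and
#' updates `W <- W + lrate * (B*I + (1 - 2y) u') W` (with a bias term) where
#' `u = W x + bias` and `y = 1/(1+exp(-u))`. When the weights blow up
#' (non-finite or huge entries) the learning rate is annealed by 0.9 and the
#' iteration restarts from identity. Convergence is declared when the
#' Frobenius norm of the weight update over a pass falls below `tol`.
#' Recovered sources are scaled to unit variance and signed so each source's
#' largest-magnitude voxel weight is positive.
#'
#' @param white Matrix n x voxels of whitened data (identity second moment
#'   across rows, checked to tolerance 1e-3).
#' @param seed Integer seed controlling the weight initialization jitter and
#'   the mini-batch permutations.
#' @param lrate Initial learning rate; default `0.00065 / log(n)`.
#' @param block Mini-batch size; default `floor(sqrt(voxels / 3))`.
#' @param max_steps Maximum passes over the data.
#' @param tol Convergence tolerance on the weight-update Frobenius norm.
#' @param anneal Learning-rate multiplier applied whenever the angle between
#'   successive weight updates exceeds 60 degrees (the updates have stopped
#'   agreeing on a direction and are mostly stochastic noise).
#' @param w_init Optional n x n initial unmixing matrix.
#' @return List with `unmixing` (n x n), `sources` (n x voxels, unit
#'   variance rows, sign-normalized), `bias`, `converged`, `steps`,
#'   `lrate_final`.
#' @export
infomax_ica <- function(white, seed = 1L, lrate = NULL, block = NULL,
                        max_steps = 512L, tol = 1e-6, anneal = 0.9,
                        w_init = NULL) {
  white <- as.matrix(white)
  n <- nrow(white)
  V <- ncol(white)
  cv <- tcrossprod(white) / (V - 1)
  if (max(abs(cv - diag(n))) > 1e-3)
    stop("precondition violation: input is not whitened")
  if (is.null(lrate)) lrate <- 0.00065 / log(max(n, 3))
  if (is.null(block)) block <- max(8L, floor(sqrt(V / 3)))
  block <- min(block, V)
  set.seed(seed)
  W <- if (is.null(w_init)) diag(n) + 1e-4 * matrix(rnorm(n * n), n, n)
       else w_init
  bias <- numeric(n)
  converged <- FALSE
  steps <- 0L
  max_w <- 1e8
  delta_old <- NULL
  while (steps < max_steps) {
    steps <- steps + 1L
    W_old <- W
    perm <- sample.int(V)
    starts <- seq(1L, V - block + 1L, by = block)
    blown <- FALSE
    for (s0 in starts) {
      idx <- perm[s0:(s0 + block - 1L)]
      X <- white[, idx, drop = FALSE]
      U <- W %*% X + bias
      Y <- 1 / (1 + exp(-U))
      G <- 1 - 2 * Y
      W <- W + lrate * (block * diag(n) + G %*% t(U)) %*% W
      bias <- bias + lrate * rowSums(G)
      if (!all(is.finite(W)) || max(abs(W)) > max_w) {
        blown <- TRUE
        break
      }
    }
    if (blown) {
      lrate <- lrate * 0.9
      W <- diag(n) + 1e-4 * matrix(rnorm(n * n), n, n)
      bias <- numeric(n)
      delta_old <- NULL
      next
    }
    delta_vec <- as.vector(W - W_old)
    delta <- sqrt(sum(delta_vec^2))
    if (delta < tol) {
      converged <- TRUE
      break
    }
    if (!is.null(delta_old)) {
      cosang <- sum(delta_vec * delta_old) /
        (delta * sqrt(sum(delta_old^2)))
      # anneal when update directions decorrelate (stochastic regime) or
      # once the update is a small consistent drift along the weight-scale
      # indeterminacy, so the update norm decays geometrically to tol
      if ((is.finite(cosang) && cosang < 0.5) || delta < 1e3 * tol)
        lrate <- lrate * anneal
    }
    delta_old <- delta_vec
  }
  if (!converged)
    warning("infomax did not converge in ", max_steps, " steps")
  S <- W %*% white
  norm <- normalize_sources(S, W)
  list(unmixing = norm$unmixing, sources = norm$sources, bias = bias,
       converged = converged, steps = steps, lrate_final = lrate)
}

# Unit-variance rows and the sign convention (largest-|weight| voxel of each
# source is positive); the unmixing rows are rescaled consistently.
normalize_sources <- function(S, W = NULL) {
  sds <- apply(S, 1, sd)
  sds[sds == 0] <- 1
  S <- S / sds
  if (!is.null(W)) W <- W / sds
  flips <- apply(S, 1, function(r) sign(r[which.max(abs(r))]))
  flips[flips == 0] <- 1
  S <- S * flips
  if (!is.null(W)) W <- W * flips
  list(sources = S, unmixing = W)
}
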