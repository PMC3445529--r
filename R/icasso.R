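#' ICASSO stability selection for infomax ICA
#'
#' Runs the infomax decomposition `n_reps` times from distinct seeds, pools
#' all `n_reps * n_ic` source estimates, clusters them by average-linkage
#' agglomerative clustering on the dissimilarity `1 - |Pearson correlation|`
#' between source maps, and returns one representative per cluster: the
#' centrotype (the estimate with maximal total similarity to its cluster).
#' The stability index of a cluster is
#' `Iq = mean intra-cluster similarity - mean extra-cluster similarity`,
#' near 1 for components re-found identically in every repetition.
#'
#' @param white Whitened matrix n_ic x voxels (see [infomax_ica()]).
#' @param n_reps Number of ICA repetitions (>= 2).
#' @param seed Master seed; repetition seeds are derived from it.
#' @param ... Passed to [infomax_ica()].
#' @return List with `sources` (n_ic x voxels centrotype maps, unit
#'   variance, sign-normalized), `unmixing` (the centrotypes' rows of their
#'   repetition's unmixing matrix, re-solved against `white`),
#'   `stability_iq` (per component, clamped to \[0, 1\]), `cluster`
#'   (membership of every pooled estimate), `converged_all`.
#' @export
icasso <- function(white, n_reps = 20L, seed = 1L, ...) {
  if (n_reps < 2) stop("n_reps must be >= 2")
  n <- nrow(white)
  seeds <- derive_seeds(seed, n_reps)
  fits <- lapply(seeds, function(s) infomax_ica(white, seed = s, ...))
  pooled <- do.call(rbind, lapply(fits, `[[`, "sources"))
  sim <- abs(cor(t(pooled)))
  sim[!is.finite(sim)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  cl <- stats::cutree(hc, k = n)
  sources <- matrix(0, n, ncol(white))
  iq <- numeric(n)
  pick <- integer(n)
  for (k in seq_len(n)) {
    members <- which(cl == k)
    intra <- sim[members, members, drop = FALSE]
    extra <- sim[members, -members, drop = FALSE]
    iq[k] <- mean(intra) - if (length(extra)) mean(extra) else 0
    pick[k] <- members[which.max(rowSums(intra))]
    sources[k, ] <- pooled[pick[k], ]
  }
  ord <- order(iq, decreasing = TRUE)
  sources <- sources[ord, , drop = FALSE]
  iq <- pmin(pmax(iq[ord], 0), 1)
  sources <- normalize_sources(sources)$sources
  # re-express the centrotype set as an unmixing of the whitened data
  unmixing <- sources %*% t(white) %*% solve(tcrossprod(white))
  list(sources = sources, unmixing = unmixing, stability_iq = iq,
       cluster = cl, centrotype_index = pick[ord],
       converged_all = all(vapply(fits, `[[`, logical(1), "converged")))
}
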