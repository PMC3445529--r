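#' Temporal PCA reduction and whitening of one run
#'
#' Principal components analysis in the temporal (scans) dimension of one
#' masked, per-voxel demeaned run: the eigendecomposition of the
#' scans x scans covariance across voxels, computed via the SVD of the data
#' matrix. The reduced data are whitened (identity second-moment across the
#' retained dimensions).
#'
#' @param run Matrix scans x voxels, each voxel column demeaned over scans.
#' @param retained Number of components to keep (<= scans and <= numerical
#'   rank).
#' @param check_demeaned Verify the per-voxel demeaning precondition.
#' @return List with `reduction` (class `pca_reduction`: `basis`
#'   retained x scans whitening operator, `debasis` scans x retained
#'   dewhitening operator, `eigenvalues`, `retained`) and `reduced`
#'   (retained x voxels whitened data).
#' @export
reduce_run <- function(run, retained, check_demeaned = TRUE) {
  run <- as.matrix(run)
  n_scans <- nrow(run)
  V <- ncol(run)
  if (retained > n_scans)
    stop("retained (", retained, ") exceeds scans (", n_scans, ")")
  if (check_demeaned) {
    mu <- colMeans(run)
    s <- apply(run, 2, sd)
    if (any(s == 0)) stop("all-zero/constant voxel column after masking")
    if (max(abs(mu) / s) > 1e-6)
      stop("run must be demeaned per voxel before reduction")
  }
  sv <- svd(run, nu = retained, nv = retained)
  ev <- sv$d^2 / (V - 1)
  rank <- sum(sv$d > max(dim(run)) * sv$d[1] * .Machine$double.eps)
  if (retained > rank)
    stop("degenerate input: retained (", retained, ") exceeds rank (",
         rank, ")")
  d_r <- sv$d[seq_len(retained)]
  basis <- sqrt(V - 1) * t(sv$u) / d_r      # retained x scans
  debasis <- sv$u %*% diag(d_r / sqrt(V - 1), retained)
  reduced <- sqrt(V - 1) * t(sv$v)
  list(reduction = structure(list(basis = basis, debasis = debasis,
                                  eigenvalues = ev, retained = retained),
                             class = "pca_reduction"),
       reduced = reduced)
}

#' Second-stage PCA across stacked reduced data
#'
#' Stacks the per-run whitened reductions of all subjects (subject-major,
#' run-minor row order) and applies the same temporal PCA to the stacked
#' matrix, yielding the whitened group data on which the ICA runs.
#'
#' @param stacked Matrix (subjects x runs x retained_1) x voxels of
#'   row-stacked reduced run data.
#' @param retained_2 Group components to keep.
#' @return As [reduce_run()]; the group `basis` rows partition by
#'   subject-run in the stacking order.
#' @export
reduce_group <- function(stacked, retained_2) {
  reduce_run(stacked, retained_2, check_demeaned = FALSE)
}
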