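## Constrained weighted least-squares deconvolution: per sample, minimize
##   sum_g w_g (b_g - sum_c R_gc x_c)^2   s.t.  x >= 0, sum(x) <= 1,
## with w_g = 1/(variability_g + eps). The remainder 1 - sum(x) is reported
## as the "uncharacterized" component.

# Primal active-set solver for  min x'Ax - 2c'x  s.t. x >= 0, 1'x <= 1,
# with A symmetric positive definite. Finite termination; returns the exact
# constrained minimizer up to linear-solve precision.
.solveConstrainedWls <- function(A, cvec, maxIter = 500L) {
  p <- length(cvec)
  scl <- max(diag(A))
  if (!is.finite(scl) || scl <= 0) stop("degenerate deconvolution system")
  A <- A / scl
  cvec <- cvec / scl
  x <- numeric(p)
  atBound <- rep(TRUE, p)     # working set: x_i = 0
  sumActive <- FALSE          # working set: 1'x = 1
  tol <- 1e-12
  for (iter in seq_len(maxIter)) {
    free <- which(!atBound)
    xNew <- numeric(p)
    if (length(free)) {
      if (sumActive) {
        K <- rbind(cbind(A[free, free, drop = FALSE], 1),
                   c(rep(1, length(free)), 0))
        sol <- solve(K, c(cvec[free], 1))
        xNew[free] <- sol[seq_along(free)]
      } else {
        xNew[free] <- solve(A[free, free, drop = FALSE], cvec[free])
      }
    }
    d <- xNew - x
    # largest feasible step toward the subproblem solution
    alpha <- 1
    blockBound <- 0L
    for (i in free) if (d[i] < -tol && x[i] + d[i] < -tol) {
      a <- x[i] / (-d[i])
      if (a < alpha) { alpha <- a; blockBound <- i }
    }
    blockSum <- FALSE
    if (!sumActive && sum(d) > tol) {
      a <- (1 - sum(x)) / sum(d)
      if (a < alpha) { alpha <- a; blockSum <- TRUE; blockBound <- 0L }
    }
    x <- x + alpha * d
    if (alpha < 1) {
      if (blockSum) sumActive <- TRUE else { atBound[blockBound] <- TRUE; x[blockBound] <- 0 }
      next
    }
    # at the subproblem optimum: check KKT multipliers
    grad <- 2 * (A %*% x - cvec)[, 1]
    mu <- if (sumActive && length(free)) -mean(grad[free]) else 0
    lambda <- grad + mu       # multipliers of the active bounds
    worst <- 0; drop <- 0L; dropSum <- FALSE
    for (i in which(atBound)) if (lambda[i] < worst) { worst <- lambda[i]; drop <- i }
    if (sumActive && mu < worst) { worst <- mu; dropSum <- TRUE; drop <- 0L }
    if (worst >= -1e-10) {
      x[x < 0] <- 0
      return(x)
    }
    if (dropSum) sumActive <- FALSE else atBound[drop] <- FALSE
  }
  stop("constrained WLS solver failed to converge")
}

#' Estimate cell-type proportions from bulk expression
#'
#' Fits, for every sample, non-negative cell-type proportions summing to at
#' most 1 by weighted least squares against the reference profiles; genes
#' are weighted by the inverse of their reference variability
#' (\code{1 / (variability + 1e-6)}). The remainder \code{1 - sum(x)} is
#' reported as the \code{"uncharacterized"} component (predominantly
#' malignant and benign epithelial cells). Genes absent from the bulk matrix
#' are dropped from the fit; an overlap below \code{overlapThreshold} is an
#' error. The fit is deterministic.
#'
#' @param bulk Non-negative TPM expression matrix, genes x samples.
#' @param ref A \linkS4class{ReferenceProfile}.
#' @param overlapThreshold Minimum fraction of reference genes that must be
#'   present in \code{bulk} (default 0.8).
#' @param mrnaScaling Optional positive per-component scaling (named over
#'   the 7 cell types plus \code{"uncharacterized"}) converting fitted mRNA
#'   fractions to cell fractions by dividing each fraction by its
#'   per-cell mRNA content and renormalizing; \code{NULL} (default) leaves
#'   fractions unscaled.
#' @return A \linkS4class{CompositionMatrix} with per-sample fit residuals
#'   (the weighted objective at the optimum).
#' @export
fitProportions <- function(bulk, ref, overlapThreshold = 0.8,
                           mrnaScaling = NULL) {
  validObject(ref)
  if (any(!is.finite(bulk))) stop("bulk expression contains non-finite values")
  if (any(bulk < 0)) stop("bulk expression must be >= 0")
  shared <- intersect(geneIds(ref), rownames(bulk))
  frac <- length(shared) / length(geneIds(ref))
  if (frac < overlapThreshold)
    stop(sprintf(
      "only %.1f%% of reference signature genes found in bulk (threshold %.0f%%)",
      100 * frac, 100 * overlapThreshold))
  R <- refMeans(ref)[shared, , drop = FALSE]
  w <- 1 / (refVariability(ref)[shared] + 1e-6)
  B <- bulk[shared, , drop = FALSE]
  A <- crossprod(R * w, R)          # R' W R
  A <- (A + t(A)) / 2
  nT <- ncol(R)
  comp <- matrix(0, nrow = ncol(B), ncol = nT + 1L,
                 dimnames = list(colnames(B), c(colnames(R), "uncharacterized")))
  resid <- numeric(ncol(B))
  for (s in seq_len(ncol(B))) {
    b <- B[, s]
    cvec <- crossprod(R, w * b)[, 1]
    x <- .solveConstrainedWls(A, cvec)
    obj <- sum(w * (b - R %*% x)^2)
    comp[s, seq_len(nT)] <- x
    comp[s, nT + 1L] <- max(0, 1 - sum(x))
    resid[s] <- max(0, obj)
  }
  if (!is.null(mrnaScaling)) {
    if (is.null(names(mrnaScaling)) ||
        !all(colnames(comp) %in% names(mrnaScaling)) || any(mrnaScaling <= 0))
      stop("mrnaScaling must be positive and named over all 8 components")
    sc <- sweep(comp, 2L, mrnaScaling[colnames(comp)], `/`)
    comp <- sc / rowSums(sc)
  }
  comp <- comp / rowSums(comp)      # absorb rounding; rows sum to 1 exactly
  new("CompositionMatrix", proportions = comp, fitResidual = resid)
}

#' Deconvolve a cohort with logging
#'
#' Batch wrapper around \code{\link{fitProportions}}: intersects the gene
#' sets once, reports the shared-gene count, and returns the per-sample
#' composition matrix.
#'
#' @inheritParams fitProportions
#' @return A \linkS4class{CompositionMatrix}.
#' @export
deconvolveCohort <- function(bulk, ref, overlapThreshold = 0.8,
                             mrnaScaling = NULL) {
  shared <- intersect(geneIds(ref), rownames(bulk))
  message(sprintf("deconvolving %d sample(s) using %d/%d shared signature genes",
                  ncol(bulk), length(shared), length(geneIds(ref))))
  fitProportions(bulk, ref, overlapThreshold = overlapThreshold,
                 mrnaScaling = mrnaScaling)
}
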