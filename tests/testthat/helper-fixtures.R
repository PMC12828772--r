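# Shared fixtures, built in code. Cohorts are cached per (n, seed, ...) so
# different test files can reuse the same simulated data without recomputing.

.cohortCache <- new.env(parent = emptyenv())

cachedCohort <- function(nPatients = 150, seed = 1, ...) {
  key <- paste(nPatients, seed, ..., sep = "_")
  if (is.null(.cohortCache[[key]]))
    .cohortCache[[key]] <- simulateCohort(
      simulationConfig(nPatients = nPatients, seed = seed, ...))
  .cohortCache[[key]]
}

cachedComposition <- function(nPatients = 150, seed = 1, ...) {
  key <- paste("comp", nPatients, seed, ..., sep = "_")
  if (is.null(.cohortCache[[key]])) {
    co <- cachedCohort(nPatients, seed, ...)
    .cohortCache[[key]] <- fitProportions(co$expression, co$reference)
  }
  .cohortCache[[key]]
}

# SubtypeLabeling from the generator's ground truth
truthLabeling <- function(truth, level = c("sample", "patient")) {
  level <- match.arg(level)
  st <- if (level == "sample") truth@sampleSubtype else truth@patientSubtype
  new("SubtypeLabeling", ids = names(st), subtype = unname(st),
      clusterToName = character(0), enrichment = matrix(numeric(0), 0, 0))
}

# minimal composition matrix from a plain samples x components matrix
asComposition <- function(m) {
  m <- m / rowSums(m)
  new("CompositionMatrix", proportions = m,
      fitResidual = rep(NA_real_, nrow(m)))
}

# grid search over {x >= 0, sum(x) <= 1}: the independent oracle for the
# constrained weighted least-squares fit. The objective is evaluated through
# its quadratic form (identical to sum_g w_g (b_g - (Rx)_g)^2 up to an
# additive constant, so the argmin is unchanged). Two types are enumerated
# exhaustively at `step`; three types use a coarse exhaustive pass followed
# by exhaustive refinement at `step` in a box around the coarse optimum,
# expanding the box until the optimum is interior (sound because the
# objective is convex).
gridSearchWls <- function(R, b, w, step = 1e-3) {
  nT <- ncol(R)
  A <- crossprod(R * w, R)
  cv <- drop(crossprod(R, w * b))
  objOf <- function(X) rowSums((X %*% A) * X) - 2 * drop(X %*% cv)
  bestOf <- function(X) X[which.min(objOf(X)), ]

  gridBox <- function(lo, hi, h) {
    # all points of the box lattice with sum <= 1
    axes <- lapply(seq_len(nT), function(j) seq(lo[j], hi[j], by = h))
    X <- as.matrix(do.call(expand.grid, axes))
    X[rowSums(X) <= 1 + 1e-12, , drop = FALSE]
  }

  if (nT <= 2) return(bestOf(gridBox(rep(0, nT), rep(1, nT), step)))
  if (nT > 3) stop("grid oracle supports <= 3 cell types")

  coarse <- bestOf(gridBox(rep(0, 3), rep(1, 3), 5e-3))
  r <- 0.02
  repeat {
    lo <- pmax(0, round((coarse - r) / step) * step)
    hi <- pmin(1, coarse + r)
    X <- gridBox(lo, hi, step)
    best <- bestOf(X)
    # expand only if the optimum sits on an artificial box face (a face
    # that is not a boundary of the feasible region itself)
    onArtificial <- any((abs(best - lo) < step / 2 & lo > step / 2) |
                        (abs(best - hi) < step / 2 & hi < 1 - step / 2))
    if (!onArtificial || r >= 1) return(best)
    r <- r * 3
  }
}

# tiny reference profile over arbitrary matrices, for toy systems
toyReference <- function(means, variability = rep(0, nrow(means))) {
  # variability 0 => unit weights up to the solver's epsilon
  if (is.null(rownames(means)))
    rownames(means) <- sprintf("g%02d", seq_len(nrow(means)))
  if (is.null(colnames(means)))
    colnames(means) <- sprintf("type%d", seq_len(ncol(means)))
  new("ReferenceProfile", means = means, variability = variability)
}
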