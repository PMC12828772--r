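#' @include AllGenerics.R
NULL

#' tmeSubtyper: cell-type-composition subtyping of bulk prostate tumors
#'
#' Deconvolves bulk RNA-seq into cell-type proportions, discovers composition
#' subtypes by resampling consensus clustering with PAM, classifies new
#' cohorts with linear discriminant analysis, quantifies multifocal
#' heterogeneity, and relates subtypes to clinicopathology and biochemical
#' recurrence. A synthetic cohort generator provides ground truth for every
#' stage.
#'
#' @name tmeSubtyper-package
#' @aliases tmeSubtyper
#' @import methods
#' @importFrom stats rnorm runif rgamma rexp setNames sd hclust cutree
#'   wilcox.test chisq.test pchisq median
#' @importFrom utils read.delim write.table head
"_PACKAGE"

.CELL_TYPES <- c("Bcells", "CD4_Tcells", "CD8_Tcells", "NKcells",
                 "Macrophages", "Endothelial", "CAFs")
.COMPONENTS <- c(.CELL_TYPES, "uncharacterized")
.SUBTYPES <- c("TCE", "EPCE", "TASCE")
.GLEASON_LEVELS <- c("low", "intermediate", "high")
.PT_LEVELS <- c("T2", "T3a", "T3b")

#' Cell-type reference expression profiles
#'
#' Signature-gene mean expression per cell type, plus a per-gene variability
#' used as an inverse weight in the deconvolution fit. Genes are rows of
#' \code{means}; cell types are columns. The epithelial/malignant compartment
#' is deliberately absent: deconvolution recovers it as the
#' \code{"uncharacterized"} remainder.
#'
#' @slot means Non-negative matrix of mean expression, genes x cell types,
#'   with row and column names.
#' @slot variability Non-negative per-gene variability, aligned with the rows
#'   of \code{means}.
#' @export
setClass("ReferenceProfile",
  representation(means = "matrix", variability = "numeric"),
  validity = function(object) {
    m <- object@means
    msgs <- character()
    if (is.null(rownames(m)) || is.null(colnames(m)))
      msgs <- c(msgs, "means must have gene rownames and cell-type colnames")
    if (anyDuplicated(rownames(m)))
      msgs <- c(msgs, "duplicate gene ids in reference")
    if (any(!is.finite(m)) || any(m < 0))
      msgs <- c(msgs, "reference means must be finite and >= 0")
    if (length(object@variability) != nrow(m))
      msgs <- c(msgs, "variability length must equal number of genes")
    if (any(!is.finite(object@variability)) || any(object@variability < 0))
      msgs <- c(msgs, "variability must be finite and >= 0")
    # identifiability: every cell type needs at least one gene whose mean for
    # it strictly exceeds its mean for every other type
    if (ncol(m) >= 2 && nrow(m) >= 1) {
      top <- apply(m, 1L, function(r) {
        o <- order(r, decreasing = TRUE)
        if (r[o[1L]] > r[o[2L]]) o[1L] else 0L
      })
      if (!all(seq_len(ncol(m)) %in% top))
        msgs <- c(msgs, "each cell type needs >= 1 gene uniquely maximal for it")
    }
    if (length(msgs)) msgs else TRUE
  })

#' Per-sample cell-type proportions
#'
#' The pipeline's central object: for each sample, the estimated (or true)
#' proportion of each of the seven reference cell types plus the
#' \code{"uncharacterized"} remainder. Rows are samples and lie on the
#' 8-simplex.
#'
#' @slot proportions Matrix, samples x components, each row summing to 1.
#' @slot fitResidual Per-sample weighted least-squares objective at the
#'   optimum (\code{NA} for compositions not produced by a fit).
#' @export
setClass("CompositionMatrix",
  representation(proportions = "matrix", fitResidual = "numeric"),
  validity = function(object) {
    p <- object@proportions
    msgs <- character()
    if (is.null(rownames(p)) || is.null(colnames(p)))
      msgs <- c(msgs, "proportions must have sample rownames and component colnames")
    if (anyDuplicated(rownames(p)))
      msgs <- c(msgs, "duplicate sample ids")
    if (any(!is.finite(p)))
      msgs <- c(msgs, "proportions must be finite")
    else {
      if (any(p < -1e-9) || any(p > 1 + 1e-9))
        msgs <- c(msgs, "proportions must lie in [0, 1]")
      if (any(abs(rowSums(p) - 1) > 1e-9))
        msgs <- c(msgs, "each sample's components must sum to 1 (tol 1e-9)")
    }
    if (length(object@fitResidual) != nrow(p))
      msgs <- c(msgs, "fitResidual length must equal number of samples")
    if (any(object@fitResidual < 0, na.rm = TRUE))
      msgs <- c(msgs, "fitResidual must be >= 0")
    if (length(msgs)) msgs else TRUE
  })

#' Standardized composition matrix
#'
#' Component-wise Z-scores of a \linkS4class{CompositionMatrix}: each
#' component column is centred and scaled across samples (sample standard
#' deviation, ddof 1). Constant columns are mapped to all-zero and flagged.
#'
#' @slot zValues Matrix of Z-scores, samples x components.
#' @slot centers,scales Per-component mean and standard deviation used.
#' @slot constant Logical flag per component; \code{TRUE} where the raw
#'   column was constant (column set to zero).
#' @export
setClass("ZMatrix",
  representation(zValues = "matrix", centers = "numeric", scales = "numeric",
                 constant = "logical"),
  validity = function(object) {
    z <- object@zValues
    msgs <- character()
    if (length(object@centers) != ncol(z) || length(object@scales) != ncol(z) ||
        length(object@constant) != ncol(z))
      msgs <- c(msgs, "centers/scales/constant must align with components")
    if (any(!is.finite(z)))
      msgs <- c(msgs, "z values must be finite")
    if (length(msgs)) msgs else TRUE
  })

#' Resampling consensus clustering result
#'
#' For each candidate number of clusters k: the consensus matrix (fraction of
#' co-sampled resamples in which a sample pair co-clustered under PAM), the
#' pair co-sampling counts, final labels from average-linkage clustering of
#' 1 - consensus, the CDF area of off-diagonal consensus values, and the
#' relative change in that area between consecutive k.
#'
#' @slot kValues Integer vector of k tried.
#' @slot consensus,pairCounts,labels Per-k lists (names \code{"k=2"}, ...).
#' @slot cdfArea,deltaAreaValues Numeric per k.
#' @slot chosenK Selected k (\code{NA} until \code{\link{selectK}}).
#' @export
setClass("ConsensusResult",
  representation(kValues = "integer", consensus = "list", pairCounts = "list",
                 labels = "list", cdfArea = "numeric",
                 deltaAreaValues = "numeric", chosenK = "integer"),
  validity = function(object) {
    msgs <- character()
    nk <- length(object@kValues)
    if (length(object@consensus) != nk || length(object@labels) != nk ||
        length(object@pairCounts) != nk || length(object@cdfArea) != nk ||
        length(object@deltaAreaValues) != nk)
      msgs <- c(msgs, "per-k slots must align with kValues")
    for (i in seq_len(nk)) {
      cm <- object@consensus[[i]]
      if (any(cm < -1e-12) || any(cm > 1 + 1e-12))
        msgs <- c(msgs, "consensus entries must lie in [0, 1]")
      if (max(abs(cm - t(cm))) > 1e-12 || any(abs(diag(cm) - 1) > 1e-12))
        msgs <- c(msgs, "consensus must be symmetric with unit diagonal")
      if (length(unique(object@labels[[i]])) != object@kValues[i])
        msgs <- c(msgs, sprintf("labels for k=%d must take exactly %d values",
                                object@kValues[i], object@kValues[i]))
    }
    if (length(unique(msgs))) unique(msgs) else TRUE
  })

#' Subtype assignment
#'
#' Assignment of samples (or patients) to the three composition subtypes:
#' TCE (T-cells enriched), EPCE (epithelial-cells enriched) and TASCE
#' (tumor-associated stromal-cells enriched), together with the
#' cluster-to-name bijection and the per-cluster mean-Z enrichment table the
#' naming was derived from.
#'
#' @slot ids Sample or patient identifiers.
#' @slot subtype Character vector over \code{c("TCE","EPCE","TASCE")},
#'   aligned with \code{ids}.
#' @slot clusterToName Named character; names are cluster ids, values
#'   subtype names (a bijection).
#' @slot enrichment Matrix of per-cluster mean Z per component.
#' @export
setClass("SubtypeLabeling",
  representation(ids = "character", subtype = "character",
                 clusterToName = "character", enrichment = "matrix"),
  validity = function(object) {
    msgs <- character()
    if (length(object@ids) != length(object@subtype))
      msgs <- c(msgs, "ids and subtype must align")
    if (anyDuplicated(object@ids))
      msgs <- c(msgs, "duplicate ids")
    if (!all(object@subtype %in% .SUBTYPES))
      msgs <- c(msgs, "subtype values must be TCE, EPCE or TASCE")
    if (length(object@clusterToName) &&
        (anyDuplicated(object@clusterToName) || anyDuplicated(names(object@clusterToName))))
      msgs <- c(msgs, "clusterToName must be a bijection")
    if (length(msgs)) msgs else TRUE
  })

#' Linear discriminant subtype classifier
#'
#' Gaussian linear discriminant model with shared (pooled, possibly
#' ridge-regularized) covariance: class means, pooled covariance, priors and
#' the feature space. Serializable to versioned JSON with
#' \code{\link{saveLdaModel}}.
#'
#' @slot classNames Class labels (3 subtypes).
#' @slot classMeans Matrix, classes x features.
#' @slot pooledCov Symmetric positive-definite feature covariance (after any
#'   recorded regularization).
#' @slot priors Positive class priors summing to 1.
#' @slot featureNames Feature (component) names.
#' @slot nPerClass Training count per class.
#' @slot regularization Ridge added to the diagonal (0 if none was needed).
#' @export
setClass("LdaModel",
  representation(classNames = "character", classMeans = "matrix",
                 pooledCov = "matrix", priors = "numeric",
                 featureNames = "character", nPerClass = "integer",
                 regularization = "numeric"),
  validity = function(object) {
    msgs <- character()
    p <- length(object@featureNames)
    k <- length(object@classNames)
    if (!all(dim(object@classMeans) == c(k, p)))
      msgs <- c(msgs, "classMeans must be classes x features")
    if (!all(dim(object@pooledCov) == c(p, p)))
      msgs <- c(msgs, "pooledCov must be features x features")
    if (max(abs(object@pooledCov - t(object@pooledCov))) > 1e-8)
      msgs <- c(msgs, "pooledCov must be symmetric")
    ev <- tryCatch(eigen(object@pooledCov, symmetric = TRUE,
                         only.values = TRUE)$values, error = function(e) NA)
    if (any(!is.finite(ev)) || any(ev <= 0))
      msgs <- c(msgs, "pooledCov must be positive definite (after regularization)")
    if (length(object@priors) != k || any(object@priors <= 0) ||
        abs(sum(object@priors) - 1) > 1e-9)
      msgs <- c(msgs, "priors must be positive and sum to 1")
    if (length(msgs)) msgs else TRUE
  })

#' Synthetic cohort configuration
#'
#' All knobs of the synthetic cohort generator: cohort shape (patients, foci,
#' samples), reference/signature sizes, subtype prevalence, the per-subtype
#' Dirichlet composition priors over the 8 components, the nested
#' patient/focus/sample perturbation scales (centered-log-ratio space),
#' multiplicative expression noise, the exponential biochemical-recurrence
#' model (baseline hazard, subtype hazard ratios, uniform censoring horizon),
#' subtype-conditional Gleason/pT probabilities, and the seed.
#'
#' @slot nPatients Number of patients.
#' @slot fociPerPatient,samplesPerFocus Integer ranges \code{c(min, max)}.
#' @slot nSignatureGenesPerType,nBackgroundGenes Reference sizes.
#' @slot subtypePrior Probability over \code{c(TCE, EPCE, TASCE)}.
#' @slot dirichletAlpha 3 x 8 matrix of Dirichlet parameters (rows subtypes,
#'   columns the 7 cell types + epithelial).
#' @slot sdPatient,sdFocus,sdSample Perturbation scales in CLR space.
#' @slot noiseSd Multiplicative log-normal expression noise sd.
#' @slot baselineHazard Events per month for the TCE reference class.
#' @slot hrEpce,hrTasce Subtype hazard ratios (TCE = 1).
#' @slot censoringMaxMonths Uniform censoring horizon.
#' @slot gleasonProbs,ptProbs 3 x 3 matrices of subtype-conditional category
#'   probabilities (rows subtypes; columns low/intermediate/high and
#'   T2/T3a/T3b).
#' @slot seed Integer seed; all randomness flows through it.
#' @export
setClass("SimulationConfig",
  representation(nPatients = "integer", fociPerPatient = "integer",
                 samplesPerFocus = "integer", nSignatureGenesPerType = "integer",
                 nBackgroundGenes = "integer", subtypePrior = "numeric",
                 dirichletAlpha = "matrix", sdPatient = "numeric",
                 sdFocus = "numeric", sdSample = "numeric", noiseSd = "numeric",
                 baselineHazard = "numeric", hrEpce = "numeric",
                 hrTasce = "numeric", censoringMaxMonths = "numeric",
                 gleasonProbs = "matrix", ptProbs = "matrix", seed = "integer"),
  validity = function(object) {
    msgs <- character()
    if (object@nPatients < 1) msgs <- c(msgs, "nPatients must be >= 1")
    for (nm in c("fociPerPatient", "samplesPerFocus")) {
      r <- slot(object, nm)
      if (length(r) != 2 || any(r < 1) || r[1] > r[2])
        msgs <- c(msgs, sprintf("%s must be an increasing range >= 1", nm))
    }
    if (abs(sum(object@subtypePrior) - 1) > 1e-9 || any(object@subtypePrior < 0))
      msgs <- c(msgs, "subtypePrior must be a probability over the 3 subtypes")
    if (!all(dim(object@dirichletAlpha) == c(3L, 8L)) ||
        any(object@dirichletAlpha <= 0))
      msgs <- c(msgs, "dirichletAlpha must be a positive 3 x 8 matrix")
    for (nm in c("sdPatient", "sdFocus", "sdSample", "noiseSd"))
      if (slot(object, nm) < 0) msgs <- c(msgs, sprintf("%s must be >= 0", nm))
    if (object@baselineHazard <= 0 || object@hrEpce <= 0 || object@hrTasce <= 0)
      msgs <- c(msgs, "hazard parameters must be > 0")
    if (object@censoringMaxMonths <= 0)
      msgs <- c(msgs, "censoringMaxMonths must be > 0")
    for (nm in c("gleasonProbs", "ptProbs")) {
      pm <- slot(object, nm)
      if (!all(dim(pm) == c(3L, 3L)) || any(pm < 0) ||
          any(abs(rowSums(pm) - 1) > 1e-9))
        msgs <- c(msgs, sprintf("%s rows must be probabilities", nm))
    }
    if (length(msgs)) msgs else TRUE
  })

#' Ground truth of a synthetic cohort
#'
#' @slot proportions True per-sample mixing proportions over the 7 cell
#'   types + epithelial (samples x 8, rows summing to 1).
#' @slot sampleSubtype,patientSubtype Planted subtype per sample / patient.
#' @slot patientLogHazard True log-hazard per patient.
#' @slot config The \linkS4class{SimulationConfig} that generated the cohort.
#' @export
setClass("SyntheticTruth",
  representation(proportions = "matrix", sampleSubtype = "character",
                 patientSubtype = "character", patientLogHazard = "numeric",
                 config = "SimulationConfig"),
  validity = function(object) {
    msgs <- character()
    p <- object@proportions
    if (any(p < 0) || any(p > 1) || any(abs(rowSums(p) - 1) > 1e-12))
      msgs <- c(msgs, "truth proportions must lie on the simplex (tol 1e-12)")
    if (length(object@sampleSubtype) != nrow(p))
      msgs <- c(msgs, "sampleSubtype must align with proportions rows")
    if (length(msgs)) msgs else TRUE
  })

## ---- accessors -----------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("geneIds", "ReferenceProfile", function(x) rownames(x@means))
#' @rdname accessors
#' @export
setMethod("cellTypeNames", "ReferenceProfile", function(x) colnames(x@means))
#' @rdname accessors
#' @export
setMethod("refMeans", "ReferenceProfile", function(x) x@means)
#' @rdname accessors
#' @export
setMethod("refVariability", "ReferenceProfile",
          function(x) setNames(x@variability, rownames(x@means)))

#' @rdname accessors
#' @export
setMethod("sampleIds", "CompositionMatrix", function(x) rownames(x@proportions))
#' @rdname accessors
#' @export
setMethod("componentNames", "CompositionMatrix", function(x) colnames(x@proportions))
#' @rdname accessors
#' @export
setMethod("proportions", "CompositionMatrix",
          function(x, margin = NULL) x@proportions)
#' @rdname accessors
#' @export
setMethod("fitResiduals", "CompositionMatrix",
          function(x) setNames(x@fitResidual, rownames(x@proportions)))

#' @rdname accessors
#' @export
setMethod("sampleIds", "ZMatrix", function(x) rownames(x@zValues))
#' @rdname accessors
#' @export
setMethod("componentNames", "ZMatrix", function(x) colnames(x@zValues))
#' @rdname accessors
#' @export
setMethod("zValues", "ZMatrix", function(x) x@zValues)

.kKey <- function(k) sprintf("k=%d", k)

#' @rdname accessors
#' @export
setMethod("consensusMatrix", "ConsensusResult", function(x, k) {
  stopifnot(k %in% x@kValues)
  x@consensus[[.kKey(k)]]
})
#' @rdname accessors
#' @export
setMethod("clusterLabels", "ConsensusResult", function(x, k) {
  stopifnot(k %in% x@kValues)
  x@labels[[.kKey(k)]]
})
#' @rdname accessors
#' @export
setMethod("deltaArea", "ConsensusResult",
          function(x) setNames(x@deltaAreaValues, names(x@consensus)))

#' @rdname accessors
#' @export
setMethod("sampleIds", "SubtypeLabeling", function(x) x@ids)
#' @rdname accessors
#' @export
setMethod("subtypes", "SubtypeLabeling", function(x) setNames(x@subtype, x@ids))
#' @rdname accessors
#' @export
setMethod("clusterToName", "SubtypeLabeling", function(x) x@clusterToName)
#' @rdname accessors
#' @export
setMethod("enrichment", "SubtypeLabeling", function(x) x@enrichment)

## ---- show methods --------------------------------------------------------

setMethod("show", "ReferenceProfile", function(object) {
  cat(sprintf("ReferenceProfile: %d genes x %d cell types\n",
              nrow(object@means), ncol(object@means)))
  cat("  cell types:", paste(colnames(object@means), collapse = ", "), "\n")
})

setMethod("show", "CompositionMatrix", function(object) {
  cat(sprintf("CompositionMatrix: %d samples x %d components\n",
              nrow(object@proportions), ncol(object@proportions)))
  cat("  components:", paste(colnames(object@proportions), collapse = ", "), "\n")
  if (!all(is.na(object@fitResidual)))
    cat(sprintf("  median fit residual: %.4g\n",
                median(object@fitResidual, na.rm = TRUE)))
})

setMethod("show", "ZMatrix", function(object) {
  cat(sprintf("ZMatrix: %d samples x %d components", nrow(object@zValues),
              ncol(object@zValues)))
  if (any(object@constant))
    cat(sprintf(" (%d constant column(s) zeroed)", sum(object@constant)))
  cat("\n")
})

setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf("ConsensusResult: k in {%s}, %d samples\n",
              paste(object@kValues, collapse = ", "),
              nrow(object@consensus[[1]])))
  cat("  delta area:", paste(sprintf("%s: %.3f", names(object@consensus),
                                     object@deltaAreaValues), collapse = "; "), "\n")
  if (!is.na(object@chosenK)) cat("  chosen k:", object@chosenK, "\n")
})

setMethod("show", "SubtypeLabeling", function(object) {
  tab <- table(factor(object@subtype, levels = .SUBTYPES))
  cat(sprintf("SubtypeLabeling: %d ids (%s)\n", length(object@ids),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "LdaModel", function(object) {
  cat(sprintf("LdaModel: %d classes, %d features\n",
              length(object@classNames), length(object@featureNames)))
  cat("  classes:", paste(sprintf("%s (n=%d)", object@classNames,
                                  object@nPerClass), collapse = ", "), "\n")
  if (object@regularization > 0)
    cat(sprintf("  ridge regularization: %.3g\n", object@regularization))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d patients, foci %d-%d, samples/focus %d-%d, seed %d\n",
    object@nPatients, object@fociPerPatient[1], object@fociPerPatient[2],
    object@samplesPerFocus[1], object@samplesPerFocus[2], object@seed))
  cat(sprintf("  HR (TCE ref): EPCE %.1f, TASCE %.1f; noise sd %.2f\n",
              object@hrEpce, object@hrTasce, object@noiseSd))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d samples, %d patients\n",
              nrow(object@proportions), length(object@patientSubtype)))
})
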