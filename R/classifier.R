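## Linear discriminant subtype classifier: closed-form training (class means,
## pooled covariance, priors), linear discriminant scoring with softmax
## posteriors, and versioned JSON serialization.

#' Train a linear discriminant classifier on compositions
#'
#' Closed-form LDA: class means are per-class feature averages; the pooled
#' covariance is the within-class scatter divided by \code{N - K}; priors
#' default to empirical class frequencies. Because the 8 simplex features
#' are linearly dependent (rows sum to 1), the pooled covariance is
#' singular; a ridge of \code{1e-8 * trace/p} is then added to the diagonal
#' (repeatedly, if needed) and recorded in the model.
#'
#' @param comp A \linkS4class{CompositionMatrix} of training samples (or a
#'   plain samples x features matrix with dimnames).
#' @param labels A \linkS4class{SubtypeLabeling} covering the samples.
#' @param priors Optional named class priors (positive, summing to 1);
#'   default empirical frequencies.
#' @return An \linkS4class{LdaModel}.
#' @export
trainLda <- function(comp, labels, priors = NULL) {
  X <- if (is(comp, "CompositionMatrix")) proportions(comp) else comp
  y <- subtypes(labels)[rownames(X)]
  if (anyNA(y)) stop("labels missing for sample(s): ",
                     paste(head(rownames(X)[is.na(y)]), collapse = ", "))
  classes <- intersect(.SUBTYPES, unique(y))
  if (length(classes) < 3) stop("training requires all 3 subtypes present")
  nPer <- vapply(classes, function(cl) sum(y == cl), integer(1))
  if (any(nPer < 2))
    stop("class(es) with < 2 samples: ",
         paste(classes[nPer < 2], collapse = ", "))
  p <- ncol(X)
  mu <- t(vapply(classes, function(cl) colMeans(X[y == cl, , drop = FALSE]),
                 numeric(p)))
  S <- matrix(0, p, p)
  for (cl in classes) {
    Xc <- sweep(X[y == cl, , drop = FALSE], 2L, mu[cl, ])
    S <- S + crossprod(Xc)
  }
  S <- S / (nrow(X) - length(classes))
  S <- (S + t(S)) / 2
  reg <- 0
  ridge <- 1e-8 * sum(diag(S)) / p
  while (min(eigen(S + diag(reg, p), symmetric = TRUE,
                   only.values = TRUE)$values) <= 1e-12 * sum(diag(S)) / p) {
    reg <- if (reg == 0) ridge else reg * 10
    if (reg > sum(diag(S))) stop("pooled covariance cannot be regularized")
  }
  if (reg > 0) {
    message(sprintf("singular pooled covariance; ridge %.3g added", reg))
    S <- S + diag(reg, p)
  }
  if (is.null(priors)) {
    priors <- nPer / sum(nPer)
  } else {
    if (is.null(names(priors)) || !all(classes %in% names(priors)))
      stop("priors must be named by class")
    priors <- priors[classes]
    if (any(priors <= 0) || abs(sum(priors) - 1) > 1e-9)
      stop("priors must be positive and sum to 1")
  }
  new("LdaModel", classNames = classes, classMeans = mu, pooledCov = S,
      priors = unname(priors), featureNames = colnames(X),
      nPerClass = unname(nPer), regularization = reg)
}

#' Predict subtypes with a trained LDA model
#'
#' Scores each sample with the linear discriminant
#' \deqn{\delta_c(x) = x^\top \Sigma^{-1} \mu_c -
#'   \tfrac12 \mu_c^\top \Sigma^{-1} \mu_c + \log \pi_c,}
#' assigns the argmax class, and reports softmax posteriors. Exact ties are
#' broken by class order with a message.
#'
#' @param model An \linkS4class{LdaModel}.
#' @param comp A \linkS4class{CompositionMatrix} (or plain samples x
#'   features matrix) whose feature names match the model's.
#' @return List with \code{labeling} (a \linkS4class{SubtypeLabeling}),
#'   \code{posterior} (samples x classes matrix) and \code{discriminants}.
#' @export
predictLda <- function(model, comp) {
  validObject(model)
  X <- if (is(comp, "CompositionMatrix")) proportions(comp) else comp
  miss <- setdiff(model@featureNames, colnames(X))
  if (length(miss))
    stop("composition lacks model feature(s): ", paste(miss, collapse = ", "))
  X <- X[, model@featureNames, drop = FALSE]
  SigInv <- solve(model@pooledCov)
  M <- model@classMeans                     # K x p
  linear <- X %*% (SigInv %*% t(M))         # n x K
  const <- -0.5 * rowSums((M %*% SigInv) * M) + log(model@priors)
  delta <- sweep(linear, 2L, const, `+`)
  colnames(delta) <- model@classNames
  lab <- apply(delta, 1L, which.max)
  ties <- apply(delta, 1L, function(d) sum(d == max(d)) > 1)
  if (any(ties))
    message(sum(ties), " tie(s) broken by class order")
  post <- exp(delta - apply(delta, 1L, max))
  post <- post / rowSums(post)
  labeling <- new("SubtypeLabeling", ids = rownames(X),
                  subtype = model@classNames[lab],
                  clusterToName = character(0),
                  enrichment = matrix(numeric(0), 0, 0))
  list(labeling = labeling, posterior = post, discriminants = delta)
}

.LDA_FORMAT_VERSION <- "1.0"

#' Serialize / restore an LDA model as versioned JSON
#'
#' The round trip preserves every field at full double precision, so
#' predictions from a restored model are bit-identical.
#'
#' @param model An \linkS4class{LdaModel}.
#' @param path JSON file path.
#' @return \code{path} (save) or an \linkS4class{LdaModel} (load).
#' @export
saveLdaModel <- function(model, path) {
  validObject(model)
  obj <- list(format = "tmeSubtyper-lda", version = .LDA_FORMAT_VERSION,
              classNames = model@classNames,
              classMeans = as.numeric(t(model@classMeans)),   # row-major
              pooledCov = as.numeric(t(model@pooledCov)),
              priors = model@priors, featureNames = model@featureNames,
              nPerClass = model@nPerClass,
              regularization = model@regularization)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveLdaModel
#' @export
loadLdaModel <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("cannot parse LDA model file '", path, "': ",
                         conditionMessage(e)))
  if (!identical(obj$format, "tmeSubtyper-lda"))
    stop("not an LDA model file: ", path)
  if (!identical(obj$version, .LDA_FORMAT_VERSION))
    stop("unsupported LDA model version '", obj$version, "' (expected ",
         .LDA_FORMAT_VERSION, ")")
  p <- length(obj$featureNames)
  k <- length(obj$classNames)
  if (length(obj$classMeans) != k * p || length(obj$pooledCov) != p * p)
    stop("corrupted LDA model file '", path, "': field sizes inconsistent")
  mu <- matrix(as.numeric(obj$classMeans), nrow = k, byrow = TRUE,
               dimnames = list(obj$classNames, obj$featureNames))
  S <- matrix(as.numeric(obj$pooledCov), nrow = p, byrow = TRUE,
              dimnames = list(obj$featureNames, obj$featureNames))
  new("LdaModel", classNames = obj$classNames, classMeans = mu,
      pooledCov = S, priors = as.numeric(obj$priors),
      featureNames = obj$featureNames, nPerClass = as.integer(obj$nPerClass),
      regularization = as.numeric(obj$regularization))
}
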