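simplexFeatures <- function(X) {
  # map unconstrained features onto the simplex so they can live in a
  # CompositionMatrix; softmax is monotone and keeps classes separable
  E <- exp(X - apply(X, 1, max))
  E / rowSums(E)
}

randomInstance <- function(seed, n = 40, p = 5, spread = 2.5) {
  set.seed(seed)
  mu <- matrix(rnorm(3 * p, sd = spread), 3)
  X <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(n * p), n, p), 2, mu[k, ], `+`)))
  dimnames(X) <- list(sprintf("s%03d", seq_len(3 * n)), paste0("f", 1:p))
  y <- rep(c("TCE", "EPCE", "TASCE"), each = n)
  comp <- asComposition(simplexFeatures(X))
  lab <- new("SubtypeLabeling", ids = rownames(X), subtype = y,
             clusterToName = character(0), enrichment = matrix(numeric(0), 0, 0))
  list(comp = comp, labels = lab)
}

test_that("training recovers class means, priors, and flags singularity", {
  inst <- randomInstance(1)
  md <- suppressMessages(trainLda(inst$comp, inst$labels))
  X <- proportions(inst$comp)
  y <- subtypes(inst$labels)[rownames(X)]
  for (cl in md@classNames)
    expect_equal(md@classMeans[cl, ], colMeans(X[y == cl, , drop = FALSE]),
                 tolerance = 1e-12)
  expect_equal(md@priors, rep(1 / 3, 3), tolerance = 1e-12)
  # simplex features sum to one, so the pooled covariance is singular and
  # the recorded ridge must be positive
  expect_message(md2 <- trainLda(inst$comp, inst$labels), "ridge")
  expect_gt(md2@regularization, 0)
  expect_true(validObject(md2))

  # class with < 2 samples is an error
  few <- new("SubtypeLabeling",
             ids = sampleIds(inst$comp),
             subtype = c("TCE", rep(c("EPCE", "TASCE"), length.out = 119)),
             clusterToName = character(0),
             enrichment = matrix(numeric(0), 0, 0))
  expect_error(suppressMessages(trainLda(inst$comp, few)), "< 2 samples")
})

test_that("prediction follows the closed-form discriminant on a 2-feature toy", {
  md <- new("LdaModel", classNames = c("TCE", "EPCE"),
            classMeans = matrix(c(0, 0, 4, 0), 2, byrow = TRUE,
                                dimnames = list(c("TCE", "EPCE"), c("f1", "f2"))),
            pooledCov = diag(2), priors = c(0.5, 0.5),
            featureNames = c("f1", "f2"), nPerClass = c(10L, 10L),
            regularization = 0)
  # predictLda also accepts a plain feature matrix (features need not be
  # simplex-constrained)
  mk <- function(x1) matrix(c(x1, 0), 1, dimnames = list("s1", c("f1", "f2")))
  # boundary at f1 = 2: below -> first class, above -> second
  expect_identical(unname(subtypes(predictLda(md, mk(1))$labeling)), "TCE")
  expect_identical(unname(subtypes(predictLda(md, mk(3))$labeling)), "EPCE")
  onB <- suppressMessages(predictLda(md, mk(2)))
  expect_equal(unname(onB$posterior[1, ]), c(0.5, 0.5), tolerance = 1e-12)
  expect_identical(unname(subtypes(onB$labeling)), "TCE")  # tie -> class order
  # hand-computed discriminant at x = (1, 0): delta = x'S^-1 mu - mu'S^-1 mu/2 + log pi
  d <- predictLda(md, mk(1))$discriminants
  expect_equal(unname(d[1, ]), c(0 - 0 + log(0.5), 4 - 8 + log(0.5)),
               tolerance = 1e-12)
  bad <- matrix(c(0.5, 0.5), 1, dimnames = list("s1", c("f1", "other")))
  expect_error(predictLda(md, bad), "f2")
})

test_that("labels agree with a brute-force Gaussian Bayes oracle", {
  mismatch <- 0L
  for (seed in 1:15) {
    inst <- randomInstance(seed, n = 30, p = 4)
    md <- suppressMessages(trainLda(inst$comp, inst$labels))
    pr <- predictLda(md, inst$comp)
    Si <- solve(md@pooledCov)
    X <- proportions(inst$comp)[, md@featureNames]
    oracle <- apply(X, 1, function(x) {
      ll <- vapply(seq_along(md@classNames), function(k) {
        d <- x - md@classMeans[k, ]
        -0.5 * drop(t(d) %*% Si %*% d) + log(md@priors[k])
      }, numeric(1))
      md@classNames[which.max(ll)]
    })
    mismatch <- mismatch + sum(subtypes(pr$labeling) != oracle)
    expect_equal(unname(rowSums(pr$posterior)), rep(1, nrow(X)),
                 tolerance = 1e-12)
  }
  expect_identical(mismatch, 0L)
})

test_that("well-separated classes are classified perfectly in training", {
  inst <- randomInstance(3, n = 30, p = 4, spread = 6)
  md <- suppressMessages(trainLda(inst$comp, inst$labels))
  pr <- predictLda(md, inst$comp)
  expect_identical(unname(subtypes(pr$labeling)),
                   unname(subtypes(inst$labels)[sampleIds(pr$labeling)]))
})

test_that("a model trained on one cohort predicts an independent cohort", {
  co1 <- cachedCohort(150, seed = 6)
  co2 <- simulateCohort(simulationConfig(nPatients = 150, seed = 106),
                        ref = co1$reference)
  cm1 <- cachedComposition(150, seed = 6)
  cm2 <- fitProportions(co2$expression, co1$reference)
  md <- suppressMessages(trainLda(cm1, truthLabeling(co1$truth)))
  pr <- predictLda(md, cm2)
  acc <- mean(subtypes(pr$labeling) ==
                co2$truth@sampleSubtype[sampleIds(pr$labeling)])
  expect_gte(acc, 0.9)
})

test_that("JSON serialization round-trips to bit-identical predictions", {
  inst <- randomInstance(5)
  md <- suppressMessages(trainLda(inst$comp, inst$labels))
  path <- withr::local_tempfile(fileext = ".json")
  saveLdaModel(md, path)
  back <- loadLdaModel(path)
  expect_identical(back@classMeans, md@classMeans)
  expect_identical(back@pooledCov, md@pooledCov)
  expect_identical(back@priors, md@priors)
  expect_identical(back@regularization, md@regularization)
  p1 <- predictLda(md, inst$comp)
  p2 <- predictLda(back, inst$comp)
  expect_identical(p1$posterior, p2$posterior)
  expect_identical(subtypes(p1$labeling), subtypes(p2$labeling))

  # corrupted and mismatched files fail with clear errors
  writeLines(substr(paste(readLines(path), collapse = ""), 1, 50), path)
  expect_error(loadLdaModel(path), "parse|corrupted")
  jsonlite::write_json(list(format = "something-else"), path,
                       auto_unbox = TRUE)
  expect_error(loadLdaModel(path), "not an LDA model")
})
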