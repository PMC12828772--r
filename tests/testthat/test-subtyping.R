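planted3 <- function(n = 60, sep = 8, seed = 1, p = 4) {
  # three Gaussian blobs separated by `sep` within-cluster sds
  set.seed(seed)
  centers <- rbind(c(0, 0), c(sep, 0), c(0, sep))
  X <- do.call(rbind, lapply(1:3, function(k)
    cbind(matrix(rnorm(n / 3 * 2), ncol = 2) + rep(centers[k, ], each = n / 3),
          matrix(rnorm(n / 3 * (p - 2)), ncol = p - 2))))
  dimnames(X) <- list(sprintf("s%03d", 1:n), sprintf("f%d", 1:p))
  # blobs are unit-sd by construction: use the coordinates directly so the
  # between-center distance stays `sep` within-cluster sds
  list(z = new("ZMatrix", zValues = X, centers = colMeans(X),
               scales = apply(X, 2, sd), constant = rep(FALSE, p)),
       truth = rep(1:3, each = n / 3))
}

test_that("zscore standardizes per component and flags constant columns", {
  # hand-checked column: (1,2,3)/6 centered and scaled (ddof 1) -> (-1, 0, 1)
  raw <- cbind(x = c(1, 2, 3) / 6, y = c(5, 4, 3) / 6)
  rownames(raw) <- paste0("s", 1:3)
  z1 <- zscore(new("CompositionMatrix", proportions = raw,
                   fitResidual = rep(NA_real_, 3)))
  expect_equal(unname(zValues(z1)[, "x"]), c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(unname(colMeans(zValues(z1))), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(zValues(z1), 2, sd)), c(1, 1), tolerance = 1e-12)

  # constant columns map to all-zero with a flag and a message
  const <- cbind(x = c(0.8, 0.8, 0.8), y = c(0.2, 0.2, 0.2))
  rownames(const) <- paste0("s", 1:3)
  expect_message(
    zx <- zscore(new("CompositionMatrix", proportions = const,
                     fitResidual = rep(NA_real_, 3))),
    "constant")
  expect_true(all(zx@constant))
  expect_true(all(zValues(zx) == 0))

  single <- new("CompositionMatrix",
                proportions = matrix(c(0.4, 0.6), 1,
                                     dimnames = list("s1", c("a", "b"))),
                fitResidual = NA_real_)
  expect_error(zscore(single), ">= 2 samples")
})

test_that("zscore values match the direct (x - mean)/sd computation", {
  comp <- cachedComposition(100, seed = 4)
  z <- zValues(zscore(comp))
  p <- proportions(comp)
  manual <- sweep(sweep(p, 2, colMeans(p)), 2, apply(p, 2, sd), `/`)
  expect_equal(z, manual, tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, ncol(z)), tolerance = 1e-9)
})

test_that("consensus on well-separated planted clusters is near-binary", {
  pl <- planted3(n = 60, sep = 8)
  res <- consensusCluster(pl$z, kRange = 2:4, nResamples = 100, seed = 7)
  cm <- consensusMatrix(res, 3)
  same <- outer(pl$truth, pl$truth, `==`)
  offdiag <- upper.tri(cm)
  expect_gt(min(cm[same & offdiag]), 0.95)
  expect_lt(max(cm[!same & offdiag]), 0.05)
  lab <- clusterLabels(res, 3)
  expect_equal(mclust::adjustedRandIndex(lab, pl$truth), 1.0)
  # consensus matrices are symmetric with unit diagonal, entries in [0, 1]
  expect_identical(cm, t(cm))
  expect_true(all(diag(cm) == 1))
  expect_true(all(cm >= 0 & cm <= 1))
})

test_that("duplicated points always co-cluster and reruns are identical", {
  X <- rbind(c(0, 0), c(0, 0), c(10, 0), c(10, 0), c(0, 10), c(0, 10),
             c(5, 5), c(5.1, 5), c(0.2, 0.1), c(10.1, 0.1))
  dimnames(X) <- list(sprintf("s%02d", 1:10), c("f1", "f2"))
  z <- new("ZMatrix", zValues = X, centers = c(0, 0), scales = c(1, 1),
           constant = c(FALSE, FALSE))
  r1 <- consensusCluster(z, kRange = 3, nResamples = 200,
                         subsampleFraction = 0.8, seed = 3)
  cm <- consensusMatrix(r1, 3)
  expect_equal(cm["s01", "s02"], 1)
  expect_equal(cm["s03", "s04"], 1)
  expect_equal(cm["s05", "s06"], 1)
  r2 <- consensusCluster(z, kRange = 3, nResamples = 200,
                         subsampleFraction = 0.8, seed = 3)
  expect_identical(r1@consensus, r2@consensus)
  expect_identical(r1@labels, r2@labels)
})

test_that("consensus preconditions are enforced", {
  pl <- planted3(n = 30)
  expect_error(consensusCluster(pl$z, nResamples = 5), ">= 10")
  expect_error(consensusCluster(pl$z, subsampleFraction = 1.2), "\\(0, 1\\)")
  expect_error(consensusCluster(pl$z, kRange = 2:30, nResamples = 10),
               "smaller than the subsample")
})

test_that("delta-area selects the planted k and flags structureless data", {
  pl <- planted3(n = 60, sep = 8)
  res <- consensusCluster(pl$z, kRange = 2:6, nResamples = 100, seed = 5)
  k <- selectK(res, policy = "delta-area")
  expect_identical(as.integer(k), 3L)
  expect_false(attr(k, "lowConfidence"))
  expect_identical(as.integer(selectK(res, policy = "fixed", fixedK = 3)), 3L)
  # a single Gaussian blob: flat profile, min(kRange) with low confidence
  set.seed(11)
  blob <- matrix(rnorm(80 * 4), 80, 4,
                 dimnames = list(sprintf("s%02d", 1:80), paste0("f", 1:4)))
  zb <- new("ZMatrix", zValues = scale(blob), centers = colMeans(blob),
            scales = apply(blob, 2, sd), constant = rep(FALSE, 4))
  resb <- consensusCluster(zb, kRange = 2:6, nResamples = 100, seed = 5)
  kb <- NULL
  expect_message(kb <- selectK(resb, policy = "delta-area"),
                 "no strongly supported k")
  expect_identical(as.integer(kb), 2L)
  expect_true(attr(kb, "lowConfidence"))
})

test_that("z-scoring then clustering is invariant to affine component rescaling", {
  comp <- cachedComposition(100, seed = 4)
  p <- proportions(comp)
  z1 <- zscore(comp)
  scaled <- p
  scaled[, "CAFs"] <- scaled[, "CAFs"] * 12 + 0.05   # affine, positive slope
  z2raw <- sweep(sweep(scaled, 2, colMeans(scaled)), 2,
                 apply(scaled, 2, sd), `/`)
  expect_equal(zValues(z1), z2raw, tolerance = 1e-9)
})

test_that("cluster naming maps enriched cell types to subtype labels", {
  co <- cachedCohort(150, seed = 6)
  comp <- cachedComposition(150, seed = 6)
  z <- zscore(comp)
  res <- consensusCluster(z, kRange = 3, nResamples = 100, seed = 6)
  lab <- clusterLabels(res, 3)
  sl <- assignSubtypeNames(lab, z)
  truth <- co$truth@sampleSubtype[sampleIds(sl)]
  expect_gte(mean(subtypes(sl) == truth), 0.95)
  # the cluster -> name map is a bijection over exactly three names
  expect_setequal(unname(clusterToName(sl)), c("TCE", "EPCE", "TASCE"))
  expect_identical(anyDuplicated(names(clusterToName(sl))), 0L)

  expect_error(assignSubtypeNames(lab[lab != 2], z), "exactly 3")
})

test_that("naming falls back greedily when criteria collide", {
  # construct Z where one cluster maximizes both the T-cell and stromal scores
  comps <- c("Bcells", "CD4_Tcells", "CD8_Tcells", "NKcells", "Macrophages",
             "Endothelial", "CAFs", "uncharacterized")
  n <- 30
  z <- matrix(0, n, 8, dimnames = list(sprintf("s%02d", 1:n), comps))
  g <- rep(1:3, each = 10)
  z[g == 1, c("CD4_Tcells", "CD8_Tcells")] <- 3
  z[g == 1, c("CAFs", "Endothelial", "Macrophages")] <- 2.5  # runner-up stromal
  z[g == 2, "uncharacterized"] <- 3
  z[g == 3, c("CAFs", "Endothelial", "Macrophages")] <- 2    # weaker stromal
  zm <- new("ZMatrix", zValues = z, centers = rep(0, 8), scales = rep(1, 8),
            constant = rep(FALSE, 8))
  lab <- setNames(g, rownames(z))
  expect_warning(sl <- assignSubtypeNames(lab, zm), "greedy")
  expect_setequal(unname(clusterToName(sl)), c("TCE", "EPCE", "TASCE"))
  # cluster 1 wins TCE (larger margin), cluster 3 takes TASCE by fallback
  expect_identical(unname(subtypes(sl)[lab == 1][1]), "TCE")
  expect_identical(unname(subtypes(sl)[lab == 3][1]), "TASCE")
})
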