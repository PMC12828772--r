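## Subtype discovery: component-wise Z-standardization, resampling consensus
## clustering with PAM, CDF-area based selection of k, and naming of the
## three clusters by their enriched cell types.

#' Standardize a composition matrix component-wise
#'
#' Z-transforms each component (column) across samples using the sample
#' standard deviation (ddof 1). Standardization is per component across
#' samples — the convention under which clustering features are comparable
#' and per-cell-type "scaled proportions" are interpretable — and the same
#' Z-scores are reused by the heterogeneity analysis. Constant columns are
#' mapped to all-zero and flagged.
#'
#' @param comp A \linkS4class{CompositionMatrix} (>= 2 samples).
#' @return A \linkS4class{ZMatrix}.
#' @export
zscore <- function(comp) {
  p <- proportions(comp)
  if (nrow(p) < 2) stop("zscore needs >= 2 samples")
  centers <- colMeans(p)
  scales <- apply(p, 2L, sd)
  constant <- scales == 0
  if (any(constant))
    message("constant component column(s) set to zero: ",
            paste(colnames(p)[constant], collapse = ", "))
  z <- sweep(p, 2L, centers, `-`)
  z[, !constant] <- sweep(z[, !constant, drop = FALSE], 2L,
                          scales[!constant], `/`)
  z[, constant] <- 0
  new("ZMatrix", zValues = z, centers = centers, scales = scales,
      constant = constant)
}

# area under the empirical CDF of the off-diagonal consensus values
.cdfArea <- function(cm) {
  v <- sort(cm[upper.tri(cm)])
  n <- length(v)
  if (n < 2) return(0)
  cdf <- seq_len(n) / n
  sum(diff(v) * cdf[-n])
}

#' Resampling consensus clustering with PAM
#'
#' For each candidate k: repeatedly subsample a fraction of the samples
#' without replacement, partition the subsample with PAM (k medoids,
#' Euclidean distance on the Z rows), and record co-membership. The
#' consensus for a sample pair is its co-clustering count divided by its
#' co-sampling count. Final labels per k come from average-linkage
#' hierarchical clustering of the dissimilarity 1 - consensus, cut at k.
#' Deterministic given \code{seed}.
#'
#' @param z A \linkS4class{ZMatrix}.
#' @param kRange Integer vector of cluster numbers to try (default 2:6).
#' @param nResamples Resamples per k (>= 10; default 1000).
#' @param subsampleFraction Fraction of samples drawn per resample (default
#'   0.8).
#' @param seed Integer seed.
#' @return A \linkS4class{ConsensusResult}.
#' @export
consensusCluster <- function(z, kRange = 2:6, nResamples = 1000L,
                             subsampleFraction = 0.8, seed = 1L) {
  zm <- zValues(z)
  n <- nrow(zm)
  kRange <- sort(as.integer(kRange))
  if (nResamples < 10) stop("nResamples must be >= 10")
  if (subsampleFraction <= 0 || subsampleFraction >= 1)
    stop("subsampleFraction must lie in (0, 1)")
  m <- floor(subsampleFraction * n)
  if (max(kRange) >= m)
    stop("max(kRange) must be smaller than the subsample size")
  set.seed(as.integer(seed))
  consensus <- list(); counts <- list(); labels <- list()
  for (k in kRange) {
    coCluster <- matrix(0, n, n)
    coSample <- matrix(0, n, n)
    for (r in seq_len(nResamples)) {
      idx <- sort(sample.int(n, m))
      cl <- cluster::pam(zm[idx, , drop = FALSE], k = k,
                         metric = "euclidean", cluster.only = TRUE,
                         pamonce = 5)
      coSample[idx, idx] <- coSample[idx, idx] + 1
      for (g in seq_len(k)) {
        mem <- idx[cl == g]
        coCluster[mem, mem] <- coCluster[mem, mem] + 1
      }
    }
    cm <- matrix(0, n, n)
    pos <- coSample > 0
    cm[pos] <- coCluster[pos] / coSample[pos]
    if (any(!pos[upper.tri(pos)]))
      message(sprintf("k=%d: %d pair(s) never co-sampled (consensus set to 0)",
                      k, sum(!pos[upper.tri(pos)])))
    diag(cm) <- 1
    dimnames(cm) <- list(rownames(zm), rownames(zm))
    hc <- hclust(stats::as.dist(1 - cm), method = "average")
    lab <- cutree(hc, k = k)
    consensus[[.kKey(k)]] <- cm
    counts[[.kKey(k)]] <- coSample
    labels[[.kKey(k)]] <- setNames(as.integer(lab), rownames(zm))
  }
  area <- vapply(consensus, .cdfArea, numeric(1))
  delta <- numeric(length(kRange))
  delta[1] <- area[1]
  if (length(kRange) > 1)
    delta[-1] <- diff(area) / area[-length(area)]
  new("ConsensusResult", kValues = kRange, consensus = consensus,
      pairCounts = counts, labels = labels, cdfArea = unname(area),
      deltaAreaValues = delta, chosenK = NA_integer_)
}

#' Select the number of clusters
#'
#' Under \code{policy = "delta-area"}: the chosen k is the smallest k beyond
#' which the relative increase in the consensus-CDF area stays below
#' \code{threshold} — i.e. the largest k whose own relative increase is at
#' least \code{threshold}. The choice is then vetted with the proportion of
#' ambiguous consensus values (PAC: off-diagonal entries strictly between
#' 0.1 and 0.9) at the chosen k: structureless data (a single Gaussian blob)
#' keeps most pairs ambiguous at every k, so when the PAC exceeds
#' \code{pacLimit} — or when the delta-area profile never drops below
#' \code{threshold}, or never reaches it — no k is strongly supported, and
#' \code{min(kRange)} is returned with a low-confidence flag. Under
#' \code{policy = "fixed"}: returns \code{fixedK} regardless of structure.
#'
#' @param res A \linkS4class{ConsensusResult} with >= 2 k values.
#' @param policy \code{"delta-area"} or \code{"fixed"}.
#' @param threshold Relative-increase threshold (default 0.1).
#' @param pacLimit Maximum proportion of ambiguous consensus values for a
#'   confident call (default 0.3; well-separated structure sits near 0,
#'   structureless blobs near 0.5).
#' @param fixedK The k returned under the fixed policy (default 3).
#' @return Integer k, with attribute \code{lowConfidence} (logical).
#' @export
selectK <- function(res, policy = c("delta-area", "fixed"), threshold = 0.1,
                    pacLimit = 0.3, fixedK = 3L) {
  policy <- match.arg(policy)
  if (policy == "fixed")
    return(structure(as.integer(fixedK), lowConfidence = FALSE))
  ks <- res@kValues
  if (length(ks) < 2) stop("selectK needs >= 2 k values")
  d <- res@deltaAreaValues
  eligible <- ks[d >= threshold]
  flat <- length(eligible) == 0L || length(eligible) == length(ks)
  if (!flat) {
    k <- max(eligible)
    cm <- res@consensus[[.kKey(k)]]
    v <- cm[upper.tri(cm)]
    pac <- mean(v > 0.1 & v < 0.9)
    if (pac <= pacLimit)
      return(structure(k, lowConfidence = FALSE))
  }
  message("no strongly supported k (flat delta-area profile or ambiguous ",
          "consensus); returning min(kRange) with low confidence")
  structure(min(ks), lowConfidence = TRUE)
}

#' Name three clusters by their enriched cell types
#'
#' Computes the per-cluster mean Z per component and assigns: TCE to the
#' cluster maximizing the mean of the CD4/CD8 T-cell components, EPCE to the
#' cluster maximizing the uncharacterized (epithelial) component, TASCE to
#' the cluster maximizing the mean of CAFs, endothelial cells and
#' macrophages. If the three argmaxes collide, clusters are assigned
#' greedily in decreasing order of score margin, with a warning.
#'
#' @param labels Named integer vector of cluster ids (exactly 3 clusters),
#'   names being sample ids.
#' @param z The \linkS4class{ZMatrix} the clustering was run on.
#' @return A \linkS4class{SubtypeLabeling}.
#' @export
assignSubtypeNames <- function(labels, z) {
  zm <- zValues(z)
  if (is.null(names(labels))) stop("labels must be named by sample id")
  if (!all(names(labels) %in% rownames(zm)))
    stop("labels contain samples absent from the Z matrix")
  cls <- sort(unique(labels))
  if (length(cls) != 3) stop("subtype naming requires exactly 3 clusters, got ",
                             length(cls))
  crit <- list(TCE = c("CD4_Tcells", "CD8_Tcells"),
               EPCE = "uncharacterized",
               TASCE = c("CAFs", "Endothelial", "Macrophages"))
  need <- unique(unlist(crit))
  if (!all(need %in% colnames(zm)))
    stop("Z matrix lacks component(s): ",
         paste(setdiff(need, colnames(zm)), collapse = ", "))
  meanZ <- t(vapply(cls, function(g)
    colMeans(zm[names(labels)[labels == g], , drop = FALSE]),
    numeric(ncol(zm))))
  rownames(meanZ) <- paste0("cluster", cls)
  scores <- vapply(crit, function(comps)
    rowMeans(meanZ[, comps, drop = FALSE]), numeric(length(cls)))
  # scores: clusters x subtypes
  pick <- apply(scores, 2L, which.max)
  if (anyDuplicated(pick)) {
    warning("subtype criteria point to overlapping clusters; using greedy ",
            "assignment by score margin")
    margin <- apply(scores, 2L, function(s) {
      o <- sort(s, decreasing = TRUE); o[1] - o[2]
    })
    pick <- setNames(integer(3), names(crit))
    taken <- integer(0)
    for (st in names(sort(margin, decreasing = TRUE))) {
      ord <- order(scores[, st], decreasing = TRUE)
      ord <- ord[!ord %in% taken]
      pick[st] <- ord[1]
      taken <- c(taken, ord[1])
    }
  }
  clusterToName <- setNames(names(crit)[order(pick)],
                            as.character(cls[sort(pick)]))
  subtype <- unname(clusterToName[as.character(labels)])
  new("SubtypeLabeling", ids = names(labels), subtype = subtype,
      clusterToName = clusterToName, enrichment = meanZ)
}

#' Write / read subtype labels as TSV
#'
#' Columns \code{sample_id}, \code{cluster} (if known) and \code{subtype}.
#'
#' @param labeling A \linkS4class{SubtypeLabeling}.
#' @param path Output path.
#' @param clusters Optional named cluster-id vector to include.
#' @return \code{path} (write) or a \linkS4class{SubtypeLabeling} (read).
#' @export
writeSubtypes <- function(labeling, path, clusters = NULL) {
  df <- data.frame(sample_id = sampleIds(labeling),
                   subtype = unname(subtypes(labeling)))
  if (!is.null(clusters))
    df$cluster <- unname(clusters[df$sample_id])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSubtypes
#' @export
loadSubtypes <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "subtype") %in% colnames(df)))
    stop("subtype file needs 'sample_id' and 'subtype' columns")
  new("SubtypeLabeling", ids = as.character(df$sample_id),
      subtype = df$subtype, clusterToName = character(0),
      enrichment = matrix(numeric(0), 0, 0))
}
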