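## Multifocal heterogeneity: cosine similarity of standardized compositions
## for every sample pair, classified as interpatient / interfocal /
## intrafocal, with Wilcoxon rank-sum comparisons and subtype concordance
## summaries.

#' Cosine similarity of two composition vectors
#'
#' \code{dot(u, v) / (||u|| ||v||)}, clamped to [-1, 1] against floating
#' point overshoot. Zero-norm vectors are an error.
#'
#' @param u,v Numeric vectors of equal length.
#' @return Similarity in [-1, 1].
#' @export
cosineSimilarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for zero vectors")
  min(1, max(-1, sum(u * v) / (nu * nv)))
}

#' All pairwise sample similarities with heterogeneity class
#'
#' Enumerates every unordered sample pair, classifies it — same focus:
#' intrafocal; same patient, different focus: interfocal; different
#' patients: interpatient — and computes the cosine similarity of the two
#' samples' Z-score rows.
#'
#' @param z A \linkS4class{ZMatrix} at sample level.
#' @param map Sample map \code{data.frame} (\code{sample_id},
#'   \code{patient_id}, \code{focus_id}) covering every sample in \code{z}.
#' @return \code{data.frame} with columns \code{sample_a}, \code{sample_b},
#'   \code{pair_class}, \code{cosine}.
#' @export
pairSimilarities <- function(z, map) {
  zm <- zValues(z)
  ids <- rownames(zm)
  unmapped <- setdiff(ids, map$sample_id)
  if (length(unmapped))
    stop("sample(s) missing from sample map: ",
         paste(head(unmapped), collapse = ", "))
  pat <- setNames(map$patient_id, map$sample_id)[ids]
  foc <- setNames(paste(map$patient_id, map$focus_id), map$sample_id)[ids]
  pairs <- utils::combn(length(ids), 2L)
  a <- pairs[1L, ]; b <- pairs[2L, ]
  cls <- ifelse(pat[a] != pat[b], "interpatient",
                ifelse(foc[a] == foc[b], "intrafocal", "interfocal"))
  cosv <- vapply(seq_along(a), function(i)
    cosineSimilarity(zm[a[i], ], zm[b[i], ]), numeric(1))
  data.frame(sample_a = ids[a], sample_b = ids[b], pair_class = cls,
             cosine = cosv, stringsAsFactors = FALSE)
}

#' Compare the three heterogeneity classes
#'
#' Two-sided Wilcoxon rank-sum tests (normal approximation with tie and
#' continuity correction) on the cosine similarities: intrafocal vs
#' interfocal, intrafocal vs interpatient, interfocal vs interpatient.
#' P-values are reported unadjusted.
#'
#' @param table Output of \code{\link{pairSimilarities}}.
#' @return \code{data.frame} with one row per comparison: group names and
#'   sizes, medians, the rank-sum statistic U, and the p-value.
#' @export
comparePairGroups <- function(table) {
  groups <- split(table$cosine, table$pair_class)
  comparisons <- list(c("intrafocal", "interfocal"),
                      c("intrafocal", "interpatient"),
                      c("interfocal", "interpatient"))
  out <- lapply(comparisons, function(cp) {
    for (g in cp) if (is.null(groups[[g]]) || length(groups[[g]]) == 0)
      stop("empty heterogeneity group: ", g)
    ga <- groups[[cp[1]]]; gb <- groups[[cp[2]]]
    wt <- wilcox.test(ga, gb, exact = FALSE, correct = TRUE)
    data.frame(group_a = cp[1], group_b = cp[2],
               n_a = length(ga), n_b = length(gb),
               median_a = median(ga), median_b = median(gb),
               U = unname(wt$statistic), p_value = wt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Subtype concordance within patients and foci
#'
#' Per patient: how many distinct subtypes its samples carry and whether
#' they are uniform; per focus with >= 2 samples: whether it is uniform;
#' plus cohort summary counts.
#'
#' @param labels Sample-level \linkS4class{SubtypeLabeling}.
#' @param map Sample map covering the labelled samples.
#' @return List with \code{patients} and \code{foci} data.frames and a
#'   \code{summary} list (\code{patientsUniform}, \code{patientsTotal},
#'   \code{fociUniform}, \code{fociMultiSample}).
#' @export
subtypeConcordance <- function(labels, map) {
  st <- subtypes(labels)
  m <- map[map$sample_id %in% names(st), , drop = FALSE]
  m$subtype <- st[m$sample_id]
  byPat <- split(m$subtype, m$patient_id)
  patients <- data.frame(
    patient_id = names(byPat),
    n_samples = vapply(byPat, length, integer(1)),
    n_subtypes = vapply(byPat, function(x) length(unique(x)), integer(1)),
    stringsAsFactors = FALSE)
  patients$uniform <- patients$n_subtypes == 1L
  focKey <- paste(m$patient_id, m$focus_id, sep = "\r")
  byFoc <- split(m$subtype, focKey)
  multi <- vapply(byFoc, length, integer(1)) >= 2L
  foci <- data.frame(
    patient_id = sub("\r.*$", "", names(byFoc)[multi]),
    focus_id = sub("^.*\r", "", names(byFoc)[multi]),
    n_samples = vapply(byFoc[multi], length, integer(1)),
    uniform = vapply(byFoc[multi], function(x) length(unique(x)) == 1L,
                     logical(1)),
    stringsAsFactors = FALSE)
  rownames(patients) <- rownames(foci) <- NULL
  list(patients = patients, foci = foci,
       summary = list(patientsUniform = sum(patients$uniform),
                      patientsTotal = nrow(patients),
                      fociUniform = sum(foci$uniform),
                      fociMultiSample = nrow(foci)))
}
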