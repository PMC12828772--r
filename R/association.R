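## Subtype vs clinicopathology: chi-square cross-tabulations against Gleason
## grade and pT stage, and Wilcoxon comparisons of CAF-marker expression
## across subtypes.

#' Default CAF marker panel
#'
#' Nine established cancer-associated fibroblast markers.
#' @export
CAF_MARKERS <- c("ACTA2", "FAP", "PDGFRB", "POSTN", "COL1A1", "FN1", "VIM",
                 "DCN", "LUM")

#' Cross-tabulate subtype against a clinical category
#'
#' Counts and row proportions of a clinical category per subtype, with a
#' Pearson chi-square test (no continuity correction) and a warning flag
#' when any expected count is below 5.
#'
#' @param labels A \linkS4class{SubtypeLabeling} (patient or sample level).
#' @param categories Factor/character vector named by (or aligned with) the
#'   labelled ids, e.g. \code{clinical$gleason_category} named by patient.
#' @return List with \code{counts}, \code{rowProportions}, \code{chisq},
#'   \code{df}, \code{p_value}, \code{lowExpected}.
#' @export
crosstabSubtype <- function(labels, categories) {
  st <- subtypes(labels)
  if (!is.null(names(categories))) {
    shared <- intersect(names(st), names(categories))
    st <- st[shared]; categories <- categories[shared]
  }
  if (length(st) == 0 || length(st) != length(categories))
    stop("labels and categories must align on a non-empty id set")
  rowFac <- factor(st, levels = intersect(.SUBTYPES, unique(st)))
  colFac <- factor(categories)
  counts <- table(subtype = rowFac, category = colFac)
  if (any(dim(counts) < 2))
    stop("cross-tabulation needs >= 2 levels on both margins")
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  props <- prop.table(counts, margin = 1L)
  list(counts = counts, rowProportions = props,
       chisq = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, lowExpected = any(ct$expected < 5))
}

#' Compare marker-gene expression across subtypes
#'
#' For each marker present in the expression matrix and each subtype pair:
#' a two-sided Wilcoxon rank-sum test (normal approximation, tie and
#' continuity correction) on log2(x + 1) expression, with the median
#' log-expression difference. Markers missing from the matrix are reported
#' but not fatal. An unadjusted p-value is the primary output; a
#' Benjamini-Hochberg column over all rows is emitted alongside.
#'
#' @param expr Expression matrix, genes x samples.
#' @param labels Sample-level \linkS4class{SubtypeLabeling}.
#' @param markers Marker gene ids (default the nine-gene CAF panel
#'   \code{\link{CAF_MARKERS}}).
#' @return \code{data.frame}: \code{marker}, \code{group_a}, \code{group_b},
#'   \code{median_a}, \code{median_b}, \code{median_diff}, \code{p_value},
#'   \code{p_adjust_bh}; attribute \code{missingMarkers}.
#' @export
markerComparison <- function(expr, labels, markers = CAF_MARKERS) {
  found <- intersect(markers, rownames(expr))
  missing <- setdiff(markers, found)
  if (length(found) == 0)
    stop("none of the requested markers are present in the expression matrix")
  if (length(missing))
    message("marker(s) absent from expression matrix: ",
            paste(missing, collapse = ", "))
  st <- subtypes(labels)
  ids <- intersect(colnames(expr), names(st))
  if (length(ids) == 0) stop("no labelled samples in the expression matrix")
  st <- st[ids]
  lv <- intersect(.SUBTYPES, unique(st))
  pairsL <- utils::combn(lv, 2L, simplify = FALSE)
  rows <- list()
  for (mk in found) {
    x <- log2(expr[mk, ids] + 1)
    for (cp in pairsL) {
      xa <- x[st == cp[1]]; xb <- x[st == cp[2]]
      # a marker constant across both groups carries no evidence of a shift
      pv <- if (length(unique(c(xa, xb))) == 1L) 1
            else wilcox.test(xa, xb, exact = FALSE, correct = TRUE)$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        marker = mk, group_a = cp[1], group_b = cp[2],
        median_a = median(xa), median_b = median(xb),
        median_diff = median(xa) - median(xb),
        p_value = pv, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjust_bh <- stats::p.adjust(out$p_value, method = "BH")
  attr(out, "missingMarkers") <- missing
  out
}
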