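## I/O for expression matrices, clinical tables, sample maps and reference
## profiles. Layout convention everywhere: genes are rows, samples are columns.

#' Read a gene-by-sample expression matrix
#'
#' Reads a tab-separated expression file (first column gene ids, header row
#' sample ids) into a validated numeric matrix. Values must be non-negative
#' and finite; duplicate gene ids are collapsed by summation; duplicate
#' sample ids are an error. FPKM/RPKM inputs are accepted and can be brought
#' onto the TPM scale with \code{\link{renormalizeTpm}} (they are
#' within-sample relative measures, so per-sample renormalization preserves
#' the information deconvolution uses).
#'
#' @param path Path to a TSV file.
#' @param unit One of \code{"tpm"}, \code{"fpkm"}, \code{"rpkm"}; recorded on
#'   the returned matrix as attribute \code{"unit"}.
#' @return Numeric matrix (genes x samples) with attribute \code{"unit"}.
#' @export
loadExpression <- function(path, unit = c("tpm", "fpkm", "rpkm")) {
  unit <- match.arg(unit)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("malformed expression file (need a gene-id column plus >= 1 sample): ",
         path)
  sampleIds <- colnames(df)[-1]
  if (anyDuplicated(sampleIds))
    stop("duplicate sample ids in header: ",
         paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))
    stop("non-numeric expression values in sample(s): ",
         paste(sampleIds[bad], collapse = ", "))
  }
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at gene '%s', sample '%s'",
                 genes[idx[1]], sampleIds[idx[2]]))
  }
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative expression at gene '%s', sample '%s'",
                 genes[idx[1]], sampleIds[idx[2]]))
  }
  if (anyDuplicated(genes)) {
    m <- rowsum(m, group = genes, reorder = FALSE)
    genes <- rownames(m)
  }
  rownames(m) <- genes
  colnames(m) <- sampleIds
  attr(m, "unit") <- unit
  m
}

#' Write an expression matrix as TSV
#'
#' Inverse of \code{\link{loadExpression}}: first column \code{gene_id},
#' one column per sample. Values are written at full precision so that a
#' write-then-read round trip is exact for representable values.
#'
#' @param m Numeric matrix, genes x samples.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Renormalize each sample to the TPM scale
#'
#' Rescales every sample (column) so it sums to one million, preserving
#' relative gene proportions within the sample. Idempotent to tolerance
#' 1e-9. All-zero samples are an error.
#'
#' @param m Non-negative expression matrix, genes x samples.
#' @return Matrix of the same shape with columns summing to 1e6; attribute
#'   \code{"unit"} set to \code{"tpm"}.
#' @export
renormalizeTpm <- function(m) {
  if (any(!is.finite(m)) || any(m < 0))
    stop("expression values must be finite and >= 0")
  cs <- colSums(m)
  if (any(cs == 0))
    stop("all-zero sample column(s): ",
         paste(colnames(m)[cs == 0], collapse = ", "))
  out <- sweep(m, 2L, 1e6 / cs, `*`)
  attr(out, "unit") <- "tpm"
  out
}

#' Map raw Gleason "a+b" scores to grade categories
#'
#' 4+4, 4+5 and above map to \code{"high"}; 4+3 maps to
#' \code{"intermediate"}; everything below maps to \code{"low"}.
#'
#' @param raw Character vector of scores like \code{"3+4"} or \code{"4+5"}.
#' @return Character vector over \code{c("low", "intermediate", "high")}.
#' @export
gleasonCategory <- function(raw) {
  parts <- regmatches(raw, regexec("^\\s*([0-9]+)\\s*\\+\\s*([0-9]+)\\s*$", raw))
  vapply(seq_along(raw), function(i) {
    p <- parts[[i]]
    if (length(p) != 3)
      stop("unparseable Gleason score '", raw[i], "' (expected 'a+b')")
    a <- as.integer(p[2]); b <- as.integer(p[3])
    if (a + b >= 8) "high"
    else if (a == 4 && b == 3) "intermediate"
    else "low"
  }, character(1))
}

#' Read a per-patient clinical table
#'
#' Expects tab-separated columns \code{patient_id}, \code{followup_months},
#' \code{bcr_event}, \code{gleason_category} (or \code{gleason_raw}, mapped
#' via \code{\link{gleasonCategory}}) and \code{pt_category}; an optional
#' \code{age} is carried through. Rows with missing survival fields are
#' dropped with a message reporting the count.
#'
#' @param path Path to a TSV file.
#' @return \code{data.frame} with validated, typed columns.
#' @export
loadClinical <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("patient_id", "followup_months", "bcr_event", "pt_category")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("clinical table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"gleason_category" %in% colnames(df)) {
    if (!"gleason_raw" %in% colnames(df))
      stop("clinical table missing column(s): gleason_category (or gleason_raw)")
    df$gleason_category <- gleasonCategory(df$gleason_raw)
  }
  dropped <- !stats::complete.cases(df[, c("followup_months", "bcr_event")])
  if (any(dropped)) {
    message(sum(dropped), " patient(s) dropped for missing survival fields")
    df <- df[!dropped, , drop = FALSE]
  }
  validateClinical(df)
}

#' Validate a clinical table
#'
#' Enforces the invariants of the clinical table (unique patient ids,
#' positive follow-up, binary event, closed category vocabularies).
#'
#' @param df \code{data.frame} with clinical columns.
#' @return The validated \code{data.frame} (factors ordered, row names
#'   cleared).
#' @export
validateClinical <- function(df) {
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient_id: ",
         paste(unique(df$patient_id[duplicated(df$patient_id)]), collapse = ", "))
  if (any(!is.finite(df$followup_months)) || any(df$followup_months <= 0))
    stop("followup_months must be finite and > 0 (offending patient(s): ",
         paste(df$patient_id[!is.finite(df$followup_months) |
                             df$followup_months <= 0], collapse = ", "), ")")
  if (!all(df$bcr_event %in% c(0L, 1L)))
    stop("bcr_event must be 0 or 1")
  badG <- !df$gleason_category %in% .GLEASON_LEVELS
  if (any(badG))
    stop("unknown gleason_category '", df$gleason_category[badG][1],
         "'; allowed: ", paste(.GLEASON_LEVELS, collapse = ", "))
  badT <- !df$pt_category %in% .PT_LEVELS
  if (any(badT))
    stop("unknown pt_category '", df$pt_category[badT][1],
         "'; allowed: ", paste(.PT_LEVELS, collapse = ", "))
  df$patient_id <- as.character(df$patient_id)
  df$bcr_event <- as.integer(df$bcr_event)
  df$gleason_category <- factor(df$gleason_category, levels = .GLEASON_LEVELS)
  df$pt_category <- factor(df$pt_category, levels = .PT_LEVELS)
  rownames(df) <- NULL
  df
}

#' Read a sample-to-patient/focus map
#'
#' Tab-separated columns \code{sample_id}, \code{patient_id},
#' \code{focus_id}. \code{focus_id} is meaningful only within its patient.
#'
#' @param path Path to a TSV file.
#' @return Validated \code{data.frame}.
#' @export
loadSampleMap <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "focus_id")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("sample map missing column(s): ",
                         paste(miss, collapse = ", "))
  validateSampleMap(df)
}

#' Validate a sample map
#'
#' @param df \code{data.frame} with columns \code{sample_id},
#'   \code{patient_id}, \code{focus_id}.
#' @return The validated \code{data.frame}.
#' @export
validateSampleMap <- function(df) {
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (anyNA(df[, c("sample_id", "patient_id", "focus_id")]))
    stop("sample map must have no missing entries")
  df$sample_id <- as.character(df$sample_id)
  df$patient_id <- as.character(df$patient_id)
  df$focus_id <- as.character(df$focus_id)
  rownames(df) <- NULL
  df
}

#' Write clinical table / sample map as TSV
#'
#' @param df Table to write.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeTable <- function(df, path) {
  out <- df
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) format(x, digits = 17, trim = TRUE,
                                                  scientific = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a reference profile
#'
#' The reference TSV has columns \code{gene_id}, one column per cell type,
#' and a final \code{variability} column.
#'
#' @param path Path to a TSV file.
#' @return A \linkS4class{ReferenceProfile}.
#' @export
loadReference <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!all(c("gene_id", "variability") %in% colnames(df)))
    stop("reference file needs 'gene_id' and 'variability' columns")
  types <- setdiff(colnames(df), c("gene_id", "variability"))
  m <- as.matrix(df[, types, drop = FALSE])
  rownames(m) <- df$gene_id
  new("ReferenceProfile", means = m, variability = df$variability)
}

#' @rdname loadReference
#' @param ref A \linkS4class{ReferenceProfile} to write.
#' @export
writeReference <- function(ref, path) {
  df <- data.frame(gene_id = geneIds(ref), refMeans(ref),
                   variability = ref@variability, check.names = FALSE)
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a composition matrix as TSV
#'
#' Sample rows, the 8 named component columns in fixed order, and the
#' per-sample fit residual.
#'
#' @param comp A \linkS4class{CompositionMatrix}.
#' @param path Output path.
#' @return \code{path} (write) or a \linkS4class{CompositionMatrix} (read).
#' @export
writeComposition <- function(comp, path) {
  df <- data.frame(sample_id = sampleIds(comp), proportions(comp),
                   fit_residual = comp@fitResidual, check.names = FALSE)
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeComposition
#' @export
loadComposition <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  comps <- setdiff(colnames(df), c("sample_id", "fit_residual"))
  p <- as.matrix(df[, comps, drop = FALSE])
  rownames(p) <- df$sample_id
  res <- if ("fit_residual" %in% colnames(df)) df$fit_residual
         else rep(NA_real_, nrow(p))
  new("CompositionMatrix", proportions = p, fitResidual = res)
}
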