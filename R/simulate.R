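## Synthetic cohort generator: block-structured reference profiles, Dirichlet
## compositions with planted subtypes, nested patient/focus/sample variance in
## centered-log-ratio space, exponential BCR times with subtype hazard ratios,
## and subtype-correlated Gleason/pT covariates.

.rdirichlet <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# uniform draw from an inclusive integer range (sample() would misread a
# scalar upper bound)
.drawRange <- function(r) if (r[1] == r[2]) r[1] else sample(seq(r[1], r[2]), 1L)

# additive Gaussian perturbation in centered-log-ratio space, mapped back to
# the simplex by softmax; keeps components positive and sum-one
.clrPerturb <- function(p, sd) {
  if (sd == 0) return(p)
  z <- log(p) + rnorm(length(p), 0, sd)
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Generate a block-structured cell-type reference profile
#'
#' Builds a synthetic stand-in for a deconvolution reference: each of the 7
#' cell types gets \code{nGenesPerType} signature genes with high mean
#' expression for that type and low cross-expression for the other types;
#' \code{nBackgroundGenes} additional genes carry zero expression in all 7
#' profiles and represent the transcriptional space of the uncharacterized
#' (epithelial/malignant) compartment, which by the deconvolution model's
#' identifying assumption does not express the immune/stromal signatures.
#' Every profile column is scaled to sum to 1e6 (TPM units over the reference
#' gene universe). Per-gene variability (the inverse-weight input of the
#' fit) is drawn positive.
#'
#' @param nGenesPerType Signature genes per cell type (>= 1).
#' @param nBackgroundGenes Background genes (>= 1).
#' @param seed Integer seed; the profile is deterministic given it.
#' @return A \linkS4class{ReferenceProfile} with
#'   \code{7 * nGenesPerType + nBackgroundGenes} genes.
#' @export
generateReference <- function(nGenesPerType = 30L, nBackgroundGenes = 90L,
                              seed = 1L) {
  stopifnot(nGenesPerType >= 1, nBackgroundGenes >= 1)
  set.seed(as.integer(seed))
  types <- .CELL_TYPES
  nSig <- nGenesPerType * length(types)
  geneIds <- c(unlist(lapply(types, function(t)
    sprintf("%s_sig_%02d", t, seq_len(nGenesPerType)))),
    sprintf("background_%03d", seq_len(nBackgroundGenes)))
  m <- matrix(0, nrow = nSig + nBackgroundGenes, ncol = length(types),
              dimnames = list(geneIds, types))
  for (j in seq_along(types)) {
    rows <- (j - 1L) * nGenesPerType + seq_len(nGenesPerType)
    own <- exp(rnorm(nGenesPerType, log(300), 0.6))
    m[rows, j] <- own
    # modest cross-expression in the other immune/stromal profiles
    for (jj in seq_along(types)[-j])
      m[rows, jj] <- own * runif(nGenesPerType, 0.005, 0.05)
  }
  m <- sweep(m, 2L, 1e6 / colSums(m), `*`)
  variability <- rgamma(nrow(m), shape = 2, scale = 5)
  new("ReferenceProfile", means = m, variability = variability)
}

# epithelial (uncharacterized-compartment) profile over the reference gene
# universe: expresses only the background genes, scaled to 1e6
.epithelialProfile <- function(ref) {
  m <- refMeans(ref)
  bg <- rowSums(m) == 0
  if (!any(bg))
    stop("reference has no background genes; cannot build epithelial profile")
  e <- numeric(nrow(m))
  e[bg] <- exp(rnorm(sum(bg), log(200), 0.8))
  e * (1e6 / sum(e))
}

#' Construct a synthetic cohort configuration
#'
#' Defaults describe a TCGA-like single-sample cohort: 405 patients, one
#' sample each, three planted composition subtypes with equal prevalence (a
#' neutral prior; cluster sizes are not reported for the cohorts this
#' emulates), an epithelial-dominated composition prior per subtype, an
#' exponential biochemical-recurrence model with hazard ratios 5.3 (EPCE)
#' and 10.9 (TASCE) versus TCE, and a censoring horizon chosen so that about
#' 13\% of patients experience an event.
#'
#' @param nPatients Number of patients.
#' @param fociPerPatient,samplesPerFocus Inclusive integer ranges
#'   \code{c(min, max)}; counts are drawn uniformly per patient / focus.
#' @param nSignatureGenesPerType,nBackgroundGenes Reference shape.
#' @param subtypePrior Prevalence of \code{c(TCE, EPCE, TASCE)}.
#' @param dirichletAlpha 3 x 8 Dirichlet parameters (rows TCE/EPCE/TASCE,
#'   columns the 7 cell types then epithelial).
#' @param sdPatient,sdFocus,sdSample Centered-log-ratio perturbation scales
#'   for the nested patient/focus/sample composition hierarchy.
#' @param noiseSd Multiplicative log-normal expression noise sd.
#' @param baselineHazard TCE hazard, events per month.
#' @param hrEpce,hrTasce Subtype hazard ratios versus TCE.
#' @param censoringMaxMonths Uniform censoring horizon in months.
#' @param gleasonProbs,ptProbs Subtype-conditional category probabilities
#'   (3 x 3, rows TCE/EPCE/TASCE). Defaults make TASCE high-grade / high-stage
#'   enriched and TCE low-grade / low-stage enriched.
#' @param seed Integer seed.
#' @return A validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nPatients = 405L,
                             fociPerPatient = c(1L, 1L),
                             samplesPerFocus = c(1L, 1L),
                             nSignatureGenesPerType = 30L,
                             nBackgroundGenes = 90L,
                             subtypePrior = c(1, 1, 1) / 3,
                             dirichletAlpha = NULL,
                             sdPatient = 0.10,
                             sdFocus = 0.15,
                             sdSample = 0.10,
                             noiseSd = 0.10,
                             baselineHazard = 4.3e-4,
                             hrEpce = 5.3,
                             hrTasce = 10.9,
                             censoringMaxMonths = 120,
                             gleasonProbs = NULL,
                             ptProbs = NULL,
                             seed = 1L) {
  if (is.null(dirichletAlpha)) dirichletAlpha <- .defaultAlpha()
  if (is.null(gleasonProbs))
    gleasonProbs <- matrix(c(0.70, 0.20, 0.10,
                             0.50, 0.30, 0.20,
                             0.25, 0.30, 0.45), nrow = 3, byrow = TRUE,
                           dimnames = list(.SUBTYPES, .GLEASON_LEVELS))
  if (is.null(ptProbs))
    ptProbs <- matrix(c(0.70, 0.20, 0.10,
                        0.50, 0.30, 0.20,
                        0.30, 0.35, 0.35), nrow = 3, byrow = TRUE,
                      dimnames = list(.SUBTYPES, .PT_LEVELS))
  new("SimulationConfig",
      nPatients = as.integer(nPatients),
      fociPerPatient = as.integer(fociPerPatient),
      samplesPerFocus = as.integer(samplesPerFocus),
      nSignatureGenesPerType = as.integer(nSignatureGenesPerType),
      nBackgroundGenes = as.integer(nBackgroundGenes),
      subtypePrior = subtypePrior, dirichletAlpha = dirichletAlpha,
      sdPatient = sdPatient, sdFocus = sdFocus, sdSample = sdSample,
      noiseSd = noiseSd, baselineHazard = baselineHazard, hrEpce = hrEpce,
      hrTasce = hrTasce, censoringMaxMonths = censoringMaxMonths,
      gleasonProbs = gleasonProbs, ptProbs = ptProbs,
      seed = as.integer(seed))
}

# per-subtype Dirichlet parameters over (7 cell types, epithelial); the
# planted directions: TCE elevates CD4/CD8 T cells, EPCE the epithelial
# component, TASCE macrophages/endothelial/CAFs
.defaultAlpha <- function() {
  rbind(
    TCE   = c(Bcells = 3, CD4_Tcells = 18, CD8_Tcells = 18, NKcells = 3,
              Macrophages = 4, Endothelial = 4, CAFs = 4, epithelial = 66),
    EPCE  = c(Bcells = 2, CD4_Tcells = 3, CD8_Tcells = 3, NKcells = 2,
              Macrophages = 3, Endothelial = 3, CAFs = 3, epithelial = 101),
    TASCE = c(Bcells = 3, CD4_Tcells = 4, CD8_Tcells = 4, NKcells = 3,
              Macrophages = 16, Endothelial = 14, CAFs = 20, epithelial = 56))
}

#' Default configuration for the multifocal heterogeneity study
#'
#' Mirrors the shape of a multisample prostatectomy series: 23 patients, 2-3
#' spatially separated foci each, 1-2 samples per focus (about 86 samples in
#' expectation). The cohort it emulates is a narrowly selected, clinically
#' homogeneous multifocal population, so patient baseline compositions are
#' drawn from one pooled high-concentration prior (the subtype-averaged
#' Dirichlet, concentration scaled up 200-fold) and the variance hierarchy
#' puts the dominant composition variance at the focus level
#' (\code{sdPatient} small, \code{sdSample} < \code{sdFocus}) — the regime
#' in which intrafocal similarity exceeds interfocal similarity while
#' interfocal and interpatient similarity are statistically comparable.
#'
#' @param seed Integer seed.
#' @return A \linkS4class{SimulationConfig}.
#' @export
multifocalDefaults <- function(seed = 1L) {
  a <- .defaultAlpha()
  pooled <- matrix(rep(colMeans(a) * 200, 3), nrow = 3, byrow = TRUE,
                   dimnames = dimnames(a))
  simulationConfig(nPatients = 23L, fociPerPatient = c(2L, 3L),
                   samplesPerFocus = c(1L, 2L), dirichletAlpha = pooled,
                   sdPatient = 0.02, sdFocus = 0.45, sdSample = 0.40,
                   noiseSd = 0.10, seed = seed)
}

#' Simulate a bulk-expression cohort with known ground truth
#'
#' Per patient: a subtype is drawn from the prior and a patient-level
#' composition from the subtype's Dirichlet; focus- and sample-level
#' compositions derive by centered-log-ratio Gaussian perturbation with the
#' configured nested scales. Bulk expression per sample is the reference
#' matrix augmented with an epithelial profile column times the sample's
#' proportion vector, with multiplicative log-normal gene noise, then
#' TPM-renormalized. Per patient, a biochemical-recurrence time is drawn
#' exponential with hazard \code{baselineHazard * HR[subtype]} (HR[TCE] = 1)
#' and censored at Uniform(0, \code{censoringMaxMonths}); Gleason and pT
#' categories are drawn from subtype-conditional multinomials. Fully
#' deterministic given \code{cfg@seed}.
#'
#' @param cfg A \linkS4class{SimulationConfig}.
#' @param ref A \linkS4class{ReferenceProfile}; defaults to
#'   \code{generateReference} with the config's shape and seed.
#' @return List with elements \code{expression} (genes x samples TPM matrix),
#'   \code{sampleMap}, \code{clinical} (data.frames), \code{truth}
#'   (\linkS4class{SyntheticTruth}) and \code{reference}.
#' @export
simulateCohort <- function(cfg, ref = NULL) {
  validObject(cfg)
  if (is.null(ref))
    ref <- generateReference(cfg@nSignatureGenesPerType, cfg@nBackgroundGenes,
                             seed = cfg@seed)
  validObject(ref)
  set.seed(cfg@seed)
  epi <- .epithelialProfile(ref)
  aug <- cbind(refMeans(ref), uncharacterized = epi)
  alpha <- cfg@dirichletAlpha
  hrBySubtype <- c(TCE = 1, EPCE = cfg@hrEpce, TASCE = cfg@hrTasce)

  sampleId <- character(); samplePatient <- character(); sampleFocus <- character()
  sampleSub <- character(); props <- list()
  patientId <- sprintf("P%03d", seq_len(cfg@nPatients))
  patientSub <- character(cfg@nPatients)
  patientLogHaz <- numeric(cfg@nPatients)
  time <- numeric(cfg@nPatients); event <- integer(cfg@nPatients)
  gleason <- character(cfg@nPatients); pt <- character(cfg@nPatients)
  age <- integer(cfg@nPatients)

  for (i in seq_len(cfg@nPatients)) {
    st <- sample(.SUBTYPES, 1L, prob = cfg@subtypePrior)
    patientSub[i] <- st
    pComp <- .clrPerturb(.rdirichlet(alpha[st, ]), cfg@sdPatient)
    nFoci <- .drawRange(cfg@fociPerPatient)
    for (f in seq_len(nFoci)) {
      fComp <- .clrPerturb(pComp, cfg@sdFocus)
      nS <- .drawRange(cfg@samplesPerFocus)
      for (s in seq_len(nS)) {
        sComp <- .clrPerturb(fComp, cfg@sdSample)
        sid <- sprintf("%s_F%d_S%d", patientId[i], f, s)
        sampleId <- c(sampleId, sid)
        samplePatient <- c(samplePatient, patientId[i])
        sampleFocus <- c(sampleFocus, sprintf("F%d", f))
        sampleSub <- c(sampleSub, st)
        props[[sid]] <- sComp
      }
    }
    lh <- log(cfg@baselineHazard) + log(hrBySubtype[st])
    patientLogHaz[i] <- lh
    tEvent <- rexp(1L, rate = exp(lh))
    tCens <- runif(1L, 0, cfg@censoringMaxMonths)
    time[i] <- max(min(tEvent, tCens), 1e-3)
    event[i] <- as.integer(tEvent <= tCens)
    gleason[i] <- sample(.GLEASON_LEVELS, 1L, prob = cfg@gleasonProbs[st, ])
    pt[i] <- sample(.PT_LEVELS, 1L, prob = cfg@ptProbs[st, ])
    age[i] <- as.integer(round(min(max(rnorm(1L, 61, 7), 40), 85)))
  }

  P <- do.call(rbind, props)
  colnames(P) <- colnames(aug)
  expr <- aug %*% t(P)                         # genes x samples, exact mixture
  if (cfg@noiseSd > 0)
    expr <- expr * exp(matrix(rnorm(length(expr), 0, cfg@noiseSd),
                              nrow = nrow(expr)))
  expr <- renormalizeTpm(expr)
  dimnames(expr) <- list(rownames(aug), sampleId)
  attr(expr, "unit") <- "tpm"

  sampleMap <- validateSampleMap(data.frame(
    sample_id = sampleId, patient_id = samplePatient, focus_id = sampleFocus,
    stringsAsFactors = FALSE))
  clinical <- validateClinical(data.frame(
    patient_id = patientId, followup_months = time, bcr_event = event,
    gleason_category = gleason, pt_category = pt, age = age,
    stringsAsFactors = FALSE))
  truth <- new("SyntheticTruth", proportions = P,
               sampleSubtype = setNames(sampleSub, sampleId),
               patientSubtype = setNames(patientSub, patientId),
               patientLogHazard = setNames(patientLogHaz, patientId),
               config = cfg)
  list(expression = expr, sampleMap = sampleMap, clinical = clinical,
       truth = truth, reference = ref)
}

#' Expected event fraction under the generator's survival model
#'
#' Analytic probability that the exponential event time precedes the uniform
#' censoring time, averaged over the subtype prior:
#' \eqn{P(T < C) = 1 - (1 - e^{-\lambda c}) / (\lambda c)} for
#' \eqn{T \sim Exp(\lambda)}, \eqn{C \sim U(0, c)}.
#'
#' @param cfg A \linkS4class{SimulationConfig}.
#' @return Expected fraction of patients with an observed event.
#' @export
expectedEventFraction <- function(cfg) {
  hr <- c(1, cfg@hrEpce, cfg@hrTasce)
  lam <- cfg@baselineHazard * hr
  cmax <- cfg@censoringMaxMonths
  pEv <- 1 - (1 - exp(-lam * cmax)) / (lam * cmax)
  sum(cfg@subtypePrior * pEv)
}

#' Write a simulated cohort to a directory
#'
#' Writes \code{expression.tsv}, \code{sample_map.tsv}, \code{clinical.tsv},
#' \code{truth.tsv} and \code{reference.tsv}.
#'
#' @param cohort Result of \code{\link{simulateCohort}}.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             sample_map = file.path(dir, "sample_map.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             truth = file.path(dir, "truth.tsv"),
             reference = file.path(dir, "reference.tsv"))
  writeExpression(cohort$expression, paths["expression"])
  writeTable(cohort$sampleMap, paths["sample_map"])
  writeTable(cohort$clinical, paths["clinical"])
  tr <- cohort$truth
  writeTable(data.frame(sample_id = rownames(tr@proportions), tr@proportions,
                        subtype = tr@sampleSubtype[rownames(tr@proportions)],
                        check.names = FALSE), paths["truth"])
  writeReference(cohort$reference, paths["reference"])
  invisible(paths)
}
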