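# tmeSubtyper

Bulk prostate-cancer RNA-seq carries a mixed signal from tumor cells and
their microenvironment: T and B lymphocytes, NK cells, macrophages,
endothelial cells and cancer-associated fibroblasts (CAFs). The fractional
make-up of that mixture — the cell-type composition — is itself a prognostic
biomarker: tumors enriched for T cells (TCE) behave more indolently, tumors
enriched for tumor-associated stromal cells (TASCE) recur earlier after
prostatectomy, with epithelial-cell-enriched tumors (EPCE) in between.

`tmeSubtyper` implements the full analysis path from a gene-by-sample TPM
matrix to those prognostic composition subtypes, for computational biologists
who want a tested, reproducible version of each stage:

1. **Deconvolution.** For each sample with expression vector *b* over the
   signature genes of a reference profile *R* (7 cell types), solve

   min<sub>x</sub> Σ<sub>g</sub> w<sub>g</sub> (b<sub>g</sub> − Σ<sub>c</sub> R<sub>gc</sub> x<sub>c</sub>)²  subject to x ≥ 0, Σ x<sub>c</sub> ≤ 1,

   with gene weights w<sub>g</sub> = 1/(variability<sub>g</sub> + ε). The
   remainder 1 − Σ x<sub>c</sub> is the "uncharacterized" fraction
   (predominantly malignant and benign epithelial cells). The small convex QP
   is solved exactly per sample by a primal active-set method.
2. **Subtype discovery.** Component-wise Z-standardization, then
   resampling consensus clustering with PAM (k medoids, Euclidean distance):
   the consensus of a sample pair is the fraction of co-sampled resamples in
   which it co-clustered. k is chosen from the relative change in the area
   under the consensus CDF, and the three clusters are named TCE / EPCE /
   TASCE from their enriched components.
3. **Classification.** A linear discriminant model (class means, pooled
   covariance, priors) trained on the labelled compositions transfers the
   subtypes to new cohorts; models serialize to versioned JSON.
4. **Multifocal heterogeneity.** Cosine similarity of Z-scored compositions
   for every sample pair, classified as intrafocal / interfocal /
   interpatient, compared with Wilcoxon rank-sum tests, plus subtype
   concordance within patients and foci.
5. **Outcome and clinicopathology.** Kaplan–Meier curves and log-rank tests
   for time to biochemical recurrence (BCR), univariable and multivariable
   Cox models (Efron ties, Wald intervals, Grambsch–Therneau proportional-
   hazards check), Harrell's concordance for nested models, chi-square
   cross-tabulations against Gleason grade and pT stage, and CAF-marker
   comparisons.

A synthetic cohort generator (`simulateCohort`) produces bulk expression as
convex mixtures of reference profiles with planted subtypes, nested
patient/focus/sample variance, exponential BCR times with subtype hazard
ratios, and subtype-correlated covariates — so every stage can be validated
against known ground truth.

## Worked example

```r
library(tmeSubtyper)

cfg     <- simulationConfig(nPatients = 120, seed = 42)
cohort  <- simulateCohort(cfg)
comp    <- deconvolveCohort(cohort$expression, cohort$reference)
#> deconvolving 120 sample(s) using 300/300 shared signature genes

round(head(proportions(comp), 3), 3)
#>            Bcells CD4_Tcells CD8_Tcells NKcells Macrophages Endothelial  CAFs uncharacterized
#> P001_F1_S1  0.052      0.088      0.210   0.006       0.032       0.039 0.030           0.544
#> P002_F1_S1  0.013      0.026      0.010   0.011       0.039       0.046 0.012           0.843
#> P003_F1_S1  0.050      0.167      0.142   0.024       0.018       0.083 0.045           0.470

z   <- zscore(comp)
res <- consensusCluster(z, kRange = 2:6, nResamples = 100, seed = 42)
res
#> ConsensusResult: k in {2, 3, 4, 5, 6}, 120 samples
#>   delta area: k=2: 0.437; k=3: 0.535; k=4: 0.076; k=5: 0.067; k=6: 0.052
selectK(res, policy = "delta-area")     # area gain collapses after k = 3
#> [1] 3

labeling <- assignSubtypeNames(clusterLabels(res, 3), z)
labeling
#> SubtypeLabeling: 120 ids (TCE: 40, EPCE: 44, TASCE: 36)

model  <- trainLda(comp, labeling)
patLab <- patientSubtypes(predictLda(model, comp)$labeling, cohort$sampleMap)
km     <- kmEstimate(cohort$clinical, subtypes(patLab))
km$logrank
#> log-rank chi-square 11.02 (df 2), p = 0.00404

coxFit(cohort$clinical, c("subtype", "gleason", "pt"), subtypeLabels = patLab)
#> Cox fit (efron ties): 120 subjects, 14 events; concordance 0.784
#>            term   coef     hr ci_lower ci_upper    se p_value
#> 1   subtypeEPCE  1.471  4.353    0.466    40.61 1.139  0.1968
#> 2  subtypeTASCE  2.579 13.182    1.422   122.17 1.136  0.0232
#> ...
```

The three delta-area values show the consensus structure saturating at
k = 3; the subtype labels then separate BCR risk (log-rank p ≈ 0.004), with
TASCE carrying the largest hazard ratio versus the TCE reference — the
qualitative pattern the subtyping is designed to expose.

The whole path (simulate or load → deconvolve → cluster → name → train →
predict → heterogeneity → survival → association) also runs as one call:

```r
runPipeline(list(outDir = "out", seed = 1, simulation = list(nPatients = 300)))
```

which writes every intermediate artifact (TSV/JSON) plus a checksummed
manifest; a rerun with the same configuration and seed is byte-identical. A
command-line wrapper lives at `inst/scripts/pipeline.R`
(`Rscript pipeline.R run --config cfg.yaml`).

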