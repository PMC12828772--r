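---
title: "Cell-type-composition subtyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type-composition subtyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery it
implements: the models and their assumptions, the parameters that matter and
their defaults, what the synthetic cohorts do and do not emulate, the
numerical choices, and the places where the design was genuinely open and a
decision had to be made.

## 1. The deconvolution model

Bulk expression is modelled as a convex mixture of cell-type-specific
profiles. For a sample with TPM vector $b$ over the reference's signature
genes, the seven cell-type proportions $x$ solve the constrained weighted
least-squares problem

$$\min_x \; \sum_g w_g \Big(b_g - \sum_c R_{gc}\,x_c\Big)^2
\qquad \text{s.t. } x \ge 0,\; \textstyle\sum_c x_c \le 1,$$

with $w_g = 1/(\mathrm{variability}_g + \varepsilon)$, $\varepsilon =
10^{-6}$, so that genes with unstable reference expression count less. The
slack $1 - \sum_c x_c$ is reported as the *uncharacterized* component and
interpreted as the epithelial/malignant compartment. The identifying
assumption, inherited from reference-based deconvolution generally, is that
this compartment does not express the immune/stromal signature genes; genes
it does express contribute a constant to the objective and do not bias $x$.

**Solver.** The problem is a tiny convex QP (7 unknowns, 1–2 active
constraints typically). A primal active-set method solves it exactly: start
at $x = 0$ with all bounds active, repeatedly solve the equality-constrained
subproblem on the free set (with the $\sum x = 1$ face handled through a KKT
system when active), step to the first blocking constraint, and drop the
constraint with the most negative multiplier until all multipliers are
non-negative (tolerance $10^{-10}$ on the scaled problem). Active-set QP
terminates finitely, so the result is exact up to linear-solve precision —
the test suite verifies agreement with exhaustive grid search at step
$10^{-3}$ and exact recovery ($\le 10^{-6}$, in practice $\sim 10^{-16}$) of
noiseless synthetic mixtures.

**Options.** Genes absent from the bulk matrix are dropped; an overlap below
80% of the reference genes (configurable) is an error, not a warning —
silently fitting a fraction of a signature is how deconvolution goes wrong
quietly. An optional per-component mRNA-content scaling converts mRNA
fractions to cell fractions (divide by per-cell mRNA content, renormalize);
it is off by default because published analyses of this kind do not always
state which output convention they used, and the unscaled fit is the
better-defined quantity.

## 2. Subtype discovery

Proportions are Z-transformed *per component across samples* (sample sd,
ddof 1). The alternative reading — standardizing each sample across its
eight components — would erase exactly the between-sample differences the
clustering is meant to find; the feature-wise convention also matches the
interpretation of "scaled proportions" per cell type and is reused
unchanged by the heterogeneity analysis, so clustering and similarity share
one standardization. Constant columns are zeroed and flagged rather than
producing NaNs.

Consensus clustering: for each candidate $k$, subsample 80% of samples
without replacement `nResamples` times (default 1000; 250 in the bundled
studies, which is where the consensus estimates stabilize at these cohort
sizes), run PAM (build + swap, Euclidean distance on Z rows), and record
co-membership. Consensus$(i,j)$ = co-clustered / co-sampled; pairs never
co-sampled (flagged; essentially impossible at the default fraction and
resample counts) get 0. Final labels per $k$ come from average-linkage
hierarchical clustering of $1 - $ consensus — the convention of the
reference implementations of consensus clustering — so the labels summarize
the consensus matrix itself rather than any single PAM run.

**Choosing k.** The area $A(k)$ under the CDF of off-diagonal consensus
values increases with $k$; the chosen $k$ is the largest whose relative
increase $(A(k)-A(k-1))/A(k-1)$ still exceeds 0.1 — equivalently, the
smallest $k$ beyond which the profile flattens. Delta-area alone cannot
recognize structureless data (for a single Gaussian blob the area keeps
growing appreciably for several $k$), so the choice is vetted with the
proportion of ambiguous consensus entries (PAC: entries in $(0.1, 0.9)$) at
the chosen $k$: well-separated structure sits near 0 (about 0.03 on the
planted cohorts), a blob near 0.5; above the 0.3 limit no $k$ is considered
strongly supported and `min(kRange)` is returned with a low-confidence
flag. A `fixed` policy returns a configured $k$ regardless, which is the
operative choice (k = 3) in the end-to-end pipeline; the delta-area result
is still recorded alongside.

**Naming.** With three clusters, per-cluster mean Z per component determines
the names: TCE maximizes the mean of the CD4/CD8 T-cell components, EPCE the
uncharacterized component, TASCE the mean of CAFs, endothelial cells and
macrophages. If two criteria point at one cluster, assignment proceeds
greedily by score margin with a warning — degenerate compositions should be
visible, not silently resolved.

## 3. The linear discriminant classifier

Training is closed-form: class means, pooled covariance $\Sigma = \sum_c
\sum_{i \in c}(x_i-\mu_c)(x_i-\mu_c)^\top/(N-3)$, priors defaulting to
empirical frequencies. Because the eight features sum to one, $\Sigma$ is
singular by construction; a ridge of $10^{-8}\,\mathrm{tr}(\Sigma)/8$ is
added (escalating tenfold if needed) and recorded in the model for audit.
Prediction uses the linear discriminant $\delta_c(x) = x^\top\Sigma^{-1}\mu_c
- \tfrac12 \mu_c^\top\Sigma^{-1}\mu_c + \log\pi_c$ with softmax posteriors
and deterministic class-order tie-breaking. The features are *raw*
proportions, not Z-scores: cross-cohort prediction with per-cohort
standardization would make the feature space depend on the cohort being
predicted, which is ill-defined for a frozen classifier. Tests verify exact
agreement with a brute-force shared-covariance Gaussian Bayes rule and
$\ge 0.9$ accuracy on independently seeded validation cohorts.

Models serialize to versioned JSON at 17 significant digits — the minimum
that round-trips IEEE doubles exactly, so a restored model predicts
bit-identically.

## 4. Multifocal heterogeneity

Every unordered sample pair is classified intrafocal (same focus),
interfocal (same patient, different foci) or interpatient, and scored with
the cosine similarity of the samples' Z-rows (clamped to $[-1,1]$ against
floating-point overshoot; Z-rows can be negative, so cosine can be too).
Group comparisons use the two-sided Wilcoxon rank-sum test with normal
approximation, tie and continuity correction, reported unadjusted across
the three comparisons. A caveat stated here deliberately: pair similarities
sharing a sample or a focus are dependent, so the rank-sum test is
anticonservative for these comparisons — simulations under exact
exchangeability show roughly 20% rejection at nominal 5%. The package
reports the tests as the field uses them; the simulation studies account
for the inflation by checking the *pattern frequency* across seeds rather
than a single p-value.

## 5. Survival and association analyses

Kaplan–Meier estimation, the log-rank test, Cox fitting, Harrell's
concordance and the Grambsch–Therneau proportional-hazards check are
delegated to the `survival` package behind this module's interface; these
are standard fits, and re-deriving them would add risk without insight.
Fixed choices: Efron tie handling (Breslow behind a flag), Wald 95%
intervals ($\exp(\hat\beta \pm 1.96\,\mathrm{se})$), reference levels TCE /
low-grade / T2, complete-case analysis with a logged exclusion count, and
the event-time *rank* transform for the PH check. The "number at risk < 5"
truncation exists only as a plotting flag on the curve points; tests never
see it. A fit whose coefficient diverges past $|20|$ (complete separation)
or returns NA is an error with guidance; inside the end-to-end pipeline a
non-estimable model is recorded and skipped rather than aborting the run,
because a sparse reference arm is a property of the cohort, not a failure
of the pipeline.

Cross-tabulations use Pearson chi-square without continuity correction and
flag expected counts below 5. Marker comparisons test $\log_2(x+1)$
expression with the same Wilcoxon variant as the heterogeneity module;
unadjusted p-values are primary (per-marker presentation), with a
Benjamini–Hochberg column emitted alongside, clearly labelled.

## 6. The synthetic cohort generator

The generator exists so that every stage has ground truth. Its structure:

* **Reference** (`generateReference`): 30 signature genes per cell type with
  log-normal own-type means and 0.5–5% cross-expression in the other
  immune/stromal profiles, plus 90 background genes expressed only by the
  epithelial compartment; every profile column is TPM-scaled. Identifiability
  (each type has a uniquely maximal gene) is enforced by a validity method.
* **Compositions**: each patient draws a subtype and a patient-level
  composition from that subtype's Dirichlet prior over the 8 components;
  focus- and sample-level compositions derive by additive Gaussian
  perturbation in centered-log-ratio space (scales `sdPatient`, `sdFocus`,
  `sdSample`) mapped back through softmax — positivity and sum-one are
  preserved by construction, and the nested scales give tunable
  patient/focus/sample variance.
* **Expression**: reference-plus-epithelial profile matrix times the
  proportion vector, times per-gene log-normal noise (`noiseSd`, default
  0.1), then TPM renormalization. With all noise off, samples are exact
  convex mixtures.
* **Outcome**: per-patient BCR time $\sim$ Exponential(baselineHazard
  $\times$ HR[subtype]) with HR(TCE) = 1, HR(EPCE) = 5.3, HR(TASCE) = 10.9,
  censored at Uniform(0, 120 months). With the default baseline hazard of
  $4.3\times10^{-4}$ per month this gives an analytic event fraction of
  12.9% — the regime of a prostatectomy cohort of ~400 patients with ~50
  biochemical recurrences. `expectedEventFraction()` exposes the closed
  form, and a test checks it against numeric integration and the empirical
  rate at n = 5000.
* **Covariates**: Gleason and pT categories from subtype-conditional
  multinomials that make TASCE high-grade/high-stage-enriched and TCE
  low-grade/low-stage-enriched.

**Default calibration.** The literature this emulates reports qualitative
orderings, not effect sizes for composition differences, so the Dirichlet
defaults were calibrated once to produce three well-separated but
overlapping subtypes (concentration ~120 per subtype, epithelial-dominated
means of roughly 55–77% uncharacterized) under a balanced subtype prior —
cluster prevalences are not reported for the cohorts emulated, and a
neutral prior is the defensible default. The TCGA-like default cohort is
405 patients, one sample each.

`multifocalDefaults()` describes a different population: 23 patients from a
narrowly selected multifocal series, 2–3 foci each, 1–2 samples per focus.
Here patient baselines come from a single pooled high-concentration prior
and the variance hierarchy is `sdPatient` (0.02) $\ll$ `sdSample` (0.40)
$<$ `sdFocus` (0.45): the observed similarity pattern this reproduces —
intrafocal similarity clearly highest, interfocal statistically
indistinguishable from interpatient — *implies* that patient identity adds
almost nothing beyond focal variation, so the generator encodes exactly
that regime. Sample-level noise is kept close to the focal scale because
the dependent rank-sum test of Section 4 otherwise over-rejects the
interfocal-vs-interpatient null even when it holds exactly.

**What the generator does not emulate**: real gene-level count
distributions (library-size effects, over-dispersion beyond log-normal
noise), epithelial expression of immune signature genes (spill-over that
biases real deconvolution), batch and FFPE artefacts, informative
censoring, and correlations between composition and covariates beyond the
planted subtype channel. Passing tests therefore demonstrate correctness of
the *algorithms* under the stated model, not robustness of the biology on
any particular real cohort.

## 7. Simulation-study conventions

The bundled studies (test suite and `scripts/acceptance.R`) use fixed
problem sizes chosen where the Monte-Carlo estimates stabilize: planted
clustering at n = 300 samples with 250 resamples; noisy-recovery error over
100 samples; heterogeneity ordering over 50 seeds of the multifocal
configuration; hazard-ratio recovery over 50 replicates of the 405-patient
cohort. In the Cox study, replicates whose TCE reference arm has fewer than
two events are excluded as non-estimable — with an expected ~3.5 reference
events, such replicates occur regularly and their finite but heavy-tailed
estimates would dominate a 50-replicate mean; the exclusion count is
reported alongside the estimates. Complete-separation fits (a diverging or
undetermined coefficient) are likewise excluded and counted.

## 8. Degenerate inputs and numerical conventions

* All-zero expression columns, unknown category vocabulary, duplicate ids,
  non-positive follow-up: errors naming the offending row or column.
* Duplicate gene ids: collapsed by summation at load, by design.
* TPM renormalization tolerance $10^{-9}$; idempotent.
* Composition simplex tolerance $10^{-9}$ (deconvolution output), truth
  simplex $10^{-12}$ (generator).
* PAM tie behavior is deterministic in the underlying implementation; all
  stochastic steps run through a single seed argument, and the pipeline
  reruns byte-identically for a fixed configuration and seed.
* Consensus entries never co-sampled default to 0 with a message; at the
  default resample counts this does not occur.

## 9. Known limitations

* The reference profile ships synthetic; analyses of real cohorts need a
  real signature matrix (the TSV format is documented in
  `?loadReference`), and results inherit its quality.
* The heterogeneity tests are anticonservative under pair dependence (see
  Section 4); interpret single-cohort p-values accordingly.
* The classifier is plain LDA on 8 features by design — no feature
  selection, no nonlinearity; with compositions this simple, more complex
  models mostly add variance.
* Survival modelling is limited to right-censored single-event BCR with
  categorical covariates; no competing risks, no time-varying effects.
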