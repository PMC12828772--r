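## End-to-end orchestration: simulate or load a cohort, deconvolve, cluster,
## name subtypes, train/apply the classifier, quantify heterogeneity, run the
## survival and clinicopathological associations, and write every artifact
## with a checksummed manifest.

#' Patient-level subtype from sample-level labels
#'
#' Majority vote of a patient's sample subtypes; ties break in the order
#' TCE, EPCE, TASCE.
#'
#' @param labeling Sample-level \linkS4class{SubtypeLabeling}.
#' @param map Sample map covering the labelled samples.
#' @return Patient-level \linkS4class{SubtypeLabeling}.
#' @export
patientSubtypes <- function(labeling, map) {
  st <- subtypes(labeling)
  m <- map[map$sample_id %in% names(st), , drop = FALSE]
  byPat <- split(st[m$sample_id], m$patient_id)
  vote <- vapply(byPat, function(x) {
    tab <- table(factor(x, levels = .SUBTYPES))
    names(tab)[which.max(tab)]
  }, character(1))
  new("SubtypeLabeling", ids = names(vote), subtype = unname(vote),
      clusterToName = character(0), enrichment = matrix(numeric(0), 0, 0))
}

.defaultPipelineConfig <- function() {
  list(seed = 1L,
       deconvolution = list(overlapThreshold = 0.8, mrnaScaling = NULL),
       clustering = list(kRange = 2:6, nResamples = 250L,
                         subsampleFraction = 0.8, kPolicy = "fixed",
                         fixedK = 3L, threshold = 0.1),
       survivalSets = list(gleason = "gleason",
                           `gleason+pt` = c("gleason", "pt"),
                           `gleason+subtype` = c("gleason", "subtype"),
                           `gleason+pt+subtype` = c("gleason", "pt", "subtype"),
                           subtype = "subtype"),
       markers = NULL)
}

.mergeConfig <- function(defaults, cfg) {
  for (nm in names(cfg)) {
    if (is.list(cfg[[nm]]) && is.list(defaults[[nm]]) &&
        !is.null(names(cfg[[nm]])))
      defaults[[nm]] <- .mergeConfig(defaults[[nm]], cfg[[nm]])
    else defaults[[nm]] <- cfg[[nm]]
  }
  defaults
}

#' Load a pipeline configuration from YAML
#'
#' The YAML mirrors the configuration list accepted by
#' \code{\link{runPipeline}}: either a \code{simulation} block (fields of
#' \code{\link{simulationConfig}}) or an \code{inputs} block (paths to
#' \code{expression}, \code{clinical}, \code{sample_map}, \code{reference},
#' plus \code{unit}), with optional \code{deconvolution},
#' \code{clustering}, \code{survivalSets}, \code{markers}, \code{seed} and
#' \code{outDir} entries.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
pipelineConfigFromYaml <- function(path) {
  yaml::read_yaml(path)
}

#' Run the full composition-subtyping pipeline
#'
#' Stages, in order: (1) simulate a cohort or load input files; (2)
#' deconvolve bulk expression into the 8-component composition; (3)
#' Z-standardize and consensus-cluster; (4) select k and, at k = 3, name the
#' clusters TCE/EPCE/TASCE; (5) train the LDA classifier on the named labels
#' and re-predict the cohort; (6) if any patient has multiple samples,
#' quantify interpatient/interfocal/intrafocal heterogeneity and subtype
#' concordance; (7) Kaplan-Meier + log-rank, univariable and multivariable
#' Cox models and the nested-model concordance comparison; (8) subtype vs
#' Gleason and pT cross-tabulations and marker comparisons. Every artifact
#' is written to \code{config$outDir} and listed in a manifest with md5
#' checksums; a rerun with the same configuration and seed reproduces
#' identical checksums.
#'
#' @param config Configuration list: \code{outDir}, \code{seed}, exactly one
#'   of \code{simulation} (a \linkS4class{SimulationConfig} or argument list
#'   for \code{\link{simulationConfig}}) or \code{inputs} (file paths), and
#'   optional \code{deconvolution}, \code{clustering}, \code{survivalSets},
#'   \code{markers} blocks (see \code{\link{pipelineConfigFromYaml}}).
#' @return Invisibly, a list with the \code{manifest} \code{data.frame}
#'   (file, stage, md5 — also written as \code{manifest.json}) and the main
#'   stage results (\code{composition}, \code{consensus}, \code{labeling},
#'   \code{model}, \code{predicted}, \code{heterogeneity}, \code{survival},
#'   \code{association}, \code{cohort}, \code{chosenK}).
#' @export
runPipeline <- function(config) {
  cfg <- .mergeConfig(.defaultPipelineConfig(), config)
  if (is.null(cfg$outDir)) stop("config$outDir is required")
  hasSim <- !is.null(cfg$simulation); hasInp <- !is.null(cfg$inputs)
  if (hasSim == hasInp)
    stop("config must contain exactly one of 'simulation' or 'inputs'")
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(file = character(), stage = character(),
                         stringsAsFactors = FALSE)
  addArtifact <- function(path, stage) {
    manifest <<- rbind(manifest,
                       data.frame(file = basename(path), stage = stage,
                                  stringsAsFactors = FALSE))
    path
  }
  runStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## stage 1: inputs
  cohort <- runStage("input", {
    if (hasSim) {
      simCfg <- cfg$simulation
      if (!is(simCfg, "SimulationConfig")) {
        if (is.null(simCfg$seed)) simCfg$seed <- cfg$seed
        simCfg <- do.call(simulationConfig, simCfg)
      }
      co <- simulateCohort(simCfg)
      for (p in writeCohort(co, cfg$outDir)) addArtifact(p, "input")
      co
    } else {
      inp <- cfg$inputs
      expr <- loadExpression(inp$expression,
                             unit = if (is.null(inp$unit)) "tpm" else inp$unit)
      if (attr(expr, "unit") != "tpm") expr <- renormalizeTpm(expr)
      list(expression = expr,
           sampleMap = loadSampleMap(inp$sample_map),
           clinical = loadClinical(inp$clinical),
           reference = loadReference(inp$reference), truth = NULL)
    }
  })

  ## stage 2: deconvolution
  comp <- runStage("deconvolution", {
    cm <- deconvolveCohort(cohort$expression, cohort$reference,
                           overlapThreshold = cfg$deconvolution$overlapThreshold,
                           mrnaScaling = cfg$deconvolution$mrnaScaling)
    writeComposition(cm, addArtifact(file.path(cfg$outDir, "composition.tsv"),
                                     "deconvolution"))
    cm
  })

  ## stage 3: standardization + consensus clustering
  cl <- cfg$clustering
  z <- runStage("zscore", zscore(comp))
  cons <- runStage("consensus", {
    res <- consensusCluster(z, kRange = cl$kRange,
                            nResamples = cl$nResamples,
                            subsampleFraction = cl$subsampleFraction,
                            seed = cfg$seed)
    for (k in res@kValues) {
      p <- addArtifact(file.path(cfg$outDir, sprintf("consensus_k%d.tsv", k)),
                       "consensus")
      write.table(format(as.data.frame(consensusMatrix(res, k)), digits = 17,
                         trim = TRUE, scientific = FALSE),
                  p, sep = "\t", quote = FALSE)
    }
    labdf <- data.frame(sample_id = rownames(zValues(z)))
    for (k in res@kValues)
      labdf[[sprintf("k%d", k)]] <- unname(clusterLabels(res, k))
    writeTable(labdf, addArtifact(file.path(cfg$outDir, "labels.tsv"),
                                  "consensus"))
    res
  })

  ## stage 4: k selection + subtype naming
  chosenK <- runStage("selectK",
    selectK(cons, policy = cl$kPolicy, threshold = cl$threshold,
            fixedK = cl$fixedK))
  deltaK <- selectK(cons, policy = "delta-area", threshold = cl$threshold)
  labeling <- runStage("naming", {
    if (chosenK != 3L)
      stop("subtype naming requires k = 3 (chosen k = ", chosenK, ")")
    lb <- assignSubtypeNames(clusterLabels(cons, 3L), z)
    writeSubtypes(lb, addArtifact(file.path(cfg$outDir, "subtypes.tsv"),
                                  "naming"),
                  clusters = clusterLabels(cons, 3L))
    lb
  })

  ## stage 5: classifier
  model <- runStage("train", {
    md <- trainLda(comp, labeling)
    saveLdaModel(md, addArtifact(file.path(cfg$outDir, "model.json"), "train"))
    md
  })
  predicted <- runStage("predict", {
    pr <- predictLda(model, comp)
    writeSubtypes(pr$labeling,
                  addArtifact(file.path(cfg$outDir, "predicted.tsv"),
                              "predict"))
    pr
  })

  ## stage 6: heterogeneity (multisample cohorts only)
  multisample <- any(table(cohort$sampleMap$patient_id) > 1)
  heterogeneity <- NULL
  if (multisample) {
    heterogeneity <- runStage("heterogeneity", {
      pairs <- pairSimilarities(z, cohort$sampleMap)
      writeTable(pairs, addArtifact(file.path(cfg$outDir, "pairs.tsv"),
                                    "heterogeneity"))
      tests <- comparePairGroups(pairs)
      writeTable(tests, addArtifact(file.path(cfg$outDir, "similarity_tests.tsv"),
                                    "heterogeneity"))
      conc <- subtypeConcordance(predicted$labeling, cohort$sampleMap)
      writeTable(conc$patients,
                 addArtifact(file.path(cfg$outDir, "concordance_patients.tsv"),
                             "heterogeneity"))
      writeTable(conc$foci,
                 addArtifact(file.path(cfg$outDir, "concordance_foci.tsv"),
                             "heterogeneity"))
      list(pairs = pairs, tests = tests, concordance = conc)
    })
  }

  ## stage 7: survival
  survivalRes <- runStage("survival", {
    patLabels <- patientSubtypes(predicted$labeling, cohort$sampleMap)
    clin <- cohort$clinical[cohort$clinical$patient_id %in%
                              sampleIds(patLabels), , drop = FALSE]
    km <- kmEstimate(clin, subtypes(patLabels))
    writeTable(km$curves, addArtifact(file.path(cfg$outDir, "km_curves.tsv"),
                                      "survival"))
    # a non-estimable model (e.g. a reference arm without usable events) is
    # a reportable outcome of the cohort, not a pipeline failure
    safeCox <- function(covs) tryCatch(
      suppressWarnings(coxFit(clin, covs, subtypeLabels = patLabels)),
      error = function(e) {
        message("Cox model [", paste(covs, collapse = "+"),
                "] not estimable: ", conditionMessage(e))
        NULL
      })
    uni <- Filter(Negate(is.null),
                  setNames(lapply(c("subtype", "gleason", "pt"), safeCox),
                           c("subtype", "gleason", "pt")))
    uniTab <- if (length(uni))
      do.call(rbind, lapply(names(uni), function(nm)
        cbind(model = nm, uni[[nm]]$terms)))
    else data.frame(model = character(), term = character())
    writeTable(uniTab, addArtifact(file.path(cfg$outDir, "cox_univariable.tsv"),
                                   "survival"))
    multi <- safeCox(c("subtype", "gleason", "pt"))
    if (!is.null(multi)) {
      writeTable(cbind(model = "subtype+gleason+pt", multi$terms),
                 addArtifact(file.path(cfg$outDir, "cox_multivariable.tsv"),
                             "survival"))
      writeTable(phTest(multi),
                 addArtifact(file.path(cfg$outDir, "ph_test.tsv"), "survival"))
    }
    mc <- tryCatch(
      modelComparison(clin, cfg$survivalSets, subtypeLabels = patLabels),
      error = function(e) {
        message("model comparison skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(mc))
      writeTable(mc, addArtifact(file.path(cfg$outDir, "model_concordance.tsv"),
                                 "survival"))
    list(km = km, univariable = uni, multivariable = multi, comparison = mc,
         patientLabels = patLabels, clinical = clin)
  })

  ## stage 8: clinicopathological association
  association <- runStage("association", {
    patLabels <- survivalRes$patientLabels
    clin <- survivalRes$clinical
    gl <- crosstabSubtype(patLabels,
                          setNames(clin$gleason_category, clin$patient_id))
    pt <- crosstabSubtype(patLabels,
                          setNames(clin$pt_category, clin$patient_id))
    writeTable(as.data.frame(gl$counts),
               addArtifact(file.path(cfg$outDir, "crosstab_gleason.tsv"),
                           "association"))
    writeTable(as.data.frame(pt$counts),
               addArtifact(file.path(cfg$outDir, "crosstab_pt.tsv"),
                           "association"))
    markers <- cfg$markers
    if (is.null(markers)) {
      markers <- grep("^CAFs_sig_", rownames(cohort$expression), value = TRUE)
      if (length(markers) == 0) markers <- CAF_MARKERS
    }
    mk <- tryCatch(markerComparison(cohort$expression, predicted$labeling,
                                    markers = markers),
                   error = function(e) NULL)
    if (!is.null(mk))
      writeTable(mk, addArtifact(file.path(cfg$outDir, "markers.tsv"),
                                 "association"))
    list(gleason = gl, pt = pt, markers = mk)
  })

  ## summary + manifest
  summaryPath <- addArtifact(file.path(cfg$outDir, "summary.json"), "summary")
  jsonlite::write_json(list(
    n_samples = ncol(cohort$expression),
    n_patients = length(unique(cohort$sampleMap$patient_id)),
    chosen_k = as.integer(chosenK),
    delta_area_k = as.integer(deltaK),
    delta_area_low_confidence = isTRUE(attr(deltaK, "lowConfidence")),
    logrank_p = survivalRes$km$logrank$p_value,
    multivariable_concordance = if (is.null(survivalRes$multivariable)) NA
                                else survivalRes$multivariable$concordance),
    summaryPath, digits = NA, auto_unbox = TRUE)

  manifest$md5 <- unname(tools::md5sum(file.path(cfg$outDir, manifest$file)))
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       digits = NA)
  invisible(list(manifest = manifest, composition = comp, consensus = cons,
                 labeling = labeling, model = model, predicted = predicted,
                 heterogeneity = heterogeneity, survival = survivalRes,
                 association = association, cohort = cohort,
                 chosenK = chosenK))
}
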