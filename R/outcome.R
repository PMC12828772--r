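## Time-to-biochemical-recurrence analysis: Kaplan-Meier curves with log-rank
## tests, Cox proportional-hazards fits (Efron ties, Wald intervals),
## Harrell's concordance, a Grambsch-Therneau proportional-hazards check,
## and nested-model concordance comparison. Model fitting is delegated to
## the survival package behind this module surface.

.covariateColumn <- function(clinical, covariate, subtypeLabels = NULL) {
  switch(covariate,
    subtype = {
      if (is.null(subtypeLabels))
        stop("covariate 'subtype' needs a SubtypeLabeling")
      st <- subtypes(subtypeLabels)[clinical$patient_id]
      factor(st, levels = .SUBTYPES)
    },
    gleason = factor(clinical$gleason_category, levels = .GLEASON_LEVELS),
    pt = factor(clinical$pt_category, levels = .PT_LEVELS),
    stop("unknown covariate '", covariate,
         "'; supported: subtype, gleason, pt"))
}

.referenceLevel <- function(covariate) {
  switch(covariate, subtype = "TCE", gleason = "low", pt = "T2")
}

# assemble the complete-case model frame for the requested covariates
.modelFrame <- function(clinical, covariates, subtypeLabels = NULL) {
  df <- data.frame(time = clinical$followup_months,
                   event = clinical$bcr_event)
  for (cv in covariates) {
    col <- .covariateColumn(clinical, cv, subtypeLabels)
    df[[cv]] <- droplevels(stats::relevel(col, ref = .referenceLevel(cv)))
  }
  keep <- stats::complete.cases(df)
  if (any(!keep))
    message(sum(!keep), " patient(s) excluded for missing covariate values")
  df[keep, , drop = FALSE]
}

#' Kaplan-Meier curves per group with a log-rank test
#'
#' Product-limit survival estimates per group plus the k-group log-rank
#' chi-square test (k - 1 degrees of freedom). The "number at risk < 5"
#' truncation used for plotting is reported as a flag per point and never
#' affects the test.
#'
#' @param clinical Validated clinical table.
#' @param groups Factor or character vector aligned with
#'   \code{clinical$patient_id} (or a named vector keyed by patient id).
#' @return List with \code{curves} (\code{data.frame}: group, time, n_risk,
#'   n_event, survival, truncated) and \code{logrank} (\code{chisq},
#'   \code{df}, \code{p_value}). For a single group \code{logrank} is
#'   \code{NULL}.
#' @export
kmEstimate <- function(clinical, groups) {
  if (!is.null(names(groups))) groups <- groups[clinical$patient_id]
  groups <- factor(groups)
  if (length(groups) != nrow(clinical))
    stop("groups must align with the clinical table")
  if (any(table(groups) == 0) || anyNA(groups))
    stop("every group needs >= 1 subject")
  df <- data.frame(time = clinical$followup_months,
                   event = clinical$bcr_event, group = groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strata <- if (is.null(fit$strata)) setNames(length(fit$time),
                                              paste0("group=", levels(groups)[1]))
            else fit$strata
  curves <- data.frame(
    group = rep(sub("^group=", "", names(strata)), strata),
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    survival = fit$surv, stringsAsFactors = FALSE)
  curves$truncated <- curves$n_risk < 5
  logrank <- NULL
  if (nlevels(groups) > 1) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
    dfree <- nlevels(groups) - 1L
    logrank <- list(chisq = unname(sd$chisq), df = dfree,
                    p_value = pchisq(sd$chisq, dfree, lower.tail = FALSE))
  }
  list(curves = curves, logrank = logrank)
}

#' Cox proportional-hazards fit with categorical covariates
#'
#' Fits a Cox model on the requested categorical covariates with fixed
#' reference levels (subtype: TCE, Gleason: low, pT: T2) using the Efron
#' method for ties (Breslow behind \code{ties}). Reports, per non-reference
#' level: the log-hazard coefficient, hazard ratio, Wald 95\% CI and Wald
#' p-value; plus the partial log-likelihood, Harrell's concordance of the
#' fitted linear predictor, and the Grambsch-Therneau proportional-hazards
#' p-values. Complete-case analysis with a logged exclusion count.
#'
#' @param clinical Validated clinical table.
#' @param covariates Subset of \code{c("subtype", "gleason", "pt")}.
#' @param subtypeLabels Patient-level \linkS4class{SubtypeLabeling} (needed
#'   when \code{"subtype"} is a covariate).
#' @param ties \code{"efron"} (default) or \code{"breslow"}.
#' @return Object of class \code{"tmeSurvivalFit"}: a list with
#'   \code{terms} (coefficient table), \code{logLik}, \code{concordance},
#'   \code{phTest}, \code{n}, \code{nEvents} and the underlying
#'   \code{coxph} fit.
#' @export
coxFit <- function(clinical, covariates, subtypeLabels = NULL,
                   ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  df <- .modelFrame(clinical, covariates, subtypeLabels)
  if (sum(df$event) < 1) stop("Cox fit requires >= 1 event")
  fm <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fm, data = df, ties = ties,
                         control = survival::coxph.control(eps = 1e-10,
                                                           iter.max = 100))
  if (anyNA(stats::coef(fit)))
    stop("Cox coefficient undetermined (a covariate level with no subjects ",
         "or no usable events)")
  if (any(abs(stats::coef(fit)) > 20))
    stop("diverging coefficient (|coef| > 20): likely complete separation; ",
         "consider pooling sparse categories")
  sm <- summary(fit)
  co <- sm$coefficients
  terms <- data.frame(
    term = rownames(co), coef = co[, "coef"], hr = co[, "exp(coef)"],
    ci_lower = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
    ci_upper = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
    se = co[, "se(coef)"], p_value = co[, "Pr(>|z|)"],
    stringsAsFactors = FALSE)
  rownames(terms) <- NULL
  ph <- tryCatch(phTestInternal(fit), error = function(e) NULL)
  structure(list(terms = terms, logLik = unname(fit$loglik[2]),
                 concordance = unname(fit$concordance["concordance"]),
                 phTest = ph, n = nrow(df), nEvents = sum(df$event),
                 covariates = covariates, ties = ties, coxph = fit),
            class = "tmeSurvivalFit")
}

#' @export
print.tmeSurvivalFit <- function(x, ...) {
  cat(sprintf("Cox fit (%s ties): %d subjects, %d events; concordance %.3f\n",
              x$ties, x$n, x$nEvents, x$concordance))
  print(x$terms, digits = 3)
  invisible(x)
}

phTestInternal <- function(fit) {
  zp <- survival::cox.zph(fit, transform = "rank")
  data.frame(term = rownames(zp$table), chisq = zp$table[, "chisq"],
             df = zp$table[, "df"], p_value = zp$table[, "p"],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Proportional-hazards check (Grambsch-Therneau)
#'
#' Correlates scaled Schoenfeld residuals with the rank of event time;
#' reports a chi-square p-value per term and globally.
#'
#' @param fit A \code{"tmeSurvivalFit"} from \code{\link{coxFit}}.
#' @return \code{data.frame} with \code{term}, \code{chisq}, \code{df},
#'   \code{p_value}; the last row is \code{GLOBAL}.
#' @export
phTest <- function(fit) {
  if (!inherits(fit, "tmeSurvivalFit")) stop("fit must come from coxFit()")
  if (fit$nEvents < 2) stop("proportional-hazards check requires >= 2 events")
  phTestInternal(fit$coxph)
}

#' Harrell's concordance index
#'
#' Probability that, among pairs whose event ordering is distinguishable
#' under censoring, the higher risk score belongs to the subject with the
#' earlier event; tied scores credit 0.5.
#'
#' @param riskScores Numeric risk scores aligned with the clinical rows
#'   (higher = higher risk).
#' @param clinical Validated clinical table.
#' @return Concordance in [0, 1].
#' @export
concordanceIndex <- function(riskScores, clinical) {
  if (length(riskScores) != nrow(clinical))
    stop("riskScores must align with the clinical table")
  df <- data.frame(time = clinical$followup_months,
                   event = clinical$bcr_event, score = riskScores)
  cc <- survival::concordance(survival::Surv(time, event) ~ score,
                              data = df, reverse = TRUE)
  counts <- cc$count
  permissible <- counts["concordant"] + counts["discordant"] +
    counts["tied.x"]
  if (!is.finite(cc$concordance) || permissible == 0)
    stop("no permissible pairs (censoring leaves no comparable pairs)")
  unname(cc$concordance)
}

#' Concordance of nested Cox models
#'
#' Fits a Cox model per requested covariate set and tabulates Harrell's
#' concordance, mirroring the incremental-value comparison of
#' Gleason-only vs Gleason + pT vs Gleason + subtype models.
#'
#' @param clinical Validated clinical table.
#' @param covariateSets Named list of covariate character vectors.
#' @param subtypeLabels Patient-level \linkS4class{SubtypeLabeling} if any
#'   set includes \code{"subtype"}.
#' @return \code{data.frame} with \code{model}, \code{covariates},
#'   \code{concordance}, \code{n}, \code{n_events}.
#' @export
modelComparison <- function(clinical, covariateSets, subtypeLabels = NULL) {
  if (is.null(names(covariateSets)))
    names(covariateSets) <- vapply(covariateSets, paste, character(1),
                                   collapse = "+")
  out <- lapply(names(covariateSets), function(nm) {
    fit <- coxFit(clinical, covariateSets[[nm]], subtypeLabels)
    data.frame(model = nm,
               covariates = paste(covariateSets[[nm]], collapse = "+"),
               concordance = fit$concordance, n = fit$n,
               n_events = fit$nEvents, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
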