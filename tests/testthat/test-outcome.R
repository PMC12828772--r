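mkClinical <- function(time, event, pt = NULL, gleason = NULL, ids = NULL) {
  n <- length(time)
  validateClinical(data.frame(
    patient_id = if (is.null(ids)) sprintf("P%03d", seq_len(n)) else ids,
    followup_months = time, bcr_event = as.integer(event),
    gleason_category = if (is.null(gleason)) rep("low", n) else gleason,
    pt_category = if (is.null(pt)) rep("T2", n) else pt,
    stringsAsFactors = FALSE))
}

test_that("Kaplan-Meier matches the hand-derived product-limit estimate", {
  cl <- mkClinical(c(1, 2), c(1, 1))
  km <- kmEstimate(cl, rep("g", 2))
  expect_equal(km$curves$survival, c(0.5, 0))
  expect_null(km$logrank)

  # without censoring the KM estimate equals the empirical survival function
  set.seed(1)
  t2 <- sort(round(rexp(40, 0.1), 4))
  cl2 <- mkClinical(t2, rep(1, 40))
  km2 <- kmEstimate(cl2, rep("g", 40))
  emp <- vapply(km2$curves$time, function(u) mean(t2 > u), numeric(1))
  expect_equal(km2$curves$survival, emp, tolerance = 1e-12)

  # censored-only group stays at survival 1
  cl3 <- mkClinical(c(5, 10, 15), c(0, 0, 0))
  km3 <- kmEstimate(cl3, rep("g", 3))
  expect_true(all(km3$curves$survival == 1))

  # two identical groups: log-rank statistic 0, p = 1
  cl4 <- mkClinical(rep(c(1, 3, 7, 9), 2), rep(c(1, 1, 0, 1), 2))
  km4 <- kmEstimate(cl4, rep(c("a", "b"), each = 4))
  expect_equal(km4$logrank$chisq, 0, tolerance = 1e-12)
  expect_equal(km4$logrank$p_value, 1, tolerance = 1e-12)

  # truncation flag marks points with < 5 at risk, but curves are untouched
  expect_identical(km2$curves$truncated, km2$curves$n_risk < 5)
  expect_error(kmEstimate(cl, c("a", NA)), ">= 1 subject")
})

test_that("Cox coefficients maximize the partial likelihood (grid oracle)", {
  # interleaved events keep the likelihood bounded: A at 1, 3, 5; B at 2, 4
  times <- c(1, 3, 5, 2, 4)
  grp <- c("T2", "T2", "T2", "T3a", "T3a")
  cl <- mkClinical(times, rep(1, 5), pt = grp)
  fit <- coxFit(cl, "pt")
  # independent 1-D grid maximization of the (no-ties) partial likelihood
  ord <- order(times)
  x <- as.integer(grp == "T3a")[ord]
  pl <- function(b) {
    risk <- exp(b * x)
    sum(b * x - vapply(seq_along(x), function(i) log(sum(risk[i:length(x)])),
                       numeric(1)))
  }
  grid <- seq(-5, 5, by = 1e-4)
  bhat <- grid[which.max(vapply(grid, pl, numeric(1)))]
  expect_lt(abs(fit$terms$coef[1] - bhat), 1e-4)

  # a group whose events all precede the other's separates: clear error
  sep <- mkClinical(c(1, 2, 3, 4), rep(1, 4),
                    pt = c("T2", "T2", "T3a", "T3a"))
  expect_error(suppressWarnings(coxFit(sep, "pt")),
               "separation|undetermined")

  # mirrored event times across groups: no effect, HR 1
  clSym <- mkClinical(c(1, 2, 3, 4, 1, 2, 3, 4), rep(1, 8),
                      pt = rep(c("T2", "T3a"), each = 4))
  fitSym <- coxFit(clSym, "pt")
  expect_equal(fitSym$terms$coef[1], 0, tolerance = 1e-8)
  expect_equal(fitSym$terms$hr[1], 1, tolerance = 1e-8)
  expect_identical(fitSym$ties, "efron")
  expect_error(coxFit(mkClinical(c(1, 2), c(0, 0)), "pt"), ">= 1 event")
})

test_that("two-group log-rank equals the squared Cox score statistic", {
  set.seed(7)
  n <- 60
  t <- round(rexp(n, 0.05), 6)          # continuous: no ties
  ev <- rbinom(n, 1, 0.8)
  grp <- rep(c("T2", "T3a"), each = n / 2)
  cl <- mkClinical(t, ev, pt = grp)
  km <- kmEstimate(cl, grp)
  sc <- survival::coxph(survival::Surv(followup_months, bcr_event) ~ pt_category,
                        data = cl)$score
  expect_equal(km$logrank$chisq, unname(sc), tolerance = 1e-6)
})

test_that("concordance handles perfect, anti-perfect, tied and random scores", {
  set.seed(3)
  t <- sort(runif(30, 1, 100))
  cl <- mkClinical(t, rep(1, 30))
  expect_equal(concordanceIndex(-t, cl), 1)   # higher risk = earlier event
  expect_equal(concordanceIndex(t, cl), 0)
  # one tied score pair: brute-force enumeration over permissible pairs
  cl3 <- mkClinical(c(1, 2, 3), c(1, 1, 1))
  sc3 <- c(5, 5, 1)
  brute <- local({
    pairs <- utils::combn(3, 2)
    vals <- apply(pairs, 2, function(ij) {
      i <- ij[1]; j <- ij[2]        # t[i] < t[j]: i is the earlier event
      if (sc3[i] > sc3[j]) 1 else if (sc3[i] == sc3[j]) 0.5 else 0
    })
    mean(vals)
  })
  expect_equal(concordanceIndex(sc3, cl3), brute)
  # random scores hover at 0.5
  set.seed(11)
  big <- mkClinical(rexp(10000, 0.01), rbinom(10000, 1, 0.5))
  expect_lt(abs(concordanceIndex(rnorm(10000), big) - 0.5), 0.02)
  expect_error(concordanceIndex(c(1, 2), mkClinical(c(4, 9), c(0, 0))),
               "no permissible pairs")
})

test_that("the proportional-hazards check calibrates under PH and detects violations", {
  set.seed(21)
  # type-I error under proportional hazards
  rej <- replicate(150, {
    n <- 80
    grp <- rep(c("T2", "T3a"), each = n / 2)
    lam <- ifelse(grp == "T3a", 0.06, 0.02)
    t <- rexp(n, lam); cens <- runif(n, 0, 60)
    cl <- mkClinical(pmax(pmin(t, cens), 1e-3), as.integer(t <= cens), pt = grp)
    tryCatch({
      fit <- suppressWarnings(coxFit(cl, "pt"))
      ph <- phTest(fit)
      ph$p_value[ph$term == "GLOBAL"] < 0.05
    }, error = function(e) NA)   # degenerate draw: no usable events
  })
  expect_lt(mean(rej, na.rm = TRUE), 0.12)
  expect_gt(mean(rej, na.rm = TRUE), 0.005)

  # a sign-flipping effect is detected: group hazard high early, low late
  rej2 <- replicate(40, {
    n <- 200
    grp <- rep(c("T2", "T3a"), each = n / 2)
    tFlip <- 10
    t <- vapply(grp, function(g) {
      if (g == "T2") rexp(1, 0.05)
      else {
        # hazard 0.15 before tFlip, 0.015 after: early risk, late protection
        u <- rexp(1, 0.15)
        if (u < tFlip) u else tFlip + rexp(1, 0.015)
      }
    }, numeric(1))
    cl <- mkClinical(pmax(t, 1e-3), rep(1, n), pt = grp)
    fit <- suppressWarnings(coxFit(cl, "pt"))
    ph <- phTest(fit)
    ph$p_value[ph$term == "GLOBAL"] < 0.05
  })
  expect_gte(mean(rej2), 0.8)

  # one event, occurring when its subject is alone at risk: the partial
  # likelihood is flat, the fit converges, and the PH check must refuse
  single <- mkClinical(c(3, 9, 5), c(0, 1, 0), pt = c("T2", "T3a", "T3a"))
  expect_error(phTest(suppressWarnings(coxFit(single, "pt"))), ">= 2 events")
})

test_that("nested model comparison ranks informative covariates", {
  co <- cachedCohort(405, seed = 15)
  lab <- truthLabeling(co$truth, "patient")
  cl <- co$clinical

  # randomized Gleason is pure noise: adding it barely moves concordance
  clNoise <- cl
  set.seed(2)
  clNoise$gleason_category <- sample(cl$gleason_category)
  mc <- modelComparison(clNoise,
                        list(subtype = "subtype",
                             both = c("subtype", "gleason")),
                        subtypeLabels = lab)
  expect_lt(abs(mc$concordance[mc$model == "both"] -
                mc$concordance[mc$model == "subtype"]), 0.02)

  # the true subtype covariate adds real signal on top of Gleason
  mc2 <- modelComparison(cl,
                         list(gleason = "gleason",
                              with_subtype = c("gleason", "subtype")),
                         subtypeLabels = lab)
  expect_gt(mc2$concordance[mc2$model == "with_subtype"],
            mc2$concordance[mc2$model == "gleason"])

  # identical covariate sets give identical concordance
  mc3 <- modelComparison(cl, list(a = "subtype", b = "subtype"),
                         subtypeLabels = lab)
  expect_identical(mc3$concordance[1], mc3$concordance[2])
})

test_that("Cox log-hazard bias shrinks as the cohort grows", {
  set.seed(5)
  biasAt <- function(n, reps) {
    est <- replicate(reps, tryCatch({
      grp <- rep(c("T2", "T3a"), each = n / 2)
      lam <- ifelse(grp == "T3a", 2, 1) * 0.03
      t <- rexp(n, lam); cens <- runif(n, 0, 80)
      cl <- mkClinical(pmax(pmin(t, cens), 1e-3), as.integer(t <= cens),
                       pt = grp)
      suppressWarnings(coxFit(cl, "pt"))$terms$coef[1]
    }, error = function(e) NA_real_))
    abs(mean(est, na.rm = TRUE) - log(2))
  }
  b100 <- biasAt(100, 40)
  b1600 <- biasAt(1600, 10)
  expect_lt(b1600, 0.08)
  expect_lt(b1600, b100 + 0.05)
})

test_that("Cox fits report Wald intervals consistent with HR = exp(coef)", {
  co <- cachedCohort(405, seed = 15)
  fit <- coxFit(co$clinical, c("subtype", "gleason", "pt"),
                subtypeLabels = truthLabeling(co$truth, "patient"))
  expect_equal(fit$terms$hr, exp(fit$terms$coef), tolerance = 1e-12)
  expect_true(all(fit$terms$ci_lower < fit$terms$ci_upper))
  expect_true(fit$concordance >= 0 && fit$concordance <= 1)
  # reference levels are TCE / low / T2: their rows must be absent
  expect_false(any(grepl("TCE|low|T2$", fit$terms$term)))
})
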