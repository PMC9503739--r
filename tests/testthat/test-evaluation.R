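classicalKappa <- function(cm) {
  n <- sum(cm)
  po <- (cm[["TP"]] + cm[["TN"]]) / n
  pe <- ((cm[["TP"]] + cm[["FP"]]) * (cm[["TP"]] + cm[["FN"]]) +
         (cm[["FN"]] + cm[["TN"]]) * (cm[["FP"]] + cm[["TN"]])) / n^2
  (po - pe) / (1 - pe)
}

test_that("confusion matrices tabulate the four outcomes", {
  lab <- c(1, 1, 0, 0)
  expect_equal(confusionPercent(lab, lab),
               c(TP = 50, FP = 0, FN = 0, TN = 50))
  expect_equal(confusionPercent(1 - lab, lab),
               c(TP = 0, FP = 50, FN = 50, TN = 0))
  expect_equal(confusionPercent(c(1, 1, 0, 0), c(1, 0, 1, 0)),
               c(TP = 25, FP = 25, FN = 25, TN = 25))
  expect_equal(sum(confusionPercent(rbinom(40, 1, 0.5), rbinom(40, 1, 0.5))),
               100)
  expect_error(confusionPercent(c(1, 0), c(1, 0, 1)), "equal length")
  expect_error(confusionPercent(c(2, 0), c(1, 0)), "binary")
})

test_that("Youden's index is sensitivity + specificity - 1", {
  expect_equal(youdenIndex(1, 1), 1)
  expect_equal(youdenIndex(0.5, 0.5), 0)
  expect_equal(youdenIndex(0.86, 0.80), 0.66)
  expect_error(youdenIndex(1.2, 0.5), "0, 1")
})

test_that("kappa reproduces worked confusion matrices", {
  expect_equal(round(cohenKappa(c(TP = 44.6, FP = 11.6, FN = 5.3,
                                  TN = 38.4)), 2), 0.66)
  expect_equal(round(cohenKappa(c(TP = 44.6, FP = 13.8, FN = 5.4,
                                  TN = 36.2)), 2), 0.62)
  expect_equal(cohenKappa(c(TP = 25, FP = 25, FN = 25, TN = 25)), 0)
  expect_equal(cohenKappa(c(TP = 50, FP = 0, FN = 0, TN = 50)), 1)
  expect_error(cohenKappa(c(TP = 0, FP = 0, FN = 0, TN = 0)), "denominator")
})

test_that("the binary kappa formula equals the classical definition", {
  set.seed(15)
  for (i in 1:1000) {
    cm <- c(TP = runif(1, 0, 50), FP = runif(1, 0, 50),
            FN = runif(1, 0, 50), TN = runif(1, 0, 50))
    expect_lt(abs(cohenKappa(cm) - classicalKappa(cm)), 1e-12)
  }
  # scale invariance: counts and percentages give the same kappa
  cm <- c(TP = 223, FP = 58, FN = 27, TN = 192)
  expect_equal(cohenKappa(cm), cohenKappa(100 * cm / sum(cm)))
})

test_that("AUC integrates parameter sweeps with known answers", {
  # perfectly separating score: sweep the threshold over a fine grid
  score <- c(rnorm(50, 0), rnorm(50, 10))
  lab <- rep(c(0, 1), each = 50)
  grid <- seq(0, 1, 0.01)
  sw <- t(vapply(quantile(score, grid), function(thr) {
    cm <- confusionPercent(as.integer(score >= thr), lab)
    c(cm[["TP"]] / (cm[["TP"]] + cm[["FN"]]),
      cm[["TN"]] / (cm[["TN"]] + cm[["FP"]]))
  }, numeric(2)))
  expect_equal(rocAuc(sw[, 1], sw[, 2]), 1)

  # antisymmetry: reversing every decision maps AUC to 1 - AUC
  set.seed(16)
  sens <- runif(20); spec <- runif(20)
  expect_equal(rocAuc(1 - sens, 1 - spec), 1 - rocAuc(sens, spec),
               tolerance = 1e-12)
  expect_error(rocAuc(numeric(0), numeric(0)), "empty")
})

test_that("random labels give chance-level AUC over the sweep", {
  aucs <- vapply(1:5, function(sd_) {
    set.seed(sd_)
    score <- rnorm(2000)
    lab <- sample(rep(c(0, 1), 1000))
    sw <- t(vapply(quantile(score, seq(0, 1, 0.02)), function(thr) {
      cm <- confusionPercent(as.integer(score >= thr), lab)
      c(cm[["TP"]] / (cm[["TP"]] + cm[["FN"]]),
        cm[["TN"]] / (cm[["TN"]] + cm[["FP"]]))
    }, numeric(2)))
    rocAuc(sw[, 1], sw[, 2])
  }, numeric(1))
  expect_true(all(aucs > 0.47 & aucs < 0.53))
})

test_that("cross-validated tuning covers every sample exactly once", {
  s <- simulateSpectra(cleanConfig(p = 100, nPerClass = 30, seed = 17))
  cv <- tuneParameterCV(s, "global", grid = c(0.3, 0.5, 0.7), kFolds = 10,
                        seed = 2)
  expect_equal(sort(unique(cv$folds)), 1:10)
  expect_equal(as.vector(table(cv$folds)), rep(6, 10))
  # stratification: each fold holds 3 spectra of each class
  expect_true(all(table(cv$folds, cv$labels) == 3))
  expect_length(cv$predictions, 60)
  expect_true(all(cv$predictions %in% 0:1))

  single <- tuneParameterCV(s, "global", grid = 0.5, kFolds = 5, seed = 2)
  expect_equal(single$optimalParameter, 0.5)

  tiny <- asSet(matrix(rnorm(12), 4, 3), labels = c(0, 0, 1, 1))
  expect_error(tuneParameterCV(tiny, "global", kFolds = 10, seed = 1),
               "fewer spectra|classes")
})

test_that("tuning with identical seeds reuses the same fold partition", {
  s <- simulateSpectra(cleanConfig(p = 100, nPerClass = 20, seed = 18))
  a <- tuneParameterCV(s, "local", grid = seq(0, 1, 0.1), seed = 4, m = 2)
  b <- tuneParameterCV(s, "global", grid = seq(0, 1, 0.1), seed = 4)
  expect_identical(a$folds, b$folds)
})

test_that("joint agreement respects structural zeros and derived rates", {
  set.seed(19)
  lab <- rbinom(300, 1, 0.5)
  p1 <- ifelse(runif(300) < 0.8, lab, 1 - lab)
  p2 <- ifelse(runif(300) < 0.75, lab, 1 - lab)
  ja <- jointAgreement(p1, p2, lab)
  tab <- ja$outcomeCrosstab
  truth1 <- c(TRUE, FALSE, TRUE, FALSE)
  expect_true(all(is.na(tab[outer(truth1, truth1, `!=`)])))
  expect_equal(sum(tab, na.rm = TRUE), 100)
  expect_equal(sum(ja$correctnessCrosstab), 100)
  # disagreement equals the off-diagonal of the correctness table
  expect_equal(ja$rates$disagreementRate, 100 * mean(p1 != p2))

  same <- jointAgreement(p1, p1, lab)
  expect_equal(same$rates$disagreementRate, 0)
  expect_equal(sum(diag(same$correctnessCrosstab)), 100)

  expect_error(jointAgreement(p1[-1], p2, lab), "equal length")
})

test_that("published joint tables yield the quoted NPV, PPV and accuracy", {
  lev <- c("TP", "FP", "FN", "TN")
  tab <- matrix(NA_real_, 4, 4, dimnames = list(lev, lev))
  tab["TP", "TP"] <- 42.1; tab["TP", "FN"] <- 2.5
  tab["FP", "FP"] <- 9.7;  tab["FP", "TN"] <- 1.9
  tab["FN", "TP"] <- 2.5;  tab["FN", "FN"] <- 2.9
  tab["TN", "FP"] <- 4.1;  tab["TN", "TN"] <- 34.3
  rates <- jointOutcomeRates(tab)
  expect_equal(round(rates$npv, 1), 92.2)
  expect_equal(round(rates$ppv), 81)
  expect_equal(rates$wrongNegativeRate, 2.9)

  ctab <- matrix(c(76.4, 4.4, 6.6, 12.6), 2, 2,
                 dimnames = list(c("correct", "wrong"),
                                 c("correct", "wrong")))
  crates <- jointCorrectnessRates(ctab)
  expect_equal(round(crates$jointAccuracy), 86)
  expect_equal(crates$disagreementRate, 11)
})

test_that("tuned kappa grows with the class effect size", {
  gaps <- c(0, 250, 500)
  meanKappa <- vapply(gaps, function(gap) {
    ks <- vapply(1:5, function(sd_) {
      peaks <- list(peakSpec(230, 25, 800), peakSpec(540, 30, 500),
                    peakSpec(1320, 40, 700),
                    peakSpec(1550, 45, 850, 850 + gap),
                    peakSpec(2930, 35, 1500))
      cfg <- syntheticConfig(p = 150, nPerClass = 50, peaks = peaks,
                             outlierRate = 0, seed = 100 + sd_)
      s <- simulateSpectra(cfg)
      cv <- tuneParameterCV(s, "global", grid = seq(0, 1, 0.05),
                            seed = sd_)
      cohenKappa(cv$confusion)
    }, numeric(1))
    mean(ks)
  }, numeric(1))
  expect_true(all(diff(meanKappa) > 0))
  expect_gt(cor(gaps, meanKappa, method = "spearman"), 0)
})
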