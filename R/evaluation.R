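#' @include AllClasses.R
NULL

#' Binary confusion matrix
#'
#' Cross-tabulates 0/1 predictions against true labels.  With
#' `percent = TRUE` (default) the four cells are expressed as percentages
#' of the total and sum to 100.
#'
#' @param predictions,labels binary vectors of equal length.
#' @param percent report percentages of the total rather than counts.
#'
#' @return named numeric vector `c(TP, FP, FN, TN)`.
#' @examples
#' confusionPercent(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
confusionPercent <- function(predictions, labels, percent = TRUE) {
  if (length(predictions) != length(labels))
    stop("predictions and labels must have equal length")
  if (!all(predictions %in% c(0, 1)) || !all(labels %in% c(0, 1)))
    stop("predictions and labels must be binary (0/1)")
  cm <- c(TP = sum(predictions == 1 & labels == 1),
          FP = sum(predictions == 1 & labels == 0),
          FN = sum(predictions == 0 & labels == 1),
          TN = sum(predictions == 0 & labels == 0))
  if (percent) cm <- 100 * cm / length(labels)
  cm
}

sensSpec <- function(cm) {
  c(sensitivity = unname(cm["TP"] / (cm["TP"] + cm["FN"])),
    specificity = unname(cm["TN"] / (cm["TN"] + cm["FP"])))
}

#' Youden's J statistic
#'
#' `J = sensitivity + specificity - 1`, in `[-1, 1]`; the criterion used to
#' tune the decision thresholds.
#'
#' @param sensitivity,specificity rates in `[0, 1]` (vectorized).
#'
#' @return numeric J.
#' @export
youdenIndex <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1, na.rm = TRUE) ||
      any(specificity < 0 | specificity > 1, na.rm = TRUE))
    stop("sensitivity and specificity must lie in [0, 1]")
  sensitivity + specificity - 1
}

#' Area under a ROC curve traced by a parameter sweep
#'
#' Builds the ROC polyline from per-parameter (sensitivity, specificity)
#' pairs -- points `(1 - specificity, sensitivity)` sorted by false
#' positive rate with the endpoints (0,0) and (1,1) appended -- and
#' integrates it by the trapezoidal rule.
#'
#' @param sensitivity,specificity equal-length numeric vectors in
#'   `[0, 1]`.
#'
#' @return AUC in `[0, 1]`.
#' @export
rocAuc <- function(sensitivity, specificity) {
  if (length(sensitivity) == 0L) stop("empty parameter sweep")
  if (any(sensitivity < 0 | sensitivity > 1) ||
      any(specificity < 0 | specificity > 1))
    stop("sensitivity and specificity must lie in [0, 1]")
  fpr <- c(0, 1 - specificity, 1)
  tpr <- c(0, sensitivity, 1)
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
}

#' Cohen's kappa from a binary confusion matrix
#'
#' Chance-corrected agreement,
#' `kappa = 2 (TP*TN - FP*FN) / ((TP+FP)(FP+TN) + (TP+FN)(FN+TN))`,
#' algebraically equal to the classical `(p_o - p_e) / (1 - p_e)` form in
#' the binary case and invariant to expressing the cells as counts or
#' percentages.
#'
#' @param cm named numeric with elements `TP`, `FP`, `FN`, `TN` (counts or
#'   percentages), e.g. the output of [confusionPercent()].
#'
#' @return kappa in `[-1, 1]`.
#' @examples
#' cohenKappa(c(TP = 44.6, FP = 11.6, FN = 5.3, TN = 38.4))
#' @export
cohenKappa <- function(cm) {
  cm <- unlist(cm)
  need <- c("TP", "FP", "FN", "TN")
  if (!all(need %in% names(cm)))
    stop("cm must contain TP, FP, FN and TN")
  TP <- cm[["TP"]]; FP <- cm[["FP"]]; FN <- cm[["FN"]]; TN <- cm[["TN"]]
  den <- (TP + FP) * (FP + TN) + (TP + FN) * (FN + TN)
  if (den <= 0) stop("kappa undefined: zero denominator")
  2 * (TP * TN - FP * FN) / den
}

## Held-out predictions at one threshold: the local statistic is the
## fitted probability, the global one the (dh, dt) distance pair.
thresholdPredict <- function(method, stat, par) {
  if (method == "local") as.integer(stat >= par)
  else classifyGeometric(stat$dh, stat$dt, par)
}

## Stratified fold assignment: within each class, shuffled indices are
## dealt round-robin over the k folds.
stratifiedFolds <- function(labels, k, seed) {
  if (length(labels) < k)
    stop("fewer spectra than folds")
  fold <- integer(length(labels))
  withSeed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Cross-validated tuning of a classifier threshold by Youden's index
#'
#' Partitions the spectra into `kFolds` class-stratified folds; in each
#' round one fold is held out, the classifier is fitted on the remaining
#' spectra (`"local"`: principal components + logistic regression;
#' `"global"`: class mean spectra) and the full threshold grid is scored
#' on the held-out fold.  Sensitivities, specificities, Youden indices and
#' confusion percentages are averaged over folds per grid value; the
#' optimum is the grid value maximizing the averaged Youden index, ties
#' resolved toward the smaller threshold (which favors sensitivity).
#'
#' @param x a \linkS4class{SpectraSet} with both classes, `N >= kFolds`.
#' @param method `"local"` (tunes lambda) or `"global"` (tunes tau).
#' @param grid candidate thresholds in `[0, 1]` (default 0, 0.01, ..., 1).
#' @param kFolds number of folds (default 10).
#' @param seed integer seed for the fold partition.
#' @param m retained principal components for the local method.
#'
#' @return list of class `"ramanCV"`: `method`, `grid`, `sweep`
#'   (data.frame of per-parameter fold-averaged sensitivity, specificity,
#'   Youden), `auc`, `optimalParameter`, `youdenAtOptimum`, `confusion`
#'   (fold-averaged percentage confusion at the optimum), `foldConfusions`
#'   (per-fold, at the optimum), `predictions` (each spectrum's prediction
#'   from the round where it was held out, at the optimum), `folds`,
#'   `labels`, `seed`.
#' @examples
#' s <- simulateSpectra(syntheticConfig(p = 120, nPerClass = 30, seed = 2,
#'                                      outlierRate = 0))
#' cv <- tuneParameterCV(s, "global", grid = seq(0, 1, 0.1), seed = 1)
#' cv$optimalParameter
#' @export
tuneParameterCV <- function(x, method = c("local", "global"),
                            grid = seq(0, 1, by = 0.01), kFolds = 10L,
                            seed = 1L, m = 4L) {
  stopifnot(methods::is(x, "SpectraSet"))
  method <- match.arg(method)
  if (length(grid) == 0L || any(grid < 0 | grid > 1))
    stop("grid must be a non-empty set of values in [0, 1]")
  grid <- sort(unique(grid))
  lab <- unname(spectraLabels(x))
  if (!all(c(0L, 1L) %in% lab))
    stop("both classes must be present")
  fold <- stratifiedFolds(lab, kFolds, seed)
  X <- spectraMatrix(x)
  nG <- length(grid)

  sens <- matrix(NA_real_, kFolds, nG)
  spec <- matrix(NA_real_, kFolds, nG)
  cmArr <- array(NA_real_, c(kFolds, nG, 4L),
                 dimnames = list(NULL, NULL, c("TP", "FP", "FN", "TN")))
  scoreList <- vector("list", kFolds)   # per-fold test statistic

  for (f in seq_len(kFolds)) {
    tr <- fold != f; te <- !tr
    if (length(unique(lab[te])) < 2L || length(unique(lab[tr])) < 2L)
      stop("a fold lost one of the classes; use stratified data with ",
           "at least kFolds spectra per class")
    trainSet <- x[, tr]
    if (method == "local") {
      model <- fitLocalModel(trainSet, m = m, lambda = 0.5)
      stat <- predictLocal(model, X[te, , drop = FALSE])
    } else {
      model <- fitGlobalModel(trainSet, tau = 0.5)
      stat <- squaredL2Distances(X[te, , drop = FALSE], model)
    }
    scoreList[[f]] <- list(test = which(te), stat = stat)
    for (g in seq_len(nG)) {
      cm <- confusionPercent(thresholdPredict(method, stat, grid[g]),
                             lab[te])
      ss <- sensSpec(cm)
      sens[f, g] <- ss["sensitivity"]
      spec[f, g] <- ss["specificity"]
      cmArr[f, g, ] <- cm
    }
  }

  sensAvg <- colMeans(sens); specAvg <- colMeans(spec)
  youdenAvg <- youdenIndex(sensAvg, specAvg)
  best <- which.max(youdenAvg)   # first max = smallest parameter on ties

  predictions <- integer(length(lab))
  foldConfusions <- vector("list", kFolds)
  for (f in seq_len(kFolds)) {
    sc <- scoreList[[f]]
    predictions[sc$test] <- thresholdPredict(method, sc$stat, grid[best])
    foldConfusions[[f]] <- cmArr[f, best, ]
  }

  structure(list(
    method = method, grid = grid,
    sweep = data.frame(parameter = grid, sensitivity = sensAvg,
                       specificity = specAvg, youden = youdenAvg),
    auc = rocAuc(sensAvg, specAvg),
    optimalParameter = grid[best],
    youdenAtOptimum = youdenAvg[best],
    confusion = colMeans(matrix(cmArr[, best, ], ncol = 4L,
                                dimnames = list(NULL, dimnames(cmArr)[[3L]]))),
    foldConfusions = foldConfusions,
    predictions = predictions, folds = fold, labels = lab,
    seed = as.integer(seed)), class = "ramanCV")
}

outcomeType <- function(pred, label) {
  ifelse(pred == 1 & label == 1, "TP",
  ifelse(pred == 1 & label == 0, "FP",
  ifelse(pred == 0 & label == 1, "FN", "TN")))
}

#' Joint agreement of the two classifiers
#'
#' Cross-tabulates, sample by sample, the outcome type (TP/FP/FN/TN) of
#' the local and global predictions.  Cells pairing outcome types that
#' imply different true labels for the same sample (e.g. local TP with
#' global TN) are structurally impossible and reported as `NA`.  A 2x2
#' correct/wrong cross-tab and the derived joint rates are also returned.
#'
#' @param localPred,globalPred 0/1 prediction vectors of the two methods.
#' @param labels true 0/1 labels.
#'
#' @return list with `outcomeCrosstab` (4x4 percentage matrix, local in
#'   rows, `NA` = impossible cell), `correctnessCrosstab` (2x2 percentage
#'   matrix) and `rates` -- see [jointOutcomeRates()] and
#'   [jointCorrectnessRates()].
#' @export
jointAgreement <- function(localPred, globalPred, labels) {
  n <- length(labels)
  if (length(localPred) != n || length(globalPred) != n)
    stop("prediction and label vectors must have equal length")
  lev <- c("TP", "FP", "FN", "TN")
  lo <- factor(outcomeType(localPred, labels), levels = lev)
  gl <- factor(outcomeType(globalPred, labels), levels = lev)
  tab <- 100 * table(local = lo, global = gl) / n
  tab <- unclass(as.matrix(tab))
  ## impossible pairings: the two outcome types disagree on the truth
  truth1 <- c(TRUE, FALSE, TRUE, FALSE)  # TP, FP, FN, TN
  tab[outer(truth1, truth1, `!=`)] <- NA_real_
  corr <- c("correct", "wrong")
  lc <- factor(ifelse(localPred == labels, "correct", "wrong"), levels = corr)
  gc <- factor(ifelse(globalPred == labels, "correct", "wrong"), levels = corr)
  ctab <- 100 * table(local = lc, global = gc) / n
  ctab <- unclass(as.matrix(ctab))
  list(outcomeCrosstab = tab, correctnessCrosstab = ctab,
       rates = c(jointOutcomeRates(tab), jointCorrectnessRates(ctab)))
}

#' Rates derived from the joint outcome cross-tab
#'
#' From a 4x4 percentage cross-tab of local (rows) by global (columns)
#' outcome types: the negative predictive value of a joint negative call
#' `NPV = TN&TN / (TN&TN + FN&FN)`, the positive predictive value of a
#' joint positive call `PPV = TP&TP / (TP&TP + FP&FP)`, and the rate of
#' wrong joint negatives (`FN&FN`).  All in percent.
#'
#' @param tab 4x4 matrix with dimnames `TP/FP/FN/TN`; `NA` cells (the
#'   structurally impossible pairings) are ignored.
#'
#' @return named list: `npv`, `ppv`, `wrongNegativeRate`.
#' @examples
#' tab <- matrix(NA_real_, 4, 4, dimnames = list(c("TP","FP","FN","TN"),
#'                                               c("TP","FP","FN","TN")))
#' tab["TN", "TN"] <- 34.3; tab["FN", "FN"] <- 2.9
#' tab["TP", "TP"] <- 42.1; tab["FP", "FP"] <- 9.7
#' jointOutcomeRates(tab)
#' @export
jointOutcomeRates <- function(tab) {
  stopifnot(all(c("TP", "FP", "FN", "TN") %in% rownames(tab)))
  bothNeg <- sum(tab["TN", "TN"], tab["FN", "FN"], na.rm = TRUE)
  bothPos <- sum(tab["TP", "TP"], tab["FP", "FP"], na.rm = TRUE)
  list(npv = if (bothNeg > 0) 100 * tab["TN", "TN"] / bothNeg else NA_real_,
       ppv = if (bothPos > 0) 100 * tab["TP", "TP"] / bothPos else NA_real_,
       wrongNegativeRate = unname(tab["FN", "FN"]))
}

#' Rates derived from the joint correctness cross-tab
#'
#' From the 2x2 percentage table of correct/wrong predictions (local in
#' rows): the joint accuracy `correct&correct / (correct&correct +
#' wrong&wrong)` -- the share of valid predictions among the samples where
#' the two methods agree -- and the disagreement rate (off-diagonal sum:
#' when the predictions differ, exactly one method is wrong).
#'
#' @param tab 2x2 matrix with dimnames `correct`/`wrong`.
#'
#' @return named list: `jointAccuracy`, `disagreementRate` (percent).
#' @examples
#' tab <- matrix(c(76.4, 4.4, 6.6, 12.6), 2, 2,
#'               dimnames = list(c("correct", "wrong"),
#'                               c("correct", "wrong")))
#' jointCorrectnessRates(tab)
#' @export
jointCorrectnessRates <- function(tab) {
  stopifnot(all(c("correct", "wrong") %in% rownames(tab)))
  agree <- tab["correct", "correct"] + tab["wrong", "wrong"]
  list(jointAccuracy = if (agree > 0)
         100 * tab["correct", "correct"] / agree else NA_real_,
       disagreementRate =
         unname(tab["correct", "wrong"] + tab["wrong", "correct"]))
}

#' Tune and evaluate both classifiers on shared folds
#'
#' Runs [tuneParameterCV()] for the local and the global method on the
#' same stratified fold partition (both draw it from `seed`), computes
#' Cohen's kappa from each method's fold-averaged confusion matrix at its
#' optimum, and cross-tabulates the two held-out prediction vectors with
#' [jointAgreement()].
#'
#' @inheritParams tuneParameterCV
#' @param lambdaGrid,tauGrid threshold grids for the two methods.
#'
#' @return list with elements `local` and `global` (each a `"ramanCV"`),
#'   `kappa` (named vector), and `joint` (see [jointAgreement()]).
#' @export
evaluateJoint <- function(x, lambdaGrid = seq(0, 1, by = 0.01),
                          tauGrid = seq(0, 1, by = 0.01), kFolds = 10L,
                          seed = 1L, m = 4L) {
  lo <- tuneParameterCV(x, "local", grid = lambdaGrid, kFolds = kFolds,
                        seed = seed, m = m)
  gl <- tuneParameterCV(x, "global", grid = tauGrid, kFolds = kFolds,
                        seed = seed)
  lab <- unname(spectraLabels(x))
  list(local = lo, global = gl,
       kappa = c(local = cohenKappa(lo$confusion),
                 global = cohenKappa(gl$confusion)),
       joint = jointAgreement(lo$predictions, gl$predictions, lab))
}
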