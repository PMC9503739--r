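#' @include AllClasses.R
NULL

#' Column-center a data matrix
#'
#' Subtracts from every entry the mean of its column, so each column
#' (Raman-shift channel) has zero mean; the subtracted means are returned
#' for centering new data consistently.
#'
#' @param X numeric matrix with spectra in rows (N >= 2).
#'
#' @return list with `Y` (centered matrix) and `means` (the column means).
#' @examples
#' centerColumns(rbind(c(1, 3), c(3, 5)))
#' @export
centerColumns <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L)
    stop("at least two spectra are needed to center columns")
  mu <- colMeans(X)
  list(Y = sweep(X, 2L, mu), means = mu)
}

#' Principal component analysis of centered spectra
#'
#' Eigendecomposition of the empirical covariance of the column-centered
#' data, computed through the thin singular value decomposition of the
#' centered matrix (numerically equivalent, and far cheaper when the
#' channel count greatly exceeds the spectrum count).  Eigenvalues use the
#' `N - 1` scaling; component "standard deviations" are their square
#' roots.  Each direction's sign is fixed so its largest-magnitude loading
#' is positive.
#'
#' @param X numeric matrix (spectra in rows) or a
#'   \linkS4class{SpectraSet}.
#'
#' @return a \linkS4class{SpectralPCA}.
#' @examples
#' pca <- fitPCA(matrix(rnorm(80), 10, 8))
#' propVariance(pca)
#' @export
fitPCA <- function(X) {
  if (methods::is(X, "SpectraSet")) X <- spectraMatrix(X)
  cc <- centerColumns(X)
  Y <- cc$Y
  if (all(Y == 0))
    stop("degenerate input: centered matrix is identically zero")
  sv <- svd(Y)
  keep <- sv$d > max(sv$d) * 1e-12
  d <- sv$d[keep]
  V <- sv$v[, keep, drop = FALSE]
  ## deterministic sign: largest-|loading| entry positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  n1 <- nrow(Y) - 1L
  methods::new("SpectralPCA", rotation = V, sdev = d / sqrt(n1),
               center = cc$means, totalVariance = sum(Y^2) / n1)
}

#' @describeIn selectComponents choose the retained component count from a
#'   fitted model: `rule = "fixed"` returns `m` unchanged;
#'   `rule = "cumulative"` returns the smallest count whose cumulative
#'   proportion of variance reaches `threshold` (in `(0, 1]`).
#' @param x a \linkS4class{SpectralPCA} or a numeric vector of
#'   per-component proportions of variance.
#' @param rule `"fixed"` or `"cumulative"`.
#' @param m retained count for the fixed rule (default 4).
#' @param threshold cumulative-variance target for the cumulative rule.
#' @export
setMethod("selectComponents", "SpectralPCA",
          function(x, rule = c("fixed", "cumulative"), m = 4L,
                   threshold = 0.95)
            selectComponents(propVariance(x), rule = rule, m = m,
                             threshold = threshold))

#' @describeIn selectComponents the same rules applied directly to a
#'   vector of proportions of variance (e.g. a published variance table).
#' @export
setMethod("selectComponents", "numeric",
          function(x, rule = c("fixed", "cumulative"), m = 4L,
                   threshold = 0.95) {
  rule <- match.arg(rule)
  if (rule == "fixed") {
    m <- as.integer(m)
    if (m < 1L || m > length(x))
      stop("fixed m must be between 1 and the number of components")
    return(m)
  }
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  cum <- cumsum(x)
  if (max(cum) < threshold)
    stop("cumulative proportion never reaches the threshold")
  which(cum >= threshold)[1L]
})

#' @describeIn SpectralPCA project new spectra on the first `m` principal
#'   directions after centering them with the TRAINING column means.
#' @param object a \linkS4class{SpectralPCA}.
#' @param m number of leading directions (default: all fitted).
#' @export
setMethod("projectSpectra", "SpectralPCA", function(object, x, m = NULL) {
  if (methods::is(x, "SpectraSet")) x <- spectraMatrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != nrow(object@rotation))
    stop("channel count of the new data does not match the model")
  if (is.null(m)) m <- ncol(object@rotation)
  m <- as.integer(m)
  if (m < 1L || m > ncol(object@rotation))
    stop("m must be between 1 and the number of fitted components")
  sweep(x, 2L, object@center) %*% object@rotation[, seq_len(m), drop = FALSE]
})

#' Logistic regression of class labels on component scores
#'
#' Maximum-likelihood fit of the binomial log-odds model
#' `logit Pr(W = 1) = beta0 + sum_i beta_i z_i` by iteratively reweighted
#' least squares, with per-coefficient standard errors from the inverse
#' observed information.  Numerically degenerate fitted probabilities
#' (complete or quasi-complete separation) are flagged rather than raised.
#'
#' @param scores numeric matrix of predictors (spectra in rows).
#' @param labels binary response (0/1), one per row.
#'
#' @return list with `beta` (intercept first), `se`, `converged`,
#'   `separation`, `logLik`.
#' @export
fitLogistic <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.numeric(labels)
  if (nrow(scores) != length(labels))
    stop("one label per score row is required")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to fit the logistic model")
  Xd <- cbind(`(Intercept)` = rep(1, nrow(scores)), scores)
  if (is.null(colnames(scores)) && ncol(scores) > 0L)
    colnames(Xd) <- c("(Intercept)", paste0("z", seq_len(ncol(scores))))
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(Xd, labels, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10,
                                                maxit = 100L)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  ## unscaled covariance from the IRLS qr decomposition (dispersion 1)
  p1 <- seq_len(fit$rank)
  covu <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
  list(beta = unname(fit$coefficients), se = sqrt(diag(covu)),
       converged = fit$converged, separation = separation,
       logLik = -fit$deviance / 2)
}

#' Fit the "local" classifier on a training set
#'
#' Centers the training matrix, fits the principal component model,
#' retains `m` components (fixed count by default, or the cumulative-
#' variance rule), regresses the class label on the training scores, and
#' stores the decision threshold `lambda`.
#'
#' @param train a \linkS4class{SpectraSet} with both classes.
#' @param m retained component count (default 4) when `rule = "fixed"`.
#' @param lambda probability threshold in `[0, 1]`.
#' @param rule,threshold component-selection rule, see
#'   [selectComponents()].
#'
#' @return a \linkS4class{LocalModel}.
#' @seealso [classifyLocal()], [predictLocal()]
#' @export
fitLocalModel <- function(train, m = 4L, lambda = 0.5,
                          rule = c("fixed", "cumulative"),
                          threshold = 0.95) {
  stopifnot(methods::is(train, "SpectraSet"))
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  pca <- fitPCA(train)
  m <- selectComponents(pca, rule = rule, m = m, threshold = threshold)
  z <- projectSpectra(pca, train, m = m)
  lg <- fitLogistic(z, spectraLabels(train))
  methods::new("LocalModel", pca = pca, m = as.integer(m), beta = lg$beta,
               se = lg$se, lambda = as.numeric(lambda),
               converged = lg$converged, separation = lg$separation)
}

#' Tumoral-class probability under the local model
#'
#' @param model a \linkS4class{LocalModel}.
#' @param x new spectra: a \linkS4class{SpectraSet}, a matrix (spectra in
#'   rows), or a single numeric spectrum.
#'
#' @return numeric vector of fitted probabilities `Pr(W = 1 | z)`.
#' @export
predictLocal <- function(model, x) {
  stopifnot(methods::is(model, "LocalModel"))
  z <- projectSpectra(model@pca, x, m = model@m)
  as.numeric(stats::plogis(model@beta[1L] + z %*% model@beta[-1L]))
}

#' Classify spectra with the local model
#'
#' Predicts tumoral (1) when the fitted probability is at least `lambda`
#' (boundary inclusive), healthy (0) otherwise.
#'
#' @inheritParams predictLocal
#' @param lambda optional threshold overriding the model's stored value.
#'
#' @return integer vector of 0/1 predictions.
#' @export
classifyLocal <- function(model, x, lambda = NULL) {
  if (is.null(lambda)) lambda <- model@lambda
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  as.integer(predictLocal(model, x) >= lambda)
}
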