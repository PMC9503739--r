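#' @include AllGenerics.R
NULL

#' Container for labelled Raman spectra
#'
#' `SpectraSet` extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' to hold a set of Raman spectra measured on a shared wavenumber grid,
#' together with a binary class label per spectrum (0 = healthy, 1 =
#' tumoral).  The single assay `"intensity"` stores Raman intensities in
#' arbitrary units with channels (Raman shifts) in rows and spectra in
#' columns, following the features-by-samples convention.  The grid is kept
#' in `rowData(x)$wavenumber` and the labels in `colData(x)$label`.
#'
#' @slot ... see \linkS4class{SummarizedExperiment}.
#'
#' @seealso [SpectraSet()] for the constructor, [simulateSpectra()],
#'   [preprocessSpectra()].
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

setValidity("SpectraSet", function(object) {
  msg <- NULL
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  w <- SummarizedExperiment::rowData(object)$wavenumber
  if (is.null(w)) {
    msg <- c(msg, "rowData must contain a 'wavenumber' column")
  } else if (any(diff(w) <= 0)) {
    msg <- c(msg, "wavenumbers must be strictly increasing")
  }
  lab <- SummarizedExperiment::colData(object)$label
  if (is.null(lab)) {
    msg <- c(msg, "colData must contain a 'label' column")
  } else if (!all(lab %in% c(0L, 1L))) {
    msg <- c(msg, "labels must be 0 (healthy) or 1 (tumoral)")
  }
  if (ncol(object) < 1L)
    msg <- c(msg, "at least one spectrum is required")
  if (is.null(msg)) TRUE else msg
})

#' Construct a SpectraSet
#'
#' @param intensities numeric matrix of Raman intensities with one row per
#'   spectrum and one column per wavenumber channel (the orientation used in
#'   delimited files; it is transposed internally to the Bioconductor
#'   features-by-samples layout).
#' @param wavenumbers strictly increasing numeric vector of Raman shifts in
#'   cm^-1, one per channel.
#' @param labels binary vector (0 = healthy, 1 = tumoral), one per spectrum.
#' @param ids character identifiers, one per spectrum.  Defaults to
#'   `"s1"`, `"s2"`, ...
#' @param injectedOutlier optional logical vector flagging spectra that
#'   carry a simulated gross artifact (see [simulateSpectra()]).
#'
#' @return A \linkS4class{SpectraSet}.
#' @examples
#' s <- SpectraSet(matrix(rnorm(20), 4, 5), wavenumbers = 1:5,
#'                 labels = c(0, 0, 1, 1))
#' spectraLabels(s)
#' @export
SpectraSet <- function(intensities, wavenumbers, labels, ids = NULL,
                       injectedOutlier = NULL) {
  intensities <- as.matrix(intensities)
  if (length(wavenumbers) != ncol(intensities))
    stop("length(wavenumbers) must equal the number of intensity columns")
  if (length(labels) != nrow(intensities))
    stop("one label per spectrum is required")
  if (is.null(ids))
    ids <- paste0("s", seq_len(nrow(intensities)))
  cd <- S4Vectors::DataFrame(label = as.integer(labels), row.names = ids)
  if (!is.null(injectedOutlier))
    cd$injectedOutlier <- as.logical(injectedOutlier)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = t(unname(intensities))),
    rowData = S4Vectors::DataFrame(wavenumber = as.numeric(wavenumbers)),
    colData = cd)
  methods::new("SpectraSet", se)
}

#' @describeIn SpectraSet Raman-shift grid (cm^-1).
#' @param x a `SpectraSet`.
#' @export
setMethod("wavenumbers", "SpectraSet", function(x)
  SummarizedExperiment::rowData(x)$wavenumber)

#' @describeIn SpectraSet integer class labels (0/1), named by spectrum id.
#' @export
setMethod("spectraLabels", "SpectraSet", function(x) {
  lab <- SummarizedExperiment::colData(x)$label
  names(lab) <- colnames(x)
  lab
})

#' @describeIn SpectraSet intensity matrix with spectra in rows and
#'   channels in columns (the orientation used by the statistical layer).
#' @export
setMethod("spectraMatrix", "SpectraSet", function(x)
  t(SummarizedExperiment::assay(x, "intensity")))

#' @describeIn SpectraSet logical flags for simulated gross artifacts, or
#'   `NULL` when the set was not simulated.
#' @export
setMethod("injectedOutlier", "SpectraSet", function(x) {
  f <- SummarizedExperiment::colData(x)$injectedOutlier
  if (is.null(f)) return(NULL)
  names(f) <- colnames(x)
  f
})

setMethod("show", "SpectraSet", function(object) {
  w <- wavenumbers(object)
  lab <- spectraLabels(object)
  cat("SpectraSet with", ncol(object), "spectra x", nrow(object),
      "channels\n")
  cat(sprintf("  Raman shift: %.1f .. %.1f cm^-1\n", w[1], w[length(w)]))
  cat(sprintf("  labels: %d healthy (0), %d tumoral (1)\n",
              sum(lab == 0L), sum(lab == 1L)))
  fl <- injectedOutlier(object)
  if (!is.null(fl))
    cat(sprintf("  simulated artifacts: %d flagged\n", sum(fl)))
  invisible(NULL)
})

#' Per-class outlier decision surface
#'
#' Channel-wise envelope `mean +/- k * sd` computed over the spectra of one
#' class; spectra leaving the band at any channel are discarded as outliers.
#'
#' @slot wavenumbers numeric grid (cm^-1).
#' @slot mean channel-wise mean spectrum (a.u.).
#' @slot sd channel-wise standard deviation (a.u., `N - 1` denominator).
#' @slot k envelope half-width in standard deviations (default 3).
#' @slot label the class (0/1) the surface was built from.
#'
#' @seealso [buildDecisionSurface()], [filterOutliers()]
#' @export
setClass("DecisionSurface",
         representation(wavenumbers = "numeric", mean = "numeric",
                        sd = "numeric", k = "numeric", label = "integer"))

setValidity("DecisionSurface", function(object) {
  msg <- NULL
  p <- length(object@wavenumbers)
  if (length(object@mean) != p || length(object@sd) != p)
    msg <- c(msg, "mean and sd must match the grid length")
  if (any(object@sd < 0))
    msg <- c(msg, "sd must be non-negative")
  if (length(object@k) != 1L || object@k <= 0)
    msg <- c(msg, "k must be a single positive number")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn DecisionSurface lower envelope `mean - k * sd`.
#' @param x a `DecisionSurface`.
#' @export
setMethod("lowerBound", "DecisionSurface", function(x) x@mean - x@k * x@sd)

#' @describeIn DecisionSurface upper envelope `mean + k * sd`.
#' @export
setMethod("upperBound", "DecisionSurface", function(x) x@mean + x@k * x@sd)

setMethod("show", "DecisionSurface", function(object) {
  cat(sprintf(
    "DecisionSurface (label %d): mean +/- %.3g sd over %d channels\n",
    object@label, object@k, length(object@mean)))
  invisible(NULL)
})

#' Principal component model of centered spectra
#'
#' Eigenstructure of the empirical covariance of the column-centered
#' training matrix, computed through the thin singular value decomposition.
#' `sdev` holds the component standard deviations (square roots of the
#' covariance eigenvalues, `N - 1` scaling); `rotation` the orthonormal
#' principal directions (loadings) as columns; `center` the training column
#' means used to center new spectra before projection.
#'
#' @slot rotation p x r orthonormal loading matrix.
#' @slot sdev component standard deviations, non-increasing.
#' @slot center training column means (length p).
#' @slot totalVariance total centered variance (trace of the covariance).
#'
#' @seealso [fitPCA()], [projectSpectra()], [selectComponents()]
#' @export
setClass("SpectralPCA",
         representation(rotation = "matrix", sdev = "numeric",
                        center = "numeric", totalVariance = "numeric"))

setValidity("SpectralPCA", function(object) {
  msg <- NULL
  if (ncol(object@rotation) != length(object@sdev))
    msg <- c(msg, "one sdev per rotation column is required")
  if (nrow(object@rotation) != length(object@center))
    msg <- c(msg, "center length must match the rotation row count")
  if (is.unsorted(rev(object@sdev)))
    msg <- c(msg, "sdev must be non-increasing")
  if (any(object@sdev < 0))
    msg <- c(msg, "sdev must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn SpectralPCA proportion of variance per component
#'   (eigenvalue over the covariance trace).
#' @param x a `SpectralPCA`.
#' @export
setMethod("propVariance", "SpectralPCA", function(x)
  x@sdev^2 / x@totalVariance)

setMethod("show", "SpectralPCA", function(object) {
  pv <- propVariance(object)
  k <- min(4L, length(pv))
  cat(sprintf("SpectralPCA: %d components over %d channels\n",
              length(object@sdev), nrow(object@rotation)))
  cat(sprintf("  first %d proportions of variance: %s\n", k,
              paste(sprintf("%.3f", pv[seq_len(k)]), collapse = ", ")))
  invisible(NULL)
})

#' The "local" classifier: principal component scores + logistic regression
#'
#' Couples a \linkS4class{SpectralPCA} (restricted to its first `m`
#' directions) with a logistic regression of the binary class label on the
#' scores, and a probability threshold `lambda`: a spectrum is called
#' tumoral (1) when the fitted probability is at least `lambda`.
#'
#' @slot pca the fitted \linkS4class{SpectralPCA}.
#' @slot m number of retained components.
#' @slot beta coefficients (intercept first), length `m + 1`.
#' @slot se standard errors of `beta` from the inverse observed
#'   information.
#' @slot lambda decision threshold in `[0, 1]`.
#' @slot converged logical, IRLS convergence.
#' @slot separation logical, `TRUE` when fitted probabilities numerically
#'   reached 0/1 (complete or quasi-complete separation).
#'
#' @seealso [fitLocalModel()], [classifyLocal()]
#' @export
setClass("LocalModel",
         representation(pca = "SpectralPCA", m = "integer",
                        beta = "numeric", se = "numeric", lambda = "numeric",
                        converged = "logical", separation = "logical"))

setValidity("LocalModel", function(object) {
  msg <- NULL
  if (length(object@beta) != object@m + 1L)
    msg <- c(msg, "beta must have m + 1 coefficients (intercept first)")
  if (length(object@se) != length(object@beta))
    msg <- c(msg, "one standard error per coefficient is required")
  if (object@lambda < 0 || object@lambda > 1)
    msg <- c(msg, "lambda must lie in [0, 1]")
  if (object@m < 1L || object@m > ncol(object@pca@rotation))
    msg <- c(msg, "m must be between 1 and the number of fitted components")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "LocalModel", function(object) {
  cat(sprintf(
    "LocalModel: logistic regression on %d principal components, lambda = %.3g\n",
    object@m, object@lambda))
  cat("  beta:", paste(sprintf("%.4g", object@beta), collapse = ", "), "\n")
  if (object@separation)
    cat("  warning: separation detected during the fit\n")
  invisible(NULL)
})

#' The "global" classifier: tau-weighted nearest mean spectrum
#'
#' Stores the healthy (`h`) and tumoral (`t`) training mean spectra and the
#' weight `tau`; a spectrum with squared distances `d_h`, `d_t` to the two
#' means is called tumoral (1) when `tau * d_t <= (1 - tau) * d_h`.
#'
#' @slot wavenumbers shared grid (cm^-1).
#' @slot h healthy mean spectrum (a.u.).
#' @slot t tumoral mean spectrum (a.u.).
#' @slot tau weight in `[0, 1]`.
#'
#' @seealso [fitGlobalModel()], [classifyGeometric()]
#' @export
setClass("GeometricModel",
         representation(wavenumbers = "numeric", h = "numeric",
                        t = "numeric", tau = "numeric"))

setValidity("GeometricModel", function(object) {
  msg <- NULL
  p <- length(object@wavenumbers)
  if (length(object@h) != p || length(object@t) != p)
    msg <- c(msg, "h and t must match the grid length")
  if (object@tau < 0 || object@tau > 1)
    msg <- c(msg, "tau must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "GeometricModel", function(object) {
  cat(sprintf(
    "GeometricModel: nearest-mean classifier over %d channels, tau = %.3g\n",
    length(object@h), object@tau))
  invisible(NULL)
})
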