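#' @include AllClasses.R
NULL

sgWeights <- function(window, polyorder) {
  ## central row of the Savitzky-Golay projection matrix = symmetric
  ## least-squares convolution weights
  signal::sgolay(p = polyorder, n = window)[(window + 1L) %/% 2L, ]
}

#' Savitzky-Golay smoothing with raw edges
#'
#' Replaces every interior channel by the value of the local least-squares
#' polynomial fit (order `polyorder`) over a symmetric window, applied as a
#' convolution.  The first and last `(window - 1) / 2` channels, where the
#' full window does not fit, keep their original raw values so that no
#' information is lost at the ends of the measured range.
#'
#' @param x numeric spectrum (length >= `window`).
#' @param window odd window length in channels (default 91).
#' @param polyorder polynomial order, `0 <= polyorder < window`
#'   (default 5).
#'
#' @return smoothed numeric vector of the same length.
#' @examples
#' y <- sin(seq(0, 4, length.out = 200)) + rnorm(200, sd = 0.05)
#' ys <- savgolSmooth(y, window = 21, polyorder = 3)
#' @export
savgolSmooth <- function(x, window = 91L, polyorder = 5L) {
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L)
    stop("window must be odd (symmetric convolution)")
  if (polyorder < 0L || polyorder >= window)
    stop("polyorder must satisfy 0 <= polyorder < window")
  if (length(x) < window)
    stop("spectrum shorter than the smoothing window")
  w <- sgWeights(window, polyorder)
  sm <- as.numeric(stats::filter(x, w, method = "convolution", sides = 2L))
  half <- (window - 1L) %/% 2L
  edge <- c(seq_len(half), seq.int(length(x) - half + 1L, length(x)))
  sm[edge] <- x[edge]
  sm
}

#' Smooth every spectrum of a set
#'
#' @param x a \linkS4class{SpectraSet}.
#' @inheritParams savgolSmooth
#' @return a \linkS4class{SpectraSet} with smoothed intensities; grid,
#'   labels and ids are unchanged.
#' @export
smoothSpectra <- function(x, window = 91L, polyorder = 5L) {
  stopifnot(methods::is(x, "SpectraSet"))
  X <- spectraMatrix(x)
  Xs <- t(apply(X, 1L, savgolSmooth, window = window, polyorder = polyorder))
  out <- x
  SummarizedExperiment::assay(out, "intensity") <- t(Xs)
  out
}

#' Build a per-class outlier decision surface
#'
#' Channel-wise mean and standard deviation (`N - 1` denominator) over all
#' spectra of a single class, giving the envelope `mean +/- k * sd`.
#'
#' @param x a \linkS4class{SpectraSet} containing one class only.
#' @param k envelope half-width in standard deviations (default 3).
#'
#' @return a \linkS4class{DecisionSurface}.
#' @examples
#' s <- SpectraSet(rbind(c(0, 0), c(2, 4)), wavenumbers = c(1, 2),
#'                 labels = c(0, 0))
#' upperBound(buildDecisionSurface(s))
#' @export
buildDecisionSurface <- function(x, k = 3) {
  stopifnot(methods::is(x, "SpectraSet"))
  lab <- unique(spectraLabels(x))
  if (length(lab) != 1L)
    stop("the surface is built per class: supply a single-label set")
  if (ncol(x) < 2L)
    stop("at least two spectra are needed to estimate the channel sd")
  if (k <= 0) stop("k must be positive")
  X <- spectraMatrix(x)
  methods::new("DecisionSurface", wavenumbers = wavenumbers(x),
               mean = colMeans(X), sd = apply(X, 2L, stats::sd),
               k = as.numeric(k), label = as.integer(lab))
}

#' Discard spectra leaving the decision surface
#'
#' A spectrum is kept if and only if it lies inside the envelope at every
#' channel (`lower <= x <= upper`, bounds inclusive).  The surface is taken
#' as given -- one pass, no re-estimation after removals.
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param surface a \linkS4class{DecisionSurface} on the same grid.
#'
#' @return list with `spectra` (the kept \linkS4class{SpectraSet}; `NULL`
#'   when everything is discarded) and `report`: `keptIds`,
#'   `discardedIds`, `discardFraction`.
#' @export
filterOutliers <- function(x, surface) {
  stopifnot(methods::is(x, "SpectraSet"),
            methods::is(surface, "DecisionSurface"))
  if (!isTRUE(all.equal(wavenumbers(x), surface@wavenumbers)))
    stop("spectra and surface are on different wavenumber grids")
  X <- spectraMatrix(x)
  lo <- lowerBound(surface); up <- upperBound(surface)
  inside <- vapply(seq_len(nrow(X)),
                   function(i) all(X[i, ] >= lo & X[i, ] <= up),
                   logical(1L))
  report <- list(keptIds = rownames(X)[inside],
                 discardedIds = rownames(X)[!inside],
                 discardFraction = mean(!inside))
  kept <- if (any(inside)) x[, inside] else NULL
  list(spectra = kept, report = report)
}

#' Full preprocessing: smooth, then filter outliers per class
#'
#' Applies Savitzky-Golay smoothing to every spectrum, builds one decision
#' surface per class from the smoothed spectra, and discards any spectrum
#' leaving its class envelope at one or more channels.
#'
#' @param x a \linkS4class{SpectraSet} with both classes.
#' @inheritParams savgolSmooth
#' @param k envelope half-width in standard deviations (default 3).
#'
#' @return list with `spectra` (kept, smoothed \linkS4class{SpectraSet},
#'   original relative order preserved), `surfaces` (per-class
#'   \linkS4class{DecisionSurface} list, names `"0"`/`"1"`) and `report`
#'   (per-class and overall discard fractions, kept/discarded ids).
#' @examples
#' s <- simulateSpectra(syntheticConfig(p = 300, nPerClass = 40, seed = 3))
#' pp <- preprocessSpectra(s, window = 31)
#' pp$report$discardFraction
#' @export
preprocessSpectra <- function(x, window = 91L, polyorder = 5L, k = 3) {
  stopifnot(methods::is(x, "SpectraSet"))
  sm <- smoothSpectra(x, window = window, polyorder = polyorder)
  lab <- spectraLabels(sm)
  surfaces <- list(); reports <- list()
  keep <- logical(ncol(sm))
  for (cl in sort(unique(lab))) {
    idx <- which(lab == cl)
    surf <- buildDecisionSurface(sm[, idx], k = k)
    res <- filterOutliers(sm[, idx], surf)
    surfaces[[as.character(cl)]] <- surf
    reports[[as.character(cl)]] <- res$report
    keep[idx] <- colnames(sm)[idx] %in% res$report$keptIds
  }
  list(spectra = if (any(keep)) sm[, keep] else NULL,
       surfaces = surfaces,
       report = list(
         perClass = reports,
         keptIds = colnames(sm)[keep],
         discardedIds = colnames(sm)[!keep],
         discardFraction = mean(!keep)))
}
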