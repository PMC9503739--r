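#' @include AllClasses.R
NULL

#' Class mean spectra
#'
#' Channel-wise arithmetic means of the healthy (label 0) and tumoral
#' (label 1) training spectra.
#'
#' @param train a \linkS4class{SpectraSet} with both classes present.
#'
#' @return list with vectors `h` (healthy mean) and `t` (tumoral mean).
#' @export
classMeans <- function(train) {
  stopifnot(methods::is(train, "SpectraSet"))
  lab <- spectraLabels(train)
  if (!all(c(0L, 1L) %in% lab))
    stop("both classes must be present to compute class means")
  X <- spectraMatrix(train)
  list(h = colMeans(X[lab == 0L, , drop = FALSE]),
       t = colMeans(X[lab == 1L, , drop = FALSE]))
}

#' Fit the "global" (nearest-mean) classifier
#'
#' @param train a \linkS4class{SpectraSet} with both classes.
#' @param tau decision weight in `[0, 1]`; 1/2 gives plain nearest-mean
#'   classification.
#'
#' @return a \linkS4class{GeometricModel}.
#' @seealso [classifyGeometric()], [squaredL2Distances()]
#' @export
fitGlobalModel <- function(train, tau = 0.5) {
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]")
  cm <- classMeans(train)
  methods::new("GeometricModel", wavenumbers = wavenumbers(train),
               h = cm$h, t = cm$t, tau = as.numeric(tau))
}

#' Squared distances to the class mean spectra
#'
#' For each spectrum, the sum over channels of squared differences to the
#' healthy and tumoral means (the squared Euclidean norm; no square root is
#' taken).
#'
#' @param x a \linkS4class{SpectraSet}, a matrix (spectra in rows) or a
#'   single numeric spectrum on the model's grid.
#' @param model a \linkS4class{GeometricModel}.
#'
#' @return data.frame with columns `dh` and `dt` (a.u.^2), one row per
#'   spectrum.
#' @export
squaredL2Distances <- function(x, model) {
  stopifnot(methods::is(model, "GeometricModel"))
  if (methods::is(x, "SpectraSet")) x <- spectraMatrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(model@h))
    stop("channel count does not match the model grid")
  data.frame(dh = rowSums(sweep(x, 2L, model@h)^2),
             dt = rowSums(sweep(x, 2L, model@t)^2))
}

#' tau-weighted nearest-mean decision
#'
#' Predicts tumoral (1) when `tau * d_t <= (1 - tau) * d_h` (boundary
#' inclusive), healthy (0) otherwise.  `tau = 0` always predicts 1;
#' `tau = 1` predicts 1 only at `d_t = 0`.
#'
#' @param dh,dt squared distances to the healthy and tumoral means
#'   (non-negative, recycled together).
#' @param tau weight in `[0, 1]`.
#'
#' @return integer vector of 0/1 predictions.
#' @examples
#' classifyGeometric(dh = 4.7e6, dt = 14.9e6, tau = 0.34)  # healthy
#' @export
classifyGeometric <- function(dh, dt, tau) {
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]")
  if (any(dh < 0) || any(dt < 0)) stop("squared distances must be >= 0")
  as.integer(tau * dt <= (1 - tau) * dh)
}

#' Classify spectra with the global model
#'
#' @inheritParams squaredL2Distances
#' @param tau optional weight overriding the model's stored value.
#'
#' @return integer vector of 0/1 predictions.
#' @export
predictGlobal <- function(model, x, tau = NULL) {
  if (is.null(tau)) tau <- model@tau
  d <- squaredL2Distances(x, model)
  classifyGeometric(d$dh, d$dt, tau)
}
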