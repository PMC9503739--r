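#' @include AllClasses.R
NULL

## Evaluate a function under a temporary RNG state so callers' streams are
## untouched.  Every stochastic entry point funnels through this.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Equally spaced Raman-shift grid
#'
#' @param p number of channels (>= 2).
#' @param minShift,maxShift interval endpoints in cm^-1; both are included
#'   in the grid.  Defaults reproduce the instrument range 50.6--3288.5
#'   cm^-1 at p = 1680.
#'
#' @return numeric vector of length `p`, strictly increasing.
#' @examples
#' g <- makeGrid(1680)
#' range(g)
#' @export
makeGrid <- function(p = 1680L, minShift = 50.6, maxShift = 3288.5) {
  if (length(p) != 1L || !is.finite(p) || p < 2)
    stop("p must be a single integer >= 2")
  if (minShift >= maxShift)
    stop("minShift must be smaller than maxShift")
  seq(minShift, maxShift, length.out = as.integer(p))
}

#' Describe one Raman band of the synthetic template
#'
#' @param center band position (cm^-1).
#' @param width half-width at half maximum (lorentzian) or Gaussian sd
#'   (cm^-1); must be positive.
#' @param amplitudeHealthy,amplitudeTumoral band heights (a.u., >= 0) for
#'   the two classes; a class difference is created by making them unequal.
#' @param shape `"lorentzian"` (default) or `"gaussian"`.
#'
#' @return a `peakSpec` list.
#' @export
peakSpec <- function(center, width, amplitudeHealthy,
                     amplitudeTumoral = amplitudeHealthy,
                     shape = c("lorentzian", "gaussian")) {
  shape <- match.arg(shape)
  if (width <= 0) stop("width must be positive")
  if (amplitudeHealthy < 0 || amplitudeTumoral < 0)
    stop("amplitudes must be non-negative")
  structure(list(center = center, width = width,
                 amplitudeHealthy = amplitudeHealthy,
                 amplitudeTumoral = amplitudeTumoral, shape = shape),
            class = "peakSpec")
}

#' Default synthetic band set
#'
#' Lorentzian bands at 230 (Ag-N stretch), 540, 1320, 1550 (aromatic C-C /
#' C-N region) and 2930 cm^-1 (CH stretch).  The class difference is
#' carried entirely by the 1550 cm^-1 band, which is markedly stronger in
#' the tumoral template.
#'
#' @return list of [peakSpec()] objects.
#' @export
defaultPeaks <- function() {
  list(peakSpec(230,  25, 800),
       peakSpec(540,  30, 500),
       peakSpec(1320, 40, 700),
       peakSpec(1550, 45, amplitudeHealthy = 600, amplitudeTumoral = 1100),
       peakSpec(2930, 35, 1500))
}

#' Configuration of the synthetic spectrum simulator
#'
#' Bundles the wavenumber grid, the band templates and the noise/artifact
#' model that [simulateSpectra()] draws from.  Defaults emulate the
#' measured data set: 1680 channels over 50.6--3288.5 cm^-1 and 1990
#' spectra per class, with smooth correlated noise and rare gross
#' artifacts.
#'
#' @param p,minShift,maxShift grid parameters, see [makeGrid()].
#' @param peaks list of [peakSpec()] bands.
#' @param baselineAmplitude height (a.u.) of the smooth broad background
#'   hump common to both classes.
#' @param noiseSdIid standard deviation (a.u.) of channel-independent
#'   noise.
#' @param noiseSdSmooth standard deviation (a.u.) of the smooth correlated
#'   noise component (moving-average-filtered Gaussian).
#' @param noiseCorrelationLength moving-average window of the smooth noise,
#'   in channels.
#' @param amplitudeJitterSd sd of the per-spectrum multiplicative template
#'   jitter (dimensionless).
#' @param outlierRate probability in `[0, 1]` that a spectrum receives a
#'   gross artifact (and is flagged).  The default 0.15 mirrors the share
#'   of measured spectra that gross experimental fluctuations typically
#'   contaminate.
#' @param outlierMagnitude artifact size in multiples of the total noise
#'   sd (default 10: gross relative to the noise floor, i.e. far outside
#'   a 3 sd envelope at the affected channels).
#' @param outlierKinds artifact repertoire: any subset of
#'   `c("spike", "shift")` (single-channel spike; signed whole-spectrum
#'   baseline shift).  Each flagged spectrum draws its kind uniformly.
#' @param nPerClass spectra per class (>= 1).
#' @param seed integer seed; identical configurations reproduce identical
#'   data bitwise.
#'
#' @return a validated `syntheticConfig` list.
#' @seealso [simulateSpectra()], [classTemplate()]
#' @export
syntheticConfig <- function(p = 1680L, minShift = 50.6, maxShift = 3288.5,
                            peaks = defaultPeaks(),
                            baselineAmplitude = 400,
                            noiseSdIid = 8,
                            noiseSdSmooth = 40,
                            noiseCorrelationLength = 60L,
                            amplitudeJitterSd = 0.03,
                            outlierRate = 0.15,
                            outlierMagnitude = 10,
                            outlierKinds = c("spike", "shift"),
                            nPerClass = 1990L,
                            seed = 1L) {
  grid <- makeGrid(p, minShift, maxShift)
  stopifnot(is.list(peaks))
  outlierKinds <- match.arg(outlierKinds, c("spike", "shift"),
                            several.ok = TRUE)
  if (noiseSdIid < 0 || noiseSdSmooth < 0 || amplitudeJitterSd < 0)
    stop("noise and jitter standard deviations must be non-negative")
  if (outlierRate < 0 || outlierRate > 1)
    stop("outlierRate must lie in [0, 1]")
  if (nPerClass < 1) stop("nPerClass must be at least 1")
  if (noiseCorrelationLength < 1)
    stop("noiseCorrelationLength must be at least 1 channel")
  structure(list(grid = grid, peaks = peaks,
                 baselineAmplitude = baselineAmplitude,
                 noiseSdIid = noiseSdIid, noiseSdSmooth = noiseSdSmooth,
                 noiseCorrelationLength = as.integer(noiseCorrelationLength),
                 amplitudeJitterSd = amplitudeJitterSd,
                 outlierRate = outlierRate,
                 outlierMagnitude = outlierMagnitude,
                 outlierKinds = outlierKinds,
                 nPerClass = as.integer(nPerClass),
                 seed = as.integer(seed)),
            class = "syntheticConfig")
}

peakProfile <- function(peak, grid, amplitude) {
  u <- (grid - peak$center) / peak$width
  if (peak$shape == "lorentzian") amplitude / (1 + u^2)
  else amplitude * exp(-u^2 / 2)
}

#' Noise-free class template
#'
#' Deterministic template spectrum for one class: a smooth broad baseline
#' plus the sum of the configured bands evaluated with that class's
#' amplitudes.  Templates of the two classes differ only at channels where
#' band amplitudes differ.
#'
#' @param config a [syntheticConfig()].
#' @param label 0 (healthy) or 1 (tumoral).
#'
#' @return numeric vector over `config$grid`.
#' @export
classTemplate <- function(config, label) {
  stopifnot(inherits(config, "syntheticConfig"), label %in% c(0, 1))
  grid <- config$grid
  mid <- (grid[1] + grid[length(grid)]) / 2
  span <- grid[length(grid)] - grid[1]
  ## broad near-flat hump: common background of the dried droplet
  tmpl <- config$baselineAmplitude * exp(-((grid - mid) / span)^2)
  for (pk in config$peaks) {
    amp <- if (label == 1) pk$amplitudeTumoral else pk$amplitudeHealthy
    tmpl <- tmpl + peakProfile(pk, grid, amp)
  }
  tmpl
}

#' Simulate a labelled two-class spectra set
#'
#' Draws `nPerClass` spectra per class as
#' `(1 + jitter) * template + smooth correlated noise + iid noise`,
#' then gives a Bernoulli(`outlierRate`) subset a gross artifact -- either
#' a single-channel spike or a signed whole-spectrum baseline shift, both
#' of `outlierMagnitude` total noise sd -- and flags it in
#' `injectedOutlier`.  All randomness flows from `config$seed` through a
#' single stream in row order (healthy block first), so identical
#' configurations reproduce identical sets bitwise.
#'
#' @param config a [syntheticConfig()].
#'
#' @return a \linkS4class{SpectraSet} with `injectedOutlier` flags.
#' @examples
#' cfg <- syntheticConfig(p = 200, nPerClass = 25, seed = 7)
#' s <- simulateSpectra(cfg)
#' table(spectraLabels(s))
#' @export
simulateSpectra <- function(config) {
  stopifnot(inherits(config, "syntheticConfig"))
  p <- length(config$grid)
  n <- 2L * config$nPerClass
  tmpl <- list(`0` = classTemplate(config, 0), `1` = classTemplate(config, 1))
  labels <- rep(c(0L, 1L), each = config$nPerClass)
  sigmaTot <- sqrt(config$noiseSdSmooth^2 + config$noiseSdIid^2)
  L <- min(config$noiseCorrelationLength, p)  # clamp for very short grids
  maKernel <- rep(1 / L, L)

  withSeed(config$seed, {
    X <- matrix(0, n, p)
    flagged <- logical(n)
    for (i in seq_len(n)) {
      x <- (1 + stats::rnorm(1L, sd = config$amplitudeJitterSd)) *
        tmpl[[as.character(labels[i])]]
      if (config$noiseSdSmooth > 0) {
        e <- stats::rnorm(p)
        sm <- as.numeric(stats::filter(e, maKernel, method = "convolution",
                                       sides = 2L, circular = TRUE))
        x <- x + sm * sqrt(L) * config$noiseSdSmooth
      }
      if (config$noiseSdIid > 0)
        x <- x + stats::rnorm(p, sd = config$noiseSdIid)
      if (config$outlierRate > 0 &&
          stats::runif(1L) < config$outlierRate) {
        flagged[i] <- TRUE
        kind <- if (length(config$outlierKinds) == 1L) config$outlierKinds
                else sample(config$outlierKinds, 1L)
        mag <- config$outlierMagnitude * sigmaTot
        if (kind == "spike") {
          j <- sample.int(p, 1L)
          x[j] <- x[j] + mag
        } else {
          x <- x + sample(c(-1, 1), 1L) * mag
        }
      }
      X[i, ] <- x
    }
    ids <- sprintf("%s%04d", ifelse(labels == 1L, "T", "H"),
                   c(seq_len(config$nPerClass), seq_len(config$nPerClass)))
    SpectraSet(X, wavenumbers = config$grid, labels = labels, ids = ids,
               injectedOutlier = flagged)
  })
}
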