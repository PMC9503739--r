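# Small-scale synthetic configurations used across the test files.

# Clean two-class set: no artifacts, modest size, clear 1550 band effect.
cleanConfig <- function(p = 200L, nPerClass = 50L, seed = 1L, ...) {
  syntheticConfig(p = p, nPerClass = nPerClass, seed = seed,
                  outlierRate = 0, ...)
}

# Null set: identical class templates (no band differs between classes).
nullPeaks <- function() {
  list(peakSpec(230,  25, 800),
       peakSpec(540,  30, 500),
       peakSpec(1320, 40, 700),
       peakSpec(1550, 45, 850),
       peakSpec(2930, 35, 1500))
}

nullConfig <- function(p = 200L, nPerClass = 50L, seed = 1L, ...) {
  syntheticConfig(p = p, nPerClass = nPerClass, seed = seed,
                  peaks = nullPeaks(), outlierRate = 0, ...)
}

# Plain matrix -> SpectraSet shortcut on a unit grid.
asSet <- function(X, labels, wavenumbers = seq_len(ncol(as.matrix(X)))) {
  SpectraSet(as.matrix(X), wavenumbers = wavenumbers, labels = labels)
}
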