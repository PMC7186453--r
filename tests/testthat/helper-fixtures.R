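# Shared desk-scale fixtures, all generated in code.

smallPhantom <- function(shape = c(16L, 16L, 6L)) {
  phantomFixture(phantomGrid(shape))
}

phantomWaveform <- function(tr = 4, nScans = 1L, blockLength = 48,
                            scanLength = 192, seed = 7L) {
  makeWaveform(c(0, 0.5, 1, 1.5), blockLength = blockLength, tr = tr,
               nScans = nScans, scanLength = scanLength, seed = seed)
}

# Hand-built dual-echo series from explicit phase/magnitude arrays
# (defaults: single volume, unit magnitude).
buildSeries <- function(phaseE1, phaseE2, magnitudeE1 = NULL,
                        magnitudeE2 = NULL, grid = NULL,
                        params = acquisitionParams(tr = 2)) {
  d4 <- dim(phaseE2)
  if (is.null(magnitudeE1)) magnitudeE1 <- array(1, d4)
  if (is.null(magnitudeE2)) magnitudeE2 <- array(1, d4)
  if (is.null(grid)) grid <- voxelGrid(d4[1:3], c(1, 1, 1))
  new("DualEchoSeries",
      magnitudeE1 = magnitudeE1, magnitudeE2 = magnitudeE2,
      phaseE1 = wrapPhase(phaseE1), phaseE2 = wrapPhase(phaseE2),
      grid = grid, params = params, truth = list())
}

# Waveform with explicit currents (e.g. a sham or sign-flipped session).
waveformFrom <- function(currents, tr, scanBoundaries = 1L, blockLength = tr) {
  new("CurrentWaveform", currents = as.numeric(currents), tr = tr,
      scanBoundaries = as.integer(scanBoundaries), blockLength = blockLength)
}
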