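test_that("block waveforms realise the protocol layouts", {
  # in-vivo protocol: 1.5-min blocks at TR 2 s -> 45 volumes per block
  wf <- makeWaveform(c(0, 1, 1.5, 2), blockLength = 90, tr = 2,
                     nScans = 2L, scanLength = 750, seed = 1)
  # every 45-volume chunk within a scan holds one constant level
  for (s in 1:2) {
    cur <- currents(wf)[(1:375) + (s - 1) * 375]
    chunk <- ceiling(seq_along(cur) / 45)
    expect_true(all(tapply(cur, chunk, function(x) length(unique(x))) == 1L))
  }
  expect_equal(nVolumes(wf), 750)
  expect_equal(scanBoundaries(wf), c(1L, 376L))
  # each scan holds each level at least once
  for (s in 1:2) {
    idx <- (1:375) + (s - 1) * 375
    expect_setequal(unique(currents(wf)[idx]), c(0, 1, 1.5, 2))
  }
  # phantom protocol: 3-min blocks at TR 4 s -> 45 volumes, 4 blocks/scan
  wfp <- makeWaveform(c(0, 0.5, 1, 1.5), blockLength = 180, tr = 4,
                      nScans = 3L, scanLength = 720, seed = 2)
  expect_equal(unname(rle(currents(wfp)[1:180])$lengths), rep(45L, 4L))
})

test_that("sham, negation, explicit order and gaps behave as specified", {
  sham <- makeWaveform(0, blockLength = 8, tr = 2, scanLength = 64)
  expect_true(all(currents(sham) == 0))
  wf <- makeWaveform(c(0, 1, 1.5, 2), blockLength = 8, tr = 2,
                     scanLength = 64, seed = 5)
  neg <- makeWaveform(-c(0, 1, 1.5, 2), blockLength = 8, tr = 2,
                      scanLength = 64, seed = 5)
  expect_identical(currents(neg), -currents(wf))
  fixed <- makeWaveform(c(1, 2), blockLength = 4, tr = 2, scanLength = 16,
                        order = c(2, 1))
  expect_equal(currents(fixed), rep(c(2, 1, 2, 1), each = 2))
  gap <- makeWaveform(c(1, 2), blockLength = 4, tr = 2, scanLength = 24,
                      order = c(1, 2), gapLength = 2)
  expect_equal(currents(gap), c(1, 1, 0, 2, 2, 0, 1, 1, 0, 2, 2, 0))
  expect_error(makeWaveform(numeric(0), 8, 2, scanLength = 16), "non-empty")
  expect_error(makeWaveform(1, blockLength = 1, tr = 2, scanLength = 16),
               "at least one TR")
  expect_error(makeWaveform(1, blockLength = 3, tr = 2, scanLength = 16),
               "multiple")
})

test_that("the canonical HRF is a unit-sum double gamma peaking near 6 s", {
  h <- canonicalHrf(0.5)
  expect_equal(sum(h), 1)
  t <- seq(0, 32, by = 0.5)
  expect_equal(t[which.max(h)], 5, tolerance = 0.3)  # mode of gamma(6,1)
  expect_lt(min(h), 0)  # undershoot present
  # block convolution converges to the block level
  x <- rep(2, 200)
  expect_equal(convolveWithHrf(x, h)[150], 2, tolerance = 1e-6)
})

test_that("phase encodes the field per the field-to-phase constant", {
  g <- voxelGrid(c(2L, 2L, 1L), c(3.4, 3.4, 5))
  fm <- fieldMap(g, array(1, dim = gridShape(g)))  # 1 nT/mA everywhere
  wf <- waveformFrom(c(0, 1), tr = 4)
  p <- acquisitionParams(tr = 4, complexNoiseSd = 0, backgroundFieldSd = 0,
                         seed = 1L)
  ser <- simulateSeries(fm, wf, p)
  inc <- ser@phaseE2[1, 1, 1, 2] - ser@phaseE2[1, 1, 1, 1]
  expect_equal(inc, 2.6752218744e8 * 1e-9 * 0.026, tolerance = 1e-9)
  expect_equal(floor(inc * 180 / pi * 100) / 100, 0.39)  # 0.39 degrees
  # echo consistency: increment scales with TE
  inc1 <- ser@phaseE1[1, 1, 1, 2] - ser@phaseE1[1, 1, 1, 1]
  expect_equal(inc / inc1, 0.026 / 0.011, tolerance = 1e-9)
})

test_that("zero current with no noise or drift gives a static phase", {
  g <- voxelGrid(c(3L, 3L, 2L), c(2, 2, 2))
  fm <- fieldMap(g, array(rnorm(18), dim = gridShape(g)))
  wf <- waveformFrom(rep(0, 5), tr = 2)
  p <- acquisitionParams(tr = 2, complexNoiseSd = 0, seed = 3L)
  ser <- simulateSeries(fm, wf, p)
  for (t in 2:5)
    expect_identical(ser@phaseE2[, , , t], ser@phaseE2[, , , 1])
})

test_that("phase wraps modulo 2*pi and closure with the truth holds", {
  g <- voxelGrid(c(2L, 1L, 1L), c(1, 1, 1))
  p <- acquisitionParams(tr = 2, complexNoiseSd = 0, backgroundFieldSd = 0,
                         seed = 1L)
  # choose Bz so gamma*Bz*I*TE2 = 2*pi + 0.1 at I = 1
  bz <- (2 * pi + 0.1) / (p@gamma * 1e-9 * p@te2)
  fm <- fieldMap(g, array(bz, dim = gridShape(g)))
  wf <- waveformFrom(c(0, 1), tr = 2)
  ser <- simulateSeries(fm, wf, p)
  expect_equal(ser@phaseE2[1, 1, 1, 2] - ser@phaseE2[1, 1, 1, 1], 0.1,
               tolerance = 1e-10)
  # wrap closure: wrapping the known unwrapped phase reproduces storage
  expect_equal(wrapPhase(truePhase(ser, 2)), ser@phaseE2, tolerance = 1e-12)
  expect_equal(wrapPhase(truePhase(ser, 1)), ser@phaseE1, tolerance = 1e-12)
})

test_that("noise-free phase responds linearly to the applied current", {
  fx <- smallPhantom(c(8L, 8L, 4L))
  wf <- waveformFrom(c(0, 1, 2), tr = 4)
  p <- acquisitionParams(tr = 4, complexNoiseSd = 0, seed = 2L)
  ser <- simulateSeries(fx$field, wf, p)
  u <- truePhase(ser, 2)
  expect_equal(u[, , , 3] - u[, , , 2], u[, , , 2] - u[, , , 1],
               tolerance = 1e-12)
})

test_that("simulation is bit-reproducible under a fixed seed", {
  fx <- smallPhantom(c(6L, 6L, 3L))
  wf <- waveformFrom(c(0, 1, 0, 1), tr = 4)
  p <- acquisitionParams(tr = 4, seed = 99L)
  s1 <- simulateSeries(fx$field, wf, p)
  s2 <- simulateSeries(fx$field, wf, p)
  expect_identical(s1@phaseE2, s2@phaseE2)
  expect_identical(s1@magnitudeE1, s2@magnitudeE1)
  p2 <- p; p2@seed <- 100L
  expect_false(identical(simulateSeries(fx$field, wf, p2)@phaseE2, s1@phaseE2))
})

test_that("a BOLD injection scales only the second-echo magnitude in-region", {
  g <- voxelGrid(c(4L, 4L, 2L), c(2, 2, 2))
  fm <- fieldMap(g, array(0, dim = gridShape(g)))
  wf <- waveformFrom(c(0, 0, 2, 2, 2, 2), tr = 2)
  region <- array(FALSE, gridShape(g)); region[1:2, , ] <- TRUE
  inj <- boldInjection(region, -0.15, canonicalHrf(2))
  p <- acquisitionParams(tr = 2, complexNoiseSd = 0, seed = 4L)
  ser <- simulateSeries(fm, wf, p, injection = inj)
  conv <- convolveWithHrf(currents(wf), canonicalHrf(2))
  expect_equal(ser@magnitudeE2[1, 1, 1, ] / p@baselineMagnitude,
               1 - 0.15 * conv, tolerance = 1e-12)
  expect_true(all(ser@magnitudeE2[3, , , ] == p@baselineMagnitude))
  expect_true(all(ser@magnitudeE1 == p@baselineMagnitude))
})

test_that("level shifts add per-scan phase offsets at the boundaries", {
  g <- voxelGrid(c(3L, 3L, 1L), c(2, 2, 2))
  fm <- fieldMap(g, array(0, dim = gridShape(g)))
  wf <- waveformFrom(rep(0, 8), tr = 2, scanBoundaries = c(1L, 5L))
  p <- acquisitionParams(tr = 2, complexNoiseSd = 0, seed = 6L)
  ser <- simulateSeries(fm, wf, p, levelShifts = c(0, 0.5))
  expect_equal(ser@phaseE2[1, 1, 1, 5] - ser@phaseE2[1, 1, 1, 4], 0.5,
               tolerance = 1e-12)
  expect_error(simulateSeries(fm, wf, p, levelShifts = c(0, 0.5, 1)),
               "one entry per scan")
})

test_that("identical cohort subjects arise when all jitter and noise vanish", {
  wf <- makeWaveform(c(0, 1), blockLength = 8, tr = 2, scanLength = 32,
                     seed = 1)
  p <- acquisitionParams(tr = 2, complexNoiseSd = 0, backgroundFieldSd = 0)
  g <- cohortGrid(c(8L, 8L, 4L))
  subs <- lapply(1:2, function(s)
    cohortSubject(s, seed = 1, grid = g, amplitudeJitterSd = 0,
                  effectJitterSd = 0, params = p, waveform = wf))
  expect_identical(fieldValues(subs[[1]]$field), fieldValues(subs[[2]]$field))
  expect_identical(subs[[1]]$series@phaseE2, subs[[2]]$series@phaseE2)
})

test_that("the bilateral pattern has opposite-signed, disjoint lobe cores", {
  pat <- bilateralFieldPattern(cohortGrid())
  v <- fieldValues(pat$field)
  expect_lt(max(v[pat$anodalMask]), 0)
  expect_gt(min(v[pat$cathodalMask]), 0)
  expect_equal(sum(pat$anodalMask & pat$cathodalMask), 0)
})
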