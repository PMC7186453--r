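test_that("detrending removes per-segment lines and is idempotent", {
  d4 <- c(2L, 2L, 1L, 20L)
  drift <- array(rep(seq_len(20) * 0.3, each = 4), d4)
  out <- detrendLinear(drift)
  expect_equal(max(abs(out)), 0, tolerance = 1e-10)
  set.seed(1)
  x <- array(rnorm(prod(d4)), d4)
  expect_equal(detrendLinear(detrendLinear(x)), detrendLinear(x),
               tolerance = 1e-10)
  # per-scan segments: opposite drifts in two scans both removed
  two <- array(rep(c(seq_len(10), seq(10, 1)) * 0.5, each = 4), d4)
  expect_equal(max(abs(detrendLinear(two, c(1L, 11L)))), 0, tolerance = 1e-10)
  # a trend-balanced block contrast survives detrending
  blocks <- rep(c(1, -1, -1, 1), each = 5)     # orthogonal to the trend
  y <- array(rep(blocks, each = 4), d4)
  expect_equal(sum(detrendLinear(y)[1, 1, 1, ] * blocks), sum(blocks^2),
               tolerance = 1e-10)
})

test_that("design assembly matches the nuisance contract", {
  wf <- makeWaveform(c(0, 1, 1.5), blockLength = 4, tr = 2, scanLength = 24,
                     seed = 2)
  X <- buildDesign(wf)
  expect_identical(colnames(X), c("intercept", "trend", "current"))
  expect_identical(X[, "current"], currents(wf))
  gs <- rnorm(12)
  X2 <- buildDesign(wf, globalSignal = gs)
  expect_identical(colnames(X2),
                   c("intercept", "trend", "current", "global_signal"))
  # zero motion columns are dropped with a record
  expect_message(X3 <- buildDesign(wf, motion = matrix(0, 12, 6)),
                 "dropping constant")
  expect_identical(attr(X3, "dropped"), paste0("motion", 1:6))
  # sham: the current column is dropped and the fit refuses slope inference
  sham <- waveformFrom(rep(0, 12), tr = 2)
  expect_message(Xs <- buildDesign(sham), "current")
  expect_false("current" %in% colnames(Xs))
  # a duplicated regressor yields a rank error naming it
  expect_error(
    buildDesign(wf, motion = cbind(currents(wf), matrix(rnorm(60), 12, 5))),
    "rank-deficient.*(motion1|current)")
  # per-scan intercepts absorb pure between-scan steps
  wf2 <- makeWaveform(c(0, 1), blockLength = 4, tr = 2, nScans = 2L,
                      scanLength = 8, seed = 1)
  step <- matrix(as.numeric(seq_len(8) >= 5), ncol = 1,
                 dimnames = list(NULL, "shift_5"))
  expect_message(X4 <- buildDesign(wf2, shifts = step), "absorbed")
  expect_true("shift_5" %in% attr(X4, "dropped"))
})

test_that("the phase GLM recovers a noise-free phantom field to 1e-6 nT/mA", {
  fx <- smallPhantom(c(10L, 10L, 4L))
  wf <- phantomWaveform(scanLength = 96)
  p <- acquisitionParams(tr = 4, complexNoiseSd = 0, seed = 31L)
  res <- runPhantomSession(fx$field, wf, p)
  m <- fieldMask(fx$field)
  expect_lt(max(abs(fieldValues(res$estimate)[m] - fieldValues(fx$field)[m])),
            1e-6)
})

test_that("slope units follow the field-to-phase constant", {
  # phase slope of gamma*1e-9*TE2 rad/mA must read exactly 1 nT/mA
  p <- acquisitionParams(tr = 2)
  slopeRad <- p@gamma * 1e-9 * p@te2
  d4 <- c(2L, 2L, 1L, 12L)
  wf <- waveformFrom(rep(c(0, 1, 1.5, 2), each = 3), tr = 2)
  vals <- array(rep(slopeRad * currents(wf), each = 4), d4)
  ps <- new("PhaseSeries", values = vals, grid = voxelGrid(d4[1:3], 1),
            quality = array(1, d4[1:3]), mask = array(TRUE, d4[1:3]),
            flags = array(FALSE, d4[1:3]))
  est <- fitPhaseGlm(ps, buildDesign(wf), p)
  expect_equal(unname(fieldValues(est)[1, 1, 1]), 1, tolerance = 1e-10)
  expect_equal(unname(est@slopeRad[1, 1, 1]), slopeRad, tolerance = 1e-12)
})

test_that("slopes are invariant to constant and linear phase offsets", {
  fx <- smallPhantom(c(8L, 8L, 3L))
  wf <- phantomWaveform(scanLength = 96)
  p <- acquisitionParams(tr = 4, seed = 32L)
  ser <- simulateSeries(fx$field, wf, p)
  ps <- unwrapDualEcho(ser)
  X <- buildDesign(wf)
  est1 <- fitPhaseGlm(ps, X, p)
  ps2 <- ps
  nT <- nVolumes(ps)
  off <- 0.8 + 0.05 * seq_len(nT)
  ps2@values <- ps@values + array(rep(off, each = prod(dim(ps@values)[1:3])),
                                  dim(ps@values))
  est2 <- fitPhaseGlm(ps2, X, p)
  expect_lt(max(abs(fieldValues(est2) - fieldValues(est1)), na.rm = TRUE),
            1e-10)
})

test_that("a drift-only series yields a null slope against the block design", {
  d4 <- c(3L, 3L, 1L, 24L)
  wf <- makeWaveform(c(0, 1, 1.5, 2), blockLength = 12, tr = 2,
                     scanLength = 48, order = 1:4)
  drift <- array(rep(seq_len(24) * 0.01, each = 9), d4)
  ps <- new("PhaseSeries", values = drift, grid = voxelGrid(d4[1:3], 1),
            quality = array(1, d4[1:3]), mask = array(TRUE, d4[1:3]),
            flags = array(FALSE, d4[1:3]))
  est <- fitPhaseGlm(ps, buildDesign(wf), acquisitionParams(tr = 2))
  expect_lt(max(abs(fieldValues(est))), 1e-9)
})

test_that("noisy phantom slopes sit within their standard errors", {
  fx <- smallPhantom(c(10L, 10L, 4L))
  wf <- phantomWaveform(scanLength = 192)
  p <- acquisitionParams(tr = 4, seed = 33L)
  res <- runPhantomSession(fx$field, wf, p)
  m <- fieldMask(fx$field)
  z <- (fieldValues(res$estimate)[m] - fieldValues(fx$field)[m]) /
    fieldSe(res$estimate)[m]
  expect_gt(mean(abs(z) < 3), 0.99)
})

test_that("magnitude GLM recovers an injected percent change and its sign", {
  d4 <- c(6L, 6L, 2L, 48L)
  wf <- makeWaveform(c(0, 0.5, 1, 1.5), blockLength = 24, tr = 4,
                     scanLength = 192, seed = 4)
  base <- 100
  patch <- array(FALSE, d4[1:3]); patch[1:3, 1:3, 1] <- TRUE
  set.seed(41)
  noise <- array(rnorm(prod(d4), 0, 0.5), d4)
  eff <- array(1, d4)
  eff[patch] <- NA  # marker; fill below
  mag <- array(base, d4) + noise
  idx <- which(patch)
  for (t in seq_len(d4[4]))
    mag[, , , t][idx] <- base * (1 + 0.05 * currents(wf)[t]) + noise[, , , t][idx]
  est <- fitMagnitudeGlm(mag, buildDesign(wf))
  inPatch <- est@pctPerMA[patch]
  # percent scaling divides by the voxel-mean magnitude, which includes the
  # injected effect at the mean applied current
  expected <- 5 / (1 + 0.05 * mean(currents(wf)))
  expect_equal(mean(inPatch), expected, tolerance = 0.05)
  expect_true(all(est@pFwe[patch] < 0.05))
  expect_true(mean(est@pFwe[!patch] < 0.05, na.rm = TRUE) < 0.2)
  # sign-flipped current waveform negates the percent change
  wfneg <- waveformFrom(-currents(wf), tr = 4)
  estn <- fitMagnitudeGlm(mag, buildDesign(wfneg))
  expect_equal(estn@pctPerMA, -est@pctPerMA, tolerance = 1e-8)
  # zero-mean voxels are excluded from percent scaling
  mag0 <- mag; mag0[6, 6, 2, ] <- 0
  est0 <- fitMagnitudeGlm(mag0, buildDesign(wf))
  expect_true(is.na(est0@pctPerMA[6, 6, 2]))
  expect_false(est0@mask[6, 6, 2])
})

test_that("magnitude FWE control keeps the familywise null error rate", {
  d4 <- c(6L, 6L, 2L, 32L)
  wf <- makeWaveform(c(0, 0.5, 1, 1.5), blockLength = 16, tr = 4,
                     scanLength = 128, seed = 5)
  X <- buildDesign(wf)
  set.seed(77)
  hits <- vapply(seq_len(100), function(i) {
    mag <- array(100 + rnorm(prod(d4)), d4)
    est <- fitMagnitudeGlm(mag, X)
    any(est@pFwe[est@mask] < 0.05)
  }, logical(1))
  # nominal familywise rate <= 0.05; allow binomial slack over 100 draws
  expect_lte(mean(hits), 0.10)
})
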