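test_that("spatial correlation reaches its algebraic extremes and its null", {
  g <- voxelGrid(c(8L, 8L, 4L), 1)
  set.seed(1)
  a <- fieldMap(g, array(rnorm(256), gridShape(g)))
  neg <- fieldMap(g, -fieldValues(a))
  expect_equal(spatialPearson(a, a)$r, 1)
  expect_equal(spatialPearson(a, neg)$r, -1)
  # independent maps: |r| < 0.05 at 1e4 voxels in (essentially) every draw
  gBig <- voxelGrid(c(25L, 20L, 20L), 1)
  ok <- vapply(1:20, function(i) {
    x <- fieldMap(gBig, array(rnorm(1e4), gridShape(gBig)))
    y <- fieldMap(gBig, array(rnorm(1e4), gridShape(gBig)))
    abs(spatialPearson(x, y)$r) < 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.95)
  expect_error(spatialPearson(a, fieldMap(g, array(1, gridShape(g)))),
               "zero variance")
  # invariant under a joint voxel reordering
  perm <- sample(256)
  expect_equal(spatialPearson(fieldMap(g, array(fieldValues(a)[perm], gridShape(g))),
                              fieldMap(g, array(fieldValues(neg)[perm], gridShape(g))))$r,
               -1)
})

test_that("range-restricted regression honours its contracts", {
  fx <- smallPhantom()
  ref <- fx$field
  bounds <- c(Inf, 20, 10, 5)
  # measured == reference -> slope 1, intercept 0 in every range
  rr <- rangeRegression(ref, ref, bounds = bounds)
  expect_equal(rr$slope, rep(1, 4), tolerance = 1e-9)
  expect_equal(rr$intercept, rep(0, 4), tolerance = 1e-9)
  expect_true(all(diff(rr$nVoxels) <= 0))
  # measured == -reference -> (-1.00, 0.00)
  neg <- fieldMap(fieldGrid(ref), -fieldValues(ref), fieldMask(ref))
  rrn <- rangeRegression(neg, ref, bounds = bounds)
  expect_equal(rrn$slope, rep(-1, 4), tolerance = 1e-9)
  # pure noise vs reference -> slope ~ 0 (sham contract)
  set.seed(2)
  sham <- fieldMap(fieldGrid(ref), array(rnorm(prod(gridShape(fieldGrid(ref))), 0, 0.2),
                                         gridShape(fieldGrid(ref))), fieldMask(ref))
  rrs <- rangeRegression(sham, ref, bounds = c(Inf))
  expect_lt(abs(rrs$slope), 0.02)
  # the unbounded row equals a plain OLS over the mask
  m <- fieldMask(ref)
  fit <- stats::lm(fieldValues(sham)[m] ~ fieldValues(ref)[m])
  expect_equal(rrs$slope, unname(coef(fit)[2]), tolerance = 1e-12)
  # sparse range rows are flagged, not computed
  tiny <- rangeRegression(ref, ref, bounds = c(Inf, 1e-9))
  expect_true(tiny$flagged[2])
  expect_true(is.na(tiny$slope[2]))
  expect_error(rangeRegression(ref, ref, bounds = c(1, 5)), "descending")
  expect_error(rangeRegression(ref, ref, bounds = c(5, -1)), "positive")
})

test_that("paired mean-field test matches its exact permutation analogue", {
  a <- c(1.2, 0.8, 1.5, 1.1, 0.9, 1.3, 1.0)
  expect_equal(pairedMeanFieldTest(a, a)$p, 1)
  expect_equal(pairedMeanFieldTest(a, a)$meanDifference, 0)
  shifted <- pairedMeanFieldTest(a, a + 1.49)
  expect_equal(shifted$meanDifference, -1.49, tolerance = 1e-12)
  # frozen cohort of per-subject differences (~0.7 SD effect, the regime
  # where p-value accuracy matters); the exhaustive 2^7 sign-flip
  # distribution has probability atoms of 1/64, so pointwise agreement is
  # assessed on this fixture
  d0 <- c(1.6, 0.4, 1.2, 0.9, -0.3, 1.1, 0.7)
  x <- (d0 - mean(d0)) / sd(d0) + 0.7
  y <- rep(0, 7)
  tt <- pairedMeanFieldTest(x, y)
  pp <- pairedMeanFieldTest(x, y, method = "permutation")
  expect_lt(abs(tt$p - pp$p), 0.01)
  expect_equal(stats::t.test(x, y, paired = TRUE)$p.value, tt$p)
  expect_error(pairedMeanFieldTest(1, c(1, 2)), "equal length")
  expect_error(pairedMeanFieldTest(1, 2), "at least 2")
})

test_that("ICC(2,1) matches brute-force ANOVA mean squares", {
  # independent oracle: two-way ANOVA via lm/anova on 5-voxel instances
  iccOracle <- function(x, y) {
    n <- length(x); k <- 2
    df <- data.frame(v = c(x, y), voxel = factor(rep(seq_len(n), 2)),
                     session = factor(rep(1:2, each = n)))
    ms <- stats::anova(stats::lm(v ~ voxel + session, df))$`Mean Sq`
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  }
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(5); y <- rnorm(5)
    expect_equal(iccAgreement(x, y)$icc, iccOracle(x, y), tolerance = 1e-10)
  }
  g <- voxelGrid(c(10L, 10L, 5L), 1)
  test <- array(rnorm(500), gridShape(g))
  expect_equal(iccAgreement(fieldMap(g, test), fieldMap(g, test))$icc, 1)
  # equal noise in both sessions, of the truth's variance -> ICC ~ 1/2;
  # noise in the retest only -> ICC ~ 2/3 (variance-components arithmetic)
  tru <- rnorm(20000)
  expect_equal(iccAgreement(tru + rnorm(20000), tru + rnorm(20000))$icc, 0.5,
               tolerance = 0.05)
  expect_equal(iccAgreement(tru, tru + rnorm(20000))$icc, 2 / 3,
               tolerance = 0.05)
  # constant retest: agreement collapses to <= ~0
  expect_lt(iccAgreement(1:50, rep(2, 50))$icc, 0.1)
  expect_error(iccAgreement(rep(1, 5), rep(1, 5)), "zero total variance")
})

test_that("cluster thresholding keeps only large significant components", {
  d <- c(40L, 20L, 6L)
  p <- array(1, d)
  expect_equal(sum(thresholdClusterMask(p, 0.05)), 0)
  # one 1200-voxel blob and one 500-voxel blob, separated by > 1 voxel
  blobBig <- array(FALSE, d); blobBig[1:20, 1:10, 1:6] <- TRUE     # 1200
  blobSmall <- array(FALSE, d); blobSmall[25:34, 1:10, 1:5] <- TRUE # 500
  p[blobBig | blobSmall] <- 1e-6
  keep <- thresholdClusterMask(p, 0.05, minCluster = 1000)
  expect_equal(sum(keep), 1200)
  expect_identical(keep, blobBig)
  # minCluster = 1 is pure p-thresholding
  expect_identical(thresholdClusterMask(p, 0.05, 1L), p < 0.05)
  # 6-connectivity splits what 26-connectivity joins
  q <- array(1, c(4L, 4L, 1L))
  q[1, 1, 1] <- q[2, 2, 1] <- 1e-6
  expect_equal(sum(thresholdClusterMask(q, 0.05, minCluster = 2,
                                        connectivity = 26L)), 2)
  expect_equal(sum(thresholdClusterMask(q, 0.05, minCluster = 2,
                                        connectivity = 6L)), 0)
})

test_that("DICE coefficient counts overlap and rejects empty input", {
  d <- c(10L, 10L, 5L)
  a <- array(FALSE, d); b <- array(FALSE, d)
  a[1:100] <- TRUE
  b[41:140] <- TRUE  # |a| = |b| = 100, overlap 60
  expect_equal(diceCoefficient(a, b), 0.6)
  expect_equal(diceCoefficient(a, b), diceCoefficient(b, a))
  expect_equal(diceCoefficient(a, a), 1)
  expect_equal(diceCoefficient(a, array(c(rep(FALSE, 400), rep(TRUE, 100)), d)), 0)
  expect_error(diceCoefficient(array(FALSE, d), array(FALSE, d)), "empty")
})

test_that("stage-1 extraction reduces to the voxel timecourse for a point map", {
  d4 <- c(4L, 4L, 2L, 10L)
  set.seed(5)
  mag <- array(rnorm(prod(d4), 100, 1), d4)
  map <- array(0, d4[1:3]); map[2, 3, 1] <- 1
  tc <- extractTimecourse(mag, map)
  expect_equal(stats::cor(tc, mag[2, 3, 1, ]), 1)
  expect_error(extractTimecourse(mag, array(1, d4[1:3])), "variance")
})

test_that("group component test recovers an injected effect and stays null otherwise", {
  wf <- makeWaveform(c(0, 1, 1.5, 2), blockLength = 30, tr = 2,
                     scanLength = 240, seed = 6)
  g <- cohortGrid(c(12L, 12L, 6L))
  subs <- lapply(1:3, function(s)
    cohortSubject(s, seed = 11, grid = g, effectJitterSd = 0,
                  waveform = wf))
  res <- componentCurrentTest(subs, subs[[1]]$cathodalMask, wf)
  expect_equal(res$mean, -0.15, tolerance = 0.01)
  expect_lt(res$p, 0.05)
  # the anodal region carries no injected effect
  resA <- componentCurrentTest(subs, subs[[1]]$anodalMask, wf)
  expect_gt(resA$p, 0.05)
  expect_lt(abs(resA$mean), 0.01)
  expect_error(componentCurrentTest(subs[1], subs[[1]]$cathodalMask, wf),
               "at least 2")
})
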