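# Pull a numeric 3D array out of the containers the validation statistics
# accept (FieldMap, FieldEstimate, plain array).
.asVolume <- function(x) {
  if (is(x, "FieldMap") || is(x, "FieldEstimate")) fieldValues(x) else x
}

.sharedMask <- function(a, b, mask) {
  m <- if (is.null(mask)) TRUE else as.logical(mask)
  for (x in list(a, b))
    if (is(x, "FieldMap") || is(x, "FieldEstimate")) m <- m & fieldMask(x)
  av <- .asVolume(a)
  if (isTRUE(m[1L]) && length(m) == 1L) m <- rep(TRUE, length(av))
  array(m, dim(av))
}

#' Spatial Pearson correlation between two maps
#'
#' Pearson correlation over masked voxels, the accuracy statistic used to
#' compare measured and simulated field maps.
#'
#' @param a,b [FieldMap-class], [FieldEstimate-class] or 3D arrays on the
#'   same grid.
#' @param mask optional 3D logical array; the maps' own masks are always
#'   intersected in.
#' @return A list: `r`, `p` (two-tailed), `n`.
#' @export
spatialPearson <- function(a, b, mask = NULL) {
  m <- .sharedMask(a, b, mask)
  x <- .asVolume(a)[m]
  y <- .asVolume(b)[m]
  if (length(x) < 3L) stop("need at least 3 masked voxels")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the maps")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Range-restricted regression of measured on reference fields
#'
#' Sensitivity analysis: ordinary least squares of the measured field on the
#' reference field, repeated over progressively weaker field ranges (voxels
#' with `|reference| <= bound`) down to the nT scale. A perfectly accurate
#' measurement keeps slope 1 / intercept 0 in every range; a sham
#' measurement keeps slope ~0.
#'
#' @param measured,reference maps on the same grid.
#' @param mask optional 3D logical array.
#' @param bounds positive bounds in nT, strictly descending; `Inf` means no
#'   restriction.
#' @return A data.frame with one row per bound: `bound`, `nVoxels`,
#'   `slope`, `intercept`, `r`, `p`, `flagged` (TRUE when fewer than 3
#'   voxels fall in the range; statistics NA there).
#' @export
rangeRegression <- function(measured, reference, mask = NULL,
                            bounds = c(Inf, 10, 5, 1)) {
  if (any(bounds <= 0)) stop("bounds must be positive")
  if (is.unsorted(rev(bounds), strictly = TRUE))
    stop("bounds must be strictly descending")
  m <- .sharedMask(measured, reference, mask)
  x <- .asVolume(reference)[m]
  y <- .asVolume(measured)[m]
  rows <- lapply(bounds, function(bd) {
    sel <- abs(x) <= bd
    n <- sum(sel)
    if (n < 3L)
      return(data.frame(bound = bd, nVoxels = n, slope = NA_real_,
                        intercept = NA_real_, r = NA_real_, p = NA_real_,
                        flagged = TRUE))
    fit <- stats::lm(y[sel] ~ x[sel])
    ct <- stats::cor.test(x[sel], y[sel])
    data.frame(bound = bd, nVoxels = n,
               slope = unname(stats::coef(fit)[2L]),
               intercept = unname(stats::coef(fit)[1L]),
               r = unname(ct$estimate), p = ct$p.value, flagged = FALSE)
  })
  do.call(rbind, rows)
}

#' Paired test of per-subject mean field strengths
#'
#' Paired two-sided test of per-subject whole-mask mean fields (e.g.
#' simulations vs measurements across a cohort). The default is the paired
#' t-test; an exhaustive sign-flip permutation test is available as an
#' exact alternative for small cohorts.
#'
#' @param a,b numeric vectors of per-subject means, equal length >= 2.
#' @param method "t" (default) or "permutation" (exhaustive sign flips,
#'   n <= 20).
#' @return A list: `meanDifference` (mean of a - b), `statistic`, `df`
#'   (t method), `p` (two-tailed), `method`.
#' @export
pairedMeanFieldTest <- function(a, b, method = c("t", "permutation")) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("a and b must have equal length")
  n <- length(a)
  if (n < 2L) stop("need at least 2 subjects")
  d <- a - b
  md <- mean(d)
  if (stats::sd(d) <= 1e-12 * max(abs(d), 1)) {
    return(list(meanDifference = md, statistic = if (md == 0) 0 else Inf,
                df = n - 1L, p = if (md == 0) 1 else 0, method = method))
  }
  if (method == "t") {
    tt <- stats::t.test(a, b, paired = TRUE)
    list(meanDifference = md, statistic = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value, method = method)
  } else {
    if (n > 20L) stop("exhaustive permutation limited to n <= 20")
    tObs <- md / (stats::sd(d) / sqrt(n))
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    tPerm <- apply(signs, 1L, function(s) {
      ds <- d * s
      sdd <- stats::sd(ds)
      if (sdd == 0) { if (mean(ds) == 0) 0 else Inf } else mean(ds) / (sdd / sqrt(n))
    })
    p <- mean(abs(tPerm) >= abs(tObs) - 1e-12)
    list(meanDifference = md, statistic = tObs, df = NA_real_, p = p,
         method = method)
  }
}

#' Intraclass correlation ICC(2,1), absolute agreement
#'
#' Test-retest reliability of voxelwise field estimates: the two-way
#' random-effects, absolute-agreement, single-measurement intraclass
#' correlation, with voxels as the subjects of measurement and sessions as
#' raters:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param test,retest maps on the same grid, or numeric vectors.
#' @param mask optional 3D logical array (map input only).
#' @return A list: `icc`, and `components` (MSR, MSC, MSE, n, k).
#' @export
iccAgreement <- function(test, retest, mask = NULL) {
  if (is.numeric(test) && is.null(dim(test))) {
    x <- test; y <- retest
  } else {
    m <- .sharedMask(test, retest, mask)
    x <- .asVolume(test)[m]
    y <- .asVolume(retest)[m]
  }
  n <- length(x)
  if (n < 3L) stop("need at least 3 masked voxels")
  dat <- cbind(x, y)
  k <- 2L
  grand <- mean(dat)
  rowM <- rowMeans(dat)
  colM <- colMeans(dat)
  ssr <- k * sum((rowM - grand)^2)
  ssc <- n * sum((colM - grand)^2)
  sst <- sum((dat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1L)
  msc <- ssc / (k - 1L)
  mse <- sse / ((n - 1L) * (k - 1L))
  denom <- msr + (k - 1L) * mse + k * (msc - mse) / n
  if (denom == 0) stop("zero total variance: ICC undefined")
  list(icc = (msr - mse) / denom,
       components = list(msr = msr, msc = msc, mse = mse, n = n, k = k))
}

# 26-connected (or 6-connected) component labelling of a logical volume.
.labelComponents <- function(sig, connectivity = 26L) {
  d <- dim(sig)
  n <- prod(d)
  lab <- integer(n)
  sigv <- as.logical(sig)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1L, , drop = FALSE]
  idxAll <- which(sigv)
  if (!length(idxAll)) return(array(lab, d))
  coord <- arrayInd(idxAll, d)
  lookup <- integer(n); lookup[idxAll] <- seq_along(idxAll)
  cur <- 0L
  for (start in seq_along(idxAll)) {
    v0 <- idxAll[start]
    if (lab[v0] != 0L) next
    cur <- cur + 1L
    queue <- v0
    lab[v0] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      cc <- coord[lookup[v], ]
      nb <- sweep(offs, 2L, cc, "+")
      ok <- nb[, 1L] >= 1L & nb[, 1L] <= d[1L] &
        nb[, 2L] >= 1L & nb[, 2L] <= d[2L] &
        nb[, 3L] >= 1L & nb[, 3L] <= d[3L]
      nb <- nb[ok, , drop = FALSE]
      ni <- nb[, 1L] + (nb[, 2L] - 1L) * d[1L] + (nb[, 3L] - 1L) * d[1L] * d[2L]
      ni <- ni[sigv[ni] & lab[ni] == 0L]
      if (length(ni)) {
        lab[ni] <- cur
        queue <- c(queue, ni)
      }
    }
  }
  array(lab, d)
}

#' Threshold a p-value map with a cluster-extent criterion
#'
#' Voxels below the p threshold are kept, then connected components smaller
#' than `minCluster` voxels are removed (26-neighbourhood by default, the
#' usual choice in fMRI cluster thresholding).
#'
#' @param pMap 3D array of voxelwise p values.
#' @param pThreshold voxelwise threshold (keep p < pThreshold).
#' @param minCluster minimum surviving cluster size in voxels (1 = pure
#'   p-thresholding).
#' @param connectivity 26 (default) or 6.
#' @return 3D logical array.
#' @export
thresholdClusterMask <- function(pMap, pThreshold, minCluster = 1L,
                                 connectivity = 26L) {
  sig <- !is.na(pMap) & pMap < pThreshold
  if (minCluster <= 1L || !any(sig)) return(sig)
  lab <- .labelComponents(sig, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minCluster)
  array(lab %in% keep & sig, dim(pMap))
}

#' DICE similarity coefficient
#'
#' Overlap between two binary masks: `2 |a & b| / (|a| + |b|)`.
#'
#' @param a,b logical arrays on the same grid; an error is raised when both
#'   are empty (the coefficient is undefined there).
#' @return A value in [0, 1].
#' @export
diceCoefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks must share a grid")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) stop("both masks are empty: DICE undefined")
  2 * sum(a & b) / (na + nb)
}

#' Extract a component timecourse (dual-regression stage 1)
#'
#' Regresses each volume's voxel pattern on a variance-normalised spatial
#' map: `tc[t] = sum(m * Y[, t]) / sum(m^2)`. With a one-voxel map this
#' returns that voxel's timecourse up to normalisation; with a binary
#' region map it is the region-mean timecourse.
#'
#' @param magnitude 4D magnitude array or [DualEchoSeries-class]
#'   (second-echo magnitude used).
#' @param map 3D numeric or logical spatial map (nonzero variance... a
#'   constant map carries no spatial pattern and is rejected).
#' @return Numeric vector, one value per volume.
#' @export
extractTimecourse <- function(magnitude, map) {
  if (is(magnitude, "DualEchoSeries")) magnitude <- magnitude@magnitudeE2
  d4 <- dim(magnitude)
  m <- as.numeric(map)
  if (length(m) != prod(d4[1:3])) stop("map does not match the series grid")
  if (stats::sd(m) == 0) stop("zero-variance spatial map")
  m <- m / stats::sd(m)
  Y <- matrix(magnitude, prod(d4[1:3]), d4[4L])
  as.numeric(crossprod(m, Y)) / sum(m^2)
}

#' Group test of component timecourses against the applied current
#'
#' Dual-regression-style two-stage analysis: per subject, the component
#' timecourse is extracted with [extractTimecourse()] (stage 1) and
#' regressed on the applied current waveform, by default convolved with the
#' haemodynamic response (stage 2); the per-subject effect is expressed as
#' a normalised signal change per mA. The group-level significance is a
#' one-sample two-tailed t-test over the per-subject betas.
#'
#' Normalisation of the stage-2 effect:
#' \describe{
#'   \item{"ratio" (default)}{slope / intercept of the raw timecourse
#'     regressed on the current regressor — the fractional signal change
#'     per mA, directly comparable to a multiplicative BOLD effect;}
#'   \item{"zscore"}{slope of the z-scored timecourse (scale-free);}
#'   \item{"none"}{raw slope in signal units per mA.}
#' }
#'
#' @param data list of subjects: 4D magnitude arrays,
#'   [DualEchoSeries-class] objects, or [cohortFixture()] subject lists.
#' @param map 3D spatial map shared by all subjects.
#' @param waveform the shared [CurrentWaveform-class].
#' @param hrf kernel for the convolution (default [canonicalHrf()] at the
#'   waveform TR).
#' @param convolve convolve the current with the HRF before stage 2
#'   (default TRUE).
#' @param normalize "ratio", "zscore" or "none".
#' @return A list: `betas` (per subject), `mean`, `se`, `statistic`, `df`,
#'   `p`, `timecourses` (volumes x subjects), `regressor`.
#' @export
componentCurrentTest <- function(data, map, waveform, hrf = NULL,
                                 convolve = TRUE,
                                 normalize = c("ratio", "zscore", "none")) {
  normalize <- match.arg(normalize)
  if (length(data) < 2L) stop("need at least 2 subjects")
  if (is.null(hrf)) hrf <- canonicalHrf(waveform@tr)
  x <- if (convolve) convolveWithHrf(waveform@currents, hrf) else waveform@currents
  getMag <- function(s) {
    if (is.list(s) && !is.null(s$series)) s <- s$series
    if (is(s, "DualEchoSeries")) s@magnitudeE2 else s
  }
  tcs <- vapply(data, function(s) {
    mag <- getMag(s)
    if (dim(mag)[4L] != length(x)) stop("subject series and waveform length differ")
    extractTimecourse(mag, map)
  }, numeric(length(x)))
  betas <- apply(tcs, 2L, function(tc) {
    if (normalize == "zscore") tc <- as.numeric(scale(tc))
    fit <- stats::lm.fit(cbind(1, x), tc)
    co <- fit$coefficients
    switch(normalize,
           ratio = co[2L] / co[1L],
           zscore = co[2L],
           none = co[2L])
  })
  tt <- stats::t.test(betas)
  list(betas = unname(betas), mean = mean(betas),
       se = stats::sd(betas) / sqrt(length(betas)),
       statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, timecourses = tcs, regressor = x)
}
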