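# rad/mA -> nT/mA: phi = gamma * Bz * TE, with Bz in nT carrying 1e-9.
radPerMAToNT <- function(slopeRad, params) {
  slopeRad / (params@gamma * params@te2) * 1e9
}

#' Linear detrending
#'
#' Removes a per-voxel least-squares line over volume index, applied per
#' scan segment; the output has zero mean and zero linear trend within each
#' segment. Idempotent.
#'
#' @param x a [PhaseSeries-class] or a 4D array.
#' @param scanBoundaries first-volume indices of each scan (default: one
#'   segment spanning the whole series).
#' @return Same type as the input.
#' @export
detrendLinear <- function(x, scanBoundaries = 1L) {
  isPS <- is(x, "PhaseSeries")
  vals <- if (isPS) x@values else x
  d4 <- dim(vals)
  nT <- d4[4L]
  if (nT < 3L) stop("need at least 3 volumes to detrend")
  v <- matrix(vals, prod(d4[1:3]), nT)
  bounds <- c(as.integer(scanBoundaries), nT + 1L)
  for (s in seq_len(length(bounds) - 1L)) {
    idx <- bounds[s]:(bounds[s + 1L] - 1L)
    X <- cbind(1, seq_along(idx) - (length(idx) + 1) / 2)
    H <- X %*% solve(crossprod(X), t(X))
    v[, idx] <- v[, idx, drop = FALSE] -
      v[, idx, drop = FALSE] %*% t(H)
  }
  out <- array(v, d4)
  if (isPS) {
    x@values <- out
    x
  } else out
}

#' Assemble a GLM design matrix
#'
#' Builds the design used to model the unwrapped phase (or the second-echo
#' magnitude): the applied current as the predictor of interest plus the
#' nuisance structure — intercept(s), linear trend(s), six motion
#' parameters, global signal and level-shift steps. When the waveform spans
#' several scans, per-scan intercept and per-scan centred trend columns are
#' used so that a per-scan linear detrend of the data leaves the current
#' slope unbiased (the design then spans the projection that the detrending
#' applies). Constant/all-zero columns are dropped with a record; a
#' rank-deficient design after cleanup is rejected naming the offending
#' columns, except that level-shift steps made redundant by per-scan
#' intercepts are dropped with a record.
#'
#' @param waveform a [CurrentWaveform-class]; its currents become the
#'   `current` column exactly.
#' @param motion optional n x 6 matrix of motion parameters (realignment is
#'   consumed, not performed; NULL means zeros, which are dropped).
#' @param globalSignal optional per-volume mean over the analysis mask.
#' @param shifts optional step-regressor matrix from [detectLevelShifts()].
#' @param perScan use per-scan intercept/trend columns when the waveform has
#'   several scans (default TRUE).
#' @return Numeric design matrix with named columns and attributes
#'   `dropped` (names of removed columns) and `scanBoundaries`.
#' @export
buildDesign <- function(waveform, motion = NULL, globalSignal = NULL,
                        shifts = NULL, perScan = TRUE) {
  stopifnot(is(waveform, "CurrentWaveform"))
  nT <- length(waveform@currents)
  bounds <- if (perScan) waveform@scanBoundaries else 1L
  ends <- c(bounds[-1L] - 1L, nT)
  cols <- list()
  multi <- length(bounds) > 1L
  for (s in seq_along(bounds)) {
    idx <- bounds[s]:ends[s]
    ic <- numeric(nT); ic[idx] <- 1
    tc <- numeric(nT); tc[idx] <- seq_along(idx) - (length(idx) + 1) / 2
    cols[[if (multi) paste0("intercept_s", s) else "intercept"]] <- ic
    cols[[if (multi) paste0("trend_s", s) else "trend"]] <- tc
  }
  cols[["current"]] <- waveform@currents
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != nT) stop("motion table must have one row per volume")
    if (ncol(motion) != 6L) stop("motion table must have 6 columns")
    for (j in 1:6) cols[[paste0("motion", j)]] <- motion[, j]
  }
  if (!is.null(globalSignal)) {
    if (length(globalSignal) != nT) stop("globalSignal must have one value per volume")
    cols[["global_signal"]] <- globalSignal - mean(globalSignal)
  }
  if (!is.null(shifts) && ncol(shifts) > 0L) {
    if (nrow(shifts) != nT) stop("shift columns must have one row per volume")
    nm <- colnames(shifts)
    if (is.null(nm)) nm <- paste0("shift_", seq_len(ncol(shifts)))
    for (j in seq_len(ncol(shifts))) cols[[nm[j]]] <- shifts[, j]
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  isIntercept <- grepl("^intercept", colnames(X))
  sds <- apply(X, 2, stats::sd)
  drop <- !isIntercept & (sds < 1e-12)
  dropped <- colnames(X)[drop]
  if (length(dropped))
    message("dropping constant/all-zero design column(s): ",
            paste(dropped, collapse = ", "))
  X <- X[, !drop, drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    if (all(grepl("^shift_", bad))) {
      message("dropping level-shift column(s) absorbed by per-scan intercepts: ",
              paste(bad, collapse = ", "))
      dropped <- c(dropped, bad)
      X <- X[, setdiff(colnames(X), bad), drop = FALSE]
    } else {
      stop("rank-deficient design after cleanup; offending column(s): ",
           paste(bad, collapse = ", "))
    }
  }
  attr(X, "dropped") <- dropped
  attr(X, "scanBoundaries") <- bounds
  X
}

# Vectorised per-voxel OLS: Y is nT x nVox. Returns coefficients, per-voxel
# residual SD and the unscaled covariance diagonal.
.voxelOls <- function(X, Y) {
  qrX <- qr(X)
  if (nrow(X) <= ncol(X))
    stop("fewer volumes than design columns: cannot fit")
  coef <- qr.coef(qrX, Y)
  res <- Y - X %*% coef
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  xtxInv <- chol2inv(chol(crossprod(X)))
  rownames(coef) <- colnames(X)
  list(coef = coef, sigma2 = sigma2, xtxInv = xtxInv, df = df)
}

#' Fit the phase GLM (field per mA)
#'
#' Ordinary least squares of the unwrapped phase time series on the design,
#' per voxel. The slope of the `current` column (rad/mA) is converted to
#' nT/mA via `slope = slopeRad / (gamma * TE2) * 1e9` and is interpreted as
#' the magnetic field induced per milliampere of applied current. Standard
#' errors come from the residual variance and the design's `(X'X)^-1`. No
#' prewhitening is applied (plain GLM).
#'
#' @param phase a [PhaseSeries-class].
#' @param design matrix from [buildDesign()]; must contain a `current`
#'   column and have one row per volume.
#' @param params the [AcquisitionParams-class] (for gamma and TE2).
#' @return A [FieldEstimate-class].
#' @export
fitPhaseGlm <- function(phase, design, params) {
  stopifnot(is(phase, "PhaseSeries"), is(params, "AcquisitionParams"))
  if (!("current" %in% colnames(design)))
    stop("design has no current column: cannot infer a field slope ",
         "(a sham/all-zero waveform is dropped by buildDesign)")
  d4 <- dim(phase@values)
  if (nrow(design) != d4[4L]) stop("design rows must equal series volumes")
  maskv <- as.logical(phase@mask)
  Y <- t(matrix(phase@values, prod(d4[1:3]), d4[4L])[maskv, , drop = FALSE])
  fit <- .voxelOls(design, Y)
  j <- match("current", colnames(design))
  slopeRad <- fit$coef[j, ]
  seRad <- sqrt(fit$sigma2 * fit$xtxInv[j, j])
  shape <- d4[1:3]
  toArr <- function(v) { a <- array(NA_real_, shape); a[maskv] <- v; a }
  new("FieldEstimate",
      slope = toArr(radPerMAToNT(slopeRad, params)),
      slopeRad = toArr(slopeRad),
      se = toArr(radPerMAToNT(seRad, params)),
      residualSd = toArr(sqrt(fit$sigma2)),
      mask = phase@mask, grid = phase@grid)
}

#' Fit the magnitude GLM (BOLD-confound screen)
#'
#' Per-voxel OLS of the second-echo magnitude on the design, reported as
#' percent signal change per mA (`100 * slope / voxel-mean magnitude`),
#' with t statistics and family-wise-error control by Bonferroni correction
#' over the mask voxels. Voxels with zero mean magnitude are excluded from
#' the percent scaling.
#'
#' @param magnitude 4D magnitude array (second echo) or a
#'   [DualEchoSeries-class] (its `magnitudeE2` is used).
#' @param design matrix from [buildDesign()] with a `current` column.
#' @param mask 3D logical array (default: all voxels).
#' @param grid optional [VoxelGrid-class] (taken from the series if given).
#' @return A [MagnitudeEstimate-class].
#' @export
fitMagnitudeGlm <- function(magnitude, design, mask = NULL, grid = NULL) {
  if (is(magnitude, "DualEchoSeries")) {
    if (is.null(grid)) grid <- magnitude@grid
    magnitude <- magnitude@magnitudeE2
  }
  if (!("current" %in% colnames(design)))
    stop("design has no current column")
  d4 <- dim(magnitude)
  if (is.null(mask)) mask <- array(TRUE, d4[1:3])
  if (is.null(grid)) grid <- voxelGrid(d4[1:3], c(1, 1, 1))
  maskv <- as.logical(mask)
  M <- matrix(magnitude, prod(d4[1:3]), d4[4L])[maskv, , drop = FALSE]
  mu <- rowMeans(M)
  fit <- .voxelOls(design, t(M))
  j <- match("current", colnames(design))
  slope <- fit$coef[j, ]
  se <- sqrt(fit$sigma2 * fit$xtxInv[j, j])
  tstat <- slope / se
  nEff <- sum(mu != 0)
  p <- 2 * stats::pt(-abs(tstat), df = fit$df)
  pFwe <- pmin(1, p * nEff)
  pct <- ifelse(mu != 0, 100 * slope / mu, NA_real_)
  pFwe[mu == 0] <- NA_real_
  shape <- d4[1:3]
  toArr <- function(v) { a <- array(NA_real_, shape); a[maskv] <- v; a }
  effMask <- array(FALSE, shape); effMask[maskv] <- mu != 0
  new("MagnitudeEstimate", pctPerMA = toArr(pct), tStat = toArr(tstat),
      pFwe = toArr(pFwe), mask = effMask, grid = grid)
}

#' Run a full synthetic phantom session
#'
#' Convenience pipeline for phantom-style validation: simulate a dual-echo
#' session in which `appliedWaveform` drives the field encoding, unwrap the
#' second-echo phase, detect level shifts, detrend per scan, and fit the
#' phase GLM with `waveform` as the nominal current predictor (pass a
#' different `appliedWaveform`, e.g. all zeros, to emulate a sham session
#' analysed with the nominal design).
#'
#' @param field a [FieldMap-class] (ground-truth nT/mA).
#' @param waveform the nominal [CurrentWaveform-class] used as predictor.
#' @param params an [AcquisitionParams-class].
#' @param appliedWaveform the waveform actually applied during simulation
#'   (default: `waveform`).
#' @param mask analysis mask (default: the field map's mask).
#' @param backgroundField,levelShifts passed to [simulateSeries()].
#' @return A list: `estimate` ([FieldEstimate-class]), `phase`
#'   ([PhaseSeries-class]), `series` ([DualEchoSeries-class]), `design`.
#' @export
runPhantomSession <- function(field, waveform, params,
                              appliedWaveform = waveform, mask = NULL,
                              backgroundField = NULL, levelShifts = NULL) {
  if (is.null(mask)) mask <- field@mask
  series <- simulateSeries(field, appliedWaveform, params,
                           backgroundField = backgroundField,
                           levelShifts = levelShifts)
  phase <- unwrapDualEcho(series, mask = mask)
  shifts <- detectLevelShifts(phase, waveform@scanBoundaries)
  phase <- detrendLinear(phase, waveform@scanBoundaries)
  nV <- prod(dim(phase@values)[1:3])
  gs <- colMeans(matrix(phase@values, nV, dim(phase@values)[4L])[as.logical(mask), , drop = FALSE])
  design <- buildDesign(waveform, globalSignal = gs, shifts = shifts)
  est <- fitPhaseGlm(phase, design, params)
  list(estimate = est, phase = phase, series = series, design = design)
}
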