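#' Phase quality map
#'
#' Per-voxel reliability score in [0, 1] used to guide region growth:
#' quality decreases with the local wrapped second differences of the phase
#' (the standard phase-derivative-variance criterion). A constant volume
#' scores 1 everywhere, and the score is invariant under a global phase
#' offset.
#'
#' @param wrapped 3D array of wrapped phase (radians).
#' @param mask 3D logical array of analysed voxels (default: all).
#' @return 3D array of scores in [0, 1] (NA outside the mask).
#' @export
qualityMap <- function(wrapped, mask = NULL) {
  d <- dim(wrapped)
  if (is.null(mask)) mask <- array(TRUE, d)
  if (!any(mask)) stop("mask is empty")
  a <- wrapped
  a[!mask] <- NA_real_
  ss <- array(0, d)
  nterms <- array(0, d)
  for (ax in 1:3) {
    if (d[ax] < 3L) next
    nxt <- shiftArray(a, ax, -1L)
    prv <- shiftArray(a, ax, +1L)
    d2 <- wrapPhase(nxt - a) - wrapPhase(a - prv)
    ok <- !is.na(d2)
    ss[ok] <- ss[ok] + d2[ok]^2
    nterms <- nterms + ok
  }
  s <- sqrt(ss / pmax(nterms, 1L))
  q <- 1 / (1 + s)
  q[nterms == 0L] <- 1
  q[!mask] <- NA_real_
  q
}

# Quality-guided region growth shared by unwrapSpatial() and the
# spatial-consistency pass: visits voxels in decreasing quality order from
# the seed and snaps each new voxel's value to the 2*pi*k congruent value
# nearest the mean of its already-visited 6-neighbours. `init` holds the
# starting values (wrapped phase for a fresh unwrap, a candidate unwrapped
# volume for a consistency pass); only 2*pi multiples are ever added, so
# congruence with `init` mod 2*pi is exact.
.regionGrow <- function(init, mask, quality, seedVoxel = NULL) {
  d <- dim(init)
  n <- prod(d)
  nbr <- neighborIndices(d)
  maskv <- as.logical(mask)
  q <- as.numeric(quality)
  q[is.na(q)] <- 0
  out <- as.numeric(init)
  visited <- logical(n)
  cand <- rep(-Inf, n)
  seedq <- q
  seedq[!maskv] <- -Inf
  nTodo <- sum(maskv)
  done <- 0L
  twopi <- 2 * pi
  firstSeed <- TRUE
  while (done < nTodo) {
    v <- which.max(cand)
    if (!is.finite(cand[v])) {
      # no frontier left: start a new connected component
      v <- if (firstSeed && !is.null(seedVoxel)) seedVoxel else which.max(seedq)
      ref <- out[v]
      firstSeed <- FALSE
    } else {
      nb <- nbr[v, ]
      nb <- nb[!is.na(nb)]
      nb <- nb[visited[nb]]
      ref <- mean(out[nb])
    }
    out[v] <- out[v] + twopi * round((ref - out[v]) / twopi)
    visited[v] <- TRUE
    cand[v] <- -Inf
    seedq[v] <- -Inf
    done <- done + 1L
    nb <- nbr[v, ]
    nb <- nb[!is.na(nb)]
    nb <- nb[maskv[nb] & !visited[nb]]
    cand[nb] <- q[nb]
  }
  out[!maskv] <- init[!maskv]
  array(out, d)
}

#' Spatial phase unwrapping by quality-guided region growth
#'
#' Unwraps a single 3D phase volume: growth starts at the seed voxel
#' (default: the highest-quality voxel) and each newly grown voxel's phase
#' is adjusted by the 2*pi multiple nearest the mean of its already
#' unwrapped neighbours. Disconnected mask components are each grown from
#' their own seed. The output is congruent with the input modulo 2*pi at
#' every voxel.
#'
#' @param wrapped 3D array of wrapped phase (radians).
#' @param mask 3D logical array (default: all voxels).
#' @param quality optional quality map (default [qualityMap()]).
#' @param seedVoxel optional linear index of the first seed.
#' @return 3D array of unwrapped phase; voxels outside the mask are
#'   returned unchanged.
#' @export
unwrapSpatial <- function(wrapped, mask = NULL, quality = NULL,
                          seedVoxel = NULL) {
  d <- dim(wrapped)
  if (is.null(mask)) mask <- array(TRUE, d)
  if (!any(mask)) stop("mask is empty")
  if (is.null(quality)) quality <- qualityMap(wrapped, mask)
  .regionGrow(wrapped, mask, quality, seedVoxel)
}

#' Unwrap a dual-echo series (4D)
#'
#' Recovers the unwrapped second-echo phase time series using the three
#' anchors available in a dual-echo block acquisition:
#' \enumerate{
#'   \item the first volume of echo 1 is unwrapped spatially (wraps are
#'     mild at the short TE);
#'   \item the first volume of echo 2 is unwrapped towards the TE-ratio
#'     prediction `phi1 * TE2/TE1` (valid when the phase is dominated by
#'     static field inhomogeneity, so phase scales with TE), choosing per
#'     voxel the 2*pi multiple nearest the prediction, followed by one
#'     spatial-consistency region-growth pass;
#'   \item subsequent volumes are unwrapped temporally per voxel under the
#'     assumption that the true phase changes by less than pi between
#'     consecutive volumes.
#' }
#' Voxels whose prediction residual still exceeds pi/2 after the spatial
#' pass are flagged as excessive-wrap voxels; if more than
#' `maxFlaggedFraction` of the mask is flagged the series is rejected as
#' unusable (error of class `excessivePhaseWraps`). The global 2*pi
#' ambiguity is fixed by placing the masked median of volume 1 inside
#' (-pi, pi].
#'
#' @param series a [DualEchoSeries-class].
#' @param mask 3D logical array of analysed voxels (default: all).
#' @param maxFlaggedFraction rejection threshold on the flagged fraction
#'   (default 0.2).
#' @return A [PhaseSeries-class] (echo-2 unwrapped phase).
#' @export
unwrapDualEcho <- function(series, mask = NULL, maxFlaggedFraction = 0.2) {
  stopifnot(is(series, "DualEchoSeries"))
  d4 <- dim(series@phaseE2)
  shape <- d4[1:3]
  nT <- d4[4L]
  if (is.null(mask)) mask <- array(TRUE, shape)
  if (!any(mask)) stop("mask is empty")
  p <- series@params
  w1 <- array(series@phaseE1[, , , 1L], shape)
  w2v1 <- array(series@phaseE2[, , , 1L], shape)
  u1 <- unwrapSpatial(w1, mask)
  pred <- u1 * (p@te2 / p@te1)
  twopi <- 2 * pi
  # the echo-1 unwrap is only defined up to a global 2*pi multiple, which
  # the TE ratio turns into a non-2*pi constant offset of the prediction;
  # that offset is identifiable as the circular mean of wrap(phase2 - pred)
  resid <- wrapPhase(w2v1 - pred)[mask]
  pred <- pred + atan2(mean(sin(resid)), mean(cos(resid)))
  u2 <- w2v1 + twopi * round((pred - w2v1) / twopi)
  q2 <- qualityMap(w2v1, mask)
  u2 <- .regionGrow(u2, mask, q2)
  flags <- array(FALSE, shape)
  flags[mask] <- abs(u2[mask] - pred[mask]) > pi / 2
  frac <- sum(flags) / sum(mask)
  if (frac > maxFlaggedFraction)
    stop(errorCondition(
      sprintf(paste("series rejected: %.1f%% of mask voxels show excessive",
                    "phase wraps (limit %.0f%%)"),
              100 * frac, 100 * maxFlaggedFraction),
      class = c("excessivePhaseWraps", "tdcsmapError")))
  # global 2*pi convention: masked median of volume 1 into (-pi, pi]
  med <- stats::median(u2[mask])
  u2 <- u2 - twopi * round(med / twopi)
  # temporal unwrapping: per-voxel 2*pi-jump counting, |dphi| < pi assumed
  nV <- prod(shape)
  w <- matrix(series@phaseE2, nV, nT)
  k <- matrix(0, nV, nT)
  k[, 1L] <- round((as.numeric(u2) - w[, 1L]) / twopi)
  if (nT > 1L) {
    for (t in 2:nT)
      k[, t] <- k[, t - 1L] - round((w[, t] - w[, t - 1L]) / twopi)
  }
  values <- array(w + twopi * k, d4)
  new("PhaseSeries", values = values, grid = series@grid, quality = q2,
      mask = array(as.logical(mask), shape), flags = flags)
}

#' Detect level shifts between scans
#'
#' Abrupt constant offsets in the phase time series between scans are
#' detected from the across-mask mean phase: a scan boundary whose
#' volume-to-volume mean-phase jump exceeds `threshold` times the robust SD
#' (1.4826 * MAD) of the within-scan jumps yields one 0/1 step regressor
#' column for the GLM.
#'
#' @param phase a [PhaseSeries-class] or 4D array of unwrapped phase.
#' @param boundaries integer first-volume indices of each scan (taken from
#'   the series' scans; must start at 1).
#' @param threshold multiple of the robust SD (default 3).
#' @param mask 3D logical array (default: the series mask, or all voxels).
#' @return Numeric matrix with `nVolumes` rows and one column per detected
#'   shift, named `shift_<volume>`; zero columns when nothing is detected.
#' @export
detectLevelShifts <- function(phase, boundaries, threshold = 3, mask = NULL) {
  if (is(phase, "PhaseSeries")) {
    if (is.null(mask)) mask <- phase@mask
    vals <- phase@values
  } else {
    vals <- phase
    if (is.null(mask)) mask <- array(TRUE, dim(vals)[1:3])
  }
  d4 <- dim(vals)
  nT <- d4[4L]
  boundaries <- as.integer(boundaries)
  if (any(boundaries < 1L | boundaries > nT))
    stop("scan boundaries outside the series length")
  v <- matrix(vals, prod(d4[1:3]), nT)
  mu <- colMeans(v[as.logical(mask), , drop = FALSE])
  dmu <- diff(mu)
  inner <- boundaries[boundaries > 1L]
  withinScan <- setdiff(seq_along(dmu), inner - 1L)
  robustSd <- stats::mad(dmu[withinScan])
  if (!is.finite(robustSd)) robustSd <- 0
  cols <- list()
  for (b in inner) {
    jump <- abs(dmu[b - 1L])
    if (jump > threshold * robustSd && jump > 0) {
      cols[[paste0("shift_", b)]] <- as.numeric(seq_len(nT) >= b)
    }
  }
  if (!length(cols)) return(matrix(numeric(0), nrow = nT, ncol = 0L))
  do.call(cbind, cols)
}
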