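#' Build a block-design current waveform
#'
#' Lays out the applied tDCS current as a block design: within each scan the
#' given current levels are applied in a (seeded) pseudo-random order, each
#' held for `blockLength` seconds, optionally separated by zero-current
#' gaps; scans are concatenated and their start volumes recorded. If a scan
#' is longer than one pass through the levels, further pseudo-random
#' permutations are appended; a truncated final block is allowed.
#'
#' @param levels current levels in mA (e.g. `c(0, 0.5, 1, 1.5)` for the
#'   phantom protocol, `c(0, 1, 1.5, 2)` for the in-vivo protocol).
#' @param blockLength block duration in s (a multiple of `tr`, >= `tr`).
#' @param tr repetition time in s.
#' @param nScans number of scans.
#' @param scanLength scan duration in s.
#' @param order optional explicit block order: a vector of indices into
#'   `levels` (recycled across scans) or a list of such vectors, one per
#'   scan. When NULL, a seeded pseudo-random permutation is drawn per scan.
#' @param seed RNG seed for the pseudo-random orders.
#' @param gapLength optional zero-current gap after each block, in s
#'   (a multiple of `tr`).
#' @return A [CurrentWaveform-class].
#' @examples
#' wf <- makeWaveform(c(0, 1, 1.5, 2), blockLength = 90, tr = 2,
#'                    nScans = 2, scanLength = 750, seed = 1)
#' table(currents(wf))
#' @export
makeWaveform <- function(levels, blockLength, tr, nScans = 1L, scanLength,
                         order = NULL, seed = NULL, gapLength = 0) {
  if (length(levels) < 1L) stop("levels must be non-empty")
  if (blockLength < tr) stop("blockLength must be at least one TR")
  for (nm in c("blockLength", "gapLength")) {
    v <- get(nm)
    if (abs(v / tr - round(v / tr)) > 1e-8)
      stop(nm, " must be a multiple of tr")
  }
  volsPerBlock <- as.integer(round(blockLength / tr))
  volsPerGap <- as.integer(round(gapLength / tr))
  volsPerScan <- as.integer(round(scanLength / tr))
  if (volsPerScan < 1L) stop("scanLength shorter than one TR")
  orders <- NULL
  if (!is.null(order)) {
    orders <- if (is.list(order)) rep_len(order, nScans) else rep(list(order), nScans)
  }
  out <- withSeed(if (is.null(seed)) NA_integer_ else seed, {
    lapply(seq_len(nScans), function(s) {
      scan <- numeric(0)
      while (length(scan) < volsPerScan) {
        ord <- if (!is.null(orders)) as.integer(orders[[s]]) else sample(length(levels))
        if (any(ord < 1L | ord > length(levels)))
          stop("order indices must address `levels`")
        blk <- rep(rep(levels[ord], each = volsPerBlock),
                   times = 1L)
        if (volsPerGap > 0L)
          blk <- as.numeric(rbind(matrix(blk, nrow = volsPerBlock),
                                  matrix(0, nrow = volsPerGap, ncol = length(ord))))
        scan <- c(scan, blk)
      }
      scan[seq_len(volsPerScan)]
    })
  })
  new("CurrentWaveform", currents = unlist(out), tr = tr,
      scanBoundaries = as.integer(1L + (seq_len(nScans) - 1L) * volsPerScan),
      blockLength = blockLength)
}

#' Canonical double-gamma HRF
#'
#' The canonical haemodynamic response function (double gamma: response peak
#' at 6 s, undershoot peak at 16 s, peak-to-undershoot ratio 6) sampled at
#' the TR and normalised to unit sum, so that a sustained block of applied
#' current converges to a plateau equal to the block's current level. This
#' makes regression betas directly interpretable as change per mA.
#'
#' @param tr sampling interval in s.
#' @param duration kernel length in s (default 32).
#' @return Numeric vector of kernel weights summing to 1.
#' @export
canonicalHrf <- function(tr, duration = 32) {
  t <- seq(0, duration, by = tr)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / sum(h)
}

#' Convolve a regressor with an HRF (causal)
#'
#' @param x per-volume regressor (e.g. applied current in mA).
#' @param hrf kernel from [canonicalHrf()].
#' @return Numeric vector of the same length as `x` (zero-padded history).
#' @export
convolveWithHrf <- function(x, hrf) {
  n <- length(x)
  out <- numeric(n)
  hrf <- hrf[seq_len(min(length(hrf), n))]
  for (j in seq_along(hrf)) {
    idx <- seq_len(n - j + 1L)
    out[idx + j - 1L] <- out[idx + j - 1L] + hrf[j] * x[idx]
  }
  out
}

#' Smooth static background field
#'
#' Draws a smooth background field inhomogeneity (nT) as a random quadratic
#' polynomial over normalised grid coordinates, scaled to a target spatial
#' standard deviation. This is the static field offset that gives each voxel
#' its baseline phase `phi0 = gamma * B0off * TE` and, at the longer echo,
#' the spatial phase wraps that the unwrapping stage must resolve.
#'
#' @param grid a [VoxelGrid-class].
#' @param sd target standard deviation in nT of the field over a fixed
#'   100 mm reference box. Calibrating against a fixed physical volume
#'   (rather than the grid itself) keeps the per-mm gradient independent of
#'   the grid size, so adjacent-voxel phase steps stay well below pi at the
#'   long echo on any grid — small fields of view see proportionally less
#'   inhomogeneity, as on a real scanner.
#' @param seed RNG seed (NULL/NA for the current stream).
#' @return 3D array of field offsets in nT.
#' @export
makeBackgroundField <- function(grid, sd = 500, seed = NULL) {
  if (sd == 0) return(array(0, dim = grid@shape))
  scale <- 50  # mm: half the reference box edge
  co <- voxelCenters(grid)
  mkBasis <- function(x, y, z)
    cbind(x, y, z, x * y, x * z, y * z, x^2, y^2, z^2)
  basis <- mkBasis((co[, 1L] - mean(range(co[, 1L]))) / scale,
                   (co[, 2L] - mean(range(co[, 2L]))) / scale,
                   (co[, 3L] - mean(range(co[, 3L]))) / scale)
  ref <- as.matrix(expand.grid(x = seq(-1, 1, length.out = 11),
                               y = seq(-1, 1, length.out = 11),
                               z = seq(-1, 1, length.out = 11)))
  refBasis <- mkBasis(ref[, 1L], ref[, 2L], ref[, 3L])
  withSeed(if (is.null(seed)) NA_integer_ else seed, {
    co9 <- stats::rnorm(ncol(basis))
    sRef <- stats::sd(drop(refBasis %*% co9))
    f <- drop(basis %*% co9) / sRef * sd
    array(f, dim = grid@shape)
  })
}

# Shared phase model of the simulator and of truePhase(): the noise-free
# unwrapped phase (V x T matrix) at one echo.
.noiseFreePhase <- function(field, waveform, params, echo, backgroundField,
                            levelShifts) {
  te <- if (echo == 1L) params@te1 else params@te2
  cur <- waveform@currents
  nT <- length(cur)
  phi <- outer(params@gamma * 1e-9 * te * as.numeric(field@values), cur)
  phi <- phi + params@gamma * 1e-9 * te * as.numeric(backgroundField)
  tAdd <- params@driftSlope * (seq_len(nT) - 1L)
  if (!is.null(levelShifts) && any(levelShifts != 0)) {
    scanOf <- findInterval(seq_len(nT), waveform@scanBoundaries)
    tAdd <- tAdd + levelShifts[scanOf]
  }
  phi + rep(tAdd, each = nrow(phi))
}

#' Simulate a dual-echo EPI series
#'
#' Generates the raw signal of a dual-echo EPI acquisition in which a known
#' field map is encoded in the phase: for voxel v, volume t and echo e the
#' noise-free complex signal is
#' `M * exp(i * (phi0_e(v) + gamma * Bz(v) * I(t) * 1e-9 * TE_e
#'   + drift * t + shift_scan))`,
#' where `phi0_e` comes from the smooth static background field. Complex
#' Gaussian noise of SD `params@complexNoiseSd` is added to the real and
#' imaginary channels, the stored phase is the wrapped argument in
#' [-pi, pi), and the stored magnitude is the modulus. An optional
#' [BoldInjection-class] scales the second-echo magnitude by
#' `1 + effectPerMA * (I convolved with hrf)(t)` inside its region. The
#' simulation ground truth (field, background, shifts, waveform, injection)
#' is retained in the result's `truth` slot for verification; see
#' [truePhase()].
#'
#' @param field a [FieldMap-class] in nT/mA.
#' @param waveform a [CurrentWaveform-class].
#' @param params an [AcquisitionParams-class]; `params@seed` seeds the
#'   background draw and the noise.
#' @param injection optional [BoldInjection-class].
#' @param backgroundField optional 3D array (nT) overriding the seeded
#'   background draw.
#' @param levelShifts optional per-scan constant phase offsets in rad
#'   (length = number of scans), emulating abrupt level shifts between
#'   scans.
#' @return A [DualEchoSeries-class].
#' @export
simulateSeries <- function(field, waveform, params, injection = NULL,
                           backgroundField = NULL, levelShifts = NULL) {
  stopifnot(is(field, "FieldMap"), is(waveform, "CurrentWaveform"),
            is(params, "AcquisitionParams"))
  grid <- field@grid
  shape <- grid@shape
  nV <- prod(shape)
  nT <- length(waveform@currents)
  if (!is.null(injection) && !identical(dim(injection@regionMask), shape))
    stop("injection regionMask does not match the field grid")
  if (!is.null(levelShifts) &&
      length(levelShifts) != length(waveform@scanBoundaries))
    stop("levelShifts must have one entry per scan")
  withSeed(params@seed, {
    if (is.null(backgroundField))
      backgroundField <- makeBackgroundField(grid, params@backgroundFieldSd)
    if (!identical(dim(backgroundField), shape))
      stop("backgroundField does not match the field grid")
    mag <- matrix(params@baselineMagnitude, nV, nT)
    magE2 <- mag
    if (!is.null(injection)) {
      conv <- convolveWithHrf(waveform@currents, injection@hrf)
      fac <- 1 + injection@effectPerMA * conv
      sel <- as.logical(injection@regionMask)
      magE2[sel, ] <- magE2[sel, ] * rep(fac, each = sum(sel))
    }
    makeEcho <- function(echo, magIn) {
      phi <- .noiseFreePhase(field, waveform, params, echo, backgroundField,
                             levelShifts)
      if (params@complexNoiseSd > 0) {
        re <- magIn * cos(phi) + stats::rnorm(nV * nT, 0, params@complexNoiseSd)
        im <- magIn * sin(phi) + stats::rnorm(nV * nT, 0, params@complexNoiseSd)
        list(mag = sqrt(re^2 + im^2), ph = wrapPhase(atan2(im, re)))
      } else {
        list(mag = magIn, ph = wrapPhase(phi))
      }
    }
    e1 <- makeEcho(1L, mag)
    e2 <- makeEcho(2L, magE2)
    d4 <- c(shape, nT)
    new("DualEchoSeries",
        magnitudeE1 = array(e1$mag, d4), magnitudeE2 = array(e2$mag, d4),
        phaseE1 = array(e1$ph, d4), phaseE2 = array(e2$ph, d4),
        grid = grid, params = params,
        truth = list(field = field, backgroundField = backgroundField,
                     levelShifts = levelShifts, waveform = waveform,
                     injection = injection))
  })
}

#' Ground-truth unwrapped phase of a simulated series
#'
#' Recomputes the noise-free unwrapped phase of a [simulateSeries()] output
#' from its retained ground truth. Wrapping this with [wrapPhase()]
#' reproduces the stored phase exactly in the noise-free case.
#'
#' @param series a [DualEchoSeries-class] with a `truth` slot.
#' @param echo 1 or 2.
#' @return 4D array of unwrapped phase in radians.
#' @export
truePhase <- function(series, echo = 2L) {
  tr <- series@truth
  if (!length(tr)) stop("series has no retained ground truth (not simulated)")
  phi <- .noiseFreePhase(tr$field, tr$waveform, series@params, echo,
                         tr$backgroundField, tr$levelShifts)
  array(phi, dim = dim(series@phaseE2))
}

#' Default cohort voxel grid
#'
#' Desk-scale stand-in for a human acquisition: 3.4 x 3.4 x 4 mm voxels.
#'
#' @param shape integer triple (default `c(20, 20, 8)`).
#' @param spacing mm spacing (default `c(3.4, 3.4, 4)`).
#' @return A [VoxelGrid-class].
#' @export
cohortGrid <- function(shape = c(20L, 20L, 8L), spacing = c(3.4, 3.4, 4)) {
  voxelGrid(shape, spacing)
}

#' Bilateral two-lobe field pattern
#'
#' The field template used by the synthetic cohort: two Gaussian lobes of
#' opposite sign centred under a left ("cathodal") and a right ("anodal")
#' patch, emulating the bipolar Bz pattern of a bilateral C3/C4 montage.
#'
#' @param grid a [VoxelGrid-class].
#' @param amplitude peak |Bz| in nT/mA (default 3, the upper end of the
#'   1-3 nT range typical of in-vivo measurements at 1 mA).
#' @param sigma Gaussian width in mm (default 12).
#' @return A list: `field` ([FieldMap-class]), `cathodalMask` and
#'   `anodalMask` (3D logical arrays, lobe cores at half maximum).
#' @export
bilateralFieldPattern <- function(grid, amplitude = 3, sigma = 12) {
  co <- voxelCenters(grid)
  ext <- grid@shape * grid@spacing
  cLeft <- c(-0.3 * ext[1L], 0, 0.15 * ext[3L])
  cRight <- c(0.3 * ext[1L], 0, 0.15 * ext[3L])
  g <- function(centre) exp(-colSums((t(co) - centre)^2) / (2 * sigma^2))
  gl <- g(cLeft); gr <- g(cRight)
  values <- amplitude * (gl - gr)
  list(field = fieldMap(grid, array(values, grid@shape)),
       cathodalMask = array(gl > 0.5, grid@shape),
       anodalMask = array(gr > 0.5, grid@shape))
}

#' Synthetic cohort of dual-echo sessions
#'
#' Generates a small human-like cohort: every subject carries the bilateral
#' two-lobe field pattern with a subject-jittered amplitude, and a BOLD
#' effect of `effectPerMA` injected into the second-echo magnitude under the
#' cathodal patch (cathodal stimulation is classically inhibitory, hence the
#' negative default). The waveform follows the in-vivo protocol: levels
#' 0/1/1.5/2 mA in 1.5-min blocks at TR 2 s, two 12.5-min scans.
#'
#' @param nSubjects number of subjects (>= 1).
#' @param seed integer seed; subject s uses sub-streams derived from it.
#' @param grid a [VoxelGrid-class] (default [cohortGrid()]).
#' @param effectPerMA injected fractional BOLD change per mA (default
#'   -0.15; set 0 for a null cohort).
#' @param amplitude mean peak |Bz| in nT/mA (default 3).
#' @param amplitudeJitterSd lognormal-free multiplicative jitter SD of the
#'   per-subject amplitude (default 0.2; 0 for identical subjects).
#' @param effectJitterSd multiplicative between-subject jitter SD of the
#'   injected BOLD effect (default 0.2): tDCS responses are well known to
#'   vary across subjects, so a realistic cohort does not share one exact
#'   effect size. Set 0 for identical responders.
#' @param params an [AcquisitionParams-class] template (TR must match the
#'   waveform); per-subject seeds are derived from `seed`.
#' @param waveform optional [CurrentWaveform-class] overriding the default
#'   protocol (shared by all subjects).
#' @return A list of subjects, each a list with `series`
#'   ([DualEchoSeries-class]), `field` ([FieldMap-class]), `waveform`,
#'   `cathodalMask` and `anodalMask`.
#' @export
cohortFixture <- function(nSubjects = 7L, seed = 1L, grid = cohortGrid(),
                          effectPerMA = -0.15, amplitude = 3,
                          amplitudeJitterSd = 0.2, effectJitterSd = 0.2,
                          params = acquisitionParams(tr = 2),
                          waveform = NULL) {
  if (nSubjects < 1L) stop("nSubjects must be >= 1")
  if (is.null(waveform))
    waveform <- makeWaveform(c(0, 1, 1.5, 2), blockLength = 90, tr = params@tr,
                             nScans = 2L, scanLength = 750, seed = seed)
  lapply(seq_len(nSubjects), function(s)
    cohortSubject(s, seed = seed, grid = grid, effectPerMA = effectPerMA,
                  amplitude = amplitude, amplitudeJitterSd = amplitudeJitterSd,
                  effectJitterSd = effectJitterSd,
                  params = params, waveform = waveform))
}

#' Generate one synthetic cohort subject
#'
#' Single-subject generator behind [cohortFixture()]; useful for processing
#' large cohorts one subject at a time without holding all series in
#' memory.
#'
#' @param subject subject index (>= 1).
#' @inheritParams cohortFixture
#' @param waveform the shared [CurrentWaveform-class].
#' @return One subject list (see [cohortFixture()]).
#' @export
cohortSubject <- function(subject, seed = 1L, grid = cohortGrid(),
                          effectPerMA = -0.15, amplitude = 3,
                          amplitudeJitterSd = 0.2, effectJitterSd = 0.2,
                          params = acquisitionParams(tr = 2),
                          waveform = NULL) {
  if (is.null(waveform))
    waveform <- makeWaveform(c(0, 1, 1.5, 2), blockLength = 90, tr = params@tr,
                             nScans = 2L, scanLength = 750, seed = seed)
  subjSeed <- (as.integer(seed) + 7919L * as.integer(subject)) %% .Machine$integer.max
  draws <- withSeed(subjSeed, stats::rnorm(2L, 0, 1))
  amp <- amplitude * exp(draws[1L] * amplitudeJitterSd)
  pat <- bilateralFieldPattern(grid, amplitude = amp)
  eff <- effectPerMA * (1 + draws[2L] * effectJitterSd)
  inj <- if (eff != 0)
    boldInjection(pat$cathodalMask, eff, canonicalHrf(params@tr))
  pars <- params
  pars@seed <- as.integer((subjSeed + 1L) %% .Machine$integer.max)
  series <- simulateSeries(pat$field, waveform, pars, injection = inj)
  list(series = series, field = pat$field, waveform = waveform,
       cathodalMask = pat$cathodalMask, anodalMask = pat$anodalMask)
}
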