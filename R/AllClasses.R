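#' @import methods
NULL

setClassUnion("arrayOrNULL", c("array", "NULL"))

#' Axis-aligned voxel grid
#'
#' A regular, axis-aligned voxel lattice in scanner coordinates. The frame is
#' right-handed with +z along the scanner main field B0; all geometry is in
#' millimetres. `origin` is the position of the centre of voxel `[1,1,1]`.
#'
#' @slot shape integer triple, number of voxels along x/y/z.
#' @slot spacing numeric triple, voxel spacing in mm (all > 0).
#' @slot origin numeric triple, mm position of the first voxel centre.
#'
#' @seealso [voxelGrid()], [voxelCenters()]
#' @export
setClass("VoxelGrid",
  representation(shape = "integer", spacing = "numeric", origin = "numeric"))

setValidity("VoxelGrid", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 1L))
    msg <- c(msg, "shape must be three integers >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be three finite values (mm)")
  if (length(msg)) msg else TRUE
})

#' Create a voxel grid
#'
#' @param shape integer triple of voxel counts.
#' @param spacing mm spacing per axis (recycled to length 3).
#' @param origin mm position of the first voxel centre. The default centres
#'   the grid on the scanner isocentre.
#' @return A [VoxelGrid-class] object.
#' @examples
#' voxelGrid(c(32, 32, 12), c(3.4, 3.4, 5))
#' @export
voxelGrid <- function(shape, spacing, origin = NULL) {
  shape <- as.integer(rep_len(shape, 3L))
  spacing <- as.numeric(rep_len(spacing, 3L))
  if (is.null(origin)) origin <- -(shape - 1L) / 2 * spacing
  new("VoxelGrid", shape = shape, spacing = spacing,
      origin = as.numeric(rep_len(origin, 3L)))
}

#' Explicit current path
#'
#' An ordered polyline carrying a signed current. Consecutive vertices define
#' straight segments; the sign convention follows the right-hand rule (a
#' positive current along +x produces +Bz on the +y side).
#'
#' @slot vertices numeric matrix (n x 3), vertex positions in mm.
#' @slot current signed current in mA.
#' @slot closed logical; whether the last vertex connects back to the first.
#' @seealso [currentPath()], [biotSavartBz()]
#' @export
setClass("CurrentPath",
  representation(vertices = "matrix", current = "numeric", closed = "logical"))

setValidity("CurrentPath", function(object) {
  v <- object@vertices
  msg <- character()
  if (!is.numeric(v) || ncol(v) != 3L) msg <- c(msg, "vertices must be an n x 3 numeric matrix")
  if (nrow(v) < 2L) msg <- c(msg, "a current path needs at least 2 vertices")
  if (nrow(v) >= 2L) {
    seglen <- sqrt(rowSums((v[-1L, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
    if (any(seglen == 0)) msg <- c(msg, "consecutive vertices must be distinct (zero-length segment)")
    if (isTRUE(object@closed) &&
        sqrt(sum((v[1L, ] - v[nrow(v), ])^2)) == 0)
      msg <- c(msg, "closed path: first and last vertex coincide, drop the duplicate")
  }
  if (length(object@current) != 1L || !is.finite(object@current))
    msg <- c(msg, "current must be a single finite value (mA)")
  if (length(msg)) msg else TRUE
})

#' Create a current path
#'
#' @param vertices n x 3 numeric matrix of mm positions.
#' @param current signed current in mA (default 1).
#' @param closed logical, connect last vertex to first (default FALSE).
#' @return A [CurrentPath-class] object.
#' @export
currentPath <- function(vertices, current = 1, closed = FALSE) {
  new("CurrentPath", vertices = as.matrix(vertices),
      current = as.numeric(current), closed = isTRUE(closed))
}

#' Per-voxel induced field map
#'
#' The z-component of the current-induced magnetic field, in nanotesla per
#' milliampere of applied current, on a [VoxelGrid-class]. The mask marks
#' voxels where the value is valid (e.g. far enough from a simulated wire).
#'
#' @slot grid the [VoxelGrid-class].
#' @slot values 3D numeric array, Bz in nT/mA (0 outside the mask).
#' @slot mask 3D logical array of valid voxels.
#' @seealso [fieldMap()], [biotSavartBz()]
#' @export
setClass("FieldMap",
  representation(grid = "VoxelGrid", values = "array", mask = "array"))

setValidity("FieldMap", function(object) {
  msg <- character()
  if (!identical(dim(object@values), object@grid@shape))
    msg <- c(msg, "values dimensions must match grid shape")
  if (!identical(dim(object@mask), object@grid@shape) || !is.logical(object@mask))
    msg <- c(msg, "mask must be a logical array matching grid shape")
  else if (any(!is.finite(object@values[object@mask])))
    msg <- c(msg, "values must be finite inside the mask")
  if (length(msg)) msg else TRUE
})

#' Create a field map
#'
#' @param grid a [VoxelGrid-class].
#' @param values 3D array of Bz in nT/mA.
#' @param mask 3D logical array (default: all voxels valid).
#' @return A [FieldMap-class] object.
#' @export
fieldMap <- function(grid, values, mask = NULL) {
  values <- array(as.numeric(values), dim = grid@shape)
  if (is.null(mask)) mask <- array(TRUE, dim = grid@shape)
  new("FieldMap", grid = grid, values = values,
      mask = array(as.logical(mask), dim = grid@shape))
}

#' Dual-echo acquisition parameters
#'
#' Timing and signal parameters of the dual-echo EPI acquisition used to
#' encode the current-induced field in the phase. Defaults follow a typical
#' 3T protocol: TE1/TE2 = 11/26 ms, with the second echo chosen for BOLD
#' contrast.
#'
#' @slot te1,te2 echo times in seconds (0 < te1 < te2).
#' @slot tr repetition time in seconds.
#' @slot gamma proton gyromagnetic ratio in rad/s/T.
#' @slot baselineMagnitude baseline signal magnitude (arbitrary units).
#' @slot complexNoiseSd standard deviation of the complex Gaussian noise
#'   added independently to the real and imaginary channel (same units as
#'   the magnitude); the complex SNR is `baselineMagnitude / complexNoiseSd`.
#' @slot driftSlope scanner phase drift in rad per volume (both echoes).
#' @slot backgroundFieldSd spatial standard deviation of the smooth static
#'   background field inhomogeneity, in nT (drives the static phase phi0).
#' @slot seed integer RNG seed for the simulator (NA for unseeded).
#' @seealso [acquisitionParams()], [simulateSeries()]
#' @export
setClass("AcquisitionParams",
  representation(te1 = "numeric", te2 = "numeric", tr = "numeric",
                 gamma = "numeric", baselineMagnitude = "numeric",
                 complexNoiseSd = "numeric", driftSlope = "numeric",
                 backgroundFieldSd = "numeric", seed = "integer"))

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  if (!(object@te1 > 0 && object@te2 > object@te1))
    msg <- c(msg, "need 0 < te1 < te2 (seconds)")
  if (!(object@tr > 0)) msg <- c(msg, "tr must be positive (seconds)")
  if (!(object@gamma > 0)) msg <- c(msg, "gamma must be positive (rad/s/T)")
  if (object@complexNoiseSd < 0) msg <- c(msg, "complexNoiseSd must be >= 0")
  if (object@baselineMagnitude <= 0) msg <- c(msg, "baselineMagnitude must be > 0")
  if (object@backgroundFieldSd < 0) msg <- c(msg, "backgroundFieldSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create acquisition parameters
#'
#' @param tr repetition time, s.
#' @param te1,te2 echo times, s.
#' @param gamma gyromagnetic ratio, rad/s/T (proton default).
#' @param baselineMagnitude baseline magnitude, arbitrary units.
#' @param complexNoiseSd complex noise SD (default gives complex SNR 50).
#' @param driftSlope phase drift, rad/volume.
#' @param backgroundFieldSd background field inhomogeneity SD, nT.
#' @param seed integer seed (NA for unseeded).
#' @return An [AcquisitionParams-class] object.
#' @examples
#' acquisitionParams(tr = 4)
#' @export
acquisitionParams <- function(tr, te1 = 0.011, te2 = 0.026,
                              gamma = 2.6752218744e8,
                              baselineMagnitude = 100, complexNoiseSd = 2,
                              driftSlope = 0, backgroundFieldSd = 500,
                              seed = NA_integer_) {
  new("AcquisitionParams", te1 = as.numeric(te1), te2 = as.numeric(te2),
      tr = as.numeric(tr), gamma = as.numeric(gamma),
      baselineMagnitude = as.numeric(baselineMagnitude),
      complexNoiseSd = as.numeric(complexNoiseSd),
      driftSlope = as.numeric(driftSlope),
      backgroundFieldSd = as.numeric(backgroundFieldSd),
      seed = as.integer(seed))
}

#' Applied current waveform
#'
#' The per-volume applied current realising a block design, concatenated
#' across scans. Currents are piecewise constant over blocks.
#'
#' @slot currents numeric vector, applied current per volume in mA.
#' @slot tr repetition time in seconds.
#' @slot scanBoundaries integer vector of first-volume indices of each scan
#'   (1-based, sorted, starting at 1).
#' @slot blockLength block duration in seconds.
#' @seealso [makeWaveform()]
#' @export
setClass("CurrentWaveform",
  representation(currents = "numeric", tr = "numeric",
                 scanBoundaries = "integer", blockLength = "numeric"))

setValidity("CurrentWaveform", function(object) {
  msg <- character()
  n <- length(object@currents)
  b <- object@scanBoundaries
  if (n < 1L) msg <- c(msg, "waveform must have at least one volume")
  if (length(b) < 1L || b[1L] != 1L || is.unsorted(b, strictly = TRUE) ||
      any(b > n))
    msg <- c(msg, "scanBoundaries must be sorted 1-based indices starting at 1, within range")
  if (!(object@tr > 0)) msg <- c(msg, "tr must be positive")
  if (length(msg)) msg else TRUE
})

#' Dual-echo magnitude and phase time series
#'
#' The raw signal of a dual-echo EPI acquisition: 4D magnitude and phase
#' arrays for each echo. Phase is stored wrapped to [-pi, pi). The `truth`
#' slot, populated by [simulateSeries()], records the simulation ground
#' truth (field map, background field, level shifts) so that synthetic data
#' retain the information needed for end-to-end verification; it is an empty
#' list for data read from disk.
#'
#' @slot magnitudeE1,magnitudeE2 4D arrays (x, y, z, t), arbitrary units.
#' @slot phaseE1,phaseE2 4D arrays, radians wrapped to [-pi, pi).
#' @slot grid the [VoxelGrid-class].
#' @slot params the [AcquisitionParams-class].
#' @slot truth list of simulation ground truth (possibly empty).
#' @seealso [simulateSeries()], [unwrapDualEcho()]
#' @export
setClass("DualEchoSeries",
  representation(magnitudeE1 = "array", magnitudeE2 = "array",
                 phaseE1 = "array", phaseE2 = "array",
                 grid = "VoxelGrid", params = "AcquisitionParams",
                 truth = "list"))

setValidity("DualEchoSeries", function(object) {
  msg <- character()
  d <- dim(object@phaseE2)
  if (length(d) != 4L) msg <- c(msg, "series arrays must be 4D (x, y, z, t)")
  for (nm in c("magnitudeE1", "magnitudeE2", "phaseE1", "phaseE2"))
    if (!identical(dim(slot(object, nm)), d))
      msg <- c(msg, "all four arrays must share the same dimensions")
  if (length(d) == 4L && !identical(d[1:3], object@grid@shape))
    msg <- c(msg, "spatial dimensions must match the grid shape")
  for (nm in c("phaseE1", "phaseE2")) {
    p <- slot(object, nm)
    if (any(p < -pi | p >= pi)) msg <- c(msg, paste(nm, "must be wrapped to [-pi, pi)"))
  }
  if (any(object@magnitudeE1 < 0) || any(object@magnitudeE2 < 0))
    msg <- c(msg, "magnitudes must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Injected BOLD effect
#'
#' A multiplicative BOLD-like effect applied to the second-echo magnitude
#' only (the first echo carries no usable BOLD contrast): inside
#' `regionMask`, the magnitude is scaled by
#' `1 + effectPerMA * (current convolved with hrf)`.
#'
#' @slot regionMask 3D logical array.
#' @slot effectPerMA normalised (fractional) signal change per mA.
#' @slot hrf haemodynamic impulse response sampled at TR, unit sum.
#' @seealso [boldInjection()], [canonicalHrf()]
#' @export
setClass("BoldInjection",
  representation(regionMask = "array", effectPerMA = "numeric", hrf = "numeric"))

setValidity("BoldInjection", function(object) {
  msg <- character()
  if (!is.logical(object@regionMask)) msg <- c(msg, "regionMask must be logical")
  s <- sum(object@hrf)
  if (!is.finite(s) || s <= 0) msg <- c(msg, "hrf must integrate to a finite positive value")
  if (length(msg)) msg else TRUE
})

#' Create a BOLD injection
#'
#' @param regionMask 3D logical array of affected voxels.
#' @param effectPerMA fractional signal change per mA (e.g. -0.15).
#' @param hrf impulse response sampled at TR; see [canonicalHrf()].
#' @return A [BoldInjection-class] object.
#' @export
boldInjection <- function(regionMask, effectPerMA, hrf) {
  new("BoldInjection", regionMask = array(as.logical(regionMask), dim = dim(regionMask)),
      effectPerMA = as.numeric(effectPerMA), hrf = as.numeric(hrf))
}

#' Unwrapped phase time series
#'
#' Output of the 4D unwrapping: unbounded real phase whose wrap is congruent
#' with the input wrapped phase, plus the quality map that guided the region
#' growth and a flag map of voxels with excessive-wrap residuals.
#'
#' @slot values 4D numeric array, unwrapped phase in radians.
#' @slot grid the [VoxelGrid-class].
#' @slot quality 3D array of per-voxel reliability scores in [0, 1].
#' @slot mask 3D logical array of analysed voxels.
#' @slot flags 3D logical array of voxels flagged for excessive wraps.
#' @seealso [unwrapDualEcho()]
#' @export
setClass("PhaseSeries",
  representation(values = "array", grid = "VoxelGrid", quality = "array",
                 mask = "array", flags = "array"))

setValidity("PhaseSeries", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 4L || !identical(d[1:3], object@grid@shape))
    msg <- c(msg, "values must be 4D with spatial dims matching the grid")
  if (!identical(dim(object@quality), object@grid@shape))
    msg <- c(msg, "quality must match the grid shape")
  if (any(object@quality < 0 | object@quality > 1, na.rm = TRUE))
    msg <- c(msg, "quality scores must lie in [0, 1]")
  if (!identical(dim(object@mask), object@grid@shape) || !is.logical(object@mask))
    msg <- c(msg, "mask must be a logical array matching the grid shape")
  if (length(msg)) msg else TRUE
})

#' Per-voxel field-per-mA estimate
#'
#' GLM output: the slope of the applied-current predictor interpreted as the
#' magnetic field induced per milliampere, in nT/mA
#' (`slope = slopeRad / (gamma * te2) * 1e9`), with its standard error and
#' the residual standard deviation of the phase fit.
#'
#' @slot slope 3D array, nT/mA.
#' @slot slopeRad 3D array, rad/mA.
#' @slot se 3D array, standard error in nT/mA.
#' @slot residualSd 3D array, residual SD in rad.
#' @slot mask 3D logical array of fitted voxels.
#' @slot grid the [VoxelGrid-class].
#' @seealso [fitPhaseGlm()]
#' @export
setClass("FieldEstimate",
  representation(slope = "array", slopeRad = "array", se = "array",
                 residualSd = "array", mask = "array", grid = "VoxelGrid"))

setValidity("FieldEstimate", function(object) {
  msg <- character()
  if (any(object@se[object@mask] < 0, na.rm = TRUE))
    msg <- c(msg, "standard errors must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Per-voxel magnitude (BOLD-confound) estimate
#'
#' GLM of the second-echo magnitude on the applied current: percent signal
#' change per mA, t statistics and family-wise-error corrected p values
#' (Bonferroni over mask voxels).
#'
#' @slot pctPerMA 3D array, percent signal change per mA.
#' @slot tStat 3D array.
#' @slot pFwe 3D array, FWE-corrected p.
#' @slot mask 3D logical array.
#' @slot grid the [VoxelGrid-class].
#' @seealso [fitMagnitudeGlm()]
#' @export
setClass("MagnitudeEstimate",
  representation(pctPerMA = "array", tStat = "array", pFwe = "array",
                 mask = "array", grid = "VoxelGrid"))
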