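# Unit bookkeeping: geometry in mm, current in mA, field in nT.
# mu0/4pi = 1e-7 T m/A; combining mm -> m (1e-3), mA -> A (1e-3) and
# T -> nT (1e9) gives a prefactor of 100 for the finite-segment closed form
# B = mu0 I/(4 pi d) (cos theta1 - cos theta2), and 200 for the infinite
# wire B = mu0 I/(2 pi d).
.BS_SEGMENT_PREF <- 100
.BS_INFINITE_PREF <- 200

#' Induced Bz from a current path (Biot-Savart)
#'
#' Computes the z-component of the magnetic field induced by a polyline
#' current path at every voxel centre, per milliampere of applied current.
#' Each straight segment contributes its exact finite-segment closed form
#' `B = mu0*I/(4*pi*d) * (cos(theta1) - cos(theta2))` along the azimuthal
#' direction, of which only the z-component is retained: MRI phase is
#' sensitive to the field along the main field B0 only. Voxels whose centre
#' lies closer than `minDistance` to any segment are masked out (the
#' line-current model diverges there).
#'
#' @param path a [CurrentPath-class].
#' @param grid a [VoxelGrid-class]; the path must be expressed in the same
#'   mm frame.
#' @param minDistance exclusion radius in mm (> 0); default half the
#'   smallest voxel spacing.
#' @return A [FieldMap-class] with values in nT per mA. Masked-out voxels
#'   hold 0 with `mask = FALSE`. If every voxel is masked the result is
#'   flagged with a warning and an empty mask.
#' @examples
#' g <- voxelGrid(c(9, 9, 3), c(2, 2, 2))
#' wire <- currentPath(rbind(c(-1e4, 0, 0), c(1e4, 0, 0)), current = 1)
#' fm <- biotSavartBz(wire, g)
#' @export
biotSavartBz <- function(path, grid, minDistance = min(grid@spacing) / 2) {
  stopifnot(is(path, "CurrentPath"), is(grid, "VoxelGrid"))
  if (!(minDistance > 0)) stop("minDistance must be > 0 (mm)")
  validObject(path)
  verts <- path@vertices
  if (path@closed) verts <- rbind(verts, verts[1L, ])
  P <- voxelCenters(grid)
  n <- nrow(P)
  bz <- numeric(n)
  dmin <- rep(Inf, n)
  for (s in seq_len(nrow(verts) - 1L)) {
    A <- verts[s, ]; B <- verts[s + 1L, ]
    seg <- B - A
    L <- sqrt(sum(seg^2))
    if (L == 0) stop("degenerate zero-length segment at vertex ", s)
    u <- seg / L
    ax <- P[, 1L] - A[1L]; ay <- P[, 2L] - A[2L]; az <- P[, 3L] - A[3L]
    t <- ax * u[1L] + ay * u[2L] + az * u[3L]
    ra2 <- ax^2 + ay^2 + az^2
    d2 <- pmax(ra2 - t^2, 0)
    # distance from voxel centre to the segment (not the infinite line)
    tc <- pmin(pmax(t, 0), L)
    dseg <- sqrt(d2 + (t - tc)^2)
    dmin <- pmin(dmin, dseg)
    rb2 <- d2 + (t - L)^2
    cos1 <- t / sqrt(ra2)
    cos2 <- (t - L) / sqrt(rb2)
    # (u x a)_z / d^2 carries both the azimuthal direction's z-component
    # and the 1/d of the closed form
    crossZ <- u[1L] * ay - u[2L] * ax
    contrib <- .BS_SEGMENT_PREF * path@current * (cos1 - cos2) * crossZ / d2
    contrib[d2 < 1e-12] <- 0  # on the segment axis the field vanishes
    bz <- bz + contrib
  }
  mask <- dmin >= minDistance
  bz[!mask] <- 0
  if (!any(mask))
    warning("empty field map: all voxels lie within minDistance of the path")
  fieldMap(grid, array(bz, dim = grid@shape), array(mask, dim = grid@shape))
}

#' Analytic infinite straight-wire Bz
#'
#' Closed-form z-component of the field of an infinite straight wire along
#' x carrying `current`, evaluated at a perpendicular offset
#' `(offsetY, offsetZ)`: `Bz = mu0*I/(2*pi) * dy / (dy^2 + dz^2)`. Serves as
#' the independent oracle for [biotSavartBz()] on long straight paths.
#'
#' @param offsetY,offsetZ perpendicular offsets from the wire in mm; must
#'   not both be zero (vectorised, recycled).
#' @param current current in mA.
#' @return Bz in nT.
#' @examples
#' analyticInfiniteWireBz(10, 0, 1)   # 20 nT
#' analyticInfiniteWireBz(0, 10, 1)   # 0: the field is azimuthal there
#' @export
analyticInfiniteWireBz <- function(offsetY, offsetZ, current) {
  r2 <- offsetY^2 + offsetZ^2
  if (any(r2 == 0)) stop("offset must be nonzero: the field diverges on the wire")
  .BS_INFINITE_PREF * current * offsetY / r2
}

#' Default phantom voxel grid
#'
#' The acquisition geometry of the wire phantom: 3.4 x 3.4 x 5 mm voxels,
#' grid centred on the isocentre.
#'
#' @param shape integer triple (default `c(32, 32, 12)`).
#' @param spacing mm spacing (default `c(3.4, 3.4, 5)`).
#' @return A [VoxelGrid-class].
#' @export
phantomGrid <- function(shape = c(32L, 32L, 12L), spacing = c(3.4, 3.4, 5)) {
  voxelGrid(shape, spacing)
}

#' Wire-in-water phantom fixture
#'
#' The validation phantom: an insulated straight wire running horizontally
#' (along x) through the midplane of a water volume. Returns the wire path
#' and its Biot-Savart field map, which shows the canonical bipolar +/- Bz
#' pattern (positive lobe on one side of the wire, negative on the other,
#' by the right-hand rule). The wire is made long enough relative to the
#' grid that the field inside is indistinguishable from the infinite-wire
#' closed form.
#'
#' @param grid a [VoxelGrid-class] (default [phantomGrid()]).
#' @param current wire current in mA (default 1).
#' @param wireY,wireZ wire position in mm (default 0, 0: through the grid
#'   centre plane).
#' @param halfLength wire half-length in mm; default 20x the largest grid
#'   extent so the finite ends contribute < 1 percent inside the grid.
#' @param wireRadius physical wire radius in mm; voxels inside the wire are
#'   always masked. The radius of the real phantom's wire is not part of the
#'   fixture's contract, so it is exposed as a parameter (default 0).
#' @param minDistance exclusion radius passed to [biotSavartBz()]; the
#'   effective exclusion is `max(minDistance, wireRadius)`.
#' @return A list with elements `path` ([CurrentPath-class]) and `field`
#'   ([FieldMap-class]).
#' @examples
#' fx <- phantomFixture(phantomGrid(c(16L, 16L, 6L)))
#' range(fieldValues(fx$field))
#' @export
phantomFixture <- function(grid = phantomGrid(), current = 1, wireY = 0,
                           wireZ = 0, halfLength = NULL, wireRadius = 0,
                           minDistance = min(grid@spacing) / 2) {
  extent <- max(grid@shape * grid@spacing)
  if (is.null(halfLength)) halfLength <- 20 * extent
  if (halfLength <= extent)
    stop("grid too large for the wire: increase halfLength")
  path <- currentPath(rbind(c(-halfLength, wireY, wireZ),
                            c(halfLength, wireY, wireZ)), current = current)
  field <- biotSavartBz(path, grid, minDistance = max(minDistance, wireRadius))
  list(path = path, field = field)
}
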