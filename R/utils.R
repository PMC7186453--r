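#' Wrap phase to [-pi, pi)
#'
#' Maps arbitrary phase values onto the principal interval [-pi, pi), the
#' storage convention used throughout the package.
#'
#' @param x numeric vector or array of phase values in radians.
#' @return `x` wrapped to [-pi, pi), same shape as the input.
#' @examples
#' wrapPhase(c(0, pi, -pi, 3 * pi + 0.1))
#' @export
wrapPhase <- function(x) {
  x - 2 * pi * floor((x + pi) / (2 * pi))
}

# Evaluate expr under a local RNG state seeded with `seed`; the caller's
# .Random.seed is untouched. seed = NA/NULL leaves the RNG stream alone.
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Voxel centre coordinates
#'
#' @param grid a [VoxelGrid-class].
#' @return An n x 3 matrix of voxel-centre positions in mm, ordered like the
#'   linear (column-major) index of arrays on this grid.
#' @export
voxelCenters <- function(grid) {
  ax <- lapply(1:3, function(k) grid@origin[k] + (seq_len(grid@shape[k]) - 1) * grid@spacing[k])
  as.matrix(expand.grid(x = ax[[1L]], y = ax[[2L]], z = ax[[3L]]))
}

#' Per-axis voxel centre coordinates
#'
#' @param grid a [VoxelGrid-class].
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return Numeric vector of voxel-centre positions along one axis, in mm.
#' @export
axisCoordinates <- function(grid, axis) {
  grid@origin[axis] + (seq_len(grid@shape[axis]) - 1) * grid@spacing[axis]
}

# 6-neighbour linear indices for every voxel of a 3D array.
# Returns an N x 6 integer matrix with NA where the neighbour is outside.
neighborIndices <- function(shape) {
  nx <- shape[1L]; ny <- shape[2L]; nz <- shape[3L]
  n <- nx * ny * nz
  idx <- seq_len(n)
  i <- (idx - 1L) %% nx + 1L
  j <- ((idx - 1L) %/% nx) %% ny + 1L
  k <- (idx - 1L) %/% (nx * ny) + 1L
  out <- matrix(NA_integer_, n, 6L)
  out[, 1L] <- ifelse(i > 1L, idx - 1L, NA_integer_)
  out[, 2L] <- ifelse(i < nx, idx + 1L, NA_integer_)
  out[, 3L] <- ifelse(j > 1L, idx - nx, NA_integer_)
  out[, 4L] <- ifelse(j < ny, idx + nx, NA_integer_)
  out[, 5L] <- ifelse(k > 1L, idx - nx * ny, NA_integer_)
  out[, 6L] <- ifelse(k < nz, idx + nx * ny, NA_integer_)
  out
}

# Shift a 3D array by one voxel along `axis` in direction `dir` (+1/-1),
# padding with NA: used for vectorised finite differences.
shiftArray <- function(a, axis, dir) {
  d <- dim(a)
  out <- array(NA_real_, d)
  src <- dst <- lapply(d, seq_len)
  if (dir > 0) { dst[[axis]] <- seq_len(d[axis] - 1L) + 1L; src[[axis]] <- seq_len(d[axis] - 1L) }
  else { dst[[axis]] <- seq_len(d[axis] - 1L); src[[axis]] <- seq_len(d[axis] - 1L) + 1L }
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <- a[src[[1L]], src[[2L]], src[[3L]]]
  out
}
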