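#' Gradient magnitude of a field map
#'
#' Per-voxel Euclidean norm of the finite-difference gradient of the field,
#' in nT per voxel step: this is the across-voxel field difference that
#' drives intravoxel dephasing of the magnitude signal. Central differences
#' are used in the interior and one-sided differences at the edges;
#' singleton axes contribute zero.
#'
#' @param field a [FieldMap-class], [FieldEstimate-class] or 3D array
#'   (nT or nT/mA; the output inherits the input's units per voxel step).
#' @param mask optional 3D logical array restricting the computation
#'   (defaults to the object's mask); values outside are NA.
#' @return 3D array of gradient magnitudes.
#' @export
gradientMagnitude <- function(field, mask = NULL) {
  if (is(field, "FieldMap") || is(field, "FieldEstimate")) {
    if (is.null(mask)) mask <- fieldMask(field)
    vals <- fieldValues(field)
  } else {
    vals <- field
    if (is.null(mask)) mask <- array(TRUE, dim(vals))
  }
  d <- dim(vals)
  a <- vals
  a[!mask] <- NA_real_
  ss <- array(0, d)
  for (ax in 1:3) {
    if (d[ax] < 2L) next
    nxt <- shiftArray(a, ax, -1L)
    prv <- shiftArray(a, ax, +1L)
    g <- (nxt - prv) / 2              # central difference, nT per voxel
    oneSidedF <- nxt - a              # forward at the low edge
    oneSidedB <- a - prv              # backward at the high edge
    g[is.na(g)] <- oneSidedF[is.na(g)]
    g[is.na(g)] <- oneSidedB[is.na(g)]
    g[is.na(g)] <- 0
    ss <- ss + g^2
  }
  out <- sqrt(ss)
  out[!mask] <- NA_real_
  out
}

#' Intravoxel dephasing signal-loss models
#'
#' Fractional magnitude signal change caused by an intravoxel phase spread
#' `phi` (radians), under two closed-form spread assumptions:
#' \describe{
#'   \item{model 1}{`1 - cos(phi/2)` — the worst case, all spins split
#'     between the two extreme phases;}
#'   \item{model 2}{`1 - sin(phi/2)/(phi/2)` — a linear spread of the phase
#'     across the voxel from 0 to the across-voxel difference.}
#' }
#' Both vanish as `phi -> 0` (the removable singularity of model 2 returns
#' 0 exactly), and model 1 >= model 2 for all positive spreads.
#'
#' @param phi phase spread in radians (>= 0, vectorised).
#' @param model 1 or 2.
#' @return Fractional signal change (dimensionless).
#' @examples
#' confoundFraction(pi, 1)  # 1 - cos(pi/2) = 1
#' @export
confoundFraction <- function(phi, model) {
  if (any(phi < 0)) stop("phi must be >= 0")
  model <- match.arg(as.character(model), c("1", "2"))
  h <- phi / 2
  if (model == "1") {
    1 - cos(h)
  } else {
    out <- ifelse(h == 0, 0, 1 - sin(h) / h)
    out[phi == 0] <- 0
    out
  }
}

#' Worst-case dephasing confound table
#'
#' Bounds how much of an observed per-mA magnitude change could be explained
#' by tDCS-induced intravoxel dephasing: the worst-case across-voxel field
#' difference is converted to a phase spread
#' `phi = gamma * gradWorst * 1e-9 * TE2` and both dephasing models are
#' compared to the observed effects as `|fs_model / observed|`.
#'
#' @param gradWorst worst-case across-voxel field difference, nT per mA.
#' @param observed data.frame with columns `label` and `perMA` (observed
#'   normalised signal change per mA, nonzero), or a named numeric vector.
#' @param params an [AcquisitionParams-class] (gamma, TE2).
#' @return A data.frame with one row per observation: `label`, `observed`,
#'   `phi` (rad), `fsModel1`, `fsModel2`, `ratioModel1`, `ratioModel2`
#'   (exact values), `ratioModel1Sig`/`ratioModel2Sig` rounded to 2
#'   significant figures, and `flagged` (TRUE where observed = 0 leaves
#'   the ratio undefined).
#' @examples
#' confoundTable(1, c("Experiment 1" = -0.15), acquisitionParams(tr = 2))
#' @export
confoundTable <- function(gradWorst, observed, params) {
  if (is.numeric(observed))
    observed <- data.frame(label = names(observed), perMA = as.numeric(observed))
  stopifnot(all(c("label", "perMA") %in% names(observed)))
  phi <- params@gamma * gradWorst * 1e-9 * params@te2
  fs1 <- confoundFraction(phi, 1)
  fs2 <- confoundFraction(phi, 2)
  flagged <- observed$perMA == 0
  if (any(flagged))
    warning("observed change of 0 leaves the confound ratio undefined; row flagged")
  r1 <- ifelse(flagged, NA_real_, abs(fs1 / observed$perMA))
  r2 <- ifelse(flagged, NA_real_, abs(fs2 / observed$perMA))
  data.frame(label = observed$label, observed = observed$perMA,
             phi = phi, fsModel1 = fs1, fsModel2 = fs2,
             ratioModel1 = r1, ratioModel2 = r2,
             ratioModel1Sig = signif(r1, 2), ratioModel2Sig = signif(r2, 2),
             flagged = flagged)
}

#' Worst-case field-gradient summary
#'
#' The worst-case across-voxel field difference over an analysis region:
#' the maximum (or, for robustness, an upper percentile) of
#' [gradientMagnitude()] inside the region, plus the histogram data of the
#' gradient distribution.
#'
#' @param field a [FieldMap-class], [FieldEstimate-class] or 3D array.
#' @param mask optional region mask.
#' @param probs quantile reported alongside the maximum (default 0.99).
#' @param breaks histogram breaks passed to [hist()].
#' @return A list: `worst` (max), `quantile`, `probs`, and `histogram`
#'   (data.frame of bin mids and counts).
#' @export
worstCaseGradient <- function(field, mask = NULL, probs = 0.99, breaks = 30) {
  g <- gradientMagnitude(field, mask)
  v <- g[!is.na(g)]
  if (!length(v)) stop("no valid voxels in the region")
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  list(worst = max(v), quantile = unname(stats::quantile(v, probs)),
       probs = probs,
       histogram = data.frame(mid = h$mids, count = h$counts))
}
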