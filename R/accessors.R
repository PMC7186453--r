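#' Accessors for tdcsmap objects
#'
#' Small accessor generics so that downstream code never touches slots
#' directly: `fieldValues`/`fieldMask`/`fieldGrid` for [FieldMap-class] and
#' [FieldEstimate-class] ([fieldValues()] on an estimate returns the slope
#' in nT/mA), grid geometry accessors for [VoxelGrid-class], `currents`/
#' `scanBoundaries`/`nVolumes` for [CurrentWaveform-class], and
#' `phaseValues` for [PhaseSeries-class].
#'
#' @param x the object.
#' @return The slot contents as plain vectors/arrays.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("fieldValues", "FieldMap", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("fieldMask", "FieldMap", function(x) x@mask)

#' @rdname accessors
#' @export
setMethod("fieldGrid", "FieldMap", function(x) x@grid)

#' @rdname accessors
#' @export
setMethod("fieldValues", "FieldEstimate", function(x) x@slope)

#' @rdname accessors
#' @export
setMethod("fieldMask", "FieldEstimate", function(x) x@mask)

#' @rdname accessors
#' @export
setMethod("fieldGrid", "FieldEstimate", function(x) x@grid)

#' @rdname accessors
#' @export
setMethod("fieldSlope", "FieldEstimate", function(x) x@slope)

#' @rdname accessors
#' @export
setMethod("fieldSe", "FieldEstimate", function(x) x@se)

#' @rdname accessors
#' @export
setMethod("gridShape", "VoxelGrid", function(x) x@shape)

#' @rdname accessors
#' @export
setMethod("gridSpacing", "VoxelGrid", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("gridOrigin", "VoxelGrid", function(x) x@origin)

#' @rdname accessors
#' @export
setMethod("currents", "CurrentWaveform", function(x) x@currents)

#' @rdname accessors
#' @export
setMethod("scanBoundaries", "CurrentWaveform", function(x) x@scanBoundaries)

#' @rdname accessors
#' @export
setMethod("nVolumes", "CurrentWaveform", function(x) length(x@currents))

#' @rdname accessors
#' @export
setMethod("nVolumes", "DualEchoSeries", function(x) dim(x@phaseE2)[4L])

#' @rdname accessors
#' @export
setMethod("nVolumes", "PhaseSeries", function(x) dim(x@values)[4L])

#' @rdname accessors
#' @export
setMethod("phaseValues", "PhaseSeries", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("fieldGrid", "PhaseSeries", function(x) x@grid)

#' @rdname accessors
#' @export
setMethod("fieldMask", "PhaseSeries", function(x) x@mask)

setMethod("show", "VoxelGrid", function(object) {
  cat("VoxelGrid:", paste(object@shape, collapse = " x "), "voxels,",
      paste(format(object@spacing, trim = TRUE), collapse = " x "), "mm spacing\n")
  cat("  origin (mm):", paste(format(object@origin, trim = TRUE), collapse = ", "), "\n")
})

setMethod("show", "CurrentPath", function(object) {
  cat("CurrentPath:", nrow(object@vertices), "vertices,",
      if (object@closed) "closed," else "open,",
      format(object@current), "mA\n")
})

setMethod("show", "FieldMap", function(object) {
  v <- object@values[object@mask]
  cat("FieldMap on", paste(object@grid@shape, collapse = " x "), "grid;",
      sum(object@mask), "of", length(object@mask), "voxels valid\n")
  if (length(v))
    cat("  Bz range (nT/mA): [", format(min(v), digits = 4), ",",
        format(max(v), digits = 4), "]\n")
  else cat("  (empty: all voxels masked)\n")
})

setMethod("show", "CurrentWaveform", function(object) {
  cat("CurrentWaveform:", length(object@currents), "volumes at TR",
      object@tr, "s;", length(object@scanBoundaries), "scan(s);",
      "levels (mA):", paste(sort(unique(object@currents)), collapse = ", "), "\n")
})

setMethod("show", "DualEchoSeries", function(object) {
  d <- dim(object@phaseE2)
  cat("DualEchoSeries:", paste(d[1:3], collapse = " x "), "voxels x", d[4L],
      "volumes; TE1/TE2 =", object@params@te1 * 1e3, "/",
      object@params@te2 * 1e3, "ms\n")
  cat("  simulation ground truth:", if (length(object@truth)) "retained" else "absent", "\n")
})

setMethod("show", "PhaseSeries", function(object) {
  d <- dim(object@values)
  cat("PhaseSeries (unwrapped):", paste(d[1:3], collapse = " x "), "voxels x",
      d[4L], "volumes;", sum(object@flags), "voxel(s) flagged\n")
})

setMethod("show", "FieldEstimate", function(object) {
  v <- object@slope[object@mask]
  cat("FieldEstimate:", sum(object@mask), "voxels fitted; slope range (nT/mA): [",
      format(min(v), digits = 4), ",", format(max(v), digits = 4), "]\n")
})

setMethod("show", "MagnitudeEstimate", function(object) {
  cat("MagnitudeEstimate:", sum(object@mask), "voxels;",
      sum(object@pFwe[object@mask] < 0.05, na.rm = TRUE),
      "significant at FWE 0.05\n")
})
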