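.pkgVersion <- function() as.character(utils::packageVersion("tdcsmap"))

.gridAffine <- function(grid) {
  aff <- diag(c(grid@spacing, 1))
  aff[1:3, 4L] <- grid@origin
  aff
}

# Extract an axis-aligned VoxelGrid from a NIfTI xform; obliques rejected.
.gridFromNifti <- function(image, path) {
  xf <- RNifti::xform(image)
  rot <- xf[1:3, 1:3]
  offDiag <- rot; diag(offDiag) <- 0
  if (any(abs(offDiag) > 1e-6) || any(diag(rot) <= 0))
    stop("oblique or flipped affine in '", path,
         "': only axis-aligned right-handed geometry is supported")
  d <- dim(image)
  voxelGrid(d[1:3], diag(rot), xf[1:3, 4L])
}

.writeVolume <- function(values, grid, path, datatype = "float") {
  ni <- RNifti::asNifti(values, datatype = datatype)
  aff <- structure(.gridAffine(grid), code = 2L)
  # sform only: the qform quaternion cannot carry anisotropic scales exactly
  ni <- RNifti::`sform<-`(ni, aff)
  RNifti::writeNifti(ni, path)
  invisible(path)
}

#' Read and write field maps as NIfTI-1
#'
#' Field maps are stored as float32 volumes in nT/mA with the grid geometry
#' in the (axis-aligned) NIfTI affine; the validity mask travels as a
#' companion 0/1 volume.
#'
#' @param field a [FieldMap-class].
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param maskPath optional path for the mask volume.
#' @return `writeFieldMap` returns the path(s) invisibly; `readFieldMap`
#'   returns a [FieldMap-class].
#' @export
writeFieldMap <- function(field, path, maskPath = NULL) {
  .writeVolume(fieldValues(field), field@grid, path)
  if (!is.null(maskPath))
    .writeVolume(array(as.numeric(field@mask), dim(field@mask)), field@grid,
                 maskPath, datatype = "uint8")
  invisible(c(path, maskPath))
}

#' @rdname writeFieldMap
#' @export
readFieldMap <- function(path, maskPath = NULL) {
  ni <- RNifti::readNifti(path)
  grid <- .gridFromNifti(ni, path)
  vals <- array(as.numeric(ni), dim(ni)[1:3])
  mask <- if (!is.null(maskPath)) {
    mi <- RNifti::readNifti(maskPath)
    array(as.numeric(mi) != 0, dim(mi)[1:3])
  } else array(is.finite(vals), dim(vals))
  vals[!mask] <- 0
  fieldMap(grid, vals, mask)
}

#' Write a binary mask as NIfTI-1
#'
#' @param mask 3D logical array.
#' @param grid the [VoxelGrid-class].
#' @param path output path.
#' @export
writeMask <- function(mask, grid, path) {
  .writeVolume(array(as.numeric(mask), dim(mask)), grid, path,
               datatype = "uint8")
}

#' Read and write acquisition parameters as JSON
#'
#' @param params an [AcquisitionParams-class].
#' @param path JSON path.
#' @return `readAcquisitionParams` returns an [AcquisitionParams-class].
#' @export
writeAcquisitionParams <- function(params, path) {
  x <- list(te1 = params@te1, te2 = params@te2, tr = params@tr,
            gamma = params@gamma, baseline_magnitude = params@baselineMagnitude,
            complex_noise_sd = params@complexNoiseSd,
            drift_slope = params@driftSlope,
            background_field_sd = params@backgroundFieldSd,
            seed = if (is.na(params@seed)) NULL else params@seed,
            software_version = .pkgVersion())
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeAcquisitionParams
#' @export
readAcquisitionParams <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  acquisitionParams(tr = x$tr, te1 = x$te1, te2 = x$te2, gamma = x$gamma,
                    baselineMagnitude = x$baseline_magnitude,
                    complexNoiseSd = x$complex_noise_sd,
                    driftSlope = x$drift_slope %||% 0,
                    backgroundFieldSd = x$background_field_sd %||% 500,
                    seed = if (is.null(x$seed)) NA_integer_ else x$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a dual-echo series to NIfTI-1 files
#'
#' Writes four float32 volumes (magnitude and phase for each echo, phase in
#' radians in [-pi, pi)) plus the acquisition parameters as JSON.
#'
#' @param series a [DualEchoSeries-class].
#' @param prefix output path prefix; files are named
#'   `<prefix>_mag_e1.nii.gz`, `<prefix>_ph_e1.nii.gz`, `<prefix>_mag_e2.nii.gz`,
#'   `<prefix>_ph_e2.nii.gz` and `<prefix>_params.json`.
#' @return Named character vector of paths, invisibly.
#' @export
writeDualEchoSeries <- function(series, prefix) {
  paths <- c(magE1 = paste0(prefix, "_mag_e1.nii.gz"),
             phE1 = paste0(prefix, "_ph_e1.nii.gz"),
             magE2 = paste0(prefix, "_mag_e2.nii.gz"),
             phE2 = paste0(prefix, "_ph_e2.nii.gz"),
             params = paste0(prefix, "_params.json"))
  .writeVolume(series@magnitudeE1, series@grid, paths[["magE1"]])
  .writeVolume(series@phaseE1, series@grid, paths[["phE1"]])
  .writeVolume(series@magnitudeE2, series@grid, paths[["magE2"]])
  .writeVolume(series@phaseE2, series@grid, paths[["phE2"]])
  writeAcquisitionParams(series@params, paths[["params"]])
  invisible(paths)
}

#' Read a dual-echo series from NIfTI-1 files
#'
#' The four volumes must share shape and affine (within 1e-4 mm). Phase is
#' expected in radians; scanner integer-scaled phase dialects are accepted
#' read-only by declaring `phaseScale` (radians per stored unit), after
#' which values are wrapped to [-pi, pi).
#'
#' @param magE1,phE1,magE2,phE2 NIfTI paths.
#' @param params an [AcquisitionParams-class] or the path of a params JSON.
#' @param phaseScale optional radians-per-unit factor for integer-scaled
#'   phase (e.g. `pi / 4096` for values spanning -4096..4095).
#' @return A [DualEchoSeries-class] (no retained ground truth).
#' @export
readDualEchoSeries <- function(magE1, phE1, magE2, phE2, params,
                               phaseScale = NULL) {
  if (is.character(params)) params <- readAcquisitionParams(params)
  paths <- c(magE1, phE1, magE2, phE2)
  imgs <- lapply(paths, RNifti::readNifti)
  dims <- lapply(imgs, function(x) dim(x))
  for (i in 2:4) {
    if (!identical(dims[[i]], dims[[1L]]))
      stop("volume shape mismatch between '", paths[1L], "' (",
           paste(dims[[1L]], collapse = "x"), ") and '", paths[i], "' (",
           paste(dims[[i]], collapse = "x"), ")")
    if (max(abs(RNifti::xform(imgs[[i]]) - RNifti::xform(imgs[[1L]]))) > 1e-4)
      stop("affine mismatch between '", paths[1L], "' and '", paths[i], "'")
  }
  if (length(dims[[1L]]) != 4L) stop("series volumes must be 4D")
  grid <- .gridFromNifti(imgs[[1L]], paths[1L])
  d4 <- dims[[1L]]
  getPhase <- function(img, path) {
    v <- as.numeric(img)
    if (!is.null(phaseScale)) v <- v * phaseScale
    v <- wrapPhase(v)
    array(v, d4)
  }
  new("DualEchoSeries",
      magnitudeE1 = array(as.numeric(imgs[[1L]]), d4),
      phaseE1 = getPhase(imgs[[2L]], phE1),
      magnitudeE2 = array(as.numeric(imgs[[3L]]), d4),
      phaseE2 = getPhase(imgs[[4L]], phE2),
      grid = grid, params = params, truth = list())
}

#' Read and write unwrapped phase series
#'
#' @param phase a [PhaseSeries-class].
#' @param path NIfTI path for the 4D phase volume (float32, radians).
#' @param flagPath optional NIfTI path for the excessive-wrap flag mask.
#' @export
writePhaseSeries <- function(phase, path, flagPath = NULL) {
  .writeVolume(phase@values, phase@grid, path)
  if (!is.null(flagPath))
    writeMask(phase@flags, phase@grid, flagPath)
  invisible(c(path, flagPath))
}

#' Write a current waveform as TSV
#'
#' Columns `volume_index` (0-based), `time_s` and `current_mA`; waveform
#' metadata (TR, block length, scan boundaries, software version) is kept
#' in `#`-comment header lines so the file round-trips losslessly.
#'
#' @param waveform a [CurrentWaveform-class].
#' @param path TSV path.
#' @export
writeWaveform <- function(waveform, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# tdcsmap ", .pkgVersion()),
               paste0("# tr_s=", format(waveform@tr, digits = 15)),
               paste0("# block_length_s=", format(waveform@blockLength, digits = 15)),
               paste0("# scan_boundaries=",
                      paste(waveform@scanBoundaries, collapse = ","))), con)
  n <- length(waveform@currents)
  df <- data.frame(volume_index = seq_len(n) - 1L,
                   time_s = (seq_len(n) - 1L) * waveform@tr,
                   current_mA = waveform@currents)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a current waveform from TSV
#'
#' Expects columns `volume_index`, `time_s`, `current_mA` with a monotone
#' 0-based volume index; extra columns are ignored with a warning. Metadata
#' comment lines written by [writeWaveform()] are honoured; otherwise TR is
#' inferred from `time_s`, the series is treated as one scan, and the block
#' length is inferred from the longest constant-current run.
#'
#' @param path TSV path.
#' @return A [CurrentWaveform-class].
#' @export
readWaveform <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty waveform file: ", path)
  meta <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, invert = TRUE, value = TRUE)
  if (!length(body)) stop("empty waveform file: ", path)
  df <- utils::read.delim(text = body, check.names = FALSE)
  need <- c("volume_index", "time_s", "current_mA")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("waveform file is missing column(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(df), need)
  if (length(extra))
    warning("ignoring extra waveform column(s): ", paste(extra, collapse = ", "))
  if (nrow(df) == 0L) stop("empty waveform file: ", path)
  if (!identical(as.integer(df$volume_index), seq_len(nrow(df)) - 1L))
    stop("volume_index must be monotone starting at 0")
  getMeta <- function(key) {
    hit <- grep(paste0("^# ?", key, "="), meta, value = TRUE)
    if (length(hit)) sub(paste0("^# ?", key, "="), "", hit[1L]) else NULL
  }
  tr <- getMeta("tr_s")
  tr <- if (!is.null(tr)) as.numeric(tr)
        else if (nrow(df) > 1L) stats::median(diff(df$time_s)) else 1
  bounds <- getMeta("scan_boundaries")
  bounds <- if (!is.null(bounds)) as.integer(strsplit(bounds, ",")[[1L]]) else 1L
  blk <- getMeta("block_length_s")
  blk <- if (!is.null(blk)) as.numeric(blk)
         else max(rle(df$current_mA)$lengths) * tr
  new("CurrentWaveform", currents = as.numeric(df$current_mA), tr = tr,
      scanBoundaries = bounds, blockLength = blk)
}

#' Write a tabular report as TSV
#'
#' @param result a data.frame.
#' @param path TSV path; a `#` header records the software version.
#' @export
writeReport <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# tdcsmap ", .pkgVersion()), con)
  utils::write.table(result, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write current paths as JSON
#'
#' @param path a [CurrentPath-class] (for writing) or a JSON path.
#' @param file JSON path.
#' @export
writeCurrentPath <- function(path, file) {
  jsonlite::write_json(list(vertices_mm = unname(split(path@vertices,
                                                       row(path@vertices)[, 1L])),
                            current_mA = path@current,
                            closed = path@closed),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeCurrentPath
#' @export
readCurrentPath <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  verts <- x$vertices_mm
  if (is.list(verts)) verts <- do.call(rbind, verts)
  currentPath(verts, current = x$current_mA, closed = isTRUE(x$closed))
}

#' Write a field estimate to NIfTI-1 and a fit report
#'
#' Writes slope, SE and t maps plus a one-row TSV report (voxel count,
#' design columns used, dropped columns).
#'
#' @param estimate a [FieldEstimate-class].
#' @param prefix output path prefix.
#' @param design optional design matrix (for the report columns).
#' @return Named character vector of paths, invisibly.
#' @export
writeFieldEstimate <- function(estimate, prefix, design = NULL) {
  paths <- c(slope = paste0(prefix, "_slope.nii.gz"),
             se = paste0(prefix, "_se.nii.gz"),
             t = paste0(prefix, "_t.nii.gz"),
             report = paste0(prefix, "_report.tsv"))
  g <- estimate@grid
  .writeVolume(estimate@slope, g, paths[["slope"]])
  .writeVolume(estimate@se, g, paths[["se"]])
  .writeVolume(estimate@slope / estimate@se, g, paths[["t"]])
  rep <- data.frame(
    n_voxels = sum(estimate@mask),
    design_columns = if (is.null(design)) NA_character_
                     else paste(colnames(design), collapse = ","),
    dropped_columns = if (is.null(design)) NA_character_
                      else paste(attr(design, "dropped"), collapse = ","))
  writeReport(rep, paths[["report"]])
  invisible(paths)
}

#' Run configuration
#'
#' A lossless on-disk description of one analysis run: acquisition
#' parameters, waveform layout, analysis bounds, seed and output prefix.
#'
#' @param params an [AcquisitionParams-class].
#' @param levels,blockLength,nScans,scanLength waveform layout (see
#'   [makeWaveform()]).
#' @param boundsNt regression range bounds in nT.
#' @param seed integer seed.
#' @param outPrefix output path prefix.
#' @return A list of class `tdcsmapRunConfig`.
#' @export
runConfig <- function(params, levels, blockLength, nScans, scanLength,
                      boundsNt = c(Inf, 10, 5, 1), seed = 1L,
                      outPrefix = "tdcsmap") {
  structure(list(params = params, levels = levels, blockLength = blockLength,
                 nScans = nScans, scanLength = scanLength,
                 boundsNt = boundsNt, seed = as.integer(seed),
                 outPrefix = outPrefix),
            class = "tdcsmapRunConfig")
}

#' @rdname runConfig
#' @param config a `tdcsmapRunConfig`.
#' @param file JSON path.
#' @export
writeRunConfig <- function(config, file) {
  p <- config$params
  x <- list(params = list(te1 = p@te1, te2 = p@te2, tr = p@tr, gamma = p@gamma,
                          baseline_magnitude = p@baselineMagnitude,
                          complex_noise_sd = p@complexNoiseSd,
                          drift_slope = p@driftSlope,
                          background_field_sd = p@backgroundFieldSd,
                          seed = if (is.na(p@seed)) NULL else p@seed),
            levels = config$levels, block_length_s = config$blockLength,
            n_scans = config$nScans, scan_length_s = config$scanLength,
            bounds_nt = ifelse(is.infinite(config$boundsNt), "Inf",
                               as.character(config$boundsNt)),
            seed = config$seed, out_prefix = config$outPrefix,
            software_version = .pkgVersion())
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  p <- x$params
  params <- acquisitionParams(tr = p$tr, te1 = p$te1, te2 = p$te2,
                              gamma = p$gamma,
                              baselineMagnitude = p$baseline_magnitude,
                              complexNoiseSd = p$complex_noise_sd,
                              driftSlope = p$drift_slope %||% 0,
                              backgroundFieldSd = p$background_field_sd %||% 500,
                              seed = if (is.null(p$seed)) NA_integer_ else p$seed)
  runConfig(params, levels = as.numeric(x$levels),
            blockLength = x$block_length_s, nScans = x$n_scans,
            scanLength = x$scan_length_s,
            boundsNt = as.numeric(ifelse(x$bounds_nt == "Inf", Inf,
                                         x$bounds_nt)),
            seed = x$seed, outPrefix = x$out_prefix)
}
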