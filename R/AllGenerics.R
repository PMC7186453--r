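#' @rdname accessors
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))

#' @rdname accessors
#' @export
setGeneric("fieldMask", function(x) standardGeneric("fieldMask"))

#' @rdname accessors
#' @export
setGeneric("fieldGrid", function(x) standardGeneric("fieldGrid"))

#' @rdname accessors
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname accessors
#' @export
setGeneric("currents", function(x) standardGeneric("currents"))

#' @rdname accessors
#' @export
setGeneric("scanBoundaries", function(x) standardGeneric("scanBoundaries"))

#' @rdname accessors
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))

#' @rdname accessors
#' @export
setGeneric("phaseValues", function(x) standardGeneric("phaseValues"))

#' @rdname accessors
#' @export
setGeneric("fieldSlope", function(x) standardGeneric("fieldSlope"))

#' @rdname accessors
#' @export
setGeneric("fieldSe", function(x) standardGeneric("fieldSe"))
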