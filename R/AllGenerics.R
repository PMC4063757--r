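#' @rdname imageGrid
#' @export
setGeneric("imageDims", function(x) standardGeneric("imageDims"))

#' @rdname imageGrid
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname imageGrid
#' @export
setGeneric("affineMatrix", function(x) standardGeneric("affineMatrix"))

#' @rdname imageGrid
#' @export
setGeneric("imageGrid", function(x, ...) standardGeneric("imageGrid"))

#' @rdname gradientTable
#' @export
setGeneric("bValues", function(x) standardGeneric("bValues"))

#' @rdname gradientTable
#' @export
setGeneric("bVectors", function(x) standardGeneric("bVectors"))

#' @rdname gradientTable
#' @export
setGeneric("b0Mask", function(x) standardGeneric("b0Mask"))

#' @rdname tractogram
#' @export
setGeneric("streamlines", function(x) standardGeneric("streamlines"))

#' @rdname tractogram
#' @export
setGeneric("stepSize", function(x) standardGeneric("stepSize"))

#' @rdname summarizeTerminations
#' @export
setGeneric("summarizeTerminations",
           function(x, ...) standardGeneric("summarizeTerminations"))

#' @rdname terminationTable
#' @export
setGeneric("indicators", function(x) standardGeneric("indicators"))

#' @rdname terminationTable
#' @export
setGeneric("voiNames", function(x) standardGeneric("voiNames"))
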