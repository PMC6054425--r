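#' @title Accessor generics
#' @name plumeMI-generics
#' @description Accessor generics for the S4 classes of the package.
#'   Concentration movies store frames as a height x width x time array;
#'   all information quantities are in bits.
#' @param object an object of one of the package's S4 classes
#' @param x an object of one of the package's S4 classes
#' @return the corresponding slot value; see the class documentation.
NULL

#' @rdname plumeMI-generics
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))

#' @rdname plumeMI-generics
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))

#' @rdname plumeMI-generics
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname plumeMI-generics
#' @export
setGeneric("sourcePixel", function(object) standardGeneric("sourcePixel"))

#' @rdname plumeMI-generics
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))

#' @rdname plumeMI-generics
#' @export
setGeneric("movieLabel", function(object) standardGeneric("movieLabel"))

#' @rdname plumeMI-generics
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname plumeMI-generics
#' @export
setGeneric("gridPoints", function(object) standardGeneric("gridPoints"))

#' @rdname plumeMI-generics
#' @export
setGeneric("gridName", function(object) standardGeneric("gridName"))

#' @rdname plumeMI-generics
#' @export
setGeneric("jitterOffsets", function(object) standardGeneric("jitterOffsets"))

#' @rdname plumeMI-generics
#' @export
setGeneric("cutpoints", function(object) standardGeneric("cutpoints"))

#' @rdname plumeMI-generics
#' @export
setGeneric("effectiveBins", function(object) standardGeneric("effectiveBins"))

#' @rdname plumeMI-generics
#' @export
setGeneric("nBits", function(object) standardGeneric("nBits"))

#' @rdname plumeMI-generics
#' @export
setGeneric("totalBits", function(object) standardGeneric("totalBits"))

#' @rdname plumeMI-generics
#' @export
setGeneric("drawsPerLocation", function(object) standardGeneric("drawsPerLocation"))

#' @rdname plumeMI-generics
#' @export
setGeneric("countsMatrix", function(object) standardGeneric("countsMatrix"))

#' @rdname plumeMI-generics
#' @export
setGeneric("miRaw", function(object) standardGeneric("miRaw"))

#' @rdname plumeMI-generics
#' @export
setGeneric("miDebiased", function(object) standardGeneric("miDebiased"))

#' @rdname plumeMI-generics
#' @export
setGeneric("miExtrapolated", function(object) standardGeneric("miExtrapolated"))

#' @rdname plumeMI-generics
#' @export
setGeneric("biasSlope", function(object) standardGeneric("biasSlope"))

#' @rdname plumeMI-generics
#' @export
setGeneric("subsetPoints", function(object) standardGeneric("subsetPoints"))
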