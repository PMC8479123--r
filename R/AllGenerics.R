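#' @rdname ToyGenome-class
#' @param x,object A package object.
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname ToyGenome-class
#' @export
setGeneric("origins", function(x) standardGeneric("origins"))

#' @rdname ToyGenome-class
#' @export
setGeneric("ctcfSites", function(x) standardGeneric("ctcfSites"))

#' @rdname ToyGenome-class
#' @export
setGeneric("enhancerModules", function(x) standardGeneric("enhancerModules"))

#' @rdname FragmentMap-class
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))

#' @rdname FragmentMap-class
#' @export
setGeneric("fragmentTable", function(x) standardGeneric("fragmentTable"))

#' @rdname ContactProfile-class
#' @export
setGeneric("contactCounts", function(x) standardGeneric("contactCounts"))

#' @rdname ContactProfile-class
#' @export
setGeneric("normalizedCounts", function(x) standardGeneric("normalizedCounts"))

#' @rdname ContactProfile-class
#' @export
setGeneric("readStats", function(x) standardGeneric("readStats"))

#' @rdname DerivativeChromosome-class
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))

#' @rdname SignalTrack-class
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

#' @rdname SignalTrack-class
#' @export
setGeneric("trackData", function(x) standardGeneric("trackData"))
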