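#' @title Accessor generics
#' @description Generics for the core colliscope containers.
#' @param x a colliscope object
#' @param ... further arguments for methods
#' @name colliscope-generics
NULL

#' @rdname colliscope-generics
#' @export
setGeneric("combos", function(x, ...) standardGeneric("combos"))

#' @rdname colliscope-generics
#' @export
setGeneric("nCombos", function(x) standardGeneric("nCombos"))

#' @rdname colliscope-generics
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))

#' @rdname colliscope-generics
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname colliscope-generics
#' @export
setGeneric("traces", function(x) standardGeneric("traces"))

#' @rdname colliscope-generics
#' @export
setGeneric("neuropil", function(x) standardGeneric("neuropil"))

#' @rdname colliscope-generics
#' @export
setGeneric("masks", function(x) standardGeneric("masks"))

#' @rdname colliscope-generics
#' @export
setGeneric("centroids", function(x, ...) standardGeneric("centroids"))

#' @rdname colliscope-generics
#' @export
setGeneric("compartments", function(x) standardGeneric("compartments"))

#' @rdname colliscope-generics
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname colliscope-generics
#' @export
setGeneric("dff", function(x) standardGeneric("dff"))
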