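#' @name ChromDyn-accessors
#' @title Accessors for ChromDyn classes
#' @description Small accessor generics used across the package instead of
#'   direct slot access.
#' @param object a ChromDyn S4 object.
#' @param ... further arguments passed to methods.
NULL

#' @rdname ChromDyn-accessors
#' @export
setGeneric("nLoci", function(object) standardGeneric("nLoci"))

#' @rdname ChromDyn-accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname ChromDyn-accessors
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))

#' @rdname ChromDyn-accessors
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))

#' @rdname ChromDyn-accessors
#' @export
setGeneric("nucleusId", function(object) standardGeneric("nucleusId"))

#' @rdname ChromDyn-accessors
#' @export
setGeneric("conditionLabel", function(object) standardGeneric("conditionLabel"))

#' @rdname ChromDyn-accessors
#' @export
setGeneric("locusIds", function(object) standardGeneric("locusIds"))

#' @rdname ChromDyn-accessors
#' @param i locus index or id.
#' @export
setGeneric("getTrajectory", function(object, i) standardGeneric("getTrajectory"))

#' @rdname ChromDyn-accessors
#' @export
setGeneric("trajectories", function(object) standardGeneric("trajectories"))

#' @rdname ChromDyn-accessors
#' @export
setGeneric("coordDims", function(object) standardGeneric("coordDims"))

#' @rdname ChromDyn-accessors
#' @export
setGeneric("alpha", function(object) standardGeneric("alpha"))

#' @rdname ChromDyn-accessors
#' @export
setGeneric("alphaMean", function(object) standardGeneric("alphaMean"))

#' @rdname ChromDyn-accessors
#' @export
setGeneric("alphaSd", function(object) standardGeneric("alphaSd"))

#' @rdname ChromDyn-accessors
#' @export
setGeneric("dAlpha", function(object) standardGeneric("dAlpha"))

#' @rdname ChromDyn-accessors
#' @export
setGeneric("rho", function(object) standardGeneric("rho"))

#' @rdname ChromDyn-accessors
#' @export
setGeneric("freeFraction", function(object) standardGeneric("freeFraction"))

#' @rdname ChromDyn-accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
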