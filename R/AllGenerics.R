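#' @name twnscreen-generics
#' @title Accessor generics
#' @description Accessors for the S4 containers of the package.
#' @param x An object.
#' @param ... Further arguments for methods.
NULL

#' @rdname twnscreen-generics
#' @export
setGeneric("nFrames", function(x, ...) standardGeneric("nFrames"))

#' @rdname twnscreen-generics
#' @export
setGeneric("frameIds", function(x, ...) standardGeneric("frameIds"))

#' @rdname twnscreen-generics
#' @export
setGeneric("waters", function(x, ...) standardGeneric("waters"))

#' @rdname twnscreen-generics
#' @export
setGeneric("rings", function(x, ...) standardGeneric("rings"))

#' @rdname twnscreen-generics
#' @export
setGeneric("nRings", function(x, ...) standardGeneric("nRings"))

#' @rdname twnscreen-generics
#' @export
setGeneric("nGroups", function(x, ...) standardGeneric("nGroups"))

#' @rdname twnscreen-generics
#' @export
setGeneric("groups", function(x, ...) standardGeneric("groups"))

#' @rdname twnscreen-generics
#' @export
setGeneric("groupCentroids", function(x, ...) standardGeneric("groupCentroids"))

#' @rdname twnscreen-generics
#' @export
setGeneric("groupPlanes", function(x, ...) standardGeneric("groupPlanes"))

#' @rdname twnscreen-generics
#' @export
setGeneric("groupOxygens", function(x, ...) standardGeneric("groupOxygens"))

#' @rdname twnscreen-generics
#' @export
setGeneric("occupancy", function(x, ...) standardGeneric("occupancy"))

#' @rdname twnscreen-generics
#' @export
setGeneric("fragIds", function(x, ...) standardGeneric("fragIds"))

#' @rdname twnscreen-generics
#' @export
setGeneric("fragAtoms", function(x, ...) standardGeneric("fragAtoms"))

#' @rdname twnscreen-generics
#' @export
setGeneric("screenRecords", function(x, ...) standardGeneric("screenRecords"))

#' @rdname twnscreen-generics
#' @export
setGeneric("siteCenter", function(x, ...) standardGeneric("siteCenter"))

#' @rdname twnscreen-generics
#' @export
setGeneric("siteRadius", function(x, ...) standardGeneric("siteRadius"))
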