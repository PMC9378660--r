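#' @include AllClasses.R
NULL

#' @rdname tsMatrix
#' @export
setGeneric("tsMatrix", function(x) standardGeneric("tsMatrix"))

#' @rdname accessors
#' @export
setGeneric("censorMask", function(x) standardGeneric("censorMask"))

#' @rdname accessors
#' @export
setGeneric("sessionIds", function(x) standardGeneric("sessionIds"))

#' @rdname accessors
#' @export
setGeneric("sessionBoundaries", function(x) standardGeneric("sessionBoundaries"))

#' @rdname accessors
#' @export
setGeneric("parcelNetworks", function(x) standardGeneric("parcelNetworks"))

#' @rdname accessors
#' @export
setGeneric("networkLabels", function(x) standardGeneric("networkLabels"))

#' @rdname accessors
#' @export
setGeneric("trueLabels", function(x) standardGeneric("trueLabels"))

#' @rdname accessors
#' @export
setGeneric("trueTransitionMatrix", function(x) standardGeneric("trueTransitionMatrix"))

#' @rdname graph-accessors
#' @export
setGeneric("nodeMembers", function(x) standardGeneric("nodeMembers"))

#' @rdname graph-accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname graph-accessors
#' @export
setGeneric("nodeEmbedding", function(x) standardGeneric("nodeEmbedding"))

#' @rdname graph-accessors
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname annotation-accessors
#' @export
setGeneric("activationProportions", function(x) standardGeneric("activationProportions"))

#' @rdname annotation-accessors
#' @export
setGeneric("meanActivation", function(x) standardGeneric("meanActivation"))

#' @rdname annotation-accessors
#' @export
setGeneric("activationSD", function(x) standardGeneric("activationSD"))

#' @rdname annotation-accessors
#' @export
setGeneric("dominantNetwork", function(x) standardGeneric("dominantNetwork"))

#' @rdname chain-accessors
#' @export
setGeneric("states", function(x) standardGeneric("states"))

#' @rdname chain-accessors
#' @export
setGeneric("transitionCounts", function(x) standardGeneric("transitionCounts"))

#' @rdname chain-accessors
#' @export
setGeneric("transitionProbabilities", function(x) standardGeneric("transitionProbabilities"))

#' @rdname accessors
#' @export
setGeneric("surrogates", function(x) standardGeneric("surrogates"))

#' @rdname runMapper
#' @export
setGeneric("runMapper", function(x, config = mapperConfig(), ...)
    standardGeneric("runMapper"))
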