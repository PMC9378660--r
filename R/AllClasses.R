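#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## label used for the uniform, no-network-dominating state throughout
.HUB <- "HUB"

#' ParcellatedTimeSeries: parcellated multivariate recording
#'
#' Container for a frames-by-parcels recording together with the metadata
#' the pipeline needs: a per-frame censor mask (frames flagged as artifact,
#' e.g. head motion), session membership (so that stitch points between
#' concatenated sessions can be excluded from transition counting), and a
#' parcel-to-network assignment. Internally the object extends
#' \linkS4class{SummarizedExperiment} with parcels as rows and frames as
#' columns; use \code{\link{tsMatrix}} to obtain the conventional
#' frames-by-parcels matrix.
#'
#' @slot frameDuration sampling interval (TR) in seconds.
#' @export
setClass("ParcellatedTimeSeries",
    contains = "SummarizedExperiment",
    representation(frameDuration = "numeric"))

setValidity("ParcellatedTimeSeries", function(object) {
    msg <- NULL
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("frame", "session", "censored") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'frame', 'session', 'censored'")
    rd <- SummarizedExperiment::rowData(object)
    if (!"network" %in% colnames(rd))
        msg <- c(msg, "rowData must contain 'network'")
    if ("session" %in% colnames(cd) && ncol(object) > 1L) {
        s <- as.integer(factor(cd$session, levels = unique(cd$session)))
        if (any(diff(s) < 0))
            msg <- c(msg, "frames of one session must be contiguous")
    }
    if (length(object@frameDuration) != 1L || object@frameDuration <= 0)
        msg <- c(msg, "frameDuration must be a single positive number")
    if (is.null(msg)) TRUE else msg
})

#' MapperConfig: parameters of the Mapper pipeline
#'
#' @slot d embedding dimension of the filter (default 2).
#' @slot k neighbour count of the k-NN graph used for geodesic distances.
#' @slot R resolution: number of bins per embedding dimension.
#' @slot G gain: percent overlap between adjacent bins.
#' @slot metric input-space metric ("euclidean" or "correlation").
#' @slot histBins histogram bins of the single-linkage gap heuristic.
#' @slot seed integer seed recorded with every graph.
#' @export
setClass("MapperConfig", representation(
    d = "integer", k = "integer", R = "integer", G = "numeric",
    metric = "character", histBins = "integer", seed = "integer"))

setValidity("MapperConfig", function(object) {
    msg <- NULL
    if (object@d < 1L) msg <- c(msg, "d must be >= 1")
    if (object@k < 1L) msg <- c(msg, "k must be >= 1")
    if (object@R < 2L) msg <- c(msg, "R must be >= 2")
    if (object@G < 0 || object@G >= 100) msg <- c(msg, "G must be in [0, 100)")
    if (object@histBins < 2L) msg <- c(msg, "histBins must be >= 2")
    if (!object@metric %in% c("euclidean", "correlation"))
        msg <- c(msg, sprintf("unknown metric '%s'", object@metric))
    if (is.null(msg)) TRUE else msg
})

#' ShapeGraph: Mapper output graph
#'
#' Nodes are partial clusters of time frames; two nodes are joined whenever
#' they share at least one frame. The per-frame 2-D filter coordinates and
#' the generating configuration are retained so graphs are reproducible and
#' can be annotated afterwards.
#'
#' @slot nodes list of integer vectors of frame indices (1-based, in the
#'   retained-frame ordering).
#' @slot adjacency binary symmetric adjacency matrix with zero diagonal.
#' @slot embedding frames-by-d matrix of filter coordinates.
#' @slot binOfNode integer id of the cover bin each node came from.
#' @slot nFrames number of retained frames covered by the graph.
#' @slot config the \linkS4class{MapperConfig} used.
#' @export
setClass("ShapeGraph", representation(
    nodes = "list", adjacency = "matrix", embedding = "matrix",
    binOfNode = "integer", nFrames = "integer", config = "MapperConfig"))

setValidity("ShapeGraph", function(object) {
    msg <- NULL
    A <- object@adjacency
    n <- length(object@nodes)
    if (!all(dim(A) == c(n, n))) msg <- c(msg, "adjacency dim must match nodes")
    if (n > 0L) {
        if (any(A != t(A))) msg <- c(msg, "adjacency must be symmetric")
        if (any(diag(A) != 0)) msg <- c(msg, "adjacency diagonal must be zero")
        if (any(A != 0 & A != 1)) msg <- c(msg, "adjacency must be binary")
        if (any(lengths(object@nodes) == 0L)) msg <- c(msg, "empty node")
        covered <- sort(unique(unlist(object@nodes)))
        if (!identical(covered, seq_len(object@nFrames)))
            msg <- c(msg, "nodes must cover every retained frame")
    }
    if (is.null(msg)) TRUE else msg
})

#' NodeAnnotation: network engagement of shape-graph nodes
#'
#' @slot proportions node-by-network matrix: fraction of a node's member
#'   frames on which the network's z-scored mean signal exceeds the
#'   activation threshold (the pie-chart data).
#' @slot meanActivation node-by-network matrix of mean z-scored activation.
#' @slot activationSD per-node standard deviation of meanActivation across
#'   networks (low for hub-like, uniformly engaged nodes).
#' @slot dominantNetwork per-node label (a network or "HUB"), filled by
#'   \code{\link{assignDominant}}.
#' @slot threshold activation threshold in z units.
#' @export
setClass("NodeAnnotation", representation(
    proportions = "matrix", meanActivation = "matrix",
    activationSD = "numeric", dominantNetwork = "character",
    threshold = "numeric"))

setValidity("NodeAnnotation", function(object) {
    msg <- NULL
    p <- object@proportions
    if (any(p < 0 | p > 1)) msg <- c(msg, "proportions must lie in [0, 1]")
    if (!identical(dim(p), dim(object@meanActivation)))
        msg <- c(msg, "proportions and meanActivation dims differ")
    if (length(object@activationSD) != nrow(p))
        msg <- c(msg, "activationSD length must equal node count")
    if (any(object@activationSD < 0)) msg <- c(msg, "activationSD must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' StateSequence: per-frame state labels with transition validity
#'
#' @slot labels per-frame state label (network names plus "HUB").
#' @slot validTransition logical of length \code{length(labels) - 1}; FALSE
#'   where consecutive retained frames straddle a censoring gap or a session
#'   stitch, so the pair is excluded from Markov counting.
#' @slot stateLevels canonical state ordering (networks first, "HUB" last).
#' @export
setClass("StateSequence", representation(
    labels = "character", validTransition = "logical",
    stateLevels = "character"))

setValidity("StateSequence", function(object) {
    if (length(object@validTransition) != max(length(object@labels) - 1L, 0L))
        return("validTransition must have length(labels) - 1 entries")
    if (!all(object@labels %in% object@stateLevels))
        return("labels outside stateLevels")
    TRUE
})

#' TransitionMatrix: empirical discrete-time Markov chain
#'
#' @slot states ordered state labels.
#' @slot counts state-by-state matrix of observed valid transitions.
#' @slot probabilities row-stochastic matrix (counts row-normalised; rows
#'   with no outgoing transitions are set uniform with a warning).
#' @export
setClass("TransitionMatrix", representation(
    states = "character", counts = "matrix", probabilities = "matrix"))

setValidity("TransitionMatrix", function(object) {
    msg <- NULL
    k <- length(object@states)
    if (!all(dim(object@counts) == c(k, k)) ||
        !all(dim(object@probabilities) == c(k, k)))
        msg <- c(msg, "counts/probabilities must be states x states")
    if (any(object@counts < 0)) msg <- c(msg, "counts must be nonnegative")
    if (k > 0 && any(abs(rowSums(object@probabilities) - 1) > 1e-12))
        msg <- c(msg, "probability rows must sum to 1")
    if (is.null(msg)) TRUE else msg
})

#' NullEnsemble: set of linearity-preserving surrogate time series
#'
#' @slot surrogates list of frames-by-parcels surrogate matrices.
#' @slot kind "phase" (phase randomisation) or "var" (vector autoregression).
#' @slot p autoregressive order (VAR surrogates).
#' @slot seeds per-instance seeds actually used.
#' @export
setClass("NullEnsemble", representation(
    surrogates = "list", kind = "character", p = "integer",
    seeds = "integer"))

setValidity("NullEnsemble", function(object) {
    msg <- NULL
    if (!object@kind %in% c("phase", "var")) msg <- c(msg, "kind must be phase/var")
    if (length(object@surrogates) < 1L) msg <- c(msg, "need >= 1 instance")
    if (length(object@seeds) != length(object@surrogates))
        msg <- c(msg, "one seed per surrogate")
    if (is.null(msg)) TRUE else msg
})
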