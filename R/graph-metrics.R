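#' @include mapper.R
NULL

.asAdjacency <- function(graph) {
    if (is(graph, "ShapeGraph")) adjacency(graph) else as.matrix(graph)
}

## igraph from a binary adjacency matrix via the edge list (avoids the
## dense-matrix conversion path, which is slow on large graphs)
.asIgraph <- function(A) {
    e <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
    g <- igraph::make_empty_graph(n = nrow(A), directed = FALSE)
    if (nrow(e)) g <- igraph::add_edges(g, as.vector(t(e)))
    g
}

#' Node degree
#'
#' Degree of node i in a binary undirected graph: the number of edges
#' joining i to the other nodes, i.e. the i-th row sum of the adjacency
#' matrix.
#'
#' @param graph a \linkS4class{ShapeGraph} or binary adjacency matrix.
#' @return integer vector of per-node degrees.
#' @export
nodeDegree <- function(graph) {
    A <- .asAdjacency(graph)
    as.integer(rowSums(A))
}

#' Degree distribution across one or more graphs
#'
#' Histogram of node degrees per graph, aggregated as mean and standard
#' error of the mean per degree bin across graphs.
#'
#' @param graphs a \linkS4class{ShapeGraph}/adjacency matrix or a list of
#'   them.
#' @return data.frame with \code{degree}, \code{mean} count and \code{sem}
#'   across graphs (sem is 0 for a single graph).
#' @export
degreeDistribution <- function(graphs) {
    if (!is.list(graphs)) graphs <- list(graphs)
    stopifnot(length(graphs) >= 1L)
    degs <- lapply(graphs, nodeDegree)
    maxd <- max(unlist(degs))
    counts <- vapply(degs, function(k) tabulate(k + 1L, nbins = maxd + 1L),
                     numeric(maxd + 1L))
    counts <- matrix(counts, nrow = maxd + 1L)
    m <- rowMeans(counts)
    sem <- if (ncol(counts) > 1L)
        apply(counts, 1L, stats::sd) / sqrt(ncol(counts)) else rep(0, maxd + 1L)
    data.frame(degree = 0:maxd, mean = m, sem = sem)
}

#' Closeness centrality
#'
#' For node i, (N - 1) divided by the sum of shortest path lengths from i to
#' all other nodes (unit edge weights). On a disconnected graph the formula
#' is applied within each connected component with N equal to the component
#' size; isolated nodes get 0. By default (\code{scaled = TRUE}) the
#' within-component value is additionally multiplied by the component's node
#' fraction (n_c - 1)/(N - 1), the Wasserman-Faust correction: on a
#' connected graph this changes nothing, while on fragmented shape graphs it
#' stops two-node components (whose raw within-component closeness is 1)
#' from dominating the upper closeness quantiles used for hub detection.
#'
#' @param graph a \linkS4class{ShapeGraph} or binary adjacency matrix.
#' @param scaled scale by component fraction (default TRUE);
#'   \code{scaled = FALSE} gives the raw within-component values.
#' @return numeric vector of per-node closeness values in [0, 1].
#' @export
closenessCentrality <- function(graph, scaled = TRUE) {
    A <- .asAdjacency(graph)
    n <- nrow(A)
    if (n == 0L) return(numeric(0))
    g <- .asIgraph(A)
    comp <- igraph::components(g)$membership
    sz <- tabulate(comp)[comp]           # component size per node
    # within a component every node is reachable, so the per-node sum of
    # path lengths is the reciprocal of igraph's unnormalised closeness
    rs <- suppressWarnings(1 / igraph::closeness(g, mode = "all"))
    cc <- ifelse(sz > 1L, (sz - 1) / rs, 0)
    if (scaled && n > 1L) cc <- cc * (sz - 1) / (n - 1)
    unname(cc)
}

#' Hub detection
#'
#' A node is a hub when it is both highly connected (degree strictly above
#' \code{degreeCutoff}) and topologically central (closeness centrality at
#' or above the top-\code{centralityTopFraction} quantile over all nodes;
#' ties at the quantile are included). The conventional degree cutoff is 20;
#' 21 is the alternative reported for the same analysis and can be set via
#' \code{degreeCutoff}.
#'
#' @param graph a \linkS4class{ShapeGraph} or adjacency matrix.
#' @param degreeCutoff degree must exceed this value (default 20).
#' @param centralityTopFraction fraction defining the closeness quantile
#'   (default 0.01, i.e. top 1 percent).
#' @return logical per-node hub flags.
#' @export
detectHubs <- function(graph, degreeCutoff = 20, centralityTopFraction = 0.01) {
    stopifnot(degreeCutoff >= 0,
              centralityTopFraction > 0, centralityTopFraction <= 1)
    k <- nodeDegree(graph)
    cc <- closenessCentrality(graph)
    thr <- stats::quantile(cc, probs = 1 - centralityTopFraction, names = FALSE)
    k > degreeCutoff & cc >= thr
}

#' Proportion of high-degree nodes
#'
#' Fraction of nodes whose degree strictly exceeds the cutoff; the tail
#' statistic compared between real data and linearity-preserving nulls.
#'
#' @param graph a \linkS4class{ShapeGraph} or adjacency matrix.
#' @param cutoff degree cutoff (default 20).
#' @return scalar proportion in [0, 1].
#' @export
highDegreeProportion <- function(graph, cutoff = 20) {
    stopifnot(cutoff >= 0)
    k <- nodeDegree(graph)
    if (!length(k)) stop("empty graph")
    mean(k > cutoff)
}
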