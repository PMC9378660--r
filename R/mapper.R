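#' @include preprocess.R
NULL

#' @describeIn MapperConfig-class constructor. Defaults follow the
#'   convention for precision-dynamics resting-state data: a 2-D geodesic
#'   neighbourhood embedding (k = 20), resolution 30 bins per dimension and
#'   70 percent overlap.
#' @param d,k,R,G,metric,histBins,seed see slots.
#' @export
mapperConfig <- function(d = 2L, k = 20L, R = 30L, G = 70, metric = "euclidean",
                         histBins = 10L, seed = 1L) {
    new("MapperConfig", d = as.integer(d), k = as.integer(k),
        R = as.integer(R), G = as.numeric(G), metric = metric,
        histBins = as.integer(histBins), seed = as.integer(seed))
}

setMethod("show", "MapperConfig", function(object) {
    cat(sprintf("MapperConfig: d=%d k=%d R=%d G=%g metric=%s histBins=%d seed=%d\n",
        object@d, object@k, object@R, object@G, object@metric,
        object@histBins, object@seed))
    invisible(object)
})

#' Pairwise distances between time frames
#'
#' @param x frames-by-parcels numeric matrix.
#' @param metric "euclidean" (on the rows as given, conventionally z-scored)
#'   or "correlation" (1 - Pearson correlation between frames).
#' @return symmetric frames-by-frames distance matrix with zero diagonal.
#' @export
pairwiseDistances <- function(x, metric = "euclidean") {
    x <- as.matrix(x)
    if (nrow(x) < 2L) stop("need at least 2 frames")
    D <- switch(metric,
        euclidean = as.matrix(stats::dist(x)),
        correlation = 1 - stats::cor(t(x)),
        stop(sprintf("unknown metric '%s'", metric)))
    dimnames(D) <- NULL
    diag(D) <- 0
    D
}

#' Geodesic distances over a k-nearest-neighbour graph
#'
#' Builds the directed k-NN graph of the input-space distance matrix,
#' symmetrises it by union, weights edges by the input distance and returns
#' all-pairs shortest-path (geodesic) distances. A disconnected neighbour
#' graph is repaired by adding, per merge, the single minimum-distance edge
#' between components (with a warning), so the result is always finite.
#'
#' @param D symmetric input-space distance matrix.
#' @param k neighbour count (k < number of frames).
#' @return symmetric matrix of geodesic distances.
#' @export
knnGeodesic <- function(D, k) {
    n <- nrow(D)
    if (k >= n) stop("k must be smaller than the number of frames")
    # k smallest off-diagonal entries per row by repeated extraction;
    # ties.method = "first" keeps neighbour choice deterministic
    nbr <- matrix(0L, n, k)
    W <- D
    diag(W) <- Inf
    for (j in seq_len(k)) {
        idx <- max.col(-W, ties.method = "first")
        nbr[, j] <- idx
        W[cbind(seq_len(n), idx)] <- Inf
    }
    from <- rep(seq_len(n), each = k)
    to <- as.integer(t(nbr))
    a <- pmin(from, to); b <- pmax(from, to)
    keep <- !duplicated(a * (n + 1) + b)
    edges <- cbind(a[keep], b[keep])
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    w <- D[edges]
    comp <- igraph::components(g)
    nBridge <- 0L
    while (comp$no > 1L) {
        Dm <- D
        same <- outer(comp$membership, comp$membership, "==")
        Dm[same] <- Inf
        ij <- arrayInd(which.min(Dm), dim(Dm))
        g <- igraph::add_edges(g, as.vector(ij))
        w <- c(w, D[ij])
        nBridge <- nBridge + 1L
        comp <- igraph::components(g)
    }
    if (nBridge > 0L)
        warning(sprintf("k-NN graph disconnected; added %d bridging edge(s)",
                        nBridge))
    gd <- igraph::distances(g, weights = w, algorithm = "dijkstra")
    dimnames(gd) <- NULL
    gd
}

#' Classical multidimensional scaling embedding
#'
#' Double-centres minus one half the squared distances and embeds on the top
#' d eigenpairs, with coordinates scaled by the root eigenvalues (classical
#' MDS / principal coordinates). The solution is made deterministic by
#' fixing the sign of each axis so that its largest-magnitude coordinate is
#' positive. If fewer than d positive eigenvalues exist the remaining axes
#' are zero-padded with a warning.
#'
#' @param gd symmetric finite distance matrix (typically geodesic).
#' @param d target dimension.
#' @return frames-by-d coordinate matrix.
#' @export
embedMDS <- function(gd, d = 2L) {
    stopifnot(is.matrix(gd), nrow(gd) == ncol(gd))
    if (any(!is.finite(gd))) stop("distance matrix must be finite")
    n <- nrow(gd)
    S <- gd^2
    rm <- rowMeans(S)
    B <- -0.5 * (S - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + mean(S))
    e <- eigen((B + t(B)) / 2, symmetric = TRUE)
    tol <- max(abs(e$values)) * 1e-12
    pos <- which(e$values > max(tol, 0))
    take <- pos[seq_len(min(d, length(pos)))]
    coords <- matrix(0, n, d)
    if (length(take))
        coords[, seq_along(take)] <-
            e$vectors[, take, drop = FALSE] %*%
            diag(sqrt(e$values[take]), length(take))
    if (length(take) < d)
        warning(sprintf("only %d positive eigenvalue(s); padding %d axis/axes with zeros",
                        length(take), d - length(take)))
    for (j in seq_len(d)) {
        i <- which.max(abs(coords[, j]))
        if (length(i) && coords[i, j] < 0) coords[, j] <- -coords[, j]
    }
    coords
}

#' Overlapping rectangular cover of the embedding
#'
#' Per axis the bounding box (expanded by 1e-9 so extreme points are
#' interior) is divided into R base intervals of width w0; bin j spans
#' [min + j w0 - h, min + (j + 1) w0 + h] with h = (G / 100) w0 / 2, so
#' adjacent bins share an overlap region of G percent of the base width.
#' With G = 0 intervals are half-open so each point falls in exactly one
#' bin. d-dimensional bins are the Cartesian products of axis intervals;
#' empty bins are dropped.
#'
#' @param coords frames-by-d coordinate matrix.
#' @param R resolution (bins per axis, >= 2).
#' @param G gain (percent overlap, 0 <= G < 100).
#' @return list of bins, each with \code{index} (per-axis bin index,
#'   1-based), \code{bounds} (2 x d matrix of lo/hi) and \code{members}
#'   (frame indices); ordered lexicographically by axis indices.
#' @export
buildCover <- function(coords, R, G) {
    coords <- as.matrix(coords)
    stopifnot(R >= 2, G >= 0, G < 100)
    n <- nrow(coords); d <- ncol(coords)
    axisBins <- vector("list", d)
    for (a in seq_len(d)) {
        x <- coords[, a]
        if (max(x) == min(x)) {     # degenerate axis: one bin holds all
            axisBins[[a]] <- list(list(lo = min(x) - 1e-9, hi = max(x) + 1e-9,
                                       members = seq_len(n)))
            next
        }
        mn <- min(x) - 1e-9; mx <- max(x) + 1e-9
        w0 <- (mx - mn) / R
        h <- (G / 100) * w0 / 2
        bins <- vector("list", R)
        j0 <- pmin(pmax(floor((x - mn) / w0), 0), R - 1)
        for (j in 0:(R - 1)) {
            lo <- mn + j * w0 - h
            hi <- mn + (j + 1) * w0 + h
            cand <- which(abs(j0 - j) <= 1)    # overlap < stride: +-1 suffices
            memb <- if (h > 0) cand[x[cand] >= lo & x[cand] <= hi]
                    else cand[x[cand] >= lo & x[cand] < hi]
            bins[[j + 1L]] <- list(lo = lo, hi = hi, members = memb)
        }
        axisBins[[a]] <- bins
    }
    nb <- vapply(axisBins, length, integer(1))
    out <- list()
    idx <- rep(1L, d)
    repeat {
        members <- axisBins[[1L]][[idx[1L]]]$members
        if (d > 1L) for (a in 2:d) {
            if (!length(members)) break
            members <- intersect(members, axisBins[[a]][[idx[a]]]$members)
        }
        if (length(members)) {
            bounds <- vapply(seq_len(d), function(a)
                c(axisBins[[a]][[idx[a]]]$lo, axisBins[[a]][[idx[a]]]$hi),
                numeric(2))
            out[[length(out) + 1L]] <- list(index = idx, bounds = bounds,
                                            members = sort(members))
        }
        # advance the last axis fastest => lexicographic order of indices
        a <- d
        repeat {
            idx[a] <- idx[a] + 1L
            if (idx[a] <= nb[a]) break
            idx[a] <- 1L
            a <- a - 1L
            if (a == 0L) break
        }
        if (a == 0L) break
    }
    attr(out, "R") <- R
    attr(out, "G") <- G
    out
}

#' Partial clustering within one cover bin
#'
#' Single-linkage clustering of the bin's member frames using the original
#' high-dimensional distances, cut at the first empty bin of a
#' \code{histBins}-bin histogram of merge heights (the classic Mapper gap
#' heuristic). If the histogram has no empty bin the whole bin forms one
#' cluster; a singleton bin yields one singleton cluster.
#'
#' @param members frame indices of the bin.
#' @param D original-space distance matrix over all frames.
#' @param histBins histogram bin count of the gap heuristic (default 10).
#' @return list of integer vectors (clusters), ordered by smallest member.
#' @export
partialCluster <- function(members, D, histBins = 10L) {
    m <- length(members)
    if (m == 0L) stop("bin is empty")
    if (m == 1L) return(list(members))
    dsub <- stats::as.dist(D[members, members, drop = FALSE])
    hc <- stats::hclust(dsub, method = "single")
    h <- hc$height
    cl <- rep(1L, m)
    if (max(h) > min(h)) {
        brk <- seq(min(h), max(h), length.out = histBins + 1L)
        counts <- tabulate(findInterval(h, brk, rightmost.closed = TRUE,
                                        left.open = TRUE, all.inside = TRUE),
                           nbins = histBins)
        empty <- which(counts == 0L)
        if (length(empty))
            cl <- stats::cutree(hc, h = brk[empty[1L]])
    }
    parts <- split(members, cl)
    parts <- parts[order(vapply(parts, min, numeric(1)))]
    lapply(unname(parts), as.integer)
}

#' Assemble the shape graph from per-bin clusters
#'
#' One node per cluster; two nodes are connected whenever their member sets
#' intersect. Node ordering is deterministic: by bin, then by cluster within
#' bin.
#'
#' @param clusters list of integer vectors of frame indices.
#' @param binIds integer bin id per cluster.
#' @param embedding frames-by-d coordinates carried along for plotting.
#' @param config the generating \linkS4class{MapperConfig}.
#' @param nFrames number of retained frames.
#' @return a \linkS4class{ShapeGraph}.
#' @export
buildShapeGraph <- function(clusters, binIds, embedding, config, nFrames) {
    nn <- length(clusters)
    A <- matrix(0, nn, nn)
    if (nn > 1L) {
        fr <- unlist(clusters)
        cl <- rep.int(seq_len(nn), lengths(clusters))
        M <- Matrix::sparseMatrix(i = fr, j = cl, x = 1,
                                  dims = c(nFrames, nn))
        tr <- Matrix::summary(Matrix::crossprod(M))  # shared-frame triplets
        off <- tr$i != tr$j
        A[cbind(tr$i[off], tr$j[off])] <- 1
        A[cbind(tr$j[off], tr$i[off])] <- 1
    }
    # adjacency from crossprod is symmetric, binary and zero-diagonal by
    # construction; skip the O(nodes^2) validity pass on this hot path
    S4Vectors::new2("ShapeGraph", nodes = lapply(clusters, as.integer),
        adjacency = A, embedding = as.matrix(embedding),
        binOfNode = as.integer(binIds), nFrames = as.integer(nFrames),
        config = config, check = FALSE)
}

## core shared by runMapper and parameterSweep: cover + partial clustering +
## graph assembly, given precomputed distances and embedding
.mapperFromEmbedding <- function(D, coords, R, G, histBins, config) {
    cover <- buildCover(coords, R, G)
    clusters <- list(); binIds <- integer(0)
    for (b in seq_along(cover)) {
        cl <- partialCluster(cover[[b]]$members, D, histBins)
        clusters <- c(clusters, cl)
        binIds <- c(binIds, rep.int(b, length(cl)))
    }
    buildShapeGraph(clusters, binIds, coords, config, nrow(coords))
}

#' Run the full Mapper pipeline
#'
#' Composes the four Mapper steps on a frames-by-parcels matrix: (1) the
#' nonlinear filter -- geodesic distances over the k-NN graph embedded into
#' d Euclidean dimensions by classical MDS; (2) overlapping d-dimensional
#' binning at resolution R and gain G; (3) partial single-linkage clustering
#' within bins using the original high-dimensional distances; (4) node
#' connection through shared frames. Applied to a
#' \linkS4class{ParcellatedTimeSeries} the data are first per-session
#' z-scored, concatenated and censor-pruned via
#' \code{\link{prepareForMapper}}.
#'
#' @param x numeric frames-by-parcels matrix (rows conventionally z-scored)
#'   or a \linkS4class{ParcellatedTimeSeries}.
#' @param config a \linkS4class{MapperConfig}.
#' @param ... unused.
#' @param verbose log stage sizes (default FALSE).
#' @return a \linkS4class{ShapeGraph}.
#' @examples
#' x <- simulateDataset(syntheticConfig(nFramesPerSession = 150,
#'     nSessions = 1))
#' g <- runMapper(x, mapperConfig(R = 10, k = 10))
#' numNodes(g)
#' @export
setMethod("runMapper", "matrix", function(x, config = mapperConfig(), ...,
                                          verbose = FALSE) {
    validObject(config)
    D <- pairwiseDistances(x, config@metric)
    if (verbose) message(sprintf("distances: %d frames", nrow(D)))
    gd <- knnGeodesic(D, config@k)
    coords <- embedMDS(gd, config@d)
    if (verbose) message(sprintf("embedded into %d dims", ncol(coords)))
    g <- .mapperFromEmbedding(D, coords, config@R, config@G,
                              config@histBins, config)
    if (verbose) message(sprintf("shape graph: %d nodes, %d edges",
                                 numNodes(g), sum(adjacency(g)) / 2))
    g
})

#' @rdname runMapper
#' @export
setMethod("runMapper", "ParcellatedTimeSeries",
    function(x, config = mapperConfig(), ..., verbose = FALSE) {
        prep <- prepareForMapper(x)
        runMapper(prep$matrix, config, verbose = verbose)
    })

#' @rdname graph-accessors
#' @export
setMethod("nodeMembers", "ShapeGraph", function(x) x@nodes)

#' Accessors for ShapeGraph
#'
#' \code{nodeMembers} returns the list of member-frame index vectors;
#' \code{adjacency} the binary adjacency matrix; \code{nodeEmbedding} the
#' per-frame filter coordinates; \code{numNodes} the node count.
#'
#' @param x a \linkS4class{ShapeGraph}.
#' @name graph-accessors
NULL

#' @rdname graph-accessors
#' @export
setMethod("adjacency", "ShapeGraph", function(x) x@adjacency)

#' @rdname graph-accessors
#' @export
setMethod("nodeEmbedding", "ShapeGraph", function(x) x@embedding)

#' @rdname graph-accessors
#' @export
setMethod("numNodes", "ShapeGraph", function(x) length(x@nodes))

setMethod("show", "ShapeGraph", function(object) {
    cat(sprintf("ShapeGraph: %d nodes, %d edges over %d frames\n",
        numNodes(object), sum(object@adjacency) / 2, object@nFrames))
    cat(sprintf("  R=%d G=%g k=%d d=%d\n", object@config@R, object@config@G,
        object@config@k, object@config@d))
    invisible(object)
})
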