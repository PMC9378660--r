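#' @include graph-metrics.R
NULL

#' Annotate shape-graph nodes with network engagement
#'
#' For each node and network, computes the fraction of the node's member
#' frames on which the z-scored network mean signal exceeds the activation
#' threshold (the pie-chart proportions), the mean activation over member
#' frames, and the per-node standard deviation of the mean activations
#' across networks. Nodes engaging all networks uniformly (hub-like
#' transition states) have low activation SD; nodes dominated by one
#' network have high SD, which is the basis of the topographic gradient.
#'
#' @param graph a \linkS4class{ShapeGraph}.
#' @param networkTS frames-by-networks matrix of z-scored network means
#'   (see \code{\link{networkMeans}}); rows must align with the graph's
#'   retained frames.
#' @param threshold activation threshold in z units (default 0.5).
#' @return a \linkS4class{NodeAnnotation}.
#' @export
annotateNodes <- function(graph, networkTS, threshold = 0.5) {
    stopifnot(is(graph, "ShapeGraph"))
    networkTS <- as.matrix(networkTS)
    if (nrow(networkTS) != graph@nFrames)
        stop(sprintf("networkTS has %d frames but the graph covers %d",
                     nrow(networkTS), graph@nFrames))
    nets <- colnames(networkTS)
    if (is.null(nets)) nets <- sprintf("net%d", seq_len(ncol(networkTS)))
    nn <- numNodes(graph)
    act <- networkTS > threshold
    prop <- matrix(NA_real_, nn, ncol(networkTS),
                   dimnames = list(NULL, nets))
    meanAct <- prop
    for (v in seq_len(nn)) {
        mem <- graph@nodes[[v]]
        prop[v, ] <- colMeans(act[mem, , drop = FALSE])
        meanAct[v, ] <- colMeans(networkTS[mem, , drop = FALSE])
    }
    new("NodeAnnotation", proportions = prop, meanActivation = meanAct,
        activationSD = apply(meanAct, 1L, stats::sd),
        dominantNetwork = character(0), threshold = threshold)
}

#' @rdname annotation-accessors
#' @export
setMethod("activationProportions", "NodeAnnotation", function(x) x@proportions)

#' Accessors for NodeAnnotation
#'
#' @param x a \linkS4class{NodeAnnotation}.
#' @name annotation-accessors
NULL

#' @rdname annotation-accessors
#' @export
setMethod("meanActivation", "NodeAnnotation", function(x) x@meanActivation)

#' @rdname annotation-accessors
#' @export
setMethod("activationSD", "NodeAnnotation", function(x) x@activationSD)

#' @rdname annotation-accessors
#' @export
setMethod("dominantNetwork", "NodeAnnotation", function(x) x@dominantNetwork)

setMethod("show", "NodeAnnotation", function(object) {
    cat(sprintf("NodeAnnotation: %d nodes x %d networks (threshold %.2f SD)\n",
        nrow(object@proportions), ncol(object@proportions), object@threshold))
    if (length(object@dominantNetwork))
        print(table(object@dominantNetwork))
    invisible(object)
})

#' Assign a dominant label to every node
#'
#' Hub-flagged nodes receive the label "HUB"; every other node is labelled
#' with the network of its largest mean activation (exact ties go to the
#' lowest network index, with a warning, by the "dominated" convention
#' \code{method = "mean"}; \code{method = "proportion"} uses the largest
#' activation proportion instead).
#'
#' @param annotation a \linkS4class{NodeAnnotation}.
#' @param hubFlags logical per-node hub flags (see \code{\link{detectHubs}}).
#' @param method "mean" (default) or "proportion".
#' @return the annotation with \code{dominantNetwork} filled in.
#' @export
assignDominant <- function(annotation, hubFlags, method = c("mean", "proportion")) {
    stopifnot(is(annotation, "NodeAnnotation"))
    method <- match.arg(method)
    M <- if (method == "mean") annotation@meanActivation
         else annotation@proportions
    nn <- nrow(M)
    if (length(hubFlags) != nn)
        stop("hubFlags must have one entry per node")
    nets <- colnames(M)
    lab <- character(nn)
    tied <- 0L
    for (v in seq_len(nn)) {
        if (hubFlags[v]) { lab[v] <- .HUB; next }
        best <- which(M[v, ] == max(M[v, ]))
        if (length(best) > 1L) tied <- tied + 1L
        lab[v] <- nets[best[1L]]
    }
    if (tied > 0L)
        warning(sprintf("%d node(s) had tied dominant activations; %s",
                        tied, "assigned to the lowest network index"))
    annotation@dominantNetwork <- lab
    annotation
}

#' Network co-localization on the shape graph
#'
#' Pearson correlation between the network columns of the node-level mean
#' activation matrix: networks that engage the same graph regions (i.e.
#' co-activate or co-deactivate across nodes) correlate positively. With
#' \code{use = "proportion"} the activation proportions are correlated
#' instead.
#'
#' @param annotation a \linkS4class{NodeAnnotation} with at least 3 nodes.
#' @param use "mean" (default) or "proportion".
#' @param sizes optional per-node weights (e.g. node member counts); when
#'   given, a size-weighted Pearson correlation is used. The default treats
#'   all nodes equally.
#' @return symmetric networks-by-networks correlation matrix with unit
#'   diagonal; zero-variance columns yield 0 entries with a warning.
#' @export
networkColocalization <- function(annotation, use = c("mean", "proportion"),
                                  sizes = NULL) {
    stopifnot(is(annotation, "NodeAnnotation"))
    use <- match.arg(use)
    M <- if (use == "mean") annotation@meanActivation
         else annotation@proportions
    if (nrow(M) < 3L) stop("co-localization needs at least 3 nodes")
    sds <- apply(M, 2L, stats::sd)
    C <- if (is.null(sizes)) {
        suppressWarnings(stats::cor(M))
    } else {
        stopifnot(length(sizes) == nrow(M), all(sizes > 0))
        suppressWarnings(stats::cov.wt(M, wt = sizes / sum(sizes),
                                       cor = TRUE)$cor)
    }
    if (any(sds == 0)) {
        warning("zero-variance network column(s); correlations set to 0")
        C[is.na(C)] <- 0
    }
    diag(C) <- 1
    C
}

#' Similarity between two symmetric matrices
#'
#' Pearson correlation of the vectorised upper triangles (diagonal
#' excluded); used to compare network co-localization matrices across
#' session halves and participants.
#'
#' @param M1,M2 symmetric matrices of the same dimension.
#' @return scalar correlation.
#' @export
matrixSimilarity <- function(M1, M2) {
    M1 <- as.matrix(M1); M2 <- as.matrix(M2)
    if (!all(dim(M1) == dim(M2))) stop("matrices must have the same shape")
    ut <- upper.tri(M1)
    stats::cor(M1[ut], M2[ut])
}
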