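#' @include annotation.R
NULL

#' Propagate node labels to individual time frames
#'
#' Each retained frame inherits a label from the shape-graph nodes
#' containing it: by default the label carried by the majority of those
#' nodes, with ties broken in favour of "HUB" when it is among the tied
#' labels and otherwise towards the lowest network index in
#' \code{stateLevels} (tie events are reported via a message). With
#' \code{method = "largestNode"} the frame instead takes the label of the
#' largest containing node (same tie-break). Transitions across censoring
#' gaps or session stitches are marked invalid using the \code{breaks}
#' bookkeeping from \code{\link{dropCensored}}.
#'
#' @param graph a \linkS4class{ShapeGraph}.
#' @param nodeLabels per-node labels (networks plus "HUB"), e.g. the
#'   \code{dominantNetwork} of an annotation.
#' @param breaks integer positions i at which the pair (frame i, frame
#'   i + 1) is not a genuine transition.
#' @param stateLevels canonical state order; defaults to the sorted network
#'   labels followed by "HUB".
#' @param method "majority" (default) or "largestNode".
#' @return a \linkS4class{StateSequence}.
#' @export
labelFrames <- function(graph, nodeLabels, breaks = integer(0),
                        stateLevels = NULL,
                        method = c("majority", "largestNode")) {
    stopifnot(is(graph, "ShapeGraph"))
    method <- match.arg(method)
    if (length(nodeLabels) != numNodes(graph))
        stop("need one label per node")
    if (is.null(stateLevels)) {
        nets <- sort(setdiff(unique(nodeLabels), .HUB))
        stateLevels <- c(nets, .HUB)
    }
    n <- graph@nFrames
    fr <- unlist(graph@nodes)
    nd <- rep.int(seq_along(graph@nodes), lengths(graph@nodes))
    byFrame <- split(nd, fr)
    sizes <- lengths(graph@nodes)
    labels <- character(n)
    ties <- 0L
    for (f in seq_len(n)) {
        nodes <- byFrame[[as.character(f)]]
        if (method == "largestNode") {
            best <- unique(nodeLabels[nodes[sizes[nodes] == max(sizes[nodes])]])
        } else {
            tab <- table(nodeLabels[nodes])
            best <- names(tab)[tab == max(tab)]
        }
        if (length(best) > 1L) {
            ties <- ties + 1L
            labels[f] <- if (.HUB %in% best) .HUB
                         else best[which.min(match(best, stateLevels))]
        } else labels[f] <- best
    }
    if (ties > 0L)
        message(sprintf("%d frame(s) had tied node labels (HUB favoured)", ties))
    valid <- rep(TRUE, max(n - 1L, 0L))
    valid[breaks] <- FALSE
    new("StateSequence", labels = labels, validTransition = valid,
        stateLevels = stateLevels)
}

#' Estimate a discrete-time Markov chain from a labelled sequence
#'
#' Counts transitions over consecutive frame pairs whose
#' \code{validTransition} flag is TRUE (pairs spanning censored frames or
#' session stitches are ignored) and row-normalises the counts. States never
#' observed in the labels are dropped from the state list with a message;
#' observed states with no outgoing valid transition get a uniform row with
#' a warning so matrices stay comparable across subjects.
#'
#' @param seq a \linkS4class{StateSequence}.
#' @return a \linkS4class{TransitionMatrix}.
#' @examples
#' s <- new("StateSequence", labels = c("A", "A", "B", "B", "A"),
#'     validTransition = rep(TRUE, 4), stateLevels = c("A", "B"))
#' transitionProbabilities(estimateChain(s))
#' @export
estimateChain <- function(seq) {
    stopifnot(is(seq, "StateSequence"))
    labels <- seq@labels
    if (length(labels) < 2L) stop("need at least 2 frames")
    states <- seq@stateLevels[seq@stateLevels %in% labels]
    dropped <- setdiff(seq@stateLevels, states)
    if (length(dropped))
        message("state(s) never observed, excluded: ",
                paste(dropped, collapse = ", "))
    k <- length(states)
    counts <- matrix(0, k, k, dimnames = list(states, states))
    fromI <- match(labels[-length(labels)], states)
    toI <- match(labels[-1L], states)
    ok <- which(seq@validTransition)
    for (i in ok) counts[fromI[i], toI[i]] <- counts[fromI[i], toI[i]] + 1
    rs <- rowSums(counts)
    prob <- counts
    if (any(rs == 0)) {
        warning("state(s) with no outgoing valid transitions; row set uniform: ",
                paste(states[rs == 0], collapse = ", "))
        prob[rs == 0, ] <- 1 / k
    }
    prob[rs > 0, ] <- counts[rs > 0, , drop = FALSE] / rs[rs > 0]
    new("TransitionMatrix", states = states, counts = counts,
        probabilities = prob)
}

#' @rdname chain-accessors
#' @export
setMethod("states", "TransitionMatrix", function(x) x@states)

#' Accessors for TransitionMatrix
#'
#' @param x a \linkS4class{TransitionMatrix}.
#' @name chain-accessors
NULL

#' @rdname chain-accessors
#' @export
setMethod("transitionCounts", "TransitionMatrix", function(x) x@counts)

#' @rdname chain-accessors
#' @export
setMethod("transitionProbabilities", "TransitionMatrix",
    function(x) x@probabilities)

setMethod("show", "TransitionMatrix", function(object) {
    cat(sprintf("TransitionMatrix over %d states (%d observed transitions)\n",
        length(object@states), sum(object@counts)))
    print(round(object@probabilities, 3))
    invisible(object)
})

#' Most likely off-diagonal destination per state
#'
#' Per-row argmax of the transition probabilities with the diagonal
#' suppressed; identifies, for each state, where the system preferentially
#' moves next (the hub state, in hub-mediated dynamics).
#'
#' @param P a \linkS4class{TransitionMatrix} or row-stochastic matrix with
#'   dimnames.
#' @return named character vector: top destination per state.
#' @export
topDestination <- function(P) {
    if (is(P, "TransitionMatrix")) P <- transitionProbabilities(P)
    stopifnot(is.matrix(P), nrow(P) >= 2L, nrow(P) == ncol(P))
    off <- P
    diag(off) <- -Inf
    dest <- colnames(P)[apply(off, 1L, which.max)]
    names(dest) <- rownames(P)
    dest
}

#' Similarity between two transition matrices
#'
#' Aligns the two matrices on the union of their state labels (missing
#' states contribute zero rows/columns, with a warning) and returns the
#' Pearson correlation of the off-diagonal transition probabilities.
#'
#' @param P1,P2 \linkS4class{TransitionMatrix} objects or named
#'   row-stochastic matrices.
#' @return scalar correlation.
#' @export
transitionSimilarity <- function(P1, P2) {
    get <- function(P) if (is(P, "TransitionMatrix"))
        transitionProbabilities(P) else as.matrix(P)
    M1 <- get(P1); M2 <- get(P2)
    s1 <- rownames(M1); s2 <- rownames(M2)
    if (is.null(s1) || is.null(s2)) stop("matrices must carry state names")
    all <- union(s1, s2)
    if (length(all) < 2L) stop("need at least 2 common states")
    if (!setequal(s1, s2))
        warning("state sets differ; missing states padded with zero rows")
    pad <- function(M) {
        out <- matrix(0, length(all), length(all), dimnames = list(all, all))
        out[rownames(M), colnames(M)] <- M
        out
    }
    M1 <- pad(M1); M2 <- pad(M2)
    off <- !diag(length(all))
    stats::cor(M1[off], M2[off])
}

#' Anticorrelation between hub occupancy and network amplitude
#'
#' Correlates the binary per-frame hub-state indicator with the amplitude of
#' the frame's dominant network (the z-scored mean signal of the network the
#' frame is labelled with; 0 for hub frames), overall and per network. In
#' hub-mediated dynamics the hub is visited when no network is elevated, so
#' the relation is negative.
#'
#' @param seq a \linkS4class{StateSequence} over the retained frames.
#' @param networkTS frames-by-networks matrix of z-scored network means.
#' @return list with \code{overall} (scalar) and \code{perNetwork} (named
#'   vector of correlations between the hub indicator and each network's
#'   signal); degenerate sequences (hub always or never occupied) give NA.
#' @export
hubRsnAnticorrelation <- function(seq, networkTS) {
    stopifnot(is(seq, "StateSequence"))
    networkTS <- as.matrix(networkTS)
    if (nrow(networkTS) != length(seq@labels))
        stop("networkTS frames must align with the label sequence")
    hub <- as.numeric(seq@labels == .HUB)
    nets <- colnames(networkTS)
    amp <- numeric(length(hub))
    idx <- match(seq@labels, nets)
    has <- !is.na(idx)
    amp[has] <- networkTS[cbind(which(has), idx[has])]
    if (stats::sd(hub) == 0)
        return(list(overall = NA_real_,
                    perNetwork = stats::setNames(rep(NA_real_, length(nets)),
                                                 nets)))
    perNet <- vapply(seq_len(ncol(networkTS)),
                     function(j) stats::cor(hub, networkTS[, j]), numeric(1))
    names(perNet) <- nets
    list(overall = stats::cor(hub, amp), perNetwork = perNet)
}
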