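# Small shared fixtures, generated in code.

tinyConfig <- function(...) {
    syntheticConfig(nNetworks = 3, parcelsPerNetwork = 8,
                    nFramesPerSession = 120, nSessions = 2,
                    censorFraction = 0.05, seed = 42, ...)
}

# hand-built shape graph: 4 frames, 3 nodes {1,2} {2,3} {3,4}, path topology
handGraph <- function() {
    nodes <- list(c(1L, 2L), c(2L, 3L), c(3L, 4L))
    A <- matrix(0, 3, 3)
    A[1, 2] <- A[2, 1] <- 1
    A[2, 3] <- A[3, 2] <- 1
    new("ShapeGraph", nodes = nodes, adjacency = A,
        embedding = matrix(0, 4, 2), binOfNode = 1:3, nFrames = 4L,
        config = mapperConfig())
}

pathAdjacency <- function(n) {
    A <- matrix(0, n, n)
    for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
    A
}

randomAdjacency <- function(n, p = 0.2) {
    A <- matrix(0, n, n)
    up <- upper.tri(A)
    A[up] <- as.numeric(runif(sum(up)) < p)
    A + t(A)
}

makeStateSequence <- function(labels, valid = NULL, levels = NULL) {
    if (is.null(valid)) valid <- rep(TRUE, length(labels) - 1)
    if (is.null(levels))
        levels <- c(sort(setdiff(unique(labels), "HUB")),
                    intersect("HUB", unique(labels)))
    new("StateSequence", labels = labels, validTransition = valid,
        stateLevels = levels)
}
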