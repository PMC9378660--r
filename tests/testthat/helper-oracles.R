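# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the implementation under test.

# Dijkstra over a weighted adjacency matrix (Inf = no edge), one source.
oracleDijkstra <- function(W, source) {
    n <- nrow(W)
    dist <- rep(Inf, n)
    dist[source] <- 0
    done <- rep(FALSE, n)
    for (step in seq_len(n)) {
        u <- which(!done)[which.min(dist[!done])]
        if (!length(u) || !is.finite(dist[u])) break
        done[u] <- TRUE
        for (v in which(is.finite(W[u, ]))) {
            alt <- dist[u] + W[u, v]
            if (alt < dist[v]) dist[v] <- alt
        }
    }
    dist
}

oracleAllPairsDijkstra <- function(W) {
    t(vapply(seq_len(nrow(W)), function(s) oracleDijkstra(W, s),
             numeric(nrow(W))))
}

# Floyd-Warshall with unit edge weights from a binary adjacency matrix.
oracleFloydWarshall <- function(A) {
    n <- nrow(A)
    D <- matrix(Inf, n, n)
    D[A == 1] <- 1
    diag(D) <- 0
    for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
    D
}

# Closeness per Eq.-style formula with component-fraction scaling, computed
# from the Floyd-Warshall matrix.
oracleCloseness <- function(A, scaled = TRUE) {
    D <- oracleFloydWarshall(A)
    n <- nrow(A)
    vapply(seq_len(n), function(i) {
        reach <- setdiff(which(is.finite(D[i, ])), i)
        if (!length(reach)) return(0)
        cc <- length(reach) / sum(D[i, reach])
        if (scaled && n > 1) cc <- cc * length(reach) / (n - 1)
        cc
    }, numeric(1))
}

# Pearson correlation from first principles.
oraclePearson <- function(x, y) {
    xm <- x - mean(x); ym <- y - mean(y)
    sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# union k-NN weighted adjacency built independently of the implementation
oracleKnnGraph <- function(D, k) {
    n <- nrow(D)
    W <- matrix(Inf, n, n)
    for (i in seq_len(n)) {
        nb <- setdiff(order(D[i, ]), i)[seq_len(k)]
        W[i, nb] <- D[i, nb]
        W[nb, i] <- D[nb, i]
    }
    W
}

# connected components of a thresholded distance graph (single-linkage cut)
oracleComponentsAtThreshold <- function(D, threshold) {
    n <- nrow(D)
    lab <- seq_len(n)
    repeat {
        changed <- FALSE
        for (i in seq_len(n)) for (j in seq_len(n)) {
            if (D[i, j] <= threshold && lab[j] != lab[i]) {
                lab[lab == lab[j]] <- lab[i]
                changed <- TRUE
            }
        }
        if (!changed) break
    }
    match(lab, unique(lab))
}
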