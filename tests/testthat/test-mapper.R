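test_that("pairwise distances match a brute-force double loop", {
    expect_equal(pairwiseDistances(rbind(c(0, 0), c(3, 4)))[1, 2], 5)
    set.seed(2)
    m <- matrix(rnorm(10 * 4), 10, 4)
    D <- pairwiseDistances(m)
    expect_identical(D, t(D))
    B <- matrix(0, 10, 10)
    for (i in 1:10) for (j in 1:10)
        B[i, j] <- sqrt(sum((m[i, ] - m[j, ])^2))
    expect_lt(max(abs(D - B)), 1e-12)
    expect_error(pairwiseDistances(m, "mahalanobis"), "unknown metric")
})

test_that("geodesics follow forced paths and match a Dijkstra oracle", {
    # collinear points, k = 1: the ends connect through the middle
    D <- pairwiseDistances(matrix(c(0, 1, 2)))
    gd <- knnGeodesic(D, 1)
    expect_equal(gd[1, 3], 2)

    set.seed(3)
    m <- matrix(rnorm(15 * 3), 15, 3)
    D <- pairwiseDistances(m)
    for (k in c(4, 14)) {          # 14 = frames - 1: complete neighbour graph
        gd <- knnGeodesic(D, k)
        oracle <- oracleAllPairsDijkstra(oracleKnnGraph(D, k))
        expect_lt(max(abs(gd - oracle)), 1e-12)
        expect_true(all(gd >= D - 1e-12))   # geodesic never beats direct
    }
    gd <- knnGeodesic(D, 14)
    expect_lt(max(abs(gd - D)), 1e-12)      # Euclidean: triangle inequality
})

test_that("disconnected neighbour graphs are bridged by one edge per merge", {
    m <- matrix(c(0, 0.1, 0.2, 10, 10.1, 10.2))
    D <- pairwiseDistances(m)
    expect_warning(gd <- knnGeodesic(D, 2), "1 bridging edge")
    expect_true(all(is.finite(gd)))
    # path end-to-end: within-chain + the single min inter-cluster bridge
    expect_equal(gd[1, 6], 0.2 + 9.8 + 0.2, tolerance = 1e-12)
})

test_that("geodesic matrices satisfy the triangle inequality", {
    set.seed(4)
    for (rep in 1:3) {
        m <- matrix(rnorm(25 * 3), 25, 3)
        gd <- suppressWarnings(knnGeodesic(pairwiseDistances(m), 4))
        for (k in 1:25)
            expect_true(all(gd <= outer(gd[, k], gd[k, ], "+") + 1e-9))
    }
})

test_that("classical MDS reproduces planar configurations up to rigid motion", {
    set.seed(5)
    orig <- matrix(rnorm(40 * 2), 40, 2)
    gd <- knnGeodesic(pairwiseDistances(orig), 39)  # geodesic = Euclidean
    emb <- embedMDS(gd, 2)
    pr <- vegan::procrustes(orig, emb)
    expect_lt(pr$ss, 1e-6)

    # two points at distance 10 embed at separation 10
    gd2 <- matrix(c(0, 10, 10, 0), 2)
    expect_equal(abs(diff(embedMDS(gd2, 1)[, 1])), 10, tolerance = 1e-8)

    # degenerate all-zero distances give all-zero coordinates
    expect_warning(z <- embedMDS(matrix(0, 4, 4), 2), "padding")
    expect_true(all(z == 0))
})

test_that("MDS output is deterministic including axis signs", {
    set.seed(6)
    m <- matrix(rnorm(30 * 5), 30, 5)
    gd <- knnGeodesic(pairwiseDistances(m), 6)
    e1 <- embedMDS(gd, 2); e2 <- embedMDS(gd, 2)
    expect_identical(e1, e2)
    for (j in 1:2) expect_gt(e1[which.max(abs(e1[, j])), j], 0)
})

test_that("the cover partitions at zero gain and overlaps as specified", {
    x <- matrix(seq(0, 1, by = 0.1))
    cov0 <- buildCover(x, 4, 0)
    memb <- unlist(lapply(cov0, `[[`, "members"))
    expect_identical(sort(memb), seq_len(11L))   # each point exactly once
    expect_identical(anyDuplicated(memb), 0L)

    # R = 2, G = 70: points within 0.175 of 0.5 fall in both bins
    cov <- buildCover(x, 2, 70)
    expect_length(cov, 2)
    both <- intersect(cov[[1]]$members, cov[[2]]$members)
    expect_equal(sort(x[both, 1]), c(0.4, 0.5, 0.6))
})

test_that("every frame is covered for random coordinates and any R, G", {
    set.seed(7)
    for (rep in 1:5) {
        co <- matrix(rnorm(60 * 2), 60, 2)
        R <- sample(2:12, 1); G <- runif(1, 0, 95)
        cov <- buildCover(co, R, G)
        expect_identical(sort(unique(unlist(lapply(cov, `[[`, "members")))),
                         seq_len(60L))
    }
})

test_that("raising the gain never shrinks adjacent-bin overlap", {
    set.seed(8)
    co <- matrix(runif(80), 80, 1)
    shared <- function(G) {
        cov <- buildCover(co, 5, G)
        idx <- vapply(cov, function(b) b$index[1], integer(1))
        tot <- 0
        for (j in seq_len(max(idx) - 1)) {
            a <- cov[[match(j, idx)]]; b <- cov[[match(j + 1, idx)]]
            if (!is.null(a) && !is.null(b))
                tot <- tot + length(intersect(a$members, b$members))
        }
        tot
    }
    vals <- vapply(c(0, 20, 40, 60, 80), shared, numeric(1))
    expect_true(all(diff(vals) >= 0))
})

test_that("degenerate axes collapse to a single bin", {
    co <- cbind(rnorm(20), rep(1, 20))
    cov <- buildCover(co, 4, 50)
    expect_true(all(vapply(cov, function(b) b$index[2], integer(1)) == 1L))
})

test_that("partial clustering splits at gaps and only at gaps", {
    pts <- matrix(c(0, 0.05, 0.1, 1.0, 1.05, 1.1))
    D <- pairwiseDistances(pts)
    cl <- partialCluster(1:6, D)
    expect_length(cl, 2)
    # brute-force: components of the graph thresholded inside the gap
    oracle <- oracleComponentsAtThreshold(D, 0.5)
    expect_setequal(lapply(cl, sort), split(1:6, oracle))

    expect_identical(partialCluster(4L, D), list(4L))
    # equidistant points: no gap, one cluster
    De <- matrix(1, 4, 4); diag(De) <- 0
    expect_length(partialCluster(1:4, De), 1)
})

test_that("shape-graph edges are exactly the nonempty member intersections", {
    emb <- matrix(0, 4, 2)
    g1 <- buildShapeGraph(list(1:2, 3:4), c(1L, 2L), emb, mapperConfig(), 4L)
    expect_true(all(adjacency(g1) == 0))
    g2 <- buildShapeGraph(list(c(1L, 2L), c(2L, 3L), 4L), 1:3, emb,
                          mapperConfig(), 4L)
    expect_equal(sum(adjacency(g2)) / 2, 1)
    expect_equal(adjacency(g2)[1, 2], 1)

    set.seed(9)
    for (rep in 1:5) {
        nn <- 8
        clusters <- lapply(seq_len(nn), function(i)
            sort(sample.int(30, sample(1:6, 1))))
        frames <- sort(unique(unlist(clusters)))
        remap <- lapply(clusters, function(cl) match(cl, frames))
        g <- buildShapeGraph(remap, rep(1:4, each = 2),
                             matrix(0, length(frames), 2), mapperConfig(),
                             length(frames))
        B <- matrix(0, nn, nn)
        for (i in seq_len(nn)) for (j in seq_len(nn))
            if (i != j && length(intersect(remap[[i]], remap[[j]])) > 0)
                B[i, j] <- 1
        expect_identical(adjacency(g), B)
    }
})

test_that("the composed pipeline separates planted clusters and is stable", {
    # two well-separated states, no hub, tiny scale
    set.seed(10)
    m <- rbind(matrix(rnorm(60 * 4, mean = 0), 60, 4),
               matrix(rnorm(60 * 4, mean = 6), 60, 4))
    cfg <- mapperConfig(R = 6, G = 50, k = 8)
    g <- suppressWarnings(runMapper(m, cfg))  # two clusters: bridged k-NN graph
    comp <- igraph::components(igraph::graph_from_adjacency_matrix(
        adjacency(g), mode = "undirected"))
    expect_gte(comp$no, 2)
    # frames of the two states never share a node
    stateOf <- rep(1:2, each = 60)
    mixed <- vapply(nodeMembers(g), function(mm)
        length(unique(stateOf[mm])) > 1, logical(1))
    expect_false(any(mixed))
    # coverage and determinism
    expect_identical(sort(unique(unlist(nodeMembers(g)))), seq_len(120L))
    g2 <- suppressWarnings(runMapper(m, cfg))
    expect_identical(adjacency(g), adjacency(g2))
    expect_identical(nodeMembers(g), nodeMembers(g2))
})

test_that("clusters within one bin never share members or edges", {
    set.seed(11)
    m <- matrix(rnorm(150 * 6), 150, 6)
    g <- runMapper(m, mapperConfig(R = 5, G = 60, k = 10))
    A <- adjacency(g)
    for (b in unique(g@binOfNode)) {
        same <- which(g@binOfNode == b)
        if (length(same) > 1) {
            expect_true(all(A[same, same] == 0))
            expect_identical(anyDuplicated(unlist(nodeMembers(g)[same])), 0L)
        }
    }
})
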