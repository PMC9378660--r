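test_that("node annotation computes proportions, means and SD as defined", {
    g <- handGraph()                      # nodes {1,2} {2,3} {3,4}
    ts <- cbind(vis = c(1, 1, 1, 0), dmn = c(0, 0, 0, 0))
    ann <- annotateNodes(g, ts, threshold = 0.5)
    expect_equal(activationProportions(ann)[1, ], c(vis = 1, dmn = 0))
    expect_equal(activationProportions(ann)[3, ], c(vis = 0.5, dmn = 0))
    expect_equal(meanActivation(ann)[1, ], c(vis = 1, dmn = 0))
    # identical means across networks give SD zero
    ts2 <- cbind(a = c(1, 1, 1, 1), b = c(1, 1, 1, 1))
    expect_equal(activationSD(annotateNodes(g, ts2)), rep(0, 3))
    expect_error(annotateNodes(g, ts[1:3, , drop = FALSE]), "frames")
})

test_that("dominant labels follow hub flags, argmax and the tie rule", {
    g <- handGraph()
    ts <- cbind(A = c(2, 2, 0, 0), B = c(0, 0, 1, 1))
    ann <- annotateNodes(g, ts)
    out <- assignDominant(ann, hubFlags = c(FALSE, FALSE, TRUE))
    expect_identical(dominantNetwork(out), c("A", "A", "HUB"))
    # exact tie goes to the lower network index, with a warning
    tsTie <- cbind(A = c(1, 1, 0, 0), B = c(1, 1, 0, 0))
    annTie <- annotateNodes(g, tsTie)
    expect_warning(outTie <- assignDominant(annTie, rep(FALSE, 3)), "tie")
    expect_identical(dominantNetwork(outTie)[1], "A")
})

test_that("co-localization is Pearson correlation over node mean activations", {
    g <- handGraph()
    ts <- cbind(A = c(1, 2, 3, 4), B = c(1, 2, 3, 4), C = c(4, 3, 2, 1))
    C <- networkColocalization(annotateNodes(g, ts))
    expect_equal(C["A", "B"], 1)
    expect_equal(C["A", "C"], -1)
    expect_identical(C, t(C))
    expect_equal(diag(C), setNames(rep(1, 3), c("A", "B", "C")))
    # brute-force Pearson on random annotations
    set.seed(5)
    ts3 <- matrix(rnorm(4 * 3), 4, 3, dimnames = list(NULL, c("A", "B", "C")))
    ann3 <- annotateNodes(g, ts3)
    C3 <- networkColocalization(ann3)
    M <- meanActivation(ann3)
    for (i in 1:2) for (j in (i + 1):3)
        expect_equal(C3[i, j], oraclePearson(M[, i], M[, j]),
                     tolerance = 1e-12)
    # zero-variance column warns and yields 0
    tsz <- cbind(A = c(1, 2, 3, 4), B = rep(0, 4))
    expect_warning(Cz <- networkColocalization(annotateNodes(g, tsz)),
                   "zero-variance")
    expect_equal(Cz["A", "B"], 0)
})

test_that("matrix similarity correlates upper triangles only", {
    set.seed(6)
    M <- matrix(rnorm(36), 6); M <- M + t(M)
    expect_equal(matrixSimilarity(M, M), 1)
    expect_error(matrixSimilarity(M, matrix(0, 3, 3)), "shape")
    # brute force on the vectorised upper triangle
    M2 <- matrix(rnorm(36), 6); M2 <- M2 + t(M2)
    ut <- upper.tri(M)
    expect_equal(matrixSimilarity(M, M2), oraclePearson(M[ut], M2[ut]),
                 tolerance = 1e-12)
    # diagonal must not influence the similarity
    M3 <- M2; diag(M3) <- 99
    expect_equal(matrixSimilarity(M, M3), matrixSimilarity(M, M2))
    # independent large symmetric matrices decorrelate
    set.seed(7)
    r <- replicate(50, {
        X <- matrix(rnorm(100), 10); X <- X + t(X)
        Y <- matrix(rnorm(100), 10); Y <- Y + t(Y)
        matrixSimilarity(X, Y)
    })
    expect_lt(abs(mean(r)), 0.1)
})

test_that("annotation proportions are equivariant under node relabeling", {
    set.seed(8)
    g <- handGraph()
    ts <- matrix(rnorm(4 * 2), 4, 2, dimnames = list(NULL, c("A", "B")))
    ann <- annotateNodes(g, ts)
    perm <- c(3L, 1L, 2L)
    gp <- new("ShapeGraph", nodes = nodeMembers(g)[perm],
              adjacency = adjacency(g)[perm, perm],
              embedding = g@embedding, binOfNode = g@binOfNode[perm],
              nFrames = g@nFrames, config = g@config)
    annp <- annotateNodes(gp, ts)
    expect_equal(activationProportions(annp),
                 activationProportions(ann)[perm, ])
})

test_that("size-weighted co-localization matches a weighted oracle", {
    set.seed(9)
    g <- handGraph()
    ts <- matrix(rnorm(4 * 2), 4, 2, dimnames = list(NULL, c("A", "B")))
    ann <- annotateNodes(g, ts)
    sizes <- c(5, 1, 1)
    Cw <- networkColocalization(ann, sizes = sizes)
    M <- meanActivation(ann)
    w <- sizes / sum(sizes)
    wcor <- function(x, y) {
        mx <- sum(w * x); my <- sum(w * y)
        sum(w * (x - mx) * (y - my)) /
            sqrt(sum(w * (x - mx)^2) * sum(w * (y - my)^2))
    }
    expect_equal(Cw["A", "B"], wcor(M[, "A"], M[, "B"]), tolerance = 1e-12)
    # equal weights reduce to the unweighted value
    expect_equal(networkColocalization(ann, sizes = rep(2, 3)),
                 networkColocalization(ann), tolerance = 1e-12)
})
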