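test_that("frame labels inherit from nodes by majority with HUB tie-break", {
    # frames: 1 in node1 only; 2 in nodes 1,2; 3 in nodes 2,3; 4 in node 3
    g <- handGraph()
    sq <- labelFrames(g, c("DMN", "DMN", "HUB"),
                      stateLevels = c("DMN", "VIS", "HUB"))
    expect_identical(sq@labels[1], "DMN")        # single containing node
    expect_identical(sq@labels[2], "DMN")        # DMN,DMN unanimous
    expect_identical(sq@labels[3], "HUB")        # DMN vs HUB tie -> HUB
    expect_identical(sq@labels[4], "HUB")

    # three containing nodes, majority DMN over HUB
    g3 <- new("ShapeGraph",
              nodes = list(1:2, 1:2, c(1L, 2L), 2:3),
              adjacency = local({
                  A <- matrix(1, 4, 4); diag(A) <- 0; A
              }),
              embedding = matrix(0, 3, 2), binOfNode = 1:4, nFrames = 3L,
              config = mapperConfig())
    sq3 <- labelFrames(g3, c("DMN", "DMN", "HUB", "VIS"),
                       stateLevels = c("DMN", "VIS", "HUB"))
    expect_identical(sq3@labels[1], "DMN")
    # non-HUB tie resolves to the lower state index
    sq4 <- suppressMessages(labelFrames(g, c("VIS", "DMN", "DMN"),
                            stateLevels = c("DMN", "VIS", "HUB")))
    expect_identical(sq4@labels[2], "DMN")

    # breaks propagate into validTransition
    sqB <- labelFrames(g, c("DMN", "DMN", "HUB"), breaks = 2L,
                       stateLevels = c("DMN", "VIS", "HUB"))
    expect_identical(sqB@validTransition, c(TRUE, FALSE, TRUE))
})

test_that("chain estimation counts only valid consecutive pairs", {
    sq <- makeStateSequence(c("A", "A", "B", "B", "A"))
    ch <- estimateChain(sq)
    expect_equal(transitionCounts(ch),
                 matrix(c(1, 1, 1, 1), 2, dimnames = list(c("A", "B"),
                                                          c("A", "B"))))
    expect_equal(transitionProbabilities(ch)["A", "B"], 0.5)
    expect_equal(sum(transitionCounts(ch)), sum(sq@validTransition))

    # invalidating the pair at positions 3-4 removes the B->B count
    sq2 <- makeStateSequence(c("A", "A", "B", "B", "A"),
                             valid = c(TRUE, TRUE, FALSE, TRUE))
    ch2 <- estimateChain(sq2)
    expect_equal(transitionCounts(ch2)["B", "B"], 0)
    expect_equal(sum(transitionCounts(ch2)), 3)

    # unobserved states are excluded with a message
    sq3 <- makeStateSequence(c("A", "A", "A"), levels = c("A", "B"))
    expect_message(ch3 <- estimateChain(sq3), "excluded")
    expect_identical(states(ch3), "A")

    # a state with no valid outgoing transition gets a uniform row
    sq4 <- makeStateSequence(c("A", "B"), valid = FALSE)
    expect_warning(ch4 <- estimateChain(sq4), "uniform")
    expect_equal(transitionProbabilities(ch4)["A", ], c(A = 0.5, B = 0.5))
    expect_true(all(abs(rowSums(transitionProbabilities(ch4)) - 1) < 1e-12))
})

test_that("chain estimation is equivariant under state relabeling", {
    set.seed(9)
    lab <- sample(c("A", "B", "C"), 60, replace = TRUE)
    ch <- estimateChain(makeStateSequence(lab))
    swap <- c(A = "C", B = "B", C = "A")
    ch2 <- estimateChain(makeStateSequence(unname(swap[lab]),
                                           levels = c("A", "B", "C")))
    P <- transitionProbabilities(ch)
    P2 <- transitionProbabilities(ch2)
    expect_equal(P[c("A", "B", "C"), c("A", "B", "C")],
                 P2[swap[c("A", "B", "C")], swap[c("A", "B", "C")]],
                 ignore_attr = TRUE)
})

test_that("top destination suppresses the diagonal", {
    P <- matrix(c(0.9, 0.3, 0.1, 0.7), 2,
                dimnames = list(c("A", "B"), c("A", "B")))
    expect_identical(unname(topDestination(P)), c("B", "A"))
    cfg <- syntheticConfig(nNetworks = 4)
    Pp <- buildPlantedChain(cfg)
    expect_true(all(topDestination(Pp)[1:4] == "HUB"))
})

test_that("transition similarity aligns states and uses off-diagonals", {
    sq <- makeStateSequence(c("A", "B", "A", "B", "A", "A"))
    ch <- estimateChain(sq)
    expect_equal(transitionSimilarity(ch, ch), 1)
    # brute-force correlation of off-diagonal entries
    set.seed(10)
    P1 <- matrix(runif(9), 3, dimnames = list(letters[1:3], letters[1:3]))
    P2 <- matrix(runif(9), 3, dimnames = list(letters[1:3], letters[1:3]))
    off <- !diag(3)
    expect_equal(transitionSimilarity(P1, P2),
                 oraclePearson(P1[off], P2[off]), tolerance = 1e-12)
    # mismatched state sets are padded with a warning
    P3 <- P2[1:2, 1:2]
    expect_warning(transitionSimilarity(P1, P3), "padded")
})

test_that("hub occupancy anticorrelates with dominant-network amplitude", {
    lab <- rep(c("HUB", "N1"), 10)
    ts <- cbind(N1 = ifelse(lab == "N1", 1, 0))
    sq <- makeStateSequence(lab, levels = c("N1", "HUB"))
    r <- hubRsnAnticorrelation(sq, ts)
    expect_equal(r$overall, -1)
    expect_equal(unname(r$perNetwork["N1"]), -1)
    # degenerate all-one-state sequences return NA
    sqc <- makeStateSequence(rep("N1", 20), levels = c("N1", "HUB"))
    expect_true(is.na(hubRsnAnticorrelation(sqc, ts)$overall))
})

test_that("largest-node frame labeling follows the biggest cluster", {
    # frames: 1 in node1; 2 in nodes 1,2; 3 in nodes 2,3; 4 in node 3;
    # node sizes 2,2,2 -> ties; make node 2 bigger by hand
    g <- new("ShapeGraph", nodes = list(c(1L, 2L), c(2L, 3L, 4L), c(3L, 4L)),
             adjacency = local({ A <- matrix(0, 3, 3)
                 A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1; A }),
             embedding = matrix(0, 4, 2), binOfNode = 1:3, nFrames = 4L,
             config = mapperConfig())
    sq <- labelFrames(g, c("VIS", "DMN", "HUB"),
                      stateLevels = c("DMN", "VIS", "HUB"),
                      method = "largestNode")
    # frames 2-4 all touch node 2 (size 3), the largest containing node
    expect_identical(sq@labels, c("VIS", "DMN", "DMN", "DMN"))
})
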