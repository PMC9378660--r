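test_that("planted chain is row-stochastic with hub as top off-diagonal entry", {
    cfg <- syntheticConfig(nNetworks = 2, hubSelfProb = 0.5,
                           peripheralSelfProb = 0.5, peripheralToHubProb = 0.4)
    P <- buildPlantedChain(cfg)
    expect_equal(rowSums(P), setNames(rep(1, 3), rownames(P)), tolerance = 1e-15)

    cfg3 <- syntheticConfig(nNetworks = 3, peripheralToHubProb = 0.6,
                            peripheralSelfProb = 0.3)
    P3 <- buildPlantedChain(cfg3)
    expect_true(all(abs(rowSums(P3) - 1) < 1e-12))
    for (s in 1:3) {
        off <- P3[s, ]; off[s] <- -Inf
        expect_identical(names(which.max(off)), "HUB")
    }
})

test_that("invalid generator probabilities are rejected by field name", {
    expect_error(syntheticConfig(hubSelfProb = 1.2), "hubSelfProb")
    expect_error(syntheticConfig(peripheralToHubProb = -0.1),
                 "peripheralToHubProb")
    expect_error(syntheticConfig(peripheralSelfProb = 0.8,
                                 peripheralToHubProb = 0.3),
                 "peripheralSelfProb \\+ peripheralToHubProb")
})

test_that("stationary distribution matches long-run simulated frequencies", {
    cfg <- syntheticConfig(nNetworks = 3, seed = 5)
    P <- buildPlantedChain(cfg)
    pi0 <- stationaryDistribution(P)
    # independent brute-force simulation oracle
    set.seed(99)
    n <- 1e5
    states <- rownames(P)
    cur <- 1L
    visits <- setNames(numeric(length(states)), states)
    for (t in seq_len(n)) {
        cur <- sample.int(length(states), 1L, prob = P[cur, ])
        visits[cur] <- visits[cur] + 1
    }
    expect_lt(max(abs(visits / n - pi0)), 0.01)
})

test_that("noiseless frames equal the state template exactly", {
    cfg <- syntheticConfig(nNetworks = 3, parcelsPerNetwork = 4,
                           nFramesPerSession = 60, nSessions = 1,
                           noiseSd = 1e-12, smoothingRho = 0,
                           censorFraction = 0, amplitude = 1.5, seed = 3)
    x <- simulateDataset(cfg)
    m <- tsMatrix(x)
    lab <- trueLabels(x)
    nets <- parcelNetworks(x)
    for (s in paste0("RSN", 1:3)) {
        rows <- which(lab == s)
        expect_equal(mean(m[rows, nets == s]), 1.5, tolerance = 1e-9)
        expect_equal(max(abs(m[rows, nets != s])), 0, tolerance = 1e-9)
    }
    hubRows <- which(lab == "HUB")
    expect_equal(max(abs(m[hubRows, ])), 0, tolerance = 1e-9)
})

test_that("a fixed seed reproduces the dataset bit for bit", {
    cfg <- tinyConfig()
    x1 <- simulateDataset(cfg)
    x2 <- simulateDataset(cfg)
    expect_identical(tsMatrix(x1), tsMatrix(x2))
    expect_identical(censorMask(x1), censorMask(x2))
    expect_identical(trueLabels(x1), trueLabels(x2))
})

test_that("empirical transitions of true labels recover the planted matrix", {
    # max-abs error of the censor-aware estimate at >= 5000 valid pairs is a
    # sampling-noise bound, so assert it as a median over three seeds
    errs <- vapply(c(8, 9, 10), function(sd) {
        cfg <- syntheticConfig(nFramesPerSession = 2900, nSessions = 2,
                               censorFraction = 0.05, seed = sd)
        x <- simulateDataset(cfg)
        sq <- trueStateSequence(x)
        expect_gte(sum(sq@validTransition), 5000)
        chain <- suppressMessages(estimateChain(sq))
        P <- buildPlantedChain(cfg)
        max(abs(transitionProbabilities(chain)[rownames(P), colnames(P)] - P))
    }, numeric(1))
    expect_lt(median(errs), 0.05)
    expect_lt(max(errs), 0.075)
})

test_that("censoring fraction and session boundaries come out as configured", {
    cfg <- syntheticConfig(nFramesPerSession = 1000, nSessions = 3,
                           censorFraction = 0.2, seed = 21)
    x <- simulateDataset(cfg)
    expect_lt(abs(mean(censorMask(x)) - 0.2), 0.025)
    expect_identical(sessionBoundaries(x), c(1000L, 2000L))
})

test_that("AR(1) noise has the configured lag-1 autocorrelation", {
    set.seed(10)
    e <- brainmapper:::.ar1Noise(20000, 1, 0.3, 1)
    ac <- cor(e[-nrow(e), 1], e[-1, 1])
    expect_lt(abs(ac - 0.3), 0.02)
})

test_that("cohort jitter controls subject specificity of the truth", {
    cfg <- tinyConfig()
    flat <- simulateCohort(cfg, nSubjects = 3, subjectJitter = 0, seed = 2)
    P0 <- buildPlantedChain(cfg)
    for (s in flat) expect_equal(s$transitionMatrix, P0)

    coh <- suppressWarnings(
        simulateCohort(cfg, nSubjects = 4, subjectJitter = 0.1, seed = 2))
    for (s in coh) {
        expect_equal(trueTransitionMatrix(s$halves[[1]]),
                     trueTransitionMatrix(s$halves[[2]]))
        expect_true(all(abs(rowSums(s$transitionMatrix) - 1) < 1e-12))
    }
    # between-subject matrices differ; within-subject correlation (1 by
    # construction) exceeds mean between-subject correlation
    sims <- c()
    for (i in 1:3) for (j in (i + 1):4)
        sims <- c(sims, cor(as.vector(coh[[i]]$transitionMatrix),
                            as.vector(coh[[j]]$transitionMatrix)))
    expect_true(all(sims < 1))
    expect_gt(1, mean(sims))
})

test_that("large jitter clips negative probabilities with a warning", {
    cfg <- tinyConfig()
    expect_warning(simulateCohort(cfg, nSubjects = 2, subjectJitter = 0.8,
                                  seed = 3),
                   "clipped")
})
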