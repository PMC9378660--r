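#' @include ParcellatedTimeSeries.R
NULL

#' SyntheticConfig: parameters of the planted-hub generator
#'
#' The generator emulates the structure the pipeline is designed to recover:
#' a latent finite-state Markov process in which one low-amplitude "hub"
#' state (no network elevated) mediates between peripheral states that each
#' elevate the parcels of a single resting-state network, observed through
#' temporally autocorrelated Gaussian noise, with censored frames and
#' multiple sessions.
#'
#' @slot nNetworks number of peripheral (network) states.
#' @slot parcelsPerNetwork parcels per network.
#' @slot nFramesPerSession frames per session.
#' @slot nSessions sessions per dataset (generated independently, then
#'   concatenated).
#' @slot hubSelfProb self-transition probability of the hub state.
#' @slot peripheralSelfProb self-transition probability of each peripheral
#'   state.
#' @slot peripheralToHubProb probability of moving from a peripheral state to
#'   the hub.
#' @slot amplitude elevation (z-scale units) of the dominant network's
#'   parcels in a peripheral state; the hub state is baseline 0 everywhere.
#' @slot noiseSd innovation standard deviation of the AR(1) observation
#'   noise.
#' @slot smoothingRho AR(1) coefficient in [0, 1) giving the noise the
#'   temporal autocorrelation of haemodynamic data.
#' @slot censorFraction expected fraction of frames flagged as censored
#'   (i.i.d. Bernoulli).
#' @slot seed integer seed; a fixed seed makes the dataset bit-identical.
#' @export
setClass("SyntheticConfig", representation(
    nNetworks = "integer", parcelsPerNetwork = "integer",
    nFramesPerSession = "integer", nSessions = "integer",
    hubSelfProb = "numeric", peripheralSelfProb = "numeric",
    peripheralToHubProb = "numeric", amplitude = "numeric",
    noiseSd = "numeric", smoothingRho = "numeric",
    censorFraction = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
    msg <- NULL
    chkp <- function(v, nm) {
        if (v < 0 || v > 1) sprintf("%s must be a probability in [0, 1]", nm)
    }
    msg <- c(msg,
        chkp(object@hubSelfProb, "hubSelfProb"),
        chkp(object@peripheralSelfProb, "peripheralSelfProb"),
        chkp(object@peripheralToHubProb, "peripheralToHubProb"))
    if (object@nNetworks < 2L) msg <- c(msg, "nNetworks must be >= 2")
    if (object@parcelsPerNetwork < 1L) msg <- c(msg, "parcelsPerNetwork must be >= 1")
    if (object@nFramesPerSession < 2L) msg <- c(msg, "nFramesPerSession must be >= 2")
    if (object@nSessions < 1L) msg <- c(msg, "nSessions must be >= 1")
    if (object@peripheralSelfProb + object@peripheralToHubProb > 1 + 1e-12)
        msg <- c(msg, "peripheralSelfProb + peripheralToHubProb must be <= 1")
    if (object@amplitude <= 0) msg <- c(msg, "amplitude must be > 0")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@smoothingRho < 0 || object@smoothingRho >= 1)
        msg <- c(msg, "smoothingRho must be in [0, 1)")
    if (object@censorFraction < 0 || object@censorFraction >= 1)
        msg <- c(msg, "censorFraction must be in [0, 1)")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn SyntheticConfig-class constructor with the package's default
#'   study conditions (6 networks x 30 parcels, 2 sessions x 500 frames).
#' @param nNetworks,parcelsPerNetwork,nFramesPerSession,nSessions,hubSelfProb
#'   see slots.
#' @param peripheralSelfProb,peripheralToHubProb,amplitude,noiseSd see slots.
#' @param smoothingRho,censorFraction,seed see slots.
#' @export
syntheticConfig <- function(nNetworks = 6L, parcelsPerNetwork = 30L,
                            nFramesPerSession = 500L, nSessions = 2L,
                            hubSelfProb = 0.5, peripheralSelfProb = 0.5,
                            peripheralToHubProb = 0.3, amplitude = 1.5,
                            noiseSd = 1, smoothingRho = 0.3,
                            censorFraction = 0.1, seed = 1L) {
    new("SyntheticConfig",
        nNetworks = as.integer(nNetworks),
        parcelsPerNetwork = as.integer(parcelsPerNetwork),
        nFramesPerSession = as.integer(nFramesPerSession),
        nSessions = as.integer(nSessions),
        hubSelfProb = hubSelfProb, peripheralSelfProb = peripheralSelfProb,
        peripheralToHubProb = peripheralToHubProb, amplitude = amplitude,
        noiseSd = noiseSd, smoothingRho = smoothingRho,
        censorFraction = censorFraction, seed = as.integer(seed))
}

setMethod("show", "SyntheticConfig", function(object) {
    cat(sprintf(paste0("SyntheticConfig: %d networks x %d parcels, ",
                       "%d session(s) x %d frames\n"),
        object@nNetworks, object@parcelsPerNetwork, object@nSessions,
        object@nFramesPerSession))
    cat(sprintf("  P(hub->hub)=%.2f P(periph->periph)=%.2f P(periph->hub)=%.2f\n",
        object@hubSelfProb, object@peripheralSelfProb,
        object@peripheralToHubProb))
    cat(sprintf("  amplitude=%.2f noiseSd=%.2f rho=%.2f censor=%.2f seed=%d\n",
        object@amplitude, object@noiseSd, object@smoothingRho,
        object@censorFraction, object@seed))
    invisible(object)
})

.syntheticStates <- function(nNetworks)
    c(sprintf("RSN%d", seq_len(nNetworks)), .HUB)

#' Planted hub-mediated transition matrix
#'
#' Builds the (nNetworks + 1)-state row-stochastic matrix of the generator:
#' from every peripheral state the hub receives
#' \code{peripheralToHubProb} and the remaining off-diagonal mass is split
#' uniformly over the other peripheral states; the hub row has
#' \code{hubSelfProb} on the diagonal and is uniform over peripheral states
#' elsewhere. The hub is therefore the single most likely off-diagonal
#' destination of every peripheral state whenever
#' \code{peripheralToHubProb} dominates.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return row-stochastic matrix with state dimnames (hub state last).
#' @examples
#' buildPlantedChain(syntheticConfig(nNetworks = 3))
#' @export
buildPlantedChain <- function(config) {
    stopifnot(is(config, "SyntheticConfig"))
    validObject(config)
    K <- config@nNetworks
    states <- .syntheticStates(K)
    P <- matrix(0, K + 1L, K + 1L, dimnames = list(states, states))
    rest <- 1 - config@peripheralSelfProb - config@peripheralToHubProb
    for (s in seq_len(K)) {
        P[s, ] <- if (K > 1L) rest / (K - 1L) else 0
        P[s, s] <- config@peripheralSelfProb
        P[s, K + 1L] <- config@peripheralToHubProb
    }
    P[K + 1L, ] <- (1 - config@hubSelfProb) / K
    P[K + 1L, K + 1L] <- config@hubSelfProb
    P / rowSums(P)
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalised to
#' sum to one.
#'
#' @param P row-stochastic matrix.
#' @return numeric vector of stationary probabilities (named like rows of P).
#' @export
stationaryDistribution <- function(P) {
    stopifnot(is.matrix(P), nrow(P) == ncol(P))
    e <- eigen(t(P))
    i <- which.min(abs(e$values - 1))
    v <- Re(e$vectors[, i])
    v <- v / sum(v)
    names(v) <- rownames(P)
    v
}

## Simulate a label path of length n from chain P, starting from the
## stationary distribution.
.simulateLabels <- function(P, n) {
    states <- rownames(P)
    K <- length(states)
    lab <- integer(n)
    lab[1L] <- sample.int(K, 1L, prob = stationaryDistribution(P))
    for (t in seq_len(n - 1L))
        lab[t + 1L] <- sample.int(K, 1L, prob = P[lab[t], ])
    states[lab]
}

## AR(1) noise matrix (frames x parcels), stationary initialisation.
.ar1Noise <- function(n, p, rho, sd) {
    if (sd == 0) return(matrix(0, n, p))
    e <- matrix(stats::rnorm(n * p, sd = sd), n, p)
    if (rho > 0) {
        e[1L, ] <- e[1L, ] / sqrt(1 - rho^2)
        for (t in 2:n) e[t, ] <- rho * e[t - 1L, ] + e[t, ]
    }
    e
}

## Shared core: simulate from a given chain and per-network amplitudes.
.simulateFromChain <- function(config, P, amplitudes) {
    K <- config@nNetworks
    states <- rownames(P)
    nParcel <- K * config@parcelsPerNetwork
    parcelNet <- rep(states[seq_len(K)], each = config@parcelsPerNetwork)
    template <- matrix(0, K + 1L, nParcel, dimnames = list(states, NULL))
    for (s in seq_len(K))
        template[s, parcelNet == states[s]] <- amplitudes[s]
    sessions <- vector("list", config@nSessions)
    labels <- vector("list", config@nSessions)
    for (ss in seq_len(config@nSessions)) {
        lab <- .simulateLabels(P, config@nFramesPerSession)
        X <- template[lab, , drop = FALSE] +
            .ar1Noise(config@nFramesPerSession, nParcel,
                      config@smoothingRho, config@noiseSd)
        sessions[[ss]] <- X
        labels[[ss]] <- lab
    }
    allX <- do.call(rbind, sessions)
    nTot <- nrow(allX)
    censor <- stats::runif(nTot) < config@censorFraction
    colnames(allX) <- sprintf("p%03d", seq_len(nParcel))
    pts <- ParcellatedTimeSeries(
        allX, parcelNetworks = parcelNet, censorMask = censor,
        sessions = rep(seq_len(config@nSessions),
                       each = config@nFramesPerSession),
        stateLabels = unlist(labels))
    S4Vectors::metadata(pts)$trueTransitionMatrix <- P
    S4Vectors::metadata(pts)$config <- config
    pts
}

#' Simulate a planted-hub parcellated dataset
#'
#' Frames in peripheral state s have mean \code{amplitude} on the parcels of
#' network s and baseline 0 elsewhere; hub frames are baseline 0 on every
#' parcel (uniform engagement across networks). Observation noise is AR(1)
#' with coefficient \code{smoothingRho} and innovation SD \code{noiseSd}.
#' Sessions are generated independently and concatenated; a random
#' \code{censorFraction} of frames is flagged censored. The ground-truth
#' per-frame labels and transition matrix travel with the object
#' (\code{\link{trueLabels}}, \code{\link{trueTransitionMatrix}}).
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return a \linkS4class{ParcellatedTimeSeries} with ground truth attached.
#' @examples
#' x <- simulateDataset(syntheticConfig(nFramesPerSession = 100))
#' table(trueLabels(x))
#' @export
simulateDataset <- function(config = syntheticConfig()) {
    validObject(config)
    set.seed(config@seed)
    P <- buildPlantedChain(config)
    .simulateFromChain(config, P,
        amplitudes = rep(config@amplitude, config@nNetworks))
}

#' Simulate a multi-subject cohort with two session-halves per subject
#'
#' Each subject receives a subject-specific transition matrix (the planted
#' chain perturbed entrywise by Gaussian jitter, clipped at zero and
#' row-renormalised) and subject-specific per-network amplitudes; the two
#' halves of one subject share these generating parameters and differ only
#' in noise, which supports within- versus between-subject reliability
#' analyses.
#'
#' @param baseConfig a \linkS4class{SyntheticConfig} shared by all subjects.
#' @param nSubjects number of subjects (>= 2).
#' @param subjectJitter SD of the entrywise perturbation of transition
#'   probabilities, and relative SD of the amplitude perturbation; 0 makes
#'   all subjects identical.
#' @param seed integer seed for the cohort.
#' @return list with one element per subject: \code{halves} (list of two
#'   \linkS4class{ParcellatedTimeSeries}), \code{transitionMatrix} and
#'   \code{amplitudes}.
#' @export
simulateCohort <- function(baseConfig = syntheticConfig(), nSubjects = 4L,
                           subjectJitter = 0.1, seed = 1L) {
    stopifnot(nSubjects >= 2L)
    validObject(baseConfig)
    set.seed(seed)
    P0 <- buildPlantedChain(baseConfig)
    K <- baseConfig@nNetworks
    subjects <- vector("list", nSubjects)
    clipped <- FALSE
    for (i in seq_len(nSubjects)) {
        P <- P0
        amplitudes <- rep(baseConfig@amplitude, K)
        if (subjectJitter > 0) {
            P <- P0 + matrix(stats::rnorm(length(P0), sd = subjectJitter),
                             nrow(P0))
            if (any(P < 0)) { clipped <- TRUE; P[P < 0] <- 0 }
            P <- P / rowSums(P)
            amplitudes <- baseConfig@amplitude *
                pmax(0.2, 1 + subjectJitter * stats::rnorm(K))
        }
        halfSeeds <- sample.int(.Machine$integer.max - 1L, 2L)
        halves <- lapply(halfSeeds, function(s) {
            set.seed(s)
            .simulateFromChain(baseConfig, P, amplitudes)
        })
        subjects[[i]] <- list(halves = halves, transitionMatrix = P,
                              amplitudes = amplitudes)
    }
    if (clipped)
        warning("subject jitter produced negative probabilities; ",
                "clipped to 0 and renormalised")
    names(subjects) <- sprintf("subject%02d", seq_len(nSubjects))
    subjects
}

#' Ground-truth state sequence of a synthetic recording
#'
#' Restricts the generator's per-frame labels to the retained (uncensored)
#' frames and marks transitions across censoring gaps or session stitches
#' invalid, yielding the sequence against which estimated chains can be
#' compared.
#'
#' @param pts a \linkS4class{ParcellatedTimeSeries} with ground-truth labels.
#' @return a \linkS4class{StateSequence}.
#' @export
trueStateSequence <- function(pts) {
    if (is.null(trueLabels(pts)))
        stop("recording carries no ground-truth state labels")
    dropped <- dropCensored(pts)
    labels <- trueLabels(dropped$pts)
    n <- length(labels)
    valid <- rep(TRUE, max(n - 1L, 0L))
    valid[dropped$breaks] <- FALSE
    nets <- sort(setdiff(unique(labels), .HUB))
    new("StateSequence", labels = labels, validTransition = valid,
        stateLevels = c(nets, .HUB))
}
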