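#' @include transitions.R
NULL

#' Phase-randomised surrogate time series
#'
#' Fourier-transforms each column, adds one common random phase vector to
#' every column's phases (the multivariate scheme that preserves
#' cross-covariance as well as each column's amplitude spectrum), enforces
#' conjugate symmetry -- the DC and Nyquist components are left real -- and
#' inverts the transform. Linear properties (autocorrelation, power
#' spectrum, lagged cross-covariance) are preserved; any nonlinear state
#' structure is destroyed.
#'
#' @param x frames-by-parcels numeric matrix (>= 4 frames).
#' @param seed optional integer seed for the phase draw.
#' @param commonPhase use one phase vector for all columns (default TRUE);
#'   FALSE draws independent phases per column, which breaks cross-column
#'   covariance.
#' @return surrogate matrix of the same dimension.
#' @export
phaseRandomize <- function(x, seed = NULL, commonPhase = TRUE) {
    x <- as.matrix(x)
    n <- nrow(x)
    if (n < 4L) stop("phase randomisation needs at least 4 frames")
    if (!is.null(seed)) set.seed(seed)
    half <- floor((n - 1) / 2)              # strictly positive frequencies
    drawRot <- function() {
        phi <- stats::runif(half, 0, 2 * pi)
        rot <- rep(1 + 0i, n)
        rot[1 + seq_len(half)] <- exp(1i * phi)
        rot[n + 1 - seq_len(half)] <- Conj(rot[1 + seq_len(half)])
        rot                                  # DC (and Nyquist if n even) = 1
    }
    rot <- drawRot()
    out <- apply(x, 2L, function(col) {
        if (!commonPhase) rot <<- drawRot()
        Re(stats::fft(stats::fft(col) * rot, inverse = TRUE)) / n
    })
    dimnames(out) <- dimnames(x)
    out
}

#' Fit a vector autoregressive model by least squares
#'
#' Ordinary least squares on the stacked lagged regression
#' x_t = c + A_1 x_(t-1) + ... + A_p x_(t-p) + e_t, with the residual
#' covariance taken as the sample covariance of the fitted residuals.
#'
#' @param x frames-by-parcels numeric matrix.
#' @param p autoregressive order (default 1).
#' @return list with \code{A} (list of p parcel-by-parcel coefficient
#'   matrices), \code{intercept}, \code{sigma} (residual covariance) and
#'   \code{p}.
#' @export
fitVAR <- function(x, p = 1L) {
    x <- as.matrix(x)
    n <- nrow(x); m <- ncol(x)
    stopifnot(p >= 1L)
    if (n <= p * m + 1L)
        warning("few frames relative to p * parcels; estimates may be unstable")
    Y <- x[(p + 1):n, , drop = FALSE]
    X <- do.call(cbind, lapply(seq_len(p), function(l)
        x[(p + 1 - l):(n - l), , drop = FALSE]))
    X <- cbind(1, X)
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
        stop("singular lagged design; reduce p or supply more frames")
    B <- qr.coef(qrX, Y)
    resid <- Y - X %*% B
    A <- lapply(seq_len(p), function(l)
        t(B[1 + ((l - 1) * m + 1):(l * m), , drop = FALSE]))
    list(A = A, intercept = as.numeric(B[1L, ]),
         sigma = stats::cov(resid), p = p)
}

## spectral radius of the VAR companion matrix
.companionRadius <- function(A) {
    p <- length(A); m <- nrow(A[[1L]])
    C <- matrix(0, m * p, m * p)
    C[seq_len(m), ] <- do.call(cbind, A)
    if (p > 1L)
        C[(m + 1):(m * p), seq_len(m * (p - 1))] <- diag(m * (p - 1))
    max(Mod(eigen(C, only.values = TRUE)$values))
}

## symmetric nearest-PSD repair by eigenvalue clipping
.nearestPSD <- function(S) {
    S <- (S + t(S)) / 2
    e <- eigen(S, symmetric = TRUE)
    if (min(e$values) >= 0) return(S)
    v <- pmax(e$values, 0)
    e$vectors %*% (v * t(e$vectors))
}

#' Simulate from a vector autoregressive model
#'
#' Gaussian innovations with the given residual covariance (Cholesky
#' factorised; repaired to the nearest positive semidefinite matrix with a
#' warning if needed), a burn-in of 500 frames discarded, and an optional
#' intercept and initial state. A fixed seed makes the draw reproducible; an
#' unstable coefficient set (companion spectral radius >= 1) triggers a
#' warning.
#'
#' @param A list of p parcel-by-parcel coefficient matrices (or one matrix).
#' @param sigma innovation covariance.
#' @param nFrames number of frames to return (after burn-in).
#' @param seed optional integer seed.
#' @param intercept optional constant term (default 0).
#' @param init optional p-by-parcels matrix of initial states (default 0).
#' @param burnin frames discarded before recording (default 500).
#' @return frames-by-parcels surrogate matrix.
#' @export
simulateVAR <- function(A, sigma, nFrames, seed = NULL, intercept = NULL,
                        init = NULL, burnin = 500L) {
    if (is.matrix(A)) A <- list(A)
    m <- nrow(A[[1L]]); p <- length(A)
    if (.companionRadius(A) >= 1)
        warning("VAR coefficients are not stable (spectral radius >= 1)")
    if (is.null(intercept)) intercept <- rep(0, m)
    if (!is.null(seed)) set.seed(seed)
    sigma <- (sigma + t(sigma)) / 2
    ch <- tryCatch(chol(sigma), error = function(e) {
        warning("innovation covariance not positive definite; ",
                "using nearest PSD repair")
        S <- .nearestPSD(sigma)
        chol(S + diag(1e-12 * max(diag(S)) + 1e-300, m))
    })
    total <- nFrames + burnin
    innov <- matrix(stats::rnorm(total * m), total, m) %*% ch
    X <- matrix(0, total + p, m)
    if (!is.null(init)) X[seq_len(p), ] <- init
    for (t in (p + 1):(total + p)) {
        acc <- intercept + innov[t - p, ]
        for (l in seq_len(p)) acc <- acc + A[[l]] %*% X[t - l, ]
        X[t, ] <- acc
    }
    X[(p + burnin + 1):(p + total), , drop = FALSE]
}

#' Generate an ensemble of surrogate datasets
#'
#' Produces \code{nInstances} linearity-preserving surrogates of the
#' retained, z-scored recording: either phase-randomised
#' (\code{kind = "phase"}) or simulated from a fitted VAR(p)
#' (\code{kind = "var"}). Instance i uses seed \code{seed + i} so ensembles
#' are reproducible yet instances differ. The conventional ensemble size is
#' 25 per recording.
#'
#' @param x frames-by-parcels matrix or \linkS4class{ParcellatedTimeSeries}
#'   (preprocessed via \code{\link{prepareForMapper}} in the latter case).
#' @param kind "phase" or "var".
#' @param nInstances ensemble size (default 25).
#' @param p VAR order (default 1).
#' @param seed base seed (default 1).
#' @return a \linkS4class{NullEnsemble}.
#' @export
generateEnsemble <- function(x, kind = c("phase", "var"), nInstances = 25L,
                             p = 1L, seed = 1L) {
    kind <- match.arg(kind)
    if (is(x, "ParcellatedTimeSeries")) x <- prepareForMapper(x)$matrix
    x <- as.matrix(x)
    stopifnot(nInstances >= 1L)
    seeds <- as.integer(seed + seq_len(nInstances))
    surr <- if (kind == "phase") {
        lapply(seeds, function(s) phaseRandomize(x, seed = s))
    } else {
        fit <- fitVAR(x, p)
        lapply(seeds, function(s) {
            set.seed(s)
            init <- x[sample.int(nrow(x) - p + 1L, 1L) + seq_len(p) - 1L, ,
                      drop = FALSE]
            simulateVAR(fit$A, fit$sigma, nrow(x), intercept = fit$intercept,
                        init = init)
        })
    }
    new("NullEnsemble", surrogates = surr, kind = kind, p = as.integer(p),
        seeds = seeds)
}

#' @rdname accessors
#' @export
setMethod("surrogates", "NullEnsemble", function(x) x@surrogates)

setMethod("show", "NullEnsemble", function(object) {
    d <- dim(object@surrogates[[1L]])
    cat(sprintf("NullEnsemble: %d %s surrogate(s) of %d x %d\n",
        length(object@surrogates), object@kind, d[1L], d[2L]))
    invisible(object)
})
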