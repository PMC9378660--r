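#' @include ParcellatedTimeSeries.R
NULL

#' Column-wise z-scoring
#'
#' Centres each column to mean 0 and scales to sample standard deviation 1
#' (n - 1 denominator). This is the harmonisation applied to every session
#' before sessions are concatenated, and to network mean signals before
#' thresholding.
#'
#' @param x numeric matrix (frames in rows).
#' @return matrix of the same shape with unit-variance, zero-mean columns.
#' @examples
#' colMeans(zscoreColumns(matrix(rnorm(30), 10, 3)))
#' @export
zscoreColumns <- function(x) {
    x <- as.matrix(x)
    if (nrow(x) < 2L) stop("z-scoring needs at least 2 frames")
    sds <- apply(x, 2L, stats::sd)
    bad <- which(sds == 0)
    if (length(bad))
        stop("constant column(s): ", paste(bad, collapse = ", "))
    scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Concatenate sessions with per-session z-scoring
#'
#' Each session matrix is z-scored column-wise and the sessions are then
#' row-stacked; the returned boundaries are the cumulative frame counts at
#' the stitch points (exclusive of the final session).
#'
#' @param sessions list of frames-by-parcels matrices with equal parcel
#'   counts.
#' @param zscore apply per-session column z-scoring before stacking
#'   (default TRUE).
#' @return list with \code{data} (stacked matrix) and \code{boundaries}
#'   (integer vector, empty for a single session).
#' @export
concatenateSessions <- function(sessions, zscore = TRUE) {
    stopifnot(is.list(sessions), length(sessions) >= 1L)
    p <- vapply(sessions, ncol, integer(1))
    if (length(unique(p)) != 1L)
        stop("sessions have mismatched parcel counts: ",
             paste(p, collapse = ", "))
    if (zscore) sessions <- lapply(sessions, zscoreColumns)
    n <- vapply(sessions, nrow, integer(1))
    list(data = do.call(rbind, sessions),
         boundaries = if (length(n) > 1L) cumsum(n)[-length(n)] else integer(0))
}

#' Remove censored frames, tracking broken adjacency
#'
#' Censored frames are removed before Mapper is run. Because the removal
#' compacts the frame ordering, pairs of retained frames that were not
#' consecutive in the original recording -- or that straddle a session
#' stitch -- must not be counted as Markov transitions later. Those
#' positions are returned as \code{breaks}: position i means the pair
#' (retained frame i, retained frame i + 1) is not a genuine transition.
#'
#' @param pts a \linkS4class{ParcellatedTimeSeries}.
#' @return list with \code{pts} (recording restricted to retained frames)
#'   and \code{breaks} (integer positions in the compacted ordering).
#' @examples
#' x <- simulateDataset(syntheticConfig(nFramesPerSession = 50))
#' dropCensored(x)$breaks
#' @export
dropCensored <- function(pts) {
    stopifnot(is(pts, "ParcellatedTimeSeries"))
    keep <- !censorMask(pts)
    if (!any(keep)) stop("all frames are censored")
    orig <- which(keep)
    sess <- sessionIds(pts)[keep]
    out <- pts[, keep]
    n <- length(orig)
    breaks <- integer(0)
    if (n > 1L) {
        gap <- diff(orig) != 1L
        stitch <- sess[-1L] != sess[-n]
        breaks <- which(gap | stitch)
    }
    list(pts = out, breaks = breaks)
}

#' Z-scored network mean time series
#'
#' Averages parcels within each resting-state network per frame and z-scores
#' each network column, yielding the signals against which the activation
#' threshold (0.5 SD by convention) is applied. Parcels with an \code{NA}
#' network assignment are excluded.
#'
#' @param pts a \linkS4class{ParcellatedTimeSeries}.
#' @param zscore z-score the network columns (default TRUE).
#' @return frames-by-networks numeric matrix with network column names.
#' @export
networkMeans <- function(pts, zscore = TRUE) {
    stopifnot(is(pts, "ParcellatedTimeSeries"))
    nets <- networkLabels(pts)
    if (!length(nets)) stop("no parcels carry a network assignment")
    x <- tsMatrix(pts)
    assign <- parcelNetworks(pts)
    out <- vapply(nets, function(nw) {
        idx <- which(!is.na(assign) & assign == nw)
        if (!length(idx)) stop(sprintf("network '%s' has no parcels", nw))
        rowMeans(x[, idx, drop = FALSE])
    }, numeric(nrow(x)))
    out <- matrix(out, nrow = nrow(x), dimnames = list(NULL, nets))
    if (zscore) out <- zscoreColumns(out)
    out
}

#' Standard preparation of a recording for Mapper
#'
#' Per-session column z-scoring, session concatenation and censored-frame
#' removal in the order the pipeline expects. Returns the retained z-scored
#' frames-by-parcels matrix, the matching retained-frame recording (for
#' network means) and the adjacency break positions for transition counting.
#'
#' @param pts a \linkS4class{ParcellatedTimeSeries}.
#' @return list with \code{matrix}, \code{pts} (retained frames, z-scored
#'   data) and \code{breaks}.
#' @export
prepareForMapper <- function(pts) {
    stopifnot(is(pts, "ParcellatedTimeSeries"))
    sess <- sessionIds(pts)
    x <- tsMatrix(pts)
    pieces <- lapply(unique(sess), function(s) x[sess == s, , drop = FALSE])
    cc <- concatenateSessions(pieces, zscore = TRUE)
    z <- ParcellatedTimeSeries(
        cc$data, parcelNetworks = parcelNetworks(pts),
        censorMask = censorMask(pts), sessions = sess,
        frameDuration = pts@frameDuration, stateLabels = trueLabels(pts))
    S4Vectors::metadata(z) <- S4Vectors::metadata(pts)
    dropped <- dropCensored(z)
    list(matrix = tsMatrix(dropped$pts), pts = dropped$pts,
         breaks = dropped$breaks)
}
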