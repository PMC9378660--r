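#' @include AllGenerics.R
NULL

#' Construct a ParcellatedTimeSeries
#'
#' @param data numeric frames-by-parcels matrix (one row per time frame, one
#'   column per parcel).
#' @param parcelNetworks character/factor of length \code{ncol(data)} mapping
#'   each parcel to its resting-state network. \code{NA} marks unassigned
#'   parcels; these are carried along but excluded from network means.
#' @param censorMask logical of length \code{nrow(data)}; \code{TRUE} flags a
#'   frame for discarding (e.g. motion-contaminated). Default: none.
#' @param sessions session identifier per frame (frames of a session must be
#'   contiguous). Default: a single session.
#' @param frameDuration sampling interval in seconds (default 1).
#' @param stateLabels optional per-frame ground-truth state labels (used by
#'   the synthetic generator).
#'
#' @return A \linkS4class{ParcellatedTimeSeries}.
#' @examples
#' x <- ParcellatedTimeSeries(matrix(rnorm(40), 10, 4),
#'     parcelNetworks = c("A", "A", "B", "B"))
#' dim(tsMatrix(x))
#' @export
ParcellatedTimeSeries <- function(data, parcelNetworks,
                                  censorMask = rep(FALSE, nrow(data)),
                                  sessions = rep(1L, nrow(data)),
                                  frameDuration = 1,
                                  stateLabels = NULL) {
    data <- as.matrix(data)
    rownames(data) <- NULL           # frames are indexed, never named
    if (!is.numeric(data)) stop("'data' must be a numeric matrix")
    if (length(parcelNetworks) != ncol(data))
        stop("'parcelNetworks' must have one entry per parcel (column)")
    if (length(censorMask) != nrow(data))
        stop("'censorMask' must have one entry per frame (row)")
    if (length(sessions) != nrow(data))
        stop("'sessions' must have one entry per frame (row)")
    pid <- colnames(data)
    if (is.null(pid)) pid <- sprintf("p%03d", seq_len(ncol(data)))
    cd <- S4Vectors::DataFrame(
        frame = seq_len(nrow(data)),
        session = as.character(sessions),
        censored = as.logical(censorMask))
    if (!is.null(stateLabels)) {
        if (length(stateLabels) != nrow(data))
            stop("'stateLabels' must have one entry per frame")
        cd$state <- as.character(stateLabels)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(ts = t(data)),
        rowData = S4Vectors::DataFrame(
            network = as.character(parcelNetworks), row.names = pid),
        colData = cd)
    new("ParcellatedTimeSeries", se, frameDuration = frameDuration)
}

#' Frames-by-parcels matrix of a recording
#'
#' @param x a \linkS4class{ParcellatedTimeSeries}.
#' @return numeric matrix with frames as rows and parcels as columns.
#' @export
setMethod("tsMatrix", "ParcellatedTimeSeries", function(x)
    t(SummarizedExperiment::assay(x, "ts")))

#' Accessors for ParcellatedTimeSeries metadata
#'
#' \code{censorMask} returns the per-frame logical censor flags;
#' \code{sessionIds} the per-frame session identifiers;
#' \code{sessionBoundaries} the 0-based frame counts at which a new session
#' starts (empty for a single session; a recording of sessions with 10 and 12
#' frames has boundary 10); \code{parcelNetworks} the parcel-to-network map;
#' \code{networkLabels} the ordered set of network names;
#' \code{trueLabels}/\code{trueTransitionMatrix} the generator ground truth
#' when present (\code{NULL} otherwise).
#'
#' @param x a \linkS4class{ParcellatedTimeSeries}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("censorMask", "ParcellatedTimeSeries", function(x)
    SummarizedExperiment::colData(x)$censored)

#' @rdname accessors
#' @export
setMethod("sessionIds", "ParcellatedTimeSeries", function(x)
    SummarizedExperiment::colData(x)$session)

#' @rdname accessors
#' @export
setMethod("sessionBoundaries", "ParcellatedTimeSeries", function(x) {
    s <- sessionIds(x)
    if (length(s) <= 1L) return(integer(0))
    which(s[-1L] != s[-length(s)])
})

#' @rdname accessors
#' @export
setMethod("parcelNetworks", "ParcellatedTimeSeries", function(x) {
    nw <- SummarizedExperiment::rowData(x)$network
    names(nw) <- rownames(x)
    nw
})

#' @rdname accessors
#' @export
setMethod("networkLabels", "ParcellatedTimeSeries", function(x) {
    nw <- SummarizedExperiment::rowData(x)$network
    unique(nw[!is.na(nw)])
})

#' @rdname accessors
#' @export
setMethod("trueLabels", "ParcellatedTimeSeries", function(x)
    SummarizedExperiment::colData(x)$state)

#' @rdname accessors
#' @export
setMethod("trueTransitionMatrix", "ParcellatedTimeSeries", function(x)
    S4Vectors::metadata(x)$trueTransitionMatrix)

setMethod("show", "ParcellatedTimeSeries", function(object) {
    cat(sprintf("ParcellatedTimeSeries: %d frames x %d parcels\n",
                ncol(object), nrow(object)))
    cat(sprintf("  sessions: %d | censored frames: %d | networks: %d\n",
                length(unique(sessionIds(object))),
                sum(censorMask(object)),
                length(networkLabels(object))))
    if (!is.null(trueLabels(object)))
        cat("  ground-truth state labels present\n")
    invisible(object)
})
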