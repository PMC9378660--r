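#' @include null-models.R
NULL

#' Parameter-perturbation sweep over resolution and gain
#'
#' Reruns the binning, partial clustering and graph-assembly stages for
#' every (R, G) combination, reusing the distance matrix and filter
#' embedding (which do not depend on R or G). The conventional perturbation
#' around R = 30, G = 70 is R in 25..35 crossed with G in 65..75, i.e. 121
#' Mapper variations. Per-cell failures are recorded without aborting the
#' sweep.
#'
#' @param x frames-by-parcels matrix or \linkS4class{ParcellatedTimeSeries}.
#' @param Rvalues,Gvalues resolution and gain grids (default 25:35 and
#'   65:75).
#' @param config base \linkS4class{MapperConfig} supplying d, k, metric and
#'   histBins.
#' @param degreeCutoff cutoff of the per-cell high-degree proportion
#'   (default 20).
#' @return data.frame with one row per cell: R, G, nodes, edges,
#'   highDegreeProportion, ok; the per-cell graphs are attached as the
#'   \code{"graphs"} attribute (NULL for failed cells).
#' @export
parameterSweep <- function(x, Rvalues = 25:35, Gvalues = 65:75,
                           config = mapperConfig(), degreeCutoff = 20) {
    stopifnot(length(Rvalues) >= 1L, length(Gvalues) >= 1L)
    if (is(x, "ParcellatedTimeSeries")) x <- prepareForMapper(x)$matrix
    x <- as.matrix(x)
    D <- pairwiseDistances(x, config@metric)
    gd <- knnGeodesic(D, config@k)
    coords <- embedMDS(gd, config@d)
    grid <- expand.grid(G = Gvalues, R = Rvalues)[, c("R", "G")]
    graphs <- vector("list", nrow(grid))
    res <- data.frame(grid, nodes = NA_integer_, edges = NA_integer_,
                      highDegreeProportion = NA_real_, ok = FALSE)
    for (i in seq_len(nrow(grid))) {
        cellCfg <- config
        cellCfg@R <- as.integer(grid$R[i]); cellCfg@G <- as.numeric(grid$G[i])
        g <- tryCatch(.mapperFromEmbedding(D, coords, cellCfg@R, cellCfg@G,
                                           config@histBins, cellCfg),
                      error = function(e) e)
        if (inherits(g, "error")) next
        graphs[[i]] <- g
        res$nodes[i] <- numNodes(g)
        res$edges[i] <- sum(adjacency(g)) / 2
        res$highDegreeProportion[i] <- highDegreeProportion(g, degreeCutoff)
        res$ok[i] <- TRUE
    }
    attr(res, "graphs") <- graphs
    res
}

#' Within- versus between-subject similarities
#'
#' Given one measurement per subject and session-half, computes the
#' similarity of the two halves of each subject (within) and of every
#' unordered cross-subject half pair (between): n subjects yield n within
#' values and 2 n (n - 1) between values. Subjects with a missing half are
#' skipped with a warning.
#'
#' @param halves list per subject of a list of two measurement objects.
#' @param similarity function of two measurements returning a scalar
#'   (e.g. \code{\link{matrixSimilarity}} or
#'   \code{\link{transitionSimilarity}}).
#' @return list with \code{within} and \code{between} numeric vectors.
#' @export
withinBetween <- function(halves, similarity) {
    stopifnot(is.list(halves), is.function(similarity))
    complete <- vapply(halves, function(h)
        is.list(h) && length(h) == 2L &&
            !is.null(h[[1L]]) && !is.null(h[[2L]]), logical(1))
    if (any(!complete)) {
        warning(sprintf("%d subject(s) missing a half; skipped",
                        sum(!complete)))
        halves <- halves[complete]
    }
    n <- length(halves)
    if (n < 2L) stop("need at least 2 complete subjects")
    within <- vapply(halves, function(h)
        similarity(h[[1L]], h[[2L]]), numeric(1))
    between <- numeric(0)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
        for (a in 1:2) for (b in 1:2)
            between <- c(between,
                         similarity(halves[[i]][[a]], halves[[j]][[b]]))
    list(within = unname(within), between = between)
}

#' One-way analysis of variance
#'
#' Classical between/within mean-square F ratio with its p-value from the F
#' distribution (equal-variance one-way ANOVA); a convenience summary for
#' comparing, e.g., real versus null high-degree proportions.
#'
#' @param groups list of numeric vectors (>= 2 groups of >= 2 values).
#' @return list with \code{F}, \code{df1}, \code{df2}, \code{p} (all NA when
#'   both between- and within-group variance are zero).
#' @examples
#' oneWayAnova(list(c(1, 2, 3), c(4, 5, 6)))  # F = 13.5 on (1, 4) df
#' @export
oneWayAnova <- function(groups) {
    stopifnot(is.list(groups), length(groups) >= 2L)
    if (any(lengths(groups) < 2L)) stop("each group needs >= 2 values")
    y <- unlist(groups)
    g <- factor(rep.int(seq_along(groups), lengths(groups)))
    if (stats::var(y) == 0)
        return(list(F = NA_real_, df1 = length(groups) - 1L,
                    df2 = length(y) - length(groups), p = NA_real_))
    ow <- stats::oneway.test(y ~ g, var.equal = TRUE)
    list(F = unname(ow$statistic), df1 = unname(ow$parameter[1L]),
         df2 = unname(ow$parameter[2L]), p = unname(ow$p.value))
}
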