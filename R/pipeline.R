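#' @include io.R
NULL

#' Run the full precision-dynamics pipeline on one recording
#'
#' Convenience composition of the package's stages: per-session z-scoring,
#' censor removal, Mapper shape graph, topological metrics and hub
#' detection, network activation annotation, dominant-label assignment,
#' frame labelling and censor-aware Markov chain estimation.
#'
#' @param pts a \linkS4class{ParcellatedTimeSeries}.
#' @param config a \linkS4class{MapperConfig}.
#' @param threshold network activation threshold in z units (default 0.5).
#' @param degreeCutoff hub degree cutoff (default 20; 21 is the documented
#'   alternative).
#' @param centralityTopFraction closeness quantile fraction (default 0.01).
#' @return list with \code{graph}, \code{networkTS}, \code{degree},
#'   \code{closeness}, \code{hubFlags}, \code{annotation}, \code{sequence}
#'   (a \linkS4class{StateSequence}), \code{chain}
#'   (a \linkS4class{TransitionMatrix}) and \code{breaks}.
#' @examples
#' x <- simulateDataset(syntheticConfig(nFramesPerSession = 150,
#'     nSessions = 1, censorFraction = 0))
#' res <- mapperPipeline(x, mapperConfig(R = 8, k = 10))
#' res$chain
#' @export
mapperPipeline <- function(pts, config = mapperConfig(), threshold = 0.5,
                           degreeCutoff = 20, centralityTopFraction = 0.01) {
    stopifnot(is(pts, "ParcellatedTimeSeries"))
    prep <- prepareForMapper(pts)
    graph <- runMapper(prep$matrix, config)
    networkTS <- networkMeans(prep$pts)
    deg <- nodeDegree(graph)
    cc <- closenessCentrality(graph)
    hubs <- detectHubs(graph, degreeCutoff, centralityTopFraction)
    ann <- annotateNodes(graph, networkTS, threshold)
    ann <- assignDominant(ann, hubs)
    nets <- colnames(networkTS)
    sq <- labelFrames(graph, ann@dominantNetwork, breaks = prep$breaks,
                      stateLevels = c(nets, .HUB))
    chain <- suppressWarnings(estimateChain(sq))
    list(graph = graph, networkTS = networkTS, degree = deg, closeness = cc,
         hubFlags = hubs, annotation = ann, sequence = sq, chain = chain,
         breaks = prep$breaks)
}

#' Summarise a pipeline result
#'
#' @param result the list returned by \code{\link{mapperPipeline}}.
#' @return list with node/edge counts, hub count, mean activation SD of hub
#'   versus other nodes, top destination per state and hub occupancy.
#' @export
pipelineReport <- function(result) {
    stopifnot(is.list(result), !is.null(result$graph))
    hubs <- result$hubFlags
    sdHub <- if (any(hubs)) mean(activationSD(result$annotation)[hubs]) else NA_real_
    sdOther <- if (any(!hubs)) mean(activationSD(result$annotation)[!hubs]) else NA_real_
    list(nNodes = numNodes(result$graph),
         nEdges = sum(adjacency(result$graph)) / 2,
         nHubs = sum(hubs),
         meanActivationSDHubs = sdHub,
         meanActivationSDOthers = sdOther,
         hubOccupancy = mean(result$sequence@labels == .HUB),
         topDestination = as.list(topDestination(result$chain)))
}
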