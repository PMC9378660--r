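#' @include reliability.R
NULL

## companion-file naming convention around a main "<stem>.tsv"
.companionPaths <- function(path) {
    stem <- sub("\\.[^.]*$", "", path)
    list(networks = paste0(stem, "_networks.tsv"),
         censor = paste0(stem, "_censor.txt"),
         sessions = paste0(stem, "_sessions.txt"),
         labels = paste0(stem, "_labels.txt"),
         transitions = paste0(stem, "_transitions.tsv"))
}

.fmt <- function(x) formatC(x, format = "g", digits = 17)

#' Write / read a parcellated recording as TSV
#'
#' The main file holds the frames-by-parcels matrix with parcel IDs as the
#' header row, at full double precision. Companion files are discovered (or
#' written) by naming convention around the main path \code{<stem>.tsv}:
#' \code{<stem>_networks.tsv} (parcel, network), \code{<stem>_censor.txt}
#' (one 0/1 per frame), \code{<stem>_sessions.txt} (session id per frame),
#' \code{<stem>_labels.txt} (ground-truth state per frame) and
#' \code{<stem>_transitions.tsv} (ground-truth transition matrix). Missing
#' companions fall back to defaults (all parcels unassigned, no censoring,
#' one session).
#'
#' @param pts a \linkS4class{ParcellatedTimeSeries}.
#' @param path main TSV path.
#' @return \code{writeTimeseriesTSV}: invisibly, the main path;
#'   \code{readTimeseriesTSV}: a \linkS4class{ParcellatedTimeSeries}.
#' @export
writeTimeseriesTSV <- function(pts, path) {
    stopifnot(is(pts, "ParcellatedTimeSeries"))
    x <- tsMatrix(pts)
    cp <- .companionPaths(path)
    out <- rbind(colnames(x), apply(x, 2L, .fmt))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(
        data.frame(parcel = colnames(x), network = unname(parcelNetworks(pts))),
        cp$networks, sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(as.character(as.integer(censorMask(pts))), cp$censor)
    writeLines(as.character(sessionIds(pts)), cp$sessions)
    if (!is.null(trueLabels(pts)))
        writeLines(trueLabels(pts), cp$labels)
    P <- trueTransitionMatrix(pts)
    if (!is.null(P)) {
        tp <- rbind(c("state", colnames(P)),
                    cbind(rownames(P), apply(P, 2L, .fmt)))
        utils::write.table(tp, cp$transitions, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
    }
    invisible(path)
}

#' @rdname writeTimeseriesTSV
#' @export
readTimeseriesTSV <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    nf <- utils::count.fields(path, sep = "\t", quote = "")
    if (!length(nf)) stop("empty file: ", path)
    if (length(unique(nf)) != 1L)
        stop(sprintf("ragged TSV: line %d has %d fields, expected %d",
                     which(nf != nf[1L])[1L], nf[nf != nf[1L]][1L], nf[1L]))
    raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             colClasses = "character")
    if (nrow(raw) == 0L) stop("no data rows in ", path)
    x <- suppressWarnings(matrix(as.numeric(as.matrix(raw)), nrow(raw),
                                 dimnames = list(NULL, colnames(raw))))
    if (anyNA(x)) {
        bad <- which(is.na(x), arr.ind = TRUE)[1L, ]
        stop(sprintf("non-numeric cell at line %d, column %d",
                     bad[1L] + 1L, bad[2L]))
    }
    cp <- .companionPaths(path)
    networks <- rep(NA_character_, ncol(x))
    if (file.exists(cp$networks)) {
        nw <- utils::read.delim(cp$networks, colClasses = "character")
        networks <- nw$network[match(colnames(x), nw$parcel)]
    }
    censor <- if (file.exists(cp$censor))
        as.logical(as.integer(readLines(cp$censor))) else rep(FALSE, nrow(x))
    sessions <- if (file.exists(cp$sessions))
        readLines(cp$sessions) else rep("1", nrow(x))
    labels <- if (file.exists(cp$labels)) readLines(cp$labels) else NULL
    pts <- ParcellatedTimeSeries(x, parcelNetworks = networks,
                                 censorMask = censor, sessions = sessions,
                                 stateLabels = labels)
    if (file.exists(cp$transitions)) {
        tp <- utils::read.delim(cp$transitions, check.names = FALSE)
        P <- as.matrix(tp[, -1L, drop = FALSE])
        rownames(P) <- tp[[1L]]
        S4Vectors::metadata(pts)$trueTransitionMatrix <- P
    }
    pts
}

#' Export / import an annotated shape graph as JSON
#'
#' The JSON document holds the full graph (node member frames, edges as id
#' pairs, per-frame embedding, configuration) plus, when given, the node
#' annotation (pie-chart proportions, mean activations, activation SD,
#' dominant labels, hub flags) and provenance metadata; numbers are written
#' at full precision so \code{readGraphJSON} reproduces the objects exactly.
#'
#' @param graph a \linkS4class{ShapeGraph}.
#' @param path output path.
#' @param annotation optional \linkS4class{NodeAnnotation}.
#' @param hubFlags optional logical per-node hub flags.
#' @return \code{exportGraphJSON}: invisibly, the path;
#'   \code{readGraphJSON}: list with \code{graph}, \code{annotation},
#'   \code{hubFlags} (NULL where absent).
#' @export
exportGraphJSON <- function(graph, path, annotation = NULL, hubFlags = NULL) {
    stopifnot(is(graph, "ShapeGraph"))
    A <- adjacency(graph)
    e <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
    cfg <- graph@config
    doc <- list(
        format = "brainmapper-shapegraph",
        version = 1L,
        config = list(d = cfg@d, k = cfg@k, R = cfg@R, G = cfg@G,
                      metric = cfg@metric, histBins = cfg@histBins,
                      seed = cfg@seed),
        nFrames = graph@nFrames,
        nodes = lapply(seq_len(numNodes(graph)), function(v) {
            nd <- list(id = v, members = graph@nodes[[v]],
                       size = length(graph@nodes[[v]]),
                       bin = graph@binOfNode[v])
            if (!is.null(annotation)) {
                nd$proportions <- as.list(annotation@proportions[v, ])
                nd$meanActivation <- as.list(annotation@meanActivation[v, ])
                nd$activationSD <- annotation@activationSD[v]
                if (length(annotation@dominantNetwork))
                    nd$dominant <- annotation@dominantNetwork[v]
            }
            if (!is.null(hubFlags)) nd$hub <- hubFlags[v]
            nd
        }),
        edges = if (nrow(e)) lapply(seq_len(nrow(e)), function(i)
            c(e[i, 1L], e[i, 2L])) else list(),
        embedding = unname(apply(graph@embedding, 1L, as.list, simplify = FALSE)),
        metadata = list(package = "brainmapper",
                        threshold = if (!is.null(annotation))
                            annotation@threshold else NULL))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(path)
}

#' @rdname exportGraphJSON
#' @export
readGraphJSON <- function(path) {
    doc <- jsonlite::read_json(path)
    if (!identical(doc$format, "brainmapper-shapegraph"))
        stop("not a brainmapper shape-graph JSON document")
    cfg <- mapperConfig(d = doc$config$d, k = doc$config$k, R = doc$config$R,
                        G = doc$config$G, metric = doc$config$metric,
                        histBins = doc$config$histBins, seed = doc$config$seed)
    nodes <- lapply(doc$nodes, function(nd) as.integer(unlist(nd$members)))
    nn <- length(nodes)
    A <- matrix(0, nn, nn)
    for (e in doc$edges) {
        i <- e[[1L]]; j <- e[[2L]]
        A[i, j] <- 1; A[j, i] <- 1
    }
    emb <- do.call(rbind, lapply(doc$embedding, function(r) unlist(r)))
    graph <- new("ShapeGraph", nodes = nodes, adjacency = A,
                 embedding = matrix(emb, nrow = doc$nFrames),
                 binOfNode = vapply(doc$nodes, function(nd)
                     as.integer(nd$bin), integer(1)),
                 nFrames = as.integer(doc$nFrames), config = cfg)
    annotation <- NULL
    if (!is.null(doc$nodes[[1L]]$proportions)) {
        nets <- names(doc$nodes[[1L]]$proportions)
        getm <- function(field) do.call(rbind, lapply(doc$nodes, function(nd)
            unlist(nd[[field]])))
        prop <- getm("proportions"); colnames(prop) <- nets
        ma <- getm("meanActivation"); colnames(ma) <- nets
        dom <- vapply(doc$nodes, function(nd)
            if (is.null(nd$dominant)) NA_character_ else nd$dominant,
            character(1))
        annotation <- new("NodeAnnotation", proportions = prop,
            meanActivation = ma,
            activationSD = vapply(doc$nodes, function(nd)
                nd$activationSD, numeric(1)),
            dominantNetwork = if (anyNA(dom)) character(0) else dom,
            threshold = doc$metadata$threshold)
    }
    hubFlags <- if (!is.null(doc$nodes[[1L]]$hub))
        vapply(doc$nodes, function(nd) isTRUE(nd$hub), logical(1)) else NULL
    list(graph = graph, annotation = annotation, hubFlags = hubFlags)
}

#' Export a shape graph as GraphML
#'
#' Writes the graph with per-node attributes (size, degree, closeness
#' centrality, hub flag, dominant label when available) for use in external
#' viewers (Gephi, Cytoscape, yEd).
#'
#' @param graph a \linkS4class{ShapeGraph}.
#' @param path output path.
#' @param annotation optional \linkS4class{NodeAnnotation} whose dominant
#'   labels are attached.
#' @param hubFlags optional logical hub flags.
#' @return invisibly, the path.
#' @export
exportGraphML <- function(graph, path, annotation = NULL, hubFlags = NULL) {
    stopifnot(is(graph, "ShapeGraph"))
    g <- igraph::graph_from_adjacency_matrix(adjacency(graph),
                                             mode = "undirected")
    igraph::V(g)$size <- lengths(graph@nodes)
    igraph::V(g)$degree <- nodeDegree(graph)
    igraph::V(g)$closeness <- closenessCentrality(graph)
    if (!is.null(hubFlags)) igraph::V(g)$hub <- as.integer(hubFlags)
    if (!is.null(annotation) && length(annotation@dominantNetwork))
        igraph::V(g)$dominant <- annotation@dominantNetwork
    igraph::write_graph(g, path, format = "graphml")
    invisible(path)
}
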