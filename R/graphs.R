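#' @importFrom igraph graph_from_data_frame make_empty_graph V E degree
NULL

# build a CoocGraph from a canonical pair frame (frequency optional -> 1)
.graphFromPairFrame <- function(df) {
    if (!"frequency" %in% names(df)) df$frequency <- rep(1L, nrow(df))
    cp <- .canonicalizePairs(as.character(df$a), as.character(df$b))
    df <- data.frame(a = cp$a, b = cp$b,
        frequency = as.integer(df$frequency), stringsAsFactors = FALSE)
    df <- df[!duplicated(.pairKey(df$a, df$b)), , drop = FALSE]
    o <- .radixOrder(df$a, df$b)                   # deterministic edge order
    df <- df[o, , drop = FALSE]
    verts <- .radixSort(unique(c(df$a, df$b)))     # deterministic vertex order
    g <- igraph::graph_from_data_frame(df, directed = FALSE,
        vertices = data.frame(name = verts, stringsAsFactors = FALSE))
    new("CoocGraph", graph = g)
}

#' Build an undirected co-occurrence graph
#'
#' Nodes are descriptors, edges are pairs with their frequency as an edge
#' attribute.  Vertices and edges are inserted in bytewise order so the
#' graph (and every export of it) is identical across runs.
#'
#' @param x A [FrequencyTable-class], [Slice-class],
#'   [LevelDistribution-class], or a data.frame with columns `a`, `b` and
#'   optionally `frequency`.
#' @param ... Unused.
#' @return A [CoocGraph-class].
#' @examples
#' g <- toGraph(FrequencyTable(data.frame(a = "A", b = "B", frequency = 2L)))
#' nodeCount(g)
#' @rdname toGraph
#' @export
setMethod("toGraph", "FrequencyTable",
    function(x, ...) .graphFromPairFrame(x@pairs))

#' @rdname toGraph
#' @export
setMethod("toGraph", "Slice", function(x, ...) .graphFromPairFrame(x@pairs))

#' @rdname toGraph
#' @export
setMethod("toGraph", "LevelDistribution", function(x, ...) {
    df <- x@pairs
    df$frequency <- rep(x@level, nrow(df))
    .graphFromPairFrame(df)
})

#' @rdname toGraph
#' @export
setMethod("toGraph", "data.frame", function(x, ...) .graphFromPairFrame(x))

#' @rdname CoocGraph-class
#' @param x,object A [CoocGraph-class].
#' @export
graphNodes <- function(x) {
    stopifnot(is(x, "CoocGraph"))
    igraph::V(x@graph)$name
}

#' @rdname CoocGraph-class
#' @return `graphEdges()`: canonical pair frame (`a`, `b`, `frequency`)
#'   sorted lexicographically.
#' @export
graphEdges <- function(x) {
    stopifnot(is(x, "CoocGraph"))
    g <- x@graph
    if (igraph::ecount(g) == 0L) return(.emptyPairFrame())
    el <- igraph::as_edgelist(g, names = TRUE)
    cp <- .canonicalizePairs(el[, 1L], el[, 2L])
    df <- data.frame(a = cp$a, b = cp$b,
        frequency = as.integer(igraph::E(g)$frequency),
        stringsAsFactors = FALSE)
    df <- df[.radixOrder(df$a, df$b), , drop = FALSE]
    rownames(df) <- NULL
    df
}

#' @rdname CoocGraph-class
#' @export
nodeCount <- function(x) {
    stopifnot(is(x, "CoocGraph")); igraph::vcount(x@graph)
}

#' @rdname CoocGraph-class
#' @export
edgeCount <- function(x) {
    stopifnot(is(x, "CoocGraph")); igraph::ecount(x@graph)
}

#' @rdname CoocGraph-class
#' @export
asIgraph <- function(x) { stopifnot(is(x, "CoocGraph")); x@graph }

setMethod("show", "CoocGraph", function(object) {
    cat("CoocGraph: ", igraph::vcount(object@graph), " node(s), ",
        igraph::ecount(object@graph), " edge(s)\n", sep = "")
})

#' Find wheel-shaped (star) motifs
#'
#' A wheel is a hub descriptor together with its neighbours as the rim:
#' the star subnetworks that stand out in high-frequency slices of
#' literature co-occurrence graphs.  Rim-rim edges are not required — the
#' motif is defined by the hub's adjacency alone — and a node may be one
#' wheel's center and another wheel's rim member (the wheel-wheel case).
#'
#' @param graph A [CoocGraph-class].
#' @param minRim Minimum rim size (hub degree), integer >= 2.  Defaults to
#'   5, the smallest wheel size worth reporting in practice.
#' @return A [S4Vectors::DataFrame] with columns `center` (character),
#'   `size` (integer) and `rim` (a [IRanges::CharacterList]), sorted by
#'   descending size then center.
#' @export
findWheels <- function(graph, minRim = 5L) {
    stopifnot(is(graph, "CoocGraph"))
    minRim <- .assertCount(minRim, "minRim", min = 2L)
    g <- graph@graph
    deg <- igraph::degree(g)
    hubs <- names(deg)[deg >= minRim]
    rims <- lapply(hubs, function(h)
        .radixSort(names(igraph::neighbors(g, h))))
    sizes <- lengths(rims)
    o <- .radixOrder(-sizes, hubs)
    S4Vectors::DataFrame(center = hubs[o], size = as.integer(sizes[o]),
        rim = IRanges::CharacterList(rims[o]))
}

#' Hub-intersection subnetwork of two wheel centers
#'
#' Given two hub nodes, returns the subgraph on the two centers plus their
#' common neighbours, keeping only edges incident to a center (including
#' the center-center edge when present).  This is the "third network dug
#' out of two interconnected wheels": e.g. two wheels sharing five rim
#' nodes yield a 7-node subnetwork in which each shared node links to both
#' centers.
#'
#' @param graph A [CoocGraph-class].
#' @param centerA,centerB Node names; both must exist in the graph.
#' @return A [CoocGraph-class] containing both centers (even when the
#'   common neighbourhood is empty).
#' @export
hubIntersection <- function(graph, centerA, centerB) {
    stopifnot(is(graph, "CoocGraph"))
    g <- graph@graph
    nodes <- igraph::V(g)$name
    for (ctr in c(centerA, centerB))
        if (!ctr %in% nodes)
            stop("center '", ctr, "' is not a node of the graph",
                call. = FALSE)
    if (centerA == centerB)
        stop("centers must be distinct", call. = FALSE)
    common <- intersect(names(igraph::neighbors(g, centerA)),
                        names(igraph::neighbors(g, centerB)))
    keepNodes <- c(centerA, centerB, common)
    ed <- graphEdges(graph)
    centers <- c(centerA, centerB)
    keep <- (ed$a %in% keepNodes & ed$b %in% keepNodes) &
        (ed$a %in% centers | ed$b %in% centers)
    sub <- .graphFromPairFrame(ed[keep, , drop = FALSE])
    # centers must appear even if isolated
    missing <- setdiff(centers, graphNodes(sub))
    if (length(missing)) {
        g2 <- igraph::add_vertices(sub@graph, length(missing),
            name = missing)
        perm <- match(igraph::V(g2)$name,
            .radixSort(igraph::V(g2)$name))
        sub <- new("CoocGraph",
            graph = igraph::permute(g2, perm))
    }
    sub
}

#' Export a co-occurrence graph for Cytoscape
#'
#' Formats:
#' \describe{
#'   \item{`sif`}{Cytoscape simple-interaction rows
#'     `nodeA<TAB>cooc<TAB>nodeB`, one per edge, canonical pair order.}
#'   \item{`graphml`}{GraphML with `frequency` as an edge attribute.}
#'   \item{`edge_tsv`}{The [writeFrequencyTable()] TSV layout; reimport via
#'     [readFrequencyTable()] + [toGraph()] reproduces the graph.}
#' }
#' Row order is deterministic in every format.
#'
#' @param graph A [CoocGraph-class].
#' @param format One of `"sif"`, `"graphml"`, `"edge_tsv"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
exportGraph <- function(graph, format = c("sif", "graphml", "edge_tsv"),
                        path) {
    stopifnot(is(graph, "CoocGraph"))
    format <- match.arg(format)
    ed <- graphEdges(graph)
    if (format == "sif") {
        writeLines(if (nrow(ed)) paste(ed$a, "cooc", ed$b, sep = "\t")
            else character(0), path, useBytes = TRUE)
    } else if (format == "edge_tsv") {
        writeFrequencyTable(FrequencyTable(ed, label = "graph"), path)
    } else {
        igraph::write_graph(graph@graph, path, format = "graphml")
    }
    invisible(path)
}
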