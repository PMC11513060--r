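#' Construct a molecular graph from an edge list
#'
#' @param edges a two-column matrix or data.frame of vertex labels, or a
#'   character vector of even length read pairwise.
#' @return a validated [MolecularGraph-class].
#' @examples
#' molecularGraph(rbind(c("a", "b"), c("b", "c"), c("c", "a")))  # triangle
#' @export
molecularGraph <- function(edges) {
    if (is.data.frame(edges)) edges <- as.matrix(edges)
    if (is.character(edges) && is.null(dim(edges))) {
        if (length(edges) %% 2L != 0L)
            stop("edge vector must have even length")
        edges <- matrix(edges, ncol = 2L, byrow = TRUE)
    }
    if (!is.matrix(edges) || ncol(edges) != 2L)
        stop("edges must be a two-column matrix")
    storage.mode(edges) <- "character"
    ## canonical storage: smaller label first, rows sorted
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
    vertices <- sort(unique(as.vector(edges)))
    new("MolecularGraph", vertices = vertices, edges = edges)
}

#' @rdname graph-accessors
#' @export
setMethod("numVertices", "MolecularGraph", function(x) length(x@vertices))

#' @rdname graph-accessors
#' @export
setMethod("numEdges", "MolecularGraph", function(x) nrow(x@edges))

#' @rdname graph-accessors
#' @export
setMethod("vertexLabels", "MolecularGraph", function(x) x@vertices)

#' @rdname graph-accessors
#' @export
setMethod("edgeMatrix", "MolecularGraph", function(x) x@edges)

#' @export
setMethod("vertexDegrees", "MolecularGraph", function(x) {
    d <- table(factor(as.vector(x@edges), levels = x@vertices))
    stats::setNames(as.integer(d), x@vertices)
})

setMethod("show", "MolecularGraph", function(object) {
    cat(sprintf("MolecularGraph with %d vertices and %d edges\n",
                numVertices(object), numEdges(object)))
    d <- vertexDegrees(object)
    tab <- table(d)
    cat("degree multiset:",
        paste(sprintf("%s:%d", names(tab), as.integer(tab)), collapse = " "),
        "\n")
})

## temperatures of all vertices as reduced rationals (internal)
.vertexTemperatureTable <- function(graph) {
    n <- numVertices(graph)
    d <- vertexDegrees(graph)
    r <- .reduceRational(d, n - d)
    data.frame(vertex = names(d), num = r$num, den = r$den,
               value = r$num / r$den, row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Vertex temperature
#'
#' The temperature of a vertex \eqn{b} of an \eqn{n}-vertex graph is
#' \eqn{T_b = d_b / (n - d_b)}, a local degree-and-order quantity.  For a
#' simple connected graph of order at least 2 it is always finite and
#' positive; it exceeds 1 exactly when \eqn{2 d_b > n}.
#'
#' @param graph a [MolecularGraph-class].
#' @param vertex a vertex label present in the graph.
#' @param rational if TRUE, return the exact value as an integer vector
#'   \code{c(num =, den =)} in lowest terms instead of a double.
#' @return numeric temperature (or reduced integer pair).
#' @examples
#' vertexTemperature(cycleGraph(6), "v1")            # 2/(6-2) = 0.5
#' vertexTemperature(pathGraph(3), "v2")             # centre: 2/(3-2) = 2
#' vertexTemperature(pathGraph(3), "v2", rational = TRUE)
#' @export
vertexTemperature <- function(graph, vertex, rational = FALSE) {
    stopifnot(is(graph, "MolecularGraph"))
    if (length(vertex) != 1L || !(vertex %in% graph@vertices))
        stop(sprintf("unknown vertex label: '%s'", vertex))
    tab <- .vertexTemperatureTable(graph)
    i <- match(vertex, tab$vertex)
    if (rational) c(num = tab$num[i], den = tab$den[i]) else tab$value[i]
}

## build a TemperatureEdgeClasses from parallel rational vectors (internal);
## canonicalises pair order and aggregates duplicate keys
.makeEdgeClasses <- function(tuNum, tuDen, tvNum, tvDen, count) {
    a <- .reduceRational(tuNum, tuDen)
    b <- .reduceRational(tvNum, tvDen)
    swap <- a$num / a$den > b$num / b$den
    cl <- data.frame(
        tuNum = ifelse(swap, b$num, a$num), tuDen = ifelse(swap, b$den, a$den),
        tvNum = ifelse(swap, a$num, b$num), tvDen = ifelse(swap, a$den, b$den),
        count = as.integer(count))
    key <- paste(cl$tuNum, cl$tuDen, cl$tvNum, cl$tvDen, sep = "/")
    agg <- rowsum(cl$count, key)
    first <- cl[match(rownames(agg), key), c("tuNum", "tuDen", "tvNum", "tvDen")]
    out <- cbind(first, count = as.integer(agg[, 1L]))
    out <- out[order(out$tuNum / out$tuDen, out$tvNum / out$tvDen), ]
    rownames(out) <- NULL
    new("TemperatureEdgeClasses", classes = out)
}

#' @export
setMethod("temperatureEdgeClasses", "MolecularGraph", function(x) {
    tab <- .vertexTemperatureTable(x)
    i <- match(x@edges[, 1L], tab$vertex)
    j <- match(x@edges[, 2L], tab$vertex)
    .makeEdgeClasses(tab$num[i], tab$den[i], tab$num[j], tab$den[j],
                     rep.int(1L, nrow(x@edges)))
})

#' @export
setMethod("edgeClasses", "TemperatureEdgeClasses", function(x) {
    cl <- x@classes
    cl$tu <- cl$tuNum / cl$tuDen
    cl$tv <- cl$tvNum / cl$tvDen
    cl
})

setMethod("show", "TemperatureEdgeClasses", function(object) {
    cl <- object@classes
    cat(sprintf("TemperatureEdgeClasses: %d class(es), %d edge(s)\n",
                nrow(cl), sum(cl$count)))
    for (i in seq_len(nrow(cl)))
        cat(sprintf("  (%d/%d, %d/%d) x %d\n", cl$tuNum[i], cl$tuDen[i],
                    cl$tvNum[i], cl$tvDen[i], cl$count[i]))
})
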