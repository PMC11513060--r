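#' Read a molecular graph from an edge-list file
#'
#' The format is one edge per line as two whitespace-separated vertex
#' labels; \code{#} starts a comment and blank lines are ignored.  Duplicate
#' edges (in either order), self-loops and disconnected graphs are errors.
#'
#' @param path file path.
#' @return a [MolecularGraph-class].
#' @export
readEdgeList <- function(path) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    lines <- readLines(path)
    stripped <- sub("#.*$", "", lines)
    keep <- which(nzchar(trimws(stripped)))
    if (!length(keep)) stop("edge-list file contains no edges")
    parts <- strsplit(trimws(stripped[keep]), "[[:space:]]+")
    bad <- which(lengths(parts) != 2L)
    if (length(bad))
        stop(sprintf("parse error at line %d: expected two vertex labels",
                     keep[bad[1L]]))
    edges <- do.call(rbind, parts)
    key <- paste(pmin(edges[, 1L], edges[, 2L]),
                 pmax(edges[, 1L], edges[, 2L]))
    if (any(edges[, 1L] == edges[, 2L])) {
        i <- which(edges[, 1L] == edges[, 2L])[1L]
        stop(sprintf("self-loop at line %d", keep[i]))
    }
    if (anyDuplicated(key)) {
        i <- which(duplicated(key))[1L]
        stop(sprintf("duplicate edge at line %d", keep[i]))
    }
    ig <- igraph::graph_from_edgelist(edges, directed = FALSE)
    ncomp <- igraph::components(ig)$no
    if (ncomp != 1L)
        stop(sprintf("graph is disconnected: %d components", ncomp))
    molecularGraph(edges)
}

#' Write a molecular graph as an edge-list file
#'
#' @param graph a [MolecularGraph-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeEdgeList <- function(graph, path) {
    stopifnot(is(graph, "MolecularGraph"))
    e <- edgeMatrix(graph)
    writeLines(paste(e[, 1L], e[, 2L]), path)
    invisible(path)
}

#' Canned graph families
#'
#' Small named families used throughout the tests and examples: the path
#' \eqn{P_n}, cycle \eqn{C_n}, complete graph \eqn{K_n} and star
#' \eqn{S_n} (one centre, n - 1 leaves).  Vertices are labelled
#' \code{"v1"..."vn"} (\code{"c"} plus leaves for the star).
#'
#' @param n graph order (>= 2 for paths/complete, >= 3 for cycles/stars).
#' @return a [MolecularGraph-class].
#' @rdname canned-graphs
#' @export
pathGraph <- function(n) {
    stopifnot(n >= 2)
    v <- paste0("v", seq_len(n))
    molecularGraph(cbind(v[-n], v[-1L]))
}

#' @rdname canned-graphs
#' @export
cycleGraph <- function(n) {
    stopifnot(n >= 3)
    v <- paste0("v", seq_len(n))
    molecularGraph(cbind(v, c(v[-1L], v[1L])))
}

#' @rdname canned-graphs
#' @export
completeGraph <- function(n) {
    stopifnot(n >= 2)
    v <- paste0("v", seq_len(n))
    molecularGraph(t(utils::combn(v, 2L)))
}

#' @rdname canned-graphs
#' @export
starGraph <- function(n) {
    stopifnot(n >= 3)
    leaves <- paste0("v", seq_len(n - 1L))
    molecularGraph(cbind("c", leaves))
}

#' Deterministic fixture graphs for oracle testing
#'
#' Produces a seeded list of small simple connected graphs: the canned
#' families (paths, cycles, complete graphs, stars) followed by random
#' connected graphs built as a random spanning tree plus extra random
#' non-tree edges.  The same seed always yields the identical list.
#'
#' @param seed integer RNG seed.
#' @param count total number of graphs.
#' @param maxOrder maximum graph order (>= 3).
#' @return list of [MolecularGraph-class] objects.
#' @export
fixtureGraphs <- function(seed, count = 20L, maxOrder = 12L) {
    stopifnot(maxOrder >= 3L, count >= 1L)
    canned <- list(pathGraph(3L), pathGraph(min(6L, maxOrder)),
                   cycleGraph(min(6L, maxOrder)),
                   completeGraph(min(4L, maxOrder)),
                   starGraph(min(5L, maxOrder)))
    canned <- canned[seq_len(min(count, length(canned)))]
    nRandom <- count - length(canned)
    if (nRandom <= 0L) return(canned)
    random <- withr::with_seed(seed,
        lapply(seq_len(nRandom), function(i) .randomConnectedGraph(maxOrder)))
    c(canned, random)
}

## random spanning tree (each vertex attaches to an earlier one) plus a
## random number of extra edges
.randomConnectedGraph <- function(maxOrder) {
    n <- sample(3:maxOrder, 1L)
    v <- paste0("v", seq_len(n))
    tree <- cbind(v[vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L)],
                  v[2:n])
    all <- t(utils::combn(v, 2L))
    key <- paste(pmin(all[, 1L], all[, 2L]), pmax(all[, 1L], all[, 2L]))
    treeKey <- paste(pmin(tree[, 1L], tree[, 2L]),
                     pmax(tree[, 1L], tree[, 2L]))
    spare <- all[!(key %in% treeKey), , drop = FALSE]
    nExtra <- sample.int(nrow(spare) + 1L, 1L) - 1L
    extra <- spare[sample.int(nrow(spare), min(nExtra, nrow(spare))), ,
                   drop = FALSE]
    molecularGraph(rbind(tree, extra))
}
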