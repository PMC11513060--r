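## Carbon nanocones CNC_k[n]: a k-gonal core surrounded by n layers of
## hexagons.  Layer j (j = 0..n) is a cycle of k(2j+1) vertices; spokes join
## each odd-position vertex of layer j to the vertex directly inward.

.checkNanoconeSpec <- function(k, n) {
    if (length(k) != 1L || k != as.integer(k) || k < 3L)
        stop("k must be an integer >= 3 (sides of the central cycle)")
    if (length(n) != 1L || n != as.integer(n) || n < 1L)
        stop("n must be an integer >= 1 (hexagon layers)")
    c(k = as.integer(k), n = as.integer(n))
}

## sum_{i=1}^{n}(3i-1) = 3n(n+1)/2 - n, the third edge-class count divided by k
.sum3im1 <- function(n) (3L * n * (n + 1L)) %/% 2L - n

#' Vertex and edge counts of the carbon nanocone CNC_k[n]
#'
#' The nanocone has \eqn{k \sum_{i=1}^{n+1} (2i-1) = k(n+1)^2} vertices and
#' \eqn{k(1 + 2n + \sum_{i=1}^{n} (3i-1))} edges.
#'
#' @param k integer >= 3, length of the central cycle.
#' @param n integer >= 1, number of hexagon layers.
#' @return named integer vector \code{c(vertices =, edges =)}.
#' @examples
#' nanoconeCounts(3, 1)  # 12 vertices, 15 edges
#' @export
nanoconeCounts <- function(k, n) {
    s <- .checkNanoconeSpec(k, n)
    k <- s["k"]; n <- s["n"]
    c(vertices = unname(k * (n + 1L) * (n + 1L)),
      edges = unname(k * (1L + 2L * n + .sum3im1(n))))
}

#' Build the carbon nanocone CNC_k[n] as an explicit molecular graph
#'
#' Layered construction with deterministic vertex labels \code{"LjSsPp"}:
#' layer \code{j = 0..n} is a single cycle through the slots
#' (segment \code{s = 0..k-1}, position \code{p = 0..2j}), and every
#' odd-position vertex of layer \code{j >= 1} is joined to the vertex at
#' position \code{p - 1} of layer \code{j - 1} in the same segment.  The
#' result matches [nanoconeCounts()] and reproduces the temperature edge
#' partition of [nanoconeEdgePartition()].
#'
#' @inheritParams nanoconeCounts
#' @return a [MolecularGraph-class].
#' @examples
#' g <- buildNanocone(3, 1)
#' table(vertexDegrees(g))  # 6 vertices of degree 2, 6 of degree 3
#' @export
buildNanocone <- function(k, n) {
    s <- .checkNanoconeSpec(k, n)
    k <- s["k"]; n <- s["n"]
    lab <- function(j, s, p) sprintf("L%dS%dP%d", j, s, p)
    edges <- vector("list", n + 1L)
    for (j in 0:n) {
        ## ring of layer j: all slots (s, p), consecutive around the cone
        slots <- do.call(rbind,
            lapply(0:(k - 1L), function(s)
                cbind(j, s, 0:(2L * j))))
        ring <- lab(slots[, 1L], slots[, 2L], slots[, 3L])
        nxt <- c(ring[-1L], ring[1L])
        layerEdges <- cbind(ring, nxt)
        if (j >= 1L) {
            ## spokes: odd positions join inward to position p - 1
            odd <- slots[slots[, 3L] %% 2L == 1L, , drop = FALSE]
            spokes <- cbind(lab(odd[, 1L], odd[, 2L], odd[, 3L]),
                            lab(odd[, 1L] - 1L, odd[, 2L], odd[, 3L] - 1L))
            layerEdges <- rbind(layerEdges, spokes)
        }
        edges[[j + 1L]] <- layerEdges
    }
    molecularGraph(do.call(rbind, edges))
}

#' Temperature edge partition of the carbon nanocone CNC_k[n]
#'
#' With \eqn{V = k(n+1)^2} vertices, the boundary degree-2 vertices have
#' temperature \eqn{T_2 = 2/(V-2)} and the interior degree-3 vertices
#' \eqn{T_3 = 3/(V-3)}.  The edge set splits into exactly three classes:
#' \eqn{(T_2, T_2)} with count \eqn{k}, \eqn{(T_2, T_3)} with count
#' \eqn{2kn}, and \eqn{(T_3, T_3)} with count
#' \eqn{k \sum_{i=1}^{n} (3i-1)}.
#'
#' @inheritParams nanoconeCounts
#' @return a [TemperatureEdgeClasses-class] with three classes.
#' @examples
#' nanoconeEdgePartition(3, 1)  # (1/5,1/5) x 3, (1/5,1/3) x 6, (1/3,1/3) x 6
#' @export
nanoconeEdgePartition <- function(k, n) {
    s <- .checkNanoconeSpec(k, n)
    k <- s["k"]; n <- s["n"]
    V <- k * (n + 1L) * (n + 1L)
    .makeEdgeClasses(
        tuNum = c(2L, 2L, 3L), tuDen = c(V - 2L, V - 2L, V - 3L),
        tvNum = c(2L, 3L, 3L), tvDen = c(V - 2L, V - 3L, V - 3L),
        count = c(k, 2L * k * n, k * .sum3im1(n)))
}

#' Closed-form temperature index of the carbon nanocone CNC_k[n]
#'
#' Evaluates an index as the three-term sum over the nanocone's temperature
#' edge partition, which is the algebraic content of the closed-form
#' expressions for these structures.  It agrees with edge-by-edge evaluation
#' on [buildNanocone()] to numerical round-off.
#'
#' @inheritParams nanoconeCounts
#' @param spec an [IndexSpec-class].
#' @return a single numeric index value.
#' @examples
#' nanoconeIndex(3, 1, indexSpec("FT"))   # 2.48 at 2 decimals
#' nanoconeIndex(6, 2, indexSpec("HT"))   # 1363.40 at 2 decimals
#' @export
nanoconeIndex <- function(k, n, spec) {
    evaluateIndex(nanoconeEdgePartition(k, n), spec)
}

## round half away from zero, the convention of the printed index tables
.round2 <- function(x, digits = 2L) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Table of temperature indices over a range of nanocones
#'
#' One row per nanocone CNC_k[n] over the requested ranges, one column per
#' index, mirroring the layout of the published index tables.
#'
#' @param kRange,nRange integer vectors of k and n values.
#' @param indices character vector of index family names (named indices
#'   only); defaults to all 13.
#' @param digits decimal places for rounding (half away from zero); use
#'   \code{NA} for full precision.
#' @return data.frame with columns k, n and one per index.
#' @examples
#' nanoconeTable(3:4, 1)
#' @export
nanoconeTable <- function(kRange = 3:7, nRange = 1:2,
                          indices = .NAMED_FAMILIES, digits = 2L) {
    grid <- expand.grid(n = nRange, k = kRange)[, c("k", "n")]
    vals <- vapply(indices, function(fam)
        mapply(function(k, n) nanoconeIndex(k, n, indexSpec(fam)),
               grid$k, grid$n),
        numeric(nrow(grid)))
    vals <- matrix(vals, nrow = nrow(grid),
                   dimnames = list(NULL, indices))
    if (!is.na(digits)) vals <- .round2(vals, digits)
    cbind(grid, as.data.frame(vals))
}
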