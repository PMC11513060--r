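#' Evaluate a temperature index
#'
#' Computes \eqn{\sum \psi(T_u, T_v)} over the edges of a graph, either
#' directly edge-by-edge (for a [MolecularGraph-class]) or as the grouped sum
#' \eqn{\sum_c count_c \, \psi(T_u^{(c)}, T_v^{(c)})} over a
#' [TemperatureEdgeClasses-class] partition.  The two routes agree to
#' numerical round-off; the grouped form is what closed-form results for
#' nanocones and benzenoids expand to.
#'
#' @param x a [MolecularGraph-class] or [TemperatureEdgeClasses-class].
#' @param spec an [IndexSpec-class] (see [indexSpec()]).
#' @return a single numeric index value.
#' @examples
#' g <- cycleGraph(6)                      # benzene skeleton
#' evaluateIndex(g, indexSpec("FT"))       # 6 * ((1/2)^2 + (1/2)^2) = 3
#' @export
setGeneric("evaluateIndex", function(x, spec) standardGeneric("evaluateIndex"))

#' Number of vertices / edges
#'
#' @param x a [MolecularGraph-class].
#' @return integer count.
#' @rdname graph-accessors
#' @export
setGeneric("numVertices", function(x) standardGeneric("numVertices"))

#' @rdname graph-accessors
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname graph-accessors
#' @export
setGeneric("vertexLabels", function(x) standardGeneric("vertexLabels"))

#' @rdname graph-accessors
#' @export
setGeneric("edgeMatrix", function(x) standardGeneric("edgeMatrix"))

#' Vertex degrees of a molecular graph
#'
#' @param x a [MolecularGraph-class].
#' @return named integer vector of degrees.
#' @export
setGeneric("vertexDegrees", function(x) standardGeneric("vertexDegrees"))

#' Group edges by unordered endpoint-temperature pair
#'
#' Partitions the edge set of a graph into classes keyed by the unordered
#' pair of endpoint temperatures (kept as exact rationals).  Counts over all
#' classes sum to the number of edges.
#'
#' @param x a [MolecularGraph-class].
#' @return a [TemperatureEdgeClasses-class].
#' @examples
#' edgeClasses(temperatureEdgeClasses(cycleGraph(6)))  # one class (1/2, 1/2) x 6
#' @export
setGeneric("temperatureEdgeClasses",
    function(x) standardGeneric("temperatureEdgeClasses"))

#' Edge-class table accessor
#'
#' @param x a [TemperatureEdgeClasses-class].
#' @return data.frame with columns tuNum, tuDen, tvNum, tvDen, count and
#'   convenience numeric columns tu, tv.
#' @export
setGeneric("edgeClasses", function(x) standardGeneric("edgeClasses"))
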