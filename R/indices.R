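#' Create an index specification
#'
#' @param family one of the named indices \code{"HT1"}, \code{"HT2"},
#'   \code{"ST"}, \code{"PT"}, \code{"RPT"}, \code{"AGT"}, \code{"FT"},
#'   \code{"TSO"}, \code{"MTSO"}, \code{"HT"}, \code{"GAT"}, \code{"RRPT"},
#'   \code{"ABCT"}, or a parametric family \code{"T1_GENERAL"},
#'   \code{"T2_GENERAL"}, \code{"F_GENERAL"}.
#' @param sigma exponent, required for (and only for) the parametric
#'   families.
#' @return an [IndexSpec-class].
#' @examples
#' indexSpec("FT")
#' indexSpec("F_GENERAL", sigma = -0.1441)
#' @export
indexSpec <- function(family, sigma = NA_real_) {
    new("IndexSpec", family = family, sigma = as.numeric(sigma))
}

#' Names of the supported index families
#'
#' @return character vector of the 13 named indices followed by the 3
#'   parametric families.
#' @export
indexFamilies <- function() c(.NAMED_FAMILIES, .GENERAL_FAMILIES)

setMethod("show", "IndexSpec", function(object) {
    if (is.na(object@sigma)) cat(sprintf("IndexSpec: %s\n", object@family))
    else cat(sprintf("IndexSpec: %s (sigma = %g)\n",
                     object@family, object@sigma))
})

#' Single-edge contribution psi(T_u, T_v) of a temperature index
#'
#' Every temperature index is a sum over edges of a symmetric map
#' \eqn{\psi(T_u, T_v)} of the endpoint temperatures.  This function
#' evaluates that map for one unordered temperature pair; it is vectorised
#' over \code{tu}/\code{tv}.
#'
#' The named maps are: HT1 \eqn{(T_u+T_v)^2}; ST \eqn{(T_u+T_v)^{-1/2}};
#' HT2 \eqn{(T_u T_v)^2}; PT \eqn{(T_u T_v)^{-1/2}}; RPT
#' \eqn{(T_u T_v)^{1/2}}; AGT \eqn{(T_u+T_v)/(2\sqrt{T_u T_v})}; FT
#' \eqn{T_u^2+T_v^2}; TSO \eqn{\sqrt{T_u^2+T_v^2}}; MTSO
#' \eqn{1/\sqrt{T_u^2+T_v^2}}; HT \eqn{2/(T_u+T_v)}; GAT
#' \eqn{2\sqrt{T_u T_v}/(T_u+T_v)}; RRPT \eqn{\sqrt{(T_u-1)(T_v-1)}};
#' ABCT \eqn{\sqrt{|(T_u+T_v-2)/(T_u T_v)|}}.  The parametric families are
#' \eqn{(T_u+T_v)^\sigma}, \eqn{(T_u T_v)^\sigma} and
#' \eqn{T_u^\sigma + T_v^\sigma}.
#'
#' RRPT is defined through the principal square root of
#' \eqn{(T_u-1)(T_v-1)}; when both temperatures sit on the same side of 1
#' the radicand is nonnegative and the value is real, while a mixed-sign
#' pair (one temperature above 1, one below) has no real value and raises a
#' domain error naming the pair.
#'
#' @param spec an [IndexSpec-class].
#' @param tu,tv positive endpoint temperatures.
#' @return numeric vector of single-edge contributions.
#' @examples
#' psiValue(indexSpec("HT1"), 1/5, 1/3)   # (8/15)^2
#' psiValue(indexSpec("GAT"), 0.7, 0.7)   # 1: AM = GM for equal values
#' psiValue(indexSpec("ABCT"), 1/3, 1/3)  # sqrt(12)
#' @export
psiValue <- function(spec, tu, tv) {
    stopifnot(is(spec, "IndexSpec"))
    if (any(tu <= 0) || any(tv <= 0))
        stop("temperatures must be strictly positive")
    sig <- spec@sigma
    switch(spec@family,
        T1_GENERAL = (tu + tv)^sig,
        T2_GENERAL = (tu * tv)^sig,
        F_GENERAL  = tu^sig + tv^sig,
        HT1  = (tu + tv)^2,
        ST   = (tu + tv)^(-0.5),
        HT2  = (tu * tv)^2,
        PT   = (tu * tv)^(-0.5),
        RPT  = sqrt(tu * tv),
        AGT  = (tu + tv) / (2 * sqrt(tu * tv)),
        FT   = tu^2 + tv^2,
        TSO  = sqrt(tu^2 + tv^2),
        MTSO = 1 / sqrt(tu^2 + tv^2),
        HT   = 2 / (tu + tv),
        GAT  = 2 * sqrt(tu * tv) / (tu + tv),
        RRPT = {
            rad <- (tu - 1) * (tv - 1)
            if (any(rad < 0)) {
                i <- which(rad < 0)[1L]
                stop(sprintf(paste0(
                    "RRPT is undefined for the mixed-sign temperature pair ",
                    "(%g, %g): (T_u - 1)(T_v - 1) < 0"),
                    tu[min(i, length(tu))], tv[min(i, length(tv))]))
            }
            sqrt(rad)
        },
        ABCT = sqrt(abs((tu + tv - 2) / (tu * tv))),
        stop("unknown index family"))
}

#' @describeIn evaluateIndex grouped sum over an edge-class partition.
#' @export
setMethod("evaluateIndex", "TemperatureEdgeClasses", function(x, spec) {
    cl <- x@classes
    sum(cl$count * psiValue(spec, cl$tuNum / cl$tuDen, cl$tvNum / cl$tvDen))
})

#' @describeIn evaluateIndex ungrouped edge-by-edge sum over a graph.
#' @export
setMethod("evaluateIndex", "MolecularGraph", function(x, spec) {
    tab <- .vertexTemperatureTable(x)
    tu <- tab$value[match(x@edges[, 1L], tab$vertex)]
    tv <- tab$value[match(x@edges[, 2L], tab$vertex)]
    sum(psiValue(spec, tu, tv))
})
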