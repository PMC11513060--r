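#' @import methods
NULL

## ---- exact rational helpers (internal) --------------------------------------
## Vertex temperatures d/(n-d) involve only small integers; they are carried as
## reduced integer pairs so that edge-class keys never collide (or split) from
## floating-point noise. Reduction happens once, at construction.

.gcd1 <- function(a, b) {
    while (b != 0L) {
        r <- a %% b
        a <- b
        b <- r
    }
    a
}

.gcd <- function(a, b) mapply(.gcd1, a, b)

## reduce num/den pairs; den must be > 0
.reduceRational <- function(num, den) {
    stopifnot(all(den > 0L), all(num > 0L))
    g <- .gcd(as.integer(num), as.integer(den))
    list(num = as.integer(num %/% g), den = as.integer(den %/% g))
}

.rationalKey <- function(num, den) paste0(num, "/", den)

## ---- MolecularGraph ---------------------------------------------------------

#' MolecularGraph: a simple connected undirected graph
#'
#' The central container of the package: a labelled simple connected graph
#' with at least two vertices, as used for molecular (hydrogen-suppressed)
#' structures.  Vertex labels are opaque strings; edges are unordered pairs.
#' Because the graph is connected with order \eqn{\ge 2}, every degree
#' \eqn{d_b} satisfies \eqn{1 \le d_b \le n - 1}, so all vertex temperatures
#' \eqn{T_b = d_b/(n - d_b)} are finite and strictly positive.
#'
#' @slot vertices character vector of distinct vertex labels.
#' @slot edges two-column character matrix; one row per undirected edge,
#'   stored with the lexicographically smaller endpoint first.
#'
#' @seealso [molecularGraph()], [vertexTemperature()],
#'   [temperatureEdgeClasses()]
#' @exportClass MolecularGraph
setClass("MolecularGraph",
    representation(vertices = "character", edges = "matrix"))

setValidity("MolecularGraph", function(object) {
    v <- object@vertices
    e <- object@edges
    msgs <- character()
    if (length(v) < 2L)
        msgs <- c(msgs, "graph must have at least 2 vertices")
    if (anyDuplicated(v))
        msgs <- c(msgs, "duplicate vertex labels")
    if (!is.character(e) || ncol(e) != 2L)
        msgs <- c(msgs, "edges must be a two-column character matrix")
    else {
        if (!all(e %in% v))
            msgs <- c(msgs, "edge endpoints must be declared vertices")
        if (any(e[, 1L] == e[, 2L]))
            msgs <- c(msgs, "self-loops are not allowed")
        key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
        if (anyDuplicated(key))
            msgs <- c(msgs, "duplicate edges are not allowed")
        ig <- igraph::graph_from_edgelist(e, directed = FALSE)
        ig <- igraph::add_vertices(ig, sum(!(v %in% unique(as.vector(e)))))
        if (igraph::components(ig)$no != 1L)
            msgs <- c(msgs, "graph must be connected")
    }
    if (length(msgs)) msgs else TRUE
})

## ---- TemperatureEdgeClasses -------------------------------------------------

#' TemperatureEdgeClasses: grouped edges by unordered temperature pair
#'
#' A disjoint partition of a graph's edge set into classes keyed by the
#' unordered pair of endpoint temperatures, stored as exact rationals.  Every
#' temperature-based index is a sum over these classes of
#' \eqn{count \times \psi(T_u, T_v)}, which is how closed-form evaluation of
#' highly symmetric structures (nanocones, benzenoids) proceeds.
#'
#' @slot classes data.frame with integer columns \code{tuNum}, \code{tuDen},
#'   \code{tvNum}, \code{tvDen}, \code{count}; each row one class with
#'   \eqn{T_u \le T_v} and \code{count >= 1}.
#'
#' @seealso [temperatureEdgeClasses()], [edgeClasses()], [evaluateIndex()]
#' @exportClass TemperatureEdgeClasses
setClass("TemperatureEdgeClasses",
    representation(classes = "data.frame"))

setValidity("TemperatureEdgeClasses", function(object) {
    cl <- object@classes
    need <- c("tuNum", "tuDen", "tvNum", "tvDen", "count")
    if (!all(need %in% names(cl)))
        return(sprintf("classes must have columns %s",
                       paste(need, collapse = ", ")))
    if (nrow(cl) == 0L)
        return("at least one edge class is required")
    if (any(cl$count < 1L))
        return("class counts must be positive")
    if (any(cl$tuNum <= 0L | cl$tuDen <= 0L | cl$tvNum <= 0L | cl$tvDen <= 0L))
        return("temperatures must be positive rationals")
    tu <- cl$tuNum / cl$tuDen
    tv <- cl$tvNum / cl$tvDen
    if (any(tu > tv))
        return("classes must be canonically ordered with T_u <= T_v")
    key <- paste(cl$tuNum, cl$tuDen, cl$tvNum, cl$tvDen)
    if (anyDuplicated(key))
        return("duplicate temperature-pair classes")
    TRUE
})

## ---- IndexSpec --------------------------------------------------------------

.NAMED_FAMILIES <- c("HT1", "HT2", "ST", "PT", "RPT", "AGT", "FT",
                     "TSO", "MTSO", "HT", "GAT", "RRPT", "ABCT")
.GENERAL_FAMILIES <- c("T1_GENERAL", "T2_GENERAL", "F_GENERAL")

#' IndexSpec: identifier of a temperature-index family
#'
#' Selects one of the thirteen named temperature indices or one of the three
#' parametric families (general first temperature index
#' \eqn{\sum (T_u + T_v)^\sigma}, general second temperature index
#' \eqn{\sum (T_u T_v)^\sigma}, and the general F-temperature index
#' \eqn{\sum (T_u^\sigma + T_v^\sigma)}).  The exponent \code{sigma} is
#' required for the parametric families and must be absent (NA) otherwise.
#' \code{sigma = 0} is admitted in the parametric families and yields the
#' degenerate constants \eqn{m}, \eqn{m} and \eqn{2m} respectively
#' (\eqn{m} = edge count); the exponent optimisation excludes 0 separately.
#'
#' @slot family character, one of the family identifiers.
#' @slot sigma numeric exponent (NA for named indices).
#'
#' @seealso [indexSpec()], [psiValue()], [evaluateIndex()]
#' @exportClass IndexSpec
setClass("IndexSpec",
    representation(family = "character", sigma = "numeric"))

setValidity("IndexSpec", function(object) {
    fam <- object@family
    if (length(fam) != 1L ||
        !(fam %in% c(.NAMED_FAMILIES, .GENERAL_FAMILIES)))
        return(sprintf("unknown index family; use one of: %s",
            paste(c(.NAMED_FAMILIES, .GENERAL_FAMILIES), collapse = ", ")))
    if (fam %in% .GENERAL_FAMILIES) {
        if (length(object@sigma) != 1L || !is.finite(object@sigma))
            return("parametric families require a finite sigma")
    } else {
        if (!(length(object@sigma) == 1L && is.na(object@sigma)))
            return("named indices must not carry a sigma")
    }
    TRUE
})

## ---- ScanConfig / ScanResult ------------------------------------------------

#' ScanConfig: grid for the exponent optimisation
#'
#' Defines the symmetric-about-zero exponent grid on which the correlation
#' curve \eqn{\rho(\beta)} is evaluated.  Grid points with
#' \eqn{|\beta| \le} \code{zeroExclusion} are dropped, matching the
#' requirement that the exponent be a non-zero real.
#'
#' @slot betaMin,betaMax numeric grid bounds with betaMin < 0 < betaMax.
#' @slot step positive grid spacing.
#' @slot zeroExclusion half-width of the excluded window around zero,
#'   at least step/2.
#'
#' @seealso [scanConfig()], [rhoCurve()]
#' @exportClass ScanConfig
setClass("ScanConfig",
    representation(betaMin = "numeric", betaMax = "numeric",
                   step = "numeric", zeroExclusion = "numeric"))

setValidity("ScanConfig", function(object) {
    if (!(object@betaMin < 0 && object@betaMax > 0))
        return("grid must satisfy betaMin < 0 < betaMax")
    if (!(object@step > 0))
        return("step must be positive")
    if (object@zeroExclusion < object@step / 2)
        return("zeroExclusion must be at least step/2")
    TRUE
})

#' ScanResult: correlation curve over an exponent grid
#'
#' @slot betas numeric grid values (zero excluded).
#' @slot rhos Pearson correlation at each grid value.
#' @slot betaStar grid value maximising |rho| (ties: smallest |beta|, then
#'   most negative).
#' @slot rhoStar correlation at betaStar.
#' @slot family index family scanned.
#' @slot mode dataset mode used ("as_printed" or "derived").
#'
#' @seealso [rhoCurve()], [dominanceIntervals()]
#' @exportClass ScanResult
setClass("ScanResult",
    representation(betas = "numeric", rhos = "numeric",
                   betaStar = "numeric", rhoStar = "numeric",
                   family = "character", mode = "character"))

setValidity("ScanResult", function(object) {
    if (length(object@betas) != length(object@rhos))
        return("betas and rhos must have equal length")
    if (any(abs(object@rhos) > 1 + 1e-12))
        return("correlations must lie in [-1, 1]")
    if (!object@betaStar %in% object@betas)
        return("betaStar must be a grid value")
    if (abs(abs(object@rhoStar) - max(abs(object@rhos))) > 1e-12)
        return("|rhoStar| must equal max |rhos|")
    TRUE
})

#' RegressionFit: simple linear regression summary
#'
#' Ordinary least-squares fit of a property on a descriptor, with the
#' goodness-of-fit quantities used in structure-property modelling: the
#' Pearson correlation and the standard error of fit
#' \eqn{s = \sqrt{\sum r_i^2 / (N - 2)}}.  95\% confidence half-widths use
#' the t-distribution with N - 2 degrees of freedom.
#'
#' @slot slope,intercept OLS estimates.
#' @slot rho Pearson correlation between x and y.
#' @slot sFit standard error of fit.
#' @slot nObs number of observations (>= 3).
#' @slot ci95Slope,ci95Intercept 95\% confidence half-widths.
#'
#' @seealso [fitLine()]
#' @exportClass RegressionFit
setClass("RegressionFit",
    representation(slope = "numeric", intercept = "numeric",
                   rho = "numeric", sFit = "numeric", nObs = "integer",
                   ci95Slope = "numeric", ci95Intercept = "numeric"))

setValidity("RegressionFit", function(object) {
    if (object@sFit < 0) return("sFit must be nonnegative")
    if (object@nObs < 3L) return("at least 3 observations are required")
    if (object@slope != 0 && sign(object@slope) != sign(object@rho))
        return("slope and correlation must agree in sign")
    TRUE
})
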