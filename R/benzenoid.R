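## Benzenoid systems: fused-hexagon planar graphs with all vertex degrees 2
## or 3.  Their edge set is determined by three global counts -- vertices v,
## hexagons p, inlets k (fissures + bays + coves + fjords) -- which is what
## makes closed-form index evaluation possible without drawing the molecule.

#' Degree-pair edge counts of a benzenoid system
#'
#' For a benzenoid system with \code{v} vertices, \code{p} hexagons and
#' \code{k} inlets, the numbers of edges whose endpoint degrees are (2,2),
#' (2,3) and (3,3) are \eqn{n_{22} = v - 2p - k + 2}, \eqn{n_{23} = 2k} and
#' \eqn{n_{33} = 3p - k - 3}.  They sum to the edge count
#' \eqn{m = v + p - 1}.
#'
#' @param v vertex count.
#' @param p hexagon count.
#' @param k inlet count.
#' @return named integer vector \code{c(n22 =, n23 =, n33 =)}.
#' @examples
#' benzenoidEdgeCounts(14, 3, 3)  # phenanthrene: 7, 6, 3
#' @export
benzenoidEdgeCounts <- function(v, p, k) {
    stopifnot(length(v) == 1L, length(p) == 1L, length(k) == 1L,
              v == as.integer(v), p == as.integer(p), k == as.integer(k))
    n22 <- v - 2L * p - k + 2L
    n23 <- 2L * k
    n33 <- 3L * p - k - 3L
    if (k < 0L || n22 < 0L || n33 < 0L)
        stop(sprintf(
            "not a valid benzenoid descriptor (v = %d, p = %d, k = %d): %s",
            v, p, k, "a degree-pair edge count would be negative"))
    c(n22 = as.integer(n22), n23 = as.integer(n23), n33 = as.integer(n33))
}

## edge-class partition of a benzenoid from (v, p, k); degree-2 vertices have
## temperature 2/(v-2), degree-3 vertices 3/(v-3)
.benzenoidEdgeClasses <- function(v, p, k) {
    cnt <- benzenoidEdgeCounts(v, p, k)
    keep <- cnt > 0L
    .makeEdgeClasses(
        tuNum = c(2L, 2L, 3L)[keep], tuDen = c(v - 2L, v - 2L, v - 3L)[keep],
        tvNum = c(2L, 3L, 3L)[keep], tvDen = c(v - 2L, v - 3L, v - 3L)[keep],
        count = cnt[keep])
}

#' Temperature index of a benzenoid system from (v, p, k)
#'
#' Evaluates any supported index over the three-class temperature edge
#' partition implied by the vertex, hexagon and inlet counts.  For the
#' general F-temperature family this is
#' \eqn{T_\beta = 2 n_{22} t_2^\beta + n_{23}(t_2^\beta + t_3^\beta) +
#' 2 n_{33} t_3^\beta} with \eqn{t_2 = 2/(v-2)}, \eqn{t_3 = 3/(v-3)}.
#'
#' @inheritParams benzenoidEdgeCounts
#' @param spec an [IndexSpec-class].
#' @return a single numeric index value.
#' @examples
#' benzenoidIndex(14, 3, 3, indexSpec("F_GENERAL", 1))  # phenanthrene, 6.6061
#' @export
benzenoidIndex <- function(v, p, k, spec) {
    evaluateIndex(.benzenoidEdgeClasses(v, p, k), spec)
}

#' Evaluate an as-printed F-temperature row
#'
#' The published per-molecule formulas have the shape
#' \eqn{a\, t_2^\beta + b\,(t_2^\beta + t_3^\beta) + c\, t_3^\beta} with
#' integer coefficients \eqn{a = 2 n_{22}}, \eqn{b = 2k}, \eqn{c = 2 n_{33}}.
#' This evaluates such a row exactly as printed, vectorised over \code{beta}.
#'
#' @param a,b,c nonnegative integer coefficients.
#' @param t2,t3 the two temperatures (numerics or reduced rationals).
#' @param beta numeric exponent vector.
#' @return numeric vector of index values, one per beta.
#' @examples
#' printedValue(12, 0, 0, 1/2, 1, beta = 1)  # benzene row at beta = 1: 6
#' @export
printedValue <- function(a, b, c, t2, t3, beta) {
    stopifnot(a >= 0, b >= 0, c >= 0, t2 > 0, t3 > 0)
    (a + b) * t2^beta + (b + c) * t3^beta
}

## invert one printed row back to (v, p, k); returns list(v, p, k) or NULL
## when no integral, invariant-satisfying descriptor reproduces the row
.invertPrintedRow <- function(a, b, c, t2_num, t2_den, t3_num, t3_den) {
    ## v from t2 = 2/(v - 2)
    if ((2L * t2_den) %% t2_num != 0L) return(NULL)
    v <- (2L * t2_den) %/% t2_num + 2L
    ## t3 must equal 3/(v - 3) as a rational
    if (t3_num * (v - 3L) != 3L * t3_den) return(NULL)
    if (b %% 2L != 0L || c %% 2L != 0L || a %% 2L != 0L) return(NULL)
    k <- b %/% 2L
    if ((c %/% 2L + k + 3L) %% 3L != 0L) return(NULL)
    p <- (c %/% 2L + k + 3L) %/% 3L
    ## consistency of the leading coefficient with n22 = v - 2p - k + 2
    n22 <- v - 2L * p - k + 2L
    if (n22 < 0L || a %/% 2L != n22) return(NULL)
    list(v = v, p = p, k = k)
}

#' The 30 lower benzenoid hydrocarbons with pi-electron energies
#'
#' Returns the bundled dataset of 30 lower benzenoid hydrocarbons: molecule
#' name, total pi-electron energy \code{e_pi} (Hueckel beta units), the
#' as-printed F-temperature coefficients (\code{a}, \code{b}, \code{c}) with
#' their two temperatures as exact rationals, and the result of an
#' algebraic audit that inverts each row back to vertex/hexagon/inlet counts
#' (\code{v}, \code{p}, \code{k_inlets}; \code{NA} where the printed row is
#' not reproducible from any valid benzenoid descriptor, with
#' \code{consistent = FALSE}).
#'
#' Two modes are offered because the published rows contain transcription
#' defects.  \code{"as_printed"} (default) reproduces the published numerics
#' verbatim -- this is the surface on which the published correlation
#' statistics were computed.  \code{"derived"} is the audited surface: rows
#' failing inversion carry \code{NA} descriptors, and index values should be
#' computed from (\code{v}, \code{p}, \code{k_inlets}) via
#' [benzenoidIndex()].  The Hexahelicene row duplicates the Coronene row in
#' print (it inverts to Coronene's descriptor); a warning flags it.
#'
#' @param mode \code{"as_printed"} or \code{"derived"}.
#' @return data.frame with 30 rows and columns \code{name}, \code{e_pi},
#'   \code{a}, \code{b}, \code{c}, \code{t2_num}, \code{t2_den},
#'   \code{t3_num}, \code{t3_den}, \code{v}, \code{p}, \code{k_inlets},
#'   \code{consistent}.
#' @examples
#' bh <- lowerBenzenoids()
#' bh[!bh$consistent, "name"]
#' @export
lowerBenzenoids <- function(mode = c("as_printed", "derived")) {
    mode <- match.arg(mode)
    path <- system.file("extdata", "lower_benzenoids.csv",
                        package = "TemperatureIndices", mustWork = TRUE)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    inv <- lapply(seq_len(nrow(df)), function(i)
        .invertPrintedRow(df$a[i], df$b[i], df$c[i], df$t2_num[i],
                          df$t2_den[i], df$t3_num[i], df$t3_den[i]))
    df$v <- vapply(inv, function(x) if (is.null(x)) NA_integer_ else x$v, 1L)
    df$p <- vapply(inv, function(x) if (is.null(x)) NA_integer_ else x$p, 1L)
    df$k_inlets <- vapply(inv,
        function(x) if (is.null(x)) NA_integer_ else x$k, 1L)
    df$consistent <- !is.na(df$v)
    if (mode == "derived")
        warning(paste("the Hexahelicene row duplicates the Coronene row in",
                      "the printed source; its inverted descriptor is",
                      "Coronene's"), call. = FALSE)
    attr(df, "mode") <- mode
    df
}

#' Descriptor (v, p, k) of one dataset record
#'
#' @param records a data.frame from [lowerBenzenoids()].
#' @param name molecule name.
#' @return named integer vector \code{c(v =, p =, k =)}; errors if the
#'   record's printed row failed the inversion audit.
#' @export
benzenoidDescriptor <- function(records, name) {
    i <- match(name, records$name)
    if (is.na(i)) stop(sprintf("no record named '%s'", name))
    if (!records$consistent[i])
        stop(sprintf(
            "record '%s' is inconsistent: its printed row cannot be %s",
            name, "reproduced from any valid (v, p, k) descriptor"))
    c(v = records$v[i], p = records$p[i], k = records$k_inlets[i])
}
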