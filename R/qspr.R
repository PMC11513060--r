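## Correlation, regression and the exponent grid search relating an index
## family evaluated on the benzenoid dataset to total pi-electron energy.

#' Pearson correlation with degenerate-input checking
#'
#' Sample Pearson correlation of two equal-length sequences.  A constant
#' sequence has zero variance and no defined correlation; it raises an
#' error rather than returning a silent value.
#'
#' @param x,y numeric vectors of equal length N >= 2.
#' @return correlation in [-1, 1].
#' @examples
#' pearsonCorrelation(c(0, 1, 2), c(0, 0, 3))  # 3/sqrt(12)
#' @export
pearsonCorrelation <- function(x, y) {
    if (length(x) != length(y)) stop("sequences must have equal length")
    if (length(x) < 2L) stop("at least 2 observations are required")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("degenerate input: a sequence is constant (zero variance)")
    stats::cor(x, y)
}

#' Ordinary least-squares line with fit diagnostics
#'
#' Fits \eqn{y = slope \cdot x + intercept} by OLS and reports the Pearson
#' correlation, the standard error of fit
#' \eqn{s = \sqrt{\sum r_i^2/(N-2)}}, and 95\% confidence half-widths for
#' both coefficients from the t-distribution with N - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length N >= 3; x must not be
#'   constant.
#' @return a [RegressionFit-class].
#' @examples
#' fitLine(c(0, 1, 2), c(0, 0, 3))  # slope 1.5, intercept -0.5, s = sqrt(1.5)
#' @export
fitLine <- function(x, y) {
    if (length(x) != length(y)) stop("sequences must have equal length")
    if (length(x) < 3L) stop("insufficient data: at least 3 observations")
    rho <- pearsonCorrelation(x, y)
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)
    halfw <- stats::qt(0.975, df = length(x) - 2L) * sm$coefficients[, 2L]
    new("RegressionFit",
        slope = unname(stats::coef(fit)[2L]),
        intercept = unname(stats::coef(fit)[1L]),
        rho = rho, sFit = sm$sigma, nObs = length(x),
        ci95Slope = unname(halfw[2L]), ci95Intercept = unname(halfw[1L]))
}

setMethod("show", "RegressionFit", function(object) {
    cat(sprintf("RegressionFit (N = %d)\n", object@nObs))
    cat(sprintf("  y = %.4f (+/- %.4f) + %.4f (+/- %.4f) x\n",
                object@intercept, object@ci95Intercept,
                object@slope, object@ci95Slope))
    cat(sprintf("  rho = %.9f, s = %.9f\n", object@rho, object@sFit))
})

#' Construct an exponent-scan configuration
#'
#' @param betaMin,betaMax grid bounds (betaMin < 0 < betaMax).  The default
#'   \code{[-5, 5]} comfortably brackets the region where the correlation
#'   curves of all three families peak.
#' @param step grid spacing.
#' @param zeroExclusion half-width of the window around 0 removed from the
#'   grid (the exponent is a non-zero real).
#' @return a [ScanConfig-class].
#' @export
scanConfig <- function(betaMin = -5, betaMax = 5, step = 1e-4,
                       zeroExclusion = max(step / 2, 5e-5)) {
    new("ScanConfig", betaMin = betaMin, betaMax = betaMax, step = step,
        zeroExclusion = zeroExclusion)
}

.scanGrid <- function(config) {
    betas <- seq(config@betaMin, config@betaMax, by = config@step)
    betas[abs(betas) > config@zeroExclusion]
}

## index value matrix for a family over the dataset: one row per beta,
## one column per molecule.  Class counts come from the printed coefficients
## (as_printed) or the audited descriptors (derived; inconsistent rows
## excluded).  For every family the per-molecule partition is
## (t2,t2) x n22, (t2,t3) x n23, (t3,t3) x n33.
.familyValues <- function(records, family, betas, mode) {
    if (mode == "derived") {
        records <- records[records$consistent, , drop = FALSE]
        cnt <- lapply(seq_len(nrow(records)), function(i)
            benzenoidEdgeCounts(records$v[i], records$p[i],
                                records$k_inlets[i]))
        n22 <- vapply(cnt, `[[`, 1L, "n22")
        n23 <- vapply(cnt, `[[`, 1L, "n23")
        n33 <- vapply(cnt, `[[`, 1L, "n33")
        t2 <- 2 / (records$v - 2)
        t3 <- 3 / (records$v - 3)
    } else {
        ## printed coefficients are a = 2 n22, b = n23 (= 2k), c = 2 n33
        n22 <- records$a / 2
        n23 <- records$b
        n33 <- records$c / 2
        t2 <- records$t2_num / records$t2_den
        t3 <- records$t3_num / records$t3_den
    }
    pow <- function(base) exp(outer(betas, log(base)))  # base^beta, G x N
    wsum <- function(...) {                 # sum of weight-scaled power terms
        terms <- list(...)
        Reduce(`+`, lapply(terms, function(t)
            sweep(pow(t$base), 2L, t$w, `*`)))
    }
    X <- switch(family,
        F_GENERAL  = wsum(list(base = t2, w = 2 * n22 + n23),
                          list(base = t3, w = n23 + 2 * n33)),
        T1_GENERAL = wsum(list(base = 2 * t2, w = n22),
                          list(base = t2 + t3, w = n23),
                          list(base = 2 * t3, w = n33)),
        T2_GENERAL = wsum(list(base = t2^2, w = n22),
                          list(base = t2 * t3, w = n23),
                          list(base = t3^2, w = n33)),
        stop("family must be one of F_GENERAL, T1_GENERAL, T2_GENERAL"))
    list(X = X, e = records$e_pi, names = records$name)
}

#' Correlation curve of an index family against pi-electron energy
#'
#' For each exponent on the grid, evaluates the chosen parametric family on
#' every dataset record and computes the Pearson correlation against the
#' \code{e_pi} column; returns the full curve with the |rho|-maximising
#' exponent.  Ties are broken deterministically: smallest |beta|, then most
#' negative.
#'
#' @param records data.frame from [lowerBenzenoids()] (or any data.frame
#'   with the same columns).
#' @param family \code{"F_GENERAL"}, \code{"T1_GENERAL"} or
#'   \code{"T2_GENERAL"}.
#' @param config a [ScanConfig-class].
#' @param mode \code{"as_printed"} (row coefficients as published) or
#'   \code{"derived"} (audited descriptors; inconsistent rows dropped).
#' @return a [ScanResult-class].
#' @examples
#' bh <- lowerBenzenoids()
#' sc <- rhoCurve(bh, "F_GENERAL", scanConfig(-1, 1, 1e-3))
#' betaStar(sc)
#' @export
rhoCurve <- function(records, family = c("F_GENERAL", "T1_GENERAL",
                                         "T2_GENERAL"),
                     config = scanConfig(), mode = c("as_printed",
                                                     "derived")) {
    family <- match.arg(family)
    mode <- match.arg(mode)
    stopifnot(is(config, "ScanConfig"))
    betas <- .scanGrid(config)
    fv <- .familyValues(records, family, betas, mode)
    if (length(fv$e) < 2L) stop("at least 2 records are required")
    X <- fv$X
    e <- fv$e
    ## row-wise Pearson correlation against e, vectorised over the grid
    Xc <- X - rowMeans(X)
    ec <- e - mean(e)
    sx <- sqrt(rowSums(Xc^2))
    if (any(sx == 0)) {
        bad <- betas[which(sx == 0)[1L]]
        stop(sprintf(paste0("degenerate input: index values are constant ",
                            "across records at beta = %g"), bad))
    }
    rhos <- as.vector(Xc %*% ec) / (sx * sqrt(sum(ec^2)))
    ## argmax of |rho|; ties -> smallest |beta|, then most negative
    best <- abs(abs(rhos) - max(abs(rhos))) < 1e-15
    cand <- betas[best]
    bStar <- cand[order(abs(cand), cand)][1L]
    new("ScanResult", betas = betas, rhos = rhos,
        betaStar = bStar, rhoStar = rhos[match(bStar, betas)],
        family = family, mode = mode)
}

#' @rdname scan-accessors
#' @param x a [ScanResult-class].
#' @return \code{betaStar}/\code{rhoStar} return the optimum;
#'   \code{scanCurve} returns a two-column data.frame (beta, rho).
#' @export
betaStar <- function(x) { stopifnot(is(x, "ScanResult")); x@betaStar }

#' @rdname scan-accessors
#' @export
rhoStar <- function(x) { stopifnot(is(x, "ScanResult")); x@rhoStar }

#' @rdname scan-accessors
#' @export
scanCurve <- function(x) {
    stopifnot(is(x, "ScanResult"))
    data.frame(beta = x@betas, rho = x@rhos)
}

setMethod("show", "ScanResult", function(object) {
    cat(sprintf("ScanResult: %s (%s mode), %d grid points\n",
                object@family, object@mode, length(object@betas)))
    cat(sprintf("  beta* = %.4f, rho* = %.9f\n",
                object@betaStar, object@rhoStar))
})

#' Grid intervals where one curve dominates another
#'
#' Maximal runs of grid points where \code{|rho_a| > |rho_b|}; both scans
#' must share the same grid.  Endpoints are grid values.
#'
#' @param curveA,curveB [ScanResult-class] objects on identical grids.
#' @return data.frame with columns betaLo, betaHi (zero rows if A never
#'   dominates).
#' @export
dominanceIntervals <- function(curveA, curveB) {
    stopifnot(is(curveA, "ScanResult"), is(curveB, "ScanResult"))
    if (length(curveA@betas) != length(curveB@betas) ||
        any(curveA@betas != curveB@betas))
        stop("scan grids differ; dominance requires identical grids")
    win <- abs(curveA@rhos) > abs(curveB@rhos)
    if (!any(win)) return(data.frame(betaLo = numeric(), betaHi = numeric()))
    r <- rle(win)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    data.frame(betaLo = curveA@betas[starts[keep]],
               betaHi = curveA@betas[ends[keep]])
}

#' Simulate pi-electron energies from a known linear law
#'
#' Builds synthetic response values \eqn{E = slope \cdot T_{\beta_0} +
#' intercept + \epsilon} with Gaussian noise on top of the index values of
#' the dataset records, for parameter-recovery experiments.
#'
#' @param records dataset rows (see [lowerBenzenoids()]).
#' @param beta0 true exponent.
#' @param slope,intercept true linear coefficients.
#' @param sd noise standard deviation.
#' @param mode dataset mode, as in [rhoCurve()].
#' @return data.frame: \code{records} with its \code{e_pi} column replaced
#'   by the simulated energies.
#' @export
simulateEnergies <- function(records, beta0, slope, intercept, sd = 0.1,
                             mode = c("as_printed", "derived")) {
    mode <- match.arg(mode)
    fv <- .familyValues(records, "F_GENERAL", beta0, mode)
    out <- records
    if (mode == "derived") out <- out[out$consistent, , drop = FALSE]
    out$e_pi <- slope * as.vector(fv$X) + intercept +
        stats::rnorm(length(fv$e), 0, sd)
    out
}
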