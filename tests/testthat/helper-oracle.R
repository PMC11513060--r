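# Independent per-edge oracle: computes any temperature index directly from
# an edge matrix with plain arithmetic, touching none of the package's
# grouping or class machinery.

oracleIndex <- function(edges, psi) {
    vertices <- sort(unique(as.vector(edges)))
    n <- length(vertices)
    deg <- sapply(vertices, function(v) sum(edges == v))
    temp <- deg / (n - deg)
    sum(apply(edges, 1L, function(e)
        psi(temp[[e[[1L]]]], temp[[e[[2L]]]])))
}

# literal psi maps, written independently from the formulas
oraclePsi <- list(
    HT1  = function(a, b) (a + b)^2,
    HT2  = function(a, b) (a * b)^2,
    ST   = function(a, b) 1 / sqrt(a + b),
    PT   = function(a, b) 1 / sqrt(a * b),
    RPT  = function(a, b) sqrt(a * b),
    AGT  = function(a, b) (a + b) / (2 * sqrt(a * b)),
    FT   = function(a, b) a^2 + b^2,
    TSO  = function(a, b) sqrt(a^2 + b^2),
    MTSO = function(a, b) 1 / sqrt(a^2 + b^2),
    HT   = function(a, b) 2 / (a + b),
    GAT  = function(a, b) 2 * sqrt(a * b) / (a + b),
    RRPT = function(a, b) sqrt((a - 1) * (b - 1)),
    ABCT = function(a, b) sqrt(abs((a + b - 2) / (a * b))))

oraclePsiGeneral <- function(family, sigma) {
    switch(family,
        T1_GENERAL = function(a, b) (a + b)^sigma,
        T2_GENERAL = function(a, b) (a * b)^sigma,
        F_GENERAL  = function(a, b) a^sigma + b^sigma)
}

# class table as a sorted plain data.frame for multiset comparison
classTable <- function(x) {
    cl <- edgeClasses(x)[, c("tuNum", "tuDen", "tvNum", "tvDen", "count")]
    cl[do.call(order, cl), , drop = FALSE]
}
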