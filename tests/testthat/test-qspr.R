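test_that("pearson correlation matches hand evaluation and rejects degenerate input", {
    expect_equal(pearsonCorrelation(c(1, 2, 3), c(2, 4, 6)), 1)
    expect_equal(pearsonCorrelation(c(1, 2, 3), c(6, 4, 2)), -1)
    expect_equal(pearsonCorrelation(c(0, 1, 2), c(0, 0, 3)), 3 / sqrt(12))
    expect_error(pearsonCorrelation(c(1, 1, 1), c(1, 2, 3)), "degenerate")
    expect_error(pearsonCorrelation(1:3, 1:4), "equal length")
})

test_that("pearson is invariant under affine maps up to the scale sign", {
    set.seed(31)
    for (i in 1:20) {
        x <- stats::rnorm(12)
        y <- stats::rnorm(12)
        a <- stats::runif(1, -4, 4)
        if (a == 0) a <- 1
        b <- stats::rnorm(1)
        r0 <- pearsonCorrelation(x, y)
        expect_equal(pearsonCorrelation(a * x + b, y), sign(a) * r0)
        expect_equal(pearsonCorrelation(x, a * y + b), sign(a) * r0)
    }
})

test_that("OLS fit reports slope, intercept and standard error of fit", {
    exact <- suppressWarnings(   # summary.lm warns on exact fits
        fitLine(c(1, 2, 3, 4), 2 * c(1, 2, 3, 4) + 1))
    expect_equal(exact@slope, 2)
    expect_equal(exact@intercept, 1)
    expect_equal(exact@sFit, 0)

    f <- fitLine(c(0, 1, 2), c(0, 0, 3))
    expect_equal(f@slope, 1.5)
    expect_equal(f@intercept, -0.5)
    expect_equal(f@sFit, sqrt(1.5))
    expect_equal(f@nObs, 3L)

    expect_error(fitLine(c(0, 1), c(2, 3)), "insufficient data")
})

test_that("OLS residuals are orthogonal to the design", {
    set.seed(8)
    for (i in 1:10) {
        x <- stats::rnorm(15)
        y <- 0.7 * x + stats::rnorm(15)
        f <- fitLine(x, y)
        r <- y - (f@slope * x + f@intercept)
        expect_lt(abs(sum(r)), 1e-9)
        expect_lt(abs(sum(r * x)), 1e-9)
    }
})

test_that("refining the scan grid never lowers the optimum |rho|", {
    bh <- lowerBenzenoids()
    coarse <- rhoCurve(bh, "F_GENERAL", scanConfig(-1, 1, 1e-2))
    fine <- rhoCurve(bh, "F_GENERAL", scanConfig(-1, 1, 1e-3))
    expect_true(all(coarse@betas %in% fine@betas))
    expect_gte(abs(rhoStar(fine)), abs(rhoStar(coarse)))
})

test_that("two records are always perfectly collinear; ties resolve deterministically", {
    bh <- lowerBenzenoids()
    sc <- rhoCurve(bh[1:2, ], "F_GENERAL", scanConfig(-0.5, 0.5, 1e-3))
    expect_true(all(abs(abs(sc@rhos) - 1) < 1e-12))
    # smallest |beta| wins, then the more negative candidate
    expect_equal(betaStar(sc), -1e-3)
})

test_that("a constant index across records is a degenerate-input error", {
    bh <- lowerBenzenoids()
    clones <- bh[c(1, 1, 1), ]
    clones$e_pi <- c(1, 2, 3)
    expect_error(rhoCurve(clones, "F_GENERAL", scanConfig(-0.1, 0.1, 1e-2)),
                 "constant across records")
})

test_that("dominance intervals cover trivial and degenerate cases", {
    bh <- lowerBenzenoids()
    cfg <- scanConfig(-1, 1, 1e-2)
    f <- rhoCurve(bh, "F_GENERAL", cfg)
    t1 <- rhoCurve(bh, "T1_GENERAL", cfg)
    # identical curves: empty dominance
    expect_equal(nrow(dominanceIntervals(f, f)), 0L)
    # dominance endpoints are grid values
    d <- dominanceIntervals(f, t1)
    expect_true(all(d$betaLo %in% f@betas))
    expect_true(all(d$betaHi %in% f@betas))
    expect_true(all(d$betaLo <= d$betaHi))
    # mismatched grids error
    other <- rhoCurve(bh, "T1_GENERAL", scanConfig(-1, 1, 2e-2))
    expect_error(dominanceIntervals(f, other), "grids differ")
})

test_that("scan recovers a planted exponent and linear law", {
    bh <- lowerBenzenoids()
    cfg <- scanConfig(-1, 1, 1e-2)
    beta0 <- -0.15
    slope0 <- 0.45
    int0 <- 2.5
    zs <- numeric()
    set.seed(501)
    for (rep in 1:20) {
        sim <- simulateEnergies(bh, beta0, slope0, int0, sd = 0.02)
        sc <- rhoCurve(sim, "F_GENERAL", cfg)
        expect_lte(abs(betaStar(sc) - beta0), cfg@step)
        # coefficient recovery is judged at the planted exponent: a one-step
        # error in beta-hat rescales the regressor and biases the slope
        fv <- TemperatureIndices:::.familyValues(sim, "F_GENERAL",
                                                 beta0, "as_printed")
        f <- fitLine(as.vector(fv$X), fv$e)
        seSlope <- f@ci95Slope / stats::qt(0.975, f@nObs - 2L)
        seInt <- f@ci95Intercept / stats::qt(0.975, f@nObs - 2L)
        zs <- c(zs, abs(f@slope - slope0) / seSlope,
                abs(f@intercept - int0) / seInt)
    }
    # a |z| > 3 excursion is a ~0.3% event per draw under correct
    # calibration; tolerate at most 2 of 40 before calling it bias
    expect_lte(sum(zs > 3), 2)
    expect_lt(mean(zs), 1.5)
})
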