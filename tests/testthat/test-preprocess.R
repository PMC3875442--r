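test_that("local linear smoothing is exact on affine data", {
    tt <- 0:9
    tc <- ExpressionTimecourses(times = tt, values = cbind(2 * tt, 5 + 0 * tt))
    for (span in c(0.4, 0.7, 1)) {
        sm <- smoothTimecourses(tc, span = span, degree = 1)
        expect_equal(unname(seriesValues(sm$smoothed)[[1]][, 1]), 2 * tt,
                     tolerance = 1e-9)
        expect_equal(unname(seriesValues(sm$derivatives)[[1]][, 1]),
                     rep(2, 10), tolerance = 1e-9)
        # constant gene: values c, derivative 0
        expect_equal(unname(seriesValues(sm$smoothed)[[1]][, 2]),
                     rep(5, 10), tolerance = 1e-9)
        expect_equal(unname(seriesValues(sm$derivatives)[[1]][, 2]),
                     rep(0, 10), tolerance = 1e-9)
    }
})

test_that("quadratic fit recovers the exact slope of t^2", {
    tt <- 0:10
    tc <- ExpressionTimecourses(times = tt, values = matrix(tt^2, ncol = 1))
    sm <- smoothTimecourses(tc, span = 1, degree = 2)
    expect_equal(seriesValues(sm$derivatives)[[1]][6, 1], 10,
                 tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("the smoother is linear in the data for fixed abscissae", {
    set.seed(21)
    tt <- sort(runif(12, 0, 5))
    x <- rnorm(12)
    y <- rnorm(12)
    # derivative-class container carries arbitrary-sign values, and the
    # derivative channel is not clipped by the floor
    sm <- function(v) smoothTimecourses(
        DerivativeTimecourses(times = tt, values = matrix(v, ncol = 1)),
        span = 0.6, degree = 1, floor = 0)
    dOf <- function(v) seriesValues(sm(v)$derivatives)[[1]][, 1]
    expect_equal(dOf(2 * x + 3 * y), 2 * dOf(x) + 3 * dOf(y),
                 tolerance = 1e-9)
})

test_that("derivative estimates converge at the local-linear rate as sampling densifies", {
    # fixed window point-count, so halving the step halves the window
    # width: interior slope bias is O(h^2) for the local linear fit
    rmse <- vapply(c(0.2, 0.1, 0.05), function(h) {
        tt <- seq(0, 6.28, by = h)
        L <- length(tt)
        tc <- DerivativeTimecourses(times = tt,
                                    values = matrix(sin(tt), ncol = 1))
        est <- seriesValues(smoothTimecourses(tc, span = 7 / L,
                                              degree = 1)$derivatives)[[1]][, 1]
        keep <- 8:(L - 7)
        sqrt(mean((est[keep] - cos(tt[keep]))^2))
    }, 0)
    expect_lt(rmse[2] / rmse[1], 0.35)
    expect_lt(rmse[3] / rmse[2], 0.35)
    # and on simulated model trajectories the estimates improve too
    m <- smallScaleModel()
    rmse2 <- vapply(c(0.5, 0.25), function(h) {
        times <- seq(0, 10, by = h)
        L <- length(times)
        tc <- simulateModel(m, c(0.2, 0.8, 0.5, 0.3), times)
        ex <- seriesValues(exactDerivatives(m, tc))[[1]]
        est <- seriesValues(smoothTimecourses(tc, span = 7 / L,
                                              degree = 1)$derivatives)[[1]]
        keep <- 4:(L - 3)
        sqrt(mean((est[keep, ] - ex[keep, ])^2))
    }, 0)
    expect_lt(rmse2[2], rmse2[1] * 0.9)
})

test_that("per-gene max normalization uses the cross-series maximum", {
    tc <- ExpressionTimecourses(
        times = list(0:2, 0:2),
        values = list(cbind(c(2, 4, 8)), cbind(c(1, 2, 4))),
        geneNames = "G1")
    nm <- normalizePerGeneMax(tc)
    expect_equal(unname(seriesValues(nm)[[1]][, 1]), c(0.25, 0.5, 1))
    expect_equal(unname(seriesValues(nm)[[2]][, 1]), c(0.125, 0.25, 0.5))
    expect_equal(seriesValues(normalizePerGeneMax(nm))[[1]],
                 seriesValues(nm)[[1]])  # idempotent
    zero <- ExpressionTimecourses(times = 0:1, values = matrix(0, 2, 1))
    expect_error(normalizePerGeneMax(zero), "positive maximum")
})

test_that("flooring clamps only values below the floor", {
    tc <- DerivativeTimecourses(times = 0:1,
                                values = cbind(c(-0.01, 0.5), c(0.2, 0.3)))
    fl <- floorLowValues(tc, 0.001)
    expect_equal(unname(seriesValues(fl)[[1]]),
                 cbind(c(0.001, 0.5), c(0.2, 0.3)))
    expect_equal(seriesValues(floorLowValues(fl, 0.001)),
                 seriesValues(fl))
    expect_equal(unname(seriesValues(floorLowValues(tc, 0))[[1]])[1, 1], 0)
})

test_that("dropping initial points shortens every series", {
    tc <- ExpressionTimecourses(
        times = list(1:50, 1:50),
        values = list(matrix(runif(100), 50), matrix(runif(100), 50)))
    dr <- dropInitialPoints(tc, 1)
    expect_equal(nSamples(dr), 98)
    expect_equal(seriesTimes(dr)[[1]], 2:50)
    expect_identical(dropInitialPoints(tc, 0), tc)
    expect_error(dropInitialPoints(tc, 50), "cannot drop")
})
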