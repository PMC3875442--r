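test_that("logit matches its closed form and rejects the boundary", {
    expect_identical(logit(0.5), 0)
    expect_equal(logit(0.1), -2.1972245773, tolerance = 1e-9)
    expect_equal(logit(sigmoidActivation(1.234)), 1.234, tolerance = 1e-12)
    expect_error(logit(0), "strictly inside")
    expect_error(logit(1), "strictly inside")
})

test_that("the transformed system computes y, validity and logits", {
    tc <- ExpressionTimecourses(times = 0:1, values = matrix(0, 2, 1))
    dv <- DerivativeTimecourses(times = 0:1, values = matrix(0.1, 2, 1))
    sys <- buildTransformedSystem(1, k1 = 1, k2 = 0.2, tc, dv)
    expect_equal(sys$y, c(0.1, 0.1))
    expect_true(all(sys$valid))
    expect_equal(sys$z, rep(-2.1972245773, 2), tolerance = 1e-9)
    # x' = k1, x = 0 gives y = 1: boundary rows are invalid
    dv1 <- DerivativeTimecourses(times = 0:1, values = matrix(1, 2, 1))
    sys1 <- buildTransformedSystem(1, k1 = 1, k2 = 0.2, tc, dv1)
    expect_false(any(sys1$valid))
    expect_identical(sys1$status, "uninformative")
})

test_that("all y lie inside (0,1) at the true rates on noise-free data", {
    fx <- smallScaleFixture(seed = 3)
    for (g in 1:4) {
        sys <- buildTransformedSystem(g, kSyn(fx$model)[g],
                                      kDeg(fx$model)[g],
                                      fx$data, fx$derivatives)
        expect_true(all(sys$y > 0 & sys$y < 1))
    }
})

test_that("transformation round trip is exact under the true parameters", {
    fx <- smallScaleFixture(seed = 5)
    m <- fx$model
    for (g in 1:4) {
        sys <- buildTransformedSystem(g, kSyn(m)[g], kDeg(m)[g],
                                      fx$data, fx$derivatives)
        lin <- drop(sys$X[sys$valid, , drop = FALSE] %*% regWeights(m)[g, ]) +
            bias(m)[g]
        expect_lt(max(abs(sys$z - lin)), 1e-10)
    }
})

test_that("a zero-regressor system returns w = 0 and b = z", {
    sys <- structure(list(y = c(0.3, 0.3), valid = c(TRUE, TRUE),
                          z = rep(logit(0.3), 2),
                          X = matrix(0, 2, 1), c = c(1, 1), gene = 1L,
                          k1 = 1, k2 = 1, eps = 1e-5, status = "ok"),
                     class = "TransformedSystem")
    lp <- solveWeightLP(sys, theta = 10)
    expect_identical(lp$status, "solved")
    expect_equal(lp$w, 0, tolerance = 1e-8)
    expect_equal(lp$b, logit(0.3), tolerance = 1e-8)
    expect_equal(lp$lpObjective, 0, tolerance = 1e-7)
})

test_that("the LP recovers the exact weight row on noise-free data", {
    fx <- smallScaleFixture(seed = 1)
    sys <- buildTransformedSystem(2, 0.2, 0.2, fx$data, fx$derivatives)
    lp <- solveWeightLP(sys, 2000)
    expect_identical(lp$status, "solved")
    expect_equal(lp$w, c(15, -10, 0, 0), tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(lp$b, -5, tolerance = 1e-6)
    # cross-check against an exact least-squares solve of the valid rows
    A <- cbind(sys$X[sys$valid, , drop = FALSE], 1)
    beta <- qr.solve(A, sys$z)
    expect_equal(c(lp$w, lp$b), unname(beta), tolerance = 1e-6)
})

test_that("LP objective equals the brute-force vertex optimum on tiny instances", {
    set.seed(42)
    for (rep in 1:100) {
        n <- sample(1:2, 1)
        m <- sample(2:4, 1)
        sys <- randomTinySystem(n, m)
        theta <- runif(1, 0.5, 5)
        lp <- solveWeightLP(sys, theta)
        expect_identical(lp$status, "solved")
        ref <- oracleLadLP(cbind(sys$X, -sys$X, 1, -1), sys$z,
                           c(rep(1, 2 * n), 0, 0), theta * sys$c)
        expect_lt(abs(lp$lpObjective - ref), 1e-8)
    }
    # also a handful of 3-gene, 5-equation instances
    for (rep in 1:5) {
        sys <- randomTinySystem(3, 5)
        lp <- solveWeightLP(sys, 2)
        ref <- oracleLadLP(cbind(sys$X, -sys$X, 1, -1), sys$z,
                           c(rep(1, 6), 0, 0), 2 * sys$c)
        expect_lt(abs(lp$lpObjective - ref), 1e-8)
    }
})

test_that("the returned LP point is optimal against random feasible perturbations", {
    set.seed(9)
    sys <- randomTinySystem(3, 8)
    theta <- 3
    lp <- solveWeightLP(sys, theta)
    objOf <- function(w, b) {
        resid <- abs(sys$z - drop(sys$X %*% w) - b)
        sum(abs(w)) + theta * sum(sys$c * resid)
    }
    for (rep in 1:1000) {
        w <- lp$w + rnorm(3, 0, 0.3)
        b <- lp$b + rnorm(1, 0, 0.3)
        expect_gte(objOf(w, b), lp$lpObjective - 1e-8)
    }
})

test_that("total weight magnitude grows with theta (sparsity pressure falls)", {
    set.seed(13)
    for (rep in 1:10) {
        sys <- randomTinySystem(3, 10)
        l1 <- vapply(c(0.5, 2, 10, 50), function(th)
            sum(abs(solveWeightLP(sys, th)$w)), 0)
        expect_true(all(diff(l1) >= -1e-7))
    }
})

test_that("outer objective is zero at truth and larger elsewhere", {
    fx <- smallScaleFixture(seed = 1)
    atTruth <- outerObjective(4, 0.2, 0.2, fx$data, fx$derivatives)
    expect_lt(atTruth$value, 1e-10)
    scaled <- outerObjective(4, 2, 0.2, fx$data, fx$derivatives)
    expect_gt(scaled$value, atTruth$value)
})

test_that("uninformative systems hit the penalty branch", {
    tc <- ExpressionTimecourses(times = 0:2, values = matrix(0.5, 3, 1))
    dv <- DerivativeTimecourses(times = 0:2, values = matrix(10, 3, 1))
    # y = (10 + k2/2)/k1 > 1 for k1 = 1: every row invalid
    out <- outerObjective(1, 1, 1, tc, dv)
    expect_identical(out$value, 1e12)
})
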