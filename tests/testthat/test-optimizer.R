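test_that("singular value thresholding is the nuclear-norm prox", {
    expect_equal(svt(diag(c(3, 1)), 2), diag(c(1, 0)))
    Y <- matrix(rnorm(12), 4, 3)
    expect_equal(svt(Y, 0), Y)
    ## prox optimality: no random perturbation does better
    set.seed(31)
    Y <- matrix(rnorm(24), 6, 4)
    tau <- 0.7
    J <- svt(Y, tau)
    fval <- function(Jc) tau * nuclearNorm(Jc) + 0.5 * sum((Jc - Y)^2)
    f0 <- fval(J)
    for (rep in 1:1000) {
        pert <- J + matrix(rnorm(24, sd = runif(1, 0.001, 0.5)), 6, 4)
        expect_gte(fval(pert), f0)
    }
})

test_that("objective equals term-by-term recomputation", {
    st <- randomState(5, 4, seed = 32)
    hp <- hyperParams(alpha = 0.3, beta = 0.7, lambda = 1.3)
    lap <- laplacianPair(st$Wd, st$Wt)
    got <- objectiveValue(st$X, st$A, lap, hp)
    want <- sum(svd(st$X)$d) +
        0.3 * sum(st$X^2) +
        0.7 * sum((st$A * st$X - st$A)^2) +
        1.3 * (sum(diag(t(st$X) %*% lap@drugLaplacian %*% st$X)) +
               sum(diag(st$X %*% lap@targetLaplacian %*% t(st$X))))
    expect_equal(got, want, tolerance = 1e-10)

    A0 <- matrix(0, 5, 4)
    expect_equal(objectiveValue(A0, A0, lap, hp), 0)
    ## X = 0: only the fidelity term survives, beta * |observed|
    expect_equal(objectiveValue(A0, st$A, lap, hp), 0.7 * sum(st$A))
    expect_error(objectiveValue(st$X * NaN, st$A, lap, hp), "NaN")
})

test_that("J update is SVT of X + Y1/mu1 at threshold 1/mu1", {
    st <- randomState(4, 3, seed = 33)
    expect_equal(updateJ(st$X, st$Y1, 2),
                 svt(st$X + st$Y1 / 2, 1 / 2))
    ## huge penalty: threshold vanishes, J -> X
    expect_equal(updateJ(st$X, 0 * st$Y1, 1e8), st$X, tolerance = 1e-6)
    expect_equal(updateJ(0 * st$X, 0 * st$Y1, 1), 0 * st$X)
})

test_that("elementwise Z update solves the dense fidelity system", {
    for (seed in 1:20) {
        st <- randomState(4, 3, seed = 100 + seed)
        beta <- runif(1, 0, 5)
        mu2 <- runif(1, 0.01, 5)
        Z <- updateZ(st$X, st$Y2, mu2, st$A, beta)
        expect_equal(Z, denseZOracle(st$X, st$Y2, mu2, st$A, beta),
                     tolerance = 1e-10)
    }
    st <- randomState(4, 3, seed = 34)
    ## beta = 0 collapses to Z = X + Y2/mu2
    expect_equal(updateZ(st$X, st$Y2, 2, st$A, 0), st$X + st$Y2 / 2)
    ## observed entries already at 1 are stationary
    Z <- updateZ(matrix(1, 4, 3), matrix(0, 4, 3), 2, matrix(1, 4, 3), 3)
    expect_equal(Z, matrix(1, 4, 3))
})

test_that("X update satisfies the stationarity (Sylvester) condition", {
    for (seed in 1:20) {
        st <- randomState(6, 5, seed = 200 + seed)
        hp <- hyperParams(alpha = runif(1, 0, 2), lambda = runif(1, 0, 3))
        mu1 <- runif(1, 0.01, 5); mu2 <- runif(1, 0.01, 5)
        lap <- laplacianPair(st$Wd, st$Wt)
        X <- updateX(st$J, st$Z, st$Y1, st$Y2, mu1, mu2, lap, hp)
        resid <- 2 * hp@alpha * X +
            2 * hp@lambda * (lap@drugLaplacian %*% X +
                             X %*% lap@targetLaplacian) +
            mu1 * (X - st$J) + mu2 * (X - st$Z) + st$Y1 + st$Y2
        rhs <- mu1 * st$J + mu2 * st$Z - st$Y1 - st$Y2
        expect_lt(max(abs(resid)), 1e-8 * (1 + max(abs(rhs))))
    }
})

test_that("X update decouples elementwise when lambda = 0", {
    st <- randomState(5, 4, seed = 35)
    lap <- laplacianPair(st$Wd, st$Wt)
    hp <- hyperParams(alpha = 0.4, lambda = 0)
    X <- updateX(st$J, st$Z, st$Y1, st$Y2, 1.5, 2.5, lap, hp)
    expect_equal(X, (1.5 * st$J + 2.5 * st$Z - st$Y1 - st$Y2) /
                     (2 * 0.4 + 1.5 + 2.5), tolerance = 1e-10)
    ## J = Z, zero multipliers, alpha = lambda = 0: X = J
    hp0 <- hyperParams(alpha = 0, lambda = 0)
    X <- updateX(st$J, st$J, 0 * st$Y1, 0 * st$Y2, 1, 1, lap, hp0)
    expect_equal(X, st$J, tolerance = 1e-10)
})

test_that("multiplier ascent and penalty schedule follow the update rule", {
    st <- randomState(4, 3, seed = 36)
    up <- updateMultipliers(st$X, st$J, st$Z, st$Y1, st$Y2, 1.5, 2.5,
                            rho = 1.2, muMax = 10)
    expect_equal(up$Y1, st$Y1 + 1.5 * (st$X - st$J))
    expect_equal(up$Y2, st$Y2 + 2.5 * (st$X - st$Z))
    expect_equal(up$mu1, 1.8)
    ## stationary when constraints hold; rho = 1 freezes penalties
    up2 <- updateMultipliers(st$X, st$X, st$X, st$Y1, st$Y2, 1, 1, rho = 1)
    expect_equal(up2$Y1, st$Y1)
    expect_equal(up2$Y2, st$Y2)
    expect_equal(up2$mu1, 1)
    ## cap
    up3 <- updateMultipliers(st$X, st$J, st$Z, st$Y1, st$Y2, 9, 9,
                             rho = 2, muMax = 10)
    expect_equal(up3$mu1, 10)
})

test_that("augmented Lagrangian does not increase across block updates", {
    sim <- simulateDTI(d = 20, t = 12, rank = 2, seed = 37)
    ds <- dtiData(sim)
    A <- interactions(ds)
    hp <- hyperParams()
    lap <- laplacianPair(drugSim(ds), targetSim(ds))
    X <- J <- Z <- A
    Y1 <- Y2 <- matrix(0, nrow(A), ncol(A))
    mu1 <- hp@mu1Init; mu2 <- hp@mu2Init
    for (it in 1:30) {
        L0 <- augLagrangian(X, J, Z, Y1, Y2, mu1, mu2, A, lap, hp)
        J <- updateJ(X, Y1, mu1)
        L1 <- augLagrangian(X, J, Z, Y1, Y2, mu1, mu2, A, lap, hp)
        Z <- updateZ(X, Y2, mu2, A, hp@beta)
        L2 <- augLagrangian(X, J, Z, Y1, Y2, mu1, mu2, A, lap, hp)
        X <- updateX(J, Z, Y1, Y2, mu1, mu2, lap, hp)
        L3 <- augLagrangian(X, J, Z, Y1, Y2, mu1, mu2, A, lap, hp)
        slack <- 1e-8 * (1 + abs(L0))
        expect_lte(L1, L0 + slack)
        expect_lte(L2, L1 + slack)
        expect_lte(L3, L2 + slack)
        up <- updateMultipliers(X, J, Z, Y1, Y2, mu1, mu2, hp@rho, hp@muMax)
        Y1 <- up$Y1; Y2 <- up$Y2; mu1 <- up$mu1; mu2 <- up$mu2
    }
})

test_that("the solver converges and is deterministic", {
    sim <- simulateDTI(seed = 38)
    ds <- dtiData(sim)
    f1 <- fitLapMC(ds)
    expect_true(converged(f1))
    expect_lte(f1@iterations, 500)
    expect_lte(max(f1@primalResiduals[f1@iterations, ]), 1e-6)
    f2 <- fitLapMC(ds)
    expect_identical(predictedScores(f1), predictedScores(f2))
})

test_that("with everything observed and dominant fidelity, X is all ones", {
    A <- matrix(1, 8, 6)
    DS <- randomWeights(8); TS <- randomWeights(6)
    hp <- hyperParams(alpha = 0, beta = 1e4, lambda = 0)
    f <- fitLapMC(A, DS, TS, hp = hp)
    expect_lt(max(abs(predictedScores(f) - 1)), 1e-2)
})

test_that("plain nuclear-norm completion honors its constraints", {
    set.seed(39)
    M <- matrix(rnorm(25), 5, 5)
    fit <- plainMC(M, matrix(TRUE, 5, 5))
    expect_true(fit$converged)
    expect_lt(max(abs(fit$X - M)), 1e-3)

    ## rank-1 recovery from 80% of the entries
    u <- runif(5) + 0.5; v <- runif(5) + 0.5
    M1 <- u %*% t(v)
    obs <- matrix(runif(25) < 0.8, 5, 5)
    fit1 <- plainMC(M1, obs, maxIter = 5000)
    expect_lt(max(abs((fit1$X - M1) * obs)), 1e-3)
    expect_lt(sqrt(sum((fit1$X - M1)^2)) / sqrt(sum(M1^2)), 1e-2)
    expect_error(plainMC(M1, matrix(FALSE, 5, 5)), "empty")
})
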