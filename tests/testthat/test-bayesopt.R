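# direct closed-form GP oracle built from plain linear algebra
gpOracle <- function(X, y, Xs, ls, sf, noise) {
  k <- function(A, B) {
    D <- as.matrix(stats::dist(rbind(A, B)))[seq_len(nrow(A)),
                                             nrow(A) + seq_len(nrow(B)),
                                             drop = FALSE]
    a <- sqrt(5) * D / ls
    sf^2 * (1 + a + a^2 / 3) * exp(-a)
  }
  K <- k(X, X) + diag(noise^2 + 1e-10, nrow(X))
  Ks <- k(X, Xs)
  Kss <- k(Xs, Xs)
  Ki <- solve(K)
  mu <- mean(y) + t(Ks) %*% Ki %*% (y - mean(y))
  S <- Kss - t(Ks) %*% Ki %*% Ks
  list(mean = as.numeric(mu), sd = sqrt(pmax(diag(S), 0)))
}

test_that("GP posterior matches the closed-form solution on small problems", {
  set.seed(5)
  for (d in c(1L, 3L)) {
    X <- matrix(runif(8 * d), ncol = d)
    y <- sin(3 * X[, 1]) + 0.1 * rowSums(X)
    gp <- fitGp(X, y, lengthscale = 0.7, signalSd = 1.2, noiseSd = 0.05,
                optimize = FALSE)
    Xs <- matrix(runif(6 * d), ncol = d)
    got <- gpPredict(gp, Xs)
    want <- gpOracle(X, y, Xs, 0.7, 1.2, 0.05)
    expect_equal(got$mean, want$mean, tolerance = 1e-8)
    expect_equal(got$sd, want$sd, tolerance = 1e-6)
  }
})

test_that("GP interpolates noise-free data and reverts to the prior far away", {
  X <- matrix(seq(0, 1, length.out = 5))
  y <- c(0.1, 0.4, 0.2, 0.8, 0.5)
  gp <- fitGp(X, y, lengthscale = 0.3, signalSd = 0.5, noiseSd = 1e-5,
              optimize = FALSE)
  pr <- gpPredict(gp, X)
  expect_equal(pr$mean, y, tolerance = 1e-6)
  far <- gpPredict(gp, matrix(50))
  expect_equal(far$mean, gp@yMean, tolerance = 1e-8)
  expect_equal(far$sd, 0.5, tolerance = 1e-8)
  # marginal-likelihood fitting runs and improves the objective
  gpOpt <- fitGp(X, y, lengthscale = 0.3, signalSd = 0.5, noiseSd = 1e-2)
  nlmlStart <- kinoforge:::.gpNlml(log(c(0.3, 0.5, 1e-2)), X, y - mean(y))
  nlmlOpt <- kinoforge:::.gpNlml(gpOpt@logParams, X, y - mean(y))
  expect_lte(nlmlOpt, nlmlStart + 1e-8)
})

test_that("expected improvement matches its closed form and limits", {
  expect_equal(expectedImprovement(0.3, 0, best = 0.5), 0)
  expect_equal(expectedImprovement(0.7, 0, best = 0.5), 0.2)
  expect_equal(expectedImprovement(0, 1, best = 0), dnorm(0),
               tolerance = 1e-12)
  expect_equal(expectedImprovement(0.2, 0.5, best = 0.4, xi = 0.1),
               (-0.3) * pnorm(-0.6) + 0.5 * dnorm(-0.6))
  expect_true(all(expectedImprovement(rnorm(50), abs(rnorm(50)), 0.2) >= 0))
})

test_that("closed-form EI matches Monte Carlo within three standard errors", {
  set.seed(99)
  n <- 1e6
  for (case in list(c(mu = 0.2, sd = 0.6, best = 0.5),
                    c(mu = 0.9, sd = 0.2, best = 0.5))) {
    draws <- rnorm(n, case["mu"], case["sd"])
    imp <- pmax(draws - case["best"], 0)
    mc <- mean(imp)
    se <- sd(imp) / sqrt(n)
    ei <- expectedImprovement(case["mu"], case["sd"], case["best"])
    expect_lt(abs(ei - mc), 3 * se)
  }
})

test_that("acquisition maximization matches a dense grid and respects bounds", {
  set.seed(2)
  X <- matrix(c(0.1, 0.45, 0.9))
  y <- c(0.2, 0.9, 0.1)
  gp <- fitGp(X, y, lengthscale = 0.2, signalSd = 0.5, noiseSd = 1e-3,
              optimize = FALSE)
  cfg <- boConfig(0, 1, acqRestarts = 10L)
  prop <- proposeNext(gp, cfg)
  grid <- seq(0, 1, length.out = 4001)
  pr <- gpPredict(gp, matrix(grid))
  ei <- expectedImprovement(pr$mean, pr$sd, max(y), cfg@eiJitter)
  expect_lt(abs(prop - grid[which.max(ei)]), 1e-3)

  # proposals stay in bounds across random small surrogates
  for (i in 1:20) {
    Xr <- matrix(runif(6), ncol = 2)
    yr <- runif(3)
    gpr <- fitGp(Xr, yr, lengthscale = 0.5, signalSd = 0.5,
                 noiseSd = 0.05, optimize = FALSE)
    cfg2 <- boConfig(c(0, 0), c(1, 1), acqRestarts = 3L)
    p <- proposeNext(gpr, cfg2)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("more acquisition restarts never find a worse EI optimum", {
  # bimodal EI: two separated high points with a low middle
  X <- matrix(c(0.05, 0.5, 0.95))
  y <- c(0.8, 0.1, 0.82)
  gp <- fitGp(X, y, lengthscale = 0.08, signalSd = 0.5, noiseSd = 1e-3,
              optimize = FALSE)
  eiAt <- function(x, cfg) {
    pr <- gpPredict(gp, matrix(x))
    expectedImprovement(pr$mean, pr$sd, max(y), cfg@eiJitter)
  }
  cfg1 <- boConfig(0, 1, acqRestarts = 1L)
  cfg10 <- boConfig(0, 1, acqRestarts = 10L)
  set.seed(7); p1 <- proposeNext(gp, cfg1)
  set.seed(7); p10 <- proposeNext(gp, cfg10)
  expect_gte(eiAt(p10, cfg10), eiAt(p1, cfg1) - 1e-10)
})

test_that("a constant objective triggers the plateau stopping rule", {
  cfg <- boConfig(c(0, 0), c(1, 1), nInitRandom = 4L, maxSteps = 100L,
                  plateauWindow = 10L, plateauTol = 0.001,
                  refitPeriod = 5L, acqRestarts = 2L, seed = 3L)
  run <- runBo(function(z) 0.5, cfg)
  expect_identical(run@stopReason, "plateau")
  expect_equal(sum(run@history$phase == "step"), 11L)  # window + 1
})

test_that("seeded BO closes in on a known concave optimum", {
  gaps <- vapply(1:5, function(s) {
    cfg <- boConfig(c(0, 0), c(1, 1), nInitRandom = 8L, maxSteps = 60L,
                    plateauWindow = 100L, refitPeriod = 10L,
                    acqRestarts = 5L, seed = 100L + s)
    run <- runBo(function(z) 1 - sum((z - c(0.3, 0.7))^2), cfg)
    1 - max(run@history$score)
  }, numeric(1))
  expect_true(all(gaps <= 0.05))
})

test_that("best-so-far trajectories are monotone and seeds lead the history", {
  cfg <- boConfig(c(0, 0), c(1, 1), nInitRandom = 5L, maxSteps = 15L,
                  refitPeriod = 5L, acqRestarts = 3L, seed = 12L)
  run <- runBo(function(z) sum(z), cfg)
  expect_true(all(diff(bestTrajectory(run)) >= 0))
  expect_true(all(run@history$score <= run@history$best + 1e-12))

  seeds <- rbind(c(0.1, 0.2), c(0.8, 0.9))
  run2 <- runBo(function(z) sum(z), cfg, seeds = seeds)
  expect_identical(run2@history$phase[1:2], c("seed", "seed"))
  expect_equal(run2@Z[1:2, ], seeds)
  expect_equal(run2@history$score[1:2], rowSums(seeds))
})
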