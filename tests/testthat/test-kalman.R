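test_that("single-observation likelihood matches the closed form", {
  th <- c(0.7, 3, 0.9); sig <- 0.3
  vstat <- th[3]^2 / (2 * th[1])
  y <- 3.4
  expect_equal(kalmanLogLik(th, sig, times = 2, y = y),
               dnorm(y, th[2], sqrt(vstat + sig^2), log = TRUE))
  # fixed initial state: transition variance replaces the stationary one
  e <- exp(-th[1] * 2)
  expect_equal(kalmanLogLik(th, sig, times = 2, y = y, x0 = 1),
               dnorm(y, th[2] + (1 - th[2]) * e,
                     sqrt(vstat * (1 - e^2) + sig^2), log = TRUE))
})

test_that("recursion equals the brute-force joint Gaussian density", {
  set.seed(401)
  th <- c(0.4, 5, 0.6); sig <- 0.25
  times <- sort(runif(12, 0, 15))
  y <- rnorm(12, 5, 1)
  vstat <- th[3]^2 / (2 * th[1])
  # full covariance of the latent states under the stationary law
  S <- vstat * exp(-th[1] * abs(outer(times, times, "-"))) +
    diag(sig^2, 12)
  L <- t(chol(S))
  z <- forwardsolve(L, y - th[2])
  brute <- -0.5 * 12 * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
  expect_equal(kalmanLogLik(th, sig, times, y), brute, tolerance = 1e-10)
})

test_that("flat-likelihood limit: huge noise removes the data updates", {
  set.seed(402)
  th <- c(0.5, 4, 0.8); sig <- 1e7
  times <- 1:8
  y <- rnorm(8, 4, 1)
  vstat <- th[3]^2 / (2 * th[1])
  direct <- sum(dnorm(y, th[2], sqrt(vstat + sig^2), log = TRUE))
  expect_equal(kalmanLogLik(th, sig, times, y), direct, tolerance = 1e-6)
})

test_that("likelihood is invariant under time/parameter rescaling", {
  set.seed(403)
  th <- c(0.5, 5, 0.7); sig <- 0.2
  times <- 1:10
  y <- rnorm(10, 5, 1)
  a <- 3.7 # rescale time by a, theta1 by 1/a, theta3 by 1/sqrt(a)
  expect_equal(kalmanLogLik(th, sig, times, y),
               kalmanLogLik(c(th[1] / a, th[2], th[3] / sqrt(a)), sig,
                            a * times, y), tolerance = 1e-12)
})

test_that("generated OU data peak the exact likelihood near the truth", {
  set.seed(404)
  m <- makeOUModel()
  ds <- generateDataset(m, M = 8, times = benchmarkTimes("ou"))
  grid <- seq(3, 8, by = 0.25) # theta2 grid around the true log-mean exp(1.61)=5
  prof <- sapply(grid, function(t2) {
    sum(sapply(seq_len(8), function(i)
      kalmanLogLik(c(ds$truth$c[i, 1], t2, ds$truth$c[i, 3]), 0.2,
                   ds$data@times[[i]], ds$data@obs[[i]][, 1])))
  })
  expect_lt(abs(grid[which.max(prof)] - 5), 0.5)
})

test_that("prior-only inference reproduces the prior law", {
  # no individuals: step 3 draws from the NIW prior, and the error scale is
  # sampled from its own prior by Metropolis
  set.seed(405)
  m <- makeOUModel()
  empty <- cellData(times = list(), obs = list())
  pri <- ssmemPriors(m)
  cfg <- inferenceConfig(nIterations = 6000, mode = "unperturbed",
                         likelihood = "kalman", burnin = 0.2, priors = pri)
  s <- runInference(m, empty, cfg)
  # mu marginal: mean mu0, sd sqrt(E Omega_jj / lambda0)
  expect_true(all(abs(colMeans(s@mu) - pri$eta$mu0) < 0.25))
  # xi prior is log-normal(log xiDefault, 1)
  lx <- log(s@xi[, 1])
  expect_lt(abs(mean(lx) - log(m@xiDefault)), 0.15)
  expect_lt(abs(sd(lx) - 1), 0.2)
})

test_that("exact Gibbs and resumed runs are bit-identical", {
  fx <- ouFixture(M = 3, seed = 406)
  cfg <- inferenceConfig(nIterations = 400, mode = "perturbed",
                         likelihood = "kalman", burnin = 0)
  set.seed(1)
  full <- runInference(fx$model, fx$ds$data, cfg)
  cfg2 <- cfg; cfg2$nIterations <- 200L
  set.seed(1)
  half <- runInference(fx$model, fx$ds$data, cfg2)
  resumed <- continueInference(fx$model, fx$ds$data, cfg2, half, 200)
  expect_identical(resumed@mu, full@mu)
  expect_identical(resumed@omega, full@omega)
  expect_identical(resumed@xi, full@xi)
})
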