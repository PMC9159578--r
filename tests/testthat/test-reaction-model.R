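test_that("mass-action propensities evaluate correctly and deterministically", {
  net <- bdNetworkR()
  h <- evaluatePropensities(net, x = 10, c = c(2, 0.5))
  expect_equal(unname(h), c(2, 5))
  # empty-reactant state: the degradation propensity vanishes
  h0 <- evaluatePropensities(net, x = 0, c = c(2, 0.5))
  expect_equal(unname(h0), c(2, 0))
  # deterministic: bit-identical on repeated evaluation
  expect_identical(evaluatePropensities(net, 7, c(1.3, 0.7)),
                   evaluatePropensities(net, 7, c(1.3, 0.7)))
  # compiled and callback paths agree
  expect_equal(unname(evaluatePropensities(bdNetworkC(), 10, c(2, 0.5))),
               unname(h))
})

test_that("Schlogl propensities match an independent symbolic evaluation", {
  m <- makeSchloglModel()
  x <- 100
  c1 <- 0.024; c2 <- 1e-4; c3 <- 146.7; c4 <- 2.5
  h <- evaluatePropensities(m@network, x, c1, kappa = c(c2, c3, c4))
  expect_equal(unname(h),
               c(c1 * x * (x - 1) / 2, c2 * x * (x - 1) * (x - 2) / 6,
                 c3, c4 * x))
  msq <- makeSchloglModel(combinatorial = FALSE)
  hsq <- evaluatePropensities(msq@network, x, c1, kappa = c(c2, c3, c4))
  expect_equal(unname(hsq), c(c1 * x^2 / 2, c2 * x^3 / 6, c3, c4 * x))
})

test_that("invalid propensities raise errors naming the reaction", {
  bad <- ReactionNetwork(matrix(c(1L, -1L), nrow = 1),
                         propensity = function(x, c, kappa, t) c(c[1], -1))
  expect_error(evaluatePropensities(bad, 1, 1), "reaction 2")
  nf <- ReactionNetwork(matrix(1L, 1, 1),
                        propensity = function(x, c, kappa, t) NaN)
  expect_error(evaluatePropensities(nf, 1, 1), "non-finite")
})

test_that("population sampling has log-normal moments and degenerate limit", {
  # degenerate law: zero covariance gives the deterministic value
  pop0 <- PopulationLaw(0, matrix(0))
  expect_true(all(sampleIndividualParameters(pop0, 20) == 1))
  # CLT check of log-moments at large M
  set.seed(1)
  pop <- PopulationLaw(c(0, 0), diag(2))
  M <- 1e5
  L <- log(sampleIndividualParameters(pop, M))
  se_mean <- 1 / sqrt(M)
  expect_true(all(abs(colMeans(L)) < 3 * se_mean))
  S <- cov(L)
  se_var <- sqrt(2 / M) # var of sample variance of N(0,1)
  expect_lt(abs(S[1, 1] - 1), 3 * se_var)
  expect_lt(abs(S[2, 2] - 1), 3 * se_var)
  expect_lt(abs(S[1, 2]), 3 / sqrt(M))
  # non-PD covariance is rejected
  expect_error(PopulationLaw(c(0, 0), matrix(c(1, 2, 2, 1), 2)), "definite")
  # benchmark shape: 40 cells x 4 rates, all positive
  cs <- sampleIndividualParameters(makeCircadianModel()@population, 40)
  expect_equal(dim(cs), c(40, 4))
  expect_true(all(cs > 0))
})

test_that("observation log-density is correct and normalizes", {
  obs <- ObservationModel(P = 1, d = 1)
  # zero residual, unit sigma
  expect_equal(observationLogDensity(obs, y = 3, x = 3, xi = 1),
               -0.5 * log(2 * pi))
  # residual 2, sigma 2: quadrature oracle for the same Gaussian
  ld <- observationLogDensity(obs, y = 2, x = 0, xi = 2)
  f <- function(y) exp(-0.5 * (y / 2)^2) / sqrt(2 * pi * 4)
  expect_equal(ld, log(f(2)))
  # numeric normalization over y
  total <- integrate(function(y) sapply(y, function(yy)
    exp(observationLogDensity(obs, yy, x = 1.3, xi = 0.7))),
    -Inf, Inf)$value
  expect_lt(abs(total - 1), 1e-6)
  expect_error(observationLogDensity(obs, 1, 1, xi = 0), "positive")
})

test_that("ratio observable evaluates the Mig1-style nonlinear observation", {
  obs <- mig1RatioObservation()
  expect_equal(observationLogDensity(obs, y = 0.5, x = c(2, 1), xi = 0.1),
               -0.5 * log(2 * pi * 0.01))
  X <- rbind(c(2, 1), c(4, 1))
  expect_equal(drop(observationMean(obs, X)), c(0.5, 0.25))
})

test_that("cell-varying initial states are taken from designated c coordinates", {
  m <- makeOUModel()
  expect_true(is.na(resolveX0(m, c(1, 2, 3))[1])) # stationary law marker
  net <- bdNetworkC()
  m2 <- SSMEMModel(net, ObservationModel(P = 1, d = 1),
                   PopulationLaw(c(0, 0, 2), diag(0.01, 3)),
                   x0FromC = 3L, simulator = "ssa")
  expect_equal(resolveX0(m2, c(1.5, 0.5, 12)), 12)
})
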