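test_that("multiESS is near n for iid draws and follows the AR(1) closed form", {
  set.seed(601)
  X <- matrix(rnorm(1e4 * 3), 1e4, 3)
  expect_lt(abs(multiESS(X) / 1e4 - 1), 0.1)
  # AR(1) with phi = 0.9: ESS = n (1 - phi) / (1 + phi)
  n <- 1e5; phi <- 0.9
  ar <- replicate(2, as.numeric(arima.sim(list(ar = phi), n)))
  ess <- multiESS(ar)
  expect_lt(abs(ess / (n * (1 - phi) / (1 + phi)) - 1), 0.15)
  # never exceeds n (up to estimator tolerance) and is affine-invariant
  A <- matrix(c(2, 0.5, -1, 3), 2)
  expect_equal(multiESS(ar %*% A) / ess, 1, tolerance = 0.05)
  expect_error(multiESS(cbind(ar[, 1], ar[, 1] * 2 + 3)), "singular|column")
  expect_error(multiESS(cbind(rnorm(100), rep(1, 100))), "constant")
})

test_that("wasserstein1 has exact translation, symmetry and triangle properties", {
  set.seed(602)
  a <- rnorm(500)
  expect_equal(wasserstein1(a, a), 0)
  expect_equal(wasserstein1(a, a + 0.73), 0.73)
  b <- rgamma(500, 2); c <- rt(500, 5)
  expect_equal(wasserstein1(a, b), wasserstein1(b, a))
  expect_lte(wasserstein1(a, c), wasserstein1(a, b) + wasserstein1(b, c) + 1e-12)
  # unequal sizes agree with the equal-size computation on merged data
  expect_equal(wasserstein1(a, a[1:250] + 0.5), wasserstein1(a[1:250] + 0.5, a))
})

test_that("wasserstein1 matches the closed form for two centred normals", {
  # W1(N(0,1), N(0,s)) = |1 - s| E|Z| = |1 - s| sqrt(2/pi)
  set.seed(603)
  n <- 1e5
  a <- rnorm(n); b <- rnorm(n, sd = 2)
  w <- wasserstein1(a, b)
  closed <- (2 - 1) * sqrt(2 / pi)
  expect_lt(abs(w - closed), 3 * 2 / sqrt(n) + 0.01)
  # quadrature oracle: integral of |qnorm(u) - qnorm(u, sd = 2)| du
  quad <- integrate(function(u) abs(qnorm(u) - qnorm(u, sd = 2)),
                    0, 1)$value
  expect_equal(closed, quad, tolerance = 1e-6)
})

test_that("tiny-sample exact multivariate distance agrees in one dimension", {
  set.seed(604)
  a <- rnorm(6); b <- rnorm(6)
  expect_equal(wassersteinExactSmall(matrix(a), matrix(b)),
               wasserstein1(a, b), tolerance = 1e-12)
  # translation in 2-d
  A <- matrix(rnorm(12), 6, 2)
  expect_equal(wassersteinExactSmall(A, A + 1), sqrt(2), tolerance = 1e-12)
})

test_that("particle tuning picks the ladder minimum for noise-free estimates", {
  # near-deterministic OU (tiny diffusion): estimator variance ~ 0
  set.seed(605)
  m <- makeOUModel(mu = log(c(0.5, 5, 0.01)), tau = c(0.01, 0.01, 0.01),
                   sigma = 0.5)
  ds <- generateDataset(m, 2, benchmarkTimes("ou"))
  cfg <- pfConfig(kind = "guided_mdb", integrator = "langevin", dt = 0.2)
  pilot <- list(c = ds$truth$c, kappa = numeric(), xi = 0.5)
  res <- tuneParticles(m, ds$data, pilot, cfg, mode = "perturbed",
                       nReplicates = 10)
  expect_true(all(res$N == res$ladder[1]))
  expect_false(res$exhausted)
})

test_that("tuned N is monotone in the variance target", {
  set.seed(606)
  fx <- ouFixture(M = 2, seed = 606)
  cfg <- pfConfig(kind = "bootstrap", integrator = "langevin", dt = 0.2)
  pilot <- list(c = fx$ds$truth$c, kappa = numeric(), xi = 0.2)
  Ns <- sapply(c(5, 1, 0.2), function(vt) {
    set.seed(1)
    max(suppressWarnings(
      tuneParticles(fx$model, fx$ds$data, pilot, cfg, mode = "perturbed",
                    varTarget = vt, nReplicates = 15)$N))
  })
  expect_true(all(diff(Ns) >= 0))
})

test_that("visual-check bands collapse for a point-mass, noise-free model", {
  set.seed(607)
  m <- makeOUModel(mu = log(c(0.5, 5, 1e-4)), tau = c(1e-6, 1e-6, 1e-6),
                   sigma = 1e-6, stationaryInit = FALSE, x0 = 3)
  bands <- posteriorVisualCheck(m, NULL, times = 1:10, MCells = 10,
                                nRepeats = 30)
  width <- bands$bands[, 3, ] - bands$bands[, 1, ]
  expect_lt(max(width), 1e-3)
  # the collapsed quantiles equal the deterministic mean path
  det <- 5 + (3 - 5) * exp(-0.5 * (1:10))
  expect_equal(bands$bands[2, 2, ], det, tolerance = 1e-2)
})

test_that("generator-parameter bands cover fresh circadian data quantiles", {
  set.seed(608)
  m <- makeCircadianModel()
  times <- benchmarkTimes("circadian")
  bands <- posteriorVisualCheck(m, NULL, times, MCells = 40, nRepeats = 120)
  fresh <- generateDataset(m, 40, times)
  obsQ <- observedQuantiles(fresh$data)
  expect_gte(bandCoverage(bands, obsQ), 0.9)
})
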