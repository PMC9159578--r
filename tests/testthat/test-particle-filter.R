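test_that("auxiliary refresh preserves the standard-normal law and correlation", {
  set.seed(201)
  m <- makeOUModel()
  cfg <- pfConfig(nParticles = 400, integrator = "langevin", dt = 0.2,
                  rho = 0.999)
  u <- makeAuxiliary(m, benchmarkTimes("ou"), cfg)
  n <- length(u$uProp)
  expect_gt(n, 3e4)
  u2 <- refreshAuxiliary(u, 0.999)
  # marginal law unchanged
  expect_lt(abs(mean(u2$uProp)), 3 / sqrt(n))
  expect_lt(abs(sd(u2$uProp) - 1), 3 / sqrt(2 * n))
  # correlation with the previous draw is rho
  r <- cor(as.numeric(u$uProp), as.numeric(u2$uProp))
  expect_lt(abs(r - 0.999), 3 * (1 - 0.999^2) / sqrt(n) + 1e-4)
  # rho = 0 refresh is independent
  u3 <- refreshAuxiliary(u, 0)
  expect_lt(abs(cor(as.numeric(u$uProp), as.numeric(u3$uProp))), 3 / sqrt(n))
  expect_error(refreshAuxiliary(u, 1), "rho")
})

test_that("invalid correlated-filter configurations are rejected", {
  expect_error(pfConfig(integrator = "ssa", rho = 0.9), "rho")
  expect_error(pfConfig(kind = "guided_mdb", integrator = "ssa"), "langevin")
  expect_error(pfConfig(rho = 1), "rho")
})

test_that("systematic resampling is unbiased with correct degenerate cases", {
  # uniform weights: every particle has exactly one offspring
  idx <- systematicResample(rep(1 / 8, 8), u = 0.37)
  expect_setequal(idx, 1:8)
  # point mass: all offspring from that particle
  expect_true(all(systematicResample(c(1, rep(0, 7)), u = 0.5) == 1))
  # brute-force expectation over many resamples for random weights
  set.seed(202)
  w <- rgamma(8, 1); w <- w / sum(w)
  counts <- numeric(8)
  nrep <- 2e4
  for (r in seq_len(nrep)) {
    idx <- systematicResample(w, u = runif(1))
    tab <- tabulate(idx, 8)
    counts <- counts + tab
  }
  expected <- 8 * w
  se <- sqrt(expected / nrep) # generous (systematic is lower-variance)
  expect_true(all(abs(counts / nrep - expected) < 4 * se + 0.005))
  expect_error(systematicResample(c(0.5, 0.6)), "probability")
})

test_that("a deterministic degenerate filter reduces to the observation density", {
  # absorbing dynamics: the state never leaves x0, so with N = 1 the
  # estimate equals the summed observation log-density along the path
  net <- nullNetwork()
  m <- SSMEMModel(net, ObservationModel(P = 1, d = 1),
                  PopulationLaw(0, matrix(0.01)), x0 = 4, simulator = "ssa")
  times <- 1:6
  y <- c(4.1, 3.9, 4.4, 4.0, 3.7, 4.2)
  cfg <- pfConfig(nParticles = 1, integrator = "ssa")
  res <- pfLogLik(m, times, y, c = 1, xi = 0.5, cfg = cfg)
  expect_equal(res$value, sum(dnorm(y, 4, 0.5, log = TRUE)))
  expect_equal(res$increments, dnorm(y, 4, 0.5, log = TRUE))
})

test_that("both filters are unbiased against the exact OU likelihood", {
  fx <- ouFixture(M = 1, seed = 203)
  y <- fx$ds$data@obs[[1]][, 1]
  theta <- fx$ds$truth$c[1, ]
  lkal <- kalmanLogLik(theta, 0.2, fx$times, y)
  set.seed(204)
  for (kind in c("bootstrap", "guided_mdb")) {
    cfg <- pfConfig(nParticles = 64, kind = kind, integrator = "langevin",
                    dt = 0.2)
    ll <- replicate(250, pfLogLik(fx$model, fx$times, y, theta,
                                  xi = 0.2, cfg = cfg)$value)
    r <- exp(ll - lkal)
    expect_lt(abs(mean(r) - 1), 3 * sd(r) / sqrt(length(r)))
  }
})

test_that("estimator variance decreases monotonically with N", {
  fx <- ouFixture(M = 1, seed = 205)
  y <- fx$ds$data@obs[[1]][, 1]
  theta <- fx$ds$truth$c[1, ]
  set.seed(206)
  vars <- sapply(c(8, 32, 128), function(N) {
    cfg <- pfConfig(nParticles = N, kind = "bootstrap",
                    integrator = "langevin", dt = 0.2)
    var(replicate(150, pfLogLik(fx$model, fx$times, y, theta, xi = 0.2,
                                cfg = cfg)$value))
  })
  expect_true(all(diff(vars) < 0))
})

test_that("correlated estimates stay strongly correlated across refreshes", {
  fx <- ouFixture(M = 1, seed = 207)
  y <- fx$ds$data@obs[[1]][, 1]
  theta <- fx$ds$truth$c[1, ]
  set.seed(208)
  runChain <- function(kind) {
    cfg <- pfConfig(nParticles = 50, kind = kind, integrator = "langevin",
                    dt = 0.2, rho = 0.999)
    u <- makeAuxiliary(fx$model, fx$times, cfg)
    vapply(seq_len(120), function(k) {
      u <<- refreshAuxiliary(u, 0.999)
      pfLogLik(fx$model, fx$times, y, theta, xi = 0.2, cfg = cfg, u = u)$value
    }, 0)
  }
  llG <- runChain("guided_mdb")
  expect_gt(cor(llG[-1], llG[-length(llG)]), 0.9)
  llB <- runChain("bootstrap")
  expect_gt(cor(llB[-1], llB[-length(llB)]), 0.8)
})

test_that("uninformative observations make the guided filter equal bootstrap", {
  # sigma -> Inf: the bridge proposal loses its conditioning and both
  # filters propagate identically from the same auxiliary numbers
  fx <- ouFixture(M = 1, seed = 209)
  y <- fx$ds$data@obs[[1]][, 1]
  theta <- fx$ds$truth$c[1, ]
  cfgG <- pfConfig(nParticles = 20, kind = "guided_mdb",
                   integrator = "langevin", dt = 0.2, rho = 0.5)
  cfgB <- pfConfig(nParticles = 20, kind = "bootstrap",
                   integrator = "langevin", dt = 0.2, rho = 0.5)
  set.seed(210)
  u <- makeAuxiliary(fx$model, fx$times, cfgG)
  big <- 1e8
  g <- pfLogLik(fx$model, fx$times, y, theta, xi = big, cfg = cfgG, u = u)
  b <- pfLogLik(fx$model, fx$times, y, theta, xi = big, cfg = cfgB, u = u)
  expect_equal(g$value, b$value, tolerance = 1e-6)
})

test_that("guided filter beats bootstrap variance on the bistable model", {
  set.seed(211)
  m <- makeSchloglModel()
  ds <- generateDataset(m, 1, benchmarkTimes("schlogl"))
  y <- ds$data@obs[[1]][, 1]
  c1 <- ds$truth$c[1, ]
  vv <- sapply(c("guided_mdb", "bootstrap"), function(kind) {
    cfg <- pfConfig(nParticles = 40, kind = kind, integrator = "langevin",
                    dt = 0.05)
    ll <- replicate(100, pfLogLik(m, benchmarkTimes("schlogl"), y, c1,
                                  m@kappaDefault, 10, cfg)$value)
    c(var = var(ll), finite = mean(is.finite(ll)))
  })
  expect_true(all(vv["finite", ] == 1))
  expect_lt(vv["var", "guided_mdb"], vv["var", "bootstrap"])
})

test_that("total particle death yields -Inf, not an exception", {
  # tau-leap negativity rule: particles driven negative are killed at the
  # next observation; killing every particle zeroes the estimate
  dn <- deathNetwork()
  m <- SSMEMModel(dn, ObservationModel(P = 1, d = 1),
                  PopulationLaw(log(200), matrix(1e-4)), x0 = 5,
                  simulator = "ssa")
  cfg <- pfConfig(nParticles = 30, integrator = "tauleap", dt = 1)
  set.seed(212)
  res <- pfLogLik(m, times = 1, y = 5, c = 200, xi = 0.5, cfg = cfg)
  expect_identical(res$value, -Inf)
  # ESS stays within [1, N] on a healthy run
  fx <- ouFixture(M = 1, seed = 213)
  cfg <- pfConfig(nParticles = 25, integrator = "langevin", dt = 0.2)
  r <- pfLogLik(fx$model, fx$times, fx$ds$data@obs[[1]][, 1],
                fx$ds$truth$c[1, ], xi = 0.2, cfg = cfg)
  expect_true(all(r$ess >= 1 - 1e-9 & r$ess <= 25 + 1e-9))
})
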