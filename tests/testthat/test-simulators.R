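test_that("absorbing states and reproducibility hold for all simulators", {
  net <- nullNetwork()
  out <- seq(1, 5)
  expect_true(all(simulateSSA(net, 1, x0 = 7, outTimes = out)@states == 7))
  expect_true(all(simulateTauLeap(net, 1, x0 = 7, outTimes = out,
                                  dt = 0.5)@states == 7))
  expect_true(all(simulateLangevin(net, 1, x0 = 7, outTimes = out,
                                   dt = 0.5)@states == 7))
  # fixed seed => bit-identical paths
  bd <- bdNetworkC()
  set.seed(99); a <- simulateSSA(bd, c(5, 1), x0 = 2, outTimes = out)
  set.seed(99); b <- simulateSSA(bd, c(5, 1), x0 = 2, outTimes = out)
  expect_identical(a@states, b@states)
  set.seed(99); a <- simulateLangevin(bd, c(5, 1), x0 = 2, outTimes = out, dt = 0.1)
  set.seed(99); b <- simulateLangevin(bd, c(5, 1), x0 = 2, outTimes = out, dt = 0.1)
  expect_identical(a@states, b@states)
})

test_that("SSA matches analytic laws of linear processes", {
  set.seed(101)
  # pure death from 50: E X(1) = 50 exp(-1), Var = 50 e^-1 (1 - e^-1)
  dn <- deathNetwork()
  n <- 1e4
  xs <- replicate(n, simulateSSA(dn, 1, x0 = 50, outTimes = 1)@states[1, 1])
  mu <- 50 * exp(-1)
  se <- sqrt(50 * exp(-1) * (1 - exp(-1)) / n)
  expect_lt(abs(mean(xs) - mu), 3 * se)
  # birth-death at stationarity: X ~ Poisson(c1/c2)
  bd <- bdNetworkC()
  xs <- replicate(n, simulateSSA(bd, c(8, 1), x0 = 8, outTimes = 12)@states[1, 1])
  expect_lt(abs(mean(xs) - 8), 3 * sqrt(8 / n))
  expect_lt(abs(var(xs) - 8), 4 * sqrt((2 * 64 + 8) / n))
  # jump paths are integer-valued and nonnegative
  tr <- simulateSSA(bd, c(8, 1), x0 = 3, outTimes = seq(0.1, 10, 0.1))
  expect_true(all(tr@states >= 0) && all(tr@states == round(tr@states)))
})

test_that("Extrande reduces to SSA for constant rates, any valid bound", {
  set.seed(102)
  bd <- bdNetworkC()
  n <- 4000
  draw <- function(f) replicate(n, f()@states[1, 1])
  xs <- draw(function() simulateSSA(bd, c(6, 1), x0 = 0, outTimes = 3))
  xe <- draw(function() simulateExtrande(bd, c(6, 1), x0 = 0, outTimes = 3,
                                         lookahead = 0.5))
  expect_gt(suppressWarnings(ks.test(xs, xe)$p.value), 0.01)
  # slack bound (10x total propensity): same law, just more thinning
  slack <- function(x, c, kappa, t0, t1) 10 * (c[1] + c[2] * x[1])
  xe10 <- draw(function() simulateExtrande(bd, c(6, 1), x0 = 0, outTimes = 3,
                                           bound = slack, lookahead = 0.5))
  expect_gt(suppressWarnings(ks.test(xs, xe10)$p.value), 0.01)
  # an invalid bound is detected at the offending time (long horizon so a
  # candidate event occurs with probability ~ 1)
  badBound <- function(x, c, kappa, t0, t1) 0.5
  set.seed(7)
  expect_error(simulateExtrande(bd, c(6, 1), x0 = 5, outTimes = 30,
                                bound = badBound), "bound violated")
})

test_that("circadian transcription rhythm has a 24 h dominant period", {
  set.seed(103)
  m <- makeCircadianModel()
  times <- benchmarkTimes("circadian")
  P <- rowMeans(vapply(seq_len(400), function(i)
    simulateCell(m, exp(m@population@mu), numeric(), times)@states[, 2],
    numeric(length(times))))
  sp <- stats::spec.pgram(P - mean(P), plot = FALSE, detrend = FALSE)
  period <- (times[2] - times[1]) / sp$freq[which.max(sp$spec)]
  expect_equal(period, 24, tolerance = 0.2)
})

test_that("tau-leap is exact for zero-order input and converges for linear nets", {
  set.seed(104)
  # single reaction 0 -> X at rate 5 over [0, 2], one leap: X ~ Poisson(10)
  bn <- birthNetwork()
  xs <- replicate(1e4, simulateTauLeap(bn, 5, x0 = 0, outTimes = 2,
                                       dt = 2)@states[1, 1])
  expect_lt(abs(mean(xs) - 10), 3 * sqrt(10 / 1e4))
  expect_lt(abs(var(xs) - 10), 4 * sqrt((2 * 100 + 10) / 1e4))
  # linear birth-death at small dt matches the analytic mean at t = 1
  bd <- bdNetworkC()
  n <- 4000
  xs <- replicate(n, simulateTauLeap(bd, c(10, 1), x0 = 0, outTimes = 1,
                                     dt = 0.02)@states[1, 1])
  manly <- 10 * (1 - exp(-1))
  expect_lt(abs(mean(xs) - manly), 3 * sqrt(manly / n) + 0.2)
  expect_error(simulateTauLeap(bd, c(1, 1), x0 = 0, outTimes = 1, dt = 0),
               "dt")
})

test_that("Langevin matches drift-only ODE and linear moments", {
  bd <- bdNetworkC()
  # drift-only: deterministic Euler solution of xdot = c1 - c2 x
  tr <- simulateLangevin(bd, c(10, 1), x0 = 0, outTimes = 1, dt = 1e-3,
                         driftOnly = TRUE)
  expect_equal(unname(tr@states[1, 1]), 10 * (1 - exp(-1)), tolerance = 1e-2)
  set.seed(105)
  n <- 4000
  xs <- replicate(n, simulateLangevin(bd, c(10, 1), x0 = 0, outTimes = 1,
                                      dt = 0.01)@states[1, 1])
  manly <- 10 * (1 - exp(-1))
  expect_lt(abs(mean(xs) - manly), 3 * sqrt(manly / n) + 0.1)
  expect_lt(abs(var(xs) / manly - 1), 0.12) # Poisson-like variance
})

test_that("Euler OU endpoints converge to the exact transition law", {
  set.seed(106)
  m <- makeOUModel()
  theta <- c(0.5, 5, 0.5)
  n <- 5000
  euler <- replicate(n, simulateLangevin(m@network, theta, x0 = 3,
                                         outTimes = 1, dt = 1e-3)@states[1, 1])
  exact <- replicate(n, simulateOUExact(theta, 1, x0 = 3))
  expect_gt(suppressWarnings(ks.test(euler, exact)$p.value), 0.01)
  # and the analytic transition moments
  e <- exp(-0.5)
  expect_lt(abs(mean(euler) - (5 + (3 - 5) * e)), 3 * sd(euler) / sqrt(n))
})

test_that("event caps guard against runaway networks", {
  expl <- ReactionNetwork(matrix(1L, 1, 1),
                          propensity = function(x, c, kappa, t) c[1] * x[1])
  expect_error(simulateSSA(expl, 5, x0 = 10, outTimes = 100, maxEvents = 1e4),
               "cap")
})
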