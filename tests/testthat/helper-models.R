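# Shared fixtures, all built in code.

# birth-death network 0 -> X (c1), X -> 0 (c2 x), via the R-callback path
bdNetworkR <- function() {
  ReactionNetwork(matrix(c(1L, -1L), nrow = 1),
                  propensity = function(x, c, kappa, t) c(c[1], c[2] * x[1]))
}

# same network through the compiled fast path
bdNetworkC <- function() {
  ReactionNetwork(matrix(c(1L, -1L), nrow = 1), builtin = "birthdeath")
}

# network with all propensities zero (absorbing state)
nullNetwork <- function(d = 1) {
  ReactionNetwork(matrix(rep(c(1L, rep(0L, d - 1)), 1), nrow = d),
                  propensity = function(x, c, kappa, t) 0)
}

# single-species pure death X -> 0 at rate c x
deathNetwork <- function() {
  ReactionNetwork(matrix(-1L, 1, 1),
                  propensity = function(x, c, kappa, t) c[1] * x[1])
}

# zero-order pure birth 0 -> X at constant rate c
birthNetwork <- function() {
  ReactionNetwork(matrix(1L, 1, 1),
                  propensity = function(x, c, kappa, t) c[1])
}

# small OU dataset for filter/inference tests
ouFixture <- function(M = 3, seed = 42) {
  set.seed(seed)
  m <- makeOUModel()
  ds <- generateDataset(m, M, benchmarkTimes("ou"))
  list(model = m, ds = ds, times = benchmarkTimes("ou"))
}
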