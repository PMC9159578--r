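# plain Metropolis-Hastings loop on an exact density (no particle filter)
mhLoop <- function(state, logTarget, theta0, n, keepEvery = 1) {
  theta <- theta0
  lp <- logTarget(theta)
  acc <- 0
  draws <- matrix(NA_real_, floor(n / keepEvery), length(theta0))
  for (it in seq_len(n)) {
    pr <- propose(state, theta)
    lp2 <- logTarget(pr$theta)
    alpha <- min(1, exp(lp2 - lp))
    if (runif(1) < alpha) {
      theta <- pr$theta; lp <- lp2; acc <- acc + 1
    }
    state <- adaptProposal(state, theta, alpha, pr$z)
    if (it %% keepEvery == 0) draws[it / keepEvery, ] <- theta
  }
  list(state = state, draws = draws, acc = acc / n)
}
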