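# Population-parameter (eta) updates: conjugate Normal-Inverse-Wishart draws
# for the log-normal population law, per-coordinate Normal-Inverse-Gamma for
# the diagonal family, Gaussian conjugate draws for the perturbed-mode
# population locations of kappa/xi, and an HMC alternative for non-conjugate
# priors.

#' Normal-Inverse-Wishart prior for (mu, Omega)
#'
#' \eqn{\Omega \sim IW(\nu_0, \Psi_0)}, \eqn{\mu | \Omega \sim N(\mu_0,
#' \Omega / \lambda_0)}. This is the conjugate prior for the Gaussian law of
#' the log individual rates, so the population step of the Gibbs sampler is
#' an exact draw.
#'
#' @param mu0 prior mean of mu
#' @param lambda0 prior pseudo-observations for mu
#' @param nu0 inverse-Wishart degrees of freedom (> dim + 1)
#' @param Psi0 inverse-Wishart scale matrix (vector = diagonal)
#' @return a list of class "niwPrior"
#' @export
niwPrior <- function(mu0, lambda0 = 1, nu0 = length(mu0) + 3, Psi0 = NULL) {
  p <- length(mu0)
  if (is.null(Psi0)) Psi0 <- diag(0.2^2 * (nu0 - p - 1), p)
  if (is.vector(Psi0) && !is.matrix(Psi0)) Psi0 <- diag(Psi0, p)
  structure(list(mu0 = as.numeric(mu0), lambda0 = lambda0, nu0 = nu0,
                 Psi0 = as.matrix(Psi0)), class = "niwPrior")
}

# inverse-Wishart draw via the Bartlett decomposition of Wishart(nu, Psi^-1)
rinvwishart <- function(nu, Psi) {
  p <- nrow(Psi)
  stopifnot(nu > p - 1)
  V <- chol2inv(chol(Psi)) # Psi^-1
  Lv <- t(chol(V))
  A <- matrix(0, p, p)
  diag(A) <- sqrt(stats::rchisq(p, df = nu - seq_len(p) + 1))
  if (p > 1) A[lower.tri(A)] <- stats::rnorm(p * (p - 1) / 2)
  W <- Lv %*% A
  W <- tcrossprod(W) # ~ Wishart(nu, Psi^-1)
  chol2inv(chol(W))
}

# NIW posterior parameters given rows of X ~ N(mu, Omega)
niwPosterior <- function(prior, X) {
  X <- as.matrix(X)
  M <- nrow(X); p <- ncol(X)
  if (M == 0) return(prior)
  xbar <- colMeans(X)
  Sc <- crossprod(sweep(X, 2, xbar)) # scatter about the sample mean
  lambdaN <- prior$lambda0 + M
  muN <- (prior$lambda0 * prior$mu0 + M * xbar) / lambdaN
  dev <- xbar - prior$mu0
  PsiN <- prior$Psi0 + Sc +
    (prior$lambda0 * M / lambdaN) * tcrossprod(dev)
  niwPrior(muN, lambdaN, prior$nu0 + M, PsiN)
}

#' Exact conjugate draw of the population parameters
#'
#' Draws \eqn{(\mu, \Omega)} from the Normal-Inverse-Wishart full
#' conditional given the log individual rates. For the diagonal family the
#' draw is done per coordinate (equivalent to independent
#' Normal-Inverse-Gamma updates with the diagonal of \eqn{\Psi_0}).
#'
#' @param prior a \code{\link{niwPrior}}
#' @param logC M x dim_c matrix of log individual rates
#' @param family "lognormal_full" or "lognormal_diag"
#' @return list with elements \code{mu} and \code{Omega}
#' @export
sampleEtaConjugate <- function(prior, logC, family = "lognormal_full") {
  logC <- as.matrix(logC)
  p <- length(prior$mu0)
  if (family == "lognormal_diag") {
    mu <- numeric(p); om <- numeric(p)
    for (j in seq_len(p)) {
      pj <- niwPrior(prior$mu0[j], prior$lambda0, prior$nu0,
                     matrix(prior$Psi0[j, j]))
      post <- niwPosterior(pj, logC[, j, drop = FALSE])
      om[j] <- post$Psi0[1, 1] / stats::rchisq(1, df = post$nu0)
      mu[j] <- stats::rnorm(1, post$mu0, sqrt(om[j] / post$lambda0))
    }
    return(list(mu = mu, Omega = diag(om, p)))
  }
  post <- niwPosterior(prior, logC)
  Omega <- rinvwishart(post$nu0, post$Psi0)
  L <- safeCholLower(Omega / post$lambda0)
  mu <- post$mu0 + as.numeric(L %*% stats::rnorm(p))
  list(mu = mu, Omega = Omega)
}

# Gaussian conjugate draw for a population location with known perturbation
# variance delta^2: logk_i ~ N(loc, delta^2), loc ~ N(m0, s0^2)
samplePopLocation <- function(logK, delta, m0, s0) {
  M <- nrow(logK)
  vpost <- 1 / (1 / s0^2 + M / delta^2)
  mpost <- vpost * (m0 / s0^2 + M * colMeans(logK) / delta^2)
  stats::rnorm(ncol(logK), mpost, sqrt(vpost))
}

# ---------------------------------------------------------------------------
# HMC eta-step (for non-conjugate priors, and as a cross-check of the
# conjugate draw). Unconstrained parameterisation:
#   phi = (mu, u, w):  Omega = L L',  diag(L) = exp(u),  L[lower] = w.
# The Jacobian of (u, w) -> Omega is log|J| = p log 2 + sum_j (p - j + 2) u_j
# (Cholesky-to-covariance factor (p - j + 1) plus exp factor 1 per diagonal).

etaUnpack <- function(phi, p) {
  mu <- phi[seq_len(p)]
  u <- phi[p + seq_len(p)]
  L <- diag(exp(u), p)
  if (p > 1) L[lower.tri(L)] <- phi[(2 * p + 1):length(phi)]
  list(mu = mu, u = u, L = L, Omega = tcrossprod(L))
}

etaPack <- function(mu, Omega) {
  L <- safeCholLower(Omega + diag(1e-12, length(mu)))
  c(mu, log(pmax(diag(L), 1e-12)), L[lower.tri(L)])
}

# log IW density (unnormalised) + log N(mu; mu0, Omega/lambda0)
niwLogDensity <- function(mu, Omega, prior) {
  p <- length(mu)
  cO <- tryCatch(chol(Omega), error = function(e) NULL)
  if (is.null(cO)) return(-Inf)
  logdet <- 2 * sum(log(diag(cO)))
  Oinv <- chol2inv(cO)
  -((prior$nu0 + p + 1) / 2) * logdet - 0.5 * sum(prior$Psi0 * Oinv) +
    dmvnormLog(mu, prior$mu0, Omega / prior$lambda0)
}

# Gaussian log-likelihood of all rows of X at (mu, L) with Omega = L L'
mvnRowsLogLik <- function(X, mu, L) {
  M <- nrow(X); p <- ncol(X)
  if (M == 0) return(0)
  dg <- diag(L)
  if (any(dg <= 0)) return(-Inf)
  Z <- forwardsolve(L, t(X) - mu)
  -0.5 * M * p * log(2 * pi) - M * sum(log(dg)) - 0.5 * sum(Z^2)
}

etaLogPost <- function(phi, X, prior) {
  p <- ncol(X)
  par <- etaUnpack(phi, p)
  if (any(!is.finite(par$Omega))) return(-Inf)
  lp <- niwLogDensity(par$mu, par$Omega, prior)
  if (!is.finite(lp)) return(-Inf)
  ll <- mvnRowsLogLik(X, par$mu, par$L)
  ljac <- p * log(2) + sum((p - seq_len(p) + 2) * par$u)
  lp + ll + ljac
}

numGrad <- function(f, x, eps = 1e-5) {
  g <- numeric(length(x))
  for (j in seq_along(x)) {
    xp <- x; xp[j] <- x[j] + eps
    xm <- x; xm[j] <- x[j] - eps
    g[j] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

#' One HMC update of the population parameters
#'
#' Leapfrog Hamiltonian Monte Carlo on the unconstrained parameterisation
#' (mu, log Cholesky diagonal, off-diagonal Cholesky entries) of the
#' Gaussian population law, with a Normal-Inverse-Wishart prior by default.
#' Step size is adapted by dual averaging towards 0.8 acceptance; the mass
#' matrix is the identity. Divergent trajectories (energy error above
#' \code{divergenceThreshold}) are rejected.
#'
#' @param logC M x p matrix of log individual rates
#' @param prior a \code{\link{niwPrior}} (also usable with any log-density
#'   via \code{logPrior})
#' @param mu,Omega current values
#' @param control list: nLeapfrog, stepSize, adaptStepSize, iteration,
#'   dual-averaging state (internal fields are carried through)
#' @param logPrior optional function(mu, Omega) replacing the NIW prior
#'   density (non-conjugate priors)
#' @return list with new \code{mu}, \code{Omega}, \code{accepted},
#'   \code{divergent} and the updated \code{control}
#' @export
sampleEtaHMC <- function(logC, prior, mu, Omega,
                         control = list(), logPrior = NULL) {
  X <- as.matrix(logC)
  p <- ncol(X)
  ctl <- modifyList(list(nLeapfrog = 10, stepSize = 0.1,
                         adaptStepSize = TRUE, targetAccept = 0.8,
                         iteration = 0, hbar = 0, logEpsBar = log(0.1),
                         mu0da = log(1), divergenceThreshold = 1000), control)
  target <- if (is.null(logPrior)) {
    function(phi) etaLogPost(phi, X, prior)
  } else {
    function(phi) {
      par <- etaUnpack(phi, p)
      lp <- logPrior(par$mu, par$Omega)
      if (!is.finite(lp)) return(-Inf)
      ljac <- p * log(2) + sum((p - seq_len(p) + 2) * par$u)
      lp + mvnRowsLogLik(X, par$mu, par$L) + ljac
    }
  }
  phi <- etaPack(mu, Omega)
  r0 <- stats::rnorm(length(phi))
  eps <- ctl$stepSize
  lp0 <- target(phi)
  H0 <- lp0 - 0.5 * sum(r0^2)
  phi1 <- phi; r <- r0
  g <- numGrad(target, phi1)
  divergent <- FALSE
  for (s in seq_len(ctl$nLeapfrog)) {
    r <- r + 0.5 * eps * g
    phi1 <- phi1 + eps * r
    lp1 <- target(phi1)
    if (!is.finite(lp1)) { divergent <- TRUE; break }
    g <- numGrad(target, phi1)
    r <- r + 0.5 * eps * g
  }
  accepted <- FALSE
  if (!divergent) {
    H1 <- target(phi1) - 0.5 * sum(r^2)
    if (!is.finite(H1) || H0 - H1 > ctl$divergenceThreshold) {
      divergent <- TRUE
      alpha <- 0
    } else {
      alpha <- min(1, exp(H1 - H0))
      accepted <- stats::runif(1) < alpha
    }
  } else alpha <- 0
  if (accepted) {
    par <- etaUnpack(phi1, p)
    mu <- par$mu; Omega <- par$Omega
  }
  # dual averaging (Nesterov-style) towards the target acceptance
  if (ctl$adaptStepSize) {
    ctl$iteration <- ctl$iteration + 1
    m <- ctl$iteration
    kappa <- 0.75; t0 <- 10; gam <- 0.05
    ctl$hbar <- (1 - 1 / (m + t0)) * ctl$hbar +
      (ctl$targetAccept - alpha) / (m + t0)
    logEps <- ctl$mu0da - sqrt(m) / gam * ctl$hbar
    w <- m^(-kappa)
    ctl$logEpsBar <- w * logEps + (1 - w) * ctl$logEpsBar
    ctl$stepSize <- exp(logEps)
  }
  list(mu = mu, Omega = Omega, accepted = accepted, divergent = divergent,
       control = ctl)
}
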