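#' Create an adaptive random-walk proposal
#'
#' Three classical adaptive Metropolis schemes for the pseudo-marginal
#' blocks, all operating on the unconstrained (log) parameter scale:
#' \describe{
#'   \item{AM}{adaptive Metropolis: proposal covariance
#'     \eqn{(2.38^2/p)\hat C + \epsilon I} with the running empirical
#'     covariance \eqn{\hat C}.}
#'   \item{AM_global}{AM with an additional global log-scale \eqn{\lambda}
#'     adapted towards a target acceptance rate.}
#'   \item{RAM}{robust adaptive Metropolis: a lower-triangular factor S is
#'     updated by rank-one Cholesky corrections
#'     \eqn{S S' \leftarrow S (I + \gamma_n (\alpha_n - \alpha^*) z z' /
#'     \|z\|^2) S'} so the realised acceptance rate is driven to
#'     \eqn{\alpha^*}.}
#' }
#' Adaptation steps decay as \eqn{\gamma_n = n^{-\beta}} (diminishing
#' adaptation).
#'
#' @param dim parameter dimension p
#' @param kind "RAM" (default), "AM" or "AM_global"
#' @param targetAcceptance target acceptance rate (RAM, AM_global)
#' @param beta decay exponent in (0.5, 1]
#' @param sigma0 pre-adaptation proposal SD (log scale)
#' @param epsReg covariance regularisation jitter
#' @return an \linkS4class{AdaptiveProposal}
#' @export
adaptiveProposal <- function(dim, kind = "RAM", targetAcceptance = 0.234,
                             beta = 0.66, sigma0 = 0.1, epsReg = 1e-8) {
  dim <- as.integer(dim)
  new("AdaptiveProposal", kind = kind, dim = dim, n = 0,
      mean = numeric(dim), cov = diag(sigma0^2, dim),
      S = diag(sigma0, dim), lambda = 0,
      alphaStar = targetAcceptance, beta = beta, epsReg = epsReg,
      sigma0 = sigma0, frozen = FALSE)
}

setMethod("show", "AdaptiveProposal", function(object) {
  cat(sprintf("AdaptiveProposal: %s, dim %d, n = %g, target %.3g\n",
              object@kind, object@dim, object@n, object@alphaStar))
})

# proposal factor: theta' = theta + F z
proposalFactor <- function(state) {
  p <- state@dim
  if (state@kind == "RAM") return(state@S)
  if (state@n < 2 * p + 2) {
    F <- diag(state@sigma0, p)
  } else {
    C <- (2.38^2 / p) * state@cov + diag(state@epsReg, p)
    F <- tryCatch(t(chol(C)), error = function(e)
      t(chol(C + diag(1e-6 * max(diag(C), 1), p))))
  }
  if (state@kind == "AM_global") F <- exp(state@lambda / 2) * F
  F
}

#' Draw a proposal
#'
#' @param state an \linkS4class{AdaptiveProposal}
#' @param theta current parameter (unconstrained scale)
#' @return list with the proposed \code{theta}, and the standard normal
#'   increment \code{z} needed by \code{\link{adaptProposal}}
#' @export
propose <- function(state, theta) {
  stopifnot(length(theta) == state@dim)
  z <- stats::rnorm(state@dim)
  list(theta = as.numeric(theta + proposalFactor(state) %*% z), z = z)
}

#' Adapt a proposal after one Metropolis decision
#'
#' @param state an \linkS4class{AdaptiveProposal}
#' @param theta chain value after the accept/reject decision (feeds the AM
#'   running moments)
#' @param alpha realised acceptance probability in [0, 1]
#' @param z the standard normal increment returned by \code{\link{propose}}
#' @return the updated \linkS4class{AdaptiveProposal}
#' @export
adaptProposal <- function(state, theta, alpha, z) {
  if (state@frozen) return(state)
  stopifnot(alpha >= 0, alpha <= 1)
  state@n <- state@n + 1
  g <- state@n^(-state@beta)
  if (state@kind %in% c("AM", "AM_global")) {
    dlt <- theta - state@mean
    state@mean <- state@mean + g * dlt
    state@cov <- state@cov + g * (tcrossprod(dlt) - state@cov)
    if (state@kind == "AM_global")
      state@lambda <- state@lambda + g * (alpha - state@alphaStar)
  } else { # RAM rank-one Cholesky update (compiled dchud/dchdd sweep)
    nz <- sum(z^2)
    if (nz > 0) {
      eta <- min(1, state@dim * g) * (alpha - state@alphaStar)
      state@S <- .ramUpdateCpp(state@S, eta, z)
    }
  }
  state
}
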