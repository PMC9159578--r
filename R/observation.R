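#' Construct an observation model
#'
#' Gaussian additive measurement: \eqn{y_l = g(x(t_l)) + \epsilon_l},
#' \eqn{\epsilon_l \sim N(0, diag(\sigma^2))} with \eqn{\sigma = \xi}. Supply
#' either a linear projection matrix \code{P} (one row per observable; the
#' guided particle filter requires this form) or a nonlinear function
#' \code{g(X, t)} taking an N x d matrix of states and returning an N x q
#' matrix of observables.
#'
#' @param P numeric matrix q x d, or a single species index to observe that
#'   species directly
#' @param g vectorised observation function, for nonlinear observables
#' @param d number of species (needed when P is given as an index)
#' @return an \linkS4class{ObservationModel}
#' @export
ObservationModel <- function(P = NULL, g = NULL, d = NULL) {
  if (!is.null(P) && length(P) == 1 && !is.matrix(P)) {
    stopifnot(!is.null(d))
    idx <- as.integer(P)
    P <- matrix(0, 1, d)
    P[1, idx] <- 1
  }
  if (is.null(P)) P <- matrix(numeric(), 0, 0)
  q <- if (nrow(P) > 0) nrow(P) else 1L
  new("ObservationModel", P = P, g = g, kind = "gaussian_additive",
      q = as.integer(q))
}

setMethod("show", "ObservationModel", function(object) {
  cat(sprintf("ObservationModel: gaussian_additive, q = %d (%s)\n", object@q,
              if (is.null(object@g)) "linear" else "nonlinear g"))
})

#' Observation map applied to states
#'
#' @param obs an \linkS4class{ObservationModel}
#' @param X N x d matrix of states (a vector is taken as one state)
#' @param t observation time
#' @return N x q matrix of noise-free observables
#' @export
observationMean <- function(obs, X, t = 0) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  if (!is.null(obs@g)) {
    G <- obs@g(X, t)
    if (is.vector(G)) G <- matrix(G, ncol = obs@q)
    G
  } else {
    X %*% t(obs@P)
  }
}

#' Gaussian observation log-density
#'
#' Log-density of one observation vector given the latent state:
#' \eqn{\sum_r \log N(y_r; g(x, t)_r, \sigma_r^2)}.
#'
#' @param obs an \linkS4class{ObservationModel}
#' @param y observed vector (length q)
#' @param x latent state vector
#' @param t observation time
#' @param xi error scales sigma (length q), strictly positive
#' @return log-density (finite for finite inputs)
#' @export
observationLogDensity <- function(obs, y, x, t = 0, xi) {
  if (any(xi <= 0)) stop("error scales sigma must be positive")
  m <- drop(observationMean(obs, x, t))
  sum(stats::dnorm(y, mean = m, sd = xi, log = TRUE))
}

#' Nuclear/cytosolic ratio observable
#'
#' The observation function used for Mig1 localisation data: the ratio of
#' the second to the first state coordinate (nuclear over cytosolic
#' intensity), measured with additive Gaussian error. Provided as a library
#' example of a nonlinear observation function.
#'
#' @return an \linkS4class{ObservationModel} with \eqn{g(x) = x_2 / x_1}
#' @export
mig1RatioObservation <- function() {
  ObservationModel(g = function(X, t) X[, 2] / X[, 1])
}
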