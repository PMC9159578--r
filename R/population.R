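#' Construct a log-normal population law
#'
#' @param mu numeric vector of log-means
#' @param Omega covariance matrix on the log scale; a vector is taken as the
#'   diagonal
#' @param family "lognormal_full" or "lognormal_diag"
#' @return a \linkS4class{PopulationLaw}
#' @export
PopulationLaw <- function(mu, Omega, family = "lognormal_full") {
  if (is.vector(Omega) && !is.matrix(Omega)) Omega <- diag(Omega, length(mu))
  new("PopulationLaw", family = family, mu = as.numeric(mu),
      Omega = as.matrix(Omega))
}

setMethod("show", "PopulationLaw", function(object) {
  cat(sprintf("PopulationLaw: %s, dim %d\n", object@family,
              length(object@mu)))
  cat("  mu :", signif(object@mu, 4), "\n")
  cat("  tau:", signif(sqrt(diag(object@Omega)), 4), "\n")
})

#' Draw cell-individual parameters from the population law
#'
#' Samples M iid rate vectors \eqn{c^{(i)} \sim LN(\mu, \Omega)}: rows of the
#' returned matrix are exp of multivariate Gaussian draws.
#'
#' @param pop a \linkS4class{PopulationLaw}
#' @param M number of individuals
#' @return M x dim_c matrix of positive rates
#' @export
sampleIndividualParameters <- function(pop, M) {
  stopifnot(is(pop, "PopulationLaw"))
  p <- length(pop@mu)
  L <- safeCholLower(pop@Omega)
  Z <- matrix(stats::rnorm(M * p), M, p)
  exp(sweep(Z %*% t(L), 2, pop@mu, "+"))
}

# lower-triangular Cholesky factor tolerating PSD matrices (zero variance
# coordinates give zero rows/cols)
safeCholLower <- function(Omega) {
  p <- nrow(Omega)
  out <- tryCatch(t(chol(Omega)), error = function(e) NULL)
  if (is.null(out)) {
    if (all(abs(Omega) < 1e-300)) return(matrix(0, p, p))
    ei <- eigen(Omega, symmetric = TRUE)
    ev <- pmax(ei$values, 0)
    out <- ei$vectors %*% diag(sqrt(ev), p)
  }
  out
}

# multivariate normal log-density (log scale population prior)
dmvnormLog <- function(x, mu, Omega) {
  p <- length(mu)
  L <- safeCholLower(Omega + diag(1e-12, p))
  z <- forwardsolve(L, x - mu)
  -0.5 * p * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}
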