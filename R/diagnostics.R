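#' Multivariate effective sample size of an MCMC chain
#'
#' \deqn{mESS = n (\det \hat\Lambda / \det \hat\Sigma)^{1/p}} where
#' \eqn{\hat\Lambda} is the sample covariance of the draws and
#' \eqn{\hat\Sigma} the multivariate batch-means estimate of the long-run
#' (asymptotic) covariance with batch size \eqn{\lfloor\sqrt n\rfloor}.
#' Higher is better; iid draws give mESS close to n.
#'
#' @param samples n x p matrix of draws (n > p)
#' @return estimated multivariate effective sample size
#' @export
multiESS <- function(samples) {
  X <- as.matrix(samples)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more draws than parameters")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("column ", which(sds == 0)[1], " is constant")
  Lam <- stats::cov(X)
  b <- floor(sqrt(n))
  a <- floor(n / b)
  Xb <- X[seq_len(a * b), , drop = FALSE]
  means <- matrix(NA_real_, a, p)
  for (k in seq_len(a))
    means[k, ] <- colMeans(Xb[((k - 1) * b + 1):(k * b), , drop = FALSE])
  grand <- colMeans(Xb)
  Sig <- b * crossprod(sweep(means, 2, grand)) / (a - 1)
  dLam <- determinant(Lam, logarithm = TRUE)$modulus
  dSig <- determinant(Sig, logarithm = TRUE)$modulus
  if (!is.finite(dSig))
    stop("singular batch-means covariance (degenerate chain)")
  as.numeric(n * exp((dLam - dSig) / p))
}

#' First-order Wasserstein distance between two univariate samples
#'
#' Computed exactly from the empirical quantile functions: for equal sample
#' sizes the mean absolute difference of matched order statistics, in
#' general the integral of the absolute ECDF difference.
#'
#' @param a,b numeric samples (any sizes)
#' @return the 1-Wasserstein (earth mover's) distance
#' @export
wasserstein1 <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  a <- sort(a); b <- sort(b)
  if (length(a) == length(b)) return(mean(abs(a - b)))
  # integral |F_a(x) - F_b(x)| dx over the pooled support
  xs <- sort(c(a, b))
  Fa <- stats::ecdf(a); Fb <- stats::ecdf(b)
  mid <- xs[-length(xs)]
  sum(abs(Fa(mid) - Fb(mid)) * diff(xs))
}

#' Exact multivariate Wasserstein distance for tiny samples
#'
#' Brute-force optimal assignment over all permutations (n <= 8): the
#' minimal mean Euclidean transport cost between two equally sized point
#' sets. Used as a cross-check of the per-parameter 1-d distances.
#'
#' @param A,B n x p matrices with equal, small n
#' @return exact first-order transport distance
#' @export
wassersteinExactSmall <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  n <- nrow(A)
  stopifnot(n == nrow(B), n <= 8)
  perms <- permutationsAll(n)
  cost <- function(pr) mean(sqrt(rowSums((A - B[pr, , drop = FALSE])^2)))
  min(apply(perms, 1, cost))
}

permutationsAll <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- permutationsAll(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  out
}

#' Tune the particle count
#'
#' Walks a geometric ladder of particle counts and returns the smallest N
#' whose log-likelihood estimator variance at a pilot parameter value is
#' below the target (default 2.0, the usual pseudo-marginal guidance). In
#' perturbed mode each individual is tuned against its own likelihood
#' variance; in unperturbed mode the variance of the summed log-likelihood
#' over all cells decides, which is why the tuned N grows with the number of
#' cells.
#'
#' @param model an \linkS4class{SSMEMModel}
#' @param data a \linkS4class{CellData}
#' @param pilot list with entries c (M x dimC matrix), kappa, xi (natural
#'   scale) -- typically the last state of a pilot run
#' @param cfg a \linkS4class{PFConfig} (its nParticles is ignored)
#' @param mode "perturbed" or "unperturbed"
#' @param varTarget variance threshold on the log-likelihood
#' @param nReplicates independent filter runs per tested N
#' @param ladder candidate particle counts (increasing)
#' @return list with \code{N} (per-individual vector in perturbed mode, a
#'   scalar otherwise), the measured \code{variance} at the chosen N, the
#'   \code{ladder}, and \code{exhausted} (TRUE if no N met the target)
#' @export
tuneParticles <- function(model, data, pilot, cfg, mode = "perturbed",
                          varTarget = 2.0, nReplicates = 25,
                          ladder = ceiling(10 * 1.5^(0:8))) {
  M <- nCells(data)
  runOne <- function(i, N) {
    c2 <- cfg
    c2@nParticles <- as.integer(N)
    replicate(nReplicates,
      pfLogLik(model, data@times[[i]], data@obs[[i]], pilot$c[i, ],
               pilot$kappa, pilot$xi, c2, u = NULL, t0 = data@t0)$value)
  }
  if (mode == "perturbed") {
    chosen <- integer(M); vars <- numeric(M); exhausted <- FALSE
    for (i in seq_len(M)) {
      vv <- NA_real_
      for (N in ladder) {
        vv <- stats::var(runOne(i, N))
        if (is.finite(vv) && vv <= varTarget) break
      }
      if (!is.finite(vv) || vv > varTarget) exhausted <- TRUE
      chosen[i] <- N; vars[i] <- vv
    }
    if (exhausted) warning("particle ladder exhausted for some individuals")
    list(N = chosen, variance = vars, ladder = ladder, exhausted = exhausted)
  } else {
    vv <- NA_real_; chosen <- ladder[length(ladder)]
    for (N in ladder) {
      sums <- rowSums(vapply(seq_len(M), function(i) runOne(i, N),
                             numeric(nReplicates)))
      vv <- stats::var(sums)
      if (is.finite(vv) && vv <= varTarget) { chosen <- N; break }
      chosen <- N
    }
    exhausted <- !is.finite(vv) || vv > varTarget
    if (exhausted) warning("particle ladder exhausted")
    list(N = chosen, variance = vv, ladder = ladder, exhausted = exhausted)
  }
}

#' Posterior-predictive quantile bands (posterior visual check)
#'
#' For each repeat, one saved posterior draw of (mu, Omega, kappa, xi) is
#' taken; M cells are simulated from scratch (population draw, exact latent
#' simulation, observation noise) and their 0.05/0.5/0.95 quantiles are
#' computed at each time point. The returned bands are the central 95%
#' intervals of each quantile across repeats -- the envelope the observed
#' data quantiles should fall inside if the model fits.
#'
#' @param model an \linkS4class{SSMEMModel}
#' @param samples a \linkS4class{PosteriorSamples} (or NULL to check the
#'   model's own default parameters, e.g. for generator self-consistency)
#' @param times observation grid
#' @param MCells cells per simulated dataset
#' @param nRepeats posterior draws / simulated datasets
#' @param t0 initial time
#' @param quantiles which per-time quantiles to track
#' @param cFactor optional multiplier per c coordinate applied to every
#'   sampled cell (e.g. c(2, 1, 1, 1) doubles the transcription rate,
#'   emulating an extra gene copy in a dosage prediction)
#' @return object of class "quantileBands": list with time grid, quantiles
#'   and an array bands[quantile, c(lower, median, upper), time]
#' @export
posteriorVisualCheck <- function(model, samples, times, MCells = 40,
                                 nRepeats = 500, t0 = 0,
                                 quantiles = c(0.05, 0.5, 0.95),
                                 cFactor = NULL) {
  nq <- length(quantiles)
  nt <- length(times)
  acc <- array(NA_real_, c(nRepeats, nq, nt))
  dropped <- 0
  for (r in seq_len(nRepeats)) {
    if (is.null(samples)) {
      mu <- model@population@mu
      Omega <- model@population@Omega
      kappa <- model@kappaDefault
      xi <- model@xiDefault
    } else {
      k <- sample.int(nrow(samples@mu), 1)
      mu <- samples@mu[k, ]
      Omega <- omegaDraw(samples, k)
      kappa <- if (ncol(samples@kappa)) samples@kappa[k, ] else numeric()
      xi <- if (ncol(samples@xi)) samples@xi[k, ] else model@xiDefault
    }
    Y <- tryCatch({
      pop <- PopulationLaw(mu, Omega, model@population@family)
      cs <- sampleIndividualParameters(pop, MCells)
      if (!is.null(cFactor)) cs <- sweep(cs, 2, cFactor, "*")
      vapply(seq_len(MCells), function(i) {
        tr <- simulateCell(model, cs[i, ], kappa, times, t0)
        g <- observationMean(model@obs, tr@states, times)
        g[, 1] + stats::rnorm(nt, 0, xi[1])
      }, numeric(nt))
    }, error = function(e) NULL)
    if (is.null(Y)) { dropped <- dropped + 1; next }
    for (qi in seq_len(nq))
      acc[r, qi, ] <- apply(Y, 1, stats::quantile, quantiles[qi])
  }
  bands <- array(NA_real_, c(nq, 3, nt),
                 dimnames = list(paste0("q", quantiles),
                                 c("lower", "median", "upper"), NULL))
  for (qi in seq_len(nq)) {
    bands[qi, 1, ] <- apply(acc[, qi, , drop = FALSE], 3, stats::quantile,
                            0.025, na.rm = TRUE)
    bands[qi, 2, ] <- apply(acc[, qi, , drop = FALSE], 3, stats::quantile,
                            0.5, na.rm = TRUE)
    bands[qi, 3, ] <- apply(acc[, qi, , drop = FALSE], 3, stats::quantile,
                            0.975, na.rm = TRUE)
  }
  structure(list(times = times, quantiles = quantiles, bands = bands,
                 dropped = dropped), class = "quantileBands")
}

#' Observed data quantiles on the observation grid
#'
#' @param data a \linkS4class{CellData} with shared observation times
#' @param quantiles quantiles to compute
#' @return matrix quantiles x time
#' @export
observedQuantiles <- function(data, quantiles = c(0.05, 0.5, 0.95)) {
  Y <- vapply(data@obs, function(y) y[, 1], numeric(length(data@times[[1]])))
  Q <- apply(Y, 1, stats::quantile, quantiles) # quantiles x time
  if (is.null(dim(Q))) Q <- matrix(Q, nrow = length(quantiles))
  Q
}

#' Fraction of time points where observed quantiles fall inside the bands
#'
#' @param bands from \code{\link{posteriorVisualCheck}}
#' @param obsQ from \code{\link{observedQuantiles}} (quantiles x time)
#' @return coverage fraction across all quantiles and time points
#' @export
bandCoverage <- function(bands, obsQ) {
  inside <- 0; total <- 0
  for (qi in seq_along(bands$quantiles)) {
    lo <- bands$bands[qi, 1, ]; hi <- bands$bands[qi, 3, ]
    inside <- inside + sum(obsQ[qi, ] >= lo & obsQ[qi, ] <= hi)
    total <- total + length(lo)
  }
  inside / total
}
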