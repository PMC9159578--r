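#' Particle-filter configuration
#'
#' @param nParticles number of particles N; a vector gives one N per cell
#'   (as chosen by per-individual tuning in perturbed mode)
#' @param kind "bootstrap" or "guided_mdb" (modified diffusion bridge; needs
#'   the Langevin integrator and a scalar linear-Gaussian observation)
#' @param integrator "ssa", "extrande", "tauleap" or "langevin"
#' @param dt substep length for the approximate integrators
#' @param rho correlation of the auxiliary random numbers across successive
#'   likelihood evaluations, in [0, 1); only meaningful for the tau-leap and
#'   Langevin integrators, whose randomness has a fixed layout
#' @param essThreshold systematic resampling is triggered when the effective
#'   sample size drops below this fraction of N (never after the final
#'   observation)
#' @param lookahead Extrande window length
#' @param maxEvents per-path event cap for the exact integrators
#' @return a \linkS4class{PFConfig}
#' @export
pfConfig <- function(nParticles = 50, kind = "bootstrap",
                     integrator = "langevin", dt = 0.1, rho = 0,
                     essThreshold = 0.5, lookahead = 1, maxEvents = 1e7) {
  new("PFConfig", nParticles = as.integer(nParticles), kind = kind,
      integrator = integrator, dt = dt, rho = rho,
      essThreshold = essThreshold, lookahead = lookahead,
      maxEvents = as.integer(maxEvents))
}

setMethod("show", "PFConfig", function(object) {
  cat(sprintf("PFConfig: %s filter, %s integrator, N = %d, rho = %g\n",
              object@kind, object@integrator, object@nParticles, object@rho))
})

integratorCode <- function(name) {
  match(name, c("ssa", "extrande", "tauleap", "langevin")) - 1L
}

# noise channels consumed per substep per particle, given model + config
noiseChannels <- function(model, cfg) {
  if (cfg@kind == "guided_mdb") return(1L)
  if (cfg@integrator == "langevin") {
    if (model@network@builtin == 100L) 1L else nReactions(model@network)
  } else if (cfg@integrator == "tauleap") {
    nReactions(model@network)
  } else 0L
}

ouStationary <- function(model) {
  model@network@builtin == 100L && is.na(model@x0[1])
}

# substep counts per inter-observation interval (must mirror src/core.cpp)
substepCounts <- function(times, t0, dt) {
  gaps <- diff(c(t0, times))
  pmax(1L, as.integer(ceiling(gaps / dt - 1e-9)))
}

#' Pre-allocate auxiliary random numbers for a correlated particle filter
#'
#' The auxiliary variables u of the pseudo-marginal scheme are standard
#' normals in a fixed layout (particle x interval x substep x noise channel,
#' plus one resampling variate per interval and, for the OU benchmark with a
#' stationary initial law, one initial draw per particle). Because the
#' layout is fixed, refreshing with \code{\link{refreshAuxiliary}} is a pure
#' array operation and successive likelihood estimates become correlated.
#' Only the tau-leap and Langevin integrators have a fixed layout; the exact
#' jump simulators always consume fresh randomness.
#'
#' @param model an \linkS4class{SSMEMModel}
#' @param times observation times of one cell
#' @param cfg a \linkS4class{PFConfig}
#' @param t0 initial time
#' @param cell cell index selecting the particle count when
#'   \code{cfg@nParticles} is a per-cell vector
#' @return list with elements \code{uProp} (N x K matrix) and
#'   \code{uResamp} (length(times) vector), all standard normal
#' @export
makeAuxiliary <- function(model, times, cfg, t0 = 0, cell = 1L) {
  if (!cfg@integrator %in% c("tauleap", "langevin")) return(NULL)
  ns <- substepCounts(times, t0, cfg@dt)
  K <- sum(ns) * noiseChannels(model, cfg) + as.integer(ouStationary(model))
  N <- if (length(cfg@nParticles) > 1L) cfg@nParticles[cell] else cfg@nParticles
  list(uProp = matrix(stats::rnorm(N * K), N, K),
       uResamp = stats::rnorm(length(times)))
}

#' Crank-Nicolson refresh of auxiliary numbers
#'
#' \eqn{u' = \rho u + \sqrt{1 - \rho^2}\, \zeta} with fresh standard normal
#' \eqn{\zeta}: preserves the standard-normal marginal law exactly while
#' correlating successive likelihood estimates.
#'
#' @param u auxiliary numbers from \code{\link{makeAuxiliary}} (or NULL)
#' @param rho correlation in [0, 1)
#' @return refreshed auxiliary numbers of the same shape
#' @export
refreshAuxiliary <- function(u, rho) {
  if (is.null(u)) return(NULL)
  stopifnot(rho >= 0, rho < 1)
  s <- sqrt(1 - rho^2)
  u$uProp[] <- rho * u$uProp + s * stats::rnorm(length(u$uProp))
  u$uResamp <- rho * u$uResamp + s * stats::rnorm(length(u$uResamp))
  u
}

#' Systematic resampling
#'
#' Maps normalized weights to offspring indices using a single uniform
#' variate: offspring k takes the particle whose cumulative weight interval
#' contains (u + k)/N. Offspring counts are unbiased: E[count_j] = N w_j.
#'
#' @param weights nonnegative weights summing to 1
#' @param u uniform variate in [0, 1)
#' @return integer vector of N ancestor indices
#' @export
systematicResample <- function(weights, u = stats::runif(1)) {
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("weights must be a probability vector")
  .systematicResampleCpp(weights, u)
}

#' Particle-filter estimate of one cell's log-likelihood
#'
#' Runs a bootstrap or guided (modified diffusion bridge) particle filter
#' for one individual and returns an unbiased estimate of
#' \eqn{\pi(y^{(i)} | c^{(i)}, \kappa, \xi)} on the exp scale: particles are
#' propagated with the configured integrator between observation times,
#' weighted by the Gaussian observation density, and systematically
#' resampled when the effective sample size drops below the configured
#' fraction of N. A value of \code{-Inf} signals that every particle died
#' (zero estimated likelihood) and is meant to trigger a Metropolis
#' rejection, not an error.
#'
#' @param model an \linkS4class{SSMEMModel}
#' @param times,y one cell's observation times and observations (vector or
#'   n x q matrix)
#' @param c,kappa,xi parameters on the natural scale (kappa excludes the
#'   model's known constants; xi are the error SDs)
#' @param cfg a \linkS4class{PFConfig}
#' @param u auxiliary numbers from \code{\link{makeAuxiliary}}, or NULL for
#'   fresh randomness
#' @param t0 initial time
#' @return list with \code{value} (log-likelihood estimate), per-observation
#'   \code{increments}, the \code{ess} trace and the resample count
#' @export
pfLogLik <- function(model, times, y, c, kappa = numeric(), xi, cfg,
                     u = NULL, t0 = 0) {
  stopifnot(is(model, "SSMEMModel"), is(cfg, "PFConfig"))
  if (!is.matrix(y)) y <- matrix(y, ncol = 1)
  if (any(xi <= 0)) stop("error scales must be positive")
  guided <- cfg@kind == "guided_mdb"
  if (guided && !is.null(model@obs@g))
    stop("guided filter requires a linear-Gaussian observation model")
  x0 <- resolveX0(model, c)
  statInit <- ouStationary(model)
  if (any(is.na(x0)) && !statInit)
    stop("initial state unresolved (NA) for a non-OU model")
  if (statInit) x0[1] <- 0 # placeholder; C++ draws the stationary init
  # a correlated filter resamples (sorted) at every observation so the
  # auxiliary-number mapping stays continuous across iterations; the
  # adaptive ESS trigger is used only when rho = 0
  essThr <- if (cfg@rho > 0) 1.0000001 else cfg@essThreshold
  res <- .pfCpp(cnet(model@network), as.numeric(c),
                fullKappa(model, kappa), as.numeric(xi), x0, t0,
                as.numeric(times), y, model@obs@P, model@obs@g,
                integratorCode(cfg@integrator), cfg@dt, cfg@nParticles[1],
                essThr, guided, cfg@rho > 0,
                if (is.null(u)) NULL else u$uProp,
                if (is.null(u)) NULL else u$uResamp,
                cfg@lookahead, if (model@network@builtin == 2L) 0L else 1L,
                cfg@maxEvents, statInit, 0)
  res[c("value", "increments", "ess", "nResample")]
}
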