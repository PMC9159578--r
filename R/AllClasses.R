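#' @import methods
NULL

#' Reaction network with stoichiometry and propensity map
#'
#' A \code{ReactionNetwork} defines the latent jump process of a model: the
#' net state change of every reaction (stoichiometry matrix, species by
#' reactions) and the propensity function \eqn{h(x, c, \kappa, t)} giving the
#' instantaneous firing rate of each reaction. Built-in networks (birth-death,
#' circadian gene expression, Schlogl) carry a compiled fast path; arbitrary
#' networks supply an R function.
#'
#' @slot stoich integer matrix, species x reactions
#' @slot propensity function \code{(x, c, kappa, t) -> numeric(R)}, or NULL
#'   when a built-in fast path is used
#' @slot builtin internal identifier of the compiled propensity (0 = none)
#' @slot speciesNames,reactionNames character vectors
#' @export
setClass("ReactionNetwork",
  representation(
    stoich = "matrix",
    propensity = "ANY",
    builtin = "integer",
    speciesNames = "character",
    reactionNames = "character"
  )
)

setValidity("ReactionNetwork", function(object) {
  S <- object@stoich
  msg <- character()
  if (!is.numeric(S) || any(S != round(S)))
    msg <- c(msg, "stoichiometry must be an integer matrix")
  if (length(object@speciesNames) != nrow(S))
    msg <- c(msg, "speciesNames length must equal nrow(stoich)")
  if (length(object@reactionNames) != ncol(S) && ncol(S) > 0)
    msg <- c(msg, "reactionNames length must equal ncol(stoich)")
  if (object@builtin == 0L && !is.function(object@propensity))
    msg <- c(msg, "a propensity function is required for non-built-in networks")
  if (length(msg)) msg else TRUE
})

#' Log-normal population law for cell-individual parameters
#'
#' Cell-individual rate vectors are modelled as \eqn{c^{(i)} \sim LN(\mu,
#' \Omega)}: the log of each cell's rates is multivariate Gaussian with mean
#' \eqn{\mu} and covariance \eqn{\Omega}. The \code{family} records whether
#' \eqn{\Omega} is unrestricted or diagonal, which decides the conjugate
#' update used for the population step of the Gibbs sampler.
#'
#' @slot family "lognormal_full" or "lognormal_diag"
#' @slot mu numeric vector of log-means
#' @slot Omega covariance matrix on the log scale
#' @export
setClass("PopulationLaw",
  representation(family = "character", mu = "numeric", Omega = "matrix")
)

setValidity("PopulationLaw", function(object) {
  msg <- character()
  p <- length(object@mu)
  if (!object@family %in% c("lognormal_full", "lognormal_diag"))
    msg <- c(msg, "family must be lognormal_full or lognormal_diag")
  if (!all(dim(object@Omega) == c(p, p)))
    msg <- c(msg, "Omega must be dim_c x dim_c")
  else {
    ev <- eigen(object@Omega, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < -1e-10 * max(abs(ev), 1)))
      msg <- c(msg, "Omega must be positive semi-definite")
  }
  if (length(msg)) msg else TRUE
})

#' Observation model: how latent states are measured
#'
#' Observations are \eqn{y_l = g(x(t_l)) + \epsilon_l} with independent
#' Gaussian error \eqn{\epsilon_l \sim N(0, diag(\sigma^2))}; the error
#' scales \eqn{\sigma} are the error parameters \eqn{\xi} of the model.
#' A linear observation is given by a selection/projection matrix \code{P}
#' (required by the guided filter); a nonlinear one (such as the nuclear to
#' cytosolic intensity ratio used for Mig1 data) by a vectorised function
#' \code{g(X, t)} operating on an N x d matrix of states.
#'
#' @slot P numeric matrix (q x d) for linear observations, or 0 x 0 matrix
#' @slot g function or NULL (nonlinear observations)
#' @slot kind only "gaussian_additive" is supported
#' @slot q number of observables
#' @export
setClass("ObservationModel",
  representation(P = "matrix", g = "ANY", kind = "character", q = "integer")
)

setValidity("ObservationModel", function(object) {
  msg <- character()
  if (object@kind != "gaussian_additive")
    msg <- c(msg, "only gaussian_additive errors are supported")
  if (is.null(object@g) && nrow(object@P) == 0)
    msg <- c(msg, "either P or g must be given")
  if (!is.null(object@g) && !is.function(object@g))
    msg <- c(msg, "g must be a function(X, t)")
  if (length(msg)) msg else TRUE
})

#' State-space mixed-effects model (SSMEM)
#'
#' Bundles the latent dynamics (a \linkS4class{ReactionNetwork} simulated by
#' a jump or Langevin integrator, or a plain SDE such as the
#' Ornstein-Uhlenbeck benchmark), the \linkS4class{ObservationModel}, the
#' parameter partition into cell-individual rates \eqn{c} (with population
#' law \eqn{c^{(i)} \sim LN(\mu, \Omega)}), cell-constant rates \eqn{\kappa},
#' and error scales \eqn{\xi}, plus the initial-state rule. Known constants
#' (for instance a rate fixed by the experimental design) live in
#' \code{kappaKnown} and are appended to \eqn{\kappa} when propensities are
#' evaluated.
#'
#' @slot network ReactionNetwork (or SDE stub for "sde" dynamics)
#' @slot dynamics "jump" or "sde"
#' @slot obs ObservationModel
#' @slot population PopulationLaw (default/simulation-truth law)
#' @slot dimC,dimKappa,dimXi parameter block dimensions
#' @slot kappaKnown known cell-constant values appended after inferred kappa
#' @slot x0 default initial state
#' @slot x0FromC integer: for each species, index of the c coordinate that
#'   sets its initial value (0 = use x0; supports cell-varying initial states)
#' @slot kappaDefault,xiDefault default (simulation-truth) values of the
#'   inferred cell-constant rates and error scales
#' @slot simulator exact simulator used for data generation and predictive
#'   checks: "ssa", "extrande" or "exact_ou"
#' @slot cNames,kappaNames,xiNames parameter names
#' @export
setClass("SSMEMModel",
  representation(
    network = "ReactionNetwork",
    dynamics = "character",
    obs = "ObservationModel",
    population = "PopulationLaw",
    dimC = "integer", dimKappa = "integer", dimXi = "integer",
    kappaKnown = "numeric",
    x0 = "numeric",
    x0FromC = "integer",
    kappaDefault = "numeric",
    xiDefault = "numeric",
    simulator = "character",
    cNames = "character", kappaNames = "character", xiNames = "character"
  )
)

setValidity("SSMEMModel", function(object) {
  msg <- character()
  if (!object@dynamics %in% c("jump", "sde"))
    msg <- c(msg, "dynamics must be 'jump' or 'sde'")
  if (length(object@population@mu) != object@dimC)
    msg <- c(msg, "population law dimension must equal dimC")
  if (length(object@x0FromC) != length(object@x0))
    msg <- c(msg, "x0FromC must have one entry per species")
  if (any(object@x0FromC > object@dimC))
    msg <- c(msg, "x0FromC indices must point into c")
  if (!object@simulator %in% c("ssa", "extrande", "exact_ou"))
    msg <- c(msg, "simulator must be ssa, extrande or exact_ou")
  if (length(msg)) msg else TRUE
})

#' Multi-cell time-series data
#'
#' Observation times and noisy observation vectors for M individuals
#' (cells). Times may differ between cells; each cell's observation matrix
#' has one row per time point and one column per observable.
#'
#' @slot times list of strictly increasing numeric vectors
#' @slot obs list of numeric matrices (n_i x q)
#' @slot t0 initial time of the latent process (shared)
#' @export
setClass("CellData",
  representation(times = "list", obs = "list", t0 = "numeric")
)

setValidity("CellData", function(object) {
  msg <- character()
  if (length(object@times) != length(object@obs))
    msg <- c(msg, "times and obs must have one entry per cell")
  for (i in seq_along(object@times)) {
    tt <- object@times[[i]]
    if (any(diff(tt) <= 0))
      msg <- c(msg, sprintf("cell %d: times must be strictly increasing", i))
    if (nrow(object@obs[[i]]) != length(tt))
      msg <- c(msg, sprintf("cell %d: obs rows must match times", i))
    if (length(tt) && tt[1] <= object@t0)
      msg <- c(msg, sprintf("cell %d: first observation must be after t0", i))
  }
  if (length(msg)) msg else TRUE
})

#' Particle-filter configuration
#'
#' @slot nParticles number of particles N
#' @slot kind "bootstrap" or "guided_mdb"
#' @slot integrator "ssa", "extrande", "tauleap" or "langevin"
#' @slot dt step size for the approximate integrators
#' @slot rho auxiliary-number correlation in [0, 1); positive rho requires a
#'   tau-leap or Langevin integrator (exact jump simulators consume an
#'   unbounded amount of randomness, so their draws cannot be laid out and
#'   correlated)
#' @slot essThreshold resample when ESS falls below this fraction of N
#' @slot lookahead Extrande window length
#' @slot maxEvents event cap per simulated path
#' @export
setClass("PFConfig",
  representation(
    nParticles = "integer", kind = "character", integrator = "character",
    dt = "numeric", rho = "numeric", essThreshold = "numeric",
    lookahead = "numeric", maxEvents = "integer"
  )
)

setValidity("PFConfig", function(object) {
  msg <- character()
  if (length(object@nParticles) < 1 || any(object@nParticles < 1))
    msg <- c(msg, "nParticles must be >= 1")
  if (!object@kind %in% c("bootstrap", "guided_mdb"))
    msg <- c(msg, "kind must be bootstrap or guided_mdb")
  if (!object@integrator %in% c("ssa", "extrande", "tauleap", "langevin"))
    msg <- c(msg, "unknown integrator")
  if (object@kind == "guided_mdb" && object@integrator != "langevin")
    msg <- c(msg, "guided_mdb requires the langevin integrator")
  if (object@rho < 0 || object@rho >= 1)
    msg <- c(msg, "rho must be in [0, 1)")
  if (object@rho > 0 && !object@integrator %in% c("tauleap", "langevin"))
    msg <- c(msg, "rho > 0 requires the tauleap or langevin integrator")
  if (object@essThreshold <= 0 || object@essThreshold > 1)
    msg <- c(msg, "essThreshold must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Adaptive random-walk proposal state
#'
#' Holds the running state of one adaptive Metropolis proposal: the adaptive
#' Metropolis (AM) with empirical-covariance scaling, AM with global scaling,
#' or the robust adaptive Metropolis (RAM) with rank-one Cholesky updates
#' targeting a fixed acceptance rate. Adaptation decays as n^(-beta) so the
#' scheme satisfies diminishing adaptation.
#'
#' @slot kind "AM", "AM_global" or "RAM"
#' @slot dim parameter dimension
#' @slot n iteration counter
#' @slot mean running mean (AM variants)
#' @slot cov running covariance (AM variants)
#' @slot S lower-triangular proposal factor (RAM)
#' @slot lambda global log-scale (AM_global)
#' @slot alphaStar target acceptance rate
#' @slot beta adaptation decay exponent in (0.5, 1]
#' @slot epsReg regularisation jitter
#' @slot sigma0 pre-adaptation proposal scale
#' @slot frozen if TRUE, adaptation is stopped
#' @export
setClass("AdaptiveProposal",
  representation(
    kind = "character", dim = "integer", n = "numeric",
    mean = "numeric", cov = "matrix", S = "matrix", lambda = "numeric",
    alphaStar = "numeric", beta = "numeric", epsReg = "numeric",
    sigma0 = "numeric", frozen = "logical"
  )
)

setValidity("AdaptiveProposal", function(object) {
  msg <- character()
  if (!object@kind %in% c("AM", "AM_global", "RAM"))
    msg <- c(msg, "kind must be AM, AM_global or RAM")
  if (object@alphaStar <= 0 || object@alphaStar >= 1)
    msg <- c(msg, "alphaStar must be in (0, 1)")
  if (object@beta <= 0.5 || object@beta > 1)
    msg <- c(msg, "beta must be in (0.5, 1]")
  if (length(msg)) msg else TRUE
})

#' Posterior samples from a Gibbs run
#'
#' @slot mu iterations x dimC matrix of population log-means
#' @slot omega iterations x (dimC*(dimC+1)/2) matrix, vech of Omega
#' @slot kappa iterations x dimKappa matrix (natural scale; population
#'   location in perturbed mode)
#' @slot xi iterations x dimXi matrix (natural scale; population location in
#'   perturbed mode)
#' @slot cSamples optional iterations x M x dimC array of individual rates
#' @slot accIndividual per-individual acceptance rates
#' @slot accConstants acceptance rate of the cell-constant block (unperturbed)
#' @slot mode "perturbed" or "unperturbed"
#' @slot burnin number of discarded initial iterations
#' @slot cNames,kappaNames,xiNames parameter names
#' @slot checkpoint internal state for exact resumption (may be empty)
#' @export
setClass("PosteriorSamples",
  representation(
    mu = "matrix", omega = "matrix", kappa = "matrix", xi = "matrix",
    cSamples = "ANY",
    accIndividual = "numeric", accConstants = "numeric",
    mode = "character", burnin = "integer",
    cNames = "character", kappaNames = "character", xiNames = "character",
    checkpoint = "list"
  )
)
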