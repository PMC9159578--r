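#' Simulated latent trajectory
#'
#' @slot times requested output times (strictly increasing)
#' @slot states matrix, length(times) x d; integer-valued for the exact jump
#'   simulators, real-valued for Langevin paths
#' @export
setClass("Trajectory", representation(times = "numeric", states = "matrix"))

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d time points, %d species\n",
              length(object@times), ncol(object@states)))
})

newTrajectory <- function(times, states, speciesNames = NULL) {
  states <- as.matrix(states)
  if (!is.null(speciesNames)) colnames(states) <- speciesNames
  new("Trajectory", times = as.numeric(times), states = states)
}

#' @describeIn simulateSSA convert a trajectory to a data frame
#' @param x a Trajectory
#' @param row.names,optional,... S3 compatibility, ignored
#' @export
as.data.frame.Trajectory <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(time = x@times, x@states)
}

checkSimArgs <- function(network, x0, outTimes, t0) {
  stopifnot(is(network, "ReactionNetwork"))
  if (length(x0) != nSpecies(network))
    stop("x0 must have one entry per species")
  if (any(diff(c(t0, outTimes)) <= 0))
    stop("outTimes must be strictly increasing and after t0")
}

#' Exact stochastic simulation (Gillespie direct method)
#'
#' Draws one exact path of the jump process defined by the network's master
#' equation, recorded at the requested output times by last-event hold.
#' Propensities must be time-invariant; use \code{\link{simulateExtrande}}
#' for time-varying rates.
#'
#' @param network a \linkS4class{ReactionNetwork}
#' @param c,kappa rate parameters (natural scale)
#' @param x0 nonnegative integer initial state
#' @param outTimes strictly increasing output times
#' @param t0 initial time
#' @param maxEvents error out after this many reaction events (runaway
#'   network guard)
#' @return a \linkS4class{Trajectory}
#' @export
simulateSSA <- function(network, c, kappa = numeric(), x0, outTimes, t0 = 0,
                        maxEvents = 1e7) {
  checkSimArgs(network, x0, outTimes, t0)
  st <- .ssaCpp(cnet(network), as.numeric(c), as.numeric(kappa),
                as.numeric(x0), t0, as.numeric(outTimes),
                as.integer(maxEvents))
  newTrajectory(outTimes, st, network@speciesNames)
}

#' Exact simulation with time-varying propensities (Extrande)
#'
#' Thinning algorithm: candidate events are generated at the bound rate B on
#' a lookahead window; a candidate at time t fires reaction j with
#' probability \eqn{h_j(x, t)/B} and is "virtual" (no-op) otherwise. Exact
#' for any time-varying propensity provided B dominates the total propensity
#' over each window at the current (fixed) state; violation of the bound at
#' an accepted candidate time is a runtime error reporting the deficit.
#'
#' @inheritParams simulateSSA
#' @param bound either NULL (built-in analytic bound for compiled
#'   time-varying networks, or total propensity at the window start for
#'   time-invariant ones), or a function
#'   \code{(x, c, kappa, t0, t1) -> B} giving an upper bound for the total
#'   propensity on the window; see \code{\link{gridExtrandeBound}} for a
#'   numeric convenience bound
#' @param lookahead window length L
#' @return a \linkS4class{Trajectory}; attributes \code{events} and
#'   \code{virtual} count real and thinned candidates
#' @export
simulateExtrande <- function(network, c, kappa = numeric(), x0, outTimes,
                             t0 = 0, bound = NULL, lookahead = 1,
                             maxEvents = 1e7) {
  checkSimArgs(network, x0, outTimes, t0)
  boundMode <- if (is.function(bound)) 2L
    else if (network@builtin == 2L) 0L else 1L
  res <- .extrandeCpp(cnet(network), as.numeric(c), as.numeric(kappa),
                      as.numeric(x0), t0, as.numeric(outTimes), lookahead,
                      boundMode, bound, as.integer(maxEvents))
  out <- newTrajectory(outTimes, res$states, network@speciesNames)
  attr(out, "events") <- res$events
  attr(out, "virtual") <- res$virtual
  out
}

#' Numeric convenience bound for Extrande
#'
#' Builds a bound function that evaluates the total propensity on a grid over
#' the lookahead window (at the current, fixed state) and multiplies the
#' maximum by a safety factor. The runtime bound check in the simulator will
#' flag any window where the factor was insufficient.
#'
#' @param network a \linkS4class{ReactionNetwork}
#' @param nGrid grid points per window
#' @param safety multiplicative safety factor
#' @return a function usable as the \code{bound} argument of
#'   \code{\link{simulateExtrande}}
#' @export
gridExtrandeBound <- function(network, nGrid = 8, safety = 1.5) {
  force(network); force(nGrid); force(safety)
  function(x, c, kappa, t0, t1) {
    ts <- seq(t0, t1, length.out = nGrid)
    m <- max(vapply(ts, function(t)
      sum(evaluatePropensities(network, x, c, kappa, t)), 0))
    safety * m
  }
}

#' Fixed-step tau-leap simulation
#'
#' Poisson leaping with fixed step: over each substep of length dt every
#' reaction fires \eqn{Poisson(h_j(x, t) dt)} times. Species driven negative
#' have their propensity inputs clamped at zero on the next evaluation.
#' Inter-observation gaps are divided into \code{ceiling(gap/dt)} equal
#' substeps (so the last substep is shortened rather than overshooting).
#'
#' @inheritParams simulateSSA
#' @param dt step length (> 0)
#' @return a \linkS4class{Trajectory}
#' @export
simulateTauLeap <- function(network, c, kappa = numeric(), x0, outTimes,
                            t0 = 0, dt) {
  checkSimArgs(network, x0, outTimes, t0)
  if (dt <= 0) stop("dt must be positive")
  st <- .tauleapCpp(cnet(network), as.numeric(c), as.numeric(kappa),
                    as.numeric(x0), t0, as.numeric(outTimes), dt)
  newTrajectory(outTimes, st, network@speciesNames)
}

#' Chemical Langevin simulation (Euler-Maruyama)
#'
#' Euler-Maruyama discretisation of the chemical Langevin equation:
#' \deqn{x \leftarrow x + S h dt + S diag(h)^{1/2} \sqrt{dt} z,}
#' with one standard normal per reaction per substep. States are
#' real-valued and may go negative; propensity evaluations clamp negative
#' state coordinates at zero.
#'
#' @inheritParams simulateTauLeap
#' @param driftOnly if TRUE the diffusion term is dropped, giving the
#'   deterministic Euler solution of the reaction-rate ODE
#' @return a \linkS4class{Trajectory}
#' @export
simulateLangevin <- function(network, c, kappa = numeric(), x0, outTimes,
                             t0 = 0, dt, driftOnly = FALSE) {
  checkSimArgs(network, x0, outTimes, t0)
  if (dt <= 0) stop("dt must be positive")
  st <- .langevinCpp(cnet(network), as.numeric(c), as.numeric(kappa),
                     as.numeric(x0), t0, as.numeric(outTimes), dt, driftOnly)
  newTrajectory(outTimes, st, network@speciesNames)
}

#' Simulate one cell of an SSMEM with its designated exact simulator
#'
#' Used by the data generator and the posterior visual check: simulates the
#' latent path with the model's exact simulator ("ssa", "extrande" or the
#' exact Ornstein-Uhlenbeck transition) for given individual rates.
#'
#' @param model an \linkS4class{SSMEMModel}
#' @param cI individual rate vector (natural scale)
#' @param kappa inferred cell-constant rates (natural scale)
#' @param outTimes output grid
#' @param t0 initial time
#' @return a \linkS4class{Trajectory} of the latent state
#' @export
simulateCell <- function(model, cI, kappa = numeric(), outTimes, t0 = 0) {
  x0 <- resolveX0(model, cI)
  kap <- fullKappa(model, kappa)
  switch(model@simulator,
    ssa = simulateSSA(model@network, cI, kap, x0, outTimes, t0),
    extrande = simulateExtrande(model@network, cI, kap, x0, outTimes, t0,
                                lookahead = extrandeLookahead(outTimes)),
    exact_ou = {
      x <- simulateOUExact(cI, outTimes, x0 = x0[1], t0 = t0)
      newTrajectory(outTimes, matrix(x, ncol = 1), model@network@speciesNames)
    })
}

# default Extrande window: a fraction of the horizon, capped at 1 time unit
extrandeLookahead <- function(outTimes) {
  min(1, diff(range(outTimes)) / 24)
}
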