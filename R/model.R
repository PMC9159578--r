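#' Construct a state-space mixed-effects model
#'
#' @param network a \linkS4class{ReactionNetwork} (or the OU stub from
#'   \code{\link{makeOUModel}})
#' @param obs an \linkS4class{ObservationModel}
#' @param population a \linkS4class{PopulationLaw} for the cell-individual
#'   rates c
#' @param dimKappa number of inferred cell-constant rates
#' @param dimXi number of error-scale parameters (defaults to the number of
#'   observables)
#' @param kappaKnown known cell-constant values, appended after the inferred
#'   kappa when propensities are evaluated
#' @param x0 default initial state
#' @param x0FromC integer vector, one entry per species: index of the c
#'   coordinate supplying that species' initial value (0 = use \code{x0});
#'   this is how cell-varying initial states are expressed as extra
#'   coordinates of c
#' @param dynamics "jump" or "sde"
#' @param simulator exact simulator for data generation and predictive
#'   checks: "ssa", "extrande" or "exact_ou"
#' @param cNames,kappaNames,xiNames parameter names
#' @return an \linkS4class{SSMEMModel}
#' @export
SSMEMModel <- function(network, obs, population, dimKappa = 0L,
                       dimXi = NULL, kappaKnown = numeric(),
                       x0 = NULL, x0FromC = NULL, dynamics = "jump",
                       simulator = "ssa", kappaDefault = NULL,
                       xiDefault = NULL,
                       cNames = NULL, kappaNames = NULL, xiNames = NULL) {
  d <- nSpecies(network)
  if (is.null(x0)) x0 <- numeric(d)
  if (is.null(x0FromC)) x0FromC <- integer(d)
  if (is.null(dimXi)) dimXi <- obs@q
  dimC <- length(population@mu)
  if (is.null(kappaDefault)) kappaDefault <- rep(1, dimKappa)
  if (is.null(xiDefault)) xiDefault <- rep(1, dimXi)
  if (is.null(cNames)) cNames <- paste0("c", seq_len(dimC))
  if (is.null(kappaNames)) kappaNames <-
      if (dimKappa > 0) paste0("kappa", seq_len(dimKappa)) else character()
  if (is.null(xiNames)) xiNames <- paste0("sigma", seq_len(dimXi))
  new("SSMEMModel", network = network, dynamics = dynamics, obs = obs,
      population = population, dimC = as.integer(dimC),
      dimKappa = as.integer(dimKappa), dimXi = as.integer(dimXi),
      kappaKnown = as.numeric(kappaKnown), x0 = as.numeric(x0),
      x0FromC = as.integer(x0FromC), simulator = simulator,
      kappaDefault = as.numeric(kappaDefault), xiDefault = as.numeric(xiDefault),
      cNames = cNames, kappaNames = kappaNames, xiNames = xiNames)
}

setMethod("show", "SSMEMModel", function(object) {
  cat(sprintf("SSMEMModel (%s dynamics, %s data simulator)\n",
              object@dynamics, object@simulator))
  cat(sprintf("  species: %d, reactions: %d\n", nSpecies(object@network),
              nReactions(object@network)))
  cat(sprintf("  parameters: c[%d] ~ LN(mu, Omega), kappa[%d], xi[%d]%s\n",
              object@dimC, object@dimKappa, object@dimXi,
              if (length(object@kappaKnown))
                sprintf(", %d known constants", length(object@kappaKnown))
              else ""))
})

# initial state of one cell given its individual rates (natural scale)
resolveX0 <- function(model, cI) {
  x0 <- model@x0
  sel <- model@x0FromC > 0L
  if (any(sel)) x0[sel] <- cI[model@x0FromC[sel]]
  x0
}

# full cell-constant vector seen by the propensity function
fullKappa <- function(model, kappa) c(as.numeric(kappa), model@kappaKnown)

#' Construct a multi-cell dataset
#'
#' @param times list of observation-time vectors (or a single vector shared
#'   by every cell)
#' @param obs list of observation matrices (n_i x q), or vectors for scalar
#'   observables
#' @param t0 initial time of the latent process
#' @return a \linkS4class{CellData}
#' @export
cellData <- function(times, obs, t0 = 0) {
  if (!is.list(obs)) obs <- list(obs)
  obs <- lapply(obs, function(y) if (is.matrix(y)) y else matrix(y, ncol = 1))
  if (!is.list(times)) times <- rep(list(as.numeric(times)), length(obs))
  new("CellData", times = times, obs = obs, t0 = t0)
}

#' Number of cells in a dataset
#' @param data a \linkS4class{CellData}
#' @export
nCells <- function(data) length(data@times)

setMethod("show", "CellData", function(object) {
  n <- vapply(object@times, length, 1L)
  cat(sprintf("CellData: %d cells, %s observation times each, t0 = %g\n",
              nCells(object),
              if (length(unique(n)) == 1) n[1] else paste(range(n), collapse = "-"),
              object@t0))
})

#' Convert a dataset to a long data frame
#'
#' @param x a \linkS4class{CellData}
#' @param row.names,optional ignored (S3 compatibility)
#' @param ... ignored
#' @return data.frame with columns cell, time and one column per observable
#' @export
as.data.frame.CellData <- function(x, row.names = NULL, optional = FALSE, ...) {
  q <- ncol(x@obs[[1]])
  out <- do.call(rbind, lapply(seq_along(x@times), function(i) {
    data.frame(cell = i, time = x@times[[i]],
               matrix(x@obs[[i]], ncol = q,
                      dimnames = list(NULL, paste0("y", seq_len(q)))))
  }))
  rownames(out) <- NULL
  out
}
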