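#' Construct a reaction network
#'
#' @param stoich integer matrix, species x reactions: net state change of
#'   each reaction
#' @param propensity function \code{(x, c, kappa, t) -> numeric(R)} returning
#'   nonnegative firing rates; may be omitted when \code{builtin} names a
#'   compiled network
#' @param speciesNames,reactionNames optional names
#' @param builtin one of "", "birthdeath", "circadian", "schlogl",
#'   "schlogl_sq"; compiled propensities used by the simulators and particle
#'   filters without R-callback overhead
#' @return a \linkS4class{ReactionNetwork}
#' @examples
#' # birth-death: 0 -> X at c1, X -> 0 at c2*x
#' net <- ReactionNetwork(
#'   stoich = matrix(c(1L, -1L), nrow = 1),
#'   propensity = function(x, c, kappa, t) c(c[1], c[2] * x[1])
#' )
#' evaluatePropensities(net, x = 10, c = c(2, 0.5))
#' @export
ReactionNetwork <- function(stoich, propensity = NULL,
                            speciesNames = NULL, reactionNames = NULL,
                            builtin = "") {
  stoich <- as.matrix(stoich)
  storage.mode(stoich) <- "integer"
  id <- builtinPropensityId(builtin)
  if (is.null(speciesNames))
    speciesNames <- paste0("X", seq_len(nrow(stoich)))
  if (is.null(reactionNames))
    reactionNames <- paste0("R", seq_len(ncol(stoich)))
  new("ReactionNetwork", stoich = stoich, propensity = propensity,
      builtin = id, speciesNames = speciesNames,
      reactionNames = reactionNames)
}

# mapping to the compiled propensity ids in src/core.cpp
builtinPropensityId <- function(name) {
  if (identical(name, "")) return(0L)
  switch(name,
    birthdeath = 1L, circadian = 2L,
    schlogl = 3L, schlogl_sq = 4L, ou_sde = 100L,
    stop("unknown built-in network: ", name)
  )
}

# internal list handed to the C++ kernels
cnet <- function(network) {
  list(stoich = network@stoich, propId = network@builtin,
       propFn = network@propensity)
}

#' Evaluate reaction propensities
#'
#' Returns the firing rate of every reaction at state \code{x} and time
#' \code{t}. Propensities must be finite and nonnegative; violations raise an
#' error naming the offending reaction.
#'
#' @param network a \linkS4class{ReactionNetwork}
#' @param x nonnegative state vector
#' @param c,kappa rate parameters on the natural (positive) scale
#' @param t time (used by time-varying propensities)
#' @return numeric vector of length R
#' @export
evaluatePropensities <- function(network, x, c, kappa = numeric(), t = 0) {
  stopifnot(is(network, "ReactionNetwork"))
  h <- .evalPropCpp(cnet(network), as.numeric(x), as.numeric(c),
                    as.numeric(kappa), t)
  names(h) <- network@reactionNames
  h
}

#' Number of species / reactions
#' @param network a \linkS4class{ReactionNetwork}
#' @export
nSpecies <- function(network) nrow(network@stoich)

#' @rdname nSpecies
#' @export
nReactions <- function(network) ncol(network@stoich)

setMethod("show", "ReactionNetwork", function(object) {
  cat(sprintf("ReactionNetwork: %d species, %d reactions%s\n",
              nSpecies(object), nReactions(object),
              if (object@builtin > 0) " (compiled)" else ""))
  cat("  species: ", paste(object@speciesNames, collapse = ", "), "\n")
})
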