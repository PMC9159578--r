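# The two pseudo-marginal Gibbs samplers. The unperturbed sampler loops
#   step 1: per-individual update of c^(i) (pseudo-marginal MH)
#   step 2: joint update of the cell-constant (kappa, xi) against the full
#           data likelihood (pseudo-marginal MH over the summed estimate)
#   step 3: exact conjugate (or HMC) draw of eta = (mu, Omega)
# The perturbed sampler lets (kappa, xi) vary weakly between cells with
# known variance delta^2 on the log scale: (kappa^(i), xi^(i)) join the
# individual block of step 1, their population locations get closed-form
# Gaussian draws in step 3, and step 2 disappears -- removing the
# high-variance summed likelihood estimate that otherwise forces large
# particle counts as the number of cells grows.

#' Default priors for an SSMEM inference run
#'
#' Normal-Inverse-Wishart prior on the population law of the individual
#' rates, centred on the model's default law; independent Gaussian priors on
#' the log of each cell-constant rate and error scale, centred on the
#' model's defaults with SD 1 (one decade at one sigma). The default NIW is
#' weakly informative: nu0 = dimC + 2 (the vaguest proper inverse-Wishart,
#' heavy-tailed in the between-cell scales) with the prior mean of Omega at
#' the model's nominal between-cell variances, and lambda0 = 0.1
#' pseudo-observations for mu.
#'
#' @param model an \linkS4class{SSMEMModel}
#' @param lambda0,nu0 NIW strength parameters
#' @param kappaSd,xiSd prior SDs on the log scale
#' @return list with fields eta (a \code{\link{niwPrior}}), kappaMean,
#'   kappaSd, xiMean, xiSd
#' @export
ssmemPriors <- function(model, lambda0 = 0.1, nu0 = model@dimC + 2,
                        kappaSd = 1, xiSd = 1) {
  p <- model@dimC
  tau2 <- pmax(diag(model@population@Omega), 0.05^2)
  list(
    eta = niwPrior(model@population@mu, lambda0, nu0,
                   diag(tau2 * max(nu0 - p - 1, 1), p)),
    kappaMean = log(model@kappaDefault), kappaSd = rep(kappaSd, model@dimKappa),
    xiMean = log(model@xiDefault), xiSd = rep(xiSd, model@dimXi)
  )
}

#' Inference configuration
#'
#' @param nIterations total Gibbs iterations
#' @param mode "perturbed" (default; cell-constant parameters vary weakly
#'   between cells and step 2 is eliminated) or "unperturbed"
#' @param delta perturbation SD on the log scale (perturbed mode)
#' @param pf a \linkS4class{PFConfig}
#' @param burnin fraction of iterations discarded
#' @param thinning keep every thinning-th post-burnin iteration
#' @param etaKind "conjugate_niw" for the exact conjugate population draw or
#'   "hmc" for leapfrog HMC (non-conjugate priors)
#' @param proposal list: kind ("RAM", "AM", "AM_global"), targetAcceptance,
#'   beta, sigma0
#' @param priors from \code{\link{ssmemPriors}}; NULL resolves defaults from
#'   the model
#' @param likelihood "pf" (particle filter) or "kalman" (exact; OU model
#'   only -- the gold-standard oracle)
#' @param shiftMove joint translation update of (mu, all log c) after the
#'   individual sweep: TRUE (every iteration, default), FALSE, or an integer
#'   k to apply it every k-th iteration. The move leaves the target
#'   invariant and removes the slow coupled drift of the population mean
#'   typical of centred hierarchies; it costs one extra likelihood estimate
#'   per cell when applied
#' @param saveIndividuals keep the per-cell c draws (memory permitting)
#' @param init optional named list overriding the initial state: c (matrix),
#'   kappa, xi, mu, Omega
#' @return config list used by \code{\link{runInference}}
#' @export
inferenceConfig <- function(nIterations = 5000, mode = "perturbed",
                            delta = 0.1, pf = pfConfig(), burnin = 0.2,
                            thinning = 1, etaKind = "conjugate_niw",
                            proposal = list(), priors = NULL,
                            likelihood = "pf", shiftMove = TRUE,
                            saveIndividuals = FALSE, init = NULL) {
  stopifnot(nIterations >= 1, mode %in% c("perturbed", "unperturbed"),
            delta > 0, etaKind %in% c("conjugate_niw", "hmc"),
            likelihood %in% c("pf", "kalman"))
  proposal <- modifyList(list(kind = "RAM", targetAcceptance = 0.234,
                              beta = 0.66, sigma0 = 0.1), proposal)
  list(nIterations = as.integer(nIterations), mode = mode, delta = delta,
       pf = pf, burnin = burnin, thinning = as.integer(thinning),
       etaKind = etaKind, proposal = proposal, priors = priors,
       likelihood = likelihood, shiftMove = shiftMove,
       saveIndividuals = saveIndividuals, init = init)
}

# likelihood backend: particle filter or exact Kalman (OU only). The PF
# branch precomputes every constant .pfCpp argument per cell: inside the
# Gibbs loop this function is the hottest R-level call site.
makeLogLik <- function(model, data, cfg) {
  if (cfg$likelihood == "kalman") {
    if (model@network@builtin != 100L)
      stop("the Kalman likelihood backend requires the OU model")
    function(i, cI, kappa, xi, u, refresh = FALSE) {
      list(value = kalmanLogLik(cI, xi[1], data@times[[i]],
                                data@obs[[i]][, 1],
                                x0 = model@x0[1], t0 = data@t0),
           aux = NULL)
    }
  } else {
    pf <- cfg$pf
    cn <- cnet(model@network)
    P <- model@obs@P; g <- model@obs@g
    icode <- integratorCode(pf@integrator)
    guided <- pf@kind == "guided_mdb"
    if (guided && !is.null(g))
      stop("guided filter requires a linear-Gaussian observation model")
    statInit <- ouStationary(model)
    sortP <- pf@rho > 0
    essThr <- if (sortP) 1.0000001 else pf@essThreshold
    boundMode <- if (model@network@builtin == 2L) 0L else 1L
    kk <- model@kappaKnown
    timesL <- data@times
    obsL <- data@obs
    t0 <- data@t0
    sel <- model@x0FromC
    x0base <- model@x0
    if (statInit) x0base[1] <- 0
    rho <- pf@rho
    Nvec <- pf@nParticles
    # refresh = TRUE performs the Crank-Nicolson auxiliary refresh inside
    # the C++ call and returns the refreshed arrays in $aux
    function(i, cI, kappa, xi, u, refresh = FALSE) {
      x0 <- x0base
      if (any(sel > 0L)) x0[sel > 0L] <- cI[sel[sel > 0L]]
      Ni <- if (length(Nvec) > 1L) Nvec[i] else Nvec
      res <- .pfCpp(cn, cI, c(kappa, kk), xi, x0, t0, timesL[[i]], obsL[[i]],
                    P, g, icode, pf@dt, Ni, essThr, guided, sortP,
                    if (is.null(u)) NULL else u$uProp,
                    if (is.null(u)) NULL else u$uResamp,
                    pf@lookahead, boundMode, pf@maxEvents, statInit,
                    if (refresh) rho else 0)
      list(value = res$value,
           aux = if (refresh && !is.null(res$uProp))
             list(uProp = res$uProp, uResamp = res$uResamp) else u)
    }
  }
}

newProposal <- function(dim, pr) {
  adaptiveProposal(dim, kind = pr$kind,
                   targetAcceptance = pr$targetAcceptance,
                   beta = pr$beta, sigma0 = pr$sigma0)
}

initChainState <- function(model, data, cfg, priors) {
  M <- nCells(data)
  p <- model@dimC; dk <- model@dimKappa; dx <- model@dimXi
  perturbed <- cfg$mode == "perturbed"
  mu <- priors$eta$mu0
  Omega <- priors$eta$Psi0 / max(priors$eta$nu0 - p - 1, 1)
  kpop <- priors$kappaMean
  xpop <- priors$xiMean
  byRow <- function(v, n) {
    if (n == 0 || length(v) == 0) return(matrix(numeric(), n, length(v)))
    matrix(rep(v, each = n), n, length(v))
  }
  logc <- matrix(stats::rnorm(M * p), M, p) %*% t(safeCholLower(Omega)) +
    byRow(mu, M)
  logkI <- byRow(kpop, M) +
    if (perturbed && dk > 0) cfg$delta * matrix(stats::rnorm(M * dk), M, dk) else 0
  logxI <- byRow(xpop, M) +
    if (perturbed && dx > 0) cfg$delta * matrix(stats::rnorm(M * dx), M, dx) else 0
  if (!is.null(cfg$init)) {
    ini <- cfg$init
    if (!is.null(ini$mu)) mu <- ini$mu
    if (!is.null(ini$Omega)) Omega <- as.matrix(ini$Omega)
    if (!is.null(ini$c)) logc <- log(as.matrix(ini$c))
    if (!is.null(ini$kappa)) {
      kpop <- log(ini$kappa); logkI <- matrix(kpop, M, dk, byrow = TRUE)
    }
    if (!is.null(ini$xi)) {
      xpop <- log(ini$xi); logxI <- matrix(xpop, M, dx, byrow = TRUE)
    }
  }
  useAux <- cfg$likelihood == "pf" && cfg$pf@rho > 0
  aux <- vector("list", M)
  dimBlock <- p + if (perturbed) dk + dx else 0
  st <- list(
    logc = logc, logkI = logkI, logxI = logxI,
    logkappa = kpop, logxi = xpop, mu = mu, Omega = Omega,
    kpop = kpop, xpop = xpop,
    ll = rep(-Inf, M), aux = aux, useAux = useAux,
    props = replicate(M, newProposal(dimBlock, cfg$proposal),
                      simplify = FALSE),
    propConst = if (!perturbed && dk + dx > 0)
      newProposal(dk + dx, cfg$proposal) else NULL,
    propShift = newProposal(p, cfg$proposal),
    hmcCtl = list(),
    accI = numeric(M), accC = 0, accShift = 0, nIter = 0,
    perturbed = perturbed
  )
  st
}

# parameters of individual i as seen by the likelihood
individualParams <- function(st, i) {
  if (st$perturbed) {
    list(c = exp(st$logc[i, ]), kappa = exp(st$logkI[i, ]),
         xi = exp(st$logxI[i, ]))
  } else {
    list(c = exp(st$logc[i, ]), kappa = exp(st$logkappa),
         xi = exp(st$logxi))
  }
}

gibbsStep1 <- function(st, model, data, cfg, priors, llFun) {
  M <- nCells(data)
  p <- model@dimC; dk <- model@dimKappa; dx <- model@dimXi
  # one Cholesky of Omega per sweep; normalizing constants cancel in the
  # Metropolis ratio, so only the quadratic forms are evaluated per cell
  Lpop <- safeCholLower(st$Omega + diag(1e-12, p))
  ldet <- sum(log(diag(Lpop)))
  Linv <- backsolve(Lpop, diag(p), upper.tri = FALSE)
  logPriorBlock <- function(logcI, logkI, logxI) {
    z <- Linv %*% (logcI - st$mu)
    lp <- -ldet - 0.5 * sum(z * z)
    if (st$perturbed) {
      if (dk > 0) lp <- lp - 0.5 * sum(((logkI - st$kpop) / cfg$delta)^2)
      if (dx > 0) lp <- lp - 0.5 * sum(((logxI - st$xpop) / cfg$delta)^2)
    }
    lp
  }
  for (i in seq_len(M)) {
    cur <- c(st$logc[i, ],
             if (st$perturbed) c(st$logkI[i, ], st$logxI[i, ]))
    prop <- propose(st$props[[i]], cur)
    th <- prop$theta
    logcP <- th[seq_len(p)]
    logkP <- if (st$perturbed && dk > 0) th[p + seq_len(dk)] else
      if (st$perturbed) numeric() else st$logkappa
    logxP <- if (st$perturbed && dx > 0) th[p + dk + seq_len(dx)] else
      if (st$perturbed) numeric() else st$logxi
    if (st$useAux && is.null(st$aux[[i]]))
      st$aux[[i]] <- makeAuxiliary(model, data@times[[i]], cfg$pf, data@t0, cell = i)
    res <- llFun(i, exp(logcP), exp(if (st$perturbed) logkP else st$logkappa),
                 exp(if (st$perturbed) logxP else st$logxi), st$aux[[i]],
                 refresh = st$useAux)
    llP <- res$value
    num <- llP + logPriorBlock(logcP,
                               if (st$perturbed) logkP else numeric(),
                               if (st$perturbed) logxP else numeric())
    den <- st$ll[i] + logPriorBlock(st$logc[i, ], st$logkI[i, ], st$logxI[i, ])
    alpha <- if (!is.finite(num)) 0 else min(1, exp(num - den))
    if (!is.finite(den)) alpha <- if (is.finite(num)) 1 else 0
    if (stats::runif(1) < alpha) {
      st$logc[i, ] <- logcP
      if (st$perturbed && dk > 0) st$logkI[i, ] <- logkP
      if (st$perturbed && dx > 0) st$logxI[i, ] <- logxP
      st$ll[i] <- llP
      if (st$useAux) st$aux[[i]] <- res$aux
      st$accI[i] <- st$accI[i] + 1
      cur <- th
    }
    st$props[[i]] <- adaptProposal(st$props[[i]], cur, alpha, prop$z)
  }
  st
}

# joint translation move: shift mu and every individual's log-rates by a
# common delta. The population-law term pi(c | mu, Omega) is invariant under
# the shift, so the acceptance ratio involves only the NIW prior on mu and
# the M individual likelihoods (re-estimated with refreshed auxiliaries).
# This targets the classic slow direction of centred hierarchies, where the
# population mean can otherwise only move as fast as the individual blocks.
gibbsStepShift <- function(st, model, data, cfg, priors, llFun) {
  M <- nCells(data)
  if (M == 0) return(st)
  prop <- propose(st$propShift, numeric(model@dimC))
  delta <- prop$theta
  muP <- st$mu + delta
  logcP <- sweep(st$logc, 2, delta, "+")
  auxP <- st$aux
  llP <- numeric(M)
  for (i in seq_len(M)) {
    if (st$useAux && is.null(st$aux[[i]]))
      st$aux[[i]] <- makeAuxiliary(model, data@times[[i]], cfg$pf, data@t0, cell = i)
    par <- individualParams(st, i)
    res <- llFun(i, exp(logcP[i, ]), par$kappa, par$xi, st$aux[[i]],
                 refresh = st$useAux)
    llP[i] <- res$value
    auxP[[i]] <- res$aux
  }
  # N(mu; mu0, Omega / lambda0) prior ratio (the IW factor cancels)
  priorP <- dmvnormLog(muP, priors$eta$mu0, st$Omega / priors$eta$lambda0)
  priorC <- dmvnormLog(st$mu, priors$eta$mu0, st$Omega / priors$eta$lambda0)
  num <- sum(llP) + priorP
  den <- sum(st$ll) + priorC
  alpha <- if (!is.finite(num)) 0 else min(1, exp(num - den))
  if (!is.finite(den)) alpha <- if (is.finite(num)) 1 else 0
  if (stats::runif(1) < alpha) {
    st$mu <- muP
    st$logc <- logcP
    st$ll <- llP
    st$aux <- auxP
    st$accShift <- st$accShift + 1
  }
  st$propShift <- adaptProposal(st$propShift, delta, alpha, prop$z)
  st
}

gibbsStep2 <- function(st, model, data, cfg, priors, llFun) {
  dk <- model@dimKappa; dx <- model@dimXi
  if (dk + dx == 0) return(st)
  M <- nCells(data)
  cur <- c(st$logkappa, st$logxi)
  prop <- propose(st$propConst, cur)
  th <- prop$theta
  logkP <- if (dk > 0) th[seq_len(dk)] else numeric()
  logxP <- if (dx > 0) th[dk + seq_len(dx)] else numeric()
  auxP <- st$aux
  llP <- numeric(M)
  for (i in seq_len(M)) {
    if (st$useAux && is.null(st$aux[[i]]))
      st$aux[[i]] <- makeAuxiliary(model, data@times[[i]], cfg$pf, data@t0, cell = i)
    res <- llFun(i, exp(st$logc[i, ]), exp(logkP), exp(logxP), st$aux[[i]],
                 refresh = st$useAux)
    llP[i] <- res$value
    auxP[[i]] <- res$aux
  }
  priorP <- sum(stats::dnorm(logkP, priors$kappaMean, priors$kappaSd, log = TRUE)) +
    sum(stats::dnorm(logxP, priors$xiMean, priors$xiSd, log = TRUE))
  priorC <- sum(stats::dnorm(st$logkappa, priors$kappaMean, priors$kappaSd, log = TRUE)) +
    sum(stats::dnorm(st$logxi, priors$xiMean, priors$xiSd, log = TRUE))
  num <- sum(llP) + priorP
  den <- sum(st$ll) + priorC
  alpha <- if (!is.finite(num)) 0 else min(1, exp(num - den))
  if (!is.finite(den)) alpha <- if (is.finite(num)) 1 else 0
  if (stats::runif(1) < alpha) {
    st$logkappa <- logkP
    st$logxi <- logxP
    st$ll <- llP
    st$aux <- auxP
    st$accC <- st$accC + 1
    cur <- th
  }
  st$propConst <- adaptProposal(st$propConst, cur, alpha, prop$z)
  st
}

gibbsStep3 <- function(st, model, cfg, priors) {
  if (cfg$etaKind == "conjugate_niw") {
    eta <- sampleEtaConjugate(priors$eta, st$logc,
                              model@population@family)
    st$mu <- eta$mu; st$Omega <- eta$Omega
  } else {
    res <- sampleEtaHMC(st$logc, priors$eta, st$mu, st$Omega, st$hmcCtl)
    st$mu <- res$mu; st$Omega <- res$Omega; st$hmcCtl <- res$control
  }
  if (st$perturbed) {
    M <- nrow(st$logc)
    if (model@dimKappa > 0 && M > 0)
      st$kpop <- samplePopLocation(st$logkI, cfg$delta, priors$kappaMean,
                                   priors$kappaSd)
    if (model@dimXi > 0 && M > 0)
      st$xpop <- samplePopLocation(st$logxI, cfg$delta, priors$xiMean,
                                   priors$xiSd)
  }
  st
}

#' Run the pseudo-marginal Gibbs sampler
#'
#' Draws from the joint posterior of the cell-individual rates, the
#' cell-constant rates, the error scales and the population parameters of a
#' state-space mixed-effects model, using particle-filter likelihood
#' estimates (or the exact Kalman likelihood for the OU benchmark).
#'
#' @param model an \linkS4class{SSMEMModel}
#' @param data a \linkS4class{CellData}
#' @param cfg from \code{\link{inferenceConfig}}
#' @return a \linkS4class{PosteriorSamples}
#' @export
runInference <- function(model, data, cfg) {
  priors <- if (is.null(cfg$priors)) ssmemPriors(model) else cfg$priors
  llFun <- makeLogLik(model, data, cfg)
  st <- initChainState(model, data, cfg, priors)
  M <- nCells(data)
  # initial likelihoods (fresh auxiliaries)
  for (i in seq_len(M)) {
    if (st$useAux)
      st$aux[[i]] <- makeAuxiliary(model, data@times[[i]], cfg$pf, data@t0, cell = i)
    par <- individualParams(st, i)
    st$ll[i] <- llFun(i, par$c, par$kappa, par$xi, st$aux[[i]])$value
  }
  runGibbsLoop(model, data, cfg, priors, llFun, st, cfg$nIterations,
               recordFrom = floor(cfg$burnin * cfg$nIterations) + 1)
}

# shared iteration loop (also used for exact resumption)
runGibbsLoop <- function(model, data, cfg, priors, llFun, st, nIter,
                         recordFrom, prev = NULL) {
  p <- model@dimC
  keep <- which(seq_len(st$nIter + nIter) >= recordFrom &
                (seq_len(st$nIter + nIter) - recordFrom) %% cfg$thinning == 0)
  keep <- keep[keep > st$nIter]
  nKeep <- length(keep)
  muS <- matrix(NA_real_, nKeep, p)
  omS <- matrix(NA_real_, nKeep, p * (p + 1) / 2)
  kaS <- matrix(NA_real_, nKeep, model@dimKappa)
  xiS <- matrix(NA_real_, nKeep, model@dimXi)
  cS <- if (cfg$saveIndividuals)
    array(NA_real_, c(nKeep, nCells(data), p)) else NULL
  vechIdx <- which(lower.tri(diag(p), diag = TRUE))
  row <- 0
  for (it in seq_len(nIter)) {
    st <- gibbsStep1(st, model, data, cfg, priors, llFun)
    doShift <- if (isTRUE(cfg$shiftMove)) TRUE else
      if (is.numeric(cfg$shiftMove) && cfg$shiftMove >= 1)
        (st$nIter %% cfg$shiftMove) == 0 else FALSE
    if (doShift) st <- gibbsStepShift(st, model, data, cfg, priors, llFun)
    if (!st$perturbed) st <- gibbsStep2(st, model, data, cfg, priors, llFun)
    st <- gibbsStep3(st, model, cfg, priors)
    st$nIter <- st$nIter + 1
    if (st$nIter %in% keep) {
      row <- row + 1
      muS[row, ] <- st$mu
      omS[row, ] <- st$Omega[vechIdx]
      if (model@dimKappa > 0)
        kaS[row, ] <- exp(if (st$perturbed) st$kpop else st$logkappa)
      if (model@dimXi > 0)
        xiS[row, ] <- exp(if (st$perturbed) st$xpop else st$logxi)
      if (cfg$saveIndividuals) cS[row, , ] <- exp(st$logc)
    }
  }
  if (!is.null(prev)) {
    muS <- rbind(prev@mu, muS); omS <- rbind(prev@omega, omS)
    kaS <- rbind(prev@kappa, kaS); xiS <- rbind(prev@xi, xiS)
    if (!is.null(prev@cSamples) && !is.null(cS)) {
      cS2 <- array(NA_real_, c(dim(prev@cSamples)[1] + dim(cS)[1],
                               dim(cS)[2], dim(cS)[3]))
      cS2[seq_len(dim(prev@cSamples)[1]), , ] <- prev@cSamples
      cS2[dim(prev@cSamples)[1] + seq_len(dim(cS)[1]), , ] <- cS
      cS <- cS2
    }
  }
  new("PosteriorSamples",
      mu = muS, omega = omS, kappa = kaS, xi = xiS, cSamples = cS,
      accIndividual = st$accI / st$nIter,
      accConstants = if (st$perturbed) NA_real_ else st$accC / st$nIter,
      mode = cfg$mode, burnin = as.integer(recordFrom - 1),
      cNames = model@cNames, kappaNames = model@kappaNames,
      xiNames = model@xiNames,
      checkpoint = list(state = st, recordFrom = recordFrom,
                        rngState = .Random.seed))
}

#' Resume a Gibbs run exactly where it stopped
#'
#' Continues sampling from the checkpoint stored in a
#' \linkS4class{PosteriorSamples}; with the same model, data and
#' configuration the concatenated run is bit-identical to an uninterrupted
#' run of the same total length.
#'
#' @param model,data,cfg as in \code{\link{runInference}}
#' @param samples the previous \linkS4class{PosteriorSamples}
#' @param nMore additional iterations
#' @return a \linkS4class{PosteriorSamples} covering the full run
#' @export
continueInference <- function(model, data, cfg, samples, nMore) {
  ck <- samples@checkpoint
  if (!length(ck)) stop("samples carry no checkpoint")
  assign(".Random.seed", ck$rngState, envir = globalenv())
  priors <- if (is.null(cfg$priors)) ssmemPriors(model) else cfg$priors
  llFun <- makeLogLik(model, data, cfg)
  runGibbsLoop(model, data, cfg, priors, llFun, ck$state, nMore,
               recordFrom = ck$recordFrom, prev = samples)
}

#' Gold-standard exact Gibbs sampler for the OU benchmark
#'
#' Identical Gibbs loops with every particle-filter estimate replaced by the
#' exact Kalman-filter likelihood: exact marginal Metropolis-Hastings, the
#' reference posterior against which the pseudo-marginal chains are
#' validated.
#'
#' @param model the OU benchmark model (\code{\link{makeOUModel}})
#' @param data a \linkS4class{CellData}
#' @param cfg from \code{\link{inferenceConfig}}; the likelihood backend is
#'   forced to "kalman"
#' @return a \linkS4class{PosteriorSamples}
#' @export
exactGibbsOU <- function(model, data, cfg) {
  cfg$likelihood <- "kalman"
  runInference(model, data, cfg)
}

setMethod("show", "PosteriorSamples", function(object) {
  cat(sprintf("PosteriorSamples: %d saved draws (%s mode, burn-in %d)\n",
              nrow(object@mu), object@mode, object@burnin))
  s <- posteriorSummary(object)
  print(s, digits = 3)
})

#' Posterior summary table
#'
#' @param samples a \linkS4class{PosteriorSamples}
#' @return data.frame with posterior mean, SD and central 95\% interval per
#'   population-level parameter (mu and tau per c coordinate, kappa, xi)
#' @export
posteriorSummary <- function(samples) {
  tau <- tauSamples(samples)
  nm <- c(paste0("mu_", samples@cNames), paste0("tau_", samples@cNames),
          samples@kappaNames, samples@xiNames)
  X <- cbind(samples@mu, tau, samples@kappa, samples@xi)
  data.frame(
    parameter = nm,
    mean = colMeans(X),
    sd = apply(X, 2, stats::sd),
    q2.5 = apply(X, 2, stats::quantile, 0.025),
    q97.5 = apply(X, 2, stats::quantile, 0.975),
    row.names = NULL
  )
}

#' Population scale draws tau = sqrt(diag(Omega))
#' @param samples a \linkS4class{PosteriorSamples}
#' @return matrix of tau draws
#' @export
tauSamples <- function(samples) {
  p <- ncol(samples@mu)
  # vech (lower.tri, diag = TRUE) column-major: diagonal positions
  pos <- integer(p)
  k <- 0
  for (j in seq_len(p)) {
    pos[j] <- k + 1
    k <- k + (p - j + 1)
  }
  sqrt(samples@omega[, pos, drop = FALSE])
}

#' Reassemble Omega from one saved draw
#' @param samples a \linkS4class{PosteriorSamples}
#' @param iter row index
#' @return covariance matrix Omega
#' @export
omegaDraw <- function(samples, iter) {
  p <- ncol(samples@mu)
  O <- matrix(0, p, p)
  O[lower.tri(O, diag = TRUE)] <- samples@omega[iter, ]
  O[upper.tri(O)] <- t(O)[upper.tri(O)]
  O
}
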