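# Configuration files, dataset and chain serialization. Configs are YAML
# with a fixed schema; chains are written both as delimited text (one file
# per parameter block, interoperable) and as a binary container (fast), with
# a JSON manifest recording seeds, a config hash and per-file checksums.

configDefaults <- function() {
  list(
    model = list(name = "circadian"),
    dataset = list(M = 40L, t0 = 0),
    inference = list(nIterations = 5000L, mode = "perturbed", delta = 0.1,
                     burnin = 0.2, thinning = 1L, etaKind = "conjugate_niw",
                     likelihood = "pf", shiftMove = TRUE,
                     saveIndividuals = FALSE),
    pf = list(nParticles = 50L, kind = "bootstrap", integrator = "langevin",
              dt = 0.1, rho = 0, essThreshold = 0.5, lookahead = 1,
              maxEvents = 1e7, nParticlesPerIndividual = NULL),
    proposal = list(kind = "RAM", targetAcceptance = 0.234, beta = 0.66,
                    sigma0 = 0.1),
    seed = 1L
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, fills in documented defaults so that every
#' setting is explicit in the resolved object, and rejects unknown keys and
#' cross-field inconsistencies (for instance a per-individual particle
#' count in unperturbed mode, where all individuals share one N).
#'
#' @param path YAML file
#' @return resolved configuration list (class "ssmemConfig")
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  resolveConfig(raw)
}

resolveConfig <- function(raw) {
  def <- configDefaults()
  bad <- setdiff(names(raw), names(def))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (sec in names(raw)) {
    if (is.list(def[[sec]])) {
      badk <- setdiff(names(raw[[sec]]), names(def[[sec]]))
      if (length(badk))
        stop("unknown keys in [", sec, "]: ", paste(badk, collapse = ", "))
    }
  }
  cfg <- modifyList(def, raw)
  # keep optional keys out of the resolved object unless set, so that
  # load -> save -> load is the identity
  cfg$pf <- cfg$pf[!vapply(cfg$pf, is.null, TRUE)]
  if (cfg$inference$mode == "unperturbed" &&
      !is.null(cfg$pf$nParticlesPerIndividual))
    stop("per-individual particle counts are only valid in perturbed mode")
  if (!cfg$model$name %in% c("circadian", "schlogl", "ou"))
    stop("unknown model name: ", cfg$model$name)
  structure(cfg, class = "ssmemConfig")
}

#' Write a resolved configuration
#'
#' @param cfg a resolved config from \code{\link{loadConfig}}
#' @param path output YAML file
#' @return path, invisibly
#' @export
saveConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Materialise package objects from a resolved configuration
#'
#' @param cfg a resolved config from \code{\link{loadConfig}}
#' @return list with the benchmark \code{model}, the \code{inference}
#'   config, the \code{pf} config and the observation \code{times}
#' @export
configToObjects <- function(cfg) {
  model <- switch(cfg$model$name,
    circadian = makeCircadianModel(),
    schlogl = makeSchloglModel(),
    ou = makeOUModel())
  pf <- pfConfig(nParticles = cfg$pf$nParticles, kind = cfg$pf$kind,
                 integrator = cfg$pf$integrator, dt = cfg$pf$dt,
                 rho = cfg$pf$rho, essThreshold = cfg$pf$essThreshold,
                 lookahead = cfg$pf$lookahead, maxEvents = cfg$pf$maxEvents)
  inf <- inferenceConfig(nIterations = cfg$inference$nIterations,
                         mode = cfg$inference$mode,
                         delta = cfg$inference$delta, pf = pf,
                         burnin = cfg$inference$burnin,
                         thinning = cfg$inference$thinning,
                         etaKind = cfg$inference$etaKind,
                         proposal = cfg$proposal,
                         likelihood = cfg$inference$likelihood,
                         shiftMove = cfg$inference$shiftMove,
                         saveIndividuals = cfg$inference$saveIndividuals)
  list(model = model, inference = inf, pf = pf,
       times = benchmarkTimes(cfg$model$name))
}

#' Write a multi-cell dataset (and its truth) as delimited text
#'
#' @param ds list from \code{\link{generateDataset}}
#' @param dir output directory (created)
#' @return paths of the observation and truth files
#' @export
writeDataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  obsPath <- file.path(dir, "observations.tsv")
  truthPath <- file.path(dir, "truth.tsv")
  utils::write.table(as.data.frame(ds$data), obsPath, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  tr <- ds$truth
  truth <- data.frame(cell = seq_len(nrow(tr$c)), tr$c)
  utils::write.table(truth, truthPath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  meta <- list(kappa = tr$kappa, xi = tr$xi, mu = tr$mu,
               Omega = as.numeric(tr$Omega))
  jsonlite::write_json(meta, file.path(dir, "truth_population.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(obsPath, truthPath))
}

#' Read a multi-cell dataset written by \code{\link{writeDataset}}
#'
#' @param dir dataset directory
#' @param t0 initial time
#' @return a \linkS4class{CellData}
#' @export
readCellData <- function(dir, t0 = 0) {
  df <- utils::read.table(file.path(dir, "observations.tsv"), header = TRUE,
                          sep = "\t")
  cells <- sort(unique(df$cell))
  ycols <- grep("^y", names(df), value = TRUE)
  cellData(
    times = lapply(cells, function(i) df$time[df$cell == i]),
    obs = lapply(cells, function(i)
      as.matrix(df[df$cell == i, ycols, drop = FALSE])),
    t0 = t0
  )
}

#' Save posterior chains
#'
#' Writes each parameter block as delimited text, the whole object as a
#' binary container, and a manifest with checksums so truncated files are
#' detected on load.
#'
#' @param samples a \linkS4class{PosteriorSamples}
#' @param dir output directory
#' @param config optional resolved config stored for provenance (hashed in
#'   the manifest)
#' @param seed seed recorded for provenance
#' @return the manifest, invisibly
#' @export
saveChains <- function(samples, dir, config = NULL, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  blocks <- list(mu = samples@mu, omega = samples@omega,
                 kappa = samples@kappa, xi = samples@xi)
  files <- character()
  for (nm in names(blocks)) {
    if (!ncol(blocks[[nm]])) next
    f <- file.path(dir, paste0("chain_", nm, ".tsv"))
    utils::write.table(blocks[[nm]], f, sep = "\t", row.names = FALSE,
                       col.names = TRUE, quote = FALSE)
    files <- c(files, f)
  }
  binPath <- file.path(dir, "chains.rds")
  slim <- samples
  slim@checkpoint <- list()
  saveRDS(slim, binPath)
  files <- c(files, binPath)
  manifest <- list(
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f)))),
    configHash = if (is.null(config)) NA else
      digestConfig(config),
    seed = seed,
    mode = samples@mode,
    nDraws = nrow(samples@mu),
    package = as.character(utils::packageVersion("ssmem"))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

digestConfig <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveConfig(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Load posterior chains saved by \code{\link{saveChains}}
#'
#' Verifies every checksum in the manifest before loading; a truncated or
#' modified file fails with an error naming the block.
#'
#' @param dir chain directory
#' @return a \linkS4class{PosteriorSamples}
#' @export
loadChains <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  for (k in seq_len(nrow(man$files))) {
    f <- file.path(dir, man$files$name[k])
    if (!file.exists(f)) stop("missing chain file: ", man$files$name[k])
    if (unname(tools::md5sum(f)) != man$files$md5[k])
      stop("checksum mismatch (truncated or modified): ", man$files$name[k])
  }
  readRDS(file.path(dir, "chains.rds"))
}

#' Write a trajectory as delimited text
#' @param traj a \linkS4class{Trajectory}
#' @param path output file
#' @return path, invisibly
#' @export
writeTrajectory <- function(traj, path) {
  utils::write.table(as.data.frame(traj), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
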