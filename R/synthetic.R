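#' Specify a synthetic community benchmark
#'
#' The generative model is a correlated lognormal-multinomial: each taxon
#' has a base log-abundance drawn from a Normal (so cross-taxon abundances
#' are lognormal and right-skewed: few abundant, many rare taxa); each
#' sample adds a latent Gaussian fluctuation whose cross-taxon correlation
#' embeds the planted modules (within a module, latent correlation `rho`
#' via a shared factor, with optional +/- sign patterns); groups add
#' per-taxon log shifts (composition turnover across e.g. successional
#' stages); counts are a multinomial draw of `depth` reads per sample.
#'
#' Planted-module taxa are placed in the abundant tail of the base
#' distribution (their expected counts must rise well above the multinomial
#' noise floor for the planted correlations to be observable at all) and do
#' not receive group shifts, so the planted blocks are group-invariant.
#'
#' @param nPerGroup samples per group (default 10).
#' @param nGroups number of groups / successional stages (default 3).
#' @param nTaxa number of taxa (default 2000).
#' @param baseLogMean,baseLogSd Normal parameters of base log-abundances
#'   (default 0 and 2; sd >= 1.5 keeps the rank-abundance curve strongly
#'   right-skewed).
#' @param sampleLogSd sd of the per-sample latent log fluctuation
#'   (default 1).
#' @param depth reads per sample (default 10065, a typical 16S library
#'   standardisation depth; use 8000 for ITS-like tables).
#' @param modules list of planted modules, each
#'   `list(taxa = <indices>, rho = <latent correlation>, sign = <+/-1
#'   vector or NULL>)`; `plantedModuleSet()` builds a standard layout.
#' @param groupEffectSd sd of per-group per-taxon log shifts (default 0.6).
#' @param envCoupling strength of the environmental coupling to the group
#'   gradient (default 1; 0 gives a null environment).
#' @param seed integer seed.
#' @return a validated [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nPerGroup = 10L, nGroups = 3L, nTaxa = 2000L,
                          baseLogMean = 0, baseLogSd = 2, sampleLogSd = 1,
                          depth = 10065L,
                          modules = plantedModuleSet(nTaxa),
                          groupEffectSd = 0.6, envCoupling = 1,
                          seed = 1L) {
  new("SyntheticSpec",
      nPerGroup = as.integer(nPerGroup), nGroups = as.integer(nGroups),
      nTaxa = as.integer(nTaxa), baseLogMean = baseLogMean,
      baseLogSd = baseLogSd, sampleLogSd = sampleLogSd,
      depth = as.integer(depth), modules = modules,
      groupEffectSd = groupEffectSd, envCoupling = envCoupling,
      seed = as.integer(seed))
}

#' Standard planted-module layout
#'
#' Four disjoint modules of `sizePer` taxa each at latent correlation
#' `rho`, the last one with a mixed +/- sign pattern so the networks carry
#' negative edges.
#'
#' @param nTaxa total taxa (modules use the first indices).
#' @param nModules number of modules.
#' @param sizePer taxa per module.
#' @param rho within-module latent correlation.
#' @return list of module descriptors for [syntheticSpec()].
#' @export
plantedModuleSet <- function(nTaxa, nModules = 4L, sizePer = 12L,
                             rho = 0.95) {
  stopifnot(nModules * sizePer <= nTaxa)
  lapply(seq_len(nModules), function(m) {
    idx <- ((m - 1L) * sizePer + 1L):(m * sizePer)
    sgn <- rep(1, sizePer)
    if (m == nModules) sgn[seq(2L, sizePer, by = 2L)] <- -1
    list(taxa = as.integer(idx), rho = rho, sign = sgn)
  })
}

#' Generate a synthetic ASV table with known ground truth
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with elements `table` (an [AsvExperiment-class] with a
#'   `stage` column in the sample metadata) and `truth` (a
#'   [SyntheticTruth-class] with the realized abundance classes, planted
#'   modules and environmental coefficients).
#' @examples
#' sim <- generateCommunity(syntheticSpec(nTaxa = 200, seed = 7))
#' sim$table
#' @export
generateCommunity <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  set.seed(spec@seed)
  nS <- spec@nPerGroup * spec@nGroups
  nT <- spec@nTaxa

  base <- stats::rnorm(nT, spec@baseLogMean, spec@baseLogSd)
  moduleOf <- rep(NA_integer_, nT)
  signOf <- rep(1, nT)
  for (m in seq_along(spec@modules)) {
    mod <- spec@modules[[m]]
    moduleOf[mod$taxa] <- m
    if (!is.null(mod$sign)) signOf[mod$taxa] <- mod$sign
    # plant modules high in the abundance ranking, clear of the count-noise
    # floor, so the planted correlations are observable (see vignette)
    base[mod$taxa] <- spec@baseLogMean +
      spec@baseLogSd * stats::runif(length(mod$taxa), 2.1, 2.5)
  }

  group <- rep(seq_len(spec@nGroups), each = spec@nPerGroup)
  shift <- matrix(stats::rnorm(spec@nGroups * nT, 0, spec@groupEffectSd),
                  spec@nGroups, nT)
  shift[, !is.na(moduleOf)] <- 0  # planted blocks are group-invariant

  z <- matrix(stats::rnorm(nS * nT), nS, nT)
  for (m in seq_along(spec@modules)) {
    mod <- spec@modules[[m]]
    f <- stats::rnorm(nS)
    z[, mod$taxa] <- sweep(
      sqrt(mod$rho) * matrix(f, nS, length(mod$taxa)) +
        sqrt(1 - mod$rho) * z[, mod$taxa, drop = FALSE],
      2L, signOf[mod$taxa], `*`)
  }

  loga <- matrix(base, nS, nT, byrow = TRUE) +
    shift[group, , drop = FALSE] + spec@sampleLogSd * z
  p <- exp(loga)
  p <- p / rowSums(p)
  counts <- t(apply(p, 1L, function(pr)
    stats::rmultinom(1L, spec@depth, pr)[, 1L]))
  dimnames(counts) <- list(sprintf("sample_%02d", seq_len(nS)),
                           sprintf("taxon_%04d", seq_len(nT)))

  phyla <- sprintf("Phylum%02d", 1 + (seq_len(nT) %% 12L))
  domain <- ifelse(seq_len(nT) %% 4L == 0L, "Fungi", "Bacteria")
  taxonomy <- paste(domain, phyla, "", "", "",
                    sprintf("Genus%04d", seq_len(nT)), sep = ";")
  metadata <- data.frame(stage = paste0("stage", group),
                         row.names = rownames(counts))
  tab <- AsvExperiment(counts, taxonomy = taxonomy, metadata = metadata,
                       samplesAsRows = TRUE)

  mra <- colMeans(counts / rowSums(counts))
  trueClass <- ifelse(mra > 0.001, "abundant",
                      ifelse(mra < 0.0001, "rare", "intermediate"))

  envVars <- c("plant_richness", "SOC", "TN", "NO3", "NH4", "TP", "EC",
               "pH", "SM", "CN", "CP", "NP")
  pattern <- rep(c(1, -1), length.out = length(envVars))
  coef <- c(stats::setNames(spec@envCoupling * pattern, envVars),
            noise_control = 0)

  truth <- new("SyntheticTruth", trueClass = unname(trueClass),
               modules = lapply(spec@modules, `[[`, "taxa"),
               moduleOf = moduleOf, signOf = signOf,
               groupShift = shift, envCoefficients = coef, spec = spec)
  list(table = tab, truth = truth)
}

#' Generate environmental covariates matching a synthetic community
#'
#' Each variable is a linear function of the group index (slope =
#' `envCoupling` times a fixed +/- pattern, recorded in the ground truth)
#' plus unit Normal noise; `noise_control` is a pure-noise variable for
#' negative controls. Deterministic given the spec's seed.
#'
#' @param spec the [SyntheticSpec-class] used for the community.
#' @param truth the matching [SyntheticTruth-class].
#' @return numeric matrix samples x variables (see [envMatrix()]).
#' @export
generateEnv <- function(spec, truth) {
  stopifnot(is(spec, "SyntheticSpec"), is(truth, "SyntheticTruth"))
  set.seed(spec@seed + 100003L)
  nS <- spec@nPerGroup * spec@nGroups
  group <- rep(seq_len(spec@nGroups), each = spec@nPerGroup)
  coef <- truth@envCoefficients
  env <- vapply(names(coef), function(v)
    coef[[v]] * group + stats::rnorm(nS), numeric(nS))
  rownames(env) <- sprintf("sample_%02d", seq_len(nS))
  env
}

#' Planted adjacency matrix of a synthetic ground truth
#'
#' @param truth a [SyntheticTruth-class].
#' @return symmetric logical matrix (taxa x taxa, zero diagonal) that is
#'   `TRUE` for every within-module taxon pair.
#' @export
plantedAdjacency <- function(truth) {
  stopifnot(is(truth, "SyntheticTruth"))
  nT <- truth@spec@nTaxa
  A <- matrix(FALSE, nT, nT,
              dimnames = list(sprintf("taxon_%04d", seq_len(nT)),
                              sprintf("taxon_%04d", seq_len(nT))))
  for (idx in truth@modules) {
    A[idx, idx] <- TRUE
  }
  diag(A) <- FALSE
  A
}
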