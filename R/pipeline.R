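#' Assemble and validate a pipeline run configuration
#'
#' Defaults mirror the canonical study design: rarefaction depth 10,065
#' (16S-scale), abundance cutoffs 0.1% / 0.01%, strict prevalence 50%,
#' fixed similarity cutoff 0.88 for cross-network comparison, Zi/Pi role
#' thresholds 2.5 / 0.62, 999 permutations, and a degree-preserving null
#' ensemble of 100 networks. With no input paths a synthetic community
#' ([syntheticSpec()]) drives the run.
#'
#' @param countsPath,countsFormat optional ASV table input (see
#'   [readAsvTable()]).
#' @param metadataPath optional sample metadata TSV with a `stage` column.
#' @param synthetic a [SyntheticSpec-class] used when no input paths are
#'   given.
#' @param rarefactionDepth reads per sample after rarefaction.
#' @param abundantCut,rareCut,prevalenceCut partition cutoffs.
#' @param cutoffMode `"fixed"` (use `similarityCutoff`) or `"rmt"` (scan).
#' @param similarityCutoff fixed similarity cutoff (default 0.88).
#' @param correlationMethod `"pearson"` or `"spearman"`.
#' @param logScale correlate log10 abundances after the fill (default
#'   TRUE; see [correlationMatrix()]).
#' @param fillValue pseudo-abundance fraction for [fillMissing()].
#' @param ziCut,piCut keystone role thresholds.
#' @param nPerm permutations for ANOSIM / Mantel.
#' @param nNull random-null ensemble size.
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @return validated config list (class `"RunConfig"`).
#' @export
runConfig <- function(countsPath = NULL, countsFormat = "tsv",
                      metadataPath = NULL,
                      synthetic = syntheticSpec(),
                      rarefactionDepth = 10065L,
                      abundantCut = 0.001, rareCut = 0.0001,
                      prevalenceCut = 0.5,
                      cutoffMode = c("fixed", "rmt"),
                      similarityCutoff = 0.88,
                      correlationMethod = "pearson",
                      logScale = TRUE,
                      fillValue = 1e-4,
                      ziCut = 2.5, piCut = 0.62,
                      nPerm = 999L, nNull = 100L, seed = 1L) {
  cutoffMode <- match.arg(cutoffMode)
  cfg <- list(countsPath = countsPath, countsFormat = countsFormat,
              metadataPath = metadataPath, synthetic = synthetic,
              rarefactionDepth = as.integer(rarefactionDepth),
              abundantCut = abundantCut, rareCut = rareCut,
              prevalenceCut = prevalenceCut, cutoffMode = cutoffMode,
              similarityCutoff = similarityCutoff,
              correlationMethod = correlationMethod,
              logScale = isTRUE(logScale),
              fillValue = fillValue, ziCut = ziCut, piCut = piCut,
              nPerm = as.integer(nPerm), nNull = as.integer(nNull),
              seed = as.integer(seed))
  class(cfg) <- "RunConfig"
  .validateConfig(cfg)
  cfg
}

.validateConfig <- function(cfg) {
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(cfg$rarefactionDepth > 0L, "rarefactionDepth must be positive")
  chk(0 < cfg$rareCut && cfg$rareCut < cfg$abundantCut &&
        cfg$abundantCut < 1, "need 0 < rareCut < abundantCut < 1")
  chk(cfg$prevalenceCut >= 0 && cfg$prevalenceCut < 1,
      "prevalenceCut must lie in [0, 1)")
  chk(cfg$similarityCutoff > 0 && cfg$similarityCutoff <= 1,
      "similarityCutoff must lie in (0, 1]")
  chk(cfg$correlationMethod %in% c("pearson", "spearman"),
      "unknown correlation method")
  chk(cfg$fillValue >= 0, "fillValue must be non-negative")
  chk(!cfg$logScale || cfg$fillValue > 0,
      "logScale requires a positive fillValue")
  chk(cfg$ziCut > 0 && cfg$piCut > 0 && cfg$piCut < 1,
      "role thresholds out of range")
  chk(cfg$nPerm >= 1L, "nPerm must be >= 1")
  chk(cfg$nNull >= 2L, "nNull must be >= 2")
  if (length(problems))
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  invisible(TRUE)
}

.stageFail <- function(stage, e) {
  stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
       call. = FALSE)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full abundant/rare network analysis pipeline
#'
#' Orchestrates: rarefaction, abundance-class partition, alpha/beta
#' diversity with group tests, per-stage x per-class co-occurrence
#' networks at the configured cutoff, topology summaries with
#' degree-preserving nulls, Zi-Pi keystone tables, and Mantel / partial
#' Mantel tests against the environment. Every report is written to
#' `outDir` as TSV and listed in `manifest.tsv` with its producing stage;
#' runs are deterministic given the config seed. Stage/class combinations
#' whose retained taxa yield no edge at the cutoff are recorded as empty
#' and skipped (expected for rare taxa at shallow depths) rather than
#' aborting the run.
#'
#' @param config a config from [runConfig()].
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the in-memory results (table, partition,
#'   networks, topologies, keystones, mantel results, manifest).
#' @export
runPipeline <- function(config, outDir = tempfile("micronet_run_")) {
  stopifnot(inherits(config, "RunConfig"))
  .validateConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(file, stage, params = "") {
    manifest[[length(manifest) + 1L]] <<-
      data.frame(file = file, stage = stage, parameters = params,
                 stringsAsFactors = FALSE)
  }
  logLines <- character()
  say <- function(...) logLines <<- c(logLines, paste0(...))

  ## -- input -------------------------------------------------------------
  truth <- NULL; env <- NULL
  tab <- tryCatch({
    if (!is.null(config$countsPath)) {
      md <- if (!is.null(config$metadataPath))
        readSampleMetadata(config$metadataPath) else NULL
      readAsvTable(config$countsPath, format = config$countsFormat,
                   metadata = md)
    } else {
      spec <- config$synthetic
      spec@seed <- config$seed
      sim <- generateCommunity(spec)
      truth <- sim$truth
      env <- generateEnv(spec, truth)
      sim$table
    }
  }, error = function(e) .stageFail("input", e))
  say("input: ", ncol(tab), " samples x ", nrow(tab), " taxa")

  ## -- rarefaction -------------------------------------------------------
  tab <- tryCatch(
    rarefyAsv(tab, config$rarefactionDepth, seed = config$seed + 1L),
    error = function(e) .stageFail("rarefaction", e))
  say("rarefaction: depth ", config$rarefactionDepth, ", ",
      ncol(tab), " samples retained")

  stages <- as.character(sampleData(tab)$stage)
  if (!length(stages) || anyNA(stages))
    .stageFail("input", simpleError("sample metadata needs a 'stage' column"))

  ## -- partition ---------------------------------------------------------
  part <- tryCatch({
    p <- classifyAbundance(tab, config$abundantCut, config$rareCut)
    prevalenceFilter(p, config$prevalenceCut)
  }, error = function(e) .stageFail("partition", e))
  counts <- table(factor(part@abundanceClass,
                         c("abundant", "intermediate", "rare")))
  say("partition: ", counts[["abundant"]], " abundant / ",
      counts[["rare"]], " rare / ", counts[["intermediate"]],
      " intermediate taxa; ", sum(part@retained),
      " retained at prevalence > ", config$prevalenceCut)
  note(.writeTsv(partitionTable(part), file.path(outDir, "partition.tsv")),
       "partition", sprintf("abundant>%g rare<%g prevalence>%g",
                            config$abundantCut, config$rareCut,
                            config$prevalenceCut))

  ## -- diversity ---------------------------------------------------------
  divRes <- tryCatch({
    ra <- relativeAbundance(tab)
    m <- asvCounts(tab)
    out <- list()
    for (cls in c("abundant", "rare")) {
      taxa <- part@taxonId[part@abundanceClass == cls]
      sub <- m[, taxa, drop = FALSE]
      keep <- rowSums(sub) > 0
      if (sum(keep) < 4L || length(taxa) < 2L) next
      alpha <- alphaDiversity(sub[keep, , drop = FALSE])
      alpha$class <- cls
      alpha$stage <- stages[keep]
      bc <- brayCurtis(sub[keep, , drop = FALSE])
      an <- anosimTest(bc, stages[keep], nPerm = config$nPerm,
                      seed = config$seed + 2L)
      ord <- pcoaOrdination(bc, nAxes = 2L)
      wil <- rbind(
        cbind(index = "chao1",
              groupCompare(alpha$chao1, alpha$stage)),
        cbind(index = "shannon",
              groupCompare(alpha$shannon, alpha$stage)))
      out[[cls]] <- list(alpha = alpha, bray = bc, anosim = an,
                         ordination = ord, wilcoxon = wil)
    }
    out
  }, error = function(e) .stageFail("diversity", e))
  if (length(divRes)) {
    alphaAll <- do.call(rbind, lapply(divRes, `[[`, "alpha"))
    note(.writeTsv(alphaAll, file.path(outDir, "diversity.tsv")),
         "diversity", "chao1+shannon per sample")
    anos <- do.call(rbind, lapply(names(divRes), function(cl)
      data.frame(class = cl, R = divRes[[cl]]$anosim$R,
                 p = divRes[[cl]]$anosim$p)))
    note(.writeTsv(anos, file.path(outDir, "anosim.tsv")), "diversity",
         sprintf("%d permutations", config$nPerm))
    wilAll <- do.call(rbind, lapply(names(divRes), function(cl)
      cbind(class = cl, divRes[[cl]]$wilcoxon)))
    note(.writeTsv(wilAll, file.path(outDir, "wilcoxon.tsv")),
         "diversity", "pairwise rank-sum")
    ords <- do.call(rbind, lapply(names(divRes), function(cl) {
      co <- divRes[[cl]]$ordination$coordinates
      data.frame(class = cl, sample = rownames(co), co,
                 row.names = NULL)
    }))
    note(.writeTsv(ords, file.path(outDir, "ordination.tsv")),
         "diversity", "PCoA on Bray-Curtis")
  }

  ## -- networks per stage x class ---------------------------------------
  nets <- list(); tops <- list(); keys <- list()
  m <- asvCounts(tab)
  for (st in unique(stages)) {
    sset <- rownames(m)[stages == st]
    stagePart <- tryCatch({
      p <- classifyAbundance(tab, config$abundantCut, config$rareCut)
      # prevalence within the stage's samples (stage-specific networks)
      p@prevalence <- unname(colMeans(m[sset, , drop = FALSE] > 0))
      prevalenceFilter(p, config$prevalenceCut)
    }, error = function(e) .stageFail("network", e))
    for (cls in c("abundant", "rare")) {
      id <- paste(st, cls, sep = "_")
      taxa <- retainedTaxaOfClass(stagePart, cls)
      if (length(taxa) < 2L) {
        say("network ", id, ": <2 retained taxa, skipped"); next
      }
      res <- tryCatch({
        ra <- relativeAbundance(m[sset, , drop = FALSE])[, taxa,
                                                         drop = FALSE]
        filled <- fillMissing(ra, fill = config$fillValue)
        sim <- suppressWarnings(
          correlationMatrix(filled, method = config$correlationMethod,
                            logScale = config$logScale))
        cutoff <- config$similarityCutoff
        if (config$cutoffMode == "rmt")
          cutoff <- chosenThreshold(rmtThresholdScan(sim))
        dom <- stats::setNames(taxonomyTable(tab)[taxa, "kingdom"], taxa)
        buildNetwork(sim, cutoff, partition = stagePart,
                     domainTags = dom)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        say("network ", id, ": empty at cutoff (",
            conditionMessage(res), ")")
        next
      }
      nets[[id]] <- res
      mods <- detectModules(res)
      nulls <- tryCatch(
        randomNull(res, nNets = config$nNull, seed = config$seed + 10L),
        error = function(e) NULL)
      tops[[id]] <- summarizeTopology(res, nulls = nulls,
                                      modules = mods, strict = FALSE)
      roles <- classifyRoles(ziPi(res, mods), config$ziCut, config$piCut)
      keys[[id]] <- keystoneTable(roles, taxonomyTable(tab))
      say("network ", id, ": ",
          topologyMetrics(tops[[id]])[["total_nodes"]], " nodes, ",
          topologyMetrics(tops[[id]])[["total_links"]], " links, ",
          sum(roles$keystone), " keystones")
      note(.writeTsv(edgeTable(res),
                     file.path(outDir, paste0("network_", id, ".tsv"))),
           "network", sprintf("cutoff %.2f", networkCutoff(res)))
    }
  }
  if (length(tops)) {
    topoDf <- .topologyReport(tops)
    note(.writeTsv(topoDf, file.path(outDir, "topology.tsv")),
         "topology", sprintf("null ensemble n=%d", config$nNull))
    keysDf <- do.call(rbind, lapply(names(keys), function(id) {
      k <- keys[[id]]
      if (!nrow(k)) return(NULL)
      cbind(network = id, k)
    }))
    if (is.null(keysDf))
      keysDf <- data.frame(network = character(), node = character())
    note(.writeTsv(keysDf, file.path(outDir, "keystone.tsv")),
         "keystone", sprintf("Zi>%g Pi>%g", config$ziCut, config$piCut))
  }

  ## -- drivers -----------------------------------------------------------
  if (!is.null(env)) {
    mantelDf <- tryCatch({
      rows <- list()
      vars <- colnames(env)
      for (cls in names(divRes)) {
        bc <- divRes[[cls]]$bray
        keepIds <- attr(bc, "Labels")
        e <- env[keepIds, , drop = FALSE]
        for (v in vars) {
          dv <- envDistance(e, v)
          others <- setdiff(vars, v)
          dc <- envDistance(e, others)
          pm <- partialMantelTest(bc, dv, dc, nPerm = config$nPerm,
                                  seed = config$seed + 3L)
          rows[[paste(cls, v)]] <- data.frame(
            class = cls, variable = v, r = pm$r, p = pm$p,
            n_permutations = pm$nPerm)
        }
      }
      do.call(rbind, rows)
    }, error = function(e) .stageFail("drivers", e))
    rownames(mantelDf) <- NULL
    note(.writeTsv(mantelDf, file.path(outDir, "mantel.tsv")),
         "drivers", sprintf("partial Mantel, %d permutations",
                            config$nPerm))
  }

  writeLines(logLines, file.path(outDir, "run.log"))
  manifestDf <- do.call(rbind, manifest)
  manifestDf$file <- basename(manifestDf$file)
  .writeTsv(manifestDf, file.path(outDir, "manifest.tsv"))

  invisible(list(table = tab, truth = truth, env = env,
                 partition = part, diversity = divRes, networks = nets,
                 topologies = tops, keystones = keys,
                 outDir = outDir, manifest = manifestDf,
                 log = logLines))
}

# wide report: one row per metric, one column per network, empirical block
# then the random-network block
.topologyReport <- function(tops) {
  metricNames <- names(topologyMetrics(tops[[1L]]))
  emp <- vapply(tops, function(t)
    topologyMetrics(t)[metricNames], numeric(length(metricNames)))
  emp <- matrix(emp, nrow = length(metricNames),
                dimnames = list(metricNames, names(tops)))
  rows <- data.frame(block = "empirical", metric = metricNames,
                     signif(emp, 4), check.names = FALSE,
                     row.names = NULL)
  nullMetrics <- c("avgCC", "GD", "HD", "transitivity", "modularity")
  nullRows <- lapply(nullMetrics, function(mn) {
    vals <- vapply(tops, function(t) {
      nd <- topologyNulls(t)
      i <- match(mn, nd$metric)
      if (is.na(i)) return(NA_character_)
      sprintf("%.3f +/- %.3f", nd$mean[i], nd$sd[i])
    }, character(1))
    c(block = "random", metric = mn, vals)
  })
  nullDf <- as.data.frame(do.call(rbind, nullRows),
                          stringsAsFactors = FALSE)
  colnames(nullDf) <- colnames(rows)
  rows[] <- lapply(rows, as.character)
  rbind(rows, nullDf)
}
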