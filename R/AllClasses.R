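#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
NULL

#' Container for an ASV count table with taxonomy and sample metadata
#'
#' `AsvExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment] with a single
#' integer `counts` assay holding amplicon sequence variant (ASV) counts.
#' Following the SummarizedExperiment convention, taxa are rows and samples
#' are columns; user-facing functions that exchange matrices with the caller
#' use the samples-by-taxa orientation common for community tables (see
#' [asvCounts()]). Per-taxon taxonomy ranks live in `rowData`, per-sample
#' metadata (e.g. the successional stage) in `colData`.
#'
#' @slot .. no additional slots beyond SummarizedExperiment.
#' @seealso [AsvExperiment()] for construction, [readAsvTable()] for file
#'   input, [rarefyAsv()] for depth standardisation.
#' @exportClass AsvExperiment
setClass("AsvExperiment", contains = "SummarizedExperiment")

setValidity("AsvExperiment", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  m <- SummarizedExperiment::assay(object, "counts")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("counts must carry taxon (row) and sample (column) names")
  if (anyDuplicated(rownames(m))) return("duplicate taxon ids")
  if (anyDuplicated(colnames(m))) return("duplicate sample ids")
  if (any(m < 0)) return("counts must be non-negative")
  if (any(m != round(m))) return("counts must be integral")
  TRUE
})

#' Abundance-class partition of the taxa of an ASV table
#'
#' Records, for every taxon, its mean relative abundance across the samples
#' used, its abundance class (`"abundant"`, `"rare"` or `"intermediate"`),
#' its prevalence (fraction of samples with a positive count) and whether it
#' is retained for network construction (class abundant or rare, prevalence
#' strictly above the prevalence cutoff).
#'
#' @slot taxonId character, taxon identifiers.
#' @slot meanRelAbund numeric, mean relative abundance as a fraction.
#' @slot abundanceClass character, one of abundant/rare/intermediate.
#' @slot prevalence numeric in \[0,1\].
#' @slot retained logical, passes class + prevalence filters.
#' @slot abundantCut,rareCut,prevalenceCut numeric, the cutoffs used.
#' @exportClass AbundancePartition
setClass("AbundancePartition",
  representation(
    taxonId = "character",
    meanRelAbund = "numeric",
    abundanceClass = "character",
    prevalence = "numeric",
    retained = "logical",
    abundantCut = "numeric",
    rareCut = "numeric",
    prevalenceCut = "numeric"
  )
)

setValidity("AbundancePartition", function(object) {
  n <- length(object@taxonId)
  if (length(object@meanRelAbund) != n || length(object@abundanceClass) != n ||
      length(object@prevalence) != n || length(object@retained) != n)
    return("slot lengths differ")
  if (!all(object@abundanceClass %in% c("abundant", "rare", "intermediate")))
    return("unknown abundance class label")
  ab <- object@abundanceClass == "abundant"
  ra <- object@abundanceClass == "rare"
  if (any(object@meanRelAbund[ab] <= object@abundantCut))
    return("abundant taxa must exceed abundantCut")
  if (any(object@meanRelAbund[ra] >= object@rareCut))
    return("rare taxa must fall below rareCut")
  TRUE
})

#' Signed taxon-taxon correlation matrix and its absolute-value similarity
#'
#' Stores the signed pairwise correlation matrix of (fill-adjusted) relative
#' abundances; the RMT machinery works on the entrywise absolute values,
#' available through [similarityValues()].
#'
#' @slot correlation numeric matrix, symmetric, unit diagonal, in \[-1,1\].
#' @slot method character, `"pearson"` or `"spearman"`.
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
  representation(correlation = "matrix", method = "character")
)

setValidity("SimilarityMatrix", function(object) {
  m <- object@correlation
  if (nrow(m) != ncol(m)) return("correlation matrix must be square")
  if (is.null(rownames(m))) return("taxon names required")
  if (max(abs(m - t(m))) > 1e-8) return("correlation matrix must be symmetric")
  if (max(abs(diag(m) - 1)) > 1e-8) return("diagonal must be 1")
  if (any(m < -1 - 1e-8) || any(m > 1 + 1e-8))
    return("correlations must lie in [-1, 1]")
  TRUE
})

#' Result of the RMT similarity-threshold scan
#'
#' One row per candidate threshold on the grid 0.30, 0.31, ..., 1.00 with
#' the size of the thresholded matrix, the chi-square distances of the
#' nearest-neighbour spacing distribution (NNSD) to the Poisson and to the
#' Gaussian-orthogonal-ensemble (GOE) forms, and whether the Poisson form
#' fits. The chosen threshold is the smallest grid value from which the
#' Poisson fit persists across all larger evaluable thresholds.
#'
#' @slot records data.frame with columns threshold, n_nodes, n_eigenvalues,
#'   chisq_poisson, chisq_goe, poisson_fits, evaluable.
#' @slot chosenThreshold numeric scalar.
#' @exportClass RmtScanResult
setClass("RmtScanResult",
  representation(records = "data.frame", chosenThreshold = "numeric")
)

#' Undirected signed co-occurrence network on taxa
#'
#' Wraps an [igraph::igraph] graph whose edges carry the signed
#' correlation (`correlation` edge attribute, with `sign` derived) and whose
#' vertices carry the taxon id (`name`), an optional `domain` tag
#' (bacteria/fungi) and the abundance class. Isolated taxa are dropped at
#' construction, so every node has degree at least one, and every edge
#' satisfies |correlation| >= cutoff.
#'
#' @slot graph an igraph object.
#' @slot cutoff numeric, the similarity cutoff that produced the network.
#' @exportClass CoNetwork
setClass("CoNetwork", representation(graph = "ANY", cutoff = "numeric"))

setValidity("CoNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph slot must be an igraph object")
  if (igraph::is_directed(g)) return("network must be undirected")
  if (any(igraph::which_loop(g))) return("self-loops are not allowed")
  if (igraph::vcount(g) > 0 && min(igraph::degree(g)) < 1)
    return("isolated nodes must be dropped")
  r <- igraph::E(g)$correlation
  if (!is.null(r) && length(r) && any(abs(r) < object@cutoff - 1e-12))
    return("edge |correlation| below cutoff")
  TRUE
})

#' Module partition of a co-occurrence network
#'
#' @slot membership named integer vector, node -> module id.
#' @slot Q numeric, Newman modularity of the partition.
#' @exportClass ModulePartition
setClass("ModulePartition",
  representation(membership = "integer", Q = "numeric")
)

#' Full topology summary of one network (one report-table column)
#'
#' Holds every empirical topology metric plus the mean and standard
#' deviation of the metrics that are compared against a degree-preserving
#' random-network ensemble.
#'
#' @slot metrics named numeric vector: total_nodes, total_links, n_negative,
#'   n_positive, pct_negative, pct_positive, powerlaw_r2, avgK, avgCC, GD,
#'   HD, CD, CB, density, transitivity, connectedness, n_modules,
#'   modularity.
#' @slot nulls data.frame with columns metric, mean, sd for
#'   avgCC, GD, HD, transitivity, modularity (empty until [randomNull()]
#'   results are folded in).
#' @exportClass TopologySummary
setClass("TopologySummary",
  representation(metrics = "numeric", nulls = "data.frame")
)

setValidity("TopologySummary", function(object) {
  m <- object@metrics
  need <- c("total_nodes", "total_links", "n_negative", "n_positive",
            "pct_negative", "pct_positive", "avgK", "density")
  if (!all(need %in% names(m))) return("missing required metric fields")
  if (m[["n_negative"]] + m[["n_positive"]] != m[["total_links"]])
    return("edge sign counts must sum to total links")
  if (m[["total_links"]] > 0 &&
      abs(m[["pct_negative"]] + m[["pct_positive"]] - 100) > 0.011)
    return("sign percentages must sum to 100")
  if (m[["density"]] < 0 || m[["density"]] > 1)
    return("density must lie in [0, 1]")
  TRUE
})

#' Specification of a synthetic community benchmark
#'
#' Describes a ground-truthed synthetic dataset: a lognormal rank-abundance
#' backbone (few abundant, many rare taxa), planted blocks of correlated
#' taxa that a co-occurrence network should recover as modules,
#' group-dependent composition shifts across (successional) groups, and
#' environmental covariates coupled to the group structure.
#'
#' @slot nPerGroup,nGroups,nTaxa integer design sizes.
#' @slot baseLogMean,baseLogSd numeric, lognormal parameters of the
#'   cross-taxon base abundance distribution (natural log scale).
#' @slot sampleLogSd numeric, sd of the per-sample latent log fluctuation.
#' @slot depth integer, sequencing depth per sample.
#' @slot modules list of lists with fields `taxa` (integer indices), `rho`
#'   (within-module latent correlation) and `sign` (+1/-1 pattern or NULL).
#' @slot groupEffectSd numeric, sd of per-group log composition shifts.
#' @slot envCoupling numeric, strength of the env-to-group coupling.
#' @slot seed integer.
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(
    nPerGroup = "integer", nGroups = "integer", nTaxa = "integer",
    baseLogMean = "numeric", baseLogSd = "numeric", sampleLogSd = "numeric",
    depth = "integer", modules = "list", groupEffectSd = "numeric",
    envCoupling = "numeric", seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  if (object@depth <= 0L) return("depth must be positive")
  if (object@nPerGroup < 1L || object@nGroups < 1L || object@nTaxa < 2L)
    return("design sizes out of range")
  idx <- unlist(lapply(object@modules, `[[`, "taxa"))
  if (length(idx)) {
    if (anyDuplicated(idx)) return("planted modules must be disjoint")
    if (any(idx < 1L) || any(idx > object@nTaxa))
      return("module taxon index out of range")
  }
  rho <- vapply(object@modules, `[[`, numeric(1), "rho")
  if (length(rho) && (any(rho <= 0) || any(rho >= 1)))
    return("module rho must lie in (0, 1)")
  TRUE
})

#' Ground truth of a synthetic community
#'
#' @slot trueClass character, per-taxon abundance class implied by the
#'   realized mean relative abundances (the same statistic the classifier
#'   uses, so recovery is exact by construction).
#' @slot modules list of integer index vectors, the planted modules.
#' @slot moduleOf integer, taxon -> planted module id (NA outside modules).
#' @slot signOf numeric, the +1/-1 latent sign of each module member.
#' @slot groupShift numeric matrix (groups x taxa) of log-scale shifts.
#' @slot envCoefficients numeric, per-variable coupling to the group index.
#' @slot spec the generating SyntheticSpec.
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(
    trueClass = "character", modules = "list", moduleOf = "integer",
    signOf = "numeric", groupShift = "matrix", envCoefficients = "numeric",
    spec = "SyntheticSpec"
  )
)
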