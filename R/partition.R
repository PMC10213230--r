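#' Relative abundances of an ASV table
#'
#' @param x an [AsvExperiment-class] or a samples-by-taxa count matrix.
#' @param ... unused.
#' @return samples-by-taxa matrix of fractions; every row sums to 1.
#' @examples
#' ae <- AsvExperiment(matrix(c(1, 1, 2), 1, 3,
#'   dimnames = list("s1", c("a", "b", "c"))))
#' relativeAbundance(ae)
#' @rdname relativeAbundance
#' @export
setMethod("relativeAbundance", "AsvExperiment", function(x, ...)
  relativeAbundance(asvCounts(x, samplesAsRows = TRUE)))

#' @rdname relativeAbundance
#' @export
setMethod("relativeAbundance", "matrix", function(x, ...) {
  tot <- rowSums(x)
  bad <- which(tot <= 0)
  if (length(bad))
    stop("all-zero sample(s): ",
         paste(rownames(x)[bad] %||% bad, collapse = ", "))
  x / tot
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify taxa into abundant / rare / intermediate classes
#'
#' Classes follow the mean relative abundance across the samples in scope:
#' abundant above `abundantCut` (default 0.001, i.e. 0.1%), rare below
#' `rareCut` (default 0.0001, i.e. 0.01%); taxa in between are
#' intermediate and belong to neither network.
#'
#' @param x an [AsvExperiment-class].
#' @param abundantCut,rareCut fractions with 0 < rareCut < abundantCut < 1.
#' @param samples optional character vector restricting the scope (e.g. the
#'   samples of one successional stage); default: all samples.
#' @return an [AbundancePartition-class]; prevalence is computed over the
#'   same sample scope, the `retained` flag is all `FALSE` until
#'   [prevalenceFilter()] is applied.
#' @export
classifyAbundance <- function(x, abundantCut = 0.001, rareCut = 0.0001,
                              samples = NULL) {
  stopifnot(is(x, "AsvExperiment"))
  if (!(0 < rareCut && rareCut < abundantCut && abundantCut < 1))
    stop("need 0 < rareCut < abundantCut < 1")
  m <- asvCounts(x, samplesAsRows = TRUE)
  if (!is.null(samples)) {
    miss <- setdiff(samples, rownames(m))
    if (length(miss)) stop("unknown samples: ", paste(miss, collapse = ", "))
    m <- m[samples, , drop = FALSE]
  }
  ra <- relativeAbundance(m)
  mra <- colMeans(ra)
  cls <- ifelse(mra > abundantCut, "abundant",
                ifelse(mra < rareCut, "rare", "intermediate"))
  prev <- colMeans(m > 0)
  new("AbundancePartition", taxonId = colnames(m),
      meanRelAbund = unname(mra), abundanceClass = unname(cls),
      prevalence = unname(prev), retained = rep(FALSE, ncol(m)),
      abundantCut = abundantCut, rareCut = rareCut,
      prevalenceCut = NA_real_)
}

#' Apply the prevalence filter for network construction
#'
#' A taxon is retained for a network when its abundance class matches
#' `classes` and it occurs (count > 0) in strictly more than `minFrac` of
#' the samples in scope — "more than 50% of samples" is read as a strict
#' inequality, so presence in exactly half the samples does not qualify.
#'
#' @param partition an [AbundancePartition-class].
#' @param minFrac prevalence cutoff (default 0.5).
#' @param classes abundance classes eligible for retention (default
#'   abundant and rare; intermediates never enter a network).
#' @return the partition with its `retained` flag set.
#' @export
prevalenceFilter <- function(partition, minFrac = 0.5,
                             classes = c("abundant", "rare")) {
  stopifnot(is(partition, "AbundancePartition"))
  partition@retained <- partition@abundanceClass %in% classes &
    partition@prevalence > minFrac
  partition@prevalenceCut <- minFrac
  validObject(partition)
  partition
}

#' Tabular view of an abundance partition
#' @param x an [AbundancePartition-class].
#' @return data.frame with columns taxon_id, mean_rel_abund, class,
#'   prevalence, retained.
#' @rdname partitionTable
#' @export
setMethod("partitionTable", "AbundancePartition", function(x)
  data.frame(taxon_id = x@taxonId, mean_rel_abund = x@meanRelAbund,
             class = x@abundanceClass, prevalence = x@prevalence,
             retained = x@retained, stringsAsFactors = FALSE))

#' Taxa retained for a network
#' @param x an [AbundancePartition-class].
#' @param class optional single class (`"abundant"` or `"rare"`) to
#'   restrict to.
#' @return character vector of taxon ids.
#' @rdname retainedTaxa
#' @export
setMethod("retainedTaxa", "AbundancePartition", function(x) x@taxonId[x@retained])

#' @rdname retainedTaxa
#' @export
retainedTaxaOfClass <- function(x, class) {
  stopifnot(is(x, "AbundancePartition"),
            class %in% c("abundant", "rare", "intermediate"))
  x@taxonId[x@retained & x@abundanceClass == class]
}

#' Abundance class labels
#' @param x an [AbundancePartition-class].
#' @return named character vector taxon -> class.
#' @export
abundanceClass <- function(x) {
  stopifnot(is(x, "AbundancePartition"))
  stats::setNames(x@abundanceClass, x@taxonId)
}

setMethod("show", "AbundancePartition", function(object) {
  tab <- table(factor(object@abundanceClass,
                      c("abundant", "intermediate", "rare")))
  cat("AbundancePartition:", length(object@taxonId), "taxa\n")
  cat("  abundant:", tab[["abundant"]], " intermediate:",
      tab[["intermediate"]], " rare:", tab[["rare"]], "\n")
  cat("  retained for networks:", sum(object@retained), "\n")
})
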