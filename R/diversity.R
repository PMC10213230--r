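#' Chao1 richness estimator
#'
#' Bias-corrected form `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` where `F1` and
#' `F2` are the numbers of singleton and doubleton taxa; never below the
#' observed richness.
#'
#' @param counts non-negative integer vector of one sample's taxon counts.
#' @return numeric estimate.
#' @examples
#' chao1(c(1, 1, 2, 3, 5))  # 5 + 2*1/(2*2) = 5.5
#' @export
chao1 <- function(counts) {
  counts <- .checkCountVector(counts)
  sObs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  sObs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon diversity index
#'
#' `-sum p_i log p_i` over taxa with positive counts, in natural-log units
#' by default.
#'
#' @param counts non-negative integer vector.
#' @param base logarithm base (default `exp(1)`; use 2 for bits).
#' @return numeric index.
#' @examples
#' shannonIndex(c(1, 1, 2))  # 1.0397 nats
#' @export
shannonIndex <- function(counts, base = exp(1)) {
  counts <- .checkCountVector(counts)
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log(p, base = base))
}

.checkCountVector <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (all(counts == 0)) stop("all-zero count vector")
  counts
}

#' Per-sample alpha-diversity report
#'
#' @param x an [AsvExperiment-class] or samples-by-taxa count matrix.
#' @return data.frame: sample, chao1, shannon.
#' @export
alphaDiversity <- function(x) {
  m <- if (is(x, "AsvExperiment")) asvCounts(x) else as.matrix(x)
  data.frame(sample = rownames(m),
             chao1 = apply(m, 1, chao1),
             shannon = apply(m, 1, shannonIndex),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(a, b) = sum |a_i - b_i| / sum (a_i + b_i)`, computed with
#' [vegan::vegdist()]. Values lie in \[0, 1\] for non-negative input.
#'
#' @param x an [AsvExperiment-class], count matrix or relative-abundance
#'   matrix (samples as rows).
#' @param relative logical, convert counts to relative abundances first
#'   (default TRUE).
#' @return a `dist` object with sample labels.
#' @export
brayCurtis <- function(x, relative = TRUE) {
  m <- if (is(x, "AsvExperiment")) asvCounts(x) else as.matrix(x)
  if (nrow(m) < 2L) stop("need at least 2 samples")
  if (any(rowSums(m) <= 0)) stop("all-zero sample(s) present")
  if (relative) m <- relativeAbundance(m)
  vegan::vegdist(m, method = "bray")
}

#' Principal coordinate analysis (PCoA)
#'
#' Classical metric scaling: Gower double-centering of -D^2/2 followed by
#' eigendecomposition. Coordinates are returned for positive eigenvalues
#' only; negative eigenvalues (possible because Bray-Curtis is non-metric)
#' are reported untouched, without Lingoes/Cailliez correction. The
#' proportion explained is relative to the sum of positive eigenvalues.
#'
#' @param d a `dist` object or square symmetric distance matrix.
#' @param nAxes number of axes to return (clipped, with a warning, to the
#'   number of positive eigenvalues).
#' @return list with `coordinates` (samples x axes), `eigenvalues` (all,
#'   decreasing) and `proportion` (per returned axis).
#' @export
pcoaOrdination <- function(d, nAxes = 2L) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (n < 2L) stop("need at least 2 samples")
  sc <- suppressWarnings(stats::cmdscale(d, k = n - 1L, eig = TRUE))
  ev <- sc$eig
  pos <- min(sum(ev > sqrt(.Machine$double.eps) * max(abs(ev))),
             ncol(sc$points))
  if (nAxes > pos) {
    warning("only ", pos, " positive eigenvalue(s); clipping axes")
    nAxes <- pos
  }
  coords <- sc$points[, seq_len(nAxes), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(nAxes))
  list(coordinates = coords,
       eigenvalues = ev,
       proportion = ev[seq_len(nAxes)] / sum(ev[ev > 0]))
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of group separation on a distance matrix,
#' via [vegan::anosim()]: `R = (rB - rW) / (M/2)` with `M = n(n-1)/2`,
#' midranks for ties, and the plus-one permutation p-value estimator (so
#' `p >= 1/(nPerm+1)`).
#'
#' @param d `dist` object or square distance matrix.
#' @param groups group labels, one per sample; every group needs >= 2
#'   samples.
#' @param nPerm number of permutations (default 999).
#' @param seed integer seed.
#' @return list with `R`, `p`, `nPerm`.
#' @export
anosimTest <- function(d, groups, nPerm = 999L, seed = 1L) {
  d <- stats::as.dist(d)
  groups <- as.factor(groups)
  if (length(groups) != attr(d, "Size"))
    stop("groups length must match the distance matrix")
  if (nlevels(droplevels(groups)) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs >= 2 samples")
  set.seed(seed)
  a <- vegan::anosim(d, groups, permutations = nPerm)
  list(R = unname(a$statistic), p = a$signif, nPerm = nPerm)
}

#' Pairwise rank-sum comparison of a diversity index between groups
#'
#' Two-sided Wilcoxon rank-sum test for every group pair, exact for small
#' tie-free samples and normal-approximated otherwise (the
#' [stats::wilcox.test()] policy). Identical constant values in both
#' groups give p = 1 with a warning.
#'
#' @param values numeric per-sample index values.
#' @param groups group labels; every group needs >= 3 samples.
#' @return data.frame: group1, group2, w_statistic, p_value.
#' @export
groupCompare <- function(values, groups) {
  groups <- as.factor(groups)
  if (length(values) != length(groups))
    stop("values and groups lengths differ")
  if (any(table(groups) < 3L)) stop("every group needs >= 3 samples")
  lev <- levels(droplevels(groups))
  pairs <- utils::combn(lev, 2L)
  res <- apply(pairs, 2L, function(pr) {
    a <- values[groups == pr[1L]]
    b <- values[groups == pr[2L]]
    if (length(unique(c(a, b))) == 1L) {
      warning("constant values in groups ", pr[1L], " and ", pr[2L])
      return(c(w = NA_real_, p = 1))
    }
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL))
    c(w = unname(wt$statistic), p = wt$p.value)
  })
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
             w_statistic = res["w", ], p_value = res["p", ],
             row.names = NULL, stringsAsFactors = FALSE)
}
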