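#' Fill structural zeros before correlation
#'
#' Zero entries of taxa that are present in more than half of the samples
#' are replaced by a small pseudo-abundance (0.01 on the percentage scale,
#' i.e. `1e-4` as a fraction by default), so that occasional dropouts of
#' otherwise well-observed taxa do not distort rank or product-moment
#' correlations. Taxa that are mostly absent are left untouched.
#'
#' @param relabund samples-by-taxa matrix of relative-abundance fractions.
#' @param fill pseudo-abundance as a fraction (default `1e-4` = 0.01%).
#' @param majorityRule logical; fill only taxa nonzero in > 50% of samples
#'   (default TRUE).
#' @return the matrix with zeros filled.
#' @export
fillMissing <- function(relabund, fill = 1e-4, majorityRule = TRUE) {
  m <- as.matrix(relabund)
  if (fill == 0) return(m)
  eligible <- if (majorityRule) colMeans(m > 0) > 0.5 else
    rep(TRUE, ncol(m))
  for (j in which(eligible)) {
    z <- m[, j] == 0
    if (any(z)) m[z, j] <- fill
  }
  m
}

#' Taxon-taxon correlation and similarity matrix
#'
#' Pairwise Pearson (default) or Spearman correlations between taxa across
#' samples; the similarity matrix used by the RMT scan is the entrywise
#' absolute value. With `logScale = TRUE` abundances are log10-transformed
#' first — this is what the pseudo-abundance fill of [fillMissing()]
#' exists for, and it both stabilises product-moment correlations of
#' heavy-tailed abundance data and lets strong negative associations reach
#' the similarity cutoff (on the raw abundance scale the Pearson
#' correlation of lognormal-like taxa is bounded well above -1). Constant
#' taxa are removed with a warning (their correlation is undefined).
#'
#' @param mat samples-by-taxa numeric matrix (fill-adjusted relative
#'   abundances).
#' @param method `"pearson"` or `"spearman"`.
#' @param logScale logical; log10-transform the (strictly positive) matrix
#'   before correlating (default FALSE).
#' @return a [SimilarityMatrix-class].
#' @export
correlationMatrix <- function(mat, method = c("pearson", "spearman"),
                              logScale = FALSE) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  if (logScale) {
    if (any(mat <= 0))
      stop("logScale requires strictly positive abundances; ",
           "apply fillMissing() first")
    mat <- log10(mat)
  }
  if (nrow(mat) < 4L) stop("need at least 4 samples for correlations")
  sds <- apply(mat, 2L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant taxa removed")
    mat <- mat[, sds > 0, drop = FALSE]
  }
  if (ncol(mat) < 2L) stop("fewer than 2 non-constant taxa")
  r <- stats::cor(mat, method = method)
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  new("SimilarityMatrix", correlation = r, method = method)
}

#' @param x a [SimilarityMatrix-class].
#' @return `similarityValues`: absolute-value similarity matrix in
#'   \[0, 1\].
#' @rdname similarityValues
#' @export
setMethod("similarityValues", "SimilarityMatrix", function(x)
  abs(x@correlation))

#' @param x a [SimilarityMatrix-class].
#' @return `correlationValues`: the signed correlation matrix.
#' @rdname correlationValues
#' @export
setMethod("correlationValues", "SimilarityMatrix", function(x)
  x@correlation)

setMethod("show", "SimilarityMatrix", function(object) {
  cat("SimilarityMatrix:", nrow(object@correlation), "taxa,",
      object@method, "correlations\n")
})

#' Build a signed co-occurrence network at a similarity cutoff
#'
#' Nodes are taxa, and an undirected edge joins taxa i and j whenever
#' |correlation(i, j)| >= cutoff. Edges keep the signed correlation;
#' isolated taxa are dropped. Abundance class and domain (bacteria/fungi)
#' tags are attached to the nodes when available.
#'
#' @param sim a [SimilarityMatrix-class].
#' @param cutoff similarity cutoff in (0, 1\]; 0.88 is a typical RMT-chosen
#'   value used for cross-network comparisons.
#' @param partition optional [AbundancePartition-class] supplying abundance
#'   classes.
#' @param domainTags optional named character vector taxon -> domain.
#' @return a [CoNetwork-class]. Errors when no edge reaches the cutoff.
#' @export
buildNetwork <- function(sim, cutoff, partition = NULL,
                         domainTags = NULL) {
  stopifnot(is(sim, "SimilarityMatrix"))
  if (!(cutoff >= 0 && cutoff <= 1)) stop("cutoff must lie in [0, 1]")
  r <- correlationValues(sim)
  A <- abs(r) >= cutoff
  diag(A) <- FALSE
  if (!any(A))
    stop("no edge at cutoff ", cutoff,
         "; lower the cutoff or provide more correlated taxa")
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           diag = FALSE)
  el <- igraph::as_edgelist(g, names = TRUE)
  rv <- r[cbind(el[, 1L], el[, 2L])]
  g <- igraph::set_edge_attr(g, "correlation", value = rv)
  g <- igraph::set_edge_attr(g, "sign",
                             value = ifelse(rv < 0, "-", "+"))
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  nm <- igraph::V(g)$name
  cls <- rep(NA_character_, length(nm))
  if (!is.null(partition)) {
    cl <- abundanceClass(partition)
    cls <- unname(cl[nm])
  }
  g <- igraph::set_vertex_attr(g, "abundanceClass", value = cls)
  dom <- rep(NA_character_, length(nm))
  if (!is.null(domainTags)) dom <- unname(domainTags[nm])
  g <- igraph::set_vertex_attr(g, "domain", value = dom)
  new("CoNetwork", graph = g, cutoff = cutoff)
}

#' @param x a [CoNetwork-class].
#' @return `networkGraph`: the underlying igraph object.
#' @rdname networkGraph
#' @export
setMethod("networkGraph", "CoNetwork", function(x) x@graph)

#' @param x a [CoNetwork-class].
#' @return `networkCutoff`: the similarity cutoff used.
#' @rdname networkCutoff
#' @export
setMethod("networkCutoff", "CoNetwork", function(x) x@cutoff)

#' @param x a [CoNetwork-class].
#' @return `edgeTable`: data.frame source, target, correlation, sign.
#' @rdname edgeTable
#' @export
setMethod("edgeTable", "CoNetwork", function(x) {
  g <- x@graph
  el <- igraph::as_edgelist(g, names = TRUE)
  data.frame(source = el[, 1L], target = el[, 2L],
             correlation = igraph::E(g)$correlation,
             sign = igraph::E(g)$sign, stringsAsFactors = FALSE)
})

#' @param x a [CoNetwork-class].
#' @return `nodeTable`: data.frame node, degree, domain, abundance class.
#' @rdname nodeTable
#' @export
setMethod("nodeTable", "CoNetwork", function(x) {
  g <- x@graph
  data.frame(node = igraph::V(g)$name,
             degree = unname(igraph::degree(g)),
             domain = igraph::V(g)$domain,
             abundance_class = igraph::V(g)$abundanceClass,
             stringsAsFactors = FALSE)
})

setMethod("show", "CoNetwork", function(object) {
  g <- object@graph
  sgn <- igraph::E(g)$sign
  cat("CoNetwork: ", igraph::vcount(g), " nodes, ", igraph::ecount(g),
      " edges (", sum(sgn == "-"), " negative) at cutoff ",
      object@cutoff, "\n", sep = "")
})
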