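.netGraph <- function(net) {
  if (is(net, "CoNetwork")) net@graph
  else if (igraph::is_igraph(net)) net
  else stop("expected a CoNetwork or igraph object")
}

.nonempty <- function(g) {
  if (igraph::vcount(g) == 0L) stop("empty network")
  g
}

#' Average degree of a network
#'
#' `avgK = 2 L / N` for N nodes and L links.
#' @param net a [CoNetwork-class] (or igraph graph).
#' @return numeric.
#' @export
avgDegree <- function(net) {
  g <- .nonempty(.netGraph(net))
  2 * igraph::ecount(g) / igraph::vcount(g)
}

#' Density of a network
#'
#' `D = 2 L / (N (N - 1))`, the fraction of realized node pairs.
#' @param net a [CoNetwork-class] (or igraph graph).
#' @return numeric in \[0, 1\].
#' @export
networkDensity <- function(net) {
  g <- .netGraph(net)
  n <- igraph::vcount(g)
  if (n < 2L) stop("density needs at least 2 nodes")
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' Edge sign counts and percentages
#'
#' @param net a [CoNetwork-class] with `sign` edge attributes.
#' @return list: n_negative, n_positive, pct_negative, pct_positive
#'   (percentages of total links, rounded to 2 decimals).
#' @export
signCounts <- function(net) {
  g <- .nonempty(.netGraph(net))
  sgn <- igraph::E(g)$sign
  if (is.null(sgn)) stop("network carries no edge signs")
  L <- length(sgn)
  nNeg <- sum(sgn == "-")
  list(n_negative = nNeg, n_positive = L - nNeg,
       pct_negative = round(100 * nNeg / L, 2),
       pct_positive = round(100 * (L - nNeg) / L, 2))
}

#' Clustering coefficients
#'
#' `avgCC` is the mean local clustering coefficient with nodes of degree
#' < 2 contributing 0 (set `dropLowDegree = TRUE` to exclude them
#' instead); `transitivity` is the global ratio 3 x triangles / connected
#' triples.
#'
#' @param net a [CoNetwork-class] (or igraph graph).
#' @param dropLowDegree logical, exclude degree-<2 nodes from the average.
#' @return list: avgCC, transitivity.
#' @export
clusteringStats <- function(net, dropLowDegree = FALSE) {
  g <- .nonempty(.netGraph(net))
  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  if (dropLowDegree) loc <- loc[igraph::degree(g) >= 2]
  glob <- igraph::transitivity(g, type = "global")
  list(avgCC = if (length(loc)) mean(loc) else 0,
       transitivity = if (is.nan(glob)) 0 else glob)
}

#' Geodesic distance summaries
#'
#' `GD` is the mean shortest-path length over connected node pairs only
#' (disconnected pairs are excluded, not imputed); `HD` is the harmonic
#' mean over all pairs, with disconnected pairs contributing zero
#' reciprocal distance: `HD = P / sum(1/d_ij)` with `P = N(N-1)/2`.
#'
#' @param net a [CoNetwork-class] (or igraph graph).
#' @return list: GD, HD.
#' @export
geodesicStats <- function(net) {
  g <- .nonempty(.netGraph(net))
  n <- igraph::vcount(g)
  if (n < 2L) return(list(GD = NA_real_, HD = NA_real_))
  d <- igraph::distances(g)
  ut <- d[upper.tri(d)]
  con <- ut[is.finite(ut)]
  P <- n * (n - 1) / 2
  list(GD = if (length(con)) mean(con) else NA_real_,
       HD = P / sum(1 / con))
}

#' Degree and betweenness centralization
#'
#' `CD = sum(k_max - k_i) / ((N - 1)(N - 2))`; `CB` uses betweenness
#' normalized by `(N - 1)(N - 2)/2` and is scaled by the star-graph
#' maximum, `CB = sum(b_max - b_i) / (N - 1)`. Both are 1 for a star and
#' 0 for any regular, vertex-transitive graph such as a cycle.
#'
#' @param net a [CoNetwork-class] (or igraph graph).
#' @return list: CD, CB.
#' @export
centralizationStats <- function(net) {
  g <- .nonempty(.netGraph(net))
  n <- igraph::vcount(g)
  if (n < 3L) stop("centralization needs at least 3 nodes")
  k <- igraph::degree(g)
  CD <- sum(max(k) - k) / ((n - 1) * (n - 2))
  b <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  CB <- sum(max(b) - b) / (n - 1)
  list(CD = CD, CB = CB)
}

#' Krackhardt connectedness
#'
#' Fraction of node pairs joined by some path:
#' `sum_c n_c (n_c - 1) / (N (N - 1))` over components c.
#'
#' @param net a [CoNetwork-class] (or igraph graph).
#' @return numeric in \[0, 1\].
#' @export
connectednessKrackhardt <- function(net) {
  g <- .nonempty(.netGraph(net))
  n <- igraph::vcount(g)
  if (n < 2L) return(0)
  cs <- igraph::components(g)$csize
  sum(cs * (cs - 1)) / (n * (n - 1))
}

#' R-squared of the power-law degree-distribution fit
#'
#' Ordinary least squares of `log(count of nodes with degree k)` on
#' `log(k)` over the observed positive degrees (log-log binned-count fit;
#' not a maximum-likelihood exponent estimate).
#'
#' @param net a [CoNetwork-class] (or igraph graph).
#' @return R-squared in \[0, 1\]. Errors with fewer than 3 distinct
#'   degrees.
#' @export
powerlawR2 <- function(net) {
  g <- .nonempty(.netGraph(net))
  k <- igraph::degree(g)
  tab <- table(k[k >= 1])
  if (length(tab) < 3L)
    stop("power-law fit needs at least 3 distinct positive degrees")
  x <- log(as.numeric(names(tab)))
  y <- log(as.numeric(tab))
  summary(stats::lm(y ~ x))$r.squared
}

#' Fast-greedy module detection
#'
#' Greedy agglomerative modularity maximization
#' ([igraph::cluster_fast_greedy()]) on the unsigned, unweighted graph;
#' `Q = sum_s (l_s/L - (d_s / 2L)^2)`. The algorithm is deterministic; the
#' `seed` argument exists for interface symmetry with the stochastic
#' steps.
#'
#' @param net a [CoNetwork-class] (or igraph graph).
#' @param seed unused (kept for a uniform stochastic-step signature).
#' @return a [ModulePartition-class].
#' @export
detectModules <- function(net, seed = NULL) {
  g <- .nonempty(.netGraph(net))
  cl <- igraph::cluster_fast_greedy(g, weights = NULL)
  mem <- as.integer(igraph::membership(cl))
  Q <- igraph::modularity(g, mem)
  # the greedy merge can return a negative-Q cut (e.g. on complete
  # graphs); the trivial one-module partition (Q = 0) is then better
  if (Q < 0) {
    mem <- rep(1L, igraph::vcount(g))
    Q <- igraph::modularity(g, mem)
  }
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(g)))
  new("ModulePartition", membership = stats::setNames(mem, nm), Q = Q)
}

#' @param x a [ModulePartition-class].
#' @return `moduleMembership`: named integer vector node -> module id.
#' @rdname moduleMembership
#' @export
setMethod("moduleMembership", "ModulePartition", function(x) x@membership)

#' Modularity of a module partition
#' @param x a [ModulePartition-class].
#' @return numeric Q.
#' @export
moduleModularity <- function(x) {
  stopifnot(is(x, "ModulePartition"))
  x@Q
}

setMethod("show", "ModulePartition", function(object) {
  cat("ModulePartition:", length(unique(object@membership)), "modules, Q =",
      round(object@Q, 4), "\n")
})

#' Degree-preserving random-network null ensemble
#'
#' Maslov-Sneppen rewiring: each replicate applies `nSwaps` double-edge
#' swap attempts (rejecting self-loops and multi-edges), which preserves
#' the degree multiset exactly, then the comparison metrics (avgCC, GD,
#' HD, transitivity, fast-greedy modularity) are recorded.
#'
#' @param net a [CoNetwork-class] (or igraph graph).
#' @param nNets ensemble size (default 100).
#' @param nSwaps swap attempts per replicate (default 10 x link count).
#' @param seed integer seed.
#' @return list with `summary` (data.frame metric, mean, sd) and `samples`
#'   (replicates x metrics data.frame). Warns when the graph admits no
#'   swap (all replicates identical).
#' @export
randomNull <- function(net, nNets = 100L, nSwaps = NULL, seed = 1L) {
  g <- .nonempty(.netGraph(net))
  L <- igraph::ecount(g)
  if (L < 2L) stop("null model needs at least 2 links")
  if (is.null(nSwaps)) nSwaps <- 10L * L
  refEdges <- .edgeKey(g)
  moved <- FALSE
  rows <- vector("list", nNets)
  for (i in seq_len(nNets)) {
    set.seed(seed + i - 1L)
    rg <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                   niter = nSwaps))
    stopifnot(identical(sort(igraph::degree(rg)), sort(igraph::degree(g))))
    if (!moved && !identical(.edgeKey(rg), refEdges)) moved <- TRUE
    cs <- clusteringStats(rg)
    gs <- geodesicStats(rg)
    rows[[i]] <- data.frame(avgCC = cs$avgCC, GD = gs$GD, HD = gs$HD,
                            transitivity = cs$transitivity,
                            modularity = detectModules(rg)@Q)
  }
  if (!moved)
    warning("graph admits no degree-preserving swap; ",
            "null ensemble is identical copies")
  samples <- do.call(rbind, rows)
  summary <- data.frame(metric = names(samples),
                        mean = vapply(samples, mean, numeric(1)),
                        sd = vapply(samples, stats::sd, numeric(1)),
                        row.names = NULL)
  list(summary = summary, samples = samples)
}

.edgeKey <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  sorted <- t(apply(el, 1L, sort))
  paste(sorted[, 1L], sorted[, 2L], sep = "|")[order(sorted[, 1L],
                                                     sorted[, 2L])]
}

#' Consolidated topology summary of one network
#'
#' Computes every report metric (node/link counts, sign counts and
#' percentages, power-law R2, avgK, avgCC, GD, HD, CD, CB, density,
#' transitivity, Krackhardt connectedness, module count and fast-greedy
#' modularity) and attaches the random-null means/sds when supplied. The
#' identity `density = avgK / (N - 1)` is asserted on every summary.
#'
#' @param net a [CoNetwork-class].
#' @param nulls optional result of [randomNull()].
#' @param modules optional precomputed [ModulePartition-class].
#' @param strict logical; if `FALSE`, metrics whose preconditions fail
#'   (e.g. power-law fit on < 3 distinct degrees) become NA with a warning
#'   instead of erroring.
#' @return a [TopologySummary-class].
#' @export
summarizeTopology <- function(net, nulls = NULL, modules = NULL,
                              strict = TRUE) {
  g <- .nonempty(.netGraph(net))
  grab <- function(expr) {
    if (strict) return(expr())
    tryCatch(expr(), error = function(e) {
      warning(conditionMessage(e)); NA_real_
    })
  }
  N <- igraph::vcount(g); L <- igraph::ecount(g)
  sc <- signCounts(net)
  cs <- clusteringStats(net)
  gs <- geodesicStats(net)
  ct <- grab(function() centralizationStats(net))
  if (length(ct) == 1L) ct <- list(CD = NA_real_, CB = NA_real_)
  if (is.null(modules)) modules <- detectModules(net)
  m <- c(total_nodes = N, total_links = L,
         n_negative = sc$n_negative, n_positive = sc$n_positive,
         pct_negative = sc$pct_negative, pct_positive = sc$pct_positive,
         powerlaw_r2 = grab(function() powerlawR2(net)),
         avgK = avgDegree(net), avgCC = cs$avgCC,
         GD = gs$GD, HD = gs$HD, CD = ct$CD, CB = ct$CB,
         density = networkDensity(net), transitivity = cs$transitivity,
         connectedness = connectednessKrackhardt(net),
         n_modules = length(unique(modules@membership)),
         modularity = modules@Q)
  stopifnot(abs(m[["density"]] - m[["avgK"]] / (N - 1)) < 1e-12)
  nullDf <- if (is.null(nulls)) {
    data.frame(metric = character(), mean = numeric(), sd = numeric())
  } else nulls$summary
  new("TopologySummary", metrics = m, nulls = nullDf)
}

#' @param x a [TopologySummary-class].
#' @return `topologyMetrics`: named numeric vector of empirical metrics.
#' @rdname topologyMetrics
#' @export
setMethod("topologyMetrics", "TopologySummary", function(x) x@metrics)

#' @param x a [TopologySummary-class].
#' @return `topologyNulls`: data.frame metric, mean, sd of the random
#'   ensemble.
#' @rdname topologyNulls
#' @export
setMethod("topologyNulls", "TopologySummary", function(x) x@nulls)

setMethod("show", "TopologySummary", function(object) {
  m <- object@metrics
  cat("TopologySummary:", m[["total_nodes"]], "nodes,",
      m[["total_links"]], "links\n")
  cat("  avgK =", round(m[["avgK"]], 3),
      " density =", round(m[["density"]], 3),
      " modularity =", round(m[["modularity"]], 3), "\n")
  if (nrow(object@nulls))
    cat("  random-null metrics attached for:",
        paste(object@nulls$metric, collapse = ", "), "\n")
})
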