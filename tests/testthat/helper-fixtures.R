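# Build a CoNetwork directly from an edge list (for hand-enumerated
# topology oracles); correlations default to +1.
makeNet <- function(edges, correlations = NULL, cutoff = 0.5,
                    isolates = NULL) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  if (is.null(correlations)) correlations <- rep(1, igraph::ecount(g))
  g <- igraph::set_edge_attr(g, "correlation", value = correlations)
  g <- igraph::set_edge_attr(g, "sign",
                             value = ifelse(correlations < 0, "-", "+"))
  new("CoNetwork", graph = g, cutoff = cutoff)
}

# graph_from_data_frame-compatible edge frame from two id vectors
edgeFrame <- function(from, to) data.frame(from = from, to = to)

# Small deterministic ASV count table: 4 samples x 4 taxa with known
# mean relative abundances (row totals 100000).
fixtureTable <- function() {
  counts <- rbind(
    s1 = c(200, 5, 50, 99745),
    s2 = c(200, 5, 50, 99745),
    s3 = c(200, 5, 50, 99745),
    s4 = c(200, 5, 50, 99745))
  colnames(counts) <- c("abund", "rare", "mid", "filler")
  AsvExperiment(counts,
                taxonomy = c("Bacteria;PhylA;;;;GenA",
                             "Bacteria;PhylB;;;;GenB",
                             "Fungi;PhylC;;;;GenC",
                             "Bacteria;PhylA;;;;GenD"),
                metadata = data.frame(stage = c("g1", "g1", "g2", "g2"),
                                      row.names = paste0("s", 1:4)))
}

# Samples-by-taxa matrix whose first two blocks are strongly correlated
# (shared factor), on Gaussian scale, for similarity/scan fixtures.
blockDataMatrix <- function(n = 30, blockSize = 15, nNoise = 30,
                            rho = 0.95, seed = 7) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * (2 * blockSize + nNoise)), n)
  f1 <- stats::rnorm(n); f2 <- stats::rnorm(n)
  b1 <- seq_len(blockSize); b2 <- blockSize + seq_len(blockSize)
  X[, b1] <- sqrt(rho) * f1 + sqrt(1 - rho) * X[, b1]
  X[, b2] <- sqrt(rho) * f2 + sqrt(1 - rho) * X[, b2]
  colnames(X) <- paste0("t", seq_len(ncol(X)))
  X
}

# Planted-module recovery measurements used by synthetic-data and
# acceptance tests.
plantedRecovery <- function(seed, cutoff = 0.88) {
  sim <- generateCommunity(syntheticSpec(seed = seed))
  part <- prevalenceFilter(classifyAbundance(sim$table))
  taxa <- retainedTaxaOfClass(part, "abundant")
  ra <- relativeAbundance(asvCounts(sim$table))[, taxa, drop = FALSE]
  sm <- correlationMatrix(fillMissing(ra), logScale = TRUE)
  net <- buildNetwork(sm, cutoff, partition = part)
  A <- plantedAdjacency(sim$truth)
  et <- edgeTable(net)
  onPlanted <- A[cbind(et$source, et$target)]
  mods <- detectModules(net)
  mem <- moduleMembership(mods)
  truthMod <- sim$truth@moduleOf[as.integer(sub("taxon_", "", names(mem)))]
  keep <- !is.na(truthMod)
  ari <- if (sum(keep) > 1)
    mclust::adjustedRandIndex(mem[keep], truthMod[keep]) else NA_real_
  list(recovered = sum(onPlanted) / (sum(A[taxa, taxa]) / 2),
       falseRate = if (nrow(et)) mean(!onPlanted) else 0,
       ari = ari, net = net, truth = sim$truth)
}
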