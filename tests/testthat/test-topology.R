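triangle <- function() makeNet(edgeFrame(c("a", "b", "c"), c("b", "c", "a")))
starNet <- function(n = 6) makeNet(edgeFrame(rep("hub", n - 1),
                                             paste0("leaf", seq_len(n - 1))))
pathNet <- function() makeNet(edgeFrame(c("a", "b"), c("b", "c")))
cycleNet <- function(n = 6) makeNet(edgeFrame(paste0("v", seq_len(n)),
                                              paste0("v", c(seq_len(n)[-1], 1))))

test_that("degree and density identities hold on toys", {
  expect_equal(avgDegree(triangle()), 2)
  expect_equal(networkDensity(makeNet(edgeFrame("a", "b"))), 1)
  tri <- triangle()
  expect_equal(networkDensity(tri), 1)
  expect_equal(networkDensity(starNet(5)), avgDegree(starNet(5)) / 4)
  expect_error(avgDegree(new("CoNetwork",
                             graph = igraph::make_empty_graph(directed = FALSE),
                             cutoff = 0.5)), "empty")
})

test_that("sign counts report percentages at two decimals", {
  net <- makeNet(edgeFrame(c("a", "b", "c"), c("b", "c", "a")),
                 correlations = c(0.9, -0.9, 0.95))
  sc <- signCounts(net)
  expect_equal(sc$n_negative, 1L)
  expect_equal(sc$pct_negative, 33.33)
  allPos <- signCounts(triangle())
  expect_equal(allPos$n_negative, 0L)
  expect_equal(allPos$pct_positive, 100)
})

test_that("clustering coefficients match hand enumeration", {
  cs <- clusteringStats(triangle())
  expect_equal(cs$avgCC, 1)
  expect_equal(cs$transitivity, 1)

  st <- clusteringStats(starNet(6))
  expect_equal(st$avgCC, 0)
  expect_equal(st$transitivity, 0)

  # triangle plus pendant: local CCs are 1, 1, 1/3, 0
  tp <- makeNet(edgeFrame(c("a", "b", "c", "c"), c("b", "c", "a", "d")))
  cp <- clusteringStats(tp)
  expect_equal(cp$avgCC, (1 + 1 + 1 / 3 + 0) / 4, tolerance = 1e-12)
  expect_equal(cp$transitivity, 0.6)
  expect_equal(clusteringStats(tp, dropLowDegree = TRUE)$avgCC,
               (1 + 1 + 1 / 3) / 3, tolerance = 1e-12)
})

test_that("geodesic summaries follow stated disconnection conventions", {
  cg <- geodesicStats(triangle())
  expect_equal(cg$GD, 1); expect_equal(cg$HD, 1)

  pg <- geodesicStats(pathNet())
  expect_equal(pg$GD, 4 / 3, tolerance = 1e-12)
  expect_equal(pg$HD, 1.2, tolerance = 1e-12)

  two <- makeNet(edgeFrame(c("a", "c"), c("b", "d")))  # two disjoint edges
  tg <- geodesicStats(two)
  expect_equal(tg$GD, 1)
  expect_equal(tg$HD, 3)

  # harmonic <= arithmetic mean on connected graphs
  set.seed(4)
  g <- igraph::sample_gnp(25, 0.25)
  while (!igraph::is_connected(g)) g <- igraph::sample_gnp(25, 0.25)
  gs <- geodesicStats(g)
  expect_lte(gs$HD, gs$GD)
})

test_that("centralization is maximal for stars and zero for cycles", {
  st <- centralizationStats(starNet(7))
  expect_equal(st$CD, 1); expect_equal(st$CB, 1)
  cy <- centralizationStats(cycleNet(8))
  expect_equal(cy$CD, 0); expect_equal(cy$CB, 0)
  expect_equal(centralizationStats(pathNet())$CD, 1)
  expect_error(centralizationStats(makeNet(edgeFrame("a", "b"))), "3 nodes")
})

test_that("Krackhardt connectedness counts reachable pairs", {
  expect_equal(connectednessKrackhardt(triangle()), 1)
  two <- makeNet(edgeFrame(c("a", "c"), c("b", "d")))
  expect_equal(connectednessKrackhardt(two), 1 / 3)
  iso <- igraph::make_empty_graph(5, directed = FALSE)
  expect_equal(connectednessKrackhardt(iso), 0)
})

test_that("power-law R2 is exact on exact log-linear degree counts", {
  # counts(k) = 64/k^2 over k in {1,2,4,8}: 64,16,4,1 nodes of each degree
  degs <- rep(c(1, 2, 4, 8), c(64, 16, 4, 1))
  set.seed(1)
  g <- igraph::sample_degseq(degs, method = "fast.heur.simple")
  expect_equal(suppressWarnings(powerlawR2(g)), 1, tolerance = 1e-12)
  expect_error(powerlawR2(cycleNet(6)), "3 distinct")
  set.seed(8)
  r2 <- powerlawR2(igraph::sample_gnp(60, 0.1))
  expect_gte(r2, 0); expect_lte(r2, 1)
})

test_that("fast-greedy modularity matches closed forms", {
  k4twice <- igraph::disjoint_union(igraph::make_full_graph(4),
                                    igraph::make_full_graph(4))
  mp <- detectModules(k4twice)
  expect_equal(length(unique(moduleMembership(mp))), 2L)
  expect_equal(moduleModularity(mp), 0.5)

  full <- detectModules(igraph::make_full_graph(6))
  expect_equal(length(unique(moduleMembership(full))), 1L)
  expect_equal(moduleModularity(full), 0)

  # any detected partition beats the trivial single-module Q = 0
  sm <- correlationMatrix(blockDataMatrix(seed = 13))
  net <- buildNetwork(sm, 0.6)
  expect_gte(moduleModularity(detectModules(net)), 0)
})

test_that("degree-preserving nulls keep the degree multiset exactly", {
  sm <- correlationMatrix(blockDataMatrix(seed = 21))
  net <- buildNetwork(sm, 0.5)
  # the per-replicate degree assertion runs inside randomNull
  nulls <- randomNull(net, nNets = 100, seed = 3)
  expect_equal(nrow(nulls$samples), 100L)
  expect_true(all(is.finite(nulls$summary$mean)))

  # planted two-block structure: empirical modularity above the null mean
  emp <- moduleModularity(detectModules(net))
  nullQ <- nulls$summary$mean[nulls$summary$metric == "modularity"]
  expect_gt(emp, nullQ)

  # a triangle admits no swap: sd 0 and a warning
  expect_warning(tri <- randomNull(triangle(), nNets = 10, seed = 1),
                 "no degree-preserving swap")
  expect_equal(unname(tri$summary$sd), rep(0, 5))
})

test_that("topology summaries are consistent and round-trip through TSV", {
  sm <- correlationMatrix(blockDataMatrix(seed = 21))
  net <- buildNetwork(sm, 0.5)
  topo <- summarizeTopology(net, nulls = randomNull(net, nNets = 5,
                                                    seed = 2))
  m <- topologyMetrics(topo)
  expect_equal(m[["n_negative"]] + m[["n_positive"]], m[["total_links"]])
  expect_equal(m[["density"]], m[["avgK"]] / (m[["total_nodes"]] - 1),
               tolerance = 1e-12)
  expect_equal(m[["pct_negative"]] + m[["pct_positive"]], 100,
               tolerance = 0.011)

  tf <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(metric = names(m), value = unname(m))
  utils::write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- utils::read.delim(tf)
  expect_equal(setNames(back$value, back$metric), m, tolerance = 1e-12)

  # non-strict mode degrades gracefully on degenerate degree sequences
  expect_warning(topoTri <- summarizeTopology(triangle(), strict = FALSE),
                 "distinct")
  expect_true(is.na(topologyMetrics(topoTri)[["powerlaw_r2"]]))
})
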