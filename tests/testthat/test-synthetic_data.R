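test_that("spec validation catches impossible designs", {
  expect_error(syntheticSpec(depth = 0), "depth")
  expect_error(syntheticSpec(nTaxa = 50,
                             modules = list(list(taxa = 45:55, rho = 0.9,
                                                 sign = NULL))),
               "out of range")
  expect_error(syntheticSpec(nTaxa = 50,
                             modules = list(list(taxa = 1:5, rho = 1.2,
                                                 sign = NULL))),
               "rho")
  overlap <- list(list(taxa = 1:5, rho = 0.9, sign = NULL),
                  list(taxa = 4:8, rho = 0.9, sign = NULL))
  expect_error(syntheticSpec(nTaxa = 50, modules = overlap), "disjoint")
})

test_that("generation is deterministic and structure-free when unplanted", {
  spec0 <- syntheticSpec(nTaxa = 100, nPerGroup = 10, depth = 10000,
                         modules = list(), groupEffectSd = 0, seed = 42)
  a <- generateCommunity(spec0)
  b <- generateCommunity(spec0)
  expect_identical(asvCounts(a$table), asvCounts(b$table))

  # no modules, no group effect: inter-taxon correlations sit at the
  # finite-sample null level (under independence the median |r| at n = 30
  # is 0.6745 / sqrt(29) ~ 0.125, so "near zero" means below ~0.15)
  ra <- relativeAbundance(a$table)
  ok <- apply(ra, 2, sd) > 0
  r <- cor(ra[, ok])
  expect_lt(median(abs(r[upper.tri(r)])), 0.15)
})

test_that("planted modules express stronger correlations than background", {
  sim <- generateCommunity(syntheticSpec(nTaxa = 500, depth = 10000,
                                         seed = 8))
  ra <- relativeAbundance(sim$table)
  A <- plantedAdjacency(sim$truth)
  modTaxa <- unlist(sim$truth@modules)
  ids <- colnames(ra)[modTaxa]
  r <- abs(cor(ra[, ids]))
  inPlant <- A[ids, ids][upper.tri(r)]
  expect_gt(mean(r[upper.tri(r)][inPlant]),
            mean(r[upper.tri(r)][!inPlant]))
})

test_that("rank-abundance distribution is right-skewed at study scale", {
  sim <- generateCommunity(syntheticSpec(seed = 1))
  cls <- sim$truth@trueClass
  expect_lt(mean(cls == "abundant"), 0.20)
  expect_gt(mean(cls == "rare"), 0.40)
})

test_that("planted adjacency is recoverable at the comparative cutoff", {
  runs <- lapply(1:10, plantedRecovery)
  rec <- vapply(runs, `[[`, numeric(1), "recovered")
  fp <- vapply(runs, `[[`, numeric(1), "falseRate")
  expect_gte(mean(rec), 0.5)
  expect_lt(mean(fp), 0.05)
})

test_that("environmental coupling drives Mantel signal, noise does not", {
  # zero coupling: env distance unrelated to composition distance
  pvals <- vapply(1:20, function(s) {
    spec <- syntheticSpec(nTaxa = 200, depth = 5000, envCoupling = 0,
                          modules = list(), seed = 1000 + s)
    sim <- generateCommunity(spec)
    env <- generateEnv(spec, sim$truth)
    mantelTest(brayCurtis(sim$table), envDistance(env),
               nPerm = 199, seed = s)$p
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)

  # strong coupling: partial Mantel (controlling the noise variable) hits
  # no planted modules here: planted blocks are group-invariant by design
  # and would dilute the group-driven composition signal in a small table
  spec <- syntheticSpec(nTaxa = 200, depth = 5000, envCoupling = 2,
                        modules = list(), seed = 77)
  sim <- generateCommunity(spec)
  env <- generateEnv(spec, sim$truth)
  pm <- partialMantelTest(brayCurtis(sim$table),
                          envDistance(env, setdiff(colnames(env),
                                                   "noise_control")),
                          envDistance(env, "noise_control"),
                          nPerm = 999, seed = 5)
  expect_gt(pm$r, 0)
  expect_lte(pm$p, 0.05)

  # deterministic under a fixed seed
  expect_identical(generateEnv(spec, sim$truth),
                   generateEnv(spec, sim$truth))
})

test_that("ground-truth classes equal the classifier's statistic", {
  sim <- generateCommunity(syntheticSpec(nTaxa = 400, depth = 8000,
                                         seed = 12))
  part <- classifyAbundance(sim$table)
  expect_identical(unname(abundanceClass(part)), sim$truth@trueClass)
})
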