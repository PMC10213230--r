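test_that("zero filling targets majority-present taxa only", {
  m <- cbind(full = c(0.2, 0.3, 0.25, 0.2, 0.4, 0.3, 0.2, 0.3, 0.2, 0.3),
             gappy = c(0.1, 0.2, 0.1, 0.3, 0.1, 0.2, 0.1, 0, 0, 0),
             sparse = c(0.5, 0.2, 0, 0, 0, 0, 0, 0, 0, 0))
  out <- fillMissing(m, fill = 1e-4)
  expect_identical(out[, "full"], m[, "full"])           # no zeros: unchanged
  expect_equal(sum(out[, "gappy"] == 1e-4), 3L)          # 7/10 present
  expect_identical(out[, "sparse"], m[, "sparse"])       # minority taxon
  expect_identical(fillMissing(m, fill = 0), m)
  expect_equal(sum(fillMissing(m, 1e-4, majorityRule = FALSE) == 1e-4),
               11L)
})

test_that("correlation matrices are valid signed similarity objects", {
  x <- c(1, 2, 3, 4, 5)
  m <- cbind(a = x, b = c(2, 4, 5, 4, 5), c = -x)
  sm <- correlationMatrix(m)
  r <- correlationValues(sm)
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))
  expect_equal(r["a", "b"], 0.7746, tolerance = 1e-4)
  expect_equal(r["a", "c"], -1)
  expect_equal(similarityValues(sm)["a", "c"], 1)
  expect_true(isSymmetric(r))

  expect_error(correlationMatrix(m[1:3, ]), "4 samples")
  expect_warning(correlationMatrix(cbind(m, flat = rep(2, 5))),
                 "constant")
  expect_error(correlationMatrix(cbind(m, neg = c(0, 1, 0, 1, 0)),
                                 logScale = TRUE), "positive")
})

test_that("spectral unfolding normalises spacings to unit mean", {
  # uniform spectrum: all unfolded spacings equal 1
  sp <- unfoldSpectrum(seq(0, 10, length.out = 50))
  expect_equal(sp, rep(1, 49), tolerance = 1e-6)

  # mean spacing within 10% of 1 for irregular spectra
  set.seed(5)
  for (ev in list(rnorm(80), rexp(120), c(rnorm(40), 5 + rexp(40)))) {
    expect_gt(mean(unfoldSpectrum(ev)), 0.9)
    expect_lt(mean(unfoldSpectrum(ev)), 1.1)
  }

  # degenerate eigenvalues collapse to one level
  ev <- c(rep(1, 10), seq(2, 6, length.out = 25))
  expect_length(unfoldSpectrum(ev), 25L)  # 26 distinct levels - 1
  expect_error(unfoldSpectrum(rep(1:3, 5)), "distinct")
})

test_that("NNSD chi-square classifier separates Poisson from GOE", {
  set.seed(42)
  poisAcc <- mean(replicate(100, nnsdTest(rexp(500))$poisson_fits))
  goeAcc <- mean(replicate(100, !nnsdTest(rWignerSpacings(500))$poisson_fits))
  expect_gte(poisAcc, 0.95)
  expect_gte(goeAcc, 0.95)

  expect_false(nnsdTest(rep(1, 50))$evaluable)   # degenerate histogram
  expect_false(nnsdTest(rexp(10))$evaluable)     # too few spacings
  tst <- nnsdTest(rexp(500))
  expect_true(tst$chisq_poisson < tst$chisq_goe)
})

test_that("RMT scan finds the threshold that isolates planted blocks", {
  sm <- correlationMatrix(blockDataMatrix(seed = 7))
  scan <- rmtThresholdScan(sm)
  rec <- scanRecords(scan)
  expect_equal(rec$threshold, seq(0.30, 1.00, by = 0.01))
  th <- chosenThreshold(scan)
  expect_false(is.na(th))
  net <- buildNetwork(sm, th)
  comp <- igraph::components(networkGraph(net))
  expect_equal(comp$no, 2L)
  mem <- split(names(comp$membership), comp$membership)
  expect_setequal(mem[[1]], paste0("t", 1:15))
  expect_setequal(mem[[2]], paste0("t", 16:30))
})

test_that("RMT scan on pure noise shows GOE statistics at low thresholds", {
  set.seed(9)
  Y <- matrix(rnorm(30 * 300), 30, 300)
  colnames(Y) <- paste0("n", seq_len(300))
  scan <- rmtThresholdScan(correlationMatrix(Y))
  rec <- scanRecords(scan)
  low <- rec[rec$threshold <= 0.45 & rec$evaluable, ]
  expect_true(all(!low$poisson_fits))
  expect_true(all(low$chisq_goe < low$chisq_poisson))

  tiny <- correlationMatrix(matrix(rnorm(5 * 6), 5,
                                   dimnames = list(NULL, paste0("t", 1:6))))
  expect_error(rmtThresholdScan(tiny), "too small")
})

test_that("network construction respects cutoff, signs and monotonicity", {
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0.9
  r[2, 3] <- r[3, 2] <- -0.9
  r[1, 3] <- r[3, 1] <- 0.5
  dimnames(r) <- list(c("a", "b", "c"), c("a", "b", "c"))
  sm <- new("SimilarityMatrix", correlation = r, method = "pearson")

  net <- buildNetwork(sm, 0.88)
  expect_equal(igraph::ecount(networkGraph(net)), 2L)
  expect_equal(igraph::vcount(networkGraph(net)), 3L)
  et <- edgeTable(net)
  expect_equal(sum(et$sign == "-"), 1L)
  expect_equal(et$correlation[et$sign == "-"], -0.9)

  full <- buildNetwork(sm, 0)
  expect_equal(igraph::ecount(networkGraph(full)), 3L)  # complete graph
  expect_error(buildNetwork(sm, 0.95), "no edge")

  # monotone in the cutoff
  sm2 <- correlationMatrix(blockDataMatrix(seed = 3))
  sizes <- vapply(c(0.3, 0.5, 0.7, 0.9), function(ct) {
    n <- tryCatch(buildNetwork(sm2, ct), error = function(e) NULL)
    if (is.null(n)) c(0, 0) else
      c(igraph::vcount(networkGraph(n)), igraph::ecount(networkGraph(n)))
  }, numeric(2))
  expect_true(all(diff(sizes[1, ]) <= 0))
  expect_true(all(diff(sizes[2, ]) <= 0))

  # sign consistency: every negative edge is a strong negative correlation
  neg <- subset(edgeTable(buildNetwork(sm2, 0.5)), sign == "-")
  expect_true(all(neg$correlation <= -0.5))
})
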