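#' Unfold an eigenvalue spectrum to unit mean spacing
#'
#' Spacing statistics are only comparable across spectra after removing the
#' system-specific level density. The cumulative spectral function is
#' smoothed by a monotone cubic spline through roughly n/10 knots (at least
#' 5), and each eigenvalue is mapped to `e_i = n * G(lambda_i)`; successive
#' differences of the unfolded levels then have mean spacing ~1.
#' Degenerate eigenvalues (within `tol`) are collapsed to a single level
#' before unfolding.
#'
#' @param eigenvalues numeric vector (any order).
#' @param tol degeneracy tolerance (default 1e-8).
#' @param minLevels minimum number of distinct levels required (default
#'   20).
#' @return numeric vector of unfolded nearest-neighbour spacings (length =
#'   distinct levels - 1), mean within 10% of 1.
#' @export
unfoldSpectrum <- function(eigenvalues, tol = 1e-8, minLevels = 20L) {
  ev <- sort(as.numeric(eigenvalues))
  # collapse degeneracies
  keep <- c(TRUE, diff(ev) > tol)
  ev <- ev[keep]
  n <- length(ev)
  if (n < minLevels)
    stop("need at least ", minLevels, " distinct eigenvalues, got ", n)

  nKnots <- max(5L, ceiling(n / 10))
  idx <- unique(round(seq(1L, n, length.out = nKnots)))
  # empirical cumulative spectral function at the knots
  Fk <- (idx - 0.5) / n
  G <- stats::splinefun(ev[idx], Fk, method = "hyman")
  e <- n * G(ev)
  d <- diff(e)
  d[d < 0] <- 0  # guard against spline round-off
  d
}

#' Sample nearest-neighbour spacings from the Wigner surmise (GOE)
#'
#' Inverse-CDF sampling of the Wigner-Dyson density
#' `(pi d / 2) exp(-pi d^2 / 4)`, the GOE spacing law with unit mean.
#'
#' @param n number of spacings.
#' @return numeric vector.
#' @export
rWignerSpacings <- function(n) {
  u <- stats::runif(n)
  2 * sqrt(-log(1 - u) / pi)
}

#' Chi-square test of the spacing distribution: Poisson vs GOE
#'
#' Bins the spacings on `[0, max]` and measures chi-square distances of the
#' observed histogram to the Poisson form `exp(-d)` and to the
#' Wigner-Dyson (GOE) form `(pi d/2) exp(-pi d^2/4)`, each renormalised to
#' the binned range. The spacing distribution is declared Poisson
#' (`poisson_fits`) when the Poisson distance is both smaller than the GOE
#' distance and below the chi-square critical value at significance
#' `alpha` with `nBins - 1` degrees of freedom.
#'
#' @param spacings numeric vector of unfolded spacings (>= 20).
#' @param nBins histogram bins (default 20).
#' @param alpha significance level of the goodness-of-fit gate (default
#'   0.001).
#' @return list with `chisq_poisson`, `chisq_goe`, `poisson_fits`,
#'   `evaluable`.
#' @export
nnsdTest <- function(spacings, nBins = 20L, alpha = 0.001) {
  s <- as.numeric(spacings)
  s <- s[is.finite(s)]
  notEval <- list(chisq_poisson = NA_real_, chisq_goe = NA_real_,
                  poisson_fits = FALSE, evaluable = FALSE)
  if (length(s) < 20L) return(notEval)
  hi <- max(s)
  if (hi <= 0 || stats::sd(s) == 0) return(notEval)  # degenerate histogram
  breaks <- seq(0, hi, length.out = nBins + 1L)
  obs <- tabulate(pmin(pmax(findInterval(s, breaks, rightmost.closed = TRUE),
                            1L), nBins), nBins)
  n <- length(s)

  cdfPois <- function(x) 1 - exp(-x)
  cdfGoe <- function(x) 1 - exp(-pi * x^2 / 4)
  expCounts <- function(cdf) {
    p <- diff(cdf(breaks)) / cdf(hi)
    n * p
  }
  # chi-square with Cochran pooling: adjacent bins are merged until every
  # expected count reaches 5, so sparse tail bins do not distort the
  # statistic; df = pooled bins - 1
  chisq <- function(E) {
    O <- obs
    pO <- numeric(0); pE <- numeric(0)
    accO <- 0; accE <- 0
    for (b in seq_along(E)) {
      accO <- accO + O[b]; accE <- accE + E[b]
      if (accE >= 5) {
        pO <- c(pO, accO); pE <- c(pE, accE)
        accO <- 0; accE <- 0
      }
    }
    if (accE > 0) {  # fold the leftover tail into the last pooled bin
      if (length(pE)) {
        pO[length(pO)] <- pO[length(pO)] + accO
        pE[length(pE)] <- pE[length(pE)] + accE
      } else {
        pO <- accO; pE <- accE
      }
    }
    list(stat = sum((pO - pE)^2 / pE), df = max(length(pE) - 1L, 1L))
  }
  cp <- chisq(expCounts(cdfPois))
  cg <- chisq(expCounts(cdfGoe))
  fits <- (cp$stat < cg$stat) &&
    (cp$stat < stats::qchisq(1 - alpha, df = cp$df))
  list(chisq_poisson = cp$stat, chisq_goe = cg$stat,
       poisson_fits = fits, evaluable = TRUE)
}

#' RMT scan of the similarity threshold
#'
#' For every threshold on the grid (default 0.30 to 1.00 in steps of
#' 0.01): entries of the similarity matrix below the threshold are zeroed,
#' taxa without any remaining off-diagonal entry are dropped, the
#' eigenvalues of the thresholded matrix are unfolded
#' ([unfoldSpectrum()]), and the spacing distribution is classified
#' ([nnsdTest()]). At low thresholds the dense, noisy matrix shows GOE
#' (Wigner-Dyson) spacing statistics; past the transition the modular
#' signal remains and spacings become Poisson. The chosen threshold is the
#' smallest grid value whose Poisson fit holds and keeps holding at every
#' larger evaluable threshold (the RMT transition is one-directional, so a
#' single noise-induced flip back to GOE disqualifies a candidate).
#'
#' @param sim a [SimilarityMatrix-class].
#' @param grid numeric vector of thresholds (default `seq(0.30, 1, 0.01)`).
#' @param minLevels minimum distinct eigenvalues for a threshold to be
#'   evaluable (default 20).
#' @param nBins,alpha passed to [nnsdTest()].
#' @return an [RmtScanResult-class]. Errors when no threshold is
#'   evaluable (input too small).
#' @export
rmtThresholdScan <- function(sim, grid = seq(0.30, 1.00, by = 0.01),
                             minLevels = 20L, nBins = 20L, alpha = 0.001) {
  stopifnot(is(sim, "SimilarityMatrix"))
  S <- similarityValues(sim)
  rec <- lapply(grid, function(th) {
    A <- S
    A[A < th] <- 0
    off <- rowSums(A > 0) - 1L  # diagonal always 1
    keep <- off > 0L
    A <- A[keep, keep, drop = FALSE]
    nKeep <- sum(keep)
    out <- data.frame(threshold = th, n_nodes = nKeep,
                      n_eigenvalues = 0L, chisq_poisson = NA_real_,
                      chisq_goe = NA_real_, poisson_fits = FALSE,
                      evaluable = FALSE)
    if (nKeep < minLevels) return(out)
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    sp <- tryCatch(unfoldSpectrum(ev, minLevels = minLevels),
                   error = function(e) NULL)
    if (is.null(sp)) return(out)
    out$n_eigenvalues <- length(sp) + 1L
    tst <- nnsdTest(sp, nBins = nBins, alpha = alpha)
    out$chisq_poisson <- tst$chisq_poisson
    out$chisq_goe <- tst$chisq_goe
    out$poisson_fits <- tst$poisson_fits
    out$evaluable <- tst$evaluable
    out
  })
  rec <- do.call(rbind, rec)
  if (!any(rec$evaluable))
    stop("no threshold evaluable; the similarity matrix is too small ",
         "for spacing statistics - provide more taxa")
  chosen <- NA_real_
  evalIdx <- which(rec$evaluable)
  for (i in evalIdx) {
    later <- evalIdx[evalIdx >= i]
    if (all(rec$poisson_fits[later])) { chosen <- rec$threshold[i]; break }
  }
  new("RmtScanResult", records = rec, chosenThreshold = chosen)
}

#' @param x an [RmtScanResult-class].
#' @return `chosenThreshold`: the selected similarity threshold (NA when
#'   the scan found no persistent Poisson regime).
#' @rdname chosenThreshold
#' @export
setMethod("chosenThreshold", "RmtScanResult", function(x)
  x@chosenThreshold)

#' @param x an [RmtScanResult-class].
#' @return `scanRecords`: the per-threshold scan data.frame.
#' @rdname scanRecords
#' @export
setMethod("scanRecords", "RmtScanResult", function(x) x@records)

setMethod("show", "RmtScanResult", function(object) {
  r <- object@records
  cat("RmtScanResult:", nrow(r), "thresholds,",
      sum(r$evaluable), "evaluable\n")
  cat("  chosen threshold:", object@chosenThreshold, "\n")
})
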