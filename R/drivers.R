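#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal distance vectors with a
#' one-sided (r_perm >= r_obs) permutation p-value under the plus-one
#' estimator, via [vegan::mantel()] — the ecological convention for
#' relating community dissimilarity to environmental distance.
#'
#' @param dA,dB `dist` objects (or square matrices) on the same samples.
#' @param nPerm permutations (default 999).
#' @param seed integer seed.
#' @return list: r, p, nPerm, partialled (NA).
#' @export
mantelTest <- function(dA, dB, nPerm = 999L, seed = 1L) {
  dA <- stats::as.dist(dA); dB <- stats::as.dist(dB)
  .checkMatched(dA, dB)
  set.seed(seed)
  m <- vegan::mantel(dA, dB, method = "pearson", permutations = nPerm)
  list(r = unname(m$statistic), p = m$signif, nPerm = nPerm,
       partialled = NA_character_)
}

#' Partial Mantel test controlling a third distance matrix
#'
#' Partial Pearson correlation
#' `r_AB.C = (r_AB - r_AC r_BC) / sqrt((1 - r_AC^2)(1 - r_BC^2))` on the
#' off-diagonal vectors, permutation p as in [mantelTest()], via
#' [vegan::mantel.partial()].
#'
#' @param dA,dB,dC `dist` objects on the same samples; `dC` is partialled
#'   out.
#' @param nPerm permutations (default 999).
#' @param seed integer seed.
#' @return list: r, p, nPerm, partialled.
#' @export
partialMantelTest <- function(dA, dB, dC, nPerm = 999L, seed = 1L) {
  dA <- stats::as.dist(dA); dB <- stats::as.dist(dB)
  dC <- stats::as.dist(dC)
  .checkMatched(dA, dB); .checkMatched(dA, dC)
  rAC <- stats::cor(as.vector(dA), as.vector(dC))
  rBC <- stats::cor(as.vector(dB), as.vector(dC))
  if (abs(rAC) >= 1 - 1e-12 || abs(rBC) >= 1 - 1e-12)
    stop("partial correlation undefined: control matrix collinear ",
         "with an input matrix")
  set.seed(seed)
  m <- vegan::mantel.partial(dA, dB, dC, method = "pearson",
                             permutations = nPerm)
  list(r = unname(m$statistic), p = m$signif, nPerm = nPerm,
       partialled = "dC")
}

.checkMatched <- function(a, b) {
  if (attr(a, "Size") != attr(b, "Size"))
    stop("distance matrices have different sizes")
  la <- attr(a, "Labels"); lb <- attr(b, "Labels")
  if (!is.null(la) && !is.null(lb) && !identical(la, lb))
    stop("distance matrices cover different samples")
  invisible(TRUE)
}

#' Euclidean distances on standardized environmental variables
#'
#' @param env samples-by-variables matrix (see [envMatrix()]).
#' @param variables optional subset of variable names.
#' @return `dist` object.
#' @export
envDistance <- function(env, variables = NULL) {
  m <- as.matrix(env)
  if (!is.null(variables)) m <- m[, variables, drop = FALSE]
  sds <- apply(m, 2L, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning("constant variable(s) dropped: ",
            paste(colnames(m)[!keep], collapse = ", "))
    m <- m[, keep, drop = FALSE]
  }
  stats::dist(scale(m))
}

#' Pearson correlations of topology metrics against environment
#'
#' One network summary per observation (e.g. per replicate or per group),
#' paired with aggregated environmental values; every metric-variable pair
#' gets a Pearson r with a two-sided t-test p and significance stars
#' (* p <= 0.05, ** p <= 0.01). Constant columns give NA with a warning.
#'
#' @param env observations-by-variables numeric matrix.
#' @param metrics observations-by-metrics numeric matrix or data.frame.
#' @return list of matrices: r, p, stars (metrics x variables).
#' @export
envTopologyCorrelation <- function(env, metrics) {
  env <- as.matrix(env)
  metrics <- as.matrix(metrics)
  if (nrow(env) != nrow(metrics))
    stop("env and metrics need matching observations")
  if (nrow(env) < 3L) stop("need at least 3 observations")
  r <- matrix(NA_real_, ncol(metrics), ncol(env),
              dimnames = list(colnames(metrics), colnames(env)))
  p <- r
  for (i in seq_len(ncol(metrics))) {
    for (j in seq_len(ncol(env))) {
      x <- metrics[, i]; y <- env[, j]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        warning("constant or insufficient data for ",
                colnames(metrics)[i], " vs ", colnames(env)[j])
        next
      }
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  stars <- ifelse(is.na(p), "",
           ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "")))
  list(r = r, p = p, stars = stars)
}
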