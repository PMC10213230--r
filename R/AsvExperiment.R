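#' Construct an AsvExperiment from a count matrix
#'
#' @param counts non-negative integer matrix of ASV counts. The canonical
#'   user-facing orientation is samples as rows and taxa as columns;
#'   set `samplesAsRows = FALSE` if taxa are rows. Row and column names are
#'   required (generated as `sample_i` / `taxon_j` when absent).
#' @param taxonomy optional character vector of semicolon-delimited rank
#'   strings (`kingdom;phylum;class;order;family;genus`), one per taxon, or
#'   a data.frame of rank columns.
#' @param metadata optional per-sample data.frame (e.g. a `stage` column
#'   with the successional stage); row names or a `sample_id` column must
#'   match the sample ids.
#' @param samplesAsRows logical, orientation of `counts`.
#'
#' @return a validated [AsvExperiment-class] object.
#' @examples
#' m <- matrix(rpois(12, 5), 3, 4,
#'             dimnames = list(paste0("s", 1:3), paste0("t", 1:4)))
#' ae <- AsvExperiment(m)
#' dim(ae)  # 4 taxa x 3 samples, SummarizedExperiment orientation
#' @export
AsvExperiment <- function(counts, taxonomy = NULL, metadata = NULL,
                          samplesAsRows = TRUE) {
  counts <- as.matrix(counts)
  if (samplesAsRows) counts <- t(counts)
  # now taxa x samples
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("taxon_", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
  storage.mode(counts) <- "double"
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")

  rd <- parseTaxonomy(taxonomy, rownames(counts))
  cd <- S4Vectors::DataFrame(row.names = colnames(counts))
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if ("sample_id" %in% names(metadata)) {
      rownames(metadata) <- metadata$sample_id
      metadata$sample_id <- NULL
    }
    miss <- setdiff(colnames(counts), rownames(metadata))
    if (length(miss))
      stop("metadata missing samples: ", paste(miss, collapse = ", "))
    cd <- S4Vectors::DataFrame(metadata[colnames(counts), , drop = FALSE])
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rd, colData = cd)
  new("AsvExperiment", se)
}

taxRanks <- c("kingdom", "phylum", "class", "order", "family", "genus")

# Split semicolon-delimited lineage strings into the six canonical ranks;
# unknown/missing ranks stay "".
parseTaxonomy <- function(taxonomy, taxonIds) {
  n <- length(taxonIds)
  if (is.null(taxonomy)) {
    rd <- S4Vectors::DataFrame(row.names = taxonIds)
    rd$taxonomy <- rep("", n)
    for (r in taxRanks) rd[[r]] <- rep("", n)
    return(rd)
  }
  if (is.data.frame(taxonomy) || is(taxonomy, "DataFrame")) {
    rd <- S4Vectors::DataFrame(taxonomy, row.names = taxonIds)
    if (is.null(rd$taxonomy))
      rd$taxonomy <- apply(as.data.frame(taxonomy), 1, paste,
                           collapse = ";")
    return(rd)
  }
  taxonomy <- as.character(taxonomy)
  if (length(taxonomy) != n)
    stop("taxonomy length must match number of taxa")
  parts <- strsplit(taxonomy, ";", fixed = TRUE)
  rank_mat <- vapply(parts, function(p) {
    p <- trimws(p)
    c(p, rep("", 6L))[seq_len(6L)]
  }, character(6L))
  rd <- S4Vectors::DataFrame(row.names = taxonIds)
  rd$taxonomy <- taxonomy
  for (i in seq_along(taxRanks)) rd[[taxRanks[i]]] <- rank_mat[i, ]
  rd
}

#' Extract the count matrix of an AsvExperiment
#'
#' @param x an [AsvExperiment-class].
#' @param samplesAsRows logical; if `TRUE` (default) the returned matrix has
#'   samples as rows and taxa as columns (the community-table convention),
#'   otherwise the internal taxa-by-samples layout.
#' @param ... unused.
#' @return numeric matrix of counts.
#' @rdname asvCounts
#' @export
setMethod("asvCounts", "AsvExperiment", function(x, samplesAsRows = TRUE,
                                                 ...) {
  m <- SummarizedExperiment::assay(x, "counts")
  if (samplesAsRows) t(m) else m
})

#' Per-taxon taxonomy table
#' @param x an [AsvExperiment-class].
#' @return a DataFrame with a `taxonomy` lineage string plus one column per
#'   rank (kingdom..genus).
#' @rdname taxonomyTable
#' @export
setMethod("taxonomyTable", "AsvExperiment", function(x)
  SummarizedExperiment::rowData(x))

#' Per-sample metadata table
#' @param x an [AsvExperiment-class].
#' @return the colData DataFrame.
#' @rdname sampleData
#' @export
setMethod("sampleData", "AsvExperiment", function(x)
  SummarizedExperiment::colData(x))

setMethod("show", "AsvExperiment", function(object) {
  cat("AsvExperiment:", nrow(object), "taxa x", ncol(object), "samples\n")
  tot <- colSums(SummarizedExperiment::assay(object, "counts"))
  cat("  sample depth: min", min(tot), "/ median", stats::median(tot),
      "/ max", max(tot), "\n")
  if ("stage" %in% colnames(SummarizedExperiment::colData(object))) {
    tab <- table(SummarizedExperiment::colData(object)$stage)
    cat("  stages:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
  }
})

#' Rarefy an ASV table to even sequencing depth
#'
#' Randomly subsamples every sample to `depth` reads without replacement
#' (multivariate hypergeometric draw), the standard depth standardisation
#' for amplicon tables (e.g. 10,065 reads for 16S, 8,000 for ITS libraries).
#' Samples whose total falls below `depth` are dropped with a warning.
#'
#' @param x an [AsvExperiment-class].
#' @param depth positive integer target depth.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return an [AsvExperiment-class] in which every sample sums to `depth`.
#'   The taxon set is unchanged (taxa may drop to all-zero counts).
#' @examples
#' ae <- AsvExperiment(matrix(c(5, 5, 10, 0), 1, 4,
#'   dimnames = list("s1", paste0("t", 1:4))))
#' rowSums(asvCounts(rarefyAsv(ae, 10, seed = 1)))
#' @export
rarefyAsv <- function(x, depth, seed = 1L) {
  stopifnot(is(x, "AsvExperiment"))
  if (!is.numeric(depth) || length(depth) != 1L || depth <= 0)
    stop("depth must be a positive integer")
  depth <- as.integer(depth)
  m <- asvCounts(x, samplesAsRows = TRUE)
  tot <- rowSums(m)
  keep <- tot >= depth
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(rownames(m)[!keep], collapse = ", "))
    m <- m[keep, , drop = FALSE]
  }
  if (nrow(m) == 0L) stop("no sample reaches the requested depth")
  set.seed(seed)
  # vegan flags tables without singletons as "not observed counts" - a
  # heuristic that misfires on simulated data; real contract violations
  # (non-integer, negative) are caught by the AsvExperiment validity
  rar <- withCallingHandlers(
    vegan::rrarefy(m, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  AsvExperiment(rar,
                taxonomy = as.data.frame(taxonomyTable(x)),
                metadata = as.data.frame(sampleData(x))[rownames(m), ,
                                                        drop = FALSE],
                samplesAsRows = TRUE)
}
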