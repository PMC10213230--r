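#' Read an ASV table from TSV or BIOM-JSON
#'
#' TSV tables may have taxa as rows (the common QIIME-style export, with an
#' optional `taxonomy` column) or samples as rows. With
#' `orientation = "auto"` the orientation is inferred: a `taxonomy` column
#' implies taxa-as-rows, otherwise the larger dimension is taken to be the
#' taxa. BIOM tables are parsed with the biomformat package
#' (observations are taxa by the BIOM convention).
#'
#' @param path path to the table.
#' @param format `"tsv"` or `"biom-json"`.
#' @param orientation `"auto"`, `"samples"` (samples as rows) or `"taxa"`.
#' @param metadata optional per-sample data.frame passed to
#'   [AsvExperiment()].
#' @return an [AsvExperiment-class].
#' @export
readAsvTable <- function(path, format = c("tsv", "biom-json"),
                         orientation = c("auto", "samples", "taxa"),
                         metadata = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)

  if (format == "biom-json") {
    b <- biomformat::read_biom(path)
    counts <- as(biomformat::biom_data(b), "matrix")  # taxa x samples
    taxo <- tryCatch(biomformat::observation_metadata(b),
                     error = function(e) NULL)
    taxstr <- NULL
    if (!is.null(taxo)) {
      taxo <- as.data.frame(taxo)
      taxstr <- apply(taxo, 1, paste, collapse = ";")[rownames(counts)]
    }
    .validateCounts(counts, path)
    return(AsvExperiment(counts, taxonomy = taxstr, metadata = metadata,
                         samplesAsRows = FALSE))
  }

  raw <- tryCatch(
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("malformed TSV '", path, "': ",
                             conditionMessage(e)))
  if (ncol(raw) < 2L) stop("malformed TSV '", path, "': need id column ",
                           "plus at least one data column")
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate row ids in '", path, "' (first at line ",
         which(duplicated(ids))[1L] + 1L, ")")
  raw <- raw[, -1L, drop = FALSE]
  rownames(raw) <- ids

  taxCol <- which(tolower(names(raw)) == "taxonomy")
  taxonomy <- NULL
  if (length(taxCol)) {
    taxonomy <- as.character(raw[[taxCol[1L]]])
    raw <- raw[, -taxCol, drop = FALSE]
  }
  bad <- which(!vapply(raw, is.numeric, logical(1)))
  if (length(bad))
    stop("non-numeric counts in '", path, "', column '",
         names(raw)[bad[1L]], "'")
  counts <- as.matrix(raw)
  .validateCounts(counts, path)

  taxaAsRows <- switch(orientation,
    taxa = TRUE,
    samples = FALSE,
    auto = if (!is.null(taxonomy)) TRUE else nrow(counts) >= ncol(counts))
  if (!taxaAsRows && !is.null(taxonomy))
    stop("a taxonomy column implies taxa as rows")
  AsvExperiment(counts, taxonomy = taxonomy, metadata = metadata,
                samplesAsRows = !taxaAsRows)
}

.validateCounts <- function(counts, path) {
  if (any(counts < 0))
    stop("negative counts in '", path, "'")
  if (any(counts != round(counts)))
    stop("non-integer counts in '", path, "'")
  invisible(TRUE)
}

#' Write an ASV table to TSV or BIOM-JSON
#'
#' The TSV layout is taxa as rows, one column per sample, a leading
#' `taxon_id` column and a trailing `taxonomy` column; [readAsvTable()]
#' round-trips it exactly.
#'
#' @param x an [AsvExperiment-class].
#' @param path output path.
#' @param format `"tsv"` or `"biom-json"`.
#' @return `path`, invisibly.
#' @export
writeAsvTable <- function(x, path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  m <- asvCounts(x, samplesAsRows = FALSE)  # taxa x samples
  tax <- as.character(taxonomyTable(x)$taxonomy)
  if (format == "tsv") {
    df <- data.frame(taxon_id = rownames(m), m, taxonomy = tax,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    om <- data.frame(taxonomy = tax, row.names = rownames(m),
                     stringsAsFactors = FALSE)
    b <- biomformat::make_biom(data = m, observation_metadata = om)
    biomformat::write_biom(b, path)
  }
  invisible(path)
}

#' Read per-sample metadata keyed by sample id
#'
#' @param path TSV with a `sample_id` column (or sample ids as first
#'   column).
#' @return data.frame with sample ids as row names.
#' @export
readSampleMetadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  key <- if ("sample_id" %in% names(df)) "sample_id" else names(df)[1L]
  rownames(df) <- as.character(df[[key]])
  df[[key]] <- NULL
  df
}

#' Assemble a validated environmental matrix from sample metadata
#'
#' Selects numeric environmental variables (e.g. plant richness, SOC, TN,
#' NO3, NH4, TP, EC, pH, SM and the stoichiometric ratios C:N, C:P, N:P)
#' in the sample order of a paired ASV table and refuses missing values.
#'
#' @param metadata data.frame of per-sample variables, sample ids as row
#'   names.
#' @param variables character, columns to keep (default: all numeric).
#' @param samples character, sample order to enforce (default: metadata
#'   order).
#' @return numeric matrix samples x variables.
#' @export
envMatrix <- function(metadata, variables = NULL, samples = NULL) {
  metadata <- as.data.frame(metadata)
  if (!is.null(samples)) {
    miss <- setdiff(samples, rownames(metadata))
    if (length(miss)) stop("metadata missing samples: ",
                           paste(miss, collapse = ", "))
    metadata <- metadata[samples, , drop = FALSE]
  }
  if (is.null(variables))
    variables <- names(metadata)[vapply(metadata, is.numeric, logical(1))]
  if (!length(variables)) stop("no numeric environmental variables")
  m <- as.matrix(metadata[, variables, drop = FALSE])
  if (anyNA(m)) stop("environmental matrix contains missing values")
  storage.mode(m) <- "double"
  m
}

#' Export a co-occurrence network for external viewers
#'
#' Edge-list TSV (columns `source`, `target`, `correlation`, `sign`) or
#' GraphML carrying the same node and edge attributes, loadable by
#' Cytoscape, Gephi and igraph.
#'
#' @param net a [CoNetwork-class].
#' @param path output path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(net, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  stopifnot(is(net, "CoNetwork"))
  g <- networkGraph(net)
  if (igraph::vcount(g) == 0L || igraph::ecount(g) == 0L)
    stop("cannot export an empty network")
  if (format == "edgelist") {
    utils::write.table(edgeTable(net), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
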