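#' Within-module (Zi) and among-module (Pi) connectivity
#'
#' For node i in module s: `Zi = (k_is - mean(k_js)) / sd(k_js)` over the
#' nodes j of module s, where `k_is` counts i's links into its own module
#' (population sd, including i; `Zi = 0` when the sd is 0). `Pi = 1 -
#' sum_t (k_it / k_i)^2` over all modules t, the participation coefficient:
#' 0 when every link stays in one module, approaching 1 as links spread
#' evenly across modules.
#'
#' @param net a [CoNetwork-class].
#' @param modules a [ModulePartition-class] covering every node.
#' @return data.frame: node, module, degree, Zi, Pi (roles unset).
#' @export
ziPi <- function(net, modules) {
  g <- .nonempty(.netGraph(net))
  stopifnot(is(modules, "ModulePartition"))
  mem <- modules@membership
  nodes <- igraph::V(g)$name
  if (!all(nodes %in% names(mem)))
    stop("every node must be assigned to a module")
  mem <- mem[nodes]
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  modIds <- sort(unique(mem))
  # k_it: links of node i into module t
  kTo <- vapply(modIds, function(t) rowSums(A[, mem == t, drop = FALSE]),
                numeric(length(nodes)))
  k <- rowSums(kTo)
  own <- match(mem, modIds)
  kOwn <- kTo[cbind(seq_along(nodes), own)]
  zi <- numeric(length(nodes))
  for (t in seq_along(modIds)) {
    inMod <- own == t
    ks <- kOwn[inMod]
    mu <- mean(ks)
    sdev <- sqrt(mean((ks - mu)^2))  # population sd
    zi[inMod] <- if (sdev == 0) 0 else (ks - mu) / sdev
  }
  pi <- 1 - rowSums((kTo / k)^2)
  data.frame(node = nodes, module = unname(mem), degree = unname(k),
             Zi = zi, Pi = pi, stringsAsFactors = FALSE)
}

#' Classify topological roles from Zi and Pi
#'
#' Threshold rules: peripheral (`Zi <= zCut`, `Pi <= pCut`), connector
#' (`Zi <= zCut`, `Pi > pCut`), module hub (`Zi > zCut`, `Pi <= pCut`),
#' network hub (`Zi > zCut`, `Pi > pCut`), with the conventional cutoffs
#' 2.5 and 0.62. Boundary values belong to the "<=" branch, so a node at
#' exactly (2.5, 0.62) is peripheral. Non-peripheral nodes form the
#' putative keystone set.
#'
#' @param nodes data.frame from [ziPi()].
#' @param zCut,pCut role thresholds (defaults 2.5 and 0.62).
#' @return the data.frame with `role` and logical `keystone` columns
#'   added.
#' @export
classifyRoles <- function(nodes, zCut = 2.5, pCut = 0.62) {
  stopifnot(all(c("Zi", "Pi") %in% names(nodes)))
  hiZ <- nodes$Zi > zCut
  hiP <- nodes$Pi > pCut
  nodes$role <- ifelse(hiZ & hiP, "network hub",
                ifelse(hiZ, "module hub",
                ifelse(hiP, "connector", "peripheral")))
  nodes$keystone <- nodes$role != "peripheral"
  nodes
}

#' Keystone report table
#'
#' All non-peripheral nodes (connectors, module hubs, network hubs) with
#' their Zi/Pi values and taxonomy, sorted by role (network hubs, module
#' hubs, connectors) and then by Zi descending.
#'
#' @param roles data.frame from [classifyRoles()].
#' @param taxonomy optional taxonomy table (as from [taxonomyTable()]) or
#'   named character vector of lineage strings, indexed by node id.
#' @return data.frame: node, module, degree, Zi, Pi, role, phylum,
#'   lowest_rank.
#' @export
keystoneTable <- function(roles, taxonomy = NULL) {
  stopifnot(all(c("role", "Zi", "Pi", "node") %in% names(roles)))
  ks <- roles[roles$role != "peripheral", , drop = FALSE]
  phylum <- rep("", nrow(ks))
  lowest <- rep("", nrow(ks))
  if (!is.null(taxonomy) && nrow(ks)) {
    if (is.character(taxonomy)) {
      lin <- taxonomy[ks$node]
    } else {
      tt <- as.data.frame(taxonomy)
      lin <- stats::setNames(as.character(tt$taxonomy),
                             rownames(tt))[ks$node]
    }
    lin[is.na(lin)] <- ""
    parts <- strsplit(lin, ";", fixed = TRUE)
    phylum <- vapply(parts, function(p)
      if (length(p) >= 2L) trimws(p[2L]) else "", character(1))
    lowest <- vapply(parts, function(p) {
      p <- trimws(p); p <- p[nzchar(p)]
      if (length(p)) p[length(p)] else ""
    }, character(1))
  }
  ks$phylum <- phylum
  ks$lowest_rank <- lowest
  ord <- order(factor(ks$role,
                      levels = c("network hub", "module hub", "connector")),
               -ks$Zi)
  ks <- ks[ord, , drop = FALSE]
  rownames(ks) <- NULL
  ks
}
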