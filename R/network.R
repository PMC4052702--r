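#' Build the interaction network induced by selected genes
#'
#' Keeps an interaction edge only when both endpoints are selected genes
#' (induced subgraph); selected genes without any kept interaction remain
#' as degree-0 nodes. Edges are canonicalized (sorted endpoints), and
#' self-loops and duplicates removed, before induction.
#'
#' @param selected character vector of selected gene ids, or a significance
#'   table (see [selectDE()]) from which genes with `selected == TRUE` are
#'   taken
#' @param edges data.frame of undirected interaction pairs with columns
#'   `gene_a`, `gene_b` (see [readEdgeList()])
#' @param direction named character vector ("up"/"down") per selected gene;
#'   taken from the significance table when one is supplied
#' @param hubThreshold exclusive degree threshold for hub calls (default
#'   10: a hub has degree strictly greater than 10)
#' @return an [InteractionNetwork-class]
#' @export
buildNetwork <- function(selected, edges, direction = NULL, hubThreshold = 10) {
  if (is(selected, "DataFrame") || is.data.frame(selected)) {
    tab <- selected[selected$selected, , drop = FALSE]
    genes <- unique(tab$gene_id[!is.na(tab$gene_id)])
    if (is.null(direction)) {
      direction <- tab$direction[!is.na(tab$gene_id)]
      names(direction) <- tab$gene_id[!is.na(tab$gene_id)]
      direction <- direction[!duplicated(names(direction))]
    }
  } else genes <- unique(as.character(selected))
  if (is.null(direction)) {
    direction <- rep("down", length(genes))
    names(direction) <- genes
  }
  if (!all(genes %in% names(direction)))
    stop("direction missing for some selected genes")
  edges <- cleanEdgeList(edges)
  keep <- edges$gene_a %in% genes & edges$gene_b %in% genes
  edges <- edges[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = genes))
  new("InteractionNetwork", graph = g,
      direction = direction[genes], hubThreshold = as.integer(hubThreshold))
}

#' @describeIn nodeDegrees Distinct-neighbor count per node of the induced
#'   interaction graph.
#' @export
setMethod("nodeDegrees", "InteractionNetwork", function(object) {
  d <- igraph::degree(object@graph, loops = FALSE)
  storage.mode(d) <- "integer"
  d
})

#' @rdname hubGenes
#' @export
setMethod("hubGenes", "InteractionNetwork", function(object, minExclusive = NULL) {
  if (is.null(minExclusive)) minExclusive <- object@hubThreshold
  d <- nodeDegrees(object)
  hubs <- d[d > minExclusive]
  names(sort(hubs, decreasing = TRUE))
})

setMethod("show", "InteractionNetwork", function(object) {
  d <- nodeDegrees(object)
  cat("InteractionNetwork (induced subgraph of selected genes)\n")
  cat("  nodes:", length(d), " edges:", igraph::ecount(object@graph), "\n")
  hubs <- hubGenes(object)
  cat("  hubs (degree >", object@hubThreshold, "):",
      if (length(hubs)) paste(hubs, collapse = ", ") else "none", "\n")
})

#' Export a network in Cytoscape-loadable plain text
#'
#' Writes a SIF edge file (`geneA pp geneB` lines; isolated nodes written
#' as bare single-node lines) and a node-attribute TSV with columns
#' `gene_id`, `degree`, `direction`, `hub`. Size-by-degree and
#' color-by-direction are attribute columns for the viewer, not rendered
#' here.
#'
#' @param network an [InteractionNetwork-class]
#' @param sifPath output path for the SIF edge file
#' @param nodePath output path for the node-attribute TSV
#' @return invisible list with the two paths
#' @export
exportNetwork <- function(network, sifPath, nodePath) {
  stopifnot(is(network, "InteractionNetwork"))
  el <- igraph::as_edgelist(network@graph)
  d <- nodeDegrees(network)
  lines <- character(0)
  if (nrow(el)) lines <- paste(el[, 1], "pp", el[, 2])
  isolated <- names(d)[d == 0L]
  lines <- c(lines, isolated)
  ok <- tryCatch({ writeLines(lines, sifPath); TRUE },
                 error = function(e) stop("cannot write SIF file: ", conditionMessage(e)))
  hubs <- hubGenes(network)
  nodeTab <- data.frame(
    gene_id = names(d),
    degree = unname(d),
    direction = unname(network@direction[names(d)]),
    hub = names(d) %in% hubs,
    stringsAsFactors = FALSE
  )
  write.table(nodeTab, nodePath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(sif = sifPath, nodes = nodePath))
}
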